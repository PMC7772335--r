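harmonic <- function(n) sum(1 / seq_len(n))

sfs_vector <- function(sfs) {
  if (inherits(sfs, "sfs_1d")) {
    list(xi = unclass(sfs)[2:attr(sfs, "n")], n = attr(sfs, "n"))
  } else if (is.numeric(sfs)) {
    list(xi = as.double(sfs), n = length(sfs) + 1L)
  } else abort("expected an sfs_1d or a numeric vector of classes 1..n-1")
}

#' Watterson's theta per site
#'
#' `theta_w = S / (a1 * L)` with `a1 = sum(1/i, i = 1..n-1)`.
#'
#' @param S Number of segregating sites.
#' @param n Haploid sample size (>= 2).
#' @param L Sequence length in bp (> 0); `L = 1` gives the per-locus value.
#' @return Per-site Watterson estimate.
#' @examples
#' watterson_theta(S = 16, n = 14, L = 1000)
#' @export
watterson_theta <- function(S, n, L = 1) {
  if (n < 2) abort("n must be >= 2")
  if (L <= 0) abort("L must be > 0")
  S / (harmonic(n - 1) * L)
}

#' Nucleotide diversity per site
#'
#' `pi = sum(i * (n - i) * xi_i) / choose(n, 2) / L`, the average number of
#' pairwise differences per site.
#'
#' @param sfs An unfolded [sfs_1d()] (or numeric vector of counts for
#'   classes `1..n-1`).
#' @param n Haploid sample size (inferred from an `sfs_1d`).
#' @param L Sequence length in bp.
#' @return Per-site nucleotide diversity.
#' @export
nucleotide_diversity <- function(sfs, n = NULL, L = 1) {
  v <- sfs_vector(sfs)
  if (is.null(n)) n <- v$n
  if (n < 2) abort("n must be >= 2")
  if (L <= 0) abort("L must be > 0")
  i <- seq_len(n - 1)
  sum(i * (n - i) * v$xi) / choose(n, 2) / L
}

tajima_constants <- function(n) {
  a1 <- harmonic(n - 1)
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' Normalized difference between mean pairwise diversity and Watterson's
#' theta; negative values indicate an excess of rare variants.
#'
#' @inheritParams nucleotide_diversity
#' @return Tajima's D. Errors when there are no segregating sites (D is
#'   undefined).
#' @export
tajimas_d <- function(sfs, n = NULL) {
  v <- sfs_vector(sfs)
  if (is.null(n)) n <- v$n
  S <- sum(v$xi)
  if (S < 1) abort("Tajima's D undefined: no segregating sites")
  k <- tajima_constants(n)
  pi_tot <- nucleotide_diversity(v$xi, n = n, L = 1)
  D_num <- pi_tot - S / k$a1
  D_den <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
  D_num / D_den
}

#' Hudson's Fst (ratio of averages)
#'
#' Computes Hudson's estimator of between-population differentiation as a
#' ratio of averages over sites: the numerator per site is
#' `(p1 - p2)^2 - p1 (1 - p1) / (n1 - 1) - p2 (1 - p2) / (n2 - 1)` and the
#' denominator `p1 (1 - p2) + p2 (1 - p1)`, summed over sites before taking
#' the ratio.
#'
#' @param x A `hap_dataset` (two populations) or a [joint_sfs()].
#' @param ... Passed to methods.
#' @return Single Fst value.
#' @export
hudson_fst <- function(x, ...) UseMethod("hudson_fst")

hudson_terms <- function(i, j, n1, n2, w = 1) {
  p1 <- i / n1; p2 <- j / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  if (sum(w * den) <= 0) abort("no usable sites for Fst")
  sum(w * num) / sum(w * den)
}

#' @rdname hudson_fst
#' @export
hudson_fst.hap_dataset <- function(x, pops = NULL, ...) {
  if (is.null(pops)) pops <- sort(unique(x$samples$pop))
  n1 <- sum(x$samples$pop == pops[1])
  n2 <- sum(x$samples$pop == pops[2])
  if (n1 < 2 || n2 < 2) abort("Hudson's Fst needs >= 2 samples per population")
  dc <- derived_counts(x, pops)
  if (nrow(dc) == 0) abort("no usable sites for Fst")
  hudson_terms(dc$i, dc$j, n1, n2)
}

#' @rdname hudson_fst
#' @export
hudson_fst.joint_sfs <- function(x, ...) {
  n1 <- attr(x, "n1"); n2 <- attr(x, "n2")
  if (n1 < 2 || n2 < 2) abort("Hudson's Fst needs >= 2 samples per population")
  td <- tidy(x)
  td <- td[!td$masked & td$count > 0, ]
  if (nrow(td) == 0) abort("no usable sites for Fst")
  hudson_terms(td$i, td$j, n1, n2, w = td$count)
}

#' Pearson chi-squared comparison of two frequency spectra
#'
#' Tests homogeneity of the shapes of two 1D SFS via a Pearson chi-squared
#' test on the `2 x (n - 1)` contingency table of frequency-class counts.
#' Classes are pooled from the high-frequency end until every expected cell
#' count is at least `pool_min`, since high-frequency classes are sparse.
#'
#' @param sfs_a,sfs_b Two [sfs_1d()] objects (or count vectors for classes
#'   `1..n-1`) with the same class structure.
#' @param pool_min Minimum expected cell count before pooling stops.
#' @return An object of class `htest` with `statistic`, `parameter` (df)
#'   and `p.value`; the pooled table is attached as `observed`.
#' @export
sfs_chisq_test <- function(sfs_a, sfs_b, pool_min = 5) {
  a <- sfs_vector(sfs_a); b <- sfs_vector(sfs_b)
  if (a$n != b$n) abort("spectra have different class structure")
  tab <- rbind(a = a$xi, b = b$xi)
  drop0 <- colSums(tab) > 0
  tab <- tab[, drop0, drop = FALSE]
  expected <- function(tb) outer(rowSums(tb), colSums(tb)) / sum(tb)
  while (ncol(tab) > 1 && any(expected(tab) < pool_min)) {
    k <- ncol(tab)
    tab[, k - 1] <- tab[, k - 1] + tab[, k]
    tab <- tab[, -k, drop = FALSE]
  }
  if (ncol(tab) < 2 || any(rowSums(tab) == 0))
    abort("degenerate table after pooling; chi-squared test not applicable")
  E <- expected(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  p <- pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = c("X-squared" = stat),
                 parameter = c(df = df), p.value = p,
                 method = "Pearson's chi-squared test on pooled SFS classes",
                 data.name = "sfs_a vs sfs_b", observed = tab),
            class = "htest")
}

#' Principal component analysis of haploid genotypes
#'
#' Singular-value decomposition of the site-centered genotype matrix
#' (samples x sites). Deterministic up to the sign of each component.
#'
#' @param ds A `hap_dataset`.
#' @param n_components Number of components to return.
#' @param scale If `TRUE`, scale each site by `sqrt(p * (1 - p))`.
#' @return List with `scores` (tibble: `sample`, `pop`, `PC1..PCk`) and
#'   `explained_variance` (proportion per component).
#' @export
pca_genotypes <- function(ds, n_components = 2, scale = FALSE) {
  if (n_samples(ds) < 2 || n_sites(ds) < 1)
    abort("PCA needs >= 2 samples and >= 1 site")
  X <- t(ds$geno) * 1.0   # samples x sites
  p <- colMeans(X)
  X <- sweep(X, 2, p)
  if (scale) {
    s <- sqrt(pmax(p * (1 - p), .Machine$double.eps))
    X <- sweep(X, 2, s, "/")
  }
  k_max <- min(dim(X)) - 1L
  if (n_components > k_max) {
    warn(paste0("only ", k_max, " components available; truncating"))
    n_components <- k_max
  }
  sv <- svd(X)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  ev <- sv$d^2 / sum(sv$d^2)
  sc <- as_tibble(scores[, seq_len(n_components), drop = FALSE],
                  .name_repair = ~ paste0("PC", seq_len(n_components)))
  list(scores = dplyr::bind_cols(tibble(sample = ds$samples$id,
                                        pop = ds$samples$pop), sc),
       explained_variance = ev[seq_len(n_components)])
}

#' Per-population summary statistics table
#'
#' Convenience wrapper computing segregating sites, Watterson's theta,
#' nucleotide diversity and Tajima's D for each population, plus Hudson's
#' Fst between them.
#'
#' @param ds A `hap_dataset` with two populations.
#' @param L Sequence length for per-site scaling.
#' @return Tibble with one row per population and an `fst` attribute.
#' @export
summary_stats <- function(ds, L = 1) {
  pops <- sort(unique(ds$samples$pop))
  jsfs <- build_joint_sfs(ds)
  rows <- lapply(seq_along(pops), function(k) {
    sfs <- marginal_sfs(jsfs, pop = k)
    v <- sfs_vector(sfs)
    S <- sum(v$xi)
    tibble(pop = pops[k], n = v$n, S = S,
           theta_w = watterson_theta(S, v$n, L),
           pi = nucleotide_diversity(sfs, L = L),
           tajimas_d = if (S >= 1) tajimas_d(sfs) else NA_real_)
  })
  out <- bind_rows(rows)
  attr(out, "fst") <- hudson_fst(ds)
  out
}
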