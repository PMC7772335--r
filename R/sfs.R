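#' Haploid genotype dataset
#'
#' Container for haploid 0/1 genotypes at biallelic sites with per-site
#' coordinates (0-based) and per-sample population labels. Constructed by
#' [simulate_dataset()] or [read_haploid_vcf()]; most users never call this
#' directly.
#'
#' @param geno Integer matrix, sites x samples, values 0 (ancestral) / 1
#'   (derived).
#' @param sites Tibble with at least `contig` and `pos` (0-based), positions
#'   strictly increasing within contig; optional `rec_rate`, `rec_class`.
#' @param samples Tibble with `id` and `pop` (two populations expected for
#'   joint analyses).
#' @param polarized Logical: are alleles polarized ancestral/derived?
#' @param provenance List of free-form provenance fields (seeds, source
#'   files, drop counts).
#' @return Object of class `hap_dataset`.
#' @export
hap_dataset <- function(geno, sites, samples, polarized = TRUE,
                        provenance = list()) {
  if (nrow(sites) != nrow(geno)) abort("sites and geno row counts differ")
  if (nrow(samples) != ncol(geno)) abort("samples and geno column counts differ")
  if (!all(geno %in% c(0L, 1L))) abort("genotypes must be 0/1")
  ord <- order(sites$contig, sites$pos)
  geno <- geno[ord, , drop = FALSE]
  sites <- sites[ord, , drop = FALSE]
  dup <- duplicated(sites[c("contig", "pos")])
  if (any(dup)) abort("duplicated site coordinates")
  structure(list(geno = geno, sites = as_tibble(sites),
                 samples = as_tibble(samples),
                 polarized = isTRUE(polarized), provenance = provenance),
            class = "hap_dataset")
}

#' @export
print.hap_dataset <- function(x, ...) {
  tabpop <- table(x$samples$pop)
  cat("<hap_dataset> ", nrow(x$sites), " sites, ",
      nrow(x$samples), " samples (",
      paste(names(tabpop), tabpop, sep = ":", collapse = ", "), "), ",
      if (x$polarized) "polarized" else "unpolarized", "\n", sep = "")
  invisible(x)
}

#' Number of sites / samples in a dataset
#' @param ds A `hap_dataset`.
#' @return Integer count.
#' @export
n_sites <- function(ds) nrow(ds$sites)

#' @rdname n_sites
#' @export
n_samples <- function(ds) nrow(ds$samples)

#' Per-site derived-allele counts by population
#'
#' @param ds A `hap_dataset` with exactly two population labels (taken in
#'   sorted label order unless `pops` is given).
#' @param pops Optional character vector of length 2 fixing which label is
#'   population 1 and 2.
#' @return Tibble with columns `contig`, `pos`, `i`, `j` (derived counts in
#'   pop 1 and 2) plus any site annotation columns.
#' @export
derived_counts <- function(ds, pops = NULL) {
  if (is.null(pops)) pops <- sort(unique(ds$samples$pop))
  if (length(pops) != 2) abort("expected exactly two populations")
  g1 <- ds$geno[, ds$samples$pop == pops[1], drop = FALSE]
  g2 <- ds$geno[, ds$samples$pop == pops[2], drop = FALSE]
  dplyr::bind_cols(ds$sites,
                   tibble(i = as.integer(rowSums(g1)),
                          j = as.integer(rowSums(g2))))
}

#' Joint site frequency spectrum
#'
#' An `(n1 + 1) x (n2 + 1)` matrix of site counts indexed by derived-allele
#' count in each population, with the monomorphic corners `(0, 0)` and
#' `(n1, n2)` masked.
#'
#' @param counts Nonnegative matrix of dimensions `(n1 + 1) x (n2 + 1)`.
#' @param folded Logical folded flag.
#' @param mask Optional logical matrix of masked entries; the corners are
#'   always masked in addition.
#' @return Object of class `joint_sfs` (a matrix with attributes).
#' @export
joint_sfs <- function(counts, folded = FALSE, mask = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("SFS counts must be nonnegative")
  n1 <- nrow(counts) - 1L
  n2 <- ncol(counts) - 1L
  if (is.null(mask)) mask <- matrix(FALSE, n1 + 1L, n2 + 1L)
  mask[1, 1] <- TRUE
  mask[n1 + 1L, n2 + 1L] <- TRUE
  counts[mask] <- 0
  structure(counts, n1 = n1, n2 = n2, mask = mask, folded = isTRUE(folded),
            class = c("joint_sfs", "matrix"))
}

#' @export
print.joint_sfs <- function(x, ...) {
  cat("<joint_sfs> ", attr(x, "n1"), " x ", attr(x, "n2"), " samples, ",
      sum(unclass(x)), " sites",
      if (attr(x, "folded")) " (folded)", "\n", sep = "")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Build the observed joint SFS from a dataset
#'
#' Each biallelic site with derived counts `(i, j)` increments one entry;
#' sites monomorphic across both populations (the masked corners) are
#' excluded.
#'
#' @inheritParams derived_counts
#' @param n1,n2 Haploid sample sizes; default taken from the population
#'   labels.
#' @return A [joint_sfs()] whose total equals the number of contributing
#'   polymorphic sites.
#' @export
build_joint_sfs <- function(ds, n1 = NULL, n2 = NULL, pops = NULL) {
  if (is.null(pops)) pops <- sort(unique(ds$samples$pop))
  if (is.null(n1)) n1 <- sum(ds$samples$pop == pops[1])
  if (is.null(n2)) n2 <- sum(ds$samples$pop == pops[2])
  dc <- derived_counts(ds, pops)
  if (any(dc$i > n1) || any(dc$j > n2))
    abort("derived count exceeds sample size")
  counts <- matrix(0, n1 + 1L, n2 + 1L)
  if (nrow(dc) > 0) {
    tab <- table(factor(dc$i, levels = 0:n1), factor(dc$j, levels = 0:n2))
    counts <- matrix(as.double(tab), n1 + 1L, n2 + 1L)
  }
  joint_sfs(counts)
}

#' One-dimensional site frequency spectrum
#'
#' Represented as a numeric vector of length `n + 1` indexed by derived
#' count `0..n`, with the monomorphic entries (0 and `n`; and entries above
#' `n/2` when folded) held at zero. `sfs_1d()` wraps a vector of counts for
#' derived classes `1..n-1`.
#'
#' @param xi Numeric vector of counts for frequency classes `1..n-1`.
#' @param n Haploid sample size.
#' @param folded Logical folded flag.
#' @return Object of class `sfs_1d`.
#' @export
sfs_1d <- function(xi, n = length(xi) + 1L, folded = FALSE) {
  if (length(xi) != n - 1L) abort("xi must have length n - 1")
  structure(c(0, as.double(xi), 0), n = as.integer(n), folded = isTRUE(folded),
            class = "sfs_1d")
}

#' @export
print.sfs_1d <- function(x, ...) {
  cat("<sfs_1d> n = ", attr(x, "n"), ", ", sum(unclass(x)), " sites",
      if (attr(x, "folded")) " (folded)", "\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' Marginal 1D SFS of a joint SFS
#'
#' Sums over the other population's index. Sites that are monomorphic in
#' the focal population (marginal count 0 or n) are excluded, matching the
#' 1D SFS one would build from the focal population alone.
#'
#' @param jsfs A [joint_sfs()].
#' @param pop 1 or 2.
#' @return An [sfs_1d()].
#' @export
marginal_sfs <- function(jsfs, pop = 1) {
  stopifnot(inherits(jsfs, "joint_sfs"))
  m <- unclass(jsfs)
  v <- if (pop == 1) rowSums(m) else colSums(m)
  n <- length(v) - 1L
  sfs_1d(v[2:n], n = n, folded = attr(jsfs, "folded"))
}

#' Fold a site frequency spectrum
#'
#' Maps derived count `i` to minor count `min(i, n - i)` and sums; folding
#' an already folded spectrum is the identity. For a joint SFS, entries
#' `(i, j)` with `i + j` above `(n1 + n2) / 2` are folded onto
#' `(n1 - i, n2 - j)` (minor-allele convention across the pooled sample).
#'
#' @param sfs An [sfs_1d()] or [joint_sfs()].
#' @return Folded object of the same class.
#' @export
fold_sfs <- function(sfs) {
  if (inherits(sfs, "sfs_1d")) {
    if (attr(sfs, "folded")) return(sfs)
    n <- attr(sfs, "n")
    x <- unclass(sfs)
    out <- numeric(n + 1L)
    for (i in 1:(n - 1L)) {
      k <- min(i, n - i)
      out[k + 1L] <- out[k + 1L] + x[i + 1L]
    }
    sfs_1d(out[2:n], n = n, folded = TRUE)
  } else if (inherits(sfs, "joint_sfs")) {
    if (attr(sfs, "folded")) return(sfs)
    n1 <- attr(sfs, "n1"); n2 <- attr(sfs, "n2")
    x <- unclass(sfs)
    res <- matrix(0, n1 + 1L, n2 + 1L)
    mask <- matrix(FALSE, n1 + 1L, n2 + 1L)
    half <- (n1 + n2) / 2
    for (i in 0:n1) for (j in 0:n2) {
      tot <- i + j
      if (tot > half || (tot == half && i > n1 - i)) {
        mask[i + 1L, j + 1L] <- TRUE
        res[n1 - i + 1L, n2 - j + 1L] <-
          res[n1 - i + 1L, n2 - j + 1L] + x[i + 1L, j + 1L]
      } else {
        res[i + 1L, j + 1L] <- res[i + 1L, j + 1L] + x[i + 1L, j + 1L]
      }
    }
    joint_sfs(res, folded = TRUE, mask = mask)
  } else {
    abort("fold_sfs expects an sfs_1d or joint_sfs")
  }
}

#' Tidy a joint SFS into long format
#'
#' @param x A [joint_sfs()].
#' @param ... Unused.
#' @return Tibble with columns `i`, `j`, `count`, `masked`.
#' @method tidy joint_sfs
#' @export
tidy.joint_sfs <- function(x, ...) {
  n1 <- attr(x, "n1"); n2 <- attr(x, "n2")
  tibble(i = rep(0:n1, times = n2 + 1L),
         j = rep(0:n2, each = n1 + 1L),
         count = as.vector(unclass(x)),
         masked = as.vector(attr(x, "mask")))
}

#' Read / write SFS text files (dadi dialect)
#'
#' Format: a header line `d1 [d2] folded|unfolded` giving the array
#' dimensions (`n + 1` per population), a line of whitespace-separated
#' counts in row-major order, and a mask line of 0/1 of the same length
#' (1 = masked).
#'
#' @param path File path.
#' @param sfs A [joint_sfs()] or [sfs_1d()].
#' @return `read_sfs()` returns a [joint_sfs()] (or [sfs_1d()] for
#'   one-dimensional files); `write_sfs()` returns `path` invisibly.
#' @export
read_sfs <- function(path) {
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  hdr <- strsplit(ln[1], "\\s+")[[1]]
  folded <- any(hdr == "folded")
  dims <- as.integer(hdr[!hdr %in% c("folded", "unfolded")])
  vals <- as.double(strsplit(paste(ln[-1][seq_len(length(ln) - 2)], collapse = " "),
                             "\\s+")[[1]])
  maskv <- as.integer(strsplit(ln[length(ln)], "\\s+")[[1]])
  if (length(vals) != prod(dims) || length(maskv) != prod(dims))
    abort("SFS file dimensions do not match header or mask line")
  if (length(dims) == 1) {
    m <- vals
    msk <- maskv == 1L
    m[msk] <- 0
    sfs_1d(m[2:(dims - 1L)], n = dims - 1L, folded = folded)
  } else {
    m <- matrix(vals, nrow = dims[1], ncol = dims[2], byrow = TRUE)
    msk <- matrix(maskv == 1L, nrow = dims[1], ncol = dims[2], byrow = TRUE)
    joint_sfs(m, folded = folded, mask = msk)
  }
}

#' @rdname read_sfs
#' @export
write_sfs <- function(sfs, path) {
  fold_tag <- if (isTRUE(attr(sfs, "folded"))) "folded" else "unfolded"
  if (inherits(sfs, "joint_sfs")) {
    m <- unclass(sfs)
    msk <- attr(sfs, "mask")
    hdr <- paste(nrow(m), ncol(m), fold_tag)
    vals <- as.vector(t(m))
    maskv <- as.integer(as.vector(t(msk)))
  } else if (inherits(sfs, "sfs_1d")) {
    n <- attr(sfs, "n")
    vals <- unclass(sfs)
    maskv <- integer(n + 1L)
    maskv[c(1L, n + 1L)] <- 1L
    if (isTRUE(attr(sfs, "folded"))) maskv[(floor(n / 2) + 2L):(n + 1L)] <- 1L
    hdr <- paste(n + 1L, fold_tag)
  } else abort("write_sfs expects a joint_sfs or sfs_1d")
  writeLines(c(hdr,
               paste(formatC(vals, digits = 12, format = "g"), collapse = " "),
               paste(maskv, collapse = " ")), path)
  invisible(path)
}
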