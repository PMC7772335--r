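#' Simulate structured-coalescent genealogies
#'
#' Draws independent genealogies for `n1 + n2` haploid samples under a
#' demographic scenario, backwards in time, with competing exponential
#' events (within-population coalescence at rate `choose(k, 2) / nu(t)`,
#' per-lineage migration at the scaled backward rates). Waiting times during
#' the derived population's exponential-recovery epoch are drawn by analytic
#' inversion of the cumulative coalescence intensity.
#'
#' @inheritParams size_trajectory
#' @param n1,n2 Haploid sample sizes in the ancestral-range and derived
#'   populations. `n2 = 0` gives a single-population simulation.
#' @param n_reps Number of independent genealogies.
#' @param seed Optional integer seed (applied with [set.seed()]); required
#'   for reproducibility, otherwise the current RNG state is used.
#' @return List of `coal_tree` objects. Each is a list with `parent`
#'   (1-based parent index, `NA` at the root), `time` (node times in scaled
#'   units, leaves at 0), `n1`, `n2`. Leaves `1..n1` belong to population 1,
#'   `n1+1 .. n1+n2` to population 2; internal nodes are numbered in
#'   coalescence-time order.
#' @examples
#' spec <- model_spec("NOMIG")
#' p <- scaled_params(nu_af = 1, nu_bot = 1, nu_eu = 1,
#'                    T_exp = 100, T_split = 1)
#' trees <- simulate_genealogies(spec, p, n1 = 4, n2 = 4, n_reps = 3, seed = 1)
#' @export
simulate_genealogies <- function(spec, params, n1, n2 = 0, n_reps = 1,
                                 seed = NULL) {
  stop_if_invalid(spec, params)
  if (n1 + n2 < 2) abort("need at least two samples in total")
  if (!is.null(seed)) set.seed(seed)
  raw <- cpp_sim_trees(n1, n2, sim_par_vec(spec, params), n_reps)
  lapply(raw, function(tr) {
    par <- tr$parent + 1L
    par[par == 0L] <- NA_integer_
    structure(list(parent = par, time = tr$time, n1 = n1, n2 = n2),
              class = "coal_tree")
  })
}

#' @export
print.coal_tree <- function(x, ...) {
  n <- x$n1 + x$n2
  cat("<coal_tree> ", n, " leaves (", x$n1, " + ", x$n2,
      "), TMRCA = ", signif(max(x$time), 4), " (scaled)\n", sep = "")
  invisible(x)
}

# Per-node descendant-leaf counts in each population.
tree_leaf_counts <- function(tree) {
  n <- tree$n1 + tree$n2
  m <- 2L * n - 1L
  c1 <- c(rep(1L, tree$n1), rep(0L, m - tree$n1))
  c2 <- c(rep(0L, tree$n1), rep(1L, tree$n2), rep(0L, m - n))
  for (v in seq_len(m - 1L)) {  # children precede parents by construction
    p <- tree$parent[v]
    c1[p] <- c1[p] + c1[v]
    c2[p] <- c2[p] + c2[v]
  }
  list(c1 = c1, c2 = c2)
}

#' Branch lengths by descendant-leaf category
#'
#' Sums branch lengths over the genealogy by the number of population-1 and
#' population-2 leaves each branch subtends. A mutation on a branch in
#' category `(i, j)` yields a site with derived-allele counts `(i, j)`, so
#' these totals are the genealogy's contribution to the expected joint SFS.
#'
#' @param tree A `coal_tree`.
#' @return `(n1 + 1) x (n2 + 1)` matrix of summed branch lengths; the
#'   monomorphic corners `(0, 0)` and `(n1, n2)` are structurally zero.
#' @export
branch_category_lengths <- function(tree) {
  stopifnot(inherits(tree, "coal_tree"))
  cc <- tree_leaf_counts(tree)
  m <- length(tree$parent)
  out <- matrix(0, tree$n1 + 1L, tree$n2 + 1L)
  for (v in seq_len(m)) {
    p <- tree$parent[v]
    if (is.na(p)) next
    len <- tree$time[p] - tree$time[v]
    out[cc$c1[v] + 1L, cc$c2[v] + 1L] <- out[cc$c1[v] + 1L, cc$c2[v] + 1L] + len
  }
  out
}

#' Total branch length of a genealogy
#' @param tree A `coal_tree`.
#' @return Sum of all branch lengths in scaled time units.
#' @export
total_branch_length <- function(tree) {
  p <- tree$parent
  ok <- !is.na(p)
  sum(tree$time[p[ok]] - tree$time[ok])
}

#' Drop infinite-sites mutations on a genealogy
#'
#' Each branch of length `l` receives `Poisson(theta_locus * l / 2)`
#' mutations (so a sample of two has expected pairwise diversity
#' `theta_locus`); external branches can receive an inflated rate to mimic
#' the rare-allele excess that linked negative selection produces in
#' low-recombination regions.
#'
#' @param tree A `coal_tree`.
#' @param theta_locus Per-locus scaled mutation parameter (>= 0).
#' @param inflation_f Multiplier (>= 1) on the mutation rate of external
#'   branches.
#' @return Tibble with one row per segregating site: columns `i`, `j`
#'   (derived counts in each population) and `branch` (the mutated node's
#'   index).
#' @export
drop_mutations <- function(tree, theta_locus, inflation_f = 1) {
  stopifnot(inherits(tree, "coal_tree"))
  if (theta_locus < 0) abort("theta_locus must be >= 0")
  if (inflation_f < 1) abort("inflation_f must be >= 1")
  if (theta_locus == 0)
    return(tibble(i = integer(), j = integer(), branch = integer()))
  cc <- tree_leaf_counts(tree)
  m <- length(tree$parent)
  v <- which(!is.na(tree$parent))
  len <- tree$time[tree$parent[v]] - tree$time[v]
  ext <- (cc$c1[v] + cc$c2[v]) == 1L
  lam <- theta_locus * len / 2 * ifelse(ext, inflation_f, 1)
  nmut <- rpois(length(v), lam)
  idx <- rep.int(v, nmut)
  tibble(i = cc$c1[idx], j = cc$c2[idx], branch = idx)
}

# Leaf membership (logical leaves x nodes) used to turn mutations into
# genotype columns.
tree_leaf_membership <- function(tree) {
  n <- tree$n1 + tree$n2
  m <- 2L * n - 1L
  mem <- matrix(FALSE, n, m)
  mem[cbind(seq_len(n), seq_len(n))] <- TRUE
  for (v in seq_len(m - 1L)) {
    p <- tree$parent[v]
    mem[, p] <- mem[, p] | mem[, v]
  }
  mem
}

#' Newick serialization of a genealogy
#'
#' @param tree A `coal_tree`.
#' @param digits Significant digits for branch lengths.
#' @return Single newick string with branch lengths in scaled time; leaves
#'   are labelled `p1_1..p1_n1`, `p2_1..p2_n2`.
#' @export
to_newick <- function(tree, digits = 10) {
  n <- tree$n1 + tree$n2
  m <- 2L * n - 1L
  kids <- vector("list", m)
  for (v in seq_len(m - 1L)) {
    p <- tree$parent[v]
    kids[[p]] <- c(kids[[p]], v)
  }
  labs <- c(paste0("p1_", seq_len(tree$n1)),
            if (tree$n2 > 0) paste0("p2_", seq_len(tree$n2)))
  bl <- function(v, p) formatC(tree$time[p] - tree$time[v],
                               digits = digits, format = "g")
  render <- function(v) {
    if (v <= n) labs[v]
    else paste0("(", paste(vapply(kids[[v]], function(ch)
      paste0(render(ch), ":", bl(ch, v)), ""), collapse = ","), ")")
  }
  paste0(render(m), ";")
}

#' Synthetic-dataset configuration
#'
#' Defines the synthetic study design the generator emulates: two
#' populations of haploid genomes (default 14 + 14), independent
#' non-recombining intronic loci assigned to three recombination-rate
#' classes, and an optional singleton excess in the low-recombination class
#' standing in for linked negative selection.
#'
#' @inheritParams size_trajectory
#' @param n1,n2 Haploid sample sizes (defaults 14 and 14).
#' @param n_loci Number of independent loci.
#' @param theta_locus Per-locus scaled mutation parameter.
#' @param recomb_class_fractions Proportions of loci in the three
#'   recombination classes `[0,1.5)`, `[1.5,3)`, `[3,14.5]` cM/Mb; must sum
#'   to 1.
#' @param singleton_inflation_f External-branch mutation-rate multiplier
#'   (>= 1) applied in the lowest recombination class only.
#' @param seed Integer seed recorded in provenance and applied before
#'   simulation.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(spec, params, n1 = 14, n2 = 14, n_loci = 500,
                       theta_locus = 5,
                       recomb_class_fractions = c(1, 1, 1) / 3,
                       singleton_inflation_f = 1, seed = 1) {
  stop_if_invalid(spec, params)
  if (n1 + n2 < 2) abort("sample sizes must total >= 2")
  if (abs(sum(recomb_class_fractions) - 1) > 1e-8 ||
      length(recomb_class_fractions) != 3 || any(recomb_class_fractions < 0))
    abort("recomb_class_fractions must be 3 nonnegative values summing to 1")
  if (singleton_inflation_f < 1) abort("singleton_inflation_f must be >= 1")
  structure(list(spec = spec, params = params, n1 = n1, n2 = n2,
                 n_loci = n_loci, theta_locus = theta_locus,
                 recomb_class_fractions = recomb_class_fractions,
                 singleton_inflation_f = singleton_inflation_f,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Representative cM/Mb rate reported for each class.
recomb_class_rates <- function() c(0.75, 2.25, 8.75)

#' Simulate a haploid two-population dataset
#'
#' Draws `n_loci` independent genealogies under the configured demography,
#' drops infinite-sites mutations, and assembles a haploid genotype dataset
#' with one pseudo-contig per locus, strictly increasing positions, and a
#' per-site recombination class. The output is polarized (0 = ancestral,
#' 1 = derived).
#'
#' @param cfg A [sim_config()].
#' @return A `hap_dataset` (see [hap_dataset()]).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n1 + cfg$n2
  samples <- tibble(
    id = c(sprintf("A%02d", seq_len(cfg$n1)),
           if (cfg$n2 > 0) sprintf("B%02d", seq_len(cfg$n2))),
    pop = c(rep("pop1", cfg$n1), rep("pop2", cfg$n2)))
  if (cfg$n_loci == 0) {
    return(hap_dataset(geno = matrix(0L, 0, n, dimnames = list(NULL, samples$id)),
                       sites = tibble(contig = character(), pos = integer(),
                                      rec_rate = double(), rec_class = integer()),
                       samples = samples, polarized = TRUE,
                       provenance = list(seed = cfg$seed, generator = "simulate_dataset")))
  }
  # class assignment: deterministic proportions, remainder to largest classes
  n_cl <- floor(cfg$n_loci * cfg$recomb_class_fractions)
  while (sum(n_cl) < cfg$n_loci) {
    k <- which.max(cfg$n_loci * cfg$recomb_class_fractions - n_cl)
    n_cl[k] <- n_cl[k] + 1
  }
  cls <- rep(1:3, times = n_cl)
  trees <- simulate_genealogies(cfg$spec, cfg$params, cfg$n1, cfg$n2,
                                n_reps = cfg$n_loci, seed = NULL)
  geno_cols <- vector("list", cfg$n_loci)
  site_rows <- vector("list", cfg$n_loci)
  rates <- recomb_class_rates()
  for (l in seq_len(cfg$n_loci)) {
    f <- if (cls[l] == 1L) cfg$singleton_inflation_f else 1
    mut <- drop_mutations(trees[[l]], cfg$theta_locus, inflation_f = f)
    if (nrow(mut) == 0) next
    mem <- tree_leaf_membership(trees[[l]])
    geno_cols[[l]] <- mem[, mut$branch, drop = FALSE] * 1L  # leaves x sites
    site_rows[[l]] <- tibble(contig = sprintf("locus_%05d", l),
                             pos = seq_len(nrow(mut)) - 1L,
                             rec_rate = rates[cls[l]],
                             rec_class = cls[l])
  }
  keep <- !vapply(geno_cols, is.null, TRUE)
  geno <- if (any(keep)) t(do.call(cbind, geno_cols[keep]))
          else matrix(0L, 0, n)
  colnames(geno) <- samples$id
  sites <- if (any(keep)) bind_rows(site_rows[keep])
           else tibble(contig = character(), pos = integer(),
                       rec_rate = double(), rec_class = integer())
  hap_dataset(geno = geno, sites = sites, samples = samples, polarized = TRUE,
              provenance = list(seed = cfg$seed, generator = "simulate_dataset",
                                model = cfg$spec$name,
                                n_loci = cfg$n_loci,
                                theta_locus = cfg$theta_locus,
                                singleton_inflation_f = cfg$singleton_inflation_f))
}

#' Simulate joint-SFS site counts over independent loci
#'
#' Fast path for SFS-level simulation: draws genealogies for `n_loci`
#' independent loci, drops Poisson mutations branch-wise (rate
#' `theta_locus/2` per unit branch length, external branches multiplied by
#' `inflation_f`), and tallies the resulting joint SFS directly without
#' materializing genotypes.
#'
#' @inheritParams simulate_genealogies
#' @param n_loci Number of independent loci.
#' @param theta_locus Per-locus scaled mutation parameter.
#' @param inflation_f External-branch mutation-rate multiplier (>= 1).
#' @param per_locus If `TRUE`, also return the per-locus 1D population-1
#'   spectra as a matrix (loci x frequency classes).
#' @return A [joint_sfs()]; with `per_locus = TRUE`, a list with elements
#'   `jsfs` and `locus_sfs1`.
#' @export
simulate_sfs_counts <- function(spec, params, n1, n2 = 0, n_loci,
                                theta_locus, inflation_f = 1, seed = NULL,
                                per_locus = FALSE) {
  stop_if_invalid(spec, params)
  if (theta_locus < 0) abort("theta_locus must be >= 0")
  if (inflation_f < 1) abort("inflation_f must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  bt <- cpp_branch_table(n1, n2, sim_par_vec(spec, params), n_loci)
  i <- bt[, "i"]; j <- bt[, "j"]
  lam <- theta_locus * bt[, "length"] / 2 *
    ifelse(i + j == 1, inflation_f, 1)
  nm <- rpois(length(lam), lam)
  counts <- matrix(0, n1 + 1L, n2 + 1L)
  idx <- i + (n1 + 1) * j + 1
  agg <- rowsum(nm, idx)
  counts[as.integer(rownames(agg))] <- agg
  out <- joint_sfs(counts)
  if (!per_locus) return(out)
  keep <- i > 0 & i < n1
  locus_sfs1 <- matrix(0, n_loci, n1 - 1L)
  if (any(keep)) {
    agg2 <- rowsum(nm[keep],
                   paste(bt[keep, "locus"], i[keep], sep = ":"))
    parts <- do.call(rbind, strsplit(rownames(agg2), ":", fixed = TRUE))
    locus_sfs1[cbind(as.integer(parts[, 1]), as.integer(parts[, 2]))] <-
      agg2[, 1]
  }
  list(jsfs = out, locus_sfs1 = locus_sfs1)
}

#' Monte-Carlo expected joint SFS per unit theta
#'
#' Averages the branch-category length matrix over `n_reps` simulated
#' genealogies and divides by two, giving the expected joint SFS per unit of
#' the mutation parameter: multiplying by `theta` yields expected site
#' counts in each frequency category. For a single constant-size population
#' the entries converge to `1/i`, the classical neutral expectation — the
#' package's primary convention check.
#'
#' @inheritParams simulate_genealogies
#' @param n_reps Number of Monte-Carlo genealogies (default 20000).
#' @return Object of class `jsfs_expectation`: list with `per_theta` and
#'   `se` matrices (`(n1+1) x (n2+1)`, monomorphic corners zero), `n_reps`,
#'   `n1`, `n2`.
#' @export
expected_jsfs <- function(spec, params, n1, n2 = 0, n_reps = 20000,
                          seed = NULL) {
  stop_if_invalid(spec, params)
  if (n_reps < 1) abort("n_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_expected_jsfs(n1, n2, sim_par_vec(spec, params), n_reps)
  mean <- res$mean
  mean[1, 1] <- 0
  mean[n1 + 1, n2 + 1] <- 0
  structure(list(per_theta = mean, se = res$se, n_reps = n_reps,
                 n1 = n1, n2 = n2),
            class = "jsfs_expectation")
}

#' @export
print.jsfs_expectation <- function(x, ...) {
  cat("<jsfs_expectation> ", x$n1, " x ", x$n2,
      " samples, ", x$n_reps, " genealogies\n", sep = "")
  cat("  total expected sites per unit theta:",
      signif(sum(x$per_theta), 5), "\n")
  invisible(x)
}
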