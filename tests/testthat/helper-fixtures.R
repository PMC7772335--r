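# Shared fixtures built in code.

# A single constant-size population expressed in the two-population
# parameterization (split so old/sizes so uniform that it is panmictic for
# any sample drawn from population 1 only).
constant_pop_params <- function() {
  scaled_params(nu_af = 1, nu_bot = 1, nu_eu = 1,
                T_exp = 1e-6, T_split = 1e-7)
}

nomig_spec <- function() model_spec("NOMIG")

# Tiny deterministic dataset: 4 + 4 haploids, hand-written genotypes.
toy_dataset <- function() {
  geno <- rbind(
    c(1, 0, 0, 0, 0, 0, 0, 0),  # singleton pop1
    c(1, 1, 0, 0, 1, 0, 0, 0),  # (2,1)
    c(0, 0, 0, 0, 1, 1, 1, 1),  # fixed in pop2
    c(1, 1, 1, 1, 0, 0, 0, 0),  # fixed in pop1
    c(0, 1, 1, 0, 0, 1, 1, 0))  # (2,2)
  storage.mode(geno) <- "integer"
  hap_dataset(
    geno = geno,
    sites = tibble::tibble(contig = "chr1", pos = c(10L, 20L, 30L, 40L, 50L)),
    samples = tibble::tibble(id = paste0("s", 1:8),
                             pop = rep(c("pop1", "pop2"), each = 4)))
}

# Manual two-leaf genealogy coalescing at tau.
two_leaf_tree <- function(tau, pops = c(1L, 1L)) {
  n1 <- sum(pops == 1L); n2 <- sum(pops == 2L)
  structure(list(parent = c(3L, 3L, NA), time = c(0, 0, tau),
                 n1 = n1, n2 = n2), class = "coal_tree")
}
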