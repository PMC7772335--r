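test_that("pairwise coalescence time matches the scaled-unit expectation", {
  trees <- simulate_genealogies(nomig_spec(), constant_pop_params(),
                                n1 = 2, n2 = 0, n_reps = 10000, seed = 11)
  tmrca <- vapply(trees, function(t) max(t$time), 0.0)
  expect_equal(mean(tmrca), 1.0, tolerance = 0.03)
})

test_that("no cross-population coalescence can predate the split without migration", {
  p <- scaled_params(nu_af = 1, nu_bot = 0.5, nu_eu = 0.5,
                     T_exp = 2, T_split = 0.5)
  trees <- simulate_genealogies(model_spec("NOMIG"), p, n1 = 3, n2 = 3,
                                n_reps = 1000, seed = 7)
  min_cross <- vapply(trees, function(tr) {
    ev <- splitmig:::tree_coal_events(tr, groups = rep(1:2, each = 3))
    min(ev$time[ev$cat != 1L & ev$cat != 2L])
  }, 0.0)
  expect_true(all(min_cross >= 0.5))

  # two lineages, one per population: TMRCA always after the split
  pair <- simulate_genealogies(model_spec("NOMIG"), p, n1 = 1, n2 = 1,
                               n_reps = 500, seed = 8)
  expect_true(all(vapply(pair, function(t) max(t$time), 0.0) > 0.5))
})

test_that("branch categories conserve total branch length", {
  # deterministic 2-leaf checks
  tr <- two_leaf_tree(0.7)
  T <- branch_category_lengths(tr)
  expect_equal(T[2, 1], 2 * 0.7)
  expect_equal(sum(T), 2 * 0.7)

  tr2 <- two_leaf_tree(1.3, pops = c(1L, 2L))
  T2 <- branch_category_lengths(tr2)
  expect_equal(T2[2, 1], 1.3)
  expect_equal(T2[1, 2], 1.3)

  # random genealogies: category sum equals total length by traversal
  p <- scaled_params(nu_af = 2, nu_bot = 0.2, nu_eu = 0.8,
                     T_exp = 1, T_split = 0.3, M_AtoE = 1, M_EtoA = 0.5)
  trees <- simulate_genealogies(model_spec("ASYMIG"), p, n1 = 2, n2 = 2,
                                n_reps = 50, seed = 3)
  for (tr in trees) {
    T <- branch_category_lengths(tr)
    expect_equal(T[1, 1], 0)
    expect_equal(T[nrow(T), ncol(T)], 0)
    expect_equal(sum(T), total_branch_length(tr), tolerance = 1e-12)
  }
})

test_that("mutation dropping is Poisson with the theta/2 convention", {
  expect_equal(nrow(drop_mutations(two_leaf_tree(0.5), 0)), 0)
  expect_error(drop_mutations(two_leaf_tree(0.5), -1), "theta")

  # E[S] = theta * a_{n-1}; n = 2 gives a_1 = 1
  set.seed(21)
  trees <- simulate_genealogies(nomig_spec(), constant_pop_params(),
                                n1 = 2, n2 = 0, n_reps = 20000, seed = 21)
  S <- vapply(trees, function(tr) nrow(drop_mutations(tr, 1)), 0L)
  expect_equal(mean(S), 1.0, tolerance = 0.03)

  # external-branch inflation doubles the singleton mean, linearly
  trees10 <- simulate_genealogies(nomig_spec(), constant_pop_params(),
                                  n1 = 10, n2 = 0, n_reps = 3000, seed = 22)
  count_singletons <- function(f, seed) {
    set.seed(seed)
    sum(vapply(trees10, function(tr) {
      m <- drop_mutations(tr, 2, inflation_f = f)
      sum(m$i == 1L)
    }, 0L))
  }
  s1 <- count_singletons(1, 101)
  s2 <- count_singletons(2, 101)
  expect_equal(s2 / s1, 2, tolerance = 0.05)
})

test_that("dataset simulation is deterministic, labelled and polymorphic across pops", {
  cfg <- sim_config(model_spec("ASYMIG"), default_asymig_params(),
                    n_loci = 200, theta_locus = 5, seed = 5)
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds1$geno, ds2$geno)
  expect_identical(ds1$sites, ds2$sites)

  expect_true(all(diff(ds1$sites$pos[ds1$sites$contig == ds1$sites$contig[1]]) > 0))
  expect_true(ds1$polarized)
  expect_equal(ds1$provenance$seed, 5L)
  expect_setequal(unique(ds1$sites$rec_class), 1:3)

  # shared ancestry + migration => some sites segregate in both populations
  dc <- derived_counts(ds1)
  expect_gt(sum(dc$i > 0 & dc$j > 0), 0)

  # empty design stays valid
  empty <- simulate_dataset(sim_config(model_spec("ASYMIG"),
                                       default_asymig_params(),
                                       n_loci = 0, seed = 1))
  expect_equal(n_sites(empty), 0)
  expect_equal(n_samples(empty), 28)
})

test_that("SFS-count simulation agrees with the mutation-dropping path", {
  # E[S] = theta * a_{n-1} per locus; n = 14, theta = 5
  res <- simulate_sfs_counts(nomig_spec(), constant_pop_params(),
                             n1 = 14, n2 = 0, n_loci = 2000,
                             theta_locus = 5, seed = 55, per_locus = TRUE)
  S_per_locus <- sum(unclass(res$jsfs)) / 2000
  expect_equal(S_per_locus, 5 * sum(1 / 1:13), tolerance = 0.03)
  # per-locus spectra sum to the pooled marginal
  expect_equal(colSums(res$locus_sfs1),
               unclass(marginal_sfs(res$jsfs, 1))[2:14])
  # singleton inflation raises exactly the singleton class
  infl <- simulate_sfs_counts(nomig_spec(), constant_pop_params(),
                              n1 = 14, n2 = 0, n_loci = 2000,
                              theta_locus = 5, inflation_f = 1.5, seed = 55)
  xi0 <- unclass(marginal_sfs(res$jsfs, 1))[2:14]
  xi1 <- unclass(marginal_sfs(infl, 1))[2:14]
  expect_equal(xi1[1] / xi0[1], 1.5, tolerance = 0.1)
  expect_equal(sum(xi1[-1]) / sum(xi0[-1]), 1, tolerance = 0.05)
})

test_that("expected joint SFS matches closed forms and attaches standard errors", {
  E <- expected_jsfs(nomig_spec(), constant_pop_params(),
                     n1 = 5, n2 = 0, n_reps = 50000, seed = 31)
  expect_equal(E$per_theta[2:5, 1], 1 / (1:4), tolerance = 0.03)
  expect_true(all(E$se[2:5, 1] > 0))
  expect_equal(E$per_theta[1, 1], 0)
  expect_equal(E$per_theta[6, 1], 0)

  E2 <- expected_jsfs(nomig_spec(), constant_pop_params(),
                      n1 = 2, n2 = 0, n_reps = 20000, seed = 32)
  expect_equal(E2$per_theta[2, 1], 1.0, tolerance = 0.03)
})

test_that("strong symmetric migration approaches the panmictic joint SFS", {
  p <- scaled_params(nu_af = 1, nu_bot = 1, nu_eu = 1, T_exp = 30,
                     T_split = 29, M_AtoE = 200, M_EtoA = 200)
  E <- expected_jsfs(model_spec("SYMIG"), p, 4, 4, n_reps = 250000, seed = 33)
  pan <- matrix(0, 5, 5)
  for (k in 1:7) for (i in max(0, k - 4):min(4, k))
    pan[i + 1, k - i + 1] <- (1 / k) * dhyper(i, 4, 4, k)
  pan[1, 1] <- 0; pan[5, 5] <- 0
  a <- E$per_theta / sum(E$per_theta)
  b <- pan / sum(pan)
  expect_lt(max(abs(a - b) / pmax(b, 1e-12)), 0.05)
})

test_that("Fst from simulated data responds to divergence and migration", {
  base <- function(T_split, M) {
    scaled_params(nu_af = 1, nu_bot = 1, nu_eu = 1, T_exp = T_split + 1,
                  T_split = T_split, M_AtoE = M, M_EtoA = M)
  }
  fst_for <- function(spec_name, T_split, M, seed = 44) {
    cfg <- sim_config(model_spec(spec_name), base(T_split, M), n1 = 8, n2 = 8,
                      n_loci = 400, theta_locus = 2, seed = seed)
    hudson_fst(simulate_dataset(cfg))
  }
  # deeper splits differentiate more (no migration)
  expect_lt(fst_for("NOMIG", 0.1, 0), fst_for("NOMIG", 1.0, 0))
  # more migration differentiates less (shared seed ladder)
  f <- vapply(c(0.5, 2, 8), function(M) fst_for("SYMIG", 0.5, M), 0.0)
  expect_true(all(diff(f) < 0))
})

test_that("newick export round-trips through ape", {
  skip_if_not_installed("ape")
  p <- scaled_params(nu_af = 2, nu_bot = 0.2, nu_eu = 0.8,
                     T_exp = 1, T_split = 0.3, M_AtoE = 1, M_EtoA = 0.5)
  tr <- simulate_genealogies(model_spec("ASYMIG"), p, 3, 3, 1, seed = 9)[[1]]
  ph <- ape::read.tree(text = to_newick(tr))
  expect_equal(ape::Ntip(ph), 6)
  expect_equal(max(ape::node.depth.edgelength(ph)), max(tr$time),
               tolerance = 1e-8)
  expect_true(ape::is.ultrametric(ph, tol = 1e-6))
})
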