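test_that("Watterson's theta uses the harmonic normalizer", {
  expect_equal(watterson_theta(S = 1, n = 2, L = 1), 1.0)
  a13 <- sum(1 / 1:13)
  expect_equal(watterson_theta(S = 16, n = 14, L = 1000), 16 / (a13 * 1000))
  expect_equal(watterson_theta(S = 16, n = 14, L = 1000), 0.005031,
               tolerance = 1e-4)
  expect_equal(watterson_theta(S = 0, n = 5, L = 10), 0)
  expect_error(watterson_theta(1, n = 1), "n")
  expect_error(watterson_theta(1, n = 5, L = 0), "L")
})

test_that("nucleotide diversity equals average pairwise differences", {
  expect_equal(nucleotide_diversity(sfs_1d(1, n = 2)), 1.0)
  # enumeration oracle: n = 4, xi = (3, 2, 1)
  # pairwise differences: sum_i i(n-i) xi_i = 3*3 + 2*4 + 1*3 = 20, /C(4,2)=6
  expect_equal(nucleotide_diversity(sfs_1d(c(3, 2, 1), n = 4)), 20 / 6)
  expect_equal(nucleotide_diversity(sfs_1d(c(0, 0, 0), n = 4)), 0)
})

test_that("Tajima's D matches the constants-based oracle and neutrality", {
  # frozen oracle value computed from the standard constants for n = 4,
  # S = 6, pi = 10/3: a1 = 11/6, a2 = 49/36, b1 = (n+1)/(3(n-1)) = 5/9,
  # b2 = 2(n^2+n+3)/(9n(n-1)) = 23/54, c1 = b1 - 1/a1,
  # c2 = b2 - (n+2)/(a1 n) + a2/a1^2, e1 = c1/a1, e2 = c2/(a1^2 + a2),
  # D = (pi - S/a1)/sqrt(e1 S + e2 S(S-1))
  a1 <- 11 / 6; a2 <- 49 / 36
  c1 <- 5 / 9 - 1 / a1
  c2 <- 23 / 54 - 6 / (4 * a1) + a2 / a1^2
  D_oracle <- (20 / 6 - 6 / a1) /
    sqrt((c1 / a1) * 6 + (c2 / (a1^2 + a2)) * 6 * 5)
  expect_equal(tajimas_d(sfs_1d(c(3, 2, 1), n = 4)), D_oracle)
  expect_equal(D_oracle, 0.18, tolerance = 0.01)
  expect_error(tajimas_d(sfs_1d(c(0, 0, 0), n = 4)), "undefined")

  # neutral constant-size loci: mean D near zero
  cfg <- sim_config(nomig_spec(), constant_pop_params(), n1 = 14, n2 = 0,
                    n_loci = 200, theta_locus = 5, seed = 91)
  trees <- simulate_genealogies(nomig_spec(), constant_pop_params(),
                                14, 0, 200, seed = 91)
  set.seed(92)
  D <- vapply(trees, function(tr) {
    m <- drop_mutations(tr, 5)
    xi <- tabulate(m$i, nbins = 13)
    if (sum(xi) < 1) return(NA_real_)
    tajimas_d(sfs_1d(xi, n = 14))
  }, 0.0)
  expect_lt(abs(mean(D, na.rm = TRUE)), 0.15)
})

test_that("theta_w and pi agree in expectation on neutral loci", {
  trees <- simulate_genealogies(nomig_spec(), constant_pop_params(),
                                14, 0, 500, seed = 93)
  set.seed(94)
  d <- vapply(trees, function(tr) {
    m <- drop_mutations(tr, 5)
    xi <- tabulate(m$i, nbins = 13)
    nucleotide_diversity(sfs_1d(xi, n = 14)) - watterson_theta(sum(xi), 14)
  }, 0.0)
  expect_lt(abs(mean(d)), 2 * sd(d) / sqrt(length(d)))
})

test_that("Hudson's Fst behaves at its reference points", {
  # identical sample frequencies, larger n: near 0 (slightly negative from
  # the finite-sample correction)
  ds <- toy_dataset()
  row <- c(rep(1L, 10), rep(0L, 10), rep(1L, 10), rep(0L, 10))
  sym <- hap_dataset(
    geno = matrix(rep(row, 3), 3, 40, byrow = TRUE),
    sites = tibble::tibble(contig = "c", pos = 0:2),
    samples = tibble::tibble(id = paste0("s", 1:40),
                             pop = rep(c("pop1", "pop2"), each = 20)))
  expect_lt(abs(hudson_fst(sym)), 0.06)
  # a fixed difference
  fixed <- hap_dataset(
    geno = matrix(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L), 1, 8),
    sites = tibble::tibble(contig = "c", pos = 0L),
    samples = ds$samples)
  expect_equal(hudson_fst(fixed), 1.0)
  # joint-SFS route agrees with the per-site route
  jsfs <- build_joint_sfs(ds)
  expect_equal(hudson_fst(jsfs), hudson_fst(ds))
})

test_that("the SFS chi-squared test detects skew and respects pooling", {
  # identical spectra: statistic 0, p = 1
  s <- sfs_1d(c(30, 20, 10), n = 4)
  r0 <- sfs_chisq_test(s, s)
  expect_equal(unname(r0$statistic), 0)
  expect_equal(r0$p.value, 1)

  # textbook 2x2 table
  r <- sfs_chisq_test(sfs_1d(c(10, 20), n = 3), sfs_1d(c(20, 10), n = 3))
  expect_equal(unname(r$statistic), 20 / 3, tolerance = 1e-6)
  expect_equal(r$p.value, 0.0098, tolerance = 0.01)

  # sparse high-frequency classes get pooled until expectations reach 5
  a <- sfs_1d(c(100, 50, 3, 1), n = 5)
  b <- sfs_1d(c(90, 60, 2, 2), n = 5)
  rp <- sfs_chisq_test(a, b)
  expect_lt(ncol(rp$observed), 4)
  expect_error(sfs_chisq_test(sfs_1d(c(1, 0), n = 3), sfs_1d(c(1, 0), n = 3)),
               "degenerate")
})

test_that("PCA separates structured samples deterministically", {
  # two groups of identical haplotypes differing at 5 sites
  g <- rbind(matrix(rep(c(1L, 1L, 1L, 0L, 0L, 0L), 5), 5, 6, byrow = TRUE))
  ds <- hap_dataset(g, tibble::tibble(contig = "c", pos = 0:4),
                    tibble::tibble(id = paste0("s", 1:6),
                                   pop = rep(c("pop1", "pop2"), each = 3)))
  res <- pca_genotypes(ds, n_components = 2)
  sc <- res$scores
  expect_true(all(sign(sc$PC1[sc$pop == "pop1"]) !=
                    sign(sc$PC1[sc$pop == "pop2"])))
  expect_lt(res$explained_variance[2], 1e-10)

  res2 <- pca_genotypes(ds, n_components = 2)
  expect_identical(res$scores, res2$scores)

  # simulated two-population data: PC1 clusters match the labels
  cfg <- sim_config(model_spec("NOMIG"),
                    scaled_params(nu_af = 1, nu_bot = 0.5, nu_eu = 0.5,
                                  T_exp = 3, T_split = 1),
                    n1 = 8, n2 = 8, n_loci = 100, theta_locus = 2, seed = 13)
  sim <- simulate_dataset(cfg)
  pc <- pca_genotypes(sim)$scores
  expect_true(all(table(pc$pop, pc$PC1 > 0) %in% c(0, 8)))

  expect_warning(pca_genotypes(ds, n_components = 10), "truncat")
})

test_that("summary_stats assembles the per-population table", {
  cfg <- sim_config(model_spec("ASYMIG"), default_asymig_params(),
                    n1 = 8, n2 = 8, n_loci = 100, theta_locus = 2, seed = 17)
  ds <- simulate_dataset(cfg)
  st <- summary_stats(ds, L = 1000)
  expect_equal(nrow(st), 2)
  expect_true(all(st$theta_w > 0))
  expect_true(is.finite(attr(st, "fst")))
  # the bottlenecked derived population is less diverse
  expect_lt(st$pi[st$pop == "pop2"], st$pi[st$pop == "pop1"])
})
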