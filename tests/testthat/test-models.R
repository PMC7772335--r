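test_that("model specs carry the scenario's free parameters and k", {
  cases <- list(NOMIG = 5, SYMIG = 6, ASYMIG = 7, RASYMIG = 8)
  for (nm in names(cases)) {
    sp <- model_spec(nm)
    expect_equal(sp$k, cases[[nm]])
    expect_equal(sp$k, length(sp$free_param_names))
    expect_true(all(sp$free_param_names %in%
                      c("nu_af", "nu_bot", "nu_eu", "T_exp", "T_split",
                        "M_AtoE", "M_EtoA", "T_mig")))
  }
  expect_setequal(model_spec("ASYMIG")$free_param_names,
                  c("nu_af", "nu_bot", "nu_eu", "T_exp", "T_split",
                    "M_AtoE", "M_EtoA"))
  expect_false("M_AtoE" %in% model_spec("nomig")$free_param_names)
  expect_error(model_spec("nomigg"), "valid choices")
})

test_that("parameter validation reports violated invariants", {
  sp <- model_spec("ASYMIG")
  ok <- scaled_params(nu_af = 4, nu_bot = 0.09, nu_eu = 0.9,
                      T_exp = 0.5, T_split = 0.175, M_AtoE = 0.4, M_EtoA = 1.2)
  expect_equal(nrow(validate_params(sp, ok)), 0)

  bad_size <- scaled_params(nu_af = 4, nu_bot = 0, nu_eu = 0.9,
                            T_exp = 0.5, T_split = 0.175)
  expect_match(validate_params(sp, bad_size)$message, "size must be > 0",
               all = FALSE)

  bad_order <- scaled_params(nu_af = 4, nu_bot = 0.1, nu_eu = 0.9,
                             T_exp = 0.1, T_split = 0.175)
  expect_match(validate_params(sp, bad_order)$message, "T_exp > T_split",
               all = FALSE)

  sym_bad <- scaled_params(nu_af = 1, nu_bot = 1, nu_eu = 1,
                           T_exp = 1, T_split = 0.5,
                           M_AtoE = 1, M_EtoA = 2)
  expect_gt(nrow(validate_params(model_spec("SYMIG"), sym_bad)), 0)

  ras_bad <- scaled_params(nu_af = 1, nu_bot = 1, nu_eu = 1,
                           T_exp = 1, T_split = 0.2,
                           M_AtoE = 1, M_EtoA = 1, T_mig = 0.3)
  expect_match(validate_params(model_spec("RASYMIG"), ras_bad)$message,
               "T_mig", all = FALSE)
})

test_that("size trajectories follow the stepwise / exponential-recovery model", {
  sp <- model_spec("ASYMIG")
  p <- scaled_params(nu_af = 4, nu_bot = 0.04, nu_eu = 0.64,
                     T_exp = 0.5, T_split = 0.2, M_AtoE = 1, M_EtoA = 1)
  expect_equal(size_trajectory(sp, p, "AF", 0.5 + 1e-9), 1.0)
  expect_equal(size_trajectory(sp, p, "AF", 0.49), 4.0)
  expect_equal(size_trajectory(sp, p, "EU", 0), 0.64)
  expect_equal(size_trajectory(sp, p, "EU", 0.2 - 1e-12), 0.04,
               tolerance = 1e-6)
  # geometric mean at the epoch midpoint
  expect_equal(size_trajectory(sp, p, "EU", 0.1), sqrt(0.04 * 0.64))
  expect_error(size_trajectory(sp, p, "EU", 0.25), "T_split")

  # continuity and monotonicity on (0, T_split)
  tt <- seq(1e-6, 0.2 - 1e-6, length.out = 200)
  nu <- size_trajectory(sp, p, "EU", tt)
  expect_true(all(diff(nu) < 0))
  expect_lt(max(abs(diff(nu))), 0.02)
})

test_that("migration gates follow the scenario", {
  p <- scaled_params(nu_af = 1, nu_bot = 1, nu_eu = 1, T_exp = 1,
                     T_split = 0.2, M_AtoE = 0.4, M_EtoA = 1.2, T_mig = 0.1)
  expect_equal(migration_matrix(model_spec("NOMIG"),
                                scaled_params(1, 1, 1, 1, 0.2), 0.1),
               matrix(0, 2, 2, dimnames = list(c("AF", "EU"), c("AF", "EU"))))
  m <- migration_matrix(model_spec("ASYMIG"), p, 0.15)
  expect_equal(m["AF", "EU"], 1.2)
  expect_equal(m["EU", "AF"], 0.4)
  # time gate
  expect_true(all(migration_matrix(model_spec("RASYMIG"), p, 0.15) == 0))
  expect_gt(sum(migration_matrix(model_spec("RASYMIG"), p, 0.05)), 0)
  expect_error(migration_matrix(model_spec("ASYMIG"), p, 0.2), "single population")
  # RASYMIG with T_mig = T_split reproduces ASYMIG at every queried time
  p2 <- scaled_params(nu_af = 1, nu_bot = 1, nu_eu = 1, T_exp = 1,
                      T_split = 0.2, M_AtoE = 0.4, M_EtoA = 1.2, T_mig = 0.2)
  for (t in c(0.01, 0.1, 0.19))
    expect_equal(migration_matrix(model_spec("RASYMIG"), p2, t),
                 migration_matrix(model_spec("ASYMIG"), p2, t))
})

test_that("physical-unit conversion matches the arithmetic and round-trips", {
  sc <- scaling_config(mu = 5.21e-9, gens_per_year = 15, L = 4020733)
  p <- default_asymig_params()
  ph <- to_physical(p, theta_hat = 14860, scaling = sc)
  N_anc <- ph$value[ph$parameter == "N_ANC"]
  expect_equal(N_anc, 14860 / (4 * 5.21e-9 * 4020733))
  expect_equal(N_anc, 177344, tolerance = 5e-3)
  T_split_years <- ph$value[ph$parameter == "T_split_years"]
  expect_equal(T_split_years, 0.17504 * 2 * N_anc / 15, tolerance = 1e-10)
  expect_equal(T_split_years, 4139, tolerance = 5e-3)
  expect_error(to_physical(p, theta_hat = 0, sc), "theta_hat")

  # round trip
  back <- from_physical(ph, sc)
  expect_equal(unclass(back$params), unclass(p), tolerance = 1e-10)
  expect_equal(back$theta_hat, 14860, tolerance = 1e-10)
})

test_that("model configs round-trip through key-value text", {
  path <- withr::local_tempfile(fileext = ".txt")
  sp <- model_spec("RASYMIG")
  p <- scaled_params(nu_af = 2.5, nu_bot = 0.05, nu_eu = 1.2,
                     T_exp = 0.9, T_split = 0.3, M_AtoE = 0.7,
                     M_EtoA = 0.2, T_mig = 0.12)
  write_model_config(sp, p, path)
  rt <- read_model_config(path)
  expect_equal(rt$spec$name, "RASYMIG")
  expect_equal(unclass(rt$params), unclass(p), tolerance = 1e-12)
})
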