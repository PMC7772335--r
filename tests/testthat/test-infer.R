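# Small shared observed spectrum for fit tests: Poisson data around a
# high-precision ASYMIG expectation, 8 + 8 samples.
sim_observed <- function(theta = 3000, n1 = 8, n2 = 8, n_reps = 30000,
                         seed = 71, params = default_asymig_params(),
                         spec = model_spec("ASYMIG")) {
  E <- expected_jsfs(spec, params, n1, n2, n_reps = n_reps, seed = seed)
  M <- theta * E$per_theta
  set.seed(seed + 1)
  joint_sfs(matrix(rpois(length(M), M), nrow(M), ncol(M)))
}

test_that("Poisson composite likelihood profiles theta analytically", {
  obs <- joint_sfs(matrix(c(0, 2, 1, 0), 2, 2))
  E <- matrix(c(0, 1, 0.5, 0), 2, 2)
  r <- poisson_loglik(obs, E)
  expect_equal(r$theta_hat, 2)
  expect_equal(r$loglik, (2 * log(2) - 2 - log(2)) + (0 - 1 - 0),
               tolerance = 1e-12)
  expect_equal(r$loglik, -2.3069, tolerance = 1e-4)

  # all-zero observation
  z <- poisson_loglik(joint_sfs(matrix(0, 2, 2)), E)
  expect_equal(z$theta_hat, 0)
  expect_equal(z$loglik, 0)

  # saturated value when expectation equals data at theta_hat = 1
  S <- matrix(c(0, 3, 4, 0), 2, 2)
  sat <- poisson_loglik(joint_sfs(S), S)
  expect_equal(sat$theta_hat, 1)
  expect_equal(sat$loglik, sum(c(3, 4) * log(c(3, 4)) - c(3, 4) -
                                 lgamma(c(3, 4) + 1)))

  # zero expectation with data present
  expect_error(poisson_loglik(obs, matrix(0, 2, 2)), "identically zero")

  # scale invariance: profiling absorbs any positive constant
  r2 <- poisson_loglik(obs, 7.3 * E)
  expect_equal(r2$loglik, r$loglik, tolerance = 1e-12)
})

test_that("fits are deterministic given the master seed and record starts", {
  obs <- sim_observed(theta = 500, n1 = 4, n2 = 4, n_reps = 5000)
  f1 <- fit_model(model_spec("SYMIG"), obs, n_starts = 3, n_mc = 500,
                  maxit = 40, seed = 99)
  f2 <- fit_model(model_spec("SYMIG"), obs, n_starts = 3, n_mc = 500,
                  maxit = 40, seed = 99)
  expect_identical(unclass(f1$params), unclass(f2$params))
  expect_identical(f1$loglik, f2$loglik)
  expect_equal(nrow(f1$starts), 3)
  expect_equal(f1$AIC, 2 * 6 - 2 * f1$loglik)

  expect_error(fit_model(model_spec("NOMIG"),
                         joint_sfs(matrix(0, 5, 5))), "no sites")

  td <- tidy(f1)
  expect_setequal(td$term, model_spec("SYMIG")$free_param_names)
  g <- glance(f1)
  expect_equal(g$model, "SYMIG")
  expect_equal(g$k, 6)
})

test_that("model choice ranks by AIC with parsimony tie-breaking", {
  obs <- sim_observed(theta = 800, n1 = 4, n2 = 4, n_reps = 5000)
  fits <- lapply(c("NOMIG", "SYMIG"), function(m)
    fit_model(model_spec(m), obs, n_starts = 2, n_mc = 400, maxit = 40,
              seed = 7))
  tb <- model_choice(fits)
  expect_equal(nrow(tb), 2)
  expect_equal(tb$delta_AIC[1], 0)
  expect_true(!is.unsorted(tb$AIC))
  expect_s3_class(attr(tb, "best"), "model_spec")

  # mismatched data refused
  obs2 <- sim_observed(theta = 100, n1 = 3, n2 = 3, n_reps = 2000)
  f_other <- fit_model(model_spec("NOMIG"), obs2, n_starts = 1, n_mc = 300,
                       maxit = 30, seed = 1)
  expect_error(model_choice(list(fits[[1]], f_other)), "different observed")

  # AIC arithmetic and parsimony on synthetic fit objects
  fa <- fits[[1]]; fb <- fits[[2]]
  fa$loglik <- -1000; fa$AIC <- 2 * fa$spec$k - 2 * fa$loglik
  expect_equal(fa$AIC, 2 * 5 + 2000)
  fb$loglik <- -1000; fb$AIC <- 2 * fb$spec$k - 2 * fb$loglik
  tb2 <- model_choice(list(fb, fa))
  expect_equal(tb2$model[1], "NOMIG")  # equal loglik: smaller k wins
})

test_that("nested models dominate in likelihood after multi-start", {
  obs <- sim_observed(theta = 1000, n1 = 6, n2 = 6, n_reps = 10000, seed = 41)
  common <- list(n_mc = 2000, maxit = 150, seed = 11)
  f_no <- do.call(fit_model, c(list(model_spec("NOMIG"), obs, n_starts = 4),
                               common))
  # warm-start each richer model from the nested optimum (standard practice)
  init_sy <- f_no$params
  init_sy["M_AtoE"] <- init_sy["M_EtoA"] <- 1e-8
  f_sy <- do.call(fit_model, c(list(model_spec("SYMIG"), obs,
                                    init = do.call(scaled_params,
                                                   as.list(unclass(init_sy))),
                                    n_starts = 4), common))
  init_as <- f_sy$params
  f_as <- do.call(fit_model, c(list(model_spec("ASYMIG"), obs,
                                    init = do.call(scaled_params,
                                                   as.list(unclass(init_as))),
                                    n_starts = 4), common))
  expect_gte(f_sy$loglik, f_no$loglik - 1e-3)
  expect_gte(f_as$loglik, f_sy$loglik - 1e-3)
})

test_that("parametric bootstrap produces percentile intervals and flags", {
  obs <- sim_observed(theta = 800, n1 = 4, n2 = 4, n_reps = 5000, seed = 51)
  fit <- fit_model(model_spec("NOMIG"), obs, n_starts = 2, n_mc = 800,
                   maxit = 60, seed = 3)
  bs <- parametric_bootstrap(fit, n_boot = 12, n_starts = 1, n_mc = 400,
                             maxit = 40, seed = 4)
  expect_equal(bs$n_boot, 12)
  expect_true(all(bs$ci$lower <= bs$ci$upper))
  expect_setequal(bs$ci$parameter, to_physical(fit$params, fit$theta_hat)$parameter)
  expect_true(all(c("lower", "upper", "point", "point_in_ci") %in% names(bs$ci)))
  expect_gt(nrow(bs$estimates), 0)

  expect_warning(
    parametric_bootstrap(fit, n_boot = 2, n_starts = 1, n_mc = 200,
                         maxit = 20, seed = 5),
    "degenerate")
})
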