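#' Poisson composite log-likelihood of a joint SFS
#'
#' Under the Poisson random-field model each unmasked SFS entry `S_ij` is an
#' independent Poisson count with mean `theta * E_ij`, where `E_ij` is the
#' expected spectrum per unit mutation parameter. `theta` is profiled
#' analytically: `theta_hat = sum(S) / sum(E)` maximizes the likelihood, and
#' the reported value is the log-likelihood at that profile maximum,
#' `sum(S * log(M) - M - log(S!))` with `M = theta_hat * E`.
#'
#' @param observed A [joint_sfs()] of observed counts.
#' @param expected_per_theta A matrix of matching dimensions or a
#'   [expected_jsfs()] result.
#' @return List with `loglik` and `theta_hat`.
#' @export
poisson_loglik <- function(observed, expected_per_theta) {
  stopifnot(inherits(observed, "joint_sfs"))
  E <- if (inherits(expected_per_theta, "jsfs_expectation"))
    expected_per_theta$per_theta else as.matrix(expected_per_theta)
  if (!all(dim(E) == dim(observed))) abort("shape mismatch")
  if (any(E < 0)) abort("expected entries must be >= 0")
  mask <- attr(observed, "mask")
  S <- unclass(observed)[!mask]
  Ev <- E[!mask]
  if (sum(Ev) == 0) {
    if (sum(S) > 0) abort("expected SFS is identically zero but data are not")
    return(list(loglik = 0, theta_hat = 0))
  }
  theta_hat <- sum(S) / sum(Ev)
  if (theta_hat == 0) return(list(loglik = 0, theta_hat = 0))
  # floor protects against Monte-Carlo zeros in cells with observed counts
  M <- theta_hat * pmax(Ev, 1e-12)
  ll <- sum(S * log(M) - M - lgamma(S + 1))
  list(loglik = ll, theta_hat = theta_hat)
}

# Internal optimizer coordinates: log sizes and times, T_exp as
# log(T_exp - T_split), T_mig as logit(T_mig / T_split).
free_to_internal <- function(spec, params) {
  p <- as.list(unclass(params))
  vapply(spec$free_param_names, function(nm) {
    switch(nm,
      T_exp = log(p$T_exp - p$T_split),
      T_mig = stats::qlogis(min(p$T_mig / p$T_split, 1 - 1e-9)),
      log(p[[nm]]))
  }, 0.0)
}

internal_to_params <- function(spec, x) {
  v <- setNames(as.list(x), spec$free_param_names)
  T_split <- exp(v$T_split)
  T_exp <- T_split + exp(v$T_exp)
  M_AtoE <- if ("M_AtoE" %in% names(v)) exp(v$M_AtoE) else 0
  M_EtoA <- if ("M_EtoA" %in% names(v)) exp(v$M_EtoA)
            else if (spec$name == "SYMIG") M_AtoE else 0
  T_mig <- if ("T_mig" %in% names(v)) T_split * stats::plogis(v$T_mig)
           else T_split
  scaled_params(nu_af = exp(v$nu_af), nu_bot = exp(v$nu_bot),
                nu_eu = exp(v$nu_eu), T_exp = T_exp, T_split = T_split,
                M_AtoE = M_AtoE, M_EtoA = M_EtoA, T_mig = T_mig)
}

internal_bounds <- function(spec) {
  lo <- vapply(spec$free_param_names, function(nm) switch(nm,
    nu_af = , nu_bot = , nu_eu = log(1e-4),
    T_split = log(1e-4), T_exp = log(1e-6),
    M_AtoE = , M_EtoA = log(1e-8),
    T_mig = -20), 0.0)
  hi <- vapply(spec$free_param_names, function(nm) switch(nm,
    nu_af = , nu_bot = , nu_eu = log(1e3),
    T_split = log(10), T_exp = log(10),
    M_AtoE = , M_EtoA = log(50),
    T_mig = 20), 0.0)
  list(lo = lo, hi = hi)
}

#' Fit a demographic model to an observed joint SFS
#'
#' Maximizes the Poisson composite likelihood over the scenario's free
#' parameters by multi-start Nelder-Mead search in log-parameter space. The
#' Monte-Carlo expected spectrum uses common random numbers — one fixed
#' genealogy seed reused for every evaluation within the fit — so the
#' objective is a deterministic, optimizable function of the parameters.
#' The mutation parameter `theta` is profiled analytically and not counted
#' among the `k` free parameters.
#'
#' @param spec A [model_spec()].
#' @param observed A [joint_sfs()] of observed counts.
#' @param init Optional [scaled_params()] starting point (defaults to a
#'   mid-range heuristic start).
#' @param n_starts Number of independent starts (>= 1); starts after the
#'   first perturb `init` by lognormal factors with sigma 0.5.
#' @param n_mc Monte-Carlo genealogies per likelihood evaluation.
#' @param maxit Nelder-Mead iteration cap per start; each start restarts
#'   the simplex once from its own endpoint, which protects against
#'   premature simplex collapse.
#' @param n_mc_refine Optional higher Monte-Carlo precision for a
#'   refinement phase: the `refine_top` best start endpoints are
#'   re-optimized under a fresh common-random-number stream with this many
#'   genealogies per evaluation, and the best refined optimum is returned.
#'   `NULL` (default) disables refinement.
#' @param refine_top Number of start endpoints carried into refinement.
#' @param maxit_refine Iteration cap per refinement search (defaults to
#'   `maxit`).
#' @param seed Master seed controlling the common-random-number stream and
#'   the start perturbations; identical seeds give identical fits.
#' @return Object of class `sm_fit`: best parameters, `theta_hat`,
#'   `loglik`, `AIC`, and a per-start record tibble.
#' @export
fit_model <- function(spec, observed, init = NULL, n_starts = 10,
                      n_mc = 20000, maxit = 250, n_mc_refine = NULL,
                      refine_top = 3, maxit_refine = maxit, seed = 1) {
  stopifnot(inherits(spec, "model_spec"), inherits(observed, "joint_sfs"))
  if (sum(unclass(observed)) == 0) abort("observed SFS has no sites")
  n1 <- attr(observed, "n1"); n2 <- attr(observed, "n2")
  if (is.null(init))
    init <- scaled_params(nu_af = 2, nu_bot = 0.1, nu_eu = 0.5,
                          T_exp = 0.5, T_split = 0.2,
                          M_AtoE = 0.5, M_EtoA = 0.5, T_mig = 0.1)
  set.seed(seed)
  mc_seed <- sample.int(2147483646L, 1)
  mc_seed_refine <- sample.int(2147483646L, 1)
  k <- length(spec$free_param_names)
  # lognormal start perturbations drawn up front (start 1 = init itself)
  pert <- matrix(rlnorm((n_starts - 1) * k, 0, 0.5), ncol = k)
  bounds <- internal_bounds(spec)

  make_objective <- function(n_reps, crn_seed) {
    function(x) {
      if (any(x < bounds$lo) || any(x > bounds$hi))
        return(1e9 + sum(pmax(bounds$lo - x, 0)^2 + pmax(x - bounds$hi, 0)^2))
      p <- internal_to_params(spec, x)
      set.seed(crn_seed)
      E <- cpp_jsfs_mean(n1, n2, sim_par_vec(spec, p), n_reps)
      E[1, 1] <- 0; E[n1 + 1, n2 + 1] <- 0
      -poisson_loglik(observed, E)$loglik
    }
  }
  nm_search <- function(x0, fn, maxit) {
    opt <- optim(x0, fn, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-7))
    # one simplex restart from the endpoint
    opt2 <- optim(opt$par, fn, method = "Nelder-Mead",
                  control = list(maxit = maxit, reltol = 1e-7))
    if (opt2$value <= opt$value) opt2 else opt
  }
  objective <- make_objective(n_mc, mc_seed)

  x0 <- free_to_internal(spec, init)
  starts <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    xs <- if (s == 1) x0 else {
      p <- as.list(unclass(init))
      for (ii in seq_len(k)) {
        nm <- spec$free_param_names[ii]
        p[[nm]] <- p[[nm]] * pert[s - 1, ii]
      }
      if (p$T_exp <= p$T_split) p$T_exp <- p$T_split * 1.5
      if (p$T_mig > p$T_split) p$T_mig <- p$T_split
      free_to_internal(spec, do.call(scaled_params, p))
    }
    xs <- pmin(pmax(xs, bounds$lo), bounds$hi)
    opt <- nm_search(xs, objective, maxit)
    starts[[s]] <- list(par = opt$par, value = opt$value,
                        convergence = opt$convergence)
  }
  vals <- vapply(starts, `[[`, 0.0, "value")
  conv <- vapply(starts, `[[`, 0L, "convergence")
  if (all(!is.finite(vals)))
    abort("all optimization starts failed", class = "splitmig_fit_error")

  if (!is.null(n_mc_refine)) {
    obj_ref <- make_objective(n_mc_refine, mc_seed_refine)
    top <- order(vals)[seq_len(min(refine_top, n_starts))]
    refined <- lapply(top, function(s)
      nm_search(starts[[s]]$par, obj_ref, maxit_refine))
    rv <- vapply(refined, `[[`, 0.0, "value")
    best_par <- refined[[which.min(rv)]]$par
    eval_seed <- mc_seed_refine
    eval_n_mc <- n_mc_refine
  } else {
    best_par <- starts[[which.min(vals)]]$par
    eval_seed <- mc_seed
    eval_n_mc <- n_mc
  }
  best_params <- internal_to_params(spec, best_par)
  set.seed(eval_seed)
  E <- cpp_expected_jsfs(n1, n2, sim_par_vec(spec, best_params), eval_n_mc)$mean
  E[1, 1] <- 0; E[n1 + 1, n2 + 1] <- 0
  pl <- poisson_loglik(observed, E)
  structure(list(
    spec = spec, params = best_params, theta_hat = pl$theta_hat,
    loglik = pl$loglik, AIC = 2 * spec$k - 2 * pl$loglik,
    expected_per_theta = E,
    starts = tibble(start = seq_len(n_starts), loglik = -vals,
                    converged = conv == 0L),
    n_mc = n_mc, seed = seed, mc_seed = mc_seed, init = init,
    n1 = n1, n2 = n2, n_obs = sum(unclass(observed))),
    class = "sm_fit")
}

#' @export
print.sm_fit <- function(x, ...) {
  cat("<sm_fit> ", x$spec$name, ": loglik = ", signif(x$loglik, 8),
      ", AIC = ", signif(x$AIC, 8),
      ", theta_hat = ", signif(x$theta_hat, 6), "\n", sep = "")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy methods for model fits
#'
#' `tidy()` returns one row per free parameter; `glance()` one row of fit
#' summaries.
#'
#' @param x An `sm_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy sm_fit
#' @export
tidy.sm_fit <- function(x, ...) {
  est <- unclass(x$params)[x$spec$free_param_names]
  tibble(term = x$spec$free_param_names, estimate = as.double(est))
}

#' @rdname tidy.sm_fit
#' @method glance sm_fit
#' @export
glance.sm_fit <- function(x, ...) {
  tibble(model = x$spec$name, k = x$spec$k, loglik = x$loglik, AIC = x$AIC,
         theta_hat = x$theta_hat, n_starts = nrow(x$starts),
         n_converged = sum(x$starts$converged), n_mc = x$n_mc)
}

#' Rank fitted models by AIC
#'
#' `AIC = 2k - 2 log L`; models are ranked ascending, ties broken by the
#' smaller parameter count (parsimony).
#'
#' @param fits List of `sm_fit` objects fitted to the same observed SFS.
#' @return Tibble `model, k, loglik, AIC, delta_AIC` (ascending AIC) with
#'   the winning `model_spec` in attribute `best`.
#' @export
model_choice <- function(fits) {
  if (length(fits) < 2) abort("model choice needs at least two fits")
  sig <- vapply(fits, function(f) paste(f$n1, f$n2, f$n_obs), "")
  if (length(unique(sig)) != 1)
    abort("fits were computed on different observed data")
  tb <- bind_rows(lapply(fits, glance)) %>%
    select("model", "k", "loglik", "AIC") %>%
    arrange(.data$AIC, .data$k) %>%
    mutate(delta_AIC = .data$AIC - min(.data$AIC))
  attr(tb, "best") <- fits[[which(vapply(fits, function(f)
    f$spec$name, "") == tb$model[1])]]$spec
  tb
}

#' Parametric-bootstrap confidence intervals
#'
#' Simulates `n_boot` pseudo-observed spectra from the fitted model
#' (independent Poisson draws around the fitted expectation, matching the
#' likelihood's own model; `method = "resim"` additionally redraws the
#' Monte-Carlo genealogies), re-fits the same scenario to each, converts
#' every replicate to physical units, and reports 2.5–97.5 percentile
#' intervals.
#'
#' @param fit An `sm_fit` from [fit_model()].
#' @param n_boot Number of bootstrap replicates (default 150).
#' @param scaling A [scaling_config()] for physical conversion.
#' @param n_starts Starts per replicate re-fit (replicates start from the
#'   fitted optimum, so fewer starts suffice).
#' @param n_mc Monte-Carlo genealogies per evaluation in the re-fits
#'   (defaults to the original fit's).
#' @param maxit Iteration cap per re-fit start.
#' @param method `"poisson"` (default) or `"resim"`.
#' @param refit_init `"warm"` starts replicate re-fits at the fitted
#'   optimum; `"original"` re-uses the original fit's initial point, so
#'   the re-estimation replicates the full original procedure (including
#'   any search bias), which percentile intervals then cancel.
#' @param seed Master seed.
#' @param ... Further arguments (e.g. `n_mc_refine`) passed to
#'   [fit_model()] for the replicate re-fits, so the re-estimation
#'   procedure can mirror the original fit.
#' @return Object of class `sm_ci`: list with `ci` (tibble `parameter,
#'   lower, upper, point, point_in_ci`), `estimates` (per-replicate physical
#'   estimates), `n_boot`, `n_failed`.
#' @export
parametric_bootstrap <- function(fit, n_boot = 150, scaling = scaling_config(),
                                 n_starts = 2, n_mc = NULL, maxit = 150,
                                 method = c("poisson", "resim"),
                                 refit_init = c("warm", "original"), seed = 1,
                                 ...) {
  stopifnot(inherits(fit, "sm_fit"))
  method <- match.arg(method)
  refit_init <- match.arg(refit_init)
  init_b <- if (refit_init == "warm" || is.null(fit$init)) fit$params
            else fit$init
  if (is.null(n_mc)) n_mc <- fit$n_mc
  if (n_boot < 10)
    warn("fewer than 10 bootstrap replicates: percentiles are degenerate")
  M <- fit$theta_hat * fit$expected_per_theta
  set.seed(seed)
  rep_seeds <- sample.int(2147483646L, 2 * n_boot)
  rows <- vector("list", n_boot)
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    set.seed(rep_seeds[b])
    Mb <- M
    if (method == "resim") {
      Eb <- cpp_expected_jsfs(fit$n1, fit$n2,
                              sim_par_vec(fit$spec, fit$params), n_mc)$mean
      Eb[1, 1] <- 0; Eb[fit$n1 + 1, fit$n2 + 1] <- 0
      Mb <- fit$theta_hat * Eb
    }
    obs_b <- joint_sfs(matrix(rpois(length(Mb), Mb), nrow(Mb), ncol(Mb)))
    fb <- tryCatch(
      fit_model(fit$spec, obs_b, init = init_b, n_starts = n_starts,
                n_mc = n_mc, maxit = maxit, seed = rep_seeds[n_boot + b],
                ...),
      error = function(e) NULL)
    if (is.null(fb) || !is.finite(fb$loglik)) {
      n_failed <- n_failed + 1L
      next
    }
    ph <- to_physical(fb$params, fb$theta_hat, scaling)
    rows[[b]] <- mutate(ph, replicate = b)
  }
  est <- bind_rows(rows)
  if (n_failed > 0.2 * n_boot)
    abort(paste0(n_failed, "/", n_boot, " bootstrap re-fits failed"),
          class = "splitmig_bootstrap_error", partial = est)
  point <- to_physical(fit$params, fit$theta_hat, scaling)
  ci <- est %>%
    group_by(.data$parameter) %>%
    summarise(lower = quantile(.data$value, 0.025),
              upper = quantile(.data$value, 0.975), .groups = "drop") %>%
    left_join(select(point, "parameter", point = "value"), by = "parameter") %>%
    mutate(point_in_ci = .data$point >= .data$lower & .data$point <= .data$upper)
  ci <- ci[match(point$parameter, ci$parameter), ]
  structure(list(ci = ci, estimates = est, n_boot = n_boot,
                 n_failed = n_failed, method = method, seed = seed),
            class = "sm_ci")
}

#' @export
print.sm_ci <- function(x, ...) {
  cat("<sm_ci> ", x$n_boot, " replicates (", x$n_failed, " failed), ",
      "2.5-97.5% percentile intervals\n", sep = "")
  print(x$ci, n = Inf)
  invisible(x)
}

#' @rdname tidy.sm_fit
#' @method tidy sm_ci
#' @export
tidy.sm_ci <- function(x, ...) x$ci
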