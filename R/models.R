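#' Demographic model scenarios
#'
#' The package fits four two-population scenarios sharing a common backbone:
#' an ancestral population of reference size `N_ANC` undergoes a stepwise
#' expansion to `nu_af * N_ANC` at time `T_exp` (scaled time before present);
#' at `T_split` a derived population splits off, is instantaneously reduced to
#' `nu_bot * N_ANC`, and recovers exponentially to its present size
#' `nu_eu * N_ANC`. The scenarios differ only in gene flow after the split:
#'
#' * `NOMIG` — no migration (5 free parameters),
#' * `SYMIG` — symmetric migration from the split onwards (6),
#' * `ASYMIG` — asymmetric migration from the split onwards (7),
#' * `RASYMIG` — asymmetric migration starting only at `T_mig` (8).
#'
#' Times are in units of `2 * N_ANC` generations before present; sizes are
#' relative to `N_ANC`; migration rates are scaled as `2 * N_ANC * m` and named
#' by their forward direction (`M_AtoE` is gene flow from the ancestral-range
#' population into the derived one).
#'
#' @param name Scenario name, one of `"NOMIG"`, `"SYMIG"`, `"ASYMIG"`,
#'   `"RASYMIG"` (case-insensitive).
#' @return A `model_spec` object: list with `name`, `free_param_names` and `k`
#'   (the free-parameter count used for AIC).
#' @examples
#' model_spec("ASYMIG")$k  # 7
#' @export
model_spec <- function(name) {
  nm <- toupper(as.character(name)[1])
  free <- switch(nm,
    NOMIG   = c("nu_af", "nu_bot", "nu_eu", "T_exp", "T_split"),
    SYMIG   = c("nu_af", "nu_bot", "nu_eu", "T_exp", "T_split", "M_AtoE"),
    ASYMIG  = c("nu_af", "nu_bot", "nu_eu", "T_exp", "T_split", "M_AtoE", "M_EtoA"),
    RASYMIG = c("nu_af", "nu_bot", "nu_eu", "T_exp", "T_split", "M_AtoE", "M_EtoA", "T_mig"),
    abort(paste0("unknown model '", name,
                 "'; valid choices: NOMIG, SYMIG, ASYMIG, RASYMIG"))
  )
  structure(list(name = nm, free_param_names = free, k = length(free)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$name, " (k = ", x$k, ")\n", sep = "")
  cat("  free parameters:", paste(x$free_param_names, collapse = ", "), "\n")
  invisible(x)
}

#' Scaled demographic parameters
#'
#' Bundles the demographic parameters in coalescent units (see
#' [model_spec()] for units). For scenarios without a migration onset the
#' `T_mig` slot defaults to `T_split` (migration active since the split);
#' for `NOMIG`-style use set both migration rates to zero.
#'
#' @param nu_af Post-expansion ancestral-population size relative to `N_ANC`.
#' @param nu_bot Derived-population bottleneck size relative to `N_ANC`.
#' @param nu_eu Present derived-population size relative to `N_ANC`.
#' @param T_exp Time of the stepwise ancestral expansion (scaled).
#' @param T_split Population split time (scaled); must be `< T_exp`.
#' @param M_AtoE,M_EtoA Scaled migration rates `2 * N_ANC * m`, named by
#'   forward direction.
#' @param T_mig Migration onset time (scaled, `RASYMIG` only); `NULL` means
#'   `T_split`.
#' @return Named numeric vector of class `scaled_params`.
#' @examples
#' p <- scaled_params(nu_af = 4.08, nu_bot = 0.089, nu_eu = 0.875,
#'                    T_exp = 0.551, T_split = 0.175,
#'                    M_AtoE = 0.4, M_EtoA = 1.23)
#' @export
scaled_params <- function(nu_af, nu_bot, nu_eu, T_exp, T_split,
                          M_AtoE = 0, M_EtoA = 0, T_mig = NULL) {
  if (is.null(T_mig)) T_mig <- T_split
  p <- c(nu_af = nu_af, nu_bot = nu_bot, nu_eu = nu_eu,
         T_exp = T_exp, T_split = T_split,
         M_AtoE = M_AtoE, M_EtoA = M_EtoA, T_mig = T_mig)
  structure(as.double(p), names = names(p), class = "scaled_params")
}

param_names_all <- function() {
  c("nu_af", "nu_bot", "nu_eu", "T_exp", "T_split", "M_AtoE", "M_EtoA", "T_mig")
}

#' Parameters of the best-fit autosomal model, in scaled units
#'
#' A convenient default parameter set in the regime the package targets:
#' a ~4x expanded ancestral range, a strong derived-population bottleneck
#' (~0.09 of `N_ANC`) with recovery to ~0.9, a recent split (~0.18 scaled)
#' and asymmetric gene flow of order one.
#'
#' @return A `scaled_params` vector.
#' @export
default_asymig_params <- function() {
  scaled_params(nu_af = 4.083, nu_bot = 0.0892, nu_eu = 0.8752,
                T_exp = 0.5511, T_split = 0.17504,
                M_AtoE = 0.4, M_EtoA = 1.23)
}

#' Validate scaled parameters against a model scenario
#'
#' Report-style validation: returns a tibble of violated invariants (zero
#' rows means the parameter set is admissible under the scenario).
#'
#' @param spec A [model_spec()].
#' @param params A [scaled_params()] vector.
#' @return Tibble with columns `invariant` and `message`; zero rows if valid.
#' @export
validate_params <- function(spec, params) {
  stopifnot(inherits(spec, "model_spec"))
  p <- as.list(unclass(params))
  v <- list()
  bad <- function(inv, msg) tibble(invariant = inv, message = msg)
  for (nm in c("nu_af", "nu_bot", "nu_eu")) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      v <- c(v, list(bad(nm, paste0(nm, ": size must be > 0"))))
  }
  for (nm in c("T_exp", "T_split")) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      v <- c(v, list(bad(nm, paste0(nm, ": time must be > 0"))))
  }
  for (nm in c("M_AtoE", "M_EtoA")) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      v <- c(v, list(bad(nm, paste0(nm, ": migration rate must be >= 0"))))
  }
  if (is.finite(p$T_exp) && is.finite(p$T_split) && p$T_exp <= p$T_split)
    v <- c(v, list(bad("T_exp > T_split",
                       "expansion must predate the split (T_exp > T_split)")))
  if (spec$name == "NOMIG" && (p$M_AtoE != 0 || p$M_EtoA != 0))
    v <- c(v, list(bad("NOMIG migration", "NOMIG requires M_AtoE = M_EtoA = 0")))
  if (spec$name == "SYMIG" && p$M_AtoE != p$M_EtoA)
    v <- c(v, list(bad("SYMIG symmetry", "SYMIG requires M_AtoE = M_EtoA")))
  if (spec$name == "RASYMIG") {
    if (!is.finite(p$T_mig) || p$T_mig <= 0)
      v <- c(v, list(bad("T_mig", "T_mig: time must be > 0")))
    else if (p$T_mig > p$T_split)
      v <- c(v, list(bad("T_mig <= T_split",
                         "migration onset must not predate the split (T_mig <= T_split)")))
  }
  if (length(v) == 0) tibble(invariant = character(), message = character())
  else bind_rows(v)
}

stop_if_invalid <- function(spec, params) {
  rep <- validate_params(spec, params)
  if (nrow(rep) > 0)
    abort(paste0("invalid parameters for ", spec$name, ": ",
                 paste(rep$message, collapse = "; ")))
  invisible(TRUE)
}

#' Relative population size through time
#'
#' Size trajectory (relative to `N_ANC`) of either population at scaled time
#' `t` before present. The ancestral population ("AF") has size `nu_af` more
#' recently than `T_exp` and 1 earlier; the derived population ("EU")
#' interpolates exponentially between `nu_eu` at present and `nu_bot` at the
#' split, and does not exist for `t >= T_split`.
#'
#' @inheritParams validate_params
#' @param pop `"AF"` or `"EU"`.
#' @param t Scaled time(s) before present.
#' @return Numeric vector of relative sizes, same length as `t`.
#' @export
size_trajectory <- function(spec, params, pop = c("AF", "EU"), t) {
  pop <- match.arg(pop)
  stop_if_invalid(spec, params)
  p <- as.list(unclass(params))
  if (any(t < 0)) abort("t must be >= 0")
  if (pop == "AF") {
    ifelse(t < p$T_exp, p$nu_af, 1.0)
  } else {
    if (any(t >= p$T_split))
      abort("derived population does not exist at t >= T_split")
    p$nu_eu * (p$nu_bot / p$nu_eu)^(t / p$T_split)
  }
}

#' Backward migration-rate matrix at a time point
#'
#' Returns the 2x2 matrix of scaled per-lineage backward migration rates at
#' scaled time `t < T_split`; entry `[from, to]` is the rate at which a
#' lineage currently in `from` jumps (backwards in time) to `to`. By the
#' package's convention that rate equals the scaled forward rate into `from`.
#'
#' @inheritParams size_trajectory
#' @return 2x2 numeric matrix with dimnames `AF`/`EU`.
#' @export
migration_matrix <- function(spec, params, t) {
  stop_if_invalid(spec, params)
  p <- as.list(unclass(params))
  if (length(t) != 1L) abort("t must be a single time point")
  if (t >= p$T_split) abort("a single population exists at t >= T_split")
  active <- switch(spec$name,
    NOMIG = FALSE,
    RASYMIG = t < p$T_mig,
    TRUE)
  m <- matrix(0, 2, 2, dimnames = list(c("AF", "EU"), c("AF", "EU")))
  if (active) {
    m["AF", "EU"] <- p$M_EtoA
    m["EU", "AF"] <- p$M_AtoE
  }
  m
}

#' Scaling constants for unit conversion
#'
#' @param mu Mutation rate per bp per generation (default `5.21e-9`, the
#'   empirical single-nucleotide rate for *Drosophila melanogaster*
#'   autosomes).
#' @param gens_per_year Generations per year (default 15).
#' @param L Effective sequence length in bp contributing to the SFS
#'   (default `4020733`, the autosomal intronic callable length of the
#'   motivating dataset; use `5859268` for the X).
#' @return List of class `scaling_config`.
#' @export
scaling_config <- function(mu = 5.21e-9, gens_per_year = 15, L = 4020733) {
  if (!all(is.finite(c(mu, gens_per_year, L))) ||
      any(c(mu, gens_per_year, L) <= 0))
    abort("all scaling constants must be strictly positive")
  structure(list(mu = mu, gens_per_year = gens_per_year, L = L),
            class = "scaling_config")
}

#' Convert scaled parameters to physical units
#'
#' `N_ANC` is recovered from the fitted mutation parameter as
#' `theta_hat / (4 * mu * L)`; sizes scale by `N_ANC`; scaled times convert
#' to years as `T * 2 * N_ANC / gens_per_year`; scaled migration rates
#' (`2 * N_ANC * m`) are reported unchanged.
#'
#' @param params A [scaled_params()] vector.
#' @param theta_hat Fitted population mutation parameter `4 * N_ANC * mu * L`.
#' @param scaling A [scaling_config()].
#' @return Tibble with columns `parameter`, `value`, `unit`.
#' @examples
#' to_physical(default_asymig_params(), theta_hat = 14860, scaling_config())
#' @export
to_physical <- function(params, theta_hat, scaling = scaling_config()) {
  stopifnot(inherits(scaling, "scaling_config"))
  if (!is.finite(theta_hat) || theta_hat <= 0) abort("theta_hat must be > 0")
  p <- as.list(unclass(params))
  if (any(unlist(p[c("nu_af", "nu_bot", "nu_eu", "T_exp", "T_split")]) <= 0))
    abort("sizes and times must be > 0")
  N_anc <- theta_hat / (4 * scaling$mu * scaling$L)
  yrs <- function(T_scaled) T_scaled * 2 * N_anc / scaling$gens_per_year
  tibble(
    parameter = c("N_ANC", "N_AF", "N_BOT", "N_EU",
                  "T_split_years", "T_exp_years", "T_mig_years",
                  "M_AtoE", "M_EtoA"),
    value = c(N_anc, p$nu_af * N_anc, p$nu_bot * N_anc, p$nu_eu * N_anc,
              yrs(p$T_split), yrs(p$T_exp), yrs(p$T_mig),
              p$M_AtoE, p$M_EtoA),
    unit = c(rep("individuals", 4), rep("years", 3), rep("2*N_ANC*m", 2))
  )
}

#' Invert [to_physical()]
#'
#' @param physical Tibble as returned by [to_physical()].
#' @param scaling The [scaling_config()] used for the forward conversion.
#' @return List with elements `params` ([scaled_params()]) and `theta_hat`.
#' @export
from_physical <- function(physical, scaling = scaling_config()) {
  v <- setNames(physical$value, physical$parameter)
  N_anc <- v[["N_ANC"]]
  sc <- function(T_years) T_years * scaling$gens_per_year / (2 * N_anc)
  list(
    params = scaled_params(
      nu_af = v[["N_AF"]] / N_anc, nu_bot = v[["N_BOT"]] / N_anc,
      nu_eu = v[["N_EU"]] / N_anc,
      T_exp = sc(v[["T_exp_years"]]), T_split = sc(v[["T_split_years"]]),
      M_AtoE = v[["M_AtoE"]], M_EtoA = v[["M_EtoA"]],
      T_mig = sc(v[["T_mig_years"]])),
    theta_hat = 4 * N_anc * scaling$mu * scaling$L
  )
}

#' Write / read a model configuration as flat key-value text
#'
#' Serializes the scenario name and scaled parameter values to a plain-text
#' `key<TAB>value` file; `read_model_config()` inverts it.
#'
#' @param spec A [model_spec()]; `params` a [scaled_params()] vector.
#' @param params Parameter vector.
#' @param path Output path.
#' @return `write_model_config()` returns `path` invisibly;
#'   `read_model_config()` a list with `spec` and `params`.
#' @export
write_model_config <- function(spec, params, path) {
  ln <- c(paste0("model\t", spec$name),
          paste0("time_unit\t2*N_ANC generations"),
          paste0(names(unclass(params)), "\t",
                 formatC(as.double(params), digits = 17, format = "g")))
  writeLines(ln, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  ln <- readLines(path)
  kv <- strsplit(ln, "\t", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  spec <- model_spec(vals[keys == "model"])
  num <- setNames(as.double(vals[keys %in% param_names_all()]),
                  keys[keys %in% param_names_all()])
  params <- do.call(scaled_params, as.list(num))
  list(spec = spec, params = params)
}

# Map scaled params to the simulator's internal parameter vector:
# (nu_af, nu_bot, nu_eu, T_exp, T_split, backward rate in AF, in EU, T_mig).
# A lineage in AF traces ancestry abroad at the forward rate into AF (M_EtoA);
# symmetrically for EU.
sim_par_vec <- function(spec, params) {
  p <- as.list(unclass(params))
  active_T_mig <- switch(spec$name,
    NOMIG = 0.0,
    RASYMIG = p$T_mig,
    p$T_split)
  c(p$nu_af, p$nu_bot, p$nu_eu, p$T_exp, p$T_split,
    p$M_EtoA, p$M_AtoE, active_T_mig)
}
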