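# Per-tree coalescence-event table with lineage group states.
# A lineage is "1" while all its descendant leaves belong to group 1, "2"
# for group 2, and "mixed" once it carries both. Event categories:
# within1 (1+1), within2 (2+2), cross (1+2), mixed (any pair involving a
# mixed lineage). Every coalescence belongs to exactly one category.
tree_coal_events <- function(tree, groups) {
  n <- tree$n1 + tree$n2
  m <- 2L * n - 1L
  state <- integer(m)            # 1, 2, or 3 = mixed
  state[seq_len(n)] <- groups
  kids <- matrix(0L, m, 2L)
  slot <- integer(m)
  for (v in seq_len(m - 1L)) {
    p <- tree$parent[v]
    slot[p] <- slot[p] + 1L
    kids[p, slot[p]] <- v
  }
  ev_cat <- integer(n - 1L)
  ev_s1 <- integer(n - 1L)
  ev_s2 <- integer(n - 1L)
  for (u in (n + 1L):m) {
    s1 <- state[kids[u, 1L]]; s2 <- state[kids[u, 2L]]
    state[u] <- if (s1 == s2 && s1 != 3L) s1 else 3L
    ev_cat[u - n] <- if (s1 == 3L || s2 == 3L) 4L
                     else if (s1 == s2) s1
                     else 3L   # cross
    ev_s1[u - n] <- s1
    ev_s2[u - n] <- s2
  }
  list(time = tree$time[(n + 1L):m], cat = ev_cat, s1 = ev_s1, s2 = ev_s2)
}

pair_counts <- function(k1, k2, k3) {
  cbind(within1 = k1 * (k1 - 1) / 2,
        within2 = k2 * (k2 - 1) / 2,
        cross = k1 * k2,
        mixed = k3 * (k1 + k2) + k3 * (k3 - 1) / 2)
}

#' Time-binned coalescence rates within and across two groups
#'
#' Hazard-style estimator from simulated genealogies: for each time bin and
#' category (within group 1, within group 2, cross, and events involving
#' mixed-ancestry lineages) the rate is the number of coalescence events of
#' that category in the bin divided by the integrated number of available
#' lineage pairs of that category over the bin, summed over genealogies. A
#' lineage counts toward group 1 (2) while all its descendant leaves belong
#' to that group.
#'
#' @param trees List of `coal_tree` genealogies.
#' @param groups Optional integer vector (1/2, one per leaf) assigning
#'   leaves to groups; defaults to the simulated population labels. Labels
#'   need not follow the simulated demes, so a panmictic sample can be
#'   split arbitrarily.
#' @param bins Numeric vector of strictly increasing bin edges (scaled
#'   time). Default: 20 logarithmically spaced bins between the 1st and
#'   99th percentiles of the observed coalescence times.
#' @param n_bins Number of default bins.
#' @return A tibble of class `rate_trajectory`: per bin, event counts and
#'   pair-exposures per category, the three rates, and the relative
#'   cross-coalescence rate `rccr = 2 * cross / (within1 + within2)`
#'   (`NA` with `rccr_defined = FALSE` where both within rates are zero or
#'   the exposure is empty).
#' @export
coalescence_rates <- function(trees, groups = NULL, bins = NULL, n_bins = 20) {
  if (length(trees) < 1) abort("need at least one genealogy")
  tr1 <- trees[[1]]
  n <- tr1$n1 + tr1$n2
  if (is.null(groups)) {
    if (tr1$n2 == 0)
      abort("single-population genealogies need an explicit group labelling")
    groups <- c(rep(1L, tr1$n1), rep(2L, tr1$n2))
  }
  if (length(groups) != n || !all(groups %in% 1:2))
    abort("groups must assign each leaf to group 1 or 2")
  ev <- lapply(trees, tree_coal_events, groups = groups)
  all_times <- unlist(lapply(ev, `[[`, "time"))
  if (is.null(bins)) {
    q <- quantile(all_times, c(0.01, 0.99))
    if (q[1] <= 0) q[1] <- min(all_times[all_times > 0])
    bins <- exp(seq(log(q[[1]]), log(q[[2]]), length.out = n_bins + 1))
  }
  if (length(bins) < 2 || is.unsorted(bins, strictly = TRUE))
    abort("bins must be strictly increasing with >= 2 edges")

  nb <- length(bins) - 1L
  cats <- c("within1", "within2", "cross", "mixed")
  events <- matrix(0, nb, 4, dimnames = list(NULL, cats))
  expo <- matrix(0, nb, 4, dimnames = list(NULL, cats))
  n1g <- sum(groups == 1L); n2g <- sum(groups == 2L)

  # piecewise-constant pair counts between consecutive events, all trees
  # stacked into flat segment vectors
  seg_s_l <- seg_e_l <- seg_pc_l <- ev_t_l <- ev_c_l <- vector("list", length(ev))
  ii <- 0L
  for (e in ev) {
    ii <- ii + 1L
    tt <- c(0, e$time)
    k1 <- n1g; k2 <- n2g; k3 <- 0
    K <- matrix(0, n - 1L, 3L)
    for (r in seq_len(n - 1L)) {
      K[r, ] <- c(k1, k2, k3)
      # the merge removes the two child lineages and adds the parent
      for (s in c(e$s1[r], e$s2[r])) {
        if (s == 1L) k1 <- k1 - 1L
        else if (s == 2L) k2 <- k2 - 1L
        else k3 <- k3 - 1L
      }
      par_state <- if (e$s1[r] == e$s2[r] && e$s1[r] != 3L) e$s1[r] else 3L
      if (par_state == 1L) k1 <- k1 + 1L
      else if (par_state == 2L) k2 <- k2 + 1L
      else k3 <- k3 + 1L
    }
    seg_s_l[[ii]] <- tt[-length(tt)]
    seg_e_l[[ii]] <- tt[-1]
    seg_pc_l[[ii]] <- K
    ev_t_l[[ii]] <- e$time
    ev_c_l[[ii]] <- e$cat
  }
  seg_s <- unlist(seg_s_l); seg_e <- unlist(seg_e_l)
  seg_pc <- do.call(rbind, seg_pc_l)
  ev_t <- unlist(ev_t_l); ev_c <- unlist(ev_c_l)
  pc <- pair_counts(seg_pc[, 1], seg_pc[, 2], seg_pc[, 3])
  for (bb in seq_len(nb)) {
    ov <- pmax(0, pmin(seg_e, bins[bb + 1]) - pmax(seg_s, bins[bb]))
    expo[bb, ] <- colSums(pc * ov)
    inb <- ev_t >= bins[bb] & ev_t < bins[bb + 1]
    events[bb, ] <- tabulate(ev_c[inb], nbins = 4)
  }
  out <- tibble(bin = seq_len(nb), t_lo = bins[-length(bins)], t_hi = bins[-1])
  for (cc in cats) {
    out[[paste0("events_", cc)]] <- unname(events[, cc])
    out[[paste0("exposure_", cc)]] <- unname(expo[, cc])
  }
  out <- out %>%
    mutate(rate_within1 = ifelse(.data$exposure_within1 > 0,
                                 .data$events_within1 / .data$exposure_within1, NA),
           rate_within2 = ifelse(.data$exposure_within2 > 0,
                                 .data$events_within2 / .data$exposure_within2, NA),
           rate_cross = ifelse(.data$exposure_cross > 0,
                               .data$events_cross / .data$exposure_cross, NA))
  out <- mutate(out,
    rccr_defined = !is.na(.data$rate_within1) & !is.na(.data$rate_within2) &
      !is.na(.data$rate_cross) &
      (.data$rate_within1 + .data$rate_within2) > 0,
    rccr = ifelse(.data$rccr_defined,
                  2 * .data$rate_cross /
                    (.data$rate_within1 + .data$rate_within2), NA))
  class(out) <- c("rate_trajectory", class(out))
  attr(out, "n_trees") <- length(trees)
  out
}

#' Relative cross-coalescence rate per bin
#'
#' `RCCR = 2 * cross / (within1 + within2)`: 1 under panmixia, 0 under
#' complete isolation. Estimation noise can push values slightly above 1;
#' they are flagged, not clipped.
#'
#' @param rt A `rate_trajectory` from [coalescence_rates()], or a tibble
#'   with columns `rate_within1`, `rate_within2`, `rate_cross`.
#' @return Tibble `bin, t_lo, t_hi, rccr, rccr_defined, above_one`.
#' @export
rccr_curve <- function(rt) {
  if (!all(c("rate_within1", "rate_within2", "rate_cross") %in% names(rt)))
    abort("expected a rate_trajectory")
  den <- rt$rate_within1 + rt$rate_within2
  defined <- !is.na(den) & den > 0 & !is.na(rt$rate_cross)
  rccr <- ifelse(defined, 2 * rt$rate_cross / den, NA)
  tibble(bin = rt$bin, t_lo = rt$t_lo, t_hi = rt$t_hi,
         rccr = rccr, rccr_defined = defined,
         above_one = !is.na(rccr) & rccr > 1)
}

#' Rescale coalescence rates to population sizes and years
#'
#' Scaled rates convert to effective sizes as `N_e = N_ref / (2 * rate)`
#' individuals (the per-bin inverse pairwise rate in units of the reference
#' size, halved because time is measured in `2 * N_ref` generations); bin
#' edges convert to years via `t * 2 * N_ref / gens_per_year`. Zero rates
#' yield infinite sizes, flagged rather than raised.
#'
#' @param rt A `rate_trajectory`.
#' @param N_ref Reference (ancestral) population size in individuals; may
#'   be derived from a fitted `theta_hat` via [to_physical()].
#' @param scaling A [scaling_config()].
#' @return The trajectory with added columns `t_lo_years`, `t_hi_years`,
#'   `Ne_within1`, `Ne_within2` and `infinite_size` flag.
#' @export
rescale_rates <- function(rt, N_ref, scaling = scaling_config()) {
  if (!is.finite(N_ref) || N_ref <= 0) abort("N_ref must be > 0")
  yrs <- 2 * N_ref / scaling$gens_per_year
  ne <- function(r) ifelse(!is.na(r) & r > 0, N_ref / (2 * r), Inf)
  mutate(rt,
         t_lo_years = .data$t_lo * yrs,
         t_hi_years = .data$t_hi * yrs,
         Ne_within1 = ne(.data$rate_within1),
         Ne_within2 = ne(.data$rate_within2),
         infinite_size = is.infinite(.data$Ne_within1) |
           is.infinite(.data$Ne_within2))
}

#' Write a rate trajectory as a tab-delimited table
#'
#' @param rt A `rate_trajectory` (optionally rescaled).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(rt, path) {
  utils::write.table(as.data.frame(rt), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
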