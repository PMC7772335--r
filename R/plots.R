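#' Plot a joint SFS as a heatmap
#'
#' @param object A [joint_sfs()].
#' @param trans Count transform for the fill scale (default `log10(1 + x)`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot joint_sfs
#' @export
autoplot.joint_sfs <- function(object, trans = function(x) log10(1 + x), ...) {
  td <- tidy(object)
  td$fill <- trans(td$count)
  td$fill[td$masked] <- NA
  ggplot2::ggplot(td, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$fill)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85",
                                  name = "log10(1 + count)") +
    ggplot2::labs(x = "derived count, population 2",
                  y = "derived count, population 1",
                  title = "Joint site frequency spectrum") +
    ggplot2::theme_minimal()
}

#' Plot observed vs fitted marginal spectra for a model fit
#'
#' @param object An `sm_fit`.
#' @param observed The [joint_sfs()] the model was fitted to.
#' @param ... Unused.
#' @return A ggplot object comparing observed and fitted marginal 1D
#'   spectra for both populations.
#' @method autoplot sm_fit
#' @export
autoplot.sm_fit <- function(object, observed, ...) {
  fitted <- joint_sfs(object$theta_hat * object$expected_per_theta)
  long <- function(jsfs, which) {
    bind_rows(
      tibble(pop = "population 1", freq = seq_len(object$n1 - 1),
             count = unclass(marginal_sfs(jsfs, 1))[2:object$n1], set = which),
      tibble(pop = "population 2", freq = seq_len(object$n2 - 1),
             count = unclass(marginal_sfs(jsfs, 2))[2:object$n2], set = which))
  }
  df <- bind_rows(long(observed, "observed"), long(fitted, "fitted"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$count,
                                   fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~pop, scales = "free_y") +
    ggplot2::labs(x = "derived-allele count", y = "sites",
                  title = paste0("Marginal SFS fit (", object$spec$name, ")")) +
    ggplot2::theme_minimal()
}

#' Plot a cross-coalescence-rate trajectory
#'
#' @param object A `rate_trajectory` from [coalescence_rates()].
#' @param ... Unused.
#' @return A ggplot of the per-bin RCCR on a log time axis, with the
#'   panmixia (1) and isolation (0) reference levels.
#' @method autoplot rate_trajectory
#' @export
autoplot.rate_trajectory <- function(object, ...) {
  df <- rccr_curve(object)
  df$t_mid <- sqrt(df$t_lo * df$t_hi)
  ggplot2::ggplot(df[df$rccr_defined, ],
                  ggplot2::aes(x = .data$t_mid, y = .data$rccr)) +
    ggplot2::geom_hline(yintercept = c(0, 1), linetype = "dotted") +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "scaled time before present",
                  y = "relative cross-coalescence rate",
                  title = "RCCR (1 = panmixia, 0 = isolation)") +
    ggplot2::theme_minimal()
}

#' Plot PCA sample scores
#'
#' @param pca Result of [pca_genotypes()].
#' @return A ggplot of PC1 vs PC2 colored by population.
#' @export
plot_pca <- function(pca) {
  ev <- round(100 * pca$explained_variance[1:2], 1)
  ggplot2::ggplot(pca$scores, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                           colour = .data$pop)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = paste0("PC1 (", ev[1], "%)"),
                  y = paste0("PC2 (", ev[2], "%)"),
                  title = "Genotype PCA") +
    ggplot2::theme_minimal()
}
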