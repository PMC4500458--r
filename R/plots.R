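#' Observed versus predicted relative abundance scatter
#'
#' One point per plot-by-species pair; a perfect model lies on the 1:1 line.
#'
#' @param obs Relative-abundance tibble.
#' @param ensemble A `maxent_ensemble` (same plots and species).
#' @return A ggplot object.
#' @export
plot_obs_vs_pred <- function(obs, ensemble) {
  O <- tidyr::pivot_longer(obs[c("plot_id", species_names(obs))], -"plot_id",
                           names_to = "species", values_to = "observed")
  d <- dplyr::left_join(O, predict_abundance(ensemble, long = TRUE),
                        by = c("plot_id", "species"))
  ggplot2::ggplot(d, ggplot2::aes(.data$observed, .data$p_pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "observed relative abundance",
                  y = "predicted relative abundance") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.stepwise_path <- function(object, ...) {
  ggplot2::ggplot(object$steps,
                  ggplot2::aes(.data$n_traits, .data$variance_explained)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(shape = if (object$direction == "forward") 16 else 1,
                        size = 2) +
    ggplot2::labs(x = "number of traits",
                  y = "variance explained",
                  title = paste(object$direction, "stepwise maxent path")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cats_permutation <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(null_stat = object$null_stats),
                  ggplot2::aes(.data$null_stat)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed_stat, colour = "red") +
    ggplot2::labs(x = "null variance explained", y = "count",
                  title = sprintf("permutation test: p = %.3g", object$p_value)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gradient_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$fitted_cwm,
    -dplyr::any_of(c("plot_id", "site_id", "depth_m")),
    names_to = "trait", values_to = "fitted_cwm")
  ggplot2::ggplot(d, ggplot2::aes(.data$depth_m, .data$fitted_cwm)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = "water depth (m)", y = "fitted CWM (fixed effects)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.lambda_trend <- function(object, ...) {
  d <- tidyr::pivot_longer(object$data,
                           -dplyr::any_of(c("plot_id", "site_id", "depth_m")),
                           names_to = "trait", values_to = "lambda")
  ggplot2::ggplot(d, ggplot2::aes(.data$depth_m, .data$lambda,
                                  group = .data$depth_m)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = "water depth (m)", y = expression(lambda)) +
    ggplot2::theme_minimal()
}
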