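#' Plot a population sweep
#'
#' For each filter, shows the mean expected error of both systems (points,
#' joined by a segment) against the performance threshold, faceted by the
#' metacognition threshold, with the fraction of viable populations where
#' the confidence-weighted system wins printed above.
#'
#' @param object A `population_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.population_sweep <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("mean_err_rebacs", "mean_err_cobacs"),
                        names_to = "system", values_to = "mean_error") |>
    dplyr::mutate(system = ifelse(.data$system == "mean_err_rebacs",
                                  "majority vote", "confidence-weighted"))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$min_performance),
                                     y = .data$mean_error,
                                     colour = .data$system,
                                     group = .data$system)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::geom_text(
      data = tibble::as_tibble(object),
      ggplot2::aes(x = factor(.data$min_performance),
                   y = pmax(.data$mean_err_rebacs, .data$mean_err_cobacs),
                   label = sprintf("%.0f%%", 100 * .data$frac_cobacs_better)),
      inherit.aes = FALSE, vjust = -1, size = 3
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$min_meta), labeller = "label_both") +
    ggplot2::labs(x = "minimum performance", y = "mean expected error",
                  colour = NULL,
                  title = "Crowd error across sampled populations",
                  subtitle = "labels: % of viable populations where the confidence-weighted system wins") +
    ggplot2::theme_minimal()
}

#' Plot a resampled filter evaluation
#'
#' Mean +/- SD of both systems' held-out errors per coupled filter,
#' faceted by the metacognition threshold.
#'
#' @param object A `filter_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.filter_evaluation <- function(object, ...) {
  long <- object$by_filter |>
    dplyr::select("min_performance", "min_meta",
                  "mean_err_rebacs", "sd_err_rebacs",
                  "mean_err_cobacs", "sd_err_cobacs") |>
    tidyr::pivot_longer(-c("min_performance", "min_meta"),
                        names_to = c(".value", "system"),
                        names_pattern = "(mean_err|sd_err)_(.*)") |>
    dplyr::mutate(system = ifelse(.data$system == "rebacs",
                                  "majority vote", "confidence-weighted"))
  pd <- ggplot2::position_dodge(width = 0.03)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$min_performance,
                                     y = .data$mean_err,
                                     colour = .data$system)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_err - .data$sd_err,
                   ymax = .data$mean_err + .data$sd_err),
      position = pd) +
    ggplot2::geom_line(position = pd) +
    ggplot2::facet_wrap(ggplot2::vars(.data$min_meta), labeller = "label_both") +
    ggplot2::labs(x = "minimum performance", y = "held-out crowd error (mean +/- SD)",
                  colour = NULL,
                  title = "Resampled societies: crowd error by filter") +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve from a trial table
#'
#' @param trials A trial tibble.
#' @param order `"type2"` (confidence vs correctness) or `"type1"`.
#' @param c_max Number of confidence levels.
#' @return A ggplot object.
#' @export
plot_roc <- function(trials, order = c("type2", "type1"), c_max = 5L) {
  order <- rlang::arg_match(order)
  pts <- roc_points(trials, order, c_max = c_max)
  a <- auroc(trials, order, c_max = c_max)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$far, y = .data$hr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false alarm rate", y = "hit rate",
      title = sprintf("%s ROC (area = %s)",
                      ifelse(order == "type2", "Type II", "Type I"),
                      ifelse(is.na(a), "undefined", sprintf("%.3f", a)))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a self-estimate calibration table
#'
#' Mean actual accuracy against the self-estimate bin, with the identity
#' line; departures from the diagonal show the direction of miscalibration.
#'
#' @param calibration Output of [dk_calibration()].
#' @return A ggplot object.
#' @export
plot_dk_calibration <- function(calibration) {
  ggplot2::ggplot(calibration,
                  ggplot2::aes(x = .data$mean_self_estimate,
                               y = .data$mean_actual,
                               size = .data$n)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "self-estimated accuracy (bin mean)",
                  y = "actual accuracy (bin mean)", size = "participants",
                  title = "Self-estimate calibration") +
    ggplot2::theme_minimal()
}
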