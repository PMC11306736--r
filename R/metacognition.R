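#' Type I / Type II confusion counts at a threshold
#'
#' Tabulates one 2x2 confusion table from a trial table. For `order =
#' "type1"` the cells cross the response with the true answer: a hit is
#' responding option 2 when option 2 is true, a false alarm is responding
#' option 2 when option 1 is true. For `order = "type2"` the cells cross
#' "confidence at least `threshold`" (the high-confidence report) with the
#' correctness of the response: a Type II hit is a high-confidence correct
#' trial, a Type II false alarm a high-confidence error.
#'
#' @param trials A tibble with columns `truth`, `response` and (for type 2)
#'   `confidence`.
#' @param order `"type1"` or `"type2"`.
#' @param threshold For type 2, the confidence level from which a report
#'   counts as "high" (closed lower bound); must lie in `2..c_max`.
#' @param c_max Number of confidence levels.
#' @return A one-row tibble with columns `order`, `threshold`, `hits`,
#'   `misses`, `false_alarms`, `correct_rejections`; counts sum to the number
#'   of trials.
#' @export
confusion_counts <- function(trials, order = c("type2", "type1"),
                             threshold = NULL, c_max = 5L) {
  order <- rlang::arg_match(order)
  if (nrow(trials) == 0) rlang::abort("`trials` is empty; counts are undefined.")
  truth <- check_options(trials$truth, "truth")
  response <- check_options(trials$response, "response")
  if (order == "type1") {
    hits <- sum(truth == 2L & response == 2L)
    misses <- sum(truth == 2L & response == 1L)
    fas <- sum(truth == 1L & response == 2L)
    crs <- sum(truth == 1L & response == 1L)
    threshold <- NA_integer_
  } else {
    if (is.null(threshold) || length(threshold) != 1 ||
        threshold < 2 || threshold > c_max) {
      rlang::abort("For type 2 counts, `threshold` must lie in 2..c_max.")
    }
    correct <- truth == response
    high <- trials$confidence >= threshold
    hits <- sum(correct & high)
    misses <- sum(correct & !high)
    fas <- sum(!correct & high)
    crs <- sum(!correct & !high)
  }
  tibble::tibble(
    order = order, threshold = as.integer(threshold),
    hits = hits, misses = misses,
    false_alarms = fas, correct_rejections = crs
  )
}

#' ROC points from graded reports
#'
#' Builds the (false-alarm rate, hit rate) pairs swept over all thresholds.
#' For type 2 the thresholds are the confidence levels `c_max .. 2`; for
#' type 1 the binary response yields a single interior point. Points are
#' anchored at (0,0) and (1,1) and sorted by false-alarm rate.
#'
#' @inheritParams confusion_counts
#' @return A tibble with columns `far`, `hr`.
#' @export
roc_points <- function(trials, order = c("type2", "type1"), c_max = 5L) {
  order <- rlang::arg_match(order)
  if (order == "type1") {
    cc <- confusion_counts(trials, "type1")
    hr <- cc$hits / (cc$hits + cc$misses)
    far <- cc$false_alarms / (cc$false_alarms + cc$correct_rejections)
    pts <- tibble::tibble(far = far, hr = hr)
  } else {
    pts <- purrr::map_dfr(seq(c_max, 2L), function(t) {
      cc <- confusion_counts(trials, "type2", threshold = t, c_max = c_max)
      tibble::tibble(
        far = cc$false_alarms / (cc$false_alarms + cc$correct_rejections),
        hr = cc$hits / (cc$hits + cc$misses)
      )
    })
  }
  dplyr::bind_rows(tibble::tibble(far = 0, hr = 0), pts,
                   tibble::tibble(far = 1, hr = 1)) |>
    dplyr::arrange(.data$far, .data$hr)
}

#' Area under the ROC curve (AUROC1 / AUROC2)
#'
#' Trapezoid-rule area under the ROC built by [roc_points()]. The type 1
#' area tracks performance; the type 2 area (AUROC2) is the metacognitive
#' sensitivity score: how well confidence separates a user's own correct
#' from incorrect responses. 0.5 means no discrimination; the archetypes in
#' [agent_params()] attain 0 ("low"), 0.5 ("medium") and 1 ("high") exactly
#' when `lapse = 0`.
#'
#' When the type-2 table is degenerate (no correct or no incorrect trials,
#' so discriminability is unmeasurable) the score is `NA_real_`; such users
#' fail any metacognition filter with a positive threshold.
#'
#' @inheritParams confusion_counts
#' @return A score in `[0, 1]`, or `NA_real_` for a degenerate type-2 table.
#' @export
auroc <- function(trials, order = c("type2", "type1"), c_max = 5L) {
  order <- rlang::arg_match(order)
  if (nrow(trials) == 0) rlang::abort("`trials` is empty; AUROC is undefined.")
  truth <- check_options(trials$truth, "truth")
  response <- check_options(trials$response, "response")
  if (order == "type2") {
    correct <- truth == response
    if (all(correct) || !any(correct)) return(NA_real_)
  } else {
    if (length(unique(truth)) < 2L) return(NA_real_)
  }
  pts <- roc_points(trials, order, c_max = c_max)
  trapezoid_area(pts$far, pts$hr)
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
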