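#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a resampled filter evaluation
#'
#' One row per coupled filter with the mean and spread of both systems'
#' errors, the mean survivor count, and the per-filter one-tailed paired
#' t-test (list-columns of per-repetition results are dropped).
#'
#' @param x A `filter_evaluation` from [resample_filter_evaluate()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.filter_evaluation <- function(x, ...) {
  x$by_filter |>
    dplyr::select(-"errs_rebacs", -"errs_cobacs", -"survivors")
}

#' Glance at a resampled filter evaluation
#'
#' The pooled across-filter one-tailed paired t-test plus the run settings.
#'
#' @inheritParams tidy.filter_evaluation
#' @return A one-row tibble.
#' @export
glance.filter_evaluation <- function(x, ...) {
  dplyr::bind_cols(
    x$pooled,
    tibble::tibble(n_filters = nrow(x$by_filter), n_reps = x$n_reps,
                   frac = x$frac, seed = x$seed)
  )
}

#' Tidy a population sweep
#'
#' @param x A `population_sweep` from [population_sweep()].
#' @param ... Unused.
#' @return The per-filter summary tibble.
#' @export
tidy.population_sweep <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Glance at a population sweep
#'
#' @inheritParams tidy.population_sweep
#' @return A one-row tibble with the sweep size, method, seed, and (for a
#'   single-filter sweep) the headline better-fraction.
#' @export
glance.population_sweep <- function(x, ...) {
  tibble::tibble(
    n_populations = x$n_populations[1],
    n_filters = nrow(x),
    method = attr(x, "method"),
    seed = attr(x, "seed"),
    frac_cobacs_better = if (nrow(x) == 1) x$frac_cobacs_better else NA_real_
  )
}

#' Serialize a system comparison to JSON
#'
#' @param report A one-row tibble from [compare_systems()].
#' @param path Output path; `NULL` returns the JSON string.
#' @param seed Optional seed to record alongside the estimates.
#' @return The JSON string, invisibly when written to `path`.
#' @export
write_system_report <- function(report, path = NULL, seed = NULL) {
  obj <- list(
    err_rebacs = report$err_rebacs,
    err_cobacs = report$err_cobacs,
    n_users_after_filter = report$n_users_after_filter,
    method = report$method,
    seed = seed
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
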