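trial_csv_cols <- function() {
  readr::cols(
    participant_id = readr::col_character(),
    task = readr::col_character(),
    trial_index = readr::col_integer(),
    truth = readr::col_integer(),
    response = readr::col_integer(),
    confidence = readr::col_integer(),
    rt_ms = readr::col_double(),
    category = readr::col_character(),
    self_estimate = readr::col_double()
  )
}

#' Read and validate a trial-level behavioral CSV
#'
#' Expects one row per trial with columns `participant_id`, `task`
#' (`"memory"` or `"tweet"`), `trial_index` (1-based, contiguous within
#' participant and task), `truth` and `response` (options 1/2), `confidence`
#' (`1..c_max`), and optional `rt_ms`, `category`, `self_estimate`. Rows
#' violating the schema are reported with their file line numbers and the
#' read is aborted.
#'
#' @param path Path to a CSV file.
#' @param c_max Number of confidence levels.
#' @return A validated tibble of trials.
#' @export
read_trials_csv <- function(path, c_max = 5L) {
  if (!file.exists(path)) rlang::abort(sprintf("File not found: %s", path))
  trials <- readr::read_csv(path, col_types = trial_csv_cols())
  required <- c("participant_id", "task", "trial_index", "truth", "response", "confidence")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf("Missing required columns: %s", paste(missing_cols, collapse = ", ")))
  }
  validate_trials(trials, c_max = c_max, line_offset = 1L)
  trials
}

#' Write a trial table to CSV
#'
#' Serializes the standard schema columns (extra columns such as ground-truth
#' probabilities from the synthetic generator are dropped).
#'
#' @param trials A trial tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  cols <- c("participant_id", "task", "trial_index", "truth", "response",
            "confidence", "rt_ms", "category", "self_estimate")
  out <- trials[, intersect(cols, names(trials)), drop = FALSE]
  readr::write_csv(out, path, na = "")
  invisible(path)
}

validate_trials <- function(trials, c_max = 5L, line_offset = 0L) {
  bad <- list()
  flag <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx) > 0) {
      lines <- paste(utils::head(idx + line_offset, 5), collapse = ", ")
      bad[[length(bad) + 1]] <<- sprintf("%s (%d rows, e.g. lines %s)", msg, length(idx), lines)
    }
  }
  flag(!(trials$task %in% c("memory", "tweet")), "unknown task label")
  flag(!(trials$truth %in% c(1L, 2L)), "truth outside option codes 1/2")
  flag(!(trials$response %in% c(1L, 2L)), "response outside option codes 1/2")
  flag(is.na(trials$confidence) | trials$confidence < 1L | trials$confidence > c_max,
       sprintf("confidence outside 1..%d", c_max))
  if ("rt_ms" %in% names(trials)) {
    flag(!is.na(trials$rt_ms) & trials$rt_ms <= 0, "non-positive response time")
  }
  ord <- trials |>
    dplyr::group_by(.data$participant_id, .data$task) |>
    dplyr::summarise(ok = identical(as.integer(.data$trial_index),
                                    seq_along(.data$trial_index)),
                     .groups = "drop")
  if (!all(ord$ok)) {
    bad[[length(bad) + 1]] <- sprintf(
      "trial_index not 1..n in presentation order for: %s",
      paste(utils::head(ord$participant_id[!ord$ok], 5), collapse = ", ")
    )
  }
  if (length(bad) > 0) {
    rlang::abort(c("Malformed trial table:", stats::setNames(unlist(bad), rep("x", length(bad)))))
  }
  invisible(trials)
}

#' Accuracy over the first trials of a table
#'
#' The pre-test performance score: accuracy over the first `n_trials` trials
#' in presentation order.
#'
#' @param trials One participant's trial tibble.
#' @param n_trials Number of leading trials to score (default 30).
#' @return Accuracy in `[0, 1]`.
#' @export
performance_score <- function(trials, n_trials = 30L) {
  if (nrow(trials) < n_trials) {
    rlang::abort(sprintf("Need at least %d trials in presentation order.", n_trials))
  }
  head_trials <- trials[order(trials$trial_index), ][seq_len(n_trials), ]
  mean(head_trials$truth == head_trials$response)
}

#' Per-participant performance and metacognition scores
#'
#' Builds the score table the filter pipeline works from: the performance
#' score is accuracy over the first `n_perf_trials` tweet-task trials, the
#' metacognition score is the memory-task AUROC2 (possibly `NA` when
#' degenerate), plus the overall tweet accuracy and, when present, the
#' end-of-task self-estimate.
#'
#' @param trials A combined trial tibble with `task` column.
#' @param n_perf_trials Leading tweet trials used for the performance score.
#' @param c_max Number of confidence levels.
#' @return A tibble with one row per participant: `participant_id`,
#'   `perf_score`, `meta_score`, `acc_tweet`, `self_estimate`.
#' @export
participant_scores <- function(trials, n_perf_trials = 30L, c_max = 5L) {
  tweet <- trials |> dplyr::filter(.data$task == "tweet")
  memory <- trials |> dplyr::filter(.data$task == "memory")
  perf <- tweet |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::arrange(.data$trial_index, .by_group = TRUE) |>
    dplyr::summarise(
      perf_score = mean((.data$truth == .data$response)[seq_len(min(n_perf_trials, dplyr::n()))]),
      acc_tweet = mean(.data$truth == .data$response),
      self_estimate = if ("self_estimate" %in% names(tweet))
        dplyr::first(stats::na.omit(.data$self_estimate)) else NA_real_,
      .groups = "drop"
    )
  meta <- memory |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      meta_score = auroc(dplyr::pick(dplyr::everything()), "type2", c_max = c_max),
      .groups = "drop"
    )
  dplyr::left_join(perf, meta, by = "participant_id") |>
    dplyr::select("participant_id", "perf_score", "meta_score",
                  "acc_tweet", "self_estimate")
}

#' Split-half consistency of the performance score
#'
#' Pearson correlation, across participants, between accuracy on the first
#' `split` tweet-task trials and accuracy on the remaining trials — the check
#' that the short pre-test score predicts held-out performance.
#'
#' @param trials A combined trial tibble (uses the tweet task).
#' @param split Number of leading trials in the first half (default 30).
#' @return A one-row tibble: `estimate` (r), `p_value`, `n_participants`.
#' @export
split_half_correlation <- function(trials, split = 30L) {
  halves <- trials |>
    dplyr::filter(.data$task == "tweet") |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      first = mean((.data$truth == .data$response)[.data$trial_index <= split]),
      rest = mean((.data$truth == .data$response)[.data$trial_index > split]),
      .groups = "drop"
    )
  if (nrow(halves) < 3) rlang::abort("Need at least 3 participants with tweet trials.")
  ct <- stats::cor.test(halves$first, halves$rest)
  tibble::tibble(estimate = unname(ct$estimate), p_value = ct$p.value,
                 n_participants = nrow(halves))
}

#' One-tailed paired t-test (a greater than b)
#'
#' Paired t statistic on the differences `a - b` with the upper-tail
#' p-value. Pairs with a missing entry are dropped. When the differences are
#' all zero the convention `t = 0, p = 0.5` applies; a constant non-zero
#' difference gives an infinite statistic.
#'
#' @param a,b Equal-length paired samples.
#' @return A one-row tibble: `t_statistic`, `p_value`, `df`, `n`.
#' @export
one_tailed_paired_t <- function(a, b) {
  if (length(a) != length(b)) rlang::abort("`a` and `b` must have equal length.")
  keep <- !is.na(a) & !is.na(b)
  d <- a[keep] - b[keep]
  n <- length(d)
  if (n < 2) rlang::abort("Need at least 2 defined pairs.")
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else {
    t_stat <- mean(d) / (sd_d / sqrt(n))
  }
  p <- stats::pt(t_stat, df = n - 1, lower.tail = FALSE)
  tibble::tibble(t_statistic = t_stat, p_value = p, df = n - 1, n = n)
}

#' Resampled filter evaluation of both crowd systems
#'
#' The end-to-end evaluation procedure for trial-level data: repeatedly draw
#' a random society of `floor(frac * N)` participants without replacement,
#' apply each coupled (performance, metacognition) filter to the society,
#' and score the surviving crowd on the held-out tweet questions
#' (`trial_index >= eval_from`) under plain majority voting (`err_rebacs`)
#' and confidence-weighted majority voting (`err_cobacs`). The same sampled
#' society is reused across all filters within a repetition. Repetitions
#' where a filter leaves no survivors record `NA` errors (reported, never
#' imputed).
#'
#' Per filter, a one-tailed paired t-test asks whether the majority-vote
#' error exceeds the confidence-weighted error across repetitions; a pooled
#' test across all filters is also computed.
#'
#' @param trials A combined trial tibble (memory + tweet tasks).
#' @param perf_filters Performance thresholds (default `c(0.4, 0.5, 0.6, 0.7)`).
#' @param meta_filters Metacognition thresholds (default `c(0.5, 0.6, 0.7)`).
#' @param frac Fraction of participants sampled per repetition.
#' @param n_reps Number of repetitions.
#' @param seed Integer seed.
#' @param eval_from First tweet trial index of the held-out evaluation set.
#' @param c_max Number of confidence levels.
#' @return An object of class `filter_evaluation`: a list with `by_filter`
#'   (per-filter summary with per-repetition results nested in list-columns),
#'   `pooled` (the across-filter t-test), and the call settings.
#' @export
resample_filter_evaluate <- function(trials,
                                     perf_filters = c(0.4, 0.5, 0.6, 0.7),
                                     meta_filters = c(0.5, 0.6, 0.7),
                                     frac = 0.6, n_reps = 100L, seed,
                                     eval_from = 31L, c_max = 5L) {
  if (frac <= 0 || frac > 1) rlang::abort("`frac` must lie in (0, 1].")
  check_seed(seed)
  scores <- participant_scores(trials, c_max = c_max)
  ids <- scores$participant_id
  n_sample <- max(1L, floor(frac * length(ids)))

  eval_trials <- trials |>
    dplyr::filter(.data$task == "tweet", .data$trial_index >= eval_from) |>
    dplyr::arrange(.data$participant_id, .data$trial_index)
  if (nrow(eval_trials) == 0) rlang::abort("No held-out tweet trials to evaluate on.")
  qn <- sort(unique(eval_trials$trial_index))
  resp <- matrix(NA_integer_, nrow = length(ids), ncol = length(qn),
                 dimnames = list(ids, qn))
  conf <- resp
  idx <- cbind(match(eval_trials$participant_id, ids),
               match(eval_trials$trial_index, qn))
  resp[idx] <- eval_trials$response
  conf[idx] <- eval_trials$confidence
  truth_q <- eval_trials$truth[match(qn, eval_trials$trial_index)]

  grid <- tidyr::expand_grid(min_meta = meta_filters, min_performance = perf_filters)
  withr::local_seed(seed)
  reps <- purrr::map(seq_len(n_reps), function(rep) {
    society <- sample(ids, n_sample)
    purrr::pmap_dfr(grid, function(min_meta, min_performance) {
      s <- scores[scores$participant_id %in% society, ]
      keep <- s$perf_score >= min_performance &
        !is.na(s$meta_score) & s$meta_score >= min_meta
      survivors <- s$participant_id[keep]
      if (length(survivors) == 0) {
        return(tibble::tibble(rep = rep, min_performance = min_performance,
                              min_meta = min_meta, n_survivors = 0L,
                              err_rebacs = NA_real_, err_cobacs = NA_real_))
      }
      rows <- match(survivors, ids)
      r <- resp[rows, , drop = FALSE]
      cf <- conf[rows, , drop = FALSE]
      count2 <- colSums(r == 2L)
      mv_ans <- ifelse(count2 < nrow(r) / 2, 1L, 2L)
      signed <- ifelse(r == 2L, 1L, -1L) * cf
      wmv_ans <- ifelse(colSums(signed) < 0, 1L, 2L)
      tibble::tibble(
        rep = rep, min_performance = min_performance, min_meta = min_meta,
        n_survivors = length(survivors),
        err_rebacs = 1 - system_accuracy(mv_ans, truth_q),
        err_cobacs = 1 - system_accuracy(wmv_ans, truth_q)
      )
    })
  }) |> dplyr::bind_rows()

  by_filter <- reps |>
    dplyr::group_by(.data$min_performance, .data$min_meta) |>
    dplyr::summarise(
      mean_err_rebacs = mean(.data$err_rebacs, na.rm = TRUE),
      sd_err_rebacs = stats::sd(.data$err_rebacs, na.rm = TRUE),
      mean_err_cobacs = mean(.data$err_cobacs, na.rm = TRUE),
      sd_err_cobacs = stats::sd(.data$err_cobacs, na.rm = TRUE),
      mean_survivors = mean(.data$n_survivors),
      n_reps_defined = sum(!is.na(.data$err_rebacs)),
      t_statistic = tryCatch(
        one_tailed_paired_t(.data$err_rebacs, .data$err_cobacs)$t_statistic,
        error = function(e) NA_real_),
      p_value = tryCatch(
        one_tailed_paired_t(.data$err_rebacs, .data$err_cobacs)$p_value,
        error = function(e) NA_real_),
      errs_rebacs = list(.data$err_rebacs),
      errs_cobacs = list(.data$err_cobacs),
      survivors = list(.data$n_survivors),
      .groups = "drop"
    )
  pooled <- tryCatch(
    one_tailed_paired_t(reps$err_rebacs, reps$err_cobacs),
    error = function(e) tibble::tibble(t_statistic = NA_real_, p_value = NA_real_,
                                       df = NA_real_, n = 0L)
  )
  structure(
    list(by_filter = by_filter, pooled = pooled, reps = reps,
         frac = frac, n_reps = n_reps, seed = seed, eval_from = eval_from),
    class = "filter_evaluation"
  )
}

#' @export
print.filter_evaluation <- function(x, digits = 1, ...) {
  cat(sprintf(
    "Resampled filter evaluation: %d reps, %.0f%% societies, held-out trials from %d\n\n",
    x$n_reps, 100 * x$frac, x$eval_from))
  fmt <- function(m, s) ifelse(is.nan(m) | is.na(m), "-",
                               sprintf("%.*f +/- %.*f", digits, 100 * m, digits, 100 * s))
  tab <- x$by_filter
  for (mm in sort(unique(tab$min_meta))) {
    cat(sprintf("min meta %.1f:\n", mm))
    sub <- tab[tab$min_meta == mm, ]
    sub <- sub[order(sub$min_performance), ]
    cat("  min perf:   ", paste(sprintf("%8.0f%%", 100 * sub$min_performance)), "\n")
    cat("  MV error:   ", paste(sprintf("%14s", fmt(sub$mean_err_rebacs, sub$sd_err_rebacs))), "\n")
    cat("  WMV error:  ", paste(sprintf("%14s", fmt(sub$mean_err_cobacs, sub$sd_err_cobacs))), "\n")
    cat("  survivors:  ", paste(sprintf("%14.1f", sub$mean_survivors)), "\n")
  }
  cat(sprintf("\nPooled one-tailed paired t (MV err > WMV err): t = %.2f, p = %.3g\n",
              x$pooled$t_statistic, x$pooled$p_value))
  invisible(x)
}

#' Calibration table for end-of-task self-estimates
#'
#' Bins participants by their self-estimated accuracy and reports the mean
#' actual accuracy per bin — the summary that exposes Dunning-Kruger-style
#' miscalibration (low self-estimators performing above their estimate and
#' high self-estimators below it).
#'
#' @param scores A tibble with `self_estimate` and `acc_tweet` columns (from
#'   [participant_scores()]).
#' @param breaks Bin edges on the self-estimate scale.
#' @return A tibble with one row per occupied bin: `bin`, `bin_low`,
#'   `bin_high`, `n`, `mean_self_estimate`, `mean_actual`.
#' @export
dk_calibration <- function(scores, breaks = seq(0, 1, by = 0.1)) {
  s <- scores |> dplyr::filter(!is.na(.data$self_estimate))
  if (nrow(s) == 0) rlang::abort("No participants with a self-estimate.")
  bin <- cut(s$self_estimate, breaks = breaks, include.lowest = TRUE, right = FALSE)
  s |>
    dplyr::mutate(bin = bin) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_self_estimate = mean(.data$self_estimate),
      mean_actual = mean(.data$acc_tweet),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      bin_low = breaks[as.integer(.data$bin)],
      bin_high = breaks[as.integer(.data$bin) + 1L]
    ) |>
    dplyr::select("bin", "bin_low", "bin_high", "n",
                  "mean_self_estimate", "mean_actual")
}

#' Per-participant confidence / response-time correlation
#'
#' Pearson correlation between reported confidence and response time within
#' each participant, with two-sided p-values, plus the counts of
#' participants with a negative correlation and with a significantly
#' negative one.
#'
#' @param trials A trial tibble with `rt_ms` present.
#' @param alpha Significance level for the negative-significant count.
#' @return An object of class `rt_correlation`: list with `by_participant`
#'   (tibble of `participant_id`, `estimate`, `p_value`, `n_trials`),
#'   `n_negative`, `n_negative_significant`, `alpha`.
#' @export
confidence_rt_correlation <- function(trials, alpha = 0.05) {
  tr <- trials |> dplyr::filter(!is.na(.data$rt_ms))
  if (nrow(tr) == 0) rlang::abort("No trials with response times.")
  by_p <- tr |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      estimate = if (stats::sd(.data$confidence) == 0 || stats::sd(.data$rt_ms) == 0)
        NA_real_ else stats::cor(.data$confidence, .data$rt_ms),
      p_value = if (stats::sd(.data$confidence) == 0 || stats::sd(.data$rt_ms) == 0)
        NA_real_ else stats::cor.test(.data$confidence, .data$rt_ms)$p.value,
      n_trials = dplyr::n(),
      .groups = "drop"
    )
  structure(
    list(
      by_participant = by_p,
      n_negative = sum(by_p$estimate < 0, na.rm = TRUE),
      n_negative_significant = sum(by_p$estimate < 0 & by_p$p_value < alpha, na.rm = TRUE),
      alpha = alpha
    ),
    class = "rt_correlation"
  )
}

#' @export
print.rt_correlation <- function(x, ...) {
  cat(sprintf(
    "Confidence-RT correlation: %d of %d participants negative, %d significantly (alpha = %g)\n",
    x$n_negative, nrow(x$by_participant), x$n_negative_significant, x$alpha))
  invisible(x)
}

#' Perceived-gender labels for tweets from vote counts
#'
#' A tweet's perceived gender is the side chosen by strictly more than
#' `threshold` (default 60%) of voters; otherwise the tweet is undecided. A
#' tweet is *simple* when its perceived gender matches the actual gender of
#' the account, and *complicated* otherwise (undecided tweets are
#' complicated).
#'
#' @param votes A tibble with columns `n_male`, `n_female`,
#'   `actual_gender` (`"male"`/`"female"`); any id columns are carried
#'   through.
#' @param threshold Vote fraction required to call a gender.
#' @return `votes` with added `perceived_gender` (`"male"`, `"female"`, or
#'   `"undecided"`) and `difficulty` (`"simple"`/`"complicated"`).
#' @export
label_tweet_gender <- function(votes, threshold = 0.6) {
  total <- votes$n_male + votes$n_female
  if (any(total < 1)) rlang::abort("Each tweet needs at least one vote.")
  perceived <- dplyr::case_when(
    votes$n_male / total > threshold ~ "male",
    votes$n_female / total > threshold ~ "female",
    TRUE ~ "undecided"
  )
  votes |>
    dplyr::mutate(
      perceived_gender = perceived,
      difficulty = ifelse(perceived == .data$actual_gender, "simple", "complicated")
    )
}

#' Account-level difficulty labels
#'
#' An account is labeled simple when the majority of its labeled tweets are
#' simple (ties are complicated).
#'
#' @param tweet_labels Output of [label_tweet_gender()] with an `account_id`
#'   column.
#' @return A tibble with one row per account: `account_id`, `n_tweets`,
#'   `n_simple`, `difficulty`.
#' @export
label_accounts <- function(tweet_labels) {
  tweet_labels |>
    dplyr::group_by(.data$account_id) |>
    dplyr::summarise(
      n_tweets = dplyr::n(),
      n_simple = sum(.data$difficulty == "simple"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      difficulty = ifelse(.data$n_simple * 2 > .data$n_tweets, "simple", "complicated")
    )
}
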