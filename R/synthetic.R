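#' Specification of a synthetic behavioral cohort
#'
#' Describes a cohort emulating the structure of the two laboratory tasks:
#' a word-recognition memory task (balanced old/new trials, 5-level
#' confidence) used to score metacognition, and a tweet author-gender task
#' (four balanced difficulty-by-gender categories, response times, an
#' end-of-task self-estimate) used to score performance and run the crowd
#' systems. Only the statistical structure is generated — truth labels,
#' categories, difficulty, confidence, response times — never stimulus
#' content.
#'
#' Defaults mirror the study conditions: 86 participants, 200 memory trials
#' (half "old"), 100 tweet questions (25 per category, the first 30 balanced
#' 15/15 by gender), memory accuracy drawn from a truncated
#' Normal(0.675, 0.074) on (0.5, 1) and tweet accuracy from a truncated
#' Normal(0.618, 0.046) on (0.45, 0.95), matching the observed accuracy
#' bands of the two tasks. "Complicated" tweet categories reduce every
#' agent's evidence separation by `complicated_d_factor`.
#'
#' @param n_participants Cohort size.
#' @param memory_trials Number of recall-phase memory trials (even).
#' @param tweet_questions Number of tweet questions (divisible by 4).
#' @param memory_perf_dist,tweet_perf_dist [perf_dist] descriptors for
#'   per-participant accuracy on each task (the tweet draw applies to the
#'   simple categories).
#' @param archetype_probs Named probabilities over confidence archetypes;
#'   one archetype per participant, shared across tasks.
#' @param rt_base_ms,rt_slope_ms,rt_noise_sd Response-time model:
#'   `rt = base - slope * confidence + Normal(0, noise)`, floored at 200 ms.
#' @param self_estimate_model `"calibrated"` (estimate tracks actual
#'   accuracy with small noise) or `"dk_biased"` (estimates compressed
#'   toward the middle, so low performers overestimate and high performers
#'   underestimate).
#' @param complicated_d_factor Multiplier on the evidence separation in the
#'   complicated tweet categories.
#' @param c_max Number of confidence levels.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 86L,
                        memory_trials = 200L,
                        tweet_questions = 100L,
                        memory_perf_dist = dist_truncnorm(0.675, 0.074, 0.5, 1),
                        tweet_perf_dist = dist_truncnorm(0.618, 0.046, 0.45, 0.95),
                        archetype_probs = c(low = 1 / 3, medium = 1 / 3, high = 1 / 3),
                        rt_base_ms = 4000, rt_slope_ms = 400, rt_noise_sd = 800,
                        self_estimate_model = c("dk_biased", "calibrated"),
                        complicated_d_factor = 0.5,
                        c_max = 5L) {
  self_estimate_model <- rlang::arg_match(self_estimate_model)
  if (tweet_questions %% 4 != 0) rlang::abort("`tweet_questions` must be divisible by 4.")
  if (memory_trials %% 2 != 0) rlang::abort("`memory_trials` must be even (half old, half new).")
  if (!setequal(names(archetype_probs), c("low", "medium", "high")) ||
      abs(sum(archetype_probs) - 1) > 1e-8 || any(archetype_probs < 0)) {
    rlang::abort("`archetype_probs` must be named probabilities over low/medium/high summing to 1.")
  }
  structure(
    list(n_participants = as.integer(n_participants),
         memory_trials = as.integer(memory_trials),
         tweet_questions = as.integer(tweet_questions),
         memory_perf_dist = memory_perf_dist,
         tweet_perf_dist = tweet_perf_dist,
         archetype_probs = archetype_probs[c("low", "medium", "high")],
         rt_base_ms = rt_base_ms, rt_slope_ms = rt_slope_ms,
         rt_noise_sd = rt_noise_sd,
         self_estimate_model = self_estimate_model,
         complicated_d_factor = complicated_d_factor,
         c_max = as.integer(c_max)),
    class = "cohort_spec"
  )
}

#' Draw a synthetic participant roster
#'
#' Assigns each participant a confidence archetype (shared across the two
#' tasks, reflecting the domain-generality of metacognitive ability) and a
#' true accuracy per task, recording the implied evidence separations and
#' the archetype's AUROC2 as recoverable ground truth.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A tibble with one row per participant: `participant_id`,
#'   `archetype`, `auroc2_true`, `perf_memory`, `perf_tweet`, `d_memory`,
#'   `d_tweet`.
#' @export
generate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  check_seed(seed)
  withr::local_seed(seed)
  n <- spec$n_participants
  arch <- sample(c("low", "medium", "high"), n, replace = TRUE,
                 prob = spec$archetype_probs)
  perf_memory <- sample_perf_dist(spec$memory_perf_dist, n)
  perf_tweet <- sample_perf_dist(spec$tweet_perf_dist, n)
  tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    archetype = arch,
    auroc2_true = c(low = 0, medium = 0.5, high = 1)[arch],
    perf_memory = perf_memory,
    perf_tweet = perf_tweet,
    d_memory = 2 * stats::qnorm(perf_memory),
    d_tweet = 2 * stats::qnorm(perf_tweet)
  )
}

rt_from_confidence <- function(confidence, spec, n) {
  pmax(200, spec$rt_base_ms - spec$rt_slope_ms * confidence +
         stats::rnorm(n, 0, spec$rt_noise_sd))
}

#' Generate recall-phase memory-task trials
#'
#' For each participant, a balanced shuffled sequence of "old" (option 1)
#' and "new" (option 2) items answered by their signal-detection agent, with
#' archetype-driven confidence and model-based response times. No feedback
#' is modeled.
#'
#' @param roster Output of [generate_cohort()].
#' @param spec The matching [cohort_spec()].
#' @param seed Integer seed.
#' @return A trial tibble in the standard schema (`task = "memory"`).
#' @export
generate_memory_trials <- function(roster, spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  check_seed(seed)
  withr::local_seed(seed)
  half <- spec$memory_trials / 2
  purrr::pmap_dfr(
    roster[, c("participant_id", "archetype", "perf_memory")],
    function(participant_id, archetype, perf_memory) {
      agent <- symmetric_params_from_performance(
        perf_memory, archetype = archetype, c_max = spec$c_max)
      truths <- sample(rep(c(1L, 2L), each = half))
      tab <- simulate_trials_impl(agent, truths)
      tibble::tibble(
        participant_id = participant_id,
        task = "memory",
        trial_index = tab$trial_index,
        truth = tab$truth,
        response = tab$response,
        confidence = tab$confidence,
        rt_ms = rt_from_confidence(tab$confidence, spec, nrow(tab)),
        category = NA_character_,
        self_estimate = NA_real_
      )
    }
  )
}

# fixed presentation order for the tweet question bank: four balanced
# categories, first 30 positions balanced 15/15 by gender
tweet_question_bank <- function(spec) {
  per_cat <- spec$tweet_questions / 4
  bank <- tidyr::expand_grid(
    gender = c("male", "female"),
    difficulty = c("simple", "complicated"),
    rep = seq_len(per_cat)
  ) |>
    dplyr::mutate(
      question_id = sprintf("Q%03d", dplyr::row_number()),
      truth = ifelse(.data$gender == "male", 1L, 2L),
      category = paste(.data$gender, .data$difficulty, sep = "_")
    )
  male_ids <- sample(bank$question_id[bank$gender == "male"], 15)
  female_ids <- sample(bank$question_id[bank$gender == "female"], 15)
  head_ids <- sample(c(male_ids, female_ids))
  tail_ids <- sample(setdiff(bank$question_id, head_ids))
  bank[match(c(head_ids, tail_ids), bank$question_id), ] |>
    dplyr::mutate(trial_index = dplyr::row_number())
}

#' Generate tweet-task trials with response times and self-estimates
#'
#' Builds one fixed question order for the cohort — four balanced
#' gender-by-difficulty categories, the first 30 trials split 15/15 by
#' gender — then simulates every participant's choices and confidence on it.
#' Complicated categories shrink each agent's evidence separation by the
#' spec's factor, so simple-category accuracy exceeds complicated-category
#' accuracy by construction. Response times follow the linear-in-confidence
#' model; each participant's end-of-task self-estimate follows the spec's
#' calibration model applied to their realized accuracy.
#'
#' The returned tibble carries a `p_correct` column (the true per-trial
#' probability of a correct response) as recoverable ground truth; it is not
#' part of the CSV schema and is dropped by [write_trials_csv()].
#'
#' @inheritParams generate_memory_trials
#' @return A trial tibble in the standard schema (`task = "tweet"`) plus
#'   `p_correct`.
#' @export
generate_tweet_trials <- function(roster, spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  check_seed(seed)
  withr::local_seed(seed)
  bank <- tweet_question_bank(spec)
  purrr::pmap_dfr(
    roster[, c("participant_id", "archetype", "d_tweet")],
    function(participant_id, archetype, d_tweet) {
      d_eff <- d_tweet * ifelse(bank$difficulty == "complicated",
                                spec$complicated_d_factor, 1)
      mu <- ifelse(bank$truth == 1L, -d_eff / 2, d_eff / 2)
      x <- stats::rnorm(nrow(bank), mu, 1)
      response <- ifelse(x <= 0, 1L, 2L)
      correct <- response == bank$truth
      mid <- as.integer(ceiling(spec$c_max / 2))
      confidence <- switch(
        archetype,
        low    = ifelse(correct, 1L, spec$c_max),
        medium = rep(mid, nrow(bank)),
        high   = ifelse(correct, spec$c_max, 1L)
      )
      acc <- mean(correct)
      est <- switch(
        spec$self_estimate_model,
        calibrated = acc + stats::rnorm(1, 0, 0.03),
        dk_biased = 0.575 + 0.3 * (acc - 0.575) + stats::rnorm(1, 0, 0.05)
      )
      tibble::tibble(
        participant_id = participant_id,
        task = "tweet",
        trial_index = bank$trial_index,
        truth = bank$truth,
        response = response,
        confidence = as.integer(confidence),
        rt_ms = rt_from_confidence(confidence, spec, nrow(bank)),
        category = bank$category,
        self_estimate = min(max(est, 0), 1),
        p_correct = stats::pnorm(d_eff / 2)
      )
    }
  )
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper drawing the roster, the memory-task trials and the
#' tweet-task trials with sub-seeds derived from one seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A list with elements `roster`, `memory`, `tweet`, and `trials`
#'   (memory and tweet tables combined, ground-truth columns dropped).
#' @export
generate_cohort_trials <- function(spec = cohort_spec(), seed) {
  check_seed(seed)
  roster <- generate_cohort(spec, seed = seed)
  memory <- generate_memory_trials(roster, spec, seed = seed + 1L)
  tweet <- generate_tweet_trials(roster, spec, seed = seed + 2L)
  trials <- dplyr::bind_rows(memory, dplyr::select(tweet, -"p_correct"))
  list(roster = roster, memory = memory, tweet = tweet, trials = trials)
}
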