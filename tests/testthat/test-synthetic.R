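# Synthetic cohort generator: rosters, memory task, tweet task.

test_that("rosters honor degenerate and stochastic specs", {
  single <- generate_cohort(cohort_spec(n_participants = 1), seed = 1)
  expect_equal(nrow(single), 1)
  expect_true(all(c("participant_id", "archetype", "perf_memory", "perf_tweet",
                    "auroc2_true") %in% names(single)))
  big <- generate_cohort(cohort_spec(n_participants = 1000), seed = 2)
  freq <- table(big$archetype) / 1000
  se <- sqrt((1 / 3) * (2 / 3) / 1000)
  expect_true(all(abs(freq - 1 / 3) < 3 * se))
  expect_true(all(big$perf_memory > 0.5 & big$perf_memory < 1))
  # identical seed, identical roster
  expect_identical(generate_cohort(cohort_spec(), seed = 9),
                   generate_cohort(cohort_spec(), seed = 9))
  expect_error(generate_cohort(cohort_spec(), seed = NULL), "seed")
  expect_error(cohort_spec(tweet_questions = 101), "divisible by 4")
})

test_that("memory tables are balanced and recover archetype metacognition", {
  spec <- cohort_spec(n_participants = 6)
  roster <- generate_cohort(spec, seed = 21)
  memory <- generate_memory_trials(roster, spec, seed = 22)
  per <- memory |> dplyr::group_by(.data$participant_id)
  counts <- per |> dplyr::summarise(n = dplyr::n(),
                                    n_old = sum(.data$truth == 1L))
  expect_true(all(counts$n == 200))
  expect_true(all(counts$n_old == 100))
  metas <- memory |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(m = auroc(dplyr::pick(dplyr::everything())), .groups = "drop") |>
    dplyr::left_join(roster, by = "participant_id")
  expect_equal(metas$m, unname(metas$auroc2_true))
})

test_that("cohort accuracy tracks the configured distribution", {
  spec <- cohort_spec(n_participants = 60)
  roster <- generate_cohort(spec, seed = 41)
  memory <- generate_memory_trials(roster, spec, seed = 42)
  acc <- memory |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(acc = mean(.data$truth == .data$response), .groups = "drop") |>
    dplyr::left_join(roster, by = "participant_id")
  # accuracy given the drawn truth is Binomial(200, perf)/200
  se_cohort <- sqrt(sum(acc$perf_memory * (1 - acc$perf_memory) / 200)) / 60
  expect_lt(abs(mean(acc$acc) - mean(acc$perf_memory)), 3 * se_cohort)
})

test_that("tweet tables have balanced categories and a balanced head", {
  spec <- cohort_spec(n_participants = 3)
  roster <- generate_cohort(spec, seed = 51)
  tweet <- generate_tweet_trials(roster, spec, seed = 52)
  one <- tweet |> dplyr::filter(.data$participant_id == roster$participant_id[1])
  expect_equal(nrow(one), 100)
  expect_equal(as.integer(table(one$category)), rep(25L, 4))
  head30 <- one[one$trial_index <= 30, ]
  expect_equal(sum(head30$truth == 1L), 15)  # 15 male, 15 female
  # all participants share one presentation order
  orders <- tweet |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(sig = paste(.data$category, collapse = "|"), .groups = "drop")
  expect_equal(dplyr::n_distinct(orders$sig), 1)
})

test_that("difficulty manipulation and RT construction leave their signatures", {
  spec <- cohort_spec(n_participants = 40, rt_noise_sd = 1e-9)
  roster <- generate_cohort(spec, seed = 61)
  tweet <- generate_tweet_trials(roster, spec, seed = 62)
  by_diff <- tweet |>
    dplyr::mutate(difficulty = ifelse(grepl("complicated", .data$category),
                                      "complicated", "simple")) |>
    dplyr::group_by(.data$difficulty) |>
    dplyr::summarise(acc = mean(.data$truth == .data$response), .groups = "drop")
  expect_gt(by_diff$acc[by_diff$difficulty == "simple"],
            by_diff$acc[by_diff$difficulty == "complicated"])
  # noiseless RT is strictly linear in confidence: r = -1 per participant
  rc <- confidence_rt_correlation(tweet)
  defined <- rc$by_participant$estimate[!is.na(rc$by_participant$estimate)]
  expect_true(all(abs(defined + 1) < 1e-6))
})

test_that("every generated fixture passes CSV validation unchanged", {
  cohort <- generate_cohort_trials(cohort_spec(n_participants = 5), seed = 71)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials_csv(cohort$trials, path)
  expect_no_error(read_trials_csv(path))
  # per-trial correctness probabilities are honest ground truth
  expect_true(all(cohort$tweet$p_correct > 0 & cohort$tweet$p_correct < 1))
  agg <- cohort$tweet |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(acc = mean(.data$truth == .data$response),
                     expected = mean(.data$p_correct), .groups = "drop")
  expect_lt(max(abs(agg$acc - agg$expected)), 3 * sqrt(0.25 / 100) + 0.05)
})
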