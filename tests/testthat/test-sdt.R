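# Signal-detection agent: Q-function, accuracy closed form, inversion,
# trial simulation.

test_that("q_function is the Gaussian upper tail", {
  expect_equal(q_function(0), 0.5)
  expect_equal(q_function(Inf), 0)
  expect_equal(q_function(-Inf), 1)
  # independent oracle: numerical integration of the standard normal density
  upper_tail <- integrate(function(u) exp(-u^2 / 2) / sqrt(2 * pi),
                          1.96, Inf)$value
  expect_equal(q_function(1.96), upper_tail, tolerance = 1e-8)
  expect_true(all(diff(q_function(seq(-3, 3, 0.5))) < 0))
  expect_error(q_function("a"), "numeric")
})

test_that("closed-form accuracy matches hand-derived cases", {
  # identical evidence distributions: chance, whatever the threshold
  same <- agent_params(mu_1 = 0.3, mu_2 = 0.3, c1 = -0.7, archetype = "medium")
  expect_equal(performance_from_params(same, 0.5), 0.5)
  # unit separation about a central threshold
  a <- agent_params(mu_1 = -1, mu_2 = 1, c1 = 0, archetype = "medium")
  expect_equal(performance_from_params(a, 0.5), pnorm(1), tolerance = 1e-9)
  # degenerate threshold: always answers option 1, accuracy equals prior
  always1 <- agent_params(mu_1 = -1, mu_2 = 1, c1 = Inf, archetype = "medium")
  expect_equal(performance_from_params(always1, 0.3), 0.3)
  # asymmetric prior mixes the two conditional accuracies
  b <- agent_params(mu_1 = -0.4, mu_2 = 0.9, sigma_1 = 1.2, c1 = 0.1,
                    archetype = "medium")
  manual <- 0.25 * pnorm((0.1 - (-0.4)) / 1.2) + 0.75 * pnorm(0.9 - 0.1)
  expect_equal(performance_from_params(b, 0.25), manual, tolerance = 1e-12)
})

test_that("accuracy inversion round-trips and is monotone in separation", {
  for (p in c(0.05, 0.3, 0.5, 0.7, 0.8413, 0.95, 0.999)) {
    params <- symmetric_params_from_performance(p, archetype = "medium")
    expect_equal(performance_from_params(params, 0.5), p, tolerance = 1e-9)
  }
  # chance accuracy means zero separation
  flat <- symmetric_params_from_performance(0.5, archetype = "medium")
  expect_equal(flat$mu_1, 0)
  expect_equal(flat$mu_2, 0)
  # inverse-CDF oracle for the documented example
  expect_equal(symmetric_params_from_performance(pnorm(1), archetype = "medium")$mu_2 * 2,
               2, tolerance = 1e-4)
  expect_error(symmetric_params_from_performance(1), "strictly between")
  expect_error(symmetric_params_from_performance(0), "strictly between")
  seps <- sapply(seq(0.5, 0.95, by = 0.05), function(p)
    symmetric_params_from_performance(p, archetype = "medium")$mu_2)
  expect_true(all(diff(seps) > 0))
})

test_that("simulated accuracy converges to the closed form", {
  truths <- rep(c(1L, 2L), 10000)
  chance <- simulate_trials(symmetric_params_from_performance(0.5 + 1e-12, archetype = "medium"),
                            truths[1:10000], seed = 101)
  expect_lt(abs(mean(chance$truth == chance$response) - 0.5), 3 * sqrt(0.25 / 10000))
  agent <- symmetric_params_from_performance(0.8, archetype = "high")
  tab <- simulate_trials(agent, rep(c(1L, 2L), 10000), seed = 202)
  expect_lt(abs(mean(tab$truth == tab$response) - 0.8),
            3 * sqrt(0.8 * 0.2 / 20000))
})

test_that("archetype and threshold confidence rules behave as defined", {
  truths <- rep(c(1L, 2L), 250)
  med <- simulate_trials(symmetric_params_from_performance(0.7, archetype = "medium"),
                         truths, seed = 5)
  expect_true(all(med$confidence == 3L))
  low <- simulate_trials(symmetric_params_from_performance(0.7, archetype = "low"),
                         truths, seed = 6)
  correct <- low$truth == low$response
  expect_true(all(low$confidence[correct] == 1L))
  expect_true(all(low$confidence[!correct] == 5L))
  thr <- simulate_trials(symmetric_params_from_performance(0.7), truths, seed = 7)
  expect_true(all(thr$confidence %in% 1:5))
  expect_gt(dplyr::n_distinct(thr$confidence), 1)
})

test_that("simulation demands a seed and rejects malformed inputs", {
  a <- symmetric_params_from_performance(0.7, archetype = "medium")
  expect_error(simulate_trials(a, c(1L, 2L)), "seed")
  expect_error(simulate_trials(a, c(1L, 2L), seed = NULL), "seed")
  expect_error(simulate_trials(a, integer(0), seed = 1), "non-empty")
  expect_error(simulate_trials(a, c(1L, 3L), seed = 1), "options 1/2")
  expect_error(agent_params(0, 0, sigma_1 = -1), "positive")
  expect_error(agent_params(0, 0, conf_thresholds_1 = c(2, 1, 3, 4)), "ascending")
})

test_that("the analytic (response, confidence) law matches simulation", {
  for (agent in list(
    symmetric_params_from_performance(0.72, archetype = "low"),
    symmetric_params_from_performance(0.65),
    agent_params(mu_1 = -0.3, mu_2 = 0.8, sigma_2 = 1.4, c1 = 0.2,
                 conf_thresholds_1 = c(0.4, 0.9, 1.3, 2.1),
                 conf_thresholds_2 = c(0.2, 0.8, 1.5, 2.5),
                 lapse = 0.1)
  )) {
    for (truth in c(1L, 2L)) {
      pmf <- response_confidence_pmf(agent, truth)
      expect_equal(sum(pmf), 1, tolerance = 1e-12)
      n <- 40000
      tab <- simulate_trials(agent, rep(truth, n), seed = truth * 11)
      emp <- matrix(0, 2, agent$c_max)
      for (r in 1:2) for (k in seq_len(agent$c_max)) {
        emp[r, k] <- mean(tab$response == r & tab$confidence == k)
      }
      # each cell within 4 binomial SEs of its analytic probability
      se <- sqrt(pmax(pmf * (1 - pmf), 1e-12) / n)
      expect_true(all(abs(emp - pmf) < 4 * se + 1e-3))
    }
  }
})
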