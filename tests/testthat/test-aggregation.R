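# Crowd answer extraction and expected-error computations.

test_that("majority vote follows the count rule with ties to the second option", {
  expect_identical(majority_vote(c(0, 0, 1)), 0L)
  expect_identical(majority_vote(c(0, 1)), 1L)   # tie
  expect_identical(majority_vote(1), 1L)
  set.seed(42)
  for (i in 1:50) {
    v <- sample(0:1, 9, replace = TRUE)
    expect_identical(majority_vote(v), as.integer(sum(v) > sum(1 - v)))
  }
  expect_error(majority_vote(integer(0)), "non-empty")
  expect_error(majority_vote(c(0, 2)), "coded 0/1")
})

test_that("weighted majority vote weighs by raw confidence and ties to +1", {
  expect_identical(weighted_majority_vote(c(-1, 1, 1), c(5, 1, 1)), -1L)
  expect_identical(weighted_majority_vote(c(1, -1), c(2, 2)), 1L)  # zero sum
  expect_error(weighted_majority_vote(c(1, -1), c(2)), "equal length")
  expect_error(weighted_majority_vote(c(1, -1), c(2, 0)), ">= 1")
})

test_that("constant confidence makes WMV identical to MV on random vote sets", {
  set.seed(7)
  for (i in 1:1000) {
    n <- sample(1:15, 1)
    v01 <- sample(0:1, n, replace = TRUE)
    conf <- rep(sample(1:5, 1), n)
    mv <- majority_vote(v01)
    wmv <- weighted_majority_vote(ifelse(v01 == 1, 1L, -1L), conf)
    expect_identical(ifelse(wmv == 1L, 1L, 0L), mv)
  }
})

test_that("system accuracy is the matching fraction", {
  expect_equal(system_accuracy(c(1, 2, 1), c(1, 2, 1)), 1)
  expect_equal(system_accuracy(c(1, 2, 1, 2), c(1, 2, 2, 2)), 0.75)
  set.seed(3)
  ans <- sample(1:2, 200, replace = TRUE)
  tru <- sample(1:2, 200, replace = TRUE)
  expect_equal(system_accuracy(ans, tru), sum(ans == tru) / 200)
  expect_error(system_accuracy(1, c(1, 2)), "equal positive length")
})

test_that("the Poisson-binomial pmf matches binomial and enumeration", {
  expect_equal(poisson_binomial_pmf(rep(0.3, 6)), dbinom(0:6, 6, 0.3),
               tolerance = 1e-12)
  p <- c(0.1, 0.5, 0.9, 0.33)
  pmf <- poisson_binomial_pmf(p)
  expect_equal(sum(pmf), 1, tolerance = 1e-12)
  # enumeration oracle
  manual <- numeric(5)
  for (pattern in 0:15) {
    bits <- as.integer(intToBits(pattern)[1:4])
    manual[sum(bits) + 1] <- manual[sum(bits) + 1] + prod(ifelse(bits == 1, p, 1 - p))
  }
  expect_equal(pmf, manual, tolerance = 1e-12)
})

test_that("exact majority-vote error reproduces hand-derived cases", {
  # a single voter is the crowd
  expect_equal(mv_error_exact(0.2, 0.8, 0.5), 1 - 0.8, tolerance = 1e-12)
  # three users at 80%: crowd correct iff at least two right
  expect_equal(mv_error_exact(rep(0.2, 3), rep(0.8, 3), 0.5),
               1 - (0.8^3 + 3 * 0.8^2 * 0.2), tolerance = 1e-12)
  # heterogeneous small crowds against full 2^N enumeration
  set.seed(11)
  for (n in 2:5) {
    p_a1 <- runif(n)
    p_a2 <- runif(n)
    expect_equal(mv_error_exact(p_a1, p_a2, 0.35),
                 mv_error_enumerate(p_a1, p_a2, 0.35), tolerance = 1e-10)
  }
})

test_that("the normal closed form evaluates its printed bracketing", {
  d <- 2 * qnorm(0.6)
  err <- mv_error_normal(c(-d / 2, d / 2), 100, 0.5)
  expect_equal(err, 0.0206, tolerance = 0.01)
  # direct re-evaluation of the two bracketed terms
  p <- pnorm(d / 2)
  m <- 100 * (1 - p); s <- sqrt(100 * p * (1 - p))
  manual <- 0.5 * (q_function((50 - m) / s) - q_function((100 - m) / s)) +
    0.5 * (q_function(-(100 - m) / s) - q_function((50 - (100 - m)) / s))
  expect_equal(err, manual, tolerance = 1e-12)
  # chance crowd stays near one half
  expect_equal(mv_error_normal(c(0, 0), 1000, 0.5), 0.5, tolerance = 0.01)
})

test_that("normal and exact majority-vote errors agree for large odd crowds", {
  for (p in seq(0.55, 0.9, by = 0.05)) {
    d <- 2 * qnorm(p)
    err_n <- mv_error_normal(c(-d / 2, d / 2), 101, 0.5)
    err_x <- mv_error_exact(rep(1 - p, 101), rep(p, 101), 0.5)
    expect_lt(abs(err_n - err_x), 0.01)
  }
})

test_that("confidence-weighted error moments match the archetype algebra", {
  # medium archetype: constant weights cancel, equal to the plain-vote form
  pop_med <- homogeneous_population(100, 0.6, "medium")
  d <- 2 * qnorm(0.6)
  expect_equal(wmv_error_normal(pop_med), mv_error_normal(c(-d / 2, d / 2), 100),
               tolerance = 1e-9)
  # misleading confidence at decent accuracy drives the crowd wrong
  expect_gt(wmv_error_normal(homogeneous_population(100, 0.7, "low")), 0.99)
  # faithful confidence rescues the crowd
  expect_lt(wmv_error_normal(homogeneous_population(100, 0.7, "high")), 0.001)
  # hand-computed moment for the misleading case: E[r c | correct side] = 6p - 5
  mom_e <- 0.7 * 1 - 0.3 * 5
  expect_equal(mom_e, -0.8)
})

test_that("normal approximation tracks the exact weighted-sum convolution", {
  for (arch in c("low", "medium", "high")) {
    for (p in c(0.55, 0.7)) {
      pop <- homogeneous_population(51, p, arch)
      expect_lt(abs(wmv_error_normal(pop) - wmv_error_exact(pop)), 0.015)
    }
  }
  # mixed-archetype population
  pop <- dplyr::bind_rows(
    homogeneous_population(20, 0.6, "high"),
    homogeneous_population(20, 0.65, "medium"),
    homogeneous_population(11, 0.7, "low")
  )
  expect_lt(abs(wmv_error_normal(pop) - wmv_error_exact(pop)), 0.02)
})

test_that("exact weighted error agrees with brute-force simulation", {
  pop <- dplyr::bind_rows(
    homogeneous_population(3, 0.75, "high"),
    homogeneous_population(2, 0.6, "low")
  )
  pop$user_id <- 1:5
  exact <- wmv_error_exact(pop, 0.5)
  set.seed(19)
  n_q <- 40000
  truths <- sample(1:2, n_q, replace = TRUE)
  wrong <- 0
  votes <- matrix(0, 5, n_q)
  for (u in 1:5) {
    correct <- runif(n_q) < pop$performance[u]
    resp2 <- ifelse(truths == 2, correct, !correct)
    conf <- if (pop$archetype[u] == "high") ifelse(correct, 5, 1) else ifelse(correct, 1, 5)
    votes[u, ] <- ifelse(resp2, 1, -1) * conf
  }
  ans <- ifelse(colSums(votes) < 0, 1L, 2L)
  mc <- mean(ans != truths)
  expect_lt(abs(mc - exact), 3 * sqrt(exact * (1 - exact) / n_q) + 1e-3)
})

test_that("all error outputs stay inside the unit interval", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    pop <- tibble::tibble(
      user_id = 1:n,
      performance = runif(n, 0.05, 0.99),
      archetype = sample(c("low", "medium", "high"), n, replace = TRUE)
    )
    pop$mu_1 <- -qnorm(pop$performance); pop$mu_2 <- qnorm(pop$performance)
    errs <- c(
      mv_error_exact(q_function(-pop$mu_1), q_function(-pop$mu_2)),
      mv_error_normal(c(mean(pop$mu_1), mean(pop$mu_2)), n),
      wmv_error_normal(pop), wmv_error_exact(pop)
    )
    expect_true(all(errs >= 0 & errs <= 1))
  }
})
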