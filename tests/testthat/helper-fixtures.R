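# Shared builders for tests: tiny trial tables and homogeneous populations.

make_trials <- function(truth, response, confidence, rt_ms = NULL) {
  tibble::tibble(
    trial_index = seq_along(truth),
    truth = as.integer(truth),
    response = as.integer(response),
    confidence = as.integer(confidence),
    rt_ms = if (is.null(rt_ms)) NA_real_ else rt_ms
  )
}

# population of n identical symmetric archetype users
homogeneous_population <- function(n, perf, archetype) {
  d <- 2 * qnorm(perf)
  tibble::tibble(
    user_id = seq_len(n),
    performance = perf,
    archetype = archetype,
    mu_1 = -d / 2,
    mu_2 = d / 2,
    auroc2 = c(low = 0, medium = 0.5, high = 1)[archetype],
    c_max = 5L
  )
}

# brute-force expected majority-vote error by enumerating all 2^n vote
# patterns (oracle for the Poisson-binomial path)
mv_error_enumerate <- function(p_vote2_a1, p_vote2_a2, prior_1 = 0.5) {
  n <- length(p_vote2_a1)
  err_side <- function(p, wrong_when) {
    total <- 0
    for (pattern in 0:(2^n - 1)) {
      votes <- as.integer(intToBits(pattern)[1:n])
      prob <- prod(ifelse(votes == 1, p, 1 - p))
      if (wrong_when(sum(votes))) total <- total + prob
    }
    total
  }
  prior_1 * err_side(p_vote2_a1, function(s) s >= n / 2) +
    (1 - prior_1) * err_side(p_vote2_a2, function(s) s < n / 2)
}

# trapezoid AUROC2 by explicit threshold enumeration (oracle for auroc())
auroc2_enumerate <- function(correct, confidence, c_max = 5L) {
  far <- hr <- numeric(0)
  for (t in seq(c_max, 2)) {
    hr <- c(hr, mean(confidence[correct] >= t))
    far <- c(far, mean(confidence[!correct] >= t))
  }
  x <- c(0, sort(far), 1)
  y <- c(0, sort(hr), 1)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}
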