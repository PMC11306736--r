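#' Majority vote over binary-coded responses
#'
#' Crowd answer for one question from responses coded 0 (first option) / 1
#' (second option): the answer is 0 when fewer than half the users chose the
#' second option, and 1 otherwise — so an exact tie resolves to 1.
#'
#' @param responses Integer vector of 0/1 votes.
#' @return 0L or 1L.
#' @export
majority_vote <- function(responses) {
  if (length(responses) == 0) rlang::abort("`responses` must be non-empty.")
  if (!is.numeric(responses) || !all(responses %in% c(0, 1))) {
    rlang::abort("`responses` must be coded 0/1.")
  }
  if (sum(responses) < length(responses) / 2) 0L else 1L
}

#' Confidence-weighted majority vote
#'
#' Crowd answer from signed responses (-1 first option, +1 second option)
#' weighted by raw integer confidence levels: the answer is -1 when the
#' weighted sum is negative and +1 otherwise (ties resolve to +1, matching
#' the [majority_vote()] tie rule after recoding).
#'
#' @param responses Integer vector of -1/+1 votes.
#' @param confidences Integer vector of confidence levels (>= 1), same length.
#' @return -1L or +1L.
#' @export
weighted_majority_vote <- function(responses, confidences) {
  if (length(responses) != length(confidences)) {
    rlang::abort("`responses` and `confidences` must have equal length.")
  }
  if (length(responses) == 0) rlang::abort("`responses` must be non-empty.")
  if (!all(responses %in% c(-1, 1))) rlang::abort("`responses` must be coded -1/+1.")
  if (!is.numeric(confidences) || any(confidences < 1)) {
    rlang::abort("`confidences` must be >= 1.")
  }
  if (sum(responses * confidences) < 0) -1L else 1L
}

#' Fraction of questions the crowd answered correctly
#'
#' @param crowd_answers,truths Equal-length vectors of options (any
#'   consistent coding).
#' @return Accuracy in `[0, 1]`; the system error is its complement.
#' @export
system_accuracy <- function(crowd_answers, truths) {
  if (length(crowd_answers) != length(truths) || length(truths) == 0) {
    rlang::abort("`crowd_answers` and `truths` must have equal positive length.")
  }
  mean(crowd_answers == truths)
}

#' Poisson-binomial probability mass function
#'
#' Distribution of the number of successes among independent Bernoulli trials
#' with heterogeneous probabilities, via the standard O(n^2) convolution.
#'
#' @param p Vector of success probabilities.
#' @return Numeric vector of length `length(p) + 1` over counts `0..n`.
#' @export
poisson_binomial_pmf <- function(p) {
  if (any(p < 0 | p > 1)) rlang::abort("`p` must be probabilities.")
  f <- 1
  for (pi in p) {
    f <- c(f * (1 - pi), 0) + c(0, f * pi)
  }
  f
}

#' Exact expected majority-vote error
#'
#' Expected error of the majority-vote crowd for heterogeneous users,
#' evaluated exactly: conditional on each truth side, the count of
#' second-option votes is Poisson-binomial, and the crowd errs when that
#' count falls on the wrong side of `N/2` (the tie count `N/2` resolves to
#' the second option, consistent with [majority_vote()]).
#'
#' @param p_vote2_given_a1 Per-user probabilities of voting the second option
#'   when the first option is true.
#' @param p_vote2_given_a2 Per-user probabilities of voting the second option
#'   when the second option is true.
#' @param prior_1 Prior probability that the first option is true.
#' @return Expected error in `[0, 1]`.
#' @export
mv_error_exact <- function(p_vote2_given_a1, p_vote2_given_a2, prior_1 = 0.5) {
  n <- length(p_vote2_given_a1)
  if (n == 0 || length(p_vote2_given_a2) != n) {
    rlang::abort("Both probability vectors must be non-empty and of equal length.")
  }
  counts <- 0:n
  pmf_a1 <- poisson_binomial_pmf(p_vote2_given_a1)
  pmf_a2 <- poisson_binomial_pmf(p_vote2_given_a2)
  err_a1 <- sum(pmf_a1[counts >= n / 2])  # crowd says option 2, truth is 1
  err_a2 <- sum(pmf_a2[counts < n / 2])   # crowd says option 1, truth is 2
  prior_1 * err_a1 + (1 - prior_1) * err_a2
}

#' Normal-approximation expected majority-vote error (homogenized)
#'
#' The closed form for a population summarized by a single pair of evidence
#' means `mu_bar = (mu_a1, mu_a2)` under the canonical `c = 0`, `sigma = 1`
#' parameterization: each user votes the second option with probability
#' `Q(-mu_i)` on truth side `i`, the vote count is approximated by
#' `Normal(m_i, s_i)` with `m_i = N Q(-mu_i)`,
#' `s_i = sqrt(N Q(-mu_i)(1 - Q(-mu_i)))`, and the error is the normal mass
#' on the wrong side of `N/2`, retaining the range-truncation terms at 0 and
#' `N`:
#' `prior_1 * (Q((N/2 - m_1)/s_1) - Q((N - m_1)/s_1)) +
#'  (1 - prior_1) * (Q(-m_2/s_2) - Q((N/2 - m_2)/s_2))`.
#'
#' For heterogeneous populations prefer the per-user-moment path used by
#' [compare_systems()] (or [mv_error_exact()]): collapsing users to the mean
#' evidence before applying `Q` biases the result.
#'
#' @param mu_bar Numeric pair: mean evidence on truth side 1 and side 2.
#' @param n_users Number of users.
#' @param prior_1 Prior probability of the first option.
#' @return Expected error, clipped to `[0, 1]`.
#' @export
mv_error_normal <- function(mu_bar, n_users, prior_1 = 0.5) {
  stopifnot(length(mu_bar) == 2, n_users >= 1)
  p <- q_function(-mu_bar)  # per-side probability of a second-option vote
  m <- n_users * p
  s <- sqrt(n_users * p * (1 - p))
  err_side <- function(m, s, lo, hi) {
    if (s > 0) q_function((lo - m) / s) - q_function((hi - m) / s)
    else as.numeric(m >= lo && m <= hi)  # degenerate point mass at m
  }
  err_a1 <- err_side(m[1], s[1], n_users / 2, n_users)
  err_a2 <- err_side(m[2], s[2], 0, n_users / 2)
  # the side-2 error band is [0, N/2) written as Q(-m/s) - Q((N/2-m)/s)
  min(max(prior_1 * err_a1 + (1 - prior_1) * err_a2, 0), 1)
}

# Per-user moments of the signed confidence-weighted vote r*c, conditional on
# each truth side. Fast closed forms for symmetric archetype users; the
# generic path integrates the (response, confidence) joint law.
weighted_vote_moments <- function(population, truth) {
  has_params <- "params" %in% names(population) &&
    any(!purrr::map_lgl(population$params, is.null))
  if (!has_params && all(population$archetype %in% c("low", "medium", "high"))) {
    p <- population$performance  # symmetric agents: correct w.p. perf on either side
    arch <- population$archetype
    cm <- if ("c_max" %in% names(population)) population$c_max else 5L
    mid <- ceiling(cm / 2)
    # r*c takes value +conf_correct w.p. p and -conf_wrong w.p. 1-p on side 2
    conf_correct <- ifelse(arch == "low", 1, ifelse(arch == "medium", mid, cm))
    conf_wrong <- ifelse(arch == "low", cm, ifelse(arch == "medium", mid, 1))
    e <- p * conf_correct - (1 - p) * conf_wrong
    e2 <- p * conf_correct^2 + (1 - p) * conf_wrong^2
    if (truth == 1L) e <- -e
    return(list(e = e, e2 = e2))
  }
  agents <- population_agents(population)
  mom <- purrr::map(agents, function(a) {
    pmf <- response_confidence_pmf(a, truth)
    rc <- outer(c(-1, 1), seq_len(a$c_max))
    list(e = sum(rc * pmf), e2 = sum(rc^2 * pmf))
  })
  list(e = purrr::map_dbl(mom, "e"), e2 = purrr::map_dbl(mom, "e2"))
}

#' Normal-approximation expected error of the confidence-weighted crowd
#'
#' Conditional on each truth side (coded -1 for option 1, +1 for option 2),
#' the weighted sum of signed votes `sum(r_n * c_n)` is approximated by a
#' normal with mean `m = sum(E[r_n c_n])` and variance `sum(Var[r_n c_n])`,
#' the per-user moments coming from each user's analytic (response,
#' confidence) joint law. The error is the normal mass landing on the wrong
#' sign (ties at 0 resolve to +1):
#' `prior_1 * Q(-m_{-1}/s_{-1}) + (1 - prior_1) * (1 - Q(-m_{+1}/s_{+1}))`.
#'
#' @param population A population tibble from [sample_population()], or any
#'   tibble with columns `performance` and `archetype` (optionally a `params`
#'   list-column of [agent_params()] for non-archetype users).
#' @param prior_1 Prior probability that the first option (side -1) is true.
#' @return Expected error, clipped to `[0, 1]`.
#' @export
wmv_error_normal <- function(population, prior_1 = 0.5) {
  if (nrow(population) == 0) rlang::abort("`population` must be non-empty.")
  err_side <- function(truth, wrong_sign) {
    mom <- weighted_vote_moments(population, truth)
    m <- sum(mom$e)
    s <- sqrt(sum(mom$e2 - mom$e^2))
    if (s > 0) {
      # mass of the weighted sum on the wrong sign; ties (sum == 0) go to +1
      if (wrong_sign == +1) q_function(-m / s) else 1 - q_function(-m / s)
    } else {
      if (wrong_sign == +1) as.numeric(m >= 0) else as.numeric(m < 0)
    }
  }
  err <- prior_1 * err_side(1L, +1) + (1 - prior_1) * err_side(2L, -1)
  min(max(err, 0), 1)
}

#' Exact expected error of the confidence-weighted crowd
#'
#' Evaluates the distribution of the integer-valued weighted sum
#' `sum(r_n * c_n)` by direct convolution of the per-user laws of `r*c`
#' (support `-c_max..-1, +1..+c_max`), then reads off the mass on the wrong
#' sign for each truth side. Serves as the oracle for [wmv_error_normal()].
#'
#' @inheritParams wmv_error_normal
#' @return Expected error in `[0, 1]`.
#' @export
wmv_error_exact <- function(population, prior_1 = 0.5) {
  if (nrow(population) == 0) rlang::abort("`population` must be non-empty.")
  agents <- population_agents(population)
  cm <- max(purrr::map_int(agents, "c_max"))
  n <- length(agents)
  err_side <- function(truth, wrong_sign) {
    # pmf over sum values -n*cm .. n*cm, index offset n*cm + 1
    width <- 2L * n * cm + 1L
    f <- numeric(width)
    f[n * cm + 1L] <- 1
    for (a in agents) {
      pmf <- response_confidence_pmf(a, truth)
      g <- numeric(width)
      for (k in seq_len(a$c_max)) {
        if (pmf[1, k] > 0) { # r = -1, shift by -k
          g[seq_len(width - k)] <- g[seq_len(width - k)] + pmf[1, k] * f[(k + 1L):width]
        }
        if (pmf[2, k] > 0) { # r = +1, shift by +k
          g[(k + 1L):width] <- g[(k + 1L):width] + pmf[2, k] * f[seq_len(width - k)]
        }
      }
      f <- g
    }
    vals <- (-n * cm):(n * cm)
    if (wrong_sign == +1) sum(f[vals >= 0]) else sum(f[vals < 0])
  }
  err <- prior_1 * err_side(1L, +1) + (1 - prior_1) * err_side(2L, -1)
  min(max(err, 0), 1)
}

# materialize agent_params for every user in a population tibble
population_agents <- function(population) {
  purrr::pmap(
    list(
      perf = population$performance,
      arch = population$archetype,
      custom = if ("params" %in% names(population)) population$params
               else vector("list", nrow(population))
    ),
    function(perf, arch, custom) {
      if (!is.null(custom)) custom
      else symmetric_params_from_performance(perf, archetype = arch)
    }
  )
}
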