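#' Upper-tail standard normal probability
#'
#' The Gaussian Q-function, `Q(z) = Pr(Z > z)` for standard normal `Z`.
#' All closed-form error expressions in this package are written in terms of
#' `Q()`, following the signal-detection convention.
#'
#' @param z Numeric vector; `-Inf` and `Inf` are allowed.
#' @return Numeric vector of upper-tail probabilities in `[0, 1]`.
#' @examples
#' q_function(0)      # 0.5
#' q_function(1.96)   # ~0.025
#' @export
q_function <- function(z) {
  if (!is.numeric(z)) {
    rlang::abort("`z` must be numeric.")
  }
  stats::pnorm(z, lower.tail = FALSE)
}

#' Signal-detection agent parameters
#'
#' Describes one user's two-choice decision model. Evidence `x` for a question
#' whose true answer is option `i` is drawn from `Normal(mu_i, sigma_i)`; the
#' Type I choice is option 1 when `x <= c1`, otherwise option 2. Confidence
#' (the Type II decision) is read off the same evidence through per-choice
#' ascending threshold lists, unless an `archetype` is set, in which case
#' confidence is a deterministic function of correctness:
#' `"low"` reports 1 when correct and `c_max` when wrong (metacognitively
#' misleading, AUROC2 = 0), `"medium"` always reports the middle level
#' (AUROC2 = 0.5), and `"high"` reports `c_max` when correct and 1 when wrong
#' (AUROC2 = 1).
#'
#' @param mu_1,mu_2 Evidence-distribution means for true option 1 / option 2.
#' @param sigma_1,sigma_2 Evidence standard deviations; must be positive.
#' @param c1 Type I decision threshold.
#' @param conf_thresholds_1,conf_thresholds_2 Strictly ascending numeric
#'   vectors of length `c_max - 1`: Type II thresholds on the evidence
#'   strength `|x - c1|` conditional on having chosen option 1 / option 2.
#'   May be empty when `archetype` is set.
#' @param archetype Optional confidence archetype, one of `"low"`, `"medium"`,
#'   `"high"`; overrides threshold-based confidence.
#' @param c_max Number of confidence levels (integer, at least 2).
#' @param lapse Probability of replacing the generated confidence with a
#'   uniformly drawn level (softens archetype AUROC2 away from exactly 0/1);
#'   default 0.
#' @return An object of class `agent_params`.
#' @seealso [symmetric_params_from_performance()], [simulate_trials()]
#' @export
agent_params <- function(mu_1, mu_2, sigma_1 = 1, sigma_2 = 1, c1 = 0,
                         conf_thresholds_1 = default_conf_thresholds(c_max),
                         conf_thresholds_2 = default_conf_thresholds(c_max),
                         archetype = NULL, c_max = 5L, lapse = 0) {
  stopifnot(
    is.numeric(mu_1), is.numeric(mu_2), length(mu_1) == 1, length(mu_2) == 1,
    is.numeric(c1), length(c1) == 1, !is.na(c1)
  )
  if (!is.numeric(sigma_1) || sigma_1 <= 0 || !is.numeric(sigma_2) || sigma_2 <= 0) {
    rlang::abort("`sigma_1` and `sigma_2` must be positive.")
  }
  c_max <- as.integer(c_max)
  if (c_max < 2L) rlang::abort("`c_max` must be an integer >= 2.")
  if (!is.null(archetype)) {
    archetype <- rlang::arg_match(archetype, c("low", "medium", "high"))
  } else {
    for (thr in list(conf_thresholds_1, conf_thresholds_2)) {
      if (length(thr) != c_max - 1L || is.unsorted(thr, strictly = TRUE)) {
        rlang::abort(
          "Confidence threshold lists must be strictly ascending with length `c_max - 1` (or set `archetype`)."
        )
      }
    }
  }
  if (lapse < 0 || lapse > 1) rlang::abort("`lapse` must be in [0, 1].")
  structure(
    list(
      mu_1 = mu_1, mu_2 = mu_2, sigma_1 = sigma_1, sigma_2 = sigma_2, c1 = c1,
      conf_thresholds_1 = conf_thresholds_1, conf_thresholds_2 = conf_thresholds_2,
      archetype = archetype, c_max = c_max, lapse = lapse
    ),
    class = "agent_params"
  )
}

#' @export
print.agent_params <- function(x, ...) {
  cat("<agent_params>\n")
  cat(sprintf("  mu: (%.3f, %.3f)  sigma: (%.3f, %.3f)  c1: %.3f\n",
              x$mu_1, x$mu_2, x$sigma_1, x$sigma_2, x$c1))
  cat(sprintf("  confidence: %s, c_max = %d, lapse = %g\n",
              if (is.null(x$archetype)) "threshold-based" else paste0("archetype '", x$archetype, "'"),
              x$c_max, x$lapse))
  invisible(x)
}

#' Default Type II threshold ladder
#'
#' Equally spaced thresholds (0.5 evidence-SD apart) on the evidence strength
#' `|x - c1|`, used when an agent has no archetype and no custom thresholds.
#'
#' @param c_max Number of confidence levels.
#' @return Ascending numeric vector of length `c_max - 1`.
#' @export
default_conf_thresholds <- function(c_max = 5L) {
  seq(0.5, by = 0.5, length.out = as.integer(c_max) - 1L)
}

#' Expected accuracy of an agent
#'
#' Closed-form probability of a correct Type I choice:
#' `Perf = prior_1 * (1 - Q((c1 - mu_1)/sigma_1)) + (1 - prior_1) * Q((c1 - mu_2)/sigma_2)`,
#' under the choice rule "option 1 iff `x <= c1`".
#'
#' @param params An [agent_params()] object.
#' @param prior_1 Prior probability that the true answer is option 1.
#' @return Probability in `[0, 1]`.
#' @export
performance_from_params <- function(params, prior_1 = 0.5) {
  stopifnot(inherits(params, "agent_params"))
  if (!is.numeric(prior_1) || prior_1 < 0 || prior_1 > 1) {
    rlang::abort("`prior_1` must be a probability in [0, 1].")
  }
  p_correct_1 <- 1 - q_function((params$c1 - params$mu_1) / params$sigma_1)
  p_correct_2 <- q_function((params$c1 - params$mu_2) / params$sigma_2)
  prior_1 * p_correct_1 + (1 - prior_1) * p_correct_2
}

#' Symmetric agent from a target accuracy
#'
#' Inverts the accuracy closed form under the canonical parameterization
#' `c1 = 0`, `sigma = 1`, `mu_1 = -d/2`, `mu_2 = +d/2`: given an accuracy
#' `perf` at equal priors, the evidence separation is `d = 2 * qnorm(perf)`.
#' Users with `perf < 0.5` get a negative separation (systematically wrong).
#'
#' @param perf Target accuracy, strictly between 0 and 1.
#' @inheritParams agent_params
#' @return An [agent_params()] object whose [performance_from_params()] at
#'   equal priors equals `perf`.
#' @export
symmetric_params_from_performance <- function(perf, archetype = NULL,
                                              conf_thresholds_1 = default_conf_thresholds(c_max),
                                              conf_thresholds_2 = default_conf_thresholds(c_max),
                                              c_max = 5L, lapse = 0) {
  if (!is.numeric(perf) || length(perf) != 1 || !is.finite(perf) || perf <= 0 || perf >= 1) {
    rlang::abort("`perf` must lie strictly between 0 and 1 (boundaries imply infinite separation).")
  }
  d <- 2 * stats::qnorm(perf)
  agent_params(
    mu_1 = -d / 2, mu_2 = d / 2, sigma_1 = 1, sigma_2 = 1, c1 = 0,
    conf_thresholds_1 = conf_thresholds_1, conf_thresholds_2 = conf_thresholds_2,
    archetype = archetype, c_max = c_max, lapse = lapse
  )
}

#' Simulate a table of two-choice trials with graded confidence
#'
#' For each trial, evidence is drawn from the truth-conditional Gaussian,
#' the response follows the threshold rule (option 1 iff `x <= c1`), and
#' confidence comes from the chosen option's ascending threshold ladder on
#' the evidence strength `|x - c1|` — or, for archetype agents, from the
#' deterministic correctness mapping described in [agent_params()]. With
#' `lapse > 0` each confidence report is replaced by a uniform level with
#' that probability.
#'
#' @param params An [agent_params()] object.
#' @param truths Integer vector of true answers, options coded 1/2.
#' @param seed Integer seed; required for reproducibility. The caller's RNG
#'   state is restored afterwards.
#' @return A tibble with columns `trial_index`, `truth`, `response`,
#'   `confidence`.
#' @export
simulate_trials <- function(params, truths, seed) {
  stopifnot(inherits(params, "agent_params"))
  truths <- check_options(truths, "truths")
  if (length(truths) == 0) rlang::abort("`truths` must be non-empty.")
  check_seed(seed)
  withr::local_seed(seed)
  simulate_trials_impl(params, truths)
}

# core generator; assumes the RNG is already positioned
simulate_trials_impl <- function(params, truths) {
  n <- length(truths)
  mu <- ifelse(truths == 1L, params$mu_1, params$mu_2)
  sg <- ifelse(truths == 1L, params$sigma_1, params$sigma_2)
  x <- stats::rnorm(n, mu, sg)
  response <- ifelse(x <= params$c1, 1L, 2L)
  correct <- response == truths
  if (!is.null(params$archetype)) {
    confidence <- switch(
      params$archetype,
      low    = ifelse(correct, 1L, params$c_max),
      medium = rep(as.integer(ceiling(params$c_max / 2)), n),
      high   = ifelse(correct, params$c_max, 1L)
    )
  } else {
    strength <- abs(x - params$c1)
    confidence <- integer(n)
    side1 <- response == 1L
    confidence[side1] <- 1L + findInterval(strength[side1], params$conf_thresholds_1)
    confidence[!side1] <- 1L + findInterval(strength[!side1], params$conf_thresholds_2)
  }
  if (params$lapse > 0) {
    flip <- stats::runif(n) < params$lapse
    confidence[flip] <- sample.int(params$c_max, sum(flip), replace = TRUE)
  }
  tibble::tibble(
    trial_index = seq_len(n),
    truth = as.integer(truths),
    response = as.integer(response),
    confidence = as.integer(confidence)
  )
}

#' Joint law of (response, confidence) for one truth side
#'
#' Analytic probability table `Pr(response = r, confidence = k | truth)` for
#' an agent, used by the closed-form confidence-weighted error moments and by
#' the exact convolution path.
#'
#' @param params An [agent_params()] object.
#' @param truth The true option, 1 or 2.
#' @return A `2 x c_max` matrix; rows are responses (option 1, option 2),
#'   columns confidence levels `1..c_max`. Entries sum to 1.
#' @export
response_confidence_pmf <- function(params, truth) {
  stopifnot(inherits(params, "agent_params"), truth %in% c(1L, 2L))
  mu <- if (truth == 1L) params$mu_1 else params$mu_2
  sg <- if (truth == 1L) params$sigma_1 else params$sigma_2
  c1 <- params$c1
  cm <- params$c_max
  pmf <- matrix(0, nrow = 2, ncol = cm,
                dimnames = list(c("option1", "option2"), seq_len(cm)))
  p_resp1 <- stats::pnorm((c1 - mu) / sg)
  if (!is.null(params$archetype)) {
    # correctness is response == truth; confidence deterministic given correctness
    p_correct <- if (truth == 1L) p_resp1 else 1 - p_resp1
    conf_when <- switch(params$archetype,
      low    = c(correct = 1L, wrong = cm),
      medium = c(correct = as.integer(ceiling(cm / 2)), wrong = as.integer(ceiling(cm / 2))),
      high   = c(correct = cm, wrong = 1L)
    )
    row_correct <- truth
    row_wrong <- 3L - truth
    pmf[row_correct, conf_when[["correct"]]] <- pmf[row_correct, conf_when[["correct"]]] + p_correct
    pmf[row_wrong, conf_when[["wrong"]]] <- pmf[row_wrong, conf_when[["wrong"]]] + (1 - p_correct)
  } else {
    # confidence k on side 1: strength c1 - x in [t_{k-1}, t_k), t_0 = 0, t_cmax = Inf
    t1 <- c(0, params$conf_thresholds_1, Inf)
    t2 <- c(0, params$conf_thresholds_2, Inf)
    for (k in seq_len(cm)) {
      pmf["option1", k] <- stats::pnorm((c1 - t1[k] - mu) / sg) -
        stats::pnorm((c1 - t1[k + 1L] - mu) / sg)
      pmf["option2", k] <- stats::pnorm((c1 + t2[k + 1L] - mu) / sg) -
        stats::pnorm((c1 + t2[k] - mu) / sg)
    }
  }
  if (params$lapse > 0) {
    p_resp <- rowSums(pmf)
    pmf <- (1 - params$lapse) * pmf +
      params$lapse * matrix(p_resp / cm, nrow = 2, ncol = cm)
  }
  pmf
}

# --- small shared validators -------------------------------------------------

check_options <- function(x, name) {
  if (!is.numeric(x) || !all(x %in% c(1, 2))) {
    rlang::abort(sprintf("`%s` must be coded as options 1/2.", name))
  }
  as.integer(x)
}

check_seed <- function(seed) {
  if (missing(seed) || is.null(seed) || length(seed) != 1 ||
      !is.numeric(seed) || !is.finite(seed) || seed != round(seed)) {
    rlang::abort("A single integer `seed` is required for reproducibility.")
  }
  invisible(as.integer(seed))
}
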