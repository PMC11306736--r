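#' Distribution descriptors for user performance
#'
#' Small descriptors used by [population_spec()] and [cohort_spec()] to state
#' how per-user accuracy is drawn. `dist_uniform()` draws from
#' `[min, max)`, `dist_point()` is a point mass, and `dist_truncnorm()` is a
#' normal truncated to `(lower, upper)` sampled by inverse-CDF.
#'
#' @param min,max Uniform bounds.
#' @param value Point-mass location.
#' @param mean,sd,lower,upper Truncated-normal parameters.
#' @return A `perf_dist` descriptor.
#' @name perf_dist
NULL

#' @rdname perf_dist
#' @export
dist_uniform <- function(min = 0.1, max = 1.0) {
  stopifnot(min < max)
  structure(list(kind = "uniform", min = min, max = max), class = "perf_dist")
}

#' @rdname perf_dist
#' @export
dist_point <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1)
  structure(list(kind = "point", value = value), class = "perf_dist")
}

#' @rdname perf_dist
#' @export
dist_truncnorm <- function(mean, sd, lower, upper) {
  stopifnot(sd > 0, lower < upper)
  structure(list(kind = "truncnorm", mean = mean, sd = sd,
                 lower = lower, upper = upper),
            class = "perf_dist")
}

#' @export
print.perf_dist <- function(x, ...) {
  cat("<perf_dist>", x$kind, ":",
      paste(names(x)[-1], unlist(x[-1]), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

sample_perf_dist <- function(dist, n) {
  if (!inherits(dist, "perf_dist")) rlang::abort("Unsupported performance distribution.")
  switch(dist$kind,
    uniform = stats::runif(n, dist$min, dist$max),
    point = rep(dist$value, n),
    truncnorm = {
      lo <- stats::pnorm(dist$lower, dist$mean, dist$sd)
      hi <- stats::pnorm(dist$upper, dist$mean, dist$sd)
      stats::qnorm(stats::runif(n, lo, hi), dist$mean, dist$sd)
    },
    rlang::abort(sprintf("Unsupported distribution kind '%s'.", dist$kind))
  )
}

perf_dist_mean <- function(dist) {
  switch(dist$kind,
    uniform = (dist$min + dist$max) / 2,
    point = dist$value,
    truncnorm = {
      a <- (dist$lower - dist$mean) / dist$sd
      b <- (dist$upper - dist$mean) / dist$sd
      dist$mean + dist$sd * (stats::dnorm(a) - stats::dnorm(b)) /
        (stats::pnorm(b) - stats::pnorm(a))
    }
  )
}

#' Generative description of a crowd population
#'
#' @param n_users Number of users per population.
#' @param n_questions Number of two-choice questions (used by Monte-Carlo
#'   error estimation; the analytic errors do not depend on it).
#' @param perf_dist A [perf_dist] descriptor for per-user accuracy.
#' @param archetype_probs Named probabilities over the `low` / `medium` /
#'   `high` confidence archetypes; must sum to 1.
#' @param prior_1 Prior probability that the first option is true.
#' @param c_max Number of confidence levels.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_users = 100L, n_questions = 200L,
                            perf_dist = dist_uniform(0.1, 1.0),
                            archetype_probs = c(low = 1 / 3, medium = 1 / 3, high = 1 / 3),
                            prior_1 = 0.5, c_max = 5L) {
  stopifnot(n_users >= 1, n_questions >= 1, inherits(perf_dist, "perf_dist"))
  if (!setequal(names(archetype_probs), c("low", "medium", "high")) ||
      abs(sum(archetype_probs) - 1) > 1e-8 || any(archetype_probs < 0)) {
    rlang::abort("`archetype_probs` must be named probabilities over low/medium/high summing to 1.")
  }
  if (prior_1 < 0 || prior_1 > 1) rlang::abort("`prior_1` must be in [0, 1].")
  structure(
    list(n_users = as.integer(n_users), n_questions = as.integer(n_questions),
         perf_dist = perf_dist,
         archetype_probs = archetype_probs[c("low", "medium", "high")],
         prior_1 = prior_1, c_max = as.integer(c_max)),
    class = "population_spec"
  )
}

#' Performance / metacognition filter thresholds
#'
#' @param min_performance Minimum accuracy to keep a user; 0 disables.
#' @param min_meta Minimum metacognition score (AUROC2) to keep a user;
#'   0 disables. Users with an undefined score fail any positive threshold.
#' @return A one-row tibble of class `filter_spec`.
#' @export
filter_spec <- function(min_performance = 0, min_meta = 0) {
  stopifnot(min_performance >= 0, min_performance <= 1,
            min_meta >= 0, min_meta <= 1)
  tibble::new_tibble(
    tibble::tibble(min_performance = min_performance, min_meta = min_meta),
    class = "filter_spec"
  )
}

#' Draw a random user population
#'
#' Samples each user's accuracy from the spec's performance distribution and
#' a confidence archetype from the archetype mixture. Users are symmetric
#' signal-detection agents (`c1 = 0`, unit variance) whose evidence means
#' follow from the drawn accuracy; the recorded metacognition score is the
#' archetype's AUROC2 (0, 0.5, 1 for low/medium/high).
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed.
#' @return A tibble with one row per user: `user_id`, `performance`,
#'   `archetype`, `mu_1`, `mu_2`, `auroc2`, `c_max`.
#' @export
sample_population <- function(spec, seed) {
  stopifnot(inherits(spec, "population_spec"))
  check_seed(seed)
  withr::local_seed(seed)
  sample_population_impl(spec)
}

sample_population_impl <- function(spec) {
  perf <- sample_perf_dist(spec$perf_dist, spec$n_users)
  arch <- sample(c("low", "medium", "high"), spec$n_users,
                 replace = TRUE, prob = spec$archetype_probs)
  d <- 2 * stats::qnorm(perf)
  tibble::tibble(
    user_id = seq_len(spec$n_users),
    performance = perf,
    archetype = arch,
    mu_1 = -d / 2,
    mu_2 = d / 2,
    auroc2 = c(low = 0, medium = 0.5, high = 1)[arch],
    c_max = spec$c_max
  )
}

#' Filter a population on performance and metacognition
#'
#' Keeps users whose accuracy is at least `min_performance` and whose
#' metacognition score is at least `min_meta`. An `NA` metacognition score
#' fails any positive `min_meta`. Order is preserved; an empty survivor set
#' is a legal result.
#'
#' @param population A population tibble (needs `performance` and a
#'   metacognition column, by default `auroc2`).
#' @param filter A [filter_spec()].
#' @param meta_col Name of the metacognition-score column.
#' @return The filtered population tibble.
#' @export
apply_filters <- function(population, filter, meta_col = "auroc2") {
  stopifnot(inherits(filter, "filter_spec"))
  if (nrow(population) == 0) rlang::abort("`population` must be non-empty.")
  meta <- population[[meta_col]]
  keep <- population$performance >= filter$min_performance
  if (filter$min_meta > 0) {
    keep <- keep & !is.na(meta) & meta >= filter$min_meta
  }
  population[keep, , drop = FALSE]
}

#' Compare majority-vote and confidence-weighted systems on one population
#'
#' Computes the expected (or simulated) error of the plain majority-vote
#' crowd (`err_rebacs`) and of the confidence-weighted crowd (`err_cobacs`)
#' for a given population.
#'
#' * `"analytic_normal"`: normal approximations built from per-user moments
#'   — for the vote count, mean `sum(p_n)` and variance `sum(p_n (1-p_n))`
#'   with `p_n = Q(-mu_n)`; for the weighted sum, the moments of
#'   [wmv_error_normal()].
#' * `"exact"`: [mv_error_exact()] and [wmv_error_exact()] convolutions.
#' * `"monte_carlo"`: simulates `n_questions` questions and aggregates with
#'   [majority_vote()] / [weighted_majority_vote()] semantics (requires
#'   `seed`).
#'
#' An empty population yields `NA` errors with `n_users_after_filter = 0`.
#'
#' @param population A population tibble (possibly already filtered).
#' @param n_questions Number of questions for the Monte-Carlo method.
#' @param prior_1 Prior probability of the first option.
#' @param method One of `"analytic_normal"`, `"exact"`, `"monte_carlo"`.
#' @param seed Integer seed; required for `"monte_carlo"`.
#' @return A one-row tibble: `err_rebacs`, `err_cobacs`,
#'   `n_users_after_filter`, `method`.
#' @export
compare_systems <- function(population, n_questions = 200L, prior_1 = 0.5,
                            method = c("analytic_normal", "exact", "monte_carlo"),
                            seed = NULL) {
  method <- rlang::arg_match(method)
  if (nrow(population) == 0) {
    return(tibble::tibble(err_rebacs = NA_real_, err_cobacs = NA_real_,
                          n_users_after_filter = 0L, method = method))
  }
  n <- nrow(population)
  if (method == "analytic_normal") {
    err_mv <- mv_error_clt(population, prior_1)
    err_wmv <- wmv_error_normal(population, prior_1)
  } else if (method == "exact") {
    p2_a1 <- q_function(-population$mu_1)
    p2_a2 <- q_function(-population$mu_2)
    err_mv <- mv_error_exact(p2_a1, p2_a2, prior_1)
    err_wmv <- wmv_error_exact(population, prior_1)
  } else {
    check_seed(seed)
    withr::local_seed(seed)
    sim <- simulate_crowd_errors(population, n_questions, prior_1)
    err_mv <- sim$err_mv
    err_wmv <- sim$err_wmv
  }
  tibble::tibble(err_rebacs = err_mv, err_cobacs = err_wmv,
                 n_users_after_filter = n, method = method)
}

# normal approximation to the majority vote with per-user moments
# (sums of independent, non-identical Bernoulli votes)
mv_error_clt <- function(population, prior_1 = 0.5) {
  n <- nrow(population)
  err_side <- function(p_vote2) {
    m <- sum(p_vote2)
    s <- sqrt(sum(p_vote2 * (1 - p_vote2)))
    list(m = m, s = s)
  }
  a1 <- err_side(q_function(-population$mu_1))
  a2 <- err_side(q_function(-population$mu_2))
  band <- function(m, s, lo, hi) {
    if (s > 0) q_function((lo - m) / s) - q_function((hi - m) / s)
    else as.numeric(m >= lo && m <= hi)
  }
  err <- prior_1 * band(a1$m, a1$s, n / 2, n) +
    (1 - prior_1) * band(a2$m, a2$s, 0, n / 2)
  min(max(err, 0), 1)
}

# Monte-Carlo crowd errors over simulated questions; RNG already positioned
simulate_crowd_errors <- function(population, n_questions, prior_1) {
  n <- nrow(population)
  truths <- ifelse(stats::runif(n_questions) < prior_1, 1L, 2L)
  agents <- population_agents(population)
  votes2 <- matrix(FALSE, nrow = n, ncol = n_questions)  # TRUE = second option
  conf <- matrix(1L, nrow = n, ncol = n_questions)
  for (u in seq_len(n)) {
    tab <- simulate_trials_impl(agents[[u]], truths)
    votes2[u, ] <- tab$response == 2L
    conf[u, ] <- tab$confidence
  }
  count2 <- colSums(votes2)
  mv_ans <- ifelse(count2 < n / 2, 1L, 2L)
  signed <- ifelse(votes2, 1L, -1L) * conf
  wmv_ans <- ifelse(colSums(signed) < 0, 1L, 2L)
  list(err_mv = 1 - system_accuracy(mv_ans, truths),
       err_wmv = 1 - system_accuracy(wmv_ans, truths))
}

#' Sweep the system comparison over many random populations
#'
#' Samples `n_populations` populations from `spec` and, for each filter in
#' `filter_grid`, filters the users and computes the paired system errors
#' with [compare_systems()]. A population is *viable* under a filter when at
#' least one user survives; the headline statistic is the fraction of viable
#' populations in which the confidence-weighted system's error is strictly
#' lower (ties count as not better).
#'
#' @param spec A [population_spec()].
#' @param n_populations Number of populations to sample.
#' @param filter_grid A list of [filter_spec()]s (default: no filtering).
#' @param seed Integer seed.
#' @param method Error computation method passed to [compare_systems()]
#'   (`"monte_carlo"` draws fresh questions inside the sweep's RNG stream).
#' @return An object of class `population_sweep`: a tibble with one row per
#'   filter (`min_performance`, `min_meta`, `n_populations`, `n_viable`,
#'   `frac_cobacs_better`, `mean_err_rebacs`, `mean_err_cobacs`,
#'   `mean_survivors`), with the per-population results in
#'   `attr(, "populations")`.
#' @export
population_sweep <- function(spec, n_populations,
                             filter_grid = list(filter_spec(0, 0)),
                             seed,
                             method = c("analytic_normal", "exact", "monte_carlo")) {
  stopifnot(inherits(spec, "population_spec"), n_populations >= 1)
  method <- rlang::arg_match(method)
  check_seed(seed)
  withr::local_seed(seed)
  if (inherits(filter_grid, "filter_spec")) filter_grid <- list(filter_grid)

  per_pop <- vector("list", n_populations)
  for (k in seq_len(n_populations)) {
    pop <- sample_population_impl(spec)
    rows <- purrr::map_dfr(filter_grid, function(f) {
      surv <- apply_filters(pop, f)
      res <- if (nrow(surv) == 0) {
        tibble::tibble(err_rebacs = NA_real_, err_cobacs = NA_real_,
                       n_users_after_filter = 0L, method = method)
      } else if (method == "monte_carlo") {
        sim <- simulate_crowd_errors(surv, spec$n_questions, spec$prior_1)
        tibble::tibble(err_rebacs = sim$err_mv, err_cobacs = sim$err_wmv,
                       n_users_after_filter = nrow(surv), method = method)
      } else {
        compare_systems(surv, spec$n_questions, spec$prior_1, method)
      }
      dplyr::bind_cols(
        tibble::tibble(min_performance = f$min_performance, min_meta = f$min_meta),
        res
      )
    })
    rows$population <- k
    per_pop[[k]] <- rows
  }
  per_pop <- dplyr::bind_rows(per_pop)

  summary <- per_pop |>
    dplyr::group_by(.data$min_performance, .data$min_meta) |>
    dplyr::summarise(
      n_populations = dplyr::n(),
      n_viable = sum(.data$n_users_after_filter > 0),
      frac_cobacs_better = mean(
        (.data$err_cobacs < .data$err_rebacs)[.data$n_users_after_filter > 0]
      ),
      mean_err_rebacs = mean(.data$err_rebacs, na.rm = TRUE),
      mean_err_cobacs = mean(.data$err_cobacs, na.rm = TRUE),
      mean_survivors = mean(.data$n_users_after_filter),
      .groups = "drop"
    )
  structure(summary,
            populations = per_pop,
            spec = spec, seed = seed, method = method,
            class = c("population_sweep", class(summary)))
}

#' @export
print.population_sweep <- function(x, ...) {
  cat(sprintf("Population sweep: %d populations, method '%s'\n",
              x$n_populations[1], attr(x, "method")))
  NextMethod()
  invisible(x)
}
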