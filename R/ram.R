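#' Radial-arm-maze trial
#'
#' An ordered sequence of arm visits by one animal. Arms are indexed 1 to
#' `n_arms`. A trial is complete when every arm has been visited at least
#' once; revisits to already-visited arms are the working-memory errors.
#'
#' @param visits Integer vector of visited arm indices, in order.
#' @param n_arms Number of arms in the maze.
#' @param chick_id,trial_number Identifiers.
#' @return An object of class `ram_trial`.
#' @export
ram_trial <- function(visits, n_arms = 8L, chick_id = NA_character_,
                      trial_number = NA_integer_) {
  visits <- as.integer(visits)
  if (length(visits) == 0) stop("visits must be non-empty", call. = FALSE)
  if (any(visits < 1 | visits > n_arms))
    stop("arm indices must lie in 1..n_arms", call. = FALSE)
  structure(list(visits = visits, n_arms = as.integer(n_arms),
                 chick_id = chick_id, trial_number = trial_number,
                 completed = length(unique(visits)) == n_arms),
            class = "ram_trial")
}

#' @export
print.ram_trial <- function(x, ...) {
  cat(sprintf("RAM trial%s: %d visits, %d errors, %s\n",
              if (is.na(x$chick_id)) "" else paste0(" [", x$chick_id, "]"),
              length(x$visits), count_errors(x),
              if (x$completed) "completed" else "incomplete"))
  invisible(x)
}

#' Count working-memory errors in a maze trial
#'
#' An error is any visit to an arm already visited in the same trial, so the
#' count is the number of visits minus the number of distinct arms visited.
#'
#' @param trial A [ram_trial()] or a plain integer vector of arm visits.
#' @return Integer error count.
#' @examples
#' count_errors(c(1, 2, 2, 3))  # 1
#' @export
count_errors <- function(trial) {
  v <- if (inherits(trial, "ram_trial")) trial$visits else as.integer(trial)
  length(v) - length(unique(v))
}

new_null_distribution <- function(model, errors, iterations, extra = list()) {
  structure(c(list(model = model,
                   iterations = iterations,
                   errors = errors,
                   mean = mean(errors),
                   sem = stats::sd(errors) / sqrt(iterations)),
              extra),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Monte Carlo null (%s model): %d iterations\n",
              x$model, x$iterations))
  cat(sprintf("  errors per trial: mean %.2f +/- %.3f (s.e.m.), sd %.2f\n",
              x$mean, x$sem, stats::sd(x$errors)))
  invisible(x)
}

#' Monte Carlo null: maze solved completely at random
#'
#' Simulates trials in which every arm carries an equal probability of being
#' chosen at each step (immediate returns to the arm just left are allowed),
#' continuing until all arms have been visited or `visit_cap` visits have
#' been made. This is the coupon-collector process, so without a cap the mean
#' error count converges to \eqn{n H_n - n} (13.7429 for 8 arms); the
#' simulation draws the waiting time for each new arm directly from its
#' geometric distribution.
#'
#' @param n_arms Number of arms.
#' @param iterations Number of simulated trials.
#' @param seed Integer seed.
#' @param visit_cap Optional maximum visits per trial (truncated trials).
#' @return A `null_distribution` with the per-iteration error counts, their
#'   mean and Monte Carlo s.e.m.
#' @export
simulate_random_null <- function(n_arms = 8L, iterations = 10000L,
                                 seed = NULL, visit_cap = NULL) {
  if (iterations < 1) stop("iterations must be >= 1", call. = FALSE)
  if (n_arms < 1) stop("n_arms must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  # draws needed to collect the k-th new arm ~ 1 + Geometric(p_k),
  # p_k = (n_arms - k + 1)/n_arms
  p <- (n_arms:1) / n_arms
  g <- matrix(stats::rgeom(iterations * n_arms, prob = rep(p, iterations)) + 1L,
              nrow = n_arms)
  totals <- colSums(g)
  if (is.null(visit_cap)) {
    errors <- totals - n_arms
    completed <- rep(TRUE, iterations)
  } else {
    cum <- apply(g, 2, cumsum)
    distinct <- colSums(cum <= visit_cap)
    capped <- totals > visit_cap
    errors <- ifelse(capped, visit_cap - distinct, totals - n_arms)
    completed <- !capped
  }
  new_null_distribution("random", as.integer(errors), iterations,
                        list(completed_fraction = mean(completed),
                             n_arms = n_arms, visit_cap = visit_cap))
}

# Analytic coupon-collector moments of the error count for an n-arm maze
# solved uniformly at random: used as the independent oracle in tests.
coupon_collector_moments <- function(n_arms) {
  p <- (n_arms:1) / n_arms
  list(mean = sum(1 / p) - n_arms, var = sum((1 - p) / p^2))
}

#' Estimate a first-order arm-transition matrix
#'
#' Pools consecutive visit pairs over all supplied trials into a matrix of
#' probabilities of moving to an arm given the arm just visited (`absolute`
#' mode), or of making each circular offset `(next - current) mod n_arms`
#' (`relative_offset` mode). Rows with no observations fall back to a uniform
#' distribution so that the chain stays well-defined. The empirical
#' distribution of first visits is recorded for the `empirical` start rule of
#' [simulate_stereotypic_null()].
#'
#' @param trials List of [ram_trial()] objects, or a data frame with columns
#'   `chick_id`, `trial`, `visit_index`, `arm`.
#' @param mode `"absolute"` or `"relative_offset"`.
#' @param n_arms Number of arms; taken from the first trial if omitted.
#' @return An object of class `transition_matrix` with integer `counts`, the
#'   row-stochastic `probs`, the `mode` and `start_probs`.
#' @export
estimate_transition_matrix <- function(trials,
                                       mode = c("absolute", "relative_offset"),
                                       n_arms = NULL) {
  mode <- match.arg(mode)
  if (is.data.frame(trials)) {
    df <- trials[order(trials$chick_id, trials$trial, trials$visit_index), ]
    key <- interaction(df$chick_id, df$trial, drop = TRUE)
    trials <- lapply(split(df$arm, key), function(v)
      ram_trial(v, n_arms = if (is.null(n_arms)) max(df$arm) else n_arms))
  }
  if (is.null(n_arms)) n_arms <- trials[[1]]$n_arms
  counts <- matrix(0L, n_arms, n_arms)
  start_counts <- integer(n_arms)
  n_trans <- 0L
  for (tr in trials) {
    v <- if (inherits(tr, "ram_trial")) tr$visits else as.integer(tr)
    start_counts[v[1]] <- start_counts[v[1]] + 1L
    if (length(v) >= 2) {
      from <- v[-length(v)]; to <- v[-1]
      for (i in seq_along(from))
        counts[from[i], to[i]] <- counts[from[i], to[i]] + 1L
      n_trans <- n_trans + length(from)
    }
  }
  if (n_trans == 0L) stop("no transitions observed in the supplied trials",
                          call. = FALSE)
  if (mode == "relative_offset") {
    off <- matrix(0L, nrow = 1, ncol = n_arms,
                  dimnames = list(NULL, paste0("offset", 0:(n_arms - 1))))
    for (i in 1:n_arms) for (j in 1:n_arms)
      off[1, ((j - i) %% n_arms) + 1] <- off[1, ((j - i) %% n_arms) + 1] +
        counts[i, j]
    offset_probs <- off[1, ] / sum(off)
    # expand to the equivalent circulant matrix over absolute arms
    probs <- matrix(0, n_arms, n_arms)
    for (i in 1:n_arms) for (j in 1:n_arms)
      probs[i, j] <- offset_probs[((j - i) %% n_arms) + 1]
    counts_out <- off
  } else {
    probs <- counts
    rs <- rowSums(counts)
    for (i in 1:n_arms)
      probs[i, ] <- if (rs[i] > 0) counts[i, ] / rs[i] else rep(1 / n_arms, n_arms)
    offset_probs <- NULL
    counts_out <- counts
  }
  structure(list(counts = counts_out, probs = probs, mode = mode,
                 n_arms = n_arms, n_transitions = n_trans,
                 offset_probs = offset_probs,
                 start_probs = if (sum(start_counts) > 0)
                   start_counts / sum(start_counts)
                 else rep(1 / n_arms, n_arms)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("Arm transition matrix (%s mode): %d arms, %d transitions\n",
              x$mode, x$n_arms, x$n_transitions))
  print(round(x$probs, 3))
  invisible(x)
}

#' Monte Carlo null: maze solved by stereotypic movement rules
#'
#' Simulates trials in which the next arm is drawn from a first-order Markov
#' chain (typically estimated from observed trials), continuing until all
#' arms are visited or `visit_cap` visits are made. This predicts the error
#' count expected if animals used fixed movement patterns (always clockwise,
#' always opposite arm, ...) rather than memory.
#'
#' @param tm A [estimate_transition_matrix()] result, or a row-stochastic
#'   matrix.
#' @param iterations Number of simulated trials.
#' @param seed Integer seed.
#' @param start_rule Start arm drawn uniformly (`"uniform"`) or from the
#'   empirical first-visit distribution (`"empirical"`, needs a
#'   `transition_matrix` object).
#' @param visit_cap Optional maximum visits per trial.
#' @param max_steps Safety bound per iteration; if the chain has not covered
#'   all arms after this many visits and no `visit_cap` was set, the chain is
#'   treated as unable to cover the maze and an error is raised.
#' @return A `null_distribution`.
#' @export
simulate_stereotypic_null <- function(tm, iterations = 10000L, seed = NULL,
                                      start_rule = c("uniform", "empirical"),
                                      visit_cap = NULL, max_steps = 10000L) {
  start_rule <- match.arg(start_rule)
  if (inherits(tm, "transition_matrix")) {
    probs <- tm$probs
    start_probs <- if (start_rule == "empirical") tm$start_probs else NULL
  } else {
    probs <- as.matrix(tm)
    if (start_rule == "empirical")
      stop("empirical start rule needs a transition_matrix object",
           call. = FALSE)
    start_probs <- NULL
  }
  n_arms <- nrow(probs)
  if (any(probs < 0) || any(abs(rowSums(probs) - 1) > 1e-9))
    stop("transition matrix rows must sum to 1 (within 1e-9)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(start_probs)) start_probs <- rep(1 / n_arms, n_arms)
  cum <- t(apply(probs, 1, cumsum))
  cum_start <- cumsum(start_probs)
  step_cap <- if (is.null(visit_cap)) max_steps else visit_cap

  errors <- integer(iterations)
  completed <- logical(iterations)
  for (it in seq_len(iterations)) {
    cur <- findInterval(stats::runif(1), cum_start) + 1L
    visited <- logical(n_arms)
    visited[cur] <- TRUE
    n_distinct <- 1L
    steps <- 1L
    while (n_distinct < n_arms && steps < step_cap) {
      cur <- findInterval(stats::runif(1), cum[cur, ]) + 1L
      if (cur > n_arms) cur <- n_arms  # guard against rounding at 1.0
      if (!visited[cur]) {
        visited[cur] <- TRUE
        n_distinct <- n_distinct + 1L
      }
      steps <- steps + 1L
    }
    if (n_distinct < n_arms && is.null(visit_cap))
      stop("chain failed to cover all arms within max_steps; ",
           "set a visit_cap for absorbing chains", call. = FALSE)
    errors[it] <- steps - n_distinct
    completed[it] <- n_distinct == n_arms
  }
  new_null_distribution("stereotypic", errors, iterations,
                        list(completed_fraction = mean(completed),
                             n_arms = n_arms, visit_cap = visit_cap,
                             start_rule = start_rule))
}

#' Compare observed maze errors with a Monte Carlo null
#'
#' One-sample t-test of the observed per-trial error counts against the null
#' model's mean, with the one-sided alternative that animals make fewer
#' errors than the null predicts (i.e. use memory). With zero observed
#' variance the comparison degenerates to an exact comparison of means and p
#' is reported as 0, 0.5 or 1.
#'
#' @param observed Numeric vector of observed error counts (>= 2 trials).
#' @param null A `null_distribution`.
#' @return An object of class `ram_null_test` with the t statistic, degrees
#'   of freedom and one-sided p-value.
#' @export
compare_to_null <- function(observed, null) {
  stopifnot(inherits(null, "null_distribution"))
  observed <- as.numeric(observed)
  if (length(observed) < 2)
    stop("need at least 2 observed trials", call. = FALSE)
  df <- length(observed) - 1L
  if (stats::sd(observed) == 0) {
    d <- mean(observed) - null$mean
    res <- list(t = if (d == 0) 0 else sign(d) * Inf,
                p = if (d < 0) 0 else if (d > 0) 1 else 0.5,
                degenerate = TRUE)
  } else {
    tt <- stats::t.test(observed, mu = null$mean, alternative = "less")
    res <- list(t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
  }
  structure(list(t = res$t, df = df, p = res$p,
                 observed_mean = mean(observed),
                 observed_sem = stats::sd(observed) / sqrt(length(observed)),
                 null_mean = null$mean, null_model = null$model,
                 n = length(observed), degenerate = res$degenerate),
            class = "ram_null_test")
}

#' @export
print.ram_null_test <- function(x, ...) {
  cat(sprintf("Observed vs %s null: t(%d) = %.2f, one-sided p = %.4g\n",
              x$null_model, x$df, x$t, x$p))
  cat(sprintf("  observed mean %.2f +/- %.2f, null mean %.2f (n = %d trials)\n",
              x$observed_mean, x$observed_sem, x$null_mean, x$n))
  if (x$degenerate) cat("  (zero observed variance: exact mean comparison)\n")
  invisible(x)
}
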