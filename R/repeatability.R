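# One-way Gaussian random-intercept model (intercept-only fixed part),
# profiled over the variance ratio theta = var_group / var_resid.
#
# For fixed theta the GLS mean, the residual quadratic form and the profiled
# residual variance are closed-form, so ML and REML reduce to a 1-D
# optimisation; this keeps a single fit cheap enough for tens of thousands of
# parametric-bootstrap refits. Balanced designs recover the classical ANOVA
# estimators exactly (var_resid = MSW, var_group = (MSB - MSW)/k).
one_way_vc <- function(y, g, method = c("REML", "ML")) {
  method <- match.arg(method)
  g <- droplevels(as.factor(g))
  k <- nlevels(g)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  nj <- as.numeric(table(g))
  if (max(nj) < 2) stop("need at least 2 records in some group", call. = FALSE)
  N <- length(y)
  ybar <- as.numeric(tapply(y, g, mean))
  ssw <- sum((y - ybar[g])^2)

  crit <- function(theta) {   # -2 log likelihood, profiled over mu, sigma2
    w <- nj / (1 + nj * theta)
    mu <- sum(w * ybar) / sum(w)
    Q <- ssw + sum(nj * (ybar - mu)^2 / (1 + nj * theta))
    ldet <- sum(log1p(nj * theta))
    if (method == "ML") {
      s2 <- Q / N
      N * log(2 * pi * s2) + ldet + N
    } else {
      s2 <- Q / (N - 1)
      (N - 1) * log(2 * pi * s2) + ldet + log(sum(w)) + (N - 1)
    }
  }
  # optimise on u = theta/(1+theta) in [0,1) to keep resolution near 0
  fu <- function(u) crit(u / (1 - u))
  opt <- stats::optimize(fu, interval = c(0, 0.99999), tol = 1e-12)
  u <- opt$minimum
  # the boundary theta = 0 is a genuine candidate (variance component on the
  # edge of the parameter space)
  if (crit(0) <= opt$objective + 1e-10) u <- 0
  theta <- u / (1 - u)

  w <- nj / (1 + nj * theta)
  mu <- sum(w * ybar) / sum(w)
  Q <- ssw + sum(nj * (ybar - mu)^2 / (1 + nj * theta))
  s2 <- if (method == "ML") Q / N else Q / (N - 1)
  list(var_group = theta * s2, var_resid = s2, mu = mu,
       loglik = -0.5 * crit(theta), theta = theta, method = method,
       n_groups = k, n_obs = N, group_sizes = nj,
       loglik_null = -0.5 * crit(0))
}

#' Variance components of a random-intercept latency model
#'
#' Fits the Gaussian random-intercept model with no fixed predictors to
#' latency records, grouped by individual or by experimental block, and
#' returns the between-group and residual variance estimates. Censored
#' latencies are entered at the cap value they were assigned (they are not
#' treated as statistically censored here, matching the assignment rule of
#' the latency assays). An optional log transform is available since latency
#' distributions are strongly right-skewed.
#'
#' @param records Data frame of latency records with columns `chick_id`,
#'   `block`, `latency_s` (see [generate_latency_data()]).
#' @param grouping `"chick"` (repeatability across trials within individuals)
#'   or `"block"` (repeatability between the pre/post blocks).
#' @param response Column holding the response.
#' @param log_transform Fit on `log(latency)`.
#' @param method `"REML"` (default, used for estimates) or `"ML"` (used for
#'   likelihood-ratio tests).
#' @return List with `var_group`, `var_resid`, `loglik` and fit metadata.
#' @export
fit_variance_components <- function(records, grouping = c("chick", "block"),
                                    response = "latency_s",
                                    log_transform = FALSE,
                                    method = c("REML", "ML")) {
  grouping <- match.arg(grouping)
  y <- records[[response]]
  if (log_transform) y <- log(y)
  g <- if (grouping == "chick") records$chick_id else records$block
  one_way_vc(y, g, method = match.arg(method))
}

#' Repeatability (intraclass correlation) of a latency trait
#'
#' Repeatability is the proportion of total variance explained by the random
#' effect of group identity, R = var_group / (var_group + var_resid), from
#' the REML fit of the intercept-only random-intercept model. Its
#' significance is assessed by a likelihood-ratio test of the random effect
#' (ML fits; the null distribution for a variance component on the boundary
#' is the 50:50 mixture of a point mass at zero and chi-square with 1 df) and
#' its confidence interval by a parametric bootstrap: data are re-simulated
#' from the fitted model, refit, and percentile bounds taken over the
#' bootstrap R values.
#'
#' @inheritParams fit_variance_components
#' @param n_bootstrap Number of parametric bootstrap replicates.
#' @param seed Integer seed for the bootstrap.
#' @param ci_level Confidence level of the percentile interval.
#' @return An object of class `repeatability_estimate` with fields `R`,
#'   `se_R`, `ci95`, `lrt_p`, `var_group`, `var_resid`, `n_bootstrap`,
#'   `grouping` and bootstrap failure counts.
#' @export
repeatability <- function(records, grouping = c("chick", "block"),
                          n_bootstrap = 10000L, seed = NULL,
                          response = "latency_s", log_transform = FALSE,
                          ci_level = 0.95) {
  grouping <- match.arg(grouping)
  if (!is.null(seed)) set.seed(seed)
  fit <- fit_variance_components(records, grouping, response, log_transform,
                                 method = "REML")
  R <- fit$var_group / (fit$var_group + fit$var_resid)

  ml <- fit_variance_components(records, grouping, response, log_transform,
                                method = "ML")
  lrt_stat <- max(0, 2 * (ml$loglik - ml$loglik_null))
  lrt_p <- if (lrt_stat <= 0) 1
           else 0.5 * stats::pchisq(lrt_stat, df = 1, lower.tail = FALSE)

  nj <- fit$group_sizes
  gidx <- rep(seq_along(nj), nj)
  boot_R <- rep(NA_real_, n_bootstrap)
  failures <- 0L
  for (b in seq_len(n_bootstrap)) {
    ystar <- fit$mu + stats::rnorm(length(nj), 0, sqrt(fit$var_group))[gidx] +
      stats::rnorm(sum(nj), 0, sqrt(fit$var_resid))
    vb <- tryCatch(one_way_vc(ystar, gidx, "REML"), error = function(e) NULL)
    if (is.null(vb)) { failures <- failures + 1L; next }
    boot_R[b] <- vb$var_group / (vb$var_group + vb$var_resid)
  }
  if (n_bootstrap > 0 && failures / n_bootstrap > 0.05)
    warning(sprintf("%d of %d bootstrap refits failed", failures, n_bootstrap))
  ok <- !is.na(boot_R)
  alpha <- (1 - ci_level) / 2
  ci <- if (any(ok)) unname(stats::quantile(boot_R[ok], c(alpha, 1 - alpha)))
        else c(NA_real_, NA_real_)
  structure(list(grouping = grouping, R = R,
                 se_R = if (any(ok)) stats::sd(boot_R[ok]) else NA_real_,
                 ci95 = ci, ci_level = ci_level,
                 lrt_stat = lrt_stat, lrt_p = lrt_p,
                 var_group = fit$var_group, var_resid = fit$var_resid,
                 n_bootstrap = as.integer(n_bootstrap),
                 bootstrap_failures = failures,
                 point_outside_ci = any(ok) && (R < ci[1] || R > ci[2]),
                 log_transform = log_transform,
                 n_groups = fit$n_groups, n_obs = fit$n_obs),
            class = "repeatability_estimate")
}

#' @export
print.repeatability_estimate <- function(x, ...) {
  cat(sprintf("Repeatability (%s): R = %.3f +/- %.3f (s.e.)\n",
              x$grouping, x$R, x$se_R))
  cat(sprintf("  %g%% CI = %.3f to %.3f (%d parametric bootstraps%s)\n",
              100 * x$ci_level, x$ci95[1], x$ci95[2], x$n_bootstrap,
              if (x$bootstrap_failures > 0)
                sprintf(", %d failed", x$bootstrap_failures) else ""))
  cat(sprintf("  LRT for the random effect: chi2 = %.2f, p = %.4g\n",
              x$lrt_stat, x$lrt_p))
  cat(sprintf("  var(group) = %.4g, var(residual) = %.4g; %d groups, %d obs%s\n",
              x$var_group, x$var_resid, x$n_groups, x$n_obs,
              if (x$log_transform) " (log scale)" else ""))
  if (isTRUE(x$point_outside_ci))
    cat("  note: point estimate falls outside the bootstrap CI\n")
  invisible(x)
}

#' Correlation between two latency traits
#'
#' Pairs records of two traits by chick, block and trial index and computes
#' the Pearson correlation with its t-test. Because latency assays are
#' right-censored at the cap, pairs in which either member is censored can be
#' dropped (`drop_censored = TRUE`) to check whether a correlation is driven
#' by animals that never left the shelter.
#'
#' @param records_a,records_b Latency record data frames (one trait each)
#'   with columns `chick_id`, `block`, `trial_index`, `latency_s`,
#'   `censored`.
#' @param drop_censored Remove pairs containing any censored latency.
#' @return List with `r`, `t`, `p`, `df`, `n` and the number of pairs
#'   dropped.
#' @export
trait_correlation <- function(records_a, records_b, drop_censored = FALSE) {
  m <- merge(records_a, records_b,
             by = c("chick_id", "block", "trial_index"),
             suffixes = c("_a", "_b"))
  dropped <- 0L
  if (drop_censored) {
    keep <- !(m$censored_a | m$censored_b)
    dropped <- sum(!keep)
    m <- m[keep, , drop = FALSE]
  }
  if (nrow(m) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  ct <- stats::cor.test(m$latency_s_a, m$latency_s_b, method = "pearson")
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       p = ct$p.value, df = unname(ct$parameter), n = nrow(m),
       n_dropped = dropped)
}
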