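#' Standardise a variable to zero mean and unit SD
#'
#' Centring on the group mean and dividing by the group standard deviation
#' (sample, n-1 convention) so that effect sizes are comparable across
#' predictors.
#'
#' @param values Numeric vector of at least 2 values with non-zero SD.
#' @param center,spread Optional pre-specified centre and spread (e.g. to
#'   scale new data on a reference group's scale).
#' @return An object of class `scaled_variable`: list with `values` (the
#'   scaled series), `center` and `spread`.
#' @examples
#' scale_values(c(1, 2, 3))$values  # -1 0 1
#' @export
scale_values <- function(values, center = NULL, spread = NULL) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (is.null(center)) center <- mean(values)
  if (is.null(spread)) spread <- stats::sd(values)
  if (!is.finite(spread) || spread <= 0)
    stop("standard deviation must be > 0 (constant input?)", call. = FALSE)
  structure(list(values = (values - center) / spread,
                 center = center, spread = spread),
            class = "scaled_variable")
}

#' @export
print.scaled_variable <- function(x, ...) {
  cat(sprintf("Scaled variable: n = %d, center %.4g, spread %.4g\n",
              length(x$values), x$center, x$spread))
  invisible(x)
}

#' Construct a fitted-model summary for AIC comparison
#'
#' Light container carrying what the AIC selection rule needs: the maximised
#' log-likelihood, the parameter count, named coefficients and a convergence
#' flag. `aic` is always `2 k - 2 loglik`.
#'
#' @param name Model label.
#' @param loglik Maximised log-likelihood.
#' @param k Number of estimated parameters.
#' @param coefficients Named numeric vector.
#' @param converged Did the fit converge.
#' @param response Label of the response variable (comparisons across
#'   different responses are refused).
#' @param n_obs Number of observations used.
#' @param fit Optional underlying fitted object.
#' @param deviations Optional character notes on simplifications relative to
#'   the design the model stands in for.
#' @return An object of class `model_fit`.
#' @export
model_fit <- function(name, loglik, k, coefficients = numeric(0),
                      converged = TRUE, response = NA_character_,
                      n_obs = NA_integer_, fit = NULL, deviations = NULL) {
  structure(list(name = name, loglik = loglik, k = as.integer(k),
                 aic = 2 * k - 2 * loglik,
                 coefficients = coefficients, converged = converged,
                 response = response, n_obs = n_obs, fit = fit,
                 deviations = deviations),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Model '%s': logLik %.3f, k = %d, AIC %.2f%s\n",
              x$name, x$loglik, x$k, x$aic,
              if (!x$converged) " (DID NOT CONVERGE)" else ""))
  if (length(x$coefficients))
    print(round(x$coefficients, 4))
  if (!is.null(x$deviations))
    cat("  deviations: ", paste(x$deviations, collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' Negative binomial regression of maze error counts
#'
#' Maximum-likelihood negative binomial regression with a log link,
#' accounting for overdispersion in error counts. The dispersion parameter
#' is profiled by ML unless `theta` is supplied (fixing a very large `theta`
#' recovers the Poisson limit). This is the simplified stand-in for a
#' negative binomial GLMM: individual identity enters as a categorical fixed
#' term where needed rather than a random effect.
#'
#' @param formula Model formula (counts on the left).
#' @param data Data frame.
#' @param theta Optional fixed dispersion; `NULL` profiles it by ML.
#' @param name Model label.
#' @return A [model_fit()].
#' @export
fit_nb_regression <- function(formula, data, theta = NULL,
                              name = deparse(formula)) {
  resp <- all.vars(formula)[1]
  if (is.null(theta)) {
    obj <- tryCatch(MASS::glm.nb(formula, data = data),
                    error = function(e) e, warning = function(w) {
                      suppressWarnings(MASS::glm.nb(formula, data = data))
                    })
    if (inherits(obj, "error"))
      return(model_fit(name, NA_real_, 0L, converged = FALSE,
                       response = resp))
    ll <- stats::logLik(obj)
    converged <- isTRUE(obj$converged)
  } else {
    obj <- stats::glm(formula, data = data,
                      family = MASS::negative.binomial(theta))
    ll <- stats::logLik(obj)
    converged <- obj$converged
  }
  model_fit(name, as.numeric(ll), attr(ll, "df"),
            coefficients = stats::coef(obj), converged = converged,
            response = resp, n_obs = stats::nobs(obj), fit = obj,
            deviations = "individual identity as categorical fixed term, not a random effect")
}

#' Linear mixed time trend of metabolic rate
#'
#' Gaussian random-intercept model of a rate on the day of measurement, fit
#' by maximum likelihood (so that AICs are comparable across fixed-effect
#' structures). Singular fits (zero estimated individual variance) fall back
#' to ordinary least squares, flagged.
#'
#' @param data Data frame.
#' @param response,time,group Column names of the rate, the day index and the
#'   individual identifier.
#' @param trend Include the time predictor; `FALSE` fits the intercept-only
#'   null with the same random effect.
#' @param name Model label.
#' @return A [model_fit()] whose coefficients include the fitted slope when
#'   `trend = TRUE`.
#' @export
fit_lmm_time_trend <- function(data, response = "vo2_ml_min", time = "day",
                               group = "chick_id", trend = TRUE,
                               name = NULL) {
  fixed <- if (trend) paste(response, "~", time) else paste(response, "~ 1")
  if (is.null(name)) name <- if (trend) "time trend" else "null (no trend)"
  fml <- stats::as.formula(paste(fixed, "+ (1 |", group, ")"))
  obj <- suppressMessages(
    lme4::lmer(fml, data = data, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular =
                                             "ignore")))
  singular <- lme4::isSingular(obj)
  if (singular) {
    ols <- stats::lm(stats::as.formula(fixed), data = data)
    ll <- stats::logLik(ols)
    return(model_fit(name, as.numeric(ll), attr(ll, "df"),
                     coefficients = stats::coef(ols), converged = TRUE,
                     response = response, n_obs = stats::nobs(ols),
                     fit = ols,
                     deviations = "singular random effect; ordinary regression fallback"))
  }
  ll <- stats::logLik(obj)
  model_fit(name, as.numeric(ll), attr(ll, "df"),
            coefficients = lme4::fixef(obj), converged = TRUE,
            response = response, n_obs = stats::nobs(obj), fit = obj)
}

#' Censored latency model (accelerated failure time)
#'
#' Weibull accelerated-failure-time model of latency to leave the shelter,
#' with right-censoring at the assay cap, fit by maximum likelihood. With
#' the shape fixed at 1 it reduces to the exponential model (closed-form
#' rate MLE `n_events / sum(t)` when nothing is censored). This is the
#' simplified stand-in for a mixed-effects survival model: predictors enter
#' as plain fixed terms.
#'
#' @param records Latency record data frame with `latency_s` and `censored`
#'   columns; at least one record must be uncensored.
#' @param predictor Optional name of a numeric column of `records` (e.g.
#'   scaled metabolic rate) entered as a fixed term; `NULL` fits the
#'   intercept-only null.
#' @param shape_fixed `NULL` (shape estimated) or `1` (exponential special
#'   case of the Weibull).
#' @param dist AFT error family: `"weibull"` (default) or `"lognormal"`
#'   (appropriate when latencies are log-normal, in which case the model is
#'   exactly Gaussian on the log scale).
#' @param name Model label.
#' @return A [model_fit()].
#' @export
fit_censored_latency_model <- function(records, predictor = NULL,
                                       shape_fixed = NULL,
                                       dist = c("weibull", "lognormal"),
                                       name = NULL) {
  if (all(records$censored))
    stop("all records are censored; the latency model is not identifiable",
         call. = FALSE)
  dist <- match.arg(dist)
  if (!is.null(shape_fixed)) {
    if (shape_fixed != 1 || dist != "weibull")
      stop("only the Weibull shape can be fixed, and only at 1",
           call. = FALSE)
    dist <- "exponential"
  }
  rhs <- if (is.null(predictor)) "1" else predictor
  if (is.null(name))
    name <- if (is.null(predictor)) "null (intercept only)"
            else paste("latency ~", predictor)
  fml <- stats::as.formula(
    paste("survival::Surv(latency_s, !censored) ~", rhs))
  obj <- survival::survreg(fml, data = records, dist = dist)
  ll <- stats::logLik(obj)
  model_fit(name, as.numeric(ll), attr(ll, "df"),
            coefficients = stats::coef(obj), converged = TRUE,
            response = "latency_s", n_obs = nrow(records), fit = obj,
            deviations = "Weibull AFT with fixed terms, not a mixed-effects survival model")
}

#' AIC model selection with a two-point margin
#'
#' A candidate model is preferred only if its AIC undercuts the simpler
#' model's by at least the margin (default 2.00); otherwise the simpler
#' (null) model is retained. The simpler model is the one with the fewest
#' parameters; non-converged fits are excluded with a warning.
#'
#' @param fits List of [model_fit()] objects for the same response.
#' @param margin AIC improvement required to prefer a more complex model.
#' @return An object of class `model_comparison` with the per-model AIC
#'   table, `delta_aic` (simpler minus best candidate) and the `selected`
#'   label.
#' @export
compare_models <- function(fits, margin = 2) {
  if (length(fits) < 2) stop("need at least 2 fits", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, TRUE, "model_fit")))
  resp <- unique(vapply(fits, `[[`, "", "response"))
  resp <- resp[!is.na(resp)]
  if (length(resp) > 1)
    stop("fits are for different responses: ", paste(resp, collapse = ", "),
         call. = FALSE)
  conv <- vapply(fits, `[[`, TRUE, "converged")
  if (any(!conv)) {
    warning(sum(!conv), " non-converged fit(s) excluded from comparison")
    fits <- fits[conv]
    if (length(fits) < 2) stop("fewer than 2 converged fits", call. = FALSE)
  }
  k <- vapply(fits, `[[`, 0L, "k")
  aic <- vapply(fits, `[[`, 0, "aic")
  names_ <- vapply(fits, `[[`, "", "name")
  i_simple <- which.min(k)
  others <- setdiff(seq_along(fits), i_simple)
  i_cand <- others[which.min(aic[others])]
  delta <- aic[i_simple] - aic[i_cand]
  selected <- if (delta >= margin) names_[i_cand] else names_[i_simple]
  structure(list(table = data.frame(model = names_, k = k,
                                    loglik = vapply(fits, `[[`, 0, "loglik"),
                                    aic = aic,
                                    stringsAsFactors = FALSE),
                 delta_aic = delta, margin = margin, selected = selected,
                 null_model = names_[i_simple],
                 candidate = names_[i_cand],
                 rule = sprintf("candidate preferred iff dAIC >= %.2f", margin),
                 fits = fits),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("AIC model comparison\n")
  print(x$table, digits = 5, row.names = FALSE)
  cat(sprintf("  dAIC (null - candidate) = %.2f; %s\n", x$delta_aic, x$rule))
  cat(sprintf("  selected: %s\n", x$selected))
  invisible(x)
}
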