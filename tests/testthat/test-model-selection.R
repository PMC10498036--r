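test_that("scaling centres on zero and unit sample SD", {
  s <- scale_values(c(1, 2, 3))
  expect_equal(s$values, c(-1, 0, 1))
  expect_equal(s$center, 2)
  expect_equal(s$spread, 1)
  # idempotence
  s2 <- scale_values(s$values)
  expect_equal(s2$values, s$values, tolerance = 1e-12)
  expect_error(scale_values(rep(4, 5)), "constant|deviation")
  expect_error(scale_values(3), "2 values")
})

test_that("model fits satisfy the AIC identity", {
  set.seed(401)
  d <- data.frame(y = rpois(60, 5), x = rnorm(60))
  fits <- list(fit_nb_regression(y ~ 1, d),
               fit_nb_regression(y ~ x, d),
               behavmet:::fit_lm_model(y ~ x, d))
  for (f in fits) expect_equal(f$aic, 2 * f$k - 2 * f$loglik)
})

test_that("negative binomial regression has the known special cases", {
  set.seed(402)
  d <- data.frame(y = rpois(200, 6), x = rnorm(200))
  # intercept-only MLE is log of the mean count
  f0 <- fit_nb_regression(y ~ 1, d)
  expect_equal(unname(f0$coefficients[1]), log(mean(d$y)), tolerance = 1e-5)
  # infinite-dispersion limit recovers the Poisson log-likelihood
  fnb <- fit_nb_regression(y ~ x, d, theta = 1e7)
  fpois <- glm(y ~ x, data = d, family = poisson)
  expect_equal(fnb$loglik, as.numeric(logLik(fpois)), tolerance = 1e-4)
})

test_that("NB regression recovers a known slope on generator-style counts", {
  set.seed(403)
  n <- 500
  x <- rnorm(n)
  beta <- 0.4
  mu <- exp(2 + beta * x)
  y <- rnbinom(n, mu = mu, size = 5)
  f <- fit_nb_regression(y ~ x, data.frame(y = y, x = x))
  se <- sqrt(diag(vcov(f$fit)))["x"]
  expect_lt(abs(unname(f$coefficients["x"]) - beta), 2 * se)
})

test_that("adding a predictor never lowers the maximised log-likelihood", {
  set.seed(404)
  d <- data.frame(y = rnbinom(80, mu = 8, size = 3), x = rnorm(80),
                  junk = rnorm(80))
  f1 <- fit_nb_regression(y ~ x, d, theta = 3)
  f2 <- fit_nb_regression(y ~ x + junk, d, theta = 3)
  expect_gte(f2$loglik, f1$loglik - 1e-8)
  l1 <- behavmet:::fit_lm_model(y ~ x, d)
  l2 <- behavmet:::fit_lm_model(y ~ x + junk, d)
  expect_gte(l2$loglik, l1$loglik - 1e-8)
})

test_that("the AIC margin rule selects as printed", {
  mk <- function(name, aic, k) model_fit(name, loglik = k - aic / 2, k = k,
                                         response = "y")
  # candidate 1.80 better: simpler model retained
  c1 <- compare_models(list(mk("null", 100, 1), mk("cand", 98.2, 2)))
  expect_equal(c1$selected, "null")
  expect_equal(c1$delta_aic, 1.8)
  # candidate 11.64 better: candidate selected
  c2 <- compare_models(list(mk("null", 100, 1), mk("cand", 88.36, 2)))
  expect_equal(c2$selected, "cand")
  expect_equal(c2$delta_aic, 11.64)
  # exactly 2.00: the boundary counts as an improvement
  c3 <- compare_models(list(mk("null", 100, 1), mk("cand", 98, 2)))
  expect_equal(c3$selected, "cand")
  # worse candidate: null retained with negative delta
  c4 <- compare_models(list(mk("null", 100, 1), mk("cand", 103, 2)))
  expect_equal(c4$selected, "null")
})

test_that("comparisons refuse mixed responses and drop failed fits", {
  a <- model_fit("a", -10, 1, response = "y")
  b <- model_fit("b", -9, 2, response = "z")
  expect_error(compare_models(list(a, b)), "different responses")
  bad <- model_fit("bad", NA_real_, 2, converged = FALSE, response = "y")
  good <- model_fit("g", -8, 2, response = "y")
  expect_warning(cm <- compare_models(list(a, good, bad)), "non-converged")
  expect_equal(nrow(cm$table), 2)
  expect_error(compare_models(list(a)), "2 fits")
})

test_that("mixed time-trend model detects a real slope and not a null one", {
  set.seed(405)
  mk_data <- function(slope) {
    d <- expand.grid(chick_id = sprintf("c%02d", 1:12), day = seq(21, 41, 4))
    d$vo2_ml_min <- 4 + slope * (d$day - 21) +
      rnorm(12, 0, 0.6)[as.integer(factor(d$chick_id))] +
      rnorm(nrow(d), 0, 0.4)
    d
  }
  d_pos <- mk_data(0.13)
  cm <- compare_models(list(
    fit_lmm_time_trend(d_pos, trend = FALSE),
    fit_lmm_time_trend(d_pos, trend = TRUE)))
  expect_equal(cm$selected, "time trend")
  expect_gt(cm$fits[[2]]$coefficients[["day"]], 0)
  expect_gt(cm$delta_aic, 2)

  d_null <- mk_data(0)
  cm0 <- compare_models(list(
    fit_lmm_time_trend(d_null, trend = FALSE),
    fit_lmm_time_trend(d_null, trend = TRUE)))
  expect_equal(cm0$selected, "null (no trend)")
})

test_that("with no group variance the mixed slope equals the OLS slope", {
  set.seed(406)
  d <- expand.grid(chick_id = sprintf("c%02d", 1:8), day = 1:6)
  d$vo2_ml_min <- 2 + 0.3 * d$day + rnorm(nrow(d), 0, 0.3)  # no group variance
  f <- fit_lmm_time_trend(d, trend = TRUE)
  ols <- lm(vo2_ml_min ~ day, d)
  # balanced design: fixed effects coincide with least squares, whether the
  # random effect collapses to the OLS fallback or stays at a tiny variance
  expect_equal(unname(f$coefficients["day"]), unname(coef(ols)["day"]),
               tolerance = 1e-6)
})

test_that("censored latency model has the exponential closed form", {
  set.seed(407)
  rec <- data.frame(latency_s = rexp(100, 1 / 40), censored = FALSE)
  f <- fit_censored_latency_model(rec, shape_fixed = 1)
  # exponential MLE: rate = n / sum(t), i.e. intercept = log(mean(t))
  expect_equal(unname(f$coefficients[1]), log(mean(rec$latency_s)),
               tolerance = 1e-6)
  ll <- length(rec$latency_s) * (log(1 / mean(rec$latency_s)) - 1)
  expect_equal(f$loglik, ll, tolerance = 1e-6)
  expect_error(fit_censored_latency_model(
    data.frame(latency_s = 600, censored = TRUE)), "censored")
})

test_that("latency model selection is calibrated and powered", {
  set.seed(408)
  sim_rec <- function(beta) {
    x <- rnorm(40)
    lat <- exp(rnorm(40, log(60) + beta * x, 0.8))
    data.frame(latency_s = pmin(lat, 600), censored = lat >= 600, x = x)
  }
  # null effect: the simpler model wins in >= 90% of replicates
  null_wins <- mean(replicate(200, {
    rec <- sim_rec(0)
    f0 <- fit_censored_latency_model(rec, name = "null")
    f1 <- fit_censored_latency_model(rec, predictor = "x", name = "cand")
    compare_models(list(f0, f1))$selected == "null"
  }))
  expect_gte(null_wins, 0.9)
  # strong effect: the predictor model is selected
  rec <- sim_rec(1.2)
  f0 <- fit_censored_latency_model(rec, name = "null")
  f1 <- fit_censored_latency_model(rec, predictor = "x", name = "cand")
  expect_equal(compare_models(list(f0, f1))$selected, "cand")
})
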