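test_that("balanced REML equals the one-way ANOVA estimators", {
  set.seed(201)
  k <- 6  # records per group
  g <- rep(1:10, each = k)
  y <- rnorm(10, 0, 2)[g] + rnorm(length(g))
  fit <- behavmet:::one_way_vc(y, g, "REML")
  msq <- anova(lm(y ~ factor(g)))
  msb <- msq$`Mean Sq`[1]; msw <- msq$`Mean Sq`[2]
  expect_equal(fit$var_resid, msw, tolerance = 1e-6)
  expect_equal(fit$var_group, (msb - msw) / k, tolerance = 1e-6)
})

test_that("variance components agree with lme4 on an unbalanced fixture", {
  set.seed(202)
  nj <- c(3, 7, 5, 9, 4, 6, 8, 2)
  g <- rep(seq_along(nj), nj)
  y <- rnorm(length(nj), 0, 1.5)[g] + rnorm(length(g), 0, 0.8)
  d <- data.frame(y = y, g = factor(g))

  ours <- behavmet:::one_way_vc(y, g, "REML")
  lmm <- lme4::lmer(y ~ 1 + (1 | g), data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lmm))
  expect_equal(ours$var_group, vc$vcov[1], tolerance = 1e-4)
  expect_equal(ours$var_resid, vc$vcov[2], tolerance = 1e-4)
  expect_equal(ours$loglik, as.numeric(logLik(lmm)), tolerance = 1e-4)

  ours_ml <- behavmet:::one_way_vc(y, g, "ML")
  lmm_ml <- lme4::lmer(y ~ 1 + (1 | g), data = d, REML = FALSE)
  expect_equal(ours_ml$loglik, as.numeric(logLik(lmm_ml)), tolerance = 1e-4)
})

test_that("repeatability is zero-ish when groups share a mean", {
  set.seed(203)
  rec <- data.frame(chick_id = rep(sprintf("c%02d", 1:12), each = 6),
                    block = "pre_RAM", trial_index = 1:6,
                    latency_s = exp(rnorm(72, log(60), 1)), censored = FALSE)
  # destroy group structure by construction: one shared mean
  r <- repeatability(rec, "chick", n_bootstrap = 200, seed = 1,
                     log_transform = TRUE)
  expect_lt(r$R, 0.15)
  expect_gt(r$lrt_p, 0.05)
})

test_that("repeatability recovers the generator's target ICC", {
  cfg <- sim_config(seed = 204)
  rec <- generate_latency_data(cfg, icc_target = 0.45, block_shift = 0,
                               seed = 204)
  r <- repeatability(rec, "chick", n_bootstrap = 500, seed = 205,
                     log_transform = TRUE)
  expect_lt(abs(r$R - 0.45), 2 * r$se_R)
  expect_true(r$ci95[1] <= 0.45 && 0.45 <= r$ci95[2])
  expect_lt(r$lrt_p, 0.05)
})

test_that("block repeatability vanishes when blocks do not differ", {
  cfg <- sim_config(seed = 206)
  rec <- generate_latency_data(cfg, icc_target = 0.45, block_shift = 0,
                               seed = 206)
  r <- repeatability(rec, "block", n_bootstrap = 200, seed = 207,
                     log_transform = TRUE)
  expect_lt(r$R, 0.2)
})

test_that("R is invariant to affine transformation of the response", {
  set.seed(208)
  rec <- data.frame(chick_id = rep(sprintf("c%02d", 1:10), each = 5),
                    block = "pre_RAM", trial_index = 1:5,
                    latency_s = NA, censored = FALSE)
  rec$latency_s <- rnorm(10, 0, 1.2)[as.integer(factor(rec$chick_id))] +
    rnorm(50) + 10
  f1 <- fit_variance_components(rec, "chick")
  rec2 <- rec; rec2$latency_s <- 7.3 * rec$latency_s - 100
  f2 <- fit_variance_components(rec2, "chick")
  R <- function(f) f$var_group / (f$var_group + f$var_resid)
  expect_equal(R(f1), R(f2), tolerance = 1e-6)
})

test_that("degenerate groupings are rejected", {
  rec <- data.frame(chick_id = "c01", block = "pre_RAM", trial_index = 1:5,
                    latency_s = 1:5 + 0.5, censored = FALSE)
  expect_error(fit_variance_components(rec, "chick"), "2 groups")
})

test_that("censoring fraction rises with the block shift", {
  cfg <- sim_config(seed = 209)
  fracs <- vapply(c(0, 0.7, 1.5), function(bs)
    mean(generate_latency_data(cfg, 0.45, block_shift = bs,
                               seed = 209)$censored), 1)
  expect_true(all(diff(fracs) >= 0))
  expect_gt(fracs[3], fracs[1])
})

test_that("latency generator honours the ICC target at scale", {
  big <- sim_config(seed = 210, n_chicks = 150)
  rec <- generate_latency_data(big, icc_target = 0, block_shift = 0,
                               seed = 210, n_trials_per_block = 10)
  f <- fit_variance_components(rec, "chick", log_transform = TRUE)
  expect_lt(f$var_group / (f$var_group + f$var_resid), 0.03)
  expect_error(generate_latency_data(big, icc_target = 1.2), "icc_target")
})

test_that("trait correlation pairs records and handles censoring flags", {
  cfg <- sim_config(seed = 211)
  a <- generate_latency_data(cfg, 0.3, seed = 211, trait = "boldness")
  b <- a; b$trait <- "neophobia"
  self <- trait_correlation(a, b)
  expect_equal(self$r, 1)

  # independent traits at large n: near-zero correlation (block shifts off,
  # since a shared block effect would itself induce correlation)
  big <- sim_config(seed = 212, n_chicks = 100)
  x <- generate_latency_data(big, 0, block_shift = 0, seed = 212,
                             trait = "boldness", n_trials_per_block = 10)
  y <- generate_latency_data(big, 0, block_shift = 0, seed = 213,
                             trait = "neophobia", n_trials_per_block = 10)
  ind <- trait_correlation(x, y)
  expect_lt(abs(ind$r), 0.1)

  # dropping censored pairs removes exactly the flagged records
  x2 <- x; x2$censored[1:10] <- TRUE
  res <- trait_correlation(x2, y, drop_censored = TRUE)
  n_bad <- sum(x2$censored | y$censored)
  expect_equal(res$n_dropped, n_bad)
  expect_equal(res$n, nrow(x2) - n_bad)
  expect_error(trait_correlation(x[1:2, ], y[1:2, ]), "3")
})
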