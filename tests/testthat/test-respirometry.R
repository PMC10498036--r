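test_that("open-flow equations reproduce direct arithmetic", {
  s <- correct_baseline_drift(flat_session())
  w <- list(start_s = 100, end_s = 400)
  expect_equal(compute_vo2(s, w), (0.2095 - 0.2050) / (1 - 0.2095) * 1600,
               tolerance = 1e-10)
  expect_equal(compute_vo2(s, w), 9.108, tolerance = 1e-3)
  expect_equal(compute_vco2(s, w), (0.0046 - 0.0004) / (1 - 0.0004) * 1600,
               tolerance = 1e-10)
  expect_equal(compute_vco2(s, w), 6.723, tolerance = 1e-3)

  # excurrent equal to incurrent: no gas exchange
  s0 <- correct_baseline_drift(flat_session(an_o2 = 0.2095, an_co2 = 0.0004))
  expect_equal(compute_vo2(s0, w), 0)
  expect_equal(compute_vco2(s0, w), 0)
})

test_that("baseline drift correction interpolates linearly between baselines", {
  s <- flat_session(b1_o2 = 0.20950, b2_o2 = 0.20900)
  s <- correct_baseline_drift(s)
  # anchors at baseline mid-times; halfway between them the incurrent
  # reference is the midpoint of the two baseline means
  mid_t <- mean(s$baseline_anchor_times)
  expect_equal(behavmet:::incurrent_at(s, mid_t, "o2"), 0.20925,
               tolerance = 1e-12)
  # identical baselines: the correction is the identity on excurrent values
  si <- correct_baseline_drift(flat_session())
  expect_equal(si$readings$o2_corrected, si$readings$o2_frac)
  expect_equal(si$readings$co2_corrected, si$readings$co2_frac)
})

test_that("missing baseline segments are reported by name", {
  r <- flat_session()$readings
  r1 <- r[r$segment != "baseline2", ]
  s1 <- respirometry_session(r1, 1600)
  expect_error(correct_baseline_drift(s1), "baseline2")
})

test_that("mass correction divides by body mass and rejects bad masses", {
  expect_equal(mass_correct(9.108, 300), 0.03036)
  expect_equal(mass_correct(0, 300), 0)
  expect_error(mass_correct(9.108, 0), "mass")
  expect_error(mass_correct(9.108, -10), "mass")
})

test_that("generator round-trip recovers the true rates", {
  cfg <- sim_config(noise_sd_frac = 0, baseline_drift_frac_per_min = 0)
  s <- generate_respirometry_session(cfg, true_vo2_ml_min = 9.108,
                                     true_vco2_ml_min = 6.8, seed = 1)
  s <- correct_baseline_drift(s)
  w <- select_window(s)
  expect_identical(w$quality_flag, "default_window")
  expect_equal(compute_vo2(s, w), 9.108, tolerance = 1e-3)
  expect_equal(compute_vco2(s, w), 6.8, tolerance = 1e-3)

  # zero consumer, zero noise/drift: excurrent equals ambient everywhere
  s0 <- generate_respirometry_session(cfg, 0, 0, seed = 2)
  expect_true(all(abs(s0$readings$o2_frac - 0.2095) < 1e-12))

  # washout time constant at the defaults
  expect_equal(s$truth$washout_tau_min, 12000 / 1600)
})

test_that("linear drift of any magnitude is removed by the correction", {
  for (drift in c(1e-5, -2e-5)) {
    cfg <- sim_config(noise_sd_frac = 0, baseline_drift_frac_per_min = drift)
    s <- correct_baseline_drift(
      generate_respirometry_session(cfg, 9.108, 6.8, seed = 3))
    v <- compute_vo2(s, select_window(s))
    expect_equal(v, 9.108, tolerance = 5e-3)
  }
})

test_that("equations are homogeneous in flow", {
  # doubling flow while halving the concentration deficit leaves rates alone
  s1 <- correct_baseline_drift(flat_session(an_o2 = 0.2050, flow = 1600))
  s2 <- correct_baseline_drift(flat_session(an_o2 = 0.20725, flow = 3200))
  w <- list(start_s = 100, end_s = 400)
  expect_equal(compute_vo2(s1, w), compute_vo2(s2, w), tolerance = 1e-10)
})

test_that("window selection avoids an injected spike", {
  cfg <- sim_config(noise_sd_frac = 1e-6, baseline_drift_frac_per_min = 0)
  s <- generate_respirometry_session(cfg, 9.108, 6.8, seed = 4)
  # O2 spike during minutes 14-15 of the animal segment
  an_start <- min(s$readings$time_s[s$readings$segment == "animal"])
  spike <- s$readings$time_s >= an_start + 14 * 60 &
    s$readings$time_s < an_start + 15 * 60
  s$readings$o2_frac[spike] <- s$readings$o2_frac[spike] + 5e-4
  s <- correct_baseline_drift(s)
  w <- select_window(s)
  expect_identical(w$quality_flag, "shifted_window")
  spike_iv <- c(an_start + 14 * 60, an_start + 15 * 60)
  expect_true(w$start_s >= spike_iv[2] || w$end_s <= spike_iv[1])
  # the chosen window still recovers the rate
  expect_equal(compute_vo2(s, w), 9.108, tolerance = 5e-3)
})

test_that("all-unstable traces fall back to the minimum-SD window", {
  set.seed(5)
  s <- flat_session(n_an = 600)
  s$readings$o2_frac <- s$readings$o2_frac +
    rnorm(nrow(s$readings), 0, 1e-4)
  s <- correct_baseline_drift(s)
  w <- select_window(s, default_start_min = 1, default_end_min = 6,
                     stability_sd_threshold = 1e-7)
  expect_identical(w$quality_flag, "shifted_window")
  expect_true(w$sd_o2 > 1e-7)  # nothing qualified; argmin returned
})

test_that("negative computed rates are clipped to zero with a warning", {
  s <- correct_baseline_drift(flat_session(an_o2 = 0.2100))
  expect_warning(v <- compute_vo2(s, list(start_s = 100, end_s = 400)),
                 "negative")
  expect_equal(v, 0)
})

test_that("session validation enforces ordering and ranges", {
  r <- flat_session()$readings
  expect_error(respirometry_session(r[rev(seq_len(nrow(r))), ], 1600),
               "increasing")
  r2 <- r; r2$o2_frac[1] <- 1.2
  expect_error(respirometry_session(r2, 1600), "fraction")
  r3 <- r; r3$segment <- rev(r3$segment)
  expect_error(respirometry_session(r3, 1600), "order")
})
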