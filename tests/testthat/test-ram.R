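test_that("error counting matches the revisit definition", {
  expect_equal(count_errors(1:8), 0)
  expect_equal(count_errors(c(1, 2, 2, 3, 4, 5, 6, 7, 8)), 1)
  expect_equal(count_errors(rep(1, 10)), 9)
  tr <- ram_trial(c(1, 2, 2, 3), n_arms = 8)
  expect_equal(count_errors(tr), 1)
  expect_false(tr$completed)
  expect_true(ram_trial(1:8, 8)$completed)
})

test_that("error counts are invariant under arm relabelling", {
  set.seed(11)
  for (i in 1:20) {
    v <- sample(1:8, 30, replace = TRUE)
    perm <- sample(8)
    expect_equal(count_errors(v), count_errors(perm[v]))
  }
})

test_that("random null converges to the coupon-collector closed form", {
  n <- 8
  p <- (n:1) / n
  exact_mean <- sum(1 / p) - n        # 8*H8 - 8 = 13.7429
  exact_var <- sum((1 - p) / p^2)     # ~76.01
  expect_equal(exact_mean, 13.742857, tolerance = 1e-6)

  nd <- simulate_random_null(8, 100000, seed = 101)
  expect_lt(abs(nd$mean - exact_mean), 3 * sqrt(exact_var / 1e5))
  expect_equal(nd$sem, sd(nd$errors) / sqrt(1e5))

  nd4 <- simulate_random_null(8, 10000, seed = 102)
  expect_lt(abs(nd4$mean - exact_mean), 3 * sqrt(exact_var / 1e4))

  # one arm: never an error
  expect_true(all(simulate_random_null(1, 100, seed = 1)$errors == 0))
})

test_that("random null respects a visit cap", {
  nd <- simulate_random_null(8, 2000, seed = 7, visit_cap = 10)
  expect_true(all(nd$errors <= 10 - 1))
  expect_lt(nd$completed_fraction, 1)
  expect_lt(nd$mean, 13.74)  # truncation can only remove errors
})

test_that("agents produce the prescribed behaviour", {
  # perfect win-shift: a permutation of all arms, zero errors
  tr <- generate_ram_trial(agent_spec("memory", 1), seed = 21)
  expect_equal(sort(tr$visits), 1:8)
  expect_equal(count_errors(tr), 0)

  # deterministic clockwise stereotypy covers the maze without errors
  tr2 <- generate_ram_trial(agent_spec("stereotypic",
                                       transition_matrix = clockwise_matrix()),
                            seed = 22)
  expect_equal(count_errors(tr2), 0)
  expect_true(tr2$completed)

  # visit cap truncates
  tr3 <- generate_ram_trial(agent_spec("random", visit_cap = 5), seed = 23)
  expect_equal(length(tr3$visits), 5)
  expect_error(generate_ram_trial(agent_spec("random"), n_arms = 1), "n_arms")
})

test_that("memory fidelity lowers error counts monotonically", {
  errs <- function(rho, seed) {
    set.seed(seed)
    mean(replicate(300, count_errors(
      generate_ram_trial(agent_spec("memory", rho)))))
  }
  e_lo <- errs(0.2, 31)
  e_hi <- errs(0.8, 32)
  e_rand <- errs(0, 33)
  expect_lt(e_hi, e_lo)
  expect_lt(e_lo, e_rand + 1)  # rho > 0 does not exceed the random mean
  expect_lt(e_lo, 13.74)
})

test_that("generators are bit-identical under a fixed seed", {
  a <- generate_ram_trial(agent_spec("memory", 0.4), seed = 55)
  b <- generate_ram_trial(agent_spec("memory", 0.4), seed = 55)
  expect_identical(a, b)
  n1 <- simulate_random_null(8, 500, seed = 56)
  n2 <- simulate_random_null(8, 500, seed = 56)
  expect_identical(n1$errors, n2$errors)
})

test_that("transition matrices are estimated and normalised correctly", {
  # single clockwise trial: each observed row is a point mass on the
  # clockwise neighbour; unvisited-from rows back off to uniform
  tm <- estimate_transition_matrix(list(ram_trial(1:8, 8)))
  expect_equal(tm$probs[1, 2], 1)
  expect_equal(tm$probs[7, 8], 1)
  expect_equal(tm$probs[8, ], rep(1 / 8, 8))  # arm 8 never a 'from' state
  expect_equal(rowSums(tm$probs), rep(1, 8))

  # relative-offset mode: offset +1 has probability 1
  tmr <- estimate_transition_matrix(list(ram_trial(1:8, 8)),
                                    mode = "relative_offset")
  expect_equal(unname(tmr$offset_probs[2]), 1)  # offset 1
  expect_equal(tmr$probs[3, 4], 1)              # circulant expansion

  expect_error(estimate_transition_matrix(list(ram_trial(3, 8))),
               "transition")
})

test_that("estimated transitions converge to the generating matrix", {
  set.seed(77)
  truth <- matrix(rgamma(64, 2), 8, 8)
  truth <- truth / rowSums(truth)
  agent <- agent_spec("stereotypic", transition_matrix = truth)
  trials <- vector("list", 6000)
  for (i in seq_along(trials)) trials[[i]] <- generate_ram_trial(agent, 8)
  n_trans <- sum(vapply(trials, function(t) length(t$visits) - 1L, 1L))
  expect_gt(n_trans, 1e5)
  est <- estimate_transition_matrix(trials)
  expect_lt(max(abs(est$probs - truth)), 0.02)
})

test_that("stereotypic null handles deterministic and degenerate chains", {
  st <- simulate_stereotypic_null(clockwise_matrix(), 200, seed = 41)
  expect_true(all(st$errors == 0))
  expect_equal(st$completed_fraction, 1)

  # absorbing self-loop chain: the cap must trigger, trials incomplete
  loop <- diag(8)
  st2 <- simulate_stereotypic_null(loop, 50, seed = 42, visit_cap = 100)
  expect_equal(st2$completed_fraction, 0)
  expect_true(all(st2$errors == 99))
  expect_error(simulate_stereotypic_null(loop, 5, seed = 43, max_steps = 500),
               "cover")
})

test_that("comparison against a null follows the one-sided t-test", {
  nd <- simulate_random_null(8, 5000, seed = 51)
  set.seed(52)
  obs <- pmax(0, round(rnorm(50, nd$mean - 3, 4)))
  res <- compare_to_null(obs, nd)
  expect_equal(res$df, 49)
  expect_lt(res$t, 0)
  expect_lt(res$p, 0.05)
  ref <- t.test(obs, mu = nd$mean, alternative = "less")
  expect_equal(res$p, ref$p.value)

  # degenerate branches
  all_mean <- rep(nd$mean, 5)
  expect_equal(compare_to_null(all_mean, nd)$p, 0.5)
  expect_equal(compare_to_null(all_mean, nd)$t, 0)
  expect_equal(compare_to_null(rep(0, 2), nd)$p, 0)
  expect_equal(compare_to_null(rep(100, 2), nd)$p, 1)
  expect_error(compare_to_null(3, nd), "2 observed")
})
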