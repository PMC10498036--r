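# Shared fixtures, built in code.

# Minimal hand-built session: flat baselines (optionally differing), constant
# animal-segment excurrent values, 1-s sampling.
flat_session <- function(b1_o2 = 0.2095, b2_o2 = b1_o2,
                         an_o2 = 0.2050,
                         b1_co2 = 0.0004, b2_co2 = b1_co2,
                         an_co2 = 0.0046,
                         n_b1 = 100, n_an = 400, n_b2 = 100,
                         flow = 1600) {
  respirometry_session(
    data.frame(
      time_s = seq_len(n_b1 + n_an + n_b2) - 1,
      segment = rep(c("baseline1", "animal", "baseline2"),
                    c(n_b1, n_an, n_b2)),
      o2_frac = rep(c(b1_o2, an_o2, b2_o2), c(n_b1, n_an, n_b2)),
      co2_frac = rep(c(b1_co2, an_co2, b2_co2), c(n_b1, n_an, n_b2))),
    flow_rate_ml_min = flow)
}

# Deterministic clockwise transition matrix (arm i -> i+1 mod n).
clockwise_matrix <- function(n_arms = 8) {
  tm <- matrix(0, n_arms, n_arms)
  for (i in seq_len(n_arms)) tm[i, i %% n_arms + 1] <- 1
  tm
}

# Independent loop-based recomputation of David's score from a proportion
# matrix, kept deliberately naive.
davids_score_loops <- function(P) {
  n <- nrow(P)
  w <- l <- w2 <- l2 <- numeric(n)
  for (i in 1:n) for (j in 1:n) {
    w[i] <- w[i] + P[i, j]
    l[i] <- l[i] + P[j, i]
  }
  for (i in 1:n) for (j in 1:n) {
    w2[i] <- w2[i] + P[i, j] * w[j]
    l2[i] <- l2[i] + P[j, i] * l[j]
  }
  w + w2 - l - l2
}

# Random win-count matrix for a group of n individuals.
random_wins <- function(n = 12, lambda = 3) {
  w <- matrix(rpois(n * n, lambda), n, n)
  diag(w) <- 0
  w
}
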