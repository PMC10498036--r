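#' Simulate censored latency records for one personality trait
#'
#' Latencies to leave a shelter are generated on the log scale as an
#' individual random intercept plus a block effect plus residual noise, then
#' exponentiated and right-censored at the assay cap (censored trials are
#' recorded at the cap with a flag, the way they are assigned in the assay).
#' The individual and residual variances are chosen so that the intraclass
#' correlation of the log latencies equals `icc_target`.
#'
#' @param config A [sim_config()]; supplies `n_chicks` and `latency_cap_s`.
#' @param icc_target Target repeatability of log latency, in \[0, 1).
#' @param block_shift Additive shift of mean log latency in the post block
#'   (positive values make animals slower to emerge after the memory-testing
#'   phase, raising the censoring fraction).
#' @param seed Integer seed.
#' @param trait Trait label stamped on the records.
#' @param n_trials_per_block Trials per individual in each of the two blocks.
#' @param mu_log Baseline mean log latency (log seconds).
#' @param total_log_var Total variance of log latency (individual +
#'   residual).
#' @param chick_effects Optional vector of pre-drawn individual intercepts
#'   (log scale), one per chick, overriding the random draw — used to share
#'   individuals across traits.
#' @param predictor_effect Optional per-chick shift of mean log latency
#'   (e.g. a metabolic-rate effect), a vector of length `n_chicks`.
#' @return Data frame with columns `chick_id`, `trait`, `block`,
#'   `trial_index`, `latency_s`, `censored`, and the ground truth
#'   (individual effects and variance components) in `attr(, "truth")`.
#' @export
generate_latency_data <- function(config, icc_target, block_shift = 0.7,
                                  seed = config$seed, trait = "boldness",
                                  n_trials_per_block = 3L,
                                  mu_log = log(60), total_log_var = 1.2,
                                  chick_effects = NULL,
                                  predictor_effect = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (icc_target < 0 || icc_target >= 1)
    stop("icc_target must lie in [0, 1)", call. = FALSE)
  set.seed(seed)
  n <- config$n_chicks
  var_i <- icc_target * total_log_var
  var_e <- (1 - icc_target) * total_log_var
  b <- if (is.null(chick_effects)) stats::rnorm(n, 0, sqrt(var_i))
       else chick_effects
  shift <- if (is.null(predictor_effect)) rep(0, n) else predictor_effect

  grid <- expand.grid(trial_index = seq_len(n_trials_per_block),
                      block = c("pre_RAM", "post_RAM"),
                      chick = seq_len(n),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  loglat <- mu_log + b[grid$chick] + shift[grid$chick] +
    ifelse(grid$block == "post_RAM", block_shift, 0) +
    stats::rnorm(nrow(grid), 0, sqrt(var_e))
  lat <- exp(loglat)
  cens <- lat >= config$latency_cap_s
  lat[cens] <- config$latency_cap_s

  out <- data.frame(chick_id = sprintf("chick%02d", grid$chick),
                    trait = trait,
                    block = grid$block,
                    trial_index = grid$trial_index,
                    latency_s = lat,
                    censored = cens,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(icc_target = icc_target, var_i = var_i,
                             var_e = var_e, mu_log = mu_log,
                             block_shift = block_shift,
                             chick_effects = b, seed = seed)
  out
}
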