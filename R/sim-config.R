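#' Configuration for the synthetic study generator
#'
#' Bundles the protocol constants of the study design the generators emulate:
#' group size, trial counts, the respirometry rig (flow rate, chamber volume,
#' ambient gas fractions, analyser drift and noise) and the latency cap used
#' in the personality assays.
#'
#' @param seed Integer seed recorded with the configuration; generators that
#'   take their own `seed` argument override it.
#' @param n_chicks Number of individuals in the group.
#' @param n_ram_trials Radial-arm-maze trials per individual.
#' @param n_arms Number of maze arms.
#' @param rmr_sessions_per_chick Respirometry sessions per individual.
#' @param flow_rate_ml_min Pull rate of ambient air through the chamber
#'   (ml min^-1).
#' @param chamber_volume_ml Respirometry chamber volume (ml). The washout time
#'   constant of the well-mixed chamber is `chamber_volume_ml /
#'   flow_rate_ml_min` minutes.
#' @param ambient_o2_frac,ambient_co2_frac Ambient (incurrent) gas fractions.
#' @param baseline_drift_frac_per_min Linear analyser/ambient drift applied to
#'   both gas channels, in absolute fraction units per minute.
#' @param noise_sd_frac Gaussian analyser noise SD, in fraction units.
#' @param latency_cap_s Right-censoring cap for latency assays (s).
#'
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 42)
#' cfg$chamber_volume_ml / cfg$flow_rate_ml_min  # washout time constant, min
#' @export
sim_config <- function(seed = 1L,
                       n_chicks = 12L,
                       n_ram_trials = 14L,
                       n_arms = 8L,
                       rmr_sessions_per_chick = 6L,
                       flow_rate_ml_min = 1600,
                       chamber_volume_ml = 12000,
                       ambient_o2_frac = 0.2095,
                       ambient_co2_frac = 0.0004,
                       baseline_drift_frac_per_min = 1e-6,
                       noise_sd_frac = 2e-6,
                       latency_cap_s = 600) {
  counts <- c(n_chicks = n_chicks, n_ram_trials = n_ram_trials,
              n_arms = n_arms, rmr_sessions_per_chick = rmr_sessions_per_chick)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all counts must be integers >= 1", call. = FALSE)
  fracs <- c(ambient_o2_frac = ambient_o2_frac,
             ambient_co2_frac = ambient_co2_frac)
  if (any(fracs <= 0 | fracs >= 1))
    stop("gas fractions must lie in (0, 1)", call. = FALSE)
  if (flow_rate_ml_min <= 0 || chamber_volume_ml <= 0)
    stop("flow rate and chamber volume must be > 0", call. = FALSE)
  if (baseline_drift_frac_per_min < 0 && abs(baseline_drift_frac_per_min) > 1)
    stop("baseline drift is a fraction per minute", call. = FALSE)
  if (noise_sd_frac < 0) stop("noise_sd_frac must be >= 0", call. = FALSE)
  if (latency_cap_s <= 0) stop("latency_cap_s must be > 0", call. = FALSE)

  structure(list(
    seed = as.integer(seed),
    n_chicks = as.integer(n_chicks),
    n_ram_trials = as.integer(n_ram_trials),
    n_arms = as.integer(n_arms),
    rmr_sessions_per_chick = as.integer(rmr_sessions_per_chick),
    flow_rate_ml_min = flow_rate_ml_min,
    chamber_volume_ml = chamber_volume_ml,
    ambient_o2_frac = ambient_o2_frac,
    ambient_co2_frac = ambient_co2_frac,
    baseline_drift_frac_per_min = baseline_drift_frac_per_min,
    noise_sd_frac = noise_sd_frac,
    latency_cap_s = latency_cap_s
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  %d chicks, %d maze trials each (%d arms), %d respirometry sessions each\n",
              x$n_chicks, x$n_ram_trials, x$n_arms, x$rmr_sessions_per_chick))
  cat(sprintf("  flow %.0f ml/min, chamber %.0f ml (washout tau %.2f min)\n",
              x$flow_rate_ml_min, x$chamber_volume_ml,
              x$chamber_volume_ml / x$flow_rate_ml_min))
  cat(sprintf("  ambient O2 %.4f, CO2 %.4f; drift %.2g/min, noise SD %.2g\n",
              x$ambient_o2_frac, x$ambient_co2_frac,
              x$baseline_drift_frac_per_min, x$noise_sd_frac))
  cat(sprintf("  latency cap %g s; seed %d\n", x$latency_cap_s, x$seed))
  invisible(x)
}

#' Behavioural agent specification for maze simulations
#'
#' Describes how a simulated animal chooses the next maze arm. A `memory`
#' agent applies a win-shift rule with fidelity `memory_fidelity`: at each
#' step, with probability rho it picks uniformly among the arms it has not yet
#' visited, otherwise uniformly among all arms. A `random` agent is the
#' rho = 0 special case. A `stereotypic` agent follows a first-order Markov
#' chain over arms given by `transition_matrix`.
#'
#' @param kind One of `"memory"`, `"random"`, `"stereotypic"`.
#' @param memory_fidelity Probability rho in \[0, 1\] of an informed
#'   (win-shift) choice; required for `memory` agents.
#' @param transition_matrix Row-stochastic matrix over arms; required for
#'   `stereotypic` agents. Rows must sum to 1 within 1e-9.
#' @param visit_cap Optional maximum number of arm visits per trial,
#'   mimicking truncated (timed-out) trials.
#'
#' @return An object of class `agent_spec`.
#' @examples
#' agent_spec("memory", memory_fidelity = 0.5)
#' agent_spec("random")
#' @export
agent_spec <- function(kind = c("memory", "random", "stereotypic"),
                       memory_fidelity = NULL,
                       transition_matrix = NULL,
                       visit_cap = NULL) {
  kind <- match.arg(kind)
  if (kind == "memory") {
    if (is.null(memory_fidelity))
      stop("memory agents need a memory_fidelity", call. = FALSE)
    if (memory_fidelity < 0 || memory_fidelity > 1)
      stop("memory_fidelity must lie in [0, 1]", call. = FALSE)
  }
  if (kind == "random") memory_fidelity <- 0
  if (kind == "stereotypic") {
    if (is.null(transition_matrix))
      stop("stereotypic agents need a transition_matrix", call. = FALSE)
    transition_matrix <- as.matrix(transition_matrix)
    if (nrow(transition_matrix) != ncol(transition_matrix))
      stop("transition_matrix must be square", call. = FALSE)
    if (any(transition_matrix < 0) ||
        any(abs(rowSums(transition_matrix) - 1) > 1e-9))
      stop("transition_matrix rows must sum to 1 (within 1e-9)", call. = FALSE)
  }
  if (!is.null(visit_cap) && (visit_cap < 1 || visit_cap != round(visit_cap)))
    stop("visit_cap must be a positive integer", call. = FALSE)
  structure(list(kind = kind, memory_fidelity = memory_fidelity,
                 transition_matrix = transition_matrix,
                 visit_cap = visit_cap),
            class = "agent_spec")
}

# Deterministic fan-out of one master seed into per-stage streams, so that
# changing e.g. maze iterations never perturbs the latency simulation.
stage_seed <- function(seed, stage) {
  stages <- c("respirometry", "ram", "latency", "dominance", "mass", "models")
  i <- match(stage, stages)
  if (is.na(i)) stop("unknown stage: ", stage, call. = FALSE)
  as.integer((as.numeric(seed) * 97 + i * 10007) %% 2147483587L)
}
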