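#' Simulate an open-flow respirometry session
#'
#' Generates one gas trace with the structure of a standard session: an
#' opening ambient baseline, the animal's chamber trace, and a closing
#' ambient baseline. The chamber is modelled as a single well-mixed
#' compartment, so the excurrent fractions relax exponentially toward the
#' steady state implied by inverting the open-flow equations, with time
#' constant `chamber_volume_ml / flow_rate_ml_min` (7.5 min at the defaults,
#' i.e. a chamber flush-out of roughly 8 min). Linear ambient drift is applied
#' to both channels and Gaussian analyser noise added on top.
#'
#' In the emulated protocol the animal sits in its chamber for the whole
#' session while the analyser samples chambers in turn, so by the time its
#' 20-min segment is recorded the chamber is already deep into equilibration;
#' `occupancy_offset_min` is the time the animal has been inside the chamber
#' when its recorded segment begins.
#'
#' @param config A [sim_config()].
#' @param true_vo2_ml_min,true_vco2_ml_min Ground-truth rates (ml min^-1).
#' @param seed Integer seed.
#' @param chick_id Identifier recorded on the session.
#' @param baseline1_min,animal_min,baseline2_min Segment lengths in minutes.
#' @param occupancy_offset_min Minutes the animal has already spent in the
#'   chamber before the recorded animal segment starts.
#' @param sample_interval_s Sampling interval of the analyser (s).
#'
#' @return A [respirometry_session()] whose `truth` field records the true
#'   rates, the washout time constant and the segment layout.
#' @export
generate_respirometry_session <- function(config,
                                          true_vo2_ml_min,
                                          true_vco2_ml_min,
                                          seed = config$seed,
                                          chick_id = "chick01",
                                          baseline1_min = 20,
                                          animal_min = 20,
                                          baseline2_min = 10,
                                          occupancy_offset_min = 40,
                                          sample_interval_s = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (true_vo2_ml_min < 0 || true_vco2_ml_min < 0)
    stop("true rates must be >= 0", call. = FALSE)
  fr <- config$flow_rate_ml_min
  fi_o2 <- config$ambient_o2_frac
  fi_co2 <- config$ambient_co2_frac
  # steady-state excurrent fractions from inverting the open-flow equations
  def_o2 <- true_vo2_ml_min * (1 - fi_o2) / fr
  def_co2 <- true_vco2_ml_min * (1 - fi_co2) / fr
  if (fi_o2 - def_o2 <= 0)
    stop("steady-state excurrent O2 would be <= 0; VO2 too large for this flow",
         call. = FALSE)
  tau_s <- config$chamber_volume_ml / fr * 60

  set.seed(seed)
  dt <- sample_interval_s
  t_b1 <- seq(0, baseline1_min * 60 - dt, by = dt)
  t_an <- seq(baseline1_min * 60, (baseline1_min + animal_min) * 60 - dt, by = dt)
  t_b2 <- seq((baseline1_min + animal_min) * 60,
              (baseline1_min + animal_min + baseline2_min) * 60 - dt, by = dt)
  tt <- c(t_b1, t_an, t_b2)
  segment <- rep(c("baseline1", "animal", "baseline2"),
                 c(length(t_b1), length(t_an), length(t_b2)))

  drift <- config$baseline_drift_frac_per_min / 60  # per second
  amb_o2 <- fi_o2 + drift * tt
  amb_co2 <- fi_co2 + drift * tt

  # time since the animal entered the chamber, for the recorded segment
  occ_s <- (t_an - t_an[1]) + occupancy_offset_min * 60
  wash <- 1 - exp(-occ_s / tau_s)
  o2 <- amb_o2
  co2 <- amb_co2
  an_idx <- segment == "animal"
  o2[an_idx] <- o2[an_idx] - def_o2 * wash
  co2[an_idx] <- co2[an_idx] + def_co2 * wash

  if (config$noise_sd_frac > 0) {
    o2 <- o2 + stats::rnorm(length(o2), 0, config$noise_sd_frac)
    co2 <- co2 + stats::rnorm(length(co2), 0, config$noise_sd_frac)
  }
  co2 <- pmax(co2, 1e-8)  # fractions must stay positive under noise

  respirometry_session(
    data.frame(time_s = tt, segment = segment, o2_frac = o2, co2_frac = co2),
    flow_rate_ml_min = fr, chick_id = chick_id,
    truth = list(true_vo2_ml_min = true_vo2_ml_min,
                 true_vco2_ml_min = true_vco2_ml_min,
                 washout_tau_min = tau_s / 60,
                 occupancy_offset_min = occupancy_offset_min,
                 seed = seed))
}
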