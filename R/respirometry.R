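#' Open-flow respirometry session
#'
#' Container for one gas trace: time-stamped excurrent O2/CO2 fractions with
#' segment labels (`baseline1` ambient reference, `animal` chamber trace,
#' `baseline2` closing ambient reference) and the pull flow rate.
#'
#' @param readings Data frame with columns `time_s`, `segment`, `o2_frac`,
#'   `co2_frac`. Times must be strictly increasing; fractions in (0, 1);
#'   `baseline1` must precede `animal` which must precede `baseline2`.
#' @param flow_rate_ml_min Flow rate at which ambient air is pulled through
#'   the chamber (ml min^-1).
#' @param chick_id Identifier of the animal in the chamber.
#' @param truth Optional list of ground-truth metadata attached by the
#'   synthetic generator (true rates, washout time constant, ...).
#'
#' @return An object of class `respirometry_session`.
#' @export
respirometry_session <- function(readings, flow_rate_ml_min,
                                 chick_id = NA_character_, truth = NULL) {
  need <- c("time_s", "segment", "o2_frac", "co2_frac")
  if (!all(need %in% names(readings)))
    stop("readings must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  readings <- as.data.frame(readings)
  if (any(diff(readings$time_s) <= 0))
    stop("reading times must be strictly increasing", call. = FALSE)
  fr <- c(readings$o2_frac, readings$co2_frac)
  if (any(fr <= 0 | fr >= 1))
    stop("gas fractions must lie in (0, 1)", call. = FALSE)
  ok <- readings$segment %in% c("baseline1", "animal", "baseline2")
  if (!all(ok)) stop("unknown segment label(s): ",
                     paste(unique(readings$segment[!ok]), collapse = ", "),
                     call. = FALSE)
  seg_order <- rle(readings$segment)$values
  want <- c("baseline1", "animal", "baseline2")
  if (!identical(seg_order, want[want %in% seg_order]) ||
      is.unsorted(match(seg_order, want)))
    stop("segments must appear in order baseline1, animal, baseline2",
         call. = FALSE)
  if (flow_rate_ml_min <= 0) stop("flow rate must be > 0", call. = FALSE)
  structure(list(readings = readings,
                 flow_rate_ml_min = flow_rate_ml_min,
                 chick_id = chick_id,
                 truth = truth,
                 corrected = FALSE,
                 incurrent = NULL),
            class = "respirometry_session")
}

#' @export
print.respirometry_session <- function(x, ...) {
  segs <- table(x$readings$segment)
  cat(sprintf("Respirometry session%s: %d readings, flow %.0f ml/min\n",
              if (is.na(x$chick_id)) "" else paste0(" (", x$chick_id, ")"),
              nrow(x$readings), x$flow_rate_ml_min))
  for (s in c("baseline1", "animal", "baseline2"))
    if (s %in% names(segs)) cat(sprintf("  %-9s %5d readings\n", s, segs[[s]]))
  if (isTRUE(x$corrected))
    cat(sprintf("  baseline-drift corrected (incurrent O2 %.5f, CO2 %.5f)\n",
                x$incurrent[["o2"]], x$incurrent[["co2"]]))
  invisible(x)
}

seg_rows <- function(session, segment) {
  session$readings[session$readings$segment == segment, , drop = FALSE]
}

#' Correct a session for ambient baseline drift
#'
#' The incurrent (ambient) reference is defined at every time point by linear
#' interpolation between the mean of the opening baseline and the mean of the
#' closing baseline (anchored at the mid-time of each baseline segment), for
#' O2 and CO2 separately. Excurrent readings in the animal segment are shifted
#' by the interpolated drift so that the opening-baseline mean can be used as
#' a constant incurrent fraction downstream. Linear drift of any magnitude is
#' removed exactly by this construction.
#'
#' @param session A [respirometry_session()].
#' @return The session with columns `o2_corrected`, `co2_corrected` added to
#'   its readings, the constant incurrent fractions stored in
#'   `session$incurrent`, and `corrected = TRUE`.
#' @export
correct_baseline_drift <- function(session) {
  stopifnot(inherits(session, "respirometry_session"))
  for (s in c("baseline1", "baseline2"))
    if (nrow(seg_rows(session, s)) == 0)
      stop("missing segment: ", s, call. = FALSE)
  b1 <- seg_rows(session, "baseline1")
  b2 <- seg_rows(session, "baseline2")
  t1 <- mean(b1$time_s); t2 <- mean(b2$time_s)
  ref <- list(o2 = c(mean(b1$o2_frac), mean(b2$o2_frac)),
              co2 = c(mean(b1$co2_frac), mean(b2$co2_frac)))
  interp <- function(anchors, t)
    anchors[1] + (anchors[2] - anchors[1]) * (t - t1) / (t2 - t1)
  t <- session$readings$time_s
  session$readings$o2_corrected <-
    session$readings$o2_frac - (interp(ref$o2, t) - ref$o2[1])
  session$readings$co2_corrected <-
    session$readings$co2_frac - (interp(ref$co2, t) - ref$co2[1])
  session$incurrent <- c(o2 = ref$o2[1], co2 = ref$co2[1])
  session$baseline_anchor_times <- c(t1, t2)
  session$corrected <- TRUE
  session
}

# Incurrent reference fraction at arbitrary times (after drift correction).
incurrent_at <- function(session, time_s, gas = c("o2", "co2")) {
  gas <- match.arg(gas)
  stopifnot(isTRUE(session$corrected))
  b1 <- seg_rows(session, "baseline1"); b2 <- seg_rows(session, "baseline2")
  a <- if (gas == "o2") c(mean(b1$o2_frac), mean(b2$o2_frac))
       else c(mean(b1$co2_frac), mean(b2$co2_frac))
  tt <- session$baseline_anchor_times
  a[1] + (a[2] - a[1]) * (time_s - tt[1]) / (tt[2] - tt[1])
}

# Running SD of x over every contiguous window of `w` samples, via cumulative
# sums (one pass, numerically adequate at trace scale).
running_sd <- function(x, w) {
  n <- length(x)
  if (w > n) return(numeric(0))
  cs <- cumsum(c(0, x)); cs2 <- cumsum(c(0, x^2))
  s <- cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]
  s2 <- cs2[(w + 1):(n + 1)] - cs2[1:(n - w + 1)]
  v <- pmax((s2 - s^2 / w) / (w - 1), 0)
  sqrt(v)
}

#' Select the scoring window of a respirometry trace
#'
#' Rates are averaged over a 5-min window of the animal segment, by default
#' minutes 13 to 18, which leaves time for the animal to settle and the
#' chamber air to turn over. If the trace is unstable there (O2 or CO2 peaks,
#' oscillation), the nearest stable 5-min window is used instead: among all
#' candidate windows on the sampling grid whose O2 and CO2 standard deviations
#' are below threshold, the one whose start is closest to the default start;
#' if no window qualifies, the window with the globally smallest (threshold-
#' normalised) SD, flagged `shifted_window`.
#'
#' @param session A drift-corrected [respirometry_session()] (raw fractions
#'   are used if the session has not been corrected).
#' @param default_start_min,default_end_min Default window, in minutes from
#'   the start of the animal segment.
#' @param stability_sd_threshold SD threshold in fraction units, applied to
#'   both gases. Default: 3 times the median windowed SD of the animal
#'   segment, per gas.
#' @return A list with `start_s`, `end_s` (absolute trace times, half-open
#'   window), `quality_flag` (`"default_window"` or `"shifted_window"`), and
#'   the window SDs.
#' @export
select_window <- function(session, default_start_min = 13,
                          default_end_min = 18,
                          stability_sd_threshold = NULL) {
  stopifnot(inherits(session, "respirometry_session"))
  an <- seg_rows(session, "animal")
  win_len_s <- (default_end_min - default_start_min) * 60
  if (nrow(an) < 2) stop("animal segment is empty or too short", call. = FALSE)
  dt <- stats::median(diff(an$time_s))
  seg_span <- an$time_s[nrow(an)] - an$time_s[1] + dt
  if (seg_span < win_len_s)
    stop("animal segment is shorter than the scoring window", call. = FALSE)

  o2 <- if (isTRUE(session$corrected)) an$o2_corrected else an$o2_frac
  co2 <- if (isTRUE(session$corrected)) an$co2_corrected else an$co2_frac
  w <- max(2L, round(win_len_s / dt))
  sd_o2 <- running_sd(o2, w)
  sd_co2 <- running_sd(co2, w)
  starts <- an$time_s[seq_along(sd_o2)]

  thr_o2 <- thr_co2 <- stability_sd_threshold
  if (is.null(stability_sd_threshold)) {
    thr_o2 <- 3 * stats::median(sd_o2)
    thr_co2 <- 3 * stats::median(sd_co2)
  }

  default_start <- an$time_s[1] + default_start_min * 60
  i_def <- which.min(abs(starts - default_start))
  pick <- function(i, flag) list(
    start_s = starts[i], end_s = starts[i] + win_len_s, quality_flag = flag,
    sd_o2 = sd_o2[i], sd_co2 = sd_co2[i],
    threshold = c(o2 = thr_o2, co2 = thr_co2))

  if (sd_o2[i_def] <= thr_o2 && sd_co2[i_def] <= thr_co2)
    return(pick(i_def, "default_window"))
  ok <- sd_o2 <= thr_o2 & sd_co2 <= thr_co2
  if (any(ok)) {
    cand <- which(ok)
    i <- cand[which.min(abs(starts[cand] - default_start))]
    return(pick(i, "shifted_window"))
  }
  # no window is stable: fall back to the least unstable one
  score <- pmax(sd_o2 / thr_o2, sd_co2 / thr_co2)
  pick(which.min(score), "shifted_window")
}

window_means <- function(session, window) {
  an <- seg_rows(session, "animal")
  if (is.list(window)) window <- c(window$start_s, window$end_s)
  sel <- an$time_s >= window[1] & an$time_s < window[2]
  if (!any(sel)) stop("window contains no animal-segment readings",
                      call. = FALSE)
  list(o2 = mean(if (isTRUE(session$corrected)) an$o2_corrected[sel]
                 else an$o2_frac[sel]),
       co2 = mean(if (isTRUE(session$corrected)) an$co2_corrected[sel]
                  else an$co2_frac[sel]),
       times = range(an$time_s[sel]))
}

#' Rate of oxygen consumption from an open-flow trace
#'
#' Applies the open-flow equation
#' \deqn{\dot{V}O_2 = \frac{F_iO_2 - F_eO_2}{1 - F_iO_2} \times FR}
#' where the incurrent fraction is the (drift-corrected) ambient baseline, the
#' excurrent fraction is the mean of the chamber trace over the scoring
#' window, and FR is the flow rate. Negative results (possible under noise)
#' are clipped to zero with a warning.
#'
#' @param session A drift-corrected [respirometry_session()].
#' @param window Window as returned by [select_window()], or a numeric
#'   `c(start_s, end_s)`.
#' @return Rate in ml min^-1.
#' @examples
#' # direct arithmetic: (0.2095 - 0.2050) / (1 - 0.2095) * 1600 = 9.108
#' @export
compute_vo2 <- function(session, window) {
  stopifnot(inherits(session, "respirometry_session"))
  if (!isTRUE(session$corrected))
    stop("session must be baseline-corrected first (correct_baseline_drift)",
         call. = FALSE)
  fi <- session$incurrent[["o2"]]
  if (fi >= 1) stop("incurrent O2 fraction must be < 1", call. = FALSE)
  fe <- window_means(session, window)$o2
  v <- (fi - fe) / (1 - fi) * session$flow_rate_ml_min
  if (v < 0) {
    warning("negative VO2 (", signif(v, 3), " ml/min) clipped to 0")
    v <- 0
  }
  v
}

#' Rate of carbon dioxide production from an open-flow trace
#'
#' Applies the companion open-flow equation
#' \deqn{\dot{V}CO_2 = \frac{F_eCO_2 - F_iCO_2}{1 - F_iCO_2} \times FR.}
#'
#' @inheritParams compute_vo2
#' @return Rate in ml min^-1.
#' @export
compute_vco2 <- function(session, window) {
  stopifnot(inherits(session, "respirometry_session"))
  if (!isTRUE(session$corrected))
    stop("session must be baseline-corrected first (correct_baseline_drift)",
         call. = FALSE)
  fi <- session$incurrent[["co2"]]
  if (fi >= 1) stop("incurrent CO2 fraction must be < 1", call. = FALSE)
  fe <- window_means(session, window)$co2
  v <- (fe - fi) / (1 - fi) * session$flow_rate_ml_min
  if (v < 0) {
    warning("negative VCO2 (", signif(v, 3), " ml/min) clipped to 0")
    v <- 0
  }
  v
}

#' Mass-correct a metabolic rate
#'
#' @param vo2 Rate in ml min^-1 (O2 or CO2).
#' @param mass_g Body mass in grams; must be positive.
#' @return Rate per gram (ml min^-1 g^-1).
#' @export
mass_correct <- function(vo2, mass_g) {
  if (any(mass_g <= 0)) stop("body mass must be > 0", call. = FALSE)
  vo2 / mass_g
}

#' Estimate resting metabolic rate from one session
#'
#' Convenience wrapper running the full chain: baseline-drift correction,
#' scoring-window selection, the two open-flow equations, and mass
#' correction.
#'
#' @param session A [respirometry_session()].
#' @param mass_g Body mass of the animal measured at the session (g).
#' @param ... Passed to [select_window()].
#' @return An object of class `rmr_estimate` with fields `chick_id`,
#'   `vo2_ml_min`, `vco2_ml_min`, `window`, `body_mass_g`,
#'   `vo2_mass_corrected`, `quality_flag`.
#' @export
estimate_rmr <- function(session, mass_g, ...) {
  s <- if (isTRUE(session$corrected)) session else correct_baseline_drift(session)
  w <- select_window(s, ...)
  vo2 <- compute_vo2(s, w)
  vco2 <- compute_vco2(s, w)
  structure(list(chick_id = s$chick_id,
                 vo2_ml_min = vo2,
                 vco2_ml_min = vco2,
                 window = c(start_s = w$start_s, end_s = w$end_s),
                 body_mass_g = mass_g,
                 vo2_mass_corrected = mass_correct(vo2, mass_g),
                 quality_flag = w$quality_flag),
            class = "rmr_estimate")
}

#' @export
print.rmr_estimate <- function(x, ...) {
  cat(sprintf("RMR estimate%s: VO2 %.3f, VCO2 %.3f ml/min (%s)\n",
              if (is.na(x$chick_id)) "" else paste0(" [", x$chick_id, "]"),
              x$vo2_ml_min, x$vco2_ml_min, x$quality_flag))
  cat(sprintf("  mass %.1f g -> %.5f ml/min/g; window %d-%d s\n",
              x$body_mass_g, x$vo2_mass_corrected,
              round(x$window[["start_s"]]), round(x$window[["end_s"]])))
  invisible(x)
}

#' Tabulate RMR estimates for a batch of sessions
#'
#' @param sessions List of [respirometry_session()] objects.
#' @param masses Data frame with columns `chick_id`, `session_index`,
#'   `mass_g` (one row per session), or a numeric vector parallel to
#'   `sessions`.
#' @param ... Passed to [estimate_rmr()].
#' @return Data frame with one row per session: chick id, session index,
#'   vo2, vco2, mass, mass-corrected vo2, window start and quality flag.
#' @export
rmr_table <- function(sessions, masses, ...) {
  mass_of <- function(i, s) {
    if (is.numeric(masses)) return(list(mass = masses[i], day = NA_real_))
    sel <- masses$chick_id == s$chick_id &
      masses$session_index == s$truth$session_index
    if (sum(sel) != 1) stop("no unique mass for session ", i, call. = FALSE)
    list(mass = masses$mass_g[sel],
         day = if ("day" %in% names(masses)) masses$day[sel] else NA_real_)
  }
  rows <- lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    mo <- mass_of(i, s)
    est <- estimate_rmr(s, mo$mass, ...)
    data.frame(chick_id = est$chick_id,
               session_index = if (!is.null(s$truth$session_index))
                 s$truth$session_index else i,
               day = if (!is.null(s$truth$day)) s$truth$day else mo$day,
               vo2_ml_min = est$vo2_ml_min,
               vco2_ml_min = est$vco2_ml_min,
               mass_g = est$body_mass_g,
               vo2_mass_corrected = est$vo2_mass_corrected,
               window_start_s = est$window[["start_s"]],
               quality_flag = est$quality_flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
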