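# Flatten a simulated study into the five CSV-shaped tables.
study_tables <- function(study) {
  sess <- do.call(rbind, lapply(seq_along(study$sessions), function(i) {
    s <- study$sessions[[i]]
    data.frame(session_id = sprintf("s%03d", i),
               chick_id = s$chick_id,
               session_index = if (!is.null(s$truth$session_index))
                 s$truth$session_index else NA_integer_,
               time_s = s$readings$time_s,
               segment = s$readings$segment,
               o2_frac = s$readings$o2_frac,
               co2_frac = s$readings$co2_frac,
               flow_ml_min = s$flow_rate_ml_min,
               stringsAsFactors = FALSE)
  }))
  lat <- do.call(rbind, study$latencies)
  rownames(lat) <- NULL
  inter <- do.call(rbind, lapply(seq_along(study$dominance), function(k) {
    w <- study$dominance[[k]]$wins
    idx <- which(w > 0, arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    data.frame(trial_id = k,
               winner_id = rownames(w)[idx[, 1]],
               loser_id = colnames(w)[idx[, 2]],
               count = w[idx],
               stringsAsFactors = FALSE)
  }))
  list(sessions = sess,
       ram_trials = ram_trials_df(study$ram_trials),
       latencies = lat,
       interactions = inter,
       masses = study$masses)
}

#' Write simulated study inputs to CSV
#'
#' Writes the five input tables (`sessions.csv`, `ram_trials.csv`,
#' `latencies.csv`, `interactions.csv`, `masses.csv`) plus a
#' `metadata.json` sidecar echoing the seed and configuration.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if missing).
#' @param config Optional [run_config()] echoed into the sidecar.
#' @return Invisibly, the vector of files written.
#' @export
write_simulated_inputs <- function(study, dir, config = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- study_tables(study)
  files <- character(0)
  for (nm in names(tabs)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tabs[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  meta <- list(seed = study$truth$seed,
               n_chicks = length(study$truth$ids),
               effects = study$truth$effects,
               config = if (!is.null(config))
                 config[c("seed", "ram", "repeatability", "effects")]
               else NULL)
  mf <- file.path(dir, "metadata.json")
  jsonlite::write_json(meta, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(files, mf))
}

#' Read study inputs back from CSV
#'
#' Inverse of [write_simulated_inputs()]: reconstructs the session objects,
#' maze trials, latency tables, interaction matrices and masses from a
#' directory of CSV files.
#'
#' @param dir Directory containing the input CSVs.
#' @return A study list in the shape produced by [simulate_study()] (without
#'   ground-truth metadata).
#' @export
read_study_inputs <- function(dir) {
  rd <- function(nm) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(f)) stop("missing input file: ", f, call. = FALSE)
    utils::read.csv(f, stringsAsFactors = FALSE)
  }
  sess_df <- rd("sessions")
  sessions <- lapply(split(sess_df, sess_df$session_id), function(d) {
    d <- d[order(d$time_s), ]
    s <- respirometry_session(
      d[, c("time_s", "segment", "o2_frac", "co2_frac")],
      flow_rate_ml_min = d$flow_ml_min[1], chick_id = d$chick_id[1])
    s$truth <- list(session_index = d$session_index[1])
    s
  })
  ram_df <- rd("ram_trials")
  ram_df <- ram_df[order(ram_df$chick_id, ram_df$trial, ram_df$visit_index), ]
  n_arms <- max(ram_df$arm)
  keys <- unique(ram_df[, c("chick_id", "trial")])
  ram_trials <- lapply(seq_len(nrow(keys)), function(i) {
    d <- ram_df[ram_df$chick_id == keys$chick_id[i] &
                  ram_df$trial == keys$trial[i], ]
    ram_trial(d$arm, n_arms = n_arms, chick_id = d$chick_id[1],
              trial_number = d$trial[1])
  })
  lat <- rd("latencies")
  latencies <- split(lat, lat$trait)
  inter <- rd("interactions")
  ids <- sort(unique(c(inter$winner_id, inter$loser_id)))
  dominance <- lapply(split(inter, inter$trial_id), function(d) {
    w <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
    for (r in seq_len(nrow(d)))
      w[d$winner_id[r], d$loser_id[r]] <- d$count[r]
    interaction_matrix(w, ids = ids)
  })
  list(sessions = unname(sessions), masses = rd("masses"),
       ram_trials = unname(ram_trials), latencies = latencies,
       dominance = unname(dominance), truth = NULL)
}

#' Validate study input tables
#'
#' Report-only schema and integrity checks: required columns, gas fractions
#' in (0, 1), strictly increasing times per session, arm indices within the
#' maze, latencies within the cap with the censoring flag consistent,
#' non-negative interaction counts, positive masses, and chick identifiers
#' consistent across tables.
#'
#' @param x A study list (from [simulate_study()] /
#'   [read_study_inputs()]), a list of tables, or a directory of CSVs.
#' @param n_arms Number of maze arms expected.
#' @param latency_cap_s Censoring cap expected in the latency table.
#' @return A data frame of violations (zero rows when everything checks
#'   out), with columns `table`, `rule` and `n`.
#' @export
validate_inputs <- function(x, n_arms = 8L, latency_cap_s = 600) {
  if (is.character(x)) x <- read_study_inputs(x)
  tabs <- if (!is.null(x$sessions) && inherits(x$sessions[[1]],
                                               "respirometry_session"))
    study_tables(x) else x
  v <- list()
  note <- function(table, rule, n)
    if (n > 0) v[[length(v) + 1]] <<- data.frame(table = table, rule = rule,
                                                n = n)

  s <- tabs$sessions
  note("sessions", "gas fraction outside (0,1)",
       sum(s$o2_frac <= 0 | s$o2_frac >= 1 | s$co2_frac <= 0 |
             s$co2_frac >= 1))
  bad_t <- sum(vapply(split(s$time_s, s$session_id),
                      function(tt) any(diff(tt) <= 0), TRUE))
  note("sessions", "times not strictly increasing", bad_t)

  r <- tabs$ram_trials
  note("ram_trials", sprintf("arm index outside 1..%d", n_arms),
       sum(r$arm < 1 | r$arm > n_arms))

  l <- tabs$latencies
  note("latencies", "latency outside (0, cap]",
       sum(l$latency_s <= 0 | l$latency_s > latency_cap_s))
  note("latencies", "censored latency not equal to cap",
       sum(l$censored & l$latency_s != latency_cap_s))

  i <- tabs$interactions
  note("interactions", "non-positive count", sum(i$count <= 0))
  note("interactions", "self-interaction", sum(i$winner_id == i$loser_id))

  m <- tabs$masses
  note("masses", "non-positive mass", sum(m$mass_g <= 0))

  ids <- unique(m$chick_id)
  note("sessions", "chick id not in masses",
       length(setdiff(unique(s$chick_id), ids)))
  note("ram_trials", "chick id not in masses",
       length(setdiff(unique(r$chick_id), ids)))
  note("latencies", "chick id not in masses",
       length(setdiff(unique(l$chick_id), ids)))
  note("interactions", "chick id not in masses",
       length(setdiff(unique(c(i$winner_id, i$loser_id)), ids)))

  if (length(v) == 0)
    return(data.frame(table = character(0), rule = character(0),
                      n = integer(0)))
  do.call(rbind, v)
}

# Write the stage outputs of a pipeline run as CSVs plus a JSON sidecar.
write_report <- function(report, study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$rmr$table, file.path(dir, "rmr_table.csv"),
                   row.names = FALSE)
  utils::write.csv(report$ram$errors, file.path(dir, "ram_errors.csv"),
                   row.names = FALSE)
  nulls <- data.frame(
    model = c("random", "stereotypic"),
    iterations = c(report$ram$random_null$iterations,
                   report$ram$stereotypic_null$iterations),
    mean = c(report$ram$random_null$mean, report$ram$stereotypic_null$mean),
    sem = c(report$ram$random_null$sem, report$ram$stereotypic_null$sem),
    seed = report$seed)
  utils::write.csv(nulls, file.path(dir, "null_summary.csv"),
                   row.names = FALSE)
  reps <- do.call(rbind, lapply(names(report$personality$repeatability),
                                function(nm) {
    r <- report$personality$repeatability[[nm]]
    data.frame(trait_grouping = nm, R = r$R, se = r$se_R,
               ci_low = r$ci95[1], ci_high = r$ci95[2], lrt_p = r$lrt_p,
               n_bootstrap = r$n_bootstrap, seed = report$seed)
  }))
  utils::write.csv(reps, file.path(dir, "repeatability.csv"),
                   row.names = FALSE)
  ds <- report$dominance$scores
  utils::write.csv(data.frame(chick_id = ds$ids, w = ds$w, w2 = ds$w2,
                              l = ds$l, l2 = ds$l2, DS = ds$DS,
                              rank = ds$rank),
                   file.path(dir, "davids_scores.csv"), row.names = FALSE)
  sel <- do.call(rbind, lapply(names(report$models), function(nm) {
    m <- report$models[[nm]]
    data.frame(comparison = nm, delta_aic = m$delta_aic,
               selected = m$selected, rule = m$rule)
  }))
  utils::write.csv(sel, file.path(dir, "model_selection.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = report$seed, deviations = report$deviations),
    file.path(dir, "run_metadata.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
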