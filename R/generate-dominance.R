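#' Simulate dyadic contest outcomes from latent dominance abilities
#'
#' Each individual receives a latent ability drawn from a normal
#' distribution; every dyad meets a Poisson number of times; and each
#' encounter is won by individual `i` over `j` with Bradley-Terry
#' probability `plogis(d_i - d_j)`. With `ability_sd = 0` every contest is a
#' coin flip and David's scores concentrate around zero; as `ability_sd`
#' grows, the score order converges to the latent ability order.
#'
#' @param config A [sim_config()]; supplies the group size.
#' @param ability_sd Standard deviation of the latent abilities (>= 0).
#' @param encounters_per_dyad_mean Poisson mean number of encounters per
#'   dyad in one trial.
#' @param seed Integer seed.
#' @param abilities Optional pre-drawn latent abilities (one per chick),
#'   used to keep abilities fixed across repeated trials.
#' @return An [interaction_matrix()] whose `truth` field holds the latent
#'   abilities.
#' @export
generate_dominance_data <- function(config, ability_sd = 1,
                                    encounters_per_dyad_mean = 2.36,
                                    seed = config$seed,
                                    abilities = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (ability_sd < 0) stop("ability_sd must be >= 0", call. = FALSE)
  if (encounters_per_dyad_mean < 0)
    stop("encounters_per_dyad_mean must be >= 0", call. = FALSE)
  set.seed(seed)
  n <- config$n_chicks
  d <- if (is.null(abilities)) stats::rnorm(n, 0, ability_sd) else abilities
  ids <- sprintf("chick%02d", seq_len(n))
  wins <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m <- stats::rpois(1, encounters_per_dyad_mean)
    if (m == 0) next
    wi <- stats::rbinom(1, m, stats::plogis(d[i] - d[j]))
    wins[i, j] <- wi
    wins[j, i] <- m - wi
  }
  interaction_matrix(wins, ids = ids,
                     truth = list(abilities = d, ability_sd = ability_sd,
                                  encounters_per_dyad_mean =
                                    encounters_per_dyad_mean,
                                  seed = seed))
}
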