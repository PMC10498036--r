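#' Simulate one radial-arm-maze trial
#'
#' Generates the ordered visit sequence of an [agent_spec()] agent: a memory
#' agent applies a win-shift rule (with probability `memory_fidelity` it picks
#' uniformly among unvisited arms, otherwise uniformly among all arms), a
#' random agent is the zero-fidelity special case, and a stereotypic agent
#' follows its first-order transition matrix. The trial ends when all arms
#' have been visited or the agent's `visit_cap` is reached.
#'
#' @param agent An [agent_spec()].
#' @param n_arms Number of maze arms (>= 2).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param chick_id,trial_number Identifiers stamped on the trial.
#' @return A [ram_trial()].
#' @export
generate_ram_trial <- function(agent, n_arms = 8L, seed = NULL,
                               chick_id = NA_character_,
                               trial_number = NA_integer_) {
  stopifnot(inherits(agent, "agent_spec"))
  if (n_arms < 2) stop("n_arms must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (agent$kind == "stereotypic" &&
      nrow(agent$transition_matrix) != n_arms)
    stop("transition matrix does not match n_arms", call. = FALSE)

  cap <- if (is.null(agent$visit_cap)) Inf else agent$visit_cap
  visits <- integer(0)
  visited <- logical(n_arms)
  cur <- NA_integer_
  repeat {
    if (agent$kind == "stereotypic") {
      cur <- if (length(visits) == 0) sample.int(n_arms, 1)
             else sample.int(n_arms, 1, prob = agent$transition_matrix[cur, ])
    } else {
      rho <- agent$memory_fidelity
      unv <- which(!visited)
      cur <- if (length(unv) > 0 && stats::runif(1) < rho)
        unv[sample.int(length(unv), 1)]
      else sample.int(n_arms, 1)
    }
    visits <- c(visits, cur)
    visited[cur] <- TRUE
    if (all(visited) || length(visits) >= cap) break
  }
  ram_trial(visits, n_arms = n_arms, chick_id = chick_id,
            trial_number = trial_number)
}
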