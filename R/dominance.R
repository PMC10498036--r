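#' Winner-loser interaction matrix
#'
#' Directed tallies of agonistic wins between all pairs in a group:
#' `wins[i, j]` is the number of interactions (shoving, pecking, wing
#' flapping, ...) in which individual `i` beat individual `j`.
#'
#' @param wins Square numeric matrix of non-negative integer win counts with
#'   zero diagonal.
#' @param ids Individual identifiers; defaults to the matrix dimnames or
#'   `id1...idn`.
#' @param behaviours Optional named list of per-behaviour win matrices of the
#'   same shape.
#' @param truth Optional ground-truth metadata (latent abilities) attached by
#'   the generator.
#' @return An object of class `interaction_matrix`.
#' @export
interaction_matrix <- function(wins, ids = NULL, behaviours = NULL,
                               truth = NULL) {
  wins <- as.matrix(wins)
  n <- nrow(wins)
  if (ncol(wins) != n) stop("wins must be square", call. = FALSE)
  if (any(wins < 0) || any(wins != round(wins)))
    stop("win counts must be non-negative integers", call. = FALSE)
  if (any(diag(wins) != 0)) stop("diagonal must be zero", call. = FALSE)
  if (is.null(ids)) ids <- rownames(wins)
  if (is.null(ids)) ids <- sprintf("id%02d", seq_len(n))
  dimnames(wins) <- list(ids, ids)
  structure(list(ids = ids, wins = wins, behaviours = behaviours,
                 truth = truth),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("Interaction matrix: %d individuals, %d interactions\n",
              length(x$ids), sum(x$wins)))
  print(x$wins)
  invisible(x)
}

#' Dyadic win proportions
#'
#' Converts win counts to the proportion of interactions won within each
#' dyad: `P[i, j] = wins[i, j] / (wins[i, j] + wins[j, i])`, with 0 entered
#' in both directions for dyads that never interacted (no information is
#' manufactured for unobserved pairs; such dyads are reported). The
#' `corrected` option applies the standard correction for unequal numbers of
#' interactions per dyad, `D[i, j] = P[i, j] - (P[i, j] - 0.5) / (n_ij + 1)`,
#' which shrinks proportions from sparsely observed dyads toward 0.5.
#'
#' @param m An [interaction_matrix()].
#' @param corrected Use the sample-size-corrected dyadic index.
#' @return Matrix of dyadic proportions with attribute `empty_dyads` (count
#'   of non-interacting pairs).
#' @export
dyadic_proportions <- function(m, corrected = FALSE) {
  stopifnot(inherits(m, "interaction_matrix"))
  w <- m$wins
  n <- w + t(w)
  P <- ifelse(n > 0, w / ifelse(n > 0, n, 1), 0)
  if (corrected) P <- ifelse(n > 0, P - (P - 0.5) / (n + 1), 0)
  diag(P) <- 0
  empty <- sum(n[upper.tri(n)] == 0)
  attr(P, "empty_dyads") <- empty
  attr(P, "corrected") <- corrected
  P
}

#' David's score dominance ranking
#'
#' Computes David's scores from a matrix of dyadic win proportions:
#' `w` (sum of i's win proportions), `w2` (w weighted by opponents' w),
#' `l` (sum of proportions lost), `l2` (l weighted by opponents' l), and
#' `DS = w + w2 - l - l2`. Scores sum to zero over the group; individuals
#' are ranked by descending DS (rank 1 = most dominant), ties broken by
#' identifier order and flagged.
#'
#' @param P Matrix of dyadic proportions from [dyadic_proportions()], or an
#'   [interaction_matrix()] (converted with the uncorrected proportions).
#' @param ids Individual identifiers; defaults to the rownames of `P`.
#' @return An object of class `davids_score_result` with per-individual
#'   `w`, `w2`, `l`, `l2`, `DS` and `rank`.
#' @export
davids_score <- function(P, ids = NULL) {
  if (inherits(P, "interaction_matrix")) {
    if (is.null(ids)) ids <- P$ids
    P <- dyadic_proportions(P)
  }
  P <- as.matrix(P)
  n <- nrow(P)
  if (is.null(ids)) ids <- rownames(P)
  if (is.null(ids)) ids <- sprintf("id%02d", seq_len(n))
  w <- unname(rowSums(P))
  l <- unname(colSums(P))
  w2 <- as.vector(P %*% w)
  l2 <- as.vector(t(P) %*% l)
  DS <- w + w2 - l - l2
  ord <- order(-DS, ids)
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  ties <- any(duplicated(DS))
  structure(list(ids = ids, P = P, w = w, w2 = w2, l = l, l2 = l2,
                 DS = DS, rank = rank, ties = ties),
            class = "davids_score_result")
}

#' @export
print.davids_score_result <- function(x, digits = 3, ...) {
  cat("David's scores (rank 1 = most dominant)\n")
  df <- data.frame(id = x$ids, w = x$w, w2 = x$w2, l = x$l, l2 = x$l2,
                   DS = x$DS, rank = x$rank)
  print(df[order(df$rank), ], digits = digits, row.names = FALSE)
  if (x$ties) cat("  note: tied scores broken by identifier order\n")
  invisible(x)
}

#' @export
summary.davids_score_result <- function(object, ...) {
  data.frame(id = object$ids, DS = object$DS, rank = object$rank)
}

#' Pool interaction matrices over trials
#'
#' Element-wise sum of win counts (and per-behaviour tallies) across repeated
#' group trials with the same individuals, so that dominance scores can be
#' computed on the pooled tallies.
#'
#' @param trials List of [interaction_matrix()] objects with identical id
#'   sets.
#' @return A pooled [interaction_matrix()].
#' @export
pool_trials <- function(trials) {
  stopifnot(length(trials) >= 1)
  ids <- trials[[1]]$ids
  for (tr in trials)
    if (!identical(tr$ids, ids))
      stop("all trials must have identical id sets", call. = FALSE)
  wins <- Reduce(`+`, lapply(trials, `[[`, "wins"))
  beh <- NULL
  if (!is.null(trials[[1]]$behaviours)) {
    nm <- names(trials[[1]]$behaviours)
    beh <- lapply(nm, function(b)
      Reduce(`+`, lapply(trials, function(tr) tr$behaviours[[b]])))
    names(beh) <- nm
  }
  interaction_matrix(wins, ids = ids, behaviours = beh)
}
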