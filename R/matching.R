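#' Distance-tolerance schedule for adaptive matching
#'
#' The matcher escalates the distance tolerance from `minimum` by `increment`
#' until the requested number of orientations is reached or `maximum` is
#' exceeded.  The defaults start very low (0.05 Angstrom) and grow slowly, so
#' the match goal alone controls how much orientation sampling a run does.
#'
#' @param minimum,increment,maximum tolerances in Angstrom.
#' @return An object of class `tolerance_schedule`.
#' @export
tolerance_schedule <- function(minimum = 0.05, increment = 0.05,
                               maximum = 1.5) {
  if (!(minimum > 0 && minimum <= maximum))
    stop("need 0 < minimum <= maximum")
  if (increment <= 0) stop("increment must be positive")
  structure(list(minimum = minimum, increment = increment, maximum = maximum),
            class = "tolerance_schedule")
}

match_colnames <- function(node_count) {
  c(paste0("l", seq_len(node_count)), paste0("r", seq_len(node_count)))
}

empty_match_set <- function(node_count, tolerance) {
  m <- matrix(integer(0), nrow = 0L, ncol = 2L * node_count)
  colnames(m) <- match_colnames(node_count)
  structure(m, tolerance = tolerance,
            stats = match_stats(node_count, 0L), class = "match_set")
}

match_stats <- function(node_count, n_matches) {
  list(node_count = node_count,
       n_matches = as.integer(n_matches),
       # each accepted candidate is validated by exactly one comparison per
       # unordered node pair: 1 + 2 + ... + (node_count - 1)
       conditions_per_match = as.integer(node_count * (node_count - 1L) / 2L),
       pair_conditions = t(combn(node_count, 2L)))
}

#' Enumerate ligand/receptor sphere correspondences (cliques)
#'
#' Complete, deterministic enumeration of all correspondences of
#' `node_count` ligand spheres onto `node_count` receptor spheres such that
#' every one of the `choose(node_count, 2)` internal distance differences
#' satisfies `|d_lig - d_rec| <= tolerance`.  With the default four nodes the
#' spheres sit at the corners of matched tetrahedra and six distances are
#' compared per candidate.  No histogram binning, no randomness: the result
#' at a lower tolerance is always a subset of the result at a higher one.
#'
#' Correspondences are returned in a canonical order: ligand 4-subsets in
#' lexicographic order of their sorted row positions, then receptor
#' assignments in lexicographic order.
#'
#' @param lig,rec [sphere_set()]s (or n x 3 coordinate matrices).
#' @param tolerance maximum allowed distance difference, Angstrom.
#' @param node_count nodes per clique; 4 in routine docking.
#' @return A `match_set`: integer matrix with columns `l1..l<k>, r1..r<k>`
#'   holding 1-based row positions, with attributes `tolerance` and `stats`
#'   (the latter records `conditions_per_match`, i.e. distance comparisons
#'   spent per completed candidate, and the node-pair conditions checked).
#'   Too few spheres on either side yields an empty match set with a
#'   message, not an error.
#' @export
enumerate_matches <- function(lig, rec, tolerance, node_count = 4L) {
  if (!is.finite(tolerance) || tolerance < 0)
    stop("tolerance must be finite and >= 0")
  node_count <- as.integer(node_count)
  if (node_count < 2L) stop("node_count must be >= 2")
  lx <- as_sphere_xyz(lig)
  rx <- as_sphere_xyz(rec)
  nl <- nrow(lx)
  nr <- nrow(rx)
  if (nl < node_count || nr < node_count) {
    message(sprintf(
      "enumerate_matches: %d ligand / %d receptor spheres, need %d per side; returning no matches",
      nl, nr, node_count))
    return(empty_match_set(node_count, tolerance))
  }
  Dl <- pairwise_distance_matrix(lx)
  Dr <- pairwise_distance_matrix(rx)
  subsets <- combn(nl, node_count)
  pieces <- vector("list", ncol(subsets))
  for (si in seq_len(ncol(subsets))) {
    s <- subsets[, si]
    # grow receptor assignments one node at a time; adding node k costs
    # k - 1 distance comparisons per candidate, 6 in total for a 4-node
    # clique that survives to completion
    cand <- matrix(seq_len(nr), ncol = 1L)
    for (k in 2:node_count) {
      if (nrow(cand) == 0L) break
      ok <- matrix(TRUE, nrow(cand), nr)
      for (a in seq_len(k - 1L)) {
        ok <- ok & (abs(Dr[cand[, a], , drop = FALSE] - Dl[s[a], s[k]]) <=
                      tolerance)
        ok[cbind(seq_len(nrow(cand)), cand[, a])] <- FALSE  # injectivity
      }
      hit <- which(ok, arr.ind = TRUE)
      cand <- cbind(cand[hit[, 1L], , drop = FALSE], hit[, 2L])
    }
    if (nrow(cand) == 0L) next
    ord <- do.call(order, lapply(seq_len(node_count), function(j) cand[, j]))
    cand <- cand[ord, , drop = FALSE]
    lig_part <- matrix(s, nrow = nrow(cand), ncol = node_count, byrow = TRUE)
    pieces[[si]] <- cbind(lig_part, cand)
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1L))]
  if (!length(pieces)) return(empty_match_set(node_count, tolerance))
  m <- do.call(rbind, pieces)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(NULL, match_colnames(node_count))
  structure(m, tolerance = tolerance,
            stats = match_stats(node_count, nrow(m)), class = "match_set")
}

#' @export
print.match_set <- function(x, ...) {
  st <- attr(x, "stats")
  cat(sprintf("<match_set> %d correspondences (%d nodes, tol %.3f A)\n",
              nrow(x), st$node_count, attr(x, "tolerance")))
  invisible(x)
}

#' Adaptive orientation matching
#'
#' Runs [enumerate_matches()] at tolerances `minimum, minimum + increment,
#' ...` until at least `match_goal` correspondences are found or the
#' schedule's maximum is passed.  All matches found at the final tolerance
#' are returned — never truncated to the goal — so the correspondence set at
#' a larger match goal is always a superset of the set at a smaller one
#' under the same schedule.  The procedure is deterministic and non-random
#' throughout.
#'
#' @param lig,rec [sphere_set()]s.
#' @param match_goal desired number of orientations (>= 1).
#' @param schedule a [tolerance_schedule()].
#' @param node_count clique size, default 4.
#' @return List with elements `matches` (a `match_set`), `tolerance` (the
#'   final tolerance, Angstrom), `n_matches`, `goal_met` (FALSE when the goal
#'   was unreachable at the schedule maximum), `match_goal`, `schedule`.
#' @export
adaptive_match <- function(lig, rec, match_goal,
                           schedule = tolerance_schedule(),
                           node_count = 4L) {
  match_goal <- as.integer(match_goal)
  if (match_goal < 1L) stop("match_goal must be >= 1")
  if (!inherits(schedule, "tolerance_schedule"))
    stop("`schedule` must be a tolerance_schedule()")
  tols <- seq(schedule$minimum,
              schedule$maximum + schedule$increment * 1e-9,
              by = schedule$increment)
  matches <- NULL
  final_tol <- tols[1L]
  for (tol in tols) {
    matches <- enumerate_matches(lig, rec, tol, node_count)
    final_tol <- tol
    if (nrow(matches) >= match_goal) break
  }
  list(matches = matches,
       tolerance = final_tol,
       n_matches = nrow(matches),
       goal_met = nrow(matches) >= match_goal,
       match_goal = match_goal,
       schedule = schedule)
}
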