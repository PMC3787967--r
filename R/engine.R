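#' Docking run parameters
#'
#' @param match_goal desired number of orientations; raising it only ever
#'   adds orientations (and so maintains or improves the best score).
#' @param schedule a [tolerance_schedule()].
#' @param bump_limit repulsive vdW limit, kcal/mol (`Inf` disables).
#' @param top_poses how many top-scoring poses to keep per molecule
#'   (classic behavior is 1; large values mainly cost memory/disk).
#' @param node_count clique size for matching, default 4.
#' @return An object of class `dock_params`.
#' @export
dock_params <- function(match_goal = 100, schedule = tolerance_schedule(),
                        bump_limit = 50, top_poses = 1, node_count = 4L) {
  if (top_poses < 1L) stop("top_poses must be >= 1")
  structure(list(match_goal = as.integer(match_goal), schedule = schedule,
                 bump_limit = bump_limit, top_poses = as.integer(top_poses),
                 node_count = as.integer(node_count)),
            class = "dock_params")
}

#' Bounded, sorted pose lists
#'
#' A `pose_list` keeps at most `capacity` poses sorted ascending by total
#' energy (best, i.e. most negative, first), with a stable tie-break on
#' orientation index then conformer index.  [insert_pose()] maintains the
#' invariant by ordered insertion; inserting a pose worse than the current
#' worst into a full list is a no-op.
#'
#' @param capacity maximum number of poses retained.
#' @return An empty `pose_list`.
#' @export
pose_list <- function(capacity = 1L) {
  structure(list(capacity = as.integer(capacity), poses = list()),
            class = "pose_list")
}

pose_key <- function(p) c(p$total, p$orientation, p$conformer)

#' @rdname pose_list
#' @param pl a `pose_list`.
#' @param pose a pose: list with at least `total`, `orientation`,
#'   `conformer` (as produced by [dock_molecule()]).
#' @export
insert_pose <- function(pl, pose) {
  k <- pose_key(pose)
  pos <- length(pl$poses) + 1L
  for (i in seq_along(pl$poses)) {
    ki <- pose_key(pl$poses[[i]])
    if (k[1L] < ki[1L] ||
        (k[1L] == ki[1L] && (k[2L] < ki[2L] ||
                             (k[2L] == ki[2L] && k[3L] < ki[3L])))) {
      pos <- i
      break
    }
  }
  if (pos > pl$capacity) return(pl)  # worse than everything in a full list
  pl$poses <- append(pl$poses, list(pose), after = pos - 1L)
  if (length(pl$poses) > pl$capacity)
    pl$poses <- pl$poses[seq_len(pl$capacity)]
  pl
}

#' @export
print.pose_list <- function(x, ...) {
  cat(sprintf("<pose_list> %d/%d poses", length(x$poses), x$capacity))
  if (length(x$poses))
    cat(sprintf("; best total %.4f kcal/mol", x$poses[[1L]]$total))
  cat("\n")
  invisible(x)
}

#' Dock one conformer hierarchy
#'
#' The full orientation-then-score pipeline for a single molecule: ligand
#' matching spheres are the heavy atoms of the rigid component; receptor
#' correspondences come from [adaptive_match()]; each correspondence is
#' turned into a least-squares rigid transform (degenerate, near-collinear
#' ones are discarded) which places every conformer of the hierarchy at
#' once; each placed conformer is scored by [pose_energy()]; bumped and
#' out-of-grid poses are discarded; the best `top_poses` survivors are kept.
#' Orientations are scored in canonical match order and conformers in file
#' order, so the run is fully deterministic.
#'
#' @param hierarchy a [conformer_hierarchy()]; if its `rigid` slot is unset,
#'   [find_rigid_component()] is applied.
#' @param rec_spheres receptor [sphere_set()].
#' @param bundle a [grid_bundle()]; precomputed interpolation is set up
#'   on the fly if absent.
#' @param params a [dock_params()].
#' @param keep_pair_status also return the status of every
#'   (orientation, conformer) pair — useful for auditing the bump filter.
#' @return An object of class `dock_result`: list with `poses` (a
#'   [pose_list()]), `status` (`"scored"`, `"no_pose"` or `"undockable"`),
#'   `n_orientations`, `final_tolerance`, `goal_met`, `tallies` (named
#'   counts of `scored`, `bumped`, `out_of_grid`, `degenerate`), and
#'   optionally `pair_status`.
#' @export
dock_molecule <- function(hierarchy, rec_spheres, bundle,
                          params = dock_params(), keep_pair_status = FALSE) {
  rigid <- hierarchy$rigid
  if (is.null(rigid)) rigid <- find_rigid_component(hierarchy)
  rigid_heavy <- rigid[hierarchy$atoms$element[rigid] != "H"]
  tallies <- c(scored = 0L, bumped = 0L, out_of_grid = 0L, degenerate = 0L)
  if (length(rigid_heavy) < params$node_count) {
    return(structure(list(poses = pose_list(params$top_poses),
                          status = "undockable", n_orientations = 0L,
                          final_tolerance = NA_real_, goal_met = FALSE,
                          tallies = tallies),
                     class = "dock_result"))
  }
  lig_spheres <- sphere_set(hierarchy$conformers[[1L]][rigid_heavy, , drop = FALSE])
  am <- adaptive_match(lig_spheres, rec_spheres, params$match_goal,
                       params$schedule, params$node_count)
  bundle <- precompute_bundle(bundle)
  sp <- atom_score_params(hierarchy)
  pl <- pose_list(params$top_poses)
  pair_status <- if (keep_pair_status) list() else NULL
  nconf <- length(hierarchy$conformers)
  for (oi in seq_len(nrow(am$matches))) {
    tr <- fit_rigid_transform(am$matches[oi, ], lig_spheres, rec_spheres)
    if (tr$degenerate) {
      tallies[["degenerate"]] <- tallies[["degenerate"]] + nconf
      if (keep_pair_status)
        pair_status[[length(pair_status) + 1L]] <-
          data.frame(orientation = oi, conformer = seq_len(nconf),
                     status = "degenerate")
      next
    }
    # the rigid transform of the correspondence places all conformers of the
    # hierarchy because they share the rigid-component coordinates
    for (ci in seq_len(nconf)) {
      coords <- orient_coordinates(tr, hierarchy$conformers[[ci]])
      pe <- pose_energy(coords, sp, bundle, params$bump_limit)
      tallies[[pe$status]] <- tallies[[pe$status]] + 1L
      if (keep_pair_status)
        pair_status[[length(pair_status) + 1L]] <-
          data.frame(orientation = oi, conformer = ci, status = pe$status)
      if (pe$status == "scored") {
        pose <- list(molecule = hierarchy$name, orientation = oi,
                     conformer = ci, correspondence = am$matches[oi, ],
                     transform = tr, coords = coords, total = pe$total,
                     terms = pe$terms, per_atom = pe$per_atom,
                     conformer_energy = hierarchy$conformer_energy[ci])
        pl <- insert_pose(pl, pose)
      }
    }
  }
  structure(list(poses = pl,
                 status = if (length(pl$poses)) "scored" else "no_pose",
                 n_orientations = nrow(am$matches),
                 final_tolerance = am$tolerance, goal_met = am$goal_met,
                 tallies = tallies,
                 pair_status = if (keep_pair_status)
                   do.call(rbind, pair_status) else NULL),
            class = "dock_result")
}

#' @export
print.dock_result <- function(x, ...) {
  cat(sprintf("<dock_result> %s: %d orientations (tol %.2f A), tallies: %s\n",
              x$status, x$n_orientations, x$final_tolerance,
              paste(names(x$tallies), x$tallies, collapse = ", ")))
  invisible(x)
}

NO_POSE_SENTINEL <- 1000  # kcal/mol; explicit status column disambiguates

#' Screen a library of molecules
#'
#' Docks each hierarchy independently with [dock_molecule()] and tabulates
#' the best score per molecule.  Individual molecule failures are recorded
#' in the table (status `"error"`), never abort the screen, and molecules
#' with no surviving pose get an explicit sentinel total of +1000 kcal/mol
#' with status `"no_pose"`.  Row order equals input order and the whole
#' screen is reproducible byte for byte.
#'
#' @param hierarchies list of [conformer_hierarchy()] objects.
#' @param rec_spheres receptor [sphere_set()].
#' @param bundle a [grid_bundle()].
#' @param params a [dock_params()].
#' @param keep_results also return the per-molecule `dock_result`s (as
#'   attribute `"results"` of the table).
#' @return A `screen_table` data frame: `id`, `status`, `total`, `vdw`,
#'   `electrostatic`, `desolvation`, `n_orientations`,
#'   `n_conformers_scored`, `n_bumped`, `n_out_of_grid`.
#' @export
screen_library <- function(hierarchies, rec_spheres, bundle,
                           params = dock_params(), keep_results = FALSE) {
  if (!length(hierarchies)) stop("need at least one molecule")
  bundle <- precompute_bundle(bundle)
  results <- vector("list", length(hierarchies))
  rows <- vector("list", length(hierarchies))
  for (i in seq_along(hierarchies)) {
    h <- hierarchies[[i]]
    res <- tryCatch(dock_molecule(h, rec_spheres, bundle, params),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(id = h$name, status = "error",
                              total = NO_POSE_SENTINEL, vdw = NA_real_,
                              electrostatic = NA_real_, desolvation = NA_real_,
                              n_orientations = NA_integer_,
                              n_conformers_scored = NA_integer_,
                              n_bumped = NA_integer_,
                              n_out_of_grid = NA_integer_,
                              stringsAsFactors = FALSE)
      next
    }
    results[[i]] <- res
    best <- if (length(res$poses$poses)) res$poses$poses[[1L]] else NULL
    rows[[i]] <- data.frame(
      id = h$name,
      status = res$status,
      total = if (is.null(best)) NO_POSE_SENTINEL else best$total,
      vdw = if (is.null(best)) NA_real_ else best$terms[["vdw"]],
      electrostatic = if (is.null(best)) NA_real_ else best$terms[["electrostatic"]],
      desolvation = if (is.null(best)) NA_real_ else best$terms[["desolvation"]],
      n_orientations = res$n_orientations,
      n_conformers_scored = res$tallies[["scored"]],
      n_bumped = res$tallies[["bumped"]],
      n_out_of_grid = res$tallies[["out_of_grid"]],
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  class(tab) <- c("screen_table", "data.frame")
  if (keep_results) attr(tab, "results") <- results
  tab
}

#' Write a screen table as TSV
#'
#' Plain tab-separated output with a fixed column order; identical screens
#' produce byte-identical files.
#'
#' @param tab a `screen_table` from [screen_library()].
#' @param path output path.
#' @export
write_score_table <- function(tab, path) {
  out <- as.data.frame(tab)
  num <- vapply(out, is.double, logical(1L))
  out[num] <- lapply(out[num], function(x)
    ifelse(is.na(x), "NA", sprintf("%.6f", x)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
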