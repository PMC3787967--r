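#' Score one atom on a grid bundle
#'
#' The grid potentials combine with atomic properties into per-term
#' energies: `vdw = sqrt_a * R(x) - sqrt_b * A(x)`, `electrostatic =
#' charge * Phi(x)`, `desolvation = desolv * D(x)` (all kcal/mol).
#'
#' @param params one row of [atom_score_params()] (or a list with `sqrt_a`,
#'   `sqrt_b`, `charge`, `desolv`).
#' @param point length-3 position, Angstrom.
#' @param bundle a [grid_bundle()].
#' @return List with `vdw`, `electrostatic`, `desolvation`, `total`, and
#'   `in_grid` (FALSE when the point falls outside the lattice, in which
#'   case the energies are `NA` and the caller should reject the pose).
#' @export
atom_energy <- function(params, point, bundle) {
  g <- bundle_lookup(bundle, matrix(as.numeric(point), 1L, 3L))
  if (is.na(g$vdw_repulsive[1L]))
    return(list(vdw = NA_real_, electrostatic = NA_real_,
                desolvation = NA_real_, total = NA_real_, in_grid = FALSE))
  vdw <- params$sqrt_a * g$vdw_repulsive[1L] - params$sqrt_b * g$vdw_attractive[1L]
  ele <- params$charge * bundle$es_scale * g$electrostatic[1L]
  des <- params$desolv * g$desolvation[1L]
  list(vdw = vdw, electrostatic = ele, desolvation = des,
       total = vdw + ele + des, in_grid = TRUE)
}

#' Score a pose with the repulsive bump filter
#'
#' Accumulates per-atom, per-term energies over the pose.  Atoms are
#' visited in order and the running sum of their (positive) repulsive vdW
#' contributions is compared against the bump limit; once it exceeds the
#' limit the pose is certain not to yield a good physical score and
#' evaluation stops with `status = "bumped"` — the grid-embedded distance
#' bump filter of older engines replaced by an energy criterion.  Any atom
#' outside the lattice gives `status = "out_of_grid"`.  Otherwise `status =
#' "scored"` with the full breakdown; the total equals the sum of the
#' per-atom terms by construction.
#'
#' @param coords n x 3 pose coordinates (Angstrom).
#' @param params [atom_score_params()] rows, one per atom.
#' @param bundle a [grid_bundle()] (precomputed or not).
#' @param bump_limit repulsive-energy limit in kcal/mol (`Inf` disables the
#'   filter; the routine default used throughout docking is 50).
#' @return List with `status`, and when scored: `total`, `terms` (named
#'   vector `vdw`, `electrostatic`, `desolvation`), `per_atom` (n x 3
#'   matrix).  When bumped, `bumped_at` gives the first atom at which the
#'   running repulsive sum crossed the limit; when out of grid,
#'   `out_of_grid_at` gives the first offending atom.
#' @export
pose_energy <- function(coords, params, bundle, bump_limit = 50) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("pose coordinates must be finite")
  if (nrow(coords) != nrow(params))
    stop("coords and params disagree on the number of atoms")
  if (!(is.numeric(bump_limit) && length(bump_limit) == 1L && bump_limit > 0))
    stop("bump_limit must be a single positive number (Inf for no limit)")
  g <- bundle_lookup(bundle, coords)
  oob <- is.na(g$vdw_repulsive)
  if (any(oob))
    return(list(status = "out_of_grid", out_of_grid_at = which(oob)[1L]))
  rep_term <- params$sqrt_a * g$vdw_repulsive
  if (is.finite(bump_limit)) {
    running <- cumsum(pmax(rep_term, 0))
    if (any(running > bump_limit))
      return(list(status = "bumped",
                  bumped_at = which(running > bump_limit)[1L]))
  }
  vdw <- rep_term - params$sqrt_b * g$vdw_attractive
  ele <- params$charge * bundle$es_scale * g$electrostatic
  des <- params$desolv * g$desolvation
  per_atom <- cbind(vdw = vdw, electrostatic = ele, desolvation = des)
  terms <- c(vdw = sum(vdw), electrostatic = sum(ele), desolvation = sum(des))
  list(status = "scored", total = sum(terms), terms = terms,
       per_atom = per_atom)
}
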