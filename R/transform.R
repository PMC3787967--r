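#' Least-squares rigid transform from a correspondence
#'
#' Kabsch superposition of the matched ligand spheres onto the matched
#' receptor spheres: the proper rotation and translation minimizing the RMSD
#' of the paired points.  Reflections are always rejected (the determinant is
#' forced to +1); docking a mirror image would be unphysical.  Near-collinear
#' point spreads cannot pin down a rotation and are flagged degenerate
#' (singular-value ratio below `degenerate_tol`); the docking engine
#' discards such correspondences.
#'
#' @param correspondence one row of a `match_set` (or an integer vector
#'   `c(l1..lk, r1..rk)` of 1-based sphere row positions).
#' @param lig,rec the [sphere_set()]s the correspondence refers to.
#' @param degenerate_tol ratio of the second to first singular value of the
#'   centered ligand points below which the geometry is declared degenerate.
#' @return An object of class `rigid_transform`: list with `rotation` (3 x 3
#'   proper orthogonal), `translation` (length 3), `rms_residual` (Angstrom)
#'   and `degenerate` (logical).
#' @export
fit_rigid_transform <- function(correspondence, lig, rec,
                                degenerate_tol = 1e-6) {
  v <- as.integer(correspondence)
  if (length(v) %% 2L != 0L) stop("correspondence must pair ligand and receptor indices")
  k <- length(v) %/% 2L
  if (k < 3L) stop("need at least three matched pairs")
  P <- as_sphere_xyz(lig)[v[seq_len(k)], , drop = FALSE]
  Q <- as_sphere_xyz(rec)[v[k + seq_len(k)], , drop = FALSE]
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp)
  Qc <- sweep(Q, 2L, cq)
  sv_spread <- svd(Pc, nu = 0L, nv = 0L)$d
  degenerate <- sv_spread[2L] < degenerate_tol * max(sv_spread[1L], .Machine$double.eps)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(cq - R %*% cp)
  fitted <- sweep(Pc %*% t(R), 2L, cq, "+")
  rms <- sqrt(mean(rowSums((fitted - Q)^2)))
  structure(list(rotation = R, translation = tr, rms_residual = rms,
                 degenerate = degenerate),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' Computes `x' = R x + t` for every row of `coords`.  One transform placed
#' from a rigid-component match is applied to every conformer sharing that
#' rigid component.
#'
#' @param transform a `rigid_transform` from [fit_rigid_transform()].
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @return Transformed n x 3 matrix.
#' @export
orient_coordinates <- function(transform, coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("`coords` must be n x 3")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  sweep(coords %*% t(transform$rotation), 2L, transform$translation, "+")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rms residual %.4f A%s\n", x$rms_residual,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}
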