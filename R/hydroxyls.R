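#' Dihedral angle of four points
#'
#' Signed torsion p1-p2-p3-p4 in radians, in (-pi, pi].
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / vnorm(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

wrap_angle <- function(a) atan2(sin(a), cos(a))

# rotate point p about the axis through `origin` with unit direction `u`
rotate_about_axis <- function(p, origin, u, angle) {
  v <- p - origin
  v_rot <- v * cos(angle) + cross3(u, v) * sin(angle) +
    u * sum(u * v) * (1 - cos(angle))
  origin + v_rot
}

# move atom `h_idx` so that dihedral(ref, c, o, h) == target, rotating about
# the c->o axis; robust to torsion sign convention
set_hydroxyl_dihedral <- function(coords, ref, c_at, o_at, h_idx, target) {
  axis <- coords[o_at, ] - coords[c_at, ]
  u <- axis / vnorm(axis)
  cur <- dihedral_angle(coords[ref, ], coords[c_at, ], coords[o_at, ],
                        coords[h_idx, ])
  for (delta in c(target - cur, cur - target)) {
    new_h <- rotate_about_axis(coords[h_idx, ], coords[o_at, ], u, delta)
    got <- dihedral_angle(coords[ref, ], coords[c_at, ], coords[o_at, ], new_h)
    if (abs(wrap_angle(got - target)) < 1e-9) {
      coords[h_idx, ] <- new_h
      return(coords)
    }
  }
  stop("failed to place hydroxyl dihedral")  # unreachable for sane geometry
}

hydroxyl_sites <- function(h) {
  bonds <- h$bonds
  nbr <- function(i) {
    c(bonds$to[bonds$from == i], bonds$from[bonds$to == i])
  }
  sites <- list()
  for (o in which(h$atoms$element == "O")) {
    nb <- nbr(o)
    hs <- nb[h$atoms$element[nb] == "H"]
    heavies <- nb[h$atoms$element[nb] != "H"]
    if (length(heavies) != 1L || h$atoms$element[heavies] != "C") next
    c_at <- heavies
    if (!length(hs)) {
      warning(sprintf("hydroxyl oxygen %d has no hydrogen; skipped", o))
      next
    }
    cn <- nbr(c_at)
    ref_cand <- sort(setdiff(cn[h$atoms$element[cn] != "H"], o))
    if (!length(ref_cand)) next
    # sp2 if the attached carbon is aromatic or carries a double bond
    cb <- bonds[bonds$from == c_at | bonds$to == c_at, , drop = FALSE]
    sp2 <- any(cb$order %in% c("ar", "2")) ||
      h$atoms$mol2_type[c_at] %in% c("C.2", "C.ar", "C.cat")
    sites[[length(sites) + 1L]] <- list(o = o, c = c_at, h = hs[1L],
                                        ref = ref_cand[1L], sp2 = sp2)
  }
  sites
}

#' Reset hydroxyl rotamers of a conformer
#'
#' Hydroxyl hydrogens attached through oxygen to an sp2 carbon (aromatic or
#' double-bonded) are reset to the two in-plane rotamers, heavy-reference
#' C-C-O-H dihedrals 0 and pi; small-molecule crystal structures show a
#' strong in-plane preference for aromatic hydroxyls, and out-of-plane
#' placements are high-energy decoy geometries.  Hydroxyls on sp3 carbons
#' are placed at three staggered positions 2*pi/3 apart (dihedrals pi/3, pi,
#' -pi/3 to the lowest-index heavy substituent).  Independent hydroxyls
#' combine as a Cartesian product, capped at `max_combinations`; the cap
#' preserves full variation of the lowest-index hydroxyls first.
#'
#' @param h a [conformer_hierarchy()] with explicit hydroxyl hydrogens.
#' @param conformer an n_atoms x 3 coordinate matrix, or the index of a
#'   conformer of `h` (default 1).
#' @param max_combinations cap on the rotamer product (default 32).
#' @return List of conformer coordinate matrices.  With no hydroxyls the
#'   input conformer is returned unchanged as a single-element list.
#' @export
reset_hydroxyls <- function(h, conformer = 1L, max_combinations = 32L) {
  coords <- if (is.matrix(conformer)) conformer else h$conformers[[conformer]]
  sites <- hydroxyl_sites(h)
  if (!length(sites)) return(list(coords))
  targets <- lapply(sites, function(s) {
    if (s$sp2) c(0, pi) else c(pi / 3, pi, -pi / 3)
  })
  # expand.grid varies the first factor fastest, so truncation to the cap
  # sacrifices variation of the later (higher-index) hydroxyls first
  combos <- do.call(expand.grid, lapply(targets, seq_along))
  if (nrow(combos) > max_combinations)
    combos <- combos[seq_len(max_combinations), , drop = FALSE]
  out <- vector("list", nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    cc <- coords
    for (si in seq_along(sites)) {
      s <- sites[[si]]
      tgt <- targets[[si]][combos[ci, si]]
      cc <- set_hydroxyl_dihedral(cc, s$ref, s$c, s$o, s$h, tgt)
    }
    out[[ci]] <- cc
  }
  out
}
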