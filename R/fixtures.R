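#' Toy four-vs-three sphere matching system
#'
#' A deterministic analog of the classic matching diagram: a toy receptor
#' with four matching spheres and a toy ligand with three, constructed so
#' that three-node matching finds exactly 2 correspondences at a distance
#' tolerance of 0.1 Angstrom and exactly 4 at 0.2 (the extra two appearing
#' only when the tolerance is raised), and none at tolerance 0.  The
#' generator verifies those counts against [enumerate_matches()] at build
#' time and aborts if construction ever failed, so the fixture is
#' self-checking.
#'
#' The ligand is a scalene-but-nearly-isosceles triangle (sides 4, 3, 3.05);
#' receptor spheres 1-3 form a triangle matching it within 0.03 (two
#' assignments because the near-equal sides can swap), and sphere 4 forms a
#' second triangle with spheres 1-2 matching only within 0.15.
#'
#' @return List with `lig` and `rec` [sphere_set()]s.
#' @export
make_fig1_system <- function() {
  d12 <- 4; d13 <- 3; d23 <- 3.05
  x3 <- (d12^2 + d13^2 - d23^2) / (2 * d12)
  lig <- sphere_set(rbind(c(0, 0, 0),
                          c(d12, 0, 0),
                          c(x3, sqrt(d13^2 - x3^2), 0)))
  rec <- sphere_set(rbind(c(10, 0, 0),
                          c(14, 0, 0),
                          c(12, sqrt(3.02^2 - 4), 0),
                          c(12, -sqrt(3.15^2 - 4), 0)))
  counts <- vapply(c(0, 0.1, 0.2), function(tol)
    nrow(enumerate_matches(lig, rec, tol, node_count = 3L)), numeric(1L))
  if (!identical(as.integer(counts), c(0L, 2L, 4L)))
    stop("fig1 fixture failed self-verification: counts ",
         paste(counts, collapse = "/"), " instead of 0/2/4")
  list(lig = lig, rec = rec)
}

#' Synthetic ring-and-tail conformer hierarchy
#'
#' Builds a small molecule with an (irregular) aromatic six-ring rigid
#' component, an aliphatic tail whose rotation generates the conformers,
#' and optional ring hydroxyls whose hydrogens start out of plane (so the
#' rotamer reset has work to do).  All coordinates, charges and desolvation
#' terms are pure functions of the seed; charges sum to integer total
#' charge; conformers share the rigid-component coordinates exactly.
#' The real ligand-building pipeline this stands in for enumerates
#' conformers with an external generator (typically a 0.4 Angstrom RMSD
#' cutoff and up to 2000 conformers); here the ensemble is tiny and
#' hand-constructed, with builder energies assigned increasing values.
#'
#' @param n_atoms heavy atoms in total (>= 5; ring takes 6 when it fits,
#'   else 5).
#' @param n_conformers conformers to generate.
#' @param n_hydroxyls ring hydroxyls (each adds one O heavy atom + one H).
#' @param seed integer seed; same spec, same molecule, byte for byte.
#' @param name molecule id (defaults to a seed-derived tag).
#' @return A [conformer_hierarchy()] with `rigid` set to the ring.
#' @export
make_hierarchy <- function(n_atoms = 10L, n_conformers = 3L,
                           n_hydroxyls = 1L, seed = 1L,
                           name = sprintf("SYN%05d", seed)) {
  n_atoms <- as.integer(n_atoms)
  n_conformers <- as.integer(n_conformers)
  n_hydroxyls <- as.integer(n_hydroxyls)
  if (n_atoms < 5L) stop("need at least 5 heavy atoms")
  ring_size <- if (n_atoms >= 6L + n_hydroxyls) 6L else 5L
  tail_len <- n_atoms - ring_size - n_hydroxyls
  if (tail_len < 0L)
    stop("n_atoms too small for the requested hydroxyl count")
  if (n_conformers < 1L) stop("need at least one conformer")
  with_seed(seed, {
    ang <- 2 * pi * (seq_len(ring_size) - 1L) / ring_size +
      runif(ring_size, -0.06, 0.06)
    rad <- 1.4 + runif(ring_size, -0.08, 0.08)
    ring <- cbind(rad * cos(ang), rad * sin(ang), 0)
    center <- colMeans(ring)

    atom_name <- sprintf("C%d", seq_len(ring_size))
    element <- rep("C", ring_size)
    mol2_type <- rep("C.ar", ring_size)
    coords <- ring
    bonds <- data.frame(from = seq_len(ring_size),
                        to = c(seq_len(ring_size)[-1L], 1L),
                        order = "ar", stringsAsFactors = FALSE)

    tail_idx <- integer(0)
    if (tail_len > 0L) {
      dir <- ring[1L, ] - center
      dir <- dir / vnorm(dir)
      prev <- 1L
      for (i in seq_len(tail_len)) {
        pos <- ring[1L, ] + dir * 1.45 * i + c(0, 0, 0.45 * (i %% 2L))
        coords <- rbind(coords, pos)
        idx <- nrow(coords)
        tail_idx <- c(tail_idx, idx)
        atom_name <- c(atom_name, sprintf("C%d", idx))
        element <- c(element, "C")
        mol2_type <- c(mol2_type, "C.3")
        bonds <- rbind(bonds, data.frame(from = prev, to = idx, order = "1"))
        prev <- idx
      }
    }

    oh <- list()
    if (n_hydroxyls > 0L) {
      carriers <- seq(3L, by = 2L, length.out = n_hydroxyls)
      if (max(carriers) > ring_size)
        stop("too many hydroxyls for the ring")
      for (ci in carriers) {
        dir <- ring[ci, ] - center
        dir <- dir / vnorm(dir)
        o_pos <- ring[ci, ] + dir * 1.36
        coords <- rbind(coords, o_pos)
        o_idx <- nrow(coords)
        atom_name <- c(atom_name, sprintf("O%d", o_idx))
        element <- c(element, "O")
        mol2_type <- c(mol2_type, "O.3")
        bonds <- rbind(bonds, data.frame(from = ci, to = o_idx, order = "1"))
        h_guess <- o_pos + 0.96 * (dir + c(0, 0, 1)) / vnorm(dir + c(0, 0, 1))
        coords <- rbind(coords, h_guess)
        h_idx <- nrow(coords)
        atom_name <- c(atom_name, sprintf("H%d", h_idx))
        element <- c(element, "H")
        mol2_type <- c(mol2_type, "H")
        bonds <- rbind(bonds, data.frame(from = o_idx, to = h_idx, order = "1"))
        oh[[length(oh) + 1L]] <- list(c = ci, o = o_idx, h = h_idx,
                                      ref = min(setdiff(
                                        c(bonds$to[bonds$from == ci],
                                          bonds$from[bonds$to == ci]),
                                        o_idx)))
      }
    }

    n_total <- nrow(coords)
    charge <- numeric(n_total)
    charge[seq_len(ring_size)] <- rep_len(c(0.15, -0.15), ring_size) +
      runif(ring_size, -0.02, 0.02)
    charge[tail_idx] <- runif(length(tail_idx), -0.1, 0.1)
    for (s in oh) {
      charge[s$o] <- -0.4
      charge[s$h] <- 0.3
    }
    charge <- round(charge, 4)
    charge[1L] <- round(charge[1L] - sum(charge), 4)
    desolv <- round(ifelse(element == "H", 0, runif(n_total, 0.05, 0.25)), 4)

    # start every hydroxyl hydrogen clearly out of the ring plane
    for (s in oh)
      coords <- set_hydroxyl_dihedral(coords, s$ref, s$c, s$o, s$h, 1.2)

    conformers <- vector("list", n_conformers)
    conformers[[1L]] <- coords
    if (n_conformers > 1L) {
      for (ci in 2:n_conformers) {
        cc <- coords
        if (length(tail_idx) >= 2L) {
          # spin the tail past its first atom about the ring-tail bond
          axis_from <- coords[1L, ]
          axis <- coords[tail_idx[1L], ] - axis_from
          u <- axis / vnorm(axis)
          theta <- (ci - 1L) * 2 * pi / n_conformers
          for (ti in tail_idx[-1L])
            cc[ti, ] <- rotate_about_axis(coords[ti, ], axis_from, u, theta)
        } else if (length(oh)) {
          s <- oh[[1L]]
          cc <- set_hydroxyl_dihedral(cc, s$ref, s$c, s$o, s$h,
                                      wrap_angle(1.2 + (ci - 1L) * 0.8))
        }
        conformers[[ci]] <- cc
      }
    }
    energies <- round(c(0, cumsum(runif(n_conformers - 1L, 1.0, 3.5))), 4)

    conformer_hierarchy(
      name = name,
      atoms = data.frame(name = atom_name, element = element,
                         mol2_type = mol2_type, charge = charge,
                         vdw_class = element, desolv = desolv,
                         stringsAsFactors = FALSE),
      bonds = bonds, conformers = conformers,
      conformer_energy = energies, rigid = seq_len(ring_size))
  })
}

# closed-form pseudo-receptor field: 12-6 Lennard-Jones sums in the
# two-grid sqrt-A/sqrt-B convention, Coulomb potential with a distance-
# independent relative dielectric of 4, and a Gaussian fractional-burial
# desolvation field.  Hard cores are regularized by distance floors so the
# sampled grids stay finite; the floors are fixture-internal.
analytic_field <- function(atoms, dielectric = 4, desolv_sigma = 2.0) {
  atoms <- as.data.frame(atoms)
  structure(list(atoms = atoms, dielectric = dielectric,
                 desolv_sigma = desolv_sigma),
            class = "analytic_field")
}

analytic_field_components <- function(field, points) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  R <- numeric(n); A <- numeric(n); phi <- numeric(n); D <- numeric(n)
  at <- field$atoms
  for (j in seq_len(nrow(at))) {
    dv <- sweep(pts, 2L, c(at$x[j], at$y[j], at$z[j]))
    r <- sqrt(rowSums(dv^2))
    R <- R + at$sqrt_a[j] / pmax(r, 0.9)^12
    A <- A + at$sqrt_b[j] / pmax(r, 1.2)^6
    phi <- phi + 332.0636 * at$charge[j] / (field$dielectric * pmax(r, 0.9))
    D <- D + exp(-r^2 / (2 * field$desolv_sigma^2))
  }
  list(vdw_repulsive = R, vdw_attractive = A, electrostatic = phi,
       desolvation = pmin(D, 1))
}

lattice_points <- function(lat) {
  ax <- lapply(1:3, function(a)
    lat$origin[a] + lat$spacing * (seq_len(lat$dims[a]) - 1L))
  as.matrix(expand.grid(x = ax[[1L]], y = ax[[2L]], z = ax[[3L]]))
}

#' Planted-site docking fixture
#'
#' Generates a complete synthetic docking problem around a seeded
#' [make_hierarchy()] molecule: pseudo-receptor atoms are planted one
#' Lennard-Jones minimum (3.8 Angstrom) radially outward from each heavy
#' atom of the molecule's first conformer, carrying opposite charges, so
#' the planted pose sits in a favorable field; the analytic field is
#' sampled onto a grid bundle; and the receptor matching spheres are placed
#' exactly at the planted rigid-component heavy atoms, mirroring the
#' standard preparation that seeds receptor spheres with the
#' crystallographic ligand atoms.  The generator verifies its own
#' postconditions — the planted pose must score below -1 kcal/mol and
#' survive a 50 kcal/mol bump limit — and aborts otherwise.
#'
#' @param seed integer seed.
#' @param n_atoms,n_conformers,n_hydroxyls passed to [make_hierarchy()].
#' @param spacing grid spacing, Angstrom.
#' @param margin grid padding around the planted pose, Angstrom.
#' @return List: `hierarchy`, `bundle` (a [grid_bundle()]), `rec_spheres`,
#'   `planted` (the planted coordinates), `field` (the analytic field for
#'   oracle checks), `receptor_atoms`, `spacing`.
#' @export
make_planted_site <- function(seed = 1L, n_atoms = 10L, n_conformers = 3L,
                              n_hydroxyls = 1L, spacing = 0.4, margin = 4.0) {
  h <- make_hierarchy(n_atoms, n_conformers, n_hydroxyls, seed)
  planted <- h$conformers[[1L]]
  heavy <- heavy_atoms(h)
  centroid <- colMeans(planted[heavy, , drop = FALSE])
  rec <- list()
  for (i in heavy) {
    dir <- planted[i, ] - centroid
    if (vnorm(dir) < 0.8) dir <- c(0, 0, 1)
    u <- dir / vnorm(dir)
    side <- c(-u[2L], u[1L], 0)
    if (vnorm(side) < 0.5) side <- c(1, 0, 0)
    side <- side / vnorm(side)
    # first offset direction whose well does not crowd another planted atom
    for (cand in list(u, c(0, 0, 1), c(0, 0, -1), side, -side,
                      (u + c(0, 0, 1)) / vnorm(u + c(0, 0, 1)),
                      (u - c(0, 0, 1)) / vnorm(u - c(0, 0, 1)))) {
      pos <- planted[i, ] + 3.8 * cand
      d_all <- sqrt(rowSums(sweep(planted, 2L, pos)^2))
      if (min(d_all[-i]) >= 3.2) {
        rec[[length(rec) + 1L]] <- data.frame(
          x = pos[1L], y = pos[2L], z = pos[3L],
          sqrt_a = sqrt(0.40) * 3.8^6, sqrt_b = sqrt(0.80) * 3.8^3,
          charge = -2 * h$atoms$charge[i])
        break
      }
    }
  }
  rec <- do.call(rbind, rec)
  field <- analytic_field(rec)
  lo <- apply(planted, 2L, min) - margin
  hi <- apply(planted, 2L, max) + margin
  dims <- pmax(ceiling((hi - lo) / spacing) + 1L, 2L)
  if (any(dims > 64L)) stop("planted-site grid exceeds the 64^3 bound")
  lat <- dock_lattice(lo, spacing, dims)
  comp <- analytic_field_components(field, lattice_points(lat))
  bundle <- grid_bundle(
    scalar_grid(lat, comp$vdw_repulsive, "vdw_repulsive", "sqrtA-weighted"),
    scalar_grid(lat, comp$vdw_attractive, "vdw_attractive", "sqrtB-weighted"),
    scalar_grid(lat, comp$electrostatic, "electrostatic", "kcal/(mol e)"),
    scalar_grid(lat, comp$desolvation, "desolvation", "fraction"))
  rigid_heavy <- h$rigid[h$atoms$element[h$rigid] != "H"]
  rec_spheres <- sphere_set(planted[rigid_heavy, , drop = FALSE])
  pe <- pose_energy(planted, atom_score_params(h), precompute_bundle(bundle),
                    bump_limit = 50)
  if (!identical(pe$status, "scored") || pe$total >= -1)
    stop(sprintf(
      "planted-site fixture failed self-verification (status %s, total %s)",
      pe$status, if (is.null(pe$total)) "NA" else sprintf("%.3f", pe$total)))
  list(hierarchy = h, bundle = bundle, rec_spheres = rec_spheres,
       planted = planted, field = field, receptor_atoms = rec,
       spacing = spacing)
}

#' Seeded synthetic score sets for enrichment metrics
#'
#' Ligand scores are drawn from Normal(-separation, 1) and decoy scores
#' from Normal(0, 1): separation 0 is the null (random enrichment), large
#' separations approach perfect early enrichment.
#'
#' @param n_ligands,n_decoys set sizes (>= 1 each).
#' @param separation mean score gap in favor of ligands.
#' @param seed integer seed; identical seeds give identical tables.
#' @return Data frame with columns `id`, `score`, `label`.
#' @export
make_score_set <- function(n_ligands, n_decoys, separation = 2, seed = 1L) {
  if (n_ligands < 1L || n_decoys < 1L) stop("need at least one of each label")
  with_seed(seed, {
    data.frame(
      id = c(sprintf("lig%04d", seq_len(n_ligands)),
             sprintf("dec%04d", seq_len(n_decoys))),
      score = c(rnorm(n_ligands, -separation, 1), rnorm(n_decoys, 0, 1)),
      label = rep(c("ligand", "decoy"), c(n_ligands, n_decoys)),
      stringsAsFactors = FALSE)
  })
}

#' Write a planted site to disk in the canonical dialects
#'
#' Emits `rec.sph` (sphere file), one `<kind>.grid` per bundle component,
#' `ligand.db2` (db2-lite) and `ligand.mol2` under `dir`.
#'
#' @param site a [make_planted_site()] result.
#' @param dir output directory (created if missing).
#' @param format grid format, `"text"` or `"binary"`.
#' @export
write_planted_site <- function(site, dir, format = "text") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_sphere_file(site$rec_spheres, file.path(dir, "rec.sph"))
  write_grid_bundle(site$bundle, dir, format)
  write_db2lite(site$hierarchy, file.path(dir, "ligand.db2"))
  write_mol2(site$hierarchy, file.path(dir, "ligand.mol2"))
  invisible(dir)
}
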