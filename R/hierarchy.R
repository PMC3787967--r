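#' Multi-conformer ligand hierarchies (flexibase style)
#'
#' A `conformer_hierarchy` bundles a molecule's topology (atoms, bonds,
#' partial charges, per-atom desolvation energies) with an ensemble of
#' complete conformations that share the coordinates of one rigid component,
#' typically a ring system.  Conformers are whole input conformations —
#' never recombinations of pieces of different conformations — so no
#' internally clashing geometry can be fabricated at dock time.  Heavy atoms
#' of the rigid component serve as the ligand matching spheres.
#'
#' @param name molecule identifier.
#' @param atoms data frame with columns `name`, `element`, `mol2_type`,
#'   `charge` (e), and optionally `vdw_class` (key into
#'   [vdw_parameter_table()], default the element symbol) and `desolv`
#'   (kcal/mol per-atom transfer term, default 0).
#' @param bonds data frame with columns `from`, `to` (1-based atom rows) and
#'   `order` (TRIPOS bond type: `"1"`, `"2"`, `"3"`, `"am"`, `"ar"`).
#' @param conformers list of n_atoms x 3 coordinate matrices (Angstrom).
#' @param conformer_energy force-field energy per conformer from the ligand
#'   builder (kcal/mol), or `NA`; carried through, never recomputed.
#' @param rigid integer vector of rigid-component atom rows, or `NULL` to
#'   defer to [find_rigid_component()].
#' @param validate check invariants (bond ranges, shared rigid coordinates).
#' @return An object of class `conformer_hierarchy`.
#' @export
conformer_hierarchy <- function(name, atoms, bonds, conformers,
                                conformer_energy = NULL, rigid = NULL,
                                validate = TRUE) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("name", "element", "mol2_type", "charge")
  if (!all(need %in% names(atoms)))
    stop("`atoms` needs columns: ", paste(need, collapse = ", "))
  if (is.null(atoms$vdw_class)) atoms$vdw_class <- atoms$element
  if (is.null(atoms$desolv)) atoms$desolv <- 0
  if (!all(is.finite(atoms$charge))) stop("partial charges must be finite")
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  if (nrow(bonds) && !all(c("from", "to", "order") %in% names(bonds)))
    stop("`bonds` needs columns from, to, order")
  bonds$from <- as.integer(bonds$from)
  bonds$to <- as.integer(bonds$to)
  bonds$order <- as.character(bonds$order)
  if (!is.list(conformers) || !length(conformers))
    stop("`conformers` must be a non-empty list of coordinate matrices")
  conformers <- lapply(conformers, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    unname(m)
  })
  if (is.null(conformer_energy)) conformer_energy <- rep(NA_real_, length(conformers))
  h <- structure(list(name = as.character(name), atoms = atoms, bonds = bonds,
                      rigid = if (is.null(rigid)) NULL else as.integer(rigid),
                      conformers = conformers,
                      conformer_energy = as.numeric(conformer_energy)),
                 class = "conformer_hierarchy")
  if (validate) validate_hierarchy(h)
  h
}

#' @export
print.conformer_hierarchy <- function(x, ...) {
  cat(sprintf("<conformer_hierarchy> %s: %d atoms, %d bonds, %d conformer(s)\n",
              x$name, nrow(x$atoms), nrow(x$bonds), length(x$conformers)))
  invisible(x)
}

n_conformers <- function(h) length(h$conformers)

heavy_atoms <- function(h) which(h$atoms$element != "H")

#' Validate a conformer hierarchy
#'
#' Checks structural consistency and the flexibase invariant: the rigid
#' component must have identical coordinates in every conformer, to within
#' `rigid_tol` after least-squares superposition onto the first conformer.
#'
#' @param h a [conformer_hierarchy()].
#' @param rigid_tol maximum allowed rigid-atom deviation, Angstrom.
#' @return `h`, invisibly; errors describe the first violated invariant.
#' @export
validate_hierarchy <- function(h, rigid_tol = 1e-3) {
  na <- nrow(h$atoms)
  if (nrow(h$bonds)) {
    ends <- c(h$bonds$from, h$bonds$to)
    if (any(ends < 1L | ends > na)) stop("bond endpoint out of range")
    if (any(h$bonds$from == h$bonds$to)) stop("bond endpoints must differ")
  }
  for (m in h$conformers) {
    if (nrow(m) != na || ncol(m) != 3L)
      stop("every conformer must be an n_atoms x 3 matrix")
    if (!all(is.finite(m))) stop("conformer coordinates must be finite")
  }
  if (length(h$conformer_energy) != length(h$conformers))
    stop("need one energy (or NA) per conformer")
  if (!is.null(h$rigid) && length(h$rigid) >= 3L && length(h$conformers) > 1L) {
    ref <- h$conformers[[1L]][h$rigid, , drop = FALSE]
    refset <- sphere_set(ref)
    k <- length(h$rigid)
    for (ci in seq_along(h$conformers)[-1L]) {
      cur <- h$conformers[[ci]][h$rigid, , drop = FALSE]
      tr <- fit_rigid_transform(c(seq_len(k), seq_len(k)),
                                sphere_set(cur), refset)
      dev <- sqrt(max(rowSums((orient_coordinates(tr, cur) - ref)^2)))
      if (dev > rigid_tol)
        stop(sprintf(
          "rigid-component coordinates differ between conformers 1 and %d by %.4g A (limit %g)",
          ci, dev, rigid_tol))
    }
  }
  invisible(h)
}

#' Find the rigid component of a molecule
#'
#' Returns the heavy atoms of the largest fused ring system, perceived as
#' the largest biconnected component (with at least three vertices) of the
#' heavy-atom bond graph.  For acyclic molecules the fallback is the largest
#' set of heavy atoms connected only by non-rotatable bonds (bonds to
#' terminal atoms, double/triple/aromatic/amide bonds).  Ties are broken
#' toward the lowest atom indices.  Fewer than three rigid heavy atoms means
#' the molecule cannot anchor orientation matching; it is flagged
#' undockable by returning an empty vector with attribute
#' `undockable = TRUE`.
#'
#' @param h a [conformer_hierarchy()].
#' @return Integer vector of atom rows (sorted), possibly empty with
#'   attribute `undockable`.
#' @export
find_rigid_component <- function(h) {
  heavy <- heavy_atoms(h)
  if (length(heavy) < 3L)
    return(structure(integer(0), undockable = TRUE))
  b <- h$bonds
  hb <- b[b$from %in% heavy & b$to %in% heavy, , drop = FALSE]
  pick_best <- function(comps) {
    # largest first; ties by lexicographic comparison of sorted indices
    comps <- comps[order(-vapply(comps, length, integer(1L)),
                         vapply(comps, function(v) paste(sprintf("%06d", v), collapse = ","),
                                character(1L)))]
    comps[[1L]]
  }
  if (nrow(hb)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(hb$from), to = as.character(hb$to)),
      directed = FALSE,
      vertices = data.frame(name = as.character(heavy)))
    bc <- igraph::biconnected_components(g)
    ringish <- Filter(function(vs) length(vs) >= 3L,
                      lapply(bc$components, function(vs) {
                        sort(as.integer(igraph::V(g)$name[as.integer(vs)]))
                      }))
    if (length(ringish)) return(pick_best(ringish))
  }
  # acyclic fallback: components of the non-rotatable-bond subgraph
  if (!nrow(hb)) return(structure(integer(0), undockable = TRUE))
  deg <- table(factor(c(hb$from, hb$to), levels = heavy))
  terminal <- as.integer(names(deg)[deg == 1L])
  nonrot <- hb$order %in% c("2", "3", "ar", "am") |
    hb$from %in% terminal | hb$to %in% terminal
  sub <- hb[nonrot, , drop = FALSE]
  if (!nrow(sub)) return(structure(integer(0), undockable = TRUE))
  g2 <- igraph::graph_from_data_frame(
    data.frame(from = as.character(sub$from), to = as.character(sub$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(heavy)))
  comps <- igraph::components(g2)
  groups <- split(as.integer(igraph::V(g2)$name), comps$membership)
  groups <- lapply(groups, sort)
  best <- pick_best(unname(groups))
  if (length(best) < 3L) return(structure(integer(0), undockable = TRUE))
  best
}

#' Filter a hierarchy to a conformer energy window
#'
#' Keeps the conformers whose builder energy lies within `width` kcal/mol of
#' the ensemble minimum; the minimum-energy conformer is always kept and the
#' input order is preserved.  Widening the window can only add conformers.
#'
#' @param h a [conformer_hierarchy()] with conformer energies.
#' @param width window width in kcal/mol (>= 0; `Inf` keeps everything).
#' @return The filtered hierarchy.
#' @export
energy_window_filter <- function(h, width) {
  if (!is.numeric(width) || length(width) != 1L || is.na(width) || width < 0)
    stop("`width` must be a single number >= 0")
  e <- h$conformer_energy
  if (anyNA(e)) stop("conformer energies are required for window filtering")
  keep <- which(e - min(e) <= width)
  h$conformers <- h$conformers[keep]
  h$conformer_energy <- e[keep]
  h
}

#' Built-in van der Waals parameter table
#'
#' Per-class Lennard-Jones coefficients in the two-grid geometric-combination
#' convention: a pair energy is `sqrt_a_i * sqrt_a_j / r^12 - sqrt_b_i *
#' sqrt_b_j / r^6`, so each atom carries the square roots of its homonuclear
#' 12-6 coefficients (`sqrt_a = sqrt(eps) * rmin^6`, `sqrt_b = sqrt(2 eps) *
#' rmin^3`).  Values are generic element-level parameters adequate for the
#' synthetic receptors used here; imported grids bring their own force field
#' implicitly.
#'
#' @return Data frame with columns `class`, `epsilon` (kcal/mol), `rmin`
#'   (Angstrom), `sqrt_a`, `sqrt_b`.
#' @export
vdw_parameter_table <- function() {
  p <- data.frame(
    class   = c("C",   "N",   "O",   "S",   "P",   "F",   "Cl",  "Br",  "H"),
    epsilon = c(0.086, 0.170, 0.210, 0.250, 0.200, 0.061, 0.265, 0.320, 0.0157),
    rmin    = c(3.816, 3.648, 3.442, 4.000, 4.200, 3.500, 3.900, 4.200, 1.200),
    stringsAsFactors = FALSE)
  p$sqrt_a <- sqrt(p$epsilon) * p$rmin^6
  p$sqrt_b <- sqrt(2 * p$epsilon) * p$rmin^3
  p
}

#' Per-atom scoring parameters of a hierarchy
#'
#' Resolves each atom's `vdw_class` against [vdw_parameter_table()] and
#' assembles the quantities the grid scorer multiplies into the receptor
#' potentials: vdW `sqrt_a`/`sqrt_b`, partial charge and the per-atom
#' desolvation energy.
#'
#' @param h a [conformer_hierarchy()].
#' @return Data frame with one row per atom: `sqrt_a`, `sqrt_b`, `charge`,
#'   `desolv`.
#' @export
atom_score_params <- function(h) {
  tab <- vdw_parameter_table()
  i <- match(h$atoms$vdw_class, tab$class)
  if (anyNA(i))
    stop("unknown vdw_class: ",
         paste(unique(h$atoms$vdw_class[is.na(i)]), collapse = ", "))
  data.frame(sqrt_a = tab$sqrt_a[i], sqrt_b = tab$sqrt_b[i],
             charge = h$atoms$charge, desolv = h$atoms$desolv)
}
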