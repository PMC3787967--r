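KNOWN_MOL2_TYPES <- c(
  "C.3", "C.2", "C.1", "C.ar", "C.cat", "N.3", "N.2", "N.1", "N.ar", "N.am",
  "N.pl3", "N.4", "O.3", "O.2", "O.co2", "O.spc", "O.t3p", "S.3", "S.2",
  "S.o", "S.o2", "P.3", "H", "H.spc", "H.t3p", "F", "Cl", "Br", "I",
  "Li", "Na", "K", "Ca", "Mg", "Zn", "Fe", "Du", "LP")

element_from_type <- function(type, name) {
  el <- sub("\\..*$", "", type)
  known <- type %in% KNOWN_MOL2_TYPES
  if (any(!known)) {
    warning("unknown mol2 atom type(s): ",
            paste(unique(type[!known]), collapse = ", "),
            "; inferring element from atom name")
    guess <- sub("[^A-Za-z].*$", "", name[!known])
    guess <- sub("^([A-Z][a-z]?).*$", "\\1", guess)
    el[!known] <- guess
  }
  el
}

#' Read a TRIPOS mol2 file into conformer hierarchies
#'
#' Parses `MOLECULE`/`ATOM`/`BOND` records (other record types and `#`
#' comment lines are skipped).  Consecutive molecule blocks that share a
#' name, atom table (names, types, charges) and bond table are collapsed
#' into a single [conformer_hierarchy()], one conformer per block, so a
#' multi-conformer ensemble written as repeated molecules round-trips into
#' one hierarchy.
#'
#' @param path mol2 file, optionally gzipped.
#' @return List of [conformer_hierarchy()] objects (rigid component unset;
#'   see [find_rigid_component()]).
#' @export
read_mol2 <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- sub("\r$", "", readLines(con, warn = FALSE))
  starts <- grep("^@<TRIPOS>MOLECULE[[:space:]]*$", lines)
  if (!length(starts)) stop("no @<TRIPOS>MOLECULE record in ", path)
  bad <- grep("^@<TRIPOS>", lines)
  malformed <- grep("^@<TRIPOS>$|^@<TRIPOS> ", lines)
  if (length(malformed))
    stop("malformed section header at line ", malformed[1L])
  ends <- c(starts[-1L] - 1L, length(lines))
  blocks <- Map(function(s, e) list(lines = lines[s:e], offset = s),
                starts, ends)
  mols <- lapply(blocks, parse_mol2_block)
  group_mol2_blocks(mols)
}

parse_mol2_block <- function(block) {
  lines <- block$lines
  offset <- block$offset
  content <- which(!grepl("^[[:space:]]*#", lines) & nzchar(trimws(lines)))
  sec_at <- grep("^@<TRIPOS>", lines)
  secs <- sub("^@<TRIPOS>", "", trimws(lines[sec_at]))
  get_section <- function(nm) {
    i <- which(secs == nm)
    if (!length(i)) return(character(0))
    from <- sec_at[i[1L]] + 1L
    to <- if (i[1L] < length(sec_at)) sec_at[i[1L] + 1L] - 1L else length(lines)
    if (to < from) return(character(0))
    body <- lines[from:to]
    body[!grepl("^[[:space:]]*#", body) & nzchar(trimws(body))]
  }
  mol_body <- get_section("MOLECULE")
  if (length(mol_body) < 2L)
    stop("incomplete MOLECULE record starting at line ", offset)
  name <- trimws(mol_body[1L])
  counts <- suppressWarnings(as.integer(strsplit(trimws(mol_body[2L]),
                                                 "[[:space:]]+")[[1L]]))
  natoms <- counts[1L]
  nbonds <- if (length(counts) >= 2L && !is.na(counts[2L])) counts[2L] else 0L
  atom_lines <- get_section("ATOM")
  if (length(atom_lines) != natoms)
    stop(sprintf("expected %d ATOM lines, found %d (molecule starting at line %d)",
                 natoms, length(atom_lines), offset))
  tok <- strsplit(trimws(atom_lines), "[[:space:]]+")
  if (any(vapply(tok, length, integer(1L)) < 6L))
    stop("short ATOM line in molecule starting at line ", offset)
  aname <- vapply(tok, `[[`, "", 2L)
  xyz <- t(vapply(tok, function(t) as.numeric(t[3:5]), numeric(3L)))
  atype <- vapply(tok, `[[`, "", 6L)
  charge <- vapply(tok, function(t)
    if (length(t) >= 9L) as.numeric(t[9L]) else 0, numeric(1L))
  bond_lines <- get_section("BOND")
  if (length(bond_lines) != nbonds)
    stop(sprintf("expected %d BOND lines, found %d (molecule starting at line %d)",
                 nbonds, length(bond_lines), offset))
  if (nbonds) {
    bt <- strsplit(trimws(bond_lines), "[[:space:]]+")
    bonds <- data.frame(from = vapply(bt, function(t) as.integer(t[2L]), integer(1L)),
                        to = vapply(bt, function(t) as.integer(t[3L]), integer(1L)),
                        order = vapply(bt, `[[`, "", 4L),
                        stringsAsFactors = FALSE)
  } else {
    bonds <- data.frame(from = integer(0), to = integer(0),
                        order = character(0), stringsAsFactors = FALSE)
  }
  list(name = name,
       atoms = data.frame(name = aname,
                          element = element_from_type(atype, aname),
                          mol2_type = atype, charge = charge,
                          stringsAsFactors = FALSE),
       bonds = bonds, xyz = xyz)
}

same_topology <- function(a, b) {
  identical(a$name, b$name) &&
    identical(a$atoms, b$atoms) &&
    identical(a$bonds, b$bonds)
}

group_mol2_blocks <- function(mols) {
  out <- list()
  i <- 1L
  while (i <= length(mols)) {
    j <- i
    while (j < length(mols) && same_topology(mols[[i]], mols[[j + 1L]])) j <- j + 1L
    out[[length(out) + 1L]] <- conformer_hierarchy(
      name = mols[[i]]$name, atoms = mols[[i]]$atoms, bonds = mols[[i]]$bonds,
      conformers = lapply(mols[i:j], `[[`, "xyz"))
    i <- j + 1L
  }
  out
}

format_mol2_block <- function(h, coords, name = h$name, comments = character(0)) {
  na <- nrow(h$atoms)
  nb <- nrow(h$bonds)
  c(if (length(comments)) paste("#", comments),
    "@<TRIPOS>MOLECULE",
    name,
    sprintf("%5d %5d %5d %5d %5d", na, nb, 1L, 0L, 0L),
    "SMALL",
    "USER_CHARGES",
    "@<TRIPOS>ATOM",
    sprintf("%7d %-8s %9.4f %9.4f %9.4f %-7s %3d %-7s %9.4f",
            seq_len(na), h$atoms$name, coords[, 1L], coords[, 2L],
            coords[, 3L], h$atoms$mol2_type, 1L, "LIG", h$atoms$charge),
    if (nb) "@<TRIPOS>BOND",
    if (nb) sprintf("%6d %5d %5d %4s", seq_len(nb), h$bonds$from,
                    h$bonds$to, h$bonds$order))
}

#' Write conformer hierarchies or docked poses as TRIPOS mol2
#'
#' With `poses = NULL` every conformer of the hierarchy is written as its
#' own molecule block (the layout [read_mol2()] folds back into one
#' hierarchy).  With a pose list, each pose becomes a molecule block
#' preceded by `#` comment lines carrying the score breakdown, and
#' optionally the per-atom, per-term decomposition.  Coordinates and partial
#' charges are printed to four decimals, the usual mol2 precision; nothing
#' of the input topology is lost.
#'
#' @param h a [conformer_hierarchy()].
#' @param path output path (plain or `.gz`).
#' @param poses optional `pose_list` (see [dock_molecule()]).
#' @param per_atom_breakdown write per-atom score comments for each pose.
#' @export
write_mol2 <- function(h, path, poses = NULL, per_atom_breakdown = FALSE) {
  blocks <- character(0)
  if (is.null(poses)) {
    for (coords in h$conformers)
      blocks <- c(blocks, format_mol2_block(h, coords))
  } else {
    ps <- if (inherits(poses, "pose_list")) poses$poses else poses
    for (k in seq_along(ps)) {
      p <- ps[[k]]
      comments <- c(
        sprintf("pose %d orientation %d conformer %d", k, p$orientation,
                p$conformer),
        sprintf("total %.6f vdw %.6f electrostatic %.6f desolvation %.6f",
                p$total, p$terms[["vdw"]], p$terms[["electrostatic"]],
                p$terms[["desolvation"]]))
      if (per_atom_breakdown)
        comments <- c(comments, sprintf(
          "atom %d vdw %.6f electrostatic %.6f desolvation %.6f",
          seq_len(nrow(p$per_atom)), p$per_atom[, "vdw"],
          p$per_atom[, "electrostatic"], p$per_atom[, "desolvation"]))
      blocks <- c(blocks,
                  format_mol2_block(h, p$coords,
                                    name = sprintf("%s_pose_%d", h$name, k),
                                    comments = comments))
    }
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(blocks, con)
  invisible(path)
}
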