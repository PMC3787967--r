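#' Read and write db2-lite hierarchy files
#'
#' db2-lite is this package's documented, line-oriented dialect of a
#' flexibase hierarchy file (see `docs/db2lite.md` in the source tree for
#' the format with a hand-readable example).  It carries everything the
#' docking engine needs per molecule: atoms with mol2 types, partial
#' charges, vdW classes and per-atom desolvation energies; bonds; the
#' rigid-component atom list; per-conformer coordinate blocks; and
#' per-conformer builder energies.  Reading is gzip-transparent and the
#' round trip is lossless (coordinates are stored at full double
#' precision).  The rigid-component invariant — identical rigid coordinates
#' across conformers — is checked on read and on write.
#'
#' Record lines (whitespace-separated tokens, `#` starts a comment):
#' \describe{
#'   \item{`db2lite 1`}{header, first line.}
#'   \item{`M name natoms nbonds nconformers nrigid`}{starts a molecule.}
#'   \item{`A i name element mol2_type charge vdw_class desolv`}{one atom.}
#'   \item{`B from to order`}{one bond.}
#'   \item{`R i1 i2 ...`}{rigid-component atom rows.}
#'   \item{`E e1 e2 ...`}{per-conformer energies (kcal/mol, `NA` allowed).}
#'   \item{`C k`}{starts conformer `k`, followed by `natoms` lines `x y z`.}
#' }
#'
#' @param path file path (plain or `.gz`).
#' @return `read_db2lite`: a list of [conformer_hierarchy()] objects (a
#'   file may hold one molecule or a library).
#' @export
read_db2lite <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines) || !grepl("^db2lite[[:space:]]+1$", lines[1L]))
    stop("not a db2-lite file (missing 'db2lite 1' header): ", path)
  toks <- strsplit(lines[-1L], "[[:space:]]+")
  out <- list()
  i <- 1L
  n <- length(toks)
  while (i <= n) {
    t <- toks[[i]]
    if (t[1L] != "M") stop("expected 'M' record, got: ", paste(t, collapse = " "))
    name <- t[2L]
    natoms <- as.integer(t[3L])
    nbonds <- as.integer(t[4L])
    nconf <- as.integer(t[5L])
    nrigid <- as.integer(t[6L])
    i <- i + 1L
    take <- function(tag, count) {
      rows <- toks[seq.int(i, length.out = count)]
      if (any(vapply(rows, `[[`, "", 1L) != tag))
        stop("malformed db2-lite: expected ", count, " '", tag, "' records")
      i <<- i + count
      rows
    }
    arows <- take("A", natoms)
    atoms <- data.frame(
      name = vapply(arows, `[[`, "", 3L),
      element = vapply(arows, `[[`, "", 4L),
      mol2_type = vapply(arows, `[[`, "", 5L),
      charge = vapply(arows, function(r) as.numeric(r[6L]), numeric(1L)),
      vdw_class = vapply(arows, `[[`, "", 7L),
      desolv = vapply(arows, function(r) as.numeric(r[8L]), numeric(1L)),
      stringsAsFactors = FALSE)
    brows <- if (nbonds) take("B", nbonds) else list()
    bonds <- data.frame(
      from = vapply(brows, function(r) as.integer(r[2L]), integer(1L)),
      to = vapply(brows, function(r) as.integer(r[3L]), integer(1L)),
      order = vapply(brows, `[[`, "", 4L),
      stringsAsFactors = FALSE)
    rrow <- take("R", 1L)[[1L]]
    rigid <- if (nrigid) as.integer(rrow[1L + seq_len(nrigid)]) else integer(0)
    erow <- take("E", 1L)[[1L]]
    energies <- suppressWarnings(as.numeric(erow[1L + seq_len(nconf)]))
    conformers <- vector("list", nconf)
    for (k in seq_len(nconf)) {
      crow <- take("C", 1L)[[1L]]
      if (as.integer(crow[2L]) != k)
        stop("db2-lite conformer blocks out of order in ", name)
      xyz <- t(vapply(toks[seq.int(i, length.out = natoms)],
                      function(r) as.numeric(r[1:3]), numeric(3L)))
      i <- i + natoms
      conformers[[k]] <- xyz
    }
    h <- conformer_hierarchy(name, atoms, bonds, conformers,
                             conformer_energy = energies,
                             rigid = if (length(rigid)) rigid else NULL,
                             validate = FALSE)
    validate_hierarchy(h)  # enforces the rigid-component invariant
    out[[length(out) + 1L]] <- h
  }
  out
}

num_repr <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 17, format = "g"))
}

#' @rdname read_db2lite
#' @param h a [conformer_hierarchy()] or a list of them.
#' @export
write_db2lite <- function(h, path) {
  hs <- if (inherits(h, "conformer_hierarchy")) list(h) else h
  lines <- "db2lite 1"
  for (hh in hs) {
    validate_hierarchy(hh)
    rigid <- if (is.null(hh$rigid)) integer(0) else hh$rigid
    a <- hh$atoms
    lines <- c(lines,
      sprintf("M %s %d %d %d %d", hh$name, nrow(a), nrow(hh$bonds),
              length(hh$conformers), length(rigid)),
      sprintf("A %d %s %s %s %s %s %s", seq_len(nrow(a)), a$name, a$element,
              a$mol2_type, num_repr(a$charge), a$vdw_class,
              num_repr(a$desolv)),
      if (nrow(hh$bonds))
        sprintf("B %d %d %s", hh$bonds$from, hh$bonds$to, hh$bonds$order),
      paste(c("R", rigid), collapse = " "),
      paste(c("E", num_repr(hh$conformer_energy)), collapse = " "))
    for (k in seq_along(hh$conformers)) {
      xyz <- hh$conformers[[k]]
      lines <- c(lines, sprintf("C %d", k),
                 paste(num_repr(xyz[, 1L]), num_repr(xyz[, 2L]),
                       num_repr(xyz[, 3L])))
    }
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
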