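#' Labelled matching-sphere sets
#'
#' Matching spheres are labelled 3D points.  On the receptor side they mark
#' hot-spots where a ligand atom is likely to sit (classically placed at the
#' crystallographic ligand heavy-atom coordinates plus nearby generated
#' spheres); on the ligand side they are the heavy-atom positions of the
#' rigid component.
#'
#' @param positions numeric matrix with three columns (x, y, z, Angstrom).
#' @param index integer labels, one per sphere, unique.  Defaults to row
#'   numbers.  Labels are carried through file I/O; all internal references
#'   to spheres (e.g. in correspondences) use 1-based row positions.
#' @return An object of class `sphere_set` with elements `index` and `xyz`.
#' @examples
#' s <- sphere_set(rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0)))
#' pairwise_distance_matrix(s)
#' @export
sphere_set <- function(positions, index = seq_len(nrow(positions))) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L)
    stop("`positions` must have three columns (x, y, z)")
  storage.mode(positions) <- "double"
  if (!all(is.finite(positions)))
    stop("sphere coordinates must be finite")
  index <- as.integer(index)
  if (length(index) != nrow(positions))
    stop("need exactly one index per sphere")
  if (anyDuplicated(index))
    stop("sphere indices must be unique")
  structure(list(index = index, xyz = unname(positions)),
            class = "sphere_set")
}

#' @export
print.sphere_set <- function(x, ...) {
  cat(sprintf("<sphere_set> %d spheres\n", nrow(x$xyz)))
  invisible(x)
}

#' Number of spheres in a set
#' @param s a `sphere_set`.
#' @export
n_spheres <- function(s) nrow(as_sphere_xyz(s))

as_sphere_xyz <- function(s) {
  if (inherits(s, "sphere_set")) return(s$xyz)
  m <- as.matrix(s)
  if (ncol(m) != 3L) stop("expected a sphere_set or an n x 3 matrix")
  storage.mode(m) <- "double"
  unname(m)
}

#' Pairwise Euclidean distance matrix of a sphere set
#'
#' @param spheres a `sphere_set` or an n x 3 coordinate matrix.
#' @return Symmetric matrix of distances in Angstrom with zero diagonal.
#' @export
pairwise_distance_matrix <- function(spheres) {
  xyz <- as_sphere_xyz(spheres)
  if (nrow(xyz) < 1L) stop("need at least one sphere")
  if (!all(is.finite(xyz))) stop("sphere coordinates must be finite")
  d <- as.matrix(dist(xyz))
  dimnames(d) <- NULL
  d
}

#' Read and write sphere files
#'
#' The canonical dialect is one sphere per line, `index x y z`, free-format
#' floats, `#` comments, optionally gzipped.  The reader is tolerant of the
#' classic SPHGEN cluster layout: any line whose first four whitespace-
#' separated tokens parse as numbers is taken as `index x y z`; other lines
#' (cluster headers, trailing columns) are skipped.
#'
#' @param path file path (plain or `.gz`).
#' @return `read_sphere_file`: a [sphere_set()].
#' @export
read_sphere_file <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(ln) {
    tok <- strsplit(ln, "[[:space:]]+")[[1L]]
    if (length(tok) < 4L) return(NULL)
    val <- suppressWarnings(as.numeric(tok[1:4]))
    if (anyNA(val)) return(NULL)
    val
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) stop("no sphere records found in ", path)
  m <- do.call(rbind, rows)
  sphere_set(m[, 2:4, drop = FALSE], index = as.integer(m[, 1L]))
}

#' @rdname read_sphere_file
#' @param spheres a [sphere_set()] to write.
#' @export
write_sphere_file <- function(spheres, path) {
  xyz <- as_sphere_xyz(spheres)
  idx <- if (inherits(spheres, "sphere_set")) spheres$index
         else seq_len(nrow(xyz))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(c("# minidock sphere file: index x y z (Angstrom)",
               sprintf("%d %.6f %.6f %.6f", idx, xyz[, 1], xyz[, 2], xyz[, 3])),
             con)
  invisible(path)
}
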