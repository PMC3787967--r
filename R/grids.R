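#' Regular lattices and scalar grids
#'
#' A `dock_lattice` is a uniform rectilinear lattice (common `spacing` on
#' all axes); a `scalar_grid` attaches an `nx x ny x nz` array of values to
#' it.  Grids pre-compute receptor potential functions — vdW repulsive and
#' attractive sums, electrostatic potential, fractional ligand desolvation —
#' which the scorer multiplies with atomic properties into energies.  Grid
#' sizes come entirely from the data (file headers); nothing is compiled
#' in.
#'
#' @param origin lattice origin, length-3, Angstrom.
#' @param spacing lattice spacing, Angstrom, > 0.
#' @param dims integer dimensions, each >= 2.
#' @return `dock_lattice`: the lattice object.
#' @export
dock_lattice <- function(origin, spacing, dims) {
  origin <- as.numeric(origin)
  dims <- as.integer(dims)
  if (length(origin) != 3L || length(dims) != 3L)
    stop("origin and dims must have length 3")
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be > 0")
  if (any(dims < 2L)) stop("need at least 2 lattice points per axis")
  structure(list(origin = origin, spacing = as.numeric(spacing), dims = dims),
            class = "dock_lattice")
}

#' @rdname dock_lattice
#' @param lattice a `dock_lattice`.
#' @param values numeric array `dims[1] x dims[2] x dims[3]`, or a vector in
#'   x-fastest order.
#' @param kind grid kind label (e.g. `"vdw_repulsive"`).
#' @param units unit label carried through file I/O.
#' @export
scalar_grid <- function(lattice, values, kind = "generic", units = "") {
  if (!inherits(lattice, "dock_lattice")) stop("`lattice` must be a dock_lattice")
  if (!is.array(values)) {
    if (length(values) != prod(lattice$dims))
      stop("values length does not match lattice dims")
    values <- array(as.numeric(values), dim = lattice$dims)
  } else if (!identical(dim(values), as.integer(lattice$dims))) {
    stop("values array dims do not match lattice dims")
  }
  if (!all(is.finite(values))) stop("grid values must be finite")
  structure(list(lattice = lattice, values = values, kind = kind,
                 units = units),
            class = "scalar_grid")
}

#' @export
print.scalar_grid <- function(x, ...) {
  d <- x$lattice$dims
  cat(sprintf("<scalar_grid> %s: %dx%dx%d, spacing %.3f A\n", x$kind,
              d[1L], d[2L], d[3L], x$lattice$spacing))
  invisible(x)
}

# fractional lattice coordinates, clamped cell index and in-cell offsets;
# shared by the naive and precomputed interpolation paths
lattice_fractional <- function(lattice, points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 3L) stop("`points` must be n x 3")
  u <- sweep(sweep(pts, 2L, lattice$origin), 2L, lattice$spacing, "/")
  d <- lattice$dims
  eps <- 1e-9
  inb <- u[, 1L] >= -eps & u[, 1L] <= d[1L] - 1 + eps &
         u[, 2L] >= -eps & u[, 2L] <= d[2L] - 1 + eps &
         u[, 3L] >= -eps & u[, 3L] <= d[3L] - 1 + eps
  i0 <- floor(u)
  for (a in 1:3) i0[, a] <- pmin(pmax(i0[, a], 0), d[a] - 2L)
  list(i0 = i0, f = u - i0, inb = inb)
}

corner_weights <- function(f) {
  # columns in (dx, dy, dz) order: 000,100,010,110,001,101,011,111
  wx0 <- 1 - f[, 1L]; wx1 <- f[, 1L]
  wy0 <- 1 - f[, 2L]; wy1 <- f[, 2L]
  wz0 <- 1 - f[, 3L]; wz1 <- f[, 3L]
  cbind(wx0 * wy0 * wz0, wx1 * wy0 * wz0, wx0 * wy1 * wz0, wx1 * wy1 * wz0,
        wx0 * wy0 * wz1, wx1 * wy0 * wz1, wx0 * wy1 * wz1, wx1 * wy1 * wz1)
}

CORNER_OFFSETS <- cbind(dx = c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L),
                        dy = c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L),
                        dz = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L))

#' Trilinear interpolation (reference path)
#'
#' Standard 8-corner trilinear blend of the grid values around each query
#' point; exact at lattice nodes and for affine fields.  Points outside the
#' lattice bounding box give `NA`, which the scorer treats as an
#' out-of-grid pose rejection.
#'
#' @param grid a [scalar_grid()].
#' @param points n x 3 query coordinates (Angstrom).
#' @return Numeric vector of interpolated values (`NA` out of bounds).
#' @export
trilinear_naive <- function(grid, points) {
  lf <- lattice_fractional(grid$lattice, points)
  n <- nrow(lf$i0)
  out <- rep(NA_real_, n)
  sel <- which(lf$inb)
  if (!length(sel)) return(out)
  i0 <- lf$i0[sel, , drop = FALSE]
  w <- corner_weights(lf$f[sel, , drop = FALSE])
  d <- grid$lattice$dims
  v <- grid$values
  acc <- numeric(length(sel))
  for (k in 1:8) {
    lin <- (i0[, 1L] + CORNER_OFFSETS[k, 1L]) +
      d[1L] * ((i0[, 2L] + CORNER_OFFSETS[k, 2L]) +
                 d[2L] * (i0[, 3L] + CORNER_OFFSETS[k, 3L])) + 1
    acc <- acc + w[, k] * v[lin]
  }
  out[sel] <- acc
  out
}

#' Precompute per-cube interpolation data
#'
#' Stores the 8 corner values of every interpolation cube contiguously so a
#' lookup touches one row instead of gathering strided corners from the 3-D
#' array.  Costs roughly 8x the source grid's memory and reconstructs it
#' exactly: `trilinear_fast()` on the result agrees with
#' [trilinear_naive()] to rounding error.
#'
#' @param grid a [scalar_grid()].
#' @return An object of class `precomputed_grid`.
#' @export
precompute_grid <- function(grid) {
  d <- grid$lattice$dims
  nc <- prod(d - 1L)
  corners <- matrix(0, nc, 8L)
  v <- grid$values
  for (k in 1:8) {
    off <- CORNER_OFFSETS[k, ]
    corners[, k] <- as.numeric(
      v[off[1L] + seq_len(d[1L] - 1L),
        off[2L] + seq_len(d[2L] - 1L),
        off[3L] + seq_len(d[3L] - 1L)])
  }
  structure(list(lattice = grid$lattice, corners = corners, kind = grid$kind),
            class = "precomputed_grid")
}

#' @rdname precompute_grid
#' @param pg a `precomputed_grid`.
#' @param points n x 3 query coordinates.
#' @export
trilinear_fast <- function(pg, points) {
  lf <- lattice_fractional(pg$lattice, points)
  n <- nrow(lf$i0)
  out <- rep(NA_real_, n)
  sel <- which(lf$inb)
  if (!length(sel)) return(out)
  i0 <- lf$i0[sel, , drop = FALSE]
  d <- pg$lattice$dims
  cube <- i0[, 1L] + (d[1L] - 1L) * (i0[, 2L] + (d[2L] - 1L) * i0[, 3L]) + 1
  w <- corner_weights(lf$f[sel, , drop = FALSE])
  out[sel] <- rowSums(pg$corners[cube, , drop = FALSE] * w)
  out
}

#' Bundle of co-registered scoring grids
#'
#' The four scalar grids the scorer reads: `vdw_repulsive` (sqrt-A-weighted
#' r^-12 sums), `vdw_attractive` (sqrt-B-weighted r^-6 sums),
#' `electrostatic` (potential, kcal/(mol e); `es_scale` rescales imported
#' grids in other units, default 1) and `desolvation` (dimensionless
#' fractional desolvation).  All four must share one lattice.
#'
#' @param vdw_repulsive,vdw_attractive,electrostatic,desolvation
#'   [scalar_grid()]s on a common lattice.
#' @param es_scale multiplicative scale applied to the electrostatic grid at
#'   scoring time.
#' @return An object of class `grid_bundle`.
#' @export
grid_bundle <- function(vdw_repulsive, vdw_attractive, electrostatic,
                        desolvation, es_scale = 1) {
  grids <- list(vdw_repulsive = vdw_repulsive, vdw_attractive = vdw_attractive,
                electrostatic = electrostatic, desolvation = desolvation)
  lat <- grids[[1L]]$lattice
  for (g in grids) {
    if (!inherits(g, "scalar_grid")) stop("all components must be scalar_grids")
    if (!identical(g$lattice, lat)) stop("all grids must share one lattice")
  }
  structure(c(grids, list(es_scale = es_scale, cache = NULL)),
            class = "grid_bundle")
}

GRID_KINDS <- c("vdw_repulsive", "vdw_attractive", "electrostatic",
                "desolvation")

#' @rdname grid_bundle
#' @param bundle a `grid_bundle`.
#' @export
precompute_bundle <- function(bundle) {
  if (!is.null(bundle$cache)) return(bundle)
  bundle$cache <- lapply(bundle[GRID_KINDS], precompute_grid)
  bundle
}

bundle_lookup <- function(bundle, points) {
  if (is.null(bundle$cache))
    lapply(bundle[GRID_KINDS], trilinear_naive, points = points)
  else
    lapply(bundle$cache, trilinear_fast, points = points)
}

#' Read and write grid files
#'
#' The on-disk format is a small self-describing header (format magic,
#' kind, units, origin, spacing, dims) followed by the values in x-fastest
#' order, either as text or as little-endian float64 (`format = "binary"`).
#' Both variants are gzip-transparent.  Grids are sized entirely from their
#' headers.
#'
#' @param grid a [scalar_grid()].
#' @param path file path (plain or `.gz`).
#' @param format `"text"` or `"binary"`.
#' @export
write_grid <- function(grid, path, format = c("text", "binary")) {
  format <- match.arg(format)
  gz <- grepl("\\.gz$", path)
  con <- if (gz) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  lat <- grid$lattice
  header <- c(paste("minidock-grid 1", format),
              paste("kind", grid$kind),
              paste("units", grid$units),
              paste("origin", paste(num_repr(lat$origin), collapse = " ")),
              paste("spacing", num_repr(lat$spacing)),
              paste("dims", paste(lat$dims, collapse = " ")))
  writeLines(header, con)
  if (format == "text") {
    writeLines(num_repr(as.numeric(grid$values)), con)
  } else {
    writeBin(as.numeric(grid$values), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  header <- readLines(con, n = 6L)
  magic <- strsplit(header[1L], "[[:space:]]+")[[1L]]
  if (length(magic) < 3L || magic[1L] != "minidock-grid")
    stop("not a minidock grid file: ", path)
  format <- magic[3L]
  field <- function(i, nm) {
    tok <- strsplit(header[i], "[[:space:]]+")[[1L]]
    if (tok[1L] != nm) stop("grid header missing field: ", nm)
    tok[-1L]
  }
  kind <- field(2L, "kind")[1L]
  units_tok <- field(3L, "units")
  units <- if (length(units_tok)) paste(units_tok, collapse = " ") else ""
  origin <- as.numeric(field(4L, "origin"))
  spacing <- as.numeric(field(5L, "spacing"))
  dims <- as.integer(field(6L, "dims"))
  lat <- dock_lattice(origin, spacing, dims)
  nval <- prod(dims)
  vals <- if (format == "binary") {
    readBin(con, "double", n = nval, size = 8L, endian = "little")
  } else {
    as.numeric(readLines(con))
  }
  if (length(vals) != nval)
    stop(sprintf("grid payload has %d values, header promises %d",
                 length(vals), nval))
  scalar_grid(lat, vals, kind = kind, units = units)
}

#' @rdname write_grid
#' @param bundle a [grid_bundle()].
#' @param dir directory to hold one `<kind>.grid` file per component.
#' @export
write_grid_bundle <- function(bundle, dir, format = c("text", "binary")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (kind in GRID_KINDS)
    write_grid(bundle[[kind]], file.path(dir, paste0(kind, ".grid")), format)
  invisible(dir)
}

#' @rdname write_grid
#' @export
read_grid_bundle <- function(dir) {
  grids <- lapply(GRID_KINDS, function(kind) {
    p <- file.path(dir, paste0(kind, ".grid"))
    if (!file.exists(p)) p <- paste0(p, ".gz")
    read_grid(p)
  })
  names(grids) <- GRID_KINDS
  grid_bundle(grids$vdw_repulsive, grids$vdw_attractive, grids$electrostatic,
              grids$desolvation)
}
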