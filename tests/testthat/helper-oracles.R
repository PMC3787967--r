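# Independent oracles, deliberately written with different algorithms than
# the package paths they check.

all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in all_permutations(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# exhaustive enumeration over all ligand subsets x injective receptor
# assignments; canonical row order matching enumerate_matches()
brute_force_matches <- function(lig, rec, tolerance, node_count = 4L) {
  lx <- if (inherits(lig, "sphere_set")) lig$xyz else lig
  rx <- if (inherits(rec, "sphere_set")) rec$xyz else rec
  nl <- nrow(lx)
  nr <- nrow(rx)
  Dl <- as.matrix(dist(lx))
  Dr <- as.matrix(dist(rx))
  if (nl < node_count || nr < node_count)
    return(matrix(integer(0), 0, 2L * node_count))
  pairs <- t(combn(node_count, 2L))
  # all injective receptor tuples, rows lexicographically unordered for now
  tuples <- do.call(rbind, unlist(lapply(
    asplit(combn(nr, node_count), 2L),
    function(ss) all_permutations(as.integer(ss))), recursive = FALSE))
  rows <- list()
  for (s in asplit(combn(nl, node_count), 2L)) {
    ok <- rep(TRUE, nrow(tuples))
    for (p in seq_len(nrow(pairs))) {
      a <- pairs[p, 1L]; bdx <- pairs[p, 2L]
      ok <- ok & abs(Dr[cbind(tuples[, a], tuples[, bdx])] -
                       Dl[s[a], s[bdx]]) <= tolerance
    }
    if (any(ok)) {
      tt <- tuples[ok, , drop = FALSE]
      rows[[length(rows) + 1L]] <-
        cbind(matrix(as.integer(s), nrow(tt), node_count, byrow = TRUE), tt)
    }
  }
  if (!length(rows)) return(matrix(integer(0), 0, 2L * node_count))
  m <- do.call(rbind, rows)
  m[do.call(order, lapply(seq_len(ncol(m)), function(j) m[, j])), ,
    drop = FALSE]
}

match_rows_as_strings <- function(m) {
  m <- unname(as.matrix(m))
  if (nrow(m) == 0L) return(character(0))
  unname(apply(m, 1L, paste, collapse = ","))
}

naive_rmsd <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))

# min-cost assignment by exhaustive permutation (square or rectangular)
brute_force_assignment_cost <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  best <- Inf
  for (cols in asplit(combn(m, n), 2L))
    for (p in all_permutations(as.integer(cols)))
      best <- min(best, sum(cost[cbind(seq_len(n), p)]))
  best
}

random_sphere_set <- function(n, box = 5) sphere_set(matrix(runif(n * 3L, 0, box), n, 3L))

# regular benzene ring, radius 1.39, in the xy plane
benzene_xyz <- function() {
  ang <- 2 * pi * (0:5) / 6
  cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
}

constant_bundle <- function(rep_val = 0, att_val = 0, es_val = 0,
                            des_val = 0, origin = c(0, 0, 0), spacing = 1,
                            dims = c(5L, 5L, 5L)) {
  lat <- dock_lattice(origin, spacing, dims)
  n <- prod(dims)
  grid_bundle(scalar_grid(lat, rep(rep_val, n), "vdw_repulsive"),
              scalar_grid(lat, rep(att_val, n), "vdw_attractive"),
              scalar_grid(lat, rep(es_val, n), "electrostatic"),
              scalar_grid(lat, rep(des_val, n), "desolvation"))
}

random_grid <- function(dims = c(6L, 5L, 7L), spacing = 0.7,
                        origin = c(-1, 0, 2)) {
  lat <- dock_lattice(origin, spacing, dims)
  scalar_grid(lat, runif(prod(dims), -5, 5), "generic")
}

# fine log10-axis quadrature of a staircase ROC curve (untied scores give
# alternating vertical/horizontal segments, so constant interpolation from
# the left is exact): an independent numerical oracle for log_auc()
log_auc_quadrature <- function(curve, lambda = 0.001, n = 400000L) {
  f <- curve$fpr
  t <- curve$tpr
  agg <- tapply(t, f, max)  # tpr reached at each fpr
  fx <- as.numeric(names(agg))
  gx <- exp(seq(log(lambda), log(1), length.out = n))
  ty <- approx(fx, as.numeric(agg), xout = gx, method = "constant",
               rule = 2)$y
  lg <- log10(gx)
  100 * sum(diff(lg) * (head(ty, -1) + ty[-1]) / 2) / log10(1 / lambda)
}
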