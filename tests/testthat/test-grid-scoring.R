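test_that("trilinear interpolation is exact at lattice nodes and on affine fields", {
  set.seed(2)
  g <- random_grid()
  lat <- g$lattice
  # every lattice node reproduces the stored value, both paths
  pts <- minidock:::lattice_points(lat)
  expect_equal(trilinear_naive(g, pts), as.numeric(g$values), tolerance = 1e-12)
  pg <- precompute_grid(g)
  expect_equal(trilinear_fast(pg, pts), as.numeric(g$values), tolerance = 1e-12)

  # affine field f = 2x - y + 3z reproduced anywhere inside
  f <- function(p) 2 * p[, 1] - p[, 2] + 3 * p[, 3]
  ga <- scalar_grid(lat, f(pts))
  q <- cbind(runif(200, lat$origin[1], lat$origin[1] + lat$spacing * (lat$dims[1] - 1)),
             runif(200, lat$origin[2], lat$origin[2] + lat$spacing * (lat$dims[2] - 1)),
             runif(200, lat$origin[3], lat$origin[3] + lat$spacing * (lat$dims[3] - 1)))
  expect_equal(trilinear_naive(ga, q), f(q), tolerance = 1e-9)
})

test_that("a cube-center query returns the mean of the eight corners", {
  lat <- dock_lattice(c(0, 0, 0), 1, c(2, 2, 2))
  g <- scalar_grid(lat, 0:7)
  expect_equal(trilinear_naive(g, matrix(0.5, 1, 3)), mean(0:7))
})

test_that("the precomputed path equals the naive path and stays within corner bounds", {
  set.seed(4)
  for (rep in 1:3) {
    g <- random_grid(dims = sample(4:9, 3), spacing = runif(1, 0.3, 1.2),
                     origin = runif(3, -3, 3))
    pg <- precompute_grid(g)
    lat <- g$lattice
    n <- 2000
    q <- sapply(1:3, function(a)
      runif(n, lat$origin[a], lat$origin[a] + lat$spacing * (lat$dims[a] - 1)))
    v1 <- trilinear_naive(g, q)
    v2 <- trilinear_fast(pg, q)
    expect_lt(max(abs(v1 - v2) / pmax(abs(v1), 1e-12)), 1e-10)
    # interpolation is a convex blend: bounded by the global value range
    expect_true(all(v1 >= min(g$values) - 1e-12 & v1 <= max(g$values) + 1e-12))
  }
  # constant grid -> every cube record constant
  gc <- scalar_grid(dock_lattice(c(0, 0, 0), 1, c(3, 3, 3)), rep(4.2, 27))
  expect_true(all(precompute_grid(gc)$corners == 4.2))
})

test_that("points outside the lattice give NA (pose-rejection signal)", {
  g <- random_grid(dims = c(4, 4, 4), spacing = 1, origin = c(0, 0, 0))
  out <- trilinear_naive(g, rbind(c(-0.5, 1, 1), c(1, 1, 3.5), c(1, 1, 1)))
  expect_true(is.na(out[1]) && is.na(out[2]) && !is.na(out[3]))
  pg <- precompute_grid(g)
  expect_identical(is.na(trilinear_fast(pg, rbind(c(-0.5, 1, 1)))), TRUE)
})

test_that("grid files round trip in text and binary, plain and gzipped", {
  set.seed(6)
  g <- random_grid()
  g$kind <- "electrostatic"
  g$units <- "kcal/(mol e)"
  for (path in c(tempfile(fileext = ".grid"), tempfile(fileext = ".grid.gz"))) {
    for (fmt in c("text", "binary")) {
      write_grid(g, path, fmt)
      b <- read_grid(path)
      expect_equal(b$values, g$values)
      expect_identical(b$lattice, g$lattice)
      expect_identical(b$kind, g$kind)
    }
  }
  # bundles round trip directory-wise
  site <- make_planted_site(seed = 3)
  dir <- tempfile()
  write_grid_bundle(site$bundle, dir)
  b2 <- read_grid_bundle(dir)
  expect_equal(b2$vdw_repulsive$values, site$bundle$vdw_repulsive$values)
  expect_equal(b2$desolvation$values, site$bundle$desolvation$values)
})

test_that("atom energies are grid potentials times atomic properties", {
  zero <- list(sqrt_a = 0, sqrt_b = 0, charge = 0, desolv = 0)
  bundle <- constant_bundle(rep_val = 3, att_val = 2, es_val = -5, des_val = 0.5)
  e0 <- atom_energy(zero, c(2, 2, 2), bundle)
  expect_equal(e0$total, 0)
  eq <- atom_energy(list(sqrt_a = 0, sqrt_b = 0, charge = 1, desolv = 0),
                    c(2, 2, 2), bundle)
  expect_equal(eq$electrostatic, -5)
  ev <- atom_energy(list(sqrt_a = 2, sqrt_b = 3, charge = 0, desolv = 2),
                    c(2, 2, 2), bundle)
  expect_equal(ev$vdw, 2 * 3 - 3 * 2)
  expect_equal(ev$desolvation, 1)
  off <- atom_energy(zero, c(99, 0, 0), bundle)
  expect_false(off$in_grid)
})

test_that("grid scoring of a single-atom receptor matches the analytic pair energy within 2% at 0.2 A spacing", {
  rec <- data.frame(x = 0, y = 0, z = 0,
                    sqrt_a = sqrt(0.3) * 3.8^6, sqrt_b = sqrt(0.6) * 3.8^3,
                    charge = 0.5)
  field <- minidock:::analytic_field(rec)
  lat <- dock_lattice(c(1.8, -2.5, -2.5), 0.2, c(26, 26, 26))
  comp <- minidock:::analytic_field_components(field,
                                               minidock:::lattice_points(lat))
  bundle <- grid_bundle(scalar_grid(lat, comp$vdw_repulsive),
                        scalar_grid(lat, comp$vdw_attractive),
                        scalar_grid(lat, comp$electrostatic),
                        scalar_grid(lat, comp$desolvation))
  probe <- list(sqrt_a = sqrt(0.1) * 3.6^6, sqrt_b = sqrt(0.2) * 3.6^3,
                charge = -0.4, desolv = 0.2)
  set.seed(10)
  for (rep in 1:25) {
    r <- runif(1, 3.4, 4.4)
    phi <- runif(1, 0, 0.5)     # polar offset from +x keeps probes in-box
    psi <- runif(1, 0, 2 * pi)
    p <- r * c(cos(phi), sin(phi) * cos(psi), sin(phi) * sin(psi))
    exact <- probe$sqrt_a * rec$sqrt_a / r^12 -
      probe$sqrt_b * rec$sqrt_b / r^6 +
      probe$charge * 332.0636 * rec$charge / (4 * r) +
      probe$desolv * exp(-r^2 / 8)
    got <- atom_energy(probe, p, bundle)
    expect_true(got$in_grid)
    expect_equal(got$total, exact, tolerance = 0.02)
  }
})

test_that("pose energies decompose exactly and rescore bitwise-identically", {
  site <- make_planted_site(seed = 2)
  h <- site$hierarchy
  b <- precompute_bundle(site$bundle)
  sp <- atom_score_params(h)
  pe <- pose_energy(site$planted, sp, b, 50)
  expect_identical(pe$status, "scored")
  expect_lt(abs(pe$total - sum(pe$per_atom)), 1e-9)
  expect_lt(abs(pe$total - sum(pe$terms)), 1e-9)
  expect_equal(pe$terms[["vdw"]], sum(pe$per_atom[, "vdw"]))
  pe2 <- pose_energy(site$planted, sp, b, 50)
  expect_identical(pe, pe2)
})

test_that("the bump filter triggers on the running repulsive sum", {
  bundle <- constant_bundle(rep_val = 60)
  one <- data.frame(sqrt_a = 1, sqrt_b = 0, charge = 0, desolv = 0)
  pe <- pose_energy(matrix(2, 1, 3), one, bundle, bump_limit = 50)
  expect_identical(pe$status, "bumped")
  expect_identical(pe$bumped_at, 1L)
  ok <- pose_energy(matrix(2, 1, 3), one, bundle, bump_limit = Inf)
  expect_identical(ok$status, "scored")
  # an empty (zero) field scores zero
  z <- pose_energy(matrix(2, 4, 3), one[rep(1, 4), ], constant_bundle(), 50)
  expect_identical(z$status, "scored")
  expect_equal(z$total, 0)
  # cumulative semantics: four atoms at 20 each pass 50 only at atom 3
  b20 <- constant_bundle(rep_val = 20)
  pe4 <- pose_energy(matrix(2, 4, 3), one[rep(1, 4), ], b20, bump_limit = 50)
  expect_identical(pe4$status, "bumped")
  expect_identical(pe4$bumped_at, 3L)
})

test_that("any out-of-grid atom rejects the whole pose", {
  bundle <- constant_bundle()
  one <- data.frame(sqrt_a = 1, sqrt_b = 0, charge = 0, desolv = 0)
  pe <- pose_energy(rbind(c(2, 2, 2), c(9, 2, 2)), one[c(1, 1), ], bundle, 50)
  expect_identical(pe$status, "out_of_grid")
  expect_identical(pe$out_of_grid_at, 2L)
})
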