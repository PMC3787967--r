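make_custom_mol <- function(atoms, bonds, coords, name = "CUSTOM") {
  conformer_hierarchy(name, atoms, bonds, list(as.matrix(coords)))
}

# cyclohexane ring with one hydroxyl (sp3 carrier), H out of plane
make_cyclohexanol <- function(h_dihedral = 1.0) {
  ang <- 2 * pi * (0:5) / 6
  ring <- cbind(1.5 * cos(ang), 1.5 * sin(ang), 0.25 * rep_len(c(1, -1), 6))
  o <- ring[1, ] + c(1.2, 0, 0.6)
  coords <- rbind(ring, o, o + c(0.5, 0.6, 0.4))
  atoms <- data.frame(
    name = c(sprintf("C%d", 1:6), "O7", "H8"),
    element = c(rep("C", 6), "O", "H"),
    mol2_type = c(rep("C.3", 6), "O.3", "H"),
    charge = c(rep(0, 6), -0.4, 0.4), stringsAsFactors = FALSE)
  bonds <- data.frame(from = c(1:6, 1, 7), to = c(2:6, 1, 7, 8),
                      order = "1", stringsAsFactors = FALSE)
  h <- make_custom_mol(atoms, bonds, coords, "CYCLOHEXANOL")
  h$conformers[[1]] <- minidock:::set_hydroxyl_dihedral(
    h$conformers[[1]], ref = 2, c_at = 1, o_at = 7, h_idx = 8, h_dihedral)
  h
}

test_that("mol2 round trip preserves atoms, bonds, charges and coordinates", {
  h <- make_hierarchy(n_atoms = 11, n_conformers = 3, n_hydroxyls = 1,
                      seed = 4)
  path <- tempfile(fileext = ".mol2")
  write_mol2(h, path)
  back <- read_mol2(path)
  expect_length(back, 1L)  # 3 MOLECULE blocks of one topology -> 1 hierarchy
  b <- back[[1]]
  expect_identical(length(b$conformers), 3L)
  expect_identical(b$atoms$name, h$atoms$name)
  expect_identical(b$atoms$mol2_type, h$atoms$mol2_type)
  expect_identical(b$atoms$element, h$atoms$element)
  expect_equal(b$atoms$charge, h$atoms$charge, tolerance = 1e-12) # 4 decimals
  expect_identical(b$bonds, h$bonds)
  for (k in 1:3)
    expect_equal(b$conformers[[k]], h$conformers[[k]], tolerance = 1e-4)
})

test_that("distinct consecutive topologies stay separate hierarchies", {
  h1 <- make_hierarchy(seed = 1)
  h2 <- make_hierarchy(seed = 2, n_atoms = 8)
  path <- tempfile(fileext = ".mol2")
  writeLines(c(readLines(write_mol2(h1, tempfile(fileext = ".mol2"))),
               readLines(write_mol2(h2, tempfile(fileext = ".mol2")))),
             path)
  back <- read_mol2(path)
  expect_length(back, 2L)
  expect_identical(vapply(back, function(x) length(x$conformers), integer(1)),
                   c(3L, 3L))
})

test_that("unknown atom types warn and fall back to name-derived elements", {
  lines <- c("@<TRIPOS>MOLECULE", "weird", " 1 0 0 0 0", "SMALL",
             "USER_CHARGES", "@<TRIPOS>ATOM",
             "1 N1 0.0 0.0 0.0 N.funky 1 LIG -0.5")
  path <- tempfile(fileext = ".mol2")
  writeLines(lines, path)
  expect_warning(mols <- read_mol2(path), "unknown mol2 atom type")
  expect_identical(mols[[1]]$atoms$element, "N")
})

test_that("mol2 parse errors carry useful context", {
  path <- tempfile(fileext = ".mol2")
  writeLines(c("@<TRIPOS>MOLECULE", "broken", " 2 0 0 0 0", "SMALL",
               "USER_CHARGES", "@<TRIPOS>ATOM",
               "1 C1 0.0 0.0 0.0 C.3 1 LIG 0.0"), path)
  expect_error(read_mol2(path), "ATOM lines")
})

test_that("our mol2 output is readable by an independent parser", {
  skip_if_not_installed("bio3d")
  h <- make_hierarchy(seed = 6, n_conformers = 1)
  path <- tempfile(fileext = ".mol2")
  write_mol2(h, path)
  m <- bio3d::read.mol2(path)
  expect_equal(nrow(m$atom), nrow(h$atoms))
  expect_equal(m$atom$charge, h$atoms$charge, tolerance = 1e-9)
  expect_equal(as.numeric(m$atom$x), h$conformers[[1]][, 1], tolerance = 1e-4)
})

test_that("db2-lite round trips losslessly, gzip-transparently", {
  h <- make_hierarchy(n_atoms = 12, n_conformers = 4, n_hydroxyls = 2,
                      seed = 9)
  plain <- tempfile(fileext = ".db2")
  gz <- tempfile(fileext = ".db2.gz")
  write_db2lite(h, plain)
  write_db2lite(h, gz)
  b1 <- read_db2lite(plain)[[1]]
  b2 <- read_db2lite(gz)[[1]]
  expect_equal(b1, h)
  expect_equal(b2, b1)
})

test_that("a hand-written two-atom db2-lite file parses to its stated fields", {
  lines <- c("db2lite 1",
             "# minimal worked example",
             "M TINY 2 1 1 0",
             "A 1 C1 C C.3 0.1 C 0.2",
             "A 2 O2 O O.3 -0.1 O 0.05",
             "B 1 2 1",
             "R",
             "E 0",
             "C 1",
             "0 0 0",
             "1.4 0 0")
  path <- tempfile(fileext = ".db2")
  writeLines(lines, path)
  h <- read_db2lite(path)[[1]]
  expect_identical(h$name, "TINY")
  expect_identical(h$atoms$element, c("C", "O"))
  expect_equal(h$atoms$charge, c(0.1, -0.1))
  expect_equal(h$atoms$desolv, c(0.2, 0.05))
  expect_identical(h$bonds$order, "1")
  expect_equal(h$conformers[[1]], rbind(c(0, 0, 0), c(1.4, 0, 0)))
  expect_equal(h$conformer_energy, 0)
})

test_that("rigid-component drift across conformers is rejected", {
  h <- make_hierarchy(seed = 2)
  h$conformers[[2]][h$rigid[1], ] <- h$conformers[[2]][h$rigid[1], ] + 0.05
  expect_error(validate_hierarchy(h), "rigid-component")
  expect_error(write_db2lite(h, tempfile()), "rigid-component")
})

test_that("rigid component is the largest fused ring system", {
  # benzene with a propyl tail -> the six ring carbons
  ang <- 2 * pi * (0:5) / 6
  ring <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  coords <- rbind(ring, ring[1, ] + c(1.5, 0, 0), ring[1, ] + c(3, 0, 0.4),
                  ring[1, ] + c(4.5, 0, 0))
  atoms <- data.frame(name = sprintf("C%d", 1:9), element = "C",
                      mol2_type = c(rep("C.ar", 6), rep("C.3", 3)),
                      charge = 0, stringsAsFactors = FALSE)
  bonds <- data.frame(from = c(1:6, 1, 7, 8), to = c(2:6, 1, 7, 8, 9),
                      order = c(rep("ar", 6), "1", "1", "1"),
                      stringsAsFactors = FALSE)
  expect_identical(find_rigid_component(make_custom_mol(atoms, bonds, coords)),
                   1:6)

  # naphthalene -> all ten carbons (edge-fused rings share a bicomponent)
  atoms10 <- data.frame(name = sprintf("C%d", 1:10), element = "C",
                        mol2_type = "C.ar", charge = 0,
                        stringsAsFactors = FALSE)
  bonds10 <- data.frame(
    from = c(1, 2, 3, 4, 5, 6, 6, 7, 8, 9, 10),
    to   = c(2, 3, 4, 5, 6, 1, 7, 8, 9, 10, 5),
    order = "ar", stringsAsFactors = FALSE)
  coords10 <- cbind(runif(10), runif(10), runif(10))
  expect_identical(
    find_rigid_component(make_custom_mol(atoms10, bonds10, coords10)),
    1:10)

  # n-butane: no >=3-atom non-rotatable set -> flagged undockable
  atoms4 <- data.frame(name = sprintf("C%d", 1:4), element = "C",
                       mol2_type = "C.3", charge = 0, stringsAsFactors = FALSE)
  bonds4 <- data.frame(from = 1:3, to = 2:4, order = "1",
                       stringsAsFactors = FALSE)
  rc <- find_rigid_component(
    make_custom_mol(atoms4, bonds4, cbind(1:4, 0, 0)))
  expect_length(rc, 0L)
  expect_true(attr(rc, "undockable"))
})

test_that("aromatic hydroxyls reset to the two in-plane rotamers", {
  h <- make_hierarchy(seed = 5, n_hydroxyls = 1)  # phenol-like, H at 1.2 rad
  s <- minidock:::hydroxyl_sites(h)[[1]]
  expect_true(s$sp2)
  rot <- reset_hydroxyls(h, 1)
  expect_length(rot, 2L)
  dihedrals <- vapply(rot, function(cc)
    dihedral_angle(cc[s$ref, ], cc[s$c, ], cc[s$o, ], cc[s$h, ]), numeric(1))
  expect_equal(sort(abs(dihedrals)), c(0, pi), tolerance = 1e-6)
  # idempotence: already in-plane input reappears unchanged as one rotamer
  again <- reset_hydroxyls(h, rot[[1]])
  expect_equal(again[[1]], rot[[1]], tolerance = 1e-9)
})

test_that("sp3 hydroxyls get three equiangular staggered rotamers", {
  h <- make_cyclohexanol()
  s <- minidock:::hydroxyl_sites(h)[[1]]
  expect_false(s$sp2)
  rot <- reset_hydroxyls(h, 1)
  expect_length(rot, 3L)
  dihedrals <- sort(vapply(rot, function(cc)
    dihedral_angle(cc[s$ref, ], cc[s$c, ], cc[s$o, ], cc[s$h, ]), numeric(1)))
  gaps <- diff(c(dihedrals, dihedrals[1] + 2 * pi))
  expect_equal(gaps, rep(2 * pi / 3, 3), tolerance = 1e-6)
  # O-H bond length is untouched by the rotation
  for (cc in rot)
    expect_equal(sqrt(sum((cc[8, ] - cc[7, ])^2)),
                 sqrt(sum((h$conformers[[1]][8, ] - h$conformers[[1]][7, ])^2)),
                 tolerance = 1e-9)
})

test_that("hydroxyls without hydrogens warn and are skipped", {
  h <- make_cyclohexanol()
  h$atoms <- h$atoms[1:7, ]
  h$bonds <- h$bonds[h$bonds$to != 8 & h$bonds$from != 8, ]
  h$conformers[[1]] <- h$conformers[[1]][1:7, ]
  expect_warning(rot <- reset_hydroxyls(h, 1), "no hydrogen")
  expect_length(rot, 1L)
})

test_that("energy-window filtering keeps the window above the minimum", {
  h <- make_hierarchy(seed = 3, n_conformers = 4)
  h$conformer_energy <- c(0, 10, 14, 31)
  keep <- function(w) energy_window_filter(h, w)$conformer_energy
  expect_equal(keep(12.5), c(0, 10))
  expect_equal(keep(15), c(0, 10, 14))
  expect_equal(keep(30), c(0, 10, 14))
  expect_equal(keep(0), 0)
  expect_equal(keep(Inf), c(0, 10, 14, 31))
  # monotone: a wider window never drops a conformer
  set.seed(8)
  for (rep in 1:5) {
    w1 <- runif(1, 0, 20)
    w2 <- w1 + runif(1, 0, 20)
    expect_true(all(keep(w1) %in% keep(w2)))
  }
  # shifting all energies leaves the selection unchanged
  h2 <- h
  h2$conformer_energy <- h$conformer_energy + 7
  expect_identical(length(energy_window_filter(h2, 12.5)$conformers), 2L)
})
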