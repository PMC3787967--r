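test_that("pairwise distance matrices obey the distance axioms", {
  expect_equal(pairwise_distance_matrix(rbind(c(0, 0, 0), c(1, 0, 0))),
               rbind(c(0, 1), c(1, 0)))
  d <- pairwise_distance_matrix(rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0)))
  expect_setequal(d[upper.tri(d)], c(3, 4, 5))
  set.seed(11)
  s <- random_sphere_set(7)
  d <- pairwise_distance_matrix(s)
  expect_identical(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_error(pairwise_distance_matrix(rbind(c(0, 0, NA))), "finite")
})

test_that("identical sphere sets contain the identity correspondence for every 4-subset at tolerance 0", {
  set.seed(42)
  s <- random_sphere_set(6)
  m <- enumerate_matches(s, s, tolerance = 0)
  got <- match_rows_as_strings(m)
  for (sub in asplit(combn(6, 4), 2))
    expect_true(paste(c(sub, sub), collapse = ",") %in% got)
})

test_that("matcher agrees with the brute-force oracle on random systems", {
  set.seed(7)
  for (rep in 1:20) {
    nl <- sample(4:8, 1)
    nr <- sample(4:8, 1)
    lig <- random_sphere_set(nl)
    rec <- random_sphere_set(nr)
    tol <- runif(1, 0.2, 0.8)
    fast <- enumerate_matches(lig, rec, tol)
    slow <- brute_force_matches(lig, rec, tol)
    expect_identical(match_rows_as_strings(unclass(fast)),
                     match_rows_as_strings(slow))
  }
})

test_that("fewer spheres than nodes gives an empty match set, not an error", {
  set.seed(1)
  expect_message(m <- enumerate_matches(random_sphere_set(3),
                                        random_sphere_set(8), 0.5))
  expect_identical(nrow(m), 0L)
})

test_that("lower-tolerance matches are always a subset of higher-tolerance matches", {
  set.seed(13)
  for (rep in 1:8) {
    lig <- random_sphere_set(6)
    rec <- random_sphere_set(8)
    t1 <- runif(1, 0.1, 0.5)
    t2 <- t1 + runif(1, 0.05, 0.6)
    m1 <- match_rows_as_strings(enumerate_matches(lig, rec, t1))
    m2 <- match_rows_as_strings(enumerate_matches(lig, rec, t2))
    expect_true(all(m1 %in% m2))
  }
})

test_that("swapping two coincident ligand spheres permutes but preserves the correspondence set", {
  set.seed(5)
  xyz <- matrix(runif(15, 0, 4), 5, 3)
  xyz <- rbind(xyz, xyz[1, ])  # sphere 6 coincides with sphere 1
  lig <- sphere_set(xyz)
  rec <- random_sphere_set(7)
  m <- enumerate_matches(lig, rec, 0.6)
  swapped <- xyz[c(6, 2:5, 1), ]
  m2 <- unclass(enumerate_matches(sphere_set(swapped), rec, 0.6))
  # map swapped labels back (1 <-> 6), then re-canonicalize each row by
  # sorting the (ligand, receptor) pairs on the ligand index
  relabel <- c(6L, 2L, 3L, 4L, 5L, 1L)
  for (j in 1:4) m2[, j] <- relabel[m2[, j]]
  m2 <- t(apply(m2, 1, function(row) {
    ord <- order(row[1:4])
    c(row[1:4][ord], row[5:8][ord])
  }))
  expect_setequal(match_rows_as_strings(m2), match_rows_as_strings(unclass(m)))
})

test_that("adaptive matching terminates at the schedule minimum for an easy goal", {
  set.seed(21)
  s <- random_sphere_set(6)
  am <- adaptive_match(s, s, match_goal = 1)
  expect_equal(am$tolerance, tolerance_schedule()$minimum)
  expect_gt(am$n_matches, 0)
  expect_true(am$goal_met)
})

test_that("a larger match goal returns a superset of a smaller one", {
  set.seed(33)
  lig <- random_sphere_set(6)
  rec <- random_sphere_set(9)
  a <- adaptive_match(lig, rec, 50)
  b <- adaptive_match(lig, rec, 500)
  expect_true(all(match_rows_as_strings(unclass(a$matches)) %in%
                    match_rows_as_strings(unclass(b$matches))))
  expect_lte(a$tolerance, b$tolerance)
})

test_that("adaptive matching is deterministic and flags unreachable goals", {
  set.seed(17)
  lig <- random_sphere_set(5)
  rec <- random_sphere_set(7)
  r1 <- adaptive_match(lig, rec, 40)
  r2 <- adaptive_match(lig, rec, 40)
  expect_identical(r1, r2)
  huge <- adaptive_match(lig, rec, 10000000)
  expect_false(huge$goal_met)
  expect_equal(huge$tolerance, tolerance_schedule()$maximum)
})

test_that("rigid transforms recover planted rotations and reject reflections", {
  set.seed(9)
  P <- matrix(runif(12, -2, 2), 4, 3)
  lig <- sphere_set(P)
  idt <- fit_rigid_transform(c(1:4, 1:4), lig, lig)
  expect_equal(idt$rotation, diag(3), tolerance = 1e-9)
  expect_equal(idt$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(idt$rms_residual, 0, tolerance = 1e-9)

  Rz <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))  # 90 degrees about z
  shift <- c(1, 2, 3)
  rec <- sphere_set(sweep(P %*% t(Rz), 2, shift, "+"))
  tr <- fit_rigid_transform(c(1:4, 1:4), lig, rec)
  expect_equal(tr$rotation, Rz, tolerance = 1e-9)
  expect_equal(tr$translation, shift, tolerance = 1e-9)
  expect_lt(tr$rms_residual, 1e-9)

  mirror <- P
  mirror[, 1] <- -mirror[, 1]
  mt <- fit_rigid_transform(c(1:4, 1:4), lig, sphere_set(mirror))
  expect_equal(det(mt$rotation), 1, tolerance = 1e-6)
  expect_gt(mt$rms_residual, 0.01)
})

test_that("collinear correspondences are flagged degenerate", {
  line <- sphere_set(cbind(1:4, 0, 0))
  tr <- fit_rigid_transform(c(1:4, 1:4), line, line)
  expect_true(tr$degenerate)
})

test_that("every emitted rotation is proper orthogonal", {
  set.seed(77)
  lig <- random_sphere_set(6)
  rec <- random_sphere_set(8)
  m <- enumerate_matches(lig, rec, 1.0)
  for (i in head(seq_len(nrow(m)), 40)) {
    tr <- fit_rigid_transform(m[i, ], lig, rec)
    expect_equal(det(tr$rotation), 1, tolerance = 1e-6)
    expect_lt(max(abs(crossprod(tr$rotation) - diag(3))), 1e-6)
  }
})

test_that("orient_coordinates is rigid and invertible", {
  set.seed(3)
  P <- matrix(runif(12, -2, 2), 4, 3)
  lig <- sphere_set(P)
  rec <- random_sphere_set(4)
  tr <- fit_rigid_transform(c(1:4, 1:4), lig, rec)
  X <- matrix(runif(30, -3, 3), 10, 3)
  idt <- fit_rigid_transform(c(1:4, 1:4), lig, lig)
  expect_equal(orient_coordinates(idt, X), X, tolerance = 1e-12)
  Y <- orient_coordinates(tr, X)
  inv <- list(rotation = t(tr$rotation),
              translation = as.numeric(-t(tr$rotation) %*% tr$translation))
  expect_equal(orient_coordinates(inv, Y), X, tolerance = 1e-9)
  expect_equal(as.matrix(dist(Y)), as.matrix(dist(X)), tolerance = 1e-9)
})
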