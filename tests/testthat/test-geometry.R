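test_that("Kabsch superposition is exact on identical and rigidly moved sets", {
  set.seed(1)
  x <- matrix(rnorm(30), 10, 3)
  fit <- kabsch_superpose(x, x)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  for (i in 1:20) {
    R <- random_rotation()
    t <- rnorm(3, sd = 5)
    moved <- x %*% R + matrix(t, 10, 3, byrow = TRUE)
    expect_lt(kabsch_superpose(moved, x)$rmsd, 1e-10)
  }
})

test_that("Kabsch RMSD matches the quaternion oracle on random sets", {
  set.seed(2)
  for (i in 1:50) {
    a <- matrix(rnorm(30), 10, 3)
    b <- matrix(rnorm(30), 10, 3)
    expect_equal(kabsch_superpose(a, b)$rmsd, kearsley_rmsd(a, b),
                 tolerance = 1e-8)
  }
})

test_that("degenerate geometries are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "collinear")
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)), ">= 3")
})

test_that("RMSD is symmetric and obeys the two-reference triangle bound", {
  set.seed(3)
  A <- matrix(rnorm(24), 8, 3)
  B <- matrix(rnorm(24), 8, 3)
  expect_equal(kabsch_superpose(A, B)$rmsd, kabsch_superpose(B, A)$rmsd,
               tolerance = 1e-10)
  dAB <- kabsch_superpose(A, B)$rmsd
  for (i in 1:20) {
    f <- matrix(rnorm(24), 8, 3)
    gap <- abs(kabsch_superpose(f, A)$rmsd - kabsch_superpose(f, B)$rmsd)
    expect_lte(gap, dAB + 1e-12)
  }
})

test_that("rmsd_series is zero for copies and translations of the reference", {
  top <- toy_topology()
  ref <- matrix(rnorm(21), 7, 3)
  coords <- array(NA_real_, dim = c(7, 3, 5))
  for (k in 1:5) coords[, , k] <- ref + matrix(rnorm(3, sd = 4), 7, 3,
                                               byrow = TRUE)
  trj <- trajectory(top, coords)
  expect_lt(max(rmsd_series(trj, ref)$value), 1e-10)
})

test_that("rmsd_series equals direct per-frame superposition calls", {
  trj <- toy_trajectory(2)
  ref <- matrix(rnorm(21), 7, 3)
  got <- rmsd_series(trj, ref)$value
  want <- c(kabsch_superpose(frame_coords(trj, 1), ref)$rmsd,
            kabsch_superpose(frame_coords(trj, 2), ref)$rmsd)
  expect_equal(got, want)
})

test_that("delta-RMSD of the references has the stated sign and magnitude", {
  refs <- make_references(synthetic_spec())
  pair <- refs$pair
  sep <- refs$rmsd_open_closed
  both <- trajectory(refs$topology,
                     array(c(refs$closed, refs$open), dim = c(62, 3, 2)))
  dr <- delta_rmsd_series(both, pair)$value
  expect_equal(dr[1], -sep, tolerance = 1e-10)  # closed frame -> negative
  expect_equal(dr[2], +sep, tolerance = 1e-10)
  expect_equal(dr[1], -dr[2], tolerance = 1e-12)
})

test_that("the geometric midpoint of symmetric references has delta-RMSD zero", {
  sr <- symmetric_reference_pair()
  mid <- (sr$open + sr$closed) / 2
  trj <- trajectory(sr$topology, mid)
  expect_lt(abs(delta_rmsd_series(trj, sr$pair)$value), 1e-9)
})

test_that("RMSF is zero for a static trajectory and errors on one frame", {
  top <- toy_topology()
  x <- matrix(rnorm(21), 7, 3)
  static <- trajectory(top, array(rep(x, 5), dim = c(7, 3, 5)))
  expect_lt(max(rmsf(static)$rmsf_nm), 1e-12)
  single <- trajectory(top, x)
  expect_error(rmsf(single), "2 frames")
})

test_that("RMSF recovers a planted single-atom oscillation (no fitting)", {
  top <- toy_topology()
  base <- matrix(rnorm(21, sd = 0.5), 7, 3)
  d <- 0.07
  coords <- array(rep(base, 4), dim = c(7, 3, 4))
  coords[3, 1, ] <- base[3, 1] + c(d, -d, d, -d)
  trj <- trajectory(top, coords)
  out <- rmsf(trj, superpose = FALSE)
  expect_equal(out$rmsf_nm[3], d, tolerance = 1e-12)
  expect_lt(max(out$rmsf_nm[-3]), 1e-12)
})

test_that("RMSF matches a two-pass mean/deviation oracle", {
  trj <- toy_trajectory(6)
  got <- rmsf(trj, superpose = FALSE)$rmsf_nm
  want <- vapply(1:7, function(i) {
    xs <- t(trj$coords[i, , ])
    mu <- colMeans(xs)
    sqrt(mean(rowSums(sweep(xs, 2, mu)^2)))
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("distance_series handles centroids and the minimum image", {
  top <- topology(1:2, c("CA", "CA"), "ALA", 1:2, "A")
  co <- array(0, dim = c(2, 3, 1))
  co[2, , 1] <- c(0.9, 0, 0)
  boxed <- trajectory(top, co, box = c(1, 1, 1))
  expect_equal(distance_series(boxed, 1, 2, use_pbc = TRUE)$value, 0.1)
  expect_equal(distance_series(boxed, 1, 2, use_pbc = FALSE)$value, 0.9)
  free <- trajectory(top, co)
  expect_error(distance_series(free, 1, 2, use_pbc = TRUE), "periodic box")
  expect_equal(distance_series(trajectory(top, array(0, c(2, 3, 1))),
                               1, 2)$value, 0)
})

test_that("group-centroid distances match a hand-computed oracle", {
  top <- topology(1:6, rep("CA", 6), "ALA", 1:6, "A")
  tri1 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  tri2 <- rbind(c(3, 0, 0), c(4, 0, 0), c(3, 1, 0))
  trj <- trajectory(top, rbind(tri1, tri2))
  want <- sqrt(sum((colMeans(tri2) - colMeans(tri1))^2))
  expect_equal(distance_series(trj, 1:3, 4:6)$value, want)
})

test_that("minimum-image distance never exceeds the plain distance", {
  set.seed(4)
  top <- topology(1:2, c("CA", "CA"), "ALA", 1:2, "A")
  for (i in 1:25) {
    co <- array(runif(6, -2, 2), dim = c(2, 3, 1))
    trj <- trajectory(top, co, box = runif(3, 0.5, 2))
    expect_lte(distance_series(trj, 1, 2, use_pbc = TRUE)$value,
               distance_series(trj, 1, 2, use_pbc = FALSE)$value + 1e-12)
  }
})
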