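test_that("distance features have m(m-1)/2 columns and match a nested-loop oracle", {
  trj <- toy_trajectory(3)
  X <- distance_feature_matrix(trj, mask = c(1, 2, 3))
  expect_equal(dim(X), c(3, 3))
  # brute-force nested loops, row-major (i < j)
  want <- t(vapply(1:3, function(k) {
    xyz <- frame_coords(trj, k, 1:3)
    out <- c()
    for (i in 1:2) for (j in (i + 1):3) {
      out <- c(out, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
    }
    out
  }, numeric(3)))
  expect_equal(X, want, ignore_attr = TRUE)
})

test_that("distance features are invariant under rigid motion of frames", {
  set.seed(5)
  trj <- toy_trajectory(4)
  moved <- trj
  for (k in 1:4) {
    R <- random_rotation()
    moved$coords[, , k] <- trj$coords[, , k] %*% R +
      matrix(rnorm(3, sd = 3), 7, 3, byrow = TRUE)
  }
  expect_equal(distance_feature_matrix(trj, 1:7),
               distance_feature_matrix(moved, 1:7), tolerance = 1e-10)
})

test_that("PCA basics: variance capture, orthonormality, eigenvalue conservation", {
  set.seed(6)
  one_axis <- cbind(rnorm(50), 0, 0)
  res <- md_pca(one_axis)
  expect_equal(res$eigenvalues[1] / sum(res$eigenvalues), 1)
  n <- 400
  X <- matrix(rnorm(n * 5), n, 5)
  res <- md_pca(X)
  expect_equal(crossprod(res$eigenvectors), diag(5), tolerance = 1e-8)
  expect_equal(sum(res$eigenvalues), sum(apply(X, 2, stats::var)),
               tolerance = 1e-10)
  # deterministic sign: largest-magnitude loading positive
  for (j in 1:5) {
    expect_gt(res$eigenvectors[which.max(abs(res$eigenvectors[, j])), j], 0)
  }
  expect_error(md_pca(X[1, , drop = FALSE]), ">= 2")
})

test_that("an isotropic Gaussian gives near-equal eigenvalues", {
  set.seed(7)
  X <- matrix(rnorm(4000 * 2), 4000, 2)
  res <- md_pca(X)
  expect_equal(res$eigenvalues[1] / res$eigenvalues[2], 1, tolerance = 0.15)
})

test_that("cartesian PCA localises a planted single-atom mode", {
  top <- toy_topology()
  base <- matrix(rnorm(21, sd = 0.4), 7, 3)
  nf <- 20
  coords <- array(rep(base, nf), dim = c(7, 3, nf))
  coords[4, 1, ] <- base[4, 1] + 0.1 * sin(seq_len(nf))
  trj <- trajectory(top, coords)
  res <- cartesian_pca(trj)
  amp <- atom_mode_amplitudes(res, 1)
  expect_equal(which.max(amp), 4)
  # fitting to the mean redistributes a little motion to the other atoms,
  # but the mode stays overwhelmingly on the planted atom
  expect_gt(amp[4], 0.85)
  expect_gt(amp[4], 3 * max(amp[-4]))
  expect_gt(res$eigenvalues[1] / sum(res$eigenvalues), 0.999)
  static <- trajectory(top, array(rep(base, 3), dim = c(7, 3, 3)))
  expect_lt(max(md_pca(t(vapply(1:3, function(k)
    as.numeric(frame_coords(static, k)), numeric(21))))$eigenvalues), 1e-20)
})

test_that("quasi-harmonic entropy recovers a prescribed spectrum", {
  lambda <- rep(c(0.004, 0.012, 0.02), 4)       # amu nm^2, 4 atoms
  ge <- make_gaussian_ensemble(lambda, masses = rep(12.011, 4),
                               n_frames = 20000, seed = 11)
  est <- quasiharmonic_entropy(ge$trajectory, superpose = FALSE)
  expect_equal(est$total, ge$entropy_quasiharmonic, tolerance = 0.02)
  schl <- quasiharmonic_entropy(ge$trajectory, superpose = FALSE,
                                method = "schlitter")
  expect_gte(schl$total, est$total)
})

test_that("entropy limits: zero variance gives zero, inflation increases it", {
  top <- topology(1:3, rep("CA", 3), "GLY", 1:3, "A")
  frozen <- trajectory(top, array(rep(rnorm(9), 10), dim = c(3, 3, 10)))
  ent <- suppressWarnings(quasiharmonic_entropy(frozen, superpose = FALSE))
  expect_equal(ent$total, 0)
  expect_equal(ent$n_modes_discarded, 9L)
  lam <- rep(0.01, 9)
  s1 <- entropy_from_spectrum(lam, 300)$total
  s2 <- entropy_from_spectrum(4 * lam, 300)$total   # 2x sigma per mode
  expect_gt(s2, s1)
  expect_error(entropy_from_spectrum(lam, -5), "temperature|> 0")
})

test_that("entropy is invariant under a rigid transform of the ensemble", {
  lambda <- rep(0.01, 12)
  ge <- make_gaussian_ensemble(lambda, masses = rep(12, 4), n_frames = 3000,
                               seed = 3)
  base <- quasiharmonic_entropy(ge$trajectory, superpose = TRUE)
  R <- random_rotation()
  moved <- ge$trajectory
  for (k in seq_len(n_frames(moved))) {
    moved$coords[, , k] <- moved$coords[, , k] %*% R + 2
  }
  rot <- quasiharmonic_entropy(moved, superpose = TRUE)
  expect_equal(rot$total, base$total, tolerance = 1e-6)
})

test_that("gromos clustering: degenerate cases", {
  top <- toy_topology()
  x <- matrix(rnorm(21), 7, 3)
  same <- trajectory(top, array(rep(x, 8), dim = c(7, 3, 8)))
  cl <- gromos_cluster(same, cutoff = 0.2)
  expect_equal(length(cl$sizes), 1)
  expect_equal(cl$sizes, 8L)
  spread <- toy_trajectory(6)
  cl2 <- gromos_cluster(spread, cutoff = 100)
  expect_equal(length(cl2$sizes), 1)
  empty <- trajectory(top, array(0, dim = c(7, 3, 0)))
  expect_error(gromos_cluster(empty, cutoff = 0.2), "empty")
  expect_error(gromos_cluster(spread, cutoff = 0), "> 0")
})

test_that("gromos recovers planted two-bundle memberships", {
  spec <- synthetic_spec(n_frames = 40, noise_sigma = 0.01,
                         stage_schedule = two_state_schedule(), seed = 8)
  b <- make_transition_trajectory(spec)
  cl <- gromos_cluster(b$trajectory, b$refs$ca_mask, cutoff = 0.2)
  expect_equal(length(cl$sizes), 2)
  expect_equal(sort(cl$sizes), c(20L, 20L))
  planted <- b$truth$per_frame$state_fraction > 0.5
  expect_true(all(table(cl$assignment, planted) %in% c(0L, 20L)))
})

test_that("cluster invariants hold: assignment complete, medoids in-cluster, sizes descending", {
  trj <- toy_trajectory(30, seed = 10)
  cl <- gromos_cluster(trj, cutoff = 0.6)
  expect_true(all(cl$assignment >= 1))
  expect_equal(sum(cl$sizes), 30)
  expect_true(all(diff(cl$sizes) <= 0))
  for (i in seq_along(cl$medoids)) {
    expect_equal(cl$assignment[match(cl$medoids[i], cl$frames)], i)
  }
})
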