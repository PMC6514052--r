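test_that("reference generation hits the requested state separation", {
  refs <- make_references(synthetic_spec())
  expect_lt(abs(refs$rmsd_open_closed - 0.6) / 0.6, 0.05)
  refs2 <- make_references(synthetic_spec(state_separation = 0.3))
  expect_lt(abs(refs2$rmsd_open_closed - 0.3) / 0.3, 0.05)
  zero <- make_references(synthetic_spec(state_separation = 0))
  expect_identical(zero$open, zero$closed)
  expect_error(make_references(synthetic_spec(state_separation = 50)),
               "unreachable")
})

test_that("reference generation is deterministic and carries the probe atoms", {
  a <- make_references(synthetic_spec(seed = 5))
  b <- make_references(synthetic_spec(seed = 5))
  expect_identical(a$open, b$open)
  expect_identical(a$closed, b$closed)
  top <- a$topology
  expect_equal(top$name[a$site_w755], "NE1")
  expect_equal(top$resid[a$site_w755], 755L)
  expect_equal(top$name[a$site_v912], "N")
  expect_equal(top$resid[a$site_v912], 912L)
  # bridgeable in the closed state, far apart in the open state
  d_closed <- sqrt(sum((a$closed[a$site_w755, ] - a$closed[a$site_v912, ])^2))
  d_open <- sqrt(sum((a$open[a$site_w755, ] - a$open[a$site_v912, ])^2))
  expect_equal(d_closed, 0.5, tolerance = 1e-9)
  expect_gt(d_open, 2 * 0.35)
})

test_that("a noise-free linear transition gives a strictly monotone crossing at the planted frame", {
  spec <- synthetic_spec(
    n_frames = 101, noise_sigma = 0,
    stage_schedule = data.frame(start_frac = 0, end_frac = 1,
                                f_start = 0, f_end = 1))
  b <- make_transition_trajectory(spec)
  dr <- delta_rmsd_series(b$trajectory, b$refs$pair)$value
  expect_true(all(diff(dr) < 0))
  expect_equal(dr, b$truth$per_frame$delta_rmsd_noise_free, tolerance = 1e-10)
  # sign change bracketed by the recorded crossing frame
  k <- b$truth$crossing_frame
  expect_lte(dr[k], b$truth$threshold)
  expect_gt(dr[k - 1], b$truth$threshold)
})

test_that("the default staged schedule plants the crossing at crossing_frac", {
  b <- make_transition_trajectory(synthetic_spec(n_frames = 500))
  expect_equal(b$truth$crossing_frame / 500, 0.4, tolerance = 0.01)
  expect_identical(
    make_transition_trajectory(synthetic_spec(n_frames = 500))$trajectory$coords,
    b$trajectory$coords)  # same seed, bit-identical
})

test_that("noisy detection lands within 20 frames of the noise-free truth across seeds", {
  hits <- vapply(1:5, function(s) {
    b <- make_transition_trajectory(synthetic_spec(n_frames = 400, seed = s))
    dr <- delta_rmsd_series(b$trajectory, b$refs$pair)
    onset <- detect_closed_onset(dr)$frame
    abs(onset - b$truth$crossing_frame)
  }, numeric(1))
  expect_true(all(hits <= 20 * 400 / 1000 + 20))  # scale-free guard
  expect_true(mean(hits <= 20) >= 0.8)
})

test_that("Gaussian ensembles honour the prescribed spectrum and scale monotonically", {
  lam <- c(0.005, 0.01, 0.02, 0.04, 0.08, 0.16)
  ge <- make_gaussian_ensemble(lam, masses = c(12, 14), n_frames = 8000,
                               seed = 2)
  # sampled variances match lambda / m per coordinate
  v <- vapply(1:2, function(a)
    apply(ge$trajectory$coords[a, , ], 1, stats::var), numeric(3))
  want <- matrix(lam / rep(c(12, 14), each = 3), 3)
  expect_equal(v, want, tolerance = 0.1)
  expect_gt(make_gaussian_ensemble(4 * lam, c(12, 14), 10,
                                   seed = 2)$entropy_quasiharmonic,
            ge$entropy_quasiharmonic)
  expect_identical(
    make_gaussian_ensemble(lam, c(12, 14), 50, seed = 7)$trajectory$coords,
    make_gaussian_ensemble(lam, c(12, 14), 50, seed = 7)$trajectory$coords)
  expect_error(make_gaussian_ensemble(lam[1:5], c(12, 14)), "3 eigenvalues")
})

test_that("solvent planting validates its schedule", {
  b <- make_transition_trajectory(synthetic_spec(
    n_frames = 10, noise_sigma = 0,
    stage_schedule = data.frame(start_frac = 0, end_frac = 1,
                                f_start = 1, f_end = 1)))
  expect_error(plant_solvent(
    b$trajectory,
    data.frame(water = 1, start_frame = 5, end_frame = 20, site = "shell"),
    b$refs$site_w755, b$refs$site_v912), "out of range")
  expect_error(plant_solvent(
    b$trajectory,
    data.frame(water = c(1, 1), start_frame = c(1, 3), end_frame = c(5, 8),
               site = "shell"),
    b$refs$site_w755, b$refs$site_v912), "overlapping")
  expect_error(plant_solvent(
    b$trajectory,
    data.frame(water = 5, start_frame = 1, end_frame = 2, site = "shell"),
    b$refs$site_w755, b$refs$site_v912, n_waters = 2), "absent")
  # bridging in the OPEN state is geometrically impossible -> error
  open_b <- make_transition_trajectory(synthetic_spec(
    n_frames = 10, noise_sigma = 0,
    stage_schedule = data.frame(start_frac = 0, end_frac = 1,
                                f_start = 0, f_end = 0)))
  expect_error(plant_solvent(
    open_b$trajectory,
    data.frame(water = 1, start_frame = 1, end_frame = 1, site = "bridge"),
    open_b$refs$site_w755, open_b$refs$site_v912), "too far")
  # empty schedule -> a trajectory with no waters and zero counts
  ps <- plant_solvent(b$trajectory,
                      data.frame(water = integer(), start_frame = integer(),
                                 end_frame = integer(), site = character()),
                      b$refs$site_w755, b$refs$site_v912)
  expect_equal(ps$truth$shell_counts$value, rep(0, 10))
  expect_equal(n_atoms(ps$trajectory), n_atoms(b$trajectory))
})
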