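# Fixture: a frozen synthetic bundle in the closed state with scripted waters.
closed_bundle <- function(n_frames = 30) {
  spec <- synthetic_spec(
    n_frames = n_frames, noise_sigma = 0,
    stage_schedule = data.frame(start_frac = 0, end_frac = 1,
                                f_start = 1, f_end = 1))
  make_transition_trajectory(spec)
}

water_solute_masks <- function(traj) {
  wm <- which(traj$topology$resname == "HOH")
  list(water = wm, solute = setdiff(seq_len(n_atoms(traj)), wm))
}

test_that("no waters gives zero counts; overlapping masks error", {
  b <- closed_bundle(5)
  n <- n_atoms(b$trajectory)
  hc <- hydration_count_series(b$trajectory, seq_len(n), integer(0))
  expect_equal(hc$value, rep(0, 5))
  expect_error(hydration_count_series(b$trajectory, 1:3, 3:5), "overlap")
})

test_that("planted shell membership is recovered exactly, cell = brute", {
  b <- closed_bundle(40)
  sched <- data.frame(
    water = c(1, 2, 2, 3, 4),
    start_frame = c(1, 5, 25, 10, 40),
    end_frame = c(40, 15, 30, 10, 40),
    site = c("shell", "shell", "bridge", "boundary", "shell"))
  ps <- plant_solvent(b$trajectory, sched, b$refs$site_w755, b$refs$site_v912)
  m <- water_solute_masks(ps$trajectory)
  hc <- hydration_count_series(ps$trajectory, m$solute, m$water)
  expect_identical(hc$value, ps$truth$shell_counts$value)
  hb <- hydration_count_series(ps$trajectory, m$solute, m$water,
                               method = "brute")
  expect_identical(hc$value, hb$value)
})

test_that("a water exactly at the cutoff is counted (inclusive boundary)", {
  b <- closed_bundle(3)
  sched <- data.frame(water = 1, start_frame = 2, end_frame = 2,
                      site = "boundary")
  ps <- plant_solvent(b$trajectory, sched, b$refs$site_w755, b$refs$site_v912)
  m <- water_solute_masks(ps$trajectory)
  cfg <- solvation_config(shell_cutoff = 0.5)
  # verify the planted min distance is exactly the cutoff, then count
  w <- frame_coords(ps$trajectory, 2, m$water)
  sol <- frame_coords(ps$trajectory, 2, m$solute)
  dmin <- min(sqrt(rowSums(sweep(sol, 2, as.numeric(w))^2)))
  expect_identical(dmin, 0.5)
  expect_equal(hydration_count_series(ps$trajectory, m$solute, m$water,
                                      cfg)$value[2], 1)
})

test_that("counts are monotone in the shell cutoff", {
  b <- closed_bundle(10)
  sched <- data.frame(water = 1:3, start_frame = 1, end_frame = 10,
                      site = "shell")
  ps <- plant_solvent(b$trajectory, sched, b$refs$site_w755, b$refs$site_v912)
  m <- water_solute_masks(ps$trajectory)
  prev <- rep(-1, 10)
  for (rc in c(0.2, 0.35, 0.5, 1.0)) {
    cur <- hydration_count_series(ps$trajectory, m$solute, m$water,
                                  solvation_config(shell_cutoff = rc))$value
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("cell-list and brute-force searches agree on random configurations", {
  set.seed(12)
  for (i in 1:10) {
    q <- matrix(runif(300, 0, 3), 100, 3)
    t <- matrix(runif(90, 0, 3), 30, 3)
    box <- if (i %% 2) c(3, 3, 3) else NULL
    expect_identical(
      within_cutoff_any(q, t, 0.4, box = box, method = "cell"),
      within_cutoff_any(q, t, 0.4, box = box, method = "brute"))
  }
})

test_that("block averaging: identity, constants, arithmetic, strict mode", {
  s <- md_series(0:9, 1:10)
  expect_equal(block_average(s, 1)$value, as.numeric(1:10))
  expect_equal(block_average(md_series(0:9, rep(7, 10)), 4)$value,
               rep(7, 3))
  ba <- block_average(s, 5)
  expect_equal(ba$value, c(3, 8))
  expect_equal(ba$time_ps, c(2, 7))
  expect_false(any(ba$partial))
  ba2 <- block_average(s, 7)
  expect_equal(ba2$partial, c(FALSE, TRUE))
  expect_error(block_average(md_series(0:2, 1:3), 5, strict = TRUE),
               "shorter")
  expect_error(block_average(s, 0), ">= 1")
})

test_that("bridging events follow the scripted occupancy pattern", {
  b <- closed_bundle(6)
  # pattern 1-1-1-0-1-1 for one water
  sched <- data.frame(water = c(1, 1), start_frame = c(1, 5),
                      end_frame = c(3, 6), site = "bridge")
  ps <- plant_solvent(b$trajectory, sched, b$refs$site_w755, b$refs$site_v912)
  m <- water_solute_masks(ps$trajectory)
  ev0 <- bridging_water_events(ps$trajectory, b$refs$site_w755,
                               b$refs$site_v912, m$water,
                               solvation_config(gap_tolerance = 0))
  expect_equal(nrow(ev0), 2)
  expect_equal(ev0$n_frames, c(3L, 2L))
  ev1 <- bridging_water_events(ps$trajectory, b$refs$site_w755,
                               b$refs$site_v912, m$water,
                               solvation_config(gap_tolerance = 1))
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$n_frames, 6L)  # the bridged gap frame is inside the run
})

test_that("a full-trajectory bridge yields one spanning interval; shell-only waters yield none", {
  b <- closed_bundle(100)
  sched <- data.frame(water = c(1, 2), start_frame = c(1, 1),
                      end_frame = c(100, 100), site = c("bridge", "shell"))
  ps <- plant_solvent(b$trajectory, sched, b$refs$site_w755, b$refs$site_v912)
  m <- water_solute_masks(ps$trajectory)
  ev <- bridging_water_events(ps$trajectory, b$refs$site_w755,
                              b$refs$site_v912, m$water)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$water_resid, 1)
  expect_equal(ev$n_frames, 100L)
  expect_equal(ev$start_ps, b$trajectory$times[1])
  expect_equal(ev$end_ps, b$trajectory$times[100])
  expect_error(
    bridging_water_events(ps$trajectory, c(b$refs$site_w755, 1),
                          b$refs$site_v912, m$water),
    "exactly one atom")
})

test_that("planted intervals are recovered exactly and conserve bridged frames", {
  b <- closed_bundle(50)
  sched <- data.frame(water = c(1, 1, 2), start_frame = c(10, 20, 30),
                      end_frame = c(12, 40, 35), site = "bridge")
  ps <- plant_solvent(b$trajectory, sched, b$refs$site_w755, b$refs$site_v912)
  m <- water_solute_masks(ps$trajectory)
  ev <- bridging_water_events(ps$trajectory, b$refs$site_w755,
                              b$refs$site_v912, m$water)
  ord <- order(ev$water_resid, ev$start_ps)
  expect_equal(ev$start_ps[ord], ps$truth$intervals$start_ps)
  expect_equal(ev$end_ps[ord], ps$truth$intervals$end_ps)
  expect_equal(ev$duration_ps[ord], ps$truth$intervals$duration_ps)
  expect_equal(sum(ev$n_frames), sum(sched$end_frame - sched$start_frame + 1))
})

test_that("residence summaries reduce intervals correctly", {
  empty <- residence_summary(data.frame(duration_ps = numeric(0)))
  expect_equal(empty$count, 0L)
  expect_true(is.na(empty$mean_ps))
  s <- residence_summary(data.frame(duration_ps = c(10, 30)))
  expect_equal(s$mean_ps, 20)
  expect_equal(s$max_ps, 30)
  expect_equal(s$total_ps, 40)
})
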