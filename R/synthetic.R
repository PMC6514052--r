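#' Specification for synthetic helix-bundle test systems
#'
#' The generator emulates, at alpha-carbon resolution, the analysis-relevant
#' structure of a nuclear-receptor ligand-binding domain: a four-helix
#' bundle whose terminal segment (the "helix 12" stand-in) swings between an
#' "open" and a "closed" position, staged interpolating transitions with
#' Gaussian positional noise, scripted solvent with known shell/bridge
#' membership, and planted hydrogen-bond geometries. Every generated object
#' is a pure function of the spec (and its seed), so downstream analyses can
#' be scored against exact ground truth.
#'
#' @param n_residues number of alpha carbons, split into four pseudo-helix
#'   segments. Default 60.
#' @param state_separation target alpha-carbon RMSD between the open and
#'   closed references, nm. Default 0.6.
#' @param noise_sigma per-coordinate Gaussian positional noise, nm.
#'   Default 0.02.
#' @param n_frames frames in a transition trajectory. Default 1000.
#' @param frame_spacing_ps time between frames, ps. Default 100 (the usual
#'   analysis cadence; the generator makes no claim of physical time).
#' @param crossing_frac fraction of the trajectory at which the noise-free
#'   state metric is planted to cross the closed-state threshold.
#'   Default 0.4.
#' @param stage_schedule `NULL` (build the default three-stage
#'   fast/fast/slow schedule around `crossing_frac`) or a data frame with
#'   columns `start_frac`, `end_frac`, `f_start`, `f_end` giving piecewise
#'   linear state-fraction targets.
#' @param seed RNG seed recorded in all outputs.
#' @return list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_residues = 60, state_separation = 0.6,
                           noise_sigma = 0.02, n_frames = 1000,
                           frame_spacing_ps = 100, crossing_frac = 0.4,
                           stage_schedule = NULL, seed = 1) {
  if (n_residues < 8) stop("n_residues must be >= 8", call. = FALSE)
  if (state_separation < 0) stop("state_separation must be >= 0",
                                 call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (n_frames < 2) stop("n_frames must be >= 2", call. = FALSE)
  if (!is.null(stage_schedule)) {
    stopifnot(all(c("start_frac", "end_frac", "f_start", "f_end") %in%
                    names(stage_schedule)))
    if (any(stage_schedule$start_frac < 0 | stage_schedule$end_frac > 1)) {
      stop("stage_schedule fractions must lie in [0, 1]", call. = FALSE)
    }
  } else if (crossing_frac <= 0.15 || crossing_frac >= 0.85) {
    stop("crossing_frac must lie in (0.15, 0.85)", call. = FALSE)
  }
  structure(
    list(n_residues = as.integer(n_residues),
         state_separation = state_separation, noise_sigma = noise_sigma,
         n_frames = as.integer(n_frames),
         frame_spacing_ps = frame_spacing_ps,
         crossing_frac = crossing_frac, stage_schedule = stage_schedule,
         seed = as.integer(seed)),
    class = "synthetic_spec")
}

# Ideal alpha-helix segment: radius 0.23 nm, rise 0.15 nm/residue, 100 deg
# twist. `axis_xy` places the helix axis; `up = FALSE` runs it downward.
helix_segment <- function(n, axis_xy, z0 = 0, up = TRUE) {
  i <- seq_len(n) - 1
  phi <- i * 100 * pi / 180
  z <- z0 + (if (up) 1 else -1) * i * 0.15
  cbind(axis_xy[1] + 0.23 * cos(phi), axis_xy[2] + 0.23 * sin(phi), z)
}

rotation_about_axis <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Generate an open/closed reference pair
#'
#' Builds a four-helix Cα bundle ("closed" reference) and derives the "open"
#' reference by rigidly rotating the terminal helix-12 segment about a hinge
#' at its first residue; the hinge angle is solved (by root finding) so the
#' whole-bundle alpha-carbon RMSD between the two references equals
#' `state_separation` within 5%. Two pseudo side-chain atoms are appended,
#' playing the roles of the conserved tryptophan side-chain nitrogen
#' (`NE1`, resid 755) and the helix-12 valine backbone nitrogen (`N`, resid
#' 912): 0.5 nm apart in the closed reference (a bridgeable geometry for a
#' 0.35 nm two-site water criterion) and far apart in the open one.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `"synthetic_references"` with elements `topology`,
#'   `open`, `closed` (coordinate matrices, nm), `ca_mask`, `site_w755`,
#'   `site_v912` (atom indices), `pair` (a [reference_pair()]) and
#'   `rmsd_open_closed` (nm).
#' @export
make_references <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_residues
  per <- n %/% 4
  len <- c(per, per, per, n - 3 * per)
  ztop <- (len[1] - 1) * 0.15
  segs <- list(
    helix_segment(len[1], c(0, 0), 0, up = TRUE),
    helix_segment(len[2], c(1.0, 0), ztop, up = FALSE),
    helix_segment(len[3], c(1.0, 1.0), 0, up = TRUE),
    helix_segment(len[4], c(0, 1.0), ztop, up = FALSE)  # "helix 12"
  )
  closed_ca <- do.call(rbind, segs)
  h12 <- (n - len[4] + 1):n
  hinge <- closed_ca[h12[1], ]

  open_for <- function(theta) {
    R <- rotation_about_axis(c(0, 1, 0), theta)
    out <- closed_ca
    out[h12, ] <- sweep(sweep(closed_ca[h12, , drop = FALSE], 2, hinge) %*%
                          t(R), 2, hinge, "+")
    out
  }
  if (spec$state_separation == 0) {
    theta <- 0
    open_for <- function(theta) closed_ca  # bitwise-identical references
  } else {
    gap <- function(th) fit_rmsd(open_for(th), closed_ca) -
      spec$state_separation
    th_max <- 2.6
    if (gap(th_max) < 0) {
      stop(sprintf(
        "state_separation %.3g nm is unreachable for this geometry (max %.3g)",
        spec$state_separation, gap(th_max) + spec$state_separation),
        call. = FALSE)
    }
    theta <- stats::uniroot(gap, c(0, th_max), tol = 1e-10)$root
  }
  open_ca <- open_for(theta)

  # Pseudo side-chain probes: V912-N rides helix 12; W755-NE1 is static and
  # sits 0.5 nm from V912-N in the CLOSED state.
  host <- h12[max(1L, round(2 * len[4] / 3))]
  axis4 <- c(0, 1.0)
  radial <- closed_ca[host, 1:2] - axis4
  radial <- radial / sqrt(sum(radial^2))
  v912_closed <- closed_ca[host, ] + c(0.1 * radial, 0)
  centre <- c(0.5, 0.5, mean(closed_ca[, 3]))
  toward <- centre - v912_closed
  toward <- toward / sqrt(sum(toward^2))
  ne1 <- v912_closed + 0.5 * toward
  v912_open <- if (theta == 0) v912_closed else {
    R <- rotation_about_axis(c(0, 1, 0), theta)
    as.numeric((v912_closed - hinge) %*% t(R)) + hinge
  }

  closed <- rbind(closed_ca, ne1, v912_closed)
  open <- rbind(open_ca, ne1, v912_open)
  rownames(closed) <- rownames(open) <- NULL
  top <- topology(
    serial = seq_len(n + 2),
    name = c(rep("CA", n), "NE1", "N"),
    resname = c(rep("ALA", n), "TRP", "VAL"),
    resid = c(seq_len(n), 755L, 912L),
    chain = "A",
    element = c(rep("C", n), "N", "N"))
  ca_mask <- seq_len(n)
  structure(
    list(topology = top, open = open, closed = closed, ca_mask = ca_mask,
         site_w755 = n + 1L, site_v912 = n + 2L,
         h12_resids = h12, hinge_theta = theta,
         pair = reference_pair(open, closed, ca_mask, ca_mask, ca_mask),
         rmsd_open_closed = fit_rmsd(open[ca_mask, ], closed[ca_mask, ])),
    class = "synthetic_references")
}

# Default three-stage schedule: fast approach, fast patching (routed through
# the planted crossing), slow final adjustment.
default_stage_schedule <- function(crossing_frac, f_cross) {
  half <- 0.15
  data.frame(
    start_frac = c(0, crossing_frac - 0.1, crossing_frac + 0.1),
    end_frac = c(crossing_frac - 0.1, crossing_frac + 0.1, 1),
    f_start = c(0, f_cross - half, f_cross + half),
    f_end = c(f_cross - half, f_cross + half, 1))
}

state_fraction_at <- function(t_frac, schedule) {
  f <- numeric(length(t_frac))
  for (i in seq_len(nrow(schedule))) {
    s <- schedule[i, ]
    inside <- t_frac >= s$start_frac & t_frac <= s$end_frac
    span <- max(s$end_frac - s$start_frac, .Machine$double.eps)
    f[inside] <- s$f_start +
      (t_frac[inside] - s$start_frac) / span * (s$f_end - s$f_start)
  }
  f[t_frac > max(schedule$end_frac)] <- schedule$f_end[nrow(schedule)]
  pmin(pmax(f, 0), 1)
}

#' Generate a staged open-to-closed transition trajectory with ground truth
#'
#' Frames interpolate linearly between the open and closed references
#' following a three-stage schedule (fast approach, fast patching, slow
#' final adjustment), with independent Gaussian noise on every coordinate.
#' The middle stage is routed through the state fraction at which the
#' noise-free delta-RMSD equals `closed_threshold` (solved by root finding
#' on the interpolation path), so the noise-free crossing lands at
#' `spec$crossing_frac` of the trajectory. The recorded ground truth is
#' always measured from the noise-free path, never assumed.
#'
#' @param spec a [synthetic_spec()].
#' @param refs optional precomputed [make_references()] output.
#' @param closed_threshold delta-RMSD closed-state threshold, nm.
#'   Default -0.1.
#' @return list of class `"synthetic_transition"`: `trajectory` (noisy),
#'   `refs`, `truth` — a list with `per_frame` (frame, time_ps,
#'   state_fraction, delta_rmsd_noise_free), `crossing_frame` (first frame
#'   whose noise-free delta-RMSD is at or below the threshold, `NA` if
#'   none), `threshold`, `f_cross`, `seed`.
#' @export
make_transition_trajectory <- function(spec, refs = NULL,
                                       closed_threshold = -0.1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(refs)) refs <- make_references(spec)
  if (refs$rmsd_open_closed <= abs(closed_threshold)) {
    stop("closed_threshold is unreachable: references are too similar",
         call. = FALSE)
  }
  ca <- refs$ca_mask
  interp <- function(f) (1 - f) * refs$open + f * refs$closed
  ddelta <- function(f) {
    x <- interp(f)[ca, , drop = FALSE]
    fit_rmsd(x, refs$closed[ca, ]) - fit_rmsd(x, refs$open[ca, ])
  }
  schedule <- spec$stage_schedule
  f_cross <- stats::uniroot(function(f) ddelta(f) - closed_threshold,
                            c(0, 1), tol = 1e-10)$root
  if (is.null(schedule)) {
    schedule <- default_stage_schedule(spec$crossing_frac, f_cross)
  }
  nf <- spec$n_frames
  t_frac <- (seq_len(nf) - 1) / (nf - 1)
  f_k <- state_fraction_at(t_frac, schedule)
  na <- nrow(refs$open)
  coords <- array(NA_real_, dim = c(na, 3, nf))
  delta_free <- numeric(nf)
  set.seed(spec$seed)
  for (k in seq_len(nf)) {
    base <- interp(f_k[k])
    delta_free[k] <- ddelta(f_k[k])
    coords[, , k] <- base +
      matrix(stats::rnorm(na * 3, sd = spec$noise_sigma), na, 3)
  }
  times <- (seq_len(nf) - 1) * spec$frame_spacing_ps
  crossing <- which(delta_free <= closed_threshold)
  structure(
    list(trajectory = trajectory(refs$topology, coords, times = times),
         refs = refs,
         truth = list(
           per_frame = data.frame(frame = seq_len(nf), time_ps = times,
                                  state_fraction = f_k,
                                  delta_rmsd_noise_free = delta_free),
           crossing_frame = if (length(crossing)) crossing[1] else NA_integer_,
           threshold = closed_threshold, f_cross = f_cross,
           seed = spec$seed)),
    class = "synthetic_transition")
}

#' Two-state hold schedule
#'
#' Convenience schedule holding the open state for the first half of the
#' trajectory and the closed state for the second half — the planted-cluster
#' scenario for clustering and PCA validation.
#' @return a stage-schedule data frame for [synthetic_spec()].
#' @export
two_state_schedule <- function() {
  data.frame(start_frac = c(0, 0.5), end_frac = c(0.5, 1),
             f_start = c(0, 1), f_end = c(0, 1))
}

#' Sample a Gaussian ensemble with a prescribed mass-weighted spectrum
#'
#' Draws `n_frames` independent frames whose mass-weighted coordinate
#' covariance is diagonal with the prescribed eigenvalues (coordinate `j` of
#' atom `a` gets variance `lambda[j] / mass[a]`), the exact generative model
#' behind the quasi-harmonic entropy estimator. The closed-form entropy of
#' the prescribed spectrum is returned alongside as ground truth.
#'
#' @param eigenvalues mass-weighted covariance eigenvalues, amu nm^2; length
#'   `3 * length(masses)`, all > 0.
#' @param masses atomic masses, amu.
#' @param n_frames frames to draw. Default 20000.
#' @param temperature K, used for the closed-form entropies. Default 300.
#' @param seed RNG seed.
#' @return list of class `"gaussian_ensemble"`: `trajectory`,
#'   `entropy_quasiharmonic` and `entropy_schlitter` (closed-form totals,
#'   J mol^-1 K^-1), `eigenvalues`, `masses`, `temperature`, `seed`.
#' @export
make_gaussian_ensemble <- function(eigenvalues, masses, n_frames = 20000,
                                   temperature = 300, seed = 1) {
  nat <- length(masses)
  if (length(eigenvalues) != 3 * nat) {
    stop("need exactly 3 eigenvalues per atom", call. = FALSE)
  }
  if (any(eigenvalues <= 0) || any(masses <= 0)) {
    stop("eigenvalues and masses must be > 0", call. = FALSE)
  }
  sds <- sqrt(eigenvalues / rep(masses, each = 3))
  set.seed(seed)
  X <- matrix(stats::rnorm(n_frames * 3 * nat), n_frames) %*% diag(sds)
  coords <- array(NA_real_, dim = c(nat, 3, n_frames))
  for (k in seq_len(n_frames)) {
    coords[, , k] <- matrix(X[k, ], nat, 3, byrow = TRUE)
  }
  top <- topology(seq_len(nat), rep("CA", nat), rep("GLY", nat),
                  seq_len(nat), "A", element = rep("C", nat), mass = masses)
  structure(
    list(trajectory = trajectory(top, coords),
         entropy_quasiharmonic =
           entropy_from_spectrum(eigenvalues, temperature)$total,
         entropy_schlitter =
           entropy_from_spectrum(eigenvalues, temperature,
                                 method = "schlitter")$total,
         eigenvalues = eigenvalues, masses = masses,
         temperature = temperature, seed = seed),
    class = "gaussian_ensemble")
}

#' Plant scripted solvent into a trajectory
#'
#' Adds water molecules (single oxygen atoms, resname `HOH`, chain `W`)
#' whose per-frame placement follows a schedule, giving exact ground truth
#' for hydration counting and bridging-water detection:
#'
#' * `site = "bridge"` — at the midpoint of the two bridge site atoms
#'   (within `bridge_cutoff` of both; an error if the sites are too far
#'   apart in a scheduled frame). Multiple simultaneous bridging waters are
#'   offset by 0.01 nm steps perpendicular to the site axis.
#' * `site = "shell"` — 60% of `shell_cutoff` outside an anchor solute atom.
#' * `site = "boundary"` — exactly `shell_cutoff` from the maximal-x solute
#'   atom along +x, so the water's minimum distance to the solute equals the
#'   cutoff exactly (the inclusive-boundary probe).
#'
#' Outside its scheduled frames a water sits ~100 nm away.
#'
#' @param traj a [trajectory()] (typically a synthetic transition bundle's).
#' @param schedule data frame with columns `water` (1-based water id),
#'   `start_frame`, `end_frame`, `site`. Rows for one water must not
#'   overlap. May have zero rows.
#' @param site_a,site_b bridge site atom indices (e.g. `refs$site_w755`,
#'   `refs$site_v912`).
#' @param cfg a [solvation_config()] supplying the cutoffs.
#' @param n_waters number of waters to add; default the largest id in the
#'   schedule.
#' @return list of class `"planted_solvent"`: `trajectory` (augmented),
#'   `truth` — list with `shell_counts` (an [md_series()] of the planted
#'   per-frame counts), `intervals` (the planted bridging residence
#'   intervals), `schedule`.
#' @export
plant_solvent <- function(traj, schedule, site_a, site_b,
                          cfg = solvation_config(),
                          n_waters = NULL) {
  nf <- n_frames(traj)
  if (nrow(schedule)) {
    stopifnot(all(c("water", "start_frame", "end_frame", "site") %in%
                    names(schedule)))
    if (any(schedule$start_frame < 1 | schedule$end_frame > nf |
            schedule$start_frame > schedule$end_frame)) {
      stop("schedule frames out of range", call. = FALSE)
    }
    if (!all(schedule$site %in% c("bridge", "shell", "boundary"))) {
      stop("schedule site must be bridge/shell/boundary", call. = FALSE)
    }
    for (w in unique(schedule$water)) {
      rows <- schedule[schedule$water == w, ]
      if (nrow(rows) > 1) {
        o <- order(rows$start_frame)
        if (any(rows$start_frame[o][-1] <= rows$end_frame[o][-nrow(rows)])) {
          stop("overlapping schedule rows for water ", w, call. = FALSE)
        }
      }
    }
  }
  if (is.null(n_waters)) {
    n_waters <- if (nrow(schedule)) max(schedule$water) else 0L
  }
  if (nrow(schedule) && max(schedule$water) > n_waters) {
    stop("schedule references absent waters", call. = FALSE)
  }

  na <- n_atoms(traj)
  top <- traj$topology
  solute_coords <- traj$coords  # original atoms only
  coords <- array(NA_real_, dim = c(na + n_waters, 3, nf))
  coords[seq_len(na), , ] <- traj$coords
  if (n_waters > 0) {
    # far-away defaults
    for (w in seq_len(n_waters)) {
      coords[na + w, 1, ] <- 100 + 3 * w
      coords[na + w, 2, ] <- 100
      coords[na + w, 3, ] <- 100
    }
    anchors <- rep(seq_len(min(na, 60)), length.out = n_waters)
    centre_of <- function(k) rowMeans(matrix(solute_coords[, , k], na, 3,
                                             byrow = FALSE))
    for (r in seq_len(nrow(schedule))) {
      w <- schedule$water[r]
      for (k in schedule$start_frame[r]:schedule$end_frame[r]) {
        if (schedule$site[r] == "bridge") {
          A <- solute_coords[site_a, , k]
          B <- solute_coords[site_b, , k]
          mid <- (A + B) / 2
          already <- schedule$water[schedule$site == "bridge" &
                                      schedule$start_frame <= k &
                                      schedule$end_frame >= k]
          rank <- match(w, sort(already)) - 1
          if (rank > 0) {
            ab <- B - A
            perp <- c(-ab[2], ab[1], 0)
            np <- sqrt(sum(perp^2))
            if (np < 1e-9) perp <- c(1, 0, 0) else perp <- perp / np
            mid <- mid + 0.01 * rank * perp
          }
          if (sqrt(sum((mid - A)^2)) > cfg$bridge_cutoff ||
              sqrt(sum((mid - B)^2)) > cfg$bridge_cutoff) {
            stop(sprintf(
              "bridge sites too far apart in frame %d for water %d", k, w),
              call. = FALSE)
          }
          coords[na + w, , k] <- mid
        } else if (schedule$site[r] == "shell") {
          anchor <- solute_coords[anchors[w], , k]
          u <- anchor - colMeans(matrix(solute_coords[, , k], na, 3))
          nu <- sqrt(sum(u^2))
          u <- if (nu < 1e-9) c(1, 0, 0) else u / nu
          coords[na + w, , k] <- anchor + 0.6 * cfg$shell_cutoff * u
        } else {  # boundary: exactly at the cutoff from the max-x atom
          imax <- which.max(solute_coords[, 1, k])
          coords[na + w, , k] <- solute_coords[imax, , k] +
            c(cfg$shell_cutoff, 0, 0)
        }
      }
    }
  }
  wtop <- if (n_waters > 0) {
    topology(max(top$serial) + seq_len(n_waters), rep("O", n_waters),
             rep("HOH", n_waters), seq_len(n_waters), "W",
             element = rep("O", n_waters))
  } else NULL
  new_top <- if (is.null(wtop)) top else {
    out <- rbind(as.data.frame(top), as.data.frame(wtop))
    class(out) <- class(top)
    out
  }
  aug <- trajectory(new_top, coords, times = traj$times, box = traj$box)

  counts <- integer(nf)
  if (nrow(schedule)) {
    for (r in seq_len(nrow(schedule))) {
      rng <- schedule$start_frame[r]:schedule$end_frame[r]
      counts[rng] <- counts[rng] + 1L
    }
  }
  spacing <- frame_spacing(traj$times)
  br <- schedule[schedule$site == "bridge", , drop = FALSE]
  intervals <- if (nrow(br)) {
    data.frame(
      water_chain = "W", water_resid = br$water, site = "bridge",
      start_ps = traj$times[br$start_frame],
      end_ps = traj$times[br$end_frame],
      duration_ps = traj$times[br$end_frame] - traj$times[br$start_frame] +
        spacing,
      n_frames = br$end_frame - br$start_frame + 1L)
  } else {
    data.frame(water_chain = character(), water_resid = integer(),
               site = character(), start_ps = numeric(), end_ps = numeric(),
               duration_ps = numeric(), n_frames = integer())
  }
  structure(
    list(trajectory = aug,
         truth = list(
           shell_counts = md_series(traj$times, counts,
                                    label = "planted shell waters",
                                    units = "count"),
           intervals = intervals, schedule = schedule)),
    class = "planted_solvent")
}
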