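#' Solvation analysis configuration
#'
#' @param shell_cutoff first-hydration-shell cutoff, nm. Default 0.5 (the
#'   conventional ~5 Angstrom first-shell radius).
#' @param bridge_cutoff bridging-water cutoff to each site atom, nm.
#'   Default 0.35.
#' @param gap_tolerance number of consecutive absent frames bridged within a
#'   residence interval. Default 0 (a strictly continuous occupancy reading);
#'   exposed because frame striding can fragment genuine residences.
#' @param use_pbc apply minimum-image distances (requires a box).
#' @return list of class `"solvation_config"`.
#' @export
solvation_config <- function(shell_cutoff = 0.5, bridge_cutoff = 0.35,
                             gap_tolerance = 0L, use_pbc = FALSE) {
  if (shell_cutoff <= 0 || bridge_cutoff <= 0) {
    stop("cutoffs must be > 0", call. = FALSE)
  }
  if (gap_tolerance < 0) stop("gap_tolerance must be >= 0", call. = FALSE)
  structure(list(shell_cutoff = shell_cutoff, bridge_cutoff = bridge_cutoff,
                 gap_tolerance = as.integer(gap_tolerance),
                 use_pbc = use_pbc),
            class = "solvation_config")
}

#' First-hydration-shell water count per frame
#'
#' Counts, for each frame, the water molecules whose oxygen atom lies within
#' `shell_cutoff` of ANY solute atom. The boundary is inclusive: a distance
#' exactly equal to the cutoff counts as inside (used consistently across
#' the package). Water molecules are identified by the water residues in
#' `water_mask`; their oxygen atom is the distance proxy.
#'
#' @param traj a [trajectory()].
#' @param solute_mask solute atom indices; by default distances are measured
#'   to these atoms as given (pass a heavy-atom selection for the usual
#'   heavy-atom convention).
#' @param water_mask water atom indices (oxygens are extracted internally).
#' @param cfg a [solvation_config()].
#' @param method `"cell"` (grid neighbour search, default) or `"brute"`
#'   (all-pairs); both give identical counts.
#' @return an [md_series()] of counts.
#' @export
hydration_count_series <- function(traj, solute_mask, water_mask,
                                   cfg = solvation_config(),
                                   method = c("cell", "brute")) {
  method <- match.arg(method)
  if (!length(solute_mask)) {
    stop("solute mask must be non-empty", call. = FALSE)
  }
  if (length(intersect(solute_mask, water_mask))) {
    stop("solute and water masks overlap", call. = FALSE)
  }
  if (!length(water_mask)) {
    return(md_series(traj$times, rep(0, n_frames(traj)),
                     label = "hydration shell waters", units = "count"))
  }
  ox <- water_oxygen_indices(traj$topology, water_mask)
  counts <- vapply(seq_len(n_frames(traj)), function(k) {
    box <- if (cfg$use_pbc && !is.null(traj$box)) traj$box[k, ] else NULL
    inside <- within_cutoff_any(
      frame_coords(traj, k, ox), frame_coords(traj, k, solute_mask),
      cfg$shell_cutoff, box = box, method = method)
    sum(inside)
  }, numeric(1))
  md_series(traj$times, counts, label = "hydration shell waters",
            units = "count")
}

# Oxygen atom index per water residue in the mask (one per residue).
water_oxygen_indices <- function(top, water_mask) {
  sub <- top[water_mask, ]
  is_ox <- toupper(sub$element) == "O"
  if (!any(is_ox)) {
    stop("water mask contains no oxygen atoms", call. = FALSE)
  }
  idx <- water_mask[is_ox]
  # one oxygen per (chain, resid)
  key <- paste(top$chain[idx], top$resid[idx])
  idx[!duplicated(key)]
}

#' Block average of a time series
#'
#' Partitions the series into consecutive non-overlapping blocks of `block`
#' samples and emits each block's (mean time, mean value). A trailing
#' partial block is emitted and flagged in the `partial` column.
#'
#' @param series an [md_series()].
#' @param block samples per block (>= 1).
#' @param strict error (rather than emit one partial block) when the series
#'   is shorter than `block`.
#' @return a data frame `time_ps`, `value`, `n`, `partial`, of class
#'   `"md_series"`.
#' @export
block_average <- function(series, block, strict = FALSE) {
  if (block < 1) stop("block must be >= 1", call. = FALSE)
  n <- nrow(series)
  if (strict && n < block) {
    stop("series shorter than one block", call. = FALSE)
  }
  g <- (seq_len(n) - 1) %/% block
  out <- data.frame(
    time_ps = as.numeric(tapply(series$time_ps, g, mean)),
    value = as.numeric(tapply(series$value, g, mean)),
    n = as.integer(tapply(series$value, g, length))
  )
  out$partial <- out$n < block
  structure(out, label = paste("block mean:", attr(series, "label") %||% ""),
            units = attr(series, "units") %||% "",
            class = c("md_series", "data.frame"))
}

#' Bridging-water residence intervals at a two-atom site
#'
#' A water bridges the site in a frame when its oxygen is within
#' `bridge_cutoff` of BOTH site atoms (inclusive boundary). For each water
#' (tracked by the chain and author residue number of its residue), maximal
#' runs of consecutive bridging frames — runs separated by at most
#' `gap_tolerance` non-bridging frames are merged — become residence
#' intervals. An interval's duration is `end_time - start_time` plus one
#' frame spacing, so a single-frame visit has the duration of one frame.
#'
#' @param traj a [trajectory()].
#' @param site_a,site_b single-atom masks (e.g. the tryptophan side-chain
#'   nitrogen `NE1` and a backbone nitrogen `N`).
#' @param water_mask water atom indices.
#' @param cfg a [solvation_config()].
#' @param site_label label stored in the `site` column.
#' @return data frame with columns `water_chain`, `water_resid`, `site`,
#'   `start_ps`, `end_ps`, `duration_ps`, `n_frames`.
#' @export
bridging_water_events <- function(traj, site_a, site_b, water_mask,
                                  cfg = solvation_config(),
                                  site_label = "bridge") {
  if (length(site_a) != 1 || length(site_b) != 1) {
    stop("site masks must each contain exactly one atom", call. = FALSE)
  }
  ox <- water_oxygen_indices(traj$topology, water_mask)
  nf <- n_frames(traj)
  occ <- matrix(FALSE, length(ox), nf)
  for (k in seq_len(nf)) {
    w <- frame_coords(traj, k, ox)
    box <- if (cfg$use_pbc && !is.null(traj$box)) traj$box[k, ] else NULL
    da <- point_distances(w, frame_coords(traj, k, site_a), box)
    db <- point_distances(w, frame_coords(traj, k, site_b), box)
    occ[, k] <- da <= cfg$bridge_cutoff & db <= cfg$bridge_cutoff
  }
  spacing <- frame_spacing(traj$times)
  top <- traj$topology
  out <- list()
  for (i in seq_along(ox)) {
    runs <- occupancy_runs(occ[i, ], cfg$gap_tolerance)
    if (!nrow(runs)) next
    out[[length(out) + 1]] <- data.frame(
      water_chain = top$chain[ox[i]],
      water_resid = top$resid[ox[i]],
      site = site_label,
      start_ps = traj$times[runs$start],
      end_ps = traj$times[runs$end],
      duration_ps = traj$times[runs$end] - traj$times[runs$start] + spacing,
      n_frames = runs$end - runs$start + 1L
    )
  }
  if (!length(out)) {
    return(data.frame(water_chain = character(), water_resid = integer(),
                      site = character(), start_ps = numeric(),
                      end_ps = numeric(), duration_ps = numeric(),
                      n_frames = integer()))
  }
  do.call(rbind, out)
}

# Maximal TRUE runs in a logical vector, with gaps of <= gap FALSE frames
# merged. Returns data.frame(start, end) of 1-based indices.
occupancy_runs <- function(flags, gap = 0L) {
  idx <- which(flags)
  if (!length(idx)) return(data.frame(start = integer(), end = integer()))
  brk <- which(diff(idx) > gap + 1L)
  starts <- idx[c(1L, brk + 1L)]
  ends <- idx[c(brk, length(idx))]
  data.frame(start = starts, end = ends)
}

frame_spacing <- function(times) {
  if (length(times) < 2) return(1)
  stats::median(diff(times))
}

#' Summarise residence intervals
#'
#' @param intervals a data frame from [bridging_water_events()] (or any with
#'   a `duration_ps` column).
#' @return list: `count`, `mean_ps`, `max_ps` (the latter two `NA` when no
#'   intervals), `total_ps`.
#' @export
residence_summary <- function(intervals) {
  n <- nrow(intervals)
  if (!n) {
    return(list(count = 0L, mean_ps = NA_real_, max_ps = NA_real_,
                total_ps = 0))
  }
  list(count = n,
       mean_ps = mean(intervals$duration_ps),
       max_ps = max(intervals$duration_ps),
       total_ps = sum(intervals$duration_ps))
}
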