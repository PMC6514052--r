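#' State-classification thresholds for the two-reference metric
#'
#' Frames are `closed` at or below `closed_max`, `open` at or above
#' `open_min`, `semi-open` in between. The conventional closed criterion is
#' delta-RMSD below -0.1 nm; the +0.1 nm open threshold is symmetric by
#' choice. The middle band operationalises the "semi-open" state — it is a
#' working definition, not an experimentally calibrated one.
#'
#' @param closed_max closed-state upper bound, nm. Default -0.1.
#' @param open_min open-state lower bound, nm. Default +0.1.
#' @return list of class `"state_thresholds"`.
#' @export
state_thresholds <- function(closed_max = -0.1, open_min = 0.1) {
  if (!(closed_max < open_min)) {
    stop("closed_max must be < open_min", call. = FALSE)
  }
  structure(list(closed_max = closed_max, open_min = open_min),
            class = "state_thresholds")
}

#' Classify frames as open / semi-open / closed
#'
#' Boundary rule (documented, inclusive): `value <= closed_max` is closed;
#' `value >= open_min` is open; otherwise semi-open.
#'
#' @param delta_rmsd an [md_series()] of delta-RMSD values (nm), or a
#'   numeric vector.
#' @param thr a [state_thresholds()].
#' @return factor with levels `closed`, `semi-open`, `open`.
#' @export
classify_states <- function(delta_rmsd, thr = state_thresholds()) {
  v <- if (is.data.frame(delta_rmsd)) delta_rmsd$value else delta_rmsd
  lab <- ifelse(v <= thr$closed_max, "closed",
                ifelse(v >= thr$open_min, "open", "semi-open"))
  factor(lab, levels = c("closed", "semi-open", "open"))
}

#' First frame at which the closed state is reached
#'
#' @inheritParams classify_states
#' @return list with `frame` (index, `NA` if never closed) and `time_ps`.
#' @export
detect_closed_onset <- function(delta_rmsd, thr = state_thresholds()) {
  states <- classify_states(delta_rmsd, thr)
  i <- which(states == "closed")
  if (!length(i)) return(list(frame = NA_integer_, time_ps = NA_real_))
  t <- if (is.data.frame(delta_rmsd)) delta_rmsd$time_ps[i[1]] else NA_real_
  list(frame = i[1], time_ps = t)
}

.known_stages <- c("delta_rmsd", "rmsf", "pca", "cluster", "entropy",
                   "hydration", "bridging", "hbonds", "charge_centers")

#' Run the configured analysis battery end-to-end
#'
#' Executes the enabled stages, in their declared order, on either a
#' synthetic transition bundle or user-supplied structures, and returns a
#' structured report; all randomness is seeded from the config, so a fixed
#' config gives byte-identical numbers. With `out_dir`, the report is
#' written as `report.json` plus per-stage CSV files.
#'
#' The config is a named list (or path to a YAML file with the same shape):
#' \preformatted{
#' seed: 1
#' input:
#'   type: synthetic          # or "pdb"
#'   spec: {n_frames: 1000, noise_sigma: 0.02, ...}   # synthetic_spec fields
#'   # for type "pdb": trajectory:, open_ref:, closed_ref:, selection:
#' stages:
#'   delta_rmsd: {enabled: true, closed_max: -0.1, open_min: 0.1}
#'   rmsf:       {enabled: false}
#'   pca:        {enabled: false, kind: distance, stride: 1, n_components: 2}
#'   cluster:    {enabled: false, cutoff: 0.2, stride: 1}
#'   entropy:    {enabled: false, temperature: 300, method: quasiharmonic}
#'   hydration:  {enabled: false, block: 10}
#'   bridging:   {enabled: false}
#'   hbonds:     {enabled: false}
#'   charge_centers: {enabled: false, epsilon: 80}
#' }
#' Disabling a stage never changes another stage's numbers. A schema
#' violation raises a config error before any computation; a failing stage
#' raises an error naming the stage (sections already written to `out_dir`
#' are preserved).
#'
#' @param config named list or YAML file path.
#' @param out_dir optional output directory.
#' @return list of class `"analysis_report"`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  validate_config(config)
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||% list()

  # ---- resolve input -------------------------------------------------
  input <- config$input
  synthetic <- identical(input$type, "synthetic")
  if (synthetic) {
    spec_args <- input$spec %||% list()
    spec_args$seed <- spec_args$seed %||% seed
    spec <- do.call(synthetic_spec, spec_args)
    bundle <- make_transition_trajectory(spec)
    traj <- bundle$trajectory
    refs <- bundle$refs$pair
    ca <- bundle$refs$ca_mask
    sites <- list(a = bundle$refs$site_w755, b = bundle$refs$site_v912)
    truth <- bundle$truth
  } else {
    traj <- read_pdb(input$trajectory)
    open_t <- read_pdb(input$open_ref)
    closed_t <- read_pdb(input$closed_ref)
    selection <- input$selection %||% "alphacarbon"
    ca <- select_atoms(traj$topology, selection)
    refs <- reference_pair(
      frame_coords(open_t, 1), frame_coords(closed_t, 1),
      select_atoms(open_t$topology, selection),
      select_atoms(closed_t$topology, selection), ca)
    sites <- NULL
    truth <- NULL
  }

  report <- list(provenance = list(
    package = "lbdtraj",
    version = as.character(utils::packageVersion("lbdtraj")),
    config_hash = rlang::hash(config),
    seed = seed,
    input_type = input$type,
    n_frames = n_frames(traj),
    n_atoms = n_atoms(traj)))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  enabled <- function(name) isTRUE(stages[[name]]$enabled)
  run_stage <- function(name, fun) {
    if (!enabled(name)) return(invisible(NULL))
    res <- tryCatch(fun(stages[[name]]),
                    error = function(e) stop(sprintf(
                      "pipeline stage '%s' failed: %s", name,
                      conditionMessage(e)), call. = FALSE))
    report[[name]] <<- res
    if (!is.null(out_dir)) write_stage_csv(name, res, out_dir)
    invisible(NULL)
  }

  run_stage("delta_rmsd", function(p) {
    thr <- state_thresholds(p$closed_max %||% -0.1, p$open_min %||% 0.1)
    dr <- delta_rmsd_series(traj, refs)
    states <- classify_states(dr, thr)
    onset <- detect_closed_onset(dr, thr)
    list(series = as.data.frame(dr), states = as.character(states),
         state_counts = as.list(table(states)),
         closed_onset = onset,
         thresholds = unclass(thr),
         truth_crossing_frame = if (!is.null(truth))
           truth$crossing_frame else NULL)
  })
  run_stage("rmsf", function(p) {
    rmsf(traj, mask = ca)
  })
  run_stage("pca", function(p) {
    kind <- p$kind %||% "distance"
    k <- p$n_components %||% 2
    res <- if (identical(kind, "cartesian")) {
      cartesian_pca(traj, ca, n_components = k)
    } else {
      md_pca(distance_feature_matrix(traj, ca, stride = p$stride %||% 1),
             n_components = k)
    }
    list(eigenvalues = res$eigenvalues,
         variance_explained = res$eigenvalues / sum(res$eigenvalues),
         projections = as.data.frame(res$projections),
         feature_kind = res$feature_kind)
  })
  run_stage("cluster", function(p) {
    cl <- gromos_cluster(traj, ca, cutoff = p$cutoff %||% 0.2,
                         stride = p$stride %||% 1)
    list(n_clusters = length(cl$sizes), sizes = cl$sizes,
         medoids = cl$medoids, assignment = cl$assignment,
         frames = cl$frames, cutoff = cl$cutoff)
  })
  run_stage("entropy", function(p) {
    ent <- quasiharmonic_entropy(
      traj, ca, temperature = p$temperature %||% 300,
      method = p$method %||% "quasiharmonic")
    list(total_J_per_molK = ent$total, method = ent$method,
         temperature = ent$temperature,
         n_modes = length(ent$eigenvalues),
         n_modes_discarded = ent$n_modes_discarded)
  })
  water_mask <- which(traj$topology$resname %in% .water_resnames)
  solute_mask <- setdiff(seq_len(n_atoms(traj)), water_mask)
  run_stage("hydration", function(p) {
    cfg <- solvation_config(shell_cutoff = p$shell_cutoff %||% 0.5)
    hs <- hydration_count_series(traj, solute_mask, water_mask, cfg)
    list(series = as.data.frame(hs),
         block_averages = as.data.frame(
           block_average(hs, p$block %||% 10)))
  })
  run_stage("bridging", function(p) {
    if (is.null(sites)) {
      stop("bridging stage needs the two site atoms (synthetic input)")
    }
    cfg <- solvation_config(bridge_cutoff = p$bridge_cutoff %||% 0.35,
                            gap_tolerance = p$gap_tolerance %||% 0)
    ev <- bridging_water_events(traj, sites$a, sites$b, water_mask, cfg)
    list(intervals = ev, summary = residence_summary(ev))
  })
  run_stage("hbonds", function(p) {
    specs <- p$specs %||% list()
    occ <- vapply(specs, function(s) {
      hb <- hbond_spec(
        donor = select_atoms(traj$topology, s$donor),
        acceptor = select_atoms(traj$topology, s$acceptor),
        hydrogen = if (is.null(s$hydrogen)) NULL else
          select_atoms(traj$topology, s$hydrogen),
        d_cutoff = s$d_cutoff %||% 0.35,
        angle_cutoff = s$angle_cutoff %||% 120)
      hbond_occupancy(traj, hb)
    }, numeric(1))
    data.frame(donor = vapply(specs, `[[`, "", "donor"),
               acceptor = vapply(specs, `[[`, "", "acceptor"),
               occupancy = occ)
  })
  run_stage("charge_centers", function(p) {
    centers <- pr_lbd_charge_centers(p$variant %||% "discussion")
    ds <- charge_center_distance_series(traj, centers$h12nt, centers$h3ct)
    eps <- p$epsilon %||% 80
    qa <- centers$h12nt$charge; qb <- centers$h3ct$charge
    list(distance = as.data.frame(ds),
         energy_kJ_per_mol = as.numeric(coulomb_energy(qa, qb, ds$value,
                                                       epsilon = eps)),
         epsilon = eps, q1 = qa, q2 = qb,
         formula = "kC*q1*q2/(eps*d)")
  })

  class(report) <- "analysis_report"
  if (!is.null(out_dir)) {
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  report
}

validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  if (is.null(config$input) || is.null(config$input$type) ||
      !config$input$type %in% c("synthetic", "pdb")) {
    stop("config error: input$type must be 'synthetic' or 'pdb'",
         call. = FALSE)
  }
  if (identical(config$input$type, "pdb")) {
    need <- c("trajectory", "open_ref", "closed_ref")
    miss <- setdiff(need, names(config$input))
    if (length(miss)) {
      stop("config error: missing input fields: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  bad <- setdiff(names(config$stages %||% list()), .known_stages)
  if (length(bad)) {
    stop("config error: unknown stages: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(config)
}

write_stage_csv <- function(name, res, out_dir) {
  pick <- function(x) if (is.data.frame(x)) x else NULL
  tbl <- pick(res) %||% pick(res$series) %||% pick(res$intervals) %||%
    pick(res$projections)
  if (!is.null(tbl)) {
    utils::write.csv(tbl, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  invisible(NULL)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report (lbdtraj)\n")
  cat(sprintf("  input: %s, %d frames, %d atoms\n",
              x$provenance$input_type, x$provenance$n_frames,
              x$provenance$n_atoms))
  for (s in setdiff(names(x), "provenance")) cat("  section:", s, "\n")
  invisible(x)
}
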