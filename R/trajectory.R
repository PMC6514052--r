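#' Build a trajectory
#'
#' A trajectory couples a topology with time-ordered coordinate frames. All
#' internal lengths are in nm (file I/O converts at the boundary) and times
#' are in ps. Coordinates live in an `n_atoms x 3 x n_frames` array; the
#' optional periodic box is orthorhombic, one row of `(lx, ly, lz)` box
#' lengths (nm) per frame.
#'
#' @param topology a [topology()] object.
#' @param coords numeric array `n_atoms x 3 x n_frames` (nm). A single
#'   `n_atoms x 3` matrix is promoted to one frame.
#' @param times frame times in ps, non-decreasing. Default `0, 1, 2, ...`.
#' @param box `NULL`, or an `n_frames x 3` matrix (or length-3 vector,
#'   recycled) of orthorhombic box lengths in nm.
#' @return An object of class `"trajectory"`: a list with elements
#'   `topology`, `coords`, `times`, `box`.
#' @examples
#' top <- topology(1:3, c("CA", "CA", "CA"), "ALA", 1:3, "A")
#' xyz <- matrix(rnorm(9), 3, 3)
#' trj <- trajectory(top, xyz)
#' n_frames(trj)
#' @export
trajectory <- function(topology, coords, times = NULL, box = NULL) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (dim(coords)[1] != nrow(topology)) {
    stop(sprintf(
      "trajectory invariant violated: %d coordinate rows for %d topology atoms",
      dim(coords)[1], nrow(topology)), call. = FALSE)
  }
  nf <- dim(coords)[3]
  if (is.null(times)) times <- seq_len(nf) - 1
  if (length(times) != nf) {
    stop("trajectory invariant violated: one time per frame required",
         call. = FALSE)
  }
  if (is.unsorted(times)) {
    stop("trajectory invariant violated: times must be non-decreasing",
         call. = FALSE)
  }
  if (!is.null(box)) {
    if (is.vector(box)) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
    stopifnot(is.matrix(box), ncol(box) == 3, nrow(box) == nf)
    if (any(box <= 0)) {
      stop("trajectory invariant violated: box must have positive volume",
           call. = FALSE)
    }
  }
  structure(
    list(topology = topology, coords = coords,
         times = as.numeric(times), box = box),
    class = "trajectory"
  )
}

#' Number of frames in a trajectory
#' @param traj a trajectory.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame's coordinates
#' @param traj a trajectory.
#' @param i frame index (1-based).
#' @param mask optional atom index mask.
#' @return `n x 3` coordinate matrix in nm.
#' @export
frame_coords <- function(traj, i, mask = NULL) {
  x <- traj$coords[, , i, drop = FALSE]
  dim(x) <- dim(x)[1:2]
  if (!is.null(mask)) x <- x[mask, , drop = FALSE]
  x
}

#' Subset a trajectory by frames
#' @param traj a trajectory.
#' @param frames integer frame indices to keep, in order.
#' @return a trajectory with the selected frames.
#' @export
subset_frames <- function(traj, frames) {
  trajectory(traj$topology, traj$coords[, , frames, drop = FALSE],
             times = traj$times[frames],
             box = if (is.null(traj$box)) NULL
                   else traj$box[frames, , drop = FALSE])
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "Trajectory: %d atoms, %d frames, t = %.6g..%.6g ps%s\n",
    n_atoms(x), n_frames(x), x$times[1], x$times[n_frames(x)],
    if (is.null(x$box)) "" else ", periodic box"))
  invisible(x)
}

#' Time series container
#'
#' Uniform container for per-frame observables: a data frame with columns
#' `time_ps` and `value`, plus `label` and `units` attributes. Written to CSV
#' with header `time_ps,value,label,units` by [write_series_csv()].
#'
#' @param times frame times, ps; non-decreasing.
#' @param values one value per time.
#' @param label short description of the observable.
#' @param units units string (e.g. `"nm"`, `"count"`).
#' @return data frame of class `"md_series"`.
#' @export
md_series <- function(times, values, label = "", units = "") {
  stopifnot(length(times) == length(values))
  if (is.unsorted(times)) {
    stop("md_series invariant violated: times must be non-decreasing",
         call. = FALSE)
  }
  structure(
    data.frame(time_ps = as.numeric(times), value = as.numeric(values)),
    label = label, units = units,
    class = c("md_series", "data.frame")
  )
}

#' Write a time series as CSV
#' @param series an [md_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  out <- data.frame(
    time_ps = series$time_ps, value = series$value,
    label = attr(series, "label") %||% "",
    units = attr(series, "units") %||% ""
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
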