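#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the
#' (optionally weighted) sum of squared deviations between `mobile %*% R + t`
#' and `reference`, via SVD of the weighted covariance of the centred
#' coordinate sets, with the determinant correction that forbids reflections.
#'
#' @param mobile `n x 3` coordinate matrix (nm).
#' @param reference `n x 3` coordinate matrix (nm), same `n`.
#' @param weights per-atom weights (e.g. masses) or `NULL` for uniform.
#' @return list with `rotation` (3x3, det +1), `translation` (length 3) such
#'   that the superposed mobile is `mobile %*% rotation + translation`
#'   (row-vector convention), and `rmsd` — the weighted RMSD (nm) after
#'   superposition.
#' @examples
#' x <- matrix(rnorm(30), 10, 3)
#' fit <- kabsch_superpose(x, x)
#' fit$rmsd  # 0
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n < 3 || nrow(reference) != n) {
    stop("superposition needs >= 3 correspondence points of equal length",
         call. = FALSE)
  }
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  stopifnot(length(w) == n, all(w >= 0), sum(w) > 0)
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  M <- sweep(mobile, 2, cm)
  P <- sweep(reference, 2, cr)
  if (is_collinear(M) || is_collinear(P)) {
    stop("degenerate geometry: correspondence points are collinear",
         call. = FALSE)
  }
  A <- crossprod(M * w, P)  # 3x3 weighted covariance
  sv <- svd(A)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  dev <- M %*% R - P
  rmsd <- sqrt(sum(w * rowSums(dev * dev)))
  list(rotation = R, translation = as.numeric(cr - cm %*% R), rmsd = rmsd)
}

is_collinear <- function(X, tol = 1e-10) {
  s <- svd(X, nu = 0, nv = 0)$d
  s[2] <= tol * max(s[1], tol)
}

# RMSD after optimal superposition; thin wrapper used all over the package.
fit_rmsd <- function(mobile, reference, weights = NULL) {
  kabsch_superpose(mobile, reference, weights)$rmsd
}

#' Per-frame RMSD to a reference structure
#'
#' Each frame is optimally superposed (Kabsch) onto the reference over the
#' given atom correspondence, and the post-fit RMSD is reported in nm. The
#' two masks give the atom correspondence: `mask_traj[i]` in the trajectory
#' pairs with `mask_ref[i]` in the reference.
#'
#' @param traj a [trajectory()].
#' @param ref_coords reference coordinates, `m x 3` (nm) — typically a frame
#'   of a reference structure already restricted to its mask, or a full
#'   coordinate set with `mask_ref` supplied.
#' @param mask_traj atom indices into `traj` (default: all atoms).
#' @param mask_ref atom indices into `ref_coords` (default: all rows).
#' @param weights optional per-atom weights.
#' @return an [md_series()] in nm.
#' @export
rmsd_series <- function(traj, ref_coords, mask_traj = NULL, mask_ref = NULL,
                        weights = NULL) {
  ref <- if (is.null(mask_ref)) as.matrix(ref_coords)
         else as.matrix(ref_coords)[mask_ref, , drop = FALSE]
  if (is.null(mask_traj)) mask_traj <- seq_len(n_atoms(traj))
  if (length(mask_traj) != nrow(ref)) {
    stop("mask lengths must match the reference atom count", call. = FALSE)
  }
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    fit_rmsd(frame_coords(traj, k, mask_traj), ref, weights)
  }, numeric(1))
  md_series(traj$times, vals, label = "RMSD", units = "nm")
}

#' Pair of reference structures for the two-reference state metric
#'
#' Couples an "open" and a "closed" reference conformation with the atom
#' correspondence used for RMSD: `mask_open`, `mask_closed` and `mask_traj`
#' must have identical lengths (>= 3) and pair position-by-position.
#'
#' @param open_coords,closed_coords full coordinate matrices (nm) of the two
#'   references.
#' @param mask_open,mask_closed atom indices into the two references.
#' @param mask_traj atom indices into trajectories analysed against this pair.
#' @return list of class `"reference_pair"`.
#' @export
reference_pair <- function(open_coords, closed_coords,
                           mask_open, mask_closed, mask_traj) {
  if (length(mask_open) != length(mask_closed) ||
      length(mask_open) != length(mask_traj) || length(mask_open) < 3) {
    stop("reference_pair masks must have identical lengths >= 3",
         call. = FALSE)
  }
  structure(
    list(open = as.matrix(open_coords)[mask_open, , drop = FALSE],
         closed = as.matrix(closed_coords)[mask_closed, , drop = FALSE],
         mask_traj = as.integer(mask_traj)),
    class = "reference_pair")
}

#' Two-reference delta-RMSD state metric
#'
#' For each frame, `delta-RMSD = RMSD(frame, closed) - RMSD(frame, open)`
#' (both Kabsch-optimal, nm). The sign convention makes closed-like frames
#' negative, so the conventional closed-state criterion "delta-RMSD below
#' -0.1 nm" applies directly; see [classify_states()].
#'
#' @param traj a [trajectory()].
#' @param refs a [reference_pair()].
#' @param weights optional per-atom weights.
#' @return an [md_series()] in nm, labelled `"dRMSD"`.
#' @export
delta_rmsd_series <- function(traj, refs, weights = NULL) {
  stopifnot(inherits(refs, "reference_pair"))
  m <- refs$mask_traj
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    x <- frame_coords(traj, k, m)
    fit_rmsd(x, refs$closed, weights) - fit_rmsd(x, refs$open, weights)
  }, numeric(1))
  md_series(traj$times, vals, label = "dRMSD", units = "nm")
}

#' Root-mean-square fluctuation per atom
#'
#' Superposes all frames onto the iteratively converged mean structure of the
#' masked atoms (start: frame 1; iterate superpose-and-average until the mean
#' moves < `tol` nm), then reports each masked atom's RMS deviation from the
#' mean position. With `superpose = FALSE` fluctuations are taken about the
#' raw per-atom means, no fitting.
#'
#' @param traj a [trajectory()] with >= 2 frames.
#' @param mask atom indices (default: all atoms). For per-residue profiles
#'   pass the alpha-carbon selection.
#' @param superpose fit frames to the mean structure first? Default `TRUE`.
#' @param tol convergence tolerance on the mean structure, nm.
#' @param max_iter iteration cap for the mean-structure refinement.
#' @return data frame with columns `chain`, `resid`, `name`, `rmsf_nm`, one
#'   row per masked atom, in mask order.
#' @export
rmsf <- function(traj, mask = NULL, superpose = TRUE, tol = 1e-6,
                 max_iter = 50) {
  if (n_frames(traj) < 2) {
    stop("RMSF needs at least 2 frames", call. = FALSE)
  }
  if (is.null(mask)) mask <- seq_len(n_atoms(traj))
  sup <- superpose_to_mean(traj, mask, superpose, tol, max_iter)
  dev2 <- apply(sup$coords, 3, function(x) rowSums((x - sup$mean)^2))
  vals <- sqrt(rowMeans(matrix(dev2, nrow = length(mask))))
  top <- traj$topology[mask, ]
  data.frame(chain = top$chain, resid = top$resid, name = top$name,
             rmsf_nm = vals, row.names = NULL)
}

# Shared by rmsf, cartesian PCA and entropy: returns masked coordinates
# (m x 3 x nf) fitted to the converged mean structure, plus that mean.
superpose_to_mean <- function(traj, mask, superpose = TRUE, tol = 1e-6,
                              max_iter = 50, weights = NULL) {
  nf <- n_frames(traj)
  m <- length(mask)
  coords <- traj$coords[mask, , , drop = FALSE]
  if (!superpose) {
    mean_xyz <- apply(coords, c(1, 2), mean)
    return(list(coords = coords, mean = mean_xyz))
  }
  ref <- coords[, , 1]
  fitted <- coords
  for (it in seq_len(max_iter)) {
    for (k in seq_len(nf)) {
      f <- kabsch_superpose(coords[, , k], ref, weights)
      fitted[, , k] <- coords[, , k] %*% f$rotation +
        matrix(f$translation, m, 3, byrow = TRUE)
    }
    new_mean <- apply(fitted, c(1, 2), mean)
    if (max(abs(new_mean - ref)) < tol) {
      return(list(coords = fitted, mean = new_mean))
    }
    ref <- new_mean
  }
  list(coords = fitted, mean = ref)
}

#' Distance between two atoms or group centroids over a trajectory
#'
#' Positions are unweighted centroids of each mask (mass-weighted on
#' request). With `use_pbc = TRUE` and a box present, the minimum-image
#' distance in the orthorhombic box is reported.
#'
#' @param traj a [trajectory()].
#' @param mask_a,mask_b non-empty atom index masks.
#' @param use_pbc apply the minimum-image convention? Requires a box.
#' @param mass_weighted use mass-weighted centroids? Default `FALSE`.
#' @return an [md_series()] in nm.
#' @export
distance_series <- function(traj, mask_a, mask_b, use_pbc = FALSE,
                            mass_weighted = FALSE) {
  if (!length(mask_a) || !length(mask_b)) {
    stop("distance_series requires non-empty selections", call. = FALSE)
  }
  if (use_pbc && is.null(traj$box)) {
    stop("use_pbc = TRUE requires a trajectory with a periodic box",
         call. = FALSE)
  }
  wa <- wb <- NULL
  if (mass_weighted) {
    wa <- traj$topology$mass[mask_a]; wa <- wa / sum(wa)
    wb <- traj$topology$mass[mask_b]; wb <- wb / sum(wb)
  }
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    a <- frame_coords(traj, k, mask_a)
    b <- frame_coords(traj, k, mask_b)
    pa <- if (is.null(wa)) colMeans(a) else colSums(a * wa)
    pb <- if (is.null(wb)) colMeans(b) else colSums(b * wb)
    d <- pb - pa
    if (use_pbc) d <- minimum_image(d, traj$box[k, ])
    sqrt(sum(d * d))
  }, numeric(1))
  md_series(traj$times, vals, label = "distance", units = "nm")
}

# Minimum-image displacement in an orthorhombic box. `d` may be a vector or
# an n x 3 matrix; `box` the (lx, ly, lz) lengths.
minimum_image <- function(d, box) {
  if (is.matrix(d)) {
    d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
  } else {
    d - box * round(d / box)
  }
}
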