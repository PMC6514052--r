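#' Pairwise-distance feature matrix for essential-dynamics PCA
#'
#' For every `stride`-th frame, computes all pairwise distances between the
#' masked atoms (typically alpha carbons). Features are rigid-motion
#' invariant, so PCA on them needs no prior superposition. Columns follow the
#' upper triangle in fixed row-major `(i < j)` order.
#'
#' @param traj a [trajectory()].
#' @param mask atom indices, length `m >= 2`.
#' @param stride keep every `stride`-th frame (>= 1).
#' @return numeric matrix, `ceiling(n_frames / stride)` rows and
#'   `m (m - 1) / 2` columns (nm), with attribute `frames` — the source frame
#'   indices.
#' @export
distance_feature_matrix <- function(traj, mask, stride = 1) {
  if (length(mask) < 2) stop("mask must select >= 2 atoms", call. = FALSE)
  if (stride < 1) stop("stride must be >= 1", call. = FALSE)
  frames <- seq(1, n_frames(traj), by = stride)
  m <- length(mask)
  # stats::dist enumerates pairs (1,2), (1,3), ..., (1,m), (2,3), ... —
  # exactly the row-major upper-triangle (i < j) ordering required here.
  X <- t(vapply(frames, function(k) {
    as.numeric(stats::dist(frame_coords(traj, k, mask)))
  }, numeric(m * (m - 1) / 2)))
  attr(X, "frames") <- frames
  X
}

#' Principal component analysis of a feature matrix
#'
#' Column-mean-centred PCA via singular value decomposition; eigenvalues are
#' the variances along each component (descending), eigenvectors are
#' orthonormal columns, and projections are the centred data scores. The sign
#' of each component is fixed by making its largest-magnitude loading
#' positive, so plots are reproducible across runs.
#'
#' @param features numeric matrix, frames in rows (>= 2), features in columns.
#' @param n_components number of components to keep (default: all).
#' @param feature_kind label stored with the result, `"distance-matrix"` or
#'   `"cartesian"`.
#' @return list of class `"md_pca"`: `mean`, `eigenvalues`, `eigenvectors`
#'   (features x components), `projections` (frames x components),
#'   `feature_kind`.
#' @export
md_pca <- function(features, n_components = NULL,
                   feature_kind = "distance-matrix") {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2) stop("PCA needs >= 2 observations", call. = FALSE)
  mu <- colMeans(features)
  Xc <- sweep(features, 2, mu)
  k_max <- min(n - 1, ncol(features))
  k <- if (is.null(n_components)) k_max else min(n_components, k_max)
  sv <- svd(Xc, nu = 0, nv = k)
  eigenvalues <- (sv$d^2 / (n - 1))[seq_len(k)]
  V <- sv$v
  # deterministic sign: largest-|loading| entry positive
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  structure(
    list(mean = mu, eigenvalues = eigenvalues, eigenvectors = V,
         projections = Xc %*% V, feature_kind = feature_kind),
    class = "md_pca")
}

#' Essential-dynamics PCA on Cartesian coordinates
#'
#' Frames are superposed onto the iteratively converged mean structure, the
#' masked coordinates flattened to `3m` features (per-atom `x, y, z` blocks)
#' and passed to [md_pca()]. Unlike the distance-feature route, eigenvectors
#' here decompose into per-atom 3-vectors, so each mode has a per-atom
#' amplitude — the usual essential-dynamics visualisation.
#'
#' @param traj a [trajectory()] with >= 2 frames.
#' @param mask atom indices (default: all atoms).
#' @param n_components components to keep (default: all).
#' @return an `"md_pca"` with `feature_kind = "cartesian"` and attribute
#'   `mask`.
#' @seealso [atom_mode_amplitudes()]
#' @export
cartesian_pca <- function(traj, mask = NULL, n_components = NULL) {
  if (is.null(mask)) mask <- seq_len(n_atoms(traj))
  sup <- superpose_to_mean(traj, mask)
  nf <- dim(sup$coords)[3]
  X <- t(vapply(seq_len(nf), function(k) as.numeric(t(sup$coords[, , k])),
                numeric(3 * length(mask))))
  res <- md_pca(X, n_components, feature_kind = "cartesian")
  attr(res, "mask") <- mask
  res
}

#' Per-atom amplitude of a Cartesian PCA mode
#'
#' @param pca_res an `"md_pca"` from [cartesian_pca()].
#' @param component component index.
#' @return numeric vector, the norm of each atom's 3-vector within the
#'   eigenvector (one value per masked atom).
#' @export
atom_mode_amplitudes <- function(pca_res, component = 1) {
  stopifnot(identical(pca_res$feature_kind, "cartesian"))
  v <- pca_res$eigenvectors[, component]
  sqrt(rowSums(matrix(v, ncol = 3, byrow = TRUE)^2))
}

#' Quasi-harmonic configurational entropy
#'
#' Treats the ensemble as a harmonic multivariate distribution of the masked
#' atoms: the mass-weighted covariance of the (superposed) Cartesian
#' coordinates is diagonalised, each retained eigenvalue \eqn{\lambda_i}
#' defines a mode frequency \eqn{\omega_i = \sqrt{k_B T / \lambda_i}}, and
#' the total entropy is the quantum-harmonic-oscillator sum
#' \deqn{S = R \sum_i \left[ \frac{x_i}{e^{x_i} - 1} - \ln(1 - e^{-x_i}) \right],
#'   \quad x_i = \hbar \omega_i / k_B T.}
#' The Schlitter variant, an upper bound computed from the same spectrum, is
#' \eqn{S = (R/2) \sum_i \ln(1 + k_B T e^2 \lambda_i / \hbar^2)} (with
#' \eqn{\lambda_i} in SI mass-weighted units, kg m\eqn{^2}).
#'
#' Modes with eigenvalues below `tol` (rigid-body remnants after
#' superposition, numerically null directions) are discarded.
#'
#' @param traj a [trajectory()].
#' @param mask atom indices (default: all). A warning is issued when fewer
#'   than `3 m + 1` frames are available for `m` masked atoms.
#' @param temperature absolute temperature, K (> 0). Default 300.
#' @param method `"quasiharmonic"` (default) or `"schlitter"`.
#' @param superpose superpose frames to the mean structure first (default
#'   `TRUE`; disable for ensembles that are already aligned, e.g. prescribed
#'   Gaussian validation ensembles).
#' @param tol rigid-body eigenvalue tolerance, amu nm^2.
#' @return list of class `"entropy_result"`: `total` (J mol^-1 K^-1),
#'   `mode_frequencies` (rad s^-1), `eigenvalues` (amu nm^2, descending),
#'   `n_modes_discarded`, `method`, `temperature`.
#' @export
quasiharmonic_entropy <- function(traj, mask = NULL, temperature = 300,
                                  method = c("quasiharmonic", "schlitter"),
                                  superpose = TRUE, tol = 1e-8) {
  method <- match.arg(method)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  if (is.null(mask)) mask <- seq_len(n_atoms(traj))
  m <- length(mask)
  nf <- n_frames(traj)
  if (nf < 3 * m + 1) {
    warning(sprintf(
      "only %d frames for %d modes; entropy estimate may be poorly converged",
      nf, 3 * m))
  }
  masses <- traj$topology$mass[mask]
  sup <- superpose_to_mean(traj, mask, superpose, weights = masses)
  X <- t(vapply(seq_len(nf), function(k) as.numeric(t(sup$coords[, , k])),
                numeric(3 * m)))
  Xc <- sweep(X, 2, colMeans(X))
  sqm <- sqrt(rep(masses, each = 3))
  C <- crossprod(sweep(Xc, 2, sqm, "*")) / (nf - 1)  # amu nm^2
  lambda <- rev(sort(eigen(C, symmetric = TRUE, only.values = TRUE)$values))
  keep <- lambda > tol
  entropy_from_spectrum(lambda[keep], temperature, method,
                        n_modes_discarded = sum(!keep))
}

#' Closed-form entropy of a prescribed mass-weighted mode spectrum
#'
#' The analytic mode sum used both by [quasiharmonic_entropy()] (on the
#' sampled spectrum) and by the synthetic Gaussian-ensemble generator (on the
#' prescribed spectrum, as exact ground truth).
#'
#' @param lambda mass-weighted covariance eigenvalues, amu nm^2 (> 0).
#' @param temperature K.
#' @param method `"quasiharmonic"` or `"schlitter"`.
#' @param n_modes_discarded bookkeeping count stored in the result.
#' @return an `"entropy_result"` (see [quasiharmonic_entropy()]).
#' @export
entropy_from_spectrum <- function(lambda, temperature,
                                  method = c("quasiharmonic", "schlitter"),
                                  n_modes_discarded = 0L) {
  method <- match.arg(method)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  lambda <- as.numeric(lambda)
  stopifnot(all(lambda > 0))
  lam_si <- lambda * .const$amu * .const$nm2_m2      # kg m^2
  kT <- .const$kB * temperature
  omega <- sqrt(kT / lam_si)                          # rad s^-1
  total <- if (method == "quasiharmonic") {
    x <- .const$hbar * omega / kT
    .const$Rgas * sum(x / expm1(x) - log1p(-exp(-x)))
  } else {
    .const$Rgas / 2 *
      sum(log1p(kT * exp(1)^2 * lam_si / .const$hbar^2))
  }
  structure(
    list(total = total, mode_frequencies = omega,
         eigenvalues = lambda, n_modes_discarded = as.integer(n_modes_discarded),
         method = method, temperature = temperature),
    class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf(
    "%s configurational entropy: %.2f J mol^-1 K^-1 (%d modes, %d discarded, T = %g K)\n",
    x$method, x$total, length(x$eigenvalues), x$n_modes_discarded,
    x$temperature))
  invisible(x)
}

#' Gromos conformational clustering
#'
#' Greedy medoid clustering on the pairwise Kabsch-RMSD matrix of the masked
#' atoms: the frame with the most neighbours within `cutoff` becomes a
#' medoid, it and its neighbours form a cluster and are removed, and the
#' procedure repeats until no frames remain. Ties on the neighbour count go
#' to the lowest frame index, making the assignment deterministic.
#'
#' @param traj a non-empty [trajectory()].
#' @param mask atom indices (default: all atoms).
#' @param cutoff RMSD neighbour cutoff, nm (> 0). The field-standard value
#'   for domain-scale conformers is 0.2 nm.
#' @param stride cluster every `stride`-th frame.
#' @return list of class `"cluster_result"`: `assignment` (per selected
#'   frame, cluster id, 1 = largest), `medoids` (frame index per cluster),
#'   `sizes` (descending), `frames` (the selected frame indices).
#' @export
gromos_cluster <- function(traj, mask = NULL, cutoff = 0.2, stride = 1) {
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  if (n_frames(traj) < 1) stop("empty trajectory", call. = FALSE)
  if (is.null(mask)) mask <- seq_len(n_atoms(traj))
  frames <- as.integer(seq(1, n_frames(traj), by = stride))
  nf <- length(frames)
  D <- pairwise_rmsd_matrix(traj, mask, frames)
  adj <- D <= cutoff
  remaining <- rep(TRUE, nf)
  assignment <- integer(nf)
  medoids <- integer(0)
  sizes <- integer(0)
  cl <- 0L
  while (any(remaining)) {
    counts <- ifelse(remaining, rowSums(adj[, remaining, drop = FALSE]), -1L)
    center <- which.max(counts)  # which.max takes the first (lowest index) tie
    members <- which(remaining & adj[center, ])
    cl <- cl + 1L
    assignment[members] <- cl
    medoids[cl] <- frames[center]
    sizes[cl] <- length(members)
    remaining[members] <- FALSE
  }
  structure(
    list(assignment = assignment, medoids = medoids, sizes = sizes,
         frames = frames, cutoff = cutoff),
    class = "cluster_result")
}

# Symmetric matrix of Kabsch RMSDs between the masked coordinates of the
# given frames.
pairwise_rmsd_matrix <- function(traj, mask, frames = seq_len(n_frames(traj))) {
  nf <- length(frames)
  xs <- lapply(frames, function(k) frame_coords(traj, k, mask))
  D <- matrix(0, nf, nf)
  if (nf > 1) {
    for (i in 1:(nf - 1)) {
      for (j in (i + 1):nf) {
        D[i, j] <- D[j, i] <- fit_rmsd(xs[[i]], xs[[j]])
      }
    }
  }
  D
}
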