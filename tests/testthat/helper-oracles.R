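# Independent oracles used to cross-check the implementation. These are
# deliberately different algorithms from the ones in R/, not refactorings.

# Quaternion-based optimal RMSD (Kearsley 1989): the smallest eigenvalue of
# the 4x4 key matrix equals the best-fit residual sum of squares.
kearsley_rmsd <- function(mobile, reference) {
  n <- nrow(mobile)
  xm <- scale(mobile, scale = FALSE)
  xr <- scale(reference, scale = FALSE)
  d <- xm - xr
  s <- xm + xr
  xd <- d[, 1]; yd <- d[, 2]; zd <- d[, 3]
  xs <- s[, 1]; ys <- s[, 2]; zs <- s[, 3]
  K <- matrix(0, 4, 4)
  K[1, 1] <- sum(xd^2 + yd^2 + zd^2)
  K[1, 2] <- K[2, 1] <- sum(ys * zd - yd * zs)
  K[1, 3] <- K[3, 1] <- sum(xd * zs - xs * zd)
  K[1, 4] <- K[4, 1] <- sum(xs * yd - xd * ys)
  K[2, 2] <- sum(ys^2 + zs^2 + xd^2)
  K[2, 3] <- K[3, 2] <- sum(xd * yd - xs * ys)
  K[2, 4] <- K[4, 2] <- sum(xd * zd - xs * zs)
  K[3, 3] <- sum(xs^2 + zs^2 + yd^2)
  K[3, 4] <- K[4, 3] <- sum(yd * zd - ys * zs)
  K[4, 4] <- sum(xs^2 + ys^2 + zd^2)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(min(ev), 0) / n)
}

# Random proper rotation matrix (QR of a Gaussian matrix, det fixed to +1).
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Brute-force gromos clustering over a precomputed distance matrix: a
# straight transcription of the algorithm, independent of gromos_cluster().
brute_gromos <- function(D, cutoff) {
  nf <- nrow(D)
  adj <- D <= cutoff
  live <- rep(TRUE, nf)
  assignment <- integer(nf)
  medoids <- integer(0)
  cl <- 0L
  while (any(live)) {
    best <- -1L; best_i <- 0L
    for (i in seq_len(nf)) {
      if (!live[i]) next
      cnt <- sum(adj[i, ] & live)
      if (cnt > best) { best <- cnt; best_i <- i }  # first max = lowest index
    }
    members <- which(live & adj[best_i, ])
    cl <- cl + 1L
    assignment[members] <- cl
    medoids[cl] <- best_i
    live[members] <- FALSE
  }
  list(assignment = assignment, medoids = medoids,
       sizes = as.integer(tabulate(assignment)))
}

# Pairwise RMSD matrix computed with the quaternion oracle.
oracle_rmsd_matrix <- function(traj, mask, frames = seq_len(n_frames(traj))) {
  xs <- lapply(frames, function(k) frame_coords(traj, k, mask))
  nf <- length(xs)
  D <- matrix(0, nf, nf)
  if (nf > 1) {
    for (i in 1:(nf - 1)) for (j in (i + 1):nf) {
      D[i, j] <- D[j, i] <- kearsley_rmsd(xs[[i]], xs[[j]])
    }
  }
  D
}

# Reference pair with an exact midpoint symmetry. With C a 180-degree
# rotation (C^2 = I) and pi an atom-relabeling involution, set
# B_i = C A_{pi(i)}. Then the proper rigid map C together with relabeling pi
# exchanges A and B while fixing every point of the linear interpolation
# midpoint, so RMSD(mid, A) = RMSD(mid, B) exactly and the noise-free
# delta-RMSD along the linear path is an odd function about f = 0.5.
symmetric_reference_pair <- function(n = 12, seed = 101) {
  set.seed(seed)
  A <- matrix(rnorm(n * 3), n, 3)
  C180 <- diag(c(-1, -1, 1))
  B <- A[n:1, , drop = FALSE] %*% C180   # pi = reversal (an involution)
  top <- topology(seq_len(n), rep("CA", n), "ALA", seq_len(n), "A")
  list(open = A, closed = B, topology = top,
       pair = reference_pair(A, B, seq_len(n), seq_len(n), seq_len(n)))
}

# Donor/hydrogen/acceptor probe with a prescribed D-H-A angle (degrees);
# the donor-acceptor distance follows from the geometry and stays inside
# the 0.35 nm cutoff for all angles used in the tests.
hbond_probe_traj <- function(angles_deg, dha = 0.1, ha = 0.19) {
  top <- topology(1:3, c("OD1", "H", "NE2"), c("ASP", "ASP", "HIS"),
                  c(1L, 1L, 2L), "A", element = c("O", "H", "N"))
  nf <- length(angles_deg)
  coords <- array(0, dim = c(3, 3, nf))
  for (k in seq_len(nf)) {
    th <- angles_deg[k] * pi / 180
    coords[1, , k] <- c(-dha, 0, 0)                      # donor
    coords[2, , k] <- c(0, 0, 0)                         # hydrogen
    coords[3, , k] <- ha * c(-cos(th), sin(th), 0)       # acceptor
  }
  trajectory(top, coords)
}

# Small toy dipeptide topology used across structio tests.
toy_topology <- function() {
  topology(
    serial = 1:7,
    name = c("N", "CA", "C", "O", "N", "CA", "NE1"),
    resname = c(rep("ALA", 4), "TRP", "TRP", "TRP"),
    resid = c(1L, 1L, 1L, 1L, 755L, 755L, 755L),
    chain = c("A", "A", "A", "A", "A", "A", "A"))
}

toy_trajectory <- function(n_frames = 4, seed = 42) {
  set.seed(seed)
  top <- toy_topology()
  coords <- array(rnorm(7 * 3 * n_frames, sd = 0.3), dim = c(7, 3, n_frames))
  trajectory(top, coords)
}
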