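# Neighbour searches shared by the solvation analyses. Both routes answer
# "which query points lie within `cutoff` (inclusive) of at least one target
# point" and must agree exactly; the cell list is the fast path, brute force
# the reference and fallback.

#' Query points within a cutoff of any target point
#'
#' @param query `nq x 3` coordinates (nm).
#' @param target `nt x 3` coordinates (nm).
#' @param cutoff distance cutoff, nm; the boundary is inclusive (`<=`).
#' @param box `NULL` or orthorhombic box lengths `(lx, ly, lz)` for
#'   minimum-image distances.
#' @param method `"cell"` for a grid (cell-list) search, `"brute"` for the
#'   all-pairs reference.
#' @return logical vector of length `nq`.
#' @export
within_cutoff_any <- function(query, target, cutoff, box = NULL,
                              method = c("cell", "brute")) {
  method <- match.arg(method)
  query <- as.matrix(query); target <- as.matrix(target)
  if (!nrow(query)) return(logical(0))
  if (!nrow(target)) return(rep(FALSE, nrow(query)))
  if (method == "brute") {
    return(brute_within(query, target, cutoff, box))
  }
  cell_within(query, target, cutoff, box)
}

brute_within <- function(query, target, cutoff, box = NULL) {
  c2 <- cutoff^2
  apply_min <- function(q) {
    d <- sweep(target, 2, q)
    if (!is.null(box)) d <- minimum_image(d, box)
    min(rowSums(d * d))
  }
  vapply(seq_len(nrow(query)),
         function(i) apply_min(query[i, ]) <= c2, logical(1))
}

cell_within <- function(query, target, cutoff, box = NULL) {
  nq <- nrow(query)
  if (!is.null(box)) {
    # wrap into [0, L); cells wrap modulo the grid
    query_w <- sweep(query, 2, box, function(x, l) x - floor(x / l) * l)
    target_w <- sweep(target, 2, box, function(x, l) x - floor(x / l) * l)
    ncell <- pmax(1L, floor(box / cutoff))
    width <- box / ncell
    origin <- c(0, 0, 0)
    wrap <- TRUE
  } else {
    origin <- pmin(apply(query, 2, min), apply(target, 2, min))
    extent <- pmax(apply(query, 2, max), apply(target, 2, max)) - origin
    ncell <- pmax(1L, pmin(floor(extent / cutoff) + 1L, 64L))
    width <- pmax(extent / ncell, cutoff)
    ncell <- pmax(1L, floor(extent / width) + 1L)
    query_w <- query; target_w <- target
    wrap <- FALSE
  }
  cell_of <- function(xyz) {
    ix <- pmin(pmax(floor(sweep(sweep(xyz, 2, origin), 2, width, "/")), 0),
               matrix(ncell - 1L, nrow(xyz), 3, byrow = TRUE))
    ix[, 1] + ncell[1] * (ix[, 2] + ncell[2] * ix[, 3]) + 1L
  }
  tcell <- cell_of(target_w)
  tindex <- split(seq_len(nrow(target_w)), tcell)
  qidx3 <- floor(sweep(sweep(query_w, 2, origin), 2, width, "/"))
  qidx3 <- pmin(pmax(qidx3, 0), matrix(ncell - 1L, nq, 3, byrow = TRUE))
  res <- logical(nq)
  c2 <- cutoff^2
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  # group queries by cell so the 27-cell gather happens once per occupied cell
  qcell_key <- qidx3[, 1] + ncell[1] * (qidx3[, 2] + ncell[2] * qidx3[, 3])
  for (grp in split(seq_len(nq), qcell_key)) {
    base <- qidx3[grp[1], ]
    neigh <- sweep(offsets, 2, base, "+")
    if (wrap) {
      neigh <- sweep(neigh, 2, ncell, function(i, n) ((i %% n) + n) %% n)
    } else {
      ok <- neigh[, 1] >= 0 & neigh[, 1] < ncell[1] &
            neigh[, 2] >= 0 & neigh[, 2] < ncell[2] &
            neigh[, 3] >= 0 & neigh[, 3] < ncell[3]
      neigh <- neigh[ok, , drop = FALSE]
    }
    keys <- unique(neigh[, 1] + ncell[1] * (neigh[, 2] + ncell[2] * neigh[, 3]) + 1L)
    cand <- unlist(tindex[as.character(keys)], use.names = FALSE)
    if (!length(cand)) next
    tc <- target_w[cand, , drop = FALSE]
    for (i in grp) {
      d <- sweep(tc, 2, query_w[i, ])
      if (!is.null(box)) d <- minimum_image(d, box)
      res[i] <- min(rowSums(d * d)) <= c2
    }
  }
  res
}

# Distances from each row of `points` to a single point `p` (1 x 3).
point_distances <- function(points, p, box = NULL) {
  d <- sweep(as.matrix(points), 2, as.numeric(p))
  if (!is.null(box)) d <- minimum_image(d, box)
  sqrt(rowSums(d * d))
}
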