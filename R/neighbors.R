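#' Minimum-image convention
#'
#' Returns the shortest periodic image of a displacement vector (or of each
#' row of a matrix of displacements) under a triclinic cell. The search
#' covers the 27 images adjacent to the rounded fractional displacement,
#' which is exact whenever the shortest image lies within one cell of the
#' naive wrap — always true for cells used with cutoffs at or below the safe
#' half-width enforced by [build_neighbor_list()].
#'
#' @param delta numeric 3-vector or N x 3 matrix of displacements (Angstrom).
#' @param cell 3x3 matrix of lattice vectors (rows).
#' @return object of the same shape as `delta`.
#' @export
minimum_image <- function(delta, cell) {
  vec <- is.null(dim(delta))
  d <- if (vec) matrix(delta, nrow = 1L) else as.matrix(delta)
  cell <- as.matrix(cell)
  if (abs(det(cell)) < 1e-10) stop("cell is not invertible")
  inv <- solve(cell)
  f <- d %*% inv
  f <- f - round(f)
  base <- f %*% cell
  best <- base
  bestd2 <- rowSums(base * base)
  for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
    if (sx == 0 && sy == 0 && sz == 0) next
    shift <- c(sx, sy, sz) %*% cell
    cand <- sweep(base, 2L, -as.numeric(shift))
    d2 <- rowSums(cand * cand)
    take <- d2 < bestd2 - 1e-300
    if (any(take)) {
      best[take, ] <- cand[take, , drop = FALSE]
      bestd2[take] <- d2[take]
    }
  }
  if (vec) as.numeric(best) else best
}

## perpendicular widths of a cell: distance between opposite faces
cell_widths <- function(cell) {
  inv <- solve(cell)
  1 / sqrt(colSums(inv^2))
}

#' Build a periodic-boundary-aware neighbor list
#'
#' All pairs of points with (minimum-image) distance at or below `cutoff`.
#' For periodic systems the cutoff must not exceed half the smallest
#' perpendicular cell width; beyond that the minimum-image convention is
#' ambiguous and an error is raised rather than silently replicating images.
#'
#' @param points N x 3 matrix of Cartesian coordinates (Angstrom).
#' @param cell optional 3x3 cell matrix; `NULL` for non-periodic systems.
#' @param cutoff positive cutoff radius (Angstrom).
#' @return a `neighbor_list`: list with `center_ids`, `neighbor_ids` (ragged
#'   list, 1-based), `displacements` (list of n_i x 3 matrices, minimum
#'   image, pointing center -> neighbor), `distances` and `cutoff`.
#' @export
build_neighbor_list <- function(points, cell = NULL, cutoff) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (cutoff <= 0) stop("cutoff must be positive")
  if (!is.null(cell)) {
    w <- cell_widths(cell)
    if (cutoff > min(w) / 2 + 1e-9)
      stop(sprintf(paste0("cutoff %.3f A exceeds the safe half-width %.3f A ",
                          "of the periodic cell; reduce the cutoff or ",
                          "enlarge the cell"), cutoff, min(w) / 2))
  }
  nbrs <- vector("list", n)
  disp <- vector("list", n)
  dist <- vector("list", n)
  if (n > 1L) {
    for (i in seq_len(n)) {
      d <- sweep(points, 2L, points[i, ])      # r_j - r_i
      if (!is.null(cell)) d <- minimum_image(d, cell)
      dd <- sqrt(rowSums(d * d))
      sel <- which(dd <= cutoff & seq_len(n) != i)
      nbrs[[i]] <- sel
      disp[[i]] <- d[sel, , drop = FALSE]
      dist[[i]] <- dd[sel]
    }
  } else {
    nbrs <- list(integer(0)); disp <- list(matrix(0, 0, 3)); dist <- list(numeric(0))
  }
  structure(list(center_ids = seq_len(n), neighbor_ids = nbrs,
                 displacements = disp, distances = dist, cutoff = cutoff),
            class = "neighbor_list")
}

#' @export
print.neighbor_list <- function(x, ...) {
  cat("<neighbor_list> ", length(x$center_ids), " centers, ",
      sum(lengths(x$neighbor_ids)), " directed pairs, cutoff ",
      x$cutoff, " A\n", sep = "")
  invisible(x)
}

#' Edge list of atom pairs within a cutoff
#'
#' Directed edges (both orientations) between all distinct atoms of a frame
#' with minimum-image distance at or below `r_c`. Used to build molecule
#' graphs for the graph classifier.
#'
#' @param frame a [simulation_frame()].
#' @param r_c cutoff (Angstrom).
#' @return list with integer vectors `src`, `dst` and numeric `dist`.
#' @export
frame_edges <- function(frame, r_c) {
  nl <- build_neighbor_list(frame$positions,
                            if (any(frame$pbc)) frame$cell else NULL, r_c)
  src <- rep(nl$center_ids, lengths(nl$neighbor_ids))
  dst <- unlist(nl$neighbor_ids, use.names = FALSE)
  dist <- unlist(nl$distances, use.names = FALSE)
  ## directed edge j -> i carries information from src j into dst i
  list(src = dst, dst = src, dist = dist)
}
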