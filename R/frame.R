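#' Construct a simulation frame
#'
#' A `simulation_frame` holds one trajectory snapshot: Cartesian atomic
#' positions in Angstrom, chemical element codes, an optional periodic cell
#' (3x3 matrix whose *rows* are the lattice vectors), per-dimension
#' periodicity flags, and an integer molecule id per atom.
#'
#' @param positions numeric N x 3 matrix of Cartesian coordinates (Angstrom).
#' @param atom_types character vector of length N with element codes.
#' @param cell 3x3 numeric matrix of lattice vectors (rows), or `NULL` for a
#'   non-periodic (cluster) frame.
#' @param pbc logical vector of length 3; ignored (all `FALSE`) when `cell`
#'   is `NULL`.
#' @param molecule_ids integer vector of length N assigning each atom to a
#'   molecule (0-based or 1-based accepted; stored as given), or `NULL` when
#'   unknown.
#' @param frame_index integer index of the frame within its trajectory.
#' @param time simulation time in ps, or `NA`.
#' @return an object of class `simulation_frame`.
#' @export
simulation_frame <- function(positions, atom_types, cell = NULL,
                             pbc = !is.null(cell) & c(TRUE, TRUE, TRUE),
                             molecule_ids = NULL, frame_index = 0L,
                             time = NA_real_) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L)
    stop("positions must be an N x 3 matrix")
  storage.mode(positions) <- "double"
  if (!all(is.finite(positions)))
    stop("positions must be finite")
  n <- nrow(positions)
  atom_types <- as.character(atom_types)
  if (length(atom_types) != n)
    stop("atom_types length (", length(atom_types),
         ") does not match atom count (", n, ")")
  if (!is.null(cell)) {
    cell <- as.matrix(cell)
    if (!all(dim(cell) == c(3L, 3L)))
      stop("cell must be a 3x3 matrix")
    storage.mode(cell) <- "double"
    if (abs(det(cell)) < 1e-10)
      stop("cell is not invertible (det ~ 0)")
  }
  pbc <- as.logical(pbc)
  if (length(pbc) == 1L) pbc <- rep(pbc, 3L)
  if (is.null(cell)) pbc <- c(FALSE, FALSE, FALSE)
  if (!is.null(molecule_ids)) {
    molecule_ids <- as.integer(molecule_ids)
    if (length(molecule_ids) != n)
      stop("molecule_ids length does not match atom count")
  }
  structure(list(positions = positions, atom_types = atom_types,
                 cell = cell, pbc = pbc, molecule_ids = molecule_ids,
                 frame_index = as.integer(frame_index),
                 time = as.numeric(time)),
            class = "simulation_frame")
}

#' @export
print.simulation_frame <- function(x, ...) {
  cat("<simulation_frame> ", nrow(x$positions), " atoms", sep = "")
  if (!is.null(x$molecule_ids))
    cat(", ", length(unique(x$molecule_ids)), " molecules", sep = "")
  if (is.null(x$cell)) cat(", non-periodic")
  else cat(", periodic cell det = ", signif(det(x$cell), 4), " A^3", sep = "")
  cat("\n")
  invisible(x)
}

#' Number of atoms in a frame
#' @param frame a `simulation_frame`
#' @return integer atom count
#' @export
n_atoms <- function(frame) nrow(frame$positions)

known_elements <- function() {
  c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg",
    "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Br", "I", "Fe", "Zn")
}

check_elements <- function(types, where = "frame") {
  bad <- setdiff(unique(types), known_elements())
  if (length(bad))
    stop("unknown element code(s) in ", where, ": ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}
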