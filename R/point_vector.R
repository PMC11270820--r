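#' Point-vector molecule template
#'
#' Reduces a rigid molecule to one position point and one or more
#' intramolecular orientation vectors. The position is a selected atom of
#' the molecule (optionally the center of geometry), and each vector slot
#' `s` is defined by a pair of atoms within the molecule.
#'
#' @param position_atom 1-based index of the position atom within the
#'   molecule's template atom ordering, or the string `"com"` for the
#'   center of geometry.
#' @param vector_specs list of integer pairs `c(from, to)` (1-based template
#'   indices), one per vector slot.
#' @return a `pv_template` object.
#' @export
pv_template <- function(position_atom = 1L, vector_specs = list()) {
  if (!identical(position_atom, "com")) position_atom <- as.integer(position_atom)
  vector_specs <- lapply(vector_specs, function(p) as.integer(p[1:2]))
  structure(list(position_atom = position_atom, vector_specs = vector_specs),
            class = "pv_template")
}

#' Validate a point-vector template against a molecule size
#'
#' Report-returning: collects problems rather than raising.
#'
#' @param template a [pv_template()].
#' @param molecule_size atoms per molecule.
#' @return character vector of problems (empty when valid).
#' @export
validate_template <- function(template, molecule_size) {
  problems <- character(0)
  pa <- template$position_atom
  if (!identical(pa, "com") && (pa < 1L || pa > molecule_size))
    problems <- c(problems, sprintf("position_atom %d out of range [1, %d]",
                                    pa, molecule_size))
  seen <- character(0)
  for (s in seq_along(template$vector_specs)) {
    p <- template$vector_specs[[s]]
    if (p[1] == p[2])
      problems <- c(problems,
                    sprintf("vector slot %d: from_atom == to_atom (%d)", s, p[1]))
    if (any(p < 1L | p > molecule_size))
      problems <- c(problems,
                    sprintf("vector slot %d: index out of range [1, %d]",
                            s, molecule_size))
    key <- paste(p, collapse = "-")
    if (key %in% seen)
      problems <- c(problems, sprintf("vector slot %d duplicates pair %s", s, key))
    seen <- c(seen, key)
  }
  problems
}

#' Extract point-vector representations for all molecules of a frame
#'
#' Intramolecular separations are unwrapped by the minimum image relative to
#' the position atom, so molecules split across periodic boundaries are
#' handled as long as they are smaller than half the cell. Orientation
#' vectors are normalized to unit length: the orientational symmetry
#' functions depend only on angles, and normalization makes them insensitive
#' to bond-length noise.
#'
#' @param frame a [simulation_frame()].
#' @param groups output of [group_molecules()].
#' @param template a [pv_template()].
#' @return list of `pv_molecule` objects with `molecule_id`, `r_I`
#'   (3-vector, Angstrom) and `v` (list of unit 3-vectors, one per slot).
#' @export
extract_point_vectors <- function(frame, groups, template) {
  cell <- if (any(frame$pbc)) frame$cell else NULL
  lapply(groups, function(g) {
    at <- g$atom_indices
    coords <- frame$positions[at, , drop = FALSE]
    anchor_idx <- if (identical(template$position_atom, "com")) 1L
                  else template$position_atom
    if (anchor_idx > nrow(coords))
      stop("template position atom index exceeds molecule size for molecule ",
           g$molecule_id)
    anchor <- coords[anchor_idx, ]
    local <- sweep(coords, 2L, anchor)
    if (!is.null(cell)) local <- minimum_image(local, cell)
    unwrapped <- sweep(local, 2L, -anchor)   # unwrapped absolute coords
    r_I <- if (identical(template$position_atom, "com"))
      colMeans(unwrapped) else anchor
    v <- lapply(seq_along(template$vector_specs), function(s) {
      p <- template$vector_specs[[s]]
      vec <- unwrapped[p[2], ] - unwrapped[p[1], ]
      nrm <- sqrt(sum(vec^2))
      if (nrm < 1e-8)
        stop("degenerate orientation vector (slot ", s, ") in molecule ",
             g$molecule_id, ": defining atoms coincide")
      vec / nrm
    })
    structure(list(molecule_id = g$molecule_id, r_I = r_I, v = v),
              class = "pv_molecule")
  })
}

#' Positions of point-vector molecules as a matrix
#' @param pv list of `pv_molecule` objects.
#' @return M x 3 matrix of molecule positions.
#' @export
pv_positions <- function(pv) {
  do.call(rbind, lapply(pv, `[[`, "r_I"))
}
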