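#' Group the atoms of a frame into molecules
#'
#' When the frame carries molecule ids they are honored (atoms of each
#' molecule are kept in frame order, which is assumed to follow the template
#' ordering). Otherwise atoms are grouped in contiguous blocks of
#' `molecule_size` — molecular dynamics engines preserve molecule blocks.
#' Distance-based bond perception is deliberately not attempted.
#'
#' @param frame a [simulation_frame()].
#' @param molecule_size atoms per molecule, used when the frame has no
#'   molecule ids (or to cross-check when it does).
#' @param template optional character vector giving the expected element
#'   sequence of one molecule; a mismatch in composition raises an error
#'   naming the offending molecule.
#' @return list of `molecule_group` objects, each with `molecule_id`
#'   (0-based), `atom_indices` (1-based frame indices) and
#'   `species_signature`.
#' @export
group_molecules <- function(frame, molecule_size = NULL, template = NULL) {
  n <- n_atoms(frame)
  if (!is.null(frame$molecule_ids)) {
    ids <- frame$molecule_ids
    uid <- sort(unique(ids))
    groups <- lapply(seq_along(uid), function(k) {
      at <- which(ids == uid[k])
      list(molecule_id = k - 1L, atom_indices = at,
           species_signature = sort(frame$atom_types[at]))
    })
  } else {
    if (is.null(molecule_size)) {
      if (is.null(template))
        stop("need molecule_size or template when the frame has no molecule ids")
      molecule_size <- length(template)
    }
    if (n %% molecule_size != 0L)
      stop("atom count ", n, " is not divisible by molecule_size ",
           molecule_size)
    nm <- n %/% molecule_size
    groups <- lapply(seq_len(nm), function(k) {
      at <- ((k - 1L) * molecule_size + 1L):(k * molecule_size)
      list(molecule_id = k - 1L, atom_indices = at,
           species_signature = sort(frame$atom_types[at]))
    })
  }
  if (!is.null(template)) {
    want <- sort(as.character(template))
    for (g in groups) {
      if (!identical(g$species_signature, want))
        stop("molecule ", g$molecule_id, " has composition {",
             paste(g$species_signature, collapse = ","),
             "} but the template expects {",
             paste(want, collapse = ","), "}")
    }
  }
  lapply(groups, function(g) structure(g, class = "molecule_group"))
}
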