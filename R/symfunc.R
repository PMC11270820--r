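#' Smooth cosine cutoff function
#'
#' `f_c(r) = 0.5 * (cos(pi * r / r_c) + 1)` for `r <= r_c`, 0 beyond — the
#' canonical companion of Behler-Parrinello symmetry functions. It equals 1
#' at r = 0, decays smoothly, and is continuously differentiable at the
#' cutoff, so descriptors change smoothly as neighbors cross `r_c`.
#'
#' @param r distances (Angstrom), vectorized.
#' @param r_c cutoff radius (Angstrom).
#' @return values in `[0, 1]`.
#' @export
cutoff_fn <- function(r, r_c) {
  if (r_c <= 0) stop("r_c must be positive")
  if (any(r < 0)) stop("negative distance passed to cutoff_fn")
  ifelse(r < r_c, 0.5 * (cos(pi * r / r_c) + 1), 0)
}

sf_kinds <- c("radial_gaussian", "radial_cosine", "orient_a", "orient_b")

#' Symmetry-function parameter record
#'
#' One entry of a descriptor set. `kind` selects the functional family and
#' determines which tunable parameters are read:
#' \describe{
#'   \item{radial_gaussian}{`sum_J exp(-eta (|r_IJ| - R_s)^2) f_c(|r_IJ|)`;
#'     uses `eta` (1/A^2), `R_s` (A).}
#'   \item{radial_cosine}{`sum_J cos(kappa |r_IJ|) f_c(|r_IJ|)`; uses
#'     `kappa` (1/A).}
#'   \item{orient_a}{`sum_J exp(-eta (cos theta^s_IJ - cos_theta_S)^2)
#'     f_c(|r_IJ|)` with `theta^s_IJ` the angle between slot-`s` vectors on
#'     molecules I and J; uses `eta`, `cos_theta_S`, `vector_slot`.}
#'   \item{orient_b}{`sum_J cos(kappa (cos theta^s_IJ - cos_theta_S))
#'     f_c(|r_IJ|)`; uses `kappa`, `cos_theta_S`, `vector_slot`.}
#' }
#'
#' @param kind one of `radial_gaussian`, `radial_cosine`, `orient_a`,
#'   `orient_b`.
#' @param eta Gaussian width parameter (1/A^2 radially, unitless on cosines).
#' @param R_s radial shift (Angstrom).
#' @param kappa wavenumber (1/A radially, unitless on cosines).
#' @param cos_theta_S angular center in `[-1, 1]`.
#' @param r_c cutoff radius (Angstrom), required.
#' @param vector_slot 1-based orientation-vector slot (orientational kinds).
#' @return an `sf_params` object.
#' @export
sf_params <- function(kind, eta = NA_real_, R_s = NA_real_, kappa = NA_real_,
                      cos_theta_S = NA_real_, r_c, vector_slot = NA_integer_) {
  kind <- match.arg(kind, sf_kinds)
  if (r_c <= 0) stop("r_c must be positive")
  need <- switch(kind,
                 radial_gaussian = c(eta = eta, R_s = R_s),
                 radial_cosine = c(kappa = kappa),
                 orient_a = c(eta = eta, cos_theta_S = cos_theta_S,
                              vector_slot = vector_slot),
                 orient_b = c(kappa = kappa, cos_theta_S = cos_theta_S,
                              vector_slot = vector_slot))
  if (anyNA(need) || any(!is.finite(need)))
    stop("kind '", kind, "' requires finite parameter(s): ",
         paste(names(need)[!is.finite(need)], collapse = ", "))
  if (!is.na(cos_theta_S) && abs(cos_theta_S) > 1)
    stop("cos_theta_S must lie in [-1, 1]")
  structure(list(kind = kind, eta = eta, R_s = R_s, kappa = kappa,
                 cos_theta_S = cos_theta_S, r_c = r_c,
                 vector_slot = as.integer(vector_slot)),
            class = "sf_params")
}

sf_feature_name <- function(p) {
  switch(p$kind,
         radial_gaussian = sprintf("G_rad.eta%g.Rs%g.rc%g", p$eta, p$R_s, p$r_c),
         radial_cosine = sprintf("G_cos.k%g.rc%g", p$kappa, p$r_c),
         orient_a = sprintf("G_oa.s%d.eta%g.cS%g.rc%g", p$vector_slot, p$eta,
                            p$cos_theta_S, p$r_c),
         orient_b = sprintf("G_ob.s%d.k%g.cS%g.rc%g", p$vector_slot, p$kappa,
                            p$cos_theta_S, p$r_c))
}

#' Assemble a descriptor set
#'
#' @param entries list of [sf_params()] records; order is fixed and is part
#'   of any trained model (a checksum binds models to their set).
#' @return a `descriptor_set` with `entries` and `feature_names`.
#' @export
descriptor_set <- function(entries) {
  stopifnot(length(entries) > 0, all(vapply(entries, inherits, TRUE, "sf_params")))
  structure(list(entries = entries,
                 feature_names = vapply(entries, sf_feature_name, character(1))),
            class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat("<descriptor_set> ", length(x$entries), " symmetry functions\n", sep = "")
  invisible(x)
}

#' Length of a descriptor set
#' @param set a [descriptor_set()]
#' @return integer number of features
#' @export
descriptor_length <- function(set) length(set$entries)

#' Checksum binding a model to its descriptor set
#' @param set a [descriptor_set()]
#' @return character md5 hash
#' @export
descriptor_set_hash <- function(set) {
  digest::digest(lapply(set$entries, unclass), algo = "md5")
}

#' Default 24-entry descriptor set
#'
#' Eight radial Gaussians on an `R_s` grid from 1 to 7 A, four radial
#' cosines on a `kappa` grid, and six entries each of the two orientational
#' families split over two vector slots: 24 molecular symmetry functions in
#' total. The published parameter tables live in supplementary material not
#' bundled here; this set reproduces the schema, count and length scales
#' and works well on the bundled fixtures. Real systems should supply their
#' own table (see [read_descriptor_config()]).
#'
#' @param r_c cutoff radius used for every entry (Angstrom).
#' @param n_slots number of orientation-vector slots available (>= 2).
#' @return a [descriptor_set()] with 24 entries.
#' @export
default_descriptor_set <- function(r_c = 8, n_slots = 2L) {
  stopifnot(n_slots >= 2L)
  entries <- list()
  for (R_s in seq(1, 7, length.out = 8))
    entries <- c(entries, list(sf_params("radial_gaussian", eta = 2,
                                         R_s = R_s, r_c = r_c)))
  for (kappa in c(0.5, 1.0, 1.5, 2.0))
    entries <- c(entries, list(sf_params("radial_cosine", kappa = kappa,
                                         r_c = r_c)))
  for (s in 1:2) for (cS in c(-1, 0, 1))
    entries <- c(entries, list(sf_params("orient_a", eta = 4, cos_theta_S = cS,
                                         r_c = r_c, vector_slot = s)))
  for (s in 1:2) for (kp in c(1, 2, 4))
    entries <- c(entries, list(sf_params("orient_b", kappa = kp,
                                         cos_theta_S = 1, r_c = r_c,
                                         vector_slot = s)))
  descriptor_set(entries)
}

## angular cosines between slot-s vectors of the center and its neighbors
slot_cosines <- function(center, neighbors, slot) {
  if (slot > length(center$v))
    stop("vector slot ", slot, " not present on molecule ",
         center$molecule_id)
  vI <- center$v[[slot]]
  vapply(neighbors, function(nb) {
    if (slot > length(nb$v))
      stop("vector slot ", slot, " not present on molecule ", nb$molecule_id)
    ct <- sum(vI * nb$v[[slot]])
    max(-1, min(1, ct))
  }, numeric(1))
}

#' Radial Gaussian symmetry function (one molecule)
#'
#' @param center a `pv_molecule` (unused by radial kinds; kept for a uniform
#'   signature).
#' @param displacements n x 3 matrix of minimum-image displacement vectors
#'   center -> neighbor (Angstrom).
#' @param params [sf_params()] with `kind = "radial_gaussian"`.
#' @return scalar value.
#' @export
radial_gaussian_sf <- function(center, displacements, params) {
  stopifnot(params$kind == "radial_gaussian")
  if (NROW(displacements) == 0L) return(0)
  d <- sqrt(rowSums(as.matrix(displacements)^2))
  sum(exp(-params$eta * (d - params$R_s)^2) * cutoff_fn(d, params$r_c))
}

#' Radial cosine symmetry function (one molecule)
#' @inheritParams radial_gaussian_sf
#' @param params [sf_params()] with `kind = "radial_cosine"`.
#' @return scalar value.
#' @export
radial_cosine_sf <- function(center, displacements, params) {
  stopifnot(params$kind == "radial_cosine")
  if (NROW(displacements) == 0L) return(0)
  d <- sqrt(rowSums(as.matrix(displacements)^2))
  sum(cos(params$kappa * d) * cutoff_fn(d, params$r_c))
}

#' Orientational symmetry function, Gaussian-in-cosine family
#'
#' @param center a `pv_molecule`.
#' @param neighbors list of neighboring `pv_molecule`s.
#' @param displacements n x 3 matrix, center -> neighbor.
#' @param params [sf_params()] with `kind = "orient_a"`.
#' @return scalar value.
#' @export
orient_a_sf <- function(center, neighbors, displacements, params) {
  stopifnot(params$kind == "orient_a")
  if (length(neighbors) == 0L) return(0)
  d <- sqrt(rowSums(as.matrix(displacements)^2))
  ct <- slot_cosines(center, neighbors, params$vector_slot)
  sum(exp(-params$eta * (ct - params$cos_theta_S)^2) * cutoff_fn(d, params$r_c))
}

#' Orientational symmetry function, cosine family
#' @inheritParams orient_a_sf
#' @param params [sf_params()] with `kind = "orient_b"`.
#' @return scalar value.
#' @export
orient_b_sf <- function(center, neighbors, displacements, params) {
  stopifnot(params$kind == "orient_b")
  if (length(neighbors) == 0L) return(0)
  d <- sqrt(rowSums(as.matrix(displacements)^2))
  ct <- slot_cosines(center, neighbors, params$vector_slot)
  sum(cos(params$kappa * (ct - params$cos_theta_S)) * cutoff_fn(d, params$r_c))
}

eval_sf <- function(center, neighbors, displacements, params) {
  switch(params$kind,
         radial_gaussian = radial_gaussian_sf(center, displacements, params),
         radial_cosine = radial_cosine_sf(center, displacements, params),
         orient_a = orient_a_sf(center, neighbors, displacements, params),
         orient_b = orient_b_sf(center, neighbors, displacements, params))
}

#' Compute per-molecule descriptor vectors
#'
#' Evaluates every symmetry function of `set` for every molecule, using a
#' molecule-level neighbor list. The sums run over neighbor molecules only
#' (J != I), truncated by each entry's cutoff.
#'
#' @param pv list of `pv_molecule` objects (one frame).
#' @param nlist [build_neighbor_list()] over the molecule positions; its
#'   cutoff must cover the largest `r_c` of the set.
#' @param set a [descriptor_set()].
#' @return numeric matrix, molecules x features, with `feature_names` as
#'   column names and molecule ids as row names.
#' @export
compute_descriptors <- function(pv, nlist, set) {
  max_rc <- max(vapply(set$entries, `[[`, 0, "r_c"))
  if (nlist$cutoff < max_rc - 1e-9)
    stop("neighbor-list cutoff (", nlist$cutoff,
         " A) is smaller than the largest symmetry-function cutoff (",
         max_rc, " A)")
  M <- length(pv)
  stopifnot(length(nlist$center_ids) == M)
  out <- matrix(0, M, descriptor_length(set),
                dimnames = list(vapply(pv, `[[`, 0L, "molecule_id"),
                                set$feature_names))
  for (i in seq_len(M)) {
    nb_ids <- nlist$neighbor_ids[[i]]
    disp <- nlist$displacements[[i]]
    nbs <- pv[nb_ids]
    for (k in seq_along(set$entries))
      out[i, k] <- eval_sf(pv[[i]], nbs, disp, set$entries[[k]])
  }
  out
}

#' Descriptors straight from a frame
#'
#' Convenience wrapper: groups molecules, extracts point-vectors, builds the
#' molecule-level neighbor list and evaluates the descriptor set.
#'
#' @param frame a [simulation_frame()].
#' @param template a [pv_template()].
#' @param set a [descriptor_set()].
#' @param molecule_size atoms per molecule (used if the frame lacks ids).
#' @return molecules x features matrix as in [compute_descriptors()].
#' @export
frame_descriptors <- function(frame, template, set = default_descriptor_set(),
                              molecule_size = NULL) {
  groups <- group_molecules(frame, molecule_size = molecule_size)
  pv <- extract_point_vectors(frame, groups, template)
  max_rc <- max(vapply(set$entries, `[[`, 0, "r_c"))
  nl <- build_neighbor_list(pv_positions(pv),
                            if (any(frame$pbc)) frame$cell else NULL, max_rc)
  compute_descriptors(pv, nl, set)
}
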