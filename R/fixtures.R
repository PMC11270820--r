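## Synthetic crystal fixtures: periodic polymorph lattices of a rigid toy
## molecule, a disordered melt, spherical clusters and two-phase slabs, with
## seeded rigid-body thermal noise. These stand in for MD snapshots so the
## classifiers and analyses are testable without simulation data.

#' Rotation matrix about an axis
#' @param axis 3-vector (normalized internally).
#' @param angle radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_axis_angle <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

## uniform random rotation via normalized quaternion
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' The rigid three-atom fixture molecule
#'
#' A planar C-O-N toy molecule: the carbon is the position atom, the C-O
#' bond (1.2 A along x) defines orientation-vector slot 1, and the C-N bond
#' (1.0 A along y) slot 2. One template serves every bundled fixture.
#'
#' @return list with `local` (3 x 3 matrix of atom coordinates in the
#'   molecule frame, rows = atoms), `elements`, `pv` (the matching
#'   [pv_template()]), and `radius` (max distance from the position atom).
#' @export
fixture_molecule <- function() {
  local <- rbind(c(0, 0, 0), c(1.2, 0, 0), c(0, 1.0, 0))
  list(local = local, elements = c("C", "O", "N"),
       pv = pv_template(1L, list(c(1L, 2L), c(1L, 3L))),
       radius = max(sqrt(rowSums(local^2))))
}

#' Fixture polymorph specification
#'
#' @param name class label of the polymorph.
#' @param lattice 3x3 matrix of unit-cell lattice vectors (rows, Angstrom).
#' @param basis list of `list(frac = <3-vector>, rot = <3x3 rotation>)`
#'   giving each molecule in the unit cell.
#' @param molecule molecule definition as from [fixture_molecule()].
#' @return a `fixture_polymorph` object.
#' @export
fixture_polymorph <- function(name, lattice, basis,
                              molecule = fixture_molecule()) {
  lattice <- as.matrix(lattice)
  stopifnot(all(dim(lattice) == c(3, 3)), abs(det(lattice)) > 1e-8,
            length(basis) >= 1)
  structure(list(name = name, lattice = lattice, basis = basis,
                 molecule = molecule),
            class = "fixture_polymorph")
}

#' The three bundled polymorph packings
#'
#' Three periodic packings of the fixture molecule that differ in both
#' density and orientational order, emulating distinct polymorphs:
#' \describe{
#'   \item{alpha}{simple cubic (a = 4 A), all molecules aligned.}
#'   \item{beta}{body-centered tetragonal (4 x 4 x 5.6 A), the second basis
#'     molecule flipped by pi about x — antiparallel layering of slot-2
#'     vectors.}
#'   \item{gamma}{herringbone-like: orthorhombic (5.4 x 4 x 4.2 A) with two
#'     molecules rotated +/- 40 degrees about z.}
#' }
#' Lattice constants were chosen so that interior molecules have
#' coordination number >= 20 within the default topology radius (molecule
#' radius + 6 A), matching the surface rule's assumptions about crystal
#' density.
#'
#' @return named list of three [fixture_polymorph()] specs.
#' @export
fixture_polymorphs <- function() {
  mol <- fixture_molecule()
  I3 <- diag(3)
  list(
    alpha = fixture_polymorph("alpha", diag(c(4, 4, 4)),
                              list(list(frac = c(0, 0, 0), rot = I3)),
                              mol),
    beta = fixture_polymorph(
      "beta", diag(c(4, 4, 5.6)),
      list(list(frac = c(0, 0, 0), rot = I3),
           list(frac = c(0.5, 0.5, 0.5),
                rot = rotation_axis_angle(c(1, 0, 0), pi))),
      mol),
    gamma = fixture_polymorph(
      "gamma", diag(c(5.4, 4, 4.2)),
      list(list(frac = c(0, 0, 0),
                rot = rotation_axis_angle(c(0, 0, 1), 40 * pi / 180)),
           list(frac = c(0.5, 0.5, 0.5),
                rot = rotation_axis_angle(c(0, 0, 1), -40 * pi / 180))),
      mol))
}

#' Rigid-body thermal noise model
#'
#' @param sigma_t standard deviation of the per-molecule Gaussian rigid
#'   translation (Angstrom, per Cartesian component).
#' @param sigma_r standard deviation of the Gaussian rotation angle
#'   (radians) about a uniformly random axis.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return a `noise_model` object.
#' @export
noise_model <- function(sigma_t = 0, sigma_r = 0, seed = NULL) {
  stopifnot(sigma_t >= 0, sigma_r >= 0)
  structure(list(sigma_t = sigma_t, sigma_r = sigma_r,
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "noise_model")
}

## assemble a frame from molecule centers + rotations
assemble_frame <- function(centers, rots, molecule, cell, pbc) {
  nm <- nrow(centers)
  nat <- nrow(molecule$local)
  pos <- matrix(0, nm * nat, 3L)
  for (m in seq_len(nm)) {
    rows <- (m - 1L) * nat + seq_len(nat)
    pos[rows, ] <- sweep(molecule$local %*% t(rots[[m]]), 2L,
                         centers[m, ], `+`)
  }
  simulation_frame(pos, rep(molecule$elements, nm), cell = cell, pbc = pbc,
                   molecule_ids = rep(seq_len(nm), each = nat))
}

## rigid noise on centers/rotations (RNG state of the caller)
apply_rigid_noise <- function(centers, rots, noise) {
  nm <- nrow(centers)
  if (noise$sigma_t > 0)
    centers <- centers + matrix(stats::rnorm(nm * 3, sd = noise$sigma_t), nm)
  if (noise$sigma_r > 0) {
    for (m in seq_len(nm)) {
      ax <- stats::rnorm(3)
      ang <- stats::rnorm(1, sd = noise$sigma_r)
      rots[[m]] <- rotation_axis_angle(ax, ang) %*% rots[[m]]
    }
  }
  list(centers = centers, rots = rots)
}

min_intermolecular_distance <- function(frame) {
  cell <- if (any(frame$pbc)) frame$cell else NULL
  pos <- frame$positions
  ids <- frame$molecule_ids
  best <- Inf
  for (i in seq_len(nrow(pos))) {
    d <- sweep(pos, 2L, pos[i, ])
    if (!is.null(cell)) d <- minimum_image(d, cell)
    dd <- sqrt(rowSums(d * d))
    dd[ids == ids[i]] <- Inf
    best <- min(best, min(dd))
  }
  best
}

lattice_centers <- function(spec, supercell) {
  cells <- as.matrix(expand.grid(0:(supercell[1] - 1L),
                                 0:(supercell[2] - 1L),
                                 0:(supercell[3] - 1L)))
  centers <- NULL
  rots <- list()
  for (b in spec$basis) {
    cc <- (sweep(cells, 2L, b$frac, `+`)) %*% spec$lattice
    centers <- rbind(centers, cc)
    rots <- c(rots, rep(list(b$rot), nrow(cc)))
  }
  ## keep molecules of one basis slot contiguous? order by cell then basis
  ord <- order(rep(seq_along(spec$basis), each = nrow(cells)) * 0 +
                 seq_len(nrow(centers)))
  list(centers = centers[ord, , drop = FALSE], rots = rots[ord])
}

#' Generate a periodic polymorph lattice frame
#'
#' A supercell of the given polymorph with optional rigid-body thermal
#' noise. At zero noise every interior molecule has an identical local
#' environment by translational symmetry.
#'
#' @param spec a [fixture_polymorph()].
#' @param supercell integer 3-vector of unit-cell repeats (>= 2 each for
#'   meaningful environments).
#' @param noise a [noise_model()].
#' @param contact minimal allowed intermolecular atom-atom distance after
#'   noise; the frame is regenerated (up to `retries` times) if violated.
#' @param retries retry budget for noisy overlap.
#' @return list with `frame` (a [simulation_frame()]) and `labels`
#'   (data.frame: `molecule_id` 0-based, `class`, `topology`).
#' @export
make_lattice_polymorph <- function(spec, supercell = c(3L, 3L, 3L),
                                   noise = noise_model(), contact = 0.5,
                                   retries = 5L) {
  stopifnot(all(supercell >= 2L))
  if (!is.null(noise$seed)) set.seed(noise$seed)
  lat <- lattice_centers(spec, supercell)
  cell <- diag(supercell) %*% spec$lattice
  for (try in seq_len(retries)) {
    st <- apply_rigid_noise(lat$centers, lat$rots, noise)
    frame <- assemble_frame(st$centers, st$rots, spec$molecule, cell,
                            pbc = c(TRUE, TRUE, TRUE))
    if (noise$sigma_t == 0 || min_intermolecular_distance(frame) > contact) {
      nm <- nrow(lat$centers)
      return(list(frame = frame,
                  labels = data.frame(molecule_id = seq_len(nm) - 1L,
                                      class = spec$name, topology = "bulk",
                                      stringsAsFactors = FALSE)))
    }
  }
  stop("could not generate a non-overlapping noisy lattice after ",
       retries, " attempts; lower the noise amplitude")
}

#' Generate a disordered melt frame
#'
#' Random sequential insertion with a hard minimum-image distance
#' constraint between molecule centers, and uniformly random molecular
#' orientations.
#'
#' @param n_molecules number of molecules to insert.
#' @param box 3-vector of orthorhombic box edges (Angstrom).
#' @param min_distance minimum center-center distance (Angstrom).
#' @param seed RNG seed.
#' @param molecule molecule definition, default [fixture_molecule()].
#' @param max_tries insertion attempts per molecule before giving up.
#' @return list with `frame` and `labels` (class `"melt"`).
#' @export
make_melt <- function(n_molecules, box = c(16, 16, 16), min_distance = 2.6,
                      seed = NULL, molecule = fixture_molecule(),
                      max_tries = 2000L) {
  if (!is.null(seed)) set.seed(seed)
  cell <- diag(box)
  centers <- matrix(NA_real_, n_molecules, 3L)
  placed <- 0L
  tries <- 0L
  while (placed < n_molecules) {
    cand <- stats::runif(3) * box
    ok <- TRUE
    if (placed > 0L) {
      d <- minimum_image(sweep(centers[seq_len(placed), , drop = FALSE],
                               2L, cand), cell)
      ok <- all(rowSums(d * d) >= min_distance^2)
    }
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- cand
      tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("random sequential insertion failed after ", max_tries,
             " attempts at molecule ", placed + 1L,
             "; lower the density or min_distance")
    }
  }
  rots <- replicate(n_molecules, random_rotation(), simplify = FALSE)
  frame <- assemble_frame(centers, rots, molecule, cell,
                          pbc = c(TRUE, TRUE, TRUE))
  list(frame = frame,
       labels = data.frame(molecule_id = seq_len(n_molecules) - 1L,
                           class = "melt", topology = "bulk",
                           stringsAsFactors = FALSE))
}

#' Carve a spherical cluster from a polymorph lattice
#'
#' Molecules of the periodic lattice whose centers lie within the sphere
#' are retained; the resulting frame is non-periodic. Topology labels are
#' assigned by the coordination-number rule (see [label_topology()]) with
#' the default radius (molecule radius + 6 A) and threshold 20.
#'
#' @param spec a [fixture_polymorph()].
#' @param diameter sphere diameter (Angstrom).
#' @param noise a [noise_model()].
#' @param cn_threshold surface threshold for the topology labels.
#' @return list with `frame`, `labels`, and `centers` (zero-noise molecule
#'   centers relative to the sphere center, for geometric oracles).
#' @export
make_cluster <- function(spec, diameter = 30, noise = noise_model(),
                         cn_threshold = 20L) {
  if (!is.null(noise$seed)) set.seed(noise$seed)
  widths <- cell_widths(spec$lattice)
  reps <- pmax(2L, ceiling(diameter / widths) + 2L)
  lat <- lattice_centers(spec, reps)
  mid <- colMeans(lat$centers)
  r <- sqrt(rowSums(sweep(lat$centers, 2L, mid)^2))
  keep <- which(r <= diameter / 2)
  if (length(keep) == 0L) stop("empty cluster: diameter too small")
  centers <- lat$centers[keep, , drop = FALSE]
  rots <- lat$rots[keep]
  st <- apply_rigid_noise(centers, rots, noise)
  frame <- assemble_frame(st$centers, st$rots, spec$molecule, cell = NULL,
                          pbc = c(FALSE, FALSE, FALSE))
  R_c <- spec$molecule$radius + 6
  cn <- vapply(seq_len(nrow(centers)), function(i)
    coordination_number(st$centers, i, R_c, cell = NULL), 0L)
  list(frame = frame,
       labels = data.frame(molecule_id = seq_len(nrow(centers)) - 1L,
                           class = spec$name,
                           topology = ifelse(cn < cn_threshold,
                                             "surface", "bulk"),
                           stringsAsFactors = FALSE),
       centers = sweep(centers, 2L, mid))
}

#' Build a periodic two-phase slab
#'
#' Stacks `n_bottom` unit cells of one polymorph and `n_top` of another
#' along an axis, periodic in all three directions (so the system contains
#' two interfaces). The phases must be commensurate in the interface plane;
#' the top phase is strained to the bottom phase's in-plane dimensions and
#' the applied strain is reported (an error beyond `strain_tol`).
#' Restricted to diagonal (orthorhombic) lattices.
#'
#' @param spec_top,spec_bottom [fixture_polymorph()] specs.
#' @param supercell_xy integer 2-vector of in-plane repeats.
#' @param n_bottom,n_top unit-cell repeats of each phase along the normal.
#' @param noise a [noise_model()].
#' @param strain_tol maximum tolerated fractional in-plane mismatch.
#' @return list with `frame`, `labels` (per-molecule phase class), and
#'   `strain` (fractional in-plane strain applied to the top phase).
#' @export
make_interface_slab <- function(spec_top, spec_bottom,
                                supercell_xy = c(3L, 3L),
                                n_bottom = 3L, n_top = 3L,
                                noise = noise_model(), strain_tol = 0.06) {
  if (!is.null(noise$seed)) set.seed(noise$seed)
  for (sp in list(spec_top, spec_bottom))
    if (any(abs(sp$lattice[upper.tri(sp$lattice)]) > 1e-10) ||
        any(abs(sp$lattice[lower.tri(sp$lattice)]) > 1e-10))
      stop("interface slabs require diagonal (orthorhombic) lattices")
  ab_bot <- diag(spec_bottom$lattice)[1:2]
  ab_top <- diag(spec_top$lattice)[1:2]
  strain <- ab_bot / ab_top - 1
  if (any(abs(strain) > strain_tol))
    stop(sprintf(paste0("in-plane lattice mismatch too large: required ",
                        "strain (%.1f%%, %.1f%%) exceeds tolerance %.1f%%"),
                 100 * strain[1], 100 * strain[2], 100 * strain_tol))
  stretch_top <- diag(c(ab_bot / ab_top, 1))
  build_phase <- function(spec, reps_z, z0, stretch = diag(3)) {
    lat <- lattice_centers(spec, c(supercell_xy, reps_z))
    centers <- lat$centers %*% stretch
    centers[, 3] <- centers[, 3] + z0
    list(centers = centers, rots = lat$rots,
         height = reps_z * spec$lattice[3, 3])
  }
  bot <- build_phase(spec_bottom, n_bottom, 0)
  top <- build_phase(spec_top, n_top, bot$height, stretch_top)
  centers <- rbind(bot$centers, top$centers)
  rots <- c(bot$rots, top$rots)
  cell <- diag(c(supercell_xy * ab_bot, bot$height + top$height))
  st <- apply_rigid_noise(centers, rots, noise)
  mol <- spec_bottom$molecule
  frame <- assemble_frame(st$centers, st$rots, mol, cell,
                          pbc = c(TRUE, TRUE, TRUE))
  nb <- nrow(bot$centers); nt <- nrow(top$centers)
  list(frame = frame,
       labels = data.frame(molecule_id = seq_len(nb + nt) - 1L,
                           class = c(rep(spec_bottom$name, nb),
                                     rep(spec_top$name, nt)),
                           topology = "bulk", stringsAsFactors = FALSE),
       strain = strain)
}

#' Apply rigid-body noise to an existing frame
#'
#' Each molecule is rigidly translated by a Gaussian displacement and
#' rotated by a Gaussian-angle rotation about a random axis through its
#' first atom; intramolecular geometry is exactly preserved.
#'
#' @param frame a [simulation_frame()] with molecule ids.
#' @param noise a [noise_model()].
#' @return the perturbed frame.
#' @export
perturb_frame <- function(frame, noise) {
  if (!is.null(noise$seed)) set.seed(noise$seed)
  if (noise$sigma_t == 0 && noise$sigma_r == 0) return(frame)
  groups <- group_molecules(frame)
  pos <- frame$positions
  cell <- if (any(frame$pbc)) frame$cell else NULL
  for (g in groups) {
    at <- g$atom_indices
    anchor <- pos[at[1], ]
    local <- sweep(pos[at, , drop = FALSE], 2L, anchor)
    if (!is.null(cell)) local <- minimum_image(local, cell)
    R <- if (noise$sigma_r > 0)
      rotation_axis_angle(stats::rnorm(3), stats::rnorm(1, sd = noise$sigma_r))
    else diag(3)
    t <- if (noise$sigma_t > 0) stats::rnorm(3, sd = noise$sigma_t) else c(0, 0, 0)
    pos[at, ] <- sweep(local %*% t(R), 2L, anchor + t, `+`)
  }
  frame$positions <- pos
  frame
}
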