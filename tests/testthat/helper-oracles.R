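## Independent brute-force oracles and shared generators for the test
## suite. Everything here is deliberately naive (scalar loops, exhaustive
## image searches) so it cannot share bugs with the vectorized package
## code paths it checks.

## exhaustive periodic-image search; range 1 (3x3x3) is sufficient for
## deltas between in-box points under mildly tilted cells, larger ranges
## for arbitrary deltas
oracle_min_image <- function(delta, cell, range = 1L) {
  best <- delta
  bestd <- sum(delta^2)
  rng <- -range:range
  for (i in rng) for (j in rng) for (k in rng) {
    cand <- delta + i * cell[1, ] + j * cell[2, ] + k * cell[3, ]
    d <- sum(cand^2)
    if (d < bestd) { best <- cand; bestd <- d }
  }
  best
}

## O(N^2) scalar pair scan; returns sorted "i-j" keys with i < j
oracle_pairs <- function(points, cell, cutoff) {
  n <- nrow(points)
  keys <- character(0)
  dists <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- points[j, ] - points[i, ]
    if (!is.null(cell)) d <- oracle_min_image(d, cell)
    dd <- sqrt(sum(d^2))
    if (dd <= cutoff) {
      keys[length(keys) + 1L] <- paste(i, j, sep = "-")
      dists[length(dists) + 1L] <- dd
    }
  }
  list(keys = keys, dists = dists)
}

## unique i<j pair keys and distances from a neighbor_list
## (paste0 turns zero-length vectors into "", hence the explicit guard)
nl_pair_keys <- function(nl) {
  keys <- character(0); dists <- numeric(0)
  for (i in seq_along(nl$neighbor_ids)) {
    js <- nl$neighbor_ids[[i]]
    sel <- which(js > i)
    if (length(sel)) {
      keys <- c(keys, paste(i, js[sel], sep = "-"))
      dists <- c(dists, nl$distances[[i]][sel])
    }
  }
  list(keys = keys, dists = dists)
}

## scalar cosine cutoff
oracle_fc <- function(r, rc) if (r >= rc) 0 else 0.5 * (cos(pi * r / rc) + 1)

## scalar-loop symmetry functions over explicit neighbor data
oracle_sf <- function(params, center_v, nb_disp, nb_v) {
  total <- 0
  n <- nrow(nb_disp)
  if (n == 0) return(0)
  for (j in seq_len(n)) {
    r <- sqrt(sum(nb_disp[j, ]^2))
    fc <- oracle_fc(r, params$r_c)
    term <- switch(params$kind,
      radial_gaussian = exp(-params$eta * (r - params$R_s)^2) * fc,
      radial_cosine = cos(params$kappa * r) * fc,
      orient_a = {
        vi <- center_v[[params$vector_slot]]
        vj <- nb_v[[j]][[params$vector_slot]]
        th <- acos(max(-1, min(1, sum(vi * vj))))
        exp(-params$eta * (cos(th) - params$cos_theta_S)^2) * fc
      },
      orient_b = {
        vi <- center_v[[params$vector_slot]]
        vj <- nb_v[[j]][[params$vector_slot]]
        th <- acos(max(-1, min(1, sum(vi * vj))))
        cos(params$kappa * (cos(th) - params$cos_theta_S)) * fc
      })
    total <- total + term
  }
  total
}

## scalar coordination count
oracle_cn <- function(positions, i, R_c, cell = NULL) {
  cnt <- 0L
  for (j in seq_len(nrow(positions))) {
    if (j == i) next
    d <- positions[j, ] - positions[i, ]
    if (!is.null(cell)) d <- oracle_min_image(d, cell)
    if (sqrt(sum(d^2)) <= R_c) cnt <- cnt + 1L
  }
  cnt
}

## random rotation matrix from the test RNG
random_rot <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

## rigidly transform a frame: positions -> positions %*% t(R) + t
transform_frame <- function(frame, R = diag(3), t = c(0, 0, 0)) {
  frame$positions <- sweep(frame$positions %*% t(R), 2L, t, `+`)
  if (!is.null(frame$cell)) frame$cell <- frame$cell %*% t(R)
  frame
}

## standard 4-class training/evaluation data for the classifiers
gen_polymorph_samples <- function(sigma, seed0, nf, supercell = c(3L, 3L, 3L),
                                  melt_n = 25L, melt_box = c(12.5, 12.5, 12.5)) {
  specs <- fixture_polymorphs()
  out <- list(); k <- 0L
  for (nm in names(specs)) for (f in seq_len(nf)) {
    k <- k + 1L
    r <- make_lattice_polymorph(specs[[nm]], supercell,
                                noise_model(sigma, sigma, seed = seed0 + k))
    out[[length(out) + 1L]] <- list(frame = r$frame, poly = r$labels$class,
                                    topo = r$labels$topology, tag = nm)
  }
  for (f in seq_len(nf)) {
    k <- k + 1L
    r <- make_melt(melt_n, melt_box, min_distance = 2.6, seed = seed0 + k)
    out[[length(out) + 1L]] <- list(frame = r$frame, poly = r$labels$class,
                                    topo = r$labels$topology, tag = "melt")
  }
  out
}

## descriptor matrix + labels from samples (4x4x4 cells needed for r_c = 8)
samples_to_descriptors <- function(samples, set = default_descriptor_set()) {
  tmpl <- fixture_molecule()$pv
  X <- NULL; y <- character(0)
  for (s in samples) {
    X <- rbind(X, frame_descriptors(s$frame, tmpl, set))
    y <- c(y, s$poly)
  }
  list(x = X, y = y)
}

## small random non-periodic "gas" of point-vector molecules
random_pv_config <- function(n, box = 14) {
  centers <- matrix(runif(n * 3, 0, box), n)
  lapply(seq_len(n), function(i) {
    v1 <- rnorm(3); v1 <- v1 / sqrt(sum(v1^2))
    v2 <- rnorm(3); v2 <- v2 / sqrt(sum(v2^2))
    structure(list(molecule_id = i - 1L, r_I = centers[i, ],
                   v = list(v1, v2)), class = "pv_molecule")
  })
}

## reduced-width GNN config used throughout the tests (the paper-scale
## defaults are far too wide for a 1-CPU test budget)
test_gnn_config <- function(...) {
  gnn_config(r_c = 6, n_bessel = 8L, node_dim = 32L, message_dim = 16L,
             graph_dim = 32L, n_convolutions = 2L, dropout = 0, ...)
}
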