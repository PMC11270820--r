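test_that("the cosine cutoff has the stated values and support", {
  expect_equal(cutoff_fn(0, 6), 1)
  expect_equal(cutoff_fn(6, 6), 0)
  expect_equal(cutoff_fn(7, 6), 0)
  expect_equal(cutoff_fn(3, 6), 0.5)
  expect_error(cutoff_fn(-1, 6), "negative")
  ## continuously differentiable at r_c: finite-difference slope -> 0
  expect_lt(abs(cutoff_fn(6 - 1e-5, 6) / 1e-5), 1e-4)
})

test_that("sf_params validates kind-specific parameters", {
  expect_error(sf_params("radial_gaussian", r_c = 6), "eta")
  expect_error(sf_params("orient_a", eta = 1, cos_theta_S = 2, r_c = 6,
                         vector_slot = 1L), "cos_theta_S")
  p <- sf_params("radial_cosine", kappa = 1.5, r_c = 6)
  expect_s3_class(p, "sf_params")
})

test_that("single-function values match their closed-form anchors", {
  center <- random_pv_config(1)[[1]]
  pg <- sf_params("radial_gaussian", eta = 0.5, R_s = 3, r_c = 6)
  expect_equal(radial_gaussian_sf(center, matrix(0, 0, 3), pg), 0)
  ## one neighbor at exactly R_s: Gaussian at its center is 1
  expect_equal(radial_gaussian_sf(center, matrix(c(3, 0, 0), 1), pg),
               cutoff_fn(3, 6))
  pc <- sf_params("radial_cosine", kappa = 2 * pi / 4, r_c = 6)
  expect_equal(radial_cosine_sf(center, matrix(c(4, 0, 0), 1), pc),
               cutoff_fn(4, 6))
  ## aligned vectors at the angular center contribute f_c each
  nb <- random_pv_config(3)
  for (j in seq_along(nb)) nb[[j]]$v <- center$v
  disp <- rbind(c(2, 0, 0), c(0, 3, 0), c(0, 0, 4))
  pa <- sf_params("orient_a", eta = 4, cos_theta_S = 1, r_c = 6,
                  vector_slot = 1L)
  expect_equal(orient_a_sf(center, nb, disp, pa),
               sum(cutoff_fn(c(2, 3, 4), 6)))
  pb <- sf_params("orient_b", kappa = 3, cos_theta_S = 1, r_c = 6,
                  vector_slot = 2L)
  expect_equal(orient_b_sf(center, nb, disp, pb),
               sum(cutoff_fn(c(2, 3, 4), 6)))
})

test_that("every kind equals the scalar-loop oracle on random configurations", {
  set.seed(31)
  kinds <- list(
    sf_params("radial_gaussian", eta = 0.7, R_s = 2.5, r_c = 6),
    sf_params("radial_cosine", kappa = 1.3, r_c = 5),
    sf_params("orient_a", eta = 2.2, cos_theta_S = -0.3, r_c = 6,
              vector_slot = 1L),
    sf_params("orient_b", kappa = 2.1, cos_theta_S = 0.4, r_c = 6,
              vector_slot = 2L))
  for (rep in 1:10) {
    pv <- random_pv_config(sample(5:12, 1), box = 8)
    center <- pv[[1]]
    nbs <- pv[-1]
    disp <- do.call(rbind, lapply(nbs, function(m) m$r_I - center$r_I))
    for (p in kinds) {
      got <- switch(p$kind,
                    radial_gaussian = radial_gaussian_sf(center, disp, p),
                    radial_cosine = radial_cosine_sf(center, disp, p),
                    orient_a = orient_a_sf(center, nbs, disp, p),
                    orient_b = orient_b_sf(center, nbs, disp, p))
      want <- oracle_sf(p, center$v, disp, lapply(nbs, `[[`, "v"))
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("the default descriptor set has 24 features and compute_descriptors fills them", {
  set <- default_descriptor_set()
  expect_equal(descriptor_length(set), 24L)
  expect_equal(length(unique(set$feature_names)), 24L)
  ## one isolated molecule: all zero
  pv <- random_pv_config(1)
  nl <- build_neighbor_list(pv_positions(pv), cutoff = 8)
  X <- compute_descriptors(pv, nl, set)
  expect_equal(dim(X), c(1L, 24L))
  expect_true(all(X == 0))
  ## cutoff guard
  nl4 <- build_neighbor_list(pv_positions(random_pv_config(3)), cutoff = 4)
  expect_error(compute_descriptors(random_pv_config(3), nl4, set), "cutoff")
})

test_that("descriptors are invariant under rotation, translation, inversion, relabeling", {
  set.seed(17)
  tmpl <- fixture_molecule()$pv
  set <- default_descriptor_set()
  res <- make_lattice_polymorph(fixture_polymorphs()$beta, c(4, 4, 4),
                                noise_model(0.08, 0.2, seed = 9))
  fr <- res$frame
  X0 <- frame_descriptors(fr, tmpl, set)
  for (tf in list(list(R = random_rot(), t = c(0, 0, 0)),
                  list(R = diag(3), t = c(5, -3, 1)),
                  list(R = -diag(3), t = c(0, 0, 0)))) {
    X1 <- frame_descriptors(transform_frame(fr, tf$R, tf$t), tmpl, set)
    expect_equal(X1, X0, tolerance = 1e-8)
  }
  ## relabel molecules: permute whole molecules in the atom ordering
  nm <- n_atoms(fr) / 3L
  perm <- sample(nm)
  atom_perm <- as.vector(matrix(seq_len(n_atoms(fr)), 3L)[, perm])
  fr2 <- simulation_frame(fr$positions[atom_perm, ],
                          fr$atom_types[atom_perm], cell = fr$cell,
                          pbc = fr$pbc,
                          molecule_ids = rep(seq_len(nm), each = 3L))
  X2 <- frame_descriptors(fr2, tmpl, set)
  expect_equal(X2[order(perm), ], X0, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("descriptors are smooth when a neighbor crosses the cutoff", {
  set <- default_descriptor_set(r_c = 6)
  mk <- function(d) {
    pv <- random_pv_config(2)
    pv[[1]]$r_I <- c(0, 0, 0); pv[[2]]$r_I <- c(d, 0, 0)
    nl <- build_neighbor_list(pv_positions(pv), cutoff = 6.5)
    compute_descriptors(pv, nl, set)[1, ]
  }
  set.seed(2)
  lo <- mk(6 - 1e-4)
  set.seed(2)
  hi <- mk(6 + 1e-4)
  expect_lt(max(abs(lo - hi)), 1e-6)
})

test_that("zero-noise polymorphs have zero variance and distinct centroids", {
  tmpl <- fixture_molecule()$pv
  cents <- list()
  for (spec in fixture_polymorphs()) {
    X <- frame_descriptors(make_lattice_polymorph(spec, c(4, 4, 4))$frame,
                           tmpl)
    expect_lt(max(apply(X, 2, stats::sd)), 1e-10)
    cents[[spec$name]] <- colMeans(X)
  }
  pairs <- utils::combn(names(cents), 2)
  for (k in seq_len(ncol(pairs))) {
    d <- sqrt(sum((cents[[pairs[1, k]]] - cents[[pairs[2, k]]])^2))
    expect_gt(d, 1)
  }
})
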