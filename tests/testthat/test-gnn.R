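test_that("the Bessel basis matches its closed form", {
  r_c <- 6
  B <- bessel_basis(c(r_c / 2, r_c), r_c, 32L)
  expect_equal(ncol(B), 32L)
  ## r = r_c: sin(n pi) = 0 for every n
  expect_equal(B[2, ], rep(0, 32), tolerance = 1e-12)
  ## r = r_c/2, n = 1: sqrt(2/r_c) sin(pi/2) / (r_c/2)
  expect_equal(B[1, 1], 2 * sqrt(2 / r_c) / r_c, tolerance = 1e-12)
  expect_error(bessel_basis(c(-1, 2), 6, 8), "positive")
})

test_that("node embeddings: identical elements map to identical rows", {
  cfg <- test_gnn_config()
  model <- gnn_init(cfg, c("C", "N", "O"), c("a", "b"), seed = 1)
  res <- make_lattice_polymorph(fixture_polymorphs()$alpha, c(3, 3, 3))
  g <- gnn_prepare(res$frame, model)
  X0 <- crystclass:::lin_fwd(model$params$Emb[g$z, ], model$params$W0,
                             model$params$b0)
  same <- which(res$frame$atom_types == "C")
  expect_equal(X0[same[1], ], X0[same[5], ])
  ## unknown element is a hard error
  fr2 <- res$frame
  fr2$atom_types[1] <- "S"
  expect_error(gnn_prepare(fr2, model), "vocabulary")
})

test_that("aggregate_max is an exact channel-wise max and permutation invariant", {
  X <- rbind(c(1, 5), c(3, 2), c(-1, 7))
  ag <- aggregate_max(X, c(1L, 1L, 2L), 2L)
  expect_equal(ag$g, rbind(c(3, 5), c(-1, 7)))
  expect_equal(aggregate_max(X[1, , drop = FALSE], 1L, 1L)$g,
               X[1, , drop = FALSE])
  expect_error(aggregate_max(X, c(1L, 1L, 1L), 2L), "empty")
  set.seed(5)
  X <- matrix(rnorm(40), 10)
  mol <- rep(1:2, each = 5)
  perm <- sample(10)
  expect_equal(aggregate_max(X[perm, ], mol[perm], 2L)$g,
               aggregate_max(X, mol, 2L)$g)
})

test_that("one graph convolution matches a handwritten scalar computation", {
  set.seed(21)
  nd <- 3L; md <- 2L
  cfg <- gnn_config(r_c = 6, n_bessel = 2L, node_dim = nd, message_dim = md,
                    graph_dim = 2L, n_convolutions = 1L, dropout = 0)
  model <- gnn_init(cfg, c("C"), c("a", "b"), seed = 21)
  p <- model$params
  X <- matrix(rnorm(3 * nd), 3)
  E <- matrix(rnorm(3 * md), 3)          # three directed edges
  src <- c(2L, 3L, 1L); dst <- c(1L, 1L, 2L)
  got <- crystclass:::gnn_layer_fwd(p, 1L, X, E, src, dst, 0, FALSE)$X
  ## -- independent scalar re-computation --
  want <- matrix(0, 3, nd)
  msg <- matrix(0, 3, md)
  for (i in 1:3) {
    es <- which(dst == i)
    if (length(es)) {
      q <- as.numeric(X[i, ] %*% p$Wq1)
      logits <- sapply(es, function(e)
        sum(q * (X[src[e], ] %*% p$Wk1 + E[e, ] %*% p$Wek1)) / sqrt(md))
      a <- exp(logits - max(logits)); a <- a / sum(a)
      for (k in seq_along(es)) {
        e <- es[k]
        msg[i, ] <- msg[i, ] + a[k] *
          as.numeric(X[src[e], ] %*% p$Wv1 + E[e, ] %*% p$Wev1)
      }
    }
  }
  for (i in 1:3) {
    y <- as.numeric(X[i, ] %*% p$Wr1) + msg[i, ]
    xp <- as.numeric(y %*% p$Wp1) + p$bp1
    u <- as.numeric(xp %*% p$Wu1) + p$bu1
    z <- xp + u * pnorm(u)
    mu <- mean(z); s <- sqrt(mean((z - mu)^2) + 1e-5)
    want[i, ] <- ((z - mu) / s) * p$lng1 + p$lnb1
  }
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("zeroed update weights reduce the node update to LayerNorm of its input", {
  set.seed(2)
  nd <- 4L; md <- 3L
  cfg <- gnn_config(r_c = 6, n_bessel = 2L, node_dim = nd, message_dim = md,
                    n_convolutions = 1L, dropout = 0)
  model <- gnn_init(cfg, c("C"), c("a", "b"), seed = 3)
  p <- model$params
  p$Wu1[] <- 0; p$bu1[] <- 0; p$lng1[] <- 1; p$lnb1[] <- 0
  X <- matrix(rnorm(2 * nd), 2)
  ## no edges: only the root path contributes
  st <- crystclass:::gnn_layer_fwd(p, 1L, X, matrix(0, 0, md), integer(0),
                                   integer(0), 0, FALSE)
  xp <- sweep((X %*% p$Wr1) %*% p$Wp1, 2L, p$bp1, `+`)
  mu <- rowMeans(xp)
  sd <- sqrt(rowMeans((xp - mu)^2) + 1e-5)
  expect_equal(st$X, (xp - mu) / sd, tolerance = 1e-10)
})

test_that("classification head outputs normalized probabilities per head", {
  cfg <- test_gnn_config(topology_head = TRUE)
  model <- gnn_init(cfg, c("C", "N", "O"), c("a", "b", "c"), seed = 6)
  res <- make_cluster(fixture_polymorphs()$alpha, 16)
  pr <- gnn_predict(model, res$frame)
  expect_equal(rowSums(pr$poly_probs), rep(1, nrow(pr$poly_probs)),
               tolerance = 1e-6)
  expect_equal(rowSums(pr$topo_probs), rep(1, nrow(pr$topo_probs)),
               tolerance = 1e-6)
  ## zeroed final layer: uniform over classes
  model$params$Wh2[] <- 0; model$params$bh2[] <- 0
  pr0 <- gnn_predict(model, res$frame)
  expect_equal(as.vector(pr0$poly_probs), rep(1 / 3, 3 * nrow(pr0$poly_probs)),
               tolerance = 1e-12)
})

test_that("inference is deterministic and invariant to the stated symmetries", {
  set.seed(13)
  cfg <- test_gnn_config()
  model <- gnn_init(cfg, c("C", "N", "O"), c("a", "b", "c"), seed = 10)
  res <- make_lattice_polymorph(fixture_polymorphs()$gamma, c(3, 3, 3),
                                noise_model(0.1, 0.2, seed = 4))
  fr <- res$frame
  p0 <- gnn_predict(model, fr)$poly_probs
  expect_identical(gnn_predict(model, fr)$poly_probs, p0)
  for (tf in list(list(R = random_rot(), t = c(2, -7, 3)),
                  list(R = -diag(3), t = c(0, 0, 0)))) {
    p1 <- gnn_predict(model, transform_frame(fr, tf$R, tf$t))$poly_probs
    expect_equal(p1, p0, tolerance = 1e-5)
  }
  ## permuting atoms within molecules leaves per-molecule outputs unchanged
  nm <- n_atoms(fr) / 3L
  atom_perm <- unlist(lapply(seq_len(nm), function(m)
    (m - 1L) * 3L + sample(3L)))
  fr2 <- simulation_frame(fr$positions[atom_perm, ],
                          fr$atom_types[atom_perm], cell = fr$cell,
                          pbc = fr$pbc,
                          molecule_ids = fr$molecule_ids[atom_perm])
  expect_equal(gnn_predict(model, fr2)$poly_probs, p0, tolerance = 1e-8)
})

test_that("atoms beyond the receptive field cannot affect a molecule's output", {
  cfg <- test_gnn_config()          # 2 convolutions, r_c = 6
  model <- gnn_init(cfg, c("C", "N", "O"), c("a", "b"), seed = 2)
  mol <- fixture_molecule()
  ## two molecules 40 A apart in vacuum: far beyond (n_conv + 1) * r_c
  mk <- function(shift) {
    pos <- rbind(mol$local, sweep(mol$local, 2L, c(40 + shift, 0, 0), `+`))
    simulation_frame(pos, rep(mol$elements, 2),
                     molecule_ids = rep(1:2, each = 3))
  }
  p1 <- gnn_predict(model, mk(0))$poly_probs
  p2 <- gnn_predict(model, mk(3.7))$poly_probs
  expect_equal(p2[1, ], p1[1, ], tolerance = 1e-12)
})

test_that("build_molecule_graph keeps the center molecule plus its r_c shell", {
  res <- make_lattice_polymorph(fixture_polymorphs()$alpha, c(4, 4, 4))
  fr <- res$frame
  groups <- group_molecules(fr)
  bg <- build_molecule_graph(fr, groups[[10]], 6)
  expect_true(all(groups[[10]]$atom_indices %in% bg$atom_indices))
  expect_equal(sum(bg$center_mask), 3L)
  ## every included non-center atom is within r_c of a center atom
  ctr <- fr$positions[groups[[10]]$atom_indices, , drop = FALSE]
  for (a in bg$atom_indices) {
    d <- sweep(ctr, 2L, fr$positions[a, ])
    d <- minimum_image(d, fr$cell)
    expect_lte(min(sqrt(rowSums(d^2))), 6 + 1e-9)
  }
  ## edge set equals the brute-force pair scan on the subframe
  sub <- fr$positions[bg$atom_indices, , drop = FALSE]
  orc <- oracle_pairs(sub, fr$cell, 6)
  keys <- unique(ifelse(bg$src < bg$dst,
                        paste0(bg$src, "-", bg$dst),
                        paste0(bg$dst, "-", bg$src)))
  expect_setequal(keys, orc$keys)
  expect_error(build_molecule_graph(fr, list(atom_indices = integer(0)), 6),
               "empty")
})

test_that("a short training run reduces the loss and checkpoints round-trip", {
  samples <- gen_polymorph_samples(0.05, 700, 1)[c(1, 2, 1, 2)]
  cfg <- test_gnn_config()
  model <- train_gnn(samples, cfg, c("alpha", "beta", "gamma", "melt"),
                     lr = 3e-3, max_epochs = 15, patience = 15, seed = 5)
  tr <- model$report$train_loss
  expect_lt(tr[length(tr)], tr[1])
  path <- withr::local_tempfile(fileext = ".json")
  save_gnn(model, path)
  m2 <- load_gnn(path)
  p1 <- gnn_predict(model, samples[[1]]$frame)$poly_probs
  p2 <- gnn_predict(m2, samples[[1]]$frame)$poly_probs
  expect_equal(p2, p1, tolerance = 1e-12)
})
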