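#' Graph classifier configuration
#'
#' Architecture hyperparameters of the molecular graph classifier: atom-type
#' node embeddings, spherical-Bessel edge embeddings, attention-based graph
#' convolutions with residual GeLU node updates and graph layer norm,
#' per-molecule max aggregation, and a softmax classification head (plus an
#' optional second surface/bulk topology head sharing the molecule
#' embedding).
#'
#' Defaults mirror the published architecture (cutoff 6 A, 32 Bessel
#' functions, 256-dimensional node and graph embeddings, 128-dimensional
#' messages, dropout 0.25, at most two convolutions — more destabilize
#' training). Tests and small fixtures use narrower widths for speed.
#'
#' @param r_c graph cutoff radius in Angstrom.
#' @param n_bessel number of spherical Bessel radial basis functions.
#' @param node_dim node embedding width.
#' @param message_dim message/attention width.
#' @param graph_dim hidden width of the classification head.
#' @param n_convolutions number of graph convolutions (1 or 2).
#' @param dropout dropout probability during training.
#' @param topology_head include the surface/bulk output head.
#' @return a `gnn_config` object.
#' @export
gnn_config <- function(r_c = 6, n_bessel = 32L, node_dim = 256L,
                       message_dim = 128L, graph_dim = 256L,
                       n_convolutions = 2L, dropout = 0.25,
                       topology_head = FALSE) {
  stopifnot(r_c > 0, n_bessel >= 1, node_dim >= 1, message_dim >= 1,
            graph_dim >= 1, n_convolutions >= 1, dropout >= 0, dropout < 1)
  if (n_convolutions > 2L)
    warning("more than two graph convolutions is known to destabilize training")
  structure(list(r_c = r_c, n_bessel = as.integer(n_bessel),
                 node_dim = as.integer(node_dim),
                 message_dim = as.integer(message_dim),
                 graph_dim = as.integer(graph_dim),
                 n_convolutions = as.integer(n_convolutions),
                 dropout = dropout, topology_head = isTRUE(topology_head)),
            class = "gnn_config")
}

#' Spherical Bessel radial basis
#'
#' `b_n(r) = sqrt(2 / r_c) * sin(n pi r / r_c) / r`, n = 1..n_bessel — the
#' zeroth-order DimeNet radial embedding. All basis functions vanish at
#' `r = r_c`, so edge features fade out smoothly at the cutoff.
#'
#' @param r vector of distances in (0, r_c].
#' @param r_c cutoff radius.
#' @param n_bessel basis size.
#' @return length(r) x n_bessel matrix.
#' @export
bessel_basis <- function(r, r_c, n_bessel) {
  if (any(r <= 0)) stop("distances must be positive")
  n <- seq_len(n_bessel)
  sqrt(2 / r_c) * sin(outer(r, n) * pi / r_c) / r
}

## --- model ---------------------------------------------------------------

#' Initialize a graph classifier
#'
#' @param config a [gnn_config()].
#' @param type_vocab character vector of the atom-type codes seen in
#'   training; unknown types at inference are a hard error.
#' @param class_names polymorph class names (softmax head order).
#' @param seed RNG seed for weight initialization.
#' @return an untrained `gnn_classifier` model.
#' @export
gnn_init <- function(config, type_vocab, class_names, seed = 1L) {
  set.seed(seed)
  nd <- config$node_dim; md <- config$message_dim; gd <- config$graph_dim
  C <- length(class_names)
  out_dim <- C + if (config$topology_head) 2L else 0L
  p <- list(
    Emb = matrix(stats::rnorm(length(type_vocab) * nd, sd = 1), length(type_vocab), nd),
    W0 = glorot(nd, nd), b0 = numeric(nd),
    We = glorot(config$n_bessel, md), be = numeric(md))
  for (l in seq_len(config$n_convolutions)) {
    p[[paste0("Wq", l)]] <- glorot(nd, md)
    p[[paste0("Wk", l)]] <- glorot(nd, md)
    p[[paste0("Wv", l)]] <- glorot(nd, md)
    p[[paste0("Wek", l)]] <- glorot(md, md)
    p[[paste0("Wev", l)]] <- glorot(md, md)
    p[[paste0("Wr", l)]] <- glorot(nd, md)
    p[[paste0("Wp", l)]] <- glorot(md, nd)
    p[[paste0("bp", l)]] <- numeric(nd)
    p[[paste0("Wu", l)]] <- glorot(nd, nd)
    p[[paste0("bu", l)]] <- numeric(nd)
    p[[paste0("lng", l)]] <- rep(1, nd)
    p[[paste0("lnb", l)]] <- numeric(nd)
  }
  p$Wh1 <- glorot(nd, gd); p$bh1 <- numeric(gd)
  p$lngh <- rep(1, gd); p$lnbh <- numeric(gd)
  p$Wh2 <- glorot(gd, out_dim); p$bh2 <- numeric(out_dim)
  structure(list(config = config, params = p,
                 type_vocab = as.character(type_vocab),
                 class_names = as.character(class_names),
                 topo_names = c("bulk", "surface")),
            class = "gnn_classifier")
}

#' @export
print.gnn_classifier <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat("<gnn_classifier> ", x$config$n_convolutions, " convolution(s), ",
      "node ", x$config$node_dim, " / message ", x$config$message_dim,
      ", ", format(np, big.mark = ","), " parameters, classes: ",
      paste(x$class_names, collapse = ", "),
      if (x$config$topology_head) " (+ topology head)", "\n", sep = "")
  invisible(x)
}

## --- graph preparation ---------------------------------------------------

#' Prepare a frame as a molecule graph batch
#'
#' Nodes are all atoms, edges all (directed) atom pairs within the graph
#' cutoff under minimum image, and each node carries its molecule
#' membership for max aggregation.
#'
#' @param frame a [simulation_frame()].
#' @param model a `gnn_classifier` (provides cutoff and type vocabulary).
#' @param groups optional precomputed [group_molecules()] output.
#' @return a `molecule_graph` list: `z` (type indices), `src`, `dst`,
#'   `dist`, `mol` (1-based molecule index per atom), `molecule_ids`,
#'   `n_mol`.
#' @export
gnn_prepare <- function(frame, model, groups = NULL) {
  z <- match(frame$atom_types, model$type_vocab)
  if (anyNA(z))
    stop("atom type(s) not in the model vocabulary: ",
         paste(unique(frame$atom_types[is.na(z)]), collapse = ", "))
  if (is.null(groups)) groups <- group_molecules(frame)
  mol <- integer(n_atoms(frame))
  for (k in seq_along(groups)) mol[groups[[k]]$atom_indices] <- k
  if (any(mol == 0L)) stop("molecule grouping does not cover all atoms")
  ed <- frame_edges(frame, model$config$r_c)
  structure(list(z = z, src = ed$src, dst = ed$dst, dist = ed$dist,
                 mol = mol, n_mol = length(groups),
                 molecule_ids = vapply(groups, `[[`, 0L, "molecule_id")),
            class = "molecule_graph")
}

#' Extract the local graph of one molecule
#'
#' The subgraph containing a center molecule's atoms plus every atom within
#' `r_c` of any of them, with all edges (minimum image when periodic)
#' between included atoms. Useful for inspecting what a single convolution
#' sees; frame-level inference uses the full frame graph so that stacked
#' convolutions keep their full receptive field.
#'
#' @param frame a [simulation_frame()].
#' @param center_molecule one `molecule_group` from [group_molecules()].
#' @param r_c cutoff radius (Angstrom).
#' @return list with `atom_indices` (frame indices of included atoms),
#'   `center_mask`, `z` (atom types), `src`, `dst`, `dist` (local indices).
#' @export
build_molecule_graph <- function(frame, center_molecule, r_c) {
  at <- center_molecule$atom_indices
  if (length(at) == 0L) stop("empty molecule")
  cell <- if (any(frame$pbc)) frame$cell else NULL
  pos <- frame$positions
  keep <- rep(FALSE, nrow(pos))
  keep[at] <- TRUE
  for (a in at) {
    d <- sweep(pos, 2L, pos[a, ])
    if (!is.null(cell)) d <- minimum_image(d, cell)
    keep[sqrt(rowSums(d * d)) <= r_c] <- TRUE
  }
  idx <- which(keep)
  sub <- simulation_frame(pos[idx, , drop = FALSE], frame$atom_types[idx],
                          cell = frame$cell, pbc = frame$pbc,
                          molecule_ids = NULL)
  ed <- frame_edges(sub, r_c)
  list(atom_indices = idx, center_mask = idx %in% at,
       z = frame$atom_types[idx], src = ed$src, dst = ed$dst, dist = ed$dist)
}

## --- forward pass --------------------------------------------------------

## group-wise softmax over edge logits grouped by destination node
group_softmax <- function(logit, group, ngroups) {
  gm <- rep(-Inf, ngroups)
  agg <- tapply(logit, group, max)
  gm[as.integer(names(agg))] <- agg
  e <- exp(logit - gm[group])
  den <- rep(1, ngroups)
  s <- rowsum(e, group)
  den[as.integer(rownames(s))] <- s
  e / den[group]
}

## scatter row-sums of x into an n x d matrix by group index
scatter_rowsum <- function(x, group, n) {
  out <- matrix(0, n, ncol(x))
  if (length(group)) {
    s <- rowsum(x, group)
    out[as.integer(rownames(s)), ] <- s
  }
  out
}

gnn_dropout <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, mask = NULL))
  mask <- matrix(stats::rbinom(length(x), 1L, 1 - p), nrow(x)) / (1 - p)
  list(y = x * mask, mask = mask)
}

## one attention graph convolution + residual node update (Eqs 3-6)
gnn_layer_fwd <- function(p, l, X, E, src, dst, dropout, training) {
  md <- ncol(E)
  Q <- X %*% p[[paste0("Wq", l)]]
  Ks <- X %*% p[[paste0("Wk", l)]]
  Vs <- X %*% p[[paste0("Wv", l)]]
  ke <- Ks[src, , drop = FALSE] + E %*% p[[paste0("Wek", l)]]
  ve <- Vs[src, , drop = FALSE] + E %*% p[[paste0("Wev", l)]]
  logit <- rowSums(Q[dst, , drop = FALSE] * ke) / sqrt(md)
  alpha <- group_softmax(logit, dst, nrow(X))
  M <- scatter_rowsum(alpha * ve, dst, nrow(X))
  Ymsg <- X %*% p[[paste0("Wr", l)]] + M
  Xp <- lin_fwd(Ymsg, p[[paste0("Wp", l)]], p[[paste0("bp", l)]])
  U <- lin_fwd(Xp, p[[paste0("Wu", l)]], p[[paste0("bu", l)]])
  G <- gelu(U)
  dp <- gnn_dropout(G, dropout, training)
  Z <- Xp + dp$y
  ln <- layernorm_fwd(Z, p[[paste0("lng", l)]], p[[paste0("lnb", l)]])
  list(X = ln$y, cache = list(Q = Q, ke = ke, ve = ve, alpha = alpha,
                              Xin = X, Ymsg = Ymsg, Xp = Xp, U = U,
                              mask = dp$mask, ln = ln, md = md))
}

gnn_layer_bwd <- function(p, l, dXout, cache, E, src, dst, grads) {
  ln <- layernorm_bwd(dXout, cache$ln, p[[paste0("lng", l)]])
  grads <- acc(grads, paste0("lng", l), ln$dgamma)
  grads <- acc(grads, paste0("lnb", l), ln$dbeta)
  dZ <- ln$dx
  dG <- if (is.null(cache$mask)) dZ else dZ * cache$mask
  dU <- dG * gelu_grad(cache$U)
  gu <- lin_bwd(dU, cache$Xp, p[[paste0("Wu", l)]])
  grads <- acc(grads, paste0("Wu", l), gu$dW)
  grads <- acc(grads, paste0("bu", l), gu$db)
  dXp <- dZ + gu$dx
  gp <- lin_bwd(dXp, cache$Ymsg, p[[paste0("Wp", l)]])
  grads <- acc(grads, paste0("Wp", l), gp$dW)
  grads <- acc(grads, paste0("bp", l), gp$db)
  dYmsg <- gp$dx
  X <- cache$Xin
  grads <- acc(grads, paste0("Wr", l), t(X) %*% dYmsg)
  dX <- dYmsg %*% t(p[[paste0("Wr", l)]])
  ## message aggregation backward
  dMe <- dYmsg[dst, , drop = FALSE]        # dL/d(alpha_e * v_e) per edge
  alpha <- cache$alpha; ve <- cache$ve; ke <- cache$ke; Q <- cache$Q
  dalpha <- rowSums(dMe * ve)
  dve <- alpha * dMe
  S <- as.numeric(scatter_rowsum(cbind(alpha * dalpha), dst, nrow(X)))
  dlogit <- alpha * (dalpha - S[dst])
  sq <- sqrt(cache$md)
  dQ <- scatter_rowsum((dlogit / sq) * ke, dst, nrow(X))
  dke <- (dlogit / sq) * Q[dst, , drop = FALSE]
  ## keys/values split into node part and edge part
  dKs <- scatter_rowsum(dke, src, nrow(X))
  dVs <- scatter_rowsum(dve, src, nrow(X))
  grads <- acc(grads, paste0("Wek", l), t(E) %*% dke)
  grads <- acc(grads, paste0("Wev", l), t(E) %*% dve)
  dE <- dke %*% t(p[[paste0("Wek", l)]]) + dve %*% t(p[[paste0("Wev", l)]])
  grads <- acc(grads, paste0("Wq", l), t(X) %*% dQ)
  grads <- acc(grads, paste0("Wk", l), t(X) %*% dKs)
  grads <- acc(grads, paste0("Wv", l), t(X) %*% dVs)
  dX <- dX + dQ %*% t(p[[paste0("Wq", l)]]) +
    dKs %*% t(p[[paste0("Wk", l)]]) + dVs %*% t(p[[paste0("Wv", l)]])
  list(dX = dX, dE = dE, grads = grads)
}

#' Per-molecule max aggregation
#'
#' Channel-wise maximum of the final atomic node embeddings over each
#' molecule — an exactly permutation-invariant molecule embedding.
#'
#' @param X atoms x channels node-embedding matrix.
#' @param mol 1-based molecule index per atom.
#' @param n_mol number of molecules.
#' @return list with `g` (n_mol x channels) and `amax` (argmax atom index
#'   per molecule and channel, used for backpropagation).
#' @export
aggregate_max <- function(X, mol, n_mol = max(mol)) {
  if (any(tabulate(mol, n_mol) == 0L)) stop("empty molecule in aggregation")
  g <- matrix(-Inf, n_mol, ncol(X))
  amax <- matrix(0L, n_mol, ncol(X))
  for (m in seq_len(n_mol)) {
    rows <- which(mol == m)
    sub <- X[rows, , drop = FALSE]
    w <- max.col(t(sub), ties.method = "first")
    amax[m, ] <- rows[w]
    g[m, ] <- sub[cbind(w, seq_len(ncol(X)))]
  }
  list(g = g, amax = amax)
}

gnn_forward <- function(model, graph, training = FALSE) {
  p <- model$params; cfg <- model$config
  X <- lin_fwd(p$Emb[graph$z, , drop = FALSE], p$W0, p$b0)
  B <- bessel_basis(graph$dist, cfg$r_c, cfg$n_bessel)
  E <- lin_fwd(B, p$We, p$be)
  caches <- vector("list", cfg$n_convolutions)
  for (l in seq_len(cfg$n_convolutions)) {
    st <- gnn_layer_fwd(p, l, X, E, graph$src, graph$dst, cfg$dropout, training)
    X <- st$X
    caches[[l]] <- st$cache
  }
  ag <- aggregate_max(X, graph$mol, graph$n_mol)
  A1 <- lin_fwd(ag$g, p$Wh1, p$bh1)
  H <- gelu(A1)
  lnh <- layernorm_fwd(H, p$lngh, p$lnbh)
  dph <- gnn_dropout(lnh$y, cfg$dropout, training)
  logits <- lin_fwd(dph$y, p$Wh2, p$bh2)
  C <- length(model$class_names)
  poly_logits <- logits[, seq_len(C), drop = FALSE]
  topo_logits <- if (cfg$topology_head)
    logits[, C + 1:2, drop = FALSE] else NULL
  list(poly_probs = softmax_rows(poly_logits),
       topo_probs = if (!is.null(topo_logits)) softmax_rows(topo_logits),
       g = ag$g,
       cache = list(B = B, E = E, layers = caches, ag = ag, A1 = A1,
                    lnh = lnh, maskh = dph$mask, Hd = dph$y, Xfinal = X))
}

gnn_backward <- function(model, graph, fwd, poly_labels, topo_labels = NULL) {
  p <- model$params; cfg <- model$config
  C <- length(model$class_names)
  n_mol <- graph$n_mol
  out_dim <- C + if (cfg$topology_head) 2L else 0L
  dlogits <- matrix(0, n_mol, out_dim)
  dlogits[, seq_len(C)] <- ce_logit_grad(fwd$poly_probs, poly_labels)
  if (cfg$topology_head && !is.null(topo_labels))
    dlogits[, C + 1:2] <- ce_logit_grad(fwd$topo_probs, topo_labels)
  grads <- list()
  ch <- fwd$cache
  g2 <- lin_bwd(dlogits, ch$Hd, p$Wh2)
  grads <- acc(grads, "Wh2", g2$dW); grads <- acc(grads, "bh2", g2$db)
  dHd <- g2$dx
  dLn <- if (is.null(ch$maskh)) dHd else dHd * ch$maskh
  lh <- layernorm_bwd(dLn, ch$lnh, p$lngh)
  grads <- acc(grads, "lngh", lh$dgamma); grads <- acc(grads, "lnbh", lh$dbeta)
  dH <- lh$dx
  dA1 <- dH * gelu_grad(ch$A1)
  g1 <- lin_bwd(dA1, ch$ag$g, p$Wh1)
  grads <- acc(grads, "Wh1", g1$dW); grads <- acc(grads, "bh1", g1$db)
  dg <- g1$dx
  ## max-pool backward: route each channel's gradient to its argmax atom
  nd <- ncol(ch$Xfinal)
  dX <- matrix(0, nrow(ch$Xfinal), nd)
  dX[cbind(as.vector(ch$ag$amax),
           rep(seq_len(nd), each = n_mol))] <- as.vector(dg)
  dE <- matrix(0, nrow(ch$E), ncol(ch$E))
  for (l in rev(seq_len(cfg$n_convolutions))) {
    bk <- gnn_layer_bwd(p, l, dX, ch$layers[[l]], ch$E, graph$src, graph$dst,
                        grads)
    dX <- bk$dX; dE <- dE + bk$dE; grads <- bk$grads
  }
  ge <- lin_bwd(dE, ch$B, p$We)
  grads <- acc(grads, "We", ge$dW); grads <- acc(grads, "be", ge$db)
  g0 <- lin_bwd(dX, p$Emb[graph$z, , drop = FALSE], p$W0)
  grads <- acc(grads, "W0", g0$dW); grads <- acc(grads, "b0", g0$db)
  dEmbRows <- g0$dx
  dEmb <- matrix(0, nrow(p$Emb), ncol(p$Emb))
  s <- rowsum(dEmbRows, graph$z)
  dEmb[as.integer(rownames(s)), ] <- s
  grads <- acc(grads, "Emb", dEmb)
  grads
}

## --- inference -----------------------------------------------------------

#' Per-molecule class probabilities from the graph classifier
#'
#' @param model a trained `gnn_classifier`.
#' @param frame a [simulation_frame()] (or a prepared `molecule_graph`).
#' @return list with `poly_probs` (molecules x classes, rows sum to 1),
#'   `topo_probs` (molecules x 2, when the topology head is enabled),
#'   `molecule_ids`, and the molecule embeddings `g`.
#' @export
gnn_predict <- function(model, frame) {
  graph <- if (inherits(frame, "molecule_graph")) frame
           else gnn_prepare(frame, model)
  fwd <- gnn_forward(model, graph, training = FALSE)
  poly <- fwd$poly_probs
  colnames(poly) <- model$class_names
  topo <- fwd$topo_probs
  if (!is.null(topo)) colnames(topo) <- model$topo_names
  list(poly_probs = poly, topo_probs = topo,
       molecule_ids = graph$molecule_ids, g = fwd$g)
}

#' Hard classification with the graph classifier
#'
#' @param model a trained `gnn_classifier`.
#' @param frame a [simulation_frame()].
#' @return data.frame as in [classify()], plus a `topology` column when the
#'   topology head is enabled.
#' @export
gnn_classify <- function(model, frame) {
  pr <- gnn_predict(model, frame)
  out <- classification_table(pr$poly_probs, model$class_names,
                              pr$molecule_ids)
  if (!is.null(pr$topo_probs)) {
    out$topology <- model$topo_names[max.col(pr$topo_probs,
                                             ties.method = "first")]
  }
  out
}

## --- training ------------------------------------------------------------

#' Train the graph classifier
#'
#' Joint cross-entropy over the polymorph head and (when enabled) the
#' surface/bulk topology head, with equal weights, optimized by Adam one
#' frame-graph per step. Training stops when the test loss has not improved
#' for `patience` epochs and the returned model is the checkpoint at the
#' test-loss minimum.
#'
#' @param samples list of training samples, each a list with `frame` (a
#'   [simulation_frame()]), `poly` (class label per molecule, matching
#'   `class_names`), and optionally `topo` (`"bulk"`/`"surface"` per
#'   molecule) when the topology head is on.
#' @param config a [gnn_config()].
#' @param class_names polymorph class names.
#' @param test_fraction fraction of samples held out as the test split
#'   (at least one sample).
#' @param lr Adam learning rate.
#' @param max_epochs epoch cap.
#' @param patience early-stopping patience in epochs.
#' @param seed RNG seed (weights, shuffling, dropout).
#' @return a trained `gnn_classifier`; `$report` holds train/test loss
#'   trajectories, the best epoch, and parameter count.
#' @export
train_gnn <- function(samples, config, class_names, test_fraction = 0.25,
                      lr = 1e-3, max_epochs = 200L, patience = 30L,
                      seed = 1L) {
  stopifnot(length(samples) >= 2L)
  type_vocab <- sort(unique(unlist(lapply(samples, function(s)
    s$frame$atom_types))))
  model <- gnn_init(config, type_vocab, class_names, seed = seed)
  if (config$topology_head &&
      any(vapply(samples, function(s) is.null(s$topo), TRUE)))
    stop("topology head enabled but some samples lack topology labels")
  prep <- lapply(samples, function(s) {
    graph <- gnn_prepare(s$frame, model)
    poly <- match(as.character(s$poly), class_names)
    if (anyNA(poly)) stop("polymorph label outside class_names")
    topo <- NULL
    if (config$topology_head) {
      topo <- match(as.character(s$topo), model$topo_names)
      if (anyNA(topo)) stop("topology labels must be 'bulk' or 'surface'")
    }
    list(graph = graph, poly = poly, topo = topo)
  })
  set.seed(seed)
  n <- length(prep)
  n_test <- max(1L, floor(n * test_fraction))
  test_idx <- sample(n, n_test)
  train_idx <- setdiff(seq_len(n), test_idx)
  if (length(train_idx) == 0L) stop("no training samples left after split")

  sample_loss <- function(params, s, training = FALSE) {
    m <- model; m$params <- params
    fwd <- gnn_forward(m, s$graph, training = training)
    loss <- cross_entropy(fwd$poly_probs, s$poly)
    if (!is.null(s$topo)) loss <- loss + cross_entropy(fwd$topo_probs, s$topo)
    list(loss = loss, fwd = fwd)
  }
  eval_split <- function(params, idx) {
    mean(vapply(prep[idx], function(s) sample_loss(params, s)$loss, 0))
  }

  params <- model$params
  state <- adam_init(params)
  train_traj <- test_traj <- numeric(0)
  best <- list(params = params, loss = eval_split(params, test_idx),
               epoch = 0L)
  stall <- 0L
  for (epoch in seq_len(max_epochs)) {
    ord <- sample(train_idx)
    ep_loss <- 0
    for (i in ord) {
      s <- prep[[i]]
      sl <- sample_loss(params, s, training = TRUE)
      m <- model; m$params <- params
      grads <- gnn_backward(m, s$graph, sl$fwd, s$poly, s$topo)
      st <- adam_step(params, grads, state, lr = lr)
      params <- st$params; state <- st$state
      ep_loss <- ep_loss + sl$loss
    }
    train_traj <- c(train_traj, ep_loss / length(ord))
    tl <- eval_split(params, test_idx)
    test_traj <- c(test_traj, tl)
    if (tl < best$loss - 1e-6) {
      best <- list(params = params, loss = tl, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  model$params <- best$params
  model$report <- list(train_loss = train_traj, test_loss = test_traj,
                       best_epoch = best$epoch, best_test_loss = best$loss,
                       n_parameters = sum(vapply(model$params, length, 0L)),
                       n_train = length(train_idx), n_test = length(test_idx))
  model
}

#' Save / load a graph-classifier checkpoint (JSON)
#'
#' @param model a `gnn_classifier`.
#' @param path checkpoint file path.
#' @return `path` (save) or the restored model (load).
#' @export
save_gnn <- function(model, path) {
  obj <- list(type = "gnn_classifier", config = unclass(model$config),
              params = lapply(model$params, as.numeric),
              param_dims = lapply(model$params, function(p)
                if (is.matrix(p)) dim(p) else length(p)),
              type_vocab = model$type_vocab, class_names = model$class_names)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_gnn
#' @export
load_gnn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "gnn_classifier"))
    stop("not a gnn_classifier checkpoint")
  cfg <- do.call(gnn_config, obj$config)
  params <- list()
  for (nm in names(obj$params)) {
    dm <- obj$param_dims[[nm]]
    v <- as.numeric(obj$params[[nm]])
    params[[nm]] <- if (length(dm) == 2L) matrix(v, dm[1], dm[2]) else v
  }
  structure(list(config = cfg, params = params,
                 type_vocab = as.character(obj$type_vocab),
                 class_names = as.character(obj$class_names),
                 topo_names = c("bulk", "surface")),
            class = "gnn_classifier")
}
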