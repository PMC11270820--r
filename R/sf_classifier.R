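#' Training configuration
#'
#' @param learning_rate Adam step size.
#' @param max_epochs upper bound on training epochs.
#' @param batch_size minibatch size (capped at the training-set size).
#' @param seed integer seed; training is bit-reproducible for a fixed seed
#'   under single-threaded BLAS.
#' @param convergence_tol relative training-loss change over a 10-epoch
#'   window below which training is declared converged.
#' @param holdout_fraction fraction of samples held out for the report's
#'   held-out accuracy (stratified by class when possible).
#' @return a `training_config` object.
#' @export
training_config <- function(learning_rate = 1e-3, max_epochs = 500L,
                            batch_size = 64L, seed = 1L,
                            convergence_tol = 1e-5,
                            holdout_fraction = 0.2) {
  stopifnot(learning_rate > 0, max_epochs >= 1, batch_size >= 1,
            convergence_tol >= 0, holdout_fraction >= 0, holdout_fraction < 1)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 convergence_tol = convergence_tol,
                 holdout_fraction = holdout_fraction),
            class = "training_config")
}

sf_mlp_forward <- function(params, x) {
  a1 <- lin_fwd(x, params$W1, params$b1); h1 <- gelu(a1)
  a2 <- lin_fwd(h1, params$W2, params$b2); h2 <- gelu(a2)
  logits <- lin_fwd(h2, params$W3, params$b3)
  list(logits = logits, probs = softmax_rows(logits),
       x = x, a1 = a1, h1 = h1, a2 = a2, h2 = h2)
}

sf_mlp_backward <- function(params, fwd, labels) {
  dlog <- ce_logit_grad(fwd$probs, labels)
  g3 <- lin_bwd(dlog, fwd$h2, params$W3)
  dh2 <- g3$dx * gelu_grad(fwd$a2)
  g2 <- lin_bwd(dh2, fwd$h1, params$W2)
  dh1 <- g2$dx * gelu_grad(fwd$a1)
  g1 <- lin_bwd(dh1, fwd$x, params$W1)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
       W3 = g3$dW, b3 = g3$db)
}

#' Train the symmetry-function classifier
#'
#' A small multilayer perceptron — two hidden layers of 25 GeLU units and a
#' softmax output — on per-molecule descriptor vectors. Features are
#' z-scored with training-set statistics stored in the model. Optimized
#' with Adam on the cross-entropy loss until the relative training-loss
#' change over a 10-epoch window falls below `convergence_tol` (or
#' `max_epochs`).
#'
#' @param x molecules x features descriptor matrix (see
#'   [compute_descriptors()]).
#' @param labels class label per row: integer (1-based) or factor/character.
#' @param config a [training_config()].
#' @param class_names optional explicit class-name ordering.
#' @param set optional [descriptor_set()]; its hash is stored so predictions
#'   can verify descriptor compatibility.
#' @param hidden hidden-layer width (default 25).
#' @return an `sf_classifier` model; its `report` element carries the loss
#'   trajectory, epochs run, and held-out accuracy.
#' @export
train_sf_classifier <- function(x, labels, config = training_config(),
                                class_names = NULL, set = NULL, hidden = 25L) {
  x <- as.matrix(x)
  if (is.null(class_names))
    class_names <- if (is.numeric(labels)) as.character(sort(unique(labels)))
                   else levels(factor(labels))
  y <- if (is.numeric(labels)) match(as.character(labels), class_names)
       else match(as.character(labels), class_names)
  if (anyNA(y)) stop("labels outside class_names")
  C <- length(class_names)
  if (C < 2L) stop("training requires at least two classes")
  d <- ncol(x)
  set.seed(config$seed)

  ## stratified holdout
  n <- nrow(x)
  test_idx <- integer(0)
  if (config$holdout_fraction > 0) {
    for (c in seq_len(C)) {
      ic <- which(y == c)
      k <- floor(length(ic) * config$holdout_fraction)
      if (k > 0) test_idx <- c(test_idx, sample(ic, k))
    }
  }
  train_idx <- setdiff(seq_len(n), test_idx)
  if (!all(seq_len(C) %in% y[train_idx]))
    stop("every class must appear in the training split")

  mu <- colMeans(x[train_idx, , drop = FALSE])
  sd <- apply(x[train_idx, , drop = FALSE], 2L, stats::sd)
  sd[sd < 1e-12] <- 1
  xs <- sweep(sweep(x, 2L, mu), 2L, sd, `/`)

  params <- list(W1 = glorot(d, hidden), b1 = numeric(hidden),
                 W2 = glorot(hidden, hidden), b2 = numeric(hidden),
                 W3 = glorot(hidden, C), b3 = numeric(C))
  state <- adam_init(params)
  xt <- xs[train_idx, , drop = FALSE]; yt <- y[train_idx]
  bs <- min(config$batch_size, length(yt))
  loss_traj <- numeric(0)
  full0 <- cross_entropy(sf_mlp_forward(params, xt)$probs, yt)
  best <- list(params = params, loss = full0)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(length(yt))
    for (start in seq(1L, length(yt), by = bs)) {
      sel <- ord[start:min(start + bs - 1L, length(yt))]
      fwd <- sf_mlp_forward(params, xt[sel, , drop = FALSE])
      grads <- sf_mlp_backward(params, fwd, yt[sel])
      st <- adam_step(params, grads, state, lr = config$learning_rate)
      params <- st$params; state <- st$state
    }
    full <- cross_entropy(sf_mlp_forward(params, xt)$probs, yt)
    loss_traj <- c(loss_traj, full)
    if (full < best$loss) best <- list(params = params, loss = full)
    if (epoch > 10L) {
      prev <- loss_traj[epoch - 10L]
      if (abs(prev - full) < config$convergence_tol * max(prev, 1e-12)) break
    }
  }
  params <- best$params

  model <- structure(
    list(layer_sizes = c(d, hidden, hidden, C), params = params,
         scaler = list(mean = mu, sd = sd), class_names = class_names,
         descriptor_set_hash = if (!is.null(set)) descriptor_set_hash(set)
                               else NA_character_,
         config = config),
    class = "sf_classifier")
  holdout_acc <- NA_real_
  if (length(test_idx)) {
    pr <- predict_proba(model, x[test_idx, , drop = FALSE])
    holdout_acc <- mean(max.col(pr, ties.method = "first") == y[test_idx])
  }
  model$report <- list(loss_trajectory = loss_traj,
                       initial_loss = full0, final_loss = best$loss,
                       epochs = length(loss_traj),
                       holdout_accuracy = holdout_acc,
                       n_train = length(train_idx), n_test = length(test_idx))
  model
}

#' @export
print.sf_classifier <- function(x, ...) {
  cat("<sf_classifier> ", paste(x$layer_sizes, collapse = "-"),
      " MLP, classes: ", paste(x$class_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Class probabilities from the symmetry-function classifier
#'
#' @param model an `sf_classifier`.
#' @param x descriptor matrix (raw scale; the model applies its stored
#'   z-score scaler).
#' @return molecules x classes probability matrix; rows sum to 1.
#' @export
predict_proba <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$layer_sizes[1])
    stop("descriptor length ", ncol(x), " does not match model input ",
         model$layer_sizes[1])
  xs <- sweep(sweep(x, 2L, model$scaler$mean), 2L, model$scaler$sd, `/`)
  p <- sf_mlp_forward(model$params, xs)$probs
  colnames(p) <- model$class_names
  p
}

#' Hard classification with tie handling
#'
#' Predicted class is the argmax probability; exact ties are broken toward
#' the lowest class index and flagged.
#'
#' @param model an `sf_classifier` (or any model with a `predict_proba`
#'   giving a matrix) — for the graph classifier use [gnn_classify()].
#' @param x descriptor matrix.
#' @param molecule_ids optional ids carried into the output.
#' @return data.frame with `molecule_id`, `class_label`, `max_prob`,
#'   `tie_flag`, plus one `prob.<class>` column per class.
#' @export
classify <- function(model, x, molecule_ids = NULL) {
  p <- predict_proba(model, x)
  classification_table(p, model$class_names, molecule_ids)
}

classification_table <- function(p, class_names, molecule_ids = NULL) {
  n <- nrow(p)
  if (is.null(molecule_ids)) {
    molecule_ids <- if (!is.null(rownames(p))) as.integer(rownames(p))
                    else seq_len(n) - 1L
  }
  pred <- max.col(p, ties.method = "first")
  mx <- p[cbind(seq_len(n), pred)]
  tie <- rowSums(abs(p - mx) < 1e-12) > 1L
  out <- data.frame(molecule_id = molecule_ids,
                    class_label = class_names[pred],
                    max_prob = mx, tie_flag = tie,
                    stringsAsFactors = FALSE)
  probs <- as.data.frame(p)
  names(probs) <- paste0("prob.", class_names)
  cbind(out, probs)
}

#' Save / load a symmetry-function classifier checkpoint (JSON)
#'
#' @param model an `sf_classifier`.
#' @param path file path for the JSON checkpoint.
#' @return `path` (save) or the restored model (load).
#' @export
save_sf_classifier <- function(model, path) {
  obj <- list(type = "sf_classifier", layer_sizes = model$layer_sizes,
              params = lapply(model$params, as.numeric),
              param_dims = lapply(model$params, function(p)
                if (is.matrix(p)) dim(p) else length(p)),
              scaler = model$scaler, class_names = model$class_names,
              descriptor_set_hash = model$descriptor_set_hash)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_sf_classifier
#' @param path file path of a saved checkpoint.
#' @export
load_sf_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "sf_classifier")) stop("not an sf_classifier checkpoint")
  params <- list()
  for (nm in names(obj$params)) {
    dm <- obj$param_dims[[nm]]
    v <- as.numeric(obj$params[[nm]])
    params[[nm]] <- if (length(dm) == 2L) matrix(v, dm[1], dm[2]) else v
  }
  structure(list(layer_sizes = as.integer(obj$layer_sizes), params = params,
                 scaler = list(mean = as.numeric(obj$scaler$mean),
                               sd = as.numeric(obj$scaler$sd)),
                 class_names = as.character(obj$class_names),
                 descriptor_set_hash = obj$descriptor_set_hash),
            class = "sf_classifier")
}
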