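## Minimal neural-network primitives with analytic gradients.
## Both classifiers are trained with these; there is no external autodiff.

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

## row-wise softmax, numerically stabilized
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

## mean cross-entropy of integer labels (1-based) under row-probabilities
cross_entropy <- function(probs, labels) {
  p <- probs[cbind(seq_along(labels), labels)]
  -mean(log(pmax(p, 1e-12)))
}

## gradient of mean CE wrt logits, given probs
ce_logit_grad <- function(probs, labels) {
  g <- probs
  g[cbind(seq_along(labels), labels)] <-
    g[cbind(seq_along(labels), labels)] - 1
  g / length(labels)
}

## --- layer norm (row-wise, learnable gain/bias) ---------------------------

layernorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = sweep(xhat, 2L, gamma, `*`) + rep(beta, each = nrow(x)),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dy, cache, gamma) {
  xhat <- cache$xhat; inv <- cache$inv
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, gamma, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * inv
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## --- linear layers --------------------------------------------------------

lin_fwd <- function(x, W, b) sweep(x %*% W, 2L, b, `+`)
## returns list(dx, dW, db)
lin_bwd <- function(dy, x, W) {
  list(dx = dy %*% t(W), dW = t(x) %*% dy, db = colSums(dy))
}

## Glorot-uniform init, seeded by the caller's RNG state
glorot <- function(nin, nout) {
  a <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -a, a), nin, nout)
}

## --- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mh <- state$m[[nm]] / bc1
    vh <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

## accumulate a gradient contribution into a (possibly empty) slot
acc <- function(store, nm, val) {
  if (is.null(store[[nm]])) store[[nm]] <- val
  else store[[nm]] <- store[[nm]] + val
  store
}
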