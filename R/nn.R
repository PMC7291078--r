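## Minimal fully-connected network machinery: Glorot init, forward pass with
## caches, backprop, Adam. Layers are lists(W, b, act) with act "relu" or
## "linear"; data flows as rows (cells) x features.

nn_layer <- function(n_in, n_out, act) {
  limit <- sqrt(6 / (n_in + n_out))
  W <- matrix(stats::runif(n_in * n_out, -limit, limit), n_in, n_out)
  list(W = W, b = numeric(n_out), act = act)
}

nn_forward <- function(layers, X, cache = FALSE) {
  A <- X
  caches <- if (cache) vector("list", length(layers))
  for (l in seq_along(layers)) {
    Z <- A %*% layers[[l]]$W
    Z <- sweep(Z, 2L, layers[[l]]$b, "+")
    A_prev <- A
    A <- if (layers[[l]]$act == "relu") pmax(Z, 0) else Z
    if (cache) caches[[l]] <- list(A_prev = A_prev, Z = Z)
  }
  if (cache) list(out = A, caches = caches) else A
}

## G: gradient of the loss w.r.t. the network output. Returns per-layer
## gradients (dW, db).
nn_backward <- function(layers, caches, G) {
  L <- length(layers)
  grads <- vector("list", L)
  delta <- G
  for (l in L:1) {
    if (layers[[l]]$act == "relu") delta <- delta * (caches[[l]]$Z > 0)
    grads[[l]] <- list(dW = crossprod(caches[[l]]$A_prev, delta),
                       db = colSums(delta))
    if (l > 1L) delta <- tcrossprod(delta, layers[[l]]$W)
  }
  grads
}

adam_init <- function(layers) {
  lapply(layers, function(l) list(
    mW = array(0, dim(l$W)), vW = array(0, dim(l$W)),
    mb = numeric(length(l$b)), vb = numeric(length(l$b))))
}

adam_step <- function(layers, grads, state, t, lr, beta1, beta2, eps) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (l in seq_along(layers)) {
    s <- state[[l]]
    g <- grads[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    layers[[l]]$W <- layers[[l]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    layers[[l]]$b <- layers[[l]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[l]] <- s
  }
  list(layers = layers, state = state)
}

#' Corrupt a matrix by random zero-masking
#'
#' Independently sets each entry to zero with probability `rate`, the
#' denoising-autoencoder corruption used during layer-wise pretraining.
#' Entries that are already zero are unaffected by construction. Uses the
#' current R random number generator state.
#'
#' @param x numeric matrix.
#' @param rate corruption probability in `[0, 1)`.
#' @param nonzero_only if `TRUE`, draw corruption indicators only for
#'   non-zero entries (the realized corruption is distributionally identical;
#'   the switch only changes random-number consumption).
#' @return corrupted copy of `x`.
#' @export
corrupt <- function(x, rate = 0.2, nonzero_only = FALSE) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(x)
  if (nonzero_only) {
    idx <- which(x != 0)
    drop <- idx[stats::runif(length(idx)) < rate]
    x[drop] <- 0
  } else {
    x[stats::runif(length(x)) < rate] <- 0
  }
  x
}

## Deterministic minibatch scheduler: shuffled indices, refilled by a fresh
## permutation when depleted ("iterations" are minibatch gradient steps).
batch_maker <- function(n, batch_size) {
  b <- min(batch_size, n)
  queue <- sample.int(n)
  function() {
    if (length(queue) < b) queue <<- c(queue, sample.int(n))
    out <- queue[seq_len(b)]
    queue <<- queue[-seq_len(b)]
    out
  }
}
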