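#' Reconstruction losses
#'
#' Per-cell losses used to train the imputation autoencoders.
#'
#' * `loss_scsdae()` — the mixture loss: mean squared error over observed
#'   (positive) entries of `x` plus `alpha` times the mean absolute value of
#'   the reconstruction at zero entries of `x`. The MSE term anchors the fit
#'   to observed expression; the L1 term shrinks imputed values at zeros so
#'   that true (biological) zeros are not filled in wholesale.
#' * `loss_sdae()` — plain mean squared error over all entries, the classical
#'   denoising-autoencoder loss.
#' * `loss_sdae0()` — mean squared error over observed entries only
#'   (identical to `loss_scsdae()` with `alpha = 0`); ignores all information
#'   carried by the zeros.
#'
#' A vector with no zero entries contributes no sparsity term; a vector with
#' no positive entries (impossible after filtering) contributes no MSE term.
#'
#' @param x numeric vector of target (uncorrupted, normalized) values.
#' @param x_prime numeric vector of reconstructed values, same length.
#' @param alpha non-negative weight of the L1 sparsity penalty.
#' @return a single numeric loss value.
#' @examples
#' loss_scsdae(c(2, 0, 1, 0), c(1, 0.5, 1, 0), alpha = 1)  # 0.75
#' loss_sdae(c(2, 0), c(1, 1))                             # 1
#' loss_sdae0(c(2, 0, 1, 0), c(1, 9, 1, 9))                # 0.5
#' @export
loss_scsdae <- function(x, x_prime, alpha = 1) {
  check_pair(x, x_prime)
  if (alpha < 0) stop("'alpha' must be non-negative")
  pos <- x > 0
  mse <- if (any(pos)) mean((x[pos] - x_prime[pos])^2) else 0
  l1 <- if (any(!pos)) mean(abs(x_prime[!pos])) else 0
  mse + alpha * l1
}

#' @rdname loss_scsdae
#' @export
loss_sdae <- function(x, x_prime) {
  check_pair(x, x_prime)
  mean((x - x_prime)^2)
}

#' @rdname loss_scsdae
#' @export
loss_sdae0 <- function(x, x_prime) {
  loss_scsdae(x, x_prime, alpha = 0)
}

check_pair <- function(x, x_prime) {
  if (length(x) != length(x_prime))
    stop("'x' and 'x_prime' must have the same length")
  invisible(NULL)
}

## Batch (rows = cells) versions used in training. Loss is the mean over
## cells of the per-cell loss; gradients are with respect to the network
## output Xp.
batch_loss <- function(X, Xp, variant, alpha) {
  if (variant == "sdae") return(mean((X - Xp)^2))
  pos <- X > 0
  npos <- rowSums(pos)
  nzero <- ncol(X) - npos
  se <- rowSums(((X - Xp)^2) * pos)
  mse <- ifelse(npos > 0, se / npos, 0)
  if (variant == "scsdae" && alpha > 0) {
    l1 <- rowSums(abs(Xp) * !pos)
    l1 <- ifelse(nzero > 0, l1 / nzero, 0)
    mean(mse + alpha * l1)
  } else {
    mean(mse)
  }
}

batch_loss_grad <- function(X, Xp, variant, alpha) {
  b <- nrow(X)
  if (variant == "sdae") return(2 * (Xp - X) / (length(X)))
  pos <- X > 0
  npos <- rowSums(pos)
  nzero <- ncol(X) - npos
  G <- 2 * (Xp - X) * pos / pmax(npos, 1L)
  if (variant == "scsdae" && alpha > 0) {
    G <- G + alpha * sign(Xp) * (!pos) / pmax(nzero, 1L)
  }
  G / b
}
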