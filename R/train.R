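#' Training control parameters
#'
#' Collects optimizer and training-schedule settings for [scsdae()] and the
#' lower-level training functions. Defaults follow common practice for Adam
#' and the reference training schedule for these networks: corruption rate
#' 0.2 for every pretraining input layer, minibatches of 256 cells, 1000
#' pretraining steps per layer, and 2000 fine-tuning steps. "Iterations" are
#' minibatch gradient steps drawn by seeded shuffling with cycling, not
#' epochs; for datasets smaller than `batch_size` the whole dataset is one
#' batch.
#'
#' @param corruption_rate probability in `[0, 1)` of zero-masking each entry
#'   of a pretraining input.
#' @param pretrain_iters minibatch steps used to pretrain each layer.
#' @param finetune_iters minibatch steps used to fine-tune the stacked
#'   network (no corruption).
#' @param batch_size minibatch size (cells).
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters.
#' @param clip if `TRUE`, imputed values are clamped at zero (expression is
#'   non-negative; the linear output layer can produce negatives).
#' @param corrupt_nonzero_only if `TRUE`, corruption indicators are drawn
#'   only for non-zero entries (equivalent in distribution; see [corrupt()]).
#' @param log_every report the training loss every this many steps when
#'   `verbose`.
#' @param verbose print progress messages.
#' @return a list of class `"scsdae_control"`.
#' @export
scsdae_control <- function(corruption_rate = 0.2,
                           pretrain_iters = 1000L,
                           finetune_iters = 2000L,
                           batch_size = 256L,
                           learning_rate = 1e-3,
                           beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7,
                           clip = TRUE,
                           corrupt_nonzero_only = FALSE,
                           log_every = 100L,
                           verbose = FALSE) {
  stopifnot(corruption_rate >= 0, corruption_rate < 1,
            pretrain_iters >= 0, finetune_iters >= 0, batch_size >= 1)
  structure(list(corruption_rate = corruption_rate,
                 pretrain_iters = as.integer(pretrain_iters),
                 finetune_iters = as.integer(finetune_iters),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 clip = clip,
                 corrupt_nonzero_only = corrupt_nonzero_only,
                 log_every = as.integer(log_every),
                 verbose = verbose),
            class = "scsdae_control")
}

## Core minibatch training loop for an arbitrary layer stack.
## `data` supplies both the (to be corrupted) input and the reconstruction
## target; the variant decides the loss/gradient. Returns updated layers and
## the per-step loss log.
train_net <- function(layers, data, iters, variant, alpha, control,
                      corruption_rate, tag = "train") {
  if (iters == 0L) return(list(layers = layers, loss = numeric(0)))
  next_batch <- batch_maker(nrow(data), control$batch_size)
  state <- adam_init(layers)
  loss_log <- numeric(iters)
  for (t in seq_len(iters)) {
    Xb <- data[next_batch(), , drop = FALSE]
    Xin <- corrupt(Xb, corruption_rate, control$corrupt_nonzero_only)
    fw <- nn_forward(layers, Xin, cache = TRUE)
    loss <- batch_loss(Xb, fw$out, variant, alpha)
    if (!is.finite(loss))
      stop(sprintf("non-finite %s loss (%.4g) at step %d; try a lower learning rate",
                   tag, loss, t))
    loss_log[t] <- loss
    grads <- nn_backward(layers, fw$caches, batch_loss_grad(Xb, fw$out, variant, alpha))
    upd <- adam_step(layers, grads, state, t, control$learning_rate,
                     control$beta1, control$beta2, control$epsilon)
    layers <- upd$layers
    state <- upd$state
    if (control$verbose && t %% control$log_every == 0L)
      message(sprintf("[%s] step %d/%d loss %.6f", tag, t, iters, loss))
  }
  list(layers = layers, loss = loss_log)
}

#' Greedy layer-wise pretraining of the stacked autoencoder
#'
#' Trains one denoising autoencoder per layer. The first maps the normalized
#' expression (width `n`) to `dims[1]` and back, minimizing the loss of the
#' chosen variant against the uncorrupted input; deeper layers map the
#' previous (uncorrupted) hidden representation down and back, minimizing
#' plain MSE. Each autoencoder's input is corrupted at
#' `control$corruption_rate`; after training, the hidden representation is
#' computed on uncorrupted input and passed to the next layer.
#'
#' @param x normalized expression matrix (cells x genes).
#' @param dims integer vector of hidden-layer widths `(d_1, ..., d_k)`; the
#'   last entry is the bottleneck. Hidden layers use ReLU except the
#'   bottleneck and reconstruction outputs, which are linear.
#' @param variant `"scsdae"`, `"sdae"`, or `"sdae0"`; selects the loss of the
#'   first (input-facing) autoencoder and of fine-tuning.
#' @param alpha sparsity-penalty weight (used by the `"scsdae"` variant).
#' @param control a [scsdae_control()] list.
#' @return a list of `k` pretrained autoencoders, each with elements
#'   `encoder`, `decoder` (weight/bias/activation lists) and `loss`
#'   (per-step training loss).
#' @export
pretrain_layers <- function(x, dims, variant = "scsdae", alpha = 1,
                            control = scsdae_control()) {
  variant <- match.arg(variant, c("scsdae", "sdae", "sdae0"))
  dims <- as.integer(dims)
  stopifnot(length(dims) >= 1L, all(dims > 0))
  k <- length(dims)
  widths <- c(ncol(x), dims)
  H <- x
  out <- vector("list", k)
  for (i in seq_len(k)) {
    enc_act <- if (i == k) "linear" else "relu"
    dec_act <- if (i == 1L) "linear" else "relu"
    layers <- list(nn_layer(widths[i], widths[i + 1L], enc_act),
                   nn_layer(widths[i + 1L], widths[i], dec_act))
    v <- if (i == 1L) variant else "sdae"
    tr <- train_net(layers, H, control$pretrain_iters, v, alpha, control,
                    corruption_rate = control$corruption_rate,
                    tag = sprintf("pretrain L%d", i))
    out[[i]] <- list(encoder = tr$layers[[1L]], decoder = tr$layers[[2L]],
                     loss = tr$loss)
    H <- nn_forward(tr$layers[1L], H)
  }
  out
}

#' Stack pretrained layers and fine-tune the deep network
#'
#' Assembles the full symmetric network
#' `x' = g_1 o ... o g_k (f_k o ... o f_1 (x))` from the pretrained encoder
#' and decoder weights and fine-tunes it (without corruption) under the
#' variant loss. With `control$finetune_iters = 0` the returned network's
#' forward pass equals the composition of the pretrained layers exactly.
#'
#' @inheritParams pretrain_layers
#' @param pretrained the list returned by [pretrain_layers()].
#' @return an object of class `"scsdae_net"`: list with `layers` (the full
#'   stack), `dims`, `variant`, `alpha`, and `loss` (fine-tuning log).
#' @export
stack_and_finetune <- function(x, pretrained, variant = "scsdae", alpha = 1,
                               control = scsdae_control()) {
  variant <- match.arg(variant, c("scsdae", "sdae", "sdae0"))
  k <- length(pretrained)
  layers <- c(lapply(pretrained, `[[`, "encoder"),
              lapply(rev(pretrained), `[[`, "decoder"))
  tr <- train_net(layers, x, control$finetune_iters, variant, alpha, control,
                  corruption_rate = 0, tag = "finetune")
  structure(list(layers = tr$layers,
                 dims = c(ncol(x), vapply(pretrained, function(p) ncol(p$encoder$W), 1L)),
                 variant = variant, alpha = alpha, loss = tr$loss),
            class = "scsdae_net")
}

#' Mask-preserving imputation
#'
#' Runs the trained network forward on the uncorrupted input and combines
#' output and input through the observed-value mask:
#' `x_imputed = x_out * (1 - m) + x * m`. Observed entries are returned
#' bit-identical to the input; only zeros are replaced by network output
#' (clamped at zero when `clip`).
#'
#' @param x normalized expression matrix.
#' @param model a trained `"scsdae_net"` (from [stack_and_finetune()]).
#' @param mask logical observed-value mask, as from [zero_mask()].
#' @param clip clamp imputed values at zero.
#' @return list with `imputed`, `output` (raw network output), and `mask`.
#' @export
impute_matrix <- function(x, model, mask = zero_mask(x), clip = TRUE) {
  stopifnot(inherits(model, "scsdae_net"))
  if (ncol(x) != model$dims[1L])
    stop(sprintf("model expects %d genes, input has %d", model$dims[1L], ncol(x)))
  if (!identical(dim(mask), dim(x))) stop("'mask' shape does not match 'x'")
  xout <- nn_forward(model$layers, x)
  imputed <- x  # observed entries stay bit-identical, attributes preserved
  repl <- xout[!mask]
  imputed[!mask] <- if (clip) pmax(repl, 0) else repl
  dimnames(xout) <- dimnames(x)
  list(imputed = imputed, output = xout, mask = mask)
}
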