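#' Fit a sparsity-penalized stacked denoising autoencoder and impute zeros
#'
#' End-to-end imputation of an expression matrix: filters unexpressed cells
#' and genes, applies library-size log normalization (logCPM), pretrains a
#' stacked denoising autoencoder greedily layer by layer with input
#' corruption, fine-tunes the stacked network, and returns the imputed
#' matrix in which every observed (non-zero) value is preserved exactly and
#' only zeros are replaced by the network reconstruction.
#'
#' Three loss variants are available. `"scsdae"` (the default) trains the
#' first autoencoder and the fine-tuning under the mixture loss
#' \deqn{L(x, x') = \frac{1}{\#\{j: x_j>0\}}\sum_{x_j>0}(x_j-x_j')^2
#'   + \alpha \frac{1}{\#\{j: x_j=0\}}\sum_{x_j=0}|x_j'|,}
#' so reconstruction is anchored to observed values while the L1 term
#' shrinks output at zero entries, discouraging wholesale imputation of true
#' biological zeros. `"sdae"` uses plain MSE over all entries and `"sdae0"`
#' the observed-entry MSE only (equivalent to `alpha = 0`). Internal
#' (hidden-to-hidden) pretraining autoencoders always use plain MSE.
#'
#' The encoder is a fully connected network with ReLU activations on all
#' hidden layers except the bottleneck; the bottleneck and the final output
#' are linear, and the decoder mirrors the encoder widths.
#'
#' @param counts non-negative expression matrix, cells in rows and genes in
#'   columns (raw counts or intensities), or an already normalized matrix if
#'   `normalized = TRUE`.
#' @param dims hidden-layer widths of the encoder, bottleneck last. The
#'   reference architecture is `c(500, 500, 2000, 10)`; smaller stacks are
#'   appropriate for smaller matrices.
#' @param variant loss variant: `"scsdae"`, `"sdae"`, or `"sdae0"`.
#' @param alpha non-negative sparsity-penalty weight. `1` works well for
#'   single-cell data (values in `(0.1, 1)` are a reasonable range); use a
#'   small value such as `0.001` when the zeros are known to be almost all
#'   technical, as in downsampled bulk data.
#' @param normalized set to `TRUE` when `counts` is already on the
#'   normalized log scale (it is then used as-is, without filtering).
#' @param log_base base of the normalization logarithm.
#' @param seed integer seed making the whole fit reproducible; `NULL` uses
#'   the current RNG state.
#' @param control a [scsdae_control()] list of training settings; the
#'   `...` arguments are passed to [scsdae_control()] for convenience.
#' @param ... further arguments to [scsdae_control()].
#' @return an object of class `"scsdae"`: a list with components
#'   \item{imputed}{the imputed matrix (normalized scale), observed entries
#'     preserved exactly,}
#'   \item{output}{the raw network reconstruction,}
#'   \item{x}{the normalized input matrix,}
#'   \item{mask}{the observed-value indicator,}
#'   \item{model}{the trained `"scsdae_net"`,}
#'   \item{pretrain_loss, finetune_loss}{training loss logs,}
#'   and the call, variant, `alpha`, dims and control settings.
#'   Methods: [print()], [summary()], [predict.scsdae()], [coef()],
#'   [fitted()], [residuals()], [plot()].
#' @examples
#' set.seed(1)
#' counts <- matrix(rpois(50 * 40, 5), 50, 40)
#' counts[sample(length(counts), 500)] <- 0
#' fit <- scsdae(counts, dims = c(16, 4), alpha = 1, seed = 1,
#'               pretrain_iters = 50, finetune_iters = 100)
#' fit
#' max(abs(fitted(fit)[fit$mask] - fit$x[fit$mask]))  # observed preserved: 0
#' @export
scsdae <- function(counts, dims = c(500, 500, 2000, 10),
                   variant = c("scsdae", "sdae", "sdae0"),
                   alpha = 1,
                   normalized = FALSE,
                   log_base = exp(1),
                   seed = NULL,
                   control = scsdae_control(...),
                   ...) {
  variant <- match.arg(variant)
  if (alpha < 0) stop("'alpha' must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  cl <- match.call()

  if (normalized) {
    x <- as_count_matrix(counts)
    lib <- attr(counts, "library_sizes")
  } else {
    counts <- filter_matrix(counts)
    x <- normalize_cpm(counts, base = log_base)
    lib <- attr(x, "library_sizes")
  }
  mask <- zero_mask(x)

  pre <- pretrain_layers(x, dims, variant, alpha, control)
  model <- stack_and_finetune(x, pre, variant, alpha, control)
  imp <- impute_matrix(x, model, mask, clip = control$clip)

  structure(list(imputed = imp$imputed,
                 output = imp$output,
                 x = x,
                 mask = mask,
                 model = model,
                 pretrain_loss = lapply(pre, `[[`, "loss"),
                 finetune_loss = model$loss,
                 dims = as.integer(dims),
                 variant = variant,
                 alpha = alpha,
                 log_base = log_base,
                 library_sizes = lib,
                 seed = seed,
                 control = control,
                 call = cl),
            class = "scsdae")
}

#' @export
print.scsdae <- function(x, ...) {
  cat(sprintf("Stacked denoising autoencoder imputation (variant: %s)\n", x$variant))
  cat(sprintf("  %d cells x %d genes; architecture %s\n",
              nrow(x$x), ncol(x$x),
              paste(c(ncol(x$x), x$dims), collapse = "-")))
  nz <- sum(!x$mask)
  cat(sprintf("  zeros imputed: %d (%.1f%% of entries); alpha = %g\n",
              nz, 100 * nz / length(x$mask), x$alpha))
  if (length(x$finetune_loss))
    cat(sprintf("  final fine-tuning loss: %.5f\n",
                mean(utils::tail(x$finetune_loss, 100))))
  invisible(x)
}

#' @export
summary.scsdae <- function(object, ...) {
  imputed_vals <- object$imputed[!object$mask]
  out <- list(variant = object$variant,
              alpha = object$alpha,
              n_cells = nrow(object$x),
              n_genes = ncol(object$x),
              dims = object$dims,
              zero_fraction = mean(!object$mask),
              imputed_nonzero_fraction = mean(imputed_vals > 0),
              imputed_mean = mean(imputed_vals),
              pretrain_final_loss = vapply(object$pretrain_loss, function(l)
                if (length(l)) mean(utils::tail(l, 100)) else NA_real_, 0),
              finetune_final_loss = if (length(object$finetune_loss))
                mean(utils::tail(object$finetune_loss, 100)) else NA_real_)
  class(out) <- "summary.scsdae"
  out
}

#' @export
print.summary.scsdae <- function(x, ...) {
  cat(sprintf("scSDAE fit (%s, alpha = %g): %d cells x %d genes, dims %s\n",
              x$variant, x$alpha, x$n_cells, x$n_genes,
              paste(x$dims, collapse = "-")))
  cat(sprintf("  input zero fraction:          %.3f\n", x$zero_fraction))
  cat(sprintf("  imputed entries left nonzero: %.3f\n", x$imputed_nonzero_fraction))
  cat(sprintf("  mean imputed value:           %.4f\n", x$imputed_mean))
  cat(sprintf("  pretrain loss (smoothed):     %s\n",
              paste(sprintf("%.4f", x$pretrain_final_loss), collapse = ", ")))
  cat(sprintf("  finetune loss (smoothed):     %.4f\n", x$finetune_final_loss))
  invisible(x)
}

#' Impute new data with a fitted scSDAE model
#'
#' Applies a trained network to new cells measured on the same genes. The
#' new matrix is normalized with the same scheme as the training data
#' (unless `normalized = TRUE`) and imputed with mask preservation.
#'
#' @param object a fitted `"scsdae"` object.
#' @param newdata cells x genes matrix on the same genes as the training
#'   data; defaults to the training input.
#' @param normalized is `newdata` already on the normalized log scale?
#' @param ... unused.
#' @return the imputed matrix.
#' @export
predict.scsdae <- function(object, newdata = NULL, normalized = FALSE, ...) {
  if (is.null(newdata)) return(object$imputed)
  x <- if (normalized) as_count_matrix(newdata)
       else normalize_cpm(as_count_matrix(newdata), base = object$log_base)
  impute_matrix(x, object$model, zero_mask(x), clip = object$control$clip)$imputed
}

#' @export
fitted.scsdae <- function(object, ...) object$imputed

#' Reconstruction residuals on observed entries
#'
#' @param object a fitted `"scsdae"` object.
#' @param ... unused.
#' @return matrix of `x - output` with `NA` at unobserved (zero) entries.
#' @export
residuals.scsdae <- function(object, ...) {
  r <- object$x - object$output
  r[!object$mask] <- NA_real_
  r
}

#' Network weights of a fitted model
#'
#' @param object a fitted `"scsdae"` object.
#' @param ... unused.
#' @return list of per-layer lists with `W`, `b` and activation, encoder
#'   layers first, then decoder layers.
#' @export
coef.scsdae <- function(object, ...) object$model$layers

#' Training loss curves
#'
#' Plots the per-step training loss of each pretraining autoencoder and of
#' the fine-tuning phase.
#'
#' @param x a fitted `"scsdae"` object.
#' @param which `"finetune"`, `"pretrain"`, or `"both"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.scsdae <- function(x, which = c("both", "finetune", "pretrain"), ...) {
  which <- match.arg(which)
  show_pre <- which != "finetune" && any(lengths(x$pretrain_loss) > 0)
  show_ft <- which != "pretrain" && length(x$finetune_loss) > 0
  np <- show_pre * length(x$pretrain_loss) + show_ft
  if (np == 0L) stop("no recorded training steps to plot")
  old <- graphics::par(mfrow = c(1, np), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  if (show_pre)
    for (i in seq_along(x$pretrain_loss))
      graphics::plot(x$pretrain_loss[[i]], type = "l", xlab = "step",
                     ylab = "loss", main = sprintf("pretrain layer %d", i), ...)
  if (show_ft)
    graphics::plot(x$finetune_loss, type = "l", xlab = "step",
                   ylab = "loss", main = "fine-tune", ...)
  invisible(x)
}
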