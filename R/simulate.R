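#' Simulated dataset container
#'
#' All simulators return an object of class `"scsdae_sim"`: a list with
#' `truth` (ground-truth matrix), `observed` (matrix after simulated
#' dropout), `dropout_mask` (logical; `TRUE` where a positive true value was
#' zeroed by the simulation — true zeros are never flagged), `group_labels`
#' (per-cell integers or `NULL`), `de_flags` (per-gene logicals or `NULL`),
#' and `params` (the generating parameters). `observed` equals `truth`
#' wherever `dropout_mask` is `FALSE` and is zero where it is `TRUE`.
#'
#' @param x an `"scsdae_sim"` object.
#' @param ... unused.
#' @name scsdae_sim
NULL

new_sim <- function(truth, observed, dropout_mask, group_labels = NULL,
                    de_flags = NULL, params = list()) {
  structure(list(truth = truth, observed = observed,
                 dropout_mask = dropout_mask,
                 group_labels = group_labels, de_flags = de_flags,
                 params = params),
            class = "scsdae_sim")
}

#' @rdname scsdae_sim
#' @export
print.scsdae_sim <- function(x, ...) {
  cat(sprintf("Simulated expression data (%s): %d cells x %d genes\n",
              x$params$design %||% "custom", nrow(x$truth), ncol(x$truth)))
  cat(sprintf("  zero fraction: truth %.3f, observed %.3f; dropouts: %d\n",
              mean(x$truth == 0), mean(x$observed == 0), sum(x$dropout_mask)))
  if (!is.null(x$group_labels))
    cat(sprintf("  groups: %s\n",
                paste(table(x$group_labels), collapse = " / ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Smooth bulk-like expression profiles along a latent trajectory
#'
#' Generates positive, microarray-like expression profiles for samples
#' ordered along a latent time, such as a developmental time course. Each
#' gene follows a smooth random trajectory (Gaussian-kernel-smoothed white
#' noise on the log scale) with gene-specific baseline and amplitude, so
#' neighbouring samples are highly correlated and the sample-sample
#' correlation matrix is banded around the diagonal. As
#' `trajectory_smoothness` grows the profiles flatten; in the limit all
#' samples are identical.
#'
#' @param n_samples number of samples (ordered along the trajectory).
#' @param n_genes number of genes.
#' @param trajectory_smoothness kernel length-scale as a fraction of the
#'   trajectory length; `0.15` gives the clear banded structure typical of
#'   a dense developmental time course.
#' @param baseline_mean,baseline_sd log-scale baseline expression per gene.
#' @param amplitude_range range of per-gene trajectory amplitudes (log
#'   scale).
#' @return a positive `n_samples x n_genes` matrix with dimnames.
#' @export
make_bulklike_profiles <- function(n_samples = 206, n_genes = 2000,
                                   trajectory_smoothness = 0.15,
                                   baseline_mean = 5, baseline_sd = 1.5,
                                   amplitude_range = c(0.5, 2)) {
  stopifnot(n_samples >= 3, n_genes >= 1, trajectory_smoothness > 0)
  ell <- trajectory_smoothness * n_samples
  d <- outer(seq_len(n_samples), seq_len(n_samples), "-")
  K <- exp(-0.5 * (d / ell)^2)
  K <- K / rowSums(K)
  ## scale rows so each smoothed value has unit variance; in the
  ## smoothness -> Inf limit every row of K is uniform and all samples
  ## share one value per gene (identical samples)
  C <- (K %*% matrix(stats::rnorm(n_samples * n_genes), n_samples, n_genes)) *
    (1 / sqrt(rowSums(K^2)))
  mu <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  amp <- stats::runif(n_genes, amplitude_range[1L], amplitude_range[2L])
  X <- exp(sweep(sweep(C, 2L, amp, "*"), 2L, mu, "+"))
  dimnames(X) <- list(paste0("sample", seq_len(n_samples)),
                      paste0("gene", seq_len(n_genes)))
  X
}

#' Downsample a matrix under a logistic capture-probability model
#'
#' Emulates technical dropout: the logit of the probability that a value is
#' captured (retained) depends linearly on the log of its true magnitude,
#' `P(captured) = sigmoid(intercept + slope * log(value))`, so small values
#' drop out preferentially. The intercept is solved by root finding so that
#' the expected overall zero fraction (pre-existing zeros plus expected
#' dropouts) matches `target_zero_rate` to within `1e-4`; each positive
#' entry is then retained by an independent Bernoulli draw.
#'
#' @param bulk positive expression matrix (samples x genes), e.g. from
#'   [make_bulklike_profiles()].
#' @param target_zero_rate desired overall zero fraction in `(0, 1)`; must
#'   exceed the matrix's pre-existing zero fraction.
#' @param slope positive slope of the capture model on the log scale.
#' @return an [`scsdae_sim`] object; `params$intercept` records the solved
#'   intercept.
#' @export
logistic_downsample <- function(bulk, target_zero_rate, slope = 1) {
  bulk <- as_count_matrix(bulk)
  stopifnot(target_zero_rate > 0, target_zero_rate < 1, slope > 0)
  pos <- bulk > 0
  z0 <- mean(!pos)
  if (target_zero_rate <= z0)
    stop(sprintf("unreachable sparsity: target %.3f <= pre-existing zero fraction %.3f",
                 target_zero_rate, z0))
  lv <- log(bulk[pos])
  n <- length(bulk)
  expected_zero <- function(b0)
    (sum(!pos) + sum(1 - stats::plogis(b0 + slope * lv))) / n
  root <- stats::uniroot(function(b0) expected_zero(b0) - target_zero_rate,
                         lower = -500, upper = 500, tol = 1e-9)
  b0 <- root$root
  if (abs(expected_zero(b0) - target_zero_rate) > 1e-4)
    stop("failed to calibrate the dropout intercept to the target zero rate")
  p_capture <- stats::plogis(b0 + slope * lv)
  captured <- stats::runif(length(lv)) < p_capture
  observed <- bulk
  observed[pos][!captured] <- 0
  dropout <- matrix(FALSE, nrow(bulk), ncol(bulk), dimnames = dimnames(bulk))
  dropout[pos][!captured] <- TRUE
  new_sim(bulk, observed, dropout,
          params = list(design = "logistic_downsample",
                        target_zero_rate = target_zero_rate,
                        slope = slope, intercept = b0,
                        realized_zero_rate = mean(observed == 0)))
}

#' Negative-binomial two-group count simulation
#'
#' Simulates a count matrix with two balanced cell groups for false-signal
#' benchmarking. Per-gene base means are drawn log-uniformly on
#' `[mean_low, mean_high]`; the first `ceiling(de_fraction * n_genes)` genes
#' are differentially expressed, with the group-2 mean multiplied or divided
#' by `fold_change` in alternation (so library sizes stay balanced), and
#' the remaining genes share one mean across groups. Counts are negative
#' binomial with size parameter `dispersion` (variance
#' `mu + mu^2/dispersion`); zeros arise naturally from sampling.
#'
#' @param n_cells,n_genes matrix dimensions; cells are split as evenly as
#'   possible between the two groups.
#' @param mean_low,mean_high range of per-gene base means.
#' @param de_fraction fraction of genes differentially expressed.
#' @param fold_change multiplicative group effect on DE genes.
#' @param dispersion negative-binomial size (inverse-overdispersion); large
#'   values approach Poisson.
#' @return an [`scsdae_sim`] object with `group_labels` (1/2) and
#'   `de_flags`; `dropout_mask` is all-`FALSE` (all zeros are sampling
#'   zeros).
#' @export
simulate_nb_two_group <- function(n_cells = 1000, n_genes = 500,
                                  mean_low = 1e3, mean_high = 1e4,
                                  de_fraction = 0.5, fold_change = 3,
                                  dispersion = 0.5) {
  stopifnot(n_cells >= 4, n_genes >= 2, mean_low > 0, mean_high >= mean_low,
            de_fraction >= 0, de_fraction <= 1, fold_change >= 1)
  if (dispersion <= 0) stop("'dispersion' must be positive")
  base_mean <- exp(stats::runif(n_genes, log(mean_low), log(mean_high)))
  n_de <- ceiling(de_fraction * n_genes)
  de <- seq_len(n_genes) <= n_de
  fc <- rep(1, n_genes)
  if (n_de > 0)
    fc[de] <- ifelse(seq_len(n_de) %% 2L == 1L, fold_change, 1 / fold_change)
  groups <- rep(1:2, length.out = n_cells)
  groups <- sort(groups)
  mu <- outer(rep(1, n_cells), base_mean)
  mu[groups == 2L, ] <- sweep(mu[groups == 2L, , drop = FALSE], 2L, fc, "*")
  counts <- matrix(stats::rnbinom(n_cells * n_genes, mu = mu, size = dispersion),
                   n_cells, n_genes,
                   dimnames = list(paste0("cell", seq_len(n_cells)),
                                   paste0("gene", seq_len(n_genes))))
  new_sim(counts, counts,
          matrix(FALSE, n_cells, n_genes, dimnames = dimnames(counts)),
          group_labels = groups, de_flags = de,
          params = list(design = "nb_two_group", mean_low = mean_low,
                        mean_high = mean_high, de_fraction = de_fraction,
                        fold_change = fold_change, dispersion = dispersion))
}

#' Spike artificial genes with controlled dropout into a matrix
#'
#' Appends `n_genes` artificial gene columns to a normalized expression
#' matrix: cells of group A draw from `Normal(mean_a, sd^2)` and cells of
#' group B from `Normal(mean_b, sd^2)`, clamped at zero (so with
#' `mean_a = 0` group A contains true zeros). Positive spiked values are
#' then zeroed independently with a probability chosen so the overall zero
#' fraction of the spiked columns reaches `zero_rate`. Group-A zeros act as
#' true biological zeros that should not be imputed; group-B zeros are
#' technical dropouts that should.
#'
#' @param x normalized expression matrix (cells x genes).
#' @param group_labels per-cell labels with exactly two distinct values;
#'   the first sorted value is group A.
#' @param n_genes number of artificial genes to append.
#' @param mean_a,mean_b group means of the spiked values.
#' @param sd common standard deviation (`sqrt(0.1)` by default, i.e.
#'   variance 0.1).
#' @param zero_rate target overall zero fraction of the spiked columns.
#' @return an [`scsdae_sim`] object whose matrices contain the original
#'   columns followed by the spiked ones; `params$spiked_cols` gives the
#'   spiked column indices and `de_flags` marks them.
#' @export
spike_artificial_genes <- function(x, group_labels, n_genes = 5,
                                   mean_a = 0, mean_b = 2, sd = sqrt(0.1),
                                   zero_rate = 0.5) {
  x <- as_count_matrix(x)
  stopifnot(length(group_labels) == nrow(x), zero_rate >= 0, zero_rate < 1,
            n_genes >= 1, sd > 0)
  lv <- sort(unique(group_labels))
  if (length(lv) != 2L) stop("exactly two groups are required")
  a <- group_labels == lv[1L]
  S <- matrix(0, nrow(x), n_genes)
  S[a, ] <- stats::rnorm(sum(a) * n_genes, mean_a, sd)
  S[!a, ] <- stats::rnorm(sum(!a) * n_genes, mean_b, sd)
  S <- pmax(S, 0)
  z0 <- mean(S == 0)
  p_drop <- if (zero_rate > z0) (zero_rate - z0) / (1 - z0) else 0
  drop <- S > 0 & matrix(stats::runif(length(S)) < p_drop, nrow(S))
  observed_sp <- S
  observed_sp[drop] <- 0
  spiked_cols <- ncol(x) + seq_len(n_genes)
  colnames_sp <- paste0("artificial", seq_len(n_genes))
  truth <- cbind(x, S)
  observed <- cbind(x, observed_sp)
  dropout <- cbind(matrix(FALSE, nrow(x), ncol(x)), drop)
  cn <- c(colnames(x) %||% paste0("gene", seq_len(ncol(x))), colnames_sp)
  rn <- rownames(x) %||% paste0("cell", seq_len(nrow(x)))
  dimnames(truth) <- dimnames(observed) <- dimnames(dropout) <- list(rn, cn)
  new_sim(truth, observed, dropout,
          group_labels = group_labels,
          de_flags = seq_len(ncol(truth)) %in% spiked_cols,
          params = list(design = "spike_artificial_genes",
                        spiked_cols = spiked_cols, mean_a = mean_a,
                        mean_b = mean_b, sd = sd, zero_rate = zero_rate,
                        drop_prob = p_drop,
                        realized_zero_rate = mean(observed_sp == 0)))
}
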