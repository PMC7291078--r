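#' Evaluation report for an imputed matrix
#'
#' Computes every applicable evaluation statistic given an imputed matrix,
#' its ground truth, and optional annotations: correlation matrix distance
#' (CMD) between sample-sample correlation structures, mean per-sample
#' Pearson correlation with the truth, gene-gene false-signal FDR/TPR
#' (Spearman + Bonferroni, when DE flags are given), Kruskal-Wallis DE
#' sensitivity/specificity (when groups and DE flags are given), and
#' per-group MAE on spiked genes (when spiked columns and groups are given).
#'
#' @param imputed,truth matrices of equal shape (cells x genes), on a
#'   comparable (normalized) scale.
#' @param groups optional per-cell group labels.
#' @param de_flags optional per-gene logical DE flags.
#' @param spiked_cols optional indices of spiked gene columns.
#' @param alpha_fw family-wise level for gene-gene detection.
#' @param fdr_level Benjamini-Hochberg level for the Kruskal-Wallis screen.
#' @return a named list of metric values.
#' @export
evaluate_imputation <- function(imputed, truth, groups = NULL,
                                de_flags = NULL, spiked_cols = NULL,
                                alpha_fw = 0.05, fdr_level = 0.05) {
  if (!identical(dim(imputed), dim(truth))) stop("shape mismatch")
  rep <- list(
    cmd = cmd(correlation_matrix(truth, "samples"),
              correlation_matrix(imputed, "samples")),
    mean_pairwise_pearson = mean(pairwise_pearson_truth(imputed, truth),
                                 na.rm = TRUE))
  if (!is.null(de_flags)) {
    det <- gene_gene_significance(imputed, alpha_fw)
    ft <- fdr_tpr(det, de_flags)
    rep$fdr <- unname(ft["fdr"])
    rep$tpr <- unname(ft["tpr"])
    if (!is.null(groups)) {
      ss <- kw_de_eval(imputed, groups, de_flags, fdr_level)
      rep$sensitivity <- unname(ss["sensitivity"])
      rep$specificity <- unname(ss["specificity"])
    }
  }
  if (!is.null(spiked_cols) && !is.null(groups)) {
    mae <- group_mae(imputed, truth, spiked_cols, groups)
    rep$mae_total <- unname(mae["mae_total"])
    rep$mae_group_a <- unname(mae["mae_a"])
    rep$mae_group_b <- unname(mae["mae_b"])
  }
  rep
}

#' Downsampling recovery benchmark
#'
#' Runs the bulk-downsampling experiment end to end: generate smooth
#' bulk-like profiles, downsample them with the logistic capture model to
#' each target zero rate, impute with each requested variant, and score
#' recovery by CMD between sample-sample correlation matrices and by the
#' mean per-sample Pearson correlation with the (normalized) truth. The
#' un-imputed dropout matrix is always scored as the `"dropout"` baseline.
#'
#' @param zero_rates target overall zero fractions.
#' @param replicates independent simulation replicates per zero rate.
#' @param variants model variants to fit (subset of
#'   `c("scsdae", "sdae", "sdae0")`).
#' @param n_samples,n_genes,trajectory_smoothness passed to
#'   [make_bulklike_profiles()].
#' @param slope capture-model slope for [logistic_downsample()].
#' @param dims,alpha,control model settings passed to [scsdae()]; the
#'   default `alpha = 0.001` is appropriate here because the simulated
#'   zeros are all technical.
#' @param seed base seed; replicate `r` uses `seed + r - 1`.
#' @return a data frame of class `"scsdae_benchmark"` with one row per
#'   (zero rate, replicate, method) and columns `cmd` and
#'   `mean_pearson`; summarize with [summary.scsdae_benchmark()].
#' @export
run_benchmark <- function(zero_rates = c(0.5, 0.6, 0.7, 0.8, 0.9),
                          replicates = 10,
                          variants = "scsdae",
                          n_samples = 206, n_genes = 2000,
                          trajectory_smoothness = 0.15,
                          slope = 1,
                          dims = c(500, 500, 2000, 10),
                          alpha = 0.001,
                          control = scsdae_control(),
                          seed = 1) {
  variants <- match.arg(variants, c("scsdae", "sdae", "sdae0"), several.ok = TRUE)
  rows <- list()
  for (r in seq_len(replicates)) {
    set.seed(seed + r - 1L)
    bulk <- make_bulklike_profiles(n_samples, n_genes, trajectory_smoothness)
    truth_norm <- normalize_cpm(bulk)
    r_truth <- correlation_matrix(truth_norm, "samples")
    for (zr in zero_rates) {
      sim <- logistic_downsample(bulk, zr, slope)
      obs_norm <- normalize_cpm(sim$observed)
      score <- function(m, method) data.frame(
        zero_rate = zr, replicate = r, method = method,
        cmd = cmd(r_truth, correlation_matrix(m, "samples")),
        mean_pearson = mean(pairwise_pearson_truth(m, truth_norm), na.rm = TRUE))
      rows[[length(rows) + 1L]] <- score(obs_norm, "dropout")
      for (v in variants) {
        fit <- scsdae(obs_norm, dims = dims, variant = v, alpha = alpha,
                      normalized = TRUE, control = control)
        rows[[length(rows) + 1L]] <- score(fit$imputed, v)
      }
    }
  }
  structure(do.call(rbind, rows), class = c("scsdae_benchmark", "data.frame"))
}

#' Summarize a downsampling benchmark
#'
#' Mean and standard deviation of CMD and mean Pearson correlation per
#' (zero rate, method) cell, in the layout of a methods x zero-rates
#' results table.
#'
#' @param object a `"scsdae_benchmark"` data frame from [run_benchmark()].
#' @param ... unused.
#' @return a data frame with columns `zero_rate`, `method`, `cmd_mean`,
#'   `cmd_sd`, `pearson_mean`, `pearson_sd`.
#' @export
summary.scsdae_benchmark <- function(object, ...) {
  agg <- function(v, f) stats::aggregate(object[[v]],
    by = list(zero_rate = object$zero_rate, method = object$method), FUN = f)$x
  key <- stats::aggregate(object$cmd,
    by = list(zero_rate = object$zero_rate, method = object$method), FUN = mean)
  data.frame(zero_rate = key$zero_rate, method = key$method,
             cmd_mean = key$x,
             cmd_sd = agg("cmd", stats::sd),
             pearson_mean = agg("mean_pearson", mean),
             pearson_sd = agg("mean_pearson", stats::sd))
}
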