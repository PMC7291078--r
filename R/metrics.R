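#' Sample-sample or gene-gene correlation matrix
#'
#' Computes the full Pearson or Spearman correlation matrix across samples
#' (rows) or genes (columns). Zero-variance vectors yield correlation 0
#' against everything (with a warning) rather than `NA`, so downstream
#' matrix distances stay defined; the diagonal is always 1.
#'
#' @param x numeric matrix, cells/samples in rows, genes in columns.
#' @param axis correlate `"samples"` (rows) or `"genes"` (columns).
#' @param method `"pearson"` or `"spearman"`.
#' @return a symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(x, axis = c("samples", "genes"),
                               method = c("pearson", "spearman")) {
  axis <- match.arg(axis)
  method <- match.arg(method)
  m <- if (axis == "samples") t(x) else x
  if (ncol(m) < 2L) stop("need at least 2 vectors to correlate")
  R <- suppressWarnings(stats::cor(m, method = method))
  if (anyNA(R)) {
    warning("zero-variance vectors present; their correlations set to 0")
    R[is.na(R)] <- 0
  }
  diag(R) <- 1
  R
}

#' Correlation matrix distance (CMD)
#'
#' `1 - tr(R1 R2) / (||R1||_F ||R2||_F)`: zero when the two correlation
#' structures are proportional, approaching one when they are maximally
#' different.
#'
#' @param r1,r2 symmetric correlation matrices of equal shape.
#' @return a number in `[0, 1]`.
#' @examples
#' cmd(diag(2), matrix(1, 2, 2))  # 1 - 1/sqrt(2)
#' @export
cmd <- function(r1, r2) {
  if (!identical(dim(r1), dim(r2))) stop("correlation matrices differ in shape")
  f1 <- sqrt(sum(r1^2))
  f2 <- sqrt(sum(r2^2))
  if (f1 == 0 || f2 == 0) stop("zero Frobenius norm")
  1 - sum(r1 * r2) / (f1 * f2)
}

#' Significant gene-gene correlations (Spearman + Bonferroni)
#'
#' Flags gene pairs whose Spearman rank correlation is significant under a
#' conservative Bonferroni correction at family-wise level `alpha_fw`
#' (threshold `alpha_fw / choose(G, 2)` per pair). P-values use the exact
#' null distribution for `n <= 10` cells (via [stats::cor.test()]) and the
#' t approximation with midrank ties handling otherwise. Constant genes are
#' reported non-significant with a warning.
#'
#' @param x cells x genes matrix.
#' @param alpha_fw family-wise type I error rate.
#' @return symmetric logical gene x gene matrix with `FALSE` diagonal.
#' @export
gene_gene_significance <- function(x, alpha_fw = 0.05) {
  n <- nrow(x)
  G <- ncol(x)
  if (n < 3L) stop("need at least 3 cells")
  if (G < 2L) stop("need at least 2 genes")
  thr <- alpha_fw / choose(G, 2)
  const <- apply(x, 2L, function(v) length(unique(v)) == 1L)
  if (any(const))
    warning(sprintf("%d constant gene(s); their pairs reported not significant",
                    sum(const)))
  if (n <= 10L) {
    P <- matrix(1, G, G)
    for (i in seq_len(G - 1L)) for (j in (i + 1L):G) {
      if (const[i] || const[j]) next
      P[i, j] <- P[j, i] <- suppressWarnings(
        stats::cor.test(x[, i], x[, j], method = "spearman")$p.value)
    }
  } else {
    ranks <- apply(x, 2L, rank)  # midranks for ties
    R <- suppressWarnings(stats::cor(ranks))
    R[is.na(R)] <- 0
    R[const, ] <- 0
    R[, const] <- 0
    tstat <- R * sqrt((n - 2) / pmax(1 - R^2, .Machine$double.eps))
    P <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  sig <- P < thr
  sig[const, ] <- FALSE
  sig[, const] <- FALSE
  diag(sig) <- FALSE
  dimnames(sig) <- list(colnames(x), colnames(x))
  sig
}

#' FDR and TPR of detected gene-gene correlations
#'
#' A detected pair counts as a true positive when both genes are
#' differentially expressed (such pairs are genuinely correlated through the
#' shared group structure); any other detected pair is a false positive.
#' With no detections the FDR is 0 by convention.
#'
#' @param detected symmetric logical gene x gene matrix (e.g. from
#'   [gene_gene_significance()]).
#' @param truth_de per-gene logical DE flags.
#' @return named numeric vector `c(fdr, tpr)`.
#' @export
fdr_tpr <- function(detected, truth_de) {
  G <- length(truth_de)
  if (!identical(dim(detected), c(G, G)))
    stop("'detected' must be a G x G matrix matching 'truth_de'")
  up <- upper.tri(detected)
  true_pair <- outer(truth_de, truth_de, "&")
  tp <- sum(detected & true_pair & up)
  fp <- sum(detected & !true_pair & up)
  n_true <- sum(true_pair & up)
  c(fdr = fp / max(1, fp + tp),
    tpr = if (n_true > 0) tp / n_true else NA_real_)
}

#' Kruskal-Wallis differential-expression evaluation
#'
#' Runs a per-gene Kruskal-Wallis test between cell groups, applies
#' Benjamini-Hochberg correction at `fdr_level`, and scores the flagged set
#' against the known DE genes: sensitivity = flagged DE / DE genes,
#' specificity = unflagged non-DE / non-DE genes.
#'
#' @param x cells x genes expression matrix.
#' @param groups per-cell group labels (at least 2 groups, each with at
#'   least 2 cells).
#' @param truth_de per-gene logical DE flags.
#' @param fdr_level Benjamini-Hochberg level (default 5% FDR).
#' @return named numeric vector `c(sensitivity, specificity)` with
#'   attribute `"p_adjusted"`.
#' @export
kw_de_eval <- function(x, groups, truth_de, fdr_level = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L || any(table(groups) < 2L))
    stop("need at least 2 groups with at least 2 cells each")
  if (length(truth_de) != ncol(x)) stop("'truth_de' length must match genes")
  p <- apply(x, 2L, function(v)
    if (length(unique(v)) == 1L) 1 else stats::kruskal.test(v, groups)$p.value)
  padj <- stats::p.adjust(p, method = "BH")
  flagged <- padj < fdr_level
  sens <- if (any(truth_de)) sum(flagged & truth_de) / sum(truth_de) else NA_real_
  spec <- if (any(!truth_de)) sum(!flagged & !truth_de) / sum(!truth_de) else NA_real_
  structure(c(sensitivity = sens, specificity = spec), p_adjusted = padj)
}

#' Per-group mean absolute error on spiked genes
#'
#' Mean absolute difference between imputed and true values over the spiked
#' gene columns, overall and split by cell group. The total MAE is the
#' entry-count-weighted mean of the group MAEs.
#'
#' @param imputed,truth matrices of equal shape.
#' @param columns indices of the spiked gene columns.
#' @param groups per-cell labels with two distinct values (sorted first
#'   value = group A).
#' @return named numeric vector `c(mae_total, mae_a, mae_b)`.
#' @export
group_mae <- function(imputed, truth, columns, groups) {
  if (!identical(dim(imputed), dim(truth))) stop("shape mismatch")
  lv <- sort(unique(groups))
  if (length(lv) != 2L) stop("exactly two groups are required")
  err <- abs(imputed[, columns, drop = FALSE] - truth[, columns, drop = FALSE])
  a <- groups == lv[1L]
  if (!any(a) || all(a)) stop("empty group")
  c(mae_total = mean(err),
    mae_a = mean(err[a, , drop = FALSE]),
    mae_b = mean(err[!a, , drop = FALSE]))
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same cells:
#' 1 for identical partitions (up to relabeling), expectation about 0 for
#' independent random partitions.
#'
#' @param labels_a,labels_b two label vectors of equal length.
#' @return a number in `[-1, 1]`.
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("label vectors differ in length")
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  npairs <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / npairs
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Per-sample Pearson correlation with the truth
#'
#' For each sample (row), the Pearson correlation between its imputed and
#' true expression vectors; the headline recovery statistic for
#' downsampling benchmarks.
#'
#' @param imputed,truth matrices of equal shape (samples x genes).
#' @return numeric vector of per-sample correlations (`NA` with a warning
#'   for zero-variance rows).
#' @export
pairwise_pearson_truth <- function(imputed, truth) {
  if (!identical(dim(imputed), dim(truth))) stop("shape mismatch")
  out <- vapply(seq_len(nrow(truth)), function(i)
    suppressWarnings(stats::cor(imputed[i, ], truth[i, ])), 0)
  if (anyNA(out)) warning("zero-variance sample(s) produced NA correlations")
  out
}
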