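# Fixture builders shared across tests. All randomness is seeded by the
# caller; builders only consume the current RNG stream.

# small sparse count matrix with a realistic zero fraction
random_counts <- function(n_cells = 30, n_genes = 20, lambda = 5, zero_frac = 0.3) {
  m <- matrix(rpois(n_cells * n_genes, lambda), n_cells, n_genes)
  m[sample(length(m), round(zero_frac * length(m)))] <- 0
  dimnames(m) <- list(paste0("c", seq_len(n_cells)), paste0("g", seq_len(n_genes)))
  m
}

# sparse scRNA-seq-like two-group base matrix on the normalized scale,
# with group labels aligned to the filtered cells
sparse_two_group_base <- function(n_cells, n_genes, ...) {
  sim <- simulate_nb_two_group(n_cells = n_cells, n_genes = n_genes,
                               mean_low = 0.05, mean_high = 10, ...)
  keep <- rowSums(sim$observed > 0) > 0
  x <- normalize_cpm(filter_matrix(sim$observed))
  list(x = x, groups = sim$group_labels[keep],
       de = sim$de_flags[match(colnames(x), colnames(sim$observed))])
}

# fast training settings for tests
quick_control <- function(pretrain = 30, finetune = 60, ...) {
  scsdae_control(pretrain_iters = pretrain, finetune_iters = finetune, ...)
}

# scalar per-element loop oracles for the losses (independent of the
# vectorized implementations)
oracle_loss <- function(x, xp, variant, alpha = 1) {
  if (variant == "sdae") {
    s <- 0
    for (j in seq_along(x)) s <- s + (x[j] - xp[j])^2
    return(s / length(x))
  }
  se <- 0; npos <- 0; l1 <- 0; nzero <- 0
  for (j in seq_along(x)) {
    if (x[j] > 0) { se <- se + (x[j] - xp[j])^2; npos <- npos + 1 }
    else { l1 <- l1 + abs(xp[j]); nzero <- nzero + 1 }
  }
  out <- if (npos > 0) se / npos else 0
  if (variant == "scsdae" && nzero > 0) out <- out + alpha * l1 / nzero
  out
}
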