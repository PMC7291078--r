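test_that("corrupt zero-masks at the requested rate and leaves zeros alone", {
  set.seed(31)
  x <- matrix(runif(100, 1, 2), 10, 10)
  expect_identical(corrupt(x, 0), x)
  big <- matrix(runif(10000, 1, 2), 100, 100)
  frac <- mean(corrupt(big, 0.2) == 0)
  expect_gt(frac, 0.18)
  expect_lt(frac, 0.22)
  # already-zero entries stay zero under any rate, and both drawing modes agree
  xz <- matrix(c(0, 1, 0, 2, 0, 3), 2, 3)
  for (r in c(0.1, 0.5, 0.9)) {
    expect_true(all(corrupt(xz, r)[xz == 0] == 0))
    expect_true(all(corrupt(xz, r, nonzero_only = TRUE)[xz == 0] == 0))
  }
  expect_error(corrupt(x, 1), "rate")
})

test_that("network gradients match finite differences for every variant", {
  set.seed(32)
  ns <- asNamespace("scsdae")
  layers <- list(ns$nn_layer(7, 5, "relu"), ns$nn_layer(5, 3, "linear"),
                 ns$nn_layer(3, 5, "relu"), ns$nn_layer(5, 7, "linear"))
  X <- matrix(abs(rnorm(6 * 7)) * rbinom(42, 1, 0.7), 6, 7)
  for (v in c("scsdae", "sdae", "sdae0")) {
    fw <- ns$nn_forward(layers, X, cache = TRUE)
    grads <- ns$nn_backward(layers, fw$caches,
                            ns$batch_loss_grad(X, fw$out, v, 0.7))
    for (k in 1:12) {
      l <- sample(4, 1)
      i <- sample(nrow(layers[[l]]$W), 1); j <- sample(ncol(layers[[l]]$W), 1)
      eps <- 1e-6
      lp <- layers; lp[[l]]$W[i, j] <- lp[[l]]$W[i, j] + eps
      lm <- layers; lm[[l]]$W[i, j] <- lm[[l]]$W[i, j] - eps
      num <- (ns$batch_loss(X, ns$nn_forward(lp, X), v, 0.7) -
              ns$batch_loss(X, ns$nn_forward(lm, X), v, 0.7)) / (2 * eps)
      expect_equal(grads[[l]]$dW[i, j], num, tolerance = 1e-4)
    }
  }
})

test_that("pretraining builds symmetric layer shapes with the right activations", {
  set.seed(33)
  x <- normalize_cpm(filter_matrix(random_counts(40, 30)))
  pre <- pretrain_layers(x, dims = c(8, 4), control = quick_control(5, 0))
  expect_length(pre, 2)
  expect_equal(dim(pre[[1]]$encoder$W), c(30L, 8L))
  expect_equal(dim(pre[[1]]$decoder$W), c(8L, 30L))
  expect_equal(dim(pre[[2]]$encoder$W), c(8L, 4L))
  expect_equal(dim(pre[[2]]$decoder$W), c(4L, 8L))
  expect_identical(pre[[1]]$encoder$act, "relu")
  expect_identical(pre[[2]]$encoder$act, "linear")  # bottleneck
  expect_identical(pre[[1]]$decoder$act, "linear")  # output
  expect_identical(pre[[2]]$decoder$act, "relu")
})

test_that("zero pretraining steps leave weights at their seeded initialization", {
  x <- matrix(runif(20 * 10, 1, 3), 20, 10)
  ns <- asNamespace("scsdae")
  set.seed(34)
  pre <- pretrain_layers(x, dims = 4, control = quick_control(0, 0))
  set.seed(34)
  enc <- ns$nn_layer(10, 4, "linear")
  dec <- ns$nn_layer(4, 10, "linear")
  expect_identical(pre[[1]]$encoder$W, enc$W)
  expect_identical(pre[[1]]$decoder$W, dec$W)
})

test_that("a one-layer DAE on a rank-1 matrix beats the column-mean baseline", {
  set.seed(35)
  u <- runif(60, 0.5, 2)
  v <- runif(25, 0.5, 2)
  x <- u %o% v  # rank 1, strictly positive
  baseline <- mean((x - rep(colMeans(x), each = nrow(x)))^2)  # oracle baseline
  pre <- pretrain_layers(x, dims = 1, variant = "sdae",
                         control = scsdae_control(pretrain_iters = 600,
                                                  corruption_rate = 0))
  expect_lt(mean(tail(pre[[1]]$loss, 20)), baseline)
})

test_that("stacking with no fine-tuning equals composing the pretrained layers", {
  set.seed(36)
  x <- normalize_cpm(filter_matrix(random_counts(50, 30)))
  pre <- pretrain_layers(x, dims = c(8, 4), control = quick_control(20, 0))
  model <- stack_and_finetune(x, pre, control = quick_control(20, 0))
  ns <- asNamespace("scsdae")
  h1 <- ns$nn_forward(list(pre[[1]]$encoder), x)
  h2 <- ns$nn_forward(list(pre[[2]]$encoder), h1)
  r1 <- ns$nn_forward(list(pre[[2]]$decoder), h2)
  out <- ns$nn_forward(list(pre[[1]]$decoder), r1)
  expect_equal(ns$nn_forward(model$layers, x), out, tolerance = 1e-12)
})

test_that("fine-tuning decreases the smoothed training loss", {
  set.seed(37)
  x <- normalize_cpm(filter_matrix(random_counts(80, 40)))
  pre <- pretrain_layers(x, dims = c(16, 4), control = quick_control(50, 0))
  model <- stack_and_finetune(x, pre,
                              control = scsdae_control(finetune_iters = 400))
  expect_lt(mean(tail(model$loss, 100)), mean(head(model$loss, 100)))
})

test_that("sdae and sdae0 share a training trajectory on a zero-free matrix", {
  x <- matrix(runif(40 * 20, 1, 4), 40, 20)
  f1 <- scsdae(x, dims = c(8, 4), variant = "sdae", normalized = TRUE,
               seed = 38, control = quick_control(30, 60))
  f2 <- scsdae(x, dims = c(8, 4), variant = "sdae0", normalized = TRUE,
               seed = 38, control = quick_control(30, 60))
  # identical up to floating summation order of the two loss code paths
  expect_equal(f1$finetune_loss, f2$finetune_loss, tolerance = 1e-10)
  expect_equal(f1$imputed, f2$imputed, tolerance = 1e-10)
})

test_that("impute_matrix honors the mask contract and clipping", {
  set.seed(39)
  x <- normalize_cpm(filter_matrix(random_counts(30, 20)))
  pre <- pretrain_layers(x, dims = 4, control = quick_control(10, 0))
  model <- stack_and_finetune(x, pre, control = quick_control(10, 0))
  m <- zero_mask(x)
  imp <- impute_matrix(x, model, m)
  expect_identical(imp$imputed[m], x[m])          # observed bit-identical
  expect_true(all(imp$imputed >= 0))
  # all-true mask: nothing changes
  all_true <- matrix(TRUE, nrow(x), ncol(x))
  expect_identical(impute_matrix(x, model, all_true)$imputed, x)
  # all-false mask: output everywhere (clamped)
  all_false <- matrix(FALSE, nrow(x), ncol(x))
  out <- impute_matrix(x, model, all_false)
  expect_equal(out$imputed, pmax(out$output, 0), ignore_attr = TRUE)
  # unclipped output may keep negatives
  out2 <- impute_matrix(x, model, all_false, clip = FALSE)
  expect_equal(out2$imputed, out2$output, ignore_attr = TRUE)
  expect_error(impute_matrix(x[, 1:5], model), "genes")
})

test_that("the end-to-end fit is seeded-deterministic and preserves observed data", {
  set.seed(40)
  counts <- random_counts(40, 25)
  f1 <- scsdae(counts, dims = c(8, 4), seed = 123, control = quick_control())
  f2 <- scsdae(counts, dims = c(8, 4), seed = 123, control = quick_control())
  expect_identical(f1$imputed, f2$imputed)
  expect_identical(f1$finetune_loss, f2$finetune_loss)
  expect_identical(f1$imputed[f1$mask], f1$x[f1$mask])
  # a zero-free matrix has nothing to impute
  dense <- matrix(rpois(30 * 15, 20) + 1, 30, 15)
  fz <- scsdae(dense, dims = 4, seed = 5, control = quick_control(10, 10))
  expect_identical(fz$imputed, fz$x)
})

test_that("imputation moves dropped-out entries closer to the truth than zeros", {
  set.seed(41)
  bulk <- make_bulklike_profiles(100, 120, trajectory_smoothness = 0.2)
  sim <- logistic_downsample(bulk, 0.6)
  truth_norm <- normalize_cpm(bulk)
  obs_norm <- normalize_cpm(sim$observed)
  fit <- scsdae(obs_norm, dims = c(32, 8), alpha = 0.001, normalized = TRUE,
                seed = 41, control = scsdae_control(pretrain_iters = 150,
                                                    finetune_iters = 300))
  dm <- sim$dropout_mask
  mse_before <- mean((truth_norm[dm] - obs_norm[dm])^2)
  mse_after <- mean((truth_norm[dm] - fit$imputed[dm])^2)
  expect_lt(mse_after, mse_before)
})

test_that("fit methods and checkpointing round-trip", {
  set.seed(42)
  counts <- random_counts(30, 20)
  fit <- scsdae(counts, dims = c(8, 4), seed = 42, control = quick_control())
  expect_output(print(fit), "Stacked denoising autoencoder")
  expect_output(print(summary(fit)), "zero fraction")
  expect_length(coef(fit), 4)  # 2 encoder + 2 decoder layers
  expect_identical(fitted(fit), fit$imputed)
  r <- residuals(fit)
  expect_true(all(is.na(r[!fit$mask])))
  expect_equal(r[fit$mask], (fit$x - fit$output)[fit$mask])
  # predict on new data preserves its observed entries
  new_counts <- random_counts(10, 20)
  p <- predict(fit, new_counts)
  xn <- normalize_cpm(new_counts)
  expect_identical(p[xn > 0], xn[xn > 0])
  expect_identical(predict(fit), fit$imputed)
  # checkpoint round trip reproduces forward passes exactly
  tmp <- tempfile(fileext = ".rds")
  write_scsdae(fit, tmp)
  back <- read_scsdae(tmp)
  expect_identical(predict(back, new_counts), p)
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
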