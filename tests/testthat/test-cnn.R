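test_that("inverse-frequency weights follow N/(2*n_c)", {
  w <- inverse_frequency_weights(rep(c("a", "b"), each = 50))
  expect_equal(unname(w), c(1, 1))
  w2 <- inverse_frequency_weights(c(rep("severe", 35), rep("nonsevere", 65)))
  expect_equal(unname(w2["severe"] / w2["nonsevere"]), 65 / 35)
  expect_equal(unname(w2["severe"]), 100 / (2 * 35))
  expect_error(inverse_frequency_weights(rep("a", 10)), "single-class")
})

test_that("the cosine-annealing schedule hits its endpoints and restarts with doubled cycles", {
  expect_equal(scheduled_lr(0, 50, 1e-4), 1e-4)
  expect_equal(scheduled_lr(50, 50, 1e-4, 1e-10), 1e-10)
  expect_equal(scheduled_lr(25, 50, 1e-4, 1e-10), (1e-4 + 1e-10) / 2)
  # warm restarts: epoch 50 starts a fresh cycle of length 100
  expect_equal(lr_at_epoch(50, t0 = 50, t_mult = 2, lr0 = 1e-4), 1e-4)
  expect_equal(lr_at_epoch(150, t0 = 50, t_mult = 2, lr0 = 1e-4), 1e-4)
  # continuity within a cycle: monotone decreasing
  lrs <- vapply(0:49, lr_at_epoch, numeric(1), t0 = 50, t_mult = 2,
                lr0 = 1e-4, floor = 1e-10)
  expect_true(all(diff(lrs) < 0))
  expect_gte(min(lrs), 1e-10)
})

test_that("weighted cross-entropy with unit weights equals the unweighted loss", {
  am <- asNamespace("aphasiamorph")
  set.seed(1)
  logits <- matrix(rnorm(20), 2, 10)
  y <- sample(1:2, 10, TRUE)
  lw <- am$weighted_ce(logits, y, c(1, 1))$loss
  p <- apply(logits, 2, function(z) exp(z - max(z)) / sum(exp(z - max(z))))
  expect_equal(lw, mean(-log(p[cbind(y, 1:10)])))
  # confident correct predictions drive the loss to zero
  big <- matrix(c(10, -10), 2, 5)
  expect_lt(am$weighted_ce(big, rep(1, 5), c(2, 0.5))$loss, 1e-3)
})

test_that("network construction follows the architecture contract", {
  spec <- architecture_spec(1)
  expect_equal(spec$fc_widths, c(128, 64, 2))
  net <- build_network(spec, c(24, 28, 24), seed = 1)
  # 4 pools: ceil division by 16 per axis
  types <- vapply(net$layers, `[[`, "", "type")
  expect_equal(sum(types == "pool"), 4)
  flat_ly <- net$layers[[which(types == "flatten")]]
  expect_equal(flat_ly$dims, as.integer(ceiling(c(24, 28, 24) / 16)))
  # penultimate width = channels of the last conv block
  feats <- extract_features(net, list(array(0, c(24, 28, 24))))
  expect_equal(ncol(feats), 64)
  # dropout sits immediately after the batchnorm that follows FC1
  fc1 <- which(types == "fc")[1]
  expect_equal(types[fc1 + 1], "bnorm")
  expect_equal(types[fc1 + 2], "dropout")
  expect_error(architecture_spec(blocks = list(c(1, 4), c(1, 8), c(1, 8), c(1, 8))),
               "channels")
  expect_error(architecture_spec(blocks = rep(list(c(1, 8)), 6)), "blocks")
})

test_that("forward passes are deterministic in eval mode and probabilities normalize", {
  net <- toy_net()
  v <- list(array(rnorm(512), c(8, 8, 8)))
  p1 <- predict_proba(net, v)
  p2 <- predict_proba(net, v)
  expect_identical(p1, p2)
  expect_equal(rowSums(p1), 1)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # softmax closed form: logits (2, 0) -> (0.881, 0.119)
  am <- asNamespace("aphasiamorph")
  lin <- linear_net(c(2, 1, 1), W = matrix(c(1, 0, 0, 0), 2, 2), b = c(0, 0))
  pp <- predict_proba(lin, list(array(c(2, 0), c(2, 1, 1))))
  expect_equal(unname(pp[1, ]), c(exp(2), 1) / (exp(2) + 1), tolerance = 1e-12)
  # duplicated subjects give identical features
  f <- extract_features(net, list(v[[1]], v[[1]]))
  expect_equal(f[1, ], f[2, ])
})

test_that("a small net separates a linearly separable toy cohort", {
  set.seed(4)
  mk <- function(mu) lapply(1:10, function(i)
    array(rnorm(216, mu, 0.1), c(6, 6, 6)))
  vols <- c(mk(-0.4), mk(0.4))
  labs <- rep(c("nonsevere", "severe"), each = 10)
  spec <- architecture_spec(blocks = list(c(1, 8), c(1, 8)), dropout_rate = 0)
  fit <- train_cnn(spec, vols, labs,
                   train_config(lr0 = 5e-3, epochs = 50, batch_size = 20,
                                t0 = 50, patience = 50, seed = 1),
                   vols, labs)
  p <- predict_proba(fit, vols)
  acc <- mean((p[, "severe"] >= 0.5) == (labs == "severe"))
  expect_equal(acc, 1.0)
  expect_true(all(is.finite(fit$history$val_loss)))
  expect_lte(nrow(fit$history), 50)
})

test_that("shuffled labels yield chance-level validation performance", {
  set.seed(8)
  vols <- lapply(1:40, function(i) array(rnorm(216), c(6, 6, 6)))
  bas <- vapply(1:3, function(s) {
    set.seed(s)
    labs <- sample(rep(c("nonsevere", "severe"), each = 20))
    spec <- architecture_spec(blocks = list(c(1, 8), c(1, 8)), dropout_rate = 0)
    fit <- train_cnn(spec, vols[1:30], labs[1:30],
                     train_config(lr0 = 1e-3, epochs = 15, batch_size = 30,
                                  t0 = 15, patience = 15, seed = s),
                     vols[31:40], labs[31:40])
    p <- predict_proba(fit, vols[31:40])
    compute_metrics(labs[31:40],
                    ifelse(p[, "severe"] >= 0.5, "severe", "nonsevere"))$balanced_accuracy
  }, numeric(1))
  expect_lt(abs(mean(bas) - 0.5), 0.2)
})

test_that("hyperparameter selection minimizes mean inner loss with the stated tie-breaks", {
  grid <- expand.grid(complexity = 1:2, dropout = c(0.6, 0.7),
                      l2 = 0.001, lr = c(1e-5, 1e-4))
  # unique minimum recovered
  losses <- seq(0.9, by = 0.05, length.out = nrow(grid))
  losses[5] <- 0.1
  expect_equal(select_best_hyperparams(losses, grid), 5)
  # ties broken by lower complexity then lower lr
  tied <- rep(1, nrow(grid))
  pick <- select_best_hyperparams(tied, grid)
  expect_equal(grid$complexity[pick], 1)
  expect_equal(grid$lr[pick], min(grid$lr))
  # single candidate returns itself
  expect_equal(select_best_hyperparams(0.3, grid[3, ]), 1)
})

test_that("tune_cnn recovers the dominant candidate on a tiny grid", {
  set.seed(2)
  mk <- function(mu, n) lapply(1:n, function(i)
    array(rnorm(216, mu, 0.2), c(6, 6, 6)))
  vols <- c(mk(-0.4, 12), mk(0.4, 12))
  labs <- rep(c("nonsevere", "severe"), each = 12)
  inner <- rep(rep(1:2, 6), 2)
  grid <- data.frame(complexity = 1, dropout = 0, l2 = c(0.001, 1e6),
                     lr = 1e-3)
  res <- tune_cnn(vols, labs, inner, grid,
                  train_config(lr0 = 1e-3, epochs = 10, batch_size = 24,
                               t0 = 10, patience = 10, seed = 1))
  # the absurd L2 candidate cannot fit and must lose
  expect_equal(res$chosen$l2, 0.001)
})
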