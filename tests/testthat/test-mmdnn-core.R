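test_that("hidden widths follow the 3N, 3N/4, 100 rule", {
  expect_identical(network_spec(100)$hidden_dims, c(300L, 75L, 100L))
  expect_identical(network_spec(600)$hidden_dims, c(1800L, 450L, 100L))
  expect_identical(network_spec(1488)$hidden_dims, c(4464L, 1116L, 100L))
  # half rounds up on the 3N/4 term
  expect_identical(network_spec(2)$hidden_dims, c(6L, 2L, 100L))
  expect_identical(network_spec(10)$hidden_dims, c(30L, 8L, 100L))
})

test_that("autoencoder forward pass honours the tied-weight equations", {
  x <- c(1.5, -2, 0.5)
  zero <- list(W1 = matrix(0, 4, 3), b1 = numeric(4), b2 = numeric(3))
  out <- ae_forward(zero, x)
  expect_equal(out$y, numeric(4))
  expect_equal(out$z, numeric(3))
  expect_equal(out$loss, 0.5 * sum(x^2))

  ident <- list(W1 = diag(3), b1 = numeric(3), b2 = numeric(3))
  xp <- c(0.2, 1, 3)
  out <- ae_forward(ident, xp)
  expect_equal(out$y, xp)
  expect_equal(out$z, xp)
  expect_equal(out$loss, 0)

  expect_error(ae_forward(zero, c(1, 2)), "match")
})

test_that("autoencoder analytic gradients match central finite differences", {
  set.seed(31)
  for (i in 1:6) {
    W <- matrix(rnorm(15, sd = 0.7), 5, 3)
    b1 <- rnorm(5, sd = 0.3)
    b2 <- rnorm(3, sd = 0.3)
    X <- matrix(rnorm(6), 3, 2)
    fw <- mmdnn:::ae_forward_batch(W, b1, b2, X)
    gr <- mmdnn:::ae_backward_batch(W, fw, X)
    loss_of <- function(W., b1., b2.)
      mmdnn:::ae_forward_batch(W., b1., b2., X)$loss
    expect_lt(rel_err(gr$W1, numeric_grad(function(w) loss_of(w, b1, b2), W)),
              1e-5)
    expect_lt(rel_err(gr$b1, numeric_grad(function(b) loss_of(W, b, b2), b1)),
              1e-5)
    expect_lt(rel_err(gr$b2, numeric_grad(function(b) loss_of(W, b1, b), b2)),
              1e-5)
  }
})

test_that("softmax cross-entropy gradients match finite differences", {
  set.seed(32)
  done <- 0
  while (done < 4) {
    layers <- mmdnn:::init_layers(c(4, 6, 5), c(6, 5, 7))
    head <- list(W = matrix(rnorm(14, sd = 0.4), 2, 7), b = rnorm(2, sd = 0.1))
    X <- matrix(rnorm(12), 4, 3)
    y <- c(0L, 1L, 1L)
    fw <- mmdnn:::mlp_forward(layers, head, X)
    # central differences are invalid across a ReLU kink; resample
    # instances whose pre-activations sit on it
    if (min(vapply(fw$A, function(a) min(abs(a)), 0)) < 1e-3) next
    done <- done + 1
    gr <- mmdnn:::mlp_backward(layers, head, X, fw, mmdnn:::one_hot(y))
    loss_with <- function(layers., head.) {
      P <- mmdnn:::mlp_forward(layers., head., X)$P
      cross_entropy(t(P), y)
    }
    for (l in 1:3) {
      num <- numeric_grad(function(w) {
        ll <- layers; ll[[l]]$W <- w; loss_with(ll, head)
      }, layers[[l]]$W)
      expect_lt(rel_err(gr$layers[[l]]$W, num), 1e-5)
      numb <- numeric_grad(function(b) {
        ll <- layers; ll[[l]]$b <- b; loss_with(ll, head)
      }, layers[[l]]$b)
      expect_lt(rel_err(gr$layers[[l]]$b, numb), 1e-5)
    }
    numh <- numeric_grad(function(w) loss_with(layers, list(W = w, b = head$b)),
                         head$W)
    expect_lt(rel_err(gr$head$W, numh), 1e-5)
  }
})

test_that("cross entropy reproduces the worked examples", {
  expect_equal(cross_entropy(matrix(c(0, 1), 1), 1), 0, tolerance = 1e-10)
  expect_equal(cross_entropy(matrix(c(0.5, 0.5), 1), 0), log(2),
               tolerance = 1e-9)
  probs <- rbind(c(0.1, 0.9), c(0.2, 0.8))
  expect_equal(cross_entropy(probs, c(1L, 1L)), -(log(0.9) + log(0.8)) / 2,
               tolerance = 1e-9)
  expect_equal(round(cross_entropy(probs, c(1L, 1L)), 6), 0.164252)
  expect_error(cross_entropy(probs, c(1L, 2L)), "0 or 1")
})

test_that("dropout is inverted, seeded, and an identity in eval mode", {
  x <- rnorm(100)
  expect_identical(apply_dropout(x, 0.5, "eval"), x)
  set.seed(5)
  big <- rep(1, 1e4)
  dropped <- apply_dropout(big, 0.5, "train")
  kept <- mean(dropped > 0)
  expect_lt(abs(kept - 0.5), 3 * sqrt(0.25 / 1e4))
  expect_true(all(dropped[dropped > 0] == 2))  # survivors scaled by 1/(1-rate)
  set.seed(9); a <- apply_dropout(big, 0.3, "train")
  set.seed(9); b <- apply_dropout(big, 0.3, "train")
  expect_identical(a, b)
  expect_error(apply_dropout(x, 1), "rate")
})

test_that("early stopping waits out patience and restores the first best", {
  st <- early_stop_state(patience = 3)
  # strictly increasing: never stops
  for (acc in seq(0.1, 0.9, by = 0.1)) {
    upd <- early_stop_update(st, acc, params = list(w = acc))
    st <- upd$state
    expect_false(upd$stop)
  }
  # constant run: stops at epoch patience + 1, best is epoch 1
  st <- early_stop_state(patience = 3)
  stopped_at <- NA
  for (e in 1:10) {
    upd <- early_stop_update(st, 0.5, params = list(w = e))
    st <- upd$state
    if (upd$stop) { stopped_at <- e; break }
  }
  expect_identical(stopped_at, 4L)
  expect_identical(st$best_epoch, 1L)
  expect_identical(st$best_params$w, 1)
  # improvement resets the counter
  st <- early_stop_state(patience = 2)
  accs <- c(0.5, 0.4, 0.6, 0.4, 0.4)
  stops <- logical(5)
  for (i in seq_along(accs)) {
    upd <- early_stop_update(st, accs[i]); st <- upd$state; stops[i] <- upd$stop
  }
  expect_identical(stops, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(st$best_epoch, 3L)
})

test_that("greedy layer-wise pretraining chains dims and lowers reconstruction loss", {
  set.seed(44)
  X <- matrix(runif(30 * 12), 30, 12)
  spec <- network_spec(12)
  cfg <- train_config(learning_rate = 1e-2, pretrain_epochs = 30,
                      batch_size = 10, seed = 3)
  stack <- pretrain_stack(sample_batch(X), spec, cfg)
  dims <- vapply(stack$layers, function(l) nrow(l$W), 0L)
  expect_identical(dims, c(36L, 9L, 100L))
  expect_identical(ncol(stack$layers[[2]]$W), 36L)  # layer 2 eats layer-1 codes
  for (h in stack$histories) expect_lt(h[length(h)], h[1])
})

test_that("a zero-initialized output layer is maximally uncertain, softmax sums to one", {
  set.seed(45)
  spec <- network_spec(6)
  cfg0 <- train_config(head_epochs = 0, pretrain_epochs = 2, seed = 2)
  X <- matrix(rnorm(10 * 6), 10, 6)
  stack <- pretrain_stack(sample_batch(X), spec, cfg0)
  net <- attach_and_train_output_layer(stack$layers,
                                       sample_batch(X, rep(0:1, 5)), cfg0)
  P <- t(mmdnn:::mlp_forward(net$layers, net$head, t(X))$P)
  expect_equal(P, matrix(0.5, 10, 2), ignore_attr = TRUE)

  cfg <- train_config(head_epochs = 30, pretrain_epochs = 2,
                      learning_rate = 1e-2, seed = 2)
  net <- attach_and_train_output_layer(stack$layers,
                                       sample_batch(X, rep(0:1, 5)), cfg)
  P <- t(mmdnn:::mlp_forward(net$layers, net$head, t(X))$P)
  expect_equal(rowSums(P), rep(1, 10), tolerance = 1e-12)
})

test_that("the output layer learns linearly separable latents", {
  set.seed(46)
  n <- 60
  X <- matrix(rnorm(n * 8), n, 8)
  spec <- network_spec(8)
  cfg <- train_config(learning_rate = 1e-2, pretrain_epochs = 10,
                      head_epochs = 300, dropout_rate = 0, seed = 5)
  stack <- pretrain_stack(sample_batch(X), spec, cfg)
  # labels defined on the encoder's own latent codes with a margin, so
  # the latents are linearly separable by construction
  L <- t(mmdnn:::branch_latents(mmdnn:::new_dnn(stack$layers, 8), t(X)))
  w_true <- rnorm(ncol(L))
  margin <- L %*% w_true - mean(L %*% w_true)
  keep <- abs(margin) > 0.25 * sd(margin)
  X <- X[keep, , drop = FALSE]
  y <- as.integer(margin[keep] > 0)
  # separating-hyperplane oracle: w_true splits the kept latents exactly
  expect_true(all(((L %*% w_true - mean(L %*% w_true))[keep] > 0) == (y == 1)))
  net <- attach_and_train_output_layer(stack$layers, sample_batch(X, y), cfg)
  P <- t(mmdnn:::mlp_forward(net$layers, net$head, t(X))$P)
  expect_gte(mean((P[, 2] > 0.5) == (y == 1)), 0.99)
})

test_that("fine-tuning is bit-reproducible and learns a toy problem", {
  set.seed(47)
  n <- 80
  X <- matrix(rnorm(n * 6), n, 6)
  y <- as.integer(X[, 1] + X[, 2] > 0)
  tr <- 1:60; va <- 61:80
  cfg <- train_config(learning_rate = 3e-3, pretrain_epochs = 5,
                      head_epochs = 5, max_epochs = 40, patience = 40,
                      batch_size = 20, seed = 9)
  run <- function() {
    stack <- pretrain_stack(sample_batch(X[tr, ]), network_spec(6), cfg)
    net <- attach_and_train_output_layer(stack$layers,
                                         sample_batch(X[tr, ], y[tr]), cfg)
    fine_tune_network(net, sample_batch(X[tr, ], y[tr]),
                      sample_batch(X[va, ], y[va]), cfg)
  }
  a <- run(); b <- run()
  expect_identical(a$history, b$history)
  expect_identical(a$net$layers, b$net$layers)
  expect_identical(a$net$head, b$net$head)
  # loss falls over training
  h <- a$history$train_loss
  expect_lt(mean(utils::tail(h, 10)), mean(utils::head(h, 10)))
  # restored parameters reproduce the recorded best validation accuracy
  acc <- mmdnn:::net_accuracy(a$net, t(X[va, ]), y[va])
  expect_equal(acc, a$history$best_val_accuracy)
})

test_that("extract_latent equals the hand-rolled matrix composition", {
  set.seed(48)
  layers <- mmdnn:::init_layers(c(5, 15, 4), c(15, 4, 100))
  net <- mmdnn:::new_dnn(layers, 5)
  x <- rnorm(5)
  lat <- extract_latent(net, x)
  expect_length(lat, 100)
  expect_identical(lat, extract_latent(net, x))  # eval-mode repeatability
  manual <- pmax(layers[[3]]$W %*%
                   pmax(layers[[2]]$W %*%
                          pmax(layers[[1]]$W %*% x + layers[[1]]$b, 0) +
                          layers[[2]]$b, 0) + layers[[3]]$b, 0)
  expect_equal(lat, as.vector(manual))
  # matrix input: one latent row per sample
  Xm <- matrix(rnorm(15), 3, 5)
  expect_equal(dim(extract_latent(net, Xm)), c(3L, 100L))
  expect_equal(extract_latent(net, Xm)[2, ], extract_latent(net, Xm[2, ]))
})

test_that("the fusion network width follows the branch count", {
  sim <- simulate_feature_tables(small_sim_cfg(seed = 61))
  rows <- which(sim$metadata$group %in% c("sNC", "sAD"))
  labels <- as.integer(sim$metadata$group[rows] == "sAD")
  # 2 branches (one modality pair at one scale) -> fusion input 200
  feats2 <- lapply(sim$features[c("volume_40", "metabolism_40")],
                   function(f) f[rows, , drop = FALSE])
  m2 <- train_mmdnn(feats2, labels, val_rows = seq(1, length(rows), by = 4),
                    tiny_cfg(3))
  expect_identical(m2$fusion$input_dim, 200L)
  expect_identical(nrow(m2$fusion$layers[[1]]$W), 600L)
  expect_identical(nrow(m2$fusion$layers[[2]]$W), 150L)
  expect_identical(m2$stage_log, c("A:branches", "B:fusion", "C:joint"))
})

test_that("predict_proba matches a manual branch-concat-fusion forward pass", {
  sim <- simulate_feature_tables(small_sim_cfg(seed = 62))
  rows <- which(sim$metadata$group %in% c("sNC", "sAD"))
  labels <- as.integer(sim$metadata$group[rows] == "sAD")
  feats <- lapply(sim$features[c("volume_40", "metabolism_80")],
                  function(f) f[rows, , drop = FALSE])
  model <- train_mmdnn(feats, labels, val_rows = seq(1, length(rows), by = 4),
                       tiny_cfg(5))
  P <- predict_proba(model, feats)
  expect_equal(unname(rowSums(P)), rep(1, length(rows)), tolerance = 1e-12)
  # manual forward on image 3
  lat <- c(extract_latent(model$branches[["volume_40"]], feats[["volume_40"]][3, ]),
           extract_latent(model$branches[["metabolism_80"]], feats[["metabolism_80"]][3, ]))
  cur <- lat
  for (l in model$fusion$layers) cur <- pmax(l$W %*% cur + l$b, 0)
  logits <- as.vector(model$fusion$head$W %*% cur + model$fusion$head$b)
  manual <- exp(logits - max(logits)); manual <- manual / sum(manual)
  expect_equal(unname(P[3, ]), manual, tolerance = 1e-12)

  expect_error(predict_proba(model, feats["volume_40"]), "cover")
  untrained <- model; untrained$stage_log <- "A:branches"
  expect_error(predict_proba(untrained, feats), "not fully trained")
})

test_that("model checkpoints round-trip through JSON plus binary tensors", {
  tmp <- withr::local_tempdir()
  sim <- simulate_feature_tables(small_sim_cfg(seed = 63))
  rows <- which(sim$metadata$group %in% c("sNC", "sAD"))
  labels <- as.integer(sim$metadata$group[rows] == "sAD")
  feats <- lapply(sim$features[c("volume_40", "metabolism_40")],
                  function(f) f[rows, , drop = FALSE])
  model <- train_mmdnn(feats, labels, val_rows = seq(1, length(rows), by = 4),
                       tiny_cfg(7))
  save_mmdnn(model, file.path(tmp, "ckpt"))
  back <- load_mmdnn(file.path(tmp, "ckpt"))
  expect_equal(predict_proba(back, feats), predict_proba(model, feats),
               tolerance = 1e-15)
  expect_identical(back$branch_names, model$branch_names)
  expect_identical(back$stage_log, model$stage_log)
})
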