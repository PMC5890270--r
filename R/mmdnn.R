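#' Network architecture rule
#'
#' Every DNN in the model — the six modality-by-scale branches and the
#' fusion network — uses three hidden layers of widths `3N`,
#' `round_half_up(3N/4)` and `100`, where `N` is its input feature
#' dimension: the first layer can span all pairwise feature interactions,
#' the following layers taper to limit overfitting, and the fixed 100-unit
#' penultimate layer is the latent code the fusion network consumes.
#'
#' @param input_dim input feature dimension `N` (number of patches, or
#'   `100 * n_branches` for the fusion network).
#' @param n_classes number of output classes (2).
#' @return list with `input_dim`, `hidden_dims` (length 3) and
#'   `n_classes`.
#' @examples
#' network_spec(100)$hidden_dims  # 300, 75, 100
#' @export
network_spec <- function(input_dim, n_classes = 2L) {
  input_dim <- as.integer(input_dim)
  if (input_dim < 1) stop("input_dim must be positive")
  list(input_dim = input_dim,
       hidden_dims = c(3L * input_dim,
                       as.integer(round_half_up(3 * input_dim / 4)),
                       100L),
       n_classes = as.integer(n_classes))
}

#' Training configuration
#'
#' Defaults follow the published training protocol: Adam with learning
#' rate 1e-4, mini-batches of 50 samples reshuffled every epoch, dropout
#' rate 0.5 after every hidden layer, and early stopping once validation
#' accuracy has not improved for 50 epochs. `pretrain_epochs` and
#' `head_epochs` bound the unsupervised and head-only phases, which run
#' for a fixed number of epochs (no early stopping).
#'
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size; a final smaller batch is used as-is.
#' @param dropout_rate drop probability in `[0, 1)`.
#' @param patience early-stopping patience in epochs.
#' @param max_epochs cap on supervised fine-tuning epochs.
#' @param pretrain_epochs epochs per autoencoder layer.
#' @param head_epochs epochs of output-layer-only training.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @param seed integer seed; all training is bit-reproducible given
#'   (seed, config, data).
#' @param standardize logical; standardize features with training-set
#'   statistics before network training (see [standardize_features()]).
#'   Applied by ensemble/experiment drivers, not by [train_mmdnn()]
#'   itself.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 50L,
                         dropout_rate = 0.5, patience = 50L,
                         max_epochs = 1000L, pretrain_epochs = 50L,
                         head_epochs = 50L, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, seed = 1L, standardize = TRUE) {
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 dropout_rate = dropout_rate, patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 head_epochs = as.integer(head_epochs),
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 seed = as.integer(seed), standardize = isTRUE(standardize)),
            class = "train_config")
}

#' Bundle samples and labels
#'
#' @param x numeric matrix, rows = samples.
#' @param labels integer 0/1 vector, one per row (may be omitted for
#'   unsupervised use).
#' @return A `sample_batch` list with `x`, `labels`, `n`.
#' @export
sample_batch <- function(x, labels = NULL) {
  x <- as.matrix(x)
  if (!is.null(labels)) {
    if (length(labels) != nrow(x)) stop("labels length must equal nrow(x)")
    if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
    labels <- as.integer(labels)
  }
  structure(list(x = x, labels = labels, n = nrow(x)), class = "sample_batch")
}

as_sample_batch <- function(data, need_labels = TRUE) {
  if (!inherits(data, "sample_batch")) data <- sample_batch(data$x, data$labels)
  if (need_labels && is.null(data$labels)) stop("labels required")
  data
}

# ---- unsupervised pretraining ----------------------------------------

# Train one tied-weight autoencoder on X (d x n) by mini-batch Adam.
ae_train <- function(X, n_hidden, cfg) {
  W <- init_weight(n_hidden, nrow(X))
  b1 <- numeric(n_hidden)
  b2 <- numeric(nrow(X))
  params <- list(W1 = W, b1 = b1, b2 = b2)
  st <- adam_state(params)
  history <- numeric(cfg$pretrain_epochs)
  for (epoch in seq_len(cfg$pretrain_epochs)) {
    losses <- c()
    for (batch in make_batches(ncol(X), cfg$batch_size)) {
      Xb <- X[, batch, drop = FALSE]
      fw <- ae_forward_batch(params$W1, params$b1, params$b2, Xb)
      gr <- ae_backward_batch(params$W1, fw, Xb)
      st <- adam_step(params, gr, st, cfg)
      losses <- c(losses, fw$loss)
    }
    history[epoch] <- mean(losses)
  }
  list(W = params$W1, b1 = params$b1, b2 = params$b2, loss_history = history)
}

pretrain_stack_impl <- function(X, hidden_dims, cfg) {
  layers <- vector("list", length(hidden_dims))
  histories <- vector("list", length(hidden_dims))
  H <- X
  for (l in seq_along(hidden_dims)) {
    ae <- ae_train(H, hidden_dims[l], cfg)
    layers[[l]] <- list(W = ae$W, b = ae$b1)
    histories[[l]] <- ae$loss_history
    H <- relu(ae$W %*% H + ae$b1)
  }
  list(layers = layers, histories = histories)
}

#' Greedy layer-wise autoencoder pretraining
#'
#' Trains the three encoder layers as a stacked autoencoder: layer 1
#' reconstructs the input features, each deeper layer reconstructs the
#' previous layer's encoded activations. Hidden widths follow
#' [network_spec()] exactly. Dropout and early stopping apply only to the
#' supervised phases; pretraining runs `cfg$pretrain_epochs` per layer.
#'
#' @param data a [sample_batch()] (labels unused) or matrix rows=samples.
#' @param spec a [network_spec()] whose `input_dim` matches the data.
#' @param cfg a [train_config()]; `cfg$seed` is applied.
#' @return list with `layers` (3 affine encoder layers, each `W`, `b`)
#'   and `histories` (per-layer mean reconstruction loss per epoch).
#' @export
pretrain_stack <- function(data, spec, cfg = train_config()) {
  if (is.matrix(data)) data <- sample_batch(data)
  data <- as_sample_batch(data, need_labels = FALSE)
  if (ncol(data$x) != spec$input_dim)
    stop("data has ", ncol(data$x), " features but spec expects ",
         spec$input_dim)
  set.seed(cfg$seed)
  pretrain_stack_impl(t(data$x), spec$hidden_dims, cfg)
}

# ---- supervised phases -----------------------------------------------

new_dnn <- function(layers, input_dim) {
  latent <- nrow(layers[[length(layers)]]$W)
  structure(list(layers = layers,
                 head = list(W = matrix(0, 2, latent), b = numeric(2)),
                 input_dim = as.integer(input_dim)),
            class = "dnn_params")
}

#' @export
print.dnn_params <- function(x, ...) {
  dims <- vapply(x$layers, function(l) nrow(l$W), 0L)
  cat(sprintf("<dnn_params> %d -> %s -> 2 (softmax)\n", x$input_dim,
              paste(dims, collapse = " -> ")))
  invisible(x)
}

net_masks <- function(net, n, cfg) {
  lapply(net$layers, function(l) dropout_mask(nrow(l$W), n, cfg$dropout_rate))
}

net_accuracy <- function(net, X, y) {
  P <- mlp_forward(net$layers, net$head, X)$P
  mean((P[2, ] > P[1, ]) == (y == 1L))
}

head_train_impl <- function(net, X, y, cfg) {
  params <- list(headW = net$head$W, headb = net$head$b)
  st <- adam_state(params)
  Y_all <- one_hot(y)
  L <- length(net$layers)
  for (epoch in seq_len(cfg$head_epochs)) {
    for (batch in make_batches(ncol(X), cfg$batch_size)) {
      Xb <- X[, batch, drop = FALSE]
      masks <- net_masks(net, length(batch), cfg)
      fw <- mlp_forward(net$layers, net$head, Xb, masks)
      d_logits <- (fw$P - Y_all[, batch, drop = FALSE]) / length(batch)
      gr <- list(headW = tcrossprod(d_logits, fw$H[[L]]),
                 headb = rowSums(d_logits))
      st <- adam_step(params, gr, st, cfg)
    }
  }
  net$head$W <- params$headW
  net$head$b <- params$headb
  net
}

#' Attach and train the softmax output layer
#'
#' Initializes a zero-weight two-class softmax layer on top of the frozen
#' pretrained encoders and trains it alone (encoder parameters fixed) with
#' dropout active on the hidden activations. With zero initialization the
#' network outputs (0.5, 0.5) for every input before the first update.
#'
#' @param encoders `layers` from [pretrain_stack()] (encoder output must
#'   be 100-d).
#' @param data a [sample_batch()] with 0/1 labels.
#' @param cfg a [train_config()]; `cfg$seed` is applied.
#' @return A `dnn_params` network.
#' @export
attach_and_train_output_layer <- function(encoders, data, cfg = train_config()) {
  data <- as_sample_batch(data)
  set.seed(cfg$seed)
  net <- new_dnn(encoders, input_dim = ncol(encoders[[1]]$W))
  head_train_impl(net, t(data$x), data$labels, cfg)
}

finetune_impl <- function(net, Xtr, ytr, Xval, yval, cfg) {
  params <- flatten_net(net)
  st <- adam_state(params)
  es <- early_stop_state(cfg$patience)
  Y_all <- one_hot(ytr)
  train_loss <- numeric(0)
  val_acc <- numeric(0)
  for (epoch in seq_len(cfg$max_epochs)) {
    losses <- c()
    for (batch in make_batches(ncol(Xtr), cfg$batch_size)) {
      Xb <- Xtr[, batch, drop = FALSE]
      Yb <- Y_all[, batch, drop = FALSE]
      masks <- net_masks(net, length(batch), cfg)
      fw <- mlp_forward(net$layers, net$head, Xb, masks)
      gr <- mlp_backward(net$layers, net$head, Xb, fw, Yb, masks)
      flat_gr <- flatten_grads(gr)
      st <- adam_step(params, flat_gr, st, cfg)
      losses <- c(losses, cross_entropy(t(fw$P), ytr[batch]))
    }
    train_loss <- c(train_loss, mean(losses))
    acc <- net_accuracy(net, Xval, yval)
    val_acc <- c(val_acc, acc)
    upd <- early_stop_update(es, acc, params)
    es <- upd$state
    if (upd$stop) break
  }
  if (!is.null(es$best_params)) net <- unflatten_net(net, es$best_params)
  list(net = net,
       history = list(train_loss = train_loss, val_accuracy = val_acc,
                      best_epoch = es$best_epoch, best_val_accuracy = es$best))
}

flatten_grads <- function(gr, prefix = "", include_head = TRUE) {
  out <- list()
  for (l in seq_along(gr$layers)) {
    out[[paste0(prefix, "W", l)]] <- gr$layers[[l]]$W
    out[[paste0(prefix, "b", l)]] <- gr$layers[[l]]$b
  }
  if (include_head) {
    out[[paste0(prefix, "headW")]] <- gr$head$W
    out[[paste0(prefix, "headb")]] <- gr$head$b
  }
  out
}

#' Fine-tune a DNN as a multilayer perceptron
#'
#' Updates all parameters (encoders and softmax head) by Adam on the
#' cross-entropy loss with dropout after every hidden layer, mini-batches
#' reshuffled every epoch, and early stopping on validation accuracy; the
#' returned network carries the best-validation parameters.
#'
#' @param net a `dnn_params` network.
#' @param train,val [sample_batch()]es with 0/1 labels; `val` must be
#'   nonempty.
#' @param cfg a [train_config()]; `cfg$seed` is applied.
#' @return list with `net` and `history` (`train_loss`, `val_accuracy`,
#'   `best_epoch`, `best_val_accuracy`).
#' @export
fine_tune_network <- function(net, train, val, cfg = train_config()) {
  train <- as_sample_batch(train)
  val <- as_sample_batch(val)
  if (val$n < 1) stop("validation set is empty")
  set.seed(cfg$seed)
  finetune_impl(net, t(train$x), train$labels, t(val$x), val$labels, cfg)
}

#' Penultimate-layer latent code
#'
#' Deterministic eval-mode output of the third hidden layer (the 100-d
#' representation fed to the fusion network), before the softmax layer.
#'
#' @param net a `dnn_params` network.
#' @param x input vector of length `net$input_dim`, or a matrix with rows
#'   = samples.
#' @return A 100-d vector, or an n x 100 matrix for matrix input.
#' @export
extract_latent <- function(net, x) {
  single <- is.null(dim(x))
  X <- if (single) matrix(x, ncol = 1) else t(x)
  if (nrow(X) != net$input_dim)
    stop("input has ", nrow(X), " features, expected ", net$input_dim)
  H <- X
  for (l in net$layers) H <- relu(l$W %*% H + l$b)
  if (single) as.vector(H) else t(H)
}

# ---- full model ------------------------------------------------------

branch_latents <- function(net, X) {
  H <- X
  for (l in net$layers) H <- relu(l$W %*% H + l$b)
  H
}

joint_train_impl <- function(model, Xs_tr, ytr, Xs_val, yval, cfg) {
  B <- length(model$branches)
  params <- list()
  for (i in seq_len(B))
    params <- c(params, flatten_net(model$branches[[i]],
                                    prefix = paste0("br", i, "_"),
                                    include_head = FALSE))
  params <- c(params, flatten_net(model$fusion, prefix = "fus_"))
  st <- adam_state(params)
  es <- early_stop_state(cfg$patience)
  Y_all <- one_hot(ytr)
  n <- ncol(Xs_tr[[1]])
  train_loss <- numeric(0)
  val_acc <- numeric(0)
  for (epoch in seq_len(cfg$max_epochs)) {
    losses <- c()
    for (batch in make_batches(n, cfg$batch_size)) {
      m <- length(batch)
      br_fw <- vector("list", B)
      br_masks <- vector("list", B)
      latents <- vector("list", B)
      for (i in seq_len(B)) {
        net <- model$branches[[i]]
        masks <- net_masks(net, m, cfg)
        Xb <- Xs_tr[[i]][, batch, drop = FALSE]
        H <- vector("list", 3); A <- vector("list", 3)
        cur <- Xb
        for (l in 1:3) {
          A[[l]] <- net$layers[[l]]$W %*% cur + net$layers[[l]]$b
          h <- relu(A[[l]])
          if (!is.null(masks[[l]])) h <- h * masks[[l]]
          H[[l]] <- h
          cur <- h
        }
        br_fw[[i]] <- list(H = H, A = A, X = Xb)
        br_masks[[i]] <- masks
        latents[[i]] <- cur
      }
      C <- do.call(rbind, latents)
      fus <- model$fusion
      fmasks <- net_masks(fus, m, cfg)
      ffw <- mlp_forward(fus$layers, fus$head, C, fmasks)
      Yb <- Y_all[, batch, drop = FALSE]
      fgr <- mlp_backward(fus$layers, fus$head, C, ffw, Yb, fmasks,
                          want_dX = TRUE)
      grads <- flatten_grads(fgr, prefix = "fus_")
      for (i in seq_len(B)) {
        net <- model$branches[[i]]
        delta <- fgr$dX[((i - 1) * 100 + 1):(i * 100), , drop = FALSE]
        fw <- br_fw[[i]]
        for (l in 3:1) {
          if (!is.null(br_masks[[i]][[l]])) delta <- delta * br_masks[[i]][[l]]
          delta <- delta * (fw$A[[l]] > 0)
          below <- if (l == 1) fw$X else fw$H[[l - 1]]
          grads[[paste0("br", i, "_W", l)]] <- tcrossprod(delta, below)
          grads[[paste0("br", i, "_b", l)]] <- rowSums(delta)
          if (l > 1) delta <- crossprod(net$layers[[l]]$W, delta)
        }
      }
      st <- adam_step(params, grads, st, cfg)
      losses <- c(losses, cross_entropy(t(ffw$P), ytr[batch]))
    }
    train_loss <- c(train_loss, mean(losses))
    P <- predict_cols(model, Xs_val)
    acc <- mean((P[2, ] > P[1, ]) == (yval == 1L))
    val_acc <- c(val_acc, acc)
    upd <- early_stop_update(es, acc, params)
    es <- upd$state
    if (upd$stop) break
  }
  if (!is.null(es$best_params)) {
    for (i in seq_len(B))
      model$branches[[i]] <- unflatten_net(model$branches[[i]], es$best_params,
                                           prefix = paste0("br", i, "_"),
                                           include_head = FALSE)
    model$fusion <- unflatten_net(model$fusion, es$best_params, prefix = "fus_")
  }
  model$history$joint <- list(train_loss = train_loss, val_accuracy = val_acc,
                              best_epoch = es$best_epoch,
                              best_val_accuracy = es$best)
  model
}

predict_cols <- function(model, Xs) {
  latents <- mapply(function(net, X) branch_latents(net, X),
                    model$branches, Xs, SIMPLIFY = FALSE)
  C <- do.call(rbind, latents)
  mlp_forward(model$fusion$layers, model$fusion$head, C)$P
}

#' Train the multimodal multiscale network
#'
#' Full three-stage protocol over the (modality, scale) feature matrices:
#'
#' * Stage A — each branch DNN is pretrained as a stacked autoencoder on
#'   its own features, its softmax head is trained with the encoders
#'   frozen, then the branch is fine-tuned end-to-end.
#' * Stage B — the fusion DNN is built on the concatenated 100-d branch
#'   latents (input `100 * n_branches`) and given the same
#'   pretrain/head/fine-tune treatment.
#' * Stage C — all branch-encoder and fusion parameters are tuned jointly
#'   through the concatenation; gradients flow from the fusion softmax
#'   only (branch heads are kept as stage-A artefacts but no longer
#'   updated).
#'
#' Validation rows steer early stopping in every supervised phase and
#' never contribute gradient updates.
#'
#' @param features named list of feature matrices (images x patches), all
#'   with identical row order; typically the six `<modality>_<scale>`
#'   matrices from [assemble_feature_matrices()] or
#'   [simulate_feature_tables()]. Standardize first if desired.
#' @param labels integer 0/1 vector, one per row.
#' @param val_rows indices of the validation rows (nonempty; the rest
#'   train).
#' @param cfg a [train_config()].
#' @return An `mmdnn_model`: branches, fusion network, `stage_log`
#'   (completed stages A/B/C), `cfg` and per-phase training history.
#' @export
train_mmdnn <- function(features, labels, val_rows, cfg = train_config()) {
  if (is.null(names(features)) || any(names(features) == ""))
    stop("features must be a named list of matrices")
  n <- nrow(features[[1]])
  ids <- rownames(features[[1]])
  for (f in features) {
    if (nrow(f) != n || !identical(rownames(f), ids))
      stop("feature matrices have mismatched row order")
  }
  labels <- as.integer(labels)
  if (length(labels) != n || !all(labels %in% 0:1))
    stop("labels must be one 0/1 value per row")
  val_rows <- sort(unique(as.integer(val_rows)))
  if (length(val_rows) < 1 || any(val_rows < 1 | val_rows > n))
    stop("val_rows must be a nonempty subset of rows")
  train_rows <- setdiff(seq_len(n), val_rows)
  if (!length(train_rows)) stop("no training rows left")

  set.seed(cfg$seed)
  branch_names <- names(features)
  model <- structure(list(branches = setNames(vector("list", length(features)),
                                              branch_names),
                          fusion = NULL, branch_names = branch_names,
                          input_dims = vapply(features, ncol, 0L),
                          cfg = cfg, stage_log = character(0),
                          history = list(branches = list())),
                     class = "mmdnn_model")

  Xs_tr <- lapply(features, function(f) t(f[train_rows, , drop = FALSE]))
  Xs_val <- lapply(features, function(f) t(f[val_rows, , drop = FALSE]))
  ytr <- labels[train_rows]
  yval <- labels[val_rows]

  for (nm in branch_names) {
    spec <- network_spec(ncol(features[[nm]]))
    stack <- pretrain_stack_impl(Xs_tr[[nm]], spec$hidden_dims, cfg)
    net <- new_dnn(stack$layers, spec$input_dim)
    net <- head_train_impl(net, Xs_tr[[nm]], ytr, cfg)
    ft <- finetune_impl(net, Xs_tr[[nm]], ytr, Xs_val[[nm]], yval, cfg)
    model$branches[[nm]] <- ft$net
    model$history$branches[[nm]] <- list(pretrain = stack$histories,
                                         finetune = ft$history)
  }
  model$stage_log <- c(model$stage_log, "A:branches")

  Ltr <- mapply(function(net, X) branch_latents(net, X),
                model$branches[branch_names], Xs_tr[branch_names],
                SIMPLIFY = FALSE)
  Lval <- mapply(function(net, X) branch_latents(net, X),
                 model$branches[branch_names], Xs_val[branch_names],
                 SIMPLIFY = FALSE)
  Ctr <- do.call(rbind, Ltr)
  Cval <- do.call(rbind, Lval)
  fspec <- network_spec(100L * length(branch_names))
  fstack <- pretrain_stack_impl(Ctr, fspec$hidden_dims, cfg)
  fnet <- new_dnn(fstack$layers, fspec$input_dim)
  fnet <- head_train_impl(fnet, Ctr, ytr, cfg)
  fft <- finetune_impl(fnet, Ctr, ytr, Cval, yval, cfg)
  model$fusion <- fft$net
  model$history$fusion <- list(pretrain = fstack$histories,
                               finetune = fft$history)
  model$stage_log <- c(model$stage_log, "B:fusion")

  model <- joint_train_impl(model, Xs_tr[branch_names], ytr,
                            Xs_val[branch_names], yval, cfg)
  model$stage_log <- c(model$stage_log, "C:joint")
  model
}

#' @export
print.mmdnn_model <- function(x, ...) {
  cat(sprintf("<mmdnn_model> %d branches (%s), fusion input %d, stages [%s]\n",
              length(x$branch_names), paste(x$branch_names, collapse = ", "),
              100L * length(x$branch_names),
              paste(x$stage_log, collapse = ", ")))
  invisible(x)
}

#' Class probabilities from a trained model
#'
#' Deterministic eval-mode forward pass (all hidden units kept): branch
#' latents are concatenated and pushed through the fusion network's
#' softmax. The positive-class probability is the per-network disease
#' staging score: 0 reads as most control-like, 1 as most AD-like.
#'
#' @param model a trained `mmdnn_model` (stage C completed).
#' @param features named list of feature matrices matching the model's
#'   branches (same names, widths and preprocessing as at training).
#' @return n x 2 matrix with columns `p_neg`, `p_pos`; rows sum to 1.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "mmdnn_model"))
  if (!"C:joint" %in% model$stage_log)
    stop("model is not fully trained (stage C missing)")
  if (!all(model$branch_names %in% names(features)))
    stop("features must cover branches: ",
         paste(model$branch_names, collapse = ", "))
  Xs <- lapply(model$branch_names, function(nm) t(features[[nm]]))
  for (i in seq_along(Xs)) {
    if (nrow(Xs[[i]]) != model$input_dims[i])
      stop("feature width mismatch for branch ", model$branch_names[i])
  }
  P <- t(predict_cols(model, Xs))
  dimnames(P) <- list(rownames(features[[model$branch_names[1]]]),
                      c("p_neg", "p_pos"))
  P
}

# ---- checkpointing ---------------------------------------------------

#' Save or load a model checkpoint
#'
#' A checkpoint directory holds `model.json` (branch names, input dims,
#' config, stage log, tensor shapes) plus one little-endian float64
#' binary file per parameter tensor.
#'
#' @param model a trained `mmdnn_model`.
#' @param dir checkpoint directory (created if needed).
#' @return `save_mmdnn` returns `dir` invisibly; `load_mmdnn` the
#'   restored `mmdnn_model`.
#' @export
save_mmdnn <- function(model, dir) {
  stopifnot(inherits(model, "mmdnn_model"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tensors <- list()
  for (i in seq_along(model$branches))
    tensors <- c(tensors, flatten_net(model$branches[[i]],
                                      prefix = paste0("br", i, "_")))
  tensors <- c(tensors, flatten_net(model$fusion, prefix = "fus_"))
  shapes <- lapply(tensors, function(t) if (is.matrix(t)) dim(t) else length(t))
  meta <- list(branch_names = model$branch_names,
               input_dims = as.list(model$input_dims),
               stage_log = model$stage_log,
               cfg = unclass(model$cfg), shapes = shapes)
  jsonlite::write_json(meta, file.path(dir, "model.json"), auto_unbox = TRUE)
  for (nm in names(tensors)) {
    con <- file(file.path(dir, paste0(nm, ".bin")), "wb")
    writeBin(as.vector(tensors[[nm]]), con, size = 8, endian = "little")
    close(con)
  }
  invisible(dir)
}

#' @rdname save_mmdnn
#' @export
load_mmdnn <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  read_tensor <- function(nm, shape) {
    con <- file(file.path(dir, paste0(nm, ".bin")), "rb")
    v <- readBin(con, "double", n = prod(shape), size = 8, endian = "little")
    close(con)
    if (length(shape) == 2) matrix(v, shape[1], shape[2]) else v
  }
  load_net <- function(prefix, input_dim) {
    layers <- lapply(1:3, function(l) {
      W <- read_tensor(paste0(prefix, "W", l), meta$shapes[[paste0(prefix, "W", l)]])
      b <- read_tensor(paste0(prefix, "b", l), meta$shapes[[paste0(prefix, "b", l)]])
      list(W = W, b = b)
    })
    net <- new_dnn(layers, input_dim)
    net$head$W <- read_tensor(paste0(prefix, "headW"),
                              meta$shapes[[paste0(prefix, "headW")]])
    net$head$b <- read_tensor(paste0(prefix, "headb"),
                              meta$shapes[[paste0(prefix, "headb")]])
    net
  }
  branch_names <- meta$branch_names
  input_dims <- setNames(as.integer(unlist(meta$input_dims)), branch_names)
  branches <- setNames(lapply(seq_along(branch_names), function(i)
    load_net(paste0("br", i, "_"), input_dims[i])), branch_names)
  fusion <- load_net("fus_", 100L * length(branch_names))
  cfg <- do.call(train_config, meta$cfg)
  structure(list(branches = branches, fusion = fusion,
                 branch_names = branch_names, input_dims = input_dims,
                 cfg = cfg, stage_log = meta$stage_log, history = list()),
            class = "mmdnn_model")
}
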