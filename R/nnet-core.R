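# Internal dense-network primitives shared by the autoencoder pretraining,
# the per-branch DNNs and the fusion network. Data matrices are laid out
# with columns = samples (d x n) so bias vectors recycle down columns.

relu <- function(A) A * (A > 0)

round_half_up <- function(x) floor(x + 0.5)

deep_copy <- function(x) {
  if (is.list(x)) lapply(x, deep_copy) else x + 0
}

# Glorot-style scaled uniform fan init
init_weight <- function(n_out, n_in) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_out * n_in, -lim, lim), n_out, n_in)
}

init_layers <- function(dims_in, dims_out) {
  mapply(function(i, o) list(W = init_weight(o, i), b = numeric(o)),
         dims_in, dims_out, SIMPLIFY = FALSE)
}

softmax_cols <- function(L) {
  m <- apply(L, 2, max)
  E <- exp(sweep(L, 2, m, "-"))
  sweep(E, 2, colSums(E), "/")
}

# One dropout mask per activation matrix; survivors pre-scaled by
# 1/(1-rate) (inverted dropout) so eval mode is the identity.
dropout_mask <- function(n_units, n_samples, rate) {
  if (rate <= 0) return(NULL)
  matrix((runif(n_units * n_samples) >= rate) / (1 - rate), n_units, n_samples)
}

# Forward through the 3 ReLU encoder layers plus softmax head.
# masks: NULL (eval) or list of per-layer dropout masks (train).
mlp_forward <- function(layers, head, X, masks = NULL) {
  H <- vector("list", length(layers))
  A <- vector("list", length(layers))
  cur <- X
  for (l in seq_along(layers)) {
    A[[l]] <- layers[[l]]$W %*% cur + layers[[l]]$b
    h <- relu(A[[l]])
    if (!is.null(masks) && !is.null(masks[[l]])) h <- h * masks[[l]]
    H[[l]] <- h
    cur <- h
  }
  logits <- head$W %*% cur + head$b
  list(H = H, A = A, P = softmax_cols(logits))
}

one_hot <- function(labels, n_classes = 2L) {
  Y <- matrix(0, n_classes, length(labels))
  Y[cbind(labels + 1L, seq_along(labels))] <- 1
  Y
}

# Gradients of the mean cross-entropy wrt all parameters; optionally also
# wrt the input columns (needed when branch encoders sit below a fusion
# network). `fw` is the mlp_forward() result under the same masks.
mlp_backward <- function(layers, head, X, fw, Y, masks = NULL,
                         want_dX = FALSE) {
  n <- ncol(X)
  d_logits <- (fw$P - Y) / n
  L <- length(layers)
  grads <- list(head = list(W = tcrossprod(d_logits, fw$H[[L]]),
                            b = rowSums(d_logits)),
                layers = vector("list", L))
  delta <- crossprod(head$W, d_logits)
  for (l in L:1) {
    if (!is.null(masks) && !is.null(masks[[l]])) delta <- delta * masks[[l]]
    delta <- delta * (fw$A[[l]] > 0)
    below <- if (l == 1) X else fw$H[[l - 1]]
    grads$layers[[l]] <- list(W = tcrossprod(delta, below),
                              b = rowSums(delta))
    if (l > 1 || want_dX) delta <- crossprod(layers[[l]]$W, delta)
  }
  if (want_dX) grads$dX <- delta
  grads
}

# ---- Adam ------------------------------------------------------------

# Flat named list of tensors -> state with zeroed first/second moments.
# The update mutates the parameter tensors in place through the C++
# kernel; callers must hold the only live reference (snapshots are taken
# with deep_copy()).
adam_state <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = deep_copy(zeros), t = 0)
}

adam_step <- function(params, grads, st, cfg) {
  st$t <- st$t + 1
  for (k in names(params)) {
    adam_update_inplace(params[[k]], grads[[k]], st$m[[k]], st$v[[k]],
                        cfg$learning_rate, cfg$beta1, cfg$beta2,
                        cfg$eps, st$t)
  }
  st
}

# Flatten a net (3 encoder layers + head) into a named tensor list whose
# elements alias the net's own matrices, so in-place Adam updates the net.
flatten_net <- function(net, prefix = "", include_head = TRUE) {
  out <- list()
  for (l in seq_along(net$layers)) {
    out[[paste0(prefix, "W", l)]] <- net$layers[[l]]$W
    out[[paste0(prefix, "b", l)]] <- net$layers[[l]]$b
  }
  if (include_head) {
    out[[paste0(prefix, "headW")]] <- net$head$W
    out[[paste0(prefix, "headb")]] <- net$head$b
  }
  out
}

# Rebuild net tensors from a flat list (used to restore early-stopping
# snapshots; deep-copies so later training cannot corrupt the snapshot).
unflatten_net <- function(net, flat, prefix = "", include_head = TRUE) {
  for (l in seq_along(net$layers)) {
    net$layers[[l]]$W <- flat[[paste0(prefix, "W", l)]] + 0
    net$layers[[l]]$b <- flat[[paste0(prefix, "b", l)]] + 0
  }
  if (include_head) {
    net$head$W <- flat[[paste0(prefix, "headW")]] + 0
    net$head$b <- flat[[paste0(prefix, "headb")]] + 0
  }
  net
}

make_batches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

# ---- Exported low-level operations -----------------------------------

#' Tied-weight autoencoder forward pass
#'
#' Encodes `y = relu(W1 x + b1)`, decodes with the tied weight
#' `z = relu(t(W1) y + b2)` and scores the reconstruction with the squared
#' error `0.5 * ||x - z||^2`.
#'
#' @param params list with `W1` (hidden x input), `b1` (hidden), `b2`
#'   (input).
#' @param x numeric input vector (length = ncol(W1)).
#' @return list with `y` (hidden code), `z` (reconstruction) and `loss`.
#' @export
ae_forward <- function(params, x) {
  if (length(x) != ncol(params$W1))
    stop("input length ", length(x), " does not match W1 columns ",
         ncol(params$W1))
  a1 <- as.vector(params$W1 %*% x + params$b1)
  y <- pmax(a1, 0)
  a2 <- as.vector(crossprod(params$W1, y) + params$b2)
  z <- pmax(a2, 0)
  list(y = y, z = z, loss = 0.5 * sum((x - z)^2))
}

# Batch autoencoder forward/backward; loss and gradients are means over
# the batch columns.
ae_forward_batch <- function(W, b1, b2, X) {
  A1 <- W %*% X + b1
  Y <- relu(A1)
  A2 <- crossprod(W, Y) + b2
  Z <- relu(A2)
  list(A1 = A1, Y = Y, A2 = A2, Z = Z,
       loss = 0.5 * sum((X - Z)^2) / ncol(X))
}

ae_backward_batch <- function(W, fw, X) {
  n <- ncol(X)
  d2 <- ((fw$Z - X) / n) * (fw$A2 > 0)
  d1 <- (W %*% d2) * (fw$A1 > 0)
  list(W1 = tcrossprod(d1, X) + tcrossprod(fw$Y, d2),
       b1 = rowSums(d1), b2 = rowSums(d2))
}

#' Mean cross-entropy of two-class probabilities
#'
#' `H = -(1/n) * sum_i log p_i[y_i]`, with probabilities clipped at 1e-12
#' before the logarithm.
#'
#' @param probs n x 2 matrix of class probabilities (rows sum to 1).
#' @param labels integer vector of 0/1 class labels.
#' @return Non-negative scalar loss.
#' @examples
#' cross_entropy(matrix(c(0.5, 0.5), 1), 0)  # log(2)
#' @export
cross_entropy <- function(probs, labels) {
  probs <- rbind(probs)
  if (nrow(probs) != length(labels))
    stop("probs rows and labels length differ")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  p_true <- probs[cbind(seq_along(labels), labels + 1L)]
  -mean(log(pmax(p_true, 1e-12)))
}

#' Dropout
#'
#' Inverted dropout: in train mode each unit is zeroed independently with
#' probability `rate` and survivors are scaled by `1/(1-rate)`, so the
#' expected activation matches eval mode, where all units are kept and the
#' input is returned unchanged.
#'
#' @param activations numeric vector or matrix of unit activations.
#' @param rate drop probability in `[0, 1)`.
#' @param mode `"train"` or `"eval"`.
#' @return Same shape as `activations`.
#' @export
apply_dropout <- function(activations, rate = 0.5, mode = c("train", "eval")) {
  mode <- match.arg(mode)
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (mode == "eval" || rate == 0) return(activations)
  keep <- (runif(length(activations)) >= rate) / (1 - rate)
  activations * keep
}

#' Early stopping on validation accuracy
#'
#' Tracks the best validation accuracy seen so far together with a
#' snapshot of the parameters that achieved it; training stops once
#' `patience` epochs elapse without strict improvement (ties keep the
#' earlier epoch). On stop, callers restore `state$best_params`.
#'
#' @param patience number of epochs without improvement tolerated.
#' @return `early_stop_state()` returns the initial state;
#'   `early_stop_update()` a list with the updated `state` and logical
#'   `stop`.
#' @export
early_stop_state <- function(patience = 50) {
  list(patience = patience, best = -Inf, best_epoch = NA_integer_,
       since = 0L, epoch = 0L, best_params = NULL)
}

#' @rdname early_stop_state
#' @param state state from [early_stop_state()] or a previous update.
#' @param epoch_val_accuracy validation accuracy of the epoch just run.
#' @param params parameters to snapshot if this epoch improves on the
#'   best (deep-copied, so later in-place updates cannot corrupt it).
#' @export
early_stop_update <- function(state, epoch_val_accuracy, params = NULL) {
  state$epoch <- state$epoch + 1L
  if (epoch_val_accuracy > state$best) {
    state$best <- epoch_val_accuracy
    state$best_epoch <- state$epoch
    state$since <- 0L
    if (!is.null(params)) state$best_params <- deep_copy(params)
  } else {
    state$since <- state$since + 1L
  }
  list(state = state, stop = state$since >= state$patience)
}
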