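# Minimal dense-network engine used by every trainable pipeline stage.
#
# A network is a list of layers, each with a weight matrix W (in x out) and
# bias b; hidden layers use tanh, the output layer is either a softmax
# (classification; optionally focal-weighted) or linear (regression,
# squared loss).  Training is minibatch SGD with classical momentum,
# optional per-layer freezing, an epoch-level example filter (used for the
# aspect-ratio cycling scheme) and early stopping on a development set.
# Everything is deterministic given the seed.

nn_new <- function(sizes, output = c("softmax", "linear"), seed = 1L) {
  output <- match.arg(output)
  stopifnot(length(sizes) >= 2L, all(sizes >= 1L))
  set.seed(as.integer(seed))
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- sizes[l]
    sd0 <- sqrt(1 / fan_in)
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * sizes[l + 1L], 0, sd0), fan_in, sizes[l + 1L]),
      b = rep(0, sizes[l + 1L])
    )
  }
  structure(list(layers = layers, sizes = sizes, output = output),
            class = "angio_nn")
}

# Copy shape-compatible leading layers of `from` into `net` (transfer
# initialization from a trained "core model"); the output layer is left at
# its fresh random initialization unless shapes match and `include_output`.
nn_transfer <- function(net, from, include_output = FALSE) {
  n <- length(net$layers)
  upto <- if (include_output) n else n - 1L
  for (l in seq_len(min(upto, length(from$layers)))) {
    if (all(dim(net$layers[[l]]$W) == dim(from$layers[[l]]$W))) {
      net$layers[[l]] <- from$layers[[l]]
    }
  }
  net
}

nn_forward <- function(net, X) {
  acts <- vector("list", length(net$layers) + 1L)
  acts[[1L]] <- X
  nl <- length(net$layers)
  for (l in seq_len(nl)) {
    Z <- sweep(acts[[l]] %*% net$layers[[l]]$W, 2L, net$layers[[l]]$b, "+")
    acts[[l + 1L]] <- if (l < nl) tanh(Z) else Z
  }
  acts
}

nn_softmax <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Predict: probabilities (softmax) or raw outputs (linear).
nn_predict <- function(net, X) {
  Z <- nn_forward(net, X)[[length(net$layers) + 1L]]
  if (net$output == "softmax") nn_softmax(Z) else Z
}

# Mean loss. Y: one-hot matrix (softmax) or numeric matrix (linear).
nn_loss <- function(net, X, Y, weights = NULL) {
  P <- nn_predict(net, X)
  if (net$output == "softmax") {
    p_t <- rowSums(P * Y)
    li <- -log(pmax(p_t, 1e-12))
  } else {
    li <- rowSums((P - Y)^2)
  }
  if (!is.null(weights)) li <- li * weights
  mean(li)
}

# One SGD step on a minibatch; velocity `vel` is updated in place-style.
nn_step <- function(net, vel, X, Y, lr, momentum, weights = NULL,
                    focal_gamma = 0, freeze = NULL) {
  n <- nrow(X)
  acts <- nn_forward(net, X)
  nl <- length(net$layers)
  Z_out <- acts[[nl + 1L]]
  if (net$output == "softmax") {
    P <- nn_softmax(Z_out)
    delta <- P - Y
    if (focal_gamma > 0) {
      p_t <- pmax(rowSums(P * Y), 1e-12)
      delta <- delta * (1 - p_t)^focal_gamma
    }
  } else {
    delta <- 2 * (Z_out - Y)
  }
  if (!is.null(weights)) delta <- delta * weights
  delta <- delta / n
  for (l in seq(nl, 1L)) {
    gW <- crossprod(acts[[l]], delta)
    gb <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(net$layers[[l]]$W)) * (1 - acts[[l]]^2)
    }
    if (!is.null(freeze) && isTRUE(freeze[l])) next
    vel[[l]]$W <- momentum * vel[[l]]$W - lr * gW
    vel[[l]]$b <- momentum * vel[[l]]$b - lr * gb
    net$layers[[l]]$W <- net$layers[[l]]$W + vel[[l]]$W
    net$layers[[l]]$b <- net$layers[[l]]$b + vel[[l]]$b
  }
  list(net = net, vel = vel)
}

# Full training loop.
#   X, Y          : design matrix and target (one-hot or numeric matrix)
#   dev_X, dev_Y  : optional development set for early stopping
#   patience      : epochs without dev-loss improvement before stopping
#   epoch_subset  : optional function(epoch) -> logical/integer index into
#                   rows of X (aspect-ratio cycling); NULL = all rows
#   lr_schedule   : optional function(epoch) -> learning rate
nn_train <- function(net, X, Y, epochs = 20L, lr = 0.05, momentum = 0.9,
                     batch_size = 32L, weights = NULL, focal_gamma = 0,
                     dev_X = NULL, dev_Y = NULL, patience = Inf,
                     epoch_subset = NULL, lr_schedule = NULL,
                     freeze = NULL, seed = 1L) {
  set.seed(as.integer(seed))
  vel <- lapply(net$layers, function(l)
    list(W = matrix(0, nrow(l$W), ncol(l$W)), b = rep(0, length(l$b))))
  best <- list(net = net, loss = Inf, epoch = 0L)
  bad <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        dev_loss = numeric())
  has_dev <- !is.null(dev_X) && nrow(dev_X) > 0L
  for (ep in seq_len(epochs)) {
    idx <- seq_len(nrow(X))
    if (!is.null(epoch_subset)) {
      sub <- epoch_subset(ep)
      if (length(sub) > 0L) idx <- idx[sub]
    }
    idx <- sample(idx)
    lr_ep <- if (is.null(lr_schedule)) lr else lr_schedule(ep)
    nb <- ceiling(length(idx) / batch_size)
    for (bi in seq_len(nb)) {
      take <- idx[((bi - 1L) * batch_size + 1L):min(bi * batch_size, length(idx))]
      st <- nn_step(net, vel, X[take, , drop = FALSE], Y[take, , drop = FALSE],
                    lr_ep, momentum,
                    weights = if (is.null(weights)) NULL else weights[take],
                    focal_gamma = focal_gamma, freeze = freeze)
      net <- st$net; vel <- st$vel
    }
    tl <- nn_loss(net, X[idx, , drop = FALSE], Y[idx, , drop = FALSE],
                  if (is.null(weights)) NULL else weights[idx])
    dl <- if (has_dev) nn_loss(net, dev_X, dev_Y) else NA_real_
    history <- rbind(history, data.frame(epoch = ep, train_loss = tl,
                                         dev_loss = dl))
    monitor <- if (has_dev) dl else tl
    if (monitor < best$loss - 1e-12) {
      best <- list(net = net, loss = monitor, epoch = ep)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) break
    }
  }
  net <- best$net
  net$history <- history
  net$stopped_epoch <- nrow(history)
  net$best_epoch <- best$epoch
  net
}

# One-hot encode a factor/character vector against a fixed vocabulary.
nn_onehot <- function(labels, vocab) {
  m <- matrix(0, length(labels), length(vocab))
  j <- match(labels, vocab)
  if (anyNA(j)) stop("label outside vocabulary: ",
                     paste(unique(labels[is.na(j)]), collapse = ", "))
  m[cbind(seq_along(labels), j)] <- 1
  m
}

# Standardization helper: fit on training features, apply everywhere.
nn_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[!is.finite(sd) | sd < 1e-8] <- 1
  list(mu = mu, sd = sd)
}

nn_scale <- function(X, scaler) {
  sweep(sweep(X, 2L, scaler$mu, "-"), 2L, scaler$sd, "/")
}

# Concatenated checksum of selected layers' parameters (freeze audits).
nn_checksum <- function(net, layers = seq_along(net$layers)) {
  v <- unlist(lapply(net$layers[layers], function(l) c(l$W, l$b)))
  sum(v * seq_along(v) %% 97)
}
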