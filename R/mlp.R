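# Minimal feed-forward binary classifier: ReLU hidden layers, sigmoid
# output, inverted dropout, Adam updates on mini-batch cross-entropy.
# Used for the tile-level response scorer (1024 -> 256 -> 64 -> 1) and,
# with small hidden sizes, for the tabular compartment classifier.

.mlp_init <- function(d_in, hidden, seed) {
  set.seed(seed)
  dims <- c(d_in, hidden, 1L)
  W <- b <- vector("list", length(dims) - 1L)
  for (l in seq_along(W)) {
    # He initialization for ReLU layers
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L],
                                  sd = sqrt(2 / dims[l])),
                     dims[l], dims[l + 1L])
    b[[l]] <- rep(0, dims[l + 1L])
  }
  list(W = W, b = b)
}

.mlp_forward <- function(par, X) {
  nl <- length(par$W)
  a <- X
  for (l in seq_len(nl - 1L)) {
    a <- pmax(sweep(a %*% par$W[[l]], 2L, par$b[[l]], "+"), 0)
  }
  z <- drop(a %*% par$W[[nl]]) + par$b[[nl]]
  1 / (1 + exp(-z))
}

.bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train a feed-forward binary scorer
#'
#' ReLU multilayer perceptron with a sigmoid output trained by Adam on
#' binary cross-entropy, with inverted dropout on hidden activations
#' and optional early stopping on a validation set (the parameters from
#' the best validation epoch are returned). Deterministic given
#' \code{seed}.
#'
#' @param X Numeric matrix (rows = samples).
#' @param y Binary 0/1 labels.
#' @param hidden Integer vector of hidden-layer sizes.
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param dropout Dropout rate on hidden activations during training.
#' @param l2 L2 penalty on weights.
#' @param max_epochs Maximum epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement); ignored without a validation set.
#' @param X_val,y_val Optional validation set.
#' @param seed RNG seed (initialization, shuffling, dropout).
#' @return Object of class \code{mlp_model} with the trained
#'   parameters, the loss traces and the input dimension.
#' @export
mlp_train <- function(X, y, hidden = c(32L), lr = 1e-3, batch_size = 32L,
                      dropout = 0, l2 = 0, max_epochs = 200L,
                      patience = 20L, X_val = NULL, y_val = NULL,
                      seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  set.seed(seed)
  par <- .mlp_init(ncol(X), hidden, seed)
  nl <- length(par$W)
  mW <- vW <- lapply(par$W, function(w) w * 0)
  mb <- vb <- lapply(par$b, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t_adam <- 0L
  n <- nrow(X)
  has_val <- !is.null(X_val)
  best_val <- Inf; best_par <- par; stale <- 0L
  train_trace <- val_trace <- numeric(0)

  for (epoch in seq_len(max_epochs)) {
    perm <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
      nb <- length(idx)
      # forward with dropout masks
      acts <- vector("list", nl)      # post-dropout activations fed to layer l+1
      zs <- vector("list", nl - 1L)
      masks <- vector("list", nl - 1L)
      a <- Xb
      for (l in seq_len(nl - 1L)) {
        z <- sweep(a %*% par$W[[l]], 2L, par$b[[l]], "+")
        h <- pmax(z, 0)
        if (dropout > 0) {
          m <- matrix(stats::runif(length(h)) >= dropout, nrow(h)) / (1 - dropout)
          h <- h * m
          masks[[l]] <- m
        }
        zs[[l]] <- z
        acts[[l]] <- a
        a <- h
      }
      acts[[nl]] <- a
      p <- 1 / (1 + exp(-(drop(a %*% par$W[[nl]]) + par$b[[nl]])))
      # backward
      dz <- matrix((p - yb) / nb, ncol = 1L)
      for (l in rev(seq_len(nl))) {
        gW <- crossprod(acts[[l]], dz) + 2 * l2 * par$W[[l]]
        gb <- colSums(dz)
        if (l > 1L) {
          da <- dz %*% t(par$W[[l]])
          if (dropout > 0) da <- da * masks[[l - 1L]]
          dz <- da * (zs[[l - 1L]] > 0)
        }
        t_adam <- if (l == nl) t_adam + 1L else t_adam
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
        cor1 <- 1 - b1^t_adam; cor2 <- 1 - b2^t_adam
        par$W[[l]] <- par$W[[l]] - lr * (mW[[l]] / cor1) /
          (sqrt(vW[[l]] / cor2) + eps)
        par$b[[l]] <- par$b[[l]] - lr * (mb[[l]] / cor1) /
          (sqrt(vb[[l]] / cor2) + eps)
      }
    }
    train_trace <- c(train_trace, .bce(.mlp_forward(par, X), y))
    if (has_val) {
      vl <- .bce(.mlp_forward(par, X_val), y_val)
      val_trace <- c(val_trace, vl)
      if (vl < best_val - 1e-6) {
        best_val <- vl; best_par <- par; stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= patience) break
      }
    }
  }
  if (has_val) par <- best_par
  structure(list(par = par, d_in = ncol(X), hidden = hidden,
                 train_loss = train_trace, val_loss = val_trace,
                 best_val = if (has_val) best_val else NA_real_,
                 epochs_run = length(train_trace), seed = seed),
            class = "mlp_model")
}

#' Predict probabilities from a trained MLP
#'
#' @param model An \code{mlp_model}.
#' @param X Numeric matrix with \code{model$d_in} columns.
#' @return Probability vector in \code{[0, 1]}, one per row.
#' @export
mlp_predict <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$d_in) {
    stop("input has ", ncol(X), " columns; model expects ", model$d_in)
  }
  .mlp_forward(model$par, X)
}
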