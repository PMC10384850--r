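# Minimal dense feed-forward network with Adam, used by both the
# autoencoder reducer (sigmoid encoder / ReLU decoder, MSE loss) and the
# MLP classifier (ReLU hidden layers, sigmoid output, cross-entropy).
# Deterministic given the seed: weight init, batch shuffling and nothing
# else draw randomness.

act_fun <- function(name) {
  switch(name,
         relu = list(f = function(z) pmax(z, 0),
                     df = function(z, a) (z > 0) * 1),
         sigmoid = list(f = function(z) 1 / (1 + exp(-z)),
                        df = function(z, a) a * (1 - a)),
         identity = list(f = function(z) z,
                         df = function(z, a) 1),
         stop("unknown activation: ", name, call. = FALSE))
}

# Glorot-uniform initialisation; `activations` has one entry per weight
# layer (length(layer_sizes) - 1).
nn_init <- function(layer_sizes, activations, seed) {
  stopifnot(length(activations) == length(layer_sizes) - 1L)
  with_seed(seed, {
    W <- vector("list", length(activations))
    b <- vector("list", length(activations))
    for (l in seq_along(activations)) {
      fan_in <- layer_sizes[l]; fan_out <- layer_sizes[l + 1L]
      lim <- sqrt(6 / (fan_in + fan_out))
      W[[l]] <- matrix(runif(fan_in * fan_out, -lim, lim),
                       nrow = fan_in, ncol = fan_out)
      b[[l]] <- rep(0, fan_out)
    }
    list(sizes = layer_sizes, activations = activations, W = W, b = b)
  })
}

nn_forward <- function(net, X, upto = length(net$W)) {
  A <- X
  Zs <- vector("list", upto); As <- vector("list", upto)
  for (l in seq_len(upto)) {
    Z <- sweep(A %*% net$W[[l]], 2, net$b[[l]], "+")
    A <- act_fun(net$activations[l])$f(Z)
    Zs[[l]] <- Z; As[[l]] <- A
  }
  list(out = A, Z = Zs, A = As)
}

# `loss`: "mse" -> 0.5-free mean squared error with identity pairing;
# "bce" -> binary cross-entropy, assumes sigmoid output layer (the
# delta simplifies to out - Y in both pairings used here).
nn_train <- function(net, X, Y, loss = c("mse", "bce"), epochs,
                     batch_size = 32L, lr = 1e-3, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8, shuffle = TRUE,
                     seed = 1L, tol = NULL, patience = 10L,
                     trace_loss = FALSE) {
  loss <- match.arg(loss)
  epochs <- assert_count(epochs, "epochs")
  n <- nrow(X)
  Y <- as.matrix(Y)
  L <- length(net$W)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(x) x * 0); vb <- mb
  t_step <- 0L
  losses <- numeric(0)
  best <- Inf; stall <- 0L
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- if (shuffle) sample.int(n) else seq_len(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
        fw <- nn_forward(net, Xb)
        out <- fw$out
        m <- length(idx)
        if (loss == "mse") {
          ep_loss <- ep_loss + sum((out - Yb)^2)
          delta <- 2 * (out - Yb) / (m * ncol(Yb))
          delta <- delta * act_fun(net$activations[L])$df(fw$Z[[L]], out)
        } else {
          p <- pmin(pmax(out, 1e-12), 1 - 1e-12)
          ep_loss <- ep_loss - sum(Yb * log(p) + (1 - Yb) * log(1 - p))
          delta <- (out - Yb) / m  # sigmoid + cross-entropy shortcut
        }
        t_step <- t_step + 1L
        for (l in L:1) {
          A_prev <- if (l == 1L) Xb else fw$A[[l - 1L]]
          gW <- crossprod(A_prev, delta)
          gb <- colSums(delta)
          if (l > 1L) {
            delta <- (delta %*% t(net$W[[l]])) *
              act_fun(net$activations[l - 1L])$df(fw$Z[[l - 1L]],
                                                  fw$A[[l - 1L]])
          }
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          mhW <- mW[[l]] / (1 - beta1^t_step)
          vhW <- vW[[l]] / (1 - beta2^t_step)
          mhb <- mb[[l]] / (1 - beta1^t_step)
          vhb <- vb[[l]] / (1 - beta2^t_step)
          net$W[[l]] <- net$W[[l]] - lr * mhW / (sqrt(vhW) + eps)
          net$b[[l]] <- net$b[[l]] - lr * mhb / (sqrt(vhb) + eps)
        }
      }
      ep_loss <- ep_loss / n
      if (trace_loss) losses <- c(losses, ep_loss)
      if (!is.null(tol)) {  # sklearn-style plateau stop
        if (ep_loss < best - tol) { best <- ep_loss; stall <- 0L }
        else {
          stall <- stall + 1L
          if (stall >= patience) break
        }
      }
    }
  })
  net$epochs_run <- if (!is.null(tol)) ep else epochs
  net$loss_trace <- losses
  net
}
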