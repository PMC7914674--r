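# Minimal MLP engine: dense layers with optional inverted dropout on the
# layer input and batch normalization between the affine map and the
# activation.  Forward passes return caches sufficient for exact backprop;
# training is plain RMSprop.  All matrices are row-major in the sample
# dimension (rows = samples).

.BN_EPS <- 1e-3       # added to the batch variance before normalizing
.BN_MOMENTUM <- 0.99  # running-statistics update: r <- m*r + (1-m)*batch

# widths: length n_layers + 1 (input width first)
# acts: one of "linear", "relu", "sigmoid", "softmax" per layer
# dropout: rate applied to each layer's *input* (0 disables)
# bn: logical per layer, batch normalization after the affine map
# Uses the current RNG state for Glorot-uniform initialization.
mlp_new <- function(widths, acts, dropout = NULL, bn = NULL) {
  nl <- length(widths) - 1L
  stopifnot(nl >= 1L, length(acts) == nl)
  if (is.null(dropout)) dropout <- rep(0, nl)
  if (is.null(bn)) bn <- rep(FALSE, nl)
  stopifnot(length(dropout) == nl, length(bn) == nl,
            all(dropout >= 0 & dropout < 1), all(widths >= 1L))
  layers <- vector("list", nl)
  for (l in seq_len(nl)) {
    fan_in <- widths[l]; fan_out <- widths[l + 1L]
    lim <- sqrt(6 / (fan_in + fan_out))
    layers[[l]] <- list(
      W = matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
      b = rep(0, fan_out),
      act = acts[l], dropout = dropout[l], bn = isTRUE(bn[l]),
      gamma = if (bn[l]) rep(1, fan_out),
      beta = if (bn[l]) rep(0, fan_out),
      rmean = if (bn[l]) rep(0, fan_out),
      rvar = if (bn[l]) rep(1, fan_out))
  }
  structure(list(layers = layers, widths = widths), class = "nirbigan_mlp")
}

.act_fwd <- function(z, act) {
  switch(act,
         linear = z,
         relu = pmax(z, 0),
         sigmoid = 1 / (1 + exp(-z)),
         softmax = {
           m <- apply(z, 1L, max)
           e <- exp(z - m)
           e / rowSums(e)
         },
         stop("unknown activation: ", act))
}

# Forward pass.  Returns list(out, cache, net); `net` carries updated BN
# running statistics when training = TRUE.
mlp_forward <- function(net, X, training = FALSE) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  m <- nrow(X)
  cache <- vector("list", length(net$layers))
  A <- X
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    mask <- NULL
    Xd <- A
    if (training && ly$dropout > 0) {
      keep <- 1 - ly$dropout
      mask <- matrix(stats::runif(length(A)) < keep, nrow = m) / keep
      Xd <- A * mask
    }
    Z <- Xd %*% ly$W + rep(ly$b, each = m)
    bn_cache <- NULL
    if (ly$bn) {
      if (training) {
        mu <- colMeans(Z)
        va <- colMeans(Z^2) - mu^2  # biased batch variance
        va <- pmax(va, 0)
        net$layers[[l]]$rmean <- .BN_MOMENTUM * ly$rmean + (1 - .BN_MOMENTUM) * mu
        net$layers[[l]]$rvar <- .BN_MOMENTUM * ly$rvar + (1 - .BN_MOMENTUM) * va
      } else {
        mu <- ly$rmean
        va <- ly$rvar
      }
      ivs <- 1 / sqrt(va + .BN_EPS)
      xhat <- (Z - rep(mu, each = m)) * rep(ivs, each = m)
      Zb <- xhat * rep(ly$gamma, each = m) + rep(ly$beta, each = m)
      bn_cache <- list(xhat = xhat, ivs = ivs, batch = training)
    } else {
      Zb <- Z
    }
    A <- .act_fwd(Zb, ly$act)
    cache[[l]] <- list(Xd = Xd, mask = mask, bn = bn_cache, A = A)
  }
  list(out = A, cache = cache, net = net)
}

# Backward pass from dA = dLoss/d(output of the last layer).  Returns
# list(grads, dX): grads[[l]] holds dW, db (and dgamma, dbeta for BN
# layers); dX is the gradient w.r.t. the network input.
mlp_backward <- function(net, cache, dA) {
  if (is.null(dim(dA))) dA <- matrix(dA, nrow = 1L)
  nl <- length(net$layers)
  grads <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    ly <- net$layers[[l]]
    cc <- cache[[l]]
    m <- nrow(dA)
    A <- cc$A
    dZb <- switch(ly$act,
                  linear = dA,
                  relu = dA * (A > 0),
                  sigmoid = dA * A * (1 - A),
                  softmax = A * (dA - rowSums(dA * A)))
    if (ly$bn) {
      bc <- cc$bn
      dgamma <- colSums(dZb * bc$xhat)
      dbeta <- colSums(dZb)
      dxhat <- dZb * rep(ly$gamma, each = m)
      if (bc$batch) {
        s1 <- colSums(dxhat)
        s2 <- colSums(dxhat * bc$xhat)
        dZ <- (dxhat - rep(s1 / m, each = m) -
                 bc$xhat * rep(s2 / m, each = m)) * rep(bc$ivs, each = m)
      } else {
        dZ <- dxhat * rep(bc$ivs, each = m)  # running stats are constants
      }
    } else {
      dgamma <- NULL; dbeta <- NULL
      dZ <- dZb
    }
    grads[[l]] <- list(dW = crossprod(cc$Xd, dZ), db = colSums(dZ),
                       dgamma = dgamma, dbeta = dbeta)
    dXd <- tcrossprod(dZ, ly$W)
    dA <- if (!is.null(cc$mask)) dXd * cc$mask else dXd
  }
  list(grads = grads, dX = dA)
}

# RMSprop with Keras-default hyperparameters.
rmsprop_state <- function(net) {
  lapply(net$layers, function(ly) {
    s <- list(W = ly$W * 0, b = ly$b * 0)
    if (ly$bn) { s$gamma <- ly$gamma * 0; s$beta <- ly$beta * 0 }
    s
  })
}

rmsprop_step <- function(net, grads, state, lr = 1e-3, rho = 0.9, eps = 1e-7) {
  upd <- function(p, g, s) {
    s2 <- rho * s + (1 - rho) * g^2
    list(p = p - lr * g / (sqrt(s2) + eps), s = s2)
  }
  for (l in seq_along(net$layers)) {
    u <- upd(net$layers[[l]]$W, grads[[l]]$dW, state[[l]]$W)
    net$layers[[l]]$W <- u$p; state[[l]]$W <- u$s
    u <- upd(net$layers[[l]]$b, grads[[l]]$db, state[[l]]$b)
    net$layers[[l]]$b <- u$p; state[[l]]$b <- u$s
    if (net$layers[[l]]$bn) {
      u <- upd(net$layers[[l]]$gamma, grads[[l]]$dgamma, state[[l]]$gamma)
      net$layers[[l]]$gamma <- u$p; state[[l]]$gamma <- u$s
      u <- upd(net$layers[[l]]$beta, grads[[l]]$dbeta, state[[l]]$beta)
      net$layers[[l]]$beta <- u$p; state[[l]]$beta <- u$s
    }
  }
  list(net = net, state = state)
}

# Flatten / restore all trainable parameters (used by finite-difference
# gradient checks and determinism tests).
mlp_get_params <- function(net) {
  unlist(lapply(net$layers, function(ly)
    c(ly$W, ly$b, ly$gamma, ly$beta)), use.names = FALSE)
}

mlp_set_params <- function(net, theta) {
  pos <- 0L
  take <- function(n) {
    out <- theta[pos + seq_len(n)]
    pos <<- pos + n
    out
  }
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    net$layers[[l]]$W <- matrix(take(length(ly$W)), nrow(ly$W), ncol(ly$W))
    net$layers[[l]]$b <- take(length(ly$b))
    if (ly$bn) {
      net$layers[[l]]$gamma <- take(length(ly$gamma))
      net$layers[[l]]$beta <- take(length(ly$beta))
    }
  }
  stopifnot(pos == length(theta))
  net
}

# Recompute BN running statistics from a reference matrix: one forward
# pass per layer using the observed statistics, which are stored as the
# new running statistics.  Dropout is not applied.
mlp_refresh_bn <- function(net, X) {
  A <- X
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    Z <- A %*% ly$W + rep(ly$b, each = nrow(A))
    if (ly$bn) {
      mu <- colMeans(Z)
      va <- pmax(colMeans(Z^2) - mu^2, 0)
      net$layers[[l]]$rmean <- mu
      net$layers[[l]]$rvar <- va
      Z <- (Z - rep(mu, each = nrow(A))) / rep(sqrt(va + .BN_EPS), each = nrow(A))
      Z <- Z * rep(ly$gamma, each = nrow(A)) + rep(ly$beta, each = nrow(A))
    }
    A <- .act_fwd(Z, ly$act)
  }
  net
}
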