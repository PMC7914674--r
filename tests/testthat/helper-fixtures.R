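# Shared miniature fixtures: everything is generated in code at test time.

tiny_grid <- function(n = 64L) wavenumber_grid(n_channels = n)

tiny_catalog <- function() class_catalog(1:4, c(1L, 1L, 2L, 2L), rep(40L, 4))

# An easy, well-separated miniature dataset: large manufacturer effect,
# little nuisance, so small networks learn it quickly.
tiny_dataset <- function(seed = 3L, n = 64L) {
  simulate_dataset(tiny_catalog(), tiny_grid(n),
                   manufacturer_effect = 0.8, noise_sd = 0.002,
                   scatter_sd = 0.02, drift_sd = 0.02, tilt_sd = 0.02,
                   outlier_prob = 0, seed = seed)
}

tiny_config <- function(n = 64L, ...) {
  bigan_config(grid = tiny_grid(n), epochs = 60L, pretrain_epochs = 40L,
               n_per_class = 20L, batch_size = 20L, ...)
}

# Brute-force scalar reference implementations of the three losses,
# deliberately written loop-wise and independent of the vectorized code.
ref_loss_classification <- function(c, c_hat, eps = 1e-7) {
  s <- 0
  for (i in seq_along(c)) {
    p <- c_hat[i]
    if (p < eps) p <- eps
    if (p > 1) p <- 1
    s <- s - c[i] * log(p)
  }
  s
}

ref_loss_discriminator <- function(y, y_hat, cls = 0, eps = 1e-7) {
  s <- 0
  for (i in seq_along(y)) {
    p <- min(max(y_hat[i], eps), 1 - eps)
    s <- s - (y[i] * log(p) + (1 - y[i]) * log(1 - p))
  }
  s + cls
}

ref_loss_generator <- function(y_hat, cls = 0, eps = 1e-7) {
  s <- 0
  for (i in seq_along(y_hat)) {
    p <- min(max(y_hat[i], eps), 1)
    s <- s - log(p)
  }
  s + cls
}

# Central finite-difference gradient of a scalar loss over all trainable
# parameters of a network.
fd_gradient <- function(net, X, lossfn, h = 1e-5, training = FALSE) {
  ns <- asNamespace("nirbigan")
  th <- ns$mlp_get_params(net)
  g <- numeric(length(th))
  for (i in seq_along(th)) {
    tp <- th; tp[i] <- th[i] + h
    tm <- th; tm[i] <- th[i] - h
    g[i] <- (lossfn(ns$mlp_forward(ns$mlp_set_params(net, tp), X,
                                   training = training)$out) -
               lossfn(ns$mlp_forward(ns$mlp_set_params(net, tm), X,
                                     training = training)$out)) / (2 * h)
  }
  g
}

analytic_gradient <- function(net, X, dAfn, training = FALSE) {
  ns <- asNamespace("nirbigan")
  f <- ns$mlp_forward(net, X, training = training)
  bk <- ns$mlp_backward(f$net, f$cache, dAfn(f$out))
  unlist(lapply(bk$grads, function(g) c(g$dW, g$db, g$dgamma, g$dbeta)),
         use.names = FALSE)
}
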