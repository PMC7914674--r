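test_that("losses agree with brute-force scalar references on random inputs", {
  set.seed(1234)
  worst <- c(cls = 0, dis = 0, gen = 0)
  for (i in 1:1000) {
    k <- sample(2:8, 1)
    c_hat <- runif(k); c_hat <- c_hat / sum(c_hat)
    cc <- as.numeric(seq_len(k) == sample(k, 1))
    worst["cls"] <- max(worst["cls"],
                        abs(loss_classification(cc, c_hat) -
                              ref_loss_classification(cc, c_hat)))
    n <- sample(1:10, 1)
    y <- rbinom(n, 1, 0.5)
    y_hat <- runif(n, 1e-4, 1 - 1e-4)
    cls <- runif(1, 0, 3)
    worst["dis"] <- max(worst["dis"],
                        abs(loss_discriminator(y, y_hat, cls) -
                              ref_loss_discriminator(y, y_hat, cls)))
    worst["gen"] <- max(worst["gen"],
                        abs(loss_generator(y_hat, cls) -
                              ref_loss_generator(y_hat, cls)))
  }
  expect_lt(max(worst), 1e-10)
})

test_that("losses reproduce hand-computed values", {
  expect_equal(loss_classification(c(0, 1), c(0, 1)), 0)
  expect_equal(loss_classification(rep(1, 29) * diag(29)[1, ], rep(1 / 29, 29)),
               log(29), tolerance = 1e-12)
  expect_equal(loss_classification(c(1, 0), c(0.8, 0.2)), -log(0.8),
               tolerance = 1e-12)
  expect_equal(loss_discriminator(c(1, 0), c(1 - 1e-7, 1e-7)), 0,
               tolerance = 1e-5)
  expect_equal(loss_discriminator(c(1, 0), c(0.5, 0.5)), 2 * log(2),
               tolerance = 1e-12)
  expect_equal(loss_discriminator(c(1, 0), c(0.5, 0.5), cls_loss = 0.5),
               2 * log(2) + 0.5, tolerance = 1e-12)
  expect_equal(loss_generator(1), 0, tolerance = 1e-6)
  expect_equal(loss_generator(c(0.5, 0.5)), 2 * log(2), tolerance = 1e-12)
  # monotonicity: lower discriminator output raises the generator loss
  expect_gt(loss_generator(0.3), loss_generator(0.6))
})

test_that("losses validate their inputs", {
  expect_error(loss_classification(c(1, 0), c(0.5, 0.2, 0.3)), "lengths")
  expect_error(loss_classification(c(1, 0), c(1.5, -0.5)), "probabilities")
  expect_error(loss_discriminator(numeric(0), numeric(0)), "empty")
  expect_error(loss_generator(numeric(0)), "empty")
})

test_that("analytic gradients match finite differences through tiny nets", {
  ns <- asNamespace("nirbigan")
  set.seed(77)
  X <- matrix(rnorm(5 * 4), 5, 4)
  Y <- diag(2)[sample(1:2, 5, replace = TRUE), ]
  # classification loss through a 4-3-2 softmax net
  netC <- ns$mlp_new(c(4, 3, 2), c("sigmoid", "softmax"))
  gC <- analytic_gradient(netC, X, function(o) -(Y / pmax(o, 1e-12)))
  fC <- fd_gradient(netC, X, function(o) loss_classification(Y, o))
  expect_lt(max(abs(gC - fC) / pmax(abs(fC), 1e-4)), 1e-4)
  # discriminator loss through a 4-3-1 sigmoid net
  y <- c(1, 0, 1, 0, 1)
  netD <- ns$mlp_new(c(4, 3, 1), c("relu", "sigmoid"))
  dafn <- function(o) {
    p <- pmin(pmax(drop(o), 1e-12), 1 - 1e-12)
    matrix(-(y / p - (1 - y) / (1 - p)), ncol = 1)
  }
  gD <- analytic_gradient(netD, X, dafn)
  fD <- fd_gradient(netD, X, function(o) loss_discriminator(y, drop(o)))
  expect_lt(max(abs(gD - fD) / pmax(abs(fD), 1e-4)), 1e-4)
  # generator loss through the same net
  gG <- analytic_gradient(netD, X, function(o)
    matrix(-1 / pmin(pmax(drop(o), 1e-12), 1), ncol = 1))
  fG <- fd_gradient(netD, X, function(o) loss_generator(drop(o)))
  expect_lt(max(abs(gG - fG) / pmax(abs(fG), 1e-4)), 1e-4)
})

test_that("batch-normalization backward matches finite differences", {
  ns <- asNamespace("nirbigan")
  set.seed(99)
  X <- matrix(rnorm(6 * 4), 6, 4)
  Y <- diag(2)[sample(1:2, 6, replace = TRUE), ]
  net <- ns$mlp_new(c(4, 3, 2), c("relu", "softmax"), bn = c(TRUE, FALSE))
  ga <- analytic_gradient(net, X, function(o) -(Y / pmax(o, 1e-12)),
                          training = TRUE)
  gf <- fd_gradient(net, X, function(o) loss_classification(Y, o),
                    training = TRUE)
  expect_lt(max(abs(ga - gf) / pmax(abs(gf), 1e-4)), 1e-4)
})

test_that("input gradients match finite differences", {
  ns <- asNamespace("nirbigan")
  set.seed(3)
  X <- matrix(rnorm(4 * 5), 4, 5)
  net <- ns$mlp_new(c(5, 4, 1), c("relu", "sigmoid"))
  f <- ns$mlp_forward(net, X)
  bk <- ns$mlp_backward(net, f$cache,
                        matrix(-1 / pmin(pmax(drop(f$out), 1e-12), 1), ncol = 1))
  num <- X * 0
  for (i in seq_along(X)) {
    Xp <- X; Xp[i] <- X[i] + 1e-5
    Xm <- X; Xm[i] <- X[i] - 1e-5
    num[i] <- (loss_generator(drop(ns$mlp_forward(net, Xp)$out)) -
                 loss_generator(drop(ns$mlp_forward(net, Xm)$out))) / 2e-5
  }
  expect_lt(max(abs(bk$dX - num) / pmax(abs(num), 1e-4)), 1e-4)
})
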