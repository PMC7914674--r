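test_that("model building enforces shapes and is seed-deterministic", {
  cfg <- tiny_config()
  m1 <- build_bigan(tiny_catalog(), cfg, seed = 4)
  m2 <- build_bigan(tiny_catalog(), cfg, seed = 4)
  expect_identical(coef(m1), coef(m2))
  m3 <- build_bigan(tiny_catalog(), cfg, seed = 5)
  expect_false(identical(coef(m1), coef(m3)))
  expect_equal(m1$networks$E$widths, c(64, 120, 30))
  expect_equal(m1$networks$G$widths, c(30, 360, 64))
  expect_equal(m1$networks$D$widths, c(64 + 30, 120, 1))
  expect_equal(m1$networks$C$widths, c(64, 150, 4))  # one logit per class
  expect_error(build_bigan(class_catalog(1, 1, 5), cfg), "at least 2")
})

test_that("network accessors satisfy their shape and range contracts", {
  m <- build_bigan(tiny_catalog(), tiny_config(), seed = 4)
  m$scaling <- list(min = 0, max = 1)
  x <- rnorm(64)
  enc <- encode(m, x)
  expect_equal(dim(enc), c(1L, 30L))
  expect_true(all(is.finite(enc)))
  expect_identical(encode(m, x), enc)  # evaluation mode is deterministic
  expect_identical(encode(m, rep(0, 64))[1, ], encode(m, rep(0, 64))[1, ])
  g <- generate_spectra(m, rnorm(30))
  expect_equal(dim(g), c(1L, 64L))
  expect_true(all(is.finite(g)))
  p <- discriminate(m, x, rnorm(30))
  expect_true(p > 0 && p < 1)
  cl <- classify(m, rbind(x, rnorm(64)))
  expect_equal(unname(rowSums(cl)), c(1, 1), tolerance = 1e-6)
  expect_true(all(cl >= 0))
  expect_error(encode(m, rnorm(10)), "columns")
  expect_error(encode(m, c(NA, rnorm(63))), "finite")
  expect_error(generate_spectra(m, rnorm(5)), "columns")
})

test_that("training-mode encoder forwards vary under dropout", {
  ns <- asNamespace("nirbigan")
  m <- build_bigan(tiny_catalog(), tiny_config(), seed = 4)
  X <- matrix(rnorm(10 * 64), 10)
  set.seed(1)
  a <- ns$mlp_forward(m$networks$E, X, training = TRUE)$out
  b <- ns$mlp_forward(m$networks$E, X, training = TRUE)$out
  expect_gt(mean((a - b)^2), 0)
})

test_that("untrained discriminator and classifier are near their symmetric points", {
  m <- build_bigan(tiny_catalog(), tiny_config(), seed = 8)
  m$scaling <- list(min = 0, max = 1)
  set.seed(2)
  X <- matrix(runif(100 * 64), 100)
  Z <- matrix(rnorm(100 * 30), 100)
  expect_lt(abs(mean(discriminate(m, X, Z)) - 0.5), 0.2)
  expect_lt(max(abs(classify(m, X) - 1 / 4)), 0.25)
})

test_that("classifier pre-training reduces loss and learns easy data", {
  ds <- tiny_dataset()
  sp <- stratified_split(ds, 0.8, seed = 2)
  cfg <- tiny_config()
  m <- build_bigan(tiny_catalog(), cfg, seed = 1)
  # zero epochs leave parameters untouched
  m0 <- pretrain_classifier(m, ds, sp, epochs = 0, seed = 1)
  expect_identical(m0$networks$C, m$networks$C)
  m1 <- pretrain_classifier(m, ds, sp, seed = 1)
  expect_lt(tail(m1$pretrain_trace$loss, 1), m1$pretrain_trace$loss[1])
  expect_gt(tail(m1$pretrain_trace$accuracy, 1), 0.9)
  # determinism under the seed
  m2 <- pretrain_classifier(m, ds, sp, seed = 1)
  expect_identical(m1$networks$C, m2$networks$C)
  expect_identical(m1$pretrain_trace, m2$pretrain_trace)
})

test_that("adversarial training is reproducible and records a finite trace", {
  ds <- tiny_dataset()
  sp <- stratified_split(ds, 0.8, seed = 2)
  cfg <- tiny_config()
  cfg$epochs <- 5L
  f1 <- bigan(ds, split = sp, config = cfg, seed = 31)
  f2 <- bigan(ds, split = sp, config = cfg, seed = 31)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$trace, f2$trace)
  expect_equal(nrow(f1$trace), 5L)
  expect_true(all(is.finite(unlist(f1$trace))))
  expect_error(train_bigan(build_bigan(tiny_catalog(), cfg, 1), ds, sp),
               "pre-trained")
})

test_that("an easy fit classifies well and beats its generator losses down", {
  ds <- tiny_dataset()
  sp <- stratified_split(ds, 0.8, seed = 2)
  fit <- bigan(ds, split = sp, config = tiny_config(), seed = 2)
  te <- split_indices(sp, "test")
  pred <- predict(fit, ds[te], seed = 4)
  expect_gt(mean(pred == ds$class_id[te]), 0.95)
  # classifier loss decreased over the adversarial phase
  expect_lt(tail(fit$trace$c_loss, 1), fit$trace$c_loss[1])
  # the trained generator responds to its latent input
  z <- rnorm(30)
  g1 <- generate_spectra(fit, z)
  g2 <- generate_spectra(fit, z + 10)
  expect_gt(sqrt(mean((g1 - g2)^2)), 0)
  expect_identical(generate_spectra(fit, z), g1)
})

test_that("checkpoints round-trip through save and load", {
  ds <- tiny_dataset()
  cfg <- tiny_config()
  cfg$epochs <- 2L
  cfg$pretrain_epochs <- 2L
  fit <- bigan(ds, train_fraction = 0.8, config = cfg, seed = 6)
  path <- tempfile(fileext = ".rds")
  save_bigan(fit, path)
  fit2 <- load_bigan(path)
  expect_identical(coef(fit2), coef(fit))
  te <- split_indices(fit$split, "test")
  expect_identical(predict(fit2, ds[te], seed = 1),
                   predict(fit, ds[te], seed = 1))
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(load_bigan(bad), "checkpoint")
  unlink(c(path, bad))
})
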