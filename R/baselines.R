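#' Classical chemometric baselines
#'
#' Constructs one of the reference baseline classifiers at its stated
#' hyperparameters:
#'
#' * `"plsda"` — PLS discriminant analysis with 30 components (the latent
#'   dimension of the Bi-GAN); classifies by the maximal predicted class
#'   indicator after latent regression on one-hot targets, equivalent to
#'   the nearest one-hot target. Backed by [mixOmics::plsda()].
#' * `"svm_linear"` — linear SVM, cost 1 ([e1071::svm()]).
#' * `"svm_rbf"` — RBF SVM, gamma 1e-4, cost 1 ([e1071::svm()]).
#' * `"knn"` — 1-nearest-neighbour ([class::knn()]).
#' * `"bp_ann"` — back-propagation ANN with layers input-k and sigmoid
#'   activation, trained by RMSprop on cross-entropy with internal min-max
#'   scaling (uses the package's own MLP engine).
#'
#' @param name Baseline name (see above).
#' @param ... Hyperparameter overrides: `ncomp` (plsda), `cost`, `gamma`
#'   (SVMs), `k` (knn), `epochs`, `batch_size`, `learning_rate` (bp_ann).
#' @return An object of class `"nir_baseline"` with a `fit_baseline()` /
#'   `predict()` interface.
#' @examples
#' b <- baseline_model("knn")
#' @export
baseline_model <- function(name = c("plsda", "svm_linear", "svm_rbf", "knn",
                                    "bp_ann"), ...) {
  name <- match.arg(name)
  hyper <- switch(name,
                  plsda = list(ncomp = 30L),
                  svm_linear = list(cost = 1),
                  svm_rbf = list(gamma = 1e-4, cost = 1),
                  knn = list(k = 1L),
                  bp_ann = list(epochs = 300L, batch_size = 60L,
                                learning_rate = 1e-3))
  dots <- list(...)
  hyper[names(dots)] <- dots
  structure(list(name = name, hyper = hyper), class = "nir_baseline")
}

#' @export
print.nir_baseline <- function(x, ...) {
  cat("NIR baseline:", x$name, "\n  hyperparameters:",
      paste(names(x$hyper), unlist(x$hyper), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Fit a baseline classifier
#'
#' @param object A [baseline_model()].
#' @param x Training spectra matrix (rows = spectra).
#' @param y Integer class labels in 1..k.
#' @param k Number of classes (default `max(y)`).
#' @return A `"fitted_baseline"` with a `predict()` method returning
#'   integer class labels.
#' @export
fit_baseline <- function(object, x, y, k = max(y)) {
  stopifnot(inherits(object, "nir_baseline"))
  x <- as.matrix(x); y <- as.integer(y); k <- as.integer(k)
  stopifnot(nrow(x) == length(y), all(y >= 1L & y <= k))
  h <- object$hyper
  fit <- switch(
    object$name,
    plsda = {
      colnames(x) <- sprintf("ch%05d", seq_len(ncol(x)))
      mixOmics::plsda(X = x, Y = factor(y, levels = 1:k), ncomp = h$ncomp)
    },
    svm_linear = e1071::svm(x, factor(y, levels = 1:k), kernel = "linear",
                            cost = h$cost, scale = FALSE),
    svm_rbf = e1071::svm(x, factor(y, levels = 1:k), kernel = "radial",
                         gamma = h$gamma, cost = h$cost, scale = FALSE),
    knn = list(train = x, cl = y),
    bp_ann = .fit_bp_ann(x, y, k, h))
  structure(list(name = object$name, hyper = h, fit = fit, k = k),
            class = "fitted_baseline")
}

.fit_bp_ann <- function(x, y, k, h) {
  scaling <- fit_scaling(x)
  xs <- scale_spectra(x, scaling)
  net <- mlp_new(c(ncol(x), k), acts = "sigmoid")
  st <- rmsprop_state(net)
  Y <- .onehot(y, k)
  n <- nrow(xs)
  for (ep in seq_len(h$epochs)) {
    ord <- sample.int(n)
    for (bi in split(ord, ceiling(seq_along(ord) / h$batch_size))) {
      fc <- mlp_forward(net, xs[bi, , drop = FALSE], training = TRUE)
      p <- .clip01(fc$out, 1e-7)
      dA <- -(Y[bi, , drop = FALSE] / p -
                (1 - Y[bi, , drop = FALSE]) / (1 - p))
      bk <- mlp_backward(fc$net, fc$cache, dA)
      up <- rmsprop_step(fc$net, bk$grads, st, lr = h$learning_rate)
      net <- up$net; st <- up$state
    }
  }
  list(net = net, scaling = scaling)
}

#' @export
predict.fitted_baseline <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  switch(
    object$name,
    plsda = {
      colnames(newx) <- sprintf("ch%05d", seq_len(ncol(newx)))
      pr <- predict(object$fit, newx, dist = "max.dist")
      as.integer(as.character(pr$class$max.dist[, object$hyper$ncomp]))
    },
    svm_linear = ,
    svm_rbf = as.integer(as.character(predict(object$fit, newx))),
    knn = as.integer(as.character(
      class::knn(object$fit$train, newx, factor(object$fit$cl),
                 k = object$hyper$k))),
    bp_ann = max.col(mlp_forward(object$fit$net,
                                 scale_spectra(newx, object$fit$scaling))$out,
                     ties.method = "first"))
}
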