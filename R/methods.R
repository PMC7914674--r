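#' @export
print.bigan <- function(x, ...) {
  cfg <- x$config
  cat("Modified Bi-GAN NIR classifier\n")
  cat(sprintf("  input: %d channels (%.0f-%.0f cm^-1), latent dim %d, %d classes\n",
              cfg$grid$n_channels, cfg$grid$start, cfg$grid$end,
              cfg$latent_dim, x$k))
  state <- if (isTRUE(x$trained)) "trained"
  else if (isTRUE(x$pretrained)) "classifier pre-trained only"
  else "untrained"
  cat("  state:", state, "\n")
  if (!is.null(x$trace))
    cat(sprintf("  %d adversarial epochs; final losses d=%.3f g=%.3f c=%.3f\n",
                nrow(x$trace), utils::tail(x$trace$d_loss, 1),
                utils::tail(x$trace$g_loss, 1),
                utils::tail(x$trace$c_loss, 1)))
  invisible(x)
}

#' @export
summary.bigan <- function(object, ...) {
  cfg <- object$config
  widths <- function(net) paste(net$widths, collapse = "-")
  out <- list(
    architecture = c(E = widths(object$networks$E),
                     G = widths(object$networks$G),
                     D = widths(object$networks$D),
                     C = widths(object$networks$C)),
    n_parameters = vapply(object$networks,
                          function(n) length(mlp_get_params(n)), numeric(1)),
    k = object$k, config = cfg, trained = isTRUE(object$trained),
    trace = object$trace, pretrain_trace = object$pretrain_trace)
  class(out) <- "summary.bigan"
  out
}

#' @export
print.summary.bigan <- function(x, ...) {
  cat("Modified Bi-GAN NIR classifier —", x$k, "classes\n")
  cat("Network architectures (layer widths):\n")
  for (nm in names(x$architecture))
    cat(sprintf("  %s: %s  (%d parameters)\n", nm, x$architecture[nm],
                x$n_parameters[nm]))
  cat(sprintf("Training: batch %d, %d adversarial epochs, %d pre-training epochs, %d per class per epoch\n",
              x$config$batch_size, x$config$epochs, x$config$pretrain_epochs,
              x$config$n_per_class))
  if (!is.null(x$trace)) {
    cat("Final losses: ")
    cat(sprintf("discriminator %.4f, generator %.4f, classifier %.4f\n",
                utils::tail(x$trace$d_loss, 1),
                utils::tail(x$trace$g_loss, 1),
                utils::tail(x$trace$c_loss, 1)))
  }
  invisible(x)
}

#' @export
coef.bigan <- function(object, ...) {
  lapply(object$networks, mlp_get_params)
}

#' Plot Bi-GAN training losses
#'
#' @param x A trained `"bigan"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.bigan <- function(x, ...) {
  if (is.null(x$trace)) stop("model has no training trace to plot")
  tr <- x$trace
  graphics::matplot(tr$epoch, cbind(tr$d_loss, tr$g_loss, tr$c_loss),
                    type = "l", lty = 1, col = c(2, 4, 3),
                    xlab = "Epoch", ylab = "Loss (batch mean)", ...)
  graphics::legend("topright", c("discriminator", "generator", "classifier"),
                   col = c(2, 4, 3), lty = 1, bty = "n")
  invisible(x)
}

#' Simulate class-conditioned synthetic spectra
#'
#' Draws `nsim` synthetic spectra conditioned on a template spectrum: the
#' template is encoded, latent codes are sampled from the conditioned prior
#' around the encoding, and the generator maps them back to spectra.
#'
#' @param object A trained `"bigan"`.
#' @param nsim Number of spectra to draw.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param template Template spectrum (vector on the raw absorbance scale).
#' @param sigma Elementwise prior scale (default `config$predict_sigma`).
#' @param ... Unused.
#' @return Matrix of `nsim` synthetic spectra on the raw absorbance scale.
#' @export
simulate.bigan <- function(object, nsim = 1L, seed = NULL, template,
                           sigma = object$config$predict_sigma, ...) {
  if (!isTRUE(object$trained)) stop("model is not trained")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (identical(sigma, "auto"))
    sigma <- if (!is.null(object$inference_sigma)) object$inference_sigma
  else 1
  mu <- drop(encode(object, template))
  d <- object$config$latent_dim
  z <- matrix(stats::rnorm(nsim * d), nsim, d) *
    rep(rep(sigma, length.out = d), each = nsim) +
    rep(mu, each = nsim)
  generate_spectra(object, z)
}

#' Model checkpointing
#'
#' Saves a trained model as a single versioned archive holding the four
#' parameter sets, optimizer state, preprocessing record, catalog and
#' configuration; `load_bigan()` refuses files without the checkpoint
#' header.
#'
#' @param model A `"bigan"`.
#' @param path File path.
#' @return `load_bigan()` returns the `"bigan"`; `save_bigan()` its `path`,
#'   invisibly.
#' @export
save_bigan <- function(model, path) {
  stopifnot(inherits(model, "bigan"))
  saveRDS(list(format = "nirbigan-checkpoint", version = 1L,
               package_version = as.character(utils::packageVersion("nirbigan")),
               model = model), path)
  invisible(path)
}

#' @rdname save_bigan
#' @export
load_bigan <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "nirbigan-checkpoint"))
    stop("not a nirbigan checkpoint: ", path)
  obj$model
}
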