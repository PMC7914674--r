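#' Cross-entropy losses of the classification-augmented Bi-GAN
#'
#' Three summed (not averaged) cross-entropy losses drive the alternating
#' optimization:
#'
#' * `loss_classification(c, c_hat)`: multi-class cross-entropy
#'   `-sum(c * log(c_hat))` between one-hot labels and predicted class
#'   probabilities. Used to pre-train the classifier on real spectra and,
#'   during adversarial training, evaluated on generated spectra against
#'   their template's label.
#' * `loss_discriminator(y, y_hat, cls_loss)`: binary cross-entropy of the
#'   discriminator on (spectrum, latent) couples — real couples labeled
#'   `y = 1`, generated couples `y = 0` — plus the classification loss.
#' * `loss_generator(y_hat, cls_loss)`: `-sum(log(y_hat))` on generated
#'   couples (the non-saturating generator objective) plus the
#'   classification loss, so class supervision steers the generator and
#'   encoder as well.
#'
#' Probabilities are clipped to `[eps, 1]` (binary terms to
#' `[eps, 1 - eps]`) before taking logarithms.
#'
#' @param c One-hot label vector of length k, or an n x k matrix of one-hot
#'   rows.
#' @param c_hat Predicted class probabilities, same shape as `c`.
#' @param y Binary source labels (1 = real couple, 0 = generated couple).
#' @param y_hat Discriminator outputs in (0, 1).
#' @param cls_loss Classification loss to add (scalar, default 0).
#' @param eps Clipping constant for logarithms (default 1e-7).
#' @return A nonnegative scalar.
#' @name bigan_losses
NULL

#' @rdname bigan_losses
#' @export
loss_classification <- function(c, c_hat, eps = 1e-7) {
  if (length(c) != length(c_hat))
    stop("label and prediction lengths differ")
  if (any(c_hat < -eps) || any(c_hat > 1 + eps))
    stop("'c_hat' must contain probabilities in [0, 1]")
  -sum(c * log(pmin(pmax(c_hat, eps), 1)))
}

#' @rdname bigan_losses
#' @export
loss_discriminator <- function(y, y_hat, cls_loss = 0, eps = 1e-7) {
  if (length(y) == 0L) stop("empty batch")
  if (length(y) != length(y_hat)) stop("'y' and 'y_hat' lengths differ")
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  -sum(y * log(p) + (1 - y) * log(1 - p)) + cls_loss
}

#' @rdname bigan_losses
#' @export
loss_generator <- function(y_hat, cls_loss = 0, eps = 1e-7) {
  if (length(y_hat) == 0L) stop("empty batch")
  -sum(log(pmin(pmax(y_hat, eps), 1))) + cls_loss
}
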