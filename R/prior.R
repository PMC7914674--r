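#' Template-conditioned latent prior
#'
#' The latent code fed to the generator is drawn from a normal distribution
#' centered on the encoding of a real template spectrum. Its elementwise
#' scale starts at 1 and, once a FIFO history of `history_depth` previous
#' encodings has filled, adapts to the local spread of recent encodings:
#'
#'   `sigma_d = sqrt( sum_j (history_jd - mu_d)^2 / (history_depth - 1) )`
#'
#' floored at `sigma_floor` so the prior never degenerates to a point mass.
#'
#' @param dim Latent dimension (default 30).
#' @param sigma_init Initial elementwise scale before the history fills
#'   (default 1).
#' @param sigma_floor Lower bound on `sigma` (default 1e-6).
#' @param history_depth Number of previous encodings retained (default 5).
#' @return An object of class `"latent_prior"` with fields `mu`, `sigma`,
#'   `history` (list, newest last), `dim`, `sigma_floor`, `history_depth`.
#' @examples
#' p <- latent_prior(dim = 1)
#' for (h in c(0, 0, 0, 0, 0)) p <- update_prior(p, h)
#' p <- update_prior(p, 2)
#' p$sigma  # sqrt(5)
#' @export
latent_prior <- function(dim = 30L, sigma_init = 1, sigma_floor = 1e-6,
                         history_depth = 5L) {
  stopifnot(dim >= 1L, sigma_floor > 0, history_depth >= 2L)
  structure(list(mu = rep(0, dim), sigma = rep(sigma_init, dim),
                 history = list(), dim = as.integer(dim),
                 sigma_init = sigma_init, sigma_floor = sigma_floor,
                 history_depth = as.integer(history_depth)),
            class = "latent_prior")
}

#' @rdname latent_prior
#' @param prior A `"latent_prior"`.
#' @param encoding New encoding vector of length `dim`.
#' @export
update_prior <- function(prior, encoding) {
  stopifnot(inherits(prior, "latent_prior"))
  encoding <- as.numeric(encoding)
  if (length(encoding) != prior$dim)
    stop("encoding has length ", length(encoding), ", prior dimension is ",
         prior$dim)
  prior$mu <- encoding
  d <- prior$history_depth
  if (length(prior$history) >= d) {
    H <- do.call(rbind, prior$history)
    dev2 <- colSums((H - rep(encoding, each = d))^2)
    prior$sigma <- pmax(sqrt(dev2 / (d - 1L)), prior$sigma_floor)
  } else {
    prior$sigma <- rep(prior$sigma_init, prior$dim)
  }
  prior$history <- c(prior$history, list(encoding))
  if (length(prior$history) > d)
    prior$history <- prior$history[-1L]
  prior
}

#' @rdname latent_prior
#' @param n Number of latent vectors to draw.
#' @export
sample_latent <- function(prior, n = 1L) {
  stopifnot(inherits(prior, "latent_prior"), n >= 1L)
  eps <- matrix(stats::rnorm(n * prior$dim), nrow = n)
  sweep(eps, 2L, prior$sigma, `*`) + rep(prior$mu, each = n)
}
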