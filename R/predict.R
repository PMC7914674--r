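#' Majority-vote generative prediction
#'
#' Predicts the class of each spectrum by repeated conditioned generation:
#' the spectrum is encoded once (evaluation mode, deterministic), then
#' `repeats` latent codes are drawn from the conditioned prior around the
#' encoding, passed through the generator and classified; each repeat casts
#' one vote (the argmax class) and the winner is the modal class, ties
#' broken toward the lowest class id. Every row gets its own seed substream
#' derived from `seed` and its sample id (its position for plain
#' matrices), so permuting dataset rows permutes the predictions
#' identically and results are independent of batch composition.
#'
#' @param object A trained `"bigan"`.
#' @param newdata A [spectral_dataset()] or spectra matrix/vector on the raw
#'   absorbance scale.
#' @param repeats Votes per spectrum (default from the config; odd values
#'   reduce ties).
#' @param seed Integer master seed for the vote sampling (default 1).
#' @param sigma Elementwise prior scale at inference: `"auto"` (the
#'   default when the config says so) uses the scale the conditioned prior
#'   adapted during training, a numeric scalar or vector fixes it; in the
#'   limit `sigma -> 0` all repeats are identical and the vote is
#'   unanimous.
#' @param type `"class"` for an integer vector of predicted class ids,
#'   `"votes"` for the full vote records.
#' @param ... Unused.
#' @return For `type = "class"`, an integer vector. For `type = "votes"`,
#'   an object of class `"bigan_votes"`: a data.frame with columns
#'   `sample_id`, `class_id` (winner) and `win_fraction`, with the full
#'   vote-count matrix (rows = spectra, columns = classes) in
#'   `attr(, "votes")` and `repeats` in `attr(, "repeats")`.
#' @export
predict.bigan <- function(object, newdata, repeats = object$config$repeats,
                          seed = 1L, sigma = object$config$predict_sigma,
                          type = c("class", "votes"), ...) {
  type <- match.arg(type)
  if (!isTRUE(object$trained)) stop("model is not trained")
  stopifnot(repeats >= 1L)
  if (identical(sigma, "auto"))
    sigma <- if (!is.null(object$inference_sigma)) object$inference_sigma
  else 1
  if (inherits(newdata, "spectral_dataset")) {
    x <- newdata$x
    ids <- newdata$sample_id
  } else {
    x <- .as_row_matrix(newdata, object$config$grid$n_channels, "spectra")
    ids <- sprintf("s%05d", seq_len(nrow(x)))
  }
  n <- nrow(x)
  d <- object$config$latent_dim
  k <- object$k
  mu <- encode(object, x)
  votes <- matrix(0L, n, k, dimnames = list(NULL, object$catalog$class_id))
  for (i in seq_len(n)) {
    set.seed(substream_seed(seed, ids[i]))
    z <- matrix(stats::rnorm(repeats * d), repeats, d) *
      rep(rep(sigma, length.out = d), each = repeats) +
      rep(mu[i, ], each = repeats)
    p <- classify(object, generate_spectra(object, z))
    v <- max.col(p, ties.method = "first")  # per-repeat ties -> lowest id
    votes[i, ] <- tabulate(v, nbins = k)
  }
  winner <- max.col(votes, ties.method = "first")  # vote ties -> lowest id
  if (type == "class") return(object$catalog$class_id[winner])
  out <- data.frame(sample_id = ids,
                    class_id = object$catalog$class_id[winner],
                    win_fraction = votes[cbind(seq_len(n), winner)] / repeats)
  attr(out, "votes") <- votes
  attr(out, "repeats") <- as.integer(repeats)
  class(out) <- c("bigan_votes", "data.frame")
  out
}

#' @export
print.bigan_votes <- function(x, ...) {
  cat(sprintf("Majority-vote predictions (%d repeats):\n",
              attr(x, "repeats")))
  print.data.frame(utils::head(x, 20L), row.names = FALSE)
  if (nrow(x) > 20L) cat("  ...", nrow(x) - 20L, "more rows\n")
  invisible(x)
}
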