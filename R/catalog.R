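#' Class catalog
#'
#' A class catalog lists the manufacturer classes of a study: for each class
#' its 1-based `class_id`, the drug family it belongs to (`drug_id`) and the
#' number of samples available (`n_samples`). Class ids must be contiguous
#' from 1.
#'
#' @param class_id Integer vector, 1..k, unique and contiguous.
#' @param drug_id Integer vector of drug-family ids (positive).
#' @param n_samples Integer vector of per-class sample counts (positive).
#' @return A `data.frame` of class `"class_catalog"`.
#' @seealso [drug_catalog()] for the bundled 29-manufacturer catalog.
#' @export
class_catalog <- function(class_id, drug_id, n_samples) {
  class_id <- as.integer(class_id)
  drug_id <- as.integer(drug_id)
  n_samples <- as.integer(n_samples)
  k <- length(class_id)
  stopifnot(length(drug_id) == k, length(n_samples) == k, k >= 1L)
  if (!identical(sort(class_id), seq_len(k)))
    stop("class ids must be unique and contiguous from 1")
  if (anyNA(drug_id) || any(drug_id < 1L)) stop("drug ids must be positive integers")
  if (anyNA(n_samples) || any(n_samples < 1L)) stop("sample counts must be positive")
  out <- data.frame(class_id = class_id, drug_id = drug_id, n_samples = n_samples)
  out <- out[order(out$class_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("class_catalog", "data.frame")
  out
}

#' Bundled 29-manufacturer drug catalog
#'
#' The reference catalog used throughout the package: 1721 NIR spectra of
#' four drug families (metformin hydrochloride, chlorpromazine hydrochloride,
#' chlorphenamine maleate and cefuroxime axetil tablets) produced by 29
#' manufacturers. Classes 1-14 belong to drug family 1, 15-19 to family 2,
#' 20-24 to family 3 and 25-29 to family 4. Per-class counts range from 21
#' to 135 and are strongly imbalanced.
#'
#' @return A `"class_catalog"` with 29 rows and 1721 total samples.
#' @examples
#' cat29 <- drug_catalog()
#' sum(cat29$n_samples)
#' @export
drug_catalog <- function() {
  counts <- c(94L, 48L, 67L, 21L, 48L, 64L, 27L, 35L, 48L, 24L, 68L, 97L,
              97L, 97L, 59L, 94L, 58L, 135L, 49L, 39L, 45L, 36L, 39L, 94L,
              56L, 29L, 27L, 89L, 37L)
  drugs <- rep(1:4, times = c(14L, 5L, 5L, 5L))
  class_catalog(seq_along(counts), drugs, counts)
}

#' Catalog summary statistics
#'
#' Descriptive statistics of the class-size distribution of a catalog:
#' total sample count, floored mean class size, extremes, and the mass
#' fraction held by the `top_k` largest classes. When `train_fraction` is
#' given, also the number of classes whose training count (see
#' [train_count()]) is at or below `train_threshold`.
#'
#' @param catalog A `"class_catalog"`.
#' @param top_k How many of the largest classes form the "head" of the
#'   distribution (default 8).
#' @param train_fraction Optional train fraction in (0,1).
#' @param train_threshold Threshold on the per-class training count
#'   (default 10); only used when `train_fraction` is given.
#' @return A list with elements `total`, `k`, `mean_floor`, `max`, `min`,
#'   `top_k`, `top_k_mass_pct`, `rest_mass_pct` and, when `train_fraction`
#'   is given, `n_classes_at_or_below`.
#' @examples
#' s <- catalog_stats(drug_catalog(), top_k = 8)
#' s$top_k_mass_pct  # 46.31
#' @export
catalog_stats <- function(catalog, top_k = 8L, train_fraction = NULL,
                          train_threshold = 10L) {
  stopifnot(inherits(catalog, "class_catalog"))
  n <- catalog$n_samples
  k <- nrow(catalog)
  top_k <- as.integer(top_k)
  if (top_k < 1L || top_k > k) stop("'top_k' must be in 1..k")
  srt <- sort(n, decreasing = TRUE)
  top_mass <- sum(srt[seq_len(top_k)]) / sum(n)
  out <- list(total = sum(n), k = k, mean_floor = floor(sum(n) / k),
              max = max(n), min = min(n), top_k = top_k,
              top_k_mass_pct = round(100 * top_mass, 2),
              rest_mass_pct = round(100 * (1 - top_mass), 2))
  if (!is.null(train_fraction)) {
    tc <- vapply(n, train_count, integer(1), train_fraction = train_fraction)
    out$train_fraction <- train_fraction
    out$train_threshold <- as.integer(train_threshold)
    out$n_classes_at_or_below <- sum(tc <= train_threshold)
  }
  out
}
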