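#' Per-class training count
#'
#' The number of training spectra a class of size `n` contributes at a given
#' train fraction: `round(train_fraction * n)` (half rounded up), clamped to
#' `[1, n - 1]` so every class keeps at least one training and one test
#' spectrum. With this convention a class of 94 at fraction 0.9 contributes
#' 85 training spectra and leaves 9 for testing, and the smallest bundled
#' class (21) contributes 6 at fraction 0.3 and 4 at fraction 0.2.
#'
#' @param n Class size (>= 2).
#' @param train_fraction Fraction in (0, 1).
#' @return Integer training count.
#' @export
train_count <- function(n, train_fraction) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("class size must be at least 2 to split")
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("'train_fraction' must be in (0, 1)")
  tc <- floor(train_fraction * n + 0.5)  # round half up, platform-stable
  as.integer(min(max(tc, 1L), n - 1L))
}

#' Stratified train/test split
#'
#' Splits every class of a dataset into disjoint train and test index sets.
#' Per class of size n, `train_count(n, train_fraction)` indices are drawn
#' uniformly without replacement for training; the remainder form the test
#' set and are never seen by training. The same seed reproduces the same
#' split exactly.
#'
#' @param dataset A [spectral_dataset()].
#' @param train_fraction Fraction in (0, 1).
#' @param seed Integer seed.
#' @return An object of class `"split_plan"`: list with `train` and `test`
#'   (named lists of integer row indices per class id), `train_fraction`,
#'   `seed`.
#' @export
stratified_split <- function(dataset, train_fraction, seed = 1L) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  cls <- sort(unique(dataset$class_id))
  sizes <- table(dataset$class_id)
  if (any(sizes < 2L))
    stop("every class needs at least 2 samples to split; class(es) ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), " too small")
  set.seed(as.integer(seed))
  train <- list(); test <- list()
  for (c_id in cls) {
    idx <- which(dataset$class_id == c_id)
    tc <- train_count(length(idx), train_fraction)
    tr <- sort(sample(idx, tc, replace = FALSE))
    train[[as.character(c_id)]] <- tr
    test[[as.character(c_id)]] <- setdiff(idx, tr)
  }
  structure(list(train = train, test = test,
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("Split plan: fraction %.2f, seed %d, %d classes, %d train / %d test\n",
              x$train_fraction, x$seed, length(x$train),
              length(unlist(x$train)), length(unlist(x$test))))
  invisible(x)
}

#' All training (or test) row indices of a split
#' @param split A `"split_plan"`.
#' @param which `"train"` or `"test"`.
#' @return Sorted integer vector of row indices.
#' @export
split_indices <- function(split, which = c("train", "test")) {
  which <- match.arg(which)
  sort(unlist(split[[which]], use.names = FALSE))
}

#' Balanced resampling with replacement
#'
#' Draws exactly `n_per_class` training row indices for every class,
#' uniformly with replacement from that class's training pool only. Every
#' class thus contributes an equal number of spectra to training, so
#' minority manufacturers are not drowned out by the majority classes.
#'
#' @param split A `"split_plan"`.
#' @param n_per_class Draws per class (>= 1).
#' @param seed Integer seed.
#' @return Integer vector of row indices of length
#'   `n_per_class * n_classes`, grouped by class in class-id order.
#' @export
balanced_resample <- function(split, n_per_class, seed = 1L) {
  stopifnot(inherits(split, "split_plan"), n_per_class >= 1L)
  if (any(lengths(split$train) == 0L))
    stop("every class needs a non-empty training pool")
  set.seed(as.integer(seed))
  cls <- names(split$train)[order(as.integer(names(split$train)))]
  unlist(lapply(cls, function(c_id) {
    pool <- split$train[[c_id]]
    pool[sample.int(length(pool), n_per_class, replace = TRUE)]
  }), use.names = FALSE)
}

#' Serialize / read a split plan as plain text
#'
#' The format is line-oriented: a header with the train fraction and seed,
#' then one line per class and partition listing row indices.
#'
#' @param split A `"split_plan"`.
#' @param path File path.
#' @return `read_split()` returns a `"split_plan"`; `write_split()` its
#'   `path`, invisibly.
#' @export
write_split <- function(split, path) {
  stopifnot(inherits(split, "split_plan"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# split_plan fraction=%.17g seed=%d",
                     split$train_fraction, split$seed), con)
  for (part in c("train", "test"))
    for (c_id in names(split[[part]]))
      writeLines(paste(part, c_id,
                       paste(split[[part]][[c_id]], collapse = " ")), con)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  lines <- readLines(path)
  hd <- regmatches(lines[1],
                   regexec("fraction=([0-9.eE+-]+) seed=([0-9]+)", lines[1]))[[1]]
  if (length(hd) != 3L) stop("not a split plan file: ", path)
  out <- list(train = list(), test = list(),
              train_fraction = as.numeric(hd[2]), seed = as.integer(hd[3]))
  for (ln in lines[-1]) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    out[[f[1]]][[f[2]]] <- as.integer(f[-(1:2)])
  }
  structure(out, class = "split_plan")
}
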