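#' Split-sweep benchmark of classifiers
#'
#' For every train fraction in `ratios` and every repetition, draws a fresh
#' stratified split, trains each registered method on the training
#' partition and evaluates it on the untouched test partition. Following
#' the reference protocol, the headline per method and ratio is the best
#' accuracy across repetitions; the mean and standard deviation across
#' repetitions are reported alongside, since a best-of-N headline is
#' optimistically biased. All repetitions are retained. A failing method is
#' recorded as `NA` with a warning rather than aborting the sweep.
#'
#' Methods are given as a named list. Each element is either a
#' [baseline_model()] or the string `"bigan"` (optionally an entire
#' [bigan_config()]), in which case the Bi-GAN is fitted with
#' majority-vote prediction.
#'
#' @param dataset A [spectral_dataset()].
#' @param methods Named list of methods (see Details).
#' @param ratios Train fractions (default 0.9 down to 0.2).
#' @param repetitions Repetitions per ratio (default 10).
#' @param seed Master seed; each (ratio, repetition) gets its own
#'   substream.
#' @param bigan_config Configuration used for `"bigan"` entries (default
#'   [bigan_config()] on the dataset grid).
#' @return An object of class `"benchmark_result"`: list with `results`
#'   (one row per ratio x method x repetition) and `best` (best accuracy
#'   per ratio x method, with mean and sd).
#' @export
run_benchmark <- function(dataset, methods,
                          ratios = seq(0.9, 0.2, by = -0.1),
                          repetitions = 10L, seed = 1L,
                          bigan_config = NULL) {
  stopifnot(inherits(dataset, "spectral_dataset"), length(methods) >= 1L,
            !is.null(names(methods)), repetitions >= 1L)
  k <- if (!is.null(dataset$catalog)) nrow(dataset$catalog)
  else max(dataset$class_id)
  if (is.null(bigan_config))
    bigan_config <- bigan_config(grid = dataset$grid)
  res <- list()
  for (r in ratios) {
    for (rep_i in seq_len(repetitions)) {
      sseed <- substream_seed(seed, sprintf("split_%.3f_%d", r, rep_i))
      split <- stratified_split(dataset, r, seed = sseed)
      tr_idx <- split_indices(split, "train")
      te_idx <- split_indices(split, "test")
      for (m in names(methods)) {
        mseed <- substream_seed(seed, sprintf("fit_%s_%.3f_%d", m, r, rep_i))
        pred <- tryCatch(
          .run_method(methods[[m]], dataset, split, tr_idx, te_idx,
                      mseed, bigan_config),
          error = function(e) {
            warning(sprintf("method '%s' failed at ratio %.2f rep %d: %s",
                            m, r, rep_i, conditionMessage(e)), call. = FALSE)
            NULL
          })
        met <- if (is.null(pred)) {
          list(accuracy = NA_real_, precision = NA_real_,
               recall = NA_real_, f1 = NA_real_)
        } else {
          classification_metrics(
            confusion_matrix(dataset$class_id[te_idx], pred, k))
        }
        res[[length(res) + 1L]] <- data.frame(
          method = m, ratio = r, repetition = rep_i,
          accuracy = met$accuracy, precision = met$precision,
          recall = met$recall, f1 = met$f1)
      }
    }
  }
  results <- do.call(rbind, res)
  best <- do.call(rbind, lapply(split(results,
                                      list(results$method, results$ratio),
                                      drop = TRUE), function(g) {
    data.frame(method = g$method[1], ratio = g$ratio[1],
               best_accuracy = suppressWarnings(max(g$accuracy, na.rm = TRUE)),
               mean_accuracy = mean(g$accuracy, na.rm = TRUE),
               sd_accuracy = stats::sd(g$accuracy))
  }))
  rownames(best) <- NULL
  structure(list(results = results, best = best, seed = as.integer(seed),
                 repetitions = as.integer(repetitions)),
            class = "benchmark_result")
}

.run_method <- function(method, dataset, split, tr_idx, te_idx, seed, cfg) {
  if (inherits(method, "nir_baseline")) {
    set.seed(seed)
    fit <- fit_baseline(method, dataset$x[tr_idx, , drop = FALSE],
                        dataset$class_id[tr_idx],
                        k = if (!is.null(dataset$catalog))
                          nrow(dataset$catalog) else max(dataset$class_id))
    return(predict(fit, dataset$x[te_idx, , drop = FALSE]))
  }
  if (inherits(method, "bigan_config")) cfg <- method
  else if (!identical(method, "bigan"))
    stop("unknown method specification")
  fit <- bigan(dataset, split = split, config = cfg, seed = seed)
  predict(fit, dataset[te_idx], seed = substream_seed(seed, "predict"))
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("Benchmark: %d repetitions per ratio (best-of-%d headline)\n",
              x$repetitions, x$repetitions))
  print(x$best, row.names = FALSE, digits = 4)
  invisible(x)
}
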