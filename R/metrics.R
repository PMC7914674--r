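#' Confusion matrix
#'
#' @param true,pred Integer label vectors in 1..k, equal length.
#' @param k Number of classes.
#' @return A k x k integer matrix; entry (i, j) counts samples of true
#'   class i predicted as class j.
#' @export
confusion_matrix <- function(true, pred, k) {
  true <- as.integer(true); pred <- as.integer(pred); k <- as.integer(k)
  if (length(true) != length(pred)) stop("label vectors differ in length")
  if (anyNA(true) || anyNA(pred)) stop("labels must not be missing")
  if (any(true < 1L | true > k) || any(pred < 1L | pred > k))
    stop("labels must lie in 1..", k)
  cm <- matrix(0L, k, k, dimnames = list(true = 1:k, pred = 1:k))
  for (i in seq_along(true))
    cm[true[i], pred[i]] <- cm[true[i], pred[i]] + 1L
  cm
}

#' Macro-averaged classification metrics
#'
#' Per-class precision (column-wise) and recall (row-wise) with the 0/0
#' convention mapped to 0, macro-averaged over classes; F1 is the harmonic
#' mean of macro precision and macro recall; accuracy is trace over total.
#' Macro averaging weights every class equally regardless of its test-set
#' size, matching the fairness emphasis of balanced training.
#'
#' @param cm A confusion matrix as returned by [confusion_matrix()].
#' @return A list with `precision`, `recall`, `f1`, `accuracy` (macro
#'   scalars) and `per_class` (data.frame of per-class precision/recall).
#' @export
classification_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (sum(cm) == 0) stop("confusion matrix is empty")
  if (any(cm < 0)) stop("confusion matrix entries must be nonnegative")
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  mp <- mean(prec); mr <- mean(rec)
  f1 <- if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0
  list(precision = mp, recall = mr, f1 = f1,
       accuracy = sum(tp) / sum(cm),
       per_class = data.frame(class_id = seq_len(nrow(cm)),
                              precision = unname(prec),
                              recall = unname(rec)))
}

#' Evaluation report
#'
#' Bundles a confusion matrix and its macro metrics with split metadata.
#'
#' @param true,pred Integer labels in 1..k.
#' @param k Number of classes.
#' @param split_fraction,seed,repetition Optional metadata recorded in the
#'   report.
#' @return An object of class `"eval_report"`.
#' @export
eval_report <- function(true, pred, k, split_fraction = NA_real_,
                        seed = NA_integer_, repetition = NA_integer_) {
  cm <- confusion_matrix(true, pred, k)
  m <- classification_metrics(cm)
  structure(c(list(confusion = cm), m,
              list(split_fraction = split_fraction, seed = seed,
                   repetition = repetition, n = length(true))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation report (n = %d%s):\n", x$n,
              if (!is.na(x$split_fraction))
                sprintf(", train fraction %.2f", x$split_fraction) else ""))
  cat(sprintf("  accuracy %.4f | macro precision %.4f | macro recall %.4f | F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Render a confusion matrix as a plain-text table
#'
#' @param cm A confusion matrix.
#' @return Character vector of lines, invisibly printed with `cat()` when
#'   used interactively.
#' @export
format_confusion <- function(cm) {
  k <- nrow(cm)
  w <- max(nchar(as.character(max(cm))), nchar(as.character(k))) + 1L
  hdr <- paste0(formatC("t\\p", width = 4),
                paste(formatC(seq_len(k), width = w), collapse = ""))
  rows <- vapply(seq_len(k), function(i)
    paste0(formatC(i, width = 4),
           paste(formatC(cm[i, ], width = w), collapse = "")),
    character(1))
  c(hdr, rows)
}
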