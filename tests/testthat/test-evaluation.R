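test_that("confusion matrices count pairs exactly", {
  cm <- confusion_matrix(c(1, 1, 2), c(1, 2, 2), 2)
  expect_equal(unname(cm), rbind(c(1L, 1L), c(0L, 1L)))
  expect_equal(sum(cm), 3L)
  # perfect predictions give a diagonal matrix
  p <- sample(1:4, 50, replace = TRUE)
  cmp <- confusion_matrix(p, p, 4)
  expect_true(all(cmp[upper.tri(cmp)] == 0) && all(cmp[lower.tri(cmp)] == 0))
  expect_equal(sum(diag(cmp)), 50L)
  expect_error(confusion_matrix(c(1, 5), c(1, 1), 4), "1..4")
  expect_error(confusion_matrix(1:3, 1:2, 3), "length")
})

test_that("classification metrics reproduce hand computations", {
  m <- classification_metrics(rbind(c(8, 2), c(2, 8)))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$f1, 0.8)
  # diagonal -> all ones
  md <- classification_metrics(diag(c(5, 3, 7)))
  expect_equal(unlist(md[c("precision", "recall", "f1", "accuracy")]),
               c(precision = 1, recall = 1, f1 = 1, accuracy = 1))
  # single-class collapse: recall of the missed class is zero
  mc <- classification_metrics(rbind(c(10, 0), c(10, 0)))
  expect_equal(mc$per_class$recall[2], 0)
  expect_equal(mc$per_class$precision[2], 0)  # 0/0 convention
  expect_error(classification_metrics(matrix(0, 2, 2)), "empty")
})

test_that("macro metrics are invariant under class relabeling", {
  set.seed(8)
  cm <- matrix(rpois(25, 4), 5, 5)
  perm <- sample(5)
  m1 <- classification_metrics(cm)
  m2 <- classification_metrics(cm[perm, perm])
  expect_equal(m2$precision, m1$precision)
  expect_equal(m2$recall, m1$recall)
  expect_equal(m2$accuracy, m1$accuracy)
})

test_that("eval reports carry consistent confusion row sums", {
  set.seed(4)
  truth <- sample(1:3, 60, replace = TRUE)
  pred <- ifelse(runif(60) < 0.8, truth, sample(1:3, 60, replace = TRUE))
  rep_ <- eval_report(truth, pred, 3, split_fraction = 0.9)
  expect_equal(unname(rowSums(rep_$confusion)),
               as.vector(table(factor(truth, 1:3))))
  expect_equal(rep_$accuracy, mean(truth == pred))
  lines <- format_confusion(rep_$confusion)
  expect_length(lines, 4L)  # header + 3 rows
})

test_that("baseline harness honors stated hyperparameters and sanity checks", {
  ds <- tiny_dataset()
  sp <- stratified_split(ds, 0.8, seed = 3)
  tr <- split_indices(sp, "train"); te <- split_indices(sp, "test")
  x <- ds$x[tr, ]; y <- ds$class_id[tr]
  expect_error(baseline_model("nope"))
  expect_equal(baseline_model("plsda")$hyper$ncomp, 30L)
  expect_equal(baseline_model("knn")$hyper$k, 1L)
  expect_equal(baseline_model("svm_rbf")$hyper$gamma, 1e-4)
  # 1-NN memorizes its training set
  knn_fit <- fit_baseline(baseline_model("knn"), x, y, k = 4)
  expect_equal(mean(predict(knn_fit, x) == y), 1)
  # every baseline clears chance on easy data
  for (nm in c("plsda", "svm_linear", "svm_rbf", "knn", "bp_ann")) {
    b <- if (nm == "plsda") baseline_model(nm, ncomp = 10L)
        else baseline_model(nm)
    set.seed(1)
    f <- fit_baseline(b, x, y, k = 4)
    acc <- mean(predict(f, ds$x[te, ]) == ds$class_id[te])
    expect_gt(acc, 1 / 4)
  }
})

test_that("benchmarks sweep, record and summarize reproducibly", {
  ds <- tiny_dataset()
  methods <- list(knn = baseline_model("knn"),
                  svm = baseline_model("svm_linear"))
  bm <- run_benchmark(ds, methods, ratios = c(0.8, 0.5), repetitions = 3,
                      seed = 5)
  expect_equal(nrow(bm$results), 2 * 3 * 2)
  expect_equal(nrow(bm$best), 4)
  # best-of-N dominates every repetition
  for (i in seq_len(nrow(bm$best))) {
    g <- bm$results[bm$results$method == bm$best$method[i] &
                      bm$results$ratio == bm$best$ratio[i], ]
    expect_true(all(bm$best$best_accuracy[i] >= g$accuracy))
  }
  bm2 <- run_benchmark(ds, methods, ratios = c(0.8, 0.5), repetitions = 3,
                       seed = 5)
  expect_identical(bm$results, bm2$results)
  # single ratio, repetition and method -> a single report row
  bm1 <- run_benchmark(ds, list(knn = baseline_model("knn")),
                       ratios = 0.8, repetitions = 1, seed = 2)
  expect_equal(nrow(bm1$results), 1L)
})
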