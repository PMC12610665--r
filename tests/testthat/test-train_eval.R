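fold1_matrix <- function() {
  m <- diag(20L, 5)
  m[2, ] <- c(0L, 19L, 1L, 0L, 0L)
  m[4, ] <- c(1L, 0L, 0L, 19L, 0L)
  dimnames(m) <- list(actual = five_classes, predicted = five_classes)
  structure(m, class = c("confusion_matrix", "matrix", "array"))
}

test_that("confusion_matrix counts actual-by-predicted pairs", {
  actual <- c("N", "N", "AS", "MR")
  predicted <- c("N", "AS", "AS", "MR")
  cm <- confusion_matrix(actual, predicted, c("AS", "MR", "N"))
  expect_equal(sum(cm), 4L)
  expect_equal(cm["N", "AS"], 1L)
  expect_equal(cm["AS", "AS"], 1L)
  # order invariance
  perm <- sample(seq_along(actual))
  expect_identical(unclass(confusion_matrix(actual[perm], predicted[perm],
                                            c("AS", "MR", "N"))), unclass(cm))
  # all-correct gives a diagonal matrix
  cm2 <- confusion_matrix(actual, actual, c("AS", "MR", "N"))
  expect_true(all(cm2[upper.tri(cm2) | lower.tri(cm2)] == 0L))
  expect_error(confusion_matrix("X", "N", c("N")), "outside")
})

test_that("metrics on the reference fold-1 matrix match the published row", {
  rep <- classification_metrics(fold1_matrix())
  expect_equal(rep$accuracy, 0.98)
  expect_equal(rep$kappa, 0.975)
  expect_equal(rep$recall, 0.98)                       # macro recall
  # published value 97.99 truncates the exact macro f1 of 97.9987
  expect_equal(rep$f1 * 100, 97.99, tolerance = 1e-4)
})

test_that("a perfect confusion matrix scores 1 on every metric", {
  cm <- confusion_matrix(rep(five_classes, 4), rep(five_classes, 4), five_classes)
  rep <- classification_metrics(cm)
  expect_equal(unlist(rep[c("accuracy", "precision", "recall", "f1", "kappa")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1, kappa = 1))
})

test_that("kappa is 0 for constant predictions on balanced binary data, 1 iff diagonal", {
  actual <- rep(c("neg", "pos"), each = 10)
  rep <- suppressWarnings(classification_metrics(
    confusion_matrix(actual, rep("neg", 20), c("neg", "pos"))))
  expect_equal(rep$kappa, 0)
  diagm <- classification_metrics(confusion_matrix(actual, actual, c("neg", "pos")))
  expect_equal(diagm$kappa, 1)
})

test_that("zero-denominator per-class ratios report 0 with a warning", {
  cm <- confusion_matrix(c("a", "a", "b"), c("a", "a", "a"), c("a", "b", "c"))
  warns <- testthat::capture_warnings(rep <- classification_metrics(cm))
  expect_true(all(grepl("zero denominator", warns)))
  expect_gte(length(warns), 1L)    # both precision and recall are degenerate
  expect_equal(unname(rep$per_class_recall["c"]), 0)
})

test_that("trapezoidal AUC equals the concordant-pair fraction", {
  # 4-sample toy set with one inversion: pairs = 2x2, one discordant
  scores <- c(0.9, 0.4, 0.6, 0.1)
  actual <- c("pos", "pos", "neg", "neg")
  expect_equal(roc_auc(scores, actual, "pos"), 3 / 4)

  set.seed(17)
  for (i in 1:6) {
    n <- 30L
    sc <- stats::runif(n)
    lab <- sample(c("neg", "pos"), n, TRUE)
    if (length(unique(lab)) < 2L) next
    pos <- sc[lab == "pos"]; neg <- sc[lab == "neg"]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(roc_auc(sc, lab, "pos"), mean(pairs), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(18)
  sc <- stats::runif(60)
  lab <- sample(c("neg", "pos"), 60, TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, levels = c("neg", "pos"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(sc, lab, "pos"), ref, tolerance = 1e-12)
})

test_that("AUC edge behavior: perfect separation, chance, degenerate input", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c("p", "p", "n", "n"), "p"), 1)
  set.seed(19)
  sc <- stats::runif(4000)
  lab <- sample(c("n", "p"), 4000, TRUE)
  expect_equal(roc_auc(sc, lab, "p"), 0.5, tolerance = 0.05)
  expect_error(roc_auc(c(0.1, 0.9), c("p", "p"), "p"), "positive and negative")
})

test_that("average precision matches hand-summed precision-recall steps", {
  expect_equal(average_precision(c(0.9, 0.8, 0.3, 0.2), c("p", "p", "n", "n"), "p"), 1)
  # ranking p n p n n: precisions at the positives are 1/1 and 2/3
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  actual <- c("p", "n", "p", "n", "n")
  expect_equal(average_precision(scores, actual, "p"), (1 + 2 / 3) / 2)
  expect_error(average_precision(c(0.5), c("n"), "p"), "no positive")
})

test_that("mAP is 1 for perfect per-class separation and averages APs", {
  probs <- diag(5)[rep(1:5, each = 3), ] * 0.8 + 0.04
  colnames(probs) <- five_classes
  actual <- rep(five_classes, each = 3)
  expect_equal(map_multiclass(probs, actual), 1)
  expect_equal(auc_multiclass(probs, actual), 1)
})

test_that("learning rate decays by 0.95 per 10,000 iterations (staircase)", {
  cfg <- train_config()
  expect_equal(decayed_learning_rate(cfg, 0L), 0.001)
  expect_equal(decayed_learning_rate(cfg, 9999L), 0.001)
  expect_equal(decayed_learning_rate(cfg, 10000L), 0.001 * 0.95)
  expect_equal(decayed_learning_rate(cfg, 25000L), 0.001 * 0.95^2)
})

test_that("training is deterministic under a fixed seed and learns a separable task", {
  feats <- toy_feature_set(120, dims = 9L, frames = 7L, seed = 41L)
  labels <- attr(feats, "labels")
  arch <- wcnn_architecture(9L, 7L, 3L)
  cfg <- train_config(epochs = 4L, batch_size = 16L, seed = 6L)
  run <- function() {
    m <- build_model(arch, seed = 6L)
    train_wcnn(m, feats, labels, cfg, label_set = c("a", "b", "c"))
  }
  m1 <- run(); m2 <- run()
  expect_identical(m1$history$train_loss, m2$history$train_loss)
  expect_identical(m1$params[[6]]$w, m2$params[[6]]$w)
  expect_gt(tail(m1$history$train_accuracy, 1), 0.9)
  expect_s3_class(glance(evaluate_scores(predict_wcnn(m1, feats), labels)),
                  "tbl_df")
})

test_that("cross_validate produces one report per fold with disjoint test sets", {
  feats <- toy_feature_set(60, classes = c("a", "b"), dims = 9L, frames = 7L,
                           seed = 42L)
  labels <- attr(feats, "labels")
  man <- as_manifest(tibble::tibble(record_id = names(feats), path = "",
                                    label = unname(labels)))
  splits <- split_dataset(man, "kfold", k = 3L, sampling = "random", seed = 2L)
  cv <- cross_validate(feats, splits, arch = wcnn_architecture(9L, 7L, 2L),
                       cfg = train_config(epochs = 2L, batch_size = 16L, seed = 3L))
  expect_length(cv$folds, 3L)
  expect_equal(nrow(cv$summary), 3L)
  expect_true(all(cv$summary$accuracy >= 0, cv$summary$accuracy <= 1))
  expect_named(per_class_summary(cv), c("class", "recall"))
})

test_that("tidiers expose per-class and long-format views", {
  rep <- classification_metrics(fold1_matrix())
  td <- tidy(rep)
  expect_equal(nrow(td), 5L)
  expect_equal(td$recall[td$class == "MR"], 0.95)
  long <- tidy(fold1_matrix())
  expect_equal(nrow(long), 25L)
  expect_equal(sum(long$n), 100L)
})
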