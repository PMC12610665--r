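#' Run the full pipeline under a validation plan
#'
#' Trains and evaluates the weighted CNN over holdout or k-fold splits of a
#' feature set: one model per fold, file-level splits, per-fold evaluation
#' reports with the complete metric family.
#'
#' @param features Named list of feature maps (names = record ids), e.g.
#'   from [extract_features]; labels taken from its `labels` attribute
#'   unless given.
#' @param labels Optional named label vector.
#' @param splits Split list from [split_dataset].
#' @param arch An [architecture_spec] (default matches the feature
#'   geometry).
#' @param cfg A [train_config].
#' @param label_set Ordered class names.
#' @param positive_class Binary positive class for the metrics.
#' @param verbose Print per-fold progress.
#' @return A `wcnn_cv` list: `folds` (list of `eval_report`s), `models`,
#'   `summary` tibble (one row per fold via [glance.eval_report]).
#' @export
cross_validate <- function(features, splits, labels = NULL, arch = NULL,
                           cfg = train_config(), label_set = NULL,
                           positive_class = NULL, verbose = FALSE) {
  if (is.null(labels)) labels <- attr(features, "labels")
  stopifnot(!is.null(names(features)), !is.null(labels),
            all(names(features) %in% names(labels)))
  if (is.null(label_set)) label_set <- sort(unique(labels))
  if (is.null(arch)) {
    d <- dim(features[[1L]])
    arch <- wcnn_architecture(d[1L], d[2L], length(label_set))
  }
  folds <- vector("list", length(splits))
  models <- vector("list", length(splits))
  for (f in seq_along(splits)) {
    sp <- splits[[f]]
    model <- build_model(arch, seed = cfg$seed + f - 1L)
    model <- train_wcnn(model, features[sp$train], labels[sp$train],
                        cfg = within_seed(cfg, cfg$seed + f - 1L),
                        label_set = label_set)
    probs <- predict_wcnn(model, features[sp$test])
    rep <- evaluate_scores(probs, labels[sp$test], positive_class = positive_class)
    rep$fold <- f
    folds[[f]] <- rep
    models[[f]] <- model
    if (verbose)
      message(sprintf("fold %d/%d: accuracy %.3f", f, length(splits), rep$accuracy))
  }
  summary <- do.call(rbind, lapply(folds, glance.eval_report))
  structure(list(folds = folds, models = models, summary = summary),
            class = "wcnn_cv")
}

within_seed <- function(cfg, seed) {
  cfg$seed <- as.integer(seed %% 2147483629)
  cfg
}

#' @export
print.wcnn_cv <- function(x, ...) {
  cat(sprintf("<wcnn_cv> %d folds\n", length(x$folds)))
  print(x$summary)
  cat(sprintf("mean accuracy: %.4f\n", mean(x$summary$accuracy)))
  invisible(x)
}

#' Per-class recall averaged over folds
#'
#' The per-category accuracy summary conventionally reported for k-fold
#' cross-validation: mean of each class's recall (diagonal over row sum)
#' across fold confusion matrices.
#'
#' @param reports List of `eval_report`s (or a `wcnn_cv`).
#' @return Tibble with columns `class` and `recall`.
#' @export
per_class_summary <- function(reports) {
  if (inherits(reports, "wcnn_cv")) reports <- reports$folds
  rec <- do.call(rbind, lapply(reports, `[[`, "per_class_recall"))
  tibble::tibble(class = colnames(rec), recall = colMeans(rec))
}

#' Reference 10-fold confusion matrices
#'
#' Bundled per-fold confusion matrices of a five-class heart-valve PCG
#' classifier evaluated under 10-fold cross-validation with balanced
#' (20 test files per class per fold) and random (100 test files per fold)
#' sampling. They serve as fixed inputs for validating the metric
#' implementations against published summary figures.
#'
#' @param sampling `"balanced"` or `"random"`.
#' @return Named list of [confusion_matrix] objects, one per fold.
#' @export
reference_fold_matrices <- function(sampling = c("balanced", "random")) {
  sampling <- match.arg(sampling)
  path <- system.file("extdata", paste0("cv_folds_", sampling, ".csv"),
                      package = "pcgwcnn")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  labels <- names(df)[-(1:2)]
  lapply(split(df, df$fold), function(d) {
    m <- as.matrix(d[labels])
    storage.mode(m) <- "integer"
    dimnames(m) <- list(actual = d$actual, predicted = labels)
    structure(m[labels, , drop = FALSE],
              class = c("confusion_matrix", "matrix", "array"))
  })
}
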