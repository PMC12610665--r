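#' Grad-CAM heatmap over the MFCC input plane
#'
#' Gradient-weighted class activation mapping: the gradient of the target
#' class's logit with respect to a convolutional layer's activations is
#' globally averaged per channel to give channel weights; the weighted
#' channel sum is rectified, bilinearly upsampled to the input geometry,
#' and min–max normalized to `[0, 1]`. The result shows which MFCC
#' dimensions and frames drive the prediction.
#'
#' @param model A trained `wcnn_model`.
#' @param feature_map A single feature-map matrix (dims x frames).
#' @param target_class Class to explain (default: the predicted class).
#' @param source_layer Index of the conv layer to read activations from
#'   (default: the last conv layer).
#' @return A `gradcam_heatmap`: matrix in `[0, 1]` with the input's
#'   geometry, attributes `target_class`, `source_layer`, and
#'   `degenerate` (TRUE when the raw map was identically zero).
#' @export
gradcam <- function(model, feature_map, target_class = NULL, source_layer = NULL) {
  arch <- model$arch
  conv_idx <- which(vapply(arch$layers, `[[`, "", "kind") == "conv")
  if (is.null(source_layer)) source_layer <- conv_idx[length(conv_idx)]
  if (!source_layer %in% conv_idx) stop("source_layer must be a conv layer index")

  x <- stack_features(list(feature_map))
  fwd <- forward_pass(model, x, train = FALSE, keep_cache = TRUE)
  probs <- fwd$out
  label_set <- model$label_set %||% as.character(seq_len(arch$n_classes))
  if (is.null(target_class)) target_class <- label_set[which.max(probs[, 1L])]
  ci <- match(target_class, label_set)
  if (is.na(ci)) stop("unknown target class: ", target_class)

  # backprop the logit (pre-softmax score) of the target class
  d_logits <- matrix(0, arch$n_classes, 1L)
  d_logits[ci, 1L] <- 1
  bwd <- backward_pass(model, fwd, d_logits, stop_at_conv = source_layer)
  grad <- bwd$d_activation                        # (Ho, Wo, C, 1)
  act <- fwd$caches[[source_layer]]$conv_out
  d <- dim(grad)
  alpha <- colMeans(matrix(grad[, , , 1L], d[1L] * d[2L], d[3L]))
  cam <- matrix(matrix(act[, , , 1L], d[1L] * d[2L], d[3L]) %*% alpha, d[1L], d[2L])
  cam <- pmax(cam, 0)
  up <- bilinear_upsample(cam, nrow(feature_map), ncol(feature_map))
  rng <- range(up)
  degenerate <- rng[2L] <= 0
  hm <- if (degenerate) up * 0 else (up - rng[1L]) / (rng[2L] - rng[1L])
  structure(hm, target_class = target_class, source_layer = source_layer,
            degenerate = degenerate,
            class = c("gradcam_heatmap", "matrix", "array"))
}

bilinear_upsample <- function(m, n_row, n_col) {
  r_src <- if (nrow(m) == 1L) rep(1, n_row) else seq(1, nrow(m), length.out = n_row)
  c_src <- if (ncol(m) == 1L) rep(1, n_col) else seq(1, ncol(m), length.out = n_col)
  r0 <- pmin(floor(r_src), nrow(m) - 1L); r0[nrow(m) == 1L] <- 1L
  c0 <- pmin(floor(c_src), ncol(m) - 1L); c0[ncol(m) == 1L] <- 1L
  fr <- r_src - r0; fc <- c_src - c0
  r1 <- pmin(r0 + 1L, nrow(m)); c1 <- pmin(c0 + 1L, ncol(m))
  out <- matrix(0, n_row, n_col)
  for (j in seq_len(n_col)) {
    top <- m[r0, c0[j]] * (1 - fr) + m[r1, c0[j]] * fr
    bot <- m[r0, c1[j]] * (1 - fr) + m[r1, c1[j]] * fr
    out[, j] <- top * (1 - fc[j]) + bot * fc[j]
  }
  out
}

#' Mean attention per feature dimension
#'
#' Averages a collection of same-shape Grad-CAM heatmaps across samples and
#' reduces over frames, yielding one attention score per MFCC dimension —
#' the summary used to judge which coefficient range the model attends to.
#'
#' @param heatmaps List of heatmap matrices (e.g. from [gradcam]).
#' @return Tibble with columns `dimension` (1-based row index) and
#'   `attention`; attribute `degenerate` is TRUE when all maps were zero.
#' @export
attention_profile <- function(heatmaps) {
  stopifnot(length(heatmaps) >= 1L)
  d <- dim(heatmaps[[1L]])
  if (!all(vapply(heatmaps, function(h) identical(dim(h), d), logical(1))))
    stop("heatmaps must share one shape")
  mean_map <- Reduce(`+`, lapply(heatmaps, unclass)) / length(heatmaps)
  prof <- rowMeans(mean_map)
  structure(tibble::tibble(dimension = seq_len(d[1L]), attention = unname(prof)),
            degenerate = all(mean_map == 0))
}
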