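#' Layer specifications for the weighted CNN
#'
#' Constructors for the ordered layer list of an [architecture_spec].
#' Convolutions are always "valid" (no padding): output size
#' `floor((in - kernel) / stride) + 1` per axis, which is what produces the
#' dimension-dropping behavior for odd input sizes at stride 2.
#'
#' @param out_channels,kernel,stride Convolution geometry (`kernel` length-2
#'   `(Kh, Kw)`).
#' @param activation `"relu"`, `"softmax"`, or `"linear"`.
#' @param batch_norm Apply per-channel batch normalization after the
#'   activation.
#' @param dropout Dropout rate applied after this layer (0 = none).
#' @param out_units Dense layer output width.
#' @return A `layer_spec` list.
#' @name layer_spec
NULL

#' @rdname layer_spec
#' @export
layer_conv <- function(out_channels, kernel = c(2L, 2L), stride = 1L,
                       activation = "relu", batch_norm = TRUE, dropout = 0) {
  stopifnot(all(kernel >= 1L), stride >= 1L, out_channels >= 1L)
  structure(list(kind = "conv", out_channels = as.integer(out_channels),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 activation = activation, batch_norm = batch_norm,
                 dropout = dropout),
            class = "layer_spec")
}

#' @rdname layer_spec
#' @export
layer_kwc <- function() structure(list(kind = "kwc"), class = "layer_spec")

#' @rdname layer_spec
#' @export
layer_flatten <- function() structure(list(kind = "flatten"), class = "layer_spec")

#' @rdname layer_spec
#' @export
layer_dense <- function(out_units, activation = "relu", dropout = 0) {
  stopifnot(out_units >= 1L)
  structure(list(kind = "dense", out_units = as.integer(out_units),
                 activation = activation, dropout = dropout),
            class = "layer_spec")
}

#' Architecture specification
#'
#' An ordered layer list plus the input geometry, from which forward shapes,
#' trainable parameter totals, and FLOP totals are all derived analytically.
#'
#' @param input_shape `(height, width, channels)` of the input feature map
#'   (MFCC dims x frames x 1).
#' @param layers List of [layer_spec] objects.
#' @param n_classes Output class count (checked against the final dense
#'   layer).
#' @return An `architecture_spec`.
#' @export
architecture_spec <- function(input_shape, layers, n_classes) {
  stopifnot(length(input_shape) == 3L, all(input_shape >= 1L))
  last <- layers[[length(layers)]]
  if (!identical(last$kind, "dense") || last$out_units != n_classes)
    stop("final layer must be a dense layer with `n_classes` units")
  arch <- structure(list(input_shape = as.integer(input_shape), layers = layers,
                         n_classes = as.integer(n_classes)),
                    class = "architecture_spec")
  forward_shapes(arch)  # validates: errors on dimension underflow
  arch
}

#' Default weighted-CNN architecture
#'
#' Three valid 2x2 convolutions (32, 64, 64 filters; strides 1, 1, 2) with
#' ReLU and batch normalization, dropout after the third block, the
#' parameter-free KWC channel-weighting layer, flatten, a 128-unit ReLU
#' dense layer with dropout, and a softmax output. With the default
#' 17 x 13 x 1 input this has 312,357 trainable parameters and a 2240-wide
#' flatten.
#'
#' @param dims,frames Input feature-map geometry (MFCC dims x frames).
#' @param n_classes Number of output classes (default 5).
#' @param dropout Dropout rate at both marked sites (default 0.3).
#' @return An [architecture_spec].
#' @export
wcnn_architecture <- function(dims = 17L, frames = 13L, n_classes = 5L,
                              dropout = 0.3) {
  architecture_spec(
    input_shape = c(dims, frames, 1L),
    layers = list(
      layer_conv(32L, c(2L, 2L), 1L),
      layer_conv(64L, c(2L, 2L), 1L),
      layer_conv(64L, c(2L, 2L), 2L, dropout = dropout),
      layer_kwc(),
      layer_flatten(),
      layer_dense(128L, "relu", dropout = dropout),
      layer_dense(n_classes, "softmax")
    ),
    n_classes = n_classes
  )
}

conv_out_dim <- function(n_in, k, s) {
  out <- (n_in - k) %/% s + 1L
  if (out < 1L) stop("convolution kernel larger than its input (", n_in, " vs ", k, ")")
  out
}

#' Propagate activation shapes through an architecture
#'
#' @param arch An [architecture_spec].
#' @return A list of integer shape vectors, one per layer (convention
#'   `(H, W, C)` until flatten, then a scalar width).
#' @export
forward_shapes <- function(arch) {
  shape <- arch$input_shape
  lapply(arch$layers, function(ly) {
    shape <<- switch(ly$kind,
      conv = c(conv_out_dim(shape[1L], ly$kernel[1L], ly$stride),
               conv_out_dim(shape[2L], ly$kernel[2L], ly$stride),
               ly$out_channels),
      kwc = shape,
      flatten = prod(shape),
      dense = ly$out_units,
      stop("unknown layer kind: ", ly$kind)
    )
    shape
  })
}

#' Count trainable parameters analytically
#'
#' Convolution layers contribute `(Kh*Kw*Cin + 1) * Cout` (weights + bias),
#' dense layers `(in + 1) * out`. The KWC layer, flatten, dropout, and batch
#' normalization contribute zero (normalization parameters are excluded by
#' convention as negligible).
#'
#' @param arch An [architecture_spec].
#' @param per_layer Return the per-layer vector instead of the total.
#' @return Integer parameter count (or vector).
#' @export
count_parameters <- function(arch, per_layer = FALSE) {
  shapes <- forward_shapes(arch)
  c_in <- arch$input_shape[3L]
  width_in <- NA_integer_
  counts <- vapply(seq_along(arch$layers), function(i) {
    ly <- arch$layers[[i]]
    out <- switch(ly$kind,
      conv = (ly$kernel[1L] * ly$kernel[2L] * c_in + 1L) * ly$out_channels,
      dense = (width_in + 1L) * ly$out_units,
      0L
    )
    sh <- shapes[[i]]
    if (length(sh) == 3L) c_in <<- sh[3L] else width_in <<- sh
    as.integer(out)
  }, integer(1))
  if (per_layer) counts else sum(counts)
}

#' Count forward-pass FLOPs analytically
#'
#' Convolutions contribute `2*Kh*Kw*Cin*Hout*Wout*Cout`, dense layers
#' `2*in*out`; every other layer counts zero.
#'
#' @inheritParams count_parameters
#' @return Numeric FLOP count (or per-layer vector).
#' @export
count_flops <- function(arch, per_layer = FALSE) {
  shapes <- forward_shapes(arch)
  c_in <- arch$input_shape[3L]
  width_in <- NA_real_
  flops <- vapply(seq_along(arch$layers), function(i) {
    ly <- arch$layers[[i]]
    sh <- shapes[[i]]
    out <- switch(ly$kind,
      conv = 2 * ly$kernel[1L] * ly$kernel[2L] * c_in * sh[1L] * sh[2L] * ly$out_channels,
      dense = 2 * width_in * ly$out_units,
      0
    )
    if (length(sh) == 3L) c_in <<- sh[3L] else width_in <<- sh
    out
  }, numeric(1))
  if (per_layer) flops else sum(flops)
}

#' Summarize an architecture as a tibble
#'
#' One row per layer with output shape, parameter count, and FLOPs — the
#' analytic layer table for any configuration.
#'
#' @param arch An [architecture_spec].
#' @return A tibble with columns `layer`, `kind`, `output_shape`, `params`,
#'   `flops`.
#' @export
arch_table <- function(arch) {
  shapes <- forward_shapes(arch)
  tibble::tibble(
    layer = seq_along(arch$layers),
    kind = vapply(arch$layers, `[[`, "", "kind"),
    output_shape = vapply(shapes, function(s) paste(s, collapse = " x "), ""),
    params = count_parameters(arch, per_layer = TRUE),
    flops = count_flops(arch, per_layer = TRUE)
  )
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("<architecture_spec> input %s, %d classes\n",
              paste(x$input_shape, collapse = " x "), x$n_classes))
  print(arch_table(x))
  cat(sprintf("total parameters: %s | total FLOPs: %s\n",
              format(count_parameters(x), big.mark = ","),
              format(count_flops(x), big.mark = ",")))
  invisible(x)
}
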