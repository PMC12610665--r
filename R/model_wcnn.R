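#' The weighted CNN engine
#'
#' The network is implemented directly on base-R arrays: valid convolutions
#' via im2col + BLAS matrix products, per-channel batch normalization, the
#' parameter-free KWC channel-weighting layer, dense layers, and a softmax
#' head, with full hand-written backpropagation (needed both for training
#' and for Grad-CAM). Activation tensors use the layout `(H, W, C, N)`.
#'
#' @name wcnn-engine
NULL

#' KWC layer forward pass
#'
#' Key Weighting Calculation: each channel of a feature tensor is rescaled
#' by its own global average, `w_c = mean_{i,j} F_c(i,j)` and
#' `F'_c = w_c * F_c`. Channels with high average activation are amplified,
#' low-average (typically noise-dominated) channels are attenuated. The
#' layer has zero parameters and is quadratically homogeneous:
#' `kwc(a * F) = a^2 * kwc(F)`.
#'
#' @param f A 3-D array `(C, H, W)` or `(H, W, C)`-agnostic: the first two
#'   margins are treated as spatial and the last as channels.
#' @return Array of the same shape.
#' @export
kwc_forward <- function(f) {
  stopifnot(is.array(f), length(dim(f)) == 3L)
  d <- dim(f)
  w <- colMeans(matrix(f, d[1L] * d[2L], d[3L]))
  array(matrix(f, d[1L] * d[2L], d[3L]) %*% diag(w, d[3L]), dim = d)
}

kwc_forward4 <- function(a) {
  d <- dim(a)                                  # (H, W, C, N)
  m <- matrix(a, d[1L] * d[2L], d[3L] * d[4L])
  w <- colMeans(m)                             # per (channel, sample)
  y <- array(m * rep(w, each = d[1L] * d[2L]), dim = d)
  list(y = y, w = matrix(w, d[3L], d[4L]))
}

kwc_backward4 <- function(dy, a, w) {
  d <- dim(a)
  hw <- d[1L] * d[2L]
  dym <- matrix(dy, hw, d[3L] * d[4L])
  am <- matrix(a, hw, d[3L] * d[4L])
  dw <- colSums(dym * am)                      # dL/dw per (c, n)
  # product rule: dL/da = w * dL/dy + (dL/dw) / (H*W), the latter constant
  # over the spatial grid of its channel
  dm <- dym * rep(as.vector(w), each = hw) + rep(dw / hw, each = hw)
  array(dm, dim = d)
}

im2col_index <- function(h_in, w_in, c_in, n, kh, kw, stride) {
  h_out <- (h_in - kh) %/% stride + 1L
  w_out <- (w_in - kw) %/% stride + 1L
  # patch-position offsets (rows) and output-location bases (cols)
  kh_i <- rep(seq_len(kh), times = kw * c_in)
  kw_i <- rep(rep(seq_len(kw), each = kh), times = c_in)
  c_i <- rep(seq_len(c_in), each = kh * kw)
  off <- (kh_i - 1L) + (kw_i - 1L) * h_in + (c_i - 1L) * h_in * w_in
  oh <- rep(seq_len(h_out), times = w_out * n)
  ow <- rep(rep(seq_len(w_out), each = h_out), times = n)
  nn <- rep(seq_len(n), each = h_out * w_out)
  base <- (oh - 1L) * stride + (ow - 1L) * stride * h_in + (nn - 1L) * h_in * w_in * c_in
  list(idx = outer(base, off, `+`) + 1L, h_out = h_out, w_out = w_out)
}

conv_forward <- function(a, w_mat, b, stride) {
  d <- dim(a)
  kh <- attr(w_mat, "kh"); kw <- attr(w_mat, "kw")
  ii <- im2col_index(d[1L], d[2L], d[3L], d[4L], kh, kw, stride)
  x_col <- matrix(a[as.vector(ii$idx)], nrow = nrow(ii$idx))  # (HoWoN) x (KhKwCin)
  y <- sweep(x_col %*% w_mat, 2L, b, `+`)              # (HoWoN) x Cout
  c_out <- ncol(w_mat)
  y_arr <- aperm(array(y, c(ii$h_out, ii$w_out, d[4L], c_out)), c(1L, 2L, 4L, 3L))
  list(y = y_arr, x_col = x_col, index = ii)
}

conv_backward <- function(dy, cache, w_mat, in_dim) {
  d_out <- dim(dy)                                     # (Ho, Wo, Cout, N)
  dy_mat <- matrix(aperm(dy, c(1L, 2L, 4L, 3L)), ncol = d_out[3L])
  dw <- crossprod(cache$x_col, dy_mat)                 # (KhKwCin) x Cout
  db <- colSums(dy_mat)
  dx_col <- dy_mat %*% t(w_mat)                        # (HoWoN) x (KhKwCin)
  dx <- numeric(prod(in_dim))
  idx <- cache$index$idx
  for (r in seq_len(ncol(idx))) {
    dx[idx[, r]] <- dx[idx[, r]] + dx_col[, r]
  }
  list(dx = array(dx, in_dim), dw = dw, db = db)
}

bn_forward <- function(a, gamma, beta, running, train, momentum = 0.9, eps = 1e-5) {
  d <- dim(a)
  m <- matrix(aperm(a, c(1L, 2L, 4L, 3L)), ncol = d[3L])   # (HWN) x C
  if (train) {
    mu <- colMeans(m)
    va <- colMeans(sweep(m, 2L, mu)^2)
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * va
  } else {
    mu <- running$mean
    va <- running$var
  }
  inv_sd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(m, 2L, mu), 2L, inv_sd, `*`)
  y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(y = aperm(array(y, d[c(1L, 2L, 4L, 3L)]), c(1L, 2L, 4L, 3L)),
       xhat = xhat, inv_sd = inv_sd, running = running, train = train)
}

bn_backward <- function(dy, cache, gamma) {
  d <- dim(dy)
  dym <- matrix(aperm(dy, c(1L, 2L, 4L, 3L)), ncol = d[3L])
  n_eff <- nrow(dym)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2L, gamma, `*`)
  centered <- if (isTRUE(cache$train)) {
    # batch statistics participate in the forward pass
    sweep(dxhat, 2L, colMeans(dxhat)) -
      cache$xhat * matrix(colMeans(dxhat * cache$xhat), n_eff, d[3L], byrow = TRUE)
  } else {
    dxhat  # eval mode: running stats are constants, BN is affine
  }
  dx <- sweep(centered, 2L, cache$inv_sd, `*`)
  list(dx = aperm(array(dx, d[c(1L, 2L, 4L, 3L)]), c(1L, 2L, 4L, 3L)),
       dgamma = dgamma, dbeta = dbeta)
}

he_init <- function(n_row, n_col, fan_in) {
  matrix(stats::rnorm(n_row * n_col, sd = sqrt(2 / fan_in)), n_row, n_col)
}

#' Build a trainable WCNN model
#'
#' Instantiates the parameters of an [architecture_spec] with seeded He
#' initialization. The model's trainable parameter total (excluding batch
#' normalization, which the analytic count excludes by convention) equals
#' [count_parameters].
#'
#' @param arch An [architecture_spec].
#' @param seed Integer seed for deterministic initialization.
#' @param bn_after_activation Apply batch normalization after the ReLU
#'   (Conv -> ReLU -> BN, the default) rather than before it.
#' @return A `wcnn_model` list with fields `arch`, `params`, `config`.
#' @export
build_model <- function(arch, seed = 1L, bn_after_activation = TRUE) {
  set.seed(seed)
  shapes <- forward_shapes(arch)
  c_in <- arch$input_shape[3L]
  width_in <- NA_integer_
  params <- vector("list", length(arch$layers))
  for (i in seq_along(arch$layers)) {
    ly <- arch$layers[[i]]
    if (ly$kind == "conv") {
      fan_in <- ly$kernel[1L] * ly$kernel[2L] * c_in
      w <- he_init(fan_in, ly$out_channels, fan_in)
      attr(w, "kh") <- ly$kernel[1L]; attr(w, "kw") <- ly$kernel[2L]
      params[[i]] <- list(
        w = w, b = numeric(ly$out_channels),
        gamma = if (isTRUE(ly$batch_norm)) rep(1, ly$out_channels),
        beta = if (isTRUE(ly$batch_norm)) numeric(ly$out_channels),
        running = list(mean = numeric(ly$out_channels), var = rep(1, ly$out_channels))
      )
    } else if (ly$kind == "dense") {
      params[[i]] <- list(w = he_init(width_in, ly$out_units, width_in),
                          b = numeric(ly$out_units))
    }
    sh <- shapes[[i]]
    if (length(sh) == 3L) c_in <- sh[3L] else width_in <- sh
  }
  structure(list(arch = arch, params = params,
                 config = list(bn_after_activation = bn_after_activation)),
            class = "wcnn_model")
}

#' Stack feature maps into a model input batch
#'
#' @param features List of equal-shape feature-map matrices.
#' @return Array `(H, W, 1, N)`.
#' @export
stack_features <- function(features) {
  d <- dim(features[[1L]])
  out <- array(0, c(d[1L], d[2L], 1L, length(features)))
  for (i in seq_along(features)) out[, , 1L, i] <- features[[i]]
  out
}

forward_pass <- function(model, x, train = FALSE, keep_cache = FALSE) {
  arch <- model$arch
  caches <- vector("list", length(arch$layers))
  a <- x
  for (i in seq_along(arch$layers)) {
    ly <- arch$layers[[i]]
    p <- model$params[[i]]
    cache <- list(a_in = if (keep_cache) a)
    if (ly$kind == "conv") {
      cache$in_dim <- dim(a)
      cv <- conv_forward(a, p$w, p$b, ly$stride)
      a <- cv$y
      if (keep_cache) cache$x_col <- cv$x_col
      cache$index <- cv$index
      if (!is.null(p$gamma) && !model$config$bn_after_activation) {
        bf <- bn_forward(a, p$gamma, p$beta, p$running, train)
        model$params[[i]]$running <- bf$running
        if (keep_cache) cache$bn <- bf[c("xhat", "inv_sd", "train")]
        a <- bf$y
      }
      if (identical(ly$activation, "relu")) {
        if (keep_cache) cache$pre_act <- a
        a <- pmax(a, 0)
      }
      if (!is.null(p$gamma) && model$config$bn_after_activation) {
        if (keep_cache) cache$post_act <- a
        bf <- bn_forward(a, p$gamma, p$beta, p$running, train)
        model$params[[i]]$running <- bf$running
        if (keep_cache) cache$bn <- bf[c("xhat", "inv_sd", "train")]
        a <- bf$y
      }
      cache$conv_out <- a                        # activation seen by Grad-CAM
      if (train && !is.null(ly$dropout) && ly$dropout > 0) {
        mask <- array(stats::runif(length(a)) >= ly$dropout, dim(a)) / (1 - ly$dropout)
        cache$mask <- mask
        a <- a * mask
      }
    } else if (ly$kind == "kwc") {
      kf <- kwc_forward4(a)
      cache$w <- kf$w
      a <- kf$y
    } else if (ly$kind == "flatten") {
      cache$in_dim <- dim(a)
      a <- matrix(a, ncol = dim(a)[4L])          # (CHW) x N, column-major flatten
    } else if (ly$kind == "dense") {
      z <- crossprod(p$w, a) + p$b               # out x N
      if (identical(ly$activation, "relu")) {
        if (keep_cache) cache$pre_act <- z
        a <- pmax(z, 0)
      } else if (identical(ly$activation, "softmax")) {
        cache$logits <- z
        zs <- sweep(z, 2L, apply(z, 2L, max))
        e <- exp(zs)
        a <- sweep(e, 2L, colSums(e), `/`)
      } else {
        a <- z
      }
      if (train && !is.null(ly$dropout) && ly$dropout > 0) {
        mask <- matrix(stats::runif(length(a)) >= ly$dropout, nrow(a)) / (1 - ly$dropout)
        cache$mask <- mask
        a <- a * mask
      }
    }
    caches[[i]] <- cache
  }
  list(out = a, caches = caches, model = model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Backward through the whole stack. `d_out` is dL/d(output activation) for
# the last layer, or dL/d(logits) when `from_logits = TRUE` (softmax + CE
# collapses to probs - targets there). Returns parameter grads and, when
# `stop_at_conv` is given, dL/d(activation) at that conv layer's output.
backward_pass <- function(model, fwd, d_out, stop_at_conv = NULL) {
  arch <- model$arch
  caches <- fwd$caches
  grads <- vector("list", length(arch$layers))
  da <- d_out
  for (i in rev(seq_along(arch$layers))) {
    ly <- arch$layers[[i]]
    p <- model$params[[i]]
    cache <- caches[[i]]
    if (ly$kind == "dense") {
      if (!is.null(cache$mask)) da <- da * cache$mask
      dz <- da
      if (identical(ly$activation, "relu")) dz <- da * (cache$pre_act > 0)
      # softmax handled by caller supplying d(logits) directly
      a_in <- cache$a_in
      grads[[i]] <- list(dw = a_in %*% t(dz), db = rowSums(dz))
      da <- p$w %*% dz
    } else if (ly$kind == "flatten") {
      da <- array(da, cache$in_dim)
    } else if (ly$kind == "kwc") {
      da <- kwc_backward4(da, cache$a_in, cache$w)
    } else if (ly$kind == "conv") {
      if (!is.null(cache$mask)) da <- da * cache$mask
      if (!is.null(stop_at_conv) && stop_at_conv == i) {
        return(list(grads = grads, d_activation = da))
      }
      g <- list()
      if (!is.null(p$gamma) && model$config$bn_after_activation) {
        bb <- bn_backward(da, cache$bn, p$gamma)
        g$dgamma <- bb$dgamma; g$dbeta <- bb$dbeta
        da <- bb$dx
      }
      if (identical(ly$activation, "relu")) da <- da * (cache$pre_act > 0)
      if (!is.null(p$gamma) && !model$config$bn_after_activation) {
        bb <- bn_backward(da, cache$bn, p$gamma)
        g$dgamma <- bb$dgamma; g$dbeta <- bb$dbeta
        da <- bb$dx
      }
      cb <- conv_backward(da, cache, p$w, cache$in_dim)
      g$dw <- cb$dw; g$db <- cb$db
      grads[[i]] <- g
      da <- cb$dx
    }
  }
  list(grads = grads, d_input = da)
}

#' Predict class probabilities
#'
#' @param model A trained `wcnn_model`.
#' @param features List of feature maps or a `(H, W, 1, N)` array.
#' @return Matrix `N x n_classes` of softmax probabilities (rows sum to 1),
#'   columns named by class when the model carries a label set.
#' @export
predict_wcnn <- function(model, features) {
  x <- if (is.list(features)) stack_features(features) else features
  probs <- t(forward_pass(model, x, train = FALSE)$out)
  if (!is.null(model$label_set)) colnames(probs) <- model$label_set
  probs
}

#' Count a built model's trainable parameters
#'
#' Sums the actual weight/bias array sizes held by the model. With
#' `include_bn = FALSE` (the analytic convention) this equals
#' [count_parameters] on the model's architecture.
#'
#' @param model A `wcnn_model`.
#' @param include_bn Include batch-norm gamma/beta.
#' @return Integer count.
#' @export
model_parameter_count <- function(model, include_bn = FALSE) {
  total <- 0L
  for (p in model$params) {
    if (is.null(p)) next
    total <- total + length(p$w) + length(p$b)
    if (include_bn && !is.null(p$gamma)) total <- total + length(p$gamma) + length(p$beta)
  }
  total
}
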