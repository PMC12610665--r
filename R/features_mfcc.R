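#' MFCC extraction configuration
#'
#' Parameters of the static-MFCC front end. Defaults reproduce the study
#' configuration used throughout the package: 0.2 s Hamming frames with 50%
#' overlap, a 2048-point FFT, 32 triangular mel filters, and 17 retained
#' static coefficients (coefficient 0 acting as the energy term).
#'
#' @param win_sec Frame length in seconds.
#' @param overlap Fractional frame overlap in `[0, 1)`.
#' @param n_fft FFT length in points; frames shorter than `n_fft` are
#'   zero-padded (e.g. the 400-sample window at 2000 Hz).
#' @param n_mels Number of triangular mel filters spanning `[0, fs/2]`.
#' @param n_static Number of static coefficients kept (DCT coefficients
#'   0..n_static-1; coefficient 0 is the energy coefficient).
#' @param include_deltas Append delta and delta-delta rows (used only for
#'   the 39-dimension configuration).
#' @param pre_emphasis Pre-emphasis coefficient in `[0, 1)`; 0.97 is the
#'   speech-processing convention.
#' @param log_floor Floor applied to filterbank energies before the log,
#'   so silent frames stay finite.
#' @return A list of class `mfcc_config`.
#' @export
mfcc_config <- function(win_sec = 0.2, overlap = 0.5, n_fft = 2048L,
                        n_mels = 32L, n_static = 17L, include_deltas = FALSE,
                        pre_emphasis = 0.97, log_floor = 1e-10) {
  stopifnot(overlap >= 0, overlap < 1, n_static <= n_mels,
            pre_emphasis >= 0, pre_emphasis < 1, win_sec > 0)
  structure(list(win_sec = win_sec, overlap = overlap, n_fft = as.integer(n_fft),
                 n_mels = as.integer(n_mels), n_static = as.integer(n_static),
                 include_deltas = include_deltas, pre_emphasis = pre_emphasis,
                 log_floor = log_floor),
            class = "mfcc_config")
}

#' Number of analysis frames for a signal
#'
#' `floor((fs * sec - winlength) / winstep) + 1`: the count of full windows
#' that fit when the window advances by `winstep` samples.
#'
#' @param fs Sampling rate in Hz.
#' @param sec Signal length in seconds.
#' @param winlength Window length in samples.
#' @param winstep Step size in samples.
#' @return Integer frame count.
#' @export
frame_count <- function(fs, sec, winlength, winstep) {
  stopifnot(winstep > 0)
  n <- fs * sec
  if (n < winlength) stop("signal shorter than one window; zero-pad first")
  as.integer(floor((n - winlength) / winstep) + 1)
}

#' Pre-emphasis high-pass filter
#'
#' `y[1] = x[1]; y[n] = x[n] - alpha * x[n-1]`, boosting high frequencies
#' before spectral analysis.
#'
#' @param x Numeric waveform.
#' @param alpha Coefficient in `[0, 1)`.
#' @return Filtered waveform, same length.
#' @export
pre_emphasize <- function(x, alpha = 0.97) {
  stopifnot(alpha >= 0, alpha < 1)
  if (length(x) <= 1L || alpha == 0) return(x)
  c(x[1L], x[-1L] - alpha * x[-length(x)])
}

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank matrix
#'
#' `n_mels` unit-peak triangular filters with centers equally spaced on the
#' mel scale between 0 Hz and `fs/2`, evaluated at the `n_fft/2 + 1`
#' non-negative FFT bin frequencies.
#'
#' @param fs Sampling rate in Hz.
#' @param n_fft FFT length.
#' @param n_mels Filter count.
#' @return A `n_mels x (n_fft/2 + 1)` matrix.
#' @export
mel_filterbank <- function(fs, n_fft, n_mels = 32L) {
  n_bins <- n_fft %/% 2L + 1L
  freqs <- (seq_len(n_bins) - 1L) * fs / n_fft
  edges <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(fs / 2), length.out = n_mels + 2L))
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; ce <- edges[m + 1L]; hi <- edges[m + 2L]
    up <- (freqs - lo) / (ce - lo)
    dn <- (hi - freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

dct2_matrix <- function(n_out, n_in) {
  # DCT-II with orthonormal scaling
  k <- seq_len(n_out) - 1L
  n <- seq_len(n_in) - 1L
  M <- sqrt(2 / n_in) * cos(outer(k, n + 0.5) * pi / n_in)
  M[1L, ] <- M[1L, ] / sqrt(2)
  M
}

#' Extract a static MFCC feature map
#'
#' Pre-emphasis, framing into overlapping Hamming windows, power spectrum by
#' FFT, triangular mel filterbank, natural log (floored), and an orthonormal
#' DCT-II keeping the first `n_static` coefficients. Rows are feature
#' dimensions, columns are frames. With `include_deltas = TRUE` the delta and
#' delta-delta rows are appended via [compute_deltas].
#'
#' @param rec An [audio_recording], already standardized to the analysis
#'   duration (see [standardize_length]).
#' @param cfg An [mfcc_config].
#' @return A `feature_map`: numeric matrix of shape `(dims, frames)` with
#'   attributes `fs` and `config`.
#' @export
extract_mfcc <- function(rec, cfg = mfcc_config()) {
  stopifnot(inherits(rec, "audio_recording"), inherits(cfg, "mfcc_config"))
  fs <- rec$fs
  winlength <- as.integer(round(cfg$win_sec * fs))
  winstep <- as.integer(round(winlength * (1 - cfg$overlap)))
  if (length(rec$samples) < winlength)
    stop("recording shorter than one analysis window; standardize_length first")
  n_fft <- max(cfg$n_fft, winlength)
  n_frames <- frame_count(fs, length(rec$samples) / fs, winlength, winstep)

  x <- pre_emphasize(rec$samples, cfg$pre_emphasis)
  starts <- (seq_len(n_frames) - 1L) * winstep
  win <- hamming_window(winlength)
  frames <- matrix(0, n_fft, n_frames)
  for (j in seq_len(n_frames)) {
    frames[seq_len(winlength), j] <- x[starts[j] + seq_len(winlength)] * win
  }
  spec <- stats::mvfft(frames)
  n_bins <- n_fft %/% 2L + 1L
  power <- abs(spec[seq_len(n_bins), , drop = FALSE])^2

  fb <- mel_filterbank(fs, n_fft, cfg$n_mels)
  logmel <- log(pmax(fb %*% power, cfg$log_floor))
  dct <- dct2_matrix(cfg$n_static, cfg$n_mels)
  fm <- dct %*% logmel
  rownames(fm) <- paste0("c", seq_len(cfg$n_static) - 1L)
  colnames(fm) <- paste0("f", seq_len(n_frames))
  fm <- structure(fm, fs = fs, config = cfg, class = c("feature_map", "matrix", "array"))
  if (isTRUE(cfg$include_deltas)) fm <- compute_deltas(fm) else fm
}

#' Append delta and delta-delta rows to a feature map
#'
#' First- and second-order temporal derivatives computed with a symmetric
#' regression window (`d_t = sum_n n (c_{t+n} - c_{t-n}) / (2 sum_n n^2)`),
#' edge frames replicated. A 13-row static map becomes the conventional
#' 39-row static + delta + delta-delta stack.
#'
#' @param fm A feature map matrix (rows = dims, cols = frames).
#' @param half_width Regression half-width `N` (default 2).
#' @return Matrix with `3 * nrow(fm)` rows.
#' @export
compute_deltas <- function(fm, half_width = 2L) {
  if (ncol(fm) < 3L) stop("need at least 3 frames for delta features")
  delta1 <- delta_of(fm, half_width)
  delta2 <- delta_of(delta1, half_width)
  out <- rbind(fm, delta1, delta2)
  rownames(out) <- c(paste0("c", seq_len(nrow(fm)) - 1L),
                     paste0("d", seq_len(nrow(fm)) - 1L),
                     paste0("dd", seq_len(nrow(fm)) - 1L))
  structure(out, fs = attr(fm, "fs"), config = attr(fm, "config"),
            class = c("feature_map", "matrix", "array"))
}

delta_of <- function(m, half_width) {
  t_max <- ncol(m)
  denom <- 2 * sum(seq_len(half_width)^2)
  d <- matrix(0, nrow(m), t_max)
  for (n in seq_len(half_width)) {
    fwd <- m[, pmin(seq_len(t_max) + n, t_max), drop = FALSE]
    bwd <- m[, pmax(seq_len(t_max) - n, 1L), drop = FALSE]
    d <- d + n * (fwd - bwd)
  }
  d / denom
}

#' Extract feature maps for a whole manifest
#'
#' Convenience wrapper: read each WAV, standardize its length, and extract
#' the configured MFCC map.
#'
#' @param manifest Manifest tibble (see [read_manifest]).
#' @param cfg An [mfcc_config].
#' @param target_sec Analysis duration in seconds.
#' @return Named list of feature maps (names = record ids), with the label
#'   vector as attribute `labels`.
#' @export
extract_features <- function(manifest, cfg = mfcc_config(), target_sec = 1.4) {
  maps <- lapply(seq_len(nrow(manifest)), function(i) {
    rec <- read_wav(manifest$path[i], label = manifest$label[i],
                    record_id = manifest$record_id[i])
    extract_mfcc(standardize_length(rec, target_sec), cfg)
  })
  names(maps) <- manifest$record_id
  structure(maps, labels = stats::setNames(manifest$label, manifest$record_id))
}
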