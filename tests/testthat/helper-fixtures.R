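# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code at test time; nothing binary ships.

five_classes <- c("AS", "MR", "MS", "MVP", "N")

# Independent naive MFCC implementation: per-frame scalar loops, written
# without reusing any of the package's vectorized internals. Used as the
# reference the fast path must match.
naive_mfcc <- function(samples, fs, win_sec = 0.2, overlap = 0.5, n_fft = 2048,
                       n_mels = 32, n_static = 17, alpha = 0.97, floor = 1e-10) {
  y <- samples
  for (i in rev(seq_along(y))[-length(y)]) y[i] <- samples[i] - alpha * samples[i - 1]
  wl <- round(win_sec * fs)
  st <- round(wl * (1 - overlap))
  nfr <- floor((length(y) - wl) / st) + 1
  ham <- 0.54 - 0.46 * cos(2 * pi * (0:(wl - 1)) / (wl - 1))
  # mel filterbank, rebuilt from the textbook definition
  m2hz <- function(m) 700 * (10^(m / 2595) - 1)
  hz2m <- function(f) 2595 * log10(1 + f / 700)
  centers <- m2hz(seq(0, hz2m(fs / 2), length.out = n_mels + 2))
  bins <- (0:(n_fft / 2)) * fs / n_fft
  out <- matrix(0, n_static, nfr)
  for (j in seq_len(nfr)) {
    fr <- y[(j - 1) * st + 1:wl] * ham
    sp <- abs(fft(c(fr, numeric(n_fft - wl))))[1:(n_fft / 2 + 1)]^2
    fbe <- numeric(n_mels)
    for (m in seq_len(n_mels)) {
      lo <- centers[m]; ce <- centers[m + 1]; hi <- centers[m + 2]
      w <- numeric(length(bins))
      ris <- bins >= lo & bins <= ce
      fal <- bins > ce & bins <= hi
      w[ris] <- (bins[ris] - lo) / (ce - lo)
      w[fal] <- (hi - bins[fal]) / (hi - ce)
      fbe[m] <- sum(w * sp)
    }
    lfb <- log(pmax(fbe, floor))
    for (k in 0:(n_static - 1)) {
      ck <- sum(lfb * cos(pi * k * (seq_len(n_mels) - 0.5) / n_mels)) * sqrt(2 / n_mels)
      if (k == 0) ck <- ck / sqrt(2)
      out[k + 1, j] <- ck
    }
  }
  out
}

# random feature maps with a class-dependent row offset: trivially separable
toy_feature_set <- function(n, classes = c("a", "b", "c"), dims = 17L,
                            frames = 13L, shift = 3, sd = 1, seed = 1L) {
  set.seed(seed)
  labels <- sample(rep(classes, length.out = n))
  feats <- lapply(labels, function(cl) {
    m <- matrix(stats::rnorm(dims * frames, sd = sd), dims, frames)
    row <- 2L + 3L * (match(cl, classes) - 1L)
    m[row, ] <- m[row, ] + shift
    m
  })
  names(feats) <- sprintf("toy%04d", seq_len(n))
  structure(feats, labels = stats::setNames(labels, names(feats)))
}

# minimal stereo 16-bit WAV writer (the package's writer is mono-only by
# design; tests need a stereo fixture to exercise channel averaging)
write_stereo_wav <- function(left, right, fs, path) {
  inter <- as.vector(rbind(
    pmax(-32768, pmin(32767, round(left * 32768))),
    pmax(-32768, pmin(32767, round(right * 32768)))
  ))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(inter) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 4L), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(as.integer(inter), con, size = 2, endian = "little")
  invisible(path)
}

# in-memory synthetic feature set built from the generator (no disk I/O)
synth_feature_set <- function(n_per_class, fs = 8000, seed = 1L,
                              target_ber = NULL, classes = five_classes) {
  idx <- 0L
  feats <- list()
  labels <- character(0)
  for (cl in classes) {
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      sr <- synth_recording(synth_config(
        fs = fs, class_spec = cl, target_ber = target_ber,
        seed = as.integer((seed * 7919L + idx) %% 2147483629L)))
      feats[[idx]] <- extract_mfcc(standardize_length(sr$recording, 1.4))
      labels[idx] <- cl
    }
  }
  names(feats) <- sprintf("s%04d", seq_along(feats))
  structure(feats, labels = stats::setNames(labels, names(feats)))
}
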