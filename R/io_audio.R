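#' Construct a labeled PCG recording
#'
#' An `audio_recording` bundles a mono waveform with its sampling rate, an
#' optional class label, and a record identifier. It is the unit every other
#' stage of the pipeline consumes.
#'
#' @param samples Numeric vector of amplitudes (dimensionless).
#' @param fs Sampling rate in Hz (positive scalar).
#' @param label Optional class label (character scalar or `NA`).
#' @param record_id Unique identifier string.
#' @return An object of class `audio_recording` with fields `samples`, `fs`,
#'   `label`, `record_id`.
#' @export
audio_recording <- function(samples, fs, label = NA_character_, record_id = "rec") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("`samples` must be non-empty")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("`fs` must be a positive scalar")
  structure(
    list(samples = samples, fs = fs, label = as.character(label),
         record_id = as.character(record_id)),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording '%s'> %d samples @ %g Hz (%.3f s), label = %s\n",
              x$record_id, length(x$samples), x$fs,
              length(x$samples) / x$fs, x$label))
  invisible(x)
}

#' Read a PCM WAV file
#'
#' Reads 16-bit integer or 32-bit float PCM RIFF/WAVE files. Multi-channel
#' input is reduced to mono by averaging channels. Amplitudes are returned as
#' doubles; 16-bit samples are scaled to \[-1, 1) by 1/32768.
#'
#' @param path Path to a `.wav` file.
#' @param label,record_id Optional metadata attached to the result;
#'   `record_id` defaults to the file name without extension.
#' @return An [audio_recording].
#' @export
read_wav <- function(path, label = NA_character_, record_id = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        n_channels   = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        sample_rate  = readBin(con, "integer", 1, size = 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, size = 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        bits         = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
      )
      extra <- sz - 16L
      if (extra > 0L) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV (missing fmt/data chunk): ", path)

  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", n = length(data_raw) / 2L, size = 2,
                 endian = "little", signed = TRUE) / 32768
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "double", n = length(data_raw) / 4L, size = 4,
                 endian = "little")
  } else {
    stop("unsupported WAV encoding (need 16-bit PCM or 32-bit float): ", path)
  }
  nc <- fmt$n_channels
  if (nc > 1L) {
    x <- x[seq_len((length(x) %/% nc) * nc)]
    x <- rowMeans(matrix(x, ncol = nc, byrow = TRUE))
  }
  if (is.null(record_id)) record_id <- sub("\\.[Ww][Aa][Vv]$", "", basename(path))
  audio_recording(x, fmt$sample_rate, label = label, record_id = record_id)
}

#' Write a recording to a PCM WAV file
#'
#' @param rec An [audio_recording].
#' @param path Output path.
#' @param bits 16 (integer PCM, default) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, bits = 16L) {
  stopifnot(inherits(rec, "audio_recording"), bits %in% c(16L, 32L))
  x <- rec$samples
  fs <- as.integer(round(rec$fs))
  con <- file(path, "wb")
  on.exit(close(con))
  bytes_per <- bits / 8L
  data_size <- length(x) * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (bits == 16L) 1L else 3L, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16L) {
    q <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Resample a recording to a new rate
#'
#' Zero-phase FFT-domain resampling: the spectrum is truncated (downsampling)
#' or zero-extended (upsampling) at the new Nyquist frequency and inverted at
#' the new length. Exact for band-limited content, which is all the pipeline
#' ever produces or analyzes.
#'
#' @param rec An [audio_recording].
#' @param fs_out Target rate in Hz.
#' @return An [audio_recording] at `fs_out`.
#' @export
resample_audio <- function(rec, fs_out) {
  stopifnot(inherits(rec, "audio_recording"), fs_out > 0)
  if (rec$fs == fs_out) return(rec)
  x <- rec$samples
  n <- length(x)
  m <- max(1L, as.integer(round(n * fs_out / rec$fs)))
  X <- stats::fft(x)
  Y <- complex(m)
  half <- min(n, m) %/% 2L
  keep <- seq_len(half + 1L)                      # DC .. new Nyquist
  Y[keep] <- X[keep]
  if (half > 0L) Y[m - seq_len(half) + 1L] <- X[n - seq_len(half) + 1L]
  if (m %% 2L == 0L && half == m %/% 2L) Y[half + 1L] <- Re(Y[half + 1L])
  y <- Re(stats::fft(Y, inverse = TRUE)) / n
  audio_recording(y, fs_out, label = rec$label, record_id = rec$record_id)
}

#' Standardize a recording to a fixed analysis length
#'
#' Recordings longer than `target_sec` are truncated (keeping the initial
#' portion); shorter recordings are zero-padded at the end. The output always
#' has exactly `round(fs * target_sec)` samples, so every file maps to
#' exactly one fixed-size segment.
#'
#' @param rec An [audio_recording].
#' @param target_sec Target duration in seconds (default 1.4).
#' @return An [audio_recording] of the standardized length.
#' @export
standardize_length <- function(rec, target_sec = 1.4) {
  stopifnot(inherits(rec, "audio_recording"), target_sec > 0)
  n_out <- as.integer(round(rec$fs * target_sec))
  x <- rec$samples
  y <- if (length(x) >= n_out) x[seq_len(n_out)] else c(x, numeric(n_out - length(x)))
  audio_recording(y, rec$fs, label = rec$label, record_id = rec$record_id)
}

#' Read / write a dataset manifest
#'
#' A manifest is a CSV with header `record_id,path,label` listing one audio
#' file per row. `record_id`s must be unique and labels must come from
#' `label_set` (inferred from the data when not given).
#'
#' @param path CSV path.
#' @param label_set Optional ordered character vector of class names.
#' @return A tibble with columns `record_id`, `path`, `label` and attribute
#'   `label_set`.
#' @export
read_manifest <- function(path, label_set = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("record_id", "path", "label")
  if (!all(req %in% names(df))) stop("manifest must have columns: ", paste(req, collapse = ", "))
  as_manifest(df[req], label_set)
}

#' @rdname read_manifest
#' @param manifest A manifest tibble/data frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest)[c("record_id", "path", "label")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_manifest
#' @export
as_manifest <- function(manifest, label_set = NULL) {
  df <- tibble::as_tibble(manifest)
  if (anyDuplicated(df$record_id)) stop("duplicate record_id in manifest")
  if (is.null(label_set)) label_set <- sort(unique(df$label))
  bad <- setdiff(unique(df$label), label_set)
  if (length(bad)) stop("labels outside label_set: ", paste(bad, collapse = ", "))
  attr(df, "label_set") <- label_set
  df
}

#' Split a dataset at the whole-file level
#'
#' Partitions a manifest for holdout or k-fold validation. Splitting is
#' strictly at the file level: a recording's segment can never occur in both
#' train and test. In k-fold mode the k test sets are pairwise disjoint and
#' cover the manifest. Balanced sampling draws an equal per-class test count
#' in every fold; random sampling ignores class when drawing test sets.
#'
#' @param manifest Manifest tibble (see [read_manifest]).
#' @param scheme `"holdout"` or `"kfold"`.
#' @param train_fraction Train proportion for holdout (default 0.9).
#' @param k Fold count for k-fold (default 10).
#' @param sampling `"balanced"` or `"random"` (k-fold only).
#' @param seed Integer seed; splits are deterministic given the seed.
#' @return A list of `k` (or 1) elements, each `list(train = ids, test = ids)`.
#' @export
split_dataset <- function(manifest, scheme = c("kfold", "holdout"),
                          train_fraction = 0.9, k = 10L,
                          sampling = c("balanced", "random"), seed = 1L) {
  scheme <- match.arg(scheme)
  sampling <- match.arg(sampling)
  ids <- manifest$record_id
  labels <- manifest$label
  n <- length(ids)

  if (scheme == "holdout") {
    stopifnot(train_fraction > 0, train_fraction < 1)
    set.seed(seed)
    n_train <- round(n * train_fraction)
    train_idx <- sample.int(n, n_train)
    return(list(list(train = ids[train_idx], test = ids[-train_idx])))
  }

  stopifnot(k >= 2L)
  set.seed(seed)
  fold_of <- integer(n)
  if (sampling == "balanced") {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      per <- length(idx) %/% k
      if (per < 1L)
        stop("class '", cl, "' too small for balanced ", k, "-fold split")
      idx <- sample(idx)
      use <- idx[seq_len(per * k)]
      fold_of[use] <- rep(seq_len(k), each = per)
      # leftovers (class size not divisible by k) spread round-robin
      left <- setdiff(idx, use)
      if (length(left)) fold_of[left] <- sample(seq_len(k), length(left))
    }
  } else {
    idx <- sample.int(n)
    per <- n %/% k
    fold_of[idx[seq_len(per * k)]] <- rep(seq_len(k), each = per)
    left <- idx[-seq_len(per * k)]
    if (length(left)) fold_of[left] <- sample(seq_len(k), length(left))
  }
  lapply(seq_len(k), function(f) {
    list(train = ids[fold_of != f], test = ids[fold_of == f])
  })
}
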