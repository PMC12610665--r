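test_that("a 2 s recording at 60 bpm contains exactly two S1 and two S2 events", {
  sr <- synth_recording(synth_config(fs = 2000, duration_sec = c(2, 2),
                                     heart_rate_bpm = c(60, 60),
                                     class_spec = "N", seed = 3L))
  expect_length(sr$ground_truth$s1_times, 2L)
  expect_length(sr$ground_truth$s2_times, 2L)
  expect_true(all(diff(sr$ground_truth$s1_times) > 0.9))
})

test_that("generation is deterministic and a zero-amplitude murmur reduces to N", {
  a <- synth_recording(synth_config(class_spec = "MS", seed = 5L))
  b <- synth_recording(synth_config(class_spec = "MS", seed = 5L))
  expect_identical(a$recording$samples, b$recording$samples)

  as0 <- synth_recording(synth_config(class_spec = "AS", murmur_amplitude = 0,
                                      seed = 7L))
  nn <- synth_recording(synth_config(class_spec = "N", seed = 7L))
  expect_identical(as0$recording$samples, nn$recording$samples)
})

test_that("murmur windows fall in the expected cycle phase per class", {
  cfg <- function(cl) synth_config(fs = 2000, duration_sec = c(3, 3),
                                   heart_rate_bpm = c(75, 75),
                                   class_spec = cl, seed = 9L)
  sys_mid <- function(sr) {
    gt <- sr$ground_truth
    vapply(gt$murmur_windows, function(w) mean(w), numeric(1))
  }
  mr <- synth_recording(cfg("MR"))
  gt <- mr$ground_truth
  # systolic: window midpoints lie between an S1 and the following S2
  for (m in sys_mid(mr)) {
    s1 <- max(gt$s1_times[gt$s1_times <= m])
    expect_lt(m - s1, 0.38 * 60 / 75)
  }
  ms <- synth_recording(cfg("MS"))
  gtm <- ms$ground_truth
  # diastolic: window starts after the S2 of its cycle
  for (w in gtm$murmur_windows) {
    expect_true(any(gtm$s2_times < w[1] &
                      gtm$s2_times > w[1] - 60 / 75))
  }
  expect_length(synth_recording(cfg("N"))$ground_truth$murmur_windows, 0L)
})

test_that("the energy ledger matches a Parseval check on the waveform", {
  sr <- synth_recording(synth_config(fs = 8000, class_spec = "MVP",
                                     target_ber = 2, seed = 13L))
  x <- sr$recording$samples
  n <- length(x)
  p <- abs(stats::fft(x))^2
  f <- (seq_len(n) - 1) * 8000 / n
  half <- f > 0 & f <= 4000
  inb <- half & f >= 20 & f <= 700
  led <- sr$ground_truth$ledger
  expect_equal(led$in_band, sum(p[inb]), tolerance = 1e-9)
  expect_equal(led$out_band, sum(p[half & !inb]), tolerance = 1e-9)
  # and ledger components account for the total spectral energy
  expect_equal(led$in_band + led$out_band, sum(p[half]), tolerance = 1e-9)
})

test_that("lowering the target BER injects strictly more noise power", {
  outs <- vapply(c(5, 1, 0.2), function(tb) {
    sr <- synth_recording(synth_config(fs = 2000, class_spec = "N",
                                       target_ber = tb, seed = 21L))
    sr$ground_truth$ledger$out_band / sr$ground_truth$ledger$in_band
  }, numeric(1))
  expect_true(all(diff(outs) > 0))
})

test_that("five-class dataset writes n_per_class files per class with durations in range", {
  dir <- withr::local_tempdir()
  man <- synth_dataset(dir, n_per_class = 3L, classes = "five",
                       cfg = synth_config(fs = 2000), seed = 2L)
  expect_equal(nrow(man), 15L)
  expect_equal(as.vector(table(man$label)), rep(3L, 5))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  durations <- vapply(man$path, function(p) {
    r <- read_wav(p); length(r$samples) / r$fs
  }, numeric(1))
  expect_true(all(durations >= 1.2 & durations <= 4))
  # regenerating with the same seed reproduces identical audio
  dir2 <- withr::local_tempdir()
  man2 <- synth_dataset(dir2, n_per_class = 3L, classes = "five",
                        cfg = synth_config(fs = 2000), seed = 2L)
  expect_identical(read_wav(man$path[1])$samples, read_wav(man2$path[1])$samples)
})

test_that("binary dataset honors the 4:1 normal:abnormal imbalance", {
  dir <- withr::local_tempdir()
  man <- synth_dataset(dir, n_per_class = 5L, classes = "binary", imbalance = 4,
                       cfg = synth_config(fs = 2000), seed = 3L)
  counts <- table(man$label)
  expect_equal(unname(counts["abnormal"]), 5L)
  expect_equal(unname(counts["normal"]), 20L)
  expect_equal(attr(man, "label_set"), c("normal", "abnormal"))
})

test_that("synthetic classes are separable by a small trained model", {
  feats <- synth_feature_set(12L, fs = 2000, seed = 5L,
                             classes = c("AS", "MS", "N"))
  labels <- attr(feats, "labels")
  model <- build_model(wcnn_architecture(17L, 13L, 3L), seed = 4L)
  model <- train_wcnn(model, feats, labels,
                      train_config(epochs = 6L, batch_size = 12L, seed = 4L),
                      label_set = c("AS", "MS", "N"))
  expect_gt(tail(model$history$train_accuracy, 1), 0.9)
})
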