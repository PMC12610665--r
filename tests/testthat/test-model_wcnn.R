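test_that("KWC forward matches element-wise arithmetic on forced examples", {
  f <- array(c(1, 3, 2, 4), c(2, 2, 1))          # single channel [[1,2],[3,4]]
  out <- kwc_forward(f)
  expect_equal(as.vector(out), c(2.5, 7.5, 5, 10))  # w = 2.5

  expect_equal(kwc_forward(array(0, c(3, 4, 2))), array(0, c(3, 4, 2)))

  two <- array(c(rep(2, 4), rep(0.5, 4)), c(2, 2, 2))
  out2 <- kwc_forward(two)
  expect_equal(out2[, , 1], matrix(4, 2, 2))     # amplified
  expect_equal(out2[, , 2], matrix(0.25, 2, 2))  # attenuated
})

test_that("KWC is positively homogeneous of degree 2", {
  set.seed(8)
  for (a in c(0.3, 2, 11)) {
    f <- array(stats::rnorm(60), c(5, 4, 3))
    expect_equal(kwc_forward(a * f), a^2 * kwc_forward(f), tolerance = 1e-12)
  }
})

test_that("forward shapes reproduce the printed layer table", {
  shapes <- forward_shapes(wcnn_architecture())
  expect_equal(shapes[[1]], c(16L, 12L, 32L))
  expect_equal(shapes[[2]], c(15L, 11L, 64L))
  expect_equal(shapes[[3]], c(7L, 5L, 64L))
  expect_equal(shapes[[5]], 2240L)

  shapes2 <- forward_shapes(wcnn_architecture(13L, 9L))
  expect_equal(shapes2[[3]], c(5L, 3L, 64L))
  expect_equal(shapes2[[5]], 960L)

  tiny <- architecture_spec(c(2, 2, 1),
                            list(layer_conv(1, c(2, 2), 1, batch_norm = FALSE),
                                 layer_flatten(), layer_dense(2, "softmax")), 2)
  expect_equal(forward_shapes(tiny)[[1]], c(1L, 1L, 1L))
  expect_error(wcnn_architecture(2L, 2L), "kernel larger")
})

test_that("analytic parameter counts match the published architecture table", {
  arch <- wcnn_architecture()
  expect_equal(count_parameters(arch, per_layer = TRUE),
               c(160L, 8256L, 16448L, 0L, 0L, 286848L, 645L))
  expect_equal(count_parameters(arch), 312357L)
  expect_equal(count_parameters(wcnn_architecture(13L, 9L)), 148517L)
  single <- architecture_spec(c(1, 1, 1), list(layer_flatten(), layer_dense(1)), 1)
  expect_equal(count_parameters(single), 2L)     # weight + bias
})

test_that("analytic FLOP counts follow the conv/dense formulas", {
  expect_equal(count_flops(wcnn_architecture()), 4474112)
  one <- architecture_spec(c(1, 1, 1),
                           list(layer_conv(1, c(1, 1), 1, batch_norm = FALSE),
                                layer_flatten(), layer_dense(1)), 1)
  expect_equal(count_flops(one, per_layer = TRUE)[1], 2)   # all factors 1
  # dense 2240 -> 128 contributes 2 * 2240 * 128
  expect_equal(count_flops(wcnn_architecture(), per_layer = TRUE)[6], 573440)
})

test_that("odd and even MFCC dims can share a parameter count (stride drop)", {
  for (d in c(13L, 15L, 17L, 19L)) {
    a_odd <- wcnn_architecture(d, 13L)
    a_even <- wcnn_architecture(d + 1L, 13L)
    if (identical(forward_shapes(a_odd)[[3]], forward_shapes(a_even)[[3]])) {
      expect_identical(count_parameters(a_odd), count_parameters(a_even))
    }
  }
  # the published pairing: 14 and 15 dims agree, as do 16 and 17
  expect_identical(count_parameters(wcnn_architecture(14L, 13L)),
                   count_parameters(wcnn_architecture(15L, 13L)))
  expect_identical(count_parameters(wcnn_architecture(16L, 13L)),
                   count_parameters(wcnn_architecture(17L, 13L)))
})

test_that("a built model's trainable parameters equal the analytic count", {
  set.seed(10)
  for (rep in 1:3) {
    dims <- sample(9:20, 1)
    frames <- sample(7:16, 1)
    classes <- sample(2:6, 1)
    arch <- wcnn_architecture(dims, frames, classes)
    model <- build_model(arch, seed = rep)
    expect_identical(model_parameter_count(model, include_bn = FALSE),
                     count_parameters(arch))
  }
})

test_that("removing the KWC layer leaves the parameter count unchanged", {
  with_kwc <- wcnn_architecture()
  no_kwc <- architecture_spec(
    c(17L, 13L, 1L),
    Filter(function(ly) ly$kind != "kwc", with_kwc$layers),
    5L)
  expect_identical(count_parameters(no_kwc), count_parameters(with_kwc))
})

test_that("forward pass emits softmax rows summing to one", {
  arch <- wcnn_architecture(9L, 7L, 4L)
  model <- build_model(arch, seed = 2)
  feats <- lapply(1:6, function(i) matrix(stats::rnorm(63), 9, 7))
  probs <- predict_wcnn(model, feats)
  expect_identical(dim(probs), c(6L, 4L))
  expect_equal(rowSums(probs), rep(1, 6), tolerance = 1e-9)
  expect_true(all(probs >= 0))
})

test_that("backpropagation matches finite differences end to end", {
  arch <- wcnn_architecture(9L, 7L, 3L, dropout = 0)
  model <- build_model(arch, seed = 3)
  set.seed(14)
  n <- 3L
  x <- array(stats::rnorm(9 * 7 * n), c(9, 7, 1, n))
  y <- matrix(0, 3, n); y[cbind(sample(3, n, TRUE), 1:n)] <- 1
  loss_of <- function(m) {
    p <- predict_wcnn(m, x)
    -mean(rowSums(t(y) * log(pmax(p, 1e-12))))
  }
  fwd <- pcgwcnn:::forward_pass(model, x, train = FALSE, keep_cache = TRUE)
  bwd <- pcgwcnn:::backward_pass(model, fwd, (fwd$out - y) / n)
  eps <- 1e-5
  worst <- 0
  for (i in seq_along(model$params)) {
    p <- model$params[[i]]
    if (is.null(p)) next
    for (nm in intersect(names(p), c("w", "b", "gamma", "beta"))) {
      if (is.null(p[[nm]])) next
      g <- bwd$grads[[i]][[switch(nm, w = "dw", b = "db",
                                  gamma = "dgamma", beta = "dbeta")]]
      if (is.null(g)) next
      for (k in sample(length(p[[nm]]), min(3L, length(p[[nm]])))) {
        up <- model; up$params[[i]][[nm]][k] <- up$params[[i]][[nm]][k] + eps
        dn <- model; dn$params[[i]][[nm]][k] <- dn$params[[i]][[nm]][k] - eps
        num <- (loss_of(up) - loss_of(dn)) / (2 * eps)
        worst <- max(worst, abs(num - g[k]) / max(1e-6, abs(num) + abs(g[k])))
      }
    }
  }
  expect_lt(worst, 1e-5)
})
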