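test_that("the convolution kernel agrees with a naive reference", {
  set.seed(1)
  x <- randTensor(7, 6, 3, 2)
  w <- randTensor(3, 3, 3, 4)
  for (stride in 1:2) {
    got <- florafusion:::convF(x, w, stride, 1L)
    expect_equal(got, naiveConv(x, w, stride, 1L), tolerance = 1e-12)
  }
  w7 <- randTensor(1, 1, 3, 2)
  expect_equal(florafusion:::convF(x, w7, 2L, 0L),
               naiveConv(x, w7, 2L, 0L), tolerance = 1e-12)
})

test_that("max pooling matches a naive reference and routes gradients", {
  set.seed(2)
  x <- randTensor(8, 8, 2, 2)
  mp <- florafusion:::maxpool_forward_cpp(x, 3L, 2L, 1L)
  naive <- array(-Inf, dim = dim(mp$out))
  for (n in 1:2) for (c in 1:2)
    for (oi in 1:4) for (oj in 1:4) {
      ri <- max(1, 2 * oi - 2):min(8, 2 * oi)
      rj <- max(1, 2 * oj - 2):min(8, 2 * oj)
      naive[oi, oj, c, n] <- max(x[ri, rj, c, n])
    }
  expect_equal(mp$out, naive)
  g <- array(1, dim = dim(mp$out))
  dx <- florafusion:::maxpool_backward_cpp(g, mp$idx, dim(x))
  expect_equal(sum(dx), length(g))        # every unit of gradient lands once
  expect_lte(sum(dx != 0), length(g))     # only at selected maxima
})

test_that("batch normalisation matches its closed form in both modes", {
  set.seed(3)
  x <- randTensor(4, 4, 3, 5)
  gamma <- c(1.5, 0.5, 2); beta <- c(0, 1, -1)
  res <- florafusion:::bnF(x, gamma, beta, rep(0, 3), rep(1, 3),
                           training = TRUE)
  for (c in 1:3) {
    v <- x[, , c, ]
    expected <- gamma[c] * (v - mean(v)) /
      sqrt(mean((v - mean(v))^2) + 1e-5) + beta[c]
    expect_equal(res$y[, , c, ], expected, tolerance = 1e-10)
  }
  # eval mode uses the supplied running statistics
  res2 <- florafusion:::bnF(x, gamma, beta, c(0.2, 0, -0.1), c(1, 2, 0.5),
                            training = FALSE)
  expect_equal(res2$y[, , 1, ],
               gamma[1] * (x[, , 1, ] - 0.2) / sqrt(1 + 1e-5) + beta[1],
               tolerance = 1e-10)
})

test_that("analytic gradients match finite differences through the network", {
  spec <- tinySpec()
  m <- buildTwoStream(spec, seed = 7)
  set.seed(9)
  xf <- randTensor(16, 16, 3, 3)
  xb <- randTensor(16, 16, 3, 3)
  y <- c(1L, 2L, 3L)
  lossAt <- function(mm) {
    fw <- florafusion:::modelForward(mm, list(f = xf, b = xb),
                                     training = TRUE)
    florafusion:::softmaxCE(fw$logits, y)$loss
  }
  fw <- florafusion:::modelForward(m, list(f = xf, b = xb), training = TRUE)
  ce <- florafusion:::softmaxCE(fw$logits, y)
  g <- florafusion:::modelBackward(m, fw$cache, ce$dlogits)
  eps <- 1e-5
  for (nm in sample(names(g), 12)) {
    i <- sample(length(m@params[[nm]]), 1)
    up <- m; up@params[[nm]][i] <- up@params[[nm]][i] + eps
    dn <- m; dn@params[[nm]][i] <- dn@params[[nm]][i] - eps
    num <- (lossAt(up) - lossAt(dn)) / (2 * eps)
    rel <- abs(num - g[[nm]][i]) / max(1e-6, abs(num) + abs(g[[nm]][i]))
    expect_lt(rel, 1e-4, label = paste("relative gradient error of", nm))
  }
})
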