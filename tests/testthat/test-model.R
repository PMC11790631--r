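test_that("the head adapts to the class count and ties break low", {
  spec18 <- ModelSpec(numClasses = 18L, stageChannels = c(4L, 4L, 6L, 8L, 10L),
                      fcDims = c(8L, 5L), inputSize = 32L)
  m <- buildTwoStream(spec18, seed = 1)
  pair <- list(front = randTensor(32, 32, 3), back = randTensor(32, 32, 3))
  out <- classifyPair(m, pair)
  expect_length(out$logits, 18L)
  out2 <- classifyPair(m, pair)
  expect_identical(out$logits, out2$logits)   # eval-mode determinism

  m3 <- buildTwoStream(tinySpec(numClasses = 3L), seed = 1)
  pair16 <- list(front = randTensor(16, 16, 3), back = randTensor(16, 16, 3))
  expect_length(classifyPair(m3, pair16)$logits, 3L)

  # all-equal logits -> lowest class index wins
  m3@params$fc5.W[] <- 0
  m3@params$fc5.b[] <- 0
  expect_equal(classifyPair(m3, pair16)$index, 1L)
  expect_equal(classifyPair(m3, pair16)$label, m3@classes[1])

  bad <- list(front = randTensor(8, 8, 3), back = randTensor(8, 8, 3))
  expect_error(classifyPair(m3, bad), "expects")
})

test_that("relabelling the streams together with the inputs changes nothing", {
  spec <- tinySpec()
  m <- buildTwoStream(spec, seed = 4)
  sw <- m
  swapName <- function(nm) {
    out <- nm
    out[startsWith(nm, "f.")] <- sub("^f\\.", "b.", nm[startsWith(nm, "f.")])
    out[startsWith(nm, "b.")] <- sub("^b\\.", "f.", nm[startsWith(nm, "b.")])
    out
  }
  names(sw@params) <- swapName(names(m@params))
  names(sw@state) <- swapName(names(m@state))
  k <- spec@fcDims[2]
  sw@params$fc5.W <- m@params$fc5.W[, c((k + 1):(2 * k), 1:k)]
  x1 <- randTensor(16, 16, 3, 2); x2 <- randTensor(16, 16, 3, 2)
  a <- florafusion:::modelForward(m, list(f = x1, b = x2))$logits
  b <- florafusion:::modelForward(sw, list(f = x2, b = x1))$logits
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("without cross terms the streams are independent single networks", {
  spec <- tinySpec(mode = "concat_only")
  m <- buildTwoStream(spec, seed = 5)
  single <- buildTwoStream(tinySpec(mode = "front_only"), seed = 5)
  shared <- grep("^f\\.", names(single@params), value = TRUE)
  for (nm in shared) single@params[[nm]] <- m@params[[nm]]
  for (nm in grep("^f\\.", names(single@state), value = TRUE))
    single@state[[nm]] <- m@state[[nm]]
  x1 <- randTensor(16, 16, 3, 2); x2 <- randTensor(16, 16, 3, 2)
  two <- florafusion:::modelForward(m, list(f = x1, b = x2))
  one <- florafusion:::modelForward(single, list(f = x1))
  expect_identical(two$cache$head$gOut$f, one$cache$head$gOut$f)
})

test_that("parameter counts follow the layer arithmetic", {
  spec <- ModelSpec(numClasses = 18L)
  m <- buildTwoStream(spec, seed = 1)
  expect_equal(length(m@params$fc5.W) + length(m@params$fc5.b),
               64 * 18 + 18)                      # 1,170
  expect_equal(length(m@params$f.conv1.W), 7 * 7 * 3 * 64)  # 9,408
  # a fused model can never have fewer parameters than one stream
  full <- buildTwoStream(fastModelSpec(), seed = 1)
  front <- buildTwoStream(fastModelSpec(mode = "front_only"), seed = 1)
  expect_gte(countParameters(full), countParameters(front))
  # and the canonical two-stream model's total, for the record
  expect_gt(countParameters(m), 2e7)
})

test_that("residual blocks follow the additive equations", {
  set.seed(8)
  blk <- makeResidualBlock(6L, 6L, stride = 1L, cross = TRUE, seed = 2)
  xf <- randTensor(4, 4, 6, 2); xb <- randTensor(4, 4, 6, 2)

  zeroF <- blk
  zeroF$params$p1.convb.W[] <- 0
  zeroF$params$p2.convb.W[] <- 0
  out <- crossStreamBlockForward(xf, xb, zeroF)
  expect_equal(out$front, xf + xb, tolerance = 1e-14)
  expect_equal(out$back, xf + xb, tolerance = 1e-14)

  # x_f = x_b = x with tied weights: cross output = single-stream + x
  tied <- blk
  for (nm in grep("^p1\\.", names(blk$params), value = TRUE))
    tied$params[[sub("^p1", "p2", nm)]] <- blk$params[[nm]]
  sblk <- list(params = blk$params[grep("^p1\\.", names(blk$params))],
               state = blk$state[grep("^p1\\.", names(blk$state))],
               lay = blk$lay, cross = FALSE)
  x <- randTensor(4, 4, 6, 2)
  crossOut <- crossStreamBlockForward(x, x, tied)
  singleOut <- residualBlockForward(x, sblk)
  expect_equal(crossOut$front, singleOut + x, tolerance = 1e-12)
  expect_equal(crossOut$back, singleOut + x, tolerance = 1e-12)

  expect_error(crossStreamBlockForward(xf, randTensor(4, 4, 5, 2), blk),
               "identical shapes")
})

test_that("FC fusion reduces to its closed forms", {
  set.seed(10)
  yf <- matrix(stats::rnorm(32 * 4), 32, 4)
  yb <- matrix(stats::rnorm(32 * 4), 32, 4)
  # identity G, alpha = 1/3: own + other/3 elementwise
  out <- fcFusionForward(yf, yb, alpha = 1 / 3)
  expect_equal(out$front, yf + yb / 3, tolerance = 1e-14)
  expect_equal(out$back, yb + yf / 3, tolerance = 1e-14)
  # alpha = 0: independent streams, bit-exact
  out0 <- fcFusionForward(yf, yb, alpha = 0)
  expect_identical(out0$front, yf)
  expect_identical(out0$back, yb)
  # equal inputs: (1 + alpha) * y through G
  G <- florafusion:::initLinear(32, 8)
  outEq <- fcFusionForward(yf, yf, alpha = 0.25,
                           weights = list(front = G, back = G))
  expect_equal(outEq$front, florafusion:::linearF(1.25 * yf, G$W, G$b),
               tolerance = 1e-12)
  expect_error(fcFusionForward(yf, yb[1:10, ]), "identical dimensions")
})
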