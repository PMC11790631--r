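diskImage <- function(S = 64, r = 20, hi = 255, lo = 0) {
  cc <- (S + 1) / 2
  rr <- sqrt(outer(seq_len(S) - cc, rep(0, S), "+")^2 +
             t(outer(seq_len(S) - cc, rep(0, S), "+"))^2)
  img <- array(lo, dim = c(S, S, 3))
  for (ch in 1:3) img[, , ch] <- ifelse(rr <= r, hi, lo)
  img
}

test_that("edge detection finds contours and nothing on flat images", {
  expect_false(any(detectEdges(array(128, dim = c(24, 24, 3)))))

  # disk: edges must lie on an annulus around the true boundary, in
  # agreement with brute-force gradient-magnitude thresholding
  S <- 64; r <- 20; cc <- (S + 1) / 2
  mask <- detectEdges(diskImage(S, r))
  px <- which(mask, arr.ind = TRUE)
  expect_gt(nrow(px), 0.5 * 2 * pi * r)
  d <- sqrt((px[, 1] - cc)^2 + (px[, 2] - cc)^2)
  expect_true(all(abs(d - r) <= 2.5))
  gray <- florafusion:::rgbToGray(diskImage(S, r))
  gx <- (gray[, c(2:S, S)] - gray[, c(1, 1:(S - 1))]) / 2
  gy <- (gray[c(2:S, S), ] - gray[c(1, 1:(S - 1)), ]) / 2
  brute <- sqrt(gx^2 + gy^2) >= 50
  bp <- which(brute, arr.ind = TRUE)
  near <- vapply(seq_len(nrow(px)), function(i)
    min((bp[, 1] - px[i, 1])^2 + (bp[, 2] - px[i, 2])^2), 1.0)
  expect_true(all(near <= 2^2))

  # synthetic flower: nonempty mask tracking the recorded petal outline
  set.seed(11)
  fl <- renderFlower("front", 2, 64, noiseSigma = 0)
  m <- detectEdges(fl$image)
  expect_gt(sum(m), 0)
  bd <- fl$meta$boundary
  ep <- which(m, arr.ind = TRUE)
  covered <- vapply(seq_len(nrow(bd)), function(i)
    min((ep[, 1] - bd[i, 1])^2 + (ep[, 2] - bd[i, 2])^2) <= 2^2, TRUE)
  expect_gt(mean(covered), 0.5)
})

trackerImage <- function(H, W) {
  img <- array(0, dim = c(H, W, 3))
  img[, , 1] <- row(matrix(0, H, W))
  img[, , 2] <- col(matrix(0, H, W))
  img
}

test_that("the crop square is centred, clipped and minimal", {
  img <- trackerImage(40, 40)
  mask <- matrix(FALSE, 40, 40)
  mask[10, 10] <- TRUE; mask[20, 30] <- TRUE
  cr <- minSquareCrop(img, mask)
  expect_equal(dim(cr)[1:2], c(21, 21))
  expect_equal(range(cr[, , 1]), c(5, 25))
  expect_equal(range(cr[, , 2]), c(10, 30))

  expect_identical(minSquareCrop(img, matrix(FALSE, 40, 40)), img)

  mask1 <- matrix(FALSE, 40, 40); mask1[17, 23] <- TRUE
  expect_equal(dim(minSquareCrop(img, mask1))[1:2], c(8, 8))

  expect_error(minSquareCrop(img, matrix(FALSE, 10, 10)), "dimensions")

  # property: contains all edges, no strictly smaller square does
  # (square canvases: on oblong images the square is capped at the short
  # side by the clipping rule, and containment can be impossible)
  set.seed(42)
  for (k in 1:20) {
    H <- W <- sample(15:40, 1)
    mask <- matrix(stats::runif(H * W) < 0.02, H, W)
    if (!any(mask)) next
    cr <- minSquareCrop(trackerImage(H, W), mask, minSide = 1L)
    side <- dim(cr)[1]
    expect_equal(side, dim(cr)[2])
    rows <- range(which(rowSums(mask) > 0))
    cols <- range(which(colSums(mask) > 0))
    expect_true(min(cr[, , 1]) <= rows[1] && max(cr[, , 1]) >= rows[2])
    expect_true(min(cr[, , 2]) <= cols[1] && max(cr[, , 2]) >= cols[2])
    expect_equal(side, max(rows[2] - rows[1] + 1, cols[2] - cols[1] + 1))
  }
})

test_that("resizing always yields the square target shape", {
  expect_equal(dim(resizeImage(array(1, c(448, 448, 3)), 224)),
               c(224, 224, 3))
  img <- array(stats::runif(224 * 224 * 3), c(224, 224, 3))
  expect_equal(resizeImage(img, 224), img)
  expect_equal(dim(resizeImage(array(1, c(100, 300, 3)), 224)),
               c(224, 224, 3))
})

test_that("rotation is bounded, seeded and symmetric on disks", {
  img <- array(stats::runif(32 * 32 * 3) * 255, c(32, 32, 3))
  expect_identical(augmentRotation(img, 0), img)
  set.seed(5); a <- augmentRotation(img, 15)
  set.seed(5); b <- augmentRotation(img, 15)
  expect_identical(a, b)

  disk <- diskImage(64, 18, hi = 200, lo = 40)
  rot <- augmentRotation(disk, 15, angle = 9)
  expect_equal(dim(rot), dim(disk))
  inner <- disk[10:54, 10:54, ]  # ignore corners exposed by the black fill
  rotInner <- rot[10:54, 10:54, ]
  expect_lt(mean(abs(rotInner - inner)), 4)
})

test_that("normalisation follows (x/255 - mean)/std per channel", {
  one <- array(255, c(2, 2, 3))
  expect_equal(normalizeImage(one, mean = rep(0, 3), std = rep(1, 3)),
               array(1, c(2, 2, 3)))
  mid <- array(127.5, c(1, 1, 3))
  out <- normalizeImage(mid, mean = rep(0.5, 3), std = rep(0.5, 3))
  expect_equal(as.vector(out), rep(0, 3), tolerance = 1e-12)
  zero <- array(0, c(2, 2, 3))
  out <- normalizeImage(zero, mean = c(0.1, 0.2, 0.3), std = c(1, 2, 4))
  expect_equal(out[1, 1, ], c(-0.1, -0.1, -0.075))
  expect_error(normalizeImage(one, std = c(0, 1, 1)), "positive")
})

test_that("the pipeline emits normalised square tensors deterministically", {
  set.seed(3)
  fl <- renderFlower("front", 1, 48, noiseSigma = 2)
  bk <- renderFlower("back", 1, 48, noiseSigma = 2)
  pair <- list(front = fl$image, back = bk$image, pair_id = "p1")
  cfg <- PreprocessConfig(targetSize = 32L)
  out1 <- preprocessPipeline(pair, cfg)
  expect_equal(dim(out1$front), c(32, 32, 3))
  expect_equal(dim(out1$back), c(32, 32, 3))
  expect_true(all(is.finite(out1$front)))
  out2 <- preprocessPipeline(pair, cfg)
  expect_identical(out1$front, out2$front)   # augment disabled -> bitwise

  # the crop window tightly contains the generator's known flower extent
  tracker <- trackerImage(48, 48)
  mask <- detectEdges(fl$image, cfg)
  cr <- minSquareCrop(tracker, mask)
  bbox <- fl$meta$bbox
  expect_lte(min(cr[, , 1]), bbox[1] + 3)
  expect_gte(max(cr[, , 1]), bbox[2] - 3)
  expect_lte(min(cr[, , 2]), bbox[3] + 3)
  expect_gte(max(cr[, , 2]), bbox[4] - 3)
})
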