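# Visual analyses: gradient-weighted class activation maps per view and a
# 2-D embedding of the fused 64-dimensional feature vectors.

#' Gradient-weighted class activation map
#'
#' Plain CAM is ill-defined for this head (three FC layers separate the
#' convolutional features from the logits), so the map is gradient-weighted:
#' the gradient of the target-class logit at each stream's final
#' convolutional feature map is channel-averaged into weights, the weighted
#' activation sum is ReLU-rectified, min-max normalised to `[0, 1]` and
#' bilinearly upsampled to the input size. One map per view.
#'
#' @param model a trained [TwoStreamModel-class].
#' @param pair preprocessed pair with `front`/`back` tensors.
#' @param targetClass class index (1-based) or label.
#' @param stage convolutional stage (1-4) whose feature maps are weighted.
#'   The default picks the deepest stage whose spatial side is at least 4
#'   pixels: the final 7x7 stage for canonical 224-pixel inputs, an earlier
#'   stage for small desk-scale inputs whose final stage is spatially
#'   degenerate (1x1).
#' @return list of matrices in `[0, 1]` named by view (`front`, `back`).
#' @export
classActivationMap <- function(model, pair, targetClass, stage = NULL) {
  spec <- model@spec
  if (is.character(targetClass))
    targetClass <- match(targetClass, model@classes)
  if (is.na(targetClass) || targetClass < 1 || targetClass > spec@numClasses)
    stop("target class out of range")
  if (is.null(stage)) {
    sh <- forwardShapes(spec)
    sides <- vapply(1:4, function(i) sh[[paste0("conv", i + 1)]][1], 1.0)
    stage <- max(c(1L, which(sides >= 4)))
  }
  stopifnot(stage %in% 1:4)
  asBatch <- function(x)
    if (length(dim(x)) == 3) array(x, dim = c(dim(x), 1)) else x
  views <- list(f = asBatch(pair$front), b = asBatch(pair$back))
  fw <- modelForward(model, views, training = FALSE)
  dLogits <- matrix(0, spec@numClasses, 1)
  dLogits[targetClass, 1] <- 1
  g <- modelBackward(model, fw$cache, dLogits, wantActGrads = TRUE)
  stageGrads <- attr(g, "stageGrads")
  out <- list()
  viewName <- c(f = "front", b = "back")
  for (st in streamKeys(spec)) {
    act <- fw$cache$stream[[st]]$stageOut[[stage]]  # (H, W, C, 1)
    grad <- stageGrads[[st]][[stage]]
    w <- apply(grad[, , , 1, drop = FALSE], 3, mean)  # channel weights
    m <- matrix(0, dim(act)[1], dim(act)[2])
    for (c in seq_along(w)) m <- m + w[c] * act[, , c, 1]
    m[m < 0] <- 0
    rng <- range(m)
    m <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
    up <- EBImage::resize(m, w = spec@inputSize, h = spec@inputSize)
    up <- pmin(pmax(matrix(up, spec@inputSize, spec@inputSize), 0), 1)
    out[[viewName[[st]]]] <- up
  }
  out
}

#' Write a heatmap overlay PNG
#'
#' @param map matrix in `[0, 1]` from [classActivationMap()].
#' @param path output PNG path.
#' @param image optional raw (H, W, 3) image (0..255) to blend under the map.
#' @return `path`, invisibly.
#' @export
writeHeatmapPNG <- function(map, path, image = NULL) {
  S <- nrow(map)
  heat <- array(0, dim = c(S, S, 3))
  heat[, , 1] <- map
  heat[, , 3] <- 1 - map
  if (!is.null(image)) {
    base <- resizeImage(image, S) / 255
    heat <- 0.5 * base + 0.5 * heat
  }
  png::writePNG(pmin(pmax(heat, 0), 1), path)
  invisible(path)
}

#' Embed fused features in two dimensions
#'
#' Extracts the 64-dimensional fused vector (the concatenation of the two
#' 32-d stream features fed to the final classifier; per-stream 32-d
#' vectors via `features = "stream"`) for every sample and embeds them
#' with t-SNE under a fixed seed.
#'
#' @param model a trained [TwoStreamModel-class].
#' @param data preprocessed data list (`front`, `back`, `labels`,
#'   optionally `classes`) or a [DatasetManifest-class].
#' @param features `"fused"` (64-d concatenation) or `"stream"` (front
#'   stream's 32-d vector).
#' @param perplexity,seed embedding settings.
#' @return data.frame with `x`, `y`, `label`.
#' @export
embedFeatures <- function(model, data, features = c("fused", "stream"),
                          perplexity = 10, seed = 1L) {
  features <- match.arg(features)
  if (is(data, "DatasetManifest")) {
    cache <- prepCache(data, model@preprocess)
    data <- finalizeTensors(cache, seq_along(cache$labels), model@preprocess)
  }
  n <- length(data$labels)
  feats <- NULL
  for (start in seq(1, n, by = 64)) {
    idx <- start:min(start + 63, n)
    views <- list(f = data$front[, , , idx, drop = FALSE],
                  b = data$back[, , , idx, drop = FALSE])
    fw <- modelForward(model, views, training = FALSE)
    fm <- t(fw$fused)
    if (features == "stream")
      fm <- fm[, seq_len(model@spec@fcDims[2]), drop = FALSE]
    feats <- rbind(feats, fm)
  }
  Y <- tsneEmbed(feats, perplexity = perplexity, seed = seed)
  labels <- if (!is.null(data$classes)) data$classes[data$labels]
            else model@classes[data$labels]
  data.frame(x = Y[, 1], y = Y[, 2], label = labels)
}

#' Write an embedding scatter plot and CSV
#'
#' @param embedding data.frame from [embedFeatures()].
#' @param csvPath output CSV path (x, y, label).
#' @param pngPath optional scatter PNG path.
#' @return `csvPath`, invisibly.
#' @export
writeEmbedding <- function(embedding, csvPath, pngPath = NULL) {
  utils::write.csv(embedding, csvPath, row.names = FALSE)
  if (!is.null(pngPath)) {
    grDevices::png(pngPath, width = 600, height = 600)
    on.exit(grDevices::dev.off())
    lab <- factor(embedding$label)
    graphics::plot(embedding$x, embedding$y, col = as.integer(lab),
                   pch = 19, xlab = "t-SNE 1", ylab = "t-SNE 2",
                   main = "Fused feature embedding")
    graphics::legend("topright", legend = levels(lab),
                     col = seq_along(levels(lab)), pch = 19, cex = 0.7)
  }
  invisible(csvPath)
}
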