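# Shared fixtures, built once per test run.

.fixtures <- new.env()

# Default-condition synthetic dataset (6 classes x 20 pairs, 64 px).
synthManifest <- function() {
  if (is.null(.fixtures$man)) {
    dir <- file.path(tempdir(), "florafusion-synth")
    .fixtures$man <- generateDataset(SynthSpec(), dir)
  }
  .fixtures$man
}

# Edge-cropped + resized tensors for the shared dataset (32 px profile).
synthCache <- function() {
  if (is.null(.fixtures$cache))
    .fixtures$cache <- florafusion:::prepCache(synthManifest(),
                                               fastPreprocessConfig())
  .fixtures$cache
}

# One trained fused model on the shared dataset (fast profile).
trainedResult <- function() {
  if (is.null(.fixtures$trained)) {
    .fixtures$trained <- runRepeatedExperiment(
      synthManifest(), fastModelSpec(),
      ExperimentProtocol(nRepeats = 1L, seed = 7L),
      fastPreprocessConfig(), fastSchedules(), cache = synthCache())
  }
  .fixtures$trained
}

# Tiny architecture for gradient/algebra tests.
tinySpec <- function(mode = "two_stream_full", numClasses = 3L) {
  ModelSpec(numClasses = numClasses, stageChannels = c(4L, 4L, 6L, 8L, 10L),
            fcDims = c(8L, 5L), inputSize = 16L, mode = mode)
}

randTensor <- function(...) {
  d <- c(...)
  array(stats::rnorm(prod(d)), dim = d)
}

# A small on-disk manifest with real PNG pairs.
makeToyManifest <- function(dir, nClasses = 2L, perClass = 3L, size = 16L) {
  dir.create(file.path(dir, "img"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (c in seq_len(nClasses)) for (i in seq_len(perClass)) {
    pid <- sprintf("c%d_i%d", c, i)
    fp <- file.path("img", paste0(pid, "_f.png"))
    bp <- file.path("img", paste0(pid, "_b.png"))
    png::writePNG(array(stats::runif(size * size * 3), c(size, size, 3)),
                  file.path(dir, fp))
    png::writePNG(array(stats::runif(size * size * 3), c(size, size, 3)),
                  file.path(dir, bp))
    rows[[length(rows) + 1]] <- data.frame(
      pair_id = pid, front_path = fp, back_path = bp,
      class_label = paste0("cls", c), origin = "toy")
  }
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  path
}

# Independent naive 2-D convolution oracle ((H,W,C,N) x (kh,kw,C,F)).
naiveConv <- function(x, w, stride, pad) {
  d <- dim(x); wd <- dim(w)
  Ho <- (d[1] + 2 * pad - wd[1]) %/% stride + 1
  Wo <- (d[2] + 2 * pad - wd[2]) %/% stride + 1
  out <- array(0, dim = c(Ho, Wo, wd[4], d[4]))
  for (n in seq_len(d[4])) for (f in seq_len(wd[4]))
    for (oi in seq_len(Ho)) for (oj in seq_len(Wo)) {
      acc <- 0
      for (c in seq_len(d[3])) for (di in seq_len(wd[1]))
        for (dj in seq_len(wd[2])) {
          i <- (oi - 1) * stride - pad + di
          j <- (oj - 1) * stride - pad + dj
          if (i >= 1 && i <= d[1] && j >= 1 && j <= d[2])
            acc <- acc + x[i, j, c, n] * w[di, dj, c, f]
        }
      out[oi, oj, f, n] <- acc
    }
  out
}
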