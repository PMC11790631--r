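test_that("front renders have the requested number of petal components", {
  for (cue in c(1L, 2L, 3L)) {
    set.seed(cue)
    fl <- renderFlower("front", cue, 64, noiseSigma = 0)
    k <- florafusion:::frontCueParams(cue)$petalCount
    lbl <- EBImage::bwlabel(fl$meta$petalMask)
    expect_equal(max(lbl), k)
  }
})

test_that("rendering is deterministic and bounded by its bounding box", {
  set.seed(9); a <- renderFlower("back", 2, 48, noiseSigma = 0)
  set.seed(9); b <- renderFlower("back", 2, 48, noiseSigma = 0)
  expect_identical(a$image, b$image)

  set.seed(10)
  fl <- renderFlower("front", 1, 48, noiseSigma = 0)
  nonbg <- which(apply(abs(fl$image - 12) > 1, c(1, 2), any), arr.ind = TRUE)
  bbox <- fl$meta$bbox
  expect_true(all(nonbg[, 1] >= bbox[1] & nonbg[, 1] <= bbox[2]))
  expect_true(all(nonbg[, 2] >= bbox[3] & nonbg[, 2] <= bbox[4]))
})

test_that("datasets land on disk with matching manifest and metadata", {
  dir <- withr::local_tempdir()
  spec <- SynthSpec(nClasses = 4L, pairsPerClass = 5L, imageSize = 24L,
                    cueOverlap = 1, seed = 3L)
  man <- generateDataset(spec, dir)
  expect_equal(nSamples(man), 20L)
  expect_length(list.files(file.path(dir, "images")), 40L)
  expect_length(list.files(file.path(dir, "meta")), 20L)
  again <- readManifest(file.path(dir, "manifest.csv"))
  expect_identical(manifestRecords(again)$pair_id,
                   manifestRecords(man)$pair_id)
  meta <- jsonlite::read_json(list.files(file.path(dir, "meta"),
                                         full.names = TRUE)[1])
  expect_named(meta, c("pair_id", "class_label", "front", "back"))
})

test_that("front-identical class pairs render identically up to noise", {
  spec <- SynthSpec()
  tab <- florafusion:::cueAssignment(spec)
  # classes 1 and 2 share a front cue by construction
  expect_equal(tab$front_cue[1], tab$front_cue[2])
  expect_false(tab$back_cue[1] == tab$back_cue[2])
  cues1 <- florafusion:::frontCueParams(tab$front_cue[1])
  cues2 <- florafusion:::frontCueParams(tab$front_cue[2])
  set.seed(77); a <- renderFlower("front", cues1, 32, noiseSigma = 0)
  set.seed(77); b <- renderFlower("front", cues2, 32, noiseSigma = 0)
  expect_identical(a$image, b$image)
})

test_that("separability bounds follow from cue enumeration", {
  spec4 <- SynthSpec(nClasses = 4L, cueOverlap = 1)
  tab <- florafusion:::cueAssignment(spec4)
  # brute-force: best decision per front-cue group gets one class right
  bruteBound <- function(groups) {
    acc <- 0
    for (g in unique(groups)) acc <- acc + 1   # one correct class per group
    acc / length(groups)
  }
  b <- bayesSeparability(spec4)
  expect_equal(b$front, bruteBound(tab$front_cue))
  expect_equal(b$front, 0.5)     # two front-identical pairs among 4 classes
  expect_equal(b$joint, 1)

  none <- bayesSeparability(SynthSpec(nClasses = 5L, cueOverlap = 0))
  expect_equal(none$front, 1)
  expect_equal(none$back, 1)

  ci <- bayesSeparability(SynthSpec())
  expect_equal(ci$front, 2 / 3)
  expect_equal(ci$back, 2 / 3)

  for (n in c(3L, 6L, 9L)) {
    sp <- SynthSpec(nClasses = n, cueOverlap = 2 / 3)
    tabN <- florafusion:::cueAssignment(sp)
    joint <- paste(tabN$front_cue, tabN$back_cue)
    expect_false(anyDuplicated(joint) > 0)     # joint cues stay a class key
    expect_equal(bayesSeparability(sp)$joint, 1)
  }
})
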