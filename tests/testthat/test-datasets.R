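test_that("manifests round-trip through CSV and validate their columns", {
  dir <- withr::local_tempdir()
  path <- makeToyManifest(dir, nClasses = 2L, perClass = 2L)
  man <- readManifest(path)
  expect_s4_class(man, "DatasetManifest")
  expect_equal(nSamples(man), 4L)
  expect_equal(classLabels(man), c("cls1", "cls2"))

  # a 3-row, 2-class table parses with file order preserved
  df <- manifestRecords(man)[c(1, 3, 2), ]
  p2 <- file.path(dir, "m2.csv")
  utils::write.csv(df, p2, row.names = FALSE, quote = FALSE)
  expect_equal(manifestRecords(readManifest(p2))$pair_id, df$pair_id)

  bad <- df[, setdiff(names(df), "back_path")]
  p3 <- file.path(dir, "m3.csv")
  utils::write.csv(bad, p3, row.names = FALSE, quote = FALSE)
  expect_error(readManifest(p3), "missing column")

  dup <- df
  dup$pair_id <- "same"
  p4 <- file.path(dir, "m4.csv")
  utils::write.csv(dup, p4, row.names = FALSE, quote = FALSE)
  expect_error(readManifest(p4), "duplicate")
})

test_that("splitting is a deterministic stratified 6:2:2 partition", {
  one <- DatasetManifest(data.frame(
    pair_id = sprintf("p%02d", 1:10), front_path = "x", back_path = "x",
    class_label = "a", origin = "o"))
  sp <- splitDataset(one, SplitSpec(seed = 7))
  expect_equal(vapply(sp, nSamples, 1L),
               c(train = 6L, val = 2L, test = 2L))
  sp2 <- splitDataset(one, SplitSpec(seed = 7))
  expect_identical(lapply(sp, function(m) sort(manifestRecords(m)$pair_id)),
                   lapply(sp2, function(m) sort(manifestRecords(m)$pair_id)))

  # 100 records over 4 classes: brute-force recount of per-class membership
  big <- DatasetManifest(data.frame(
    pair_id = sprintf("p%03d", 1:100), front_path = "x", back_path = "x",
    class_label = rep(c("a", "b", "c", "d"), each = 25), origin = "o"))
  sp <- splitDataset(big, SplitSpec(seed = 3))
  ids <- lapply(sp, function(m) manifestRecords(m)$pair_id)
  expect_length(unique(unlist(ids)), 100)          # coverage
  expect_equal(sum(lengths(ids)), 100)             # disjointness
  for (cl in c("a", "b", "c", "d")) {
    counts <- vapply(sp, function(m)
      sum(manifestRecords(m)$class_label == cl), 1L)
    expect_equal(unname(counts), c(15L, 5L, 5L))   # 60/20/20 %
  }
  tiny <- DatasetManifest(data.frame(
    pair_id = c("p1", "p2"), front_path = "x", back_path = "x",
    class_label = "a", origin = "o"))
  expect_error(splitDataset(tiny), "too small")
})

test_that("view pairs load as RGB arrays at their native resolution", {
  dir <- withr::local_tempdir()
  fp <- file.path(dir, "f.png"); bp <- file.path(dir, "b.png")
  png::writePNG(array(stats::runif(64 * 64 * 3), c(64, 64, 3)), fp)
  png::writePNG(array(stats::runif(32 * 48 * 3), c(32, 48, 3)), bp)
  rec <- data.frame(pair_id = "p1", front_path = fp, back_path = bp,
                    class_label = "a", origin = "o")
  pair <- loadViewPair(rec)
  expect_equal(dim(pair$front), c(64, 64, 3))
  expect_equal(dim(pair$back), c(32, 48, 3))
  expect_true(all(pair$front >= 0 & pair$front <= 255))

  gray <- file.path(dir, "g.png")
  png::writePNG(matrix(stats::runif(256), 16, 16), gray)
  rec$front_path <- gray
  pair <- loadViewPair(rec)
  expect_equal(dim(pair$front), c(16, 16, 3))
  expect_equal(pair$front[, , 1], pair$front[, , 3])

  corrupt <- file.path(dir, "c.png")
  writeLines("not a png", corrupt)
  rec$front_path <- corrupt
  expect_error(loadViewPair(rec), "decode")
  rec$front_path <- file.path(dir, "missing.png")
  expect_error(loadViewPair(rec), "not found")
})

test_that("the generator's manifest has one record per class/pair combination", {
  dir <- withr::local_tempdir()
  man <- generateDataset(SynthSpec(nClasses = 18L, pairsPerClass = 4L,
                                   imageSize = 24L, seed = 2L), dir)
  expect_equal(nSamples(man), 72L)
  expect_length(classLabels(man), 18L)
})
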