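tinyData <- function(n, spec, seed = 1) {
  set.seed(seed)
  list(front = randTensor(spec@inputSize, spec@inputSize, 3, n),
       back = randTensor(spec@inputSize, spec@inputSize, 3, n),
       labels = rep_len(seq_len(spec@numClasses), n))
}

test_that("freezing excludes exactly the shallow layers from updates", {
  spec <- tinySpec()
  m <- buildTwoStream(spec, seed = 2)
  expect_length(freezeShallow(m, 0L)@frozen, 0L)
  m13 <- freezeShallow(m, 13L)
  expect_gt(length(m13@frozen), 0)
  expect_lt(length(setdiff(names(m@params), m13@frozen)),
            length(names(m@params)))
  expect_false(any(grepl("\\.s4\\.|fc|bnf", m13@frozen)))
  expect_error(freezeShallow(m, 18L), "cannot freeze")
})

test_that("pretrained shallow weights are copied exactly and checked", {
  spec <- tinySpec()
  m <- buildTwoStream(spec, seed = 3)
  src <- list("conv1.W" = randTensor(7, 7, 3, 4),
              "s1.b1.conva.W" = randTensor(3, 3, 4, 4))
  m2 <- initFromPretrained(m, src)
  expect_identical(m2@params$f.conv1.W, src$`conv1.W`)
  expect_identical(m2@params$b.conv1.W, src$`conv1.W`)
  expect_identical(m2@params$`f.s1.b1.conva.W`, src$`s1.b1.conva.W`)
  expect_identical(m2@params$fc5.W, m@params$fc5.W)  # deep untouched
  bad <- list("conv1.W" = randTensor(7, 7, 3, 9))
  expect_error(initFromPretrained(m, bad), "shape mismatch")
  # random fallback: same seed, same initialisation
  a <- buildTwoStream(spec, seed = 11)
  b <- buildTwoStream(spec, seed = 11)
  expect_identical(initFromPretrained(a, NULL)@params, b@params)
})

test_that("staged training overfits a single pair and reproduces itself", {
  spec <- tinySpec(numClasses = 2L)
  train <- tinyData(1, spec, seed = 4)
  # batch norm reduces a single 1x1 deep feature to a constant, so the fit
  # happens in the head; a coarse rate and enough steps drive the loss down
  sched <- list(StageSchedule(0L, 150L, 1e-1, 1L))
  set.seed(5)
  m <- buildTwoStream(spec, seed = 5)
  tr <- trainStaged(m, train, train, sched)
  expect_lt(tail(tr$history$train_loss, 1), 0.01)
  expect_equal(unname(tr$bestValAccuracy), 1)
  # best checkpoint is never worse than the final epoch
  expect_gte(tr$bestValAccuracy, tail(tr$history$val_accuracy, 1))

  sched2 <- list(StageSchedule(13L, 2L, 1e-3, 2L),
                 StageSchedule(0L, 2L, 1e-3, 2L))
  set.seed(6); h1 <- trainStaged(buildTwoStream(spec, seed = 6),
                                 train, train, sched2)$history
  set.seed(6); h2 <- trainStaged(buildTwoStream(spec, seed = 6),
                                 train, train, sched2)$history
  expect_identical(h1, h2)
  expect_error(trainStaged(m, list(front = train$front, back = train$back,
                                   labels = integer(0)), train, sched),
               "empty")
})

test_that("training history can be streamed as JSON lines", {
  spec <- tinySpec(numClasses = 2L)
  train <- tinyData(2, spec, seed = 7)
  path <- withr::local_tempfile()
  set.seed(7)
  trainStaged(buildTwoStream(spec, seed = 7), train, train,
              list(StageSchedule(0L, 2L, 1e-3, 2L)), historyPath = path)
  lines <- readLines(path)
  expect_length(lines, 2L)
  rec <- jsonlite::fromJSON(lines[1])
  expect_named(rec, c("stage", "epoch", "train_loss", "val_accuracy"))
})

test_that("the repeated experiment aggregates per-repeat metrics", {
  man <- synthManifest()
  res <- runRepeatedExperiment(
    man, fastModelSpec(), ExperimentProtocol(nRepeats = 2L, seed = 31L),
    fastPreprocessConfig(), fastSchedules(), cache = synthCache())
  expect_equal(nrow(res$perRepeat), 2L)
  expect_equal(res$report@accuracy, mean(res$perRepeat$accuracy))
  expect_equal(sum(res$report@confusion), 2L * 24L)  # two 20% test splits
  expect_s4_class(res$lastModel, "TwoStreamModel")
})
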