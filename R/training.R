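# Staged transfer-learning training: stage one trains the deep layers with
# the shallow backbone frozen (20 epochs, lr 1e-3 at canonical scale), stage two
# fine-tunes everything at a lower rate (30 epochs, lr 1e-4), Adam with
# cross-entropy throughout, best-validation-accuracy checkpointing, and a
# repeated-split experiment protocol around it.

# Parameter names of the first `nConv` convolutional layers of one stream
# (stem first, then block convs in network order). Batch norms travel with
# their convolution; a projection shortcut travels with its block's first
# convolution.
convLayerParamNames <- function(st, nConv, blocksPerStage = 2L) {
  if (nConv == 0) return(character(0))
  out <- c(paste0(st, ".conv1.W"), paste0(st, ".bn1.gamma"),
           paste0(st, ".bn1.beta"))
  layer <- 1L
  for (i in 1:4) for (j in seq_len(blocksPerStage)) {
    pfx <- sprintf("%s.s%d.b%d.", st, i, j)
    layer <- layer + 1L  # conv a
    if (layer <= nConv)
      out <- c(out, paste0(pfx, c("conva.W", "bna.gamma", "bna.beta",
                                  "proj.W")))
    layer <- layer + 1L  # conv b
    if (layer <= nConv)
      out <- c(out, paste0(pfx, c("convb.W", "bnb.gamma", "bnb.beta")))
  }
  out
}

#' Freeze the shallow convolutional layers
#'
#' Excludes the first `nConvLayers` convolutional layers of every stream
#' (with their batch-norm parameters and any projection shortcut inside
#' those layers) from gradient updates. Frozen batch-norm layers also stop
#' updating their running statistics. `nConvLayers = 0` unfreezes
#' everything.
#'
#' @param model a [TwoStreamModel-class].
#' @param nConvLayers conv layers per stream to freeze (13 freezes the stem
#'   plus stages 1-3 of the canonical backbone).
#' @return the model with its `frozen` slot set.
#' @export
freezeShallow <- function(model, nConvLayers) {
  spec <- model@spec
  if (nConvLayers > countConvLayers(spec))
    stop("cannot freeze ", nConvLayers, " layers; the stream has ",
         countConvLayers(spec))
  frozen <- character(0)
  for (st in streamKeys(spec))
    frozen <- c(frozen,
                convLayerParamNames(st, nConvLayers, spec@blocksPerStage))
  model@frozen <- intersect(frozen, names(model@params))
  model
}

#' Initialise the shallow backbone from pretrained weights
#'
#' Copies a caller-supplied set of shallow weights (stream-agnostic names,
#' e.g. `conv1.W`, `s1.b1.conva.W`, ...) into the first 13 convolutional
#' layers of every stream; all remaining layers keep their (seeded) fresh
#' initialisation. With `source = NULL` the model keeps its random
#' initialisation entirely -- the offline fallback when no pretrained
#' weight file is available.
#'
#' @param model a [TwoStreamModel-class].
#' @param source named list of arrays, or NULL for the random fallback.
#' @param nConvLayers how many shallow layers the source covers (default 13).
#' @return the updated model.
#' @export
initFromPretrained <- function(model, source = NULL, nConvLayers = 13L) {
  if (is.null(source)) return(model)
  spec <- model@spec
  for (st in streamKeys(spec)) {
    targets <- convLayerParamNames(st, nConvLayers, spec@blocksPerStage)
    targets <- intersect(targets, names(model@params))
    for (nm in targets) {
      key <- sub(paste0("^", st, "\\."), "", nm)
      if (is.null(source[[key]])) next
      src <- source[[key]]
      if (!identical(dim2(src), dim2(model@params[[nm]])))
        stop("pretrained weight shape mismatch for ", key, ": source ",
             paste(dim2(src), collapse = "x"), ", model ",
             paste(dim2(model@params[[nm]]), collapse = "x"))
      model@params[[nm]] <- src
    }
  }
  model
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# Evaluation-mode prediction over a data list (front/back/labels) in chunks.
predictData <- function(model, data, batchSize = 64L) {
  n <- length(data$labels)
  pred <- integer(n)
  for (start in seq(1, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1, n)
    views <- list(f = data$front[, , , idx, drop = FALSE],
                  b = data$back[, , , idx, drop = FALSE])
    fw <- modelForward(model, views, training = FALSE)
    pred[idx] <- apply(fw$logits, 2, which.max)
  }
  pred
}

evaluateAccuracy <- function(model, data) {
  mean(predictData(model, data) == data$labels)
}

#' Staged training with best-checkpoint selection
#'
#' Runs the two-stage schedule: the shallow backbone frozen for stage one,
#' everything trainable in stage two, each stage with its own learning rate
#' and a fresh optimiser state. After every epoch the model is evaluated on
#' the validation set and the best-accuracy checkpoint (weights plus
#' batch-norm statistics) is kept; that checkpoint is returned.
#'
#' @param model a freshly initialised [TwoStreamModel-class].
#' @param trainData,valData lists with `front`/`back` (S, S, 3, N) tensors
#'   and integer `labels`.
#' @param schedules list of [StageSchedule-class] objects (default: the
#'   canonical 20-epoch frozen stage then 30-epoch fine-tune).
#' @param historyPath optional path; per-epoch records are appended as JSON
#'   lines `{stage, epoch, train_loss, val_accuracy}`.
#' @param verbose print per-epoch progress.
#' @return list with `model` (best checkpoint), `history` (data.frame) and
#'   `bestValAccuracy`.
#' @export
trainStaged <- function(model, trainData, valData,
                        schedules = canonicalSchedules(),
                        historyPath = NULL, verbose = FALSE) {
  nTrain <- length(trainData$labels)
  if (nTrain == 0 || length(valData$labels) == 0)
    stop("empty training or validation set")
  best <- list(acc = -Inf, params = model@params, state = model@state)
  history <- list()
  for (si in seq_along(schedules)) {
    sched <- schedules[[si]]
    model <- freezeShallow(model, sched@frozenConvLayers)
    opt <- optimInit(model@params, sched@optimizer)
    for (ep in seq_len(sched@epochs)) {
      ord <- sample.int(nTrain)
      losses <- c()
      for (start in seq(1, nTrain, by = sched@batchSize)) {
        idx <- ord[start:min(start + sched@batchSize - 1, nTrain)]
        views <- list(f = trainData$front[, , , idx, drop = FALSE],
                      b = trainData$back[, , , idx, drop = FALSE])
        fw <- modelForward(model, views, training = TRUE)
        model@state <- fw$state
        ce <- softmaxCE(fw$logits, trainData$labels[idx])
        if (!is.finite(ce$loss))
          stop("non-finite training loss at stage ", si, " epoch ", ep,
               " (learning rate ", sched@learningRate, ")")
        losses <- c(losses, ce$loss)
        grads <- modelBackward(model, fw$cache, ce$dlogits)
        up <- optimStep(model@params, grads, opt, sched@learningRate,
                        frozen = model@frozen)
        model@params <- up$params
        opt <- up$state
      }
      valAcc <- evaluateAccuracy(model, valData)
      if (valAcc > best$acc)
        best <- list(acc = valAcc, params = model@params,
                     state = model@state)
      rec <- list(stage = si, epoch = ep, train_loss = mean(losses),
                  val_accuracy = valAcc)
      history[[length(history) + 1]] <- rec
      if (!is.null(historyPath))
        cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
            file = historyPath, append = TRUE, sep = "")
      if (verbose)
        message(sprintf("stage %d epoch %2d  loss %.4f  val acc %.3f",
                        si, ep, mean(losses), valAcc))
    }
  }
  model@params <- best$params
  model@state <- best$state
  model@frozen <- character(0)
  list(model = model,
       history = do.call(rbind, lapply(history, as.data.frame)),
       bestValAccuracy = best$acc)
}

#' Canonical staged schedule
#' @return list of two [StageSchedule-class] stages (13 frozen/20 epochs/1e-3,
#'   then 0 frozen/30 epochs/1e-4, batch 24, Adam).
#' @export
canonicalSchedules <- function() {
  list(StageSchedule(13L, 20L, 1e-3, 24L),
       StageSchedule(0L, 30L, 1e-4, 24L))
}

#' Desk-scale ("fast") staged schedule
#'
#' Five epochs with the shallow backbone frozen, then ten epochs unfrozen,
#' batch 24, Adam. Both stages use learning rate 1e-3: the canonical
#' 1e-4 fine-tuning rate presumes ImageNet-pretrained shallow weights,
#' whereas the fast profile trains from random initialisation, where 1e-4
#' underfits within the short schedule.
#'
#' @return list of two [StageSchedule-class] stages.
#' @export
fastSchedules <- function() {
  list(StageSchedule(13L, 5L, 1e-3, 24L),
       StageSchedule(0L, 10L, 1e-3, 24L))
}

#' Desk-scale model specification
#'
#' The reduced profile used for tests and continuous integration: 32x32
#' inputs, stage widths 8-8-16-32-64, FC widths 32-16. The architecture
#' (stage/block structure, fusion placement, alpha) is identical to the
#' canonical 224-input model.
#'
#' @param numClasses classes (default 6).
#' @param mode architecture variant.
#' @param fusionAlpha FC fusion weight.
#' @return a [ModelSpec-class].
#' @export
fastModelSpec <- function(numClasses = 6L, mode = "two_stream_full",
                          fusionAlpha = 1 / 3) {
  ModelSpec(numClasses = numClasses,
            stageChannels = c(8L, 8L, 16L, 32L, 64L),
            fcDims = c(32L, 16L), fusionAlpha = fusionAlpha,
            mode = mode, inputSize = 32L)
}

#' Desk-scale preprocessing configuration matching [fastModelSpec()]
#' @param augment enable rotation augmentation.
#' @return a [PreprocessConfig-class] with 32-pixel targets.
#' @export
fastPreprocessConfig <- function(augment = TRUE) {
  PreprocessConfig(targetSize = 32L, augment = augment)
}

#' Repeated-split experiment
#'
#' For each repeat: a fresh stratified 6:2:2 split, a fresh (seeded) model
#' initialisation, staged training with best-validation checkpointing, and
#' a test-set evaluation. Repeat `r` uses seed `protocol@seed + r - 1` for
#' everything random in that repeat. Images are edge-cropped and resized
#' once up front; rotation augmentation is drawn per repeat on the training
#' split only.
#'
#' @param manifest a [DatasetManifest-class].
#' @param spec a [ModelSpec-class].
#' @param protocol an [ExperimentProtocol-class].
#' @param config a [PreprocessConfig-class] (target size must match the
#'   spec's input size).
#' @param schedules stage list, see [trainStaged()].
#' @param measureTime also measure average single-sample inference time on
#'   the last repeat's model.
#' @param verbose print progress.
#' @param cache internal: reuse a preprocessed image cache.
#' @return list with `report` (aggregate [EvalReport-class], mean metrics,
#'   summed confusion), `perRepeat` (data.frame of per-repeat metrics) and
#'   `lastModel`.
#' @export
runRepeatedExperiment <- function(manifest, spec, protocol,
                                  config = fastPreprocessConfig(),
                                  schedules = fastSchedules(),
                                  measureTime = FALSE, verbose = FALSE,
                                  cache = NULL) {
  stopifnot(config@targetSize == spec@inputSize)
  if (is.null(cache)) cache <- prepCache(manifest, config)
  classes <- manifest@classes
  rows <- list()
  confTotal <- matrix(0, length(classes), length(classes),
                      dimnames = list(classes, classes))
  lastModel <- NULL
  for (r in seq_len(protocol@nRepeats)) {
    seedR <- protocol@seed + r - 1L
    splits <- splitDataset(manifest, SplitSpec(
      trainFraction = protocol@split@trainFraction,
      valFraction = protocol@split@valFraction,
      testFraction = protocol@split@testFraction,
      seed = seedR, stratified = protocol@split@stratified))
    idxOf <- function(m) match(m@records$pair_id, cache$pair_id)
    set.seed(seedR)
    trainData <- finalizeTensors(cache, idxOf(splits$train), config,
                                 augment = config@augment)
    valData <- finalizeTensors(cache, idxOf(splits$val), config)
    testData <- finalizeTensors(cache, idxOf(splits$test), config)
    model <- buildTwoStream(spec, preprocess = config, classes = classes,
                            seed = seedR)
    model <- initFromPretrained(model, NULL)
    tr <- trainStaged(model, trainData, valData, schedules,
                      verbose = verbose)
    pred <- predictData(tr$model, testData)
    conf <- confusionMatrix(classes[testData$labels], classes[pred], classes)
    met <- computeMetrics(conf)
    confTotal <- confTotal + conf
    rows[[r]] <- data.frame(repeat_index = r, seed = seedR,
                            accuracy = met$accuracy,
                            recall_macro = met$recallMacro,
                            f1_macro = met$f1Macro,
                            std_between_classes = met$stdBetweenClasses,
                            best_val_accuracy = tr$bestValAccuracy)
    lastModel <- tr$model
    if (verbose)
      message(sprintf("repeat %d/%d: test acc %.3f", r, protocol@nRepeats,
                      met$accuracy))
  }
  perRepeat <- do.call(rbind, rows)
  ait <- if (measureTime) {
    pair <- list(front = testData$front[, , , 1], back = testData$back[, , , 1])
    measureInferenceTime(lastModel, list(pair))
  } else NA_real_
  report <- EvalReport(accuracy = mean(perRepeat$accuracy),
                       recallMacro = mean(perRepeat$recall_macro),
                       f1Macro = mean(perRepeat$f1_macro),
                       stdBetweenClasses = mean(perRepeat$std_between_classes),
                       paramCount = countParameters(lastModel),
                       avgInferenceTime = ait, confusion = confTotal)
  list(report = report, perRepeat = perRepeat, lastModel = lastModel)
}

#' The eight-variant ablation grid
#'
#' Front view only, back view only, plain two-stream concatenation,
#' cross-stream residual connections only, and the full model with FC
#' fusion weight alpha in {1, 1/2, 1/4, 1/3}.
#'
#' @param base a template [ModelSpec-class] supplying widths and input size.
#' @return named list of [ModelSpec-class] variants.
#' @export
defaultAblationGrid <- function(base = fastModelSpec()) {
  variant <- function(mode, alpha = base@fusionAlpha) {
    ModelSpec(numClasses = base@numClasses,
              stageChannels = base@stageChannels,
              blocksPerStage = base@blocksPerStage, fcDims = base@fcDims,
              fusionAlpha = alpha, crossResidualStage = base@crossResidualStage,
              fcFusionEnabled = !(mode %in% c("front_only", "back_only",
                                              "concat_only",
                                              "conv_cross_only")),
              mode = mode, inputSize = base@inputSize)
  }
  list("front_only" = variant("front_only"),
       "back_only" = variant("back_only"),
       "concat_only" = variant("concat_only"),
       "conv_cross_only" = variant("conv_cross_only"),
       "alpha_1" = variant("two_stream_full", 1),
       "alpha_1_2" = variant("two_stream_full", 1 / 2),
       "alpha_1_4" = variant("two_stream_full", 1 / 4),
       "alpha_1_3" = variant("two_stream_full", 1 / 3))
}

#' Run an ablation grid
#'
#' One repeated experiment per architecture variant, rendered as a table
#' with one row per variant and the accuracy / macro recall / macro F1 /
#' between-class STD columns (percentages).
#'
#' @param manifest a [DatasetManifest-class].
#' @param protocol an [ExperimentProtocol-class].
#' @param grid named list of [ModelSpec-class] variants
#'   (default [defaultAblationGrid()]).
#' @param config,schedules see [runRepeatedExperiment()].
#' @param verbose print progress.
#' @return data.frame with columns `method`, `acc`, `recall`, `f1`, `std`;
#'   the full per-variant results are attached as attribute `"results"`.
#' @export
runAblationGrid <- function(manifest, protocol, grid = defaultAblationGrid(),
                            config = fastPreprocessConfig(),
                            schedules = fastSchedules(), verbose = FALSE) {
  if (length(grid) == 0) stop("empty ablation grid")
  cache <- prepCache(manifest, config)
  results <- list()
  for (nm in names(grid)) {
    if (verbose) message("ablation variant: ", nm)
    results[[nm]] <- runRepeatedExperiment(manifest, grid[[nm]], protocol,
                                           config, schedules, cache = cache,
                                           verbose = verbose)
  }
  tab <- do.call(rbind, lapply(names(results), function(nm) {
    rep <- results[[nm]]$report
    data.frame(method = nm, acc = 100 * rep@accuracy,
               recall = 100 * rep@recallMacro, f1 = 100 * rep@f1Macro,
               std = rep@stdBetweenClasses)
  }))
  attr(tab, "results") <- results
  tab
}
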