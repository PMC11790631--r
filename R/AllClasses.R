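#' @importFrom methods new validObject setClass setGeneric setMethod is slot show
NULL

#' Manifest of paired front/back specimen images
#'
#' A `DatasetManifest` holds one row per specimen: an identifier, the file
#' paths of the front-view and back-view images, the cultivar class label and
#' an informational origin tag. The manifest is the single source of pairing;
#' no filename conventions are ever inferred.
#'
#' @slot records data.frame with columns `pair_id`, `front_path`, `back_path`,
#'   `class_label`, `origin`, in file order.
#' @slot classes character vector of class labels, sorted lexicographically.
#' @export
setClass("DatasetManifest",
  representation(records = "data.frame", classes = "character"),
  validity = function(object) {
    need <- c("pair_id", "front_path", "back_path", "class_label", "origin")
    miss <- setdiff(need, names(object@records))
    if (length(miss) > 0)
      return(paste("manifest is missing column(s):", paste(miss, collapse = ", ")))
    if (anyDuplicated(object@records$pair_id))
      return("duplicate pair_id in manifest")
    if (!all(object@records$class_label %in% object@classes))
      return("record class_label not present in the manifest's class set")
    TRUE
  }
)

#' @describeIn DatasetManifest-class constructor; `classes` defaults to the
#'   sorted unique labels of `records`.
#' @param records data.frame of records (see slots).
#' @param classes optional explicit ordered label set.
#' @export
DatasetManifest <- function(records, classes = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in intersect(names(records),
                        c("pair_id", "front_path", "back_path",
                          "class_label", "origin")))
    records[[col]] <- as.character(records[[col]])
  if (is.null(classes)) classes <- sort(unique(records$class_label))
  new("DatasetManifest", records = records, classes = as.character(classes))
}

#' Stratified split proportions
#'
#' Train/validation/test fractions (default 6:2:2) with an explicit seed.
#' @slot trainFraction,valFraction,testFraction numeric proportions summing to 1.
#' @slot seed integer random seed for the split.
#' @slot stratified logical; split within each class when TRUE.
#' @export
setClass("SplitSpec",
  representation(trainFraction = "numeric", valFraction = "numeric",
                 testFraction = "numeric", seed = "integer",
                 stratified = "logical"),
  validity = function(object) {
    fr <- c(object@trainFraction, object@valFraction, object@testFraction)
    if (any(fr < 0)) return("split fractions must be non-negative")
    if (abs(sum(fr) - 1) > 1e-9) return("split fractions must sum to 1")
    TRUE
  }
)

#' @describeIn SplitSpec-class constructor.
#' @param trainFraction,valFraction,testFraction proportions (default 0.6/0.2/0.2).
#' @param seed integer seed.
#' @param stratified stratify by class (default TRUE).
#' @export
SplitSpec <- function(trainFraction = 0.6, valFraction = 0.2,
                      testFraction = 0.2, seed = 1L, stratified = TRUE) {
  new("SplitSpec", trainFraction = trainFraction, valFraction = valFraction,
      testFraction = testFraction, seed = as.integer(seed),
      stratified = stratified)
}

#' Preprocessing configuration
#'
#' Parameters of the five-step preprocessing chain: Canny edge detection,
#' minimal-square crop, resize, optional random rotation, normalisation.
#'
#' @slot cannyLow,cannyHigh hysteresis thresholds on 8-bit gradient magnitude.
#' @slot targetSize side of the square network input, pixels.
#' @slot maxRotationDeg rotation augmentation bound, degrees.
#' @slot normMean,normStd per-channel normalisation constants applied to
#'   intensities rescaled to `[0, 1]` (defaults: ImageNet statistics, because
#'   the staged training transfers ImageNet-pretrained shallow weights).
#' @slot augment apply random rotation (training only).
#' @slot lockAngles use one rotation angle for both views of a pair.
#' @export
setClass("PreprocessConfig",
  representation(cannyLow = "numeric", cannyHigh = "numeric",
                 targetSize = "integer", maxRotationDeg = "numeric",
                 normMean = "numeric", normStd = "numeric",
                 augment = "logical", lockAngles = "logical"),
  validity = function(object) {
    if (object@cannyLow <= 0 || object@cannyHigh <= object@cannyLow)
      return("need 0 < cannyLow < cannyHigh")
    if (object@targetSize <= 0) return("targetSize must be positive")
    if (object@maxRotationDeg < 0) return("maxRotationDeg must be >= 0")
    if (length(object@normMean) != 3 || length(object@normStd) != 3)
      return("normMean/normStd must have 3 channels")
    if (any(object@normStd <= 0)) return("normStd must be positive")
    TRUE
  }
)

#' @describeIn PreprocessConfig-class constructor.
#' @param cannyLow,cannyHigh Canny thresholds (defaults 50/150).
#' @param targetSize square input side (default 224).
#' @param maxRotationDeg rotation bound (default 15).
#' @param normMean,normStd per-channel constants (default ImageNet).
#' @param augment enable rotation augmentation.
#' @param lockAngles same angle for front and back.
#' @export
PreprocessConfig <- function(cannyLow = 50, cannyHigh = 150, targetSize = 224L,
                             maxRotationDeg = 15,
                             normMean = c(0.485, 0.456, 0.406),
                             normStd = c(0.229, 0.224, 0.225),
                             augment = FALSE, lockAngles = FALSE) {
  new("PreprocessConfig", cannyLow = cannyLow, cannyHigh = cannyHigh,
      targetSize = as.integer(targetSize), maxRotationDeg = maxRotationDeg,
      normMean = normMean, normStd = normStd, augment = augment,
      lockAngles = lockAngles)
}

#' Two-stream architecture description
#'
#' Describes the full two-stream residual network: a 17-convolution backbone
#' per stream (7x7 stem + four stages of two basic blocks), whose final
#' 512-channel stage uses cross-stream residual connections, a per-stream
#' fully connected chain 512 -> 128 -> 32 whose inputs are fused by the
#' weighted sum own + alpha * other (default alpha = 1/3), and a joint
#' classifier on the 64-dimensional concatenation.
#'
#' @slot numClasses number of cultivar classes (>= 2).
#' @slot stageChannels integer(5): stem channels then the four stage widths
#'   (canonical: 64, 64, 128, 256, 512).
#' @slot blocksPerStage basic blocks per stage (2).
#' @slot fcDims integer(2): per-stream FC widths (canonical: 128, 32).
#' @slot fusionAlpha cross-stream weight in the FC fusion.
#' @slot crossResidualStage stage index carrying cross-stream residuals
#'   (default 4L, the final stage).
#' @slot fcFusionEnabled apply the weighted FC fusion.
#' @slot mode one of `"two_stream_full"`, `"front_only"`, `"back_only"`,
#'   `"concat_only"`, `"conv_cross_only"`.
#' @slot inputSize square input side the model expects.
#' @export
setClass("ModelSpec",
  representation(numClasses = "integer", stageChannels = "integer",
                 blocksPerStage = "integer", fcDims = "integer",
                 fusionAlpha = "numeric", crossResidualStage = "integer",
                 fcFusionEnabled = "logical", mode = "character",
                 inputSize = "integer"),
  validity = function(object) {
    modes <- c("two_stream_full", "front_only", "back_only",
               "concat_only", "conv_cross_only")
    if (!(object@mode %in% modes))
      return(paste("mode must be one of:", paste(modes, collapse = ", ")))
    if (object@numClasses < 2) return("numClasses must be >= 2")
    if (length(object@stageChannels) != 5) return("stageChannels must have 5 entries")
    if (length(object@fcDims) != 2) return("fcDims must have 2 entries")
    if (object@fusionAlpha < 0) return("fusionAlpha must be >= 0")
    if (!(object@crossResidualStage %in% 1:4))
      return("crossResidualStage must be in 1..4")
    TRUE
  }
)

#' @describeIn ModelSpec-class constructor with the canonical defaults.
#' @param numClasses classes (default 18).
#' @param stageChannels stem + stage widths.
#' @param blocksPerStage blocks per stage.
#' @param fcDims per-stream FC widths.
#' @param fusionAlpha FC fusion weight (default 1/3).
#' @param crossResidualStage stage with cross-stream residuals.
#' @param fcFusionEnabled enable weighted FC fusion.
#' @param mode architecture variant.
#' @param inputSize input side in pixels (default 224).
#' @export
ModelSpec <- function(numClasses = 18L,
                      stageChannels = c(64L, 64L, 128L, 256L, 512L),
                      blocksPerStage = 2L, fcDims = c(128L, 32L),
                      fusionAlpha = 1 / 3, crossResidualStage = 4L,
                      fcFusionEnabled = TRUE, mode = "two_stream_full",
                      inputSize = 224L) {
  if (mode %in% c("front_only", "back_only", "concat_only"))
    fcFusionEnabled <- FALSE
  if (mode == "conv_cross_only") fcFusionEnabled <- FALSE
  new("ModelSpec", numClasses = as.integer(numClasses),
      stageChannels = as.integer(stageChannels),
      blocksPerStage = as.integer(blocksPerStage),
      fcDims = as.integer(fcDims), fusionAlpha = fusionAlpha,
      crossResidualStage = as.integer(crossResidualStage),
      fcFusionEnabled = fcFusionEnabled, mode = mode,
      inputSize = as.integer(inputSize))
}

#' One stage of the staged training schedule
#'
#' @slot frozenConvLayers conv layers per stream excluded from updates
#'   (13 in stage one, 0 in stage two).
#' @slot epochs training epochs.
#' @slot learningRate Adam learning rate.
#' @slot batchSize minibatch size.
#' @slot optimizer `"adam"`, `"sgd"` (momentum 0.9), `"rmsprop"` or `"nadam"`.
#' @export
setClass("StageSchedule",
  representation(frozenConvLayers = "integer", epochs = "integer",
                 learningRate = "numeric", batchSize = "integer",
                 optimizer = "character"),
  validity = function(object) {
    if (object@epochs <= 0) return("epochs must be > 0")
    if (object@learningRate <= 0) return("learningRate must be > 0")
    if (object@batchSize <= 0) return("batchSize must be > 0")
    if (!(object@optimizer %in% c("adam", "sgd", "rmsprop", "nadam")))
      return("unknown optimizer")
    TRUE
  }
)

#' @describeIn StageSchedule-class constructor.
#' @param frozenConvLayers,epochs,learningRate,batchSize,optimizer see slots.
#' @export
StageSchedule <- function(frozenConvLayers = 13L, epochs = 20L,
                          learningRate = 1e-3, batchSize = 24L,
                          optimizer = "adam") {
  new("StageSchedule", frozenConvLayers = as.integer(frozenConvLayers),
      epochs = as.integer(epochs), learningRate = learningRate,
      batchSize = as.integer(batchSize), optimizer = optimizer)
}

#' Repeated-split experiment protocol
#'
#' @slot nRepeats number of independent split/train/test repetitions.
#' @slot split a [SplitSpec-class].
#' @slot seed run-level seed; repeat r uses `seed + r - 1`.
#' @export
setClass("ExperimentProtocol",
  representation(nRepeats = "integer", split = "SplitSpec", seed = "integer"),
  validity = function(object)
    if (object@nRepeats < 1) "nRepeats must be >= 1" else TRUE
)

#' @describeIn ExperimentProtocol-class constructor.
#' @param nRepeats repetitions (canonical default 50).
#' @param split a [SplitSpec-class].
#' @param seed run-level integer seed.
#' @export
ExperimentProtocol <- function(nRepeats = 50L, split = SplitSpec(),
                               seed = 1L) {
  new("ExperimentProtocol", nRepeats = as.integer(nRepeats), split = split,
      seed = as.integer(seed))
}

#' Synthetic paired-view dataset specification
#'
#' The generator draws flower-like images whose class identity is split
#' between views: some class pairs share identical front cues (petal count,
#' petal hue, centre radius) and are distinguishable only by their back cues
#' (calyx ring count, ring hue, bract pattern), and vice versa. The joint
#' (front, back) cue vector is always unique per class, so both views
#' together identify the class perfectly while either view alone is
#' ambiguous on the constructed overlap pairs.
#'
#' @slot nClasses number of classes (>= 2).
#' @slot pairsPerClass image pairs per class.
#' @slot imageSize square image side, pixels.
#' @slot cueOverlap fraction of classes involved in a single-view-identical
#'   pair (applied to each view's cue assignment).
#' @slot noiseSigma Gaussian pixel noise, 8-bit units.
#' @slot backgroundMode `"plain"` or `"textured"`.
#' @slot seed generator seed.
#' @export
setClass("SynthSpec",
  representation(nClasses = "integer", pairsPerClass = "integer",
                 imageSize = "integer", cueOverlap = "numeric",
                 noiseSigma = "numeric", backgroundMode = "character",
                 seed = "integer"),
  validity = function(object) {
    if (object@nClasses < 2) return("nClasses must be >= 2")
    if (object@cueOverlap < 0 || object@cueOverlap > 1)
      return("cueOverlap must be in [0, 1]")
    if (!(object@backgroundMode %in% c("plain", "textured")))
      return("backgroundMode must be 'plain' or 'textured'")
    TRUE
  }
)

#' @describeIn SynthSpec-class constructor; defaults are the desk-scale
#'   conditions (6 classes, 20 pairs/class, 64 px, single-view Bayes bounds
#'   2/3 in each view).
#' @param nClasses,pairsPerClass,imageSize,cueOverlap,noiseSigma,backgroundMode,seed
#'   see slots.
#' @export
SynthSpec <- function(nClasses = 6L, pairsPerClass = 20L, imageSize = 64L,
                      cueOverlap = 2 / 3, noiseSigma = 8,
                      backgroundMode = "plain", seed = 1L) {
  new("SynthSpec", nClasses = as.integer(nClasses),
      pairsPerClass = as.integer(pairsPerClass),
      imageSize = as.integer(imageSize), cueOverlap = cueOverlap,
      noiseSigma = noiseSigma, backgroundMode = backgroundMode,
      seed = as.integer(seed))
}

#' Evaluation report
#'
#' Bundle of the six evaluation metrics plus the confusion matrix:
#' accuracy, macro recall, macro F1, the population standard deviation of
#' per-class recall in percentage points (stability across classes),
#' trainable parameter count, and average single-sample inference time.
#'
#' @slot accuracy,recallMacro,f1Macro proportions in `[0, 1]`.
#' @slot stdBetweenClasses percentage points.
#' @slot paramCount integer.
#' @slot avgInferenceTime seconds per sample (NA when not measured).
#' @slot confusion class x class count matrix (true rows, predicted columns).
#' @export
setClass("EvalReport",
  representation(accuracy = "numeric", recallMacro = "numeric",
                 f1Macro = "numeric", stdBetweenClasses = "numeric",
                 paramCount = "numeric", avgInferenceTime = "numeric",
                 confusion = "matrix"))

#' @describeIn EvalReport-class constructor.
#' @param accuracy,recallMacro,f1Macro,stdBetweenClasses,paramCount,avgInferenceTime,confusion
#'   see slots.
#' @export
EvalReport <- function(accuracy, recallMacro, f1Macro, stdBetweenClasses,
                       paramCount = NA_real_, avgInferenceTime = NA_real_,
                       confusion = matrix(0, 0, 0)) {
  new("EvalReport", accuracy = accuracy, recallMacro = recallMacro,
      f1Macro = f1Macro, stdBetweenClasses = stdBetweenClasses,
      paramCount = paramCount, avgInferenceTime = avgInferenceTime,
      confusion = confusion)
}

#' A built (possibly trained) two-stream model
#'
#' @slot spec the [ModelSpec-class] the model was built from.
#' @slot params named list of weight arrays.
#' @slot state named list of batch-norm running statistics.
#' @slot frozen character vector of parameter names excluded from updates.
#' @slot classes class-label ordering the logits refer to.
#' @slot preprocess the [PreprocessConfig-class] used for its inputs.
#' @export
setClass("TwoStreamModel",
  representation(spec = "ModelSpec", params = "list", state = "list",
                 frozen = "character", classes = "character",
                 preprocess = "PreprocessConfig"))

setMethod("show", "DatasetManifest", function(object) {
  cat(sprintf("DatasetManifest: %d pairs, %d classes\n",
              nrow(object@records), length(object@classes)))
  cat("  classes:", paste(utils::head(object@classes, 8), collapse = ", "),
      if (length(object@classes) > 8) "..." else "", "\n")
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: mode=%s, %d classes, input %dx%d\n", object@mode,
              object@numClasses, object@inputSize, object@inputSize))
  cat(sprintf("  stages: %s; fc: %s; alpha=%.3g; cross stage %d; fc fusion %s\n",
              paste(object@stageChannels, collapse = "-"),
              paste(object@fcDims, collapse = "-"), object@fusionAlpha,
              object@crossResidualStage, object@fcFusionEnabled))
})

setMethod("show", "TwoStreamModel", function(object) {
  cat(sprintf("TwoStreamModel (%s): %d classes, %s trainable parameters\n",
              object@spec@mode, object@spec@numClasses,
              format(countParameters(object), big.mark = ",")))
  if (length(object@frozen) > 0)
    cat(sprintf("  %d parameter tensors frozen\n", length(object@frozen)))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf(
    "EvalReport: acc %.3f, macro recall %.3f, macro F1 %.3f, class STD %.2f pp\n",
    object@accuracy, object@recallMacro, object@f1Macro,
    object@stdBetweenClasses))
  if (!is.na(object@paramCount))
    cat(sprintf("  params %s; AIT %s\n",
                format(object@paramCount, big.mark = ","),
                if (is.na(object@avgInferenceTime)) "not measured"
                else sprintf("%.4f s", object@avgInferenceTime)))
})

#' Accessors
#'
#' @param x a florafusion object.
#' @name accessors
NULL

#' @describeIn accessors class labels of a manifest or model.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
#' @rdname accessors
#' @export
setMethod("classLabels", "DatasetManifest", function(x) x@classes)
#' @rdname accessors
#' @export
setMethod("classLabels", "TwoStreamModel", function(x) x@classes)

#' @describeIn accessors records data.frame of a manifest.
#' @export
setGeneric("manifestRecords", function(x) standardGeneric("manifestRecords"))
#' @rdname accessors
#' @export
setMethod("manifestRecords", "DatasetManifest", function(x) x@records)

#' @describeIn accessors number of sample pairs.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setMethod("nSamples", "DatasetManifest", function(x) nrow(x@records))
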