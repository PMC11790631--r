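# The six evaluation metrics: accuracy, macro recall, macro F1, the
# between-class stability STD, the parameter count and the average
# single-sample inference time, plus the confusion matrix they derive from.

#' Confusion matrix
#'
#' Entry (i, j) counts samples of true class i predicted as class j, with
#' rows and columns in the supplied class order (the manifest's ordering).
#'
#' @param yTrue,yPred label vectors of equal length.
#' @param classes ordered class label set.
#' @return class x class integer matrix with dimnames.
#' @export
confusionMatrix <- function(yTrue, yPred, classes) {
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred differ in length")
  bad <- setdiff(unique(c(yTrue, yPred)), classes)
  if (length(bad) > 0)
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  ti <- factor(yTrue, levels = classes)
  pi <- factor(yPred, levels = classes)
  m <- table(ti, pi)
  matrix(as.integer(m), nrow = length(classes),
         dimnames = list(classes, classes))
}

#' Metrics from a confusion matrix
#'
#' Accuracy is trace/total. Per-class recall is the diagonal over row sums;
#' per-class precision the diagonal over column sums (taken as 0 for an
#' empty column). Macro recall and macro F1 average the per-class values
#' with equal class weight. The between-class STD is the population
#' standard deviation of the per-class recalls, expressed in percentage
#' points -- the stability measure reported alongside the other metrics.
#'
#' @param confusion non-negative count matrix (true rows, predicted
#'   columns) with at least one sample in every class row.
#' @param average `"macro"` (default) or `"weighted"` (row-sum weights) for
#'   recall and F1.
#' @return list with `accuracy`, `recallMacro`, `f1Macro`,
#'   `stdBetweenClasses`, and the per-class `recall`/`precision`/`f1`.
#' @export
computeMetrics <- function(confusion, average = c("macro", "weighted")) {
  average <- match.arg(average)
  confusion <- as.matrix(confusion)
  if (any(confusion < 0)) stop("negative counts in confusion matrix")
  rs <- rowSums(confusion)
  if (any(rs == 0)) stop("empty class row in confusion matrix")
  cs <- colSums(confusion)
  d <- diag(confusion)
  recall <- d / rs
  precision <- ifelse(cs > 0, d / cs, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  w <- if (average == "macro") rep(1 / length(rs), length(rs)) else rs / sum(rs)
  popSd <- sqrt(mean((recall - mean(recall))^2))
  list(accuracy = sum(d) / sum(confusion),
       recallMacro = sum(w * recall),
       f1Macro = sum(w * f1),
       stdBetweenClasses = 100 * popSd,
       recall = recall, precision = precision, f1 = f1)
}

#' Average inference time
#'
#' Mean wall-clock time of a batch-size-1 forward pass, over `nTimed`
#' single-sample calls after `nWarmup` discarded warm-up calls.
#' Preprocessing is excluded. Hardware-dependent; reported for context
#' only.
#'
#' @param model a [TwoStreamModel-class].
#' @param pairs list of preprocessed pairs (each with `front`/`back`).
#' @param nWarmup,nTimed warm-up and timed call counts.
#' @return seconds per sample.
#' @export
measureInferenceTime <- function(model, pairs, nWarmup = 2L, nTimed = 10L) {
  stopifnot(nTimed >= 1)
  pick <- function(k) pairs[[(k - 1) %% length(pairs) + 1]]
  for (k in seq_len(nWarmup)) classifyPair(model, pick(k))
  times <- vapply(seq_len(nTimed), function(k) {
    t0 <- proc.time()[["elapsed"]]
    classifyPair(model, pick(k))
    proc.time()[["elapsed"]] - t0
  }, 1.0)
  mean(times)
}

#' Evaluate a trained model on a manifest
#'
#' Preprocesses the manifest's pairs (no augmentation), predicts, and
#' assembles the full [EvalReport-class].
#'
#' @param model a trained [TwoStreamModel-class].
#' @param manifest a [DatasetManifest-class] with the model's class set.
#' @param measureTime also time single-sample inference.
#' @return an [EvalReport-class].
#' @export
evaluateOnManifest <- function(model, manifest, measureTime = FALSE) {
  if (!identical(manifest@classes, model@classes))
    stop("class labels of the manifest do not match the model's")
  config <- model@preprocess
  cache <- prepCache(manifest, config)
  data <- finalizeTensors(cache, seq_along(cache$labels), config)
  pred <- predictData(model, data)
  conf <- confusionMatrix(manifest@classes[data$labels],
                          manifest@classes[pred], manifest@classes)
  met <- computeMetrics(conf)
  ait <- if (measureTime) {
    pair <- list(front = data$front[, , , 1], back = data$back[, , , 1])
    measureInferenceTime(model, list(pair))
  } else NA_real_
  EvalReport(accuracy = met$accuracy, recallMacro = met$recallMacro,
             f1Macro = met$f1Macro,
             stdBetweenClasses = met$stdBetweenClasses,
             paramCount = countParameters(model), avgInferenceTime = ait,
             confusion = conf)
}

#' Serialise an evaluation report
#'
#' Writes the metric bundle as JSON and, optionally, the confusion matrix
#' as a CSV with class labels as header row and first column.
#'
#' @param report an [EvalReport-class].
#' @param jsonPath output JSON path.
#' @param confusionCsvPath optional CSV path for the confusion matrix.
#' @return `jsonPath`, invisibly.
#' @export
writeEvalReport <- function(report, jsonPath, confusionCsvPath = NULL) {
  obj <- list(accuracy = report@accuracy, recall_macro = report@recallMacro,
              f1_macro = report@f1Macro,
              std_between_classes = report@stdBetweenClasses,
              param_count = report@paramCount,
              avg_inference_time = report@avgInferenceTime)
  jsonlite::write_json(obj, jsonPath, auto_unbox = TRUE, digits = NA)
  if (!is.null(confusionCsvPath) && length(report@confusion) > 0)
    utils::write.csv(as.data.frame(report@confusion), confusionCsvPath)
  invisible(jsonPath)
}
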