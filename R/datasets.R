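#' Read a pairing manifest from CSV
#'
#' The manifest is a UTF-8 comma-delimited table with header columns
#' `pair_id,front_path,back_path,class_label,origin`. Relative image paths
#' are resolved against the manifest's own directory. Record order is file
#' order; the class set is sorted lexicographically. Image readability is
#' checked lazily at load time, not here.
#'
#' @param path path to the CSV file.
#' @return a [DatasetManifest-class].
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("pair_id", "front_path", "back_path", "class_label", "origin")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("manifest format error: missing column(s) ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$pair_id))
    stop("manifest validation error: duplicate pair_id")
  base <- dirname(normalizePath(path))
  for (col in c("front_path", "back_path")) {
    rel <- !grepl("^(/|[A-Za-z]:)", df[[col]])
    df[[col]][rel] <- file.path(base, df[[col]][rel])
  }
  DatasetManifest(df)
}

#' Write a manifest to CSV
#'
#' @param manifest a [DatasetManifest-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.csv(manifest@records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a manifest into train / validation / test
#'
#' Stratified 6:2:2 splitting (or any fractions in the [SplitSpec-class]).
#' Within each class, `floor(trainFraction * n)` records go to train,
#' `floor(valFraction * n)` to validation and the remainder to test, so the
#' test set is never empty and the rounding is deterministic. The same seed
#' always yields the same split.
#'
#' @param manifest a [DatasetManifest-class].
#' @param spec a [SplitSpec-class].
#' @return named list of three `DatasetManifest`s: `train`, `val`, `test`.
#' @export
splitDataset <- function(manifest, spec = SplitSpec()) {
  stopifnot(is(manifest, "DatasetManifest"), is(spec, "SplitSpec"))
  validObject(spec)
  rec <- manifest@records
  groups <- if (spec@stratified) split(seq_len(nrow(rec)), rec$class_label)
            else list(all = seq_len(nrow(rec)))
  if (spec@stratified) {
    small <- vapply(groups, length, 1L) < 5L
    if (any(small))
      stop("class too small for stratified splitting: ",
           paste(names(groups)[small], collapse = ", "))
  }
  set.seed(spec@seed)
  idx <- list(train = integer(0), val = integer(0), test = integer(0))
  for (g in groups) {
    n <- length(g)
    perm <- g[sample.int(n)]
    nTrain <- floor(spec@trainFraction * n)
    nVal <- floor(spec@valFraction * n)
    idx$train <- c(idx$train, perm[seq_len(nTrain)])
    idx$val <- c(idx$val, perm[nTrain + seq_len(nVal)])
    idx$test <- c(idx$test, perm[setdiff(seq_len(n), seq_len(nTrain + nVal))])
  }
  lapply(idx, function(i)
    DatasetManifest(rec[sort(i), , drop = FALSE], classes = manifest@classes))
}

# Decode one image file to an (H, W, 3) array on the 8-bit 0..255 scale.
# Grayscale images are promoted to three identical channels.
readImageArray <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("failed to decode image '", path,
                                           "': ", conditionMessage(e)))
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(a)[3] == 1) a <- array(rep(a, 3), dim = c(dim(a)[1:2], 3))
  # EBImage stores (x = column, y = row); transpose to (row, col, channel).
  aperm(a, c(2, 1, 3)) * 255
}

#' Load the raw front/back image pair of one record
#'
#' @param record one-row data.frame (a row of [manifestRecords()]) or a
#'   [DatasetManifest-class] together with `pairId`.
#' @param pairId pair identifier when `record` is a manifest.
#' @return list with `front` and `back` (H, W, 3) arrays on the 0..255
#'   scale, original resolutions retained, plus `pair_id` and `class_label`.
#' @export
loadViewPair <- function(record, pairId = NULL) {
  if (is(record, "DatasetManifest")) {
    rec <- record@records
    record <- rec[rec$pair_id == pairId, , drop = FALSE]
    if (nrow(record) != 1) stop("pair_id not found in manifest: ", pairId)
  }
  list(front = readImageArray(record$front_path),
       back = readImageArray(record$back_path),
       pair_id = record$pair_id, class_label = record$class_label)
}
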