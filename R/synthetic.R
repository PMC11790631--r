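# Procedural paired-view flower images. Class identity is deliberately
# split across views: the front shows a petal rosette (cue: petal count,
# petal hue, centre-disk radius), the back shows concentric calyx rings
# with bract spokes (cue: ring count, ring hue, spoke count). Cue
# assignment makes some class pairs identical on the front and resolvable
# only on the back, and vice versa, while the joint (front, back) cue
# vector is always a perfect class key.

# Deterministic cue grouping. With overlap o, floor(o * n / 2) class pairs
# share a front cue: pairs (1,2), (3,4), ...; back pairs are offset by one,
# (2,3), (4,5), ..., so a front-ambiguous pair is never also
# back-ambiguous and joint cues stay unique.
cueAssignment <- function(spec) {
  n <- spec@nClasses
  nPairs <- floor(spec@cueOverlap * n / 2)
  groupsFor <- function(firstMember) {
    grp <- integer(n)
    g <- 0L
    k <- firstMember
    used <- rep(FALSE, n)
    while (k + 1 <= n && g < nPairs) {
      g <- g + 1L
      grp[c(k, k + 1)] <- g
      used[c(k, k + 1)] <- TRUE
      k <- k + 2L
    }
    for (c in which(!used)) {
      g <- g + 1L
      grp[c] <- g
    }
    grp
  }
  front <- groupsFor(1L)
  back <- groupsFor(2L)
  joint <- paste(front, back)
  if (anyDuplicated(joint))
    stop("internal error: joint cue vector is not unique per class")
  data.frame(class = seq_len(n), front_cue = front, back_cue = back)
}

hueRGB <- function(hueDeg, s = 0.85, v = 0.9) {
  as.vector(grDevices::col2rgb(grDevices::hsv(hueDeg / 360, s, v)))
}

# Rendering parameters for a front or back cue id.
frontCueParams <- function(cue) {
  counts <- c(8L, 12L, 6L, 10L, 5L, 9L, 7L, 11L)
  hues <- c(0, 55, 210, 300, 120, 180, 270, 30)
  radii <- c(0.10, 0.16, 0.12, 0.18, 0.14, 0.11, 0.17, 0.13)
  k <- (cue - 1L) %% 8L + 1L
  list(petalCount = counts[k], petalHue = hues[k], centerRadius = radii[k])
}

backCueParams <- function(cue) {
  counts <- c(3L, 5L, 2L, 4L, 6L, 3L, 5L, 2L)
  hues <- c(120, 35, 270, 190, 0, 320, 90, 230)
  spokes <- c(8L, 12L, 6L, 10L, 14L, 7L, 9L, 11L)
  k <- (cue - 1L) %% 8L + 1L
  list(ringCount = counts[k], ringHue = hues[k], bractSpokes = spokes[k])
}

maskBoundary <- function(mask) {
  interior <- mask &
    shiftMat(mask, 1, 0) & shiftMat(mask, -1, 0) &
    shiftMat(mask, 0, 1) & shiftMat(mask, 0, -1)
  which(mask & !interior, arr.ind = TRUE)
}

#' Render one synthetic flower view
#'
#' Draws a front view (radial petal rosette plus central disk) or a back
#' view (concentric calyx rings with darker bract spokes and a receptacle
#' disk) on a plain or textured background, with per-image random global
#' rotation, centre jitter, scale jitter and Gaussian pixel noise. All
#' randomness comes from R's RNG, so a seeded caller gets identical images.
#'
#' @param view `"front"` or `"back"`.
#' @param cues cue parameter list (petal count/hue/centre radius for the
#'   front; ring count/hue/spoke count for the back) or an integer cue id.
#' @param imageSize square side in pixels.
#' @param noiseSigma Gaussian pixel noise on the 8-bit scale.
#' @param backgroundMode `"plain"` or `"textured"`.
#' @return list with `image` ((S, S, 3), 0..255) and `meta` (ground-truth
#'   `bbox` = c(rmin, rmax, cmin, cmax), `boundary` pixel coordinates,
#'   `cues`, and for front views the logical `petalMask`).
#' @export
renderFlower <- function(view = c("front", "back"), cues, imageSize = 64L,
                         noiseSigma = 8, backgroundMode = "plain") {
  view <- match.arg(view)
  if (is.numeric(cues) && is.null(names(cues)))
    cues <- if (view == "front") frontCueParams(as.integer(cues))
            else backCueParams(as.integer(cues))
  S <- as.integer(imageSize)
  img <- array(0, dim = c(S, S, 3))
  bgLevel <- 12   # dark backdrop, emulating high-contrast studio imaging
  if (backgroundMode == "textured") {
    tex <- matrix(stats::runif(S * S, -12, 12), S, S)
    for (ch in 1:3) img[, , ch] <- bgLevel + tex
  } else {
    img[, , ] <- bgLevel
  }

  cx <- (S + 1) / 2 + stats::runif(1, -0.03, 0.03) * S
  cy <- (S + 1) / 2 + stats::runif(1, -0.03, 0.03) * S
  rot <- stats::runif(1, 0, 2 * pi)
  scale <- stats::runif(1, 0.9, 1.05)
  R <- 0.38 * S * scale
  rows <- matrix(seq_len(S), S, S)
  cols <- matrix(seq_len(S), S, S, byrow = TRUE)
  xx <- cols - cx
  yy <- rows - cy
  rr <- sqrt(xx^2 + yy^2)
  th <- atan2(yy, xx)
  vJit <- stats::runif(1, -0.08, 0.05)

  paint <- function(img, mask, rgb) {
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- rgb[ch]
      img[, , ch] <- plane
    }
    img
  }

  if (view == "front") {
    k <- cues$petalCount
    # petals are polar wedges (annulus sectors): angular half-width 0.31 of
    # the spacing, so the k petals are pairwise disjoint at every radius
    halfAng <- 0.31 * 2 * pi / k
    ang <- (th - rot) %% (2 * pi / k)
    ang <- pmin(ang, 2 * pi / k - ang)
    petalMask <- rr >= 0.3 * R & rr <= R & ang <= halfAng
    disk <- rr <= cues$centerRadius * S * scale
    petalRGB <- hueRGB(cues$petalHue, v = 0.9 + vJit)
    img <- paint(img, petalMask, petalRGB)
    img <- paint(img, disk & !petalMask, hueRGB(48, s = 0.9, v = 0.65 + vJit))
    flowerMask <- petalMask | disk
    boundary <- maskBoundary(petalMask)
  } else {
    m <- cues$ringCount
    flowerMask <- rr <= R
    for (i in seq_len(m)) {
      ring <- rr > (i - 1) / m * R & rr <= i / m * R
      # outermost ring bright so the flower silhouette stays high-contrast
      vv <- (if ((m - i) %% 2 == 0) 0.85 else 0.55) + vJit
      img <- paint(img, ring, hueRGB(cues$ringHue, s = 0.75, v = vv))
    }
    spokes <- flowerMask & rr > 0.4 * R &
      abs(sin(cues$bractSpokes / 2 * (th - rot))) > 0.97
    img <- paint(img, spokes, hueRGB(cues$ringHue, s = 0.9, v = 0.25))
    recept <- rr <= 0.12 * R
    img <- paint(img, recept, hueRGB(30, s = 0.8, v = 0.45 + vJit))
    boundary <- maskBoundary(flowerMask)
    petalMask <- NULL
  }

  if (noiseSigma > 0)
    img <- img + array(stats::rnorm(S * S * 3, sd = noiseSigma),
                       dim = c(S, S, 3))
  img <- pmin(pmax(img, 0), 255)
  fm <- which(flowerMask, arr.ind = TRUE)
  meta <- list(bbox = c(min(fm[, 1]), max(fm[, 1]), min(fm[, 2]), max(fm[, 2])),
               boundary = boundary, cues = cues)
  if (!is.null(petalMask)) meta$petalMask <- petalMask
  list(image = img, meta = meta)
}

#' Generate a paired-view dataset on disk
#'
#' Writes `nClasses * pairsPerClass` front/back PNG pairs, a per-image
#' metadata JSON (bounding box, cue vector, boundary pixel count) and a
#' manifest CSV compatible with [readManifest()]. Deterministic under the
#' spec's seed.
#'
#' @param spec a [SynthSpec-class].
#' @param outDir output directory (created if needed).
#' @return the [DatasetManifest-class], re-read from the written CSV.
#' @export
generateDataset <- function(spec, outDir) {
  validObject(spec)
  dir.create(file.path(outDir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(outDir, "meta"), showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  set.seed(spec@seed)
  cueTab <- cueAssignment(spec)
  classes <- sprintf("class%02d", seq_len(spec@nClasses))
  rows <- list()
  for (c in seq_len(spec@nClasses)) {
    fc <- frontCueParams(cueTab$front_cue[c])
    bc <- backCueParams(cueTab$back_cue[c])
    for (i in seq_len(spec@pairsPerClass)) {
      pid <- sprintf("%s_p%03d", classes[c], i)
      paths <- file.path("images", paste0(pid, c("_front", "_back"), ".png"))
      rf <- renderFlower("front", fc, spec@imageSize, spec@noiseSigma,
                         spec@backgroundMode)
      rb <- renderFlower("back", bc, spec@imageSize, spec@noiseSigma,
                         spec@backgroundMode)
      png::writePNG(rf$image / 255, file.path(outDir, paths[1]))
      png::writePNG(rb$image / 255, file.path(outDir, paths[2]))
      jsonlite::write_json(
        list(pair_id = pid, class_label = classes[c],
             front = list(bbox = rf$meta$bbox, cues = fc,
                          n_boundary = nrow(rf$meta$boundary)),
             back = list(bbox = rb$meta$bbox, cues = bc,
                         n_boundary = nrow(rb$meta$boundary))),
        file.path(outDir, "meta", paste0(pid, ".json")),
        auto_unbox = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        pair_id = pid, front_path = paths[1], back_path = paths[2],
        class_label = classes[c],
        origin = sprintf("origin%d", (c - 1) %% 3 + 1))
    }
  }
  manifestPath <- file.path(outDir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifestPath, row.names = FALSE,
                   quote = FALSE)
  readManifest(manifestPath)
}

#' Theoretical single-view and joint accuracy bounds
#'
#' Enumerates the cue assignment of a [SynthSpec-class] (noiseless cue
#' model, equal class priors): within a group of g classes sharing a cue,
#' the best single-view classifier is right with probability 1/g. The
#' joint bound is 1 by the uniqueness invariant.
#'
#' @param spec a [SynthSpec-class].
#' @return list with `front`, `back` and `joint` accuracy bounds.
#' @export
bayesSeparability <- function(spec) {
  tab <- cueAssignment(spec)
  boundFor <- function(groups) {
    size <- table(groups)
    mean(1 / as.numeric(size[as.character(groups)]))
  }
  list(front = boundFor(tab$front_cue), back = boundFor(tab$back_cue),
       joint = 1)
}
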