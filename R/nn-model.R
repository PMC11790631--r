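# The two-stream residual network.
#
# Each stream is a 17-convolution backbone: a 7x7/2 stem, a 3x3/2 max pool,
# then four stages of two pre-activation basic blocks
# (BN -> ReLU -> 3x3 conv -> BN -> ReLU -> 3x3 conv, added to an identity or
# 1x1-projection shortcut), a final BN+ReLU, and global average pooling.
# Pre-activation blocks keep the residual update purely additive,
# out = h(x) + F(x, W), so the cross-stream form out_p = h(x_p) + h(x_q) +
# F(x_p, W_p) holds exactly at the block outputs. The last stage's blocks
# are cross-stream in the fused modes; the shortcut of its downsampling
# block projects the summed identities, proj(x_p + x_q), one projection per
# stream. The FC head runs 512 -> 128 -> 32 per stream with the weighted
# fusion u_p = y_p + alpha * y_q applied to the inputs of both FC layers,
# then concatenates the two 32-vectors and classifies with a joint FC.

streamKeys <- function(spec) {
  switch(spec@mode,
         front_only = "f", back_only = "b", c("f", "b"))
}

crossConvEnabled <- function(spec) {
  spec@mode %in% c("two_stream_full", "conv_cross_only") &&
    length(streamKeys(spec)) == 2
}

fcFusionActive <- function(spec) {
  spec@fcFusionEnabled && length(streamKeys(spec)) == 2
}

stageLayout <- function(spec) {
  ch <- spec@stageChannels
  lapply(1:4, function(i) {
    lapply(seq_len(spec@blocksPerStage), function(j) {
      inCh <- if (j == 1) ch[i] else ch[i + 1]
      stride <- if (i > 1 && j == 1) 2L else 1L
      list(stage = i, block = j, inCh = inCh, outCh = ch[i + 1],
           stride = stride, downsample = (stride != 1 || inCh != ch[i + 1]))
    })
  })
}

# Parameters of one pre-activation basic block under a name prefix.
initBlockParams <- function(lay) {
  p <- list()
  p[["bna.gamma"]] <- rep(1, lay$inCh)
  p[["bna.beta"]] <- rep(0, lay$inCh)
  p[["conva.W"]] <- initConv(3, 3, lay$inCh, lay$outCh)
  p[["bnb.gamma"]] <- rep(1, lay$outCh)
  p[["bnb.beta"]] <- rep(0, lay$outCh)
  p[["convb.W"]] <- initConv(3, 3, lay$outCh, lay$outCh)
  if (lay$downsample)
    p[["proj.W"]] <- initConv(1, 1, lay$inCh, lay$outCh)
  p
}

initBlockState <- function(lay) {
  list("bna.rm" = rep(0, lay$inCh), "bna.rv" = rep(1, lay$inCh),
       "bnb.rm" = rep(0, lay$outCh), "bnb.rv" = rep(1, lay$outCh))
}

#' Build a two-stream (or single-stream) model
#'
#' Initialises all weights (He initialisation for convolutions and FC
#' layers, unit/zero batch-norm parameters) from R's RNG, so a seeded call
#' is fully reproducible.
#'
#' @param spec a [ModelSpec-class].
#' @param preprocess the [PreprocessConfig-class] its inputs come from
#'   (stored with the model; defaults to a config matching `spec@inputSize`).
#' @param classes class-label ordering for the logits (defaults to
#'   `"class01"..`).
#' @param seed optional integer seed.
#' @return a [TwoStreamModel-class].
#' @export
buildTwoStream <- function(spec, preprocess = NULL, classes = NULL,
                           seed = NULL) {
  validObject(spec)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(preprocess))
    preprocess <- PreprocessConfig(targetSize = spec@inputSize)
  if (is.null(classes))
    classes <- sprintf("class%02d", seq_len(spec@numClasses))
  sts <- streamKeys(spec)
  layout <- stageLayout(spec)
  params <- list()
  state <- list()
  for (st in sts) {
    pfx <- function(nm) paste0(st, ".", nm)
    params[[pfx("conv1.W")]] <- initConv(7, 7, 3, spec@stageChannels[1])
    params[[pfx("bn1.gamma")]] <- rep(1, spec@stageChannels[1])
    params[[pfx("bn1.beta")]] <- rep(0, spec@stageChannels[1])
    state[[pfx("bn1.rm")]] <- rep(0, spec@stageChannels[1])
    state[[pfx("bn1.rv")]] <- rep(1, spec@stageChannels[1])
    for (i in 1:4) for (j in seq_len(spec@blocksPerStage)) {
      lay <- layout[[i]][[j]]
      bp <- initBlockParams(lay)
      bs <- initBlockState(lay)
      names(bp) <- paste0(st, sprintf(".s%d.b%d.", i, j), names(bp))
      names(bs) <- paste0(st, sprintf(".s%d.b%d.", i, j), names(bs))
      params <- c(params, bp)
      state <- c(state, bs)
    }
    C5 <- spec@stageChannels[5]
    params[[pfx("bnf.gamma")]] <- rep(1, C5)
    params[[pfx("bnf.beta")]] <- rep(0, C5)
    state[[pfx("bnf.rm")]] <- rep(0, C5)
    state[[pfx("bnf.rv")]] <- rep(1, C5)
    l1 <- initLinear(C5, spec@fcDims[1])
    params[[pfx("fc1.W")]] <- l1$W; params[[pfx("fc1.b")]] <- l1$b
    l2 <- initLinear(spec@fcDims[1], spec@fcDims[2])
    params[[pfx("fc2.W")]] <- l2$W; params[[pfx("fc2.b")]] <- l2$b
  }
  concatDim <- length(sts) * spec@fcDims[2]
  l5 <- initLinear(concatDim, spec@numClasses)
  params[["fc5.W"]] <- l5$W; params[["fc5.b"]] <- l5$b
  new("TwoStreamModel", spec = spec, params = params, state = state,
      frozen = character(0), classes = as.character(classes),
      preprocess = preprocess)
}

# Batch-norm prefixes whose layers are frozen (run in eval mode).
frozenBnPrefixes <- function(frozen) {
  bn <- grep("\\.(gamma)$", frozen, value = TRUE)
  sub("\\.gamma$", "", bn)
}

# ---- forward ---------------------------------------------------------------

# One BN call threading model state; `S` is an environment holding the
# mutable running statistics for the whole forward pass.
bnLayer <- function(x, P, S, pfx, training, frozenBN) {
  tr <- training && !(pfx %in% frozenBN)
  res <- bnF(x, P[[paste0(pfx, ".gamma")]], P[[paste0(pfx, ".beta")]],
             S$stats[[paste0(pfx, ".rm")]], S$stats[[paste0(pfx, ".rv")]], tr)
  if (tr) {
    S$stats[[paste0(pfx, ".rm")]] <- res$rm
    S$stats[[paste0(pfx, ".rv")]] <- res$rv
  }
  res
}

# Residual transform F of a pre-activation basic block.
blockResidualF <- function(x, P, S, pfx, stride, training, frozenBN) {
  b1 <- bnLayer(x, P, S, paste0(pfx, "bna"), training, frozenBN)
  r1 <- reluF(b1$y)
  c1 <- convF(r1, P[[paste0(pfx, "conva.W")]], stride, 1L)
  b2 <- bnLayer(c1, P, S, paste0(pfx, "bnb"), training, frozenBN)
  r2 <- reluF(b2$y)
  c2 <- convF(r2, P[[paste0(pfx, "convb.W")]], 1L, 1L)
  list(out = c2, cache = list(x = x, b1 = b1$cache, b1y = b1$y, r1 = r1,
                              b2 = b2$cache, b2y = b2$y, r2 = r2,
                              stride = stride, pfx = pfx))
}

blockResidualB <- function(gradOut, P, cc) {
  g <- list()
  cb <- convB(cc$r2, P[[paste0(cc$pfx, "convb.W")]], gradOut, 1L, 1L)
  g[[paste0(cc$pfx, "convb.W")]] <- cb$dw
  d <- reluB(cb$dx, cc$b2y)
  bb <- bnB(d, cc$b2)
  g[[paste0(cc$pfx, "bnb.gamma")]] <- bb$dgamma
  g[[paste0(cc$pfx, "bnb.beta")]] <- bb$dbeta
  ca <- convB(cc$r1, P[[paste0(cc$pfx, "conva.W")]], bb$dx, cc$stride, 1L)
  g[[paste0(cc$pfx, "conva.W")]] <- ca$dw
  d <- reluB(ca$dx, cc$b1y)
  ba <- bnB(d, cc$b1)
  g[[paste0(cc$pfx, "bna.gamma")]] <- ba$dgamma
  g[[paste0(cc$pfx, "bna.beta")]] <- ba$dbeta
  list(dx = ba$dx, grads = g)
}

# Single-stream block: out = h(x) + F(x).
blockForward <- function(x, P, S, pfx, lay, training, frozenBN) {
  fr <- blockResidualF(x, P, S, pfx, lay$stride, training, frozenBN)
  if (lay$downsample) {
    sc <- convF(x, P[[paste0(pfx, "proj.W")]], lay$stride, 0L)
  } else sc <- x
  list(out = sc + fr$out,
       cache = list(res = fr$cache, lay = lay, x = x, pfx = pfx))
}

blockBackward <- function(gradOut, P, cc) {
  rb <- blockResidualB(gradOut, P, cc$res)
  g <- rb$grads
  if (cc$lay$downsample) {
    pb <- convB(cc$x, P[[paste0(cc$pfx, "proj.W")]], gradOut, cc$lay$stride, 0L)
    g[[paste0(cc$pfx, "proj.W")]] <- pb$dw
    dx <- rb$dx + pb$dx
  } else dx <- rb$dx + gradOut
  list(dx = dx, grads = g)
}

# Cross-stream block pair: out_p = h(x_p + x_q) + F(x_p, W_p), both streams
# computed synchronously from the pre-update inputs. For downsampling
# blocks the per-stream projection is applied to the summed identities.
crossBlockForward <- function(xs, P, S, pfxs, lay, training, frozenBN) {
  xsum <- xs[[1]] + xs[[2]]
  out <- list(); caches <- list()
  for (k in 1:2) {
    fr <- blockResidualF(xs[[k]], P, S, pfxs[[k]], lay$stride, training,
                         frozenBN)
    sc <- if (lay$downsample)
      convF(xsum, P[[paste0(pfxs[[k]], "proj.W")]], lay$stride, 0L)
    else xsum
    out[[k]] <- sc + fr$out
    caches[[k]] <- fr$cache
  }
  list(out = out, cache = list(res = caches, lay = lay, xsum = xsum,
                               pfxs = pfxs))
}

crossBlockBackward <- function(gradOuts, P, cc) {
  g <- list()
  dxs <- list(0, 0)
  dsum <- 0
  for (k in 1:2) {
    rb <- blockResidualB(gradOuts[[k]], P, cc$res[[k]])
    g <- c(g, rb$grads)
    dxs[[k]] <- rb$dx
    if (cc$lay$downsample) {
      pb <- convB(cc$xsum, P[[paste0(cc$pfxs[[k]], "proj.W")]], gradOuts[[k]],
                  cc$lay$stride, 0L)
      g[[paste0(cc$pfxs[[k]], "proj.W")]] <- pb$dw
      dsum <- dsum + pb$dx
    } else dsum <- dsum + gradOuts[[k]]
  }
  list(dx1 = dxs[[1]] + dsum, dx2 = dxs[[2]] + dsum, grads = g)
}

# Full forward pass. `views` is list(f = front tensor, b = back tensor),
# each (H, W, 3, N). Returns logits (K x N), the cache needed for backward
# and the (possibly updated) running statistics.
modelForward <- function(model, views, training = FALSE) {
  spec <- model@spec
  P <- model@params
  sts <- streamKeys(spec)
  frozenBN <- frozenBnPrefixes(model@frozen)
  S <- new.env(parent = emptyenv())
  S$stats <- model@state
  layout <- stageLayout(spec)
  cross <- crossConvEnabled(spec)
  cache <- list(stream = list(), spec = spec)

  acts <- list()
  for (st in sts) {
    x <- views[[st]]
    if (is.null(x)) stop("missing input view for stream '", st, "'")
    pfx <- function(nm) paste0(st, ".", nm)
    c1 <- convF(x, P[[pfx("conv1.W")]], 2L, 3L)
    b1 <- bnLayer(c1, P, S, pfx("bn1"), training, frozenBN)
    r1 <- reluF(b1$y)
    mp <- maxpool_forward_cpp(r1, 3L, 2L, 1L)
    cache$stream[[st]] <- list(x = x, c1 = c1, b1 = b1$cache, b1y = b1$y,
                               r1dim = dim(r1), mpidx = mp$idx,
                               stages = vector("list", 4))
    acts[[st]] <- mp$out
  }

  for (i in 1:4) {
    crossHere <- cross && i == spec@crossResidualStage
    for (j in seq_len(spec@blocksPerStage)) {
      lay <- layout[[i]][[j]]
      if (crossHere) {
        pfxs <- lapply(sts, function(st) sprintf("%s.s%d.b%d.", st, i, j))
        cb <- crossBlockForward(list(acts[[sts[1]]], acts[[sts[2]]]), P, S,
                                pfxs, lay, training, frozenBN)
        acts[[sts[1]]] <- cb$out[[1]]
        acts[[sts[2]]] <- cb$out[[2]]
        cache$stream[[sts[1]]]$stages[[i]][[j]] <- cb$cache
        cache$stream[[sts[2]]]$stages[[i]][[j]] <- list(crossShared = TRUE)
      } else {
        for (st in sts) {
          pfx <- sprintf("%s.s%d.b%d.", st, i, j)
          bf <- blockForward(acts[[st]], P, S, pfx, lay, training, frozenBN)
          acts[[st]] <- bf$out
          cache$stream[[st]]$stages[[i]][[j]] <- bf$cache
        }
      }
    }
    for (st in sts) cache$stream[[st]]$stageOut[[i]] <- acts[[st]]
  }

  z <- list()
  for (st in sts) {
    pfx <- function(nm) paste0(st, ".", nm)
    bf <- bnLayer(acts[[st]], P, S, pfx("bnf"), training, frozenBN)
    rf <- reluF(bf$y)
    cache$stream[[st]]$bnf <- bf$cache
    cache$stream[[st]]$bnfy <- bf$y
    cache$stream[[st]]$gapIn <- rf
    cache$stream[[st]]$gapDim <- dim(rf)
    zs <- gapF(rf)
    z[[st]] <- matrix(zs, nrow = dim(rf)[3])
  }

  fuse <- fcFusionActive(spec)
  alpha <- spec@fusionAlpha
  u <- list(); a <- list(); aPre <- list(); v <- list(); gOut <- list()
  gPre <- list()
  for (st in sts) {
    q <- setdiff(sts, st)
    u[[st]] <- if (fuse) z[[st]] + alpha * z[[q]] else z[[st]]
  }
  for (st in sts) {
    aPre[[st]] <- linearF(u[[st]], P[[paste0(st, ".fc1.W")]],
                          P[[paste0(st, ".fc1.b")]])
    a[[st]] <- reluF(aPre[[st]])
  }
  for (st in sts) {
    q <- setdiff(sts, st)
    v[[st]] <- if (fuse) a[[st]] + alpha * a[[q]] else a[[st]]
  }
  for (st in sts) {
    gPre[[st]] <- linearF(v[[st]], P[[paste0(st, ".fc2.W")]],
                          P[[paste0(st, ".fc2.b")]])
    gOut[[st]] <- reluF(gPre[[st]])
  }
  concat <- do.call(rbind, gOut[sts])
  logits <- linearF(concat, P[["fc5.W"]], P[["fc5.b"]])
  cache$head <- list(z = z, u = u, a = a, aPre = aPre, v = v, gOut = gOut,
                     gPre = gPre, concat = concat, sts = sts, fuse = fuse,
                     alpha = alpha)
  list(logits = logits, cache = cache, state = S$stats,
       fused = concat)
}

# Full backward pass from dLogits; returns named parameter gradients and,
# when `wantActGrads`, the gradient at each stream's GAP input (for CAM).
modelBackward <- function(model, cache, dLogits, wantActGrads = FALSE) {
  spec <- cache$spec
  P <- model@params
  hd <- cache$head
  sts <- hd$sts
  g <- list()

  lb <- linearB(hd$concat, P[["fc5.W"]], dLogits)
  g[["fc5.W"]] <- lb$dW; g[["fc5.b"]] <- lb$db
  dim2 <- spec@fcDims[2]
  dg <- list()
  for (k in seq_along(sts))
    dg[[sts[k]]] <- lb$dx[((k - 1) * dim2 + 1):(k * dim2), , drop = FALSE]

  dv <- list()
  for (st in sts) {
    d <- reluB(dg[[st]], hd$gPre[[st]])
    lb2 <- linearB(hd$v[[st]], P[[paste0(st, ".fc2.W")]], d)
    g[[paste0(st, ".fc2.W")]] <- lb2$dW
    g[[paste0(st, ".fc2.b")]] <- lb2$db
    dv[[st]] <- lb2$dx
  }
  da <- list()
  for (st in sts) {
    q <- setdiff(sts, st)
    da[[st]] <- if (hd$fuse) dv[[st]] + hd$alpha * dv[[q]] else dv[[st]]
  }
  du <- list()
  for (st in sts) {
    d <- reluB(da[[st]], hd$aPre[[st]])
    lb1 <- linearB(hd$u[[st]], P[[paste0(st, ".fc1.W")]], d)
    g[[paste0(st, ".fc1.W")]] <- lb1$dW
    g[[paste0(st, ".fc1.b")]] <- lb1$db
    du[[st]] <- lb1$dx
  }
  dz <- list()
  for (st in sts) {
    q <- setdiff(sts, st)
    dz[[st]] <- if (hd$fuse) du[[st]] + hd$alpha * du[[q]] else du[[st]]
  }

  dact <- list()
  actGrads <- list()
  for (st in sts) {
    sc <- cache$stream[[st]]
    dgap <- gapB(dz[[st]], sc$gapDim)
    if (wantActGrads) actGrads[[st]] <- dgap
    d <- reluB(dgap, sc$bnfy)
    bb <- bnB(d, sc$bnf)
    g[[paste0(st, ".bnf.gamma")]] <- bb$dgamma
    g[[paste0(st, ".bnf.beta")]] <- bb$dbeta
    dact[[st]] <- bb$dx
  }

  layout <- stageLayout(spec)
  cross <- crossConvEnabled(spec)
  stageGrads <- list()
  for (i in 4:1) {
    if (wantActGrads)
      for (st in sts) stageGrads[[st]][[i]] <- dact[[st]]
    crossHere <- cross && i == spec@crossResidualStage
    for (j in rev(seq_len(spec@blocksPerStage))) {
      if (crossHere) {
        cc <- cache$stream[[sts[1]]]$stages[[i]][[j]]
        cb <- crossBlockBackward(list(dact[[sts[1]]], dact[[sts[2]]]), P, cc)
        g <- addGrads(g, cb$grads)
        dact[[sts[1]]] <- cb$dx1
        dact[[sts[2]]] <- cb$dx2
      } else {
        for (st in sts) {
          cc <- cache$stream[[st]]$stages[[i]][[j]]
          bb <- blockBackward(dact[[st]], P, cc)
          g <- addGrads(g, bb$grads)
          dact[[st]] <- bb$dx
        }
      }
    }
  }

  for (st in sts) {
    sc <- cache$stream[[st]]
    pfx <- function(nm) paste0(st, ".", nm)
    dmp <- maxpool_backward_cpp(dact[[st]], sc$mpidx, as.integer(sc$r1dim))
    d <- reluB(dmp, sc$b1y)
    bb <- bnB(d, sc$b1)
    g[[pfx("bn1.gamma")]] <- bb$dgamma
    g[[pfx("bn1.beta")]] <- bb$dbeta
    cb <- convB(sc$x, P[[pfx("conv1.W")]], bb$dx, 2L, 3L)
    g[[pfx("conv1.W")]] <- cb$dw
  }
  if (wantActGrads) {
    attr(g, "actGrads") <- actGrads
    attr(g, "stageGrads") <- stageGrads
  }
  g
}

addGrads <- function(g, more) {
  for (nm in names(more))
    g[[nm]] <- if (is.null(g[[nm]])) more[[nm]] else g[[nm]] + more[[nm]]
  g
}

# ---- exposed architecture operations --------------------------------------

#' Stage-by-stage output shapes
#'
#' Walks the convolution arithmetic of the backbone and reports the shape
#' after the stem convolution, the max pool, each residual stage, global
#' average pooling and each fully connected layer. For a 224-pixel input
#' with the canonical widths this is 112x112x64, 56x56x64, 56x56x64,
#' 28x28x128, 14x14x256, 7x7x512, 1x1x512, then 128, 32, a 64-d
#' concatenation and one logit per class.
#'
#' @param spec a [ModelSpec-class].
#' @param inputSize square input side (defaults to `spec@inputSize`).
#' @return named list of dimension vectors.
#' @export
forwardShapes <- function(spec, inputSize = spec@inputSize) {
  convOut <- function(h, k, s, p) floor((h + 2 * p - k) / s) + 1
  ch <- spec@stageChannels
  h <- convOut(inputSize, 7, 2, 3)
  shapes <- list(conv1 = c(h, h, ch[1]))
  h <- convOut(h, 3, 2, 1)
  shapes$maxpool <- c(h, h, ch[1])
  for (i in 1:4) {
    if (i > 1) h <- convOut(h, 3, 2, 1)
    shapes[[paste0("conv", i + 1)]] <- c(h, h, ch[i + 1])
  }
  shapes$avgpool <- c(1, 1, ch[5])
  shapes$fc_stream_1 <- spec@fcDims[1]
  shapes$fc_stream_2 <- spec@fcDims[2]
  nStreams <- length(streamKeys(spec))
  shapes$concat <- nStreams * spec@fcDims[2]
  shapes$logits <- spec@numClasses
  shapes
}

#' Number of convolutional layers per stream
#'
#' Counts the stem convolution plus the two 3x3 convolutions of every basic
#' block (17 for the canonical four-stage, two-block backbone). Projection
#' shortcuts are not counted, following the usual ResNet-18 accounting.
#'
#' @param spec a [ModelSpec-class].
#' @return integer.
#' @export
countConvLayers <- function(spec) {
  1L + 4L * spec@blocksPerStage * 2L
}

#' Number of shallow (freezable) convolutional layers per stream
#'
#' The stem plus stages 1-3, i.e. everything before the cross-stream fusion
#' stage: 13 layers for the canonical backbone.
#'
#' @param spec a [ModelSpec-class].
#' @return integer.
#' @export
countShallowConvLayers <- function(spec) {
  1L + 3L * spec@blocksPerStage * 2L
}

#' Build a standalone residual block
#'
#' Creates the parameter set of one (optionally cross-stream) pre-activation
#' basic block, mainly for direct inspection of the fusion arithmetic.
#'
#' @param inCh,outCh input/output channels.
#' @param stride 1 or 2 (2 implies a projection shortcut).
#' @param cross build the cross-stream variant (two parameter sets).
#' @param seed optional seed.
#' @return a list with the layer parameters, running statistics and layout.
#' @export
makeResidualBlock <- function(inCh, outCh, stride = 1L, cross = FALSE,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lay <- list(inCh = inCh, outCh = outCh, stride = as.integer(stride),
              downsample = (stride != 1 || inCh != outCh))
  nStreams <- if (cross) 2L else 1L
  params <- list(); state <- list()
  for (k in seq_len(nStreams)) {
    bp <- initBlockParams(lay)
    bs <- initBlockState(lay)
    names(bp) <- paste0("p", k, ".", names(bp))
    names(bs) <- paste0("p", k, ".", names(bs))
    params <- c(params, bp)
    state <- c(state, bs)
  }
  list(params = params, state = state, lay = lay, cross = cross)
}

#' Forward pass of a cross-stream residual block
#'
#' Computes, synchronously from the pre-update inputs,
#' `out_p = h(x_p) + h(x_q) + F(x_p, W_p)` for both streams, where `h` is
#' the identity (or, when the block downsamples, a 1x1 projection of the
#' summed identities) and `F` is the block's residual transform.
#'
#' @param xFront,xBack activation tensors (H, W, C, N) of identical shape.
#' @param block a block from [makeResidualBlock()] with `cross = TRUE`.
#' @param training use batch statistics in the batch norms.
#' @return list with `front` and `back` output tensors.
#' @export
crossStreamBlockForward <- function(xFront, xBack, block, training = FALSE) {
  if (!identical(dim(xFront), dim(xBack)))
    stop("cross-stream block requires identical shapes in both streams")
  if (!isTRUE(block$cross)) stop("block was not built with cross = TRUE")
  P <- block$params
  S <- new.env(parent = emptyenv())
  S$stats <- block$state
  cb <- crossBlockForward(list(xFront, xBack), P, S,
                          list("p1.", "p2."), block$lay, training,
                          character(0))
  list(front = cb$out[[1]], back = cb$out[[2]])
}

#' Forward pass of a single-stream residual block
#'
#' `out = h(x) + F(x, W)` with identity (or projection) shortcut `h`.
#'
#' @param x activation tensor (H, W, C, N).
#' @param block a block from [makeResidualBlock()] with `cross = FALSE`.
#' @param training use batch statistics in the batch norms.
#' @return output tensor.
#' @export
residualBlockForward <- function(x, block, training = FALSE) {
  P <- block$params
  S <- new.env(parent = emptyenv())
  S$stats <- block$state
  bf <- blockForward(x, P, S, "p1.", block$lay, training, character(0))
  bf$out
}

#' Weighted fully connected fusion
#'
#' For each stream `p`, computes `out_p = G_p(y_p + alpha * y_q)` from the
#' pre-update inputs, where `G_p` is that stream's FC transform (identity
#' when no weights are given) and `alpha` the cross-stream weight
#' (default 1/3, i.e. own:other = 1 : 1/3).
#'
#' @param yFront,yBack (features x N) matrices (plain vectors accepted).
#' @param alpha cross-stream weight.
#' @param weights optional list with `front`/`back` elements, each
#'   `list(W, b)`, applied after the fusion sum.
#' @return list with fused `front` and `back` outputs.
#' @export
fcFusionForward <- function(yFront, yBack, alpha = 1 / 3, weights = NULL) {
  yFront <- as.matrix(yFront); yBack <- as.matrix(yBack)
  if (!identical(dim(yFront), dim(yBack)))
    stop("fc fusion requires identical dimensions in both streams")
  uF <- yFront + alpha * yBack
  uB <- yBack + alpha * yFront
  if (!is.null(weights)) {
    uF <- linearF(uF, weights$front$W, weights$front$b)
    uB <- linearF(uB, weights$back$W, weights$back$b)
  }
  list(front = uF, back = uB)
}

#' Classify one preprocessed view pair
#'
#' Runs an evaluation-mode forward pass and returns the logits and the
#' predicted class (argmax; ties broken towards the lowest class index).
#'
#' @param model a [TwoStreamModel-class].
#' @param pair list with normalised `front`/`back` tensors of shape
#'   (inputSize, inputSize, 3) (or with a trailing batch dimension).
#' @return list with `logits` (vector or K x N matrix), `index` and `label`.
#' @export
classifyPair <- function(model, pair) {
  spec <- model@spec
  asBatch <- function(x) {
    if (is.null(x)) return(NULL)
    if (length(dim(x)) == 3) x <- array(x, dim = c(dim(x), 1))
    if (dim(x)[1] != spec@inputSize || dim(x)[2] != spec@inputSize)
      stop("input is ", dim(x)[1], "x", dim(x)[2], " but the model expects ",
           spec@inputSize, "x", spec@inputSize,
           " -- run preprocessPipeline() first")
    x
  }
  views <- list(f = asBatch(pair$front), b = asBatch(pair$back))
  fw <- modelForward(model, views, training = FALSE)
  idx <- apply(fw$logits, 2, which.max)
  list(logits = if (ncol(fw$logits) == 1) drop(fw$logits) else fw$logits,
       index = idx, label = model@classes[idx])
}

#' Count trainable parameters
#'
#' Total number of scalar entries over all learnable tensors (convolution
#' and FC weights, FC biases, batch-norm scale/shift), excluding any
#' currently frozen tensors and the batch-norm running statistics.
#'
#' @param model a [TwoStreamModel-class].
#' @return numeric count.
#' @export
countParameters <- function(model) {
  nm <- setdiff(names(model@params), model@frozen)
  sum(vapply(model@params[nm], length, 1L))
}
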