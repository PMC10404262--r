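## Dense-block encoder--decoder segmentation network.
##
## Wiring (fixed; width set by kernelsPerConv * sizeScale = growth g):
## three encoder dense blocks, a bottleneck block and three decoder
## dense blocks (7 total), each block three norm-ReLU-conv-dropout
## operations with dense concatenation, followed by a norm-ReLU-1x1x1
## transition to 2g channels; 2x average pooling between encoder levels,
## nearest-neighbor upsampling plus skip concatenation between decoder
## levels; final 1x1x1 convolution to 4 classes + per-voxel softmax.

segGrowth <- function(mcfg) {
  max(2L, as.integer(round(mcfg@kernelsPerConv * mcfg@sizeScale)))
}

segInitParams <- function(mcfg) {
  if (mcfg@nDenseBlocks != 7L)
    stop("the encoder-decoder wiring is defined for 7 dense blocks")
  g <- segGrowth(mcfg)
  nc <- mcfg@convsPerBlock
  cin <- mcfg@inputChannels
  skipC <- 2L * g
  list(
    b1 = denseBlockInit(cin, g, nc),   t1 = transInit(cin + nc * g, skipC),
    b2 = denseBlockInit(skipC, g, nc), t2 = transInit(skipC + nc * g, skipC),
    b3 = denseBlockInit(skipC, g, nc), t3 = transInit(skipC + nc * g, skipC),
    b4 = denseBlockInit(skipC, g, nc), t4 = transInit(skipC + nc * g, skipC),
    b5 = denseBlockInit(2L * skipC, g, nc),
    t5 = transInit(2L * skipC + nc * g, skipC),
    b6 = denseBlockInit(2L * skipC, g, nc),
    t6 = transInit(2L * skipC + nc * g, skipC),
    b7 = denseBlockInit(2L * skipC, g, nc),
    final = xavierConv(2L * skipC + nc * g, mcfg@nClasses, 1L))
}

segForward <- function(params, x, dims, mcfg, training = FALSE) {
  dr <- mcfg@dropoutRate
  half <- function(d) as.integer(d / 2L)
  d0 <- as.integer(dims); d1 <- half(d0); d2 <- half(d1); d3 <- half(d2)

  lvl <- function(bp, tp, xin, dd) {
    bf <- denseBlockForward(bp, xin, dd, dr, training)
    tf <- transForward(tp, bf$y, dd)
    list(b = bf, t = tf, y = tf$y)
  }
  e0 <- lvl(params$b1, params$t1, x, d0)
  p0 <- poolForward(e0$y, d0)
  e1 <- lvl(params$b2, params$t2, p0$y, d1)
  p1 <- poolForward(e1$y, d1)
  e2 <- lvl(params$b3, params$t3, p1$y, d2)
  p2 <- poolForward(e2$y, d2)
  bt <- lvl(params$b4, params$t4, p2$y, d3)
  u2 <- unpoolForward(bt$y, d2)
  d2f <- lvl(params$b5, params$t5, cbind(u2$y, e2$y), d2)
  u1 <- unpoolForward(d2f$y, d1)
  d1f <- lvl(params$b6, params$t6, cbind(u1$y, e1$y), d1)
  u0 <- unpoolForward(d1f$y, d0)
  b7 <- denseBlockForward(params$b7, cbind(u0$y, e0$y), d0, dr, training)
  fin <- convForward(params$final, b7$y, d0, 1L)
  list(z = fin$y,
       cache = list(e0 = e0, p0 = p0, e1 = e1, p1 = p1, e2 = e2, p2 = p2,
                    bt = bt, u2 = u2, d2f = d2f, u1 = u1, d1f = d1f,
                    u0 = u0, b7 = b7, fin = fin,
                    dims = list(d0 = d0, d1 = d1, d2 = d2, d3 = d3)))
}

segBackward <- function(params, cache, gz, mcfg) {
  dm <- cache$dims
  lvlBack <- function(bp, tp, lv, gy, dd) {
    tb <- transBackward(tp, lv$t, gy, dd)
    bb <- denseBlockBackward(bp, lv$b, tb$gx, dd)
    list(gx = bb$gx, gb = bb$g, gt = tb$g)
  }
  g <- list()
  fb <- convBackward(params$final, cache$fin, gz, dm$d0, 1L)
  g$final <- fb$g
  b7b <- denseBlockBackward(params$b7, cache$b7, fb$gx, dm$d0)
  g$b7 <- b7b$g
  w0 <- ncol(cache$u0$y)
  gu0 <- b7b$gx[, seq_len(w0), drop = FALSE]
  ge0skip <- b7b$gx[, -seq_len(w0), drop = FALSE]
  gd1 <- unpoolBackward(cache$u0, gu0)
  l <- lvlBack(params$b6, params$t6, cache$d1f, gd1, dm$d1)
  g$b6 <- l$gb; g$t6 <- l$gt
  w1 <- ncol(cache$u1$y)
  gu1 <- l$gx[, seq_len(w1), drop = FALSE]
  ge1skip <- l$gx[, -seq_len(w1), drop = FALSE]
  gd2 <- unpoolBackward(cache$u1, gu1)
  l <- lvlBack(params$b5, params$t5, cache$d2f, gd2, dm$d2)
  g$b5 <- l$gb; g$t5 <- l$gt
  w2 <- ncol(cache$u2$y)
  gu2 <- l$gx[, seq_len(w2), drop = FALSE]
  ge2skip <- l$gx[, -seq_len(w2), drop = FALSE]
  gbt <- unpoolBackward(cache$u2, gu2)
  l <- lvlBack(params$b4, params$t4, cache$bt, gbt, dm$d3)
  g$b4 <- l$gb; g$t4 <- l$gt
  gp2 <- poolBackward(cache$p2, l$gx)
  l <- lvlBack(params$b3, params$t3, cache$e2, gp2 + ge2skip, dm$d2)
  g$b3 <- l$gb; g$t3 <- l$gt
  gp1 <- poolBackward(cache$p1, l$gx)
  l <- lvlBack(params$b2, params$t2, cache$e1, gp1 + ge1skip, dm$d1)
  g$b2 <- l$gb; g$t2 <- l$gt
  gp0 <- poolBackward(cache$p0, l$gx)
  l <- lvlBack(params$b1, params$t1, cache$e0, gp0 + ge0skip, dm$d0)
  g$b1 <- l$gb; g$t1 <- l$gt
  g[names(params)]
}

# Fused softmax + (optionally spatially-weighted) cross-entropy.
# Returns the loss and the gradient with respect to the logits.
ceLossGrad <- function(z, yOneHot, w = NULL) {
  p <- softmaxRows(z)
  lp <- log(clampProb(p))
  if (is.null(w)) {
    n <- nrow(z)
    list(loss = -sum(yOneHot * lp) / n, gz = (p - yOneHot) / n,
         allMasked = FALSE)
  } else {
    nPos <- sum(w > 0)
    if (nPos == 0)
      return(list(loss = 0, gz = 0 * z, allMasked = TRUE))
    list(loss = -sum(w * rowSums(yOneHot * lp)) / nPos,
         gz = (w * (p - yOneHot)) / nPos, allMasked = FALSE)
  }
}

#' Build an untrained segmentation model
#'
#' Constructs the dense-block encoder--decoder with Xavier-initialized
#' kernels; deterministic given the seed.
#'
#' @param mcfg A [SegModelConfig-class].
#' @param seed Integer seed for initialization.
#' @param tcfg Optional [TrainConfig-class] stored with the model.
#' @return An untrained [SegModel-class].
#' @export
#' @examples
#' m <- buildSegModel(segModelConfig(sizeScale = 0.25), seed = 1)
#' m
buildSegModel <- function(mcfg = segModelConfig(), seed = 1L,
                          tcfg = trainConfig(seed = seed)) {
  params <- withSeed(seed, segInitParams(mcfg))
  new("SegModel", params = params, config = mcfg, trainConfig = tcfg,
      lossTrace = numeric(0), normalization = "zscore")
}

#' Cross-entropy segmentation loss
#'
#' The mean over voxels of `-sum_i Y_i ln X_i` over the four classes,
#' with probabilities clamped to `[1e-7, 1]` before the logarithm.
#'
#' @param probs A [ProbabilityMaps-class] or 4D probability array.
#' @param target A [LabelVolume-class], 3D integer array, or one-hot 4D
#'   array aligned with `probs`.
#' @return Non-negative scalar loss.
#' @export
segmentationLoss <- function(probs, target) {
  p <- if (is(probs, "ProbabilityMaps")) probs@voxels else probs
  y <- targetOneHot(target, dim(p))
  stopIfShapeMismatch(p, y, "probabilities and target")
  n <- prod(dim(p)[1:3])
  -sum(y * log(clampProb(p))) / n
}

targetOneHot <- function(target, pdim) {
  if (is(target, "LabelVolume")) return(oneHot(target@voxels, 4L))
  if (length(dim(target)) == 3L) return(oneHot(target, 4L))
  target
}

# Shared minibatch SGD loop over patch lists.
# patches: list of list(x = N x C matrix, y = N x 4 one-hot, w = NULL or
# numeric N). forward/backward are architecture closures.
trainLoop <- function(params, patches, dims, tcfg, forward, backward,
                      lossGrad) {
  velocity <- treeZero(params)
  trace <- numeric(tcfg@nEpochs)
  nP <- length(patches)
  bs <- max(1L, min(tcfg@batchSize, nP))
  withSeed(tcfg@seed, {
    for (epoch in seq_len(tcfg@nEpochs)) {
      lr <- tcfg@learningRate * tcfg@lrDecay^(epoch - 1L)
      ord <- sample.int(nP)
      losses <- numeric(0)
      i <- 1L
      while (i <= nP) {
        batch <- ord[i:min(i + bs - 1L, nP)]
        gAcc <- NULL
        bl <- 0
        for (pi in batch) {
          pt <- patches[[pi]]
          fw <- forward(params, pt$x, dims, training = TRUE)
          lg <- lossGrad(fw$z, pt$y, pt$w)
          bl <- bl + lg$loss
          if (!lg$allMasked) {
            gr <- backward(params, fw$cache, lg$gz)
            gAcc <- if (is.null(gAcc)) gr else treeMap2(`+`, gAcc, gr)
          }
        }
        if (!is.null(gAcc)) {
          gAcc <- treeMap2(function(g, .) g / length(batch), gAcc, gAcc)
          st <- sgdStep(params, gAcc, velocity, lr, tcfg@momentum)
          params <- st$params
          velocity <- st$velocity
        }
        losses <- c(losses, bl / length(batch))
        i <- i + bs
      }
      trace[epoch] <- mean(losses)
    }
  })
  list(params = params, trace = trace)
}

# Turn a (volume, labels, weights) triple into training patches.
segPatchesFromSubject <- function(intensity, labels, weights, tcfg, seed) {
  v <- zscoreChannels(intensity@voxels)
  ps <- extractPatches(intensityVolume(v, intensity@spacing),
                       labels = labels, weights = weights,
                       n = tcfg@patchesPerSubject, size = tcfg@patchSize,
                       seed = seed)
  n <- length(ps@intensity)
  sz <- ps@patchSize
  lapply(seq_len(n), function(i) {
    x <- matrix(ps@intensity[[i]], ncol = dim(ps@intensity[[i]])[4])
    y <- matrix(oneHot(ps@labels[[i]], 4L), ncol = 4L)
    w <- if (is.null(ps@weights[[i]])) NULL else as.vector(ps@weights[[i]])
    list(x = x, y = y, w = w)
  })
}

#' Train the source-domain segmentation model
#'
#' Minibatch SGD on randomly extracted patches with the cross-entropy
#' loss; learning rate multiplied by `lrDecay` after each epoch. The
#' returned model carries the per-epoch mean loss trace.
#'
#' @param subjects List of labeled subjects, each a list with elements
#'   `intensity` ([IntensityVolume-class]) and `labels`
#'   ([LabelVolume-class]).
#' @param tcfg A [TrainConfig-class].
#' @param mcfg A [SegModelConfig-class].
#' @param init Optional [SegModel-class] to warm-start from (used by the
#'   domain-adaptation step); when NULL a fresh Xavier-initialized model
#'   is built from `tcfg@seed`.
#' @return A trained [SegModel-class].
#' @export
trainSourceModel <- function(subjects, tcfg = trainConfig(),
                             mcfg = segModelConfig(), init = NULL) {
  if (length(subjects) < 1L) stop("need at least one labeled subject")
  patches <- list()
  for (si in seq_along(subjects)) {
    s <- subjects[[si]]
    patches <- c(patches, segPatchesFromSubject(
      s$intensity, s$labels, s$weights, tcfg,
      seed = childSeed(tcfg@seed, paste0("patches", si))))
  }
  model <- if (is.null(init)) buildSegModel(mcfg, seed = tcfg@seed, tcfg = tcfg)
    else init
  mcfgUse <- model@config
  dims <- rep(tcfg@patchSize, 3L)
  fit <- trainLoop(
    model@params, patches, dims, tcfg,
    forward = function(p, x, d, training)
      segForward(p, x, d, mcfgUse, training),
    backward = function(p, cache, gz) segBackward(p, cache, gz, mcfgUse),
    lossGrad = ceLossGrad)
  new("SegModel", params = fit$params, config = mcfgUse, trainConfig = tcfg,
      lossTrace = fit$trace, normalization = model@normalization)
}

#' Segment a whole volume with a trained model
#'
#' Sliding-window patch inference: probabilities are predicted per patch
#' (dropout off), averaged where windows overlap, renormalized, and the
#' label is the arg-max class with ties broken toward the lowest code.
#'
#' @param model A trained [SegModel-class].
#' @param volume An [IntensityVolume-class].
#' @param stride Window stride in voxels; default the model's
#'   `inferenceStride` (50% overlap when unset).
#' @return List with `labels` ([LabelVolume-class]) and `probs`
#'   ([ProbabilityMaps-class]).
#' @export
predictSegmentation <- function(model, volume, stride = NULL) {
  tcfg <- model@trainConfig
  size <- tcfg@patchSize
  d <- dim(volume@voxels)[1:3]
  if (any(d < size))
    stop(sprintf("volume extent %s smaller than patch size %d",
                 paste(d, collapse = "x"), size))
  if (is.null(stride))
    stride <- if (is.na(tcfg@inferenceStride)) max(1L, size %/% 2L)
      else tcfg@inferenceStride
  v <- zscoreChannels(volume@voxels)
  corners <- slidingCorners(d, size, stride)
  dims <- rep(size, 3L)
  blocks <- vector("list", nrow(corners))
  for (i in seq_len(nrow(corners))) {
    c0 <- corners[i, ]
    blk <- v[c0[1]:(c0[1] + size - 1L), c0[2]:(c0[2] + size - 1L),
             c0[3]:(c0[3] + size - 1L), , drop = FALSE]
    x <- matrix(blk, ncol = dim(blk)[4])
    fw <- segForward(model@params, x, dims, model@config, training = FALSE)
    blocks[[i]] <- array(softmaxRows(fw$z), dim = c(dims, 4L))
  }
  probs <- reconstructFromPatches(blocks, corners, d, volume@spacing)
  labelsFromProbs(probs)
}

#' Arg-max labels from probability maps
#'
#' @param probs A [ProbabilityMaps-class].
#' @return List with `labels` and `probs` (ties toward the lowest code).
#' @export
labelsFromProbs <- function(probs) {
  m <- matrix(probs@voxels, ncol = 4L)
  lab <- max.col(m, ties.method = "first") - 1L
  list(labels = labelVolume(array(lab, dim = dim(probs@voxels)[1:3]),
                            probs@spacing),
       probs = probs)
}
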