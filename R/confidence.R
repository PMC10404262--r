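## Confidence model (ConM): predicts, per voxel, how likely the
## automated segmentation agrees with the (unseen) manual label. A small
## U-Net takes the one-hot segmentation (4 channels) concatenated with
## the tissue probability maps (4 channels) and outputs a logistic
## reliability score; training minimizes the class-balanced binary
## cross-entropy with the misclassified branch scaled by a = 0.1.

#' Binary agreement map between automated and manual labels
#'
#' 1 where the automated segmentation equals the manual label, 0
#' elsewhere. The mean of the map is the voxel accuracy.
#'
#' @param autoSeg A [LabelVolume-class] (automated segmentation).
#' @param manual A [LabelVolume-class] (manual labels), same shape.
#' @return A binary [ConfidenceMap-class].
#' @export
agreementMap <- function(autoSeg, manual) {
  stopIfShapeMismatch(autoSeg@voxels, manual@voxels,
                      "automated and manual labels")
  confidenceMap((autoSeg@voxels == manual@voxels) * 1.0, autoSeg@spacing)
}

#' Class-balanced confidence loss
#'
#' Mean over voxels of `-(Y_c ln X_c + a (1 - Y_c) ln(1 - X_c))` with
#' predictions clamped to `[1e-7, 1 - 1e-7]`. The constant `a` (default
#' 0.1) down-weights the (rare) misclassified voxels' branch.
#'
#' @param pred A [ConfidenceMap-class] or numeric array of predictions.
#' @param target A [ConfidenceMap-class] or binary array of targets.
#' @param params A [ConfLossParams-class].
#' @return Non-negative scalar loss.
#' @export
confidenceLoss <- function(pred, target, params = confLossParams()) {
  x <- if (is(pred, "ConfidenceMap")) pred@voxels else pred
  y <- if (is(target, "ConfidenceMap")) target@voxels else target
  if (length(x) != length(y)) stop("shape mismatch between pred and target")
  eps <- 1e-7
  x <- pmin(pmax(x, eps), 1 - eps)
  mean(-(y * log(x) + params@a * (1 - y) * log(1 - x)))
}

## ---- U-Net architecture ------------------------------------------------

confInitParams <- function(inChannels, width) {
  w <- as.integer(width)
  list(
    e0a = transInit(inChannels, w, 3L), e0b = transInit(w, w, 3L),
    e1a = transInit(w, 2L * w, 3L),     e1b = transInit(2L * w, 2L * w, 3L),
    bt  = transInit(2L * w, 2L * w, 3L),
    d1  = transInit(4L * w, 2L * w, 3L),
    d0  = transInit(3L * w, w, 3L),
    final = xavierConv(w, 1L, 1L))
}

confForward <- function(params, x, dims, training = FALSE) {
  d0 <- as.integer(dims); d1 <- as.integer(d0 / 2L); d2 <- as.integer(d1 / 2L)
  a0 <- transForward(params$e0a, x, d0, 3L)
  b0 <- transForward(params$e0b, a0$y, d0, 3L)
  p0 <- poolForward(b0$y, d0)
  a1 <- transForward(params$e1a, p0$y, d1, 3L)
  b1 <- transForward(params$e1b, a1$y, d1, 3L)
  p1 <- poolForward(b1$y, d1)
  bt <- transForward(params$bt, p1$y, d2, 3L)
  u1 <- unpoolForward(bt$y, d1)
  c1 <- transForward(params$d1, cbind(u1$y, b1$y), d1, 3L)
  u0 <- unpoolForward(c1$y, d0)
  c0 <- transForward(params$d0, cbind(u0$y, b0$y), d0, 3L)
  fin <- convForward(params$final, c0$y, d0, 1L)
  list(z = fin$y,
       cache = list(a0 = a0, b0 = b0, p0 = p0, a1 = a1, b1 = b1, p1 = p1,
                    bt = bt, u1 = u1, c1 = c1, u0 = u0, c0 = c0, fin = fin,
                    dims = list(d0 = d0, d1 = d1, d2 = d2)))
}

confBackward <- function(params, cache, gz) {
  dm <- cache$dims
  g <- list()
  fb <- convBackward(params$final, cache$fin, gz, dm$d0, 1L)
  g$final <- fb$g
  tb <- transBackward(params$d0, cache$c0, fb$gx, dm$d0, 3L)
  g$d0 <- tb$g
  w0 <- ncol(cache$u0$y)
  gu0 <- tb$gx[, seq_len(w0), drop = FALSE]
  gb0skip <- tb$gx[, -seq_len(w0), drop = FALSE]
  gc1 <- unpoolBackward(cache$u0, gu0)
  tb <- transBackward(params$d1, cache$c1, gc1, dm$d1, 3L)
  g$d1 <- tb$g
  w1 <- ncol(cache$u1$y)
  gu1 <- tb$gx[, seq_len(w1), drop = FALSE]
  gb1skip <- tb$gx[, -seq_len(w1), drop = FALSE]
  gbt <- unpoolBackward(cache$u1, gu1)
  tb <- transBackward(params$bt, cache$bt, gbt, dm$d2, 3L)
  g$bt <- tb$g
  gp1 <- poolBackward(cache$p1, tb$gx)
  tb <- transBackward(params$e1b, cache$b1, gp1 + gb1skip, dm$d1, 3L)
  g$e1b <- tb$g
  tb2 <- transBackward(params$e1a, cache$a1, tb$gx, dm$d1, 3L)
  g$e1a <- tb2$g
  gp0 <- poolBackward(cache$p0, tb2$gx)
  tb <- transBackward(params$e0b, cache$b0, gp0 + gb0skip, dm$d0, 3L)
  g$e0b <- tb$g
  tb2 <- transBackward(params$e0a, cache$a0, tb$gx, dm$d0, 3L)
  g$e0a <- tb2$g
  g[names(params)]
}

sigmoid <- function(z) 1 / (1 + exp(-z))

confLossGrad <- function(a) {
  force(a)
  function(z, y, w) {
    p <- sigmoid(z)
    eps <- 1e-7
    pc <- pmin(pmax(p, eps), 1 - eps)
    n <- length(z)
    loss <- mean(-(y * log(pc) + a * (1 - y) * log(1 - pc)))
    gz <- (a * (1 - y) * p - y * (1 - p)) / n
    list(loss = loss, gz = gz, allMasked = FALSE)
  }
}

# One-hot segmentation (4 ch) concatenated with probability maps (4 ch).
confInputArray <- function(autoSeg, probs) {
  stopIfShapeMismatch(autoSeg@voxels, probs@voxels,
                      "segmentation and probability maps")
  d <- dim(autoSeg@voxels)
  x <- array(0, dim = c(d, 8L))
  x[, , , 1:4] <- oneHot(autoSeg@voxels, 4L)
  x[, , , 5:8] <- probs@voxels
  x
}

#' K-fold self-testing of the segmentation model
#'
#' Splits the labeled subjects into K folds, trains a segmentation model
#' on each complement, and predicts the held-out subjects, so every
#' subject receives exactly one automated segmentation from a model that
#' never saw it. These out-of-fold pairs are the training data for the
#' confidence model.
#'
#' @param subjects List of labeled subjects (`intensity`, `labels`).
#' @param K Number of folds (default 2).
#' @param tcfg A [TrainConfig-class].
#' @param mcfg A [SegModelConfig-class].
#' @param .train,.predict Training and prediction functions, exposed so
#'   the fold protocol can be exercised with lightweight stand-ins;
#'   defaults are [trainSourceModel()] and [predictSegmentation()].
#' @return List, one element per subject: `auto` ([LabelVolume-class]),
#'   `probs` ([ProbabilityMaps-class]), `manual`, `fold`.
#' @export
kfoldSelfTest <- function(subjects, K = 2L, tcfg = trainConfig(),
                          mcfg = segModelConfig(),
                          .train = trainSourceModel,
                          .predict = predictSegmentation) {
  n <- length(subjects)
  K <- as.integer(K)
  if (n < K) stop(sprintf("need at least K = %d subjects, got %d", K, n))
  perm <- withSeed(childSeed(tcfg@seed, "folds"), sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep_len(seq_len(K), n)
  out <- vector("list", n)
  for (k in seq_len(K)) {
    trainIdx <- which(fold != k)
    testIdx <- which(fold == k)
    tk <- tcfg
    tk@seed <- childSeed(tcfg@seed, paste0("fold", k))
    model <- .train(subjects[trainIdx], tk, mcfg)
    for (i in testIdx) {
      pr <- .predict(model, subjects[[i]]$intensity)
      out[[i]] <- list(auto = pr$labels, probs = pr$probs,
                       manual = subjects[[i]]$labels, fold = k)
    }
  }
  out
}

#' Train the confidence model
#'
#' Fits the U-Net on patches of (one-hot automated segmentation,
#' probability maps) against the binary agreement target, with the
#' class-balanced loss. Trained strictly after, and independently of,
#' the segmentation model.
#'
#' @param pairs List from [kfoldSelfTest()]: per subject `auto`,
#'   `probs`, `manual`.
#' @param tcfg A [TrainConfig-class].
#' @param params A [ConfLossParams-class].
#' @param depth U-Net pooling depth (fixed wiring uses 2).
#' @param width Channels of the first level (default 8).
#' @return A trained [ConfModel-class].
#' @export
trainConfidenceModel <- function(pairs, tcfg = trainConfig(),
                                 params = confLossParams(), depth = 2L,
                                 width = 8L) {
  if (length(pairs) < 1L) stop("need at least one (auto, probs, manual) pair")
  patches <- list()
  for (si in seq_along(pairs)) {
    pr <- pairs[[si]]
    x <- confInputArray(pr$auto, pr$probs)
    target <- agreementMap(pr$auto, pr$manual)
    ps <- extractPatches(intensityVolume(x, pr$auto@spacing),
                         labels = pr$auto, weights = target@voxels,
                         n = tcfg@patchesPerSubject, size = tcfg@patchSize,
                         seed = childSeed(tcfg@seed, paste0("confpatch", si)))
    patches <- c(patches, lapply(seq_along(ps@intensity), function(i) {
      list(x = matrix(ps@intensity[[i]], ncol = 8L),
           y = as.vector(ps@weights[[i]]), w = NULL)
    }))
  }
  initParams <- withSeed(childSeed(tcfg@seed, "confinit"),
                         confInitParams(8L, width))
  dims <- rep(tcfg@patchSize, 3L)
  fit <- trainLoop(
    initParams, patches, dims, tcfg,
    forward = function(p, x, d, training) confForward(p, x, d, training),
    backward = confBackward,
    lossGrad = confLossGrad(params@a))
  new("ConfModel", params = fit$params, depth = as.integer(depth),
      width = as.integer(width), inChannels = 8L, trainConfig = tcfg,
      lossParams = params, lossTrace = fit$trace)
}

#' Predict a voxel-wise confidence map
#'
#' Sliding-window inference of the confidence U-Net over the (one-hot
#' segmentation, probability maps) input; overlapping windows are
#' averaged. Values lie in (0, 1).
#'
#' @param confModel A trained [ConfModel-class].
#' @param autoSeg A [LabelVolume-class] automated segmentation.
#' @param probs The matching [ProbabilityMaps-class].
#' @param stride Window stride; defaults to the model's inference stride.
#' @return A [ConfidenceMap-class].
#' @export
predictConfidence <- function(confModel, autoSeg, probs, stride = NULL) {
  tcfg <- confModel@trainConfig
  size <- tcfg@patchSize
  x <- confInputArray(autoSeg, probs)
  d <- dim(x)[1:3]
  if (any(d < size))
    stop(sprintf("volume extent %s smaller than patch size %d",
                 paste(d, collapse = "x"), size))
  if (is.null(stride))
    stride <- if (is.na(tcfg@inferenceStride)) max(1L, size %/% 2L)
      else tcfg@inferenceStride
  corners <- slidingCorners(d, size, stride)
  dims <- rep(size, 3L)
  acc <- array(0, dim = d)
  cnt <- array(0, dim = d)
  for (i in seq_len(nrow(corners))) {
    c0 <- corners[i, ]
    xi <- c0[1]:(c0[1] + size - 1L)
    yi <- c0[2]:(c0[2] + size - 1L)
    zi <- c0[3]:(c0[3] + size - 1L)
    blk <- matrix(x[xi, yi, zi, , drop = FALSE], ncol = 8L)
    fw <- confForward(confModel@params, blk, dims, training = FALSE)
    acc[xi, yi, zi] <- acc[xi, yi, zi] + array(sigmoid(fw$z), dim = dims)
    cnt[xi, yi, zi] <- cnt[xi, yi, zi] + 1
  }
  cnt[cnt == 0] <- 1
  confidenceMap(acc / cnt, autoSeg@spacing)
}

#' Probability histograms of correct vs misclassified voxels
#'
#' For voxels whose reference label is the given class, the histogram of
#' the predicted class probability, split by whether the automated label
#' matches the reference. Misclassified voxels concentrate near 0.5
#' while correct voxels concentrate near 1 -- the diagnostic that
#' motivates reusing one confidence model across age domains.
#'
#' @param probs A [ProbabilityMaps-class].
#' @param autoSeg Automated [LabelVolume-class].
#' @param truth Reference [LabelVolume-class].
#' @param class `"GM"`, `"WM"`, `"CSF"` or an integer code 1..3.
#' @param nBins Number of histogram bins on `[0, 1]`.
#' @return List with `breaks`, normalized `correct` and `misclassified`
#'   frequencies (each summing to 1 when nonempty), voxel counts, empty
#'   flags, and a `table` data.frame (binEdge, freqCorrect, freqMis).
#' @export
probabilityHistograms <- function(probs, autoSeg, truth, class = "WM",
                                  nBins = 20L) {
  code <- if (is.character(class)) TISSUE_CODES[[class]] else as.integer(class)
  stopIfShapeMismatch(probs@voxels, truth@voxels, "probs and truth")
  stopIfShapeMismatch(autoSeg@voxels, truth@voxels, "autoSeg and truth")
  sel <- truth@voxels == code
  p <- probs@voxels[, , , code + 1L][sel]
  correct <- (autoSeg@voxels == code)[sel]
  breaks <- seq(0, 1, length.out = nBins + 1L)
  tab <- function(v) {
    if (!length(v)) return(rep(0, nBins))
    h <- hist(pmin(pmax(v, 0), 1), breaks = breaks, plot = FALSE)$counts
    h / sum(h)
  }
  hc <- tab(p[correct])
  hm <- tab(p[!correct])
  list(breaks = breaks, correct = hc, misclassified = hm,
       nCorrect = sum(correct), nMis = sum(!correct),
       emptyCorrect = !any(correct), emptyMis = all(correct),
       table = data.frame(binEdge = breaks[-length(breaks)],
                          freqCorrect = hc, freqMis = hm))
}
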