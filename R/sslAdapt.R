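## Target-domain self-supervised adaptation: confidence-gated weight
## maps, the spatially-weighted cross-entropy, pseudo-label training,
## and the gradual label-propagation chain across domains.

#' Confidence-gated spatial weight map
#'
#' The piecewise rule `w(x) = M_cp(x)` where `M_cp(x) >= 0.5` (threshold
#' inclusive) and `w(x) = 0` elsewhere, applied voxel-wise. Idempotent
#' on its own output.
#'
#' @param conf A [ConfidenceMap-class] (or numeric array in `[0, 1]`).
#' @param threshold Gating threshold (default 0.5).
#' @return Numeric array of weights in `{0} U [threshold, 1]`.
#' @export
#' @examples
#' weightMap(confidenceMap(array(c(0.49, 0.5, 0.51, 1), c(1, 2, 2))))
weightMap <- function(conf, threshold = 0.5) {
  m <- if (is(conf, "ConfidenceMap")) conf@voxels else conf
  ifelse(m >= threshold, m, 0)
}

#' Spatially-weighted cross-entropy loss
#'
#' `-w * sum_i Y_i ln X_i` per voxel, averaged over the voxels with
#' positive weight (so tighter gating does not shrink the effective
#' learning rate). With `w == 1` everywhere this reduces exactly to
#' [segmentationLoss()]. When every weight is zero the loss is 0 and the
#' result carries `attr(, "allMasked") = TRUE`.
#'
#' @param probs A [ProbabilityMaps-class] or 4D probability array.
#' @param target Pseudo-label target: [LabelVolume-class], 3D integer
#'   array or one-hot 4D array.
#' @param weights Weight map from [weightMap()] (3D array).
#' @return Scalar loss with attribute `allMasked`.
#' @export
weightedSegmentationLoss <- function(probs, target, weights) {
  p <- if (is(probs, "ProbabilityMaps")) probs@voxels else probs
  y <- targetOneHot(target, dim(p))
  stopIfShapeMismatch(p, y, "probabilities and target")
  w <- as.vector(weights)
  if (length(w) != prod(dim(p)[1:3]))
    stop("weights shape does not match the volume")
  nPos <- sum(w > 0)
  if (nPos == 0) {
    out <- 0
    attr(out, "allMasked") <- TRUE
    return(out)
  }
  perVox <- -rowSums(matrix(y * log(clampProb(p)), ncol = 4L))
  out <- sum(w * perVox) / nPos
  attr(out, "allMasked") <- FALSE
  out
}

#' Generate confidence-gated pseudo-labels for target volumes
#'
#' Runs the segmentation model on each unlabeled target volume, scores
#' the prediction with the confidence model, and gates the confidence
#' through [weightMap()]. The retained-voxel fraction (weight > 0) is
#' reported overall and per tissue; reliable voxels may come from tissue
#' boundaries as well as interiors.
#'
#' @param segModel A trained [SegModel-class].
#' @param confModel A trained [ConfModel-class].
#' @param volumes List of [IntensityVolume-class] target volumes.
#' @param threshold Gating threshold (default 0.5).
#' @return List per volume: `labels` (pseudo [LabelVolume-class]),
#'   `probs`, `conf` ([ConfidenceMap-class]), `weights` (array),
#'   `retained` (overall fraction), `retainedByTissue` (named fractions).
#' @export
makePseudoLabels <- function(segModel, confModel, volumes, threshold = 0.5) {
  lapply(volumes, function(vol) {
    pr <- predictSegmentation(segModel, vol)
    conf <- predictConfidence(confModel, pr$labels, pr$probs)
    w <- weightMap(conf, threshold)
    lab <- pr$labels@voxels
    byTissue <- vapply(TISSUE_NAMES, function(nm) {
      sel <- lab == TISSUE_CODES[[nm]]
      if (!any(sel)) NA_real_ else mean(w[sel] > 0)
    }, numeric(1))
    list(labels = pr$labels, probs = pr$probs, conf = conf, weights = w,
         retained = mean(w > 0), retainedByTissue = byTissue)
  })
}

#' Adapt the segmentation model to a target domain
#'
#' Trains a new domain-specific model on the target volumes' patches
#' against confidence-gated pseudo-labels with the spatially-weighted
#' cross-entropy. The new model warm-starts from the source model's
#' weights by default (switchable for ablation); the source model is
#' left untouched. No target-domain manual labels are used.
#'
#' @param sourceModel A trained [SegModel-class].
#' @param confModel A trained [ConfModel-class] (not retrained per
#'   domain).
#' @param volumes List of unlabeled [IntensityVolume-class] target
#'   volumes.
#' @param tcfg A [TrainConfig-class] for the adaptation run.
#' @param warmStart Logical; start from `initModel`'s weights (TRUE) or
#'   from a fresh Xavier initialization (FALSE).
#' @param threshold Confidence gating threshold.
#' @param initModel Model whose weights seed the new domain model when
#'   `warmStart` is TRUE; defaults to `sourceModel` (the pseudo-label
#'   teacher).
#' @param sourceSubjects Optional list of source-domain subjects
#'   (`intensity`, `labels`, optional `weights`) whose (possibly
#'   self-generated) labels anchor the training set: the effective
#'   source domain of the propagation step. Their patches are mixed
#'   with the target-domain pseudo-label patches.
#' @return List with `model` (adapted [SegModel-class]) and `pseudo`
#'   (the [makePseudoLabels()] output used for training).
#' @export
adaptToDomain <- function(sourceModel, confModel, volumes,
                          tcfg = sourceModel@trainConfig, warmStart = TRUE,
                          threshold = 0.5, initModel = sourceModel,
                          sourceSubjects = list()) {
  if (length(volumes) < 1L) stop("need at least one target volume")
  pseudo <- makePseudoLabels(sourceModel, confModel, volumes, threshold)
  mcfg <- sourceModel@config
  patches <- list()
  for (si in seq_along(volumes)) {
    patches <- c(patches, segPatchesFromSubject(
      volumes[[si]], pseudo[[si]]$labels, pseudo[[si]]$weights, tcfg,
      seed = childSeed(tcfg@seed, paste0("adapt", si))))
  }
  for (si in seq_along(sourceSubjects)) {
    s <- sourceSubjects[[si]]
    patches <- c(patches, segPatchesFromSubject(
      s$intensity, s$labels, s$weights, tcfg,
      seed = childSeed(tcfg@seed, paste0("adaptsrc", si))))
  }
  init <- if (warmStart) initModel else buildSegModel(mcfg, tcfg@seed, tcfg)
  dims <- rep(tcfg@patchSize, 3L)
  fit <- trainLoop(
    init@params, patches, dims, tcfg,
    forward = function(p, x, d, training) segForward(p, x, d, mcfg, training),
    backward = function(p, cache, gz) segBackward(p, cache, gz, mcfg),
    lossGrad = ceLossGrad)
  model <- new("SegModel", params = fit$params, config = mcfg,
               trainConfig = tcfg, lossTrace = fit$trace,
               normalization = sourceModel@normalization)
  list(model = model, pseudo = pseudo)
}

#' Gradual label propagation along a domain chain
#'
#' Applies the self-supervised adaptation step by step along the
#' propagation plan: the model adapted to domain k becomes the effective
#' source for domain k+1, so labels flow gradually from the labeled
#' source domain to the farthest target domain instead of jumping the
#' full distribution gap at once. The confidence model is trained once
#' on the source domain and reused at every step.
#'
#' @param sourceSubjects Labeled source-domain subjects (`intensity`,
#'   `labels`).
#' @param plan A [PropagationPlan-class]; the first id is the source
#'   domain.
#' @param targetVolumes Named list (by domain id) of lists of unlabeled
#'   [IntensityVolume-class] volumes for every later plan domain.
#' @param tcfg,mcfg Training and architecture configuration.
#' @param confModel Optional pre-trained [ConfModel-class]; when NULL it
#'   is trained via [kfoldSelfTest()] + [trainConfidenceModel()].
#' @param sourceModel Optional pre-trained source [SegModel-class].
#' @param K Folds for the confidence self-testing (default 2).
#' @param warmStart Passed to [adaptToDomain()].
#' @param anchorPrevious Logical (default TRUE): each step also trains
#'   on the previous domain's self-segmented volumes -- the effective
#'   source domain of that step, mirroring the protocol in which a
#'   domain with automated segmentations plays the source role for the
#'   next -- in addition to the new target's gated pseudo-labels. With
#'   FALSE each domain-specific model trains on its own domain's
#'   pseudo-labels only.
#' @return List with `models` (named by domain id, including the
#'   source), `confModel`, and `log` (data.frame, one row per adapted
#'   domain: retained fractions and final training loss).
#' @export
gradualPropagation <- function(sourceSubjects, plan = propagationPlan(),
                               targetVolumes = list(),
                               tcfg = trainConfig(), mcfg = segModelConfig(),
                               confModel = NULL, sourceModel = NULL,
                               K = 2L, warmStart = TRUE,
                               anchorPrevious = TRUE) {
  domains <- plan@domains
  if (is.null(sourceModel))
    sourceModel <- trainSourceModel(sourceSubjects, tcfg, mcfg)
  models <- list()
  models[[domains[1L]]] <- sourceModel
  if (length(domains) == 1L)
    return(list(models = models, confModel = confModel,
                log = data.frame()))
  missing <- setdiff(domains[-1L], names(targetVolumes))
  if (length(missing))
    stop(sprintf("missing unlabeled volumes for domain(s): %s",
                 paste(missing, collapse = ", ")))
  if (is.null(confModel)) {
    pairs <- kfoldSelfTest(sourceSubjects, K = K, tcfg = tcfg, mcfg = mcfg)
    confModel <- trainConfidenceModel(pairs, tcfg)
  }
  logRows <- list()
  current <- sourceModel
  # the effective source domain of each step: the labeled source
  # subjects first, then the previous domain's self-segmented volumes
  anchor <- if (anchorPrevious) sourceSubjects else list()
  for (k in seq_along(domains)[-1L]) {
    dom <- domains[k]
    tk <- tcfg
    tk@seed <- childSeed(tcfg@seed, paste0("domain", dom))
    ad <- adaptToDomain(current, confModel, targetVolumes[[dom]],
                        tcfg = tk, warmStart = warmStart,
                        sourceSubjects = anchor)
    models[[dom]] <- ad$model
    if (anchorPrevious) {
      # re-segment this domain with its adapted model: these self-
      # segmented subjects become the source domain of the next step
      anchorPseudo <- makePseudoLabels(ad$model, confModel,
                                       targetVolumes[[dom]])
      anchor <- lapply(seq_along(targetVolumes[[dom]]), function(i)
        list(intensity = targetVolumes[[dom]][[i]],
             labels = anchorPseudo[[i]]$labels,
             weights = anchorPseudo[[i]]$weights))
    }
    ret <- mean(vapply(ad$pseudo, function(p) p$retained, numeric(1)))
    logRows[[length(logRows) + 1L]] <- data.frame(
      domain = dom,
      nVolumes = length(targetVolumes[[dom]]),
      retained = ret,
      finalLoss = ad$model@lossTrace[length(ad$model@lossTrace)])
    current <- ad$model
  }
  list(models = models, confModel = confModel,
       log = do.call(rbind, logRows))
}
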