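#' Construct a LabelVolume
#'
#' @param voxels 3D integer array with codes in 0..3.
#' @param spacing Voxel spacing in mm (recycled to length 3).
#' @return A [LabelVolume-class].
#' @export
labelVolume <- function(voxels, spacing = c(0.8, 0.8, 0.8)) {
  storage.mode(voxels) <- "integer"
  new("LabelVolume", voxels = voxels, spacing = rep_len(as.numeric(spacing), 3L))
}

#' Construct an IntensityVolume
#'
#' @param voxels 4D numeric array `[x, y, z, channel]` (a 3D array is
#'   promoted to a single channel).
#' @param spacing Voxel spacing in mm.
#' @param domainId Character domain tag.
#' @return An [IntensityVolume-class].
#' @export
intensityVolume <- function(voxels, spacing = c(0.8, 0.8, 0.8), domainId = "") {
  if (length(dim(voxels)) == 3L) dim(voxels) <- c(dim(voxels), 1L)
  new("IntensityVolume", voxels = voxels,
      spacing = rep_len(as.numeric(spacing), 3L), domainId = domainId)
}

#' Construct ProbabilityMaps
#'
#' @param voxels 4D numeric array `[x, y, z, class]`, 4 classes,
#'   simplex-valid per voxel.
#' @param spacing Voxel spacing in mm.
#' @return A [ProbabilityMaps-class].
#' @export
probabilityMaps <- function(voxels, spacing = c(0.8, 0.8, 0.8)) {
  new("ProbabilityMaps", voxels = voxels,
      spacing = rep_len(as.numeric(spacing), 3L))
}

#' Construct a ConfidenceMap
#'
#' @param voxels 3D numeric array with values in `[0, 1]`.
#' @param spacing Voxel spacing in mm.
#' @return A [ConfidenceMap-class].
#' @export
confidenceMap <- function(voxels, spacing = c(0.8, 0.8, 0.8)) {
  new("ConfidenceMap", voxels = voxels,
      spacing = rep_len(as.numeric(spacing), 3L))
}

#' Construct a DomainSpec
#'
#' Defaults describe a high-contrast "24-month-like" domain: on the
#' T1w-like channel WM is brightest, then GM, then CSF; the T2w-like
#' channel inverts the CSF/WM ordering. Units are arbitrary.
#'
#' @param domainId Character label.
#' @param means,sds 4x2 matrices (rows background, CSF, GM, WM; columns
#'   channel 1 and 2).
#' @param noiseSigma Additive Gaussian noise sd (after blurring).
#' @param blurSigma Gaussian partial-volume blur width in voxels.
#' @param t2Inverted Logical polarity flag for channel 2.
#' @return A [DomainSpec-class].
#' @export
#' @examples
#' spec <- domainSpec()
#' contrastIndex(spec)
domainSpec <- function(domainId = "24m",
                       means = defaultTissueMeans(),
                       sds = defaultTissueSds(),
                       noiseSigma = 3, blurSigma = 0.6, t2Inverted = TRUE) {
  dimnames(means) <- dimnames(sds) <- list(TISSUE_NAMES, c("T1", "T2"))
  new("DomainSpec", domainId = domainId, means = means, sds = sds,
      noiseSigma = noiseSigma, blurSigma = blurSigma, t2Inverted = t2Inverted)
}

#' @rdname domainSpec
#' @export
defaultTissueMeans <- function() {
  matrix(c(  5, 25, 55, 75,    # T1w-like: CSF dark, WM bright
             5, 85, 55, 35),   # T2w-like: CSF bright, WM dark
         nrow = 4L, dimnames = list(TISSUE_NAMES, c("T1", "T2")))
}

#' @rdname domainSpec
#' @export
defaultTissueSds <- function() {
  matrix(5, nrow = 4L, ncol = 2L,
         dimnames = list(TISSUE_NAMES, c("T1", "T2")))
}

#' Construct a SegModelConfig
#'
#' @param nClasses Number of classes (fixed at 4).
#' @param nDenseBlocks Dense blocks along the two paths (7).
#' @param convsPerBlock Convolutions per block (3).
#' @param kernelsPerConv Kernels per convolution (16).
#' @param dropoutRate Dropout rate (0.1).
#' @param inputChannels Input channels (2).
#' @param sizeScale Width multiplier for desk-scale runs (1).
#' @return A [SegModelConfig-class].
#' @export
segModelConfig <- function(nClasses = 4L, nDenseBlocks = 7L,
                           convsPerBlock = 3L, kernelsPerConv = 16L,
                           dropoutRate = 0.1, inputChannels = 2L,
                           sizeScale = 1) {
  new("SegModelConfig", nClasses = as.integer(nClasses),
      nDenseBlocks = as.integer(nDenseBlocks),
      convsPerBlock = as.integer(convsPerBlock),
      kernelsPerConv = as.integer(kernelsPerConv),
      dropoutRate = dropoutRate, inputChannels = as.integer(inputChannels),
      sizeScale = sizeScale)
}

#' Construct a TrainConfig
#'
#' @param learningRate Initial SGD learning rate (0.005).
#' @param lrDecay Per-epoch learning-rate multiplier (0.1).
#' @param momentum Classical momentum coefficient (0.9).
#' @param nEpochs Number of epochs (4).
#' @param batchSize Minibatch size (8).
#' @param patchesPerSubject Patches sampled per subject (1000).
#' @param patchSize Cubic patch edge length, multiple of 8 (32).
#' @param inferenceStride Sliding-window stride at inference; `NA` means
#'   50% overlap.
#' @param seed Integer RNG seed.
#' @return A [TrainConfig-class].
#' @export
trainConfig <- function(learningRate = 0.005, lrDecay = 0.1, momentum = 0.9,
                        nEpochs = 4L, batchSize = 8L,
                        patchesPerSubject = 1000L, patchSize = 32L,
                        inferenceStride = NA_integer_, seed = 1L) {
  new("TrainConfig", learningRate = learningRate, lrDecay = lrDecay,
      momentum = momentum, nEpochs = as.integer(nEpochs),
      batchSize = as.integer(batchSize),
      patchesPerSubject = as.integer(patchesPerSubject),
      patchSize = as.integer(patchSize),
      inferenceStride = as.integer(inferenceStride), seed = as.integer(seed))
}

#' Construct ConfLossParams
#'
#' @param a Class-balance constant, > 0 (0.1).
#' @return A [ConfLossParams-class].
#' @export
confLossParams <- function(a = 0.1) new("ConfLossParams", a = a)

#' Construct a PropagationPlan
#'
#' @param domains Ordered character vector of domain ids, labeled source
#'   domain first. Default mirrors the six-step chain 24m -> 0-3m.
#' @return A [PropagationPlan-class].
#' @export
propagationPlan <- function(domains = defaultDomainIds()) {
  new("PropagationPlan", domains = domains)
}

#' Default domain identifiers
#'
#' Six domains mirroring ages at which infant cerebellum MRI contrast
#' progressively collapses.
#'
#' @return Character vector "24m", "18m", "12m", "9m", "6m", "0-3m".
#' @export
defaultDomainIds <- function() c("24m", "18m", "12m", "9m", "6m", "0-3m")
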