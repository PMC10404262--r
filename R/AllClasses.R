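## S4 containers. Volumes wrap plain arrays plus voxel spacing in mm; heavy
## numeric work happens on the raw arrays, the classes enforce the contracts.

setClassUnion("arrayOrNULL", c("array", "NULL"))

#' LabelVolume: integer tissue map
#'
#' A 3D integer tissue map with codes 0 (background), 1 (CSF), 2 (GM),
#' 3 (WM) and isotropic-or-not voxel spacing in mm.
#'
#' @slot voxels 3D integer array with values in 0..3.
#' @slot spacing Numeric length-3, mm per voxel along each axis.
#' @export
setClass("LabelVolume",
  representation(voxels = "array", spacing = "numeric"),
  validity = function(object) {
    v <- object@voxels
    if (length(dim(v)) != 3L) return("voxels must be a 3D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive values (mm)")
    bad <- setdiff(unique(as.vector(v)), 0:3)
    if (length(bad))
      return(paste0("label codes outside {0,1,2,3}: ",
                    paste(head(bad, 5), collapse = ", ")))
    TRUE
  })

#' IntensityVolume: multi-channel image volume
#'
#' A 3D volume with 2 channels by default (T1w-like and T2w-like), stored
#' as a 4D array `[x, y, z, channel]`.
#'
#' @slot voxels 4D numeric array, finite values.
#' @slot spacing Numeric length-3 voxel spacing in mm.
#' @slot domainId Character tag of the imaging domain ("" if unknown).
#' @export
setClass("IntensityVolume",
  representation(voxels = "array", spacing = "numeric", domainId = "character"),
  validity = function(object) {
    v <- object@voxels
    if (length(dim(v)) != 4L) return("voxels must be a 4D array [x,y,z,channel]")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive values (mm)")
    if (!all(is.finite(v))) return("intensities must be finite")
    TRUE
  })

#' ProbabilityMaps: per-voxel class probabilities
#'
#' Four per-voxel tissue probabilities on the simplex (sum 1 within 1e-6).
#'
#' @slot voxels 4D numeric array `[x, y, z, class]` with 4 classes.
#' @slot spacing Numeric length-3 voxel spacing in mm.
#' @export
setClass("ProbabilityMaps",
  representation(voxels = "array", spacing = "numeric"),
  validity = function(object) {
    v <- object@voxels
    if (length(dim(v)) != 4L || dim(v)[4] != 4L)
      return("voxels must be a 4D array with 4 class channels")
    if (any(v < -1e-9)) return("negative probabilities")
    s <- rowSums(matrix(v, ncol = 4L))
    if (max(abs(s - 1)) > 1e-6)
      return("per-voxel probabilities must sum to 1 within 1e-6")
    TRUE
  })

#' ConfidenceMap: voxel-wise reliability scores
#'
#' Per-voxel reliability of an automated segmentation, in `[0, 1]`; the
#' output M_cp of the confidence network (or a binary agreement target).
#'
#' @slot voxels 3D numeric array in `[0, 1]`.
#' @slot spacing Numeric length-3 voxel spacing in mm.
#' @export
setClass("ConfidenceMap",
  representation(voxels = "array", spacing = "numeric"),
  validity = function(object) {
    v <- object@voxels
    if (length(dim(v)) != 3L) return("voxels must be a 3D array")
    if (any(v < 0 | v > 1)) return("confidence values must lie in [0,1]")
    TRUE
  })

#' DomainSpec: tissue intensity model of one imaging domain
#'
#' Per-tissue, per-channel intensity means and standard deviations plus
#' noise and partial-volume blur parameters. One DomainSpec emulates one
#' age/site domain; a series of them with shrinking GM--WM contrast
#' emulates the contrast collapse towards younger infants.
#'
#' @slot domainId Character label, e.g. "24m".
#' @slot means 4x2 matrix (rows background, CSF, GM, WM; columns T1w-like,
#'   T2w-like) of intensity means in arbitrary units.
#' @slot sds 4x2 matrix of within-tissue standard deviations, all > 0.
#' @slot noiseSigma Additive Gaussian noise sd applied after blurring.
#' @slot blurSigma Gaussian partial-volume blur width in voxels.
#' @slot t2Inverted Logical; TRUE when the second channel inverts the
#'   CSF/WM intensity ordering relative to the first (as T2w does).
#' @export
setClass("DomainSpec",
  representation(domainId = "character", means = "matrix", sds = "matrix",
                 noiseSigma = "numeric", blurSigma = "numeric",
                 t2Inverted = "logical"),
  validity = function(object) {
    if (!all(dim(object@means) == c(4L, 2L))) return("means must be 4x2")
    if (!all(dim(object@sds) == c(4L, 2L))) return("sds must be 4x2")
    if (any(object@sds < 0)) return("standard deviations must be >= 0")
    if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
    if (object@blurSigma < 0) return("blurSigma must be >= 0")
    if (isTRUE(object@t2Inverted) &&
        object@means["CSF", 2L] <= object@means["WM", 2L])
      return("t2Inverted requires CSF > WM mean intensity on channel 2")
    TRUE
  })

#' PatchSet: patch representation of a volume
#'
#' Cubic blocks cut from one volume, with optional aligned label and
#' weight blocks, plus enough geometry to reassemble predictions.
#'
#' @slot intensity List of 4D arrays `size^3 x channels`.
#' @slot labels List of 3D integer arrays (or NULL per entry).
#' @slot weights List of 3D numeric arrays (or NULL per entry).
#' @slot corners Integer matrix n x 3 of 1-based corner positions.
#' @slot patchSize Integer edge length.
#' @slot sourceShape Integer length-3 extents of the source volume.
#' @slot sourceSpacing Numeric length-3 spacing of the source volume.
#' @export
setClass("PatchSet",
  representation(intensity = "list", labels = "list", weights = "list",
                 corners = "matrix", patchSize = "integer",
                 sourceShape = "integer", sourceSpacing = "numeric"),
  validity = function(object) {
    n <- length(object@intensity)
    if (nrow(object@corners) != n) return("one corner per patch required")
    if (any(object@corners < 1L)) return("corners must be 1-based positive")
    hi <- sweep(object@corners, 2L, object@sourceShape - object@patchSize + 1L)
    if (any(hi > 0L)) return("patch exceeds source volume extent")
    TRUE
  })

#' SegModelConfig: architecture of the segmentation network
#'
#' The dense-block encoder--decoder contract: seven dense blocks along a
#' contracting and an expanding path, three norm-ReLU-conv-dropout
#' operations per block, 16 kernels per convolution, dropout 0.1, two
#' input channels and a final convolution + softmax over 4 classes.
#' `sizeScale` multiplies the kernel count so desk-scale CPU runs can
#' shrink width without changing the wiring.
#'
#' @slot nClasses Integer, fixed at 4.
#' @slot nDenseBlocks Integer number of dense blocks (7).
#' @slot convsPerBlock Integer convolutions per dense block (3).
#' @slot kernelsPerConv Integer growth rate per convolution (16).
#' @slot dropoutRate Numeric dropout probability (0.1).
#' @slot inputChannels Integer input channels (2: T1w-like, T2w-like).
#' @slot sizeScale Numeric width multiplier for desk-scale runs.
#' @export
setClass("SegModelConfig",
  representation(nClasses = "integer", nDenseBlocks = "integer",
                 convsPerBlock = "integer", kernelsPerConv = "integer",
                 dropoutRate = "numeric", inputChannels = "integer",
                 sizeScale = "numeric"),
  validity = function(object) {
    if (object@nClasses != 4L) return("nClasses is fixed at 4")
    if (object@nDenseBlocks < 1L) return("need at least one dense block")
    if (object@dropoutRate < 0 || object@dropoutRate >= 1)
      return("dropoutRate must be in [0,1)")
    if (object@sizeScale <= 0) return("sizeScale must be positive")
    TRUE
  })

#' TrainConfig: optimization settings
#'
#' SGD with Xavier initialization, learning rate 0.005 multiplied by 0.1
#' after each epoch; 1000 patches of size 32^3 per subject by default.
#' Momentum, epoch count and batch size are package choices the training
#' recipe leaves open.
#'
#' @slot learningRate Numeric initial learning rate (0.005).
#' @slot lrDecay Numeric per-epoch multiplier (0.1).
#' @slot momentum Numeric classical momentum coefficient (0.9).
#' @slot nEpochs Integer epochs (default 4).
#' @slot batchSize Integer minibatch size (default 8).
#' @slot patchesPerSubject Integer patches sampled per subject (1000).
#' @slot patchSize Integer cubic patch edge (32).
#' @slot inferenceStride Integer sliding-window stride at inference;
#'   `NA` means 50% overlap (patchSize / 2).
#' @slot seed Integer RNG seed for sampling, init and dropout.
#' @export
setClass("TrainConfig",
  representation(learningRate = "numeric", lrDecay = "numeric",
                 momentum = "numeric", nEpochs = "integer",
                 batchSize = "integer", patchesPerSubject = "integer",
                 patchSize = "integer", inferenceStride = "integer",
                 seed = "integer"),
  validity = function(object) {
    if (object@learningRate <= 0) return("learningRate must be > 0")
    if (object@nEpochs < 1L) return("nEpochs must be >= 1")
    if (object@patchSize < 8L || object@patchSize %% 8L != 0L)
      return("patchSize must be a multiple of 8 (three pooling levels)")
    if (object@momentum < 0 || object@momentum >= 1)
      return("momentum must be in [0,1)")
    TRUE
  })

#' ConfLossParams: class-balance constant of the confidence loss
#'
#' The constant `a` scaling the penalty on misclassified voxels in the
#' confidence loss; 0.1 alleviates the volume bias between correctly
#' classified (many) and misclassified (few) voxels.
#'
#' @slot a Numeric, > 0 (default 0.1).
#' @export
setClass("ConfLossParams",
  representation(a = "numeric"),
  validity = function(object) {
    if (length(object@a) != 1L || object@a <= 0) return("a must be > 0")
    TRUE
  })

#' PropagationPlan: ordered domain chain
#'
#' The gradual label-propagation order from the labeled source domain to
#' the farthest target domain (default 24m -> 18m -> 12m -> 9m -> 6m ->
#' 0-3m).
#'
#' @slot domains Character vector of domain ids, source first, no repeats.
#' @export
setClass("PropagationPlan",
  representation(domains = "character"),
  validity = function(object) {
    if (length(object@domains) < 1L) return("plan must name >= 1 domain")
    if (anyDuplicated(object@domains)) return("domain ids must not repeat")
    TRUE
  })

#' SegModel: trained segmentation network
#'
#' Parameters plus configuration of a dense-block encoder--decoder
#' segmentation network; produced by [buildSegModel()] and the training
#' functions.
#'
#' @slot params List of layer parameter lists (weights, biases, affine
#'   normalization parameters).
#' @slot config A [SegModelConfig-class].
#' @slot trainConfig A [TrainConfig-class] (the one used to train, or the
#'   one supplied at construction).
#' @slot lossTrace Numeric per-epoch mean training loss (empty if untrained).
#' @slot normalization Character; "zscore" channel-wise volume
#'   normalization applied before patch extraction and inference.
#' @export
setClass("SegModel",
  representation(params = "list", config = "SegModelConfig",
                 trainConfig = "TrainConfig", lossTrace = "numeric",
                 normalization = "character"))

#' ConfModel: trained confidence network
#'
#' A U-Net style encoder--decoder that maps (one-hot segmentation,
#' probability maps) to a voxel-wise reliability score in (0, 1).
#'
#' @slot params List of layer parameter lists.
#' @slot depth Integer number of pooling levels.
#' @slot width Integer channels per convolution.
#' @slot inChannels Integer input channels (8 = 4 one-hot + 4 probability).
#' @slot trainConfig A [TrainConfig-class].
#' @slot lossParams A [ConfLossParams-class].
#' @slot lossTrace Numeric per-epoch mean training loss.
#' @export
setClass("ConfModel",
  representation(params = "list", depth = "integer", width = "integer",
                 inChannels = "integer", trainConfig = "TrainConfig",
                 lossParams = "ConfLossParams", lossTrace = "numeric"))
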