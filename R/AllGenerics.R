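#' Access the voxel array of a volume object
#'
#' @param x A volume-like object (LabelVolume, IntensityVolume,
#'   ProbabilityMaps, ConfidenceMap).
#' @return The underlying array.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' Voxel spacing in mm
#'
#' @param x A volume-like object.
#' @return Numeric length-3 spacing in mm.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Domain identifier
#'
#' @param x An object carrying a domain tag.
#' @return Character domain id.
#' @export
setGeneric("domainId", function(x) standardGeneric("domainId"))

#' Per-epoch training loss trace
#'
#' @param x A trained model.
#' @return Numeric vector, one mean loss per epoch.
#' @export
setGeneric("lossTrace", function(x) standardGeneric("lossTrace"))

#' Scalar tissue-contrast index of a domain
#'
#' `|mean_GM - mean_WM| / pooled sd` on the first (T1w-like) channel,
#' where the pooled sd folds in the additive noise:
#' `sqrt(mean(sd_GM^2, sd_WM^2) + noiseSigma^2)`. The index strictly
#' decreases along an age-descending domain series.
#'
#' @param x A [DomainSpec-class] or list of them.
#' @return Numeric contrast index (vector for a list).
#' @export
setGeneric("contrastIndex", function(x) standardGeneric("contrastIndex"))

#' @rdname voxels
#' @export
setMethod("voxels", "LabelVolume", function(x) x@voxels)
#' @rdname voxels
#' @export
setMethod("voxels", "IntensityVolume", function(x) x@voxels)
#' @rdname voxels
#' @export
setMethod("voxels", "ProbabilityMaps", function(x) x@voxels)
#' @rdname voxels
#' @export
setMethod("voxels", "ConfidenceMap", function(x) x@voxels)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "LabelVolume", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "IntensityVolume", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "ProbabilityMaps", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "ConfidenceMap", function(x) x@spacing)

#' @rdname domainId
#' @export
setMethod("domainId", "IntensityVolume", function(x) x@domainId)
#' @rdname domainId
#' @export
setMethod("domainId", "DomainSpec", function(x) x@domainId)

#' @rdname lossTrace
#' @export
setMethod("lossTrace", "SegModel", function(x) x@lossTrace)
#' @rdname lossTrace
#' @export
setMethod("lossTrace", "ConfModel", function(x) x@lossTrace)

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@voxels)
  tab <- table(factor(object@voxels, levels = 0:3,
                      labels = TISSUE_NAMES))
  cat(sprintf("LabelVolume %dx%dx%d, spacing %s mm\n", d[1], d[2], d[3],
              paste(format(object@spacing), collapse = "x")))
  print(tab)
})

setMethod("show", "IntensityVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("IntensityVolume %dx%dx%d, %d channel(s), spacing %s mm%s\n",
              d[1], d[2], d[3], d[4],
              paste(format(object@spacing), collapse = "x"),
              if (nzchar(object@domainId))
                paste0(", domain ", object@domainId) else ""))
})

setMethod("show", "ProbabilityMaps", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ProbabilityMaps %dx%dx%d, 4 classes, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(object@spacing), collapse = "x")))
})

setMethod("show", "ConfidenceMap", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ConfidenceMap %dx%dx%d, mean %.3f, range [%.3f, %.3f]\n",
              d[1], d[2], d[3], mean(object@voxels), min(object@voxels),
              max(object@voxels)))
})

setMethod("show", "DomainSpec", function(object) {
  cat(sprintf("DomainSpec '%s': contrast index %.3f, noise %.2f, blur %.2f vox\n",
              object@domainId, contrastIndex(object), object@noiseSigma,
              object@blurSigma))
  m <- cbind(object@means, object@sds)
  colnames(m) <- c("mean.T1", "mean.T2", "sd.T1", "sd.T2")
  print(round(m, 2))
})

setMethod("show", "PatchSet", function(object) {
  cat(sprintf("PatchSet: %d patches of %d^3 from a %s volume\n",
              length(object@intensity), object@patchSize,
              paste(object@sourceShape, collapse = "x")))
})

setMethod("show", "SegModel", function(object) {
  cfg <- object@config
  cat(sprintf(paste0("SegModel: %d dense blocks, growth %d (sizeScale %.2f), ",
                     "%s\n"),
              cfg@nDenseBlocks,
              max(2L, as.integer(round(cfg@kernelsPerConv * cfg@sizeScale))),
              cfg@sizeScale,
              if (length(object@lossTrace))
                sprintf("trained %d epoch(s), final loss %.4f",
                        length(object@lossTrace),
                        object@lossTrace[length(object@lossTrace)])
              else "untrained"))
})

setMethod("show", "ConfModel", function(object) {
  cat(sprintf("ConfModel: U-Net depth %d, width %d, %d input channels, %s\n",
              object@depth, object@width, object@inChannels,
              if (length(object@lossTrace))
                sprintf("trained %d epoch(s), final loss %.4f",
                        length(object@lossTrace),
                        object@lossTrace[length(object@lossTrace)])
              else "untrained"))
})

setMethod("show", "PropagationPlan", function(object) {
  cat("PropagationPlan:", paste(object@domains, collapse = " -> "), "\n")
})
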