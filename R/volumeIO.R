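## NIfTI I/O, isotropic resampling, and the patch representation used
## for training and sliding-window inference.

#' Write a volume to NIfTI-1
#'
#' Label volumes are written as 3D int16; intensity volumes as 4D float
#' with channels along the fourth dimension; confidence maps as 3D
#' float. Voxel spacing goes into the header. For an
#' [IntensityVolume-class] with a non-empty domain id a JSON sidecar
#' `<path minus extensions>.json` records the id.
#'
#' @param volume A [LabelVolume-class], [IntensityVolume-class] or
#'   [ConfidenceMap-class].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
writeVolume <- function(volume, path) {
  if (is(volume, "LabelVolume")) {
    dtype <- "int16"
  } else if (is(volume, "IntensityVolume") || is(volume, "ConfidenceMap")) {
    dtype <- "float"
  } else {
    stop("writeVolume handles LabelVolume, IntensityVolume and ConfidenceMap")
  }
  img <- RNifti::asNifti(volume@voxels)
  RNifti::pixdim(img) <- volume@spacing
  RNifti::writeNifti(img, path, datatype = dtype)
  if (is(volume, "IntensityVolume") && nzchar(volume@domainId)) {
    side <- sub("\\.nii(\\.gz)?$", ".json", path)
    jsonlite::write_json(list(domainId = volume@domainId), side,
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a volume from NIfTI-1
#'
#' A 3D file with integer-valued voxels is returned as a
#' [LabelVolume-class] (codes validated to 0..3); a 4D file becomes an
#' [IntensityVolume-class] with one channel per fourth-dimension volume.
#' Spacing is taken from the header.
#'
#' @param path NIfTI file path.
#' @param kind `"auto"` (default), `"label"` or `"intensity"`.
#' @return A [LabelVolume-class] or [IntensityVolume-class].
#' @export
readVolume <- function(path, kind = c("auto", "label", "intensity")) {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  v <- array(as.vector(as.array(img)), dim = dim(img))
  spc <- RNifti::pixdim(img)[seq_len(min(3L, length(dim(v))))]
  spc <- rep_len(as.numeric(spc), 3L)
  nd <- length(dim(v))
  if (kind == "auto") kind <- if (nd >= 4L) "intensity" else "label"
  if (kind == "label") {
    if (nd != 3L) stop("label volumes must be 3D")
    if (any(abs(v - round(v)) > 1e-6))
      stop("label file contains non-integer values")
    codes <- unique(as.vector(round(v)))
    bad <- setdiff(codes, 0:3)
    if (length(bad))
      stop(sprintf("label file contains codes outside {0,1,2,3}: %s",
                   paste(sort(bad), collapse = ", ")))
    labelVolume(array(as.integer(round(v)), dim = dim(v)), spc)
  } else {
    if (nd == 3L) dim(v) <- c(dim(v), 1L)
    if (nd > 4L) stop("intensity volumes must be 3D or 4D")
    dom <- ""
    side <- sub("\\.nii(\\.gz)?$", ".json", path)
    if (file.exists(side)) {
      meta <- try(jsonlite::read_json(side), silent = TRUE)
      if (!inherits(meta, "try-error") && !is.null(meta$domainId))
        dom <- as.character(meta$domainId)
    }
    intensityVolume(v * 1.0, spc, domainId = dom)
  }
}

#' Resample a volume to isotropic spacing
#'
#' Intensities are interpolated trilinearly, labels by nearest neighbor
#' (so output codes are a subset of input codes). Output extent per axis
#' is `round(extent * spacing / target)`. A volume already at the target
#' spacing is returned with an identical voxel array.
#'
#' @param volume A [LabelVolume-class] or [IntensityVolume-class].
#' @param targetSpacing Target isotropic spacing in mm (default 0.8).
#' @return The resampled volume of the same class.
#' @export
resampleIsotropic <- function(volume, targetSpacing = 0.8) {
  spc <- volume@spacing
  if (all(abs(spc - targetSpacing) < 1e-12)) return(volume)
  isLab <- is(volume, "LabelVolume")
  v <- volume@voxels
  d <- dim(v)[1:3]
  newd <- pmax(1L, as.integer(round(d * spc / targetSpacing)))
  # voxel-center aligned source coordinates (1-based)
  coord <- function(axis) {
    x <- ((seq_len(newd[axis]) - 0.5) * targetSpacing / spc[axis]) + 0.5
    pmin(pmax(x, 1), d[axis])
  }
  cx <- coord(1L); cy <- coord(2L); cz <- coord(3L)
  if (isLab) {
    ix <- pmin(pmax(round(cx), 1L), d[1])
    iy <- pmin(pmax(round(cy), 1L), d[2])
    iz <- pmin(pmax(round(cz), 1L), d[3])
    out <- v[ix, iy, iz, drop = FALSE]
    return(labelVolume(array(out, dim = newd), rep(targetSpacing, 3L)))
  }
  nch <- dim(v)[4]
  out <- array(0, dim = c(newd, nch))
  fx <- floor(cx); fy <- floor(cy); fz <- floor(cz)
  tx <- cx - fx; ty <- cy - fy; tz <- cz - fz
  x0 <- pmin(fx, d[1]); x1 <- pmin(fx + 1, d[1])
  y0 <- pmin(fy, d[2]); y1 <- pmin(fy + 1, d[2])
  z0 <- pmin(fz, d[3]); z1 <- pmin(fz + 1, d[3])
  WX <- cbind(1 - tx, tx); WY <- cbind(1 - ty, ty); WZ <- cbind(1 - tz, tz)
  XS <- cbind(x0, x1); YS <- cbind(y0, y1); ZS <- cbind(z0, z1)
  for (ch in seq_len(nch)) {
    acc <- array(0, dim = newd)
    for (a in 1:2) for (b in 1:2) for (cc in 1:2) {
      w <- outer(outer(WX[, a], WY[, b]), WZ[, cc])
      acc <- acc + w * v[XS[, a], YS[, b], ZS[, cc], ch, drop = FALSE][, , , 1L]
    }
    out[, , , ch] <- acc
  }
  intensityVolume(out, rep(targetSpacing, 3L), domainId = volume@domainId)
}

#' Randomly extract cubic patches from a volume
#'
#' Corners are drawn uniformly over positions whose patch overlaps the
#' non-background mask (the labels' foreground when labels are supplied,
#' otherwise an intensity threshold at the channel-1 mean); sampling is
#' deterministic given the seed. Aligned label and weight blocks are cut
#' when available.
#'
#' @param intensity An [IntensityVolume-class] (or 4D array).
#' @param labels Optional [LabelVolume-class] aligned with `intensity`.
#' @param weights Optional 3D numeric array of per-voxel weights.
#' @param n Number of patches (default 1000).
#' @param size Cubic patch edge length (default 32).
#' @param seed Integer seed.
#' @return A [PatchSet-class].
#' @export
extractPatches <- function(intensity, labels = NULL, weights = NULL,
                           n = 1000L, size = 32L, seed = 1L) {
  v <- if (is(intensity, "IntensityVolume")) intensity@voxels else intensity
  spc <- if (is(intensity, "IntensityVolume")) intensity@spacing else c(1, 1, 1)
  d <- dim(v)[1:3]
  size <- as.integer(size)
  if (any(d < size))
    stop(sprintf("volume extent %s smaller than patch size %d",
                 paste(d, collapse = "x"), size))
  lab <- if (is.null(labels)) NULL else labels@voxels
  mask <- if (!is.null(lab)) lab > 0L else v[, , , 1L] > mean(v[, , , 1L])
  if (!any(mask)) mask[] <- TRUE
  idx <- which(mask, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2L, min) - size + 1L, 1L)
  hi <- pmin(apply(idx, 2L, max), d - size + 1L)
  corners <- withSeed(seed, {
    out <- matrix(0L, nrow = n, ncol = 3L)
    for (i in seq_len(n)) {
      for (try in seq_len(100L)) {
        c0 <- c(sample.int(hi[1] - lo[1] + 1L, 1L) + lo[1] - 1L,
                sample.int(hi[2] - lo[2] + 1L, 1L) + lo[2] - 1L,
                sample.int(hi[3] - lo[3] + 1L, 1L) + lo[3] - 1L)
        sub <- mask[c0[1]:(c0[1] + size - 1L), c0[2]:(c0[2] + size - 1L),
                    c0[3]:(c0[3] + size - 1L)]
        if (any(sub)) break
      }
      out[i, ] <- c0
    }
    out
  })
  cut <- function(arr, c0, fourD) {
    if (fourD)
      arr[c0[1]:(c0[1] + size - 1L), c0[2]:(c0[2] + size - 1L),
          c0[3]:(c0[3] + size - 1L), , drop = FALSE]
    else
      arr[c0[1]:(c0[1] + size - 1L), c0[2]:(c0[2] + size - 1L),
          c0[3]:(c0[3] + size - 1L), drop = FALSE]
  }
  ints <- lapply(seq_len(n), function(i) cut(v, corners[i, ], TRUE))
  labs <- if (is.null(lab)) rep(list(NULL), n)
    else lapply(seq_len(n), function(i) cut(lab, corners[i, ], FALSE))
  wts <- if (is.null(weights)) rep(list(NULL), n)
    else lapply(seq_len(n), function(i) cut(weights, corners[i, ], FALSE))
  new("PatchSet", intensity = ints, labels = labs, weights = wts,
      corners = corners, patchSize = size, sourceShape = as.integer(d),
      sourceSpacing = spc)
}

#' Reassemble per-voxel probabilities from patch predictions
#'
#' Per-voxel probabilities are averaged over all covering patches and
#' renormalized to the simplex. Every voxel of the foreground mask (all
#' voxels when no mask is given) must be covered by at least one patch.
#' Voxels covered by no patch are set to background probability 1.
#'
#' @param blocks List of 4D probability blocks `size^3 x 4`.
#' @param corners Integer matrix n x 3 of 1-based corners.
#' @param shape Integer length-3 source volume extents.
#' @param spacing Voxel spacing of the source volume.
#' @param mask Optional logical array: foreground that must be covered.
#' @return A [ProbabilityMaps-class].
#' @export
reconstructFromPatches <- function(blocks, corners, shape,
                                   spacing = c(0.8, 0.8, 0.8), mask = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(blocks) == nrow(corners))
  acc <- array(0, dim = c(shape, 4L))
  cnt <- array(0, dim = shape)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    sz <- dim(b)[1:3]
    c0 <- corners[i, ]
    xi <- c0[1]:(c0[1] + sz[1] - 1L)
    yi <- c0[2]:(c0[2] + sz[2] - 1L)
    zi <- c0[3]:(c0[3] + sz[3] - 1L)
    acc[xi, yi, zi, ] <- acc[xi, yi, zi, , drop = FALSE] + b
    cnt[xi, yi, zi] <- cnt[xi, yi, zi] + 1
  }
  uncovered <- cnt == 0
  if (!is.null(mask) && any(mask & uncovered))
    stop(sprintf("coverage error: %d foreground voxel(s) not covered by any patch",
                 sum(mask & uncovered)))
  cnt[uncovered] <- 1
  acc <- acc / as.vector(cnt)
  if (any(uncovered)) {
    bg <- acc[, , , 1L]
    bg[uncovered] <- 1
    acc[, , , 1L] <- bg
  }
  tot <- rowSums(matrix(acc, ncol = 4L))
  acc <- acc / array(tot, dim = dim(acc))
  probabilityMaps(acc, spacing)
}
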