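## Synthetic multi-domain cerebellum phantom.
##
## The white matter core is a recursively branched, dilated tree (a desk-
## scale stand-in for the folded arbor vitae), wrapped in a thin gray
## matter shell and a CSF shell. Per-domain intensity rendering draws
## voxel intensities from tissue distributions, applies a Gaussian
## partial-volume blur, and adds Gaussian noise. A domain series shrinks
## the tissue contrast step by step and grows the noise, emulating the
## collapse of GM/WM contrast towards younger ages.

#' @rdname contrastIndex
#' @export
setMethod("contrastIndex", "DomainSpec", function(x) {
  gap <- abs(x@means["GM", 1L] - x@means["WM", 1L])
  pooled <- sqrt(mean(x@sds[c("GM", "WM"), 1L]^2) + x@noiseSigma^2)
  as.numeric(gap / pooled)
})

#' @rdname contrastIndex
#' @export
setMethod("contrastIndex", "list", function(x) {
  vapply(x, contrastIndex, numeric(1))
})

#' Generate a tree-structured tissue label phantom
#'
#' Carves a recursively branching white-matter tree (each branch a
#' dilated line segment; children start where the parent ends, so the
#' tree is one 26-connected component by construction), then wraps it in
#' a gray-matter shell of the requested thickness and a CSF shell,
#' leaving the remainder background.
#'
#' @param shape Integer length-3 volume extents (each >= 32).
#' @param branchDepth Number of branching generations (>= 1).
#' @param gmThickness GM shell thickness in voxels (>= 1).
#' @param seed Integer seed; the phantom is a pure function of the
#'   arguments and the seed.
#' @param csfThickness CSF shell thickness in voxels.
#' @param spacing Voxel spacing in mm (default 0.8 isotropic).
#' @return A [LabelVolume-class] containing all four tissue codes.
#' @export
#' @examples
#' lab <- makeLabelPhantom(c(48, 48, 48), branchDepth = 3, seed = 7)
#' table(voxels(lab))
makeLabelPhantom <- function(shape = c(64L, 64L, 64L), branchDepth = 4L,
                             gmThickness = 2L, seed = 1L,
                             csfThickness = 2L, spacing = c(0.8, 0.8, 0.8)) {
  shape <- as.integer(rep_len(shape, 3L))
  branchDepth <- as.integer(branchDepth)
  if (branchDepth < 1L) stop("branchDepth must be >= 1")
  if (gmThickness < 1L) stop("gmThickness must be >= 1")
  rootRadius <- max(2L, as.integer(round(min(shape) / 28)))
  margin <- gmThickness + csfThickness + rootRadius + 2L
  if (min(shape) < 32L || min(shape) < 8L * branchDepth + 2L * margin)
    stop(sprintf(
      "shape %s too small to contain %d branching levels (need >= %d per axis)",
      paste(shape, collapse = "x"), branchDepth,
      max(32L, 8L * branchDepth + 2L * margin)))

  lo <- margin + 1L
  hi <- shape - margin
  segments <- withSeed(seed, {
    segs <- list()
    grow <- function(p, dir, len, level) {
      q <- pmin(pmax(p + len * dir, lo), hi)
      r <- max(1L, as.integer(round(rootRadius * 0.75^(level - 1L))))
      segs[[length(segs) + 1L]] <<- list(p = p, q = q, r = r)
      if (level < branchDepth) {
        for (child in 1:2) {
          # tilt the direction by 30-60 degrees at a random azimuth
          theta <- runif(1, pi / 6, pi / 3)
          phi <- runif(1, 0, 2 * pi)
          # orthonormal frame around dir
          u <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
          e1 <- u - sum(u * dir) * dir
          e1 <- e1 / sqrt(sum(e1^2))
          e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
                  dir[3] * e1[1] - dir[1] * e1[3],
                  dir[1] * e1[2] - dir[2] * e1[1])
          nd <- cos(theta) * dir +
            sin(theta) * (cos(phi) * e1 + sin(phi) * e2)
          nd <- nd / sqrt(sum(nd^2))
          grow(q, nd, len * 0.68, level + 1L)
        }
      }
    }
    trunkLen <- 0.34 * (min(shape) - 2 * margin)
    start <- c(shape[1] / 2, shape[2] / 2, lo + 1)
    grow(start, c(0, 0, 1), trunkLen, 1L)
    segs
  })

  wm <- array(FALSE, dim = shape)
  for (s in segments) {
    len <- sqrt(sum((s$q - s$p)^2))
    nSamp <- max(2L, ceiling(len / 0.5) + 1L)
    ts <- seq(0, 1, length.out = nSamp)
    pts <- cbind(s$p[1] + ts * (s$q[1] - s$p[1]),
                 s$p[2] + ts * (s$q[2] - s$p[2]),
                 s$p[3] + ts * (s$q[3] - s$p[3]))
    centers <- unique(round(pts))
    rr <- s$r
    off <- as.matrix(expand.grid(-rr:rr, -rr:rr, -rr:rr))
    off <- off[rowSums(off^2) <= (rr + 0.4)^2, , drop = FALSE]
    for (i in seq_len(nrow(off))) {
      vox <- sweep(centers, 2L, off[i, ], "+")
      keep <- vox[, 1] >= 1 & vox[, 1] <= shape[1] &
        vox[, 2] >= 1 & vox[, 2] <= shape[2] &
        vox[, 3] >= 1 & vox[, 3] <= shape[3]
      vox <- vox[keep, , drop = FALSE]
      wm[vox] <- TRUE
    }
  }

  gmAll <- dilate3(wm, gmThickness, 26L) & !wm
  # Where shells of nearby branches merge the cortex would thicken; carve
  # CSF-filled fissures there (as between folia) so every GM voxel keeps a
  # non-GM voxel in its 26-neighborhood.
  gm <- gmAll
  repeat {
    interior <- gm & !dilate3(!gm, 1L, 26L)
    if (!any(interior)) break
    gm[interior] <- FALSE
  }
  csf <- dilate3(wm | gmAll, csfThickness, 26L) & !(wm | gm)
  labels <- array(0L, dim = shape)
  labels[csf] <- 1L
  labels[gm] <- 2L
  labels[wm] <- 3L
  labelVolume(labels, spacing)
}

#' Build an age-descending series of imaging domains
#'
#' Starting from a base (high-contrast, "24-month-like") domain, each
#' successive spec pulls the CSF/GM/WM means towards their common center
#' so the GM--WM intensity gap shrinks by `contrastDecay` per step, and
#' scales the additive noise by `1 + noiseGrowth`. The contrast index
#' over the series is strictly decreasing.
#'
#' @param base A [DomainSpec-class]; becomes domain 1 unchanged.
#' @param nDomains Number of domains (>= 2; default 6).
#' @param contrastDecay Fractional contrast loss per step, in (0, 1).
#' @param noiseGrowth Fractional noise growth per step (>= 0).
#' @param domainIds Optional character ids; defaults to the 24m..0-3m
#'   names when `nDomains` is 6.
#' @return List of [DomainSpec-class], source domain first.
#' @export
#' @examples
#' series <- makeDomainSeries(domainSpec(), 6, 0.25, 0.1)
#' round(contrastIndex(series), 3)
makeDomainSeries <- function(base = domainSpec(), nDomains = 6L,
                             contrastDecay = 0.25, noiseGrowth = 0.1,
                             domainIds = NULL) {
  nDomains <- as.integer(nDomains)
  if (nDomains < 2L) stop("nDomains must be >= 2")
  if (contrastDecay <= 0 || contrastDecay >= 1)
    stop("contrastDecay must lie in (0, 1)")
  if (noiseGrowth < 0) stop("noiseGrowth must be >= 0")
  if (is.null(domainIds))
    domainIds <- if (nDomains <= 6L) head(defaultDomainIds(), nDomains)
      else paste0("d", seq_len(nDomains) - 1L)
  stopifnot(length(domainIds) == nDomains)

  fg <- c("CSF", "GM", "WM")
  center <- colMeans(base@means[fg, , drop = FALSE])
  out <- vector("list", nDomains)
  for (k in seq_len(nDomains)) {
    shrink <- (1 - contrastDecay)^(k - 1L)
    means <- base@means
    ctr <- matrix(center, nrow = 3L, ncol = 2L, byrow = TRUE)
    means[fg, ] <- ctr + shrink * (base@means[fg, ] - ctr)
    out[[k]] <- domainSpec(
      domainId = domainIds[k], means = means, sds = base@sds,
      noiseSigma = base@noiseSigma * (1 + noiseGrowth)^(k - 1L),
      blurSigma = base@blurSigma,
      t2Inverted = base@t2Inverted &&
        means["CSF", 2L] > means["WM", 2L])
  }
  names(out) <- domainIds
  out
}

#' Render a two-channel intensity volume from a label phantom
#'
#' Per voxel, intensities are drawn from the tissue's per-channel normal
#' distribution, the volume is blurred with a Gaussian of width
#' `blurSigma` voxels (partial-volume emulation), and Gaussian noise of
#' sd `noiseSigma` is added. Deterministic given the seed.
#'
#' @param labels A [LabelVolume-class].
#' @param spec A [DomainSpec-class].
#' @param seed Integer seed.
#' @return An [IntensityVolume-class] with 2 channels and the labels'
#'   shape and spacing.
#' @export
renderIntensities <- function(labels, spec, seed = 1L) {
  stopifnot(is(labels, "LabelVolume"), is(spec, "DomainSpec"))
  lab <- labels@voxels
  d <- dim(lab)
  n <- length(lab)
  v <- array(0, dim = c(d, 2L))
  withSeed(seed, {
    for (ch in 1:2) {
      meanMap <- spec@means[as.vector(lab) + 1L, ch]
      sdMap <- spec@sds[as.vector(lab) + 1L, ch]
      x <- array(meanMap + sdMap * rnorm(n), dim = d)
      x <- gaussianBlur3(x, spec@blurSigma)
      if (spec@noiseSigma > 0) x <- x + rnorm(n, 0, spec@noiseSigma)
      v[, , , ch] <- x
    }
  })
  intensityVolume(v, labels@spacing, domainId = spec@domainId)
}

#' Inject topological defects into a label map
#'
#' Emulates the "hole" and "handle" failure modes of automated
#' segmentations of the folded white-matter tree: a hole relabels a
#' small interior WM region as GM; a handle adds a spurious WM bridge
#' protruding across the adjacent GM/CSF gap. Defect sites are kept
#' mutually distant so each defect is a separate connected component of
#' the returned mask. Voxels outside the mask are untouched.
#'
#' @param labels A [LabelVolume-class].
#' @param nDefects Number of defects to inject (>= 0).
#' @param kinds Character subset of `c("hole", "handle")`.
#' @param seed Integer seed.
#' @return List with `labels` (modified [LabelVolume-class]), `mask`
#'   (logical array of altered voxels), `kinds` (kind per injected
#'   defect) and `nClipped` (defects dropped for lack of sites; a
#'   warning is raised when positive).
#' @export
injectTopologyDefects <- function(labels, nDefects, kinds = c("hole", "handle"),
                                  seed = 1L) {
  stopifnot(is(labels, "LabelVolume"))
  kinds <- match.arg(kinds, several.ok = TRUE)
  nDefects <- as.integer(nDefects)
  if (nDefects < 0L) stop("nDefects must be >= 0")
  lab <- labels@voxels
  d <- dim(lab)
  mask <- array(FALSE, dim = d)
  if (nDefects == 0L)
    return(list(labels = labels, mask = mask, kinds = character(0),
                nClipped = 0L))

  wm <- lab == 3L
  # hole sites: WM voxels whose 6-neighborhood is entirely WM (interior)
  eroded <- !dilate3(!wm, 1L, 6L)
  holeSites <- which(eroded)
  # handle sites: non-WM voxels at Chebyshev distance exactly 2 from WM
  d1 <- dilate3(wm, 1L, 26L)
  d2 <- dilate3(wm, 2L, 26L)
  handleSites <- which(d2 & !d1 & lab != 0L)

  res <- withSeed(seed, {
    chosen <- list()
    usedCenters <- matrix(numeric(0), ncol = 3L)
    kindSeq <- rep_len(kinds, nDefects)
    nClipped <- 0L
    out <- lab
    kindsDone <- character(0)
    for (i in seq_len(nDefects)) {
      kind <- kindSeq[i]
      sites <- if (kind == "hole") holeSites else handleSites
      ok <- FALSE
      for (try in seq_len(200L)) {
        if (!length(sites)) break
        s <- sites[sample.int(length(sites), 1L)]
        ctr <- arrayInd(s, d)
        if (nrow(usedCenters) &&
            min(apply(abs(sweep(usedCenters, 2L, as.numeric(ctr))), 1L, max)) < 6)
          next
        if (kind == "hole") {
          box <- expand.grid(
            max(1L, ctr[1] - 1L):min(d[1], ctr[1] + 1L),
            max(1L, ctr[2] - 1L):min(d[2], ctr[2] + 1L),
            max(1L, ctr[3] - 1L):min(d[3], ctr[3] + 1L))
          box <- as.matrix(box)
          sel <- box[out[box] == 3L, , drop = FALSE]
          if (!nrow(sel)) next
          out[sel] <- 2L
          mask[sel] <- TRUE
        } else {
          # nearest WM voxel within a 5-box around the site
          box <- as.matrix(expand.grid(
            max(1L, ctr[1] - 3L):min(d[1], ctr[1] + 3L),
            max(1L, ctr[2] - 3L):min(d[2], ctr[2] + 3L),
            max(1L, ctr[3] - 3L):min(d[3], ctr[3] + 3L)))
          wmBox <- box[out[box] == 3L, , drop = FALSE]
          if (!nrow(wmBox)) next
          dist2 <- rowSums(sweep(wmBox, 2L, as.numeric(ctr))^2)
          w0 <- wmBox[which.min(dist2), ]
          dir <- as.numeric(ctr) - as.numeric(w0)
          nrm <- sqrt(sum(dir^2))
          if (nrm < 1e-9) next
          dir <- dir / nrm
          ts <- seq(0, nrm + 2.5, by = 0.5)
          pts <- unique(round(sweep(outer(ts, dir), 2L, as.numeric(w0), "+")))
          keep <- pts[, 1] >= 1 & pts[, 1] <= d[1] &
            pts[, 2] >= 1 & pts[, 2] <= d[2] &
            pts[, 3] >= 1 & pts[, 3] <= d[3]
          pts <- pts[keep, , drop = FALSE]
          sel <- pts[out[pts] != 3L & out[pts] != 0L, , drop = FALSE]
          if (nrow(sel) < 2L) next
          out[sel] <- 3L
          mask[sel] <- TRUE
        }
        usedCenters <- rbind(usedCenters, as.numeric(ctr))
        kindsDone <- c(kindsDone, kind)
        ok <- TRUE
        break
      }
      if (!ok) nClipped <- nClipped + 1L
    }
    list(out = out, mask = mask, kinds = kindsDone, nClipped = nClipped)
  })

  if (res$nClipped > 0L)
    warning(sprintf("clipped %d defect(s): no admissible sites left",
                    res$nClipped))
  list(labels = labelVolume(res$out, labels@spacing), mask = res$mask,
       kinds = res$kinds, nClipped = res$nClipped)
}
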