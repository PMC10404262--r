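## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stage label (stays < 2^31).
childSeed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}

clampProb <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1)

# One-hot encode an integer label array into an [<dims>, nClasses] array.
oneHot <- function(labels, nClasses = 4L) {
  d <- dim(labels)
  out <- array(0, dim = c(d, nClasses))
  m <- matrix(out, ncol = nClasses)
  m[cbind(seq_along(labels), as.vector(labels) + 1L)] <- 1
  array(m, dim = c(d, nClasses))
}

# Row-wise softmax of an N x C matrix, numerically stabilized.
softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Separable 3D Gaussian blur (sigma in voxels) applied channel-wise to a
# 3D array; truncated at 3 sigma, kernel renormalized.
gaussianBlur3 <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w <- w / sum(w)
  d <- dim(x)
  blur1 <- function(a, axis) {
    out <- array(0, dim = d)
    for (j in seq(-r, r)) {
      wt <- w[j + r + 1L]
      src <- pmin(pmax(seq_len(d[axis]) + j, 1L), d[axis])  # replicate edges
      out <- out + wt * switch(axis,
        a[src, , , drop = FALSE],
        a[, src, , drop = FALSE],
        a[, , src, drop = FALSE])
    }
    out
  }
  blur1(blur1(blur1(x, 1L), 2L), 3L)
}

# Binary dilation of a logical 3D array by `iters` steps of the given
# connectivity (26 = Chebyshev ball, 6 = cross).
dilate3 <- function(mask, iters = 1L, connectivity = 26L) {
  d <- dim(mask)
  shift1 <- function(a, axis, by) {
    idx <- seq_len(d[axis]) - by
    idx[idx < 1L] <- 1L
    idx[idx > d[axis]] <- d[axis]
    switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
           a[, , idx, drop = FALSE])
  }
  for (it in seq_len(iters)) {
    if (connectivity == 26L) {
      m1 <- mask | shift1(mask, 1L, 1L) | shift1(mask, 1L, -1L)
      m2 <- m1 | shift1(m1, 2L, 1L) | shift1(m1, 2L, -1L)
      mask <- m2 | shift1(m2, 3L, 1L) | shift1(m2, 3L, -1L)
    } else {
      mask <- mask |
        shift1(mask, 1L, 1L) | shift1(mask, 1L, -1L) |
        shift1(mask, 2L, 1L) | shift1(mask, 2L, -1L) |
        shift1(mask, 3L, 1L) | shift1(mask, 3L, -1L)
    }
  }
  mask
}

# 26- or 6-connected component labeling via the compiled BFS.
labelComponents <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- .ccLabel(as.vector(mask), as.integer(d), as.integer(connectivity))
  array(lab, dim = d)
}

# Regular sliding-window corner grid covering [1, extent] with the last
# window flush against the boundary (1-based corners).
slidingCorners1d <- function(extent, size, stride) {
  if (extent < size) stop("volume extent smaller than patch size")
  pos <- seq.int(1L, extent - size + 1L, by = stride)
  if (pos[length(pos)] != extent - size + 1L) pos <- c(pos, extent - size + 1L)
  as.integer(pos)
}

slidingCorners <- function(shape, size, stride) {
  g <- expand.grid(slidingCorners1d(shape[1], size, stride),
                   slidingCorners1d(shape[2], size, stride),
                   slidingCorners1d(shape[3], size, stride))
  as.matrix(g)
}

# Otsu threshold on a numeric vector (256-bin histogram).
otsuThreshold <- function(x) {
  r <- range(x)
  if (diff(r) <= 0) return(r[1])
  br <- seq(r[1], r[2], length.out = 257L)
  h <- as.numeric(tabulate(findInterval(x, br, all.inside = TRUE), 256L))
  w <- cumsum(h)
  m <- cumsum(h * seq_len(256L))
  tot <- w[256L]; mt <- m[256L]
  between <- (mt * w - m * tot)^2 / (w * (tot - w) + 1e-12)
  mids <- (br[-257L] + br[-1L]) / 2
  mids[which.max(between[-256L])]
}

# Channel-wise standardization of an intensity array (4D) over the
# foreground (cerebellum) region: background voxels dominate the volume,
# so statistics are taken inside an Otsu mask of channel 1, as intensity
# normalization over the extracted brain region is done in MRI pipelines.
zscoreChannels <- function(v) {
  fg <- v[, , , 1L] > otsuThreshold(as.vector(v[, , , 1L]))
  if (sum(fg) < 32L) fg[] <- TRUE
  for (ch in seq_len(dim(v)[4])) {
    x <- v[, , , ch]
    mu <- mean(x[fg])
    s <- sd(x[fg])
    v[, , , ch] <- if (s > 0) (x - mu) / s else x - mu
  }
  v
}

sameShape <- function(a, b) identical(dim(a)[1:3], dim(b)[1:3])

stopIfShapeMismatch <- function(a, b, what = "volumes") {
  if (!sameShape(a, b))
    stop(sprintf("shape mismatch between %s: %s vs %s", what,
                 paste(dim(a)[1:3], collapse = "x"),
                 paste(dim(b)[1:3], collapse = "x")))
  invisible(TRUE)
}
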