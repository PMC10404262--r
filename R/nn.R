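## Minimal deterministic 3D CNN engine.
##
## Feature maps are N x C matrices (N voxels of a cubic block in R's
## column-major order, C channels); convolutions run through the
## compiled im2col/GEMM kernels. Layers follow the norm -> ReLU -> conv
## -> dropout pattern of the dense blocks; normalization uses per-sample
## (instance) statistics with a learnable affine, so inference needs no
## running averages and training equals evaluation behavior.

NORM_EPS <- 1e-5

xavierConv <- function(cin, cout, k) {
  fanIn <- cin * k^3
  fanOut <- cout * k^3
  list(W = matrix(rnorm(fanIn * cout, sd = sqrt(2 / (fanIn + fanOut))),
                  nrow = fanIn, ncol = cout),
       b = numeric(cout))
}

normInit <- function(c) list(gamma = rep(1, c), beta = rep(0, c))

convForward <- function(p, x, dims, k) {
  y <- .conv3Forward(x, as.integer(dims), p$W, p$b, as.integer(k))
  list(y = y, x = x)
}

convBackward <- function(p, cache, gy, dims, k) {
  r <- .conv3Backward(cache$x, as.integer(dims), p$W, gy, as.integer(k))
  list(gx = r$gx, g = list(W = r$gW, b = as.numeric(r$gb)))
}

# Channel-wise learnable affine normalization. Inputs are standardized
# once per volume (z-score) before patch extraction, so the per-layer
# "normalize" step rescales channels without re-centering each patch --
# per-patch statistics would erase absolute intensity, which is the
# dominant tissue cue, and would turn uniform background patches into
# amplified noise.
normForward <- function(p, x) {
  y <- sweep(sweep(x, 2L, p$gamma, "*"), 2L, p$beta, "+")
  list(y = y, x = x)
}

normBackward <- function(p, cache, gy) {
  ggamma <- colSums(gy * cache$x)
  gbeta <- colSums(gy)
  gx <- sweep(gy, 2L, p$gamma, "*")
  list(gx = gx, g = list(gamma = ggamma, beta = gbeta))
}

reluForward <- function(x) list(y = pmax(x, 0), mask = x > 0)
reluBackward <- function(cache, gy) gy * cache$mask

dropoutForward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- (runif(length(x)) >= rate) / (1 - rate)
  dim(mask) <- dim(x)
  list(y = x * mask, mask = mask)
}
dropoutBackward <- function(cache, gy) {
  if (is.null(cache$mask)) gy else gy * cache$mask
}

## ---- 2x average pooling / nearest-neighbor unpooling -------------------

.poolIdxCache <- new.env(parent = emptyenv())

poolChildIdx <- function(dims) {
  key <- paste(dims, collapse = "x")
  hit <- .poolIdxCache[[key]]
  if (!is.null(hit)) return(hit)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  ox <- nx %/% 2L; oy <- ny %/% 2L; oz <- nz %/% 2L
  gi <- rep(seq_len(ox), times = oy * oz)
  gj <- rep(rep(seq_len(oy), each = ox), times = oz)
  gk <- rep(seq_len(oz), each = ox * oy)
  idx <- matrix(0L, nrow = ox * oy * oz, ncol = 8L)
  s <- 0L
  for (c in 0:1) for (b in 0:1) for (a in 0:1) {
    s <- s + 1L
    idx[, s] <- (2L * gi - 1L + a) +
      (2L * gj - 2L + b) * nx +
      (2L * gk - 2L + c) * nx * ny
  }
  .poolIdxCache[[key]] <- idx
  idx
}

poolForward <- function(x, dims) {
  ci <- poolChildIdx(dims)
  y <- (x[ci[, 1], , drop = FALSE] + x[ci[, 2], , drop = FALSE] +
        x[ci[, 3], , drop = FALSE] + x[ci[, 4], , drop = FALSE] +
        x[ci[, 5], , drop = FALSE] + x[ci[, 6], , drop = FALSE] +
        x[ci[, 7], , drop = FALSE] + x[ci[, 8], , drop = FALSE]) / 8
  list(y = y, dims = dims)
}

poolBackward <- function(cache, gy) {
  ci <- poolChildIdx(cache$dims)
  gx <- matrix(0, nrow = prod(cache$dims), ncol = ncol(gy))
  g8 <- gy / 8
  for (s in 1:8) gx[ci[, s], ] <- g8
  gx
}

unpoolForward <- function(x, outDims) {
  ci <- poolChildIdx(outDims)
  y <- matrix(0, nrow = prod(outDims), ncol = ncol(x))
  for (s in 1:8) y[ci[, s], ] <- x
  list(y = y, outDims = outDims)
}

unpoolBackward <- function(cache, gy) {
  ci <- poolChildIdx(cache$outDims)
  gx <- gy[ci[, 1], , drop = FALSE]
  for (s in 2:8) gx <- gx + gy[ci[, s], , drop = FALSE]
  gx
}

## ---- dense block (norm -> ReLU -> conv -> dropout, dense concat) -------

denseBlockInit <- function(cin, growth, nConvs) {
  norms <- convs <- vector("list", nConvs)
  c <- cin
  for (j in seq_len(nConvs)) {
    norms[[j]] <- normInit(c)
    convs[[j]] <- xavierConv(c, growth, 3L)
    c <- c + growth
  }
  list(norms = norms, convs = convs)
}

denseBlockForward <- function(p, x, dims, dropout, training) {
  nConvs <- length(p$convs)
  feats <- list(x)
  caches <- vector("list", nConvs)
  for (j in seq_len(nConvs)) {
    inp <- if (j == 1L) x else do.call(cbind, feats)
    nf <- normForward(p$norms[[j]], inp)
    rf <- reluForward(nf$y)
    cf <- convForward(p$convs[[j]], rf$y, dims, 3L)
    df <- dropoutForward(cf$y, dropout, training)
    feats[[j + 1L]] <- df$y
    caches[[j]] <- list(norm = nf, relu = rf, conv = cf, drop = df)
  }
  list(y = do.call(cbind, feats), feats = feats, caches = caches)
}

denseBlockBackward <- function(p, cache, gy, dims) {
  nConvs <- length(p$convs)
  widths <- vapply(cache$feats, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  gfeats <- lapply(seq_along(widths), function(i)
    gy[, starts[i]:ends[i], drop = FALSE])
  gnorms <- gconvs <- vector("list", nConvs)
  for (j in rev(seq_len(nConvs))) {
    cj <- cache$caches[[j]]
    g <- dropoutBackward(cj$drop, gfeats[[j + 1L]])
    cb <- convBackward(p$convs[[j]], cj$conv, g, dims, 3L)
    gconvs[[j]] <- cb$g
    g <- reluBackward(cj$relu, cb$gx)
    nb <- normBackward(p$norms[[j]], cj$norm, g)
    gnorms[[j]] <- nb$g
    ginp <- nb$gx
    for (i in seq_len(j)) {
      gfeats[[i]] <- gfeats[[i]] +
        ginp[, starts[i]:ends[i], drop = FALSE]
    }
  }
  list(gx = gfeats[[1L]], g = list(norms = gnorms, convs = gconvs))
}

## ---- norm -> ReLU -> conv stage (k = 1 transition, k = 3 U-Net unit) ---

transInit <- function(cin, cout, k = 1L) {
  list(norm = normInit(cin), conv = xavierConv(cin, cout, k))
}

stageKernel <- function(p, cin = NULL) {
  as.integer(round((nrow(p$conv$W) / length(p$norm$gamma))^(1 / 3)))
}

transForward <- function(p, x, dims, k = 1L) {
  nf <- normForward(p$norm, x)
  rf <- reluForward(nf$y)
  cf <- convForward(p$conv, rf$y, dims, k)
  list(y = cf$y, norm = nf, relu = rf, conv = cf)
}

transBackward <- function(p, cache, gy, dims, k = 1L) {
  cb <- convBackward(p$conv, cache$conv, gy, dims, k)
  g <- reluBackward(cache$relu, cb$gx)
  nb <- normBackward(p$norm, cache$norm, g)
  list(gx = nb$gx, g = list(norm = nb$g, conv = cb$g))
}

## ---- parameter-tree arithmetic (SGD with momentum) ---------------------

treeMap2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- treeMap2(f, a[[nm]], b[[nm]])
    out
  } else if (is.numeric(a)) f(a, b) else a
}

treeZero <- function(a) {
  if (is.list(a)) lapply(a, treeZero)
  else if (is.numeric(a)) a * 0 else a
}

sgdStep <- function(params, grads, velocity, lr, momentum) {
  velocity <- treeMap2(function(v, g) momentum * v - lr * g, velocity, grads)
  params <- treeMap2(function(p, v) p + v, params, velocity)
  list(params = params, velocity = velocity)
}
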