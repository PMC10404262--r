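# Independent brute-force oracles (plain per-voxel loops), shared by the
# unit tests and the acceptance suite. They deliberately avoid the
# package's vectorized code paths.

bruteSegLoss <- function(p, y, eps = 1e-7) {
  d <- dim(p)[1:3]
  tot <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    for (cls in 1:4) {
      x <- min(max(p[i, j, k, cls], eps), 1)
      tot <- tot - y[i, j, k, cls] * log(x)
    }
  }
  tot / prod(d)
}

bruteWeightedSegLoss <- function(p, y, w, eps = 1e-7) {
  d <- dim(p)[1:3]
  tot <- 0
  nPos <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (w[i, j, k] > 0) nPos <- nPos + 1
    vox <- 0
    for (cls in 1:4) {
      x <- min(max(p[i, j, k, cls], eps), 1)
      vox <- vox - y[i, j, k, cls] * log(x)
    }
    tot <- tot + w[i, j, k] * vox
  }
  if (nPos == 0) 0 else tot / nPos
}

bruteConfLoss <- function(x, y, a, eps = 1e-7) {
  n <- length(x)
  tot <- 0
  for (i in seq_len(n)) {
    xi <- min(max(x[i], eps), 1 - eps)
    tot <- tot - (y[i] * log(xi) + a * (1 - y[i]) * log(1 - xi))
  }
  tot / n
}

bruteDice <- function(a, b) {
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(NA_real_)
  2 * sum(a & b) / (na + nb)
}

bruteSurface <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    exposed <- FALSE
    for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      p <- c(i, j, k) + o
      if (any(p < 1) || any(p > d) || !mask[p[1], p[2], p[3]]) {
        exposed <- TRUE
        break
      }
    }
    out[i, j, k] <- exposed
  }
  out
}

bruteHd95 <- function(a, b, spacing) {
  sa <- which(bruteSurface(a), arr.ind = TRUE)
  sb <- which(bruteSurface(b), arr.ind = TRUE)
  pa <- sweep(sa, 2L, spacing, "*")
  pb <- sweep(sb, 2L, spacing, "*")
  allD <- function(p, q) {
    apply(p, 1L, function(x) min(sqrt(colSums((t(q) - x)^2))))
  }
  max(quantile(allD(pa, pb), 0.95, type = 7, names = FALSE),
      quantile(allD(pb, pa), 0.95, type = 7, names = FALSE))
}
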