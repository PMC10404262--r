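test_that("label phantom contains all tissues, one WM component, and is deterministic", {
  lab <- makeLabelPhantom(c(64, 64, 64), branchDepth = 3, gmThickness = 2,
                          seed = 7)
  expect_s4_class(lab, "LabelVolume")
  expect_setequal(unique(as.vector(voxels(lab))), 0:3)
  wm <- voxels(lab) == 3L
  comp <- CerebSSL:::labelComponents(wm, 26L)
  expect_identical(max(comp), 1L)
  lab2 <- makeLabelPhantom(c(64, 64, 64), branchDepth = 3, gmThickness = 2,
                           seed = 7)
  expect_identical(voxels(lab), voxels(lab2))
  lab3 <- makeLabelPhantom(c(64, 64, 64), branchDepth = 3, gmThickness = 2,
                           seed = 8)
  expect_false(identical(voxels(lab), voxels(lab3)))
})

test_that("every GM voxel touches a non-GM voxel in its 26-neighborhood", {
  lab <- makeLabelPhantom(c(64, 64, 64), branchDepth = 3, gmThickness = 2,
                          seed = 7)
  v <- voxels(lab)
  d <- dim(v)
  idx <- which(v == 2L, arr.ind = TRUE)
  touches <- vapply(seq_len(nrow(idx)), function(i) {
    p <- idx[i, ]
    nb <- v[max(1, p[1] - 1):min(d[1], p[1] + 1),
            max(1, p[2] - 1):min(d[2], p[2] + 1),
            max(1, p[3] - 1):min(d[3], p[3] + 1)]
    any(nb != 2L)
  }, logical(1))
  expect_equal(mean(touches), 1.0)
})

test_that("undersized volumes are rejected with a sizing error", {
  expect_error(makeLabelPhantom(c(16, 16, 16), branchDepth = 2, seed = 1),
               "too small")
  expect_error(makeLabelPhantom(c(40, 40, 40), branchDepth = 8, seed = 1),
               "too small")
})

test_that("domain series shrinks the GM-WM gap geometrically and monotonically", {
  base <- domainSpec()
  series <- makeDomainSeries(base, nDomains = 6, contrastDecay = 0.3,
                             noiseGrowth = 0.1)
  expect_length(series, 6L)
  expect_identical(series[[1L]]@means, base@means)
  gap0 <- abs(base@means["GM", 1] - base@means["WM", 1])
  for (k in seq_along(series)) {
    gapK <- abs(series[[k]]@means["GM", 1] - series[[k]]@means["WM", 1])
    expect_equal(gapK, gap0 * 0.7^(k - 1), tolerance = 1e-12)
    expect_equal(series[[k]]@noiseSigma, base@noiseSigma * 1.1^(k - 1),
                 tolerance = 1e-12)
  }
  ci <- contrastIndex(series)
  expect_true(all(diff(ci) < 0))
  # the index recomputed from the returned specs is the gap over the
  # pooled sd, which reduces to c0 * (1-decay)^k up to the noise term
  ciNoNoise <- vapply(series, function(s)
    abs(s@means["GM", 1] - s@means["WM", 1]) /
      sqrt(mean(s@sds[c("GM", "WM"), 1]^2)), numeric(1))
  expect_equal(unname(ciNoNoise / ciNoNoise[1]), 0.7^(0:5),
               tolerance = 1e-12)
})

test_that("domain series edge cases behave as specified", {
  base <- domainSpec()
  two <- makeDomainSeries(base, nDomains = 2, contrastDecay = 0.3)
  expect_length(two, 2L)
  expect_identical(two[[1L]]@means, base@means)
  flat <- makeDomainSeries(base, nDomains = 4, contrastDecay = 0.3,
                           noiseGrowth = 0)
  expect_true(all(vapply(flat, function(s) s@noiseSigma, numeric(1)) ==
                    base@noiseSigma))
  expect_error(makeDomainSeries(base, 4, contrastDecay = 1.2), "contrastDecay")
  expect_error(makeDomainSeries(base, 1, contrastDecay = 0.3), "nDomains")
})

test_that("degenerate rendering reproduces tissue means exactly", {
  lab <- makeLabelPhantom(c(40, 40, 40), branchDepth = 2, seed = 3)
  spec <- domainSpec(sds = matrix(0, 4, 2), noiseSigma = 0, blurSigma = 0)
  img <- renderIntensities(lab, spec, seed = 1)
  v <- voxels(img)
  for (code in 0:3) {
    sel <- voxels(lab) == code
    expect_equal(unique(as.vector(v[, , , 1][sel])),
                 unname(spec@means[code + 1L, 1L]))
    expect_equal(unique(as.vector(v[, , , 2][sel])),
                 unname(spec@means[code + 1L, 2L]))
  }
})

test_that("rendered tissue means match the domain parameters within 3 standard errors", {
  lab <- makeLabelPhantom(c(64, 64, 64), branchDepth = 3, seed = 5)
  spec <- domainSpec(blurSigma = 0, noiseSigma = 0)
  img <- renderIntensities(lab, spec, seed = 9)
  v1 <- voxels(img)[, , , 1]
  for (code in 1:3) {
    sel <- voxels(lab) == code
    n <- sum(sel)
    se <- spec@sds[code + 1L, 1L] / sqrt(n)
    expect_lt(abs(mean(v1[sel]) - spec@means[code + 1L, 1L]), 3 * se)
  }
  # rendering is deterministic given the seed
  img2 <- renderIntensities(lab, spec, seed = 9)
  expect_identical(voxels(img), voxels(img2))
})

test_that("T2w-like channel inverts the CSF/WM ordering", {
  lab <- makeLabelPhantom(c(48, 48, 48), branchDepth = 3, seed = 5)
  spec <- domainSpec()
  img <- renderIntensities(lab, spec, seed = 2)
  v <- voxels(img)
  csf <- voxels(lab) == 1L
  wm <- voxels(lab) == 3L
  expect_gt(mean(v[, , , 2][csf]), mean(v[, , , 2][wm]))
  expect_lt(mean(v[, , , 1][csf]), mean(v[, , , 1][wm]))
})

test_that("GM/WM histogram overlap grows towards the youngest domain", {
  lab <- makeLabelPhantom(c(64, 64, 64), branchDepth = 3, seed = 5)
  series <- makeDomainSeries(domainSpec())
  overlap <- function(spec) {
    v1 <- voxels(renderIntensities(lab, spec, seed = 4))[, , , 1]
    gm <- v1[voxels(lab) == 2L]
    wm <- v1[voxels(lab) == 3L]
    br <- seq(min(v1), max(v1), length.out = 51L)
    hg <- hist(gm, breaks = br, plot = FALSE)$counts / length(gm)
    hw <- hist(wm, breaks = br, plot = FALSE)$counts / length(wm)
    sum(pmin(hg, hw))
  }
  expect_gt(overlap(series[[6L]]), overlap(series[[1L]]))
})

test_that("defect injection is local, componentwise, and conserves geometry", {
  lab <- makeLabelPhantom(c(64, 64, 64), branchDepth = 4, seed = 7)
  none <- injectTopologyDefects(lab, 0, seed = 1)
  expect_identical(voxels(none$labels), voxels(lab))
  expect_false(any(none$mask))

  holes <- injectTopologyDefects(lab, 3, kinds = "hole", seed = 5)
  comp <- CerebSSL:::labelComponents(holes$mask, 26L)
  expect_identical(max(comp), 3L)
  expect_true(all(voxels(lab)[holes$mask] == 3L))        # formerly WM
  expect_true(all(voxels(holes$labels)[holes$mask] == 2L))  # now GM
  expect_identical(voxels(holes$labels)[!holes$mask],
                   voxels(lab)[!holes$mask])
  expect_identical(dim(voxels(holes$labels)), dim(voxels(lab)))
  expect_identical(voxelSpacing(holes$labels), voxelSpacing(lab))

  handles <- injectTopologyDefects(lab, 2, kinds = "handle", seed = 5)
  expect_true(all(voxels(lab)[handles$mask] != 3L))      # formerly not WM
  expect_true(all(voxels(handles$labels)[handles$mask] == 3L))
  expect_identical(voxels(handles$labels)[!handles$mask],
                   voxels(lab)[!handles$mask])

  again <- injectTopologyDefects(lab, 3, kinds = "hole", seed = 5)
  expect_identical(voxels(again$labels), voxels(holes$labels))
})

test_that("defect requests beyond available sites are clipped with a warning", {
  lab <- makeLabelPhantom(c(64, 64, 64), branchDepth = 2, seed = 2)
  expect_warning(res <- injectTopologyDefects(lab, 500, kinds = "hole",
                                              seed = 3),
                 "clipped")
  expect_gt(res$nClipped, 0L)
  expect_identical(length(res$kinds) + res$nClipped, 500L)
})
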