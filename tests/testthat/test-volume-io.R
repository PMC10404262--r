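test_that("NIfTI round-trip preserves both volume kinds bit-exactly", {
  dir <- withr::local_tempdir()
  lab <- makeLabelPhantom(c(40, 40, 40), branchDepth = 2, seed = 4)
  img <- renderIntensities(lab, domainSpec(), seed = 2)
  pLab <- file.path(dir, "lab.nii.gz")
  pImg <- file.path(dir, "img.nii.gz")
  writeVolume(lab, pLab)
  writeVolume(img, pImg)
  lab2 <- readVolume(pLab)
  img2 <- readVolume(pImg)
  expect_s4_class(lab2, "LabelVolume")
  expect_identical(voxels(lab2), voxels(lab))
  expect_equal(voxelSpacing(lab2), voxelSpacing(lab))
  expect_s4_class(img2, "IntensityVolume")
  expect_identical(dim(voxels(img2)), dim(voxels(img)))
  expect_equal(voxels(img2), voxels(img), tolerance = 1e-6)  # float storage
  expect_identical(domainId(img2), "24m")                    # JSON sidecar
})

test_that("label files with out-of-range or non-integer codes are rejected", {
  dir <- withr::local_tempdir()
  bad <- RNifti::asNifti(array(c(0L, 1L, 4L, 2L, 0L, 1L, 2L, 3L),
                           dim = c(2, 2, 2)))
  p <- file.path(dir, "bad.nii.gz")
  RNifti::writeNifti(bad, p)
  expect_error(readVolume(p, kind = "label"), "outside \\{0,1,2,3\\}.*4")
  frac <- RNifti::asNifti(array(c(0, 0.5, 1, 2, 0, 1, 2, 3),
                            dim = c(2, 2, 2)))
  p2 <- file.path(dir, "frac.nii.gz")
  RNifti::writeNifti(frac, p2)
  expect_error(readVolume(p2, kind = "label"), "non-integer")
})

test_that("4D files become multi-channel intensity volumes", {
  dir <- withr::local_tempdir()
  arr <- array(rnorm(4 * 4 * 4 * 2), dim = c(4, 4, 4, 2))
  p <- file.path(dir, "two.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), p)
  v <- readVolume(p)
  expect_s4_class(v, "IntensityVolume")
  expect_identical(dim(voxels(v))[4], 2L)
})

test_that("isotropic resampling honors interpolation contracts", {
  lab <- makeLabelPhantom(c(40, 40, 40), branchDepth = 2, seed = 4)
  same <- resampleIsotropic(lab, 0.8)
  expect_identical(voxels(same), voxels(lab))

  img <- renderIntensities(lab, domainSpec(), seed = 2)
  img1 <- intensityVolume(voxels(img), c(1, 1, 1), domainId = "x")
  res <- resampleIsotropic(img1, 0.8)
  expect_identical(dim(voxels(res))[1:3], rep(50L, 3L))  # round(40 * 1 / 0.8)
  expect_equal(voxelSpacing(res), rep(0.8, 3L))

  lab1 <- labelVolume(voxels(lab), c(1, 1, 1))
  resL <- resampleIsotropic(lab1, 0.8)
  expect_true(all(unique(as.vector(voxels(resL))) %in%
                    unique(as.vector(voxels(lab)))))
  imgIdent <- resampleIsotropic(img1, 1.0)
  expect_identical(voxels(imgIdent), voxels(img1))
})

test_that("patch extraction follows size, count, bounds and determinism contracts", {
  lab <- makeLabelPhantom(c(48, 48, 48), branchDepth = 3, seed = 4)
  img <- renderIntensities(lab, domainSpec(), seed = 2)
  ps <- extractPatches(img, lab, n = 50, size = 16, seed = 3)
  expect_length(ps@intensity, 50L)
  expect_true(all(vapply(ps@intensity, function(b)
    identical(dim(b), c(16L, 16L, 16L, 2L)), logical(1))))
  expect_true(all(ps@corners >= 1L))
  expect_true(all(sweep(ps@corners, 2L, c(48L, 48L, 48L) - 16L + 1L) <= 0L))
  # every patch overlaps the non-background mask
  fg <- voxels(lab) > 0L
  overlaps <- vapply(seq_len(50L), function(i) {
    c0 <- ps@corners[i, ]
    any(fg[c0[1]:(c0[1] + 15L), c0[2]:(c0[2] + 15L), c0[3]:(c0[3] + 15L)])
  }, logical(1))
  expect_true(all(overlaps))
  ps2 <- extractPatches(img, lab, n = 50, size = 16, seed = 3)
  expect_identical(ps@corners, ps2@corners)
  expect_error(extractPatches(img, lab, n = 5, size = 64, seed = 1),
               "smaller than patch")
})

test_that("label blocks align with intensity blocks", {
  lab <- makeLabelPhantom(c(48, 48, 48), branchDepth = 3, seed = 4)
  img <- renderIntensities(lab, domainSpec(), seed = 2)
  ps <- extractPatches(img, lab, n = 10, size = 16, seed = 3)
  i <- 7L
  c0 <- ps@corners[i, ]
  expect_identical(ps@labels[[i]],
                   voxels(lab)[c0[1]:(c0[1] + 15L), c0[2]:(c0[2] + 15L),
                               c0[3]:(c0[3] + 15L)])
})

test_that("patch reconstruction averages overlaps and renormalizes", {
  shape <- c(8L, 8L, 8L)
  mkBlock <- function(p) {
    b <- array(0, dim = c(shape, 4L))
    for (k in 1:4) b[, , , k] <- p[k]
    b
  }
  one <- reconstructFromPatches(list(mkBlock(c(0.1, 0.2, 0.3, 0.4))),
                                matrix(1L, 1, 3), shape)
  expect_equal(as.vector(voxels(one)[1, 1, 1, ]), c(0.1, 0.2, 0.3, 0.4))

  twin <- reconstructFromPatches(
    list(mkBlock(c(0.1, 0.2, 0.3, 0.4)), mkBlock(c(0.1, 0.2, 0.3, 0.4))),
    matrix(1L, 2, 3), shape)
  expect_equal(voxels(twin), voxels(one))

  # two overlapping constant blocks: overlap voxels are (p + q) / 2
  half <- c(4L, 8L, 8L)
  blockOf <- function(p) {
    b <- array(0, dim = c(half, 4L))
    for (k in 1:4) b[, , , k] <- p[k]
    b
  }
  p <- c(0.7, 0.1, 0.1, 0.1); q <- c(0.1, 0.1, 0.1, 0.7)
  rec <- reconstructFromPatches(
    list(blockOf(p), blockOf(q)),
    rbind(c(1L, 1L, 1L), c(3L, 1L, 1L)), c(6L, 8L, 8L))
  expect_equal(as.vector(voxels(rec)[4, 1, 1, ]), (p + q) / 2)
  expect_equal(as.vector(voxels(rec)[1, 1, 1, ]), p)

  sums <- rowSums(matrix(voxels(rec), ncol = 4L))
  expect_true(all(abs(sums - 1) < 1e-6))
})

test_that("uncovered foreground voxels raise a coverage error", {
  shape <- c(8L, 8L, 8L)
  blk <- array(0.25, dim = c(4L, 4L, 4L, 4L))
  mask <- array(TRUE, dim = shape)
  expect_error(reconstructFromPatches(list(blk), matrix(1L, 1, 3), shape,
                                      mask = mask),
               "coverage error")
})
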