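# Loss functions against independent per-voxel summation oracles
# (defined in helper-oracles.R).

test_that("segmentation loss has the closed-form degenerate values", {
  y <- oneHotFixture(c(5, 5, 5))
  expect_lt(segmentationLoss(y$probs, y$labels), 1e-6)  # perfect prediction
  uni <- array(0.25, dim = c(5, 5, 5, 4))
  expect_equal(segmentationLoss(uni, y$labels), log(4), tolerance = 1e-12)
})

test_that("segmentation loss equals the brute-force oracle on random instances", {
  withr::local_seed(1)
  for (rep in 1:100) {
    p <- randomProbArray(c(5, 5, 5))
    lab <- array(sample(0:3, 125, replace = TRUE), dim = c(5, 5, 5))
    y <- CerebSSL:::oneHot(lab, 4L)
    expect_equal(segmentationLoss(p, lab), bruteSegLoss(p, y),
                 tolerance = 1e-6)
  }
})

test_that("weighted loss reduces to the plain loss at unit weights and obeys its oracle", {
  withr::local_seed(2)
  for (rep in 1:100) {
    p <- randomProbArray(c(5, 5, 5))
    lab <- array(sample(0:3, 125, replace = TRUE), dim = c(5, 5, 5))
    y <- CerebSSL:::oneHot(lab, 4L)
    w <- array(runif(125), dim = c(5, 5, 5))
    w[w < 0.4] <- 0
    expect_equal(as.numeric(weightedSegmentationLoss(p, lab, w)),
                 bruteWeightedSegLoss(p, y, w), tolerance = 1e-6)
  }
  p <- randomProbArray(c(5, 5, 5))
  lab <- array(sample(0:3, 125, replace = TRUE), dim = c(5, 5, 5))
  ones <- array(1, dim = c(5, 5, 5))
  expect_identical(as.numeric(weightedSegmentationLoss(p, lab, ones)),
                   segmentationLoss(p, lab))
  zeros <- array(0, dim = c(5, 5, 5))
  z <- weightedSegmentationLoss(p, lab, zeros)
  expect_identical(as.numeric(z), 0)
  expect_true(attr(z, "allMasked"))
})

test_that("weighted loss scales linearly in a global weight constant", {
  withr::local_seed(3)
  p <- randomProbArray(c(5, 5, 5))
  lab <- array(sample(0:3, 125, replace = TRUE), dim = c(5, 5, 5))
  w <- array(runif(125, 0.5, 1), dim = c(5, 5, 5))
  l1 <- as.numeric(weightedSegmentationLoss(p, lab, w))
  l2 <- as.numeric(weightedSegmentationLoss(p, lab, 0.5 * w))
  expect_equal(l2, 0.5 * l1, tolerance = 1e-12)
})

test_that("confidence loss reproduces direct evaluations of its formula", {
  one <- array(1, dim = c(2, 2, 1))
  half <- array(0.5, dim = c(2, 2, 1))
  expect_lt(confidenceLoss(one, one), 1e-5)
  expect_equal(confidenceLoss(half, one), -log(0.5), tolerance = 1e-12)
  zeroTarget <- array(0, dim = c(2, 2, 1))
  expect_equal(confidenceLoss(half, zeroTarget), -0.1 * log(0.5),
               tolerance = 1e-12)
})

test_that("confidence loss equals its brute-force oracle on random maps", {
  withr::local_seed(4)
  for (rep in 1:100) {
    x <- array(runif(125), dim = c(5, 5, 5))
    y <- array(rbinom(125, 1, 0.8), dim = c(5, 5, 5))
    expect_equal(confidenceLoss(x, y), bruteConfLoss(x, y, 0.1),
                 tolerance = 1e-6)
  }
})

test_that("the class-balance constant makes the loss asymmetric by factor a", {
  for (x in c(0.01, 0.2, 0.5, 0.9, 0.99)) {
    lossWrong <- confidenceLoss(array(x, c(1, 1, 1)), array(0, c(1, 1, 1)))
    lossRight <- confidenceLoss(array(1 - x, c(1, 1, 1)),
                                array(1, c(1, 1, 1)))
    expect_equal(lossWrong, 0.1 * lossRight, tolerance = 1e-9)
  }
  expect_error(confidenceLoss(array(0.5, c(1, 1, 1)), array(1, c(1, 1, 1)),
                              confLossParams(a = -1)), "a must be > 0")
})
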