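test_that("network gradients match finite differences", {
  # spot-check the compiled conv kernels and layer backward passes
  ns <- asNamespace("CerebSSL")
  mcfg <- segModelConfig(sizeScale = 0.125)
  dims <- c(8L, 8L, 8L)
  params <- ns$withSeed(1, ns$segInitParams(mcfg))
  withr::local_seed(42)
  x <- matrix(rnorm(512 * 2), 512, 2)
  y <- matrix(0, 512, 4)
  y[cbind(1:512, sample(1:4, 512, TRUE))] <- 1
  fw <- ns$segForward(params, x, dims, mcfg, training = FALSE)
  lg <- ns$ceLossGrad(fw$z, y, NULL)
  gr <- ns$segBackward(params, fw$cache, lg$gz, mcfg)
  lossOf <- function(p) {
    f <- ns$segForward(p, x, dims, mcfg, training = FALSE)
    ns$ceLossGrad(f$z, y, NULL)$loss
  }
  eps <- 1e-6
  paths <- list(list("b1", "convs", 1, "W"), list("t3", "conv", "W"),
                list("b7", "norms", 1, "beta"), list("final", "W"))
  getLeaf <- function(b, p) { for (k in p) b <- b[[k]]; b }
  modLeaf <- function(b, p, i, d) {
    if (length(p) == 1) { b[[p[[1]]]][i] <- b[[p[[1]]]][i] + d; b }
    else { b[[p[[1]]]] <- modLeaf(b[[p[[1]]]], p[-1], i, d); b }
  }
  for (lp in paths) {
    gv <- getLeaf(gr, lp)
    i <- which.max(abs(gv))
    num <- (lossOf(modLeaf(params, lp, i, eps)) -
            lossOf(modLeaf(params, lp, i, -eps))) / (2 * eps)
    expect_equal(gv[i], num, tolerance = 1e-4)
  }
})

test_that("model construction is deterministic and forward output simplex-valid", {
  mcfg <- segModelConfig(sizeScale = 0.25)
  m1 <- buildSegModel(mcfg, seed = 3)
  m2 <- buildSegModel(mcfg, seed = 3)
  expect_identical(m1@params, m2@params)
  m3 <- buildSegModel(mcfg, seed = 4)
  expect_false(identical(m1@params, m3@params))

  ns <- asNamespace("CerebSSL")
  withr::local_seed(1)
  x <- matrix(rnorm(512 * 2), 512, 2)
  fw <- ns$segForward(m1@params, x, c(8L, 8L, 8L), mcfg, training = FALSE)
  expect_identical(dim(fw$z), c(512L, 4L))
  p <- ns$softmaxRows(fw$z)
  expect_true(all(p >= 0))
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_error(buildSegModel(segModelConfig(nDenseBlocks = 5L)),
               "7 dense blocks")
})

test_that("labels are the arg-max of the probabilities with ties to the lowest code", {
  probs <- array(0, dim = c(2, 1, 1, 4))
  probs[1, 1, 1, ] <- c(0.1, 0.2, 0.3, 0.4)
  probs[2, 1, 1, ] <- c(0.25, 0.25, 0.25, 0.25)
  out <- labelsFromProbs(probabilityMaps(probs, rep(0.8, 3)))
  expect_identical(voxels(out$labels)[1, 1, 1], 3L)  # WM wins
  expect_identical(voxels(out$labels)[2, 1, 1], 0L)  # tie -> background
})

test_that("training descends and is deterministic under a fixed seed", {
  series <- makeDomainSeries(domainSpec())
  sub <- makeSubject(series[[1L]], 77L, shape = c(48L, 48L, 48L),
                     branchDepth = 3L)
  tcfg <- deskTrainConfig(seed = 9L, patchesPerSubject = 48L)
  mcfg <- deskModelConfig()
  m1 <- trainSourceModel(list(sub), tcfg, mcfg)
  expect_length(lossTrace(m1), 2L)
  expect_lt(lossTrace(m1)[2], lossTrace(m1)[1])
  m2 <- trainSourceModel(list(sub), tcfg, mcfg)
  expect_identical(lossTrace(m1), lossTrace(m2))
  expect_identical(m1@params$final$W, m2@params$final$W)
  expect_error(trainSourceModel(list(), tcfg, mcfg), "at least one")
})

test_that("a tiny source model segments a held-out same-domain phantom well", {
  setup <- cachedSourceSetup()
  held <- makeSubject(setup$series[[1L]], 909L)
  pr <- predictSegmentation(setup$model, held$intensity)
  # labels recomputed from the returned probabilities agree everywhere
  m <- matrix(voxels(pr$probs), ncol = 4L)
  expect_identical(as.vector(voxels(pr$labels)),
                   max.col(m, ties.method = "first") - 1L)
  rep <- evaluateSegmentation(pr$labels, held$labels)
  expect_gt(rep$dice[rep$class == "WM"], 0.8)
  expect_gt(rep$dice[rep$class == "GM"], 0.8)
  # prediction is deterministic
  pr2 <- predictSegmentation(setup$model, held$intensity)
  expect_identical(voxels(pr$probs), voxels(pr2$probs))
  expect_error(predictSegmentation(setup$model,
    intensityVolume(array(0, c(4, 4, 4, 2)))), "smaller than patch")
})
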