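test_that("weight map applies the piecewise confidence rule bit-exactly", {
  eps <- 1e-12
  grid <- c(0, 0.1, 0.25, 0.49, 0.5 - eps, 0.5, 0.5 + eps, 0.51, 0.75,
            0.99, 1)
  m <- array(grid, dim = c(length(grid), 1, 1))
  w <- weightMap(confidenceMap(m))
  expected <- ifelse(grid >= 0.5, grid, 0)
  expect_identical(as.vector(w), expected)
  # boundary cases called out explicitly
  expect_identical(weightMap(array(0.5, c(1, 1, 1)))[1], 0.5)
  expect_identical(weightMap(array(0.49, c(1, 1, 1)))[1], 0)
  expect_identical(weightMap(array(1, c(1, 1, 1)))[1], 1)
})

test_that("weight map is idempotent on its own output", {
  withr::local_seed(8)
  m <- array(runif(1000), dim = c(10, 10, 10))
  w <- weightMap(m)
  expect_identical(weightMap(w), w)
  expect_true(all(w == 0 | w >= 0.5))
})

test_that("fold assignments give every subject exactly one out-of-fold prediction", {
  subjects <- lapply(1:4, function(i) list(intensity = i, labels = i))
  trainedOn <- list()
  stubTrain <- function(subs, tcfg, mcfg) {
    ids <- vapply(subs, function(s) s$intensity, numeric(1))
    trainedOn[[length(trainedOn) + 1L]] <<- ids
    list(ids = ids)
  }
  stubPredict <- function(model, intensity) {
    list(labels = list(seenBy = model$ids, subject = intensity),
         probs = NULL)
  }
  out <- kfoldSelfTest(subjects, K = 2L, tcfg = trainConfig(seed = 3L),
                       .train = stubTrain, .predict = stubPredict)
  expect_length(out, 4L)
  expect_length(trainedOn, 2L)                       # two models trained
  expect_identical(sort(unlist(trainedOn)), c(1, 2, 3, 4))
  for (i in 1:4) {
    expect_identical(out[[i]]$auto$subject, i)       # predicted once each
    expect_false(i %in% out[[i]]$auto$seenBy)        # by an unseen model
  }
  folds <- vapply(out, function(o) o$fold, integer(1))
  expect_identical(sort(unique(folds)), 1:2)
  expect_identical(as.vector(table(folds)), c(2L, 2L))
})

test_that("K equal to the subject count gives leave-one-out behavior", {
  subjects <- lapply(1:3, function(i) list(intensity = i, labels = i))
  stubTrain <- function(subs, tcfg, mcfg)
    list(ids = vapply(subs, function(s) s$intensity, numeric(1)))
  stubPredict <- function(model, intensity)
    list(labels = list(seenBy = model$ids, subject = intensity), probs = NULL)
  out <- kfoldSelfTest(subjects, K = 3L, tcfg = trainConfig(seed = 1L),
                       .train = stubTrain, .predict = stubPredict)
  for (i in 1:3) {
    expect_length(out[[i]]$auto$seenBy, 2L)          # trained on the rest
    expect_false(i %in% out[[i]]$auto$seenBy)
  }
  expect_error(kfoldSelfTest(subjects[1:2], K = 3L), "at least K")
})

test_that("agreement map marks exactly the disagreeing voxels", {
  lab <- makeLabelPhantom(c(40, 40, 40), branchDepth = 2, seed = 9)
  same <- agreementMap(lab, lab)
  expect_true(all(voxels(same) == 1))

  one <- voxels(lab)
  one[20, 20, 20] <- (one[20, 20, 20] + 1L) %% 4L
  oneOff <- agreementMap(labelVolume(one), lab)
  expect_equal(sum(voxels(oneOff) == 0), 1L)
  expect_equal(voxels(oneOff)[20, 20, 20], 0)

  withr::local_seed(3)
  a <- labelVolume(array(sample(0:3, 512, TRUE), dim = c(8, 8, 8)))
  b <- labelVolume(array(sample(0:3, 512, TRUE), dim = c(8, 8, 8)))
  acc <- mean(voxels(a) == voxels(b))
  expect_equal(mean(voxels(agreementMap(a, b))), acc)
  expect_error(agreementMap(a, lab), "shape mismatch")
})

test_that("probability histograms are normalized and flag empty classes", {
  y <- oneHotFixture(c(8, 8, 8))
  lab <- labelVolume(y$labels)
  probs <- probabilityMaps(0.92 * y$probs + 0.02, rep(0.8, 3))
  h <- probabilityHistograms(probs, lab, lab, class = "WM", nBins = 10)
  expect_true(h$emptyMis)                     # all-correct segmentation
  expect_equal(sum(h$correct), 1, tolerance = 1e-12)
  flip <- y$labels
  flip[y$labels == 3L][1:5] <- 2L
  h2 <- probabilityHistograms(probs, labelVolume(flip), lab, class = "WM")
  expect_false(h2$emptyMis)
  expect_equal(sum(h2$misclassified), 1, tolerance = 1e-12)
  expect_identical(h2$nMis, 5L)
  empty <- labelVolume(array(0L, dim = c(8, 8, 8)))
  h3 <- probabilityHistograms(probs, empty, empty, class = "WM")
  expect_true(h3$emptyCorrect && h3$emptyMis)
})

test_that("adaptation on source-domain data is harmless and pseudo-labels obey their contracts", {
  setup <- cachedSourceSetup()
  tgt <- makeSubject(setup$series[[1L]], 303L)
  held <- makeSubject(setup$series[[1L]], 909L)
  ad <- adaptToDomain(setup$model, setup$confModel, list(tgt$intensity),
                      setup$tcfg)
  before <- evaluateSegmentation(
    predictSegmentation(setup$model, held$intensity)$labels, held$labels)
  after <- evaluateSegmentation(
    predictSegmentation(ad$model, held$intensity)$labels, held$labels)
  # no-harm: same-domain self-training must not cost more than 0.02 Dice
  expect_true(all(after$dice >= before$dice - 0.02))
  pl <- ad$pseudo[[1L]]
  # on an easy defect-free phantom nearly all voxels pass the gate
  expect_gt(pl$retained, 0.9)
  expect_true(all(pl$retainedByTissue >= 0 & pl$retainedByTissue <= 1,
                  na.rm = TRUE))
  # pseudo-labels are exactly the arg-max of the model probabilities
  m <- matrix(voxels(pl$probs), ncol = 4L)
  expect_identical(as.vector(voxels(pl$labels)),
                   max.col(m, ties.method = "first") - 1L)
  # the source model itself is untouched by adaptation
  expect_identical(setup$model@params, cachedSourceSetup()$model@params)
  expect_error(adaptToDomain(setup$model, setup$confModel, list(),
                             setup$tcfg), "at least one")
})
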