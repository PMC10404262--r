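# Shared fixtures: small phantoms and desk-scale training configs, all
# generated in code at test time.

deskTrainConfig <- function(seed = 1L, nEpochs = 2L,
                            patchesPerSubject = 256L) {
  trainConfig(patchSize = 8L, patchesPerSubject = patchesPerSubject,
              nEpochs = nEpochs, batchSize = 1L, inferenceStride = 8L,
              seed = seed)
}

deskModelConfig <- function() segModelConfig(sizeScale = 0.25)

makeSubject <- function(spec, seed, shape = c(64L, 64L, 64L),
                        branchDepth = 4L) {
  lab <- makeLabelPhantom(shape, branchDepth = branchDepth, seed = seed)
  list(intensity = renderIntensities(lab, spec, seed = seed + 1000L),
       labels = lab)
}

# Random small label pair for metric oracles.
randomLabelPair <- function(shape, pFill = 0.2) {
  n <- prod(shape)
  a <- array(as.integer(runif(n) < pFill) * 3L, dim = shape)
  b <- array(as.integer(runif(n) < pFill) * 3L, dim = shape)
  list(seg = labelVolume(a, c(0.8, 0.8, 0.8)),
       ref = labelVolume(b, c(0.8, 0.8, 0.8)))
}

# A random label block together with its exact one-hot probabilities.
oneHotFixture <- function(shape) {
  lab <- array(sample(0:3, prod(shape), replace = TRUE), dim = shape)
  list(labels = lab, probs = CerebSSL:::oneHot(lab, 4L))
}

# Random simplex-valid probability array.
randomProbArray <- function(shape) {
  z <- array(rexp(prod(shape) * 4L), dim = c(shape, 4L))
  tot <- array(rowSums(matrix(z, ncol = 4L)), dim = dim(z))
  z / tot
}

# Heavyweight shared fixtures (trained models) are built once per test
# run and cached here.
.cache <- new.env(parent = emptyenv())

cachedSourceSetup <- function() {
  if (!is.null(.cache$sourceSetup)) return(.cache$sourceSetup)
  series <- makeDomainSeries(domainSpec())
  tcfg <- deskTrainConfig(seed = 11L)
  mcfg <- deskModelConfig()
  subjects <- list(makeSubject(series[[1L]], 101L),
                   makeSubject(series[[1L]], 202L))
  model <- trainSourceModel(subjects, tcfg, mcfg)
  pairs <- kfoldSelfTest(subjects, K = 2L, tcfg = tcfg, mcfg = mcfg)
  confModel <- trainConfidenceModel(pairs, tcfg)
  .cache$sourceSetup <- list(series = series, tcfg = tcfg, mcfg = mcfg,
                             subjects = subjects, model = model,
                             pairs = pairs, confModel = confModel)
  .cache$sourceSetup
}
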