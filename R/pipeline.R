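## End-to-end driver: simulate a multi-domain phantom study, train the
## source segmentation and confidence models, propagate along the
## domain chain, and evaluate per domain against the phantoms' ground
## truth. Every stage seed derives from the single run seed, so a run
## is reproducible from its config alone.

#' Default run configuration
#'
#' Desk-scale settings for the full pipeline on synthetic phantoms:
#' 64^3 volumes at 0.8 mm, six domains with contrast decay 0.25 and
#' noise growth 0.1 per step, a narrow (sizeScale 0.25) network trained
#' on 8^3 patches.
#'
#' @param seed Integer master seed.
#' @param outDir Output directory (`NULL` for no artifacts written).
#' @return Named list of configuration values; see the fields in the
#'   source for meanings.
#' @export
defaultRunConfig <- function(seed = 1L, outDir = NULL) {
  list(
    seed = as.integer(seed),
    outDir = outDir,
    shape = c(64L, 64L, 64L),
    spacingMm = 0.8,
    branchDepth = 4L,
    gmThickness = 2L,
    nDomains = 6L,
    contrastDecay = 0.25,
    noiseGrowth = 0.1,
    nSourceSubjects = 2L,
    nTargetPerDomain = 1L,
    sizeScale = 0.25,
    patchSize = 8L,
    patchesPerSubject = 256L,
    nEpochs = 2L,
    adaptEpochs = 2L,
    batchSize = 1L,
    inferenceStride = 8L,
    K = 2L,
    warmStart = TRUE)
}

validateRunConfig <- function(config) {
  req <- c("seed", "shape", "nDomains", "contrastDecay", "nSourceSubjects",
           "nTargetPerDomain", "patchSize", "patchesPerSubject", "nEpochs")
  miss <- setdiff(req, names(config))
  if (length(miss))
    stop(sprintf("invalid run config: missing field(s) %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (config$nSourceSubjects < 1L)
    stop("invalid run config: the source domain needs >= 1 labeled subject",
         call. = FALSE)
  if (config$nDomains < 2L)
    stop("invalid run config: need a source and >= 1 target domain",
         call. = FALSE)
  invisible(TRUE)
}

runTrainConfig <- function(config, seed) {
  trainConfig(patchSize = config$patchSize,
              patchesPerSubject = config$patchesPerSubject,
              nEpochs = config$nEpochs, batchSize = config$batchSize,
              inferenceStride = config$inferenceStride, seed = seed)
}

#' Simulate a multi-domain phantom study
#'
#' Generates, per domain, labeled source subjects (first domain),
#' unlabeled target volumes and one labeled evaluation phantom; each
#' phantom has its own tree geometry.
#'
#' @param config Run configuration (see [defaultRunConfig()]).
#' @return List with `series` (domain specs), `source` (labeled
#'   subjects), `targets` (named list of unlabeled volume lists) and
#'   `eval` (named list of labeled subjects).
#' @export
simulateStudy <- function(config = defaultRunConfig()) {
  series <- makeDomainSeries(domainSpec(), config$nDomains,
                             config$contrastDecay, config$noiseGrowth)
  ids <- vapply(series, domainId, character(1))
  mkSubject <- function(spec, tag) {
    s1 <- childSeed(config$seed, paste0(tag, "geom"))
    lab <- makeLabelPhantom(config$shape, config$branchDepth,
                            config$gmThickness, seed = s1,
                            spacing = rep(config$spacingMm, 3L))
    img <- renderIntensities(lab, spec,
                             seed = childSeed(config$seed, paste0(tag, "img")))
    list(intensity = img, labels = lab)
  }
  source <- lapply(seq_len(config$nSourceSubjects), function(i)
    mkSubject(series[[1L]], paste0("src", i)))
  targets <- list()
  evals <- list()
  for (k in seq_along(ids)[-1L]) {
    dom <- ids[k]
    targets[[dom]] <- lapply(seq_len(config$nTargetPerDomain), function(i)
      mkSubject(series[[k]], paste0(dom, "tgt", i))$intensity)
    evals[[dom]] <- mkSubject(series[[k]], paste0(dom, "eval"))
  }
  list(series = series, source = source, targets = targets, eval = evals)
}

#' Run the full self-supervised segmentation pipeline
#'
#' simulate -> train-source -> K-fold self-test -> train-confidence ->
#' gradual adaptation along the domain chain -> per-domain evaluation
#' (adapted model vs direct transfer of the source model). Writes
#' checkpoints, NIfTI volumes, a CSV report and a JSON log when
#' `config$outDir` is set.
#'
#' @param config Run configuration list or path to a JSON file with the
#'   same fields (see [defaultRunConfig()]).
#' @return List with `metrics` (data.frame: domain, class, model, dice,
#'   hd95), `models`, `confModel`, `log`.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  base <- defaultRunConfig()
  config <- utils::modifyList(base, config[!vapply(config, is.null,
                                                   logical(1))])
  validateRunConfig(config)
  stageLog <- list()
  note <- function(stage, ...) {
    stageLog[[length(stageLog) + 1L]] <<- list(
      stage = stage, info = sprintf(...),
      seed = config$seed, time = format(Sys.time(), "%H:%M:%S"))
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  runStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  note("simulate", "generating %d-domain phantom study (%s voxels)",
       config$nDomains, paste(config$shape, collapse = "x"))
  study <- runStage("simulate", simulateStudy(config))
  ids <- vapply(study$series, domainId, character(1))
  plan <- propagationPlan(ids)
  mcfg <- segModelConfig(sizeScale = config$sizeScale)
  tcfg <- runTrainConfig(config, childSeed(config$seed, "train"))

  note("train-source", "training source model on %d labeled subject(s)",
       length(study$source))
  sourceModel <- runStage("train-source",
                          trainSourceModel(study$source, tcfg, mcfg))
  note("train-confidence", "K = %d self-testing + confidence training",
       config$K)
  confModel <- runStage("train-confidence", {
    pairs <- kfoldSelfTest(study$source, K = config$K, tcfg = tcfg,
                           mcfg = mcfg)
    trainConfidenceModel(pairs, tcfg)
  })
  note("adapt", "gradual propagation %s", paste(ids, collapse = " -> "))
  adaptTcfg <- tcfg
  adaptTcfg@nEpochs <- as.integer(config$adaptEpochs %||% tcfg@nEpochs)
  prop <- runStage("adapt", gradualPropagation(
    study$source, plan, study$targets, adaptTcfg, mcfg,
    confModel = confModel, sourceModel = sourceModel,
    warmStart = config$warmStart))

  note("evaluate", "scoring adapted vs direct-transfer models per domain")
  rows <- list()
  for (dom in ids[-1L]) {
    ev <- study$eval[[dom]]
    for (mdl in c("ssl", "direct")) {
      model <- if (mdl == "ssl") prop$models[[dom]] else sourceModel
      pr <- runStage("evaluate", predictSegmentation(model, ev$intensity))
      rep <- evaluateSegmentation(pr$labels, ev$labels)
      rows[[length(rows) + 1L]] <- cbind(domain = dom, model = mdl, rep)
    }
  }
  metrics <- do.call(rbind, rows)

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(metrics, file.path(config$outDir, "metrics.csv"),
              row.names = FALSE)
    for (dom in ids[-1L]) {
      ev <- study$eval[[dom]]
      pr <- predictSegmentation(prop$models[[dom]], ev$intensity)
      writeVolume(pr$labels,
                  file.path(config$outDir, sprintf("seg_%s.nii.gz", dom)))
    }
    jsonlite::write_json(
      list(config = config[setdiff(names(config), "outDir")],
           stages = stageLog,
           propagation = prop$log),
      file.path(config$outDir, "run_log.json"), auto_unbox = TRUE,
      digits = NA)
    saveRDS(prop$models, file.path(config$outDir, "models.rds"))
  }
  list(metrics = metrics, models = prop$models, confModel = confModel,
       log = prop$log, study = study)
}
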