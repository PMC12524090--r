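#' @include backbones.R pseudo_labeling.R
NULL

# Orchestration: supervised baselines, semi-supervised runs (single-model
# and consensus + fusion), experiment grids over labelled fractions, and
# the phantom benchmark.

#' Run configuration for the semi-supervised pipeline
#'
#' @param mode `"supervised_only"`, `"ssl_single"` (one model filters its
#'   own pseudo-labels) or `"ssl_consensus_fusion"` (two branches vote; the
#'   final classifier is the fusion model trained on the merged set).
#' @param labelledFraction labelled fraction used when the config drives a
#'   split.
#' @param schedule a [thresholdSchedule()].
#' @param loss a [lossConfig()].
#' @param train a [trainConfig()] for the supervised warm-up.
#' @param tiny use the tiny architecture profile (desk scale)?
#' @param epochsPerIteration retraining epochs after each pseudo-label
#'   merge (default 10; full-length retraining is supported by raising it).
#' @param refreshBranches in consensus mode, retrain the branches on the
#'   merged set after each merge?
#' @param retrainFromScratch re-initialise optimizer state at each
#'   retraining instead of continuing (warm start is the default).
#' @param disagreementPolicy,confidenceCombine passed to [consensusVote()].
#' @param graySize,rgbSize view sizes for the dual-branch mode; `NULL`
#'   keeps the native image size.
#' @param seed root seed; all stage seeds are fanned out from it.
#' @return a validated list of class `runConfig`.
#' @export
runConfig <- function(mode = c("ssl_single", "supervised_only",
                               "ssl_consensus_fusion"),
                      labelledFraction = 0.1,
                      schedule = thresholdSchedule(),
                      loss = lossConfig(),
                      train = trainConfig(epochs = 50L),
                      tiny = TRUE,
                      epochsPerIteration = 10L,
                      refreshBranches = TRUE,
                      retrainFromScratch = FALSE,
                      disagreementPolicy = "reject",
                      confidenceCombine = "max",
                      graySize = NULL, rgbSize = NULL,
                      seed = 1L) {
  mode <- match.arg(mode)
  stopIfNot(labelledFraction > 0 && labelledFraction <= 1,
            "labelledFraction must lie in (0, 1]")
  stopIfNot(inherits(schedule, "thresholdSchedule"), "bad schedule")
  stopIfNot(inherits(loss, "lossConfig"), "bad loss config")
  stopIfNot(inherits(train, "trainConfig"), "bad train config")
  stopIfNot(epochsPerIteration >= 1, "epochsPerIteration must be >= 1")
  structure(list(mode = mode, labelledFraction = labelledFraction,
                 schedule = schedule, loss = loss, train = train,
                 tiny = isTRUE(tiny),
                 epochsPerIteration = as.integer(epochsPerIteration),
                 refreshBranches = isTRUE(refreshBranches),
                 retrainFromScratch = isTRUE(retrainFromScratch),
                 disagreementPolicy = disagreementPolicy,
                 confidenceCombine = confidenceCombine,
                 graySize = graySize, rgbSize = rgbSize,
                 seed = as.integer(seed)),
            class = "runConfig")
}

specFromData <- function(data, channels = NULL) {
  d <- imageDim(data)
  datasetSpec(datasetClassNames(data), d[1], d[2],
              if (is.null(channels)) d[3] else channels)
}

makeReport <- function(mode, model, test, ledger, records, split, config,
                       mergedSize) {
  probs <- predictProba(model, test)
  pred <- max.col(probValues(probs), ties.method = "first")
  lab <- if (is(test, "DualViews")) test@gray else test
  rep <- classificationReport(lab@labels, pred,
                              nClasses = length(lab@classNames),
                              classNames = lab@classNames)
  precision <- NA_real_
  if (NROW(records) > 0 && length(split@hiddenLabels)) {
    truth <- split@hiddenLabels[records$sample_id]
    precision <- mean(records$label == truth)
  }
  structure(list(mode = mode, testAccuracy = rep$accuracy, report = rep,
                 ledger = ledger, records = records,
                 pseudoLabelPrecision = precision,
                 mergedSize = mergedSize, config = config,
                 seed = config$seed),
            class = "sslRunReport")
}

#' @export
print.sslRunReport <- function(x, ...) {
  cat(sprintf("%s run: test accuracy %.4f", x$mode, x$testAccuracy))
  if (!is.na(x$pseudoLabelPrecision))
    cat(sprintf(", pseudo-label precision %.4f", x$pseudoLabelPrecision))
  cat("\n")
  if (NROW(x$ledger)) print(x$ledger)
  invisible(x)
}

buildForConfig <- function(spec, config, stream) {
  buildCustomCNN(spec, tiny = config$tiny, seed = fanSeed(config$seed, stream))
}

#' Supervised baseline run
#'
#' Trains the configured model on the labelled subset only and evaluates
#' on the test set; the unlabelled pool is untouched and the report's
#' ledger is empty.
#'
#' @param split a [SplitResult-class].
#' @param test a [LabeledDataset-class] never seen in training.
#' @param config a [runConfig()].
#' @return an `sslRunReport` list: `mode`, `testAccuracy`, `report`
#'   (a `classReport`), `ledger`, `pseudoLabelPrecision` (NA here),
#'   `config`, `seed`.
#' @export
runSupervisedBaseline <- function(split, test, config = runConfig()) {
  stopIfNot(nSamples(split@labelled) > 0, "labelled set is empty")
  spec <- specFromData(split@labelled)
  model <- buildForConfig(spec, config, 1L)
  tc <- config$train
  tc$seed <- fanSeed(config$seed, 2L)
  fitClassifier(model, split@labelled, config = tc)
  makeReport("supervised_only", model, test, emptyLedger(), emptyRecords(),
             split, config, mergedSize = nSamples(split@labelled))
}

#' Semi-supervised pseudo-labelling run
#'
#' Executes the full loop: supervised warm-up on the labelled subset, then
#' per mode either single-model confidence filtering or dual-branch
#' consensus voting over the unlabelled pool, merging accepted
#' pseudo-labels into the training set and retraining between iterations
#' under the threshold schedule. In `ssl_consensus_fusion` mode the final
#' classifier is the fusion model trained on the merged set. The test set
#' is never touched by pseudo-labelling (enforced by id-set disjointness).
#'
#' @inheritParams runSupervisedBaseline
#' @return an `sslRunReport`; `pseudoLabelPrecision` is the fraction of
#'   accepted pseudo-labels matching the hidden truth (synthetic data
#'   only).
#' @export
runSSL <- function(split, test, config = runConfig()) {
  stopIfNot(nSamples(split@labelled) > 0, "labelled set is empty")
  stopIfNot(nSamples(split@unlabelled) > 0, "unlabelled pool is empty")
  if (length(intersect(sampleIds(split@unlabelled), sampleIds(test))) ||
      length(intersect(sampleIds(split@labelled), sampleIds(test))))
    stop("test ids overlap the training data", call. = FALSE)
  if (config$mode == "ssl_single") runSSLSingle(split, test, config)
  else if (config$mode == "ssl_consensus_fusion") runSSLFusion(split, test, config)
  else stop("runSSL requires an ssl mode", call. = FALSE)
}

runSSLSingle <- function(split, test, config) {
  spec <- specFromData(split@labelled)
  model <- buildForConfig(spec, config, 1L)
  tc <- config$train
  tc$seed <- fanSeed(config$seed, 2L)
  fitClassifier(model, split@labelled, config = tc)

  poolAll <- split@unlabelled
  state <- new.env(parent = emptyenv())
  state$records <- emptyRecords()
  retrainCfg <- config$train
  retrainCfg$epochs <- config$epochsPerIteration

  scorer <- function(pool) predictProba(model, pool)
  hook <- function(accepted, iteration) {
    state$records <- rbind(state$records, accepted)
    merged <- mergeWithPseudo(split@labelled, poolAll, state$records)
    retrainCfg$seed <- fanSeed(config$seed, 100L + iteration)
    fitClassifier(model, merged$data, config = retrainCfg,
                  isPseudo = merged$isPseudo, lambda = config$loss$lambda,
                  warmStart = !config$retrainFromScratch)
  }
  out <- iterativePseudoLabel(scorer, poolAll, config$schedule, hook)
  makeReport("ssl_single", model, test, out$ledger, out$records, split,
             config,
             mergedSize = nSamples(split@labelled) + NROW(out$records))
}

runSSLFusion <- function(split, test, config) {
  d <- imageDim(split@labelled)
  gs <- config$graySize %||% d[1]
  rs <- config$rgbSize %||% d[1]
  labViews <- renderDualViews(split@labelled, gs, rs)
  poolViews <- renderDualViews(split@unlabelled, gs, rs)
  testViews <- renderDualViews(test, gs, rs)

  graySpec <- datasetSpec(datasetClassNames(split@labelled), gs, gs, 1L)
  rgbSpec <- datasetSpec(datasetClassNames(split@labelled), rs, rs, 3L)
  bGray <- buildCustomCNN(graySpec, tiny = config$tiny,
                          seed = fanSeed(config$seed, 1L))
  bRGB <- buildTransferBranch(rgbSpec, tiny = config$tiny,
                              seed = fanSeed(config$seed, 3L))
  tc <- config$train
  tc$seed <- fanSeed(config$seed, 2L)
  fitClassifier(bGray, labViews@gray, config = tc)
  tc$seed <- fanSeed(config$seed, 4L)
  fitClassifier(bRGB, labViews@rgb, config = tc)

  state <- new.env(parent = emptyenv())
  state$records <- emptyRecords()
  retrainCfg <- config$train
  retrainCfg$epochs <- config$epochsPerIteration

  scorer <- function(pool) {
    ids <- sampleIds(pool)
    list(predictProba(bGray, poolViews@gray[ids]),
         predictProba(bRGB, poolViews@rgb[ids]))
  }
  hook <- function(accepted, iteration) {
    state$records <- rbind(state$records, accepted)
    if (!config$refreshBranches) return(invisible())
    mg <- mergeWithPseudo(labViews@gray, poolViews@gray, state$records)
    mr <- mergeWithPseudo(labViews@rgb, poolViews@rgb, state$records)
    retrainCfg$seed <- fanSeed(config$seed, 100L + iteration)
    fitClassifier(bGray, mg$data, config = retrainCfg,
                  isPseudo = mg$isPseudo, lambda = config$loss$lambda,
                  warmStart = !config$retrainFromScratch)
    retrainCfg$seed <- fanSeed(config$seed, 200L + iteration)
    fitClassifier(bRGB, mr$data, config = retrainCfg,
                  isPseudo = mr$isPseudo, lambda = config$loss$lambda,
                  warmStart = !config$retrainFromScratch)
  }
  out <- iterativePseudoLabel(scorer, split@unlabelled, config$schedule, hook,
                              disagreementPolicy = config$disagreementPolicy,
                              confidenceCombine = config$confidenceCombine)

  fusion <- buildFusionModel(bGray, bRGB, seed = fanSeed(config$seed, 5L))
  mg <- mergeWithPseudo(labViews@gray, poolViews@gray, out$records)
  mr <- mergeWithPseudo(labViews@rgb, poolViews@rgb, out$records)
  mergedViews <- new("DualViews", gray = mg$data, rgb = mr$data)
  fc <- config$train
  fc$seed <- fanSeed(config$seed, 6L)
  fitClassifier(fusion, mergedViews, config = fc, isPseudo = mg$isPseudo,
                lambda = config$loss$lambda)
  makeReport("ssl_consensus_fusion", fusion, testViews, out$ledger,
             out$records, split, config,
             mergedSize = nSamples(split@labelled) + NROW(out$records))
}

# Merge the labelled set with accepted pseudo-labels drawn from the pool.
# Returns the merged LabeledDataset plus the pseudo flag per sample; no
# sample can appear twice because pool and labelled ids are disjoint.
mergeWithPseudo <- function(labelled, pool, records) {
  if (NROW(records) == 0L)
    return(list(data = labelled, isPseudo = rep(FALSE, nSamples(labelled))))
  sub <- pool[records$sample_id]
  d <- dim(labelled@images)
  images <- array(0, dim = c(d[1:3], d[4] + nSamples(sub)))
  images[, , , seq_len(d[4])] <- labelled@images
  images[, , , d[4] + seq_len(nSamples(sub))] <- sub@images
  merged <- new("LabeledDataset", images = images,
                sampleIds = c(labelled@sampleIds, sub@sampleIds),
                classNames = labelled@classNames,
                labels = c(labelled@labels, as.integer(records$label)))
  list(data = merged,
       isPseudo = c(rep(FALSE, d[4]), rep(TRUE, nSamples(sub))))
}

#' Grid of paired supervised/semi-supervised runs
#'
#' Cross-product over labelled fractions and seeds: each cell splits the
#' training data, runs the supervised baseline and the semi-supervised run
#' on the same split, and records both accuracies. Individual cell
#' failures are recorded (`error` column) and the grid continues.
#'
#' @param data training [LabeledDataset-class].
#' @param test held-out [LabeledDataset-class].
#' @param fractions labelled fractions to sweep.
#' @param seeds integer seeds; one pair of runs per (fraction, seed).
#' @param config template [runConfig()]; its seed/fraction fields are
#'   overridden per cell.
#' @return a `data.frame` with columns `fraction`, `seed`,
#'   `supervised_acc`, `ssl_acc`, `pseudo_precision`, `error`.
#' @export
runGrid <- function(data, test, fractions, seeds, config = runConfig()) {
  stopIfNot(length(fractions) >= 1 && length(seeds) >= 1,
            "need non-empty fractions and seeds")
  rows <- list()
  for (f in fractions) {
    for (s in seeds) {
      cell <- config
      cell$labelledFraction <- f
      cell$seed <- as.integer(s)
      row <- data.frame(fraction = f, seed = as.integer(s),
                        supervised_acc = NA_real_, ssl_acc = NA_real_,
                        pseudo_precision = NA_real_,
                        error = NA_character_, stringsAsFactors = FALSE)
      res <- tryCatch({
        split <- stratifiedSplit(data, f, seed = fanSeed(s, 7L))
        sup <- runSupervisedBaseline(split, test, cell)
        ssl <- runSSL(split, test, cell)
        list(sup = sup, ssl = ssl)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        row$error <- conditionMessage(res)
      } else {
        row$supervised_acc <- res$sup$testAccuracy
        row$ssl_acc <- res$ssl$testAccuracy
        row$pseudo_precision <- res$ssl$pseudoLabelPrecision
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Phantom benchmark: paired supervised vs semi-supervised accuracy
#'
#' The package's standing desk-scale experiment: generate a fixed phantom
#' training set and test set, then for each seed draw a stratified split
#' at the given labelled fraction and run the supervised baseline and the
#' semi-supervised pipeline on it. In the low-label regime the
#' semi-supervised run is expected to recover accuracy the baseline loses.
#'
#' Defaults: 50 images per class for training and 25 for testing at
#' 32x32 pixels (the tiny architectures' native size), noise SD 10,
#' difficulty 0.3, 10% labelled, tiny single-model profile with a
#' 30-epoch warm-up and 10 epochs per pseudo-label iteration.
#'
#' @param fraction labelled fraction (default 0.1).
#' @param seeds integer vector; one paired run per seed (default 0:9).
#' @param perClassCount,testPerClass phantom counts per class.
#' @param imageSize phantom side in pixels.
#' @param noiseSd,difficulty phantom generator parameters.
#' @param config a [runConfig()]; seed and fraction are set per cell.
#' @return the [runGrid()] `data.frame` for the single fraction.
#' @export
phantomBenchmark <- function(fraction = 0.1, seeds = 0:9,
                             perClassCount = 50L, testPerClass = 25L,
                             imageSize = 32L, noiseSd = 10, difficulty = 0.3,
                             config = runConfig()) {
  trainData <- generatePhantoms(phantomConfig(perClassCount, imageSize,
                                              noiseSd, difficulty, seed = 101L))
  testData <- generatePhantoms(phantomConfig(testPerClass, imageSize,
                                             noiseSd, difficulty, seed = 202L))
  # test ids must not collide with training ids
  testData@sampleIds <- paste0("test_", testData@sampleIds)
  runGrid(trainData, testData, fractions = fraction, seeds = seeds,
          config = config)
}
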