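# Desk-scale pipeline tests use a small phantom cohort and short training
# budgets; the standing 10-seed benchmark lives in the acceptance suite.

pipelineFixture <- function() {
  train <- generatePhantoms(phantomConfig(12, 32, 10, 0.3, seed = 301))
  test <- generatePhantoms(phantomConfig(6, 32, 10, 0.3, seed = 302))
  test@sampleIds <- paste0("test_", test@sampleIds)
  list(train = train, test = test)
}

quickConfig <- function(mode = "ssl_single", seed = 1, ...) {
  runConfig(mode = mode, seed = seed,
            train = trainConfig(epochs = 15, seed = seed),
            epochsPerIteration = 4L, ...)
}

test_that("the supervised baseline trains only on labels and is reproducible", {
  fx <- pipelineFixture()
  split <- stratifiedSplit(fx$train, 0.5, seed = 2)
  r1 <- suppressWarnings(runSupervisedBaseline(split, fx$test, quickConfig(seed = 3)))
  expect_equal(nrow(r1$ledger), 0L)
  expect_true(is.na(r1$pseudoLabelPrecision))
  expect_gte(r1$testAccuracy, 0); expect_lte(r1$testAccuracy, 1)
  r2 <- suppressWarnings(runSupervisedBaseline(split, fx$test, quickConfig(seed = 3)))
  expect_identical(r1$testAccuracy, r2$testAccuracy)
  emptySplit <- new("SplitResult",
                    labelled = fx$train[integer()],
                    unlabelled = unlabeledPool(array(0, c(32, 32, 1, 0)),
                                               datasetClassNames(fx$train)),
                    hiddenLabels = integer(), fraction = 0.5, seed = 1L)
  expect_error(runSupervisedBaseline(emptySplit, fx$test, quickConfig()),
               "empty")
})

test_that("a degenerate threshold makes the semi-supervised run a no-op", {
  fx <- pipelineFixture()
  split <- stratifiedSplit(fx$train, 0.5, seed = 2)
  cfg <- quickConfig(seed = 3, schedule = thresholdSchedule(1.0))
  r <- suppressWarnings(runSSL(split, fx$test, cfg))
  # softmax confidences are strictly below 1, so nothing is accepted
  expect_true(all(r$ledger$accepted == 0))
  expect_equal(nrow(r$records), 0L)
  expect_equal(r$mergedSize, nSamples(split@labelled))
})

test_that("single-model pseudo-labelling merges, retrains and accounts samples", {
  fx <- pipelineFixture()
  split <- stratifiedSplit(fx$train, 0.25, seed = 4)
  cfg <- runConfig(seed = 5, train = trainConfig(epochs = 40, seed = 5),
                   epochsPerIteration = 5L)
  r <- runSSL(split, fx$test, cfg)
  expect_s3_class(r, "sslRunReport")
  # ledger conservation at every iteration
  if (nrow(r$ledger)) {
    expect_equal(r$ledger$accepted[1] + r$ledger$rejected[1],
                 nSamples(split@unlabelled))
    if (nrow(r$ledger) > 1) {
      expect_equal(r$ledger$accepted[-1] + r$ledger$rejected[-1],
                   r$ledger$rejected[-nrow(r$ledger)])
    }
  }
  # merged-set accounting and no duplicated samples
  expect_equal(r$mergedSize, nSamples(split@labelled) + nrow(r$records))
  expect_false(anyDuplicated(r$records$sample_id) > 0)
  expect_true(all(r$records$sample_id %in% sampleIds(split@unlabelled)))
  # pseudo-label precision is measurable on synthetic data
  if (nrow(r$records)) {
    expect_gte(r$pseudoLabelPrecision, 0)
    expect_lte(r$pseudoLabelPrecision, 1)
  }
})

test_that("the test set is never pseudo-labelled or merged", {
  fx <- pipelineFixture()
  split <- stratifiedSplit(fx$train, 0.5, seed = 2)
  leaky <- fx$test
  leaky@sampleIds <- sampleIds(split@unlabelled)[seq_len(nSamples(leaky))]
  expect_error(runSSL(split, leaky, quickConfig()), "overlap")
})

test_that("the consensus + fusion mode runs end to end with a coherent report", {
  fx <- pipelineFixture()
  split <- stratifiedSplit(fx$train, 0.4, seed = 6)
  cfg <- quickConfig(mode = "ssl_consensus_fusion", seed = 7)
  r <- suppressWarnings(runSSL(split, fx$test, cfg))
  expect_equal(r$mode, "ssl_consensus_fusion")
  expect_true(all(r$records$policy == "consensus"))
  expect_equal(r$mergedSize, nSamples(split@labelled) + nrow(r$records))
  expect_gte(r$testAccuracy, 0); expect_lte(r$testAccuracy, 1)
  expect_true(all(r$ledger$accepted + r$ledger$rejected > 0))
})

test_that("grids pair supervised and semi-supervised runs per cell", {
  fx <- pipelineFixture()
  g <- suppressWarnings(runGrid(fx$train, fx$test, fractions = c(0.5),
                                seeds = c(1, 2), config = quickConfig()))
  expect_equal(nrow(g), 2L)
  expect_named(g, c("fraction", "seed", "supervised_acc", "ssl_acc",
                    "pseudo_precision", "error"))
  expect_true(all(is.na(g$error)))
  expect_true(all(g$supervised_acc >= 0 & g$supervised_acc <= 1))
  # paired columns feed the paired t-test directly (two cells may tie,
  # which the t-test flags as degenerate)
  tt <- suppressWarnings(pairedTTest(g$supervised_acc * 100, g$ssl_acc * 100))
  expect_s3_class(tt, "pairedTTest")
})

test_that("a stricter threshold never lowers pseudo-label precision", {
  fx <- pipelineFixture()
  split <- stratifiedSplit(fx$train, 0.25, seed = 9)
  base <- trainConfig(epochs = 40, seed = 9)
  strict <- runSSL(split, fx$test,
                   runConfig(seed = 9, train = base, epochsPerIteration = 4L,
                             schedule = thresholdSchedule(rep(0.98, 3), 3)))
  loose <- runSSL(split, fx$test,
                  runConfig(seed = 9, train = base, epochsPerIteration = 4L,
                            schedule = thresholdSchedule(rep(0.90, 3), 3)))
  if (nrow(strict$records) && nrow(loose$records)) {
    expect_gte(strict$pseudoLabelPrecision, loose$pseudoLabelPrecision)
  }
  expect_gte(nrow(loose$records), nrow(strict$records))
})
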