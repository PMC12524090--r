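test_that("confidence filter applies the >= tau rule with argmax labels", {
  v <- rbind(a = c(0.99, 0.003, 0.004, 0.003),
             b = c(0.97, 0.01, 0.01, 0.01))
  p <- probabilityMatrix(v)
  r98 <- confidenceFilter(p, 0.98)
  expect_equal(r98$accepted$sample_id, "a")
  expect_equal(r98$accepted$label, 1L)
  expect_equal(r98$accepted$confidence, 0.99)
  expect_equal(r98$rejected, "b")
  r95 <- confidenceFilter(p, 0.95)
  expect_setequal(r95$accepted$sample_id, c("a", "b"))
  # boundary is inclusive (>= tau, not >)
  pb <- probabilityMatrix(rbind(edge = c(0.98, 0.02 / 3, 0.02 / 3, 0.02 / 3)))
  expect_equal(confidenceFilter(pb, 0.98)$accepted$sample_id, "edge")
  # argmax ties break toward the lowest class index
  pt <- probabilityMatrix(rbind(tie = c(0.5, 0.5, 0, 0)))
  expect_equal(confidenceFilter(pt, 0.5)$accepted$label, 1L)
  # malformed rows are rejected
  bad <- matrix(c(0.5, 0.2), 1, dimnames = list("x", NULL))
  expect_error(confidenceFilter(bad, 0.9), "sum to 1")
})

test_that("confidence filter equals the per-row loop oracle on 1000 rows", {
  p <- randomProbMatrix(1000, seed = 10)
  v <- probValues(p)
  prevAccepted <- character()
  for (tau in c(0.98, 0.95, 0.90)) {
    got <- confidenceFilter(p, tau)
    want <- oracleConfidenceFilter(v, tau)
    expect_identical(got$accepted$sample_id, want$ids)
    expect_identical(got$accepted$label, as.integer(want$labels))
    expect_identical(got$rejected, want$rejected)
    expect_equal(nrow(got$accepted) + length(got$rejected), nrow(v))
    # relaxing tau only grows the accepted set
    expect_true(all(prevAccepted %in% got$accepted$sample_id))
    prevAccepted <- got$accepted$sample_id
    # every accepted record satisfies its own threshold
    expect_true(all(got$accepted$confidence >= tau))
  }
})

test_that("consensus voting accepts agreement and honours the policies", {
  a <- probabilityMatrix(rbind(s1 = c(0.004, 0.003, 0.99, 0.003),
                               s2 = c(0.6, 0.2, 0.1, 0.1),
                               s3 = c(0.97, 0.01, 0.01, 0.01)))
  b <- probabilityMatrix(rbind(s1 = c(0.005, 0.005, 0.985, 0.005),
                               s2 = c(0.05, 0.05, 0.05, 0.85),
                               s3 = c(0.96, 0.02, 0.01, 0.01)))
  r <- consensusVote(a, b, 0.98)
  expect_equal(r$accepted$sample_id, "s1")   # both argmax class 3
  expect_equal(r$accepted$label, 3L)
  expect_equal(r$accepted$confidence, 0.99)  # max of the two confidences
  expect_setequal(r$rejected, c("s2", "s3"))
  # disagreement accepted only under max_confidence and when above tau
  r2 <- consensusVote(a, b, 0.80, disagreementPolicy = "max_confidence")
  s2row <- r2$accepted[r2$accepted$sample_id == "s2", ]
  expect_equal(s2row$label, 4L)  # model b is the more confident voter
  # agreement below tau stays rejected
  r3 <- consensusVote(a, b, 0.98)
  expect_true("s3" %in% r3$rejected)
  # mean combination: mean(0.97, 0.96) = 0.965 fails tau 0.97, max passes
  r4 <- consensusVote(a, b, 0.97, confidenceCombine = "mean")
  expect_false("s3" %in% r4$accepted$sample_id)
  expect_true("s3" %in% consensusVote(a, b, 0.97)$accepted$sample_id)
  # misaligned ids error
  c2 <- probabilityMatrix(probValues(b), sampleIds = c("s1", "sX", "s3"))
  expect_error(consensusVote(a, c2, 0.9), "aligned")
})

test_that("consensus equals the loop oracle on 500 random pairs", {
  a <- randomProbMatrix(500, seed = 21)
  b <- randomProbMatrix(500, seed = 22)
  va <- probValues(a); vb <- probValues(b)
  for (policy in c("reject", "max_confidence")) {
    got <- consensusVote(a, b, 0.9, disagreementPolicy = policy)
    want <- oracleConsensus(va, vb, 0.9, policy)
    expect_identical(got$accepted$sample_id, want$ids)
    expect_identical(got$accepted$label, as.integer(want$labels))
    expect_identical(got$rejected, want$rejected)
  }
})

test_that("the iterative rejection loop reproduces the hand-traced ledger", {
  conf <- c(rep(0.99, 5), rep(0.96, 3), rep(0.92, 2), 0.5)
  ids <- sprintf("u%02d", seq_along(conf))
  names(conf) <- ids
  pool <- unlabeledPool(array(runif(16 * 11) * 255, c(4, 4, 1, 11)),
                        classNames = letters[1:4], sampleIds = ids)
  seen <- list()
  hook <- function(accepted, iteration) seen[[iteration]] <<- accepted
  out <- iterativePseudoLabel(scriptedScorer(conf), pool,
                              thresholdSchedule(c(0.98, 0.95, 0.90)), hook)
  expect_equal(out$ledger$accepted, c(5L, 3L, 2L))
  expect_equal(out$ledger$rejected, c(6L, 3L, 1L))
  expect_equal(out$ledger$threshold, c(0.98, 0.95, 0.90))
  # conservation at every iteration: accepted + rejected = pool size
  poolSizes <- c(11L, 6L, 3L)
  expect_equal(out$ledger$accepted + out$ledger$rejected, poolSizes)
  # pools are nested: iteration t+1 processed exactly the rejects of t
  expect_equal(nrow(out$records), 10L)
  expect_false("u11" %in% out$records$sample_id)  # permanently excluded
  expect_true(all(out$records$confidence >=
                    out$ledger$threshold[out$records$iteration]))
  # the hook saw each accepted batch exactly once
  expect_equal(vapply(seen, nrow, integer(1)), c(5L, 3L, 2L))
})

test_that("degenerate pools terminate the loop cleanly", {
  # everything confident: single iteration, nothing rejected
  conf <- rep(0.99, 4); names(conf) <- sprintf("u%d", 1:4)
  pool <- unlabeledPool(array(1, c(4, 4, 1, 4)), letters[1:4], names(conf))
  out <- iterativePseudoLabel(scriptedScorer(conf), pool,
                              thresholdSchedule(c(0.98, 0.95)))
  expect_equal(nrow(out$ledger), 1L)
  expect_equal(out$ledger$rejected, 0L)
  # empty pool: empty ledger, hook never invoked
  hookRan <- FALSE
  outE <- iterativePseudoLabel(scriptedScorer(numeric()),
                               pool[integer()], thresholdSchedule(),
                               function(a, t) hookRan <<- TRUE)
  expect_equal(nrow(outE$ledger), 0L)
  expect_false(hookRan)
})

test_that("a failing retrain hook aborts with the partial ledger preserved", {
  conf <- c(rep(0.99, 2), rep(0.92, 2)); names(conf) <- sprintf("u%d", 1:4)
  pool <- unlabeledPool(array(1, c(4, 4, 1, 4)), letters[1:4], names(conf))
  hook <- function(accepted, iteration) {
    if (iteration == 2) stop("gradient exploded")
  }
  err <- tryCatch(
    iterativePseudoLabel(scriptedScorer(conf), pool,
                         thresholdSchedule(c(0.98, 0.90)), hook),
    error = function(e) e)
  expect_s3_class(err, "pseudoLabelRetrainError")
  expect_match(conditionMessage(err), "iteration 2")
  expect_equal(nrow(err$ledger), 2L)
  expect_equal(err$ledger$accepted, c(2L, 2L))
})

test_that("cross-entropy losses match closed forms and the naive oracle", {
  onehot <- probabilityMatrix(rbind(a = c(1, 0, 0, 0)))
  expect_equal(supervisedLoss(onehot, 1L), 0)
  uniform <- probabilityMatrix(rbind(a = rep(0.25, 4), b = rep(0.25, 4)))
  expect_equal(supervisedLoss(uniform, c(2L, 4L)), log(4))
  # zero probability for the true class is clamped, not infinite
  expect_lt(supervisedLoss(onehot, 2L), 28)
  # random batch vs per-sample summation oracle
  p <- randomProbMatrix(64, seed = 5)
  set.seed(6); y <- sample(1:4, 64, replace = TRUE)
  expect_equal(supervisedLoss(p, y), oracleCrossEntropy(probValues(p), y),
               tolerance = 1e-10)
  # unsupervised loss over pseudo-label records
  rec <- confidenceFilter(p, 0.5)$accepted
  expect_equal(unsupervisedLoss(p, rec),
               oracleCrossEntropy(probValues(p)[rec$sample_id, , drop = FALSE],
                                  rec$label),
               tolerance = 1e-10)
  # empty pseudo-label set contributes zero by convention
  expect_equal(unsupervisedLoss(p, rec[0, ]), 0)
  # identical predictions and labels give equal supervised/unsupervised values
  recAll <- confidenceFilter(p, 1e-9)$accepted
  expect_equal(unsupervisedLoss(p, recAll), supervisedLoss(p, recAll$label))
})

test_that("the total loss combines terms with an optional lambda ramp", {
  expect_equal(totalLoss(1.5, 2.5, lossConfig(lambda = 0)), 1.5)
  expect_equal(totalLoss(1.5, 2.5, lossConfig(lambda = 1)), 4.0)
  cfg <- lossConfig(lambda = 1, rampEpochs = 10)
  expect_equal(totalLoss(1, 2, cfg, epoch = 5), 1 + 0.5 * 2)
  expect_equal(totalLoss(1, 2, cfg, epoch = 20), 3)  # ramp saturates
  expect_equal(totalLoss(1, 2, lossConfig(lambda = 0.5), epoch = 3), 2)
})

test_that("threshold schedules validate their shape", {
  expect_error(thresholdSchedule(c(0.9, 0.95)), "non-increasing")
  expect_error(thresholdSchedule(c(1.2, 0.9)), "\\(0, 1\\]")
  s <- thresholdSchedule(c(0.98, 0.95), maxIterations = 4)
  expect_equal(pseudofuse:::scheduleThresholdAt(s, 4), 0.95)  # recycled tail
})
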