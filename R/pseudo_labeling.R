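# The method core: confidence filtering, two-model consensus voting,
# threshold scheduling, the iterative rejection loop, and the
# supervised/unsupervised loss assembly.

#' Threshold schedule for iterative pseudo-labelling
#'
#' A non-increasing list of confidence thresholds, one per iteration; the
#' default `0.98, 0.95, 0.90` starts strict (only near-certain predictions
#' are promoted) and relaxes so later rounds can leverage more of the
#' unlabelled pool. A constant schedule (e.g. `rep(0.98, 3)`) re-scores
#' rejected samples at a fixed bar instead.
#'
#' @param thresholds non-increasing reals in (0, 1].
#' @param maxIterations maximum iterations T (default: schedule length;
#'   when longer, the last threshold is recycled).
#' @return a validated list of class `thresholdSchedule`.
#' @export
thresholdSchedule <- function(thresholds = c(0.98, 0.95, 0.90),
                              maxIterations = length(thresholds)) {
  stopIfNot(length(thresholds) >= 1 && all(thresholds > 0 & thresholds <= 1),
            "thresholds must lie in (0, 1]")
  stopIfNot(all(diff(thresholds) <= 0), "thresholds must be non-increasing")
  stopIfNot(maxIterations >= 1, "maxIterations must be >= 1")
  structure(list(thresholds = as.double(thresholds),
                 maxIterations = as.integer(maxIterations)),
            class = "thresholdSchedule")
}

scheduleThresholdAt <- function(schedule, t) {
  th <- schedule$thresholds
  th[min(t, length(th))]
}

#' Loss weighting configuration
#'
#' `lambda` balances the contribution of the pseudo-label loss against the
#' supervised loss; it can be ramped linearly over the first `rampEpochs`
#' epochs (0 = constant).
#'
#' @param lambda non-negative weight (default 1).
#' @param rampEpochs epochs over which lambda ramps from 0 to its value.
#' @return a validated list of class `lossConfig`.
#' @export
lossConfig <- function(lambda = 1, rampEpochs = 0L) {
  stopIfNot(is.finite(lambda) && lambda >= 0, "lambda must be finite and >= 0")
  stopIfNot(rampEpochs >= 0, "rampEpochs must be >= 0")
  structure(list(lambda = as.double(lambda), rampEpochs = as.integer(rampEpochs)),
            class = "lossConfig")
}

emptyRecords <- function() {
  data.frame(sample_id = character(), label = integer(),
             confidence = numeric(), iteration = integer(),
             policy = character(), stringsAsFactors = FALSE)
}

checkProbMatrix <- function(probs) {
  v <- probValues(probs)
  if (is.null(rownames(v)))
    stop("probability rows must be named by sample id", call. = FALSE)
  if (nrow(v) && max(abs(rowSums(v) - 1)) > 1e-6)
    stop("probability rows must sum to 1", call. = FALSE)
  v
}

#' Confidence-threshold pseudo-label filter
#'
#' A sample is promoted to a pseudo-label when its maximum softmax
#' probability reaches the threshold (`max p >= tau`, boundary inclusive);
#' the assigned label is the argmax (ties broken toward the lowest class
#' index). Accepted and rejected ids partition the input.
#'
#' @param probs a [ProbabilityMatrix-class] (or matrix with sample-id row
#'   names, rows summing to 1).
#' @param tau confidence threshold in (0, 1].
#' @param iteration iteration number recorded in the accepted records.
#' @return `list(accepted = <record data.frame>, rejected = <character ids>)`;
#'   records carry `sample_id`, `label`, `confidence`, `iteration`, `policy`.
#' @export
#' @examples
#' p <- probabilityMatrix(rbind(a = c(0.99, 0.01), b = c(0.6, 0.4)))
#' confidenceFilter(p, 0.98)
confidenceFilter <- function(probs, tau, iteration = 1L) {
  stopIfNot(tau > 0 && tau <= 1, "tau must lie in (0, 1]")
  v <- checkProbMatrix(probs)
  if (nrow(v) == 0L) return(list(accepted = emptyRecords(), rejected = character()))
  conf <- apply(v, 1, max)
  lab <- max.col(v, ties.method = "first")
  ok <- conf >= tau
  nOk <- sum(ok)
  accepted <- data.frame(sample_id = rownames(v)[ok], label = lab[ok],
                         confidence = unname(conf[ok]),
                         iteration = rep(as.integer(iteration), nOk),
                         policy = rep("single_model", nOk),
                         stringsAsFactors = FALSE)
  list(accepted = accepted, rejected = rownames(v)[!ok])
}

#' Two-model consensus (decision-level fusion) pseudo-label filter
#'
#' With two voters, "majority voting" is agreement: a pseudo-label is
#' accepted when both models predict the same class and the combined
#' confidence reaches the threshold. On disagreement the default policy
#' rejects the sample (safest for label purity); the `max_confidence`
#' policy instead accepts the more confident model's label when that
#' confidence reaches the threshold.
#'
#' @param probsA,probsB row-aligned [ProbabilityMatrix-class] objects from
#'   the two branches.
#' @param tau confidence threshold in (0, 1].
#' @param disagreementPolicy `"reject"` (default) or `"max_confidence"`.
#' @param confidenceCombine how the agreed confidence is summarised:
#'   `"max"` (default) or `"mean"` of the two confidences.
#' @param iteration iteration number recorded in the accepted records.
#' @return as [confidenceFilter()], with `policy = "consensus"`.
#' @export
consensusVote <- function(probsA, probsB, tau,
                          disagreementPolicy = c("reject", "max_confidence"),
                          confidenceCombine = c("max", "mean"),
                          iteration = 1L) {
  disagreementPolicy <- match.arg(disagreementPolicy)
  confidenceCombine <- match.arg(confidenceCombine)
  stopIfNot(tau > 0 && tau <= 1, "tau must lie in (0, 1]")
  a <- checkProbMatrix(probsA)
  b <- checkProbMatrix(probsB)
  if (!identical(rownames(a), rownames(b)))
    stop("probability matrices are not aligned on sample ids", call. = FALSE)
  if (nrow(a) == 0L) return(list(accepted = emptyRecords(), rejected = character()))
  labA <- max.col(a, ties.method = "first")
  labB <- max.col(b, ties.method = "first")
  confA <- apply(a, 1, max)
  confB <- apply(b, 1, max)
  agree <- labA == labB
  comb <- if (confidenceCombine == "max") pmax(confA, confB)
          else (confA + confB) / 2
  acceptAgree <- agree & comb >= tau
  label <- labA
  conf <- comb
  acceptDis <- rep(FALSE, nrow(a))
  if (disagreementPolicy == "max_confidence") {
    hi <- pmax(confA, confB)
    acceptDis <- !agree & hi >= tau
    useA <- confA >= confB
    label[!agree] <- ifelse(useA[!agree], labA[!agree], labB[!agree])
    conf[!agree] <- hi[!agree]
  }
  ok <- acceptAgree | acceptDis
  nOk <- sum(ok)
  accepted <- data.frame(sample_id = rownames(a)[ok], label = label[ok],
                         confidence = unname(conf[ok]),
                         iteration = rep(as.integer(iteration), nOk),
                         policy = rep("consensus", nOk),
                         stringsAsFactors = FALSE)
  list(accepted = accepted, rejected = rownames(a)[!ok])
}

#' Iterative pseudo-labelling with rejection
#'
#' Runs the iterative rejection loop: at iteration t the *current remaining
#' pool* is scored, samples at or above the iteration's threshold are
#' accepted and handed to `retrainHook`, and the rejected samples form the
#' pool of iteration t+1. The loop ends after `maxIterations` or when the
#' pool empties; samples still rejected at the final iteration are
#' permanently excluded (their count is the ledger's last `rejected`
#' entry).
#'
#' @param scorer function taking an [UnlabeledPool-class] and returning a
#'   [ProbabilityMatrix-class] (single-model filtering) or a list of two
#'   (consensus voting).
#' @param pool the initial [UnlabeledPool-class].
#' @param schedule a [thresholdSchedule()].
#' @param retrainHook optional `function(accepted, iteration)` invoked after
#'   each iteration with new accepted records; typically retrains the
#'   model(s) on the merged set. An error in the hook aborts the loop but
#'   the ledger rows already produced are preserved in the error condition
#'   (field `ledger`).
#' @param ... passed to [consensusVote()] (e.g. `disagreementPolicy`).
#' @return `list(records, ledger)`: all accepted records across iterations
#'   and a ledger `data.frame` with one row per iteration —
#'   `(iteration, threshold, accepted, rejected)`.
#' @export
iterativePseudoLabel <- function(scorer, pool, schedule = thresholdSchedule(),
                                 retrainHook = NULL, ...) {
  stopIfNot(is.function(scorer), "scorer must be a function")
  ledger <- emptyLedger()
  records <- emptyRecords()
  for (t in seq_len(schedule$maxIterations)) {
    if (nSamples(pool) == 0L) break
    tau <- scheduleThresholdAt(schedule, t)
    sc <- scorer(pool)
    res <- if (is.list(sc) && !is(sc, "ProbabilityMatrix") && length(sc) == 2L) {
      consensusVote(sc[[1]], sc[[2]], tau, iteration = t, ...)
    } else {
      confidenceFilter(sc, tau, iteration = t)
    }
    ledger <- rbind(ledger, data.frame(
      iteration = t, threshold = tau,
      accepted = nrow(res$accepted), rejected = length(res$rejected)))
    records <- rbind(records, res$accepted)
    if (nrow(res$accepted) && !is.null(retrainHook)) {
      tryCatch(retrainHook(res$accepted, t), error = function(e) {
        stop(errorCondition(
          paste0("retrain hook failed at iteration ", t, ": ",
                 conditionMessage(e)),
          ledger = ledger, records = records,
          class = "pseudoLabelRetrainError"))
      })
    }
    if (length(res$rejected) == 0L) {
      pool <- pool[integer()]
      break
    }
    pool <- pool[res$rejected]
  }
  list(records = records, ledger = ledger)
}

emptyLedger <- function() {
  data.frame(iteration = integer(), threshold = numeric(),
             accepted = integer(), rejected = integer())
}

#' Mean categorical cross-entropy against true labels
#'
#' Natural-log cross-entropy averaged over the batch. A zero predicted
#' probability for the true class is clamped at 1e-12 to keep the loss
#' finite.
#'
#' @param probs a [ProbabilityMatrix-class] or matrix of row distributions.
#' @param labels integer class indices (1-based), aligned with the rows.
#' @return a single number.
#' @export
#' @examples
#' supervisedLoss(probabilityMatrix(rbind(a = c(1, 0, 0, 0))), 1)  # 0
supervisedLoss <- function(probs, labels) {
  v <- checkProbMatrix(probs)
  labels <- as.integer(labels)
  stopIfNot(length(labels) == nrow(v), "labels must align with rows")
  stopIfNot(all(labels >= 1L & labels <= ncol(v)), "labels out of range")
  p <- v[cbind(seq_len(nrow(v)), labels)]
  mean(-log(pmax(p, 1e-12)))
}

#' Mean cross-entropy against pseudo-labels
#'
#' Treats accepted pseudo-labels as ground truth. Returns 0 for an empty
#' pseudo-label set (by convention: no unsupervised term).
#'
#' @param probs a [ProbabilityMatrix-class] covering (at least) the
#'   pseudo-labelled samples.
#' @param records accepted-record `data.frame` from [confidenceFilter()] /
#'   [consensusVote()].
#' @return a single number.
#' @export
unsupervisedLoss <- function(probs, records) {
  if (NROW(records) == 0L) return(0)
  v <- checkProbMatrix(probs)
  idx <- match(records$sample_id, rownames(v))
  if (anyNA(idx))
    stop("records reference samples missing from the probability matrix",
         call. = FALSE)
  p <- v[cbind(idx, as.integer(records$label))]
  mean(-log(pmax(p, 1e-12)))
}

#' Combine supervised and unsupervised losses
#'
#' `total = l_sup + lambda_eff * l_unsup`, where `lambda_eff` ramps
#' linearly from 0 to `lambda` over `rampEpochs` (constant `lambda` when
#' `rampEpochs = 0`).
#'
#' @param lsup,lunsup the two loss components.
#' @param config a [lossConfig()].
#' @param epoch current epoch (used by the ramp).
#' @return a single number.
#' @export
#' @examples
#' totalLoss(1, 2, lossConfig(lambda = 1, rampEpochs = 10), epoch = 5)  # 2
totalLoss <- function(lsup, lunsup, config = lossConfig(), epoch = 1L) {
  stopIfNot(is.finite(lsup) && is.finite(lunsup), "losses must be finite")
  lambdaEff <- if (config$rampEpochs > 0) {
    config$lambda * min(1, epoch / config$rampEpochs)
  } else config$lambda
  lsup + lambdaEff * lunsup
}

#' Write an iteration ledger as CSV
#'
#' Columns `(iteration, threshold, accepted, rejected)` — the machine twin
#' of the per-iteration rejection bookkeeping tables.
#'
#' @param ledger ledger `data.frame` from [iterativePseudoLabel()] or a run
#'   report.
#' @param path output path.
#' @return the ledger, invisibly.
#' @export
writeLedger <- function(ledger, path) {
  utils::write.csv(ledger, path, row.names = FALSE)
  invisible(ledger)
}

#' Write accepted pseudo-label records as CSV
#'
#' Columns `(sample_id, label, confidence, iteration, policy)`.
#'
#' @param records accepted-record `data.frame`.
#' @param path output path.
#' @return the records, invisibly.
#' @export
writePseudoLabels <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(records)
}
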