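# Shared fixtures and independent reference implementations ("oracles")
# used across the suite. Everything is built in code at test time.

# -- random probability matrices ------------------------------------------

randomProbMatrix <- function(n, C = 4L, seed = 1L) {
  set.seed(seed)
  v <- matrix(stats::rexp(n * C), n, C)
  v <- v / rowSums(v)
  rownames(v) <- sprintf("r%04d", seq_len(n))
  probabilityMatrix(v)
}

# -- naive per-row loop oracles (independent of the vectorised paths) -----

oracleConfidenceFilter <- function(v, tau) {
  acceptedIds <- character(); labels <- integer(); confs <- numeric()
  rejected <- character()
  for (i in seq_len(nrow(v))) {
    row <- v[i, ]
    conf <- max(row)
    if (conf >= tau) {
      acceptedIds <- c(acceptedIds, rownames(v)[i])
      labels <- c(labels, which(row == conf)[1])
      confs <- c(confs, conf)
    } else {
      rejected <- c(rejected, rownames(v)[i])
    }
  }
  list(ids = acceptedIds, labels = labels, confs = confs, rejected = rejected)
}

oracleConsensus <- function(a, b, tau, policy = "reject") {
  ids <- character(); labels <- integer(); rejected <- character()
  for (i in seq_len(nrow(a))) {
    la <- which.max(a[i, ]); lb <- which.max(b[i, ])
    ca <- max(a[i, ]); cb <- max(b[i, ])
    if (la == lb && max(ca, cb) >= tau) {
      ids <- c(ids, rownames(a)[i]); labels <- c(labels, la)
    } else if (la != lb && policy == "max_confidence" && max(ca, cb) >= tau) {
      ids <- c(ids, rownames(a)[i])
      labels <- c(labels, if (ca >= cb) la else lb)
    } else {
      rejected <- c(rejected, rownames(a)[i])
    }
  }
  list(ids = ids, labels = labels, rejected = rejected)
}

oracleCrossEntropy <- function(v, labels) {
  total <- 0
  for (i in seq_len(nrow(v))) {
    total <- total + (-log(max(v[i, labels[i]], 1e-12)))
  }
  total / nrow(v)
}

oracleAucPairs <- function(scores, pos) {
  concordant <- 0; ties <- 0; total <- 0
  for (i in which(pos)) {
    for (j in which(!pos)) {
      total <- total + 1
      if (scores[i] > scores[j]) concordant <- concordant + 1
      else if (scores[i] == scores[j]) ties <- ties + 1
    }
  }
  (concordant + ties / 2) / total
}

# -- toy datasets ----------------------------------------------------------

# Two linearly separable classes: a bright blob in the top-left vs the
# bottom-right quadrant. A closed-form linear rule (sign of the quadrant
# brightness difference) classifies it perfectly, which is the
# separability oracle used alongside network training.
twoBlobDataset <- function(nPerClass = 10L, size = 32L, seed = 1L) {
  set.seed(seed)
  n <- 2L * nPerClass
  arr <- array(0, dim = c(size, size, 1L, n))
  labels <- integer(n)
  q <- size %/% 2
  for (i in seq_len(n)) {
    cls <- if (i <= nPerClass) 1L else 2L
    img <- matrix(stats::runif(size * size, 0, 40), size, size)
    r0 <- if (cls == 1L) 2L else q + 2L
    rows <- r0:(r0 + q %/% 2)
    img[rows, rows] <- img[rows, rows] + 180
    arr[, , 1L, i] <- pmin(img, 255)
    labels[i] <- cls
  }
  labeledDataset(arr, labels, classNames = c("topleft", "bottomright"))
}

twoBlobLinearRuleAccuracy <- function(data) {
  d <- dim(imageArray(data))
  q <- d[1] %/% 2
  n <- d[4]
  pred <- integer(n)
  for (i in seq_len(n)) {
    img <- imageArray(data)[, , 1, i]
    pred[i] <- if (mean(img[1:q, 1:q]) > mean(img[(q + 1):d[1], (q + 1):d[2]]))
      1L else 2L
  }
  mean(pred == classLabels(data))
}

# -- scripted scorer with frozen confidences ------------------------------

# Emits a probability matrix whose max-probabilities are fixed per sample,
# independent of any training: used to hand-trace the rejection loop.
scriptedScorer <- function(confidences) {
  force(confidences)
  function(pool) {
    ids <- sampleIds(pool)
    conf <- confidences[ids]
    v <- t(vapply(conf, function(p) c(p, rep((1 - p) / 3, 3)), numeric(4)))
    rownames(v) <- ids
    probabilityMatrix(v)
  }
}

smallPhantoms <- function(perClass = 10L, size = 32L, seed = 7L) {
  generatePhantoms(phantomConfig(perClassCount = perClass, imageSize = size,
                                 noiseSd = 10, difficulty = 0.3, seed = seed))
}
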