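# Compact feedforward/convolutional network engine in base R.
#
# Design: a model is a list of layer descriptors plus parameter/optimizer
# state held in an environment. Convolution is im2col-based (patch indices
# are precomputed once per layer, so forward/backward reduce to one matrix
# multiplication and one rowsum scatter); pooling is non-overlapping max
# with first-index tie-breaking; everything is single-threaded and
# deterministic under a seed. Image batches use the H x W x C x n layout.

nnConv <- function(filters, kernel) list(type = "conv", filters = as.integer(filters), k = as.integer(kernel))
nnPool <- function(size) list(type = "pool", size = as.integer(size))
nnFlatten <- function() list(type = "flatten")
nnGAP <- function() list(type = "gap")
nnDropout <- function(rate) list(type = "dropout", rate = rate)
nnDense <- function(units, activation = "relu", feature = FALSE)
  list(type = "dense", units = as.integer(units), activation = activation,
       feature = isTRUE(feature))

# im2col index matrix: (k*k*C) x (oh*ow) linear indices into an H x W x C
# array (column-major). Output positions are column-major over (oh, ow).
im2colIndex <- function(H, W, C, k) {
  oh <- H - k + 1L; ow <- W - k + 1L
  # offsets of one patch, ordered (dr, dc, ch)
  off <- expand.grid(dr = 0:(k - 1L), dc = 0:(k - 1L), ch = 0:(C - 1L))
  base <- expand.grid(r = seq_len(oh), c = seq_len(ow))
  # linear index: r + (c-1)*H + ch*H*W
  idx <- outer(off$dr + off$dc * H + off$ch * H * W,
               base$r + (base$c - 1L) * H, `+`)
  storage.mode(idx) <- "integer"
  attr(idx, "outdim") <- c(oh, ow)
  idx
}

# pooling index matrix: (s*s) x (oh*ow*C) for non-overlapping pooling
poolIndex <- function(H, W, C, s) {
  oh <- H %/% s; ow <- W %/% s
  off <- expand.grid(dr = 0:(s - 1L), dc = 0:(s - 1L))
  base <- expand.grid(r = (seq_len(oh) - 1L) * s + 1L,
                      c = (seq_len(ow) - 1L) * s + 1L,
                      ch = 0:(C - 1L))
  idx <- outer(off$dr + off$dc * H,
               base$r + (base$c - 1L) * H + base$ch * H * W, `+`)
  storage.mode(idx) <- "integer"
  attr(idx, "outdim") <- c(oh, ow)
  idx
}

# Build a model: infer shapes, allocate parameters (He initialisation,
# seeded), precompute gather indices.
nnBuild <- function(arch, inputShape, seed = 1L) {
  shape <- as.integer(inputShape)  # c(H, W, C) or a flat width
  layers <- vector("list", length(arch))
  withSeed(seed, {
    for (i in seq_along(arch)) {
      L <- arch[[i]]
      if (L$type == "conv") {
        stopIfNot(length(shape) == 3L, "conv layer needs spatial input")
        H <- shape[1]; W <- shape[2]; C <- shape[3]
        stopIfNot(H >= L$k && W >= L$k, "input smaller than conv kernel")
        fanIn <- L$k * L$k * C
        L$W <- matrix(stats::rnorm(L$filters * fanIn, 0, sqrt(2 / fanIn)),
                      L$filters, fanIn)
        L$b <- numeric(L$filters)
        L$idx <- im2colIndex(H, W, C, L$k)
        L$inShape <- shape
        shape <- c(attr(L$idx, "outdim"), L$filters)
      } else if (L$type == "pool") {
        H <- shape[1]; W <- shape[2]; C <- shape[3]
        L$idx <- poolIndex(H, W, C, L$size)
        L$inShape <- shape
        shape <- c(attr(L$idx, "outdim"), C)
      } else if (L$type == "flatten") {
        L$inShape <- shape
        shape <- prod(shape)
      } else if (L$type == "gap") {
        stopIfNot(length(shape) == 3L, "gap layer needs spatial input")
        L$inShape <- shape
        shape <- shape[3]
      } else if (L$type == "dropout") {
        L$inShape <- shape
      } else if (L$type == "dense") {
        stopIfNot(length(shape) == 1L, "dense layer needs flat input")
        fanIn <- shape
        L$W <- matrix(stats::rnorm(L$units * fanIn, 0, sqrt(2 / fanIn)),
                      L$units, fanIn)
        L$b <- numeric(L$units)
        L$inShape <- shape
        shape <- L$units
      } else stop("unknown layer type: ", L$type)
      L$outShape <- shape
      layers[[i]] <- L
    }
  })
  env <- new.env(parent = emptyenv())
  env$layers <- layers
  env$inputShape <- as.integer(inputShape)
  env$outputShape <- shape
  env$opt <- NULL
  env
}

# batch helpers: images are (H,W,C,n) arrays, flat features (f, n) matrices
batchCount <- function(x) { d <- dim(x); d[length(d)] }
sliceBatch <- function(x, idx) {
  if (length(dim(x)) == 4L) x[, , , idx, drop = FALSE]
  else x[, idx, drop = FALSE]
}

# Forward pass. x: array (H,W,C,n) or matrix (features, n).
# Returns list(probs or out, caches, feature) where `feature` is the
# activation of the layer flagged feature = TRUE (features x n).
nnForward <- function(model, x, training = FALSE) {
  layers <- model$layers
  n <- if (length(dim(x)) == 4L) dim(x)[4] else ncol(x)
  caches <- vector("list", length(layers))
  feature <- NULL
  for (i in seq_along(layers)) {
    L <- layers[[i]]
    if (L$type == "conv") {
      s <- L$inShape; od <- attr(L$idx, "outdim")
      P <- od[1] * od[2]; k2C <- nrow(L$idx)
      xm <- matrix(x, prod(s), n)
      cols <- xm[as.vector(L$idx), , drop = FALSE]
      dim(cols) <- c(k2C, P * n)
      z <- L$W %*% cols + L$b
      a <- z * (z > 0)                       # ReLU
      caches[[i]] <- list(cols = cols, mask = z > 0)
      x <- aperm(array(a, c(L$filters, od[1], od[2], n)), c(2, 3, 1, 4))
    } else if (L$type == "pool") {
      s <- L$inShape; od <- attr(L$idx, "outdim")
      C <- s[3]; PpC <- ncol(L$idx); s2 <- nrow(L$idx)
      xm <- matrix(x, prod(s), n)
      cols <- xm[as.vector(L$idx), , drop = FALSE]
      dim(cols) <- c(s2, PpC * n)
      best <- cols[1, ]; arg <- rep(1L, PpC * n)
      for (r in 2:s2) {
        v <- cols[r, ]
        sel <- v > best
        if (any(sel)) { best[sel] <- v[sel]; arg[sel] <- r }
      }
      caches[[i]] <- list(arg = arg)
      x <- array(best, c(od[1], od[2], C, n))
    } else if (L$type == "flatten") {
      x <- matrix(x, prod(L$inShape), n)
    } else if (L$type == "gap") {
      s <- L$inShape
      xm <- matrix(x, s[1] * s[2], s[3] * n)
      x <- matrix(colMeans(xm), s[3], n)
    } else if (L$type == "dropout") {
      if (training && L$rate > 0) {
        keep <- 1 - L$rate
        mask <- (stats::runif(length(x)) < keep) / keep
        dim(mask) <- dim(x)
        caches[[i]] <- list(mask = mask)
        x <- x * mask
      }
    } else if (L$type == "dense") {
      z <- L$W %*% x + L$b
      if (L$activation == "relu") {
        a <- z * (z > 0)
        caches[[i]] <- list(x = x, mask = z > 0)
      } else if (L$activation == "softmax") {
        zs <- sweep(z, 2, apply(z, 2, max))
        ez <- exp(zs)
        a <- sweep(ez, 2, colSums(ez), "/")
        caches[[i]] <- list(x = x)
      } else {
        a <- z
        caches[[i]] <- list(x = x)
      }
      if (L$feature) feature <- a
      x <- a
    }
  }
  list(out = x, caches = caches, feature = feature)
}

# Backward pass from dOut at the softmax pre-activation convention:
# for the final softmax layer pass dOut = (probs - Y) * columnCoeff, which
# is the gradient wrt the logits. Returns list of per-layer gradients.
nnBackward <- function(model, caches, dOut, n) {
  layers <- model$layers
  grads <- vector("list", length(layers))
  d <- dOut
  for (i in rev(seq_along(layers))) {
    L <- layers[[i]]
    if (L$type == "dense") {
      cache <- caches[[i]]
      if (L$activation == "relu") d <- d * cache$mask
      # softmax: d already wrt logits; linear: identity
      grads[[i]] <- list(W = d %*% t(cache$x), b = rowSums(d))
      d <- t(L$W) %*% d
    } else if (L$type == "dropout") {
      if (!is.null(caches[[i]])) d <- d * caches[[i]]$mask
    } else if (L$type == "gap") {
      s <- L$inShape
      dm <- matrix(0, s[1] * s[2], s[3] * n)
      dm <- sweep(dm, 2, as.vector(d) / (s[1] * s[2]), `+`)
      d <- array(dm, c(s[1], s[2], s[3], n))
    } else if (L$type == "flatten") {
      d <- array(d, c(L$inShape, n))
    } else if (L$type == "pool") {
      s <- L$inShape; od <- attr(L$idx, "outdim")
      PpC <- ncol(L$idx)
      arg <- caches[[i]]$arg
      m <- length(arg)
      colj <- rep(seq_len(PpC), times = n)
      srcIdx <- L$idx[cbind(arg, colj)]
      im <- rep(seq_len(n), each = PpC)
      dx <- matrix(0, prod(s), n)
      dx[cbind(srcIdx, im)] <- as.vector(d)
      d <- array(dx, c(s, n))
    } else if (L$type == "conv") {
      s <- L$inShape; od <- attr(L$idx, "outdim")
      P <- od[1] * od[2]; k2C <- nrow(L$idx)
      cache <- caches[[i]]
      dm <- aperm(d, c(3, 1, 2, 4))          # (F, oh, ow, n)
      dm <- matrix(dm, L$filters, P * n)
      dm <- dm * cache$mask                  # ReLU gate
      grads[[i]] <- list(W = dm %*% t(cache$cols), b = rowSums(dm))
      dcols <- t(L$W) %*% dm                 # (k2C, P*n)
      dim(dcols) <- c(k2C * P, n)
      gv <- as.vector(L$idx)
      rs <- rowsum(dcols, gv)
      dx <- matrix(0, prod(s), n)
      dx[as.integer(rownames(rs)), ] <- rs
      d <- array(dx, c(s, n))
    }
  }
  grads
}

# Adam / Adamax update (in place on the model environment).
nnOptimStep <- function(model, grads, lr, beta1, beta2, eps = 1e-8,
                        adamax = FALSE) {
  if (is.null(model$opt)) {
    model$opt <- list(t = 0L, m = list(), v = list())
  }
  opt <- model$opt
  opt$t <- opt$t + 1L
  t <- opt$t
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in c("W", "b")) {
      key <- paste0(i, ".", p)
      gp <- g[[p]]
      m <- opt$m[[key]]; v <- opt$v[[key]]
      if (is.null(m)) { m <- gp * 0; v <- gp * 0 }
      m <- beta1 * m + (1 - beta1) * gp
      if (adamax) {
        v <- pmax(beta2 * v, abs(gp))
        step <- lr * (m / (1 - beta1^t)) / (v + eps)
      } else {
        v <- beta2 * v + (1 - beta2) * gp^2
        mhat <- m / (1 - beta1^t)
        vhat <- v / (1 - beta2^t)
        step <- lr * mhat / (sqrt(vhat) + eps)
      }
      model$layers[[i]][[p]] <- model$layers[[i]][[p]] - step
      opt$m[[key]] <- m; opt$v[[key]] <- v
    }
  }
  model$opt <- opt
  invisible(model)
}

nnSnapshotParams <- function(model) {
  lapply(model$layers, function(L) list(W = L$W, b = L$b))
}

nnRestoreParams <- function(model, snap) {
  for (i in seq_along(snap)) {
    if (!is.null(snap[[i]]$W)) {
      model$layers[[i]]$W <- snap[[i]]$W
      model$layers[[i]]$b <- snap[[i]]$b
    }
  }
  invisible(model)
}

# Predict class probabilities for a batch array (no dropout, batched).
nnPredict <- function(model, x, batchSize = 64L) {
  n <- batchCount(x)
  C <- model$outputShape
  out <- matrix(0, C, n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batchSize - 1L, n)
    out[, i:j] <- nnForward(model, sliceBatch(x, i:j), training = FALSE)$out
    i <- j + 1L
  }
  out
}

# Extract the flagged feature-layer activations (featureDim x n).
nnFeatures <- function(model, x, batchSize = 64L) {
  n <- batchCount(x)
  outs <- vector("list", 0L)
  i <- 1L
  while (i <= n) {
    j <- min(i + batchSize - 1L, n)
    f <- nnForward(model, sliceBatch(x, i:j), training = FALSE)$feature
    if (is.null(f)) stop("model has no feature layer", call. = FALSE)
    outs[[length(outs) + 1L]] <- f
    i <- j + 1L
  }
  do.call(cbind, outs)
}

# Mini-batch training loop with per-sample loss coefficients.
#
# x: (H,W,C,n) array (already preprocessed); y: integer labels 1..C;
# isPseudo: logical flag per sample — in each batch the loss is
# mean CE over genuine labels + lambda * mean CE over pseudo-labels,
# mirroring the two-term objective of semi-supervised training.
# val: optional list(x=, y=) used for the LR callback and checkpointing.
nnFit <- function(model, x, y, isPseudo = NULL, lambda = 1,
                  epochs = 10L, batchSize = 32L,
                  lr = 1e-3, beta1 = 0.9, beta2 = 0.999, adamax = FALSE,
                  lrCallback = NULL, val = NULL, seed = 1L,
                  checkpoint = TRUE, verbose = FALSE) {
  n <- batchCount(x)
  C <- model$outputShape
  if (is.null(isPseudo)) isPseudo <- rep(FALSE, n)
  cbState <- if (!is.null(lrCallback))
    list(lr = lr, consumed = rep(FALSE, length(lrCallback$accuracyThresholds)))
  else list(lr = lr, consumed = logical())
  bestVal <- -Inf
  bestSnap <- NULL
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     trainAcc = numeric(), valAcc = numeric(),
                     lr = numeric())
  withSeed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      totalLoss <- 0; totalCorrect <- 0L
      i <- 1L
      while (i <= n) {
        j <- min(i + batchSize - 1L, n)
        b <- ord[i:j]
        xb <- sliceBatch(x, b)
        yb <- y[b]
        pb <- isPseudo[b]
        fw <- nnForward(model, xb, training = TRUE)
        probs <- fw$out
        m <- length(b)
        Y <- matrix(0, C, m); Y[cbind(yb, seq_len(m))] <- 1
        nl <- sum(!pb); np <- sum(pb)
        coefs <- ifelse(pb,
                        if (np > 0) lambda / np else 0,
                        if (nl > 0) 1 / nl else 0)
        ce <- -log(pmax(probs[cbind(yb, seq_len(m))], 1e-12))
        totalLoss <- totalLoss + sum(ce * coefs) * m
        pred <- max.col(t(probs), ties.method = "first")
        totalCorrect <- totalCorrect + sum(pred == yb)
        dOut <- sweep(probs - Y, 2, coefs, `*`)
        grads <- nnBackward(model, fw$caches, dOut, m)
        nnOptimStep(model, grads, lr = cbState$lr, beta1 = beta1,
                    beta2 = beta2, adamax = adamax)
        i <- j + 1L
      }
      valAcc <- NA_real_
      if (!is.null(val) && length(val$y)) {
        vp <- nnPredict(model, val$x)
        valAcc <- mean(max.col(t(vp), ties.method = "first") == val$y)
        if (!is.null(lrCallback)) {
          cbState <- lrCallbackStep(cbState, valAcc, lrCallback)
        }
        if (checkpoint && valAcc >= bestVal) {
          bestVal <- valAcc
          bestSnap <- nnSnapshotParams(model)
        }
      }
      hist <- rbind(hist, data.frame(epoch = ep, loss = totalLoss / n,
                                     trainAcc = totalCorrect / n,
                                     valAcc = valAcc, lr = cbState$lr))
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  acc %.3f  val %.3f  lr %.2g",
                        ep, totalLoss / n, totalCorrect / n, valAcc, cbState$lr))
      }
    }
  })
  if (checkpoint && !is.null(bestSnap)) nnRestoreParams(model, bestSnap)
  hist
}
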