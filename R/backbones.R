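#' @include AllClasses.R
NULL

# Architecture registry: custom CNN branch, transfer branch, fusion head,
# plus optimizer and learning-rate-callback configuration.

#' Learning-rate callback configuration
#'
#' "Reduce LR on multiple accuracies": whenever the validation accuracy
#' surpasses a not-yet-consumed threshold, the learning rate is multiplied
#' by `factor` (never below `minLr`); each threshold fires at most once.
#'
#' @param accuracyThresholds strictly increasing accuracies in (0, 1).
#' @param factor multiplicative decay in (0, 1).
#' @param minLr learning-rate floor.
#' @return a validated list of class `lrCallbackConfig`.
#' @export
lrCallbackConfig <- function(accuracyThresholds = c(0.96, 0.99, 0.9935),
                             factor = 0.75, minLr = 1e-4) {
  stopIfNot(all(diff(accuracyThresholds) > 0) &&
              all(accuracyThresholds > 0 & accuracyThresholds < 1),
            "accuracyThresholds must be strictly increasing in (0, 1)")
  stopIfNot(factor > 0 && factor < 1, "factor must lie in (0, 1)")
  stopIfNot(minLr > 0, "minLr must be positive")
  structure(list(accuracyThresholds = accuracyThresholds, factor = factor,
                 minLr = minLr),
            class = "lrCallbackConfig")
}

#' One step of the multi-threshold learning-rate callback
#'
#' @param state list with elements `lr` (current learning rate) and
#'   `consumed` (logical vector aligned with the thresholds).
#' @param valAccuracy validation accuracy after the epoch.
#' @param config an [lrCallbackConfig()].
#' @return the updated state.
#' @export
#' @examples
#' st <- list(lr = 0.001, consumed = c(FALSE, FALSE, FALSE))
#' lrCallbackStep(st, 0.97, lrCallbackConfig())$lr  # 0.00075
lrCallbackStep <- function(state, valAccuracy, config = lrCallbackConfig()) {
  for (i in seq_along(config$accuracyThresholds)) {
    if (!state$consumed[i] && config$accuracyThresholds[i] < valAccuracy) {
      state$lr <- max(state$lr * config$factor, config$minLr)
      state$consumed[i] <- TRUE
    }
  }
  state
}

#' Training configuration
#'
#' @param epochs training epochs (default 50).
#' @param batchSize mini-batch size (default 32).
#' @param optimizer `"adam"` or `"adamax"`.
#' @param learningRate initial learning rate.
#' @param beta1,beta2 first/second-moment decay rates.
#' @param lrCallback an [lrCallbackConfig()] or `NULL`.
#' @param valFraction fraction of the training data carved out as a
#'   validation set when none is supplied (default 0.1); used for the LR
#'   callback and for best-checkpoint selection.
#' @param augment an [augmentConfig()] applied to the training images, or
#'   `NULL` for normalization only.
#' @param checkpoint restore the weights of the best validation epoch after
#'   fitting?
#' @param seed integer seed controlling shuffling, dropout and the
#'   validation carve-out.
#' @param verbose print per-epoch progress?
#' @return a validated list of class `trainConfig`.
#' @export
trainConfig <- function(epochs = 50L, batchSize = 32L, optimizer = "adam",
                        learningRate = 1e-3, beta1 = 0.85, beta2 = 0.9925,
                        lrCallback = lrCallbackConfig(), valFraction = 0.1,
                        augment = NULL, checkpoint = TRUE, seed = 1L,
                        verbose = FALSE) {
  stopIfNot(epochs >= 1, "epochs must be >= 1")
  stopIfNot(batchSize >= 1, "batchSize must be >= 1")
  stopIfNot(learningRate > 0, "learningRate must be positive")
  stopIfNot(optimizer %in% c("adam", "adamax"), "unknown optimizer")
  structure(list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 optimizer = optimizer, learningRate = learningRate,
                 beta1 = beta1, beta2 = beta2, lrCallback = lrCallback,
                 valFraction = valFraction, augment = augment,
                 checkpoint = isTRUE(checkpoint), seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "trainConfig")
}

#' Classifier: a trainable network honouring the classifier contract
#'
#' Built by [buildCustomCNN()], [buildTransferBranch()] or
#' [buildFusionModel()]. Weights and training history live in the `state`
#' environment (reference semantics: fitting updates the object in place).
#'
#' @slot arch short architecture tag (e.g. `"customCNN"`).
#' @slot nClasses number of output classes.
#' @slot featureDim width of the feature vector used for fusion.
#' @slot inputShape expected per-image `c(H, W, C)`.
#' @slot state environment holding the network, optimizer defaults and
#'   history.
#' @export
setClass("Classifier", representation(
  arch = "character",
  nClasses = "integer",
  featureDim = "integer",
  inputShape = "integer",
  state = "environment"
))

#' FusionClassifier: dual-branch feature-fusion model
#'
#' Concatenates the feature vectors of a grayscale branch and an RGB branch
#' and classifies them with a shared dense head. `featureDim` is the fused
#' width (sum of the branch widths).
#'
#' @slot branchGray grayscale branch (a [Classifier-class]).
#' @slot branchRGB RGB branch.
#' @export
setClass("FusionClassifier", contains = "Classifier", representation(
  branchGray = "Classifier",
  branchRGB = "Classifier"
))

setMethod("show", "Classifier", function(object) {
  cat(sprintf("%s classifier: input %s, %d classes, featureDim %d%s\n",
              object@arch, paste(object@inputShape, collapse = "x"),
              object@nClasses, object@featureDim,
              if (isTRUE(object@state$trained)) " [trained]" else ""))
})

#' @rdname classifier-contract
#' @export
setMethod("featureDim", "Classifier", function(object) object@featureDim)

#' Build the custom texture-oriented CNN branch
#'
#' The full variant takes 168x168 single-channel input through four
#' convolutional layers — two with 64 filters and 5x5 kernels, two with 128
#' filters and 4x4 kernels — each followed by max-pooling (3x3 after the
#' first block, 2x2 thereafter), then a flatten and a 512-unit ReLU dense
#' layer feeding the softmax; the 512 dense activations are the branch's
#' feature vector. Its default optimizer is Adam with learning rate 0.001,
#' beta1 = 0.85, beta2 = 0.9925.
#'
#' The tiny variant (two conv blocks of 8 and 16 filters, 32-unit dense,
#' input >= 32x32) honours the same contract at desk scale and is the
#' profile used by the package's own phantom experiments.
#'
#' @param spec a [DatasetSpec-class] with `channels = 1`.
#' @param tiny build the tiny variant?
#' @param seed weight-initialisation seed.
#' @return a [Classifier-class] with `featureDim` 512 (full) or 32 (tiny).
#' @export
buildCustomCNN <- function(spec, tiny = FALSE, seed = 1L) {
  if (spec@channels != 1L)
    stop("the custom CNN branch requires single-channel input", call. = FALSE)
  H <- spec@imageHeight; W <- spec@imageWidth
  if (tiny) {
    stopIfNot(H >= 32L && W >= 32L, "tiny custom CNN needs input >= 32x32")
    arch <- list(nnConv(8, 3), nnPool(2), nnConv(16, 3), nnPool(2),
                 nnFlatten(), nnDense(32, "relu", feature = TRUE),
                 nnDense(length(spec@classNames), "softmax"))
    fdim <- 32L
  } else {
    stopIfNot(H == 168L && W == 168L, "full custom CNN expects 168x168 input")
    arch <- list(nnConv(64, 5), nnPool(3), nnConv(64, 5), nnPool(2),
                 nnConv(128, 4), nnPool(2), nnConv(128, 4), nnPool(2),
                 nnFlatten(), nnDense(512, "relu", feature = TRUE),
                 nnDense(length(spec@classNames), "softmax"))
    fdim <- 512L
  }
  state <- new.env(parent = emptyenv())
  state$net <- nnBuild(arch, c(H, W, 1L), seed = seed)
  state$defaults <- list(optimizer = "adam", learningRate = 1e-3,
                         beta1 = 0.85, beta2 = 0.9925)
  state$trained <- FALSE
  new("Classifier", arch = if (tiny) "customCNN-tiny" else "customCNN",
      nClasses = length(spec@classNames), featureDim = fdim,
      inputShape = c(H, W, 1L), state = state)
}

#' Build the transfer branch (pluggable feature extractor + dense head)
#'
#' The head follows global average pooling with Dropout(0.5), a 128-unit
#' ReLU dense layer and another Dropout(0.5) before the softmax; the
#' 128 dense activations are the branch's feature vector, and the default
#' optimizer is Adamax with learning rate 1e-4.
#'
#' `backbone` may be any callable mapping a normalized `H x W x 3 x n`
#' array to a 4-d feature map; it is treated as frozen and only the head is
#' trained. With `backbone = NULL` a small randomly-initialised
#' convolutional stack is built in and trained end-to-end — the desk-scale
#' profile, which also keeps the package buildable without any pretrained
#' weights. A standard pretrained residual network can be plugged in where
#' one is available offline.
#'
#' @param spec a [DatasetSpec-class] with `channels = 3`.
#' @param backbone optional frozen feature-extractor function.
#' @param tiny build the tiny variant (two conv blocks, 16-unit head)?
#' @param seed weight-initialisation seed.
#' @return a [Classifier-class] with `featureDim` 128 (full) or 16 (tiny).
#' @export
buildTransferBranch <- function(spec, backbone = NULL, tiny = FALSE,
                                seed = 1L) {
  if (spec@channels != 3L)
    stop("the transfer branch requires 3-channel input", call. = FALSE)
  H <- spec@imageHeight; W <- spec@imageWidth
  C <- length(spec@classNames)
  headUnits <- if (tiny) 16L else 128L
  state <- new.env(parent = emptyenv())
  if (is.null(backbone)) {
    convs <- if (tiny) {
      list(nnConv(8, 3), nnPool(2), nnConv(16, 3), nnPool(2),
           nnConv(32, 3))
    } else {
      list(nnConv(16, 3), nnPool(2), nnConv(32, 3), nnPool(2),
           nnConv(64, 3), nnPool(2))
    }
    # global average pooling needs enough feature maps to carry the signal
    # at desk scale; the tiny profile also halves the dropout (a 16-unit
    # head under 0.5 dropout barely trains on tens of images)
    drop <- if (tiny) 0.25 else 0.5
    arch <- c(convs, list(nnGAP(), nnDropout(drop),
                          nnDense(headUnits, "relu", feature = TRUE),
                          nnDropout(drop), nnDense(C, "softmax")))
    state$net <- nnBuild(arch, c(H, W, 3L), seed = seed)
    state$backbone <- NULL
  } else {
    stopIfNot(is.function(backbone), "backbone must be a function")
    probe <- backbone(array(0, dim = c(H, W, 3L, 1L)))
    if (length(dim(probe)) != 4L)
      stop("backbone must return a 4-d feature map (h, w, f, n)", call. = FALSE)
    arch <- list(nnGAP(), nnDropout(0.5),
                 nnDense(headUnits, "relu", feature = TRUE),
                 nnDropout(0.5), nnDense(C, "softmax"))
    state$net <- nnBuild(arch, dim(probe)[1:3], seed = seed)
    state$backbone <- backbone
  }
  # the paper-scale head learns at Adamax 1e-4; the tiny desk profile uses
  # 1e-3 so that its randomly-initialised backbone trains in desk budgets
  state$defaults <- list(optimizer = "adamax",
                         learningRate = if (tiny) 1e-3 else 1e-4,
                         beta1 = 0.9, beta2 = 0.999)
  state$trained <- FALSE
  new("Classifier", arch = if (tiny) "transfer-tiny" else "transfer",
      nClasses = C, featureDim = headUnits, inputShape = c(H, W, 3L),
      state = state)
}

#' Build the dual-branch fusion model
#'
#' Concatenates the branch feature vectors into a fused representation of
#' width `featureDim(branchGray) + featureDim(branchRGB)` (640 with the
#' full branches: 512 + 128), then applies Dropout(0.5), a ReLU dense
#' layer (256 units; 32 when the fused width is small), Dropout(0.3) and
#' the softmax. The head trains with Adam at learning rate 1e-4 on the
#' frozen branch features; it consumes paired grayscale/RGB views of the
#' same samples ([DualViews-class]).
#'
#' @param branchGray single-channel branch ([Classifier-class]).
#' @param branchRGB 3-channel branch.
#' @param headUnits dense-head width; defaults to 256, or 32 when the
#'   fused width is below 64.
#' @param seed weight-initialisation seed.
#' @return a [FusionClassifier-class]; `featureDim` is the fused width.
#' @export
buildFusionModel <- function(branchGray, branchRGB, headUnits = NULL,
                             seed = 1L) {
  stopIfNot(is(branchGray, "Classifier") && is(branchRGB, "Classifier"),
            "branches must be Classifier objects")
  stopIfNot(branchGray@nClasses == branchRGB@nClasses,
            "branches must share the class count")
  fused <- branchGray@featureDim + branchRGB@featureDim
  if (is.null(headUnits)) headUnits <- if (fused < 64L) 32L else 256L
  C <- branchGray@nClasses
  arch <- list(nnDropout(0.5), nnDense(as.integer(headUnits), "relu"),
               nnDropout(0.3), nnDense(C, "softmax"))
  state <- new.env(parent = emptyenv())
  state$net <- nnBuild(arch, fused, seed = seed)
  state$defaults <- list(optimizer = "adam",
                         learningRate = if (fused < 64L) 1e-3 else 1e-4,
                         beta1 = 0.9, beta2 = 0.999)
  state$trained <- FALSE
  new("FusionClassifier", arch = "fusion", nClasses = C,
      featureDim = as.integer(fused),
      inputShape = branchGray@inputShape, state = state,
      branchGray = branchGray, branchRGB = branchRGB)
}

# ---- shared input plumbing ----

# Coerce a container/array to a normalized (H,W,C,n) array plus ids.
# Containers arrive on the 8-bit scale; scoring always happens on clean
# (normalization-only) images.
asModelInput <- function(object, newdata) {
  if (is(newdata, "ImageSet")) {
    ids <- newdata@sampleIds
    x <- newdata@images
  } else {
    x <- promoteImageArray(newdata)
    ids <- sprintf("s%04d", seq_len(dim(x)[4]))
  }
  d <- dim(x)
  if (!all(d[1:3] == object@inputShape)) {
    stop(sprintf("input shape %s does not match the model's %s",
                 paste(d[1:3], collapse = "x"),
                 paste(object@inputShape, collapse = "x")), call. = FALSE)
  }
  if (max(x) > 1) x <- x / 255
  list(x = x, ids = ids)
}

carveValidation <- function(n, valFraction, seed) {
  nv <- max(1L, floor(n * valFraction))
  if (nv >= n) nv <- max(0L, n - 1L)
  withSeed(seed, sample.int(n, nv))
}

#' @rdname classifier-contract
#' @param validation optional held-out [LabeledDataset-class]; when `NULL`
#'   and `config$valFraction > 0`, a validation set is carved from `data`.
#' @param config a [trainConfig()]; optimizer fields default to the
#'   architecture's own settings when left at their defaults.
#' @param isPseudo logical flag per training sample marking pseudo-labelled
#'   entries; their loss term is weighted by `lambda`.
#' @param lambda weight of the pseudo-label loss term.
#' @param warmStart continue from the current weights (default) instead of
#'   re-initialising the optimizer state.
#' @export
setMethod("fitClassifier", "Classifier",
  function(object, data, validation = NULL, config = trainConfig(),
           isPseudo = NULL, lambda = 1, warmStart = TRUE, ...) {
    stopIfNot(is(data, "LabeledDataset"), "data must be a LabeledDataset")
    st <- object@state
    defaults <- st$defaults
    opts <- resolveOptimizer(config, defaults)

    x <- data@images
    y <- data@labels
    n <- dim(x)[4]
    if (!is.null(config$augment)) {
      aug <- augmentBatch(data, config$augment, seed = fanSeed(config$seed, 77L))
      x <- aug@images
    }
    valIdx <- integer()
    if (is.null(validation) && config$valFraction > 0 && n >= 5L) {
      valIdx <- carveValidation(n, config$valFraction, fanSeed(config$seed, 11L))
    }
    if (length(valIdx)) {
      # validation images are never augmented
      val <- list(x = prepArray(data@images[, , , valIdx, drop = FALSE]),
                  y = y[valIdx])
      keep <- setdiff(seq_len(n), valIdx)
      x <- x[, , , keep, drop = FALSE]
      y <- y[keep]
      isPseudo <- if (is.null(isPseudo)) NULL else isPseudo[keep]
    } else if (!is.null(validation)) {
      vin <- asModelInput(object, validation)
      val <- list(x = vin$x, y = validation@labels)
    } else val <- NULL

    x <- prepArray(x)
    if (!is.null(st$backbone)) {
      x <- st$backbone(x)
      if (!is.null(val)) val$x <- st$backbone(val$x)
    }
    if (!warmStart) st$net$opt <- NULL
    # checkpoint selection and the accuracy-threshold LR callback need a
    # validation accuracy with finer resolution than a handful of samples;
    # below 8 validation images both degenerate to noise and are disabled
    valOk <- !is.null(val) && length(val$y) >= 8L
    hist <- nnFit(st$net, x, y, isPseudo = isPseudo, lambda = lambda,
                  epochs = config$epochs, batchSize = config$batchSize,
                  lr = opts$learningRate, beta1 = opts$beta1,
                  beta2 = opts$beta2, adamax = opts$optimizer == "adamax",
                  lrCallback = if (valOk) config$lrCallback else NULL,
                  val = val,
                  seed = fanSeed(config$seed, 23L),
                  checkpoint = config$checkpoint && valOk,
                  verbose = config$verbose)
    st$trained <- TRUE
    st$history <- if (is.null(st$history)) hist else rbind(st$history, hist)
    invisible(object)
  })

# use architecture defaults unless the user changed the trainConfig fields
resolveOptimizer <- function(config, defaults) {
  base <- trainConfig()
  pick <- function(field) {
    if (identical(config[[field]], base[[field]])) defaults[[field]]
    else config[[field]]
  }
  list(optimizer = pick("optimizer"), learningRate = pick("learningRate"),
       beta1 = pick("beta1"), beta2 = pick("beta2"))
}

prepArray <- function(x) if (max(x) > 1) x / 255 else x

#' @rdname classifier-contract
#' @export
setMethod("predictProba", "Classifier", function(object, newdata, ...) {
  inp <- asModelInput(object, newdata)
  st <- object@state
  x <- inp$x
  if (!is.null(st$backbone)) x <- st$backbone(x)
  probs <- t(nnPredict(st$net, x))
  probabilityMatrix(probs, inp$ids)
})

#' @rdname classifier-contract
#' @export
setMethod("extractFeatures", "Classifier", function(object, newdata, ...) {
  inp <- asModelInput(object, newdata)
  st <- object@state
  x <- inp$x
  if (!is.null(st$backbone)) x <- st$backbone(x)
  f <- t(nnFeatures(st$net, x))
  rownames(f) <- inp$ids
  f
})

# ---- fusion methods ----

fusedFeatures <- function(object, views) {
  stopIfNot(is(views, "DualViews"), "the fusion model consumes DualViews")
  fg <- extractFeatures(object@branchGray, views@gray)
  fr <- extractFeatures(object@branchRGB, views@rgb)
  if (!identical(rownames(fg), rownames(fr)))
    stop("mismatched sample pairing between the two views", call. = FALSE)
  cbind(fg, fr)
}

#' @rdname classifier-contract
#' @export
setMethod("fitClassifier", "FusionClassifier",
  function(object, data, validation = NULL, config = trainConfig(),
           isPseudo = NULL, lambda = 1, warmStart = TRUE, ...) {
    stopIfNot(is(data, "DualViews"), "fusion training data must be DualViews")
    stopIfNot(is(data@gray, "LabeledDataset"), "fusion views must be labelled")
    feats <- t(fusedFeatures(object, data))      # fused x n
    y <- data@gray@labels
    n <- ncol(feats)
    st <- object@state
    opts <- resolveOptimizer(config, st$defaults)
    val <- NULL
    if (!is.null(validation)) {
      vf <- t(fusedFeatures(object, validation))
      val <- list(x = vf, y = validation@gray@labels)
    } else if (config$valFraction > 0 && n >= 5L) {
      vi <- carveValidation(n, config$valFraction, fanSeed(config$seed, 11L))
      val <- list(x = feats[, vi, drop = FALSE], y = y[vi])
      keep <- setdiff(seq_len(n), vi)
      feats <- feats[, keep, drop = FALSE]
      y <- y[keep]
      isPseudo <- if (is.null(isPseudo)) NULL else isPseudo[keep]
    }
    if (!warmStart) st$net$opt <- NULL
    valOk <- !is.null(val) && length(val$y) >= 8L
    hist <- nnFit(st$net, feats, y, isPseudo = isPseudo, lambda = lambda,
                  epochs = config$epochs, batchSize = config$batchSize,
                  lr = opts$learningRate, beta1 = opts$beta1,
                  beta2 = opts$beta2, adamax = opts$optimizer == "adamax",
                  lrCallback = if (valOk) config$lrCallback else NULL,
                  val = val,
                  seed = fanSeed(config$seed, 23L),
                  checkpoint = config$checkpoint && valOk,
                  verbose = config$verbose)
    st$trained <- TRUE
    st$history <- if (is.null(st$history)) hist else rbind(st$history, hist)
    invisible(object)
  })

#' @rdname classifier-contract
#' @export
setMethod("predictProba", "FusionClassifier", function(object, newdata, ...) {
  feats <- t(fusedFeatures(object, newdata))
  probs <- t(nnPredict(object@state$net, feats))
  probabilityMatrix(probs, newdata@gray@sampleIds)
})

#' @rdname classifier-contract
#' @export
setMethod("extractFeatures", "FusionClassifier", function(object, newdata, ...) {
  fusedFeatures(object, newdata)
})
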