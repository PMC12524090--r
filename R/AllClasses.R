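#' @include AllGenerics.R
NULL

# Central S4 containers: dataset spec, labelled/unlabelled image sets,
# split results, probability matrices and dual-view pairs.

#' DatasetSpec: the shape contract of a classification task
#'
#' Describes a `C`-class image classification task: the ordered class names
#' (which fix the integer class indices 1..C), the per-image pixel
#' dimensions and the channel count (1 = grayscale, 3 = RGB).
#'
#' @slot classNames ordered character vector of unique class names (C >= 2).
#' @slot imageHeight,imageWidth positive integer pixel dimensions.
#' @slot channels integer, 1 or 3.
#' @export
setClass("DatasetSpec", representation(
  classNames = "character",
  imageHeight = "integer",
  imageWidth = "integer",
  channels = "integer"
))

setValidity("DatasetSpec", function(object) {
  msg <- character()
  if (length(object@classNames) < 2L) msg <- c(msg, "need at least 2 classes")
  if (anyDuplicated(object@classNames)) msg <- c(msg, "class names must be unique")
  if (length(object@imageHeight) != 1L || is.na(object@imageHeight) || object@imageHeight < 1L)
    msg <- c(msg, "imageHeight must be a positive integer")
  if (length(object@imageWidth) != 1L || is.na(object@imageWidth) || object@imageWidth < 1L)
    msg <- c(msg, "imageWidth must be a positive integer")
  if (!object@channels %in% c(1L, 3L)) msg <- c(msg, "channels must be 1 or 3")
  if (length(msg)) msg else TRUE
})

#' Construct a DatasetSpec
#'
#' @param classNames ordered character vector of class names. The order
#'   fixes the integer class indices; supply an explicit order for
#'   reproducibility (alphabetical is used by the image-folder reader when
#'   none is given).
#' @param imageHeight,imageWidth image dimensions in pixels.
#' @param channels 1 (grayscale) or 3 (RGB).
#' @return a [DatasetSpec-class].
#' @export
#' @examples
#' datasetSpec(c("a", "b"), 32, 32, 1)
datasetSpec <- function(classNames, imageHeight, imageWidth, channels = 1L) {
  new("DatasetSpec", classNames = as.character(classNames),
      imageHeight = as.integer(imageHeight), imageWidth = as.integer(imageWidth),
      channels = as.integer(channels))
}

#' ImageSet: a bag of same-shaped images
#'
#' Internal parent of [LabeledDataset-class] and [UnlabeledPool-class].
#' Pixel data live in a single `H x W x C x n` array; values are on the
#' 8-bit `[0, 255]` scale until [normalizeImages()] maps them to `[0, 1]`.
#'
#' @slot images numeric array `H x W x C x n`.
#' @slot sampleIds character vector of unique sample identifiers (length n).
#' @slot classNames ordered class names of the task the images belong to.
#' @export
setClass("ImageSet", representation(
  images = "array",
  sampleIds = "character",
  classNames = "character"
))

setValidity("ImageSet", function(object) {
  msg <- character()
  d <- dim(object@images)
  if (length(d) != 4L) msg <- c(msg, "images must be a 4-d array (H, W, C, n)")
  else {
    if (d[4] != length(object@sampleIds))
      msg <- c(msg, "number of images must equal number of sampleIds")
    if (!d[3] %in% c(1L, 3L)) msg <- c(msg, "channel dimension must be 1 or 3")
  }
  if (anyDuplicated(object@sampleIds)) msg <- c(msg, "sampleIds must be unique")
  if (length(msg)) msg else TRUE
})

#' LabeledDataset: images with class labels
#'
#' @slot labels integer class indices in `1..C`, aligned with the samples.
#' @seealso [labeledDataset()], [stratifiedSplit()], [generatePhantoms()]
#' @export
setClass("LabeledDataset", contains = "ImageSet",
         representation(labels = "integer"))

setValidity("LabeledDataset", function(object) {
  msg <- character()
  n <- length(object@sampleIds)
  C <- length(object@classNames)
  if (length(object@labels) != n) msg <- c(msg, "labels must align with samples")
  if (n > 0 && (anyNA(object@labels) || any(object@labels < 1L) || any(object@labels > C)))
    msg <- c(msg, sprintf("labels must lie in 1..%d", C))
  if (length(msg)) msg else TRUE
})

#' UnlabeledPool: images without labels
#'
#' @seealso [unlabeledPool()], [stratifiedSplit()]
#' @export
setClass("UnlabeledPool", contains = "ImageSet")

#' Construct a LabeledDataset
#'
#' @param images numeric array `H x W x C x n` (or `H x W x n`, promoted to
#'   a single channel).
#' @param labels integer class indices in `1..length(classNames)`.
#' @param classNames ordered class names.
#' @param sampleIds optional character ids; defaults to `"s0001"...`.
#' @return a [LabeledDataset-class].
#' @export
labeledDataset <- function(images, labels, classNames, sampleIds = NULL) {
  images <- promoteImageArray(images)
  n <- dim(images)[4]
  if (is.null(sampleIds)) sampleIds <- sprintf("s%04d", seq_len(n))
  new("LabeledDataset", images = images, sampleIds = as.character(sampleIds),
      classNames = as.character(classNames), labels = as.integer(labels))
}

#' Construct an UnlabeledPool
#'
#' @inheritParams labeledDataset
#' @return an [UnlabeledPool-class].
#' @export
unlabeledPool <- function(images, classNames, sampleIds = NULL) {
  images <- promoteImageArray(images)
  n <- dim(images)[4]
  if (is.null(sampleIds)) sampleIds <- sprintf("s%04d", seq_len(n))
  new("UnlabeledPool", images = images, sampleIds = as.character(sampleIds),
      classNames = as.character(classNames))
}

promoteImageArray <- function(images) {
  d <- dim(images)
  if (is.null(d)) stop("images must be an array", call. = FALSE)
  if (length(d) == 2L) d <- c(d, 1L, 1L)          # single grayscale image
  else if (length(d) == 3L) d <- c(d[1:2], 1L, d[3])  # stack of grayscale
  else if (length(d) != 4L) stop("images must have 2-4 dimensions", call. = FALSE)
  array(as.double(images), dim = d)
}

#' SplitResult: a labelled/unlabelled partition of a dataset
#'
#' Produced by [stratifiedSplit()]. The true classes of the unlabelled pool
#' are retained in `hiddenLabels` purely so that pseudo-label precision can
#' be measured on synthetic data; training code paths only ever receive the
#' [UnlabeledPool-class] and cannot see them.
#'
#' @slot labelled a [LabeledDataset-class].
#' @slot unlabelled an [UnlabeledPool-class].
#' @slot hiddenLabels named integer vector: true class per unlabelled id.
#' @slot fraction the requested labelled fraction.
#' @slot seed the seed the split was drawn with.
#' @export
setClass("SplitResult", representation(
  labelled = "LabeledDataset",
  unlabelled = "UnlabeledPool",
  hiddenLabels = "integer",
  fraction = "numeric",
  seed = "integer"
))

setValidity("SplitResult", function(object) {
  msg <- character()
  if (length(object@hiddenLabels) != nSamples(object@unlabelled))
    msg <- c(msg, "hiddenLabels must cover the unlabelled pool")
  if (length(intersect(object@labelled@sampleIds, object@unlabelled@sampleIds)))
    msg <- c(msg, "labelled and unlabelled ids must be disjoint")
  if (length(msg)) msg else TRUE
})

#' ProbabilityMatrix: per-sample class-probability rows
#'
#' An `n x C` matrix of softmax outputs; every row is a probability
#' distribution (non-negative, summing to 1 within 1e-6). Row names carry
#' the sample ids.
#'
#' @slot values the numeric matrix.
#' @seealso [probabilityMatrix()], [confidenceFilter()], [consensusVote()]
#' @export
setClass("ProbabilityMatrix", representation(values = "matrix"))

setValidity("ProbabilityMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (is.null(rownames(v))) msg <- c(msg, "rows must be named by sample id")
  if (nrow(v) > 0) {
    if (min(v) < -1e-9 || max(v) > 1 + 1e-9)
      msg <- c(msg, "entries must lie in [0, 1]")
    if (max(abs(rowSums(v) - 1)) > 1e-6)
      msg <- c(msg, "rows must sum to 1 within 1e-6")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ProbabilityMatrix
#'
#' @param values `n x C` numeric matrix of row distributions.
#' @param sampleIds character ids for the rows (or pre-set row names).
#' @return a [ProbabilityMatrix-class].
#' @export
probabilityMatrix <- function(values, sampleIds = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(sampleIds)) stop("sampleIds are required", call. = FALSE)
  rownames(values) <- as.character(sampleIds)
  new("ProbabilityMatrix", values = values)
}

#' DualViews: paired grayscale and RGB renderings of the same samples
#'
#' Produced by [renderDualViews()]; the two views share sample ids and
#' ordering so that the two network branches see the same sample through
#' their respective input modalities.
#'
#' @slot gray grayscale view (single channel).
#' @slot rgb RGB view (channel-replicated).
#' @export
setClass("DualViews", representation(gray = "ImageSet", rgb = "ImageSet"))

setValidity("DualViews", function(object) {
  if (!identical(object@gray@sampleIds, object@rgb@sampleIds))
    return("gray and rgb views must share sample ids and ordering")
  TRUE
})

# ---- accessors ----

#' @rdname imageset-accessors
#' @export
setMethod("imageArray", "ImageSet", function(x) x@images)

#' @rdname imageset-accessors
#' @export
setMethod("sampleIds", "ImageSet", function(x) x@sampleIds)

#' @rdname imageset-accessors
#' @export
setMethod("classLabels", "LabeledDataset", function(x) x@labels)

#' @rdname imageset-accessors
#' @export
setMethod("nSamples", "ImageSet", function(x) dim(x@images)[4])

#' @rdname imageset-accessors
#' @export
setMethod("imageDim", "ImageSet", function(x) dim(x@images)[1:3])

#' @export
#' @describeIn datasetClassNames class names stored in a DatasetSpec.
setMethod("datasetClassNames", "DatasetSpec", function(x) x@classNames)

#' @export
#' @describeIn datasetClassNames class names carried by an image container.
setMethod("datasetClassNames", "ImageSet", function(x) x@classNames)

#' Subset an image container by index or sample id
#'
#' @param x a [LabeledDataset-class] or [UnlabeledPool-class].
#' @param i integer, logical or character (sample-id) index.
#' @param j,...,drop ignored.
#' @return a container of the same class.
#' @name imageset-subset
#' @aliases [,LabeledDataset,ANY,ANY,ANY-method [,UnlabeledPool,ANY,ANY,ANY-method
NULL

resolveIdx <- function(x, i) {
  if (is.character(i)) {
    j <- match(i, x@sampleIds)
    if (anyNA(j)) stop("unknown sample ids: ", paste(i[is.na(j)], collapse = ", "), call. = FALSE)
    j
  } else if (is.logical(i)) which(i) else as.integer(i)
}

#' @rdname imageset-subset
#' @export
setMethod("[", "LabeledDataset", function(x, i, j, ..., drop = FALSE) {
  k <- resolveIdx(x, i)
  new("LabeledDataset", images = x@images[, , , k, drop = FALSE],
      sampleIds = x@sampleIds[k], classNames = x@classNames,
      labels = x@labels[k])
})

#' @rdname imageset-subset
#' @export
setMethod("[", "UnlabeledPool", function(x, i, j, ..., drop = FALSE) {
  k <- resolveIdx(x, i)
  new("UnlabeledPool", images = x@images[, , , k, drop = FALSE],
      sampleIds = x@sampleIds[k], classNames = x@classNames)
})

# ---- show methods ----

setMethod("show", "DatasetSpec", function(object) {
  cat(sprintf("DatasetSpec: %d classes [%s], %dx%dx%d\n",
              length(object@classNames), paste(object@classNames, collapse = ", "),
              object@imageHeight, object@imageWidth, object@channels))
})

setMethod("show", "LabeledDataset", function(object) {
  d <- dim(object@images)
  tab <- tabulate(object@labels, nbins = length(object@classNames))
  cat(sprintf("LabeledDataset: %d samples of %dx%dx%d\n", d[4], d[1], d[2], d[3]))
  cat("  per class:", paste(sprintf("%s=%d", object@classNames, tab), collapse = " "), "\n")
})

setMethod("show", "UnlabeledPool", function(object) {
  d <- dim(object@images)
  cat(sprintf("UnlabeledPool: %d samples of %dx%dx%d\n", d[4], d[1], d[2], d[3]))
})

setMethod("show", "SplitResult", function(object) {
  cat(sprintf("SplitResult (fraction %.3g, seed %d): %d labelled / %d unlabelled\n",
              object@fraction, object@seed, nSamples(object@labelled),
              nSamples(object@unlabelled)))
})

setMethod("show", "ProbabilityMatrix", function(object) {
  v <- object@values
  cat(sprintf("ProbabilityMatrix: %d samples x %d classes\n", nrow(v), ncol(v)))
  if (nrow(v)) {
    print(utils::head(round(v, 4), 4))
    if (nrow(v) > 4) cat("  ...\n")
  }
})

setMethod("show", "DualViews", function(object) {
  dg <- dim(object@gray@images); dr <- dim(object@rgb@images)
  cat(sprintf("DualViews: %d samples; gray %dx%dx%d, rgb %dx%dx%d\n",
              dg[4], dg[1], dg[2], dg[3], dr[1], dr[2], dr[3]))
})

#' Extract the numeric matrix from a ProbabilityMatrix
#'
#' @param x a [ProbabilityMatrix-class].
#' @return the underlying `n x C` matrix with sample-id row names.
#' @export
probValues <- function(x) {
  if (is(x, "ProbabilityMatrix")) x@values else as.matrix(x)
}
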