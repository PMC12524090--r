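# Generics for the pseudofuse data containers and classifier contract.

#' @title Accessors for image containers
#' @description `imageArray()` returns the pixel array (`H x W x C x n`),
#'   `sampleIds()` the sample identifiers, `classLabels()` the integer class
#'   indices (1-based), `nSamples()` the number of samples and `imageDim()`
#'   the per-image dimensions `c(H, W, C)`.
#' @param x an image container ([LabeledDataset-class], [UnlabeledPool-class]).
#' @return see description.
#' @name imageset-accessors
#' @aliases imageArray sampleIds classLabels nSamples imageDim
#' @examples
#' d <- generatePhantoms(phantomConfig(perClassCount = 2, imageSize = 16))
#' nSamples(d); imageDim(d); head(sampleIds(d)); classLabels(d)
NULL

#' @rdname imageset-accessors
#' @export
setGeneric("imageArray", function(x) standardGeneric("imageArray"))

#' @rdname imageset-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname imageset-accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname imageset-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname imageset-accessors
#' @export
setGeneric("imageDim", function(x) standardGeneric("imageDim"))

#' Class names of a container or spec
#' @param x a [DatasetSpec-class] or image container.
#' @return character vector of class names in index order.
#' @export
setGeneric("datasetClassNames", function(x) standardGeneric("datasetClassNames"))

#' @title The classifier contract
#' @description Every classifier built by [buildCustomCNN()],
#'   [buildTransferBranch()] or [buildFusionModel()] honours a common
#'   contract: `fitClassifier()` trains it and records a history,
#'   `predictProba()` returns a [ProbabilityMatrix-class] whose rows are
#'   per-class softmax distributions, `extractFeatures()` returns the
#'   intermediate feature matrix (`n x featureDim`) used for fusion, and
#'   `featureDim()` reports that width.
#' @param object a classifier object.
#' @param data training data (a [LabeledDataset-class], or a
#'   [DualViews-class] with labels for the fusion model).
#' @param newdata data to predict on (matching the training container type).
#' @param ... further arguments (e.g. `validation`, `config`).
#' @return `fitClassifier()` returns the classifier (invisibly) with its
#'   training history stored; `predictProba()` a [ProbabilityMatrix-class];
#'   `extractFeatures()` a numeric matrix; `featureDim()` an integer.
#' @name classifier-contract
NULL

#' @rdname classifier-contract
#' @export
setGeneric("fitClassifier", function(object, data, ...) standardGeneric("fitClassifier"))

#' @rdname classifier-contract
#' @export
setGeneric("predictProba", function(object, newdata, ...) standardGeneric("predictProba"))

#' @rdname classifier-contract
#' @export
setGeneric("extractFeatures", function(object, newdata, ...) standardGeneric("extractFeatures"))

#' @rdname classifier-contract
#' @export
setGeneric("featureDim", function(object) standardGeneric("featureDim"))
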