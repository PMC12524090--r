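# Training-time augmentation and normalization.
#
# Training pipeline order: augmentation operates on the raw 8-bit scale and
# normalization comes after it; evaluation data are normalized only.

#' Augmentation configuration
#'
#' Magnitudes of the stochastic training-time transforms. `rotationFraction`
#' is expressed as a fraction of a full turn (0.02 = up to ±7.2°), matching
#' the fraction-based semantics of common augmentation layers;
#' `contrastRange` 0.10 scales the deviation from the image mean by a
#' factor uniform in `1 ± 0.10`; `zoomRange` and `translateRange` default to
#' a conservative 5% each (zoom factor in `1 ± zoomRange`, translation up
#' to `translateRange` of the image side).
#'
#' @param horizontalFlip apply a horizontal flip with probability 0.5?
#' @param rotationFraction max rotation as a fraction of a full turn.
#' @param contrastRange half-width of the contrast scaling interval.
#' @param zoomRange half-width of the zoom factor interval.
#' @param translateRange max translation as a fraction of the image side.
#' @return a validated list of class `augmentConfig`.
#' @export
augmentConfig <- function(horizontalFlip = TRUE, rotationFraction = 0.02,
                          contrastRange = 0.10, zoomRange = 0.05,
                          translateRange = 0.05) {
  stopIfNot(rotationFraction >= 0 && contrastRange >= 0 &&
              zoomRange >= 0 && translateRange >= 0,
            "augmentation ranges must be non-negative")
  structure(list(horizontalFlip = isTRUE(horizontalFlip),
                 rotationFraction = rotationFraction,
                 contrastRange = contrastRange,
                 zoomRange = zoomRange,
                 translateRange = translateRange),
            class = "augmentConfig")
}

#' Normalize 8-bit images to [0, 1]
#'
#' Divides every pixel by 255. Inputs must be on the `[0, 255]` scale;
#' values outside it, or an input that already looks normalized
#' (maximum <= 1), raise an error — the latter guards against the classic
#' double-normalization bug. A genuinely all-black 8-bit image trips the
#' same guard; this is a documented trade-off.
#'
#' @param x a numeric array/matrix of pixels, or an image container
#'   ([LabeledDataset-class], [UnlabeledPool-class], [DualViews-class]),
#'   normalized slot-wise.
#' @return same shape/class as `x`, pixel values in `[0, 1]`.
#' @export
#' @examples
#' normalizeImages(matrix(c(0, 127.5, 255), 1))
normalizeImages <- function(x) {
  if (is(x, "DualViews")) {
    return(new("DualViews", gray = normalizeImages(x@gray),
               rgb = normalizeImages(x@rgb)))
  }
  if (is(x, "ImageSet")) {
    y <- x
    y@images <- normalizeImages(x@images)
    return(y)
  }
  r <- range(x)
  if (r[1] < 0 || r[2] > 255) {
    stop("pixel values outside [0, 255]; refusing to normalize", call. = FALSE)
  }
  if (r[2] <= 1) {
    stop("input already appears normalized (max <= 1); ",
         "refusing to normalize twice", call. = FALSE)
  }
  x / 255
}

#' Apply a stochastic augmentation draw to one image
#'
#' Draws, from a stream seeded by `drawSeed`: a horizontal flip (probability
#' 0.5 when enabled), a rotation uniform in `± rotationFraction` of a full
#' turn, a contrast factor uniform in `1 ± contrastRange`, a zoom factor in
#' `1 ± zoomRange` and a translation within `± translateRange` of the side.
#' Geometry is resampled bilinearly with reflection at the borders, so
#' rotation leaves no dark corners. With all ranges 0 and flip disabled the
#' image is returned unchanged. Output shape always equals input shape.
#'
#' @param image `H x W` matrix or `H x W x C` array (raw or normalized).
#' @param config an [augmentConfig()].
#' @param drawSeed integer seed of this draw; the same seed reproduces the
#'   same transform.
#' @return the augmented image, same shape as the input.
#' @export
augmentImage <- function(image, config = augmentConfig(), drawSeed = 1L) {
  stopIfNot(inherits(config, "augmentConfig"), "config must be an augmentConfig")
  withSeed(as.integer(drawSeed), {
    doFlip <- config$horizontalFlip && stats::runif(1) < 0.5
    angle <- if (config$rotationFraction > 0)
      stats::runif(1, -1, 1) * config$rotationFraction * 2 * pi else 0
    contrast <- if (config$contrastRange > 0)
      stats::runif(1, 1 - config$contrastRange, 1 + config$contrastRange) else 1
    zoom <- if (config$zoomRange > 0)
      stats::runif(1, 1 - config$zoomRange, 1 + config$zoomRange) else 1
    d <- dim(image)
    shift <- if (config$translateRange > 0)
      stats::runif(2, -1, 1) * config$translateRange * d[1:2] else c(0, 0)

    out <- image
    if (doFlip) out <- flipHorizontal(out)
    out <- affineTransform(out, angle = angle, zoom = zoom, translate = shift)
    if (contrast != 1) {
      m <- mean(out)
      lo <- min(image); hi <- max(image)
      out <- pmin(pmax(m + contrast * (out - m), min(0, lo)), max(1, hi))
    }
    out
  })
}

# Augment a whole container; per-image draw seeds are fanned out from `seed`.
augmentBatch <- function(data, config, seed) {
  y <- data
  n <- dim(data@images)[4]
  for (i in seq_len(n)) {
    y@images[, , , i] <- augmentImage(data@images[, , , i, drop = TRUE],
                                      config, drawSeed = fanSeed(seed, i))
  }
  y
}

#' Build the evaluation pipeline (normalization only)
#'
#' Test and validation data receive no stochastic transform: the returned
#' function simply normalizes. It is deterministic — two passes over the
#' same data yield identical tensors — and inherits the repeated-application
#' guard of [normalizeImages()].
#'
#' @return a function of one image container/array.
#' @export
makeEvalPipeline <- function() {
  f <- function(x) normalizeImages(x)
  attr(f, "steps") <- "normalize"
  f
}

#' Build the training pipeline (augmentation, then normalization)
#'
#' Augmentation operates on the raw 8-bit scale and normalization is applied
#' afterwards, preserving the integrity of the geometric transforms. With
#' all ranges zero and flip disabled the result equals the evaluation
#' pipeline's output.
#'
#' @param config an [augmentConfig()].
#' @param seed integer; per-image draw seeds are derived from it.
#' @return a function of one image container; `attr(, "steps")` exposes the
#'   composition order.
#' @export
makeTrainPipeline <- function(config = augmentConfig(), seed = 1L) {
  force(config); force(seed)
  f <- function(x) normalizeImages(augmentBatch(x, config, seed))
  attr(f, "steps") <- c("augment", "normalize")
  f
}
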