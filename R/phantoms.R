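#' @include AllClasses.R
NULL

# Seeded four-class phantom-image generator. The phantoms emulate, at desk
# scale, a grayscale axial "brain" image with one of three lesion
# morphologies or none: the geometry is invented, but the classes are
# designed so that the ragged-mass vs ring-mass pair is the hardest to
# separate, analogous to meningioma being the hardest tumor class in real
# MRI cohorts.

#' Configuration of the phantom generator
#'
#' @param perClassCount images per class.
#' @param imageSize square image side in pixels (>= 16).
#' @param noiseSd additive Gaussian pixel noise SD, in grey-level units on
#'   the `[0, 255]` scale.
#' @param difficulty real in `[0, 1]`; interpolates the lesion contrast
#'   toward the background, so larger values make the classes overlap more.
#' @param seed integer seed; generation is byte-identical per seed.
#' @return a validated config list of class `phantomConfig`.
#' @export
#' @examples
#' phantomConfig(perClassCount = 10)
phantomConfig <- function(perClassCount = 50L, imageSize = 64L, noiseSd = 10,
                          difficulty = 0.3, seed = 0L) {
  stopIfNot(perClassCount >= 1, "perClassCount must be positive")
  stopIfNot(imageSize >= 16, "imageSize must be at least 16")
  stopIfNot(noiseSd >= 0, "noiseSd must be non-negative")
  stopIfNot(difficulty >= 0 && difficulty <= 1, "difficulty must lie in [0, 1]")
  structure(list(perClassCount = as.integer(perClassCount),
                 imageSize = as.integer(imageSize),
                 noiseSd = as.double(noiseSd),
                 difficulty = as.double(difficulty),
                 seed = as.integer(seed)),
            class = "phantomConfig")
}

phantomClassNames <- function() {
  c("ragged_mass", "ring_mass", "focal_bright", "no_lesion")
}

#' Generate a four-class phantom dataset
#'
#' Each image is a smooth elliptical "brain" background over a dark field,
#' plus a class-specific lesion template and Gaussian pixel noise:
#'
#' * `ragged_mass` — eccentric bright ellipse with a ragged (angularly
#'   perturbed) edge;
#' * `ring_mass` — bright annulus;
#' * `focal_bright` — small high-intensity disc in the lower half;
#' * `no_lesion` — background only.
#'
#' Every sample gets its own pose jitter (up to ±10% translation and
#' rotation of the template), which is part of generation and distinct from
#' training-time augmentation. `difficulty` linearly interpolates the
#' lesion peak toward the background intensity; at 1 the three lesion
#' classes collapse onto `no_lesion`. Intensities are clipped to
#' `[0, 255]` and left real-valued in memory (8-bit quantisation happens at
#' [writeImageFolder()]).
#'
#' @param config a [phantomConfig()].
#' @return a [LabeledDataset-class] with `4 * perClassCount` samples,
#'   exactly `perClassCount` per class.
#' @export
#' @examples
#' d <- generatePhantoms(phantomConfig(perClassCount = 5, imageSize = 32))
#' table(classLabels(d))
generatePhantoms <- function(config = phantomConfig()) {
  stopIfNot(inherits(config, "phantomConfig"), "config must be a phantomConfig")
  S <- config$imageSize
  n <- config$perClassCount
  cn <- phantomClassNames()
  arr <- array(0, dim = c(S, S, 1L, 4L * n))
  labels <- integer(4L * n)
  ids <- character(4L * n)
  withSeed(config$seed, {
    k <- 0L
    for (cl in 1:4) {
      for (i in seq_len(n)) {
        k <- k + 1L
        arr[, , 1L, k] <- phantomImage(cl, S, config$noiseSd, config$difficulty)
        labels[k] <- cl
        ids[k] <- sprintf("%s_%03d", cn[cl], i)
      }
    }
  })
  new("LabeledDataset", images = arr, sampleIds = ids, classNames = cn,
      labels = labels)
}

# One phantom image; consumes RNG draws (pose jitter, edge raggedness,
# pixel noise) from the caller's seeded stream.
phantomImage <- function(classIdx, size, noiseSd, difficulty) {
  # normalized coordinates in [-1, 1]; y grows downward (rows)
  ax <- seq(-1, 1, length.out = size)
  X <- matrix(rep(ax, each = size), size, size)   # column coordinate
  Y <- matrix(rep(ax, times = size), size, size)  # row coordinate

  # pose jitter: +-10% rotation (of a half turn) and translation
  th <- stats::runif(1, -0.1, 0.1) * pi
  tx <- stats::runif(1, -0.1, 0.1)
  ty <- stats::runif(1, -0.1, 0.1)
  Xr <- cos(th) * (X - tx) - sin(th) * (Y - ty)
  Yr <- sin(th) * (X - tx) + cos(th) * (Y - ty)

  soft <- function(z, w) 1 / (1 + exp(-z / w))   # smooth edge profile

  bgLevel <- 90; outLevel <- 5; peak <- 225
  e <- (Xr / 0.80)^2 + (Yr / 0.88)^2
  img <- outLevel + (bgLevel - outLevel) * soft(1 - e, 0.05)

  lesionPeak <- bgLevel + (peak - bgLevel) * (1 - difficulty)
  amp <- lesionPeak - bgLevel

  if (classIdx == 1L) {            # eccentric ragged ellipse
    cx <- 0.25; cy <- -0.12
    dx <- (Xr - cx) / 1.15; dy <- (Yr - cy) / 0.85
    rho <- sqrt(dx^2 + dy^2)
    phi <- atan2(dy, dx)
    p1 <- stats::runif(1, 0, 2 * pi); p2 <- stats::runif(1, 0, 2 * pi)
    rEdge <- 0.30 * (1 + 0.22 * sin(5 * phi + p1) + 0.12 * sin(9 * phi + p2))
    img <- img + amp * soft(rEdge - rho, 0.02)
  } else if (classIdx == 2L) {     # bright ring
    cx <- -0.10; cy <- 0.05
    rho <- sqrt((Xr - cx)^2 + (Yr - cy)^2)
    r0 <- 0.30; halfw <- 0.085
    ring <- soft(rho - (r0 - halfw), 0.02) * soft((r0 + halfw) - rho, 0.02)
    img <- img + amp * ring
  } else if (classIdx == 3L) {     # small bright disc, lower half
    cx <- stats::runif(1, -0.15, 0.15); cy <- 0.40
    rho <- sqrt((Xr - cx)^2 + (Yr - cy)^2)
    img <- img + amp * soft(0.13 - rho, 0.015)
  }                                # classIdx 4: background only

  if (noiseSd > 0) {
    img <- img + matrix(stats::rnorm(size * size, 0, noiseSd), size, size)
  }
  pmin(pmax(img, 0), 255)
}

#' Render paired grayscale and RGB views of a dataset
#'
#' Produces the two input modalities consumed by the dual-branch
#' architecture: a resized single-channel view (default 168x168x1) for the
#' texture branch, and a channel-replicated, resized RGB view (default
#' 224x224x3) for the transfer branch. Sample ids and ordering are shared
#' between the views.
#'
#' @param data a single-channel [LabeledDataset-class] or
#'   [UnlabeledPool-class].
#' @param graySize side of the grayscale view (default 168).
#' @param rgbSize side of the RGB view (default 224).
#' @return a [DualViews-class]; each view keeps the class of `data` (the
#'   gray view of a labelled input is labelled, etc.).
#' @export
renderDualViews <- function(data, graySize = 168L, rgbSize = 224L) {
  stopIfNot(is(data, "ImageSet"), "data must be an image container")
  d <- dim(data@images)
  if (d[3] != 1L) stop("dual views require single-channel input", call. = FALSE)
  n <- d[4]
  gArr <- array(0, dim = c(graySize, graySize, 1L, n))
  rArr <- array(0, dim = c(rgbSize, rgbSize, 3L, n))
  for (i in seq_len(n)) {
    im <- data@images[, , 1L, i]
    gArr[, , 1L, i] <- resizeBilinear(im, graySize, graySize)
    r1 <- resizeBilinear(im, rgbSize, rgbSize)
    rArr[, , 1L, i] <- r1; rArr[, , 2L, i] <- r1; rArr[, , 3L, i] <- r1
  }
  mk <- function(arr) {
    if (is(data, "LabeledDataset")) {
      new("LabeledDataset", images = arr, sampleIds = data@sampleIds,
          classNames = data@classNames, labels = data@labels)
    } else {
      new("UnlabeledPool", images = arr, sampleIds = data@sampleIds,
          classNames = data@classNames)
    }
  }
  new("DualViews", gray = mk(gArr), rgb = mk(rArr))
}
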