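# Stratified labelled/unlabelled splitting and image-folder I/O.

#' Stratified labelled/unlabelled split
#'
#' Partitions a labelled dataset into a labelled subset and an unlabelled
#' pool while preserving the class proportions. The overall labelled count
#' is `round(fraction * n)`; per-class counts follow the largest-remainder
#' rule (floor each class quota, then hand out the remaining slots in order
#' of decreasing fractional remainder), so totals are conserved and every
#' class stays within one sample of its exact quota.
#'
#' The true classes of the pool samples are retained in the result's
#' `hiddenLabels` slot so that pseudo-label precision can be scored on
#' synthetic data; they are never passed to training code.
#'
#' @param data a [LabeledDataset-class]; every class must be represented.
#' @param labelledFraction fraction in (0, 1] of samples to keep labelled.
#' @param seed integer seed; the split is deterministic given
#'   (data, fraction, seed).
#' @return a [SplitResult-class].
#' @export
#' @examples
#' d <- generatePhantoms(phantomConfig(perClassCount = 10, imageSize = 16))
#' s <- stratifiedSplit(d, 0.8, seed = 1)
#' nSamples(s@labelled); nSamples(s@unlabelled)
stratifiedSplit <- function(data, labelledFraction, seed = 1L) {
  stopIfNot(is(data, "LabeledDataset"), "data must be a LabeledDataset")
  stopIfNot(labelledFraction > 0 && labelledFraction <= 1,
            "labelledFraction must lie in (0, 1]")
  C <- length(data@classNames)
  counts <- tabulate(data@labels, nbins = C)
  if (any(counts == 0L)) {
    stop("class without samples: ",
         paste(data@classNames[counts == 0L], collapse = ", "), call. = FALSE)
  }
  perClass <- largestRemainderCounts(counts, labelledFraction)
  labIdx <- withSeed(as.integer(seed), {
    unlist(lapply(seq_len(C), function(cl) {
      idx <- which(data@labels == cl)
      if (perClass[cl] >= length(idx)) idx
      else sort(sample(idx, perClass[cl]))
    }))
  })
  labIdx <- sort(labIdx)
  poolIdx <- setdiff(seq_len(nSamples(data)), labIdx)
  labelled <- data[labIdx]
  pool <- new("UnlabeledPool", images = data@images[, , , poolIdx, drop = FALSE],
              sampleIds = data@sampleIds[poolIdx], classNames = data@classNames)
  hidden <- data@labels[poolIdx]
  names(hidden) <- data@sampleIds[poolIdx]
  new("SplitResult", labelled = labelled, unlabelled = pool,
      hiddenLabels = hidden, fraction = labelledFraction,
      seed = as.integer(seed))
}

# Largest-remainder apportionment of round(fraction * sum(counts)) labelled
# slots across classes. Ties in the remainders are broken by class order.
largestRemainderCounts <- function(counts, fraction) {
  total <- floor(fraction * sum(counts) + 0.5)
  quota <- fraction * counts
  base <- pmin(floor(quota), counts)
  left <- total - sum(base)
  if (left > 0) {
    room <- counts - base
    rem <- quota - floor(quota)
    ord <- order(-rem, seq_along(counts))
    for (i in ord) {
      if (left == 0) break
      add <- min(room[i], left, 1L)
      base[i] <- base[i] + add
      left <- left - add
    }
    # if single passes were not enough (heavily skewed rounding), fill greedily
    while (left > 0) {
      i <- which.max(counts - base)
      base[i] <- base[i] + 1L
      left <- left - 1L
    }
  } else if (left < 0) {
    while (left < 0) {
      i <- which.max(base)
      base[i] <- base[i] - 1L
      left <- left + 1L
    }
  }
  as.integer(base)
}

#' Read an image-folder tree into a LabeledDataset
#'
#' Expects the layout `root/<class_name>/<file>.png`, one subdirectory per
#' class of `spec`. Labels are assigned from the directory name via the
#' spec's class ordering; files are visited in lexicographic path order so
#' the result is identical across file systems. Images are decoded from
#' 8-bit PNG to the `[0, 255]` scale and resized to the spec's dimensions
#' when they differ.
#'
#' @param root directory containing one subdirectory per class.
#' @param spec a [DatasetSpec-class].
#' @return a [LabeledDataset-class].
#' @export
readImageFolder <- function(root, spec) {
  stopIfNot(dir.exists(root), "no such directory: ", root)
  subdirs <- sortLex(list.dirs(root, recursive = FALSE, full.names = FALSE))
  unknown <- setdiff(subdirs, spec@classNames)
  if (length(unknown)) {
    stop("unknown class directories: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(spec@classNames, subdirs)
  if (length(missing)) {
    stop("missing class directories: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  H <- spec@imageHeight; W <- spec@imageWidth; C <- spec@channels
  imgs <- list(); labels <- integer(); ids <- character()
  for (cl in seq_along(spec@classNames)) {
    cname <- spec@classNames[cl]
    files <- sortLex(list.files(file.path(root, cname), full.names = TRUE))
    if (!length(files)) stop("empty class directory: ", cname, call. = FALSE)
    for (f in files) {
      img <- decodeImageFile(f, C)
      if (dim(img)[1] != H || dim(img)[2] != W) img <- resizeBilinear(img, H, W)
      imgs[[length(imgs) + 1L]] <- img
      labels <- c(labels, cl)
      ids <- c(ids, paste0(cname, "/", basename(f)))
    }
  }
  arr <- array(0, dim = c(H, W, C, length(imgs)))
  for (i in seq_along(imgs)) arr[, , , i] <- imgs[[i]]
  new("LabeledDataset", images = arr, sampleIds = ids,
      classNames = spec@classNames, labels = labels)
}

decodeImageFile <- function(path, channels) {
  if (!grepl("\\.png$", path, ignore.case = TRUE)) {
    stop("cannot decode (only PNG is supported): ", path, call. = FALSE)
  }
  img <- tryCatch(png::readPNG(path), error = function(e) {
    stop("cannot decode image file: ", path, " (", conditionMessage(e), ")",
         call. = FALSE)
  })
  d <- dim(img)
  if (length(d) == 3L && d[3] >= 3L) {
    img <- img[, , 1:3, drop = FALSE]           # drop alpha if present
    if (channels == 1L) img <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  } else {
    if (length(d) == 3L) img <- img[, , 1]
    if (channels == 3L) img <- array(rep(img, 3L), dim = c(d[1], d[2], 3L))
  }
  img <- array(img, dim = c(dim(img)[1], dim(img)[2], channels))
  img * 255
}

#' Write a LabeledDataset as an image-folder tree
#'
#' Writes one 8-bit grayscale (or RGB) PNG per sample under
#' `root/<class_name>/`, returning a manifest of the files written. An
#' empty dataset produces an empty manifest and creates no directories.
#'
#' @param data a [LabeledDataset-class]; pixel values on the `[0, 255]` scale.
#' @param root destination directory.
#' @param overwrite overwrite existing files? Collisions error otherwise.
#' @return a `data.frame` with columns `sample_id`, `path`, `class_name`,
#'   `label`.
#' @export
writeImageFolder <- function(data, root, overwrite = FALSE) {
  stopIfNot(is(data, "LabeledDataset"), "data must be a LabeledDataset")
  n <- nSamples(data)
  manifest <- data.frame(sample_id = character(), path = character(),
                         class_name = character(), label = integer(),
                         stringsAsFactors = FALSE)
  if (n == 0L) return(manifest)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cname <- data@classNames[data@labels[i]]
    cdir <- file.path(root, cname)
    dir.create(cdir, showWarnings = FALSE)
    fname <- paste0(gsub("[^A-Za-z0-9_.-]", "_", data@sampleIds[i]), ".png")
    path <- file.path(cdir, fname)
    if (file.exists(path) && !overwrite) {
      stop("file exists (use overwrite = TRUE): ", path, call. = FALSE)
    }
    img <- data@images[, , , i]
    img <- round(pmin(pmax(img, 0), 255)) / 255
    png::writePNG(img, path)
    rows[[i]] <- data.frame(sample_id = data@sampleIds[i], path = path,
                            class_name = cname, label = data@labels[i],
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Write a split manifest CSV
#'
#' Records which sample landed in which role of a [SplitResult-class]:
#' columns `sample_id`, `role` (`labelled`/`unlabelled`/`test`),
#' `label_or_NA` and `seed`. Unlabelled rows carry `NA` labels — the hidden
#' truth stays hidden.
#'
#' @param split a [SplitResult-class].
#' @param path output CSV path.
#' @param test optional test [LabeledDataset-class] to append as `test` rows.
#' @return the manifest `data.frame`, invisibly.
#' @export
writeSplitManifest <- function(split, path, test = NULL) {
  lab <- data.frame(sample_id = split@labelled@sampleIds, role = "labelled",
                    label_or_NA = split@labelled@labels,
                    seed = split@seed, stringsAsFactors = FALSE)
  unl <- data.frame(sample_id = split@unlabelled@sampleIds, role = "unlabelled",
                    label_or_NA = NA_integer_, seed = split@seed,
                    stringsAsFactors = FALSE)
  m <- rbind(lab, unl)
  if (!is.null(test)) {
    m <- rbind(m, data.frame(sample_id = test@sampleIds, role = "test",
                             label_or_NA = test@labels, seed = split@seed,
                             stringsAsFactors = FALSE))
  }
  utils::write.csv(m, path, row.names = FALSE)
  invisible(m)
}
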