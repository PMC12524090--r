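test_that("stratified split preserves class balance and conserves samples", {
  d <- smallPhantoms(25)  # 100 samples, 4 x 25
  s <- stratifiedSplit(d, 0.8, seed = 1)
  expect_equal(nSamples(s@labelled), 80L)
  expect_equal(nSamples(s@unlabelled), 20L)
  expect_equal(unname(tabulate(classLabels(s@labelled), 4)), rep(20L, 4))
  # conservation: union of ids is the input's id set
  expect_setequal(c(sampleIds(s@labelled), sampleIds(s@unlabelled)),
                  sampleIds(d))
  # fraction 1.0: identity case
  s1 <- stratifiedSplit(d, 1.0, seed = 3)
  expect_equal(nSamples(s1@unlabelled), 0L)
  expect_setequal(sampleIds(s1@labelled), sampleIds(d))
})

test_that("split counts follow the largest-remainder rule (brute force)", {
  # 7 samples in classes {4, 3}, fraction 0.5
  arr <- array(runif(8 * 8 * 7) * 255, c(8, 8, 1, 7))
  d <- labeledDataset(arr, c(1, 1, 1, 1, 2, 2, 2), c("a", "b"))
  # brute-force largest-remainder: total = round(3.5) = 4,
  # quotas (2.0, 1.5) -> base (2, 1), one leftover goes to the larger
  # remainder (class b) -> (2, 2)
  quotas <- 0.5 * c(4, 3)
  base <- floor(quotas)
  leftover <- floor(sum(quotas) + 0.5) - sum(base)
  ord <- order(-(quotas - base))
  for (k in seq_len(leftover)) base[ord[k]] <- base[ord[k]] + 1
  for (seed in 1:5) {
    s <- stratifiedSplit(d, 0.5, seed = seed)
    got <- tabulate(classLabels(s@labelled), 2)
    expect_equal(got, base)
    expect_equal(nSamples(s@labelled) + nSamples(s@unlabelled), 7L)
  }
})

test_that("split stratification error and invariants hold across fractions", {
  d <- smallPhantoms(9)  # 36 samples
  counts <- tabulate(classLabels(d), 4)
  for (f in c(0.1, 0.33, 0.5, 0.77)) {
    s <- stratifiedSplit(d, f, seed = 11)
    labc <- tabulate(classLabels(s@labelled), 4)
    expect_true(all(abs(labc - f * counts) <= 1))  # within 1 of the quota
    expect_length(intersect(sampleIds(s@labelled), sampleIds(s@unlabelled)), 0)
    # hidden labels match the generator's truth
    expect_equal(unname(s@hiddenLabels),
                 classLabels(d)[match(names(s@hiddenLabels), sampleIds(d))])
  }
  # determinism
  expect_identical(stratifiedSplit(d, 0.4, seed = 5),
                   stratifiedSplit(d, 0.4, seed = 5))
  # a class without samples errors by name
  bad <- labeledDataset(array(1, c(4, 4, 1, 2)), c(1, 1), c("x", "y"))
  expect_error(stratifiedSplit(bad, 0.5, seed = 1), "y")
})

test_that("image-folder write/read round-trips 8-bit pixels exactly", {
  d <- smallPhantoms(3, size = 16)
  root <- withr::local_tempdir()
  manifest <- writeImageFolder(d, file.path(root, "imgs"))
  expect_equal(nrow(manifest), 12L)
  expect_length(list.dirs(file.path(root, "imgs"), recursive = FALSE), 4L)

  spec <- datasetSpec(datasetClassNames(d), 16, 16, 1)
  back <- readImageFolder(file.path(root, "imgs"), spec)
  expect_equal(nSamples(back), 12L)
  # reader orders by class then file name; match on written ids
  key <- paste0(manifest$class_name, "/", basename(manifest$path))
  idx <- match(sampleIds(back), key)
  expect_false(anyNA(idx))
  expect_equal(classLabels(back), manifest$label[idx])
  # pixel values identical after the writer's 8-bit quantisation
  expect_equal(imageArray(back)[, , , order(idx), drop = FALSE],
               round(pmin(pmax(imageArray(d), 0), 255)),
               tolerance = 1e-12)
  # collision errors without overwrite
  expect_error(writeImageFolder(d, file.path(root, "imgs")), "overwrite")
  expect_silent(writeImageFolder(d, file.path(root, "imgs"), overwrite = TRUE))
})

test_that("image-folder reader rejects unknown and empty class directories", {
  root <- withr::local_tempdir()
  d <- smallPhantoms(2, size = 16)
  writeImageFolder(d, root, overwrite = TRUE)
  spec <- datasetSpec(datasetClassNames(d), 16, 16, 1)
  dir.create(file.path(root, "mystery"))
  expect_error(readImageFolder(root, spec), "mystery")
  unlink(file.path(root, "mystery"), recursive = TRUE)
  unlink(list.files(file.path(root, "ring_mass"), full.names = TRUE))
  expect_error(readImageFolder(root, spec), "ring_mass")
})

test_that("writer manifest length equals dataset size; empty set writes nothing", {
  empty <- labeledDataset(array(0, c(4, 4, 1, 0)), integer(), c("a", "b"))
  root <- withr::local_tempdir()
  m <- writeImageFolder(empty, file.path(root, "none"))
  expect_equal(nrow(m), 0L)
  expect_false(dir.exists(file.path(root, "none")))
  for (n in c(1L, 7L, 23L)) {
    arr <- array(runif(16 * n) * 255, c(4, 4, 1, n))
    d <- labeledDataset(arr, rep(1:2, length.out = n), c("a", "b"),
                        sampleIds = sprintf("id%03d", seq_len(n)))
    m <- writeImageFolder(d, file.path(root, paste0("set", n)))
    expect_equal(nrow(m), n)
  }
})

test_that("split manifest records roles and hides pool labels", {
  d <- smallPhantoms(4, size = 16)
  s <- stratifiedSplit(d, 0.5, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  m <- writeSplitManifest(s, path)
  got <- read.csv(path)
  expect_named(got, c("sample_id", "role", "label_or_NA", "seed"))
  expect_true(all(is.na(got$label_or_NA[got$role == "unlabelled"])))
  expect_false(anyNA(got$label_or_NA[got$role == "labelled"]))
})
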