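# Thermal input handling: readers, conversion, resizing, augmentation,
# splitting.

test_that("temperature matrices scale to 16-bit and round-trip exactly", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("30 31", "32 33"), path)
  rec <- loadThermalImage(path)
  expect_identical(dim(rec@pixels), c(2L, 2L, 1L))
  expect_equal(min(rec@pixels), 0)
  expect_equal(max(rec@pixels), 1)
  expect_identical(rec@temperature, rbind(c(30, 31), c(32, 33)))

  m <- matrix(runif(12, 28, 36), 3, 4)
  p2 <- withr::local_tempfile(fileext = ".txt")
  writeTemperatureMatrix(m, p2)
  expect_identical(loadThermalImage(p2)@temperature, m)

  p3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("30 31", "32"), p3)
  expect_error(loadThermalImage(p3), "ragged")
  expect_error(loadThermalImage("no-such-file.png"), "cannot read")
})

test_that("raster readers preserve the frame geometry", {
  px <- matrix(seq(0, 1, length.out = 480 * 640), 480, 640)
  path <- withr::local_tempfile(fileext = ".tiff")
  tiff::writeTIFF(px, path, bits.per.sample = 16L)
  rec <- loadThermalImage(path)
  expect_identical(dim(rec@pixels)[1:2], c(480L, 640L))
  expect_equal(rec@pixels[, , 1L], px, tolerance = 2 / 65535)
})

test_that("grayscale conversion uses fixed luminance weights", {
  white <- thermogram(array(1, c(4, 4, 3)))
  expect_equal(max(toGrayscale(white)@pixels), 1)
  set.seed(21)
  px <- array(runif(5 * 7 * 3), c(5, 7, 3))
  g <- toGrayscale(thermogram(px))@pixels[, , 1L]
  # per-pixel weighted-sum oracle (direct loop)
  for (i in 1:5) for (j in 1:7) {
    expect_equal(g[i, j],
                 0.299 * px[i, j, 1] + 0.587 * px[i, j, 2] +
                   0.114 * px[i, j, 3])
  }
  expect_true(all(g >= apply(px, c(1, 2), min) - 1e-12) &&
                all(g <= apply(px, c(1, 2), max) + 1e-12))
  # idempotence: replicated grayscale collapses back to itself
  rep3 <- thermogram(array(px[, , c(1, 1, 1)], c(5, 7, 3)),
                     colorMode = "grayscale")
  expect_equal(toGrayscale(rep3)@pixels[, , 1L], px[, , 1L])
})

test_that("resizeToNetwork yields the square 3-channel network input", {
  rec <- thermogram(matrix(runif(480 * 640), 480, 640))
  out <- resizeToNetwork(rec, 299L)
  expect_identical(dim(out@pixels), c(299L, 299L, 3L))
  # identity resize keeps pixels
  small <- thermogram(matrix(runif(299^2), 299, 299))
  expect_equal(resizeToNetwork(small, 299L,
                               replicateChannels = FALSE)@pixels,
               small@pixels)
  # a constant image stays constant at any size
  const <- thermogram(matrix(0.42, 50, 80))
  expect_true(all(abs(resizeToNetwork(const, 32L)@pixels - 0.42) < 1e-9))
})

test_that("augmentation is seeded, identity-able, and moves deltas", {
  rec <- thermogram(matrix(runif(60 * 60), 60, 60))
  still <- augmentationPolicy(flipVerticalAxis = FALSE, maxTranslation = 0L,
                              maxScaleFraction = 0)
  expect_identical(augmentRecord(rec, still)@pixels, rec@pixels)

  policy <- augmentationPolicy(seed = 7L)
  set.seed(policy@seed); a <- augmentRecord(rec, policy)
  set.seed(policy@seed); b <- augmentRecord(rec, policy)
  expect_identical(a@pixels, b@pixels)
  expect_identical(dim(a@pixels), dim(rec@pixels))

  # translation by (0, +5): the delta peak moves 5 columns
  delta <- matrix(0, 40, 40); delta[20, 18] <- 1
  tr <- translateRecord(thermogram(delta), 0L, 5L)
  peak <- which(tr@pixels[, , 1L] == 1, arr.ind = TRUE)
  expect_identical(unname(peak[1, ]), c(20L, 23L))
  # left-right mirroring via the policy flips columns
  flip <- augmentationPolicy(flipVerticalAxis = TRUE, maxTranslation = 0L,
                             maxScaleFraction = 0)
  set.seed(1)  # first runif < 0.5 draw triggers the flip
  flipped <- NULL
  for (k in 1:10) {
    cand <- augmentRecord(thermogram(delta), flip)
    if (!identical(cand@pixels, thermogram(delta)@pixels)) {
      flipped <- cand; break
    }
  }
  expect_false(is.null(flipped))
  pk <- which(flipped@pixels[, , 1L] == 1, arr.ind = TRUE)
  expect_identical(unname(pk[1, ]), c(20L, 40L - 18L + 1L))
})

test_that("stratified splits are exact, seeded and proportion-preserving", {
  labels <- c(rep("healthy", 1019), rep("sick", 862))
  manifest <- data.frame(path = sprintf("img%04d", seq_along(labels)),
                         label = labels, stringsAsFactors = FALSE)
  sp <- splitDataset(manifest, 0.7, seed = 3L)
  expect_identical(nrow(sp$train) + nrow(sp$test), nrow(manifest))
  expect_identical(length(intersect(sp$train$path, sp$test$path)), 0L)
  # per-class floor rounding: 1019 -> 713 train / 306 test;
  # 862 -> 603 train / 259 test
  expect_identical(as.integer(table(sp$test$label)[c("healthy", "sick")]),
                   c(306L, 259L))
  sp2 <- splitDataset(manifest, 0.7, seed = 3L)
  expect_identical(sp$train$path, sp2$train$path)
  sp3 <- splitDataset(manifest, 0.5, seed = 1L)
  expect_identical(as.integer(table(sp3$train$label)[c("healthy", "sick")]),
                   c(509L, 431L))
  # measure preservation across the supported sweep
  for (f in c(0.8, 0.7, 0.6, 0.5, 0.4)) {
    spf <- splitDataset(manifest, f, seed = 1L)
    for (cl in c("healthy", "sick")) {
      n <- sum(labels == cl)
      expect_lte(abs(sum(spf$train$label == cl) - f * n), 1)
    }
  }
  expect_error(splitDataset(manifest[manifest$label == "sick", ], 0.7),
               "stratification")
  expect_error(splitDataset(manifest, 1.2), "trainFraction")
})
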