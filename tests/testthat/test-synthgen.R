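# Synthetic thermogram simulator: symmetry, lesion contrast, quantization,
# determinism, dataset generation and separability.

tinyCfg <- function(noiseSd = 0, seed = 5L, ...) {
  simulationConfig(frameHeight = 60L, frameWidth = 80L, noiseSd = noiseSd,
                   seed = seed, ...)
}

test_that("noise-free healthy frames are exactly mirror-symmetric", {
  for (seed in 1:5) {
    tg <- generateThermogram(tinyCfg(), "healthy", seed = seed)
    m <- tg@temperature
    expect_identical(m, m[, ncol(m):1])
    expect_equal(asymmetryStatistic(tg), 0)
    expect_identical(nrow(tg@lesions), 0L)
  }
})

test_that("noise-free sick frames carry the lesion elevation exactly", {
  cfg <- tinyCfg(deltaTRange = c(2, 2), lesionCountLambda = 0)
  for (seed in 1:8) {
    tg <- generateThermogram(cfg, "sick", seed = seed)
    expect_identical(nrow(tg@lesions), 1L)
    # analytic field at the lesion peak: asymmetry equals delta_t
    expect_equal(asymmetryStatistic(tg), 2, tolerance = 1e-9)
    expect_true(tg@lesions$side %in% c("left", "right"))
  }
})

test_that("frames are bit-identical under the same seed", {
  cfg <- tinyCfg(noiseSd = 0.08)
  a <- generateThermogram(cfg, "sick", seed = 42)
  b <- generateThermogram(cfg, "sick", seed = 42)
  expect_identical(a@temperature, b@temperature)
  expect_identical(a@pixels, b@pixels)
  expect_identical(a@lesions, b@lesions)
  c <- generateThermogram(cfg, "sick", seed = 43)
  expect_false(identical(a@temperature, c@temperature))
})

test_that("16-bit quantization error is bounded by the window step", {
  cfg <- tinyCfg(noiseSd = 0.05)
  tg <- generateThermogram(cfg, "sick", seed = 9)
  window <- cfg@windowRange
  implied <- window[1] + tg@pixels[, , 1L] * diff(window)
  inWindow <- tg@temperature >= window[1] & tg@temperature <= window[2]
  expect_lte(max(abs(implied[inWindow] - tg@temperature[inWindow])),
             diff(window) / 65535)
})

test_that("color rendering uses the fixed palette and keeps 3 channels", {
  expect_identical(length(thermalPalette()), 256L)
  expect_identical(thermalPalette(), thermalPalette())
  tg <- generateThermogram(tinyCfg(), "healthy", colorMode = "color",
                           seed = 2)
  expect_identical(dim(tg@pixels)[3], 3L)
  expect_identical(tg@colorMode, "color")
})

test_that("generateDataset writes the requested counts reproducibly", {
  cfg <- tinyCfg(noiseSd = 0.05, seed = 77L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generateDataset(10L, 10L, cfg, d1)
  expect_identical(as.integer(table(m1$label)[c("healthy", "sick")]),
                   c(10L, 10L))
  expect_identical(nrow(m1), 20L)
  expect_true(all(file.exists(file.path(d1, m1$path))))
  m2 <- generateDataset(10L, 10L, cfg, d2)
  expect_identical(m1, m2)
  h1 <- tools::md5sum(file.path(d1, m1$path))
  h2 <- tools::md5sum(file.path(d2, m2$path))
  expect_identical(unname(h1), unname(h2))
  # manifest CSV bytes identical too
  expect_identical(unname(tools::md5sum(file.path(d1, "manifest.csv"))),
                   unname(tools::md5sum(file.path(d2, "manifest.csv"))))
})

test_that("asymmetry statistics separate classes when delta_t >> noise", {
  cfg <- tinyCfg(noiseSd = 0, deltaTRange = c(2, 2.5), seed = 31L)
  dir <- withr::local_tempdir()
  man <- generateDataset(6L, 6L, cfg, dir)
  rep <- separabilityReport(file.path(dir, "manifest.csv"))
  healthy <- rep$perClass[rep$perClass$label == "healthy", ]
  sick <- rep$perClass[rep$perClass$label == "sick", ]
  expect_lt(healthy$max, sick$min)   # disjoint class ranges
  expect_identical(rep$overlap, 0)
})

test_that("delta_t 0 is an honest negative control", {
  # a 'sick' population with no thermal contrast is indistinguishable
  cfg <- tinyCfg(noiseSd = 0.1, deltaTRange = c(1e-6, 2e-6), seed = 13L)
  dir <- withr::local_tempdir()
  man <- generateDataset(8L, 8L, cfg, dir)
  rep <- separabilityReport(file.path(dir, "manifest.csv"))
  healthy <- rep$perClass[rep$perClass$label == "healthy", ]
  sick <- rep$perClass[rep$perClass$label == "sick", ]
  expect_lt(abs(healthy$mean - sick$mean),
            3 * sqrt(healthy$sd^2 / healthy$n + sick$sd^2 / sick$n) + 0.05)
  expect_gt(rep$overlap, 0)
})

test_that("empirical asymmetry overlap matches a Monte-Carlo estimate", {
  # moderate noise: compare the dataset's sick-class statistic spread with
  # a direct simulation of the same generative model
  cfg <- tinyCfg(noiseSd = 0.15, deltaTRange = c(1, 1.5), seed = 47L,
                 lesionCountLambda = 0)
  dir <- withr::local_tempdir()
  man <- generateDataset(15L, 15L, cfg, dir)
  rep <- separabilityReport(file.path(dir, "manifest.csv"))
  # Monte-Carlo draw of the healthy-class statistic: max |N - mirrored N|
  # over the frame, i.e. max of |differences| of independent normals
  set.seed(1)
  H <- cfg@frameHeight; W <- cfg@frameWidth
  mc <- replicate(300, {
    eps <- matrix(rnorm(H * W, sd = cfg@noiseSd), H, W)
    max(abs(eps - eps[, W:1]))
  })
  healthy <- rep$perClass[rep$perClass$label == "healthy", ]
  expect_lt(abs(healthy$mean - mean(mc)), 4 * sd(mc))
})
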