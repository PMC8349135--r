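# Synthetic breast thermogram simulator.
#
# The simulator emulates the statistical structure the classifier relies
# on, not the biophysics: a frontal torso-shaped region at a baseline skin
# temperature with a smooth, *bilaterally mirror-symmetric* anatomical
# variation (healthy), and the same field plus one or more localized
# Gaussian hot spots confined to one breast (sick) — the thermographic
# signature of tumor-associated hypervascularity. Sensor noise is additive
# Gaussian; frames are quantized to 16 bits over a physiological rendering
# window and can be rendered grayscale or false-color.

#' Construct a simulator configuration
#'
#' Defaults emulate the acquisition protocol of the reference database:
#' 480 x 640 16-bit frames, room temperature between 18 and 25 deg C,
#' baseline skin temperature 33 deg C, lesion peak elevations of 1-3
#' deg C. The rendering window defaults to 22-38 deg C (physiological)
#' rather than the camera's full range, to preserve contrast.
#'
#' @param frameHeight,frameWidth frame size, pixels.
#' @param baselineTemp baseline skin temperature, deg C.
#' @param ambientTemp room temperature, deg C, in `[18, 25]`.
#' @param gradientAmp amplitude of the smooth anatomical variation, deg C.
#' @param noiseSd sensor noise standard deviation, deg C.
#' @param lesionCountLambda Poisson mean of extra lesions beyond the first.
#' @param deltaTRange lesion peak elevation range `c(min, max)`, deg C.
#' @param windowRange rendering window `c(low, high)`, deg C.
#' @param seed master seed.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(frameHeight = 480L, frameWidth = 640L,
                             baselineTemp = 33, ambientTemp = 22,
                             gradientAmp = 0.4, noiseSd = 0.05,
                             lesionCountLambda = 0.3,
                             deltaTRange = c(1, 3),
                             windowRange = c(22, 38), seed = 1L) {
  methods::new("SimulationConfig",
    frameHeight = as.integer(frameHeight), frameWidth = as.integer(frameWidth),
    baselineTemp = baselineTemp, ambientTemp = ambientTemp,
    gradientAmp = gradientAmp, noiseSd = noiseSd,
    lesionCountLambda = lesionCountLambda, deltaTRange = deltaTRange,
    windowRange = windowRange, seed = as.integer(seed))
}

# Torso mask and breast centers, in fractional frame coordinates.
.torsoGeometry <- function(H, W) {
  r <- (seq_len(H) - 0.5) / H
  c <- (seq_len(W) - 0.5) / W
  cc <- matrix(c, H, W, byrow = TRUE)
  rr <- matrix(r, H, W)
  # torso: wide ellipse covering the central ~70% of the frame
  mask <- ((cc - 0.5) / 0.36)^2 + ((rr - 0.52) / 0.46)^2 <= 1
  list(mask = mask, rr = rr, cc = cc,
       breastRow = 0.45, breastColL = 0.32, breastColR = 0.68,
       breastRadius = 0.14)
}

# Smooth mirror-symmetric anatomical field: low-resolution random grid,
# bilinearly upsampled on the left half and mirrored onto the right.
.smoothSymmetricField <- function(H, W, amp) {
  gh <- 6L; gw <- 4L
  grid <- matrix(stats::rnorm(gh * gw, sd = 1), gh, gw)
  half <- ceiling(W / 2)
  up <- .resizePlane(array(grid, c(gh, gw, 1L)), H, half)[, , 1L]
  full <- matrix(0, H, W)
  full[, seq_len(half)] <- up
  full[, W:(W - half + 1L)] <- up  # mirror about the midline
  amp * full / max(abs(full))
}

.breastMaskFor <- function(geo, side) {
  colC <- if (side == "left") geo$breastColL else geo$breastColR
  ((geo$cc - colC) / geo$breastRadius)^2 +
    ((geo$rr - geo$breastRow) / geo$breastRadius)^2 <= 1
}

.placeLesion <- function(geo, H, W, deltaT, maxTries = 50L) {
  side <- sample(c("left", "right"), 1L)
  bm <- .breastMaskFor(geo, side)
  # keep the lesion center off the midline by at least 2 radii so its
  # footprint never overlaps its own mirror image
  mid <- (W + 1) / 2
  for (i in seq_len(maxTries)) {
    radius <- stats::runif(1, 0.05, 0.10) * min(H, W)
    idx <- which(bm, arr.ind = TRUE)
    pick <- idx[sample(nrow(idx), 1L), ]
    if (abs(pick[2L] - mid) > 2 * radius)
      return(data.frame(row = pick[1L], col = pick[2L], radius = radius,
                        deltaT = deltaT, side = side,
                        stringsAsFactors = FALSE))
  }
  stop("could not place a lesion inside the breast mask after ",
       maxTries, " attempts")
}

.lesionField <- function(H, W, lesions) {
  field <- matrix(0, H, W)
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (i in seq_len(nrow(lesions))) {
    s <- lesions$radius[i] / 2  # Gaussian sd: disc edge at ~2 sd
    bump <- lesions$deltaT[i] *
      exp(-((rr - lesions$row[i])^2 + (cc - lesions$col[i])^2) / (2 * s^2))
    field <- pmax(field, bump)
  }
  field
}

.quantize16 <- function(temperature, window) {
  x <- (temperature - window[1]) / diff(window)
  x <- pmin(pmax(x, 0), 1)
  round(x * 65535) / 65535
}

#' Fixed false-color palette for thermogram rendering
#'
#' A fixed 256-entry "ironbow"-style ramp (black, blue, magenta, orange,
#' yellow, white); documented and frozen so color renders are
#' reproducible.
#'
#' @return character vector of 256 hex colors.
#' @export
thermalPalette <- function() {
  grDevices::colorRampPalette(c("#000000", "#20008C", "#7D00A6", "#C63D00",
                                "#F08C00", "#FFD700", "#FFFFFF"))(256)
}

.renderColor <- function(intensity) {
  pal <- thermalPalette()
  idx <- pmin(pmax(floor(intensity * 255) + 1L, 1L), 256L)
  rgb <- grDevices::col2rgb(pal[idx]) / 255
  H <- nrow(intensity); W <- ncol(intensity)
  array(c(matrix(rgb[1, ], H, W), matrix(rgb[2, ], H, W),
          matrix(rgb[3, ], H, W)), c(H, W, 3L))
}

#' Generate one synthetic thermogram
#'
#' Healthy frames are exactly mirror-symmetric about the midline column
#' before noise; sick frames add 1 or more Gaussian hot spots confined to
#' one breast with peak elevation drawn from `deltaTRange`. Temperatures
#' are quantized to 16 bits over `windowRange` and rendered grayscale (the
#' quantized intensity) or false-color (see [thermalPalette()]).
#'
#' @param config a [SimulationConfig-class].
#' @param label `"healthy"` or `"sick"`.
#' @param colorMode `"grayscale"` or `"color"` rendering.
#' @param seed optional seed for this frame; defaults to `config@seed`.
#' @return a [Thermogram-class] carrying the temperature field, the
#'   rendered pixels and the lesion table.
#' @examples
#' cfg <- simulationConfig(frameHeight = 60, frameWidth = 80, noiseSd = 0)
#' tg <- generateThermogram(cfg, "sick", seed = 7)
#' nrow(tg@lesions) >= 1
#' @export
generateThermogram <- function(config, label = c("healthy", "sick"),
                               colorMode = c("grayscale", "color"),
                               seed = NULL) {
  methods::validObject(config)
  label <- match.arg(label)
  colorMode <- match.arg(colorMode)
  if (is.null(seed)) seed <- config@seed
  H <- config@frameHeight; W <- config@frameWidth
  .withSeed(seed, {
    geo <- .torsoGeometry(H, W)
    temp <- matrix(config@ambientTemp, H, W)
    body <- config@baselineTemp + .smoothSymmetricField(H, W, config@gradientAmp)
    temp[geo$mask] <- body[geo$mask]
    lesions <- .emptyLesions()
    if (label == "sick") {
      nles <- 1L + stats::rpois(1L, config@lesionCountLambda)
      for (i in seq_len(nles)) {
        dT <- stats::runif(1, config@deltaTRange[1], config@deltaTRange[2])
        lesions <- rbind(lesions, .placeLesion(geo, H, W, dT))
      }
      temp <- temp + .lesionField(H, W, lesions)
    }
    if (config@noiseSd > 0)
      temp <- temp + matrix(stats::rnorm(H * W, sd = config@noiseSd), H, W)
    intensity <- .quantize16(temp, config@windowRange)
    px <- if (colorMode == "color") .renderColor(intensity)
          else array(intensity, c(H, W, 1L))
    methods::new("Thermogram", temperature = temp, pixels = px,
                 label = label, colorMode = colorMode,
                 sourceId = sprintf("synthetic:seed=%d", as.integer(seed)),
                 lesions = lesions)
  })
}

#' Left-right maximum asymmetry statistic
#'
#' `max |T(r, c) - T(r, mirror(c))|` over the frame: exactly 0 for a
#' noise-free healthy frame (mirror symmetry) and equal to the largest
#' lesion peak elevation for a noise-free sick frame whose lesions sit
#' clear of the midline.
#'
#' @param record a [Thermogram-class] (temperature field used when
#'   present, otherwise the grayscale intensity rescaled by the default
#'   window).
#' @return the asymmetry statistic, deg C (or window units).
#' @export
asymmetryStatistic <- function(record) {
  m <- record@temperature
  if (!length(m)) {
    px <- if (dim(record@pixels)[3L] == 1L) record@pixels[, , 1L]
          else toGrayscale(record)@pixels[, , 1L]
    m <- px * 16  # default 22-38 window span
  }
  max(abs(m - m[, ncol(m):1L]))
}

#' Generate a synthetic dataset on disk
#'
#' Writes one image file per record (16-bit grayscale TIFF or 8-bit color
#' PNG) plus a manifest CSV with columns `path`, `label`, `seed`,
#' `nLesions`, `maxDeltaT`. Per-image seeds are drawn once from the
#' master seed, so any single record, or the whole dataset, regenerates
#' byte-identically.
#'
#' @param nHealthy,nSick class sizes. The emulated study population is
#'   1019 healthy and 862 sick frames; desk-scale runs use far fewer.
#' @param config a [SimulationConfig-class].
#' @param outDir output directory (created if missing).
#' @param colorMode `"grayscale"` or `"color"`.
#' @return the manifest data.frame (also written to
#'   `file.path(outDir, "manifest.csv")`), invisibly.
#' @export
generateDataset <- function(nHealthy = 1019L, nSick = 862L, config,
                            outDir, colorMode = c("grayscale", "color")) {
  colorMode <- match.arg(colorMode)
  if (nHealthy < 0L || nSick < 0L) stop("class sizes must be >= 0")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("I/O error: cannot create '", outDir, "'")
  n <- nHealthy + nSick
  labels <- c(rep("healthy", nHealthy), rep("sick", nSick))
  seeds <- .withSeed(config@seed,
                     sample.int(.Machine$integer.max - 1L, n))
  ext <- if (colorMode == "color") "png" else "tiff"
  paths <- file.path(outDir, sprintf("%s_%04d.%s", labels, seq_len(n), ext))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tg <- generateThermogram(config, labels[i], colorMode, seed = seeds[i])
    if (colorMode == "color") {
      png::writePNG(tg@pixels, paths[i])
    } else {
      tiff::writeTIFF(tg@pixels[, , 1L], paths[i], bits.per.sample = 16L)
    }
    rows[[i]] <- data.frame(
      path = basename(paths[i]), label = labels[i], seed = seeds[i],
      nLesions = nrow(tg@lesions),
      maxDeltaT = if (nrow(tg@lesions)) max(tg@lesions$deltaT) else 0,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Class separation of the asymmetry statistic over a dataset
#'
#' Recomputes [asymmetryStatistic()] for every manifest record and
#' summarizes its class-conditional distributions: per-class mean, sd,
#' range, and the overlap fraction (share of sick frames whose statistic
#' falls at or below the healthy maximum). With lesion elevations well
#' above the noise level the two distributions separate and the overlap
#' is 0.
#'
#' @param manifest manifest data.frame from [generateDataset()] (or the
#'   path of a manifest CSV); paths are resolved relative to `dir`.
#' @param dir directory holding the images (defaults to the manifest's
#'   directory when `manifest` is a path).
#' @param statistics optional pre-computed per-record statistics (skips
#'   file reading; mainly for Monte-Carlo cross-checks).
#' @return list with `perClass` (data.frame) and `overlap` (fraction).
#' @export
separabilityReport <- function(manifest, dir = ".", statistics = NULL) {
  if (is.character(manifest)) {
    dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (any(!table(manifest$label) >= 2L) || length(unique(manifest$label)) < 2L)
    stop("need at least 2 records per class")
  stat <- statistics
  if (is.null(stat))
    stat <- vapply(file.path(dir, manifest$path), function(p)
      asymmetryStatistic(loadThermalImage(p)), numeric(1))
  byClass <- split(stat, manifest$label)
  perClass <- do.call(rbind, lapply(names(byClass), function(cl)
    data.frame(label = cl, n = length(byClass[[cl]]),
               mean = mean(byClass[[cl]]), sd = stats::sd(byClass[[cl]]),
               min = min(byClass[[cl]]), max = max(byClass[[cl]]),
               stringsAsFactors = FALSE)))
  overlap <- mean(byClass[["sick"]] <= max(byClass[["healthy"]]))
  list(perClass = perClass, overlap = overlap)
}
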