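# Thermal input handling: raster and temperature-matrix readers, grayscale
# conversion, resizing to the network input geometry, seeded augmentation
# and stratified dataset splitting.

.luminanceWeights <- c(0.299, 0.587, 0.114)

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

.as3d <- function(px) {
  if (is.matrix(px)) px <- array(px, c(dim(px), 1L))
  if (length(dim(px)) == 3L && dim(px)[3L] == 4L)
    px <- px[, , 1:3, drop = FALSE]  # drop alpha
  px
}

#' Construct a thermogram record
#'
#' @param pixels matrix or height x width x channels array of intensities
#'   in `[0, 1]`.
#' @param label `"healthy"`, `"sick"` or `NA`.
#' @param colorMode `"color"` or `"grayscale"`; inferred from the channel
#'   count when missing.
#' @param sourceId provenance string.
#' @param temperature optional matrix of temperatures (deg C).
#' @param lesions optional lesion data.frame.
#' @return a [Thermogram-class].
#' @export
thermogram <- function(pixels, label = NA_character_, colorMode = NULL,
                       sourceId = "", temperature = matrix(numeric(), 0, 0),
                       lesions = .emptyLesions()) {
  pixels <- .as3d(pixels)
  if (is.null(colorMode))
    colorMode <- if (dim(pixels)[3L] >= 3L) "color" else "grayscale"
  methods::new("Thermogram", temperature = temperature, pixels = pixels,
               label = as.character(label), colorMode = colorMode,
               sourceId = sourceId, lesions = lesions)
}

.emptyLesions <- function() {
  data.frame(row = numeric(), col = numeric(), radius = numeric(),
             deltaT = numeric(), side = character(), stringsAsFactors = FALSE)
}

.readTemperatureMatrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l)
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]]))
  if (length(unique(lengths(rows))) != 1L)
    stop("format error: ragged rows in temperature matrix '", path, "'")
  m <- do.call(rbind, rows)
  if (anyNA(m)) stop("format error: non-numeric entry in '", path, "'")
  m
}

#' Write a temperature matrix as whitespace-delimited text
#'
#' Inverse of the text branch of [loadThermalImage()]; values are written
#' at full precision so a write/read round trip reproduces the
#' temperatures exactly.
#'
#' @param temperature numeric matrix, deg C.
#' @param path output file.
#' @export
writeTemperatureMatrix <- function(temperature, path) {
  lines <- apply(temperature, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Load a thermal image or temperature matrix
#'
#' Reads PNG, TIFF or JPEG rasters (bit depth preserved through the
#' `[0, 1]` intensity scale the readers use), or a whitespace-delimited
#' temperature-matrix text file (extension `.txt` or `.dat`), which is
#' min-max scaled onto the 16-bit intensity range with the raw
#' temperatures kept alongside.
#'
#' @param path input file.
#' @param declaredMode `"auto"` (default, from channel count), `"color"`
#'   or `"grayscale"`.
#' @param label optional ground-truth label to attach.
#' @return a [Thermogram-class].
#' @export
loadThermalImage <- function(path, declaredMode = c("auto", "color",
                                                    "grayscale"),
                             label = NA_character_) {
  declaredMode <- match.arg(declaredMode)
  if (!file.exists(path)) stop("format error: cannot read '", path, "'")
  ext <- tolower(tools::file_ext(path))
  temperature <- matrix(numeric(), 0, 0)
  if (ext %in% c("txt", "dat")) {
    temperature <- .readTemperatureMatrix(path)
    rng <- range(temperature)
    px <- if (diff(rng) == 0) matrix(0, nrow(temperature), ncol(temperature))
          else (temperature - rng[1]) / diff(rng)
    # quantize to the 16-bit grid the raster writers use
    px <- round(px * 65535) / 65535
  } else if (ext == "png") {
    px <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    img <- EBImage::imageData(EBImage::readImage(path))
    px <- if (length(dim(img)) == 2L) t(img) else aperm(img, c(2L, 1L, 3L))
  } else {
    stop("format error: unsupported file type '.", ext, "'")
  }
  px <- .as3d(px)
  mode <- if (declaredMode == "auto") NULL else declaredMode
  thermogram(px, label = label, colorMode = mode, sourceId = path,
             temperature = temperature)
}

#' Convert a color record to grayscale
#'
#' Fixed luminance weights (0.299, 0.587, 0.114); already-grayscale
#' records pass through unchanged, and 3-channel replicated grayscale
#' collapses back to its single channel (idempotence).
#'
#' @param record a [Thermogram-class].
#' @return the grayscale record (1 channel).
#' @export
toGrayscale <- function(record) {
  px <- record@pixels
  if (dim(px)[3L] == 1L) return(record)
  if (dim(px)[3L] != 3L) stop("expected a 1- or 3-channel record")
  w <- .luminanceWeights
  g <- px[, , 1L] * w[1] + px[, , 2L] * w[2] + px[, , 3L] * w[3]
  methods::initialize(record, pixels = array(g, c(dim(g), 1L)),
                      colorMode = "grayscale")
}

.resizePlane <- function(px, h, w) {
  # EBImage uses (x, y[, c]) ordering; transpose in and out.
  out <- EBImage::resize(aperm(px, c(2L, 1L, 3L)), w = w, h = h,
                         filter = "bilinear")
  aperm(.as3d(out), c(2L, 1L, 3L))
}

#' Resize a record to the square network input
#'
#' Bilinear resize to `side` x `side`; single-channel inputs are
#' replicated to 3 channels for network ingestion (the color mode tag is
#' kept, since replication adds no chromatic information).
#'
#' @param record a [Thermogram-class].
#' @param side target side length in pixels (299 for the full-size
#'   networks, 75 for the tiny variants).
#' @param replicateChannels replicate grayscale to 3 channels.
#' @return the resized record.
#' @export
resizeToNetwork <- function(record, side = 299L, replicateChannels = TRUE) {
  px <- record@pixels
  d <- dim(px)
  if (d[1L] != side || d[2L] != side) px <- .resizePlane(px, side, side)
  px <- pmin(pmax(px, 0), 1)
  if (replicateChannels && dim(px)[3L] == 1L)
    px <- array(px[, , rep(1L, 3L)], c(side, side, 3L))
  methods::initialize(record, pixels = px)
}

#' Construct an augmentation policy
#'
#' @param flipVerticalAxis random left-right mirroring with p = 0.5.
#' @param maxTranslation maximum translation per axis, pixels (default 30).
#' @param maxScaleFraction maximum upscale per axis (default 0.10).
#' @param seed integer stream seed.
#' @param flipUpDown read "flip along the vertical axis" as up-down
#'   motion instead of the default left-right mirroring.
#' @return an [AugmentationPolicy-class].
#' @export
augmentationPolicy <- function(flipVerticalAxis = TRUE, maxTranslation = 30L,
                               maxScaleFraction = 0.10, seed = 1L,
                               flipUpDown = FALSE) {
  methods::new("AugmentationPolicy",
               flipVerticalAxis = isTRUE(flipVerticalAxis),
               flipUpDown = isTRUE(flipUpDown),
               maxTranslation = as.integer(maxTranslation),
               maxScaleFraction = maxScaleFraction, seed = as.integer(seed))
}

.translatePlane <- function(px, dy, dx) {
  d <- dim(px)
  rows <- pmin(pmax(seq_len(d[1L]) - dy, 1L), d[1L])  # edge replication
  cols <- pmin(pmax(seq_len(d[2L]) - dx, 1L), d[2L])
  px[rows, cols, , drop = FALSE]
}

#' Apply one random augmentation draw
#'
#' Applies, in order: mirroring with probability 0.5 (left-right by
#' default), per-axis upscaling with factors uniform in
#' `[1, 1 + maxScaleFraction]` followed by a center crop back to the
#' original size, and integer translation uniform in
#' `[-maxTranslation, maxTranslation]` per axis with edge-replication
#' fill. Output dimensions always equal input dimensions. Draws come from
#' the current R generator: seed it (e.g. with `policy@seed`) to make an
#' augmentation stream reproducible.
#'
#' @param record a [Thermogram-class].
#' @param policy an [AugmentationPolicy-class].
#' @return the augmented record.
#' @export
augmentRecord <- function(record, policy) {
  methods::validObject(policy)
  px <- record@pixels
  d <- dim(px)
  if (policy@flipVerticalAxis && stats::runif(1) < 0.5) {
    px <- if (policy@flipUpDown) px[d[1L]:1L, , , drop = FALSE]
          else px[, d[2L]:1L, , drop = FALSE]
  }
  if (policy@maxScaleFraction > 0) {
    s <- 1 + stats::runif(2) * policy@maxScaleFraction
    nh <- max(d[1L], as.integer(round(d[1L] * s[1])))
    nw <- max(d[2L], as.integer(round(d[2L] * s[2])))
    if (nh != d[1L] || nw != d[2L]) {
      big <- .resizePlane(px, nh, nw)
      r0 <- (nh - d[1L]) %/% 2L
      c0 <- (nw - d[2L]) %/% 2L
      px <- big[r0 + seq_len(d[1L]), c0 + seq_len(d[2L]), , drop = FALSE]
    }
  }
  if (policy@maxTranslation > 0) {
    t2 <- sample(seq(-policy@maxTranslation, policy@maxTranslation), 2L,
                 replace = TRUE)
    px <- .translatePlane(px, t2[1L], t2[2L])
  }
  methods::initialize(record, pixels = px)
}

#' Translate a record by a fixed integer offset
#'
#' Deterministic building block of [augmentRecord()]: shifts the image
#' down by `dy` rows and right by `dx` columns with edge-replication fill.
#'
#' @param record a [Thermogram-class].
#' @param dy,dx integer offsets (rows, columns).
#' @return the translated record.
#' @export
translateRecord <- function(record, dy = 0L, dx = 0L) {
  methods::initialize(record,
                      pixels = .translatePlane(record@pixels,
                                               as.integer(dy),
                                               as.integer(dx)))
}

#' Remove fixed margins (crude region-of-interest crop)
#'
#' Fixed-margin removal of frame borders (arms, neck and abdomen borders
#' in frontal torso thermograms). Margins are fractions of the frame.
#'
#' @param record a [Thermogram-class].
#' @param top,bottom,left,right fractions of the frame to remove.
#' @return the cropped record.
#' @export
cropFixedMargin <- function(record, top = 0.1, bottom = 0.1,
                            left = 0.1, right = 0.1) {
  d <- dim(record@pixels)
  r <- (1L + floor(d[1L] * top)):(d[1L] - floor(d[1L] * bottom))
  c <- (1L + floor(d[2L] * left)):(d[2L] - floor(d[2L] * right))
  if (length(r) < 1L || length(c) < 1L) stop("margins remove the whole frame")
  methods::initialize(record,
                      pixels = record@pixels[r, c, , drop = FALSE])
}

#' Stratified train/test split
#'
#' Splits records by class label: per class, `floor(trainFraction * n)`
#' records go to the training set and the remainder to the test set, with
#' the within-class order shuffled under `seed`. The split partitions the
#' input exactly (no overlap, union = input).
#'
#' @param records list of [Thermogram-class] objects, or a data.frame with
#'   a `label` column (e.g. a dataset manifest).
#' @param trainFraction fraction in (0, 1); the protocol sweeps 0.8, 0.7,
#'   0.6, 0.5 and 0.4.
#' @param seed integer seed.
#' @return list with elements `train` and `test` of the same type as
#'   `records` (for a data.frame input, row subsets).
#' @export
splitDataset <- function(records, trainFraction = 0.7, seed = 1L) {
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie strictly between 0 and 1")
  labels <- if (is.data.frame(records)) records$label
            else vapply(records, function(r) r@label, character(1))
  if (anyNA(labels)) stop("stratification error: unlabeled records")
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop("stratification error: a class has zero members")
  idxTrain <- integer(0)
  .withSeed(seed, {
    for (cl in classes) {
      ix <- which(labels == cl)
      ntr <- floor(trainFraction * length(ix))
      if (ntr < 1L || ntr >= length(ix))
        stop("stratification error: class '", cl,
             "' too small for this split")
      idxTrain <- c(idxTrain, sample(ix)[seq_len(ntr)])
    }
  })
  idxTrain <- sort(idxTrain)
  take <- function(ix) if (is.data.frame(records))
    records[ix, , drop = FALSE] else records[ix]
  list(train = take(idxTrain),
       test = take(setdiff(seq_along(labels), idxTrain)))
}
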