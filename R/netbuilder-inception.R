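# Builders for the inception V3 / V4 feature trunks and the modified-V4
# (MV4) variant whose seven inception-B blocks are replaced by a shallower
# four-branch block preserving the 1024-channel concatenated output.
#
# Where the network description leaves internals open (stem branch widths,
# strides, reduction geometry) the canonical published inception
# configurations are used; all widths funnel through .sw() so the same
# builders produce the width-scaled "tiny" variants.

.sw <- function(nf, scale) max(1L, as.integer(round(nf * scale)))

# ---- V4 blocks -------------------------------------------------------------

.v4Stem <- function(gb, from, sc) {
  c1 <- gbConvUnit(gb, "stem.conv1", from, 3L, nf = .sw(32, sc), stride = 2L)
  c2 <- gbConvUnit(gb, "stem.conv2", c1, 3L, nf = .sw(32, sc))
  c3 <- gbConvUnit(gb, "stem.conv3", c2, 3L, nf = .sw(64, sc), same = TRUE)
  p1 <- gbAdd(gb, "stem.pool1", "maxpool", c3, fh = 3L, fw = 3L, stride = 2L,
              pad = 0L, same = FALSE)
  c4 <- gbConvUnit(gb, "stem.conv4", c3, 3L, nf = .sw(96, sc), stride = 2L)
  m1 <- gbAdd(gb, "stem.mix1", "concat", c(p1, c4))
  a1 <- gbConvUnit(gb, "stem.b1.conv1", m1, 1L, nf = .sw(64, sc))
  a2 <- gbConvUnit(gb, "stem.b1.conv2", a1, 3L, nf = .sw(96, sc))
  b1 <- gbConvUnit(gb, "stem.b2.conv1", m1, 1L, nf = .sw(64, sc))
  b2 <- gbConvUnit(gb, "stem.b2.conv2", b1, 7L, fw = 1L, nf = .sw(64, sc),
                   same = TRUE)
  b3 <- gbConvUnit(gb, "stem.b2.conv3", b2, 1L, fw = 7L, nf = .sw(64, sc),
                   same = TRUE)
  b4 <- gbConvUnit(gb, "stem.b2.conv4", b3, 3L, nf = .sw(96, sc))
  m2 <- gbAdd(gb, "stem.mix2", "concat", c(a2, b4))
  c5 <- gbConvUnit(gb, "stem.conv5", m2, 3L, nf = .sw(192, sc), stride = 2L)
  p2 <- gbAdd(gb, "stem.pool2", "maxpool", m2, fh = 3L, fw = 3L, stride = 2L,
              pad = 0L, same = FALSE)
  gbAdd(gb, "stem.mix3", "concat", c(c5, p2))
}

.v4InceptionA <- function(gb, from, tag, sc) {
  p <- gbAdd(gb, paste0(tag, ".pool"), "avgpool", from, fh = 3L, fw = 3L,
             stride = 1L, same = TRUE)
  b0 <- gbConvUnit(gb, paste0(tag, ".b0.conv"), p, 1L, nf = .sw(96, sc))
  b1 <- gbConvUnit(gb, paste0(tag, ".b1.conv"), from, 1L, nf = .sw(96, sc))
  b2a <- gbConvUnit(gb, paste0(tag, ".b2.conv1"), from, 1L, nf = .sw(64, sc))
  b2 <- gbConvUnit(gb, paste0(tag, ".b2.conv2"), b2a, 3L, nf = .sw(96, sc),
                   same = TRUE)
  b3a <- gbConvUnit(gb, paste0(tag, ".b3.conv1"), from, 1L, nf = .sw(64, sc))
  b3b <- gbConvUnit(gb, paste0(tag, ".b3.conv2"), b3a, 3L, nf = .sw(96, sc),
                    same = TRUE)
  b3 <- gbConvUnit(gb, paste0(tag, ".b3.conv3"), b3b, 3L, nf = .sw(96, sc),
                   same = TRUE)
  gbAdd(gb, paste0(tag, ".mix"), "concat", c(b0, b1, b2, b3))
}

.v4ReductionA <- function(gb, from, sc) {
  p <- gbAdd(gb, "ra.pool", "maxpool", from, fh = 3L, fw = 3L, stride = 2L,
             pad = 0L, same = FALSE)
  b1 <- gbConvUnit(gb, "ra.b1.conv", from, 3L, nf = .sw(384, sc), stride = 2L)
  b2a <- gbConvUnit(gb, "ra.b2.conv1", from, 1L, nf = .sw(192, sc))
  b2b <- gbConvUnit(gb, "ra.b2.conv2", b2a, 3L, nf = .sw(224, sc), same = TRUE)
  b2 <- gbConvUnit(gb, "ra.b2.conv3", b2b, 3L, nf = .sw(256, sc), stride = 2L)
  gbAdd(gb, "ra.mix", "concat", c(p, b1, b2))
}

# Canonical inception-B: 128 + 384 + 256 + 256 = 1024 concatenated channels.
.v4InceptionB <- function(gb, from, tag, sc) {
  p <- gbAdd(gb, paste0(tag, ".pool"), "avgpool", from, fh = 3L, fw = 3L,
             stride = 1L, same = TRUE)
  b0 <- gbConvUnit(gb, paste0(tag, ".b0.conv"), p, 1L, nf = .sw(128, sc))
  b1 <- gbConvUnit(gb, paste0(tag, ".b1.conv"), from, 1L, nf = .sw(384, sc))
  b2a <- gbConvUnit(gb, paste0(tag, ".b2.conv1"), from, 1L, nf = .sw(192, sc))
  b2b <- gbConvUnit(gb, paste0(tag, ".b2.conv2"), b2a, 1L, fw = 7L,
                    nf = .sw(224, sc), same = TRUE)
  b2 <- gbConvUnit(gb, paste0(tag, ".b2.conv3"), b2b, 7L, fw = 1L,
                   nf = .sw(256, sc), same = TRUE)
  b3a <- gbConvUnit(gb, paste0(tag, ".b3.conv1"), from, 1L, nf = .sw(192, sc))
  b3b <- gbConvUnit(gb, paste0(tag, ".b3.conv2"), b3a, 1L, fw = 7L,
                    nf = .sw(192, sc), same = TRUE)
  b3c <- gbConvUnit(gb, paste0(tag, ".b3.conv3"), b3b, 7L, fw = 1L,
                    nf = .sw(224, sc), same = TRUE)
  b3d <- gbConvUnit(gb, paste0(tag, ".b3.conv4"), b3c, 1L, fw = 7L,
                    nf = .sw(224, sc), same = TRUE)
  b3 <- gbConvUnit(gb, paste0(tag, ".b3.conv5"), b3d, 7L, fw = 1L,
                   nf = .sw(256, sc), same = TRUE)
  gbAdd(gb, paste0(tag, ".mix"), "concat", c(b0, b1, b2, b3))
}

# Modified inception-B: 3x3 avgpool capped by a conv (256 filters, 1x1 by
# default); direct 1x1; 1x1 stem feeding two parallel 3x3 convs. Default
# widths 256 + 384 + 192 + 192 = 1024.
.mv4InceptionB <- function(gb, from, tag, config, sc) {
  fs <- config@parallelFilterSize
  p <- gbAdd(gb, paste0(tag, ".pool"), "avgpool", from, fh = 3L, fw = 3L,
             stride = 1L, same = TRUE)
  b0 <- gbConvUnit(gb, paste0(tag, ".b0.conv"), p, config@avgpoolConvSize,
                   nf = .sw(config@avgpoolBranchFilters, sc), same = TRUE)
  b1 <- gbConvUnit(gb, paste0(tag, ".b1.conv"), from, 1L,
                   nf = .sw(config@directBranchFilters, sc))
  b2a <- gbConvUnit(gb, paste0(tag, ".b2.conv1"), from, 1L,
                    nf = .sw(config@stem1x1Filters, sc))
  b2 <- gbConvUnit(gb, paste0(tag, ".b2.conv2"), b2a, fs,
                   nf = .sw(config@parallelBranchFilters[1L], sc), same = TRUE)
  b3 <- gbConvUnit(gb, paste0(tag, ".b3.conv"), b2a, fs,
                   nf = .sw(config@parallelBranchFilters[2L], sc), same = TRUE)
  gbAdd(gb, paste0(tag, ".mix"), "concat", c(b0, b1, b2, b3))
}

.v4ReductionB <- function(gb, from, sc) {
  p <- gbAdd(gb, "rb.pool", "maxpool", from, fh = 3L, fw = 3L, stride = 2L,
             pad = 0L, same = FALSE)
  b1a <- gbConvUnit(gb, "rb.b1.conv1", from, 1L, nf = .sw(192, sc))
  b1 <- gbConvUnit(gb, "rb.b1.conv2", b1a, 3L, nf = .sw(192, sc), stride = 2L)
  b2a <- gbConvUnit(gb, "rb.b2.conv1", from, 1L, nf = .sw(256, sc))
  b2b <- gbConvUnit(gb, "rb.b2.conv2", b2a, 1L, fw = 7L, nf = .sw(256, sc),
                    same = TRUE)
  b2c <- gbConvUnit(gb, "rb.b2.conv3", b2b, 7L, fw = 1L, nf = .sw(320, sc),
                    same = TRUE)
  b2 <- gbConvUnit(gb, "rb.b2.conv4", b2c, 3L, nf = .sw(320, sc), stride = 2L)
  gbAdd(gb, "rb.mix", "concat", c(p, b1, b2))
}

.v4InceptionC <- function(gb, from, tag, sc) {
  p <- gbAdd(gb, paste0(tag, ".pool"), "avgpool", from, fh = 3L, fw = 3L,
             stride = 1L, same = TRUE)
  b0 <- gbConvUnit(gb, paste0(tag, ".b0.conv"), p, 1L, nf = .sw(256, sc))
  b1 <- gbConvUnit(gb, paste0(tag, ".b1.conv"), from, 1L, nf = .sw(256, sc))
  b2a <- gbConvUnit(gb, paste0(tag, ".b2.conv1"), from, 1L, nf = .sw(384, sc))
  b2l <- gbConvUnit(gb, paste0(tag, ".b2.conv2a"), b2a, 1L, fw = 3L,
                    nf = .sw(256, sc), same = TRUE)
  b2r <- gbConvUnit(gb, paste0(tag, ".b2.conv2b"), b2a, 3L, fw = 1L,
                    nf = .sw(256, sc), same = TRUE)
  b3a <- gbConvUnit(gb, paste0(tag, ".b3.conv1"), from, 1L, nf = .sw(384, sc))
  b3b <- gbConvUnit(gb, paste0(tag, ".b3.conv2"), b3a, 1L, fw = 3L,
                    nf = .sw(448, sc), same = TRUE)
  b3c <- gbConvUnit(gb, paste0(tag, ".b3.conv3"), b3b, 3L, fw = 1L,
                    nf = .sw(512, sc), same = TRUE)
  b3l <- gbConvUnit(gb, paste0(tag, ".b3.conv4a"), b3c, 3L, fw = 1L,
                    nf = .sw(256, sc), same = TRUE)
  b3r <- gbConvUnit(gb, paste0(tag, ".b3.conv4b"), b3c, 1L, fw = 3L,
                    nf = .sw(256, sc), same = TRUE)
  gbAdd(gb, paste0(tag, ".mix"), "concat", c(b0, b1, b2l, b2r, b3l, b3r))
}

# ---- V3 blocks (canonical factorized geometry) -----------------------------

.v3Stem <- function(gb, from, sc) {
  c1 <- gbConvUnit(gb, "stem.conv1", from, 3L, nf = .sw(32, sc), stride = 2L)
  c2 <- gbConvUnit(gb, "stem.conv2", c1, 3L, nf = .sw(32, sc))
  c3 <- gbConvUnit(gb, "stem.conv3", c2, 3L, nf = .sw(64, sc), same = TRUE)
  p1 <- gbAdd(gb, "stem.pool1", "maxpool", c3, fh = 3L, fw = 3L, stride = 2L,
              pad = 0L, same = FALSE)
  c4 <- gbConvUnit(gb, "stem.conv4", p1, 1L, nf = .sw(80, sc))
  c5 <- gbConvUnit(gb, "stem.conv5", c4, 3L, nf = .sw(192, sc))
  gbAdd(gb, "stem.pool2", "maxpool", c5, fh = 3L, fw = 3L, stride = 2L,
        pad = 0L, same = FALSE)
}

.v3InceptionA <- function(gb, from, tag, poolFilters, sc) {
  b0 <- gbConvUnit(gb, paste0(tag, ".b0.conv"), from, 1L, nf = .sw(64, sc))
  b1a <- gbConvUnit(gb, paste0(tag, ".b1.conv1"), from, 1L, nf = .sw(48, sc))
  b1 <- gbConvUnit(gb, paste0(tag, ".b1.conv2"), b1a, 5L, nf = .sw(64, sc),
                   same = TRUE)
  b2a <- gbConvUnit(gb, paste0(tag, ".b2.conv1"), from, 1L, nf = .sw(64, sc))
  b2b <- gbConvUnit(gb, paste0(tag, ".b2.conv2"), b2a, 3L, nf = .sw(96, sc),
                    same = TRUE)
  b2 <- gbConvUnit(gb, paste0(tag, ".b2.conv3"), b2b, 3L, nf = .sw(96, sc),
                   same = TRUE)
  p <- gbAdd(gb, paste0(tag, ".pool"), "avgpool", from, fh = 3L, fw = 3L,
             stride = 1L, same = TRUE)
  b3 <- gbConvUnit(gb, paste0(tag, ".b3.conv"), p, 1L, nf = .sw(poolFilters, sc))
  gbAdd(gb, paste0(tag, ".mix"), "concat", c(b0, b1, b2, b3))
}

.v3ReductionA <- function(gb, from, sc) {
  b0 <- gbConvUnit(gb, "ra.b0.conv", from, 3L, nf = .sw(384, sc), stride = 2L)
  b1a <- gbConvUnit(gb, "ra.b1.conv1", from, 1L, nf = .sw(64, sc))
  b1b <- gbConvUnit(gb, "ra.b1.conv2", b1a, 3L, nf = .sw(96, sc), same = TRUE)
  b1 <- gbConvUnit(gb, "ra.b1.conv3", b1b, 3L, nf = .sw(96, sc), stride = 2L)
  p <- gbAdd(gb, "ra.pool", "maxpool", from, fh = 3L, fw = 3L, stride = 2L,
             pad = 0L, same = FALSE)
  gbAdd(gb, "ra.mix", "concat", c(b0, b1, p))
}

.v3InceptionB <- function(gb, from, tag, mid, sc) {
  b0 <- gbConvUnit(gb, paste0(tag, ".b0.conv"), from, 1L, nf = .sw(192, sc))
  b1a <- gbConvUnit(gb, paste0(tag, ".b1.conv1"), from, 1L, nf = .sw(mid, sc))
  b1b <- gbConvUnit(gb, paste0(tag, ".b1.conv2"), b1a, 1L, fw = 7L,
                    nf = .sw(mid, sc), same = TRUE)
  b1 <- gbConvUnit(gb, paste0(tag, ".b1.conv3"), b1b, 7L, fw = 1L,
                   nf = .sw(192, sc), same = TRUE)
  b2a <- gbConvUnit(gb, paste0(tag, ".b2.conv1"), from, 1L, nf = .sw(mid, sc))
  b2b <- gbConvUnit(gb, paste0(tag, ".b2.conv2"), b2a, 7L, fw = 1L,
                    nf = .sw(mid, sc), same = TRUE)
  b2c <- gbConvUnit(gb, paste0(tag, ".b2.conv3"), b2b, 1L, fw = 7L,
                    nf = .sw(mid, sc), same = TRUE)
  b2d <- gbConvUnit(gb, paste0(tag, ".b2.conv4"), b2c, 7L, fw = 1L,
                    nf = .sw(mid, sc), same = TRUE)
  b2 <- gbConvUnit(gb, paste0(tag, ".b2.conv5"), b2d, 1L, fw = 7L,
                   nf = .sw(192, sc), same = TRUE)
  p <- gbAdd(gb, paste0(tag, ".pool"), "avgpool", from, fh = 3L, fw = 3L,
             stride = 1L, same = TRUE)
  b3 <- gbConvUnit(gb, paste0(tag, ".b3.conv"), p, 1L, nf = .sw(192, sc))
  gbAdd(gb, paste0(tag, ".mix"), "concat", c(b0, b1, b2, b3))
}

.v3ReductionB <- function(gb, from, sc) {
  b0a <- gbConvUnit(gb, "rb.b0.conv1", from, 1L, nf = .sw(192, sc))
  b0 <- gbConvUnit(gb, "rb.b0.conv2", b0a, 3L, nf = .sw(320, sc), stride = 2L)
  b1a <- gbConvUnit(gb, "rb.b1.conv1", from, 1L, nf = .sw(192, sc))
  b1b <- gbConvUnit(gb, "rb.b1.conv2", b1a, 1L, fw = 7L, nf = .sw(192, sc),
                    same = TRUE)
  b1c <- gbConvUnit(gb, "rb.b1.conv3", b1b, 7L, fw = 1L, nf = .sw(192, sc),
                    same = TRUE)
  b1 <- gbConvUnit(gb, "rb.b1.conv4", b1c, 3L, nf = .sw(192, sc), stride = 2L)
  p <- gbAdd(gb, "rb.pool", "maxpool", from, fh = 3L, fw = 3L, stride = 2L,
             pad = 0L, same = FALSE)
  gbAdd(gb, "rb.mix", "concat", c(b0, b1, p))
}

.v3InceptionC <- function(gb, from, tag, sc) {
  b0 <- gbConvUnit(gb, paste0(tag, ".b0.conv"), from, 1L, nf = .sw(320, sc))
  b1a <- gbConvUnit(gb, paste0(tag, ".b1.conv1"), from, 1L, nf = .sw(384, sc))
  b1l <- gbConvUnit(gb, paste0(tag, ".b1.conv2a"), b1a, 1L, fw = 3L,
                    nf = .sw(384, sc), same = TRUE)
  b1r <- gbConvUnit(gb, paste0(tag, ".b1.conv2b"), b1a, 3L, fw = 1L,
                    nf = .sw(384, sc), same = TRUE)
  b2a <- gbConvUnit(gb, paste0(tag, ".b2.conv1"), from, 1L, nf = .sw(448, sc))
  b2b <- gbConvUnit(gb, paste0(tag, ".b2.conv2"), b2a, 3L, nf = .sw(384, sc),
                    same = TRUE)
  b2l <- gbConvUnit(gb, paste0(tag, ".b2.conv3a"), b2b, 1L, fw = 3L,
                    nf = .sw(384, sc), same = TRUE)
  b2r <- gbConvUnit(gb, paste0(tag, ".b2.conv3b"), b2b, 3L, fw = 1L,
                    nf = .sw(384, sc), same = TRUE)
  p <- gbAdd(gb, paste0(tag, ".pool"), "avgpool", from, fh = 3L, fw = 3L,
             stride = 1L, same = TRUE)
  b3 <- gbConvUnit(gb, paste0(tag, ".b3.conv"), p, 1L, nf = .sw(192, sc))
  gbAdd(gb, paste0(tag, ".mix"), "concat", c(b0, b1l, b1r, b2l, b2r, b3))
}

# ---- public builders -------------------------------------------------------

#' Configuration for the modified inception-B block
#'
#' `literal = FALSE` (default) uses widths 256 + 384 + 192 + 192 = 1024
#' with a 1x1 conv capping the average-pool branch, honoring both the
#' feature-preservation constraint (the modified block keeps the canonical
#' 1024 concatenated output channels) and the requirement that the
#' modified block be cheaper than the canonical one. `literal = TRUE`
#' follows the textual branch description instead: a 3x3 conv under the
#' average pool and two parallel 256-filter branches
#' (256 + 384 + 256 + 256 = 1152 channels), which breaks both constraints;
#' building a network with it requires `strict = FALSE`.
#'
#' @param avgpoolBranchFilters,avgpoolConvSize,directBranchFilters,
#'   stem1x1Filters,parallelBranchFilters,parallelFilterSize see
#'   [MV4BlockConfig-class].
#' @param literal select the literal-text 1152-channel widths.
#' @return an [MV4BlockConfig-class].
#' @export
mv4BlockConfig <- function(avgpoolBranchFilters = 256L,
                           avgpoolConvSize = if (literal) 3L else 1L,
                           directBranchFilters = 384L,
                           stem1x1Filters = 192L,
                           parallelBranchFilters = if (literal)
                             c(256L, 256L) else c(192L, 192L),
                           parallelFilterSize = 3L,
                           literal = FALSE) {
  methods::new("MV4BlockConfig",
    avgpoolBranchFilters = as.integer(avgpoolBranchFilters),
    avgpoolConvSize = as.integer(avgpoolConvSize),
    directBranchFilters = as.integer(directBranchFilters),
    stem1x1Filters = as.integer(stem1x1Filters),
    parallelBranchFilters = as.integer(parallelBranchFilters),
    parallelFilterSize = as.integer(parallelFilterSize))
}

.mv4ConcatChannels <- function(config) {
  config@avgpoolBranchFilters + config@directBranchFilters +
    sum(config@parallelBranchFilters)
}

.checkInputShape <- function(inputShape, minSide = 63L) {
  s <- tensorShape(inputShape[1], inputShape[2], inputShape[3])
  if (s[1] < minSide || s[2] < minSide)
    stop("invalid geometry: input ", s[1], "x", s[2],
         " is below the stem's minimum receptive requirement (",
         minSide, "x", minSide, ")")
  s
}

#' Build the inception V4 layer graph
#'
#' Stem, 4 inception-A blocks, reduction-A, 7 inception-B blocks,
#' reduction-B, 3 inception-C blocks, then the classification head. Every
#' convolution is followed by batch normalization and ReLU activation. At
#' the default 299 x 299 x 3 input the feature dimension entering the head
#' is 1536.
#'
#' @param inputShape input tensor shape, see [tensorShape()].
#' @param head head specification; default [defaultHead]`("v4")`.
#' @param widthScale multiplier applied to every filter count (1 = full
#'   size; small values give desk-scale "tiny" variants).
#' @return a [NetworkGraph-class] named `"inception_v4"`.
#' @examples
#' g <- buildInceptionV4()
#' architectureSummary(g)
#' @export
buildInceptionV4 <- function(inputShape = c(299, 299, 3),
                             head = defaultHead("v4"),
                             widthScale = 1) {
  .checkInputShape(inputShape)
  .validateHead(head)
  gb <- graphBuilder()
  gbAdd(gb, "input", "input")
  x <- .v4Stem(gb, "input", widthScale)
  for (i in 1:4) x <- .v4InceptionA(gb, x, paste0("a", i), widthScale)
  x <- .v4ReductionA(gb, x, widthScale)
  for (i in 1:7) x <- .v4InceptionB(gb, x, paste0("b", i), widthScale)
  x <- .v4ReductionB(gb, x, widthScale)
  for (i in 1:3) x <- .v4InceptionC(gb, x, paste0("c", i), widthScale)
  .gbAttachHead(gb, x, head)
  g <- gbFinish(gb, "inception_v4")
  methods::validObject(g)
  inferShapes(g, inputShape)  # construction contract: shapes must infer
  g
}

#' Build the modified inception MV4 layer graph
#'
#' Identical to [buildInceptionV4()] except that all 7 inception-B blocks
#' are replaced by the shallower modified block (see
#' [makeModifiedInceptionB()]). Under the default configuration each
#' modified block still outputs exactly 1024 concatenated channels, so
#' reduction-B and the inception-C stages are unchanged, while the graph
#' has strictly fewer nodes, edges, parameters and FLOPs than V4.
#'
#' @inheritParams buildInceptionV4
#' @param blockConfig an [MV4BlockConfig-class].
#' @param strict enforce the 1024-channel feature-preservation constraint
#'   (at `widthScale = 1`); set `FALSE` to build the literal-text
#'   1152-channel variant.
#' @return a [NetworkGraph-class] named `"inception_mv4"`.
#' @export
buildInceptionMV4 <- function(inputShape = c(299, 299, 3),
                              head = defaultHead("mv4"),
                              blockConfig = mv4BlockConfig(),
                              strict = TRUE,
                              widthScale = 1) {
  .checkInputShape(inputShape)
  .validateHead(head)
  methods::validObject(blockConfig)
  if (strict && widthScale == 1 && .mv4ConcatChannels(blockConfig) != 1024L)
    stop("configuration error: modified inception-B branch widths sum to ",
         .mv4ConcatChannels(blockConfig),
         " channels, not 1024; use strict = FALSE to allow this")
  gb <- graphBuilder()
  gbAdd(gb, "input", "input")
  x <- .v4Stem(gb, "input", widthScale)
  for (i in 1:4) x <- .v4InceptionA(gb, x, paste0("a", i), widthScale)
  x <- .v4ReductionA(gb, x, widthScale)
  for (i in 1:7) x <- .mv4InceptionB(gb, x, paste0("b", i), blockConfig,
                                     widthScale)
  x <- .v4ReductionB(gb, x, widthScale)
  for (i in 1:3) x <- .v4InceptionC(gb, x, paste0("c", i), widthScale)
  .gbAttachHead(gb, x, head)
  g <- gbFinish(gb, "inception_mv4")
  methods::validObject(g)
  inferShapes(g, inputShape)
  g
}

#' Build the inception V3 layer graph
#'
#' Stem, 3 inception-A blocks, reduction-A, 4 inception-B blocks,
#' reduction-B, 2 inception-C blocks, then the classification head, with
#' the canonical factorized filter geometry. At the default input the
#' feature dimension entering the head is 2048.
#'
#' @inheritParams buildInceptionV4
#' @return a [NetworkGraph-class] named `"inception_v3"`.
#' @export
buildInceptionV3 <- function(inputShape = c(299, 299, 3),
                             head = defaultHead("v3"),
                             widthScale = 1) {
  .checkInputShape(inputShape, minSide = 75L)
  .validateHead(head)
  gb <- graphBuilder()
  gbAdd(gb, "input", "input")
  x <- .v3Stem(gb, "input", widthScale)
  pools <- c(32L, 64L, 64L)
  for (i in 1:3) x <- .v3InceptionA(gb, x, paste0("a", i), pools[i], widthScale)
  x <- .v3ReductionA(gb, x, widthScale)
  mids <- c(128L, 160L, 160L, 192L)
  for (i in 1:4) x <- .v3InceptionB(gb, x, paste0("b", i), mids[i], widthScale)
  x <- .v3ReductionB(gb, x, widthScale)
  for (i in 1:2) x <- .v3InceptionC(gb, x, paste0("c", i), widthScale)
  .gbAttachHead(gb, x, head)
  g <- gbFinish(gb, "inception_v3")
  methods::validObject(g)
  inferShapes(g, inputShape)
  g
}

#' Build one modified inception-B block as a standalone fragment
#'
#' Returns the four-branch modified block as a small [NetworkGraph-class]
#' whose input node stands for the incoming feature map and whose sink is
#' the concat node. All branches preserve spatial dimensions ("same"
#' geometry), so for an H x W x `inChannels` input the output is
#' H x W x (sum of branch widths) — 1024 channels under the default
#' configuration.
#'
#' @param blockConfig an [MV4BlockConfig-class].
#' @param inChannels number of incoming channels (metadata only; the
#'   fragment infers shapes for whatever input it is given).
#' @return a [NetworkGraph-class] named `"custom"`.
#' @examples
#' frag <- makeModifiedInceptionB()
#' shapes <- inferShapes(frag, c(17, 17, 1024))
#' shapes[[frag@outputId]][3]  # 1024
#' @export
makeModifiedInceptionB <- function(blockConfig = mv4BlockConfig(),
                                   inChannels = 1024L) {
  methods::validObject(blockConfig)
  if (inChannels < 1L) stop("inChannels must be >= 1")
  gb <- graphBuilder()
  gbAdd(gb, "input", "input")
  .mv4InceptionB(gb, "input", "b", blockConfig, 1)
  g <- gbFinish(gb, "custom")
  methods::validObject(g)
  g
}

#' Build the canonical inception-B block as a standalone fragment
#'
#' The unmodified V4 inception-B block (branch widths
#' 128 + 384 + 256 + 256 = 1024), for side-by-side comparison with
#' [makeModifiedInceptionB()].
#'
#' @return a [NetworkGraph-class] named `"custom"`.
#' @export
makeCanonicalInceptionB <- function() {
  gb <- graphBuilder()
  gbAdd(gb, "input", "input")
  .v4InceptionB(gb, "input", "b", 1)
  g <- gbFinish(gb, "custom")
  methods::validObject(g)
  g
}

#' Count inception blocks per stage
#'
#' @param graph a [NetworkGraph-class] built by one of the builders.
#' @return named integer vector with the number of inception-A, -B and -C
#'   blocks (stages named `a<i>`, `b<i>`, `c<i>`).
#' @export
inceptionBlockCounts <- function(graph) {
  st <- unique(.stageOf(graph@nodes$id))
  c(a = sum(grepl("^a[0-9]+$", st)),
    b = sum(grepl("^b[0-9]+$", st)),
    c = sum(grepl("^c[0-9]+$", st)))
}
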