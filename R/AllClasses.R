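#' @import methods
NULL

#' Layer graph for an inception-style convolutional network
#'
#' A directed acyclic layer graph. Nodes are rows of the `nodes` data.frame
#' (one row per layer), edges are directed pairs of node ids. This is the
#' common representation used for inception V3, V4 and the modified MV4, as
#' well as for block fragments and user-defined graphs.
#'
#' Node columns: `id` (unique string), `kind` (one of `input`, `conv`,
#' `batchnorm`, `activation`, `maxpool`, `avgpool`, `concat`, `dropout`,
#' `global_avg_pool`, `dense`, `softmax`, `classification`), `fh`/`fw`
#' (filter height/width in pixels, conv/pool only), `nf` (number of filters,
#' conv/dense only), `stride`, `pad` (pixels, `NA` when `same`), `same`
#' (logical, "same" padding), `rate` (dropout rate), `trainable`.
#'
#' @slot nodes data.frame of layer nodes (see Details).
#' @slot edges data.frame with character columns `from`, `to`.
#' @slot inputId id of the unique input node.
#' @slot outputId id of the unique sink node.
#' @slot name one of `"inception_v3"`, `"inception_v4"`, `"inception_mv4"`,
#'   `"custom"`.
#' @seealso [buildInceptionV4()], [inferShapes()], [countParameters()]
#' @exportClass NetworkGraph
setClass("NetworkGraph",
  representation(
    nodes   = "data.frame",
    edges   = "data.frame",
    inputId = "character",
    outputId = "character",
    name    = "character"
  )
)

.nodeKinds <- c("input", "conv", "batchnorm", "activation", "maxpool",
                "avgpool", "concat", "dropout", "global_avg_pool", "dense",
                "softmax", "classification")

setValidity("NetworkGraph", function(object) {
  nd <- object@nodes
  ed <- object@edges
  msgs <- character()
  if (anyDuplicated(nd$id)) msgs <- c(msgs, "duplicated node ids")
  if (!all(nd$kind %in% .nodeKinds))
    msgs <- c(msgs, paste("unknown node kind:",
                          paste(setdiff(nd$kind, .nodeKinds), collapse = ", ")))
  if (nrow(ed) > 0 && !all(c(ed$from, ed$to) %in% nd$id))
    msgs <- c(msgs, "edge references unknown node id")
  indeg <- table(factor(ed$to, levels = nd$id))
  outdeg <- table(factor(ed$from, levels = nd$id))
  inputs <- nd$id[nd$kind == "input"]
  if (length(inputs) != 1L)
    msgs <- c(msgs, "graph must have exactly one input node")
  else {
    if (indeg[[inputs]] != 0L) msgs <- c(msgs, "input node has incoming edges")
    if (!identical(object@inputId, inputs))
      msgs <- c(msgs, "inputId does not name the input node")
  }
  sinks <- nd$id[outdeg[nd$id] == 0L]
  if (length(sinks) != 1L)
    msgs <- c(msgs, "graph must have exactly one terminal (sink) node")
  else if (!identical(object@outputId, sinks))
    msgs <- c(msgs, "outputId does not name the sink node")
  cls <- nd$id[nd$kind == "classification"]
  if (length(cls) > 1L)
    msgs <- c(msgs, "at most one classification node allowed")
  if (length(cls) == 1L && !identical(cls, object@outputId))
    msgs <- c(msgs, "classification node must be the terminal node")
  bad <- nd$id[nd$kind == "concat" & indeg[nd$id] < 2L]
  if (length(bad))
    msgs <- c(msgs, paste("concat node with in-degree < 2:", bad[1L]))
  bad <- nd$id[!(nd$kind %in% c("concat", "input")) & indeg[nd$id] != 1L]
  if (length(bad))
    msgs <- c(msgs, paste("non-concat node must have in-degree 1:", bad[1L]))
  conv <- nd[nd$kind %in% c("conv", "maxpool", "avgpool"), ]
  if (nrow(conv)) {
    if (any(is.na(conv$fh) | conv$fh < 1L | is.na(conv$fw) | conv$fw < 1L))
      msgs <- c(msgs, "conv/pool filter dims must be >= 1")
    if (any(is.na(conv$stride) | conv$stride < 1L))
      msgs <- c(msgs, "conv/pool stride must be >= 1")
  }
  cd <- nd[nd$kind %in% c("conv", "dense"), ]
  if (nrow(cd) && any(is.na(cd$nf) | cd$nf < 1L))
    msgs <- c(msgs, "conv/dense nodes need num_filters >= 1")
  dr <- nd[nd$kind == "dropout", ]
  if (nrow(dr) && any(is.na(dr$rate) | dr$rate < 0 | dr$rate > 1))
    msgs <- c(msgs, "dropout nodes need a rate in [0, 1]")
  if (any(!is.na(nd$rate[nd$kind != "dropout"])))
    msgs <- c(msgs, "dropout_rate only allowed on dropout nodes")
  # acyclicity via Kahn's algorithm
  if (length(msgs) == 0L && is.null(.topoOrder(nd$id, ed)))
    msgs <- c(msgs, "graph contains a cycle")
  if (length(msgs) == 0L) {
    reach <- .reachableFrom(object@inputId, nd$id, ed)
    if (!all(nd$id %in% reach))
      msgs <- c(msgs, "every node must be reachable from the input")
  }
  if (length(msgs)) msgs else TRUE
})

#' Configuration of the modified inception-B block (MV4)
#'
#' Filter widths of the four-branch shallow replacement for the inception-B
#' block: an average-pool branch capped by a 3x3 convolution, a direct 1x1
#' branch, and a 1x1 stem feeding two parallel 3x3 convolutions. The default
#' widths (256 + 384 + 192 + 192) preserve the canonical inception-B output
#' of 1024 concatenated feature channels, so the downstream reduction-B and
#' inception-C stages are geometry-compatible unchanged.
#'
#' @slot avgpoolBranchFilters filters of the conv under the average pool.
#' @slot avgpoolConvSize spatial size of that conv (default 1; the heavy
#'   literal-text reading uses 3).
#' @slot directBranchFilters filters of the direct 1x1 branch.
#' @slot stem1x1Filters filters of the 1x1 conv feeding the parallel pair.
#' @slot parallelBranchFilters integer pair, the two parallel conv widths.
#' @slot parallelFilterSize spatial size of the parallel convs (default 3).
#' @seealso [mv4BlockConfig()], [makeModifiedInceptionB()]
#' @exportClass MV4BlockConfig
setClass("MV4BlockConfig",
  representation(
    avgpoolBranchFilters = "integer",
    avgpoolConvSize      = "integer",
    directBranchFilters  = "integer",
    stem1x1Filters       = "integer",
    parallelBranchFilters = "integer",
    parallelFilterSize   = "integer"
  )
)

setValidity("MV4BlockConfig", function(object) {
  msgs <- character()
  w <- c(object@avgpoolBranchFilters, object@directBranchFilters,
         object@stem1x1Filters, object@parallelBranchFilters)
  if (length(object@parallelBranchFilters) != 2L)
    msgs <- c(msgs, "parallelBranchFilters must be a pair of counts")
  if (any(w < 1L)) msgs <- c(msgs, "all filter counts must be >= 1")
  if (object@parallelFilterSize < 1L)
    msgs <- c(msgs, "parallelFilterSize must be >= 1")
  if (object@avgpoolConvSize < 1L)
    msgs <- c(msgs, "avgpoolConvSize must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Structural summary of a layer graph
#'
#' @slot name network name.
#' @slot layerCount number of nodes (one node = one layer).
#' @slot connectionCount number of directed edges.
#' @slot parameterCount total analytic parameter count.
#' @slot trainableParameterCount parameters of trainable nodes only.
#' @slot flopsEstimate multiply-accumulate estimate for one forward pass.
#' @slot stageShapes data.frame (stage, height, width, channels) of the
#'   output shape at the end of each named stage, in topological order.
#' @exportClass ArchitectureSummary
setClass("ArchitectureSummary",
  representation(
    name = "character",
    layerCount = "integer",
    connectionCount = "integer",
    parameterCount = "numeric",
    trainableParameterCount = "numeric",
    flopsEstimate = "numeric",
    stageShapes = "data.frame"
  )
)

#' Confusion-matrix counts for a binary classifier
#'
#' Integer counts of true positives, true negatives, false positives and
#' false negatives; the sole input to the diagnostic metric suite.
#'
#' @slot tp,tn,fp,fn non-negative integer counts; their total must be >= 1.
#' @seealso [confusionCounts()], [evaluateCounts()]
#' @exportClass ConfusionCounts
setClass("ConfusionCounts",
  representation(tp = "integer", tn = "integer",
                 fp = "integer", fn = "integer")
)

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@tn, object@fp, object@fn)
  if (length(v) != 4L || anyNA(v)) return("tp/tn/fp/fn must be single integers")
  if (any(v < 0L)) return("counts must be non-negative")
  if (sum(v) < 1L) return("total count must be >= 1")
  TRUE
})

#' Diagnostic metric report
#'
#' The twelve diagnostic metrics computed from a [ConfusionCounts-class]
#' object. `accuracy` is on the percent scale; all other rate-like metrics
#' are fractions in `[0, 1]`; `lrp`/`lrn` are non-negative likelihood
#' ratios. A metric whose defining ratio has a zero denominator is
#' *undefined* and carried as `NA` (never as 0 or infinity). Note `auc`
#' here is the balanced accuracy (mean of sensitivity and specificity) and
#' `eer = 1 - auc`, following the convention of the diagnostic table this
#' suite reproduces, not the ROC area.
#'
#' @slot counts the input [ConfusionCounts-class].
#' @slot accuracy percent correct.
#' @slot sensitivity,specificity,precision,npv,fpr,fnr,auc,eer,f1 fractions.
#' @slot lrp,lrn positive/negative likelihood ratios.
#' @seealso [evaluateCounts()], [formatReportTable()]
#' @exportClass MetricReport
setClass("MetricReport",
  representation(
    counts = "ConfusionCounts",
    accuracy = "numeric", sensitivity = "numeric", specificity = "numeric",
    precision = "numeric", npv = "numeric", fpr = "numeric", fnr = "numeric",
    lrp = "numeric", lrn = "numeric", auc = "numeric", eer = "numeric",
    f1 = "numeric"
  )
)

setValidity("MetricReport", function(object) {
  fr <- c(object@sensitivity, object@specificity, object@precision,
          object@npv, object@fpr, object@fnr, object@auc, object@eer,
          object@f1)
  if (any(!is.na(fr) & (fr < -1e-12 | fr > 1 + 1e-12)))
    return("fractional metrics must lie in [0, 1] when defined")
  lr <- c(object@lrp, object@lrn)
  if (any(!is.na(lr) & lr < 0))
    return("likelihood ratios must be non-negative when defined")
  if (!is.na(object@accuracy) && (object@accuracy < 0 || object@accuracy > 100))
    return("accuracy (percent) must lie in [0, 100]")
  TRUE
})

#' A (possibly synthetic) breast thermogram
#'
#' Couples the physical temperature field (degrees Celsius) with its
#' rendered raster (16-bit grayscale intensities or 8-bit false color),
#' the ground-truth class label and, for simulated pathology, the lesion
#' metadata.
#'
#' @slot temperature numeric matrix of skin temperatures (deg C), or a
#'   0-row/0-col matrix when the record was loaded from a raster only.
#' @slot pixels numeric array height x width x channels with values in
#'   `[0, 1]` (raster intensities).
#' @slot label `"healthy"`, `"sick"`, or `NA` for unlabeled records.
#' @slot colorMode `"color"` or `"grayscale"`.
#' @slot sourceId free-text provenance string.
#' @slot lesions data.frame (row, col, radius, deltaT, side), 0 rows when
#'   healthy or unknown.
#' @seealso [generateThermogram()], [loadThermalImage()]
#' @exportClass Thermogram
setClass("Thermogram",
  representation(
    temperature = "matrix",
    pixels = "array",
    label = "character",
    colorMode = "character",
    sourceId = "character",
    lesions = "data.frame"
  )
)

setValidity("Thermogram", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || any(d < 1L))
    return("pixels must be a height x width x channels array")
  if (!object@colorMode %in% c("color", "grayscale"))
    return("colorMode must be 'color' or 'grayscale'")
  if (object@colorMode == "grayscale" && !d[3L] %in% c(1L, 3L))
    return("grayscale records must have 1 channel (or 3 replicated ones)")
  if (!is.na(object@label) && !object@label %in% c("healthy", "sick"))
    return("label must be 'healthy', 'sick' or NA")
  TRUE
})

#' Seeded augmentation policy
#'
#' Mirrors the augmentation protocol used for thermogram training sets:
#' random mirroring across the vertical (left-right) axis, integer
#' translation up to `maxTranslation` pixels per axis, and up-scaling up to
#' `maxScaleFraction` per axis, all drawn from a seeded generator.
#'
#' @slot flipVerticalAxis enable random left-right mirroring (p = 0.5).
#' @slot flipUpDown interpret the flip as up-down instead (off by default;
#'   left-right is the anatomically meaningful reading for bilateral
#'   breast symmetry).
#' @slot maxTranslation maximum absolute translation per axis, pixels.
#' @slot maxScaleFraction maximum upscale fraction per axis, in `[0, 1)`.
#' @slot seed integer seed identifying the augmentation stream.
#' @seealso [augmentRecord()]
#' @exportClass AugmentationPolicy
setClass("AugmentationPolicy",
  representation(
    flipVerticalAxis = "logical",
    flipUpDown = "logical",
    maxTranslation = "integer",
    maxScaleFraction = "numeric",
    seed = "integer"
  )
)

setValidity("AugmentationPolicy", function(object) {
  if (object@maxTranslation < 0L) return("maxTranslation must be >= 0")
  if (object@maxScaleFraction < 0 || object@maxScaleFraction >= 1)
    return("maxScaleFraction must be in [0, 1)")
  TRUE
})

#' Configuration of the synthetic thermogram simulator
#'
#' @slot frameHeight,frameWidth raster size in pixels (default 480 x 640,
#'   the native resolution of the emulated acquisition).
#' @slot baselineTemp torso baseline skin temperature, deg C.
#' @slot ambientTemp room temperature, deg C; default range 18-25.
#' @slot gradientAmp amplitude of the smooth anatomical variation, deg C.
#' @slot noiseSd sensor noise standard deviation, deg C.
#' @slot lesionCountLambda Poisson mean of extra lesions beyond the first.
#' @slot deltaTRange lesion peak elevation range, deg C (default 1-3).
#' @slot windowRange rendering window (deg C) mapped onto the 16-bit scale.
#' @slot seed master seed.
#' @seealso [simulationConfig()], [generateThermogram()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    frameHeight = "integer", frameWidth = "integer",
    baselineTemp = "numeric", ambientTemp = "numeric",
    gradientAmp = "numeric", noiseSd = "numeric",
    lesionCountLambda = "numeric", deltaTRange = "numeric",
    windowRange = "numeric", seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  if (object@frameHeight < 8L || object@frameWidth < 8L)
    return("frame must be at least 8 x 8 pixels")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (length(object@deltaTRange) != 2L ||
      any(object@deltaTRange <= 0) || diff(object@deltaTRange) < 0)
    return("deltaTRange must be an increasing positive pair")
  if (length(object@windowRange) != 2L || diff(object@windowRange) <= 0)
    return("windowRange must be an increasing pair")
  if (object@ambientTemp < 18 || object@ambientTemp > 25)
    return("ambientTemp must lie in [18, 25] (protocol room temperature)")
  TRUE
})

#' Configuration of one training/evaluation run
#'
#' @slot model `"v3"`, `"v4"`, `"mv4"`, `"tiny-v4"` or `"tiny-mv4"`.
#' @slot optimizer `"sgdm"` (momentum 0.9), `"adam"` or `"rmsprop"`.
#' @slot learningRate per-step factor, > 0.
#' @slot epochs number of passes over the training split.
#' @slot batchSize minibatch size (default 10).
#' @slot trainFraction fraction of each class used for training.
#' @slot freezeConvs number of leading conv layers marked non-trainable.
#' @slot head head specification (see [defaultHead()]); `list()` = model
#'   default.
#' @slot seed integer seed for split, initialization and minibatch order.
#' @slot repeats number of repeated runs for [summarizeRepeats()] use.
#' @seealso [trainAndEvaluate()], [runGrid()]
#' @exportClass ExperimentConfig
setClass("ExperimentConfig",
  representation(
    model = "character", optimizer = "character",
    learningRate = "numeric", epochs = "integer", batchSize = "integer",
    trainFraction = "numeric", freezeConvs = "integer",
    head = "list", seed = "integer", repeats = "integer"
  )
)

setValidity("ExperimentConfig", function(object) {
  if (!object@model %in% c("v3", "v4", "mv4", "tiny-v4", "tiny-mv4"))
    return("unknown model")
  if (!object@optimizer %in% c("sgdm", "adam", "rmsprop"))
    return("unknown optimizer")
  if (object@learningRate <= 0) return("learningRate must be > 0")
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@trainFraction <= 0 || object@trainFraction >= 1)
    return("trainFraction must lie in (0, 1)")
  if (object@freezeConvs < 0L) return("freezeConvs must be >= 0")
  if (object@repeats < 1L) return("repeats must be >= 1")
  TRUE
})

#' Result of one training/evaluation run
#'
#' @slot config the [ExperimentConfig-class] used.
#' @slot history data.frame (epoch, trainAccuracy, valAccuracy), percent.
#' @slot counts final held-out [ConfusionCounts-class].
#' @slot report final [MetricReport-class].
#' @slot wallTime elapsed seconds (informational only).
#' @slot seed the seed actually used.
#' @slot failed TRUE when the loss diverged (non-finite); metrics then
#'   reflect the last finite state.
#' @exportClass RunResult
setClass("RunResult",
  representation(
    config = "ExperimentConfig",
    history = "data.frame",
    counts = "ConfusionCounts",
    report = "MetricReport",
    wallTime = "numeric",
    seed = "integer",
    failed = "logical"
  )
)

#' Summary of repeated runs
#'
#' @slot meanAccuracy mean of the per-run accuracies, percent.
#' @slot marginalError half-width of the t-based confidence interval for
#'   the mean, percent.
#' @slot confidence confidence level of the interval.
#' @slot nRepeats number of runs.
#' @slot accuracies the per-run accuracies.
#' @seealso [summarizeRepeats()]
#' @exportClass RepeatSummary
setClass("RepeatSummary",
  representation(
    meanAccuracy = "numeric", marginalError = "numeric",
    confidence = "numeric", nRepeats = "integer", accuracies = "numeric"
  )
)

setValidity("RepeatSummary", function(object) {
  if (object@marginalError < 0) return("marginalError must be >= 0")
  if (object@meanAccuracy < min(object@accuracies) - 1e-9 ||
      object@meanAccuracy > max(object@accuracies) + 1e-9)
    return("mean must lie within [min, max] of the runs")
  TRUE
})
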