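# Training/evaluation harness: single runs, grids over
# optimizer x learning rate x epochs x model x split, and repeat
# statistics. Full-size V3/V4/MV4 training is supported but the intended
# desk-scale path is the width-scaled "tiny" variants (75 x 75 input,
# widths scaled by 1/8), which preserve the block topology exactly.

.tinyScale <- 0.125
.tinySide <- 75L
.fullSide <- 299L

#' Construct an experiment configuration
#'
#' @param model `"v3"`, `"v4"`, `"mv4"`, `"tiny-v4"` or `"tiny-mv4"`.
#' @param optimizer `"sgdm"`, `"adam"` or `"rmsprop"`.
#' @param learningRate per-step factor (the protocol grid spans 1e-2 to
#'   1e-6).
#' @param epochs training passes (protocol grid: 3-10, 20, 30).
#' @param batchSize minibatch size (protocol default 10).
#' @param trainFraction per-class training fraction (protocol default 0.7).
#' @param freezeConvs leading conv layers to freeze (e.g. 10).
#' @param head head spec; `NULL` selects the model default.
#' @param seed master seed for split, init, minibatch order and dropout.
#' @param repeats repeats for [runRepeats()].
#' @return an [ExperimentConfig-class].
#' @export
experimentConfig <- function(model = "tiny-mv4", optimizer = "sgdm",
                             learningRate = 1e-4, epochs = 3L,
                             batchSize = 10L, trainFraction = 0.7,
                             freezeConvs = 0L, head = NULL, seed = 1L,
                             repeats = 5L) {
  methods::new("ExperimentConfig",
    model = model, optimizer = optimizer, learningRate = learningRate,
    epochs = as.integer(epochs), batchSize = as.integer(batchSize),
    trainFraction = trainFraction, freezeConvs = as.integer(freezeConvs),
    head = if (is.null(head)) list() else head, seed = as.integer(seed),
    repeats = as.integer(repeats))
}

.modelSide <- function(model)
  if (startsWith(model, "tiny")) .tinySide else .fullSide

.buildModelGraph <- function(config) {
  model <- config@model
  tiny <- startsWith(model, "tiny")
  scale <- if (tiny) .tinyScale else 1
  base <- sub("^tiny-", "", model)
  # tiny variants default to the dropout-free head: at 1/8 width the
  # full-size 0.8 rate leaves too few active pooled features for stable
  # small-batch training
  head <- if (length(config@head)) config@head else if (tiny)
    defaultHead("v3", classes = 2L) else
    defaultHead(if (base == "v3") "v3" else base)
  side <- .modelSide(model)
  g <- switch(base,
    v3 = buildInceptionV3(c(side, side, 3), head, widthScale = scale),
    v4 = buildInceptionV4(c(side, side, 3), head, widthScale = scale),
    mv4 = buildInceptionMV4(c(side, side, 3), head, widthScale = scale))
  if (config@freezeConvs > 0L) g <- freezePrefix(g, config@freezeConvs)
  g
}

.loadRecords <- function(manifest, dir = ".", side = .tinySide) {
  if (is.character(manifest)) {
    dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (is.data.frame(manifest)) {
    recs <- lapply(seq_len(nrow(manifest)), function(i)
      loadThermalImage(file.path(dir, manifest$path[i]),
                       label = manifest$label[i]))
  } else recs <- manifest  # list of Thermogram records
  lapply(recs, resizeToNetwork, side = side)
}

.recordsToBatch <- function(records, idx, side, flip = FALSE) {
  x <- array(0, c(side, side, 3L, length(idx)))
  for (k in seq_along(idx)) {
    px <- records[[idx[k]]]@pixels
    # per-image standardization: removes the inter-subject baseline and
    # contrast variation so the network sees relative thermal structure
    px <- (px - mean(px)) / (stats::sd(px) + 1e-8)
    # protocol augmentation: random mirroring across the vertical axis
    if (flip && stats::runif(1) < 0.5) px <- px[, side:1L, , drop = FALSE]
    x[, , , k] <- px
  }
  x
}

# refresh batch-norm running statistics over the training records.
# exact = TRUE replaces the statistics with the cumulative mean of the
# batch statistics (momentum 1/k at the k-th batch), which reaches the
# dataset-level fixed point that an exponential moving average cannot;
# exact = FALSE nudges the EMA along (used between epochs, where the
# statistics are already close)
.calibrateBatchNorm <- function(net, records, side, batchSize,
                                exact = FALSE, sweeps = 1L) {
  n <- length(records)
  for (s in seq_len(sweeps)) {
    k <- 0L
    for (at in seq(1L, n, by = batchSize)) {
      k <- k + 1L
      ix <- at:min(at + batchSize - 1L, n)
      forwardPass(net, .recordsToBatch(records, ix, side),
                  training = TRUE,
                  bnMomentum = if (exact) 1 / k else 0.1)
    }
  }
  invisible(net)
}

.classLevels <- c("healthy", "sick")

.labelsOf <- function(records)
  vapply(records, function(r) r@label, character(1))

.evalScores <- function(net, records, side, chunk = 50L) {
  scores <- numeric(length(records))
  for (at in seq(1L, length(records), by = chunk)) {
    ix <- at:min(at + chunk - 1L, length(records))
    scores[ix] <- predictScores(net, .recordsToBatch(records, ix, side))
  }
  scores
}

# operating-point calibration: the decision threshold on the log-odds
# score that maximizes accuracy on the (training) labels; ties resolve
# to the candidate closest to the symmetric point 0
.chooseThreshold <- function(scores, positive) {
  o <- order(scores)
  s <- scores[o]
  cand <- c(s[1L] - 1, (s[-length(s)] + s[-1L]) / 2, s[length(s)] + 1, 0)
  acc <- vapply(cand, function(t) mean((scores > t) == positive), numeric(1))
  best <- cand[acc == max(acc)]
  best[which.min(abs(best))]
}

.evalAccuracy <- function(net, records, side, threshold = 0, chunk = 50L) {
  labels <- .labelsOf(records)
  truth <- match(labels, .classLevels)
  scores <- .evalScores(net, records, side, chunk)
  pred <- ifelse(scores > threshold, 2L, 1L)
  list(accuracy = 100 * mean(pred == truth),
       truth = truth, pred = pred)
}

#' Train a classifier and evaluate it on the held-out split
#'
#' Loads the manifest records, resizes them to the model's input side,
#' makes a stratified per-class split, trains the configured model with
#' softmax cross-entropy loss under the configured optimizer (SGDM =
#' stochastic gradient descent with momentum 0.9; Adam and RMSprop with
#' conventional defaults), and evaluates on the held-out records after
#' every epoch. The decision threshold is calibrated on the training
#' split (the operating point on the log-odds score with the highest
#' training accuracy), the standard operating-point selection for a
#' diagnostic classifier; the held-out split is never touched. The entire run — split, initialization, minibatch order,
#' dropout — is driven by `config@seed`, so a repeated run is
#' deterministic. A non-finite loss flags the run as failed instead of
#' raising.
#'
#' @param config an [ExperimentConfig-class].
#' @param manifest dataset manifest: data.frame with `path`/`label`
#'   columns, the path of a manifest CSV, or a list of
#'   [Thermogram-class] records.
#' @param dir directory for manifest paths.
#' @param shuffleLabels permute training labels (negative control).
#' @param pretrained optional backbone weights from
#'   [pretrainTinyBackbone()] (or [networkWeights()]); the run then
#'   fine-tunes instead of training from scratch, mirroring the
#'   transfer-learning protocol.
#' @param returnWeights attach the trained weights to the result as
#'   attribute `"weights"` (used for pretraining).
#' @param augmentFlip apply random left-right mirroring to training
#'   batches (the anatomically meaningful reading of flipping along the
#'   vertical axis; fresh draws every epoch).
#' @param bnFrozen keep batch-norm statistics fixed during training
#'   (see [forwardPass()]; off by default — with this engine's width-
#'   scaled networks, batch statistics during fine-tuning are more
#'   stable).
#' @return a [RunResult-class].
#' @export
trainAndEvaluate <- function(config, manifest, dir = ".",
                             shuffleLabels = FALSE, pretrained = NULL,
                             returnWeights = FALSE, augmentFlip = FALSE,
                             bnFrozen = FALSE) {
  methods::validObject(config)
  side <- .modelSide(config@model)
  records <- .loadRecords(manifest, dir, side)
  t0 <- proc.time()[["elapsed"]]
  graph <- .buildModelGraph(config)
  failed <- FALSE
  history <- NULL
  .withSeed(config@seed, {
    sp <- splitDataset(records, config@trainFraction, seed = config@seed)
    train <- sp$train
    test <- sp$test
    trainLabels <- .labelsOf(train)
    if (shuffleLabels) trainLabels <- sample(trainLabels)
    truth <- match(trainLabels, .classLevels)
    net <- initNetwork(graph, c(side, side, 3L), weights = pretrained)
    # frozen-statistics fine-tuning: adapt the running statistics to the
    # fine-tuning inputs first, then keep them fixed throughout training
    if (bnFrozen)
      .calibrateBatchNorm(net, train, side, config@batchSize,
                          exact = TRUE, sweeps = 3L)
    opt <- makeOptimizer(config@optimizer, config@learningRate)
    n <- length(train)
    for (epoch in seq_len(config@epochs)) {
      ord <- sample(n)
      correct <- 0L
      for (at in seq(1L, n, by = config@batchSize)) {
        ix <- ord[at:min(at + config@batchSize - 1L, n)]
        x <- .recordsToBatch(train, ix, side, flip = augmentFlip)
        onehot <- matrix(0, 2L, length(ix))
        onehot[cbind(truth[ix], seq_along(ix))] <- 1
        fwd <- forwardPass(net, x, training = TRUE, bnEval = bnFrozen)
        loss <- crossEntropy(fwd, onehot)
        if (!is.finite(loss)) { failed <- TRUE; break }
        correct <- correct + sum(apply(fwd$probs, 2L, which.max) == truth[ix])
        grads <- backwardPass(net, fwd, onehot)
        net <- applyGradients(net, grads, opt)
      }
      if (failed) break
      if (!bnFrozen) .calibrateBatchNorm(net, train, side, config@batchSize)
      trainScores <- .evalScores(net, train, side)
      threshold <- .chooseThreshold(trainScores, truth == 2L)
      ev <- .evalAccuracy(net, test, side, threshold)
      history <- rbind(history, data.frame(
        epoch = epoch, trainAccuracy = 100 * correct / n,
        valAccuracy = ev$accuracy))
    }
    threshold <- if (failed) 0 else
      .chooseThreshold(.evalScores(net, train, side), truth == 2L)
    ev <- .evalAccuracy(net, test, side, threshold)
    counts <- confusionFromPredictions(
      .classLevels[ev$truth], .classLevels[ev$pred], positiveLabel = "sick")
    out <- methods::new("RunResult",
      config = config,
      history = if (is.null(history))
        data.frame(epoch = integer(), trainAccuracy = numeric(),
                   valAccuracy = numeric()) else history,
      counts = counts, report = evaluateCounts(counts),
      wallTime = proc.time()[["elapsed"]] - t0,
      seed = config@seed, failed = failed)
    if (returnWeights) attr(out, "weights") <- networkWeights(net)
    out
  })
}

#' Pretrain a tiny backbone on a disjoint synthetic corpus
#'
#' The reference protocol fine-tunes a pretrained inception backbone; the
#' desk-scale analogue pretrains the width-scaled backbone once, on a
#' synthetic thermogram corpus generated by the package itself (broader
#' lesion elevations, higher noise, its own seed), and reuses those
#' weights as the starting point of fine-tuning runs. No external weights
#' are involved.
#'
#' @param model `"tiny-v4"` or `"tiny-mv4"`.
#' @param nPerClass corpus size per class.
#' @param epochs pretraining epochs.
#' @param seed corpus and pretraining seed.
#' @param colorMode corpus rendering (`"grayscale"` or `"color"`).
#' @param decay run the second half of the epochs at a tenth of the
#'   learning rate (step decay); off by default — the single-rate
#'   schedule transferred better in pilots.
#' @param optimizer,learningRate pretraining optimizer settings (Adam at
#'   1e-2 by default: fastest early progress from random initialization).
#'   Mirror augmentation is deliberately off: the backbone specializes to
#'   the sidedness statistics it will be fine-tuned on.
#' @return named weight list for the `pretrained` argument of
#'   [trainAndEvaluate()], with the achieved pretraining validation
#'   accuracy in attribute `"valAccuracy"`.
#' @export
pretrainTinyBackbone <- function(model = "tiny-mv4", nPerClass = 300L,
                                 epochs = 30L, seed = 1L,
                                 optimizer = "adam", learningRate = 1e-2,
                                 colorMode = "grayscale", decay = FALSE) {
  simCfg <- simulationConfig(frameHeight = 120L, frameWidth = 160L,
                             noiseSd = 0.05, deltaTRange = c(2, 3),
                             gradientAmp = 0.4,
                             seed = as.integer(seed) + 7919L)
  frameSeeds <- .withSeed(simCfg@seed,
                          sample.int(.Machine$integer.max - 1L,
                                     2L * nPerClass))
  labels <- rep(c("healthy", "sick"), each = nPerClass)
  records <- lapply(seq_along(labels), function(i)
    generateThermogram(simCfg, labels[i], colorMode,
                       seed = frameSeeds[i]))
  # two-phase schedule: the second half runs at a tenth of the rate,
  # the conventional step decay that finishes convergence
  e1 <- if (decay) as.integer(ceiling(epochs / 2)) else as.integer(epochs)
  cfg <- experimentConfig(model = model, optimizer = optimizer,
                          learningRate = learningRate,
                          epochs = e1, seed = as.integer(seed))
  res <- trainAndEvaluate(cfg, records, returnWeights = TRUE)
  if (decay && epochs - e1 > 0L) {
    cfg2 <- experimentConfig(model = model, optimizer = optimizer,
                             learningRate = learningRate / 10,
                             epochs = as.integer(epochs) - e1,
                             seed = as.integer(seed) + 1L)
    res <- trainAndEvaluate(cfg2, records, returnWeights = TRUE,
                            pretrained = attr(res, "weights"))
  }
  w <- attr(res, "weights")
  # backbone only: the classification head is dropped so fine-tuning
  # trains a fresh classifier on its own labels (and a shuffled-label
  # negative control honestly collapses to chance)
  w <- w[!grepl("^head\\.", names(w))]
  attr(w, "valAccuracy") <- res@report@accuracy
  attr(w, "model") <- model
  w
}

#' Run an experiment grid
#'
#' One run per cell of the cartesian product of the supplied axes.
#' Results are returned long-format (one row per cell) and can be pivoted
#' into the conventional layout (rows = epochs, columns = optimizer x
#' learning rate) with [pivotGrid()]. When `csvPath` is given the long
#' table is written after every cell, and an existing file is reused to
#' resume: completed cells are not re-run.
#'
#' @param baseConfig an [ExperimentConfig-class]; per-cell values
#'   override its fields.
#' @param axes named list with any of `optimizer`, `learningRate`,
#'   `epochs`, `model`, `trainFraction`.
#' @param manifest,dir forwarded to [trainAndEvaluate()].
#' @param csvPath optional long-format CSV to write/resume.
#' @return data.frame with the axis columns, `valAccuracy`,
#'   `trainAccuracy`, `seed` and `failed`.
#' @export
runGrid <- function(baseConfig, axes, manifest, dir = ".", csvPath = NULL) {
  allowed <- c("optimizer", "learningRate", "epochs", "model",
               "trainFraction")
  if (!length(axes) || !all(names(axes) %in% allowed))
    stop("axes must be a non-empty named list drawn from: ",
         paste(allowed, collapse = ", "))
  cells <- expand.grid(axes, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  done <- NULL
  if (!is.null(csvPath) && file.exists(csvPath))
    done <- utils::read.csv(csvPath, stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    cfg <- baseConfig
    for (nm in names(cells)) methods::slot(cfg, nm) <-
      if (nm == "epochs") as.integer(cells[i, nm]) else cells[i, nm]
    key <- paste(vapply(names(cells), function(nm)
      format(cells[i, nm]), character(1)), collapse = "|")
    if (!is.null(done)) {
      hit <- done[done$cell == key, , drop = FALSE]
      if (nrow(hit)) { rows[[i]] <- hit[1L, ]; next }
    }
    res <- trainAndEvaluate(cfg, manifest, dir)
    h <- res@history
    rows[[i]] <- data.frame(
      cell = key, cells[i, , drop = FALSE],
      valAccuracy = if (nrow(h)) h$valAccuracy[nrow(h)] else NA_real_,
      trainAccuracy = if (nrow(h)) h$trainAccuracy[nrow(h)] else NA_real_,
      seed = res@seed, failed = res@failed,
      stringsAsFactors = FALSE, row.names = NULL)
    if (!is.null(csvPath))
      utils::write.csv(do.call(rbind, rows), csvPath, row.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(csvPath)) utils::write.csv(out, csvPath, row.names = FALSE)
  out
}

#' Pivot grid results into the conventional accuracy table
#'
#' Rows are epochs, columns are optimizer x learning-rate combinations,
#' cells are the final validation accuracies.
#'
#' @param gridResults output of [runGrid()].
#' @return data.frame with an `epoch` column plus one column per
#'   optimizer/learning-rate pair.
#' @export
pivotGrid <- function(gridResults) {
  if (!"epochs" %in% names(gridResults))
    stop("grid results need an 'epochs' axis to pivot")
  opt <- if ("optimizer" %in% names(gridResults)) gridResults$optimizer
         else "all"
  lr <- if ("learningRate" %in% names(gridResults))
    format(gridResults$learningRate, scientific = FALSE, trim = TRUE)
    else "all"
  colKey <- paste(opt, lr, sep = "@")
  tab <- tapply(gridResults$valAccuracy, list(gridResults$epochs, colKey),
                function(v) v[1L])
  out <- data.frame(epoch = as.integer(rownames(tab)), tab,
                    check.names = FALSE, row.names = NULL)
  out[order(out$epoch), , drop = FALSE]
}

#' Summarize repeated run accuracies
#'
#' Mean accuracy with a t-based confidence half-width (the "marginal
#' error" attached to repeated-run means).
#'
#' @param accuracies per-run accuracies, percent; at least 2.
#' @param confidence confidence level (default 0.95).
#' @return a [RepeatSummary-class].
#' @examples
#' summarizeRepeats(c(99.64, 100, 99.64, 99.64, 99.82))
#' @export
summarizeRepeats <- function(accuracies, confidence = 0.95) {
  if (length(accuracies) < 2L)
    stop("insufficient repeats: need at least 2 runs")
  n <- length(accuracies)
  s <- stats::sd(accuracies)
  half <- stats::qt((1 + confidence) / 2, df = n - 1L) * s / sqrt(n)
  methods::new("RepeatSummary",
    meanAccuracy = mean(accuracies), marginalError = half,
    confidence = confidence, nRepeats = as.integer(n),
    accuracies = accuracies)
}

#' Repeat a training run under derived seeds
#'
#' Runs [trainAndEvaluate()] `repeats` times with seeds
#' `config@seed + 0:(repeats-1)` and summarizes the final validation
#' accuracies.
#'
#' @param config an [ExperimentConfig-class] (its `repeats` slot is the
#'   default count).
#' @param manifest,dir forwarded to [trainAndEvaluate()].
#' @param repeats number of runs.
#' @param pretrained optional shared backbone weights (see
#'   [pretrainTinyBackbone()]).
#' @return list with `results` (list of [RunResult-class]) and `summary`
#'   (a [RepeatSummary-class]).
#' @export
runRepeats <- function(config, manifest, dir = ".",
                       repeats = config@repeats, pretrained = NULL) {
  results <- lapply(seq_len(repeats) - 1L, function(k) {
    cfg <- config
    cfg@seed <- config@seed + k
    trainAndEvaluate(cfg, manifest, dir, pretrained = pretrained)
  })
  acc <- vapply(results, function(r)
    r@report@accuracy, numeric(1))
  list(results = results, summary = summarizeRepeats(acc))
}

#' @describeIn RunResult-class compact display.
#' @param object a `RunResult`.
#' @export
setMethod("show", "RunResult", function(object) {
  h <- object@history
  cat(sprintf("RunResult [%s, %s, lr=%g, %d epochs]%s\n",
              object@config@model, object@config@optimizer,
              object@config@learningRate, object@config@epochs,
              if (object@failed) " FAILED (divergent loss)" else ""))
  if (nrow(h))
    cat(sprintf("  final accuracy: train %.2f%%, validation %.2f%%\n",
                h$trainAccuracy[nrow(h)], h$valAccuracy[nrow(h)]))
  methods::show(object@counts)
})

#' @describeIn RepeatSummary-class compact display.
#' @param object a `RepeatSummary`.
#' @export
setMethod("show", "RepeatSummary", function(object) {
  cat(sprintf("RepeatSummary: mean %.3f%% +/- %.2f%% (%d runs, %.0f%% CI)\n",
              object@meanAccuracy, object@marginalError, object@nRepeats,
              100 * object@confidence))
})
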