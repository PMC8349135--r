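# Independent oracles used across the suite. These re-derive quantities
# by brute force, deliberately sharing no code with the implementation.

# Count valid filter placements by enumerating positions on a padded
# 1-D grid (independent check of the closed-form output-size formula).
enumerateOutputSize <- function(W, F, P, S) {
  padded <- W + 2 * P
  starts <- seq(1, padded - F + 1, by = S)
  length(starts)
}

# Recursive memoized shape evaluator over a NetworkGraph; applies the
# output-size formula per node from scratch, independent of inferShapes'
# iterative topological walk.
bruteForceShapes <- function(graph, inputShape) {
  nd <- graph@nodes
  ed <- graph@edges
  memo <- new.env(parent = emptyenv())
  padOf <- function(row, f) {
    if (isTRUE(row$same)) (f - 1L) %/% 2L
    else if (is.na(row$pad)) 0L else row$pad
  }
  eval1 <- function(W, F, P, S) (W - F + 2L * P) %/% S + 1L
  shapeOf <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    row <- as.list(nd[match(id, nd$id), ])
    ins <- ed$from[ed$to == id]
    s <- switch(row$kind,
      input = as.integer(inputShape),
      concat = {
        parts <- lapply(ins, shapeOf)
        c(parts[[1]][1], parts[[1]][2],
          sum(vapply(parts, `[`, integer(1), 3L)))
      },
      conv = {
        p <- shapeOf(ins[1])
        c(eval1(p[1], row$fh, padOf(row, row$fh), row$stride),
          eval1(p[2], row$fw, padOf(row, row$fw), row$stride),
          row$nf)
      },
      maxpool = ,
      avgpool = {
        p <- shapeOf(ins[1])
        c(eval1(p[1], row$fh, padOf(row, row$fh), row$stride),
          eval1(p[2], row$fw, padOf(row, row$fw), row$stride),
          p[3])
      },
      global_avg_pool = c(1L, 1L, shapeOf(ins[1])[3]),
      dense = c(1L, 1L, row$nf),
      shapeOf(ins[1]))
    memo[[id]] <- as.integer(s)
    s
  }
  stats::setNames(lapply(nd$id, shapeOf), nd$id)
}

# Materialize-and-count parameter oracle: builds every weight tensor at
# its declared dimensions and sums element counts.
materializeAndCount <- function(graph, inputShape, includeBatchnorm = TRUE,
                                includeBias = FALSE) {
  shapes <- bruteForceShapes(graph, inputShape)
  nd <- graph@nodes
  ed <- graph@edges
  total <- 0
  for (i in seq_len(nrow(nd))) {
    id <- nd$id[i]
    ins <- ed$from[ed$to == id]
    if (nd$kind[i] == "conv") {
      cin <- shapes[[ins[1]]][3]
      w <- array(0, c(nd$fh[i], nd$fw[i], cin, nd$nf[i]))
      total <- total + length(w)
      if (includeBias) total <- total + length(numeric(nd$nf[i]))
    } else if (nd$kind[i] == "dense") {
      cin <- shapes[[ins[1]]][3]
      total <- total + length(matrix(0, cin, nd$nf[i])) +
        length(numeric(nd$nf[i]))
    } else if (nd$kind[i] == "batchnorm" && includeBatchnorm) {
      ch <- shapes[[id]][3]
      total <- total + 4 * length(numeric(ch))
    }
  }
  total
}

# Random small valid layer graph: a chain of conv/pool/batchnorm/
# activation nodes with an occasional two-branch concat, ending in a
# classification head.
randomSmallGraph <- function(seed) {
  set.seed(seed)
  gb <- ThermoInception:::graphBuilder()
  ThermoInception:::gbAdd(gb, "input", "input")
  cur <- "input"
  n <- sample(2:5, 1)
  for (i in seq_len(n)) {
    kind <- sample(c("conv", "maxpool", "avgpool", "branch"), 1,
                   prob = c(0.5, 0.15, 0.15, 0.2))
    id <- paste0("n", i)
    if (kind == "conv") {
      f <- sample(c(1L, 3L), 1)
      cur <- ThermoInception:::gbConvUnit(gb, id, cur, f,
                                          nf = sample(2:6, 1),
                                          same = (f == 3L))
    } else if (kind == "branch") {
      a <- ThermoInception:::gbConvUnit(gb, paste0(id, ".a"), cur, 1L,
                                        nf = sample(2:5, 1))
      b <- ThermoInception:::gbConvUnit(gb, paste0(id, ".b"), cur, 3L,
                                        nf = sample(2:5, 1), same = TRUE)
      cur <- ThermoInception:::gbAdd(gb, paste0(id, ".mix"), "concat",
                                     c(a, b))
    } else {
      cur <- ThermoInception:::gbAdd(gb, id, kind, cur, fh = 2L, fw = 2L,
                                     stride = 2L, pad = 0L, same = FALSE)
    }
  }
  ThermoInception:::.gbAttachHead(gb, cur, defaultHead("v3"))
  g <- ThermoInception:::gbFinish(gb, "custom")
  methods::validObject(g)
  g
}

# Exact rational evaluation of the metric suite (integer numerators and
# denominators; NA on zero denominators).
rationalMetrics <- function(tp, tn, fp, fn) {
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  sen <- rat(tp, tp + fn); spe <- rat(tn, fp + tn)
  prec <- rat(tp, tp + fp); npv <- rat(tn, tn + fn)
  list(
    accuracy = 100 * (tp + tn) / (tp + tn + fp + fn),
    sensitivity = sen, specificity = spe, precision = prec, npv = npv,
    fpr = if (is.na(spe)) NA_real_ else rat(fp, tn + fp),
    fnr = if (is.na(sen)) NA_real_ else rat(fn, tp + fn),
    lrp = if (is.na(sen) || is.na(spe) || spe == 1) NA_real_ else
      rat(tp * (fp + tn), (tp + fn) * fp),
    lrn = if (is.na(sen) || is.na(spe) || spe == 0) NA_real_ else
      rat(fn * (fp + tn), (tp + fn) * tn),
    auc = if (is.na(sen) || is.na(spe)) NA_real_ else (sen + spe) / 2,
    eer = if (is.na(sen) || is.na(spe)) NA_real_ else 1 - (sen + spe) / 2,
    f1 = if (is.na(sen) || is.na(prec) || sen + prec == 0) NA_real_ else
      rat(2 * tp, 2 * tp + fp + fn))
}

metricSlots <- c("accuracy", "sensitivity", "specificity", "precision",
                 "npv", "fpr", "fnr", "lrp", "lrn", "auc", "eer", "f1")

reportAsList <- function(rep) {
  stats::setNames(lapply(metricSlots, function(s) methods::slot(rep, s)),
                  metricSlots)
}
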