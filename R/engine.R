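# Desk-scale execution engine for layer graphs: weight initialization,
# minibatch forward/backward passes over the explicit graph, and the
# SGDM / Adam / RMSprop update rules. Convolution and pooling kernels are
# compiled (src/engine.cpp); everything runs single-threaded and fully
# seeded, so runs are deterministic.
#
# Activations are arrays (H, W, C, N); labels are one-hot (K, N).

.convPads <- function(node) {
  c(.resolvePad(node$fh, node$stride, node$pad, node$same, node$id),
    .resolvePad(node$fw, node$stride, node$pad, node$same, node$id))
}

#' Initialize network weights
#'
#' He-normal initialization for conv and dense weights (sd
#' `sqrt(2 / fanIn)`), zero biases, unit batch-norm scale. Draws come
#' from the current R generator.
#'
#' @param graph a [NetworkGraph-class].
#' @param inputShape input tensor shape.
#' @param weights optional named weight list from [networkWeights()]
#'   (e.g. a pretrained backbone); entries whose node id and tensor
#'   dimensions match the graph replace the random initialization.
#' @return an opaque network state list (graph, shapes, parameters).
#' @export
initNetwork <- function(graph, inputShape, weights = NULL) {
  shapes <- inferShapes(graph, inputShape)
  nd <- graph@nodes
  ed <- graph@edges
  ord <- .topoOrder(nd$id, ed)
  preds <- split(ed$from, factor(ed$to, levels = nd$id))
  succs <- split(ed$to, factor(ed$from, levels = nd$id))
  params <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(nd))) {
    id <- nd$id[i]
    kind <- nd$kind[i]
    if (kind == "conv") {
      cin <- shapes[[preds[[id]][1L]]][3]
      fanIn <- nd$fh[i] * nd$fw[i] * cin
      params[[id]] <- list(
        W = array(stats::rnorm(fanIn * nd$nf[i], sd = sqrt(2 / fanIn)),
                  c(nd$fh[i], nd$fw[i], cin, nd$nf[i])),
        b = numeric(nd$nf[i]))
    } else if (kind == "dense") {
      cin <- shapes[[preds[[id]][1L]]][3]
      params[[id]] <- list(
        W = matrix(stats::rnorm(cin * nd$nf[i], sd = sqrt(2 / cin)),
                   cin, nd$nf[i]),
        b = numeric(nd$nf[i]))
    } else if (kind == "batchnorm") {
      ch <- shapes[[id]][3]
      params[[id]] <- list(gamma = rep(1, ch), beta = numeric(ch),
                           runMean = numeric(ch), runVar = rep(1, ch))
    }
  }
  if (!is.null(weights)) {
    for (id in names(weights)) {
      cur <- params[[id]]
      w <- weights[[id]]
      if (is.null(cur)) next
      ok <- all(vapply(names(cur), function(nm)
        !is.null(w[[nm]]) &&
          identical(dim(cur[[nm]]), dim(w[[nm]])) &&
          length(cur[[nm]]) == length(w[[nm]]), logical(1)))
      if (ok) params[[id]] <- w[names(cur)]
    }
  }
  nodes <- stats::setNames(lapply(seq_len(nrow(nd)), function(i)
    as.list(nd[i, ])), nd$id)
  list(graph = graph, inputShape = inputShape, shapes = shapes,
       order = ord, preds = preds, succs = succs, nodes = nodes,
       params = params)
}

#' Extract the weights of a network state
#'
#' @param net network state from [initNetwork()].
#' @return named list (node id -> parameter list) suitable for the
#'   `weights` argument of [initNetwork()].
#' @export
networkWeights <- function(net) {
  out <- list()
  for (id in ls(net$params)) out[[id]] <- net$params[[id]]
  out
}

.bnEps <- 1e-5
.bnMomentum <- 0.1

.channelMatrix <- function(a) {
  d <- dim(a)
  matrix(aperm(a, c(1L, 2L, 4L, 3L)), ncol = d[3L])
}

.fromChannelMatrix <- function(m, d) {
  aperm(array(m, c(d[1L], d[2L], d[4L], d[3L])), c(1L, 2L, 4L, 3L))
}

#' Run a forward pass
#'
#' @param net network state from [initNetwork()].
#' @param x input array (H, W, C, N).
#' @param training use batch statistics for batch norm and apply dropout
#'   (draws from the current R generator); `FALSE` uses running
#'   statistics and identity dropout.
#' @param bnEval keep batch norm in inference mode (running statistics)
#'   even while training — the standard recipe for fine-tuning a
#'   pretrained backbone without destabilizing its statistics.
#' @param bnMomentum weight of the current batch in the running-statistic
#'   update (training mode only).
#' @return list with `acts` (per-node activations), `cache` (backward
#'   intermediates), `probs` (softmax output, K x N) and `logits` (the
#'   pre-softmax scores), when present.
#' @export
forwardPass <- function(net, x, training = FALSE, bnEval = FALSE,
                        bnMomentum = .bnMomentum) {
  acts <- new.env(parent = emptyenv())
  cache <- new.env(parent = emptyenv())
  probs <- NULL
  logits <- NULL
  for (id in net$order) {
    node <- net$nodes[[id]]
    kind <- node$kind
    inIds <- net$preds[[id]]
    a <- if (length(inIds)) acts[[inIds[1L]]] else NULL
    out <- switch(kind,
      input = x,
      conv = {
        p <- .convPads(node)
        pp <- net$params[[id]]
        .cppConvForward(a, pp$W, pp$b, node$stride, p[1L], p[2L])
      },
      batchnorm = {
        pp <- net$params[[id]]
        bnTrain <- training && !bnEval
        r <- .cppBNForward(a, pp$gamma, pp$beta, pp$runMean, pp$runVar,
                           bnTrain, bnMomentum, .bnEps)
        if (bnTrain) {
          pp$runMean <- r$runMean
          pp$runVar <- r$runVar
          net$params[[id]] <- pp
        }
        cache[[id]] <- list(xhat = r$xhat, invStd = r$invStd,
                            training = bnTrain)
        r$y
      },
      activation = {
        cache[[id]] <- a > 0
        pmax(a, 0)
      },
      maxpool = {
        p <- .convPads(node)
        r <- .cppPoolForward(a, node$fh, node$fw, node$stride, p[1L], p[2L], 0L)
        cache[[id]] <- list(arg = r$arg, xdim = dim(a))
        r$y
      },
      avgpool = {
        p <- .convPads(node)
        r <- .cppPoolForward(a, node$fh, node$fw, node$stride, p[1L], p[2L], 1L)
        cache[[id]] <- list(xdim = dim(a), pads = p)
        r$y
      },
      concat = {
        parts <- lapply(inIds, function(i) acts[[i]])
        chans <- vapply(parts, function(p) dim(p)[3L], integer(1))
        cache[[id]] <- list(chans = chans)
        d1 <- dim(parts[[1L]])
        out <- array(0, c(d1[1L], d1[2L], sum(chans), d1[4L]))
        at <- 0L
        for (p in parts) {
          out[, , at + seq_len(dim(p)[3L]), ] <- p
          at <- at + dim(p)[3L]
        }
        out
      },
      dropout = {
        if (training) {
          keep <- 1 - node$rate
          mask <- array(stats::runif(length(a)) < keep, dim(a)) / keep
          cache[[id]] <- mask
          a * mask
        } else a
      },
      global_avg_pool = {
        d <- dim(a)
        cache[[id]] <- d
        array(colMeans(matrix(a, nrow = d[1L] * d[2L])),
              c(1L, 1L, d[3L], d[4L]))
      },
      dense = {
        d <- dim(a)
        X <- matrix(a, nrow = prod(d[1:3]))  # features x N
        pp <- net$params[[id]]
        cache[[id]] <- list(X = X, d = d)
        Y <- crossprod(pp$W, X) + pp$b
        array(Y, c(1L, 1L, nrow(Y), ncol(Y)))
      },
      softmax = {
        d <- dim(a)
        L <- matrix(a, nrow = d[3L] * d[1L] * d[2L])
        logits <- L
        L <- sweep(L, 2L, apply(L, 2L, max))
        P <- exp(L)
        P <- sweep(P, 2L, colSums(P), `/`)
        probs <- P
        array(P, d)
      },
      classification = a,
      stop("engine: unsupported node kind '", kind, "'"))
    acts[[id]] <- out
  }
  list(acts = acts, cache = cache, probs = probs, logits = logits)
}

#' Run a backward pass (softmax cross-entropy loss)
#'
#' @param net network state.
#' @param fwd result of [forwardPass()] with `training = TRUE`.
#' @param onehot one-hot label matrix (K x N).
#' @return environment mapping node id to its parameter gradients.
#' @export
backwardPass <- function(net, fwd, onehot) {
  acts <- fwd$acts
  cache <- fwd$cache
  grads <- new.env(parent = emptyenv())
  dacts <- new.env(parent = emptyenv())
  # a node needs an input gradient only if some upstream node owns
  # trainable parameters; below the frozen prefix backprop is skipped
  hasParams <- function(id) {
    n <- net$nodes[[id]]
    n$trainable && n$kind %in% c("conv", "dense", "batchnorm")
  }
  upTrain <- stats::setNames(logical(length(net$order)), net$order)
  for (id in net$order) {
    ps <- net$preds[[id]]
    upTrain[[id]] <- any(vapply(ps, function(p)
      upTrain[[p]] || hasParams(p), logical(1)))
  }
  addGrad <- function(id, g) {
    if (!upTrain[[id]] && !hasParams(id)) return(invisible(NULL))
    dacts[[id]] <- if (is.null(dacts[[id]])) g else dacts[[id]] + g
  }
  N <- ncol(onehot)
  for (id in rev(net$order)) {
    node <- net$nodes[[id]]
    kind <- node$kind
    inIds <- net$preds[[id]]
    dy <- dacts[[id]]
    if (kind == "classification") {
      # seed the chain at the softmax predecessor (fused with the loss)
      addGrad(inIds[1L], array(0, dim(acts[[id]])))
      next
    }
    if (kind == "softmax") {
      d <- dim(acts[[id]])
      dlog <- (fwd$probs - onehot) / N
      addGrad(inIds[1L], array(dlog, d))
      next
    }
    if (is.null(dy)) next
    switch(kind,
      input = NULL,
      conv = {
        pp <- net$params[[id]]
        p <- .convPads(node)
        r <- .cppConvBackward(acts[[inIds[1L]]], pp$W, dy, node$stride,
                              p[1L], p[2L])
        if (node$trainable) grads[[id]] <- list(W = r$dw, b = r$db)
        addGrad(inIds[1L], r$dx)
      },
      batchnorm = {
        cc <- cache[[id]]
        pp <- net$params[[id]]
        r <- .cppBNBackward(cc$xhat, cc$invStd, pp$gamma, dy, cc$training)
        if (node$trainable)
          grads[[id]] <- list(gamma = r$dgamma, beta = r$dbeta)
        addGrad(inIds[1L], r$dx)
      },
      activation = addGrad(inIds[1L], dy * cache[[id]]),
      maxpool = {
        cc <- cache[[id]]
        addGrad(inIds[1L], .cppMaxPoolBackward(dy, cc$arg, cc$xdim))
      },
      avgpool = {
        cc <- cache[[id]]
        addGrad(inIds[1L],
                .cppAvgPoolBackward(dy, cc$xdim, node$fh, node$fw,
                                    node$stride, cc$pads[1L], cc$pads[2L]))
      },
      concat = {
        chans <- cache[[id]]$chans
        at <- 0L
        for (k in seq_along(inIds)) {
          addGrad(inIds[k], dy[, , at + seq_len(chans[k]), , drop = FALSE])
          at <- at + chans[k]
        }
      },
      dropout = {
        mask <- cache[[id]]
        addGrad(inIds[1L], if (is.null(mask)) dy else dy * mask)
      },
      global_avg_pool = {
        d <- cache[[id]]
        g <- matrix(dy, nrow = d[3L] * d[4L]) / (d[1L] * d[2L])
        dx <- array(rep(as.numeric(dy) / (d[1L] * d[2L]),
                        each = d[1L] * d[2L]), d)
        addGrad(inIds[1L], dx)
      },
      dense = {
        cc <- cache[[id]]
        pp <- net$params[[id]]
        dY <- matrix(dy, nrow = dim(dy)[3L])
        if (node$trainable)
          grads[[id]] <- list(W = cc$X %*% t(dY), b = rowSums(dY))
        addGrad(inIds[1L], array(pp$W %*% dY, cc$d))
      },
      stop("engine: no backward rule for kind '", kind, "'"))
  }
  grads
}

#' Create an optimizer state
#'
#' SGDM uses momentum 0.9; Adam uses beta1 0.9, beta2 0.999, eps 1e-8;
#' RMSprop uses decay 0.9, eps 1e-8 (the conventional defaults).
#'
#' @param method `"sgdm"`, `"adam"` or `"rmsprop"`.
#' @param learningRate per-step factor.
#' @return an opaque optimizer state environment.
#' @export
makeOptimizer <- function(method = c("sgdm", "adam", "rmsprop"),
                          learningRate = 1e-4) {
  method <- match.arg(method)
  st <- new.env(parent = emptyenv())
  st$method <- method
  st$lr <- learningRate
  st$slot1 <- new.env(parent = emptyenv())  # velocity / 1st moment / ms
  st$slot2 <- new.env(parent = emptyenv())  # 2nd moment (adam)
  st$t <- 0L
  st
}

.optUpdate <- function(st, key, p, g) {
  lr <- st$lr
  if (st$method == "sgdm") {
    v <- st$slot1[[key]]
    if (is.null(v)) v <- 0 * g
    v <- 0.9 * v - lr * g
    st$slot1[[key]] <- v
    p + v
  } else if (st$method == "adam") {
    m <- st$slot1[[key]]; v <- st$slot2[[key]]
    if (is.null(m)) { m <- 0 * g; v <- 0 * g }
    m <- 0.9 * m + 0.1 * g
    v <- 0.999 * v + 0.001 * g^2
    st$slot1[[key]] <- m; st$slot2[[key]] <- v
    mh <- m / (1 - 0.9^st$t)
    vh <- v / (1 - 0.999^st$t)
    p - lr * mh / (sqrt(vh) + 1e-8)
  } else {
    s <- st$slot1[[key]]
    if (is.null(s)) s <- 0 * g
    s <- 0.9 * s + 0.1 * g^2
    st$slot1[[key]] <- s
    p - lr * g / (sqrt(s) + 1e-8)
  }
}

#' Apply one optimizer step
#'
#' @param net network state.
#' @param grads gradients from [backwardPass()].
#' @param opt optimizer state from [makeOptimizer()].
#' @return the updated network state (parameters are environments, so the
#'   update is in place; the state is returned for convenience).
#' @export
applyGradients <- function(net, grads, opt) {
  opt$t <- opt$t + 1L
  for (id in ls(grads)) {
    g <- grads[[id]]
    pp <- net$params[[id]]
    for (nm in names(g))
      pp[[nm]] <- .optUpdate(opt, paste0(id, ".", nm), pp[[nm]], g[[nm]])
    net$params[[id]] <- pp
  }
  net
}

#' Cross-entropy loss of a forward pass
#'
#' @param fwd result of [forwardPass()].
#' @param onehot one-hot labels (K x N).
#' @return mean negative log-likelihood.
#' @export
crossEntropy <- function(fwd, onehot) {
  -mean(log(pmax(colSums(fwd$probs * onehot), 1e-12)))
}

#' Predict class indices for a batch
#'
#' @param net network state.
#' @param x input array (H, W, C, N).
#' @return integer vector of 1-based class indices (argmax of softmax).
#' @export
predictClasses <- function(net, x) {
  fwd <- forwardPass(net, x, training = FALSE)
  apply(fwd$probs, 2L, function(p) {
    if (!any(is.finite(p))) return(1L)  # degenerate (diverged) network
    which.max(p)
  })
}

#' Decision scores for a batch (binary networks)
#'
#' The log-odds of the positive (second) class: the difference of the
#' two pre-softmax logits. Unlike the softmax probability this never
#' underflows, so it supports operating-point calibration.
#'
#' @param net network state.
#' @param x input array (H, W, C, N).
#' @return numeric vector of scores (positive favors the second class).
#' @export
predictScores <- function(net, x) {
  fwd <- forwardPass(net, x, training = FALSE)
  s <- fwd$logits[2L, ] - fwd$logits[1L, ]
  s[!is.finite(s)] <- 0
  s
}
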