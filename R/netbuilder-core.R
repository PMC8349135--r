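# Core graph machinery: construction helpers, topological order, shape
# inference via the convolution output-size formula, parameter counting,
# FLOP estimation, freezing, head attachment and canonical serialization.

.topoOrder <- function(ids, edges) {
  # Kahn's algorithm; NULL when the graph has a cycle.
  indeg <- stats::setNames(integer(length(ids)), ids)
  if (nrow(edges)) {
    tb <- table(edges$to)
    indeg[names(tb)] <- as.integer(tb)
  }
  adj <- split(edges$to, factor(edges$from, levels = ids))
  queue <- ids[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    # stable: pick the first queued id (insertion order) for determinism
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (w in adj[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) != length(ids)) NULL else out
}

.reachableFrom <- function(start, ids, edges) {
  adj <- split(edges$to, factor(edges$from, levels = ids))
  seen <- stats::setNames(logical(length(ids)), ids)
  stack <- start
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[[v]]) next
    seen[[v]] <- TRUE
    stack <- c(stack, adj[[v]])
  }
  ids[seen]
}

.emptyNodes <- function() {
  data.frame(id = character(), kind = character(),
             fh = integer(), fw = integer(), nf = integer(),
             stride = integer(), pad = integer(), same = logical(),
             rate = numeric(), trainable = logical(),
             stringsAsFactors = FALSE)
}

# Mutable builder (environment) used by the architecture constructors.
graphBuilder <- function() {
  gb <- new.env(parent = emptyenv())
  gb$nodes <- list()
  gb$edges <- list()
  gb
}

gbAdd <- function(gb, id, kind, from = character(),
                  fh = NA_integer_, fw = NA_integer_, nf = NA_integer_,
                  stride = NA_integer_, pad = NA_integer_, same = NA,
                  rate = NA_real_, trainable = TRUE) {
  gb$nodes[[length(gb$nodes) + 1L]] <- list(
    id = id, kind = kind, fh = as.integer(fh), fw = as.integer(fw),
    nf = as.integer(nf), stride = as.integer(stride),
    pad = as.integer(pad), same = as.logical(same), rate = rate,
    trainable = trainable)
  for (f in from)
    gb$edges[[length(gb$edges) + 1L]] <- list(from = f, to = id)
  invisible(id)
}

# conv + batchnorm + ReLU triple; returns the id of the ReLU node.
gbConvUnit <- function(gb, id, from, fh, fw = fh, nf, stride = 1L,
                       pad = 0L, same = FALSE) {
  gbAdd(gb, id, "conv", from, fh = fh, fw = fw, nf = nf,
        stride = stride, pad = if (same) NA_integer_ else pad, same = same)
  gbAdd(gb, paste0(id, ".bn"), "batchnorm", id)
  gbAdd(gb, paste0(id, ".relu"), "activation", paste0(id, ".bn"))
  paste0(id, ".relu")
}

gbFinish <- function(gb, name = "custom") {
  nodes <- do.call(rbind, lapply(gb$nodes, function(n)
    data.frame(n, stringsAsFactors = FALSE)))
  if (is.null(nodes)) nodes <- .emptyNodes()
  edges <- do.call(rbind, lapply(gb$edges, function(e)
    data.frame(e, stringsAsFactors = FALSE)))
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE)
  outdeg <- table(factor(edges$from, levels = nodes$id))
  sink <- nodes$id[outdeg[nodes$id] == 0L]
  methods::new("NetworkGraph", nodes = nodes, edges = edges,
               inputId = nodes$id[nodes$kind == "input"][1L],
               outputId = sink[1L], name = name)
}

#' Spatial output size of a convolution or pooling window
#'
#' Computes `floor((W - F + 2P) / S) + 1`, the number of valid filter
#' placements along one spatial dimension of length `W` for a filter of
#' size `F`, zero padding `P` on each side and stride `S`. When the
#' division is not exact the result is the floor, with a warning (partial
#' windows at the border are dropped).
#'
#' @param inputSize spatial extent W, pixels.
#' @param filterSize filter extent F, pixels.
#' @param padding zero padding P per side, pixels.
#' @param stride step S, pixels, >= 1.
#' @param what label used in error messages to name the dimension.
#' @return integer output extent, >= 1.
#' @examples
#' convOutputSize(299, 3, 1, 1)  # 299 ("same" geometry)
#' convOutputSize(299, 3, 0, 2)  # 149
#' @export
convOutputSize <- function(inputSize, filterSize, padding, stride,
                           what = "dimension") {
  args <- c(inputSize, filterSize, padding, stride)
  if (anyNA(args) || any(args != as.integer(args)))
    stop("invalid geometry for ", what, ": all arguments must be integers")
  if (stride < 1L) stop("invalid geometry for ", what, ": stride must be >= 1")
  num <- inputSize - filterSize + 2L * padding
  if (num < 0L)
    stop("invalid geometry for ", what, ": filter of size ", filterSize,
         " with padding ", padding, " exceeds input of size ", inputSize)
  if (num %% stride != 0L)
    warning("non-integer output extent for ", what,
            "; flooring (border windows dropped)")
  out <- num %/% as.integer(stride) + 1L
  if (out < 1L)
    stop("invalid geometry for ", what, ": non-positive output size")
  as.integer(out)
}

#' Validate and normalize a tensor shape
#'
#' @param height,width,channels strictly positive integers.
#' @return named integer vector `c(height=, width=, channels=)`.
#' @export
tensorShape <- function(height, width, channels) {
  v <- c(height = height, width = width, channels = channels)
  if (anyNA(v) || any(v != as.integer(v)) || any(v < 1))
    stop("tensor shape components must be strictly positive integers")
  stats::setNames(as.integer(v), c("height", "width", "channels"))
}

.resolvePad <- function(f, stride, pad, same, what) {
  if (isTRUE(same)) {
    if (stride != 1L)
      stop("'same' padding is only supported at stride 1 (", what, ")")
    if ((f - 1L) %% 2L != 0L)
      stop("'same' padding requires an odd filter size (", what, ")")
    (f - 1L) %/% 2L
  } else {
    if (is.na(pad)) 0L else pad
  }
}

.nodeOutputShape <- function(node, inShapes) {
  # inShapes: list of c(h, w, c) of the node's predecessors (topo order of
  # arrival; concat is the only multi-input kind and is order-insensitive
  # for channels).
  kind <- node$kind
  if (kind == "concat") {
    sp <- vapply(inShapes, function(s) s[1:2], integer(2))
    if (any(sp[1, ] != sp[1, 1]) || any(sp[2, ] != sp[2, 1]))
      stop("shape conflict at concat node '", node$id,
           "': spatial dims of inputs differ")
    return(c(sp[1, 1], sp[2, 1], sum(vapply(inShapes, `[`, integer(1), 3L))))
  }
  s <- inShapes[[1L]]
  switch(kind,
    conv = {
      ph <- .resolvePad(node$fh, node$stride, node$pad, node$same, node$id)
      pw <- .resolvePad(node$fw, node$stride, node$pad, node$same, node$id)
      c(convOutputSize(s[1], node$fh, ph, node$stride, paste0(node$id, " height")),
        convOutputSize(s[2], node$fw, pw, node$stride, paste0(node$id, " width")),
        node$nf)
    },
    maxpool = ,
    avgpool = {
      ph <- .resolvePad(node$fh, node$stride, node$pad, node$same, node$id)
      pw <- .resolvePad(node$fw, node$stride, node$pad, node$same, node$id)
      c(convOutputSize(s[1], node$fh, ph, node$stride, paste0(node$id, " height")),
        convOutputSize(s[2], node$fw, pw, node$stride, paste0(node$id, " width")),
        s[3])
    },
    global_avg_pool = c(1L, 1L, s[3]),
    dense = c(1L, 1L, node$nf),
    s  # input/batchnorm/activation/dropout/softmax/classification: unchanged
  )
}

#' Infer the output tensor shape of every node
#'
#' Walks the graph in topological order applying the output-size formula
#' (see [convOutputSize()]) per node. Concat nodes require identical
#' spatial dimensions among their inputs and sum channel counts; global
#' average pooling maps H x W x C to 1 x 1 x C.
#'
#' @param graph a [NetworkGraph-class].
#' @param inputShape shape fed to the input node, see [tensorShape()].
#' @return named list mapping node id to `c(height, width, channels)`.
#' @export
inferShapes <- function(graph, inputShape) {
  inputShape <- tensorShape(inputShape[1], inputShape[2], inputShape[3])
  nd <- graph@nodes
  ed <- graph@edges
  ord <- .topoOrder(nd$id, ed)
  if (is.null(ord)) stop("graph contains a cycle")
  preds <- split(ed$from, factor(ed$to, levels = nd$id))
  shapes <- vector("list", nrow(nd))
  names(shapes) <- nd$id
  for (id in ord) {
    node <- as.list(nd[match(id, nd$id), ])
    shapes[[id]] <- if (node$kind == "input") unname(inputShape) else
      as.integer(unname(.nodeOutputShape(node, shapes[preds[[id]]])))
  }
  shapes
}

.paramTable <- function(graph, inputShape, includeBatchnorm = TRUE,
                        includeBias = FALSE) {
  shapes <- inferShapes(graph, inputShape)
  ed <- graph@edges
  nd <- graph@nodes
  preds <- split(ed$from, factor(ed$to, levels = nd$id))
  n <- nrow(nd)
  params <- numeric(n)
  for (i in seq_len(n)) {
    id <- nd$id[i]
    kind <- nd$kind[i]
    if (kind == "conv") {
      cin <- shapes[[preds[[id]][1L]]][3]
      cout <- nd$nf[i]
      params[i] <- nd$fh[i] * nd$fw[i] * cin * cout +
        if (includeBias) cout else 0
    } else if (kind == "dense") {
      cin <- shapes[[preds[[id]][1L]]][3]
      params[i] <- cin * nd$nf[i] + nd$nf[i]
    } else if (kind == "batchnorm" && includeBatchnorm) {
      ch <- shapes[[id]][3]
      params[i] <- 2 * ch + 2 * ch  # scale/shift + running mean/var
    }
  }
  data.frame(id = nd$id, kind = nd$kind, params = params,
             trainable = nd$trainable, stringsAsFactors = FALSE)
}

#' Analytic parameter count of a layer graph
#'
#' Per node: conv contributes `Fh * Fw * Cin * Cout` (plus `Cout` biases
#' when `includeBias`), dense contributes `Cin * Cout + Cout`, batchnorm
#' contributes `2C` trainable scale/shift plus `2C` non-trainable running
#' statistics when `includeBatchnorm`; all other kinds contribute 0.
#' Frozen nodes are still counted in the total; the trainable count
#' excludes them (and always excludes running statistics).
#'
#' @inheritParams inferShapes
#' @param includeBatchnorm count batch-normalization parameters.
#' @param includeBias count conv biases (dense biases always counted).
#' @return list with `total`, `trainable`, and `perNode` (named vector).
#' @export
countParameters <- function(graph, inputShape,
                            includeBatchnorm = TRUE, includeBias = FALSE) {
  tab <- .paramTable(graph, inputShape, includeBatchnorm, includeBias)
  trainable <- ifelse(tab$kind == "batchnorm", tab$params / 2, tab$params)
  trainable[!tab$trainable] <- 0
  list(total = sum(tab$params),
       trainable = sum(trainable),
       perNode = stats::setNames(tab$params, tab$id))
}

#' Multiply-accumulate estimate for one forward pass
#'
#' Conv contributes `Hout * Wout * Fh * Fw * Cin * Cout`; dense
#' contributes `Cin * Cout`; all other kinds contribute 0.
#'
#' @inheritParams inferShapes
#' @return numeric multiply-accumulate count.
#' @export
estimateFlops <- function(graph, inputShape) {
  shapes <- inferShapes(graph, inputShape)
  ed <- graph@edges
  nd <- graph@nodes
  preds <- split(ed$from, factor(ed$to, levels = nd$id))
  total <- 0
  for (i in seq_len(nrow(nd))) {
    id <- nd$id[i]
    if (nd$kind[i] == "conv") {
      cin <- shapes[[preds[[id]][1L]]][3]
      out <- shapes[[id]]
      total <- total + prod(out[1:2]) * nd$fh[i] * nd$fw[i] * cin * nd$nf[i]
    } else if (nd$kind[i] == "dense") {
      cin <- shapes[[preds[[id]][1L]]][3]
      total <- total + cin * nd$nf[i]
    }
  }
  total
}

.stageOf <- function(ids) sub("\\..*$", "", ids)

#' Structural summary of a graph
#'
#' Counts every node of every kind as one layer and every directed edge as
#' one connection, and reports the analytic parameter count, the FLOP
#' estimate and the output shape at the end of each named stage (the id
#' prefix before the first dot), in topological order.
#'
#' @inheritParams inferShapes
#' @param includeBatchnorm,includeBias forwarded to [countParameters()].
#' @return an [ArchitectureSummary-class].
#' @export
architectureSummary <- function(graph, inputShape = c(299, 299, 3),
                                includeBatchnorm = TRUE, includeBias = FALSE) {
  shapes <- inferShapes(graph, inputShape)
  ord <- .topoOrder(graph@nodes$id, graph@edges)
  stages <- .stageOf(ord)
  last <- ord[!duplicated(stages, fromLast = TRUE)][
    order(match(unique(stages), stages))]
  ss <- do.call(rbind, lapply(last, function(id) {
    s <- shapes[[id]]
    data.frame(stage = .stageOf(id), height = s[1], width = s[2],
               channels = s[3], stringsAsFactors = FALSE)
  }))
  pc <- countParameters(graph, inputShape, includeBatchnorm, includeBias)
  methods::new("ArchitectureSummary",
    name = graph@name,
    layerCount = nrow(graph@nodes),
    connectionCount = nrow(graph@edges),
    parameterCount = pc$total,
    trainableParameterCount = pc$trainable,
    flopsEstimate = estimateFlops(graph, inputShape),
    stageShapes = ss)
}

#' Freeze the leading convolution layers of a graph
#'
#' Marks the first `nConvs` convolution nodes (in topological order) as
#' non-trainable, the standard transfer-learning device of keeping early
#' generic filters fixed. Each frozen conv's batch-normalization companion
#' is frozen with it. `region = "stem"` freezes every node of the stem
#' stage instead (the whole initial convolution stack).
#'
#' @param graph a [NetworkGraph-class].
#' @param nConvs number of leading conv nodes to freeze; must not exceed
#'   the number of conv nodes.
#' @param region optional named region (currently `"stem"`); overrides
#'   `nConvs`.
#' @return the graph with updated `trainable` flags.
#' @export
freezePrefix <- function(graph, nConvs = 0L, region = NULL) {
  nd <- graph@nodes
  if (!is.null(region)) {
    if (!identical(region, "stem")) stop("unknown region: ", region)
    sel <- .stageOf(nd$id) == "stem"
    if (!any(sel)) stop("graph has no stem stage")
    nd$trainable[sel] <- FALSE
  } else {
    ord <- .topoOrder(nd$id, graph@edges)
    convs <- ord[nd$kind[match(ord, nd$id)] == "conv"]
    if (nConvs > length(convs))
      stop("nConvs (", nConvs, ") exceeds the number of conv layers (",
           length(convs), ")")
    frozen <- convs[seq_len(nConvs)]
    nd$trainable[nd$id %in% c(frozen, paste0(frozen, ".bn"))] <- FALSE
  }
  graph@nodes <- nd
  methods::validObject(graph)
  graph
}

#' Default classification heads
#'
#' The V3 head is global average pooling + dense(2) + softmax; the V4/MV4
#' head inserts a dropout layer with rate 0.8 between pooling and the
#' dense layer. Both end in a 2-class classification node (sick/healthy).
#'
#' @param model `"v3"`, `"v4"` or `"mv4"`.
#' @param classes number of output classes.
#' @return a head specification: list of `list(kind = ..., ...)` entries.
#' @export
defaultHead <- function(model = c("v4", "v3", "mv4"), classes = 2L) {
  model <- match.arg(model)
  h <- list(list(kind = "global_avg_pool"))
  if (model %in% c("v4", "mv4"))
    h <- c(h, list(list(kind = "dropout", rate = 0.8)))
  c(h, list(list(kind = "dense", units = as.integer(classes)),
            list(kind = "softmax"),
            list(kind = "classification")))
}

.validateHead <- function(head) {
  if (!length(head)) stop("invalid head: empty specification")
  kinds <- vapply(head, function(h) h$kind, character(1))
  ok <- c("global_avg_pool", "dropout", "dense", "softmax", "classification")
  if (!all(kinds %in% ok))
    stop("invalid head: unknown element kind '",
         setdiff(kinds, ok)[1L], "'")
  if (kinds[length(kinds)] != "classification")
    stop("invalid head: must end in a classification node")
  invisible(kinds)
}

.gbAttachHead <- function(gb, from, head) {
  .validateHead(head)
  for (i in seq_along(head)) {
    h <- head[[i]]
    id <- paste0("head.", i, ".", h$kind)
    switch(h$kind,
      global_avg_pool = gbAdd(gb, id, "global_avg_pool", from),
      dropout = gbAdd(gb, id, "dropout", from, rate = h$rate),
      dense = gbAdd(gb, id, "dense", from, nf = h$units),
      softmax = gbAdd(gb, id, "softmax", from),
      classification = gbAdd(gb, id, "classification", from))
    from <- id
  }
  from
}

#' Append a classification head to a feature trunk
#'
#' @param graph a [NetworkGraph-class] whose sink is a feature node (no
#'   classification node yet).
#' @param head ordered list of head elements drawn from
#'   `global_avg_pool`, `dropout(rate)`, `dense(units)`, `softmax`,
#'   `classification`; the final element must be `classification`.
#' @return the extended graph.
#' @export
attachHead <- function(graph, head) {
  .validateHead(head)
  if (any(graph@nodes$kind == "classification"))
    stop("graph already has a classification head")
  gb <- graphBuilder()
  for (i in seq_len(nrow(graph@nodes))) gb$nodes[[i]] <- as.list(graph@nodes[i, ])
  for (i in seq_len(nrow(graph@edges))) gb$edges[[i]] <- as.list(graph@edges[i, ])
  .gbAttachHead(gb, graph@outputId, head)
  g <- gbFinish(gb, graph@name)
  methods::validObject(g)
  g
}
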