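# Canonical JSON serialization of layer graphs. Node ids are sorted and
# field order is fixed, so two isomorphic builds serialize to the same
# string and graph equality checks reduce to string equality.

.nodeToList <- function(row) {
  out <- list(id = row$id, kind = row$kind)
  if (!is.na(row$fh)) out$filter_height <- row$fh
  if (!is.na(row$fw)) out$filter_width <- row$fw
  if (!is.na(row$nf)) out$num_filters <- row$nf
  if (!is.na(row$stride)) out$stride <- row$stride
  if (isTRUE(row$same)) out$padding <- "same"
  else if (!is.na(row$pad)) out$padding <- row$pad
  if (!is.na(row$rate)) out$dropout_rate <- row$rate
  out$trainable <- row$trainable
  out
}

#' Serialize a layer graph to canonical JSON
#'
#' Nodes are sorted by id, edges sorted by (from, to), and keys emitted in
#' a fixed order, so serialization is canonical: two graphs are
#' structurally identical iff their JSON strings are equal.
#'
#' @param graph a [NetworkGraph-class].
#' @param path optional file to write to.
#' @return the JSON string, invisibly when `path` is given.
#' @seealso [graphFromJSON()], [graphDiff()]
#' @export
graphToJSON <- function(graph, path = NULL) {
  nd <- graph@nodes[order(graph@nodes$id), , drop = FALSE]
  ed <- graph@edges[order(graph@edges$from, graph@edges$to), , drop = FALSE]
  doc <- list(
    format = "thermoinception-graph/1",
    name = graph@name,
    input_id = graph@inputId,
    output_id = graph@outputId,
    nodes = lapply(seq_len(nrow(nd)), function(i) .nodeToList(as.list(nd[i, ]))),
    edges = lapply(seq_len(nrow(ed)), function(i)
      list(from = ed$from[i], to = ed$to[i])))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' Read a layer graph from its canonical JSON serialization
#'
#' @param path file path, or a JSON string.
#' @return a [NetworkGraph-class].
#' @export
graphFromJSON <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (!identical(doc$format, "thermoinception-graph/1"))
    stop("not a recognized graph document")
  nodes <- do.call(rbind, lapply(doc$nodes, function(n) {
    same <- identical(n$padding, "same")
    data.frame(
      id = n$id, kind = n$kind,
      fh = if (is.null(n$filter_height)) NA_integer_ else as.integer(n$filter_height),
      fw = if (is.null(n$filter_width)) NA_integer_ else as.integer(n$filter_width),
      nf = if (is.null(n$num_filters)) NA_integer_ else as.integer(n$num_filters),
      stride = if (is.null(n$stride)) NA_integer_ else as.integer(n$stride),
      pad = if (same || is.null(n$padding)) NA_integer_ else as.integer(n$padding),
      same = if (is.null(n$padding)) NA else same,
      rate = if (is.null(n$dropout_rate)) NA_real_ else n$dropout_rate,
      trainable = isTRUE(n$trainable),
      stringsAsFactors = FALSE)
  }))
  edges <- do.call(rbind, lapply(doc$edges, function(e)
    data.frame(from = e$from, to = e$to, stringsAsFactors = FALSE)))
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE)
  g <- methods::new("NetworkGraph", nodes = nodes, edges = edges,
                    inputId = doc$input_id, outputId = doc$output_id,
                    name = doc$name)
  methods::validObject(g)
  g
}

#' Structural difference between two layer graphs
#'
#' @param a,b [NetworkGraph-class] objects.
#' @return list with `identical` (logical), `nodesOnlyA`, `nodesOnlyB`,
#'   `changedNodes` (same id, different attributes), `edgesOnlyA`,
#'   `edgesOnlyB`.
#' @export
graphDiff <- function(a, b) {
  key <- function(g) {
    nd <- g@nodes[order(g@nodes$id), , drop = FALSE]
    stats::setNames(vapply(seq_len(nrow(nd)), function(i)
      jsonlite::toJSON(.nodeToList(as.list(nd[i, ])), auto_unbox = TRUE),
      character(1)), nd$id)
  }
  ka <- key(a); kb <- key(b)
  shared <- intersect(names(ka), names(kb))
  edgeKey <- function(g) paste(g@edges$from, g@edges$to, sep = " -> ")
  res <- list(
    nodesOnlyA = setdiff(names(ka), names(kb)),
    nodesOnlyB = setdiff(names(kb), names(ka)),
    changedNodes = shared[ka[shared] != kb[shared]],
    edgesOnlyA = setdiff(edgeKey(a), edgeKey(b)),
    edgesOnlyB = setdiff(edgeKey(b), edgeKey(a)))
  res$identical <- all(lengths(res) == 0L)
  res
}

#' @describeIn NetworkGraph-class compact structural display.
#' @param object a `NetworkGraph`.
#' @export
setMethod("show", "NetworkGraph", function(object) {
  kinds <- table(object@nodes$kind)
  cat("NetworkGraph <", object@name, ">: ",
      nrow(object@nodes), " layers, ", nrow(object@edges), " connections\n",
      sep = "")
  cat("  kinds:", paste(names(kinds), as.integer(kinds), sep = ":",
                        collapse = " "), "\n")
  bc <- inceptionBlockCounts(object)
  if (any(bc > 0))
    cat("  inception blocks: A=", bc["a"], " B=", bc["b"], " C=", bc["c"],
        "\n", sep = "")
})

#' @describeIn ArchitectureSummary-class tabular display.
#' @param object an `ArchitectureSummary`.
#' @export
setMethod("show", "ArchitectureSummary", function(object) {
  cat("ArchitectureSummary <", object@name, ">\n", sep = "")
  cat(sprintf("  layers: %d  connections: %d\n",
              object@layerCount, object@connectionCount))
  cat(sprintf("  parameters: %s (trainable %s)\n",
              format(object@parameterCount, big.mark = ","),
              format(object@trainableParameterCount, big.mark = ",")))
  cat(sprintf("  multiply-accumulates/image: %s\n",
              format(object@flopsEstimate, big.mark = ",", scientific = TRUE)))
  cat("  stage output shapes:\n")
  s <- object@stageShapes
  for (i in seq_len(nrow(s)))
    cat(sprintf("    %-8s %4d x %4d x %4d\n", s$stage[i], s$height[i],
                s$width[i], s$channels[i]))
})
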