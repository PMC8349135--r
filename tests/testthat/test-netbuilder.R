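# Layer-graph builders: output-size formula, architecture composition,
# shape inference, parameter/FLOP accounting, freezing, serialization.

test_that("convOutputSize matches the closed form and the enumeration oracle", {
  expect_identical(convOutputSize(299, 3, 1, 1), 299L)  # 'same' identity
  expect_identical(convOutputSize(299, 3, 0, 2), 149L)
  # derived by enumerating filter placements on the padded grid
  expect_identical(enumerateOutputSize(480, 7, 3, 2), 240L)
  expect_identical(suppressWarnings(convOutputSize(480, 7, 3, 2)), 240L)
  for (case in list(c(64, 5, 2, 1), c(100, 3, 0, 3), c(17, 3, 1, 2),
                    c(8, 8, 0, 1), c(31, 1, 0, 5))) {
    expect_identical(
      suppressWarnings(convOutputSize(case[1], case[2], case[3], case[4])),
      enumerateOutputSize(case[1], case[2], case[3], case[4]),
      info = paste(case, collapse = ","))
  }
  expect_error(convOutputSize(3, 7, 0, 1), "invalid geometry")
  expect_error(convOutputSize(10.5, 3, 0, 1), "integers")
  expect_warning(convOutputSize(10, 3, 0, 2), "flooring")
})

test_that("inception V4 has the documented composition", {
  g <- buildInceptionV4()
  bc <- inceptionBlockCounts(g)
  expect_identical(unname(bc), c(4L, 7L, 3L))
  shapes <- inferShapes(g, c(299, 299, 3))
  # every canonical inception-B concat output has 1024 channels
  for (i in 1:7)
    expect_identical(shapes[[paste0("b", i, ".mix")]][3], 1024L)
  # the head sees 1536 features
  expect_identical(shapes[["head.1.global_avg_pool"]][3], 1536L)
  # conv nodes are each followed by batchnorm then activation
  nd <- g@nodes
  for (cid in nd$id[nd$kind == "conv"]) {
    succ <- g@edges$to[g@edges$from == cid]
    expect_identical(nd$kind[match(succ, nd$id)], "batchnorm")
  }
  # V4/MV4 default head carries the 0.8 dropout
  expect_true(any(nd$kind == "dropout" & nd$rate == 0.8))
})

test_that("inception V3 has the documented composition", {
  g <- buildInceptionV3()
  bc <- inceptionBlockCounts(g)
  expect_identical(unname(bc), c(3L, 4L, 2L))
  shapes <- inferShapes(g, c(299, 299, 3))
  expect_identical(shapes[["head.1.global_avg_pool"]][3], 2048L)
  # V3 head has no dropout node
  expect_false(any(g@nodes$kind == "dropout"))
})

test_that("modified inception-B preserves 1024 features and spatial dims", {
  frag <- makeModifiedInceptionB()
  shapes <- inferShapes(frag, c(17, 17, 1024))
  out <- shapes[[frag@outputId]]
  expect_identical(out, c(17L, 17L, 1024L))
  # arbitrary input channels/extent: spatial dims always preserved
  shapes2 <- inferShapes(frag, c(9, 11, 64))
  expect_identical(shapes2[[frag@outputId]][1:2], c(9L, 11L))
  # node-count reduction vs the canonical block is a positive constant
  delta <- nrow(makeCanonicalInceptionB()@nodes) - nrow(frag@nodes)
  expect_gt(delta, 0)
})

test_that("MV4 replaces all 7 inception-B blocks and stays 1024-wide", {
  g <- buildInceptionMV4()
  expect_identical(unname(inceptionBlockCounts(g)["b"]), 7L)
  shapes <- inferShapes(g, c(299, 299, 3))
  for (i in 1:7)
    expect_identical(shapes[[paste0("b", i, ".mix")]][3], 1024L)
  expect_identical(shapes[["head.1.global_avg_pool"]][3], 1536L)
})

test_that("the 1152-channel literal block config needs the strict override", {
  lit <- mv4BlockConfig(literal = TRUE)
  expect_error(buildInceptionMV4(blockConfig = lit), "1024")
  g <- buildInceptionMV4(blockConfig = lit, strict = FALSE)
  shapes <- inferShapes(g, c(299, 299, 3))
  expect_identical(shapes[["b1.mix"]][3], 1152L)
})

test_that("MV4 is strictly smaller than V4 with an identical head", {
  head <- defaultHead("v4")
  v4 <- buildInceptionV4(head = head)
  mv4 <- buildInceptionMV4(head = head)
  s4 <- architectureSummary(v4)
  sm <- architectureSummary(mv4)
  expect_lt(sm@layerCount, s4@layerCount)
  expect_lt(sm@connectionCount, s4@connectionCount)
  expect_lt(sm@parameterCount, s4@parameterCount)
  expect_lt(sm@flopsEstimate, s4@flopsEstimate)
  # structural delta uniformity: 7 x the per-block reduction
  dBlock <- nrow(makeCanonicalInceptionB()@nodes) -
    nrow(makeModifiedInceptionB()@nodes)
  expect_identical(s4@layerCount - sm@layerCount, 7L * dBlock)
  dEdges <- nrow(makeCanonicalInceptionB()@edges) -
    nrow(makeModifiedInceptionB()@edges)
  expect_identical(s4@connectionCount - sm@connectionCount, 7L * dEdges)
})

test_that("shape inference agrees with the brute-force evaluator", {
  for (build in list(buildInceptionV3, buildInceptionV4, buildInceptionMV4)) {
    g <- build()
    a <- inferShapes(g, c(299, 299, 3))
    b <- bruteForceShapes(g, c(299, 299, 3))
    for (id in g@nodes$id)
      expect_identical(as.integer(a[[id]]), b[[id]], info = id)
  }
  for (seed in 1:25) {
    g <- randomSmallGraph(seed)
    a <- inferShapes(g, c(32, 32, 3))
    b <- bruteForceShapes(g, c(32, 32, 3))
    for (id in g@nodes$id)
      expect_identical(as.integer(a[[id]]), b[[id]],
                       info = paste(seed, id))
  }
})

test_that("shape conflicts at concat nodes are reported by node name", {
  gb <- ThermoInception:::graphBuilder()
  ThermoInception:::gbAdd(gb, "input", "input")
  a <- ThermoInception:::gbAdd(gb, "a", "conv", "input", fh = 3L, fw = 3L,
                               nf = 4L, stride = 1L, pad = 0L, same = FALSE)
  b <- ThermoInception:::gbAdd(gb, "b", "conv", "input", fh = 1L, fw = 1L,
                               nf = 4L, stride = 1L, pad = 0L, same = FALSE)
  ThermoInception:::gbAdd(gb, "mix", "concat", c(a, b))
  g <- ThermoInception:::gbFinish(gb, "custom")
  expect_error(inferShapes(g, c(16, 16, 3)), "mix")
})

test_that("parameter counting matches simple closed forms", {
  gb <- ThermoInception:::graphBuilder()
  ThermoInception:::gbAdd(gb, "input", "input")
  ThermoInception:::gbAdd(gb, "d", "dense", "input", nf = 2L)
  ThermoInception:::gbAdd(gb, "cls", "classification", "d")
  g <- ThermoInception:::gbFinish(gb, "custom")
  expect_equal(countParameters(g, c(1, 1, 1536))$total, 1536 * 2 + 2)

  gb <- ThermoInception:::graphBuilder()
  ThermoInception:::gbAdd(gb, "input", "input")
  ThermoInception:::gbAdd(gb, "c", "conv", "input", fh = 3L, fw = 3L,
                          nf = 32L, stride = 1L, pad = 1L, same = FALSE)
  ThermoInception:::gbAdd(gb, "cls", "classification", "c")
  g <- ThermoInception:::gbFinish(gb, "custom")
  expect_equal(countParameters(g, c(8, 8, 3), includeBias = FALSE)$total,
               3 * 3 * 3 * 32)
})

test_that("parameter counting equals the materialize-and-count oracle", {
  for (seed in 1:20) {
    g <- randomSmallGraph(seed + 100)
    for (opts in list(c(TRUE, FALSE), c(TRUE, TRUE), c(FALSE, FALSE))) {
      expect_equal(
        countParameters(g, c(32, 32, 3), includeBatchnorm = opts[1],
                        includeBias = opts[2])$total,
        materializeAndCount(g, c(32, 32, 3), includeBatchnorm = opts[1],
                            includeBias = opts[2]),
        info = paste("seed", seed, paste(opts, collapse = "/")))
    }
  }
})

test_that("FLOP estimation follows the conv/dense accounting rules", {
  gb <- ThermoInception:::graphBuilder()
  ThermoInception:::gbAdd(gb, "input", "input")
  ThermoInception:::gbAdd(gb, "c", "conv", "input", fh = 1L, fw = 1L,
                          nf = 1L, stride = 1L, pad = 0L, same = FALSE)
  ThermoInception:::gbAdd(gb, "cls", "classification", "c")
  g <- ThermoInception:::gbFinish(gb, "custom")
  expect_equal(estimateFlops(g, c(1, 1, 1)), 1)
  # area scaling: doubling H and W scales conv FLOPs by 4
  expect_equal(estimateFlops(g, c(2, 2, 1)), 4)
})

test_that("summaries count every node as a layer and every edge once", {
  gb <- ThermoInception:::graphBuilder()
  ThermoInception:::gbAdd(gb, "input", "input")
  ThermoInception:::gbAdd(gb, "c", "conv", "input", fh = 3L, fw = 3L,
                          nf = 4L, stride = 1L, pad = 1L, same = FALSE)
  ThermoInception:::gbAdd(gb, "c.bn", "batchnorm", "c")
  ThermoInception:::gbAdd(gb, "c.relu", "activation", "c.bn")
  ThermoInception:::gbAdd(gb, "cls", "classification", "c.relu")
  g <- ThermoInception:::gbFinish(gb, "custom")
  s <- architectureSummary(g, c(8, 8, 3))
  expect_identical(s@layerCount, 5L)
  expect_identical(s@connectionCount, 4L)
  # edge-set cardinality computed independently
  expect_identical(s@connectionCount,
                   length(paste(g@edges$from, g@edges$to)))
})

test_that("freezePrefix freezes leading convs in topological order", {
  g <- buildInceptionV4()
  expect_identical(freezePrefix(g, 0L)@nodes$trainable, g@nodes$trainable)
  g10 <- freezePrefix(g, 10L)
  nd <- g10@nodes
  expect_identical(sum(nd$kind == "conv" & !nd$trainable), 10L)
  ord <- ThermoInception:::.topoOrder(nd$id, g10@edges)
  convOrd <- ord[nd$kind[match(ord, nd$id)] == "conv"]
  expect_true(all(!nd$trainable[match(convOrd[1:10], nd$id)]))
  expect_true(all(nd$trainable[match(convOrd[-(1:10)], nd$id)]))
  # trainable parameter count decreases accordingly
  p0 <- countParameters(g, c(299, 299, 3))
  p10 <- countParameters(g10, c(299, 299, 3))
  expect_identical(p0$total, p10$total)
  expect_lt(p10$trainable, p0$trainable)
  expect_error(freezePrefix(g, 10000L), "exceeds")
})

test_that("freezing the whole stem leaves only downstream weights trainable", {
  g <- freezePrefix(buildInceptionV4(), region = "stem")
  nd <- g@nodes
  stem <- grepl("^stem", nd$id)
  expect_true(all(!nd$trainable[stem]))
  expect_true(all(nd$trainable[!stem]))
})

test_that("attachHead validates the head and appends it after the features", {
  frag <- makeModifiedInceptionB()
  g <- attachHead(frag, defaultHead("v4"))
  expect_identical(g@nodes$kind[match(g@outputId, g@nodes$id)],
                   "classification")
  expect_error(attachHead(frag, list(list(kind = "global_avg_pool"))),
               "classification")
  expect_error(attachHead(frag, list(list(kind = "flatten"),
                                     list(kind = "classification"))),
               "invalid head")
  # dense output width 2 for the two-class task
  nd <- g@nodes
  expect_identical(nd$nf[nd$kind == "dense"], 2L)
})

test_that("builds are deterministic and serialization round-trips", {
  a <- graphToJSON(buildInceptionMV4())
  b <- graphToJSON(buildInceptionMV4())
  expect_identical(a, b)
  g <- buildInceptionV3()
  path <- withr::local_tempfile(fileext = ".json")
  graphToJSON(g, path)
  g2 <- graphFromJSON(path)
  expect_identical(graphToJSON(g2), graphToJSON(g))
  expect_true(graphDiff(g, g2)$identical)
  d <- graphDiff(buildInceptionV4(), buildInceptionMV4())
  expect_false(d$identical)
  expect_true(length(d$nodesOnlyA) > 0)
})

test_that("graph validity rejects malformed structures", {
  g <- buildInceptionV4()
  bad <- g
  bad@nodes$kind[bad@nodes$id == "input"] <- "conv"
  expect_error(methods::validObject(bad))
  bad2 <- g
  bad2@edges <- rbind(bad2@edges,
                      data.frame(from = g@outputId, to = "input"))
  expect_error(methods::validObject(bad2))
  expect_error(buildInceptionV4(c(40, 40, 3)), "invalid geometry")
})
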