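# Execution engine: analytic gradients vs finite differences, forward
# shape agreement with inferShapes, optimizer updates, determinism.

makeMicroGraph <- function() {
  gb <- ThermoInception:::graphBuilder()
  ThermoInception:::gbAdd(gb, "input", "input")
  x <- ThermoInception:::gbConvUnit(gb, "s.conv", "input", 3L, nf = 3L,
                                    same = TRUE)
  ThermoInception:::gbAdd(gb, "s.pool", "maxpool", x, fh = 2L, fw = 2L,
                          stride = 2L, pad = 0L, same = FALSE)
  ThermoInception:::gbAdd(gb, "s.avg", "avgpool", "s.pool", fh = 3L,
                          fw = 3L, stride = 1L, same = TRUE)
  ThermoInception:::.gbAttachHead(gb, "s.avg", defaultHead("v3"))
  ThermoInception:::gbFinish(gb, "custom")
}

test_that("analytic gradients match finite differences", {
  # micro graph with conv/bn/relu/maxpool/avgpool/gap/dense/softmax, plus
  # a modified-B fragment (concat, parallel branches, dropout head)
  graphs <- list(
    list(g = makeMicroGraph(), shape = c(6L, 6L, 2L)),
    list(g = attachHead(makeModifiedInceptionB(
           mv4BlockConfig(avgpoolBranchFilters = 2L,
                          directBranchFilters = 3L, stem1x1Filters = 2L,
                          parallelBranchFilters = c(2L, 2L))),
         defaultHead("v4")),
         shape = c(5L, 5L, 4L)))
  for (case in graphs) {
    set.seed(11)
    net <- initNetwork(case$g, case$shape)
    x <- array(runif(prod(case$shape) * 3), c(case$shape, 3L))
    onehot <- matrix(0, 2, 3)
    onehot[cbind(c(1, 2, 1), 1:3)] <- 1
    lossAt <- function() {
      set.seed(99)  # freeze dropout masks across evaluations
      crossEntropy(forwardPass(net, x, training = TRUE), onehot)
    }
    set.seed(99)
    fwd <- forwardPass(net, x, training = TRUE)
    grads <- backwardPass(net, fwd, onehot)
    for (id in ls(grads)) {
      for (sl in names(grads[[id]])) {
        ga <- grads[[id]][[sl]]
        idxs <- unique(round(seq(1, length(ga),
                                 length.out = min(4, length(ga)))))
        for (i in idxs) {
          pp <- net$params[[id]]
          orig <- pp[[sl]][i]
          eps <- 1e-5
          pp[[sl]][i] <- orig + eps; net$params[[id]] <- pp
          lp <- lossAt()
          pp[[sl]][i] <- orig - eps; net$params[[id]] <- pp
          lm <- lossAt()
          pp[[sl]][i] <- orig; net$params[[id]] <- pp
          gn <- (lp - lm) / (2 * eps)
          expect_lt(abs(ga[i] - gn) / max(1e-4, abs(gn), abs(ga[i])),
                    1e-3)
        }
      }
    }
  }
})

test_that("forward activation shapes agree with inferShapes", {
  g <- buildInceptionMV4(c(75, 75, 3), widthScale = 0.125,
                         head = defaultHead("v3"))
  set.seed(4)
  net <- initNetwork(g, c(75, 75, 3))
  x <- array(runif(75 * 75 * 3 * 2), c(75, 75, 3, 2))
  fwd <- forwardPass(net, x, training = FALSE)
  shapes <- inferShapes(g, c(75, 75, 3))
  for (id in g@nodes$id) {
    a <- fwd$acts[[id]]
    expect_identical(dim(a)[1:3], as.integer(shapes[[id]]), info = id)
    expect_identical(dim(a)[4], 2L, info = id)
  }
  # softmax output is a probability distribution per sample
  expect_equal(colSums(fwd$probs), rep(1, 2))
})

test_that("frozen nodes receive no gradient entries", {
  g <- freezePrefix(makeMicroGraph(), 1L)
  set.seed(2)
  net <- initNetwork(g, c(6, 6, 2))
  x <- array(runif(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  onehot <- matrix(c(1, 0, 0, 1), 2, 2)
  fwd <- forwardPass(net, x, training = TRUE)
  grads <- backwardPass(net, fwd, onehot)
  expect_false("s.conv" %in% ls(grads))
  expect_true("head.2.dense" %in% ls(grads))
})

test_that("optimizer update rules follow their definitions", {
  g <- rep(0.5, 3)
  # SGDM: v = 0.9 v - lr g
  opt <- makeOptimizer("sgdm", 0.1)
  opt$t <- 1L
  p1 <- ThermoInception:::.optUpdate(opt, "k", rep(1, 3), g)
  expect_equal(p1, rep(1 - 0.05, 3))
  p2 <- ThermoInception:::.optUpdate(opt, "k", p1, g)
  expect_equal(p2, p1 + (0.9 * (-0.05) - 0.05))
  # Adam first step: p - lr * g/(|g| + eps) elementwise sign step
  opt <- makeOptimizer("adam", 0.01)
  opt$t <- 1L
  pa <- ThermoInception:::.optUpdate(opt, "k", rep(0, 3), g)
  expect_equal(pa, rep(-0.01 * 0.5 / (0.5 + 1e-8), 3), tolerance = 1e-6)
  # RMSprop first step
  opt <- makeOptimizer("rmsprop", 0.01)
  opt$t <- 1L
  pr <- ThermoInception:::.optUpdate(opt, "k", rep(0, 3), g)
  expect_equal(pr, rep(-0.01 * 0.5 / (sqrt(0.1 * 0.25) + 1e-8), 3),
               tolerance = 1e-6)
})

test_that("weight injection replaces matching nodes only", {
  g <- makeMicroGraph()
  set.seed(1); netA <- initNetwork(g, c(6, 6, 2))
  w <- networkWeights(netA)
  set.seed(2); netB <- initNetwork(g, c(6, 6, 2), weights = w)
  expect_identical(netB$params[["s.conv"]]$W, netA$params[["s.conv"]]$W)
  expect_identical(netB$params[["head.2.dense"]]$W,
                   netA$params[["head.2.dense"]]$W)
  # mismatched dims are ignored, not forced
  w2 <- w
  w2[["s.conv"]]$W <- array(0, c(1, 1, 2, 3))
  set.seed(3); netC <- initNetwork(g, c(6, 6, 2), weights = w2)
  expect_false(identical(netC$params[["s.conv"]]$W, w2[["s.conv"]]$W))
})

test_that("seeded forward/backward training steps are deterministic", {
  g <- makeMicroGraph()
  run <- function() {
    set.seed(8)
    net <- initNetwork(g, c(6, 6, 2))
    opt <- makeOptimizer("sgdm", 1e-2)
    x <- array(runif(6 * 6 * 2 * 4), c(6, 6, 2, 4))
    onehot <- matrix(0, 2, 4); onehot[cbind(c(1, 2, 1, 2), 1:4)] <- 1
    for (i in 1:3) {
      fwd <- forwardPass(net, x, training = TRUE)
      net <- applyGradients(net, backwardPass(net, fwd, onehot), opt)
    }
    networkWeights(net)
  }
  expect_identical(run(), run())
})
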