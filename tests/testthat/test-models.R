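numGradCheck <- function(lossFn, params, grads, nPerArray = 3, h = 1e-5) {
  worst <- 0
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(nPerArray, length(params[[nm]])))
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - h
      num <- (lossFn(pp) - lossFn(pm)) / (2 * h)
      worst <- max(worst, abs(num - grads[[nm]][i]) /
                     max(1e-6, abs(num) + abs(grads[[nm]][i])))
    }
  }
  worst
}

test_that("classifier backprop matches numerical gradients", {
  set.seed(101)
  net <- tinyPWC(filters = 3, seed = 5)
  x <- array(runif(24 * 24 * 3), c(24, 24, 3))
  fw <- wsiseg:::pwcForward(net, x)
  expect_equal(sum(fw$probs), 1, tolerance = 1e-12)
  ce <- wsiseg:::softmaxCrossEntropy(fw$logits, 1L)
  bk <- wsiseg:::pwcBackward(net, fw$cache, ce$dlogits)
  lossFn <- function(p) {
    net@params <- p
    wsiseg:::softmaxCrossEntropy(wsiseg:::pwcForward(net, x)$logits, 1L)$loss
  }
  expect_lt(numGradCheck(lossFn, net@params, bk$grads), 1e-4)
})

test_that("U-Net backprop matches numerical gradients (both skip settings)", {
  set.seed(102)
  x <- array(runif(8 * 8 * 4), c(8, 8, 4))
  truth <- randomMask(8, 8)
  for (ts in c(FALSE, TRUE)) {
    net <- tinyUNet(inputSize = 8, depth = 2, filters = c(3L, 5L),
                    dropout = 0, topSkip = ts, seed = 6)
    fw <- wsiseg:::unetForward(net, x)
    expect_equal(fw$probs[, , 1] + fw$probs[, , 2],
                 matrix(1, 8, 8), tolerance = 1e-12)
    dl <- wsiseg:::diceLossSoftmax(fw$logits, truth)
    bk <- wsiseg:::unetBackward(net, fw$cache, dl$dlogits)
    lossFn <- function(p) {
      net@params <- p
      wsiseg:::diceLossSoftmax(wsiseg:::unetForward(net, x)$logits,
                               truth)$loss
    }
    expect_lt(numGradCheck(lossFn, net@params, bk$grads), 1e-4)
  }
})

test_that("weight initialisation is seed-deterministic", {
  expect_identical(tinyPWC(seed = 3)@params, tinyPWC(seed = 3)@params)
  expect_false(identical(tinyPWC(seed = 3)@params, tinyPWC(seed = 4)@params))
  expect_identical(tinyUNet(seed = 3)@params, tinyUNet(seed = 3)@params)
  x <- array(runif(224 * 224 * 3), c(224, 224, 3))
  net <- tinyPWC(seed = 3)
  expect_identical(networkForward(net, x), networkForward(net, x))
})

test_that("untruncated fused branches expose the 1920 + 2048 feature width", {
  fu <- pwcFused(truncA = "bn", truncB = "post_bn")
  expect_equal(sum(fu@config$branchWidths), 3968)
  head <- fu@layers[fu@layers$layer == "predictions", ]
  expect_equal(head$params, 3968 * 2 + 2)
  ## default truncation keeps the fused extractor lightweight
  expect_lt(paramCount(pwcFused()), 14e6)
  expect_error(pwcFused(truncA = "no_such_layer"), "valid names")
})

test_that("single-backbone heads follow the documented conventions", {
  dn <- pwcBaseline("densenet201")
  noTop <- sum(wsiseg:::archDenseNet201()$params)
  expect_equal(paramCount(dn), noTop + 1920 * 2 + 2)
  vg <- pwcBaseline("vgg19")
  expect_true(all(c("fc1", "fc2") %in% vg@layers$layer))
  expect_equal(vg@layers$params[vg@layers$layer == "predictions"],
               4096 * 2 + 2)
  expect_error(pwcBaseline("alexnet"), "valid")
})

test_that("the symbolic refinement U-Net honours its contracts", {
  un <- refinementUNet()
  tb <- networkLayers(un)
  expect_equal(tb$out_h[tb$layer == "softmax"], 1120)
  expect_equal(tb$out_c[tb$layer == "softmax"], 2)
  expect_lt(paramCount(un), 2e6)     # the "lightweight" contract
  expect_error(refinementUNet(inputSize = 1000), "divisible")
  ## toggling the top skip changes only the first decoder block's input
  withSkip <- refinementUNet(topSkip = TRUE)
  d1 <- networkLayers(withSkip)
  expect_gt(paramCount(withSkip), paramCount(un))
  changed <- setdiff(d1$layer, tb$layer)
  expect_equal(changed, "skip1")
})

test_that("complexity reports satisfy the delta identities", {
  mb <- pwcBaseline("mobilenetv2")
  self <- complexityReport(mb, mb)
  expect_equal(self@deltaParamsPct, 0)
  expect_equal(self@deltaFlopsPct, 0)
  r <- complexityReport(pwcBaseline("densenet201"), mb)
  expect_equal(r@deltaParamsPct,
               (r@paramsModel - r@paramsBaseline) / r@paramsBaseline * 100,
               tolerance = 1e-9)
  tab <- complexityTable(models = c("mobilenetv2", "densenet201"))
  expect_equal(nrow(tab), 3)  # fused + two baselines
  expect_true(all(tab$flops_M > 0))
})

test_that("doubling a toy dense width doubles its dense-layer parameters", {
  mk <- function(width) {
    a <- wsiseg:::newArch(8L, 8L, 1L)
    wsiseg:::aGAP(a)
    wsiseg:::aDense(a, "hidden", width)
    wsiseg:::aDense(a, "out", 2L)
    wsiseg:::archTable(a)
  }
  t1 <- mk(16L); t2 <- mk(32L)
  expect_equal(t2$params[t2$layer == "hidden"],
               2 * t1$params[t1$layer == "hidden"])
})

test_that("saliency maps are normalized gradients of the class score", {
  set.seed(7)
  ## linear probe: map must be proportional to |w| per pixel
  probe <- denseProbe(c(6, 6, 1), seed = 2)
  x <- array(runif(36), c(6, 6, 1))
  sal <- saliencyMap(probe, x, classIndex = 2)
  w <- abs(matrix(probe@params$W[, 2], 6, 6))
  expect_equal(sal, (w - min(w)) / (max(w) - min(w)), tolerance = 1e-12)
  ## constant-output (zero-weight) model: guard yields an all-zero map
  z <- denseProbe(c(6, 6, 1), seed = 2)
  z@params$W[] <- 0
  expect_true(all(saliencyMap(z, x) == 0))
  ## classifier saliency has the patch's spatial shape
  net <- tinyPWC(filters = 2, seed = 1)
  patch <- array(runif(32 * 32 * 3), c(32, 32, 3))
  s2 <- saliencyMap(net, patch)
  expect_identical(dim(s2), c(32L, 32L))
  expect_true(all(s2 >= 0 & s2 <= 1))
  expect_error(saliencyMap(constantModel(0.5), patch), "differentiable")
})

test_that("stub models honour the probability contract", {
  cm <- constantModel(0.7)
  p <- networkForward(cm, array(0, c(4, 4, 3)))
  expect_equal(p, c(0.3, 0.7))
  expect_equal(predictPatchProb(cm, array(1, c(4, 4, 3))), 0.7)
})
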