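## a U-Net whose head bias forces the tumor probability to ~0 everywhere;
## used to test cascade plumbing without training
suppressedUNet <- function(size = 140L) {
  net <- tinyUNet(inputSize = size, seed = 1)
  net@params$head_W[] <- 0
  net@params$head_b <- c(10, -10)
  net
}

test_that("heatmaps hold per-tile probabilities with glass fixed at zero", {
  b <- sharedFixture()
  hm <- predictHeatmap(constantModel(0.7), b@image)
  expect_s4_class(hm, "Heatmap")
  expect_identical(dim(hm@probs), c(5L, 5L))     # 1120 / 224
  expect_true(all(hm@probs[hm@kept] == 0.7))
  expect_true(all(hm@probs[!hm@kept] == 0))
  expect_true(validObject(hm))
  ## all-glass image: nothing kept, all-zero heatmap
  white <- array(1, c(448, 448, 3))
  hw <- predictHeatmap(constantModel(0.9), white)
  expect_true(all(hw@probs == 0))
  expect_true(!any(hw@kept))
})

test_that("stitching preserves constants, bounds and the checkerboard mean", {
  mkHm <- function(p) new("Heatmap", probs = p,
                          kept = matrix(TRUE, nrow(p), ncol(p)),
                          tileSize = 224L, stride = 224L,
                          sourceDim = c(448L, 448L))
  cst <- stitchAndResize(mkHm(matrix(0.4, 2, 2)), 64)
  expect_true(all(abs(cst - 0.4) < 1e-12))
  grid <- matrix(c(0, 1, 1, 0), 2, 2)
  up <- stitchAndResize(mkHm(grid), 8)
  expect_true(all(up >= 0 & up <= 1))
  expect_equal(mean(up), mean(grid), tolerance = 1e-6)
  nn <- stitchAndResize(mkHm(grid), 8, nearest = TRUE)
  expect_true(all(nn %in% c(0, 1)))
})

test_that("refinement consumes RGB + heatmap and emits probabilities", {
  set.seed(12)
  net <- tinyUNet(inputSize = 36, depth = 2, filters = c(3L, 4L), seed = 2)
  rgb <- array(runif(36 * 36 * 3), c(36, 36, 3))
  heat <- matrix(runif(36 * 36), 36, 36)
  p <- refineHeatmap(net, rgb, heat)
  expect_identical(dim(p), c(36L, 36L))
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p, refineHeatmap(net, rgb, heat))  # deterministic
  expect_error(refineHeatmap(net, rgb, matrix(0, 10, 10)), "differ")
})

test_that("8-connected labelling joins diagonal pixels", {
  m <- matrix(0, 6, 6); m[1, 1] <- 1; m[2, 2] <- 1; m[5, 5] <- 1
  lab <- wsiseg:::labelComponents8(m)
  expect_equal(max(lab), 2)
  expect_equal(lab[1, 1], lab[2, 2])
  expect_true(lab[5, 5] != lab[1, 1])
})

test_that("post-processing removes fragments and smooths but keeps bodies", {
  empty <- matrix(0L, 50, 50)
  expect_true(all(postprocessMask(empty) == 0))
  ## a 3x3 blob (area 9) dies under minFragmentArea = 10
  frag <- matrix(0L, 50, 50); frag[10:12, 10:12] <- 1L
  cfg <- postprocessConfig(minFragmentArea = 10)
  expect_true(all(postprocessMask(frag, cfg) == 0))
  ## a 101x101 solid square survives with its interior intact
  big <- matrix(0L, 160, 160); big[20:120, 20:120] <- 1L
  out <- postprocessMask(big, postprocessConfig(minFragmentArea = 10))
  expect_true(all(out[40:100, 40:100] == 1))
  expect_true(sum(out) <= sum(big))           # opening/median never grow it
  expect_true(all(out[1:10, ] == 0))
  ## fragment removal never increases the component count
  set.seed(41)
  for (rep in 1:5) {
    m <- (wsiseg:::smoothNoise(80, 4) > 0.8) + 0
    pre <- max(wsiseg:::labelComponents8(m))
    post <- postprocessMask(m, postprocessConfig(minFragmentArea = 30,
                                                 medianKernel = 3L,
                                                 openingKernel = 3L))
    expect_lte(max(wsiseg:::labelComponents8(post)), max(pre, 1))
  }
})

test_that("post-processing is nearly idempotent in area on fixture-like masks", {
  ## masks built the way the generator builds tumor blobs (radial profile
  ## plus low-pass noise, thresholded), at the refinement frame scale
  set.seed(55)
  n <- 140
  ys <- rep.int(seq_len(n), n); xs <- rep(seq_len(n), each = n)
  for (rep in 1:20) {
    tumor <- matrix(FALSE, n, n)
    bnoise <- 0.25 * wsiseg:::smoothNoise(n, sigma = n / 24)
    for (b in seq_len(sample(1:3, 1))) {
      cy <- sample(20:120, 1); cx <- sample(20:120, 1)
      rad <- (n / 4.5) * runif(1, 0.65, 1)
      blob <- matrix(1 - sqrt((ys - cy)^2 + (xs - cx)^2) / rad, n, n)
      tumor <- tumor | ((blob + bnoise) > 0)
    }
    p1 <- postprocessMask(tumor + 0)
    if (sum(p1) == 0) next
    p2 <- postprocessMask(p1)
    expect_lte(abs(sum(p2) - sum(p1)) / sum(p1), 0.05)
  }
})

test_that("the full cascade composes and an all-glass slide stays empty", {
  white <- array(1, c(448, 448, 3))
  res <- segmentWSI(white, constantModel(0.9), suppressedUNet(140))
  expect_true(all(res$post == 0))
  expect_true(all(res$maskHeatmapOnly == 0))
  b <- sharedFixture()
  res2 <- segmentWSI(b@image, constantModel(0.7), suppressedUNet(140))
  expect_identical(dim(res2$stitched), c(140L, 140L))
  expect_true(all(res2$stitched >= 0 & res2$stitched <= 1))
  expect_true(all(res2$refined >= 0 & res2$refined <= 1))
  ## classifier-only path alone yields a valid mask (stage composability)
  expect_true(all(res2$maskHeatmapOnly %in% c(0L, 1L)))
})

test_that("mask down-sampling binarizes cleanly", {
  m <- matrix(0L, 100, 100); m[30:70, 30:70] <- 1L
  d <- downsampleImage(m, 50, binarize = 0.5)
  expect_identical(dim(d), c(50L, 50L))
  expect_true(all(d %in% c(0L, 1L)))
  expect_equal(mean(d), mean(m), tolerance = 0.05)
})
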