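test_that("lens sampling respects ranges, draw order and determinism", {
  cfg <- distortionConfig(nLenses = 3, radiusRange = c(5, 20),
                          strengthRange = c(-0.4, 0.4))
  expect_equal(nrow(sampleLenses(distortionConfig(nLenses = 0,
                                                  radiusRange = c(5, 20)),
                                 50, 50, seed = 1)), 0)
  a <- sampleLenses(cfg, 100, 80, seed = 7)
  b <- sampleLenses(cfg, 100, 80, seed = 7)
  expect_identical(a, b)
  for (s in 1:300) {
    l <- sampleLenses(cfg, 100, 80, seed = s)
    expect_true(all(l$cx >= 0 & l$cx < 80))
    expect_true(all(l$cy >= 0 & l$cy < 100))
    expect_true(all(l$R >= 5 & l$R <= 20))
    expect_true(all(l$S >= -0.4 & l$S <= 0.4))
  }
  expect_warning(sampleLenses(cfg, 10, 10, seed = 1), "rmax")
})

test_that("distortion matches the literal per-pixel reference on a ramp", {
  img <- array(seq_len(49), c(7, 7, 1))
  lens <- data.frame(cx = 3, cy = 3, R = 3, S = 0.5)
  expect_identical(multiLensDistort(img, lens), refMultiLens(img, lens))
})

test_that("vectorized distortion is bit-identical to the reference loop", {
  set.seed(99)
  for (rep in 1:30) {
    H <- sample(8:48, 1); W <- sample(8:48, 1); C <- sample(1:3, 1)
    img <- array(runif(H * W * C), c(H, W, C))
    lenses <- sampleLenses(
      distortionConfig(nLenses = sample(1:4, 1),
                       radiusRange = c(2L, as.integer(max(3, min(H, W) %/% 2))),
                       strengthRange = c(-0.6, 0.6)),
      H, W)
    expect_identical(multiLensDistort(img, lenses), refMultiLens(img, lenses))
  }
})

test_that("identity cases leave the image untouched", {
  set.seed(3)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  ## no lenses
  expect_identical(multiLensDistort(img, sampleLenses(
    distortionConfig(nLenses = 0, radiusRange = c(2, 8)), 32, 32)), img)
  ## zero strength
  lz <- data.frame(cx = c(5, 20), cy = c(10, 25), R = c(8, 6), S = c(0, 0))
  expect_equal(multiLensDistort(img, lz), img)
  ## radius-1 lens touches only its own centre, which maps to itself
  l1 <- data.frame(cx = 16, cy = 16, R = 1, S = 0.9)
  expect_equal(multiLensDistort(img, l1), img)
})

test_that("lens centres and out-of-disk pixels are unchanged; copy semantics", {
  set.seed(11)
  for (rep in 1:20) {
    img <- array(runif(40 * 40 * 2), c(40, 40, 2))
    lenses <- sampleLenses(distortionConfig(nLenses = 3,
                                            radiusRange = c(3, 12),
                                            strengthRange = c(-0.8, 0.8)),
                           40, 40)
    out <- multiLensDistort(img, lenses)
    ## a lens leaves its own centre in place (single-lens application;
    ## with several overlapping lenses a later lens may move an earlier
    ## lens's centre)
    for (i in seq_len(nrow(lenses))) {
      solo <- multiLensDistort(img, lenses[i, ])
      expect_equal(solo[lenses$cy[i] + 1, lenses$cx[i] + 1, ],
                   img[lenses$cy[i] + 1, lenses$cx[i] + 1, ])
    }
    ## locality: pixels with r >= R for every lens are untouched
    ys <- rep(0:39, 40); xs <- rep(0:39, each = 40)
    outside <- rep(TRUE, 1600)
    for (i in seq_len(nrow(lenses)))
      outside <- outside &
        (sqrt((xs - lenses$cx[i])^2 + (ys - lenses$cy[i])^2) >= lenses$R[i])
    for (ch in 1:2) {
      pl <- img[, , ch]; po <- out[, , ch]
      expect_identical(po[cbind(ys + 1, xs + 1)][outside],
                       pl[cbind(ys + 1, xs + 1)][outside])
    }
    ## nearest-neighbour gather: every output value exists in the input
    expect_true(all(out %in% img))
  }
})

test_that("matrix images and mismatched lens tables are handled", {
  m <- matrix(runif(100), 10, 10)
  lens <- data.frame(cx = 5, cy = 5, R = 4, S = 0.5)
  out <- multiLensDistort(m, lens)
  expect_true(is.matrix(out))
  expect_identical(dim(out), dim(m))
  expect_error(multiLensDistort(m, data.frame(cx = 50, cy = 5, R = 4, S = 0)),
               "inside")
})
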