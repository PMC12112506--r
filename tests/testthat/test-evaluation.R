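test_that("dice and iou match hand-computed values and conventions", {
  a <- matrix(0, 4, 4); b <- matrix(0, 4, 4)
  a[1, 1:4] <- 1; b[1, 1:2] <- 1            # |A|=4, |B|=2, overlap 2
  expect_equal(diceScore(a, b), 2 * 2 / 6)
  i <- matrix(0, 3, 3); j <- matrix(0, 3, 3)
  i[1, 1:3] <- 1; j[1, 2:3] <- 1; j[2, 1] <- 1  # int 2, union 4
  expect_equal(iouScore(i, j), 0.5)
  idm <- matrix(rbinom(64, 1, 0.5), 8, 8)
  idm[1, 1] <- 1
  expect_equal(diceScore(idm, idm), 1)
  expect_equal(iouScore(idm, idm), 1)
  z <- matrix(0, 8, 8)
  expect_equal(diceScore(z, z), 1)          # both empty: perfect agreement
  expect_equal(iouScore(z, z), 1)
  expect_equal(diceScore(z, idm), 0)
  d1 <- matrix(0, 4, 4); d2 <- matrix(0, 4, 4)
  d1[1, 1] <- 1; d2[4, 4] <- 1
  expect_equal(diceScore(d1, d2), 0)
  expect_error(diceScore(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("the dice-iou identity and symmetry hold on random masks", {
  set.seed(23)
  for (rep in 1:100) {
    a <- randomMask(12, 12, runif(1, 0.1, 0.9))
    b <- randomMask(12, 12, runif(1, 0.1, 0.9))
    dsc <- diceScore(a, b); iou <- iouScore(a, b)
    expect_equal(dsc, 2 * iou / (1 + iou), tolerance = 1e-12)
    expect_identical(dsc, diceScore(b, a))
    expect_identical(iou, iouScore(b, a))
  }
})

test_that("average Hausdorff distance behaves on constructed masks", {
  m <- randomMask(10, 10, 0.5); m[1, 1] <- 1
  expect_equal(hausdorffAvg(m, m), 0)
  a <- matrix(0, 9, 9); b <- matrix(0, 9, 9)
  a[5, 2] <- 1; b[5, 5] <- 1                # single pixels 3 apart
  expect_equal(hausdorffAvg(a, b), 3)
  ## a single pixel translated by t is exactly t away
  for (t in c(1, 2, 4)) {
    pA <- matrix(0, 20, 20); pA[10, 5] <- 1
    pB <- matrix(0, 20, 20); pB[10, 5 + t] <- 1
    expect_equal(hausdorffAvg(pA, pB), t)
  }
  ## translating an interior blob by t: every boundary pixel has its
  ## translated copy at distance t, so the average is bounded by t,
  ## positive, and monotone in t
  ds <- vapply(1:5, function(t) {
    blobA <- matrix(0, 40, 40); blobA[15:20, 10:15] <- 1
    blobB <- matrix(0, 40, 40); blobB[15:20, 10:15 + t] <- 1
    hausdorffAvg(blobA, blobB)
  }, 0)
  expect_true(all(ds > 0 & ds <= 1:5))
  expect_true(all(diff(ds) > 0))
  ## maximum Hausdorff of an interior-blob translation is exactly t
  blobA <- matrix(0, 40, 40); blobA[15:20, 10:15] <- 1
  blobB <- matrix(0, 40, 40); blobB[15:20, 14:19] <- 1
  expect_equal(hausdorffDistance(blobA, blobB, "max"), 4)
  expect_error(hausdorffAvg(matrix(0, 9, 9), b), "empty")
  expect_gte(hausdorffDistance(a, b, "max"), hausdorffAvg(a, b))
})

test_that("precision/recall/F1 match hand counts and guard zero division", {
  expect_equal(unlist(patchPRF1(c(1, 1, 0, 0), c(1, 1, 0, 0))[1:3]),
               c(precision = 1, recall = 1, f1 = 1))
  ## TP=8, FP=2, FN=2
  labels <- c(rep(1, 10), rep(0, 10))
  preds <- c(rep(1, 8), 0, 0, rep(0, 8), 1, 1)
  r <- patchPRF1(labels, preds)
  expect_equal(r$precision, 0.8)
  expect_equal(r$recall, 0.8)
  expect_equal(r$f1, 0.8)
  r0 <- patchPRF1(c(1, 1, 0), c(0, 0, 0))
  expect_equal(r0$recall, 0)
  expect_true(r0$degenerate)
  expect_error(patchPRF1(c(1, 0), c(1)), "length")
})

test_that("evaluateRun pairs masks by name and aggregates mean/median", {
  pd <- tempfile(); td <- tempfile()
  dir.create(pd); dir.create(td)
  truth1 <- matrix(0, 32, 32); truth1[5:20, 5:20] <- 1
  ## prediction with DSC exactly 0.8: |A|=256, |B|=144, overlap 160
  pred1 <- matrix(0, 32, 32); pred1[5:20, 5:14] <- 1; pred1[25, 25] <- 1
  stopifnot(abs(diceScore(pred1, truth1) -
                2 * 160 / (256 + 161)) < 1e-12)
  truth2 <- truth1; pred2 <- truth1
  writeImageHWC(pred1, file.path(pd, "s1.png"))
  writeImageHWC(pred2, file.path(pd, "s2.png"))
  writeImageHWC(truth1, file.path(td, "s1.png"))
  writeImageHWC(truth2, file.path(td, "s2.png"))
  out <- tempfile(fileext = ".csv")
  rep <- evaluateRun(pd, td, out = out)
  expect_equal(nrow(rep$perImage), 2)
  d1 <- diceScore(pred1, truth1)
  expect_equal(rep$perImage$dsc, c(d1, 1))
  agg <- rep$aggregate
  expect_equal(agg$mean[agg$metric == "dsc"], (d1 + 1) / 2)
  expect_equal(agg$median[agg$metric == "dsc"], (d1 + 1) / 2)
  expect_true(file.exists(out))
  expect_equal(nrow(read.csv(out)), 2)
  file.remove(file.path(pd, "s2.png"))
  expect_error(evaluateRun(pd, td), "unpaired")
})

test_that("the qualitative rubric is a six-level ordered scale", {
  for (v in 0:5) {
    q <- qualScore(v)
    expect_s3_class(q, "ordered")
    expect_equal(as.character(q), as.character(v))
    expect_true(nchar(attr(q, "description")) > 10)
  }
  expect_true(qualScore(5) > qualScore(3))
  expect_match(attr(qualScore(4), "description"), "sparse")
  expect_error(qualScore(6), "0..5")
  expect_error(qualScore(2.5), "0..5")
})
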