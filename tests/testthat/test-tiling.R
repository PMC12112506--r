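test_that("tissue detection returns a binary mask and ignores blank glass", {
  white <- array(1, c(240, 240, 3))
  m <- tissueMask(white)
  expect_identical(dim(m), c(240L, 240L))
  expect_true(all(m == 0))
  b <- sharedFixture()
  tm <- tissueMask(b@image)
  expect_true(all(tm %in% c(0L, 1L)))
  jac <- sum(tm & b@tissueMask) / sum(tm | b@tissueMask)
  expect_gte(jac, 0.8)
})

test_that("the tile grid is row-major, disjoint and drops ragged margins", {
  expect_equal(nrow(tileGrid(448, 448)), 4)
  expect_equal(nrow(tileGrid(450, 448)), 4)
  g <- tileGrid(672, 448, 224)
  expect_equal(nrow(g), 6)
  expect_equal(g$row[1:2], c(0, 0))  # row-major ordering
  ## exhaustive disjointness/bounds via coverage counting
  cover <- matrix(0L, 672, 448)
  for (i in seq_len(nrow(g))) {
    ys <- (g$y0[i] + 1):(g$y0[i] + g$size[i])
    xs <- (g$x0[i] + 1):(g$x0[i] + g$size[i])
    expect_true(max(ys) <= 672 && max(xs) <= 448)
    cover[ys, xs] <- cover[ys, xs] + 1L
  }
  expect_lte(max(cover), 1L)
  expect_warning(g0 <- tileGrid(100, 100), "smaller")
  expect_equal(nrow(g0), 0)
})

test_that("tile labelling applies the tissue and tumor thresholds literally", {
  rules <- tileRules()
  lbl <- function(tf, uf) wsiseg:::labelFromFractions(tf, uf, rules)$label
  expect_equal(lbl(0.20, 0.10), "excluded")   # not enough tissue
  expect_equal(lbl(0.25, 0.10), "excluded")   # strictly more than 25% needed
  expect_equal(lbl(0.90, 0.05), "tumor")      # 5% tumor is enough
  expect_equal(lbl(0.90, 0.03), "excluded")   # ambiguous sliver
  expect_equal(lbl(0.90, 0.00), "non_tumor")  # non-tumor must be tumor-free
  ## monotone in tumor fraction at fixed tissue fraction
  labs <- vapply(c(0, 0.01, 0.04, 0.05, 0.5, 1), function(u) lbl(0.9, u), "")
  expect_equal(labs, c("non_tumor", "excluded", "excluded", "tumor", "tumor",
                       "tumor"))
})

test_that("labelTile measures fractions from the masks themselves", {
  tissue <- matrix(0L, 224, 224); tissue[1:112, ] <- 1L   # exactly half
  tumor <- matrix(0L, 224, 224); tumor[1:56, 1:112] <- 1L # eighth
  res <- labelTile(list(y0 = 0L, x0 = 0L, size = 224L), tissue, tumor)
  expect_equal(res$tissueFraction, 0.5)
  expect_equal(res$tumorFraction, 1 / 8)
  expect_equal(res$label, "tumor")
})

test_that("the 448x448 toy image emits 1 tumor + 2 non-tumor and excludes glass", {
  tissue <- matrix(0L, 448, 448)
  tumor <- matrix(0L, 448, 448)
  tissue[1:224, 1:224] <- 1L; tumor[1:224, 1:224] <- 1L  # all-tumor tile
  tissue[1:224, 225:448] <- 1L                           # tissue-only tile
  tissue[225:448, 1:224] <- 1L                           # tissue-only tile
  ## bottom-right quadrant stays glass
  img <- array(0.5, c(448, 448, 3))
  res <- extractLabeledPatches(img = img, tissue = tissue, tumor = tumor)
  expect_equal(sum(res$labels == 1), 1)
  expect_equal(sum(res$labels == 0), 2)
  expect_equal(sum(res$manifest$label == "excluded"), 1)
  expect_length(res$patches, 3)
  ## manifest fractions equal direct pixel recounts
  for (i in seq_len(nrow(res$manifest))) {
    r <- res$manifest[i, ]
    ys <- (r$y0 + 1):(r$y0 + 224); xs <- (r$x0 + 1):(r$x0 + 224)
    expect_equal(r$tissue_fraction, mean(tissue[ys, xs]))
    expect_equal(r$tumor_fraction, mean(tumor[ys, xs]))
  }
})

test_that("raising the tissue threshold never keeps more tiles", {
  set.seed(17)
  for (rep in 1:5) {
    tissue <- randomMask(448, 448, runif(1, 0.2, 0.8))
    tumor <- tissue * randomMask(448, 448, 0.3)
    kept <- vapply(c(0.1, 0.25, 0.5, 0.75), function(mt) {
      r <- suppressWarnings(extractLabeledPatches(
        img = NULL, tissue = tissue, tumor = tumor,
        rules = tileRules(minTissue = mt, minTumor = 0.05),
        keepImages = FALSE))
      length(r$labels)
    }, 0)
    expect_true(all(diff(kept) <= 0))
  }
})

test_that("a fixture with no tumor yields only non-tumor labels", {
  b <- suppressWarnings(generateFixture(
    fixtureSpec(seed = 9, imageSize = 1120, nTumorBlobs = 0)))
  res <- extractLabeledPatches(b, keepImages = FALSE)
  expect_true(all(res$labels == 0))
})
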