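test_that("fixture specs validate their invariants", {
  expect_error(fixtureSpec(imageSize = 1000), "divisible")
  expect_error(fixtureSpec(imageSize = 1120, tissueCoverage = 1.2), "0, 1")
  expect_error(fixtureSpec(imageSize = 1120, nTumorBlobs = -1), ">= 0")
  expect_s4_class(fixtureSpec(seed = 1, imageSize = 1120), "FixtureSpec")
})

test_that("generation is bit-reproducible and satisfies bundle invariants", {
  sp <- fixtureSpec(seed = 13, imageSize = 1120)
  a <- suppressWarnings(generateFixture(sp))
  b <- suppressWarnings(generateFixture(sp))
  expect_identical(a@image, b@image)
  expect_identical(a@tumorMask, b@tumorMask)
  expect_identical(a@psaRegions, b@psaRegions)
  expect_true(validObject(a))
  expect_true(all(a@tumorMask <= a@tissueMask))
})

test_that("a no-tumor spec yields an empty tumor mask and non-tumor regions only", {
  b <- suppressWarnings(generateFixture(
    fixtureSpec(seed = 2, imageSize = 1120, nTumorBlobs = 0)))
  expect_true(all(b@tumorMask == 0))
  expect_true(all(b@psaRegions$label == "non_tumor"))
})

test_that("measured tissue coverage tracks the requested fraction", {
  b <- suppressWarnings(generateFixture(
    fixtureSpec(seed = 1, imageSize = 1120, tissueCoverage = 0.5)))
  expect_lt(abs(mean(b@tissueMask) - 0.5), 0.1)
})

test_that("patch sets honour balanced and imbalanced requests", {
  ps <- sharedPatchSet()   # counts c(4, 5): the 40:50 ratio at desk scale
  expect_equal(sum(ps$labels == 1), 4)
  expect_equal(sum(ps$labels == 0), 5)
  expect_length(ps$regions, 9)
  expect_equal(nrow(ps$manifest), 9)
  expect_true(all(vapply(ps$regions, function(r)
    all(dim(r) == c(232, 232, 3)), TRUE)))
  ps2 <- suppressWarnings(generatePatchSet(
    fixtureSpec(seed = 21, imageSize = 1120), nPerClass = 2))
  expect_equal(as.vector(table(ps2$labels)), c(2, 2))
  expect_error(generatePatchSet(fixtureSpec(seed = 1, imageSize = 1120),
                                nPerClass = 0), ">= 1")
})

test_that("a tiny reference classifier separates classes; separability is monotone", {
  fitF1 <- function(sep, seed) {
    ps <- suppressWarnings(generatePatchSet(
      fixtureSpec(seed = seed, imageSize = 1120, separability = sep),
      counts = c(6L, 6L)))
    X <- t(vapply(ps$regions, patchFeatures, numeric(4)))
    y <- ps$labels
    idx <- seq_along(y)
    test <- idx[idx %% 3 == 0]; train <- setdiff(idx, test)
    fit <- suppressWarnings(
      glm(y[train] ~ ., data = as.data.frame(X[train, , drop = FALSE]),
          family = binomial))
    pred <- as.integer(predict(fit, as.data.frame(X[test, , drop = FALSE]),
                               type = "response") >= 0.5)
    patchPRF1(y[test], pred)$f1
  }
  f1High <- fitF1(1, 31)
  expect_gte(f1High, 0.95)
  f1s <- c(fitF1(0.05, 33), fitF1(0.45, 33), fitF1(1, 33))
  expect_true(all(diff(f1s) >= 0))
})

test_that("GeoJSON regions round-trip through the QuPath dialect", {
  b <- sharedFixture()
  path <- tempfile(fileext = ".geojson")
  writeRegionsGeoJSON(b@psaRegions, path)
  back <- readRegionsGeoJSON(path)
  expect_equal(back$y0, b@psaRegions$y0)
  expect_equal(back$x1, b@psaRegions$x1)
  expect_equal(back$label, b@psaRegions$label)
  js <- jsonlite::read_json(path)
  expect_equal(js$type, "FeatureCollection")
  expect_true(all(vapply(js$features, function(f)
    !is.null(f$properties$classification$name), TRUE)))
})

test_that("fixture bundles write and reload consistently", {
  b <- sharedFixture()
  dir <- tempfile()
  writeFixtureBundle(b, dir)
  expect_true(all(file.exists(file.path(dir,
    c("image.png", "tumor_mask.png", "tissue_mask.png", "regions.geojson",
      "manifest.json")))))
  tm <- readImageHWC(file.path(dir, "tumor_mask.png"))
  expect_equal(unname((tm > 0.5) + 0L), unname(b@tumorMask + 0L))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 7)
  expect_equal(man$imageSize, 1120)
})
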