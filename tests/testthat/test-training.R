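## a small deterministic region set that trains in seconds: solid-colour
## regions with two visibly different classes
toyRegionSet <- function(n = 8, size = 232L, seed = 1) {
  wsiseg:::withLocalSeed(seed, {
    regions <- list(); labels <- integer(0)
    for (i in seq_len(n)) {
      lab <- i %% 2L
      base <- if (lab == 1L) c(0.25, 0.2, 0.5) else c(0.9, 0.75, 0.8)
      img <- array(rep(base, each = size * size), c(size, size, 3)) +
        array(rnorm(size * size * 3, sd = 0.03), c(size, size, 3))
      regions[[i]] <- wsiseg:::clampNum(img, 0, 1)
      labels <- c(labels, lab)
    }
    list(regions = regions, labels = labels)
  })
}

test_that("classifier training records history and stays finite", {
  ts <- toyRegionSet()
  net <- tinyPWC(filters = 4, seed = 2)
  fit <- trainPWC(net, ts, pwcTrainConfig(lr = 1e-2, maxEpochs = 2L,
                                          patience = 2L, batchSize = 4L),
                  seed = 3)
  expect_equal(nrow(fit$history), 2)
  expect_true(all(is.finite(fit$history$trainLoss)))
  expect_true(all(is.finite(fit$history$valLoss)))
  expect_true(all(fit$history$valF1 >= 0 & fit$history$valF1 <= 1))
})

test_that("identical seeds reproduce the training trajectory exactly", {
  ts <- toyRegionSet()
  cfg <- pwcTrainConfig(lr = 1e-2, maxEpochs = 2L, patience = 2L,
                        batchSize = 4L)
  f1 <- trainPWC(tinyPWC(filters = 4, seed = 2), ts, cfg, seed = 9)
  f2 <- trainPWC(tinyPWC(filters = 4, seed = 2), ts, cfg, seed = 9)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$net@params, f2$net@params)
})

test_that("a separable toy set is learned quickly with held-out F1 >= 0.9", {
  ts <- toyRegionSet(n = 12, seed = 4)
  net <- tinyPWC(filters = 4, seed = 5)
  fit <- trainPWC(net, ts, pwcTrainConfig(lr = 1e-2, maxEpochs = 20L,
                                          patience = 20L, batchSize = 2L),
                  seed = 6)
  expect_gte(tail(fit$history$valF1, 1), 0.9)
  expect_lte(nrow(fit$history), 20)
})

test_that("the dice loss takes its documented extreme values", {
  g <- matrix(0, 20, 20); g[5:15, 5:15] <- 1
  expect_lte(diceLoss(g, g), 1 / (2 * sum(g) + 1))   # eps-bounded near 0
  expect_gte(diceLoss(1 - g, g), 0.99)               # all-wrong: about 1
  expect_equal(diceLoss(matrix(0, 4, 4), matrix(0, 4, 4)), 0) # empty-empty
  expect_error(diceLoss(matrix(0, 2, 2), matrix(0, 3, 3)), "mismatch")
})

test_that("refinement training improves the monitored dice on a toy task", {
  set.seed(31)
  sz <- 36L
  mkPair <- function() {
    y <- matrix(0L, sz, sz)
    cy <- sample(10:26, 1); cx <- sample(10:26, 1)
    y[(cy - 6):(cy + 6), (cx - 6):(cx + 6)] <- 1L
    x <- array(rnorm(sz * sz * 4, sd = 0.1), c(sz, sz, 4))
    x[, , 4] <- x[, , 4] + y          # heatmap channel carries the signal
    list(x = x, y = y)
  }
  pairs <- replicate(6, mkPair(), simplify = FALSE)
  net <- tinyUNet(inputSize = sz, depth = 2, filters = c(4L, 8L),
                  dropout = 0, seed = 8)
  fit <- trainRefinement(net, pairs,
                         unetTrainConfig(lr = 1e-2, maxEpochs = 15L,
                                         patience = 15L), seed = 9)
  expect_lte(nrow(fit$history), 15)
  expect_gt(tail(fit$history$valDice, 1), fit$history$valDice[1])
  expect_true(all(is.finite(fit$history$trainLoss)))
  ## early stopping restored the best-validation-loss weights
  expect_equal(fit$bestEpoch, which.min(fit$history$valLoss))
})

test_that("training rejects empty or malformed sources", {
  expect_error(trainPWC(tinyPWC(), list(regions = list(), labels = integer())),
               "empty")
  net <- tinyUNet(inputSize = 16, depth = 2, filters = c(2L, 3L), seed = 1)
  bad <- list(list(x = array(0, c(8, 8, 4)), y = matrix(0, 8, 8)))
  expect_error(trainRefinement(net, bad), "match")
})
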