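#' Training configuration for the patch-wise classifier
#'
#' Defaults follow the published recipe: Adamax at learning rate 1e-4,
#' categorical crossentropy, F1 monitored, up to 200 epochs with early
#' stopping on validation loss. An epoch takes exactly one random 224-pixel
#' crop from every training region.
#'
#' @param lr learning rate (default 1e-4).
#' @param maxEpochs epoch cap (default 200).
#' @param patience early-stopping patience in epochs (default 20).
#' @param batchSize regions per optimizer step (default 32).
#' @param cropSize training crop edge (default 224).
#' @param optimizer "adamax" (default) or "adam".
#' @return a list of class \code{pwcTrainConfig}.
#' @export
pwcTrainConfig <- function(lr = 1e-4, maxEpochs = 200L, patience = 20L,
                           batchSize = 32L, cropSize = 224L,
                           optimizer = c("adamax", "adam")) {
  stopifnot(lr > 0, patience >= 1)
  structure(list(lr = lr, maxEpochs = as.integer(maxEpochs),
                 patience = as.integer(patience),
                 batchSize = as.integer(batchSize),
                 cropSize = as.integer(cropSize),
                 optimizer = match.arg(optimizer)),
            class = "pwcTrainConfig")
}

#' Training configuration for the refinement U-Net
#'
#' Defaults follow the published recipe: Adam at 1e-4, Dice loss, thresholded
#' Dice monitored, batch size 2, up to 300 epochs with early stopping on
#' validation loss.
#'
#' @param lr learning rate (default 1e-4).
#' @param maxEpochs epoch cap (default 300).
#' @param patience early-stopping patience (default 30).
#' @param batchSize samples per optimizer step (default 2).
#' @param diceEps Dice-loss smoothing (default 1).
#' @param threshold probability threshold for the monitored Dice (default
#'   0.5).
#' @return a list of class \code{unetTrainConfig}.
#' @export
unetTrainConfig <- function(lr = 1e-4, maxEpochs = 300L, patience = 30L,
                            batchSize = 2L, diceEps = 1, threshold = 0.5) {
  stopifnot(lr > 0, patience >= 1, batchSize >= 1)
  structure(list(lr = lr, maxEpochs = as.integer(maxEpochs),
                 patience = as.integer(patience),
                 batchSize = as.integer(batchSize), diceEps = diceEps,
                 threshold = threshold),
            class = "unetTrainConfig")
}

centerCrop <- function(img, size) {
  d <- dim(img)
  if (d[1] == size && d[2] == size) return(img)
  y0 <- (d[1] - size) %/% 2L + 1L; x0 <- (d[2] - size) %/% 2L + 1L
  img[y0:(y0 + size - 1L), x0:(x0 + size - 1L), , drop = FALSE]
}

## stratified train/validation index split (ensures both classes in both)
splitIndices <- function(labels, valFraction) {
  val <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    nv <- max(1L, round(length(idx) * valFraction))
    val <- c(val, sample(idx, nv))
  }
  list(train = setdiff(seq_along(labels), val), val = sort(val))
}

dropFrozen <- function(grads, frozen) {
  for (nm in frozen) grads[nm] <- list(NULL)
  grads
}

#' Train a patch-wise classifier on a labelled region set
#'
#' One epoch visits every training region once, taking a fresh random crop
#' and a fresh draw of the augmentation stack each time; validation uses
#' deterministic centre crops without augmentation. Training stops when the
#' validation loss has not improved for \code{patience} epochs (or at
#' \code{maxEpochs}) and the best-validation weights are restored.
#'
#' @param net a trainable classifier (see [tinyPWC()]).
#' @param patchSet list with \code{regions} and \code{labels} as returned by
#'   [generatePatchSet()].
#' @param config a [pwcTrainConfig()].
#' @param seed integer seed; fixes the split, crops, augmentation and
#'   batching.
#' @param valFraction fraction of regions held out per class (default 0.25).
#' @param augment an [augmentConfig()] applied to training crops, or NULL.
#' @return list with \code{net} (trained), \code{history} (data.frame:
#'   epoch, trainLoss, valLoss, valF1) and \code{bestEpoch}.
#' @export
trainPWC <- function(net, patchSet, config = pwcTrainConfig(), seed = 1L,
                     valFraction = 0.25, augment = NULL) {
  if (!length(patchSet$regions)) stop("empty patch source")
  withLocalSeed(seed, {
    sp <- splitIndices(patchSet$labels, valFraction)
    evalSet <- function(p) {
      net@params <- p
      losses <- numeric(length(sp$val)); preds <- integer(length(sp$val))
      for (j in seq_along(sp$val)) {
        i <- sp$val[j]
        x <- centerCrop(patchSet$regions[[i]], config$cropSize)
        fw <- pwcForward(net, x)
        losses[j] <- softmaxCrossEntropy(fw$logits, patchSet$labels[i])$loss
        preds[j] <- as.integer(fw$probs[2L] >= 0.5)
      }
      list(loss = mean(losses),
           f1 = patchPRF1(patchSet$labels[sp$val], preds)$f1)
    }
    opt <- optimizerInit(net@params, config$optimizer, lr = config$lr)
    best <- list(loss = Inf, params = net@params, epoch = 0L)
    hist <- list()
    for (epoch in seq_len(config$maxEpochs)) {
      ord <- sample(sp$train)
      acc <- NULL; nAcc <- 0L; epochLoss <- 0
      for (i in ord) {
        x <- randomCrop(patchSet$regions[[i]], config$cropSize)
        if (!is.null(augment)) x <- standardAugment(x, augment)
        fw <- pwcForward(net, x, training = TRUE)
        ce <- softmaxCrossEntropy(fw$logits, patchSet$labels[i])
        epochLoss <- epochLoss + ce$loss
        bk <- pwcBackward(net, fw$cache, ce$dlogits)
        acc <- addGrads(acc, bk$grads); nAcc <- nAcc + 1L
        if (nAcc >= config$batchSize) {
          st <- optimizerStep(opt, net@params,
                              dropFrozen(scaleGrads(acc, 1 / nAcc),
                                         net@config$frozen))
          opt <- st$opt; net@params <- st$params
          acc <- NULL; nAcc <- 0L
        }
      }
      if (nAcc > 0L) {
        st <- optimizerStep(opt, net@params,
                            dropFrozen(scaleGrads(acc, 1 / nAcc),
                                       net@config$frozen))
        opt <- st$opt; net@params <- st$params
      }
      ev <- evalSet(net@params)
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  trainLoss = epochLoss / length(ord),
                                  valLoss = ev$loss, valF1 = ev$f1)
      if (ev$loss < best$loss - 1e-9)
        best <- list(loss = ev$loss, params = net@params, epoch = epoch)
      if (epoch - best$epoch >= config$patience) break
    }
    net@params <- best$params
    list(net = net, history = do.call(rbind, hist), bestEpoch = best$epoch)
  })
}

#' Train the refinement U-Net on (4-channel input, mask) pairs
#'
#' Dice loss on the tumor channel of the per-pixel softmax; batch updates of
#' \code{batchSize} samples; early stopping on validation loss with
#' best-weights restoration; the monitored metric is the Dice of the
#' thresholded prediction.
#'
#' @param net a trainable [tinyUNet()].
#' @param pairs list of \code{list(x = H x W x 4 array, y = H x W binary
#'   mask)}.
#' @param config a [unetTrainConfig()].
#' @param seed integer seed.
#' @param valFraction fraction of pairs held out (default 0.25, at least 1).
#' @return list with \code{net}, \code{history} (epoch, trainLoss, valLoss,
#'   valDice) and \code{bestEpoch}.
#' @export
trainRefinement <- function(net, pairs, config = unetTrainConfig(),
                            seed = 1L, valFraction = 0.25) {
  if (!length(pairs)) stop("empty pair source")
  sz <- net@config$inputSize
  for (p in pairs)
    if (!identical(dim(p$x), c(sz, sz, net@config$inCh)) ||
        !identical(dim(p$y), c(sz, sz)))
      stop("pair shapes must match the network input")
  withLocalSeed(seed, {
    nv <- max(1L, round(length(pairs) * valFraction))
    val <- sample(seq_along(pairs), nv)
    trainIdx <- setdiff(seq_along(pairs), val)
    evalSet <- function(p) {
      net@params <- p
      ls <- numeric(length(val)); dc <- numeric(length(val))
      for (j in seq_along(val)) {
        pr <- pairs[[val[j]]]
        fw <- unetForward(net, pr$x)
        ls[j] <- diceLossSoftmax(fw$logits, pr$y, config$diceEps)$loss
        dc[j] <- diceScore(fw$probs[, , 2L] >= config$threshold, pr$y)
      }
      list(loss = mean(ls), dice = mean(dc))
    }
    opt <- optimizerInit(net@params, "adam", lr = config$lr)
    best <- list(loss = Inf, params = net@params, epoch = 0L)
    hist <- list()
    for (epoch in seq_len(config$maxEpochs)) {
      ord <- sample(trainIdx)
      acc <- NULL; nAcc <- 0L; epochLoss <- 0
      for (i in ord) {
        pr <- pairs[[i]]
        fw <- unetForward(net, pr$x, training = TRUE)
        dl <- diceLossSoftmax(fw$logits, pr$y, config$diceEps)
        epochLoss <- epochLoss + dl$loss
        bk <- unetBackward(net, fw$cache, dl$dlogits)
        acc <- addGrads(acc, bk$grads); nAcc <- nAcc + 1L
        if (nAcc >= config$batchSize) {
          st <- optimizerStep(opt, net@params, scaleGrads(acc, 1 / nAcc))
          opt <- st$opt; net@params <- st$params
          acc <- NULL; nAcc <- 0L
        }
      }
      if (nAcc > 0L) {
        st <- optimizerStep(opt, net@params, scaleGrads(acc, 1 / nAcc))
        opt <- st$opt; net@params <- st$params
      }
      ev <- evalSet(net@params)
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  trainLoss = epochLoss / length(ord),
                                  valLoss = ev$loss, valDice = ev$dice)
      if (ev$loss < best$loss - 1e-9)
        best <- list(loss = ev$loss, params = net@params, epoch = epoch)
      if (epoch - best$epoch >= config$patience) break
    }
    net@params <- best$params
    list(net = net, history = do.call(rbind, hist), bestEpoch = best$epoch)
  })
}
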