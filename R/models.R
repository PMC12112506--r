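## ---------------------------------------------------------------------------
## Trainable tiny networks.
##
## The tiny fused patch classifier mirrors the full-scale design — two
## convolutional branches consume the identical input, each is globally
## average pooled, features are concatenated and a 2-unit softmax head
## decides — at a width/depth that trains in minutes on one CPU. The tiny
## U-Net mirrors the refinement network (4-channel input, conv+norm+ReLU
## blocks, max pooling, nearest-neighbour upsampling, optional top skip).
## ---------------------------------------------------------------------------

heInit <- function(k, cin, cout) {
  matrix(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
         k * k * cin, cout)
}

layerRowsFromParams <- function(params) {
  do.call(rbind, lapply(names(params), function(nm) {
    data.frame(layer = nm, type = "weights", out_h = NA_integer_,
               out_w = NA_integer_, out_c = NA_integer_,
               params = length(params[[nm]]), flops = 0)
  }))
}

#' Build the trainable tiny fused patch classifier
#'
#' Two branches with different receptive fields (5x5 and 7x7 stem kernels,
#' stride 4) process the same patch; each stem is followed by ReLU, 2x2 max
#' pooling and a 3x3 conv, then global average pooling. Pooled features are
#' concatenated and classified by a 2-unit softmax dense layer. With
#' \code{frozenPrefix = "stems"} the stem convolutions are excluded from
#' optimizer updates (the fine-tuning convention of freezing early layers).
#'
#' @param filters channels per branch (default 8).
#' @param seed RNG seed for weight initialisation.
#' @param frozenPrefix "none" (default) or "stems".
#' @return a trainable [WsiNetwork-class] of kind "tinyPWC".
#' @export
tinyPWC <- function(filters = 8L, seed = 1L, frozenPrefix = c("none", "stems")) {
  frozenPrefix <- match.arg(frozenPrefix)
  f <- as.integer(filters)
  params <- withLocalSeed(seed, list(
    WA1 = heInit(5L, 3L, f), bA1 = numeric(f),
    WA2 = heInit(3L, f, f), bA2 = numeric(f),
    WB1 = heInit(7L, 3L, f), bB1 = numeric(f),
    WB2 = heInit(3L, f, f), bB2 = numeric(f),
    Wh = matrix(rnorm(2L * 2L * f, sd = sqrt(1 / (2 * f))), 2L * f, 2L),
    bh = numeric(2L)))
  frozen <- if (frozenPrefix == "stems") c("WA1", "bA1", "WB1", "bB1")
            else character(0)
  new("WsiNetwork", name = "tiny-fused-pwc", kind = "tinyPWC",
      layers = layerRowsFromParams(params), params = params, state = list(),
      config = list(filters = f, stride = 4L, kA = 5L, kB = 7L,
                    frozen = frozen))
}

pwcBranchFwd <- function(x, W1, b1, W2, b2, k1, stride) {
  c1 <- convFwd(x, W1, b1, k = k1, stride = stride, pad = "valid")
  r1 <- reluFwd(c1$out)
  p1 <- poolFwd(r1$out)
  c2 <- convFwd(p1$out, W2, b2, k = 3L, stride = 1L, pad = "same")
  r2 <- reluFwd(c2$out)
  g <- gapFwd(r2$out)
  list(out = g$out, cache = list(c1 = c1, r1 = r1, p1 = p1, c2 = c2,
                                 r2 = r2, g = g))
}

pwcBranchBwd <- function(dFeat, cache) {
  dg <- gapBwd(dFeat, cache$g$cache)
  dr2 <- reluBwd(dg, cache$r2$cache)
  bc2 <- convBwd(dr2, cache$c2$cache)
  dp1 <- poolBwd(bc2$dx, cache$p1$cache)
  dr1 <- reluBwd(dp1, cache$r1$cache)
  bc1 <- convBwd(dr1, cache$c1$cache)
  list(dx = bc1$dx, dW1 = bc1$dW, db1 = bc1$db, dW2 = bc2$dW, db2 = bc2$db)
}

pwcForward <- function(net, x, training = FALSE) {
  p <- net@params; cf <- net@config
  A <- pwcBranchFwd(x, p$WA1, p$bA1, p$WA2, p$bA2, cf$kA, cf$stride)
  B <- pwcBranchFwd(x, p$WB1, p$bB1, p$WB2, p$bB2, cf$kB, cf$stride)
  feat <- c(A$out, B$out)
  dn <- denseFwd(feat, p$Wh, p$bh)
  probs <- softmaxVec(dn$out)
  list(probs = probs, logits = dn$out,
       cache = list(A = A, B = B, dn = dn, f = cf$filters))
}

pwcBackward <- function(net, cache, dlogits) {
  bd <- denseBwd(dlogits, cache$dn$cache)
  f <- cache$f
  dA <- pwcBranchBwd(bd$dx[seq_len(f)], cache$A$cache)
  dB <- pwcBranchBwd(bd$dx[f + seq_len(f)], cache$B$cache)
  list(grads = list(WA1 = dA$dW1, bA1 = dA$db1, WA2 = dA$dW2, bA2 = dA$db2,
                    WB1 = dB$dW1, bB1 = dB$db1, WB2 = dB$dW2, bB2 = dB$db2,
                    Wh = bd$dW, bh = bd$db),
       dx = dA$dx + dB$dx)
}

#' Build the trainable tiny refinement U-Net
#'
#' Same block structure as [refinementUNet()] (conv 3x3 + per-channel
#' normalization + ReLU, twice per level; 2x2 max pooling; nearest-neighbour
#' upsampling; per-pixel 2-class softmax head), at a desk-scale default of a
#' 140-pixel frame and two resolution levels. The top-most skip connection
#' is removed by default, mirroring the full-scale design.
#'
#' @param inputSize input edge, divisible by \code{2^depth} (default 140).
#' @param depth resolution levels (default 2).
#' @param filters filters per level (default \code{c(8, 16)}).
#' @param inCh input channels (default 4: RGB + heatmap).
#' @param topSkip keep the top skip connection (default FALSE).
#' @param dropout spatial dropout probability in training (default 0.1).
#' @param seed RNG seed for weight initialisation.
#' @return a trainable [WsiNetwork-class] of kind "tinyUNet".
#' @export
tinyUNet <- function(inputSize = 140L, depth = 2L, filters = c(8L, 16L),
                     inCh = 4L, topSkip = FALSE, dropout = 0.1, seed = 1L) {
  depth <- as.integer(depth); filters <- as.integer(filters)
  if (length(filters) != depth) stop("filters must have one entry per level")
  if (inputSize %% 2L^depth != 0L) stop("inputSize must be divisible by 2^depth")
  params <- withLocalSeed(seed, {
    ps <- list()
    addBlock <- function(ps, nm, cin, cout) {
      ps[[paste0(nm, "_W1")]] <- heInit(3L, cin, cout)
      ps[[paste0(nm, "_g1")]] <- rep(1, cout)
      ps[[paste0(nm, "_b1")]] <- numeric(cout)
      ps[[paste0(nm, "_W2")]] <- heInit(3L, cout, cout)
      ps[[paste0(nm, "_g2")]] <- rep(1, cout)
      ps[[paste0(nm, "_b2")]] <- numeric(cout)
      ps
    }
    cin <- inCh
    for (i in seq_len(depth - 1L)) {
      ps <- addBlock(ps, sprintf("enc%d", i), cin, filters[i])
      cin <- filters[i]
    }
    ps <- addBlock(ps, "bot", cin, filters[depth])
    cin <- filters[depth]
    for (i in rev(seq_len(depth - 1L))) {
      skip <- if (i == 1L) topSkip else TRUE
      cdec <- cin + if (skip) filters[i] else 0L
      ps <- addBlock(ps, sprintf("dec%d", i), cdec, filters[i])
      cin <- filters[i]
    }
    ps$head_W <- heInit(1L, cin, 2L)
    ps$head_b <- numeric(2L)
    ps
  })
  new("WsiNetwork", name = "tiny-refinement-unet", kind = "tinyUNet",
      layers = layerRowsFromParams(params), params = params, state = list(),
      config = list(inputSize = as.integer(inputSize), depth = depth,
                    filters = filters, inCh = as.integer(inCh),
                    topSkip = topSkip, dropout = dropout, frozen = character(0)))
}

unetBlockFwd <- function(x, p, nm, dropout, training) {
  c1 <- convFwd(x, p[[paste0(nm, "_W1")]], NULL, k = 3L)
  n1 <- normFwd(c1$out, p[[paste0(nm, "_g1")]], p[[paste0(nm, "_b1")]])
  r1 <- reluFwd(n1$out)
  c2 <- convFwd(r1$out, p[[paste0(nm, "_W2")]], NULL, k = 3L)
  n2 <- normFwd(c2$out, p[[paste0(nm, "_g2")]], p[[paste0(nm, "_b2")]])
  r2 <- reluFwd(n2$out)
  dp <- spatialDropoutFwd(r2$out, dropout, training)
  list(out = dp$out, cache = list(c1 = c1, n1 = n1, r1 = r1, c2 = c2,
                                  n2 = n2, r2 = r2, dp = dp))
}

unetBlockBwd <- function(dOut, cache, nm, grads) {
  dd <- spatialDropoutBwd(dOut, cache$dp$cache)
  dr2 <- reluBwd(dd, cache$r2$cache)
  bn2 <- normBwd(dr2, cache$n2$cache)
  bc2 <- convBwd(bn2$dx, cache$c2$cache)
  dr1 <- reluBwd(bc2$dx, cache$r1$cache)
  bn1 <- normBwd(dr1, cache$n1$cache)
  bc1 <- convBwd(bn1$dx, cache$c1$cache)
  grads[[paste0(nm, "_W1")]] <- bc1$dW
  grads[[paste0(nm, "_g1")]] <- bn1$dgamma
  grads[[paste0(nm, "_b1")]] <- bn1$dbeta
  grads[[paste0(nm, "_W2")]] <- bc2$dW
  grads[[paste0(nm, "_g2")]] <- bn2$dgamma
  grads[[paste0(nm, "_b2")]] <- bn2$dbeta
  list(dx = bc1$dx, grads = grads)
}

unetForward <- function(net, x, training = FALSE) {
  cf <- net@config; p <- net@params
  if (!identical(dim(x)[1:2], rep(cf$inputSize, 2L)) ||
      dim(x)[3] != cf$inCh)
    stop(sprintf("input must be %dx%dx%d", cf$inputSize, cf$inputSize,
                 cf$inCh))
  caches <- list(); skips <- list()
  h <- x
  for (i in seq_len(cf$depth - 1L)) {
    nm <- sprintf("enc%d", i)
    bl <- unetBlockFwd(h, p, nm, cf$dropout, training)
    caches[[nm]] <- bl$cache
    skips[[i]] <- bl$out
    pl <- poolFwd(bl$out)
    caches[[paste0("pool", i)]] <- pl$cache
    h <- pl$out
  }
  bl <- unetBlockFwd(h, p, "bot", cf$dropout, training)
  caches$bot <- bl$cache
  h <- bl$out
  for (i in rev(seq_len(cf$depth - 1L))) {
    up <- upsampleFwd(h)
    caches[[paste0("up", i)]] <- up$cache
    h <- up$out
    useSkip <- if (i == 1L) cf$topSkip else TRUE
    caches[[paste0("useSkip", i)]] <- useSkip
    if (useSkip) {
      sk <- skips[[i]]
      caches[[paste0("skipC", i)]] <- dim(h)[3]
      h <- array(c(h, sk), c(dim(h)[1:2], dim(h)[3] + dim(sk)[3]))
    }
    nm <- sprintf("dec%d", i)
    bl <- unetBlockFwd(h, p, nm, cf$dropout, training)
    caches[[nm]] <- bl$cache
    h <- bl$out
  }
  hd <- convFwd(h, p$head_W, p$head_b, k = 1L)
  caches$head <- hd$cache
  probs <- softmaxPlane(hd$out)
  list(probs = probs, logits = hd$out, cache = caches)
}

unetBackward <- function(net, cache, dlogits) {
  cf <- net@config
  grads <- list()
  bh <- convBwd(dlogits, cache$head)
  grads$head_W <- bh$dW; grads$head_b <- bh$db
  dh <- bh$dx
  dskips <- list()
  for (i in seq_len(cf$depth - 1L)) {
    nm <- sprintf("dec%d", i)
    res <- unetBlockBwd(dh, cache[[nm]], nm, grads)
    grads <- res$grads; dh <- res$dx
    if (cache[[paste0("useSkip", i)]]) {
      cUp <- cache[[paste0("skipC", i)]]
      dskips[[i]] <- dh[, , (cUp + 1L):dim(dh)[3], drop = FALSE]
      dh <- dh[, , seq_len(cUp), drop = FALSE]
    } else dskips[i] <- list(NULL)
    dh <- upsampleBwd(dh, cache[[paste0("up", i)]])
  }
  res <- unetBlockBwd(dh, cache$bot, "bot", grads)
  grads <- res$grads; dh <- res$dx
  for (i in rev(seq_len(cf$depth - 1L))) {
    dh <- poolBwd(dh, cache[[paste0("pool", i)]])
    if (length(dskips) >= i && !is.null(dskips[[i]]))
      dh <- dh + dskips[[i]]
    nm <- sprintf("enc%d", i)
    res <- unetBlockBwd(dh, cache[[nm]], nm, grads)
    grads <- res$grads; dh <- res$dx
  }
  list(grads = grads, dx = dh)
}

#' Build a dense probe network (flatten + 2-unit softmax)
#'
#' A minimal differentiable model used for analytic saliency checks and as a
#' cheap linear classifier on small inputs.
#'
#' @param inputDim input dimensions c(H, W, C).
#' @param seed RNG seed; weights ~ N(0, 0.01).
#' @return a trainable [WsiNetwork-class] of kind "dense".
#' @export
denseProbe <- function(inputDim, seed = 1L) {
  n <- prod(inputDim)
  params <- withLocalSeed(seed,
    list(W = matrix(rnorm(n * 2L, sd = 0.01), n, 2L), b = numeric(2L)))
  new("WsiNetwork", name = "dense-probe", kind = "dense",
      layers = layerRowsFromParams(params), params = params, state = list(),
      config = list(inputDim = as.integer(inputDim), frozen = character(0)))
}

#' Build a constant-probability stub model
#'
#' Always predicts the given tumor probability; useful for exercising the
#' heatmap plumbing without training.
#'
#' @param p tumor probability in [0, 1].
#' @return a [WsiNetwork-class] of kind "constant".
#' @export
constantModel <- function(p = 0.5) {
  new("WsiNetwork", name = sprintf("constant-%.2f", p), kind = "constant",
      layers = data.frame(layer = "const", type = "constant", out_h = NA,
                          out_w = NA, out_c = 2L, params = 0, flops = 0),
      params = list(), state = list(), config = list(p = p))
}

#' Forward pass of a trainable network
#'
#' @param net a trainable [WsiNetwork-class].
#' @param x input array.
#' @param training logical; enables dropout.
#' @return for classifiers, a length-2 probability vector (non-tumor,
#'   tumor); for the U-Net, an H x W x 2 per-pixel probability array.
#' @export
networkForward <- function(net, x, training = FALSE) {
  switch(net@kind,
    tinyPWC = pwcForward(net, x, training)$probs,
    tinyUNet = unetForward(net, x, training)$probs,
    dense = softmaxVec(denseFwd(as.vector(x), net@params$W,
                                net@params$b)$out),
    constant = c(1 - net@config$p, net@config$p),
    stop("network of kind '", net@kind, "' has no forward pass"))
}

#' Tumor probability of one patch under a patch classifier
#'
#' @param net classifier network.
#' @param patch H x W x 3 array.
#' @return tumor-class probability.
#' @export
predictPatchProb <- function(net, patch) {
  pr <- networkForward(net, patch)
  pr[2L]
}
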