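## ---------------------------------------------------------------------------
## Minimal neural-network layer library (single-sample arrays H x W x C).
##
## Convolutions are computed by im2col + matrix multiply with cached index
## matrices; backward passes are hand-derived and verified against numerical
## gradients in the test suite. This is deliberately small: it exists to make
## the tiny patch classifier and tiny refinement U-Net trainable at desk
## scale, fully deterministically, on a single CPU.
## ---------------------------------------------------------------------------

## cache of im2col index matrices keyed by geometry
.idxCache <- new.env(parent = emptyenv())

im2colIndex <- function(H, W, C, k, stride, Hp, Wp, Ho, Wo) {
  key <- paste(H, W, C, k, stride, Hp, sep = "_")
  hit <- .idxCache[[key]]
  if (!is.null(hit)) return(hit)
  ## top-left linear index (1-based) of each output window in padded array
  oy <- rep.int(seq.int(0L, by = stride, length.out = Ho), Wo)
  ox <- rep(seq.int(0L, by = stride, length.out = Wo), each = Ho)
  base <- oy + ox * Hp + 1L                     # channel 0, col-major
  ## offsets: ky fastest, then kx, then channel (matches weight flattening)
  ky <- rep.int(0:(k - 1L), k * C)
  kx <- rep(rep(0:(k - 1L), each = k), C)
  ch <- rep(0:(C - 1L), each = k * k)
  off <- ky + kx * Hp + ch * (Hp * Wp)
  idx <- outer(base, off, "+")
  storage.mode(idx) <- "integer"
  res <- list(idx = idx)
  .idxCache[[key]] <- res
  res
}

## pad = "same" (stride 1 only) or integer pad or "valid"
convFwd <- function(x, Wm, b = NULL, k, stride = 1L, pad = "same") {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  p <- if (identical(pad, "same")) (k - 1L) %/% 2L
       else if (identical(pad, "valid")) 0L else as.integer(pad)
  Hp <- H + 2L * p; Wp <- W + 2L * p
  Ho <- (Hp - k) %/% stride + 1L; Wo <- (Wp - k) %/% stride + 1L
  xp <- if (p > 0L) {
    tmp <- array(0, c(Hp, Wp, C))
    tmp[(p + 1L):(p + H), (p + 1L):(p + W), ] <- x
    tmp
  } else x
  ix <- im2colIndex(H, W, C, k, stride, Hp, Wp, Ho, Wo)
  cols <- xp[as.vector(ix$idx)]
  dim(cols) <- c(Ho * Wo, k * k * C)
  out <- cols %*% Wm
  if (!is.null(b)) out <- sweep(out, 2L, b, "+")
  list(out = array(out, c(Ho, Wo, ncol(Wm))),
       cache = list(cols = cols, ix = ix, dims = d, pdims = c(Hp, Wp, C),
                    p = p, k = k, stride = stride, Wm = Wm))
}

convBwd <- function(dOut, cache) {
  d3 <- dim(dOut)
  dOutMat <- matrix(dOut, d3[1] * d3[2], d3[3])
  dW <- crossprod(cache$cols, dOutMat)
  db <- colSums(dOutMat)
  dcols <- tcrossprod(dOutMat, cache$Wm)
  pd <- cache$pdims
  dxp <- numeric(prod(pd))
  idx <- cache$ix$idx
  for (j in seq_len(ncol(idx))) {
    tgt <- idx[, j]
    dxp[tgt] <- dxp[tgt] + dcols[, j]
  }
  dim(dxp) <- pd
  p <- cache$p; d <- cache$dims
  dx <- if (p > 0L) dxp[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), ,
                        drop = FALSE]
        else dxp
  list(dx = dx, dW = dW, db = db)
}

reluFwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
reluBwd <- function(dOut, cache) dOut * cache

## 2x2 max pooling, stride 2; odd trailing rows/cols are dropped
poolFwd <- function(x) {
  d <- dim(x); H <- d[1] - d[1] %% 2L; W <- d[2] - d[2] %% 2L
  i1 <- seq(1L, H, 2L); i2 <- seq(2L, H, 2L)
  j1 <- seq(1L, W, 2L); j2 <- seq(2L, W, 2L)
  a <- x[i1, j1, , drop = FALSE]; b <- x[i2, j1, , drop = FALSE]
  cc <- x[i1, j2, , drop = FALSE]; e <- x[i2, j2, , drop = FALSE]
  out <- pmax(a, b, cc, e)
  ## first-match tie-break, fixed order (a, b, c, e)
  arg <- 1L * (a == out)
  arg[arg == 0 & b == out] <- 2L
  arg[arg == 0 & cc == out] <- 3L
  arg[arg == 0] <- 4L
  list(out = out, cache = list(arg = arg, dims = d, H = H, W = W))
}

poolBwd <- function(dOut, cache) {
  d <- cache$dims
  dx <- array(0, d)
  i1 <- seq(1L, cache$H, 2L); i2 <- seq(2L, cache$H, 2L)
  j1 <- seq(1L, cache$W, 2L); j2 <- seq(2L, cache$W, 2L)
  arg <- cache$arg
  dx[i1, j1, ] <- dx[i1, j1, ] + dOut * (arg == 1L)
  dx[i2, j1, ] <- dx[i2, j1, ] + dOut * (arg == 2L)
  dx[i1, j2, ] <- dx[i1, j2, ] + dOut * (arg == 3L)
  dx[i2, j2, ] <- dx[i2, j2, ] + dOut * (arg == 4L)
  dx
}

gapFwd <- function(x) {
  d <- dim(x)
  list(out = colMeans(matrix(x, d[1] * d[2], d[3])), cache = d)
}
gapBwd <- function(dOut, cache) {
  d <- cache
  array(rep(dOut / (d[1] * d[2]), each = d[1] * d[2]), d)
}

denseFwd <- function(x, Wd, b) list(out = drop(crossprod(Wd, x)) + b,
                                    cache = list(x = x, Wd = Wd))
denseBwd <- function(dOut, cache) {
  list(dx = drop(cache$Wd %*% dOut), dW = tcrossprod(cache$x, dOut),
       db = dOut)
}

## Per-channel spatial normalization with learned scale/shift. Statistics are
## computed over the H x W plane of the sample at both train and eval time
## (no train/test statistics mismatch; deterministic inference). It fills the
## batch-norm slot of the conv blocks at the batch sizes used here.
normFwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x); n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  v <- colSums(xc * xc) / n
  istd <- 1 / sqrt(v + eps)
  xh <- sweep(xc, 2L, istd, "*")
  out <- sweep(sweep(xh, 2L, gamma, "*"), 2L, beta, "+")
  list(out = array(out, d),
       cache = list(xh = xh, istd = istd, gamma = gamma, d = d, n = n))
}

normBwd <- function(dOut, cache) {
  d <- cache$d; n <- cache$n
  dym <- matrix(dOut, n, d[3])
  dgamma <- colSums(dym * cache$xh)
  dbeta <- colSums(dym)
  dxh <- sweep(dym, 2L, cache$gamma, "*")
  ## standard batch-norm input gradient over the n spatial positions
  t1 <- sweep(dxh, 2L, colMeans(dxh))
  t2 <- sweep(cache$xh, 2L, colSums(dxh * cache$xh) / n, "*")
  dx <- sweep(t1 - t2, 2L, cache$istd, "*")
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

## spatial dropout: whole channels are dropped with probability p (train only)
spatialDropoutFwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, cache = NULL))
  d <- dim(x)
  keep <- runif(d[3]) >= p
  scale <- ifelse(keep, 1 / (1 - p), 0)
  list(out = sweep(x, 3L, scale, "*"), cache = scale)
}
spatialDropoutBwd <- function(dOut, cache) {
  if (is.null(cache)) return(dOut)
  sweep(dOut, 3L, cache, "*")
}

upsampleFwd <- function(x) {
  d <- dim(x)
  i <- rep(seq_len(d[1]), each = 2L); j <- rep(seq_len(d[2]), each = 2L)
  list(out = x[i, j, , drop = FALSE], cache = d)
}
upsampleBwd <- function(dOut, cache) {
  d <- cache
  i1 <- seq(1L, 2L * d[1], 2L); j1 <- seq(1L, 2L * d[2], 2L)
  dOut[i1, j1, , drop = FALSE] + dOut[i1 + 1L, j1, , drop = FALSE] +
    dOut[i1, j1 + 1L, , drop = FALSE] + dOut[i1 + 1L, j1 + 1L, , drop = FALSE]
}

softmaxVec <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

## per-pixel softmax over the channel axis (C = 2 here, but generic)
softmaxPlane <- function(z) {
  d <- dim(z)
  m <- matrix(z, d[1] * d[2], d[3])
  mx <- m[, 1L]
  for (j in seq_len(d[3])[-1L]) mx <- pmax(mx, m[, j])
  e <- exp(m - mx)
  array(e / rowSums(e), d)
}

## cross-entropy on a 2-class softmax; returns loss and dlogits
softmaxCrossEntropy <- function(logits, y) {
  p <- softmaxVec(logits)
  dlogits <- p
  dlogits[y + 1L] <- dlogits[y + 1L] - 1
  list(loss = -log(max(p[y + 1L], 1e-12)), p = p, dlogits = dlogits)
}

## soft Dice loss on the tumor channel of a per-pixel 2-class softmax
## (smoothing eps keeps the loss defined on empty masks); returns loss and
## the gradient with respect to the logits plane
diceLossSoftmax <- function(logits, truth, eps = 1) {
  p <- softmaxPlane(logits)
  p1 <- p[, , 2L]
  num <- 2 * sum(p1 * truth) + eps
  den <- sum(p1) + sum(truth) + eps
  dice <- num / den
  dP1 <- -(2 * truth * den - num) / den^2
  ## softmax jacobian, 2 channels: dz1 = p1 p0 dP1, dz0 = -p1 p0 dP1
  w <- p1 * p[, , 1L] * dP1
  dlogits <- array(0, dim(logits))
  dlogits[, , 2L] <- w
  dlogits[, , 1L] <- -w
  list(loss = 1 - dice, dice = dice, dlogits = dlogits)
}

#' Soft Dice loss between a predicted tumor-probability map and a mask
#'
#' \eqn{1 - (2\sum pg + \epsilon) / (\sum p + \sum g + \epsilon)} with
#' additive smoothing \eqn{\epsilon = 1} by default.
#'
#' @param prob numeric matrix of tumor probabilities in [0,1].
#' @param truth binary matrix of the same shape.
#' @param eps smoothing constant (default 1).
#' @return numeric loss in [0, 1).
#' @export
diceLoss <- function(prob, truth, eps = 1) {
  if (!identical(dim(prob), dim(truth))) stop("shape mismatch")
  1 - (2 * sum(prob * truth) + eps) / (sum(prob) + sum(truth) + eps)
}

## ---------------------------------------------------------------------------
## Optimizers: parameter lists are named lists of numeric arrays
## ---------------------------------------------------------------------------

optimizerInit <- function(params, type = c("adam", "adamax"), lr = 1e-4,
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  type <- match.arg(type)
  list(type = type, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))))
}

optimizerStep <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    if (opt$type == "adam") {
      opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g * g
      mhat <- opt$m[[nm]] / (1 - b1^opt$t)
      vhat <- opt$v[[nm]] / (1 - b2^opt$t)
      params[[nm]] <- params[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
    } else {                      # adamax: infinity-norm second moment
      opt$v[[nm]] <- pmax(b2 * opt$v[[nm]], abs(g))
      params[[nm]] <- params[[nm]] -
        (opt$lr / (1 - b1^opt$t)) * opt$m[[nm]] / (opt$v[[nm]] + opt$eps)
    }
  }
  list(opt = opt, params = params)
}

## elementwise sum of two gradient lists
addGrads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

scaleGrads <- function(g, s) lapply(g, function(x) x * s)
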