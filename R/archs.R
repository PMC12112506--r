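## ---------------------------------------------------------------------------
## Symbolic architecture enumeration.
##
## Each builder walks the architecture layer by layer, tracking spatial size
## and channels, and records exact parameter counts (convention of framework
## model summaries: all weights, including the non-trainable running
## statistics of batch normalization) plus FLOPs estimated as 2 x
## multiply-accumulates for a single 224x224x3 forward pass.
## ---------------------------------------------------------------------------

newArch <- function(H = 224L, W = 224L, C = 3L) {
  a <- new.env(parent = emptyenv())
  a$rows <- list(); a$H <- H; a$W <- W; a$C <- C
  a
}

archRow <- function(a, name, type, params, flops) {
  a$rows[[length(a$rows) + 1L]] <-
    data.frame(layer = name, type = type, out_h = a$H, out_w = a$W,
               out_c = a$C, params = params, flops = flops)
  invisible(a)
}

archTable <- function(a) do.call(rbind, a$rows)

## spatial update shared by conv/pool
stepDims <- function(a, kh, kw, stride, pad) {
  if (pad == "same") {
    a$H <- as.integer(ceiling(a$H / stride))
    a$W <- as.integer(ceiling(a$W / stride))
  } else {
    a$H <- as.integer((a$H - kh) %/% stride + 1L)
    a$W <- as.integer((a$W - kw) %/% stride + 1L)
  }
}

aConv <- function(a, name, cout, k, stride = 1L, pad = "same", bias = FALSE) {
  kh <- k[1]; kw <- if (length(k) > 1L) k[2] else k[1]
  cin <- a$C
  stepDims(a, kh, kw, stride, pad)
  a$C <- as.integer(cout)
  p <- kh * kw * cin * cout + if (bias) cout else 0
  f <- (2 * kh * kw * cin + if (bias) 1 else 0) * cout * a$H * a$W
  archRow(a, name, "conv", p, f)
}

aDWConv <- function(a, name, k = 3L, stride = 1L, pad = "same") {
  stepDims(a, k, k, stride, pad)
  archRow(a, name, "dwconv", k * k * a$C, 2 * k * k * a$C * a$H * a$W)
}

## scale = FALSE drops gamma (3 weights per channel instead of 4)
aBN <- function(a, name, scale = TRUE) {
  archRow(a, name, "batchnorm", (if (scale) 4L else 3L) * a$C,
          2 * a$C * a$H * a$W)
}

aPool <- function(a, name, k, stride = k, pad = "valid", type = "maxpool") {
  stepDims(a, k, k, stride, pad)
  archRow(a, name, type, 0, k * k * a$C * a$H * a$W)
}

aGAP <- function(a, name = "avg_pool") {
  f <- a$H * a$W * a$C
  a$H <- 1L; a$W <- 1L
  archRow(a, name, "gap", 0, f)
}

aDense <- function(a, name, cout, bias = TRUE) {
  cin <- a$C; a$C <- as.integer(cout)
  archRow(a, name, "dense", cin * cout + if (bias) cout else 0,
          2 * cin * cout)
}

aNote <- function(a, name, type = "activation") archRow(a, name, type, 0, 0)

## run branches from the current position; each is a function(a) operating on
## a fork; outputs are concatenated on the channel axis (spatial must agree)
aBranches <- function(a, name, ...) {
  fns <- list(...)
  outs <- lapply(fns, function(fn) {
    fork <- newArch(a$H, a$W, a$C)
    fn(fork)
    fork
  })
  hs <- vapply(outs, function(x) x$H, 0L)
  if (length(unique(hs)) != 1L) stop("branch spatial sizes disagree")
  for (o in outs) a$rows <- c(a$rows, o$rows)
  a$H <- outs[[1]]$H; a$W <- outs[[1]]$W
  a$C <- as.integer(sum(vapply(outs, function(x) x$C, 0L)))
  aNote(a, name, "concat")
}

## ---------------------------------------------------------------------------
## Backbones (feature extractors without classification top), input 224x224x3
## ---------------------------------------------------------------------------

archVGG19 <- function() {
  a <- newArch()
  cfg <- list(c(64, 64), c(128, 128), c(256, 256, 256, 256),
              c(512, 512, 512, 512), c(512, 512, 512, 512))
  for (b in seq_along(cfg)) {
    for (l in seq_along(cfg[[b]]))
      aConv(a, sprintf("block%d_conv%d", b, l), cfg[[b]][l], 3L, bias = TRUE)
    aPool(a, sprintf("block%d_pool", b), 2L)
  }
  archTable(a)
}

archMobileNetV2 <- function() {
  a <- newArch()
  aConv(a, "Conv1", 32L, 3L, 2L); aBN(a, "bn_Conv1")
  settings <- list(c(1, 16, 1, 1), c(6, 24, 2, 2), c(6, 32, 3, 2),
                   c(6, 64, 4, 2), c(6, 96, 3, 1), c(6, 160, 3, 2),
                   c(6, 320, 1, 1))
  id <- 0L
  for (s in settings) {
    t <- s[1]; cout <- s[2]; n <- s[3]; stride <- s[4]
    for (i in seq_len(n)) {
      st <- if (i == 1L) stride else 1L
      cin <- a$C
      if (t != 1) {
        aConv(a, sprintf("block_%d_expand", id), cin * t, 1L)
        aBN(a, sprintf("block_%d_expand_BN", id))
      }
      aDWConv(a, sprintf("block_%d_depthwise", id), 3L, st)
      aBN(a, sprintf("block_%d_depthwise_BN", id))
      aConv(a, sprintf("block_%d_project", id), cout, 1L)
      aBN(a, sprintf("block_%d_project_BN", id))
      id <- id + 1L
    }
  }
  aConv(a, "Conv_1", 1280L, 1L); aBN(a, "Conv_1_bn")
  archTable(a)
}

archResNet101V2 <- function() {
  a <- newArch()
  aConv(a, "conv1_conv", 64L, 7L, 2L, bias = TRUE)
  aPool(a, "pool1_pool", 3L, 2L, pad = "same")
  stacks <- list(c(64, 3, 2), c(128, 4, 2), c(256, 23, 2), c(512, 3, 1))
  for (si in seq_along(stacks)) {
    f <- stacks[[si]][1]; nb <- stacks[[si]][2]; stride <- stacks[[si]][3]
    for (b in seq_len(nb)) {
      nm <- sprintf("conv%d_block%d", si + 1L, b)
      st <- if (b == nb) stride else 1L  # pre-act stacks downsample last
      aBN(a, paste0(nm, "_preact_bn"))
      cinPre <- a$C
      ## shortcut conv only in the first block of a stack
      shortcutParams <- if (b == 1L) (cinPre + 1L) * 4L * f else 0L
      aConv(a, paste0(nm, "_1_conv"), f, 1L)
      aBN(a, paste0(nm, "_1_bn"))
      aConv(a, paste0(nm, "_2_conv"), f, 3L, st)
      aBN(a, paste0(nm, "_2_bn"))
      aConv(a, paste0(nm, "_3_conv"), 4L * f, 1L, bias = TRUE)
      if (shortcutParams)
        archRow(a, paste0(nm, "_0_conv"), "conv", shortcutParams,
                2 * cinPre * 4 * f * a$H * a$W)
      aNote(a, paste0(nm, "_out"), "add")
    }
  }
  aBN(a, "post_bn")
  archTable(a)
}

archDenseNet201 <- function() {
  a <- newArch()
  aConv(a, "conv1/conv", 64L, 7L, 2L)
  aBN(a, "conv1/bn")
  aPool(a, "pool1", 3L, 2L, pad = "same")
  blocks <- c(6L, 12L, 48L, 32L); growth <- 32L
  for (bi in seq_along(blocks)) {
    for (l in seq_len(blocks[bi])) {
      nm <- sprintf("conv%d_block%d", bi + 1L, l)
      cin <- a$C
      aBN(a, paste0(nm, "_0_bn"))
      a$C <- 4L * growth
      archRow(a, paste0(nm, "_1_conv"), "conv", cin * 4L * growth,
              2 * cin * 4 * growth * a$H * a$W)
      aBN(a, paste0(nm, "_1_bn"))
      a$C <- growth
      archRow(a, paste0(nm, "_2_conv"), "conv", 9L * 4L * growth * growth,
              2 * 9 * 4 * growth * growth * a$H * a$W)
      a$C <- cin + growth
      aNote(a, paste0(nm, "_concat"), "concat")
    }
    if (bi < length(blocks)) {
      nm <- sprintf("pool%d", bi + 1L)
      aBN(a, paste0(nm, "_bn"))
      aConv(a, paste0(nm, "_conv"), a$C %/% 2L, 1L)
      aPool(a, paste0(nm, "_pool"), 2L, 2L, type = "avgpool")
    }
  }
  aBN(a, "bn")
  archTable(a)
}

## conv + BN(scale = FALSE) building block of the inception architecture
iCBN <- function(a, name, cout, kh, kw = kh, stride = 1L, pad = "same") {
  aConv(a, paste0(name, "_conv"), cout, c(kh, kw), stride, pad)
  aBN(a, paste0(name, "_bn"), scale = FALSE)
}

archInceptionV3 <- function() {
  a <- newArch()
  iCBN(a, "c1", 32L, 3L, stride = 2L, pad = "valid")
  iCBN(a, "c2", 32L, 3L, pad = "valid")
  iCBN(a, "c3", 64L, 3L)
  aPool(a, "pool1", 3L, 2L)
  iCBN(a, "c4", 80L, 1L, pad = "valid")
  iCBN(a, "c5", 192L, 3L, pad = "valid")
  aPool(a, "pool2", 3L, 2L)

  inceptionA <- function(a, id, poolC) {
    aBranches(a, paste0("mixed", id),
      function(f) iCBN(f, paste0("m", id, "_1x1"), 64L, 1L),
      function(f) { iCBN(f, paste0("m", id, "_5x5r"), 48L, 1L)
                    iCBN(f, paste0("m", id, "_5x5"), 64L, 5L) },
      function(f) { iCBN(f, paste0("m", id, "_3x3r"), 64L, 1L)
                    iCBN(f, paste0("m", id, "_3x3a"), 96L, 3L)
                    iCBN(f, paste0("m", id, "_3x3b"), 96L, 3L) },
      function(f) { aPool(f, paste0("m", id, "_pool"), 3L, 1L, pad = "same",
                          type = "avgpool")
                    iCBN(f, paste0("m", id, "_poolc"), poolC, 1L) })
  }
  inceptionA(a, 0L, 32L); inceptionA(a, 1L, 64L); inceptionA(a, 2L, 64L)

  ## reduction
  aBranches(a, "mixed3",
    function(f) iCBN(f, "m3_3x3", 384L, 3L, stride = 2L, pad = "valid"),
    function(f) { iCBN(f, "m3_dblr", 64L, 1L)
                  iCBN(f, "m3_dbla", 96L, 3L)
                  iCBN(f, "m3_dblb", 96L, 3L, stride = 2L, pad = "valid") },
    function(f) aPool(f, "m3_pool", 3L, 2L))

  inceptionB <- function(a, id, c7) {
    aBranches(a, paste0("mixed", id),
      function(f) iCBN(f, paste0("m", id, "_1x1"), 192L, 1L),
      function(f) { iCBN(f, paste0("m", id, "_7a"), c7, 1L)
                    iCBN(f, paste0("m", id, "_7b"), c7, 1L, 7L)
                    iCBN(f, paste0("m", id, "_7c"), 192L, 7L, 1L) },
      function(f) { iCBN(f, paste0("m", id, "_d1"), c7, 1L)
                    iCBN(f, paste0("m", id, "_d2"), c7, 7L, 1L)
                    iCBN(f, paste0("m", id, "_d3"), c7, 1L, 7L)
                    iCBN(f, paste0("m", id, "_d4"), c7, 7L, 1L)
                    iCBN(f, paste0("m", id, "_d5"), 192L, 1L, 7L) },
      function(f) { aPool(f, paste0("m", id, "_pool"), 3L, 1L, pad = "same",
                          type = "avgpool")
                    iCBN(f, paste0("m", id, "_poolc"), 192L, 1L) })
  }
  inceptionB(a, 4L, 128L); inceptionB(a, 5L, 160L)
  inceptionB(a, 6L, 160L); inceptionB(a, 7L, 192L)

  aBranches(a, "mixed8",
    function(f) { iCBN(f, "m8_3r", 192L, 1L)
                  iCBN(f, "m8_3", 320L, 3L, stride = 2L, pad = "valid") },
    function(f) { iCBN(f, "m8_7r", 192L, 1L)
                  iCBN(f, "m8_7a", 192L, 1L, 7L)
                  iCBN(f, "m8_7b", 192L, 7L, 1L)
                  iCBN(f, "m8_7c", 192L, 3L, stride = 2L, pad = "valid") },
    function(f) aPool(f, "m8_pool", 3L, 2L))

  inceptionC <- function(a, id) {
    aBranches(a, paste0("mixed", id),
      function(f) iCBN(f, paste0("m", id, "_1x1"), 320L, 1L),
      function(f) { iCBN(f, paste0("m", id, "_3r"), 384L, 1L)
                    aBranches(f, paste0("m", id, "_3split"),
                      function(g) iCBN(g, paste0("m", id, "_3a"), 384L, 1L, 3L),
                      function(g) iCBN(g, paste0("m", id, "_3b"), 384L, 3L, 1L)) },
      function(f) { iCBN(f, paste0("m", id, "_dr"), 448L, 1L)
                    iCBN(f, paste0("m", id, "_d3"), 384L, 3L)
                    aBranches(f, paste0("m", id, "_dsplit"),
                      function(g) iCBN(g, paste0("m", id, "_da"), 384L, 1L, 3L),
                      function(g) iCBN(g, paste0("m", id, "_db"), 384L, 3L, 1L)) },
      function(f) { aPool(f, paste0("m", id, "_pool"), 3L, 1L, pad = "same",
                          type = "avgpool")
                    iCBN(f, paste0("m", id, "_poolc"), 192L, 1L) })
  }
  inceptionC(a, 9L); inceptionC(a, 10L)
  archTable(a)
}

archEfficientNetV2B0 <- function() {
  a <- newArch()
  aConv(a, "stem_conv", 32L, 3L, 2L); aBN(a, "stem_bn")
  ## (kind, expand, kernel, stride, out, repeats, se)
  stages <- list(
    list("fused", 1, 3, 1, 16, 1, 0),
    list("fused", 4, 3, 2, 32, 2, 0),
    list("fused", 4, 3, 2, 48, 2, 0),
    list("mb",    4, 3, 2, 96, 3, 0.25),
    list("mb",    6, 3, 1, 112, 5, 0.25),
    list("mb",    6, 3, 2, 192, 8, 0.25))
  bi <- 1L
  for (s in stages) {
    kind <- s[[1]]; e <- s[[2]]; k <- s[[3]]; stride <- s[[4]]
    cout <- s[[5]]; reps <- s[[6]]; se <- s[[7]]
    for (r in seq_len(reps)) {
      st <- if (r == 1L) stride else 1L
      cin <- a$C
      nm <- sprintf("block%d", bi)
      if (kind == "fused") {
        if (e != 1) {
          aConv(a, paste0(nm, "_expand"), cin * e, k, st)
          aBN(a, paste0(nm, "_expand_bn"))
          aConv(a, paste0(nm, "_project"), cout, 1L)
          aBN(a, paste0(nm, "_project_bn"))
        } else {
          aConv(a, paste0(nm, "_conv"), cout, k, st)
          aBN(a, paste0(nm, "_bn"))
        }
      } else {
        ce <- cin * e
        aConv(a, paste0(nm, "_expand"), ce, 1L)
        aBN(a, paste0(nm, "_expand_bn"))
        aDWConv(a, paste0(nm, "_dw"), k, st)
        aBN(a, paste0(nm, "_dw_bn"))
        if (se > 0) {
          cse <- max(1L, as.integer(cin * se))
          archRow(a, paste0(nm, "_se_reduce"), "conv",
                  ce * cse + cse, 2 * ce * cse)
          archRow(a, paste0(nm, "_se_expand"), "conv",
                  cse * ce + ce, 2 * cse * ce)
        }
        aConv(a, paste0(nm, "_project"), cout, 1L)
        aBN(a, paste0(nm, "_project_bn"))
      }
      bi <- bi + 1L
    }
  }
  aConv(a, "top_conv", 1280L, 1L); aBN(a, "top_bn")
  archTable(a)
}

backboneRegistry <- function() {
  list(vgg19 = archVGG19, mobilenetv2 = archMobileNetV2,
       resnet101v2 = archResNet101V2, densenet201 = archDenseNet201,
       inceptionv3 = archInceptionV3, efficientnetv2b0 = archEfficientNetV2B0)
}

## feature width (channels) at the end of a no-top backbone table
tableOutC <- function(tb) tb$out_c[nrow(tb)]

#' Build a single-backbone patch classifier (symbolic)
#'
#' Adds the 2-class head to a standard backbone: global average pooling
#' followed by a 2-unit softmax dense layer, for every backbone except
#' VGG19, which keeps its two 4096-unit fully connected layers with the
#' final layer replaced by 2 units. These conventions reproduce the
#' published per-model parameter counts.
#'
#' @param backbone one of \code{"vgg19"}, \code{"resnet101v2"},
#'   \code{"mobilenetv2"}, \code{"efficientnetv2b0"}, \code{"inceptionv3"},
#'   \code{"densenet201"}.
#' @return a symbolic [WsiNetwork-class] (use [paramCount()],
#'   [flopsCount()], [complexityReport()]).
#' @examples
#' round(paramCount(pwcBaseline("mobilenetv2")) / 1e6, 2)  # 2.26
#' @export
pwcBaseline <- function(backbone) {
  reg <- backboneRegistry()
  backbone <- tolower(backbone)
  if (!backbone %in% names(reg))
    stop("unknown backbone '", backbone, "'; valid: ",
         paste(names(reg), collapse = ", "))
  a <- newArch()
  tb <- reg[[backbone]]()
  a$rows <- split(tb, seq_len(nrow(tb)))
  a$H <- tb$out_h[nrow(tb)]; a$W <- tb$out_w[nrow(tb)]
  a$C <- tableOutC(tb)
  if (backbone == "vgg19") {
    a$C <- as.integer(a$H * a$W * a$C); a$H <- 1L; a$W <- 1L
    aNote(a, "flatten", "flatten")
    aDense(a, "fc1", 4096L)
    aDense(a, "fc2", 4096L)
    aDense(a, "predictions", 2L)
  } else {
    aGAP(a)
    aDense(a, "predictions", 2L)
  }
  aNote(a, "softmax", "softmax")
  new("WsiNetwork", name = backbone, kind = "symbolic",
      layers = archTable(a), params = list(), state = list(),
      config = list(backbone = backbone, head = "gap_dense2"))
}

## truncate a backbone layer table at a named layer (inclusive)
truncateArch <- function(tb, at) {
  i <- match(at, tb$layer)
  if (is.na(i))
    stop("unknown truncation layer '", at, "'; valid names include: ",
         paste(tail(tb$layer, 25), collapse = ", "))
  tb[seq_len(i), , drop = FALSE]
}

#' Build the fused dual-backbone patch classifier (symbolic)
#'
#' Both truncated backbones consume the identical 224x224x3 input in
#' parallel; each branch ends with global average pooling, the pooled
#' features are concatenated, and a single 2-unit softmax dense layer forms
#' the head. The published truncation points were chosen by an empirical
#' search and never stated, so they are exposed as configuration; the
#' defaults cut the dense backbone at the end of its third dense block and
#' the residual backbone at the end of its second stage, which keeps the
#' fused feature extractor under 14 M parameters.
#'
#' @param truncA named layer at which to cut the DenseNet-style branch
#'   (default \code{"conv4_block48_concat"}, 1792 channels).
#' @param truncB named layer at which to cut the ResNet-style branch
#'   (default \code{"conv3_block4_out"}, 512 channels).
#' @return a symbolic [WsiNetwork-class].
#' @export
pwcFused <- function(truncA = "conv4_block48_concat",
                     truncB = "conv3_block4_out") {
  ta <- truncateArch(archDenseNet201(), truncA)
  tb <- truncateArch(archResNet101V2(), truncB)
  a <- newArch()
  a$rows <- c(split(ta, seq_len(nrow(ta))), split(tb, seq_len(nrow(tb))))
  cA <- tableOutC(ta); cB <- tableOutC(tb)
  a$H <- 1L; a$W <- 1L
  a$C <- as.integer(cA + cB)
  aNote(a, "gap_concat", "concat")
  aDense(a, "predictions", 2L)
  aNote(a, "softmax", "softmax")
  new("WsiNetwork", name = "fused-pwc", kind = "symbolic",
      layers = archTable(a), params = list(), state = list(),
      config = list(truncA = truncA, truncB = truncB,
                    branchWidths = c(cA, cB)))
}

## ---------------------------------------------------------------------------
## Refinement U-Net enumeration (shared by the symbolic and trainable builds)
## ---------------------------------------------------------------------------

unetLayerTable <- function(inputSize = 1120L, depth = 5L,
                           filters = c(8L, 16L, 32L, 64L, 128L),
                           inCh = 4L, topSkip = FALSE) {
  if (length(filters) != depth) stop("filters must have one entry per level")
  if (inputSize %% 2^depth != 0L)
    stop("inputSize must be divisible by 2^depth")
  a <- newArch(as.integer(inputSize), as.integer(inputSize), as.integer(inCh))
  convBlock <- function(nm, cout) {
    aConv(a, paste0(nm, "_conv1"), cout, 3L); aBN(a, paste0(nm, "_bn1"))
    aConv(a, paste0(nm, "_conv2"), cout, 3L); aBN(a, paste0(nm, "_bn2"))
  }
  for (i in seq_len(depth - 1L)) {
    convBlock(sprintf("enc%d", i), filters[i])
    aPool(a, sprintf("pool%d", i), 2L)
  }
  convBlock("bottleneck", filters[depth])
  for (i in rev(seq_len(depth - 1L))) {
    a$H <- a$H * 2L; a$W <- a$W * 2L
    aNote(a, sprintf("up%d", i), "upsample")
    skip <- if (i == 1L) topSkip else TRUE
    if (skip) {
      a$C <- as.integer(a$C + filters[i])
      aNote(a, sprintf("skip%d", i), "concat")
    }
    convBlock(sprintf("dec%d", i), filters[i])
  }
  aConv(a, "head", 2L, 1L, bias = TRUE)
  aNote(a, "softmax", "softmax")
  archTable(a)
}

#' Build the lightweight refinement U-Net (symbolic)
#'
#' A small U-Net that consumes the 4-channel concatenation of a down-sampled
#' RGB slide and the stitched heatmap and emits a 2-channel per-pixel
#' softmax. Blocks are conv(3x3)+BN+ReLU pairs; down-sampling is 2x2 max
#' pooling, up-sampling nearest-neighbour. The top-most skip connection is
#' removed by default (an ablation hook: re-enable with \code{topSkip =
#' TRUE}); this was found to reduce small fragments around the segmentation
#' perimeter.
#'
#' @param inputSize input edge in pixels, divisible by \code{2^depth}
#'   (default 1120).
#' @param depth number of resolution levels (default 5).
#' @param filters filters per level (default \code{c(8,16,32,64,128)}: the
#'   "lightweight" contract, under 2 M parameters).
#' @param inCh input channels (default 4).
#' @param topSkip keep the top-most skip connection (default FALSE).
#' @return a symbolic [WsiNetwork-class].
#' @export
refinementUNet <- function(inputSize = 1120L, depth = 5L,
                           filters = c(8L, 16L, 32L, 64L, 128L), inCh = 4L,
                           topSkip = FALSE) {
  tb <- unetLayerTable(inputSize, depth, filters, inCh, topSkip)
  new("WsiNetwork", name = "refinement-unet", kind = "symbolic",
      layers = tb, params = list(), state = list(),
      config = list(inputSize = as.integer(inputSize), depth = as.integer(depth),
                    filters = as.integer(filters), inCh = as.integer(inCh),
                    topSkip = topSkip))
}
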