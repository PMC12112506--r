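#' Profile model complexity against a baseline
#'
#' Parameters are counted exactly (every weight, including non-trainable
#' normalization statistics); FLOPs are estimated for one forward pass of a
#' 224x224x3 input with multiplies and adds counted separately (2 x
#' multiply-accumulates). Relative deltas are computed from the unrounded
#' counts:
#' \deqn{\Delta(\%) = (x_{model} - x_{baseline}) / x_{baseline} \times 100.}
#'
#' @param model a [WsiNetwork-class].
#' @param baseline a [WsiNetwork-class] (conventionally the lightest
#'   backbone under comparison, here MobileNetV2).
#' @return a [ComplexityReport-class].
#' @examples
#' complexityReport(pwcBaseline("densenet201"), pwcBaseline("mobilenetv2"))
#' @export
complexityReport <- function(model, baseline) {
  stopifnot(is(model, "WsiNetwork"), is(baseline, "WsiNetwork"))
  pm <- paramCount(model); pb <- paramCount(baseline)
  fm <- flopsCount(model); fb <- flopsCount(baseline)
  new("ComplexityReport", modelName = model@name,
      baselineName = baseline@name,
      flopsModel = fm, flopsBaseline = fb,
      paramsModel = pm, paramsBaseline = pb,
      deltaFlopsPct = (fm - fb) / fb * 100,
      deltaParamsPct = (pm - pb) / pb * 100)
}

#' Complexity table over the standard backbones
#'
#' One row per backbone classifier (and optionally the fused model), in
#' millions, with deltas relative to the chosen baseline.
#'
#' @param models character vector of backbone names (default all six).
#' @param baseline baseline backbone name (default "mobilenetv2").
#' @param includeFused include the fused dual-backbone classifier row.
#' @return data.frame with \code{model, flops_M, params_M, delta_flops_pct,
#'   delta_params_pct}.
#' @export
complexityTable <- function(models = c("vgg19", "resnet101v2", "mobilenetv2",
                                       "efficientnetv2b0", "inceptionv3",
                                       "densenet201"),
                            baseline = "mobilenetv2", includeFused = TRUE) {
  base <- pwcBaseline(baseline)
  nets <- lapply(models, pwcBaseline)
  if (includeFused) nets <- c(list(pwcFused()), nets)
  rows <- lapply(nets, function(m) {
    r <- complexityReport(m, base)
    data.frame(model = r@modelName, flops_M = r@flopsModel / 1e6,
               params_M = r@paramsModel / 1e6,
               delta_flops_pct = r@deltaFlopsPct,
               delta_params_pct = r@deltaParamsPct)
  })
  do.call(rbind, rows)
}
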