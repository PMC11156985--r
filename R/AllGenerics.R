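#' Gelman-Rubin potential scale reduction factor
#'
#' @param object chains: a numeric matrix (iterations x chains), a list of
#'   equal-length numeric vectors, or a [PrevalenceFit-class].
#' @param ... further arguments passed to methods.
#' @return The potential scale reduction factor (a scalar for a single
#'   quantity; a named vector for a fit).
#' @export
setGeneric("gelmanRubin", function(object, ...) standardGeneric("gelmanRubin"))

#' Summarise a posterior sample
#'
#' @param object a [PrevalenceFit-class] (or a plain draws matrix/list in
#'   other methods).
#' @param ... further arguments passed to methods.
#' @export
setGeneric("summarizePosterior",
           function(object, ...) standardGeneric("summarizePosterior"))

#' Pooled posterior draws of the orchard-level prevalence
#'
#' @param object a [PrevalenceFit-class].
#' @param ... further arguments passed to methods.
#' @export
setGeneric("orchardPrevalence",
           function(object, ...) standardGeneric("orchardPrevalence"))

#' Export posterior draws to CSV
#'
#' @param object a [PrevalenceFit-class].
#' @param path output CSV path.
#' @param ... further arguments passed to methods.
#' @export
setGeneric("exportChains",
           function(object, path, ...) standardGeneric("exportChains"))

#' @describeIn PriorSpec-class compact display
#' @param object a `PriorSpec`.
#' @export
setMethod("show", "PriorSpec", function(object) {
  cat("PriorSpec\n")
  cat(sprintf("  lambda ~ U(%g, %g)\n", object@lambdaLower, object@lambdaUpper))
  cat(sprintf("  tau    ~ U(%g, %g)\n", object@tauLower, object@tauUpper))
  cat(sprintf("  pi     ~ Beta(%g, %g)\n", object@piAlpha, object@piBeta))
  cat(sprintf("  delta  ~ Beta(%g, %g)\n", object@deltaAlpha, object@deltaBeta))
  cat(sprintf("  1/sigma ~ U(%g, %g)\n",
              object@invSigmaLower, object@invSigmaUpper))
})

#' @describeIn OrchardDesign-class compact display
#' @param object an `OrchardDesign`.
#' @export
setMethod("show", "OrchardDesign", function(object) {
  cat(sprintf(
    "OrchardDesign: %d block(s), %g fruit/block, n = %g per sample\n",
    object@B, object@N, object@n))
  cat("  traps/block D:", paste(object@D, collapse = " "), "\n")
  cat("  consignments/block C:", paste(object@C, collapse = " "), "\n")
})

#' @describeIn SurveillanceData-class compact display
#' @param object a `SurveillanceData`.
#' @export
setMethod("show", "SurveillanceData", function(object) {
  cat(sprintf("SurveillanceData over %d block(s)\n", length(object@x)))
  cat("  trap catches x:", paste(object@x, collapse = " "), "\n")
  cat("  detections  y:", paste(object@y, collapse = " "), "\n")
})

#' @describeIn BetaParams-class compact display
#' @param object a `BetaParams`.
#' @export
setMethod("show", "BetaParams", function(object) {
  cat(sprintf("Beta(%g, %g): mean %.6g, cv %.6g\n", object@alpha,
              object@beta, betaMean(object), betaCV(object)))
})

#' @describeIn PrevalenceFit-class compact display
#' @param object a `PrevalenceFit`.
#' @export
setMethod("show", "PrevalenceFit", function(object) {
  s <- object@settings
  cat(sprintf(
    "PrevalenceFit: %d chain(s) x %d draws, %d block(s)%s\n",
    s@chains, s@iterations %/% s@thin, object@design@B,
    if (object@blockEffects) ", block random effects" else ""))
  op <- orchardPrevalence(object)
  cat(sprintf("  orchard prevalence: mean %.3g, q95 %.3g\n",
              mean(op), stats::quantile(op, 0.95, names = FALSE)))
})

#' @describeIn SimulatedDataset-class compact display
#' @param object a `SimulatedDataset`.
#' @export
setMethod("show", "SimulatedDataset", function(object) {
  cat(sprintf(
    "SimulatedDataset: %d block(s), pest intensity %g, lambda_O %.3g\n",
    object@design@B, object@pestIntensity, object@lambdaO))
  cat(sprintf("  orchard-mean true prevalence: %.4g\n",
              object@orchardPrevalence))
})

#' @describeIn ScenarioConfig-class compact display
#' @param object a `ScenarioConfig`.
#' @export
setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf("ScenarioConfig \"%s\": B = %d, all data %s\n", object@name,
              object@design@B,
              if (all(object@data@x == 0L) && all(object@data@y == 0L))
                "zero" else "observed"))
})

#' Mean of a Beta distribution
#' @param params a [BetaParams-class].
#' @return `alpha / (alpha + beta)`.
#' @export
betaMean <- function(params) params@alpha / (params@alpha + params@beta)

#' Coefficient of variation of a Beta distribution
#' @param params a [BetaParams-class].
#' @return standard deviation divided by the mean.
#' @export
betaCV <- function(params) {
  a <- params@alpha; b <- params@beta
  sqrt(b / (a * (a + b + 1)))
}

#' Quantile of a Beta distribution
#' @param params a [BetaParams-class].
#' @param p probability level(s).
#' @return the quantile(s), via the regularised incomplete Beta inverse.
#' @export
betaQuantile <- function(params, p) stats::qbeta(p, params@alpha, params@beta)

#' @describeIn PrevalenceFit-class the fitted design
#' @param object a `PrevalenceFit`.
#' @export
orchardDesign <- function(object) object@design

#' @describeIn PrevalenceFit-class the priors used
#' @export
priorSpec <- function(object) object@priors

#' @describeIn PrevalenceFit-class the per-chain draws as a
#'   [coda::mcmc.list]
#' @export
posteriorDraws <- function(object) object@draws
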