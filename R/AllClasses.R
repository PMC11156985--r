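#' @import methods
NULL

## Named prior levels used throughout scenario work. Trap encounter rates
## come as "low"/"high" uniform ranges; inspection sensitivity as
## low/medium/high informative Beta distributions (means 10%, 50%, 90%).
.tau_levels <- list(
  low  = c(0.0075, 0.0125),
  high = c(0.075, 0.125)
)

.delta_levels <- list(
  low    = c(10, 90),
  medium = c(50, 50),
  high   = c(90, 10)
)

## new() with Class passed by exact name: a slot called "C" would otherwise
## partially match new()'s first formal argument `Class`.
.newS4 <- function(.Class, ...) methods::new(Class = .Class, ...)

#' Prior hyperparameters for the hierarchical prevalence model
#'
#' Holds the hyperparameters of the priors on the mean number of fruit
#' infested per pest (\eqn{\lambda}, uniform), the areal trap encounter rate
#' per season (\eqn{\tau}, uniform), the overall prevalence of infested
#' fruit (\eqn{\pi}, Beta), the per-fruit consignment inspection sensitivity
#' (\eqn{\delta}, Beta), and the reciprocal of the block random-effect
#' standard deviation (\eqn{1/\sigma}, uniform). Note the prior is on
#' \eqn{1/\sigma} itself, not on the precision \eqn{1/\sigma^2}; the default
#' \eqn{1/\sigma \sim U(0,1)} keeps the implicit prior on block-level
#' prevalence close to flat.
#'
#' @slot lambdaLower,lambdaUpper numeric, uniform bounds for \eqn{\lambda}
#'   (fruit infested per pest).
#' @slot tauLower,tauUpper numeric, uniform bounds for \eqn{\tau}
#'   (effective area per trap per season).
#' @slot piAlpha,piBeta numeric, Beta shape parameters for \eqn{\pi}.
#' @slot deltaAlpha,deltaBeta numeric, Beta shape parameters for
#'   \eqn{\delta}.
#' @slot invSigmaLower,invSigmaUpper numeric, uniform bounds for
#'   \eqn{1/\sigma}.
#' @seealso [PriorSpec()] for the user-facing constructor with named
#'   sensitivity and encounter-rate levels.
#' @export
setClass("PriorSpec", representation(
  lambdaLower = "numeric", lambdaUpper = "numeric",
  tauLower = "numeric", tauUpper = "numeric",
  piAlpha = "numeric", piBeta = "numeric",
  deltaAlpha = "numeric", deltaBeta = "numeric",
  invSigmaLower = "numeric", invSigmaUpper = "numeric"
))

setValidity("PriorSpec", function(object) {
  sc <- function(x) length(x) == 1L && is.finite(x)
  all_scalar <- all(vapply(
    list(object@lambdaLower, object@lambdaUpper, object@tauLower,
         object@tauUpper, object@piAlpha, object@piBeta, object@deltaAlpha,
         object@deltaBeta, object@invSigmaLower, object@invSigmaUpper),
    sc, logical(1)))
  if (!all_scalar)
    return("all hyperparameters must be finite scalars")
  msgs <- character(0)
  if (object@lambdaLower < 0 || object@tauLower < 0 ||
      object@invSigmaLower < 0)
    msgs <- c(msgs, "lower bounds must be non-negative")
  if (object@lambdaLower >= object@lambdaUpper)
    msgs <- c(msgs, "lambdaLower must be < lambdaUpper")
  if (object@tauLower >= object@tauUpper)
    msgs <- c(msgs, "tauLower must be < tauUpper")
  if (object@invSigmaLower >= object@invSigmaUpper)
    msgs <- c(msgs, "invSigmaLower must be < invSigmaUpper")
  if (object@piAlpha <= 0 || object@piBeta <= 0)
    msgs <- c(msgs, "Beta shapes for pi must be > 0")
  if (object@deltaAlpha <= 0 || object@deltaBeta <= 0)
    msgs <- c(msgs, "Beta shapes for delta must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PriorSpec
#'
#' Defaults reproduce the illustrative priors of the source production-system
#' model: \eqn{\lambda \sim U(20, 30)}, \eqn{\pi \sim Beta(1, 1)},
#' \eqn{1/\sigma \sim U(0, 1)}, with named levels for the trap encounter
#' rate (`tau = "low"` gives \eqn{U(0.0075, 0.0125)}, `"high"` gives
#' \eqn{U(0.075, 0.125)}) and the inspection sensitivity (`delta = "low"`
#' Beta(10, 90), `"medium"` Beta(50, 50), `"high"` Beta(90, 10)). Numeric
#' values may be given instead of level names: `tau = c(lower, upper)` and
#' `delta = c(alpha, beta)`.
#'
#' @param tau character level (`"low"`/`"high"`) or numeric `c(lower, upper)`.
#' @param delta character level (`"low"`/`"medium"`/`"high"`) or numeric
#'   `c(alpha, beta)`.
#' @param lambda numeric `c(lower, upper)` uniform bounds for the mean
#'   number of fruit infested per pest.
#' @param pi numeric `c(alpha, beta)` Beta shapes for overall prevalence.
#' @param invSigma numeric `c(lower, upper)` uniform bounds for
#'   \eqn{1/\sigma}.
#' @return A [PriorSpec-class] object.
#' @examples
#' PriorSpec()                       # tau low, delta medium
#' PriorSpec(tau = "high", delta = "high")
#' PriorSpec(tau = c(0.0075, 0.015)) # explicit bounds
#' @export
PriorSpec <- function(tau = "low", delta = "medium",
                      lambda = c(20, 30), pi = c(1, 1),
                      invSigma = c(0, 1)) {
  if (is.character(tau))
    tau <- .tau_levels[[match.arg(tau, names(.tau_levels))]]
  if (is.character(delta))
    delta <- .delta_levels[[match.arg(delta, names(.delta_levels))]]
  new("PriorSpec",
      lambdaLower = lambda[1], lambdaUpper = lambda[2],
      tauLower = tau[1], tauUpper = tau[2],
      piAlpha = pi[1], piBeta = pi[2],
      deltaAlpha = delta[1], deltaBeta = delta[2],
      invSigmaLower = invSigma[1], invSigmaUpper = invSigma[2])
}

#' Orchard design: blocks, fruit, traps and consignment sampling effort
#'
#' @slot B integer, number of production blocks.
#' @slot N numeric, number of fruit per block (assumed constant).
#' @slot D numeric length-`B`, density of traps per block (traps per unit
#'   area over the season of fruit vulnerability).
#' @slot C numeric length-`B`, number of consignment samples inspected per
#'   block.
#' @slot n numeric, pieces of fruit per consignment sample (industry
#'   standard 600).
#' @export
setClass("OrchardDesign", representation(
  B = "integer", N = "numeric", D = "numeric", C = "numeric", n = "numeric"
))

setValidity("OrchardDesign", function(object) {
  msgs <- character(0)
  if (length(object@B) != 1L || object@B < 1L)
    msgs <- c(msgs, "B must be a single count >= 1")
  if (length(object@N) != 1L || !is.finite(object@N) || object@N < 1)
    msgs <- c(msgs, "N must be a single count >= 1")
  if (length(object@n) != 1L || !is.finite(object@n) || object@n < 1)
    msgs <- c(msgs, "n must be a single count >= 1")
  if (length(object@D) != object@B || any(!is.finite(object@D)) ||
      any(object@D < 0))
    msgs <- c(msgs, "D must be length B with D_i >= 0")
  if (length(object@C) != object@B || any(!is.finite(object@C)) ||
      any(object@C < 0))
    msgs <- c(msgs, "C must be length B with C_i >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct an OrchardDesign
#'
#' @param B number of production blocks.
#' @param N fruit per block; the default \eqn{10 \times 10^6} is indicative
#'   of a cherry production block.
#' @param D trap density per block; a scalar is recycled to all blocks.
#' @param C consignment samples per block; a scalar is recycled.
#' @param n pieces per consignment sample (default 600).
#' @return An [OrchardDesign-class] object.
#' @examples
#' OrchardDesign(B = 10, D = 5, C = 10)
#' @export
OrchardDesign <- function(B = 1L, N = 10e6, D = 0, C = 0, n = 600) {
  B <- as.integer(B)
  .newS4("OrchardDesign", B = B, N = as.numeric(N),
         D = rep_len(as.numeric(D), B), C = rep_len(as.numeric(C), B),
         n = as.numeric(n))
}

#' Observed surveillance and inspection counts
#'
#' Per-block observations: `x` the number of pests caught in traps over the
#' season, `y` the number of infested fruit found across all consignment
#' samples inspected from the block.
#'
#' @slot x integer vector, trap catches per block.
#' @slot y integer vector, infested-fruit detections per block (summed over
#'   its consignment samples).
#' @export
setClass("SurveillanceData", representation(x = "integer", y = "integer"))

setValidity("SurveillanceData", function(object) {
  msgs <- character(0)
  if (length(object@x) != length(object@y))
    msgs <- c(msgs, "x and y must have equal length")
  if (any(is.na(object@x)) || any(object@x < 0L))
    msgs <- c(msgs, "x must be non-negative integers")
  if (any(is.na(object@y)) || any(object@y < 0L))
    msgs <- c(msgs, "y must be non-negative integers")
  if (length(msgs)) msgs else TRUE
})

#' Construct SurveillanceData
#'
#' @param x trap catches per block (non-negative integers).
#' @param y infested-fruit detections per block (non-negative integers).
#' @return A [SurveillanceData-class] object.
#' @examples
#' SurveillanceData(x = c(0, 1), y = c(0, 0))
#' @export
SurveillanceData <- function(x, y) {
  new("SurveillanceData", x = as.integer(x), y = as.integer(y))
}

#' All-zero observations for a design
#'
#' The operational "clean" scenario: no pests caught in any trap and no
#' infested fruit found in any consignment sample.
#'
#' @param design an [OrchardDesign-class].
#' @return A [SurveillanceData-class] with `x = y = 0` for every block.
#' @export
allZeroData <- function(design) {
  stopifnot(is(design, "OrchardDesign"))
  SurveillanceData(x = rep(0L, design@B), y = rep(0L, design@B))
}

#' Check that observations are consistent with a design
#'
#' Enforces the cross-invariants that cannot be checked by either class
#' alone: equal block counts, `y_i <= n * C_i`, and `x_i = 0` wherever the
#' block has no traps.
#'
#' @param data a [SurveillanceData-class].
#' @param design an [OrchardDesign-class].
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validateData <- function(data, design) {
  stopifnot(is(data, "SurveillanceData"), is(design, "OrchardDesign"))
  if (length(data@x) != design@B)
    stop("data has ", length(data@x), " blocks but design has ", design@B)
  if (any(data@y > design@n * design@C))
    stop("y_i exceeds the number of fruit inspected (n * C_i) in some block")
  if (any(data@x > 0L & design@D == 0))
    stop("x_i > 0 in a block with no traps (D_i = 0)")
  invisible(TRUE)
}

#' MCMC sampler settings
#'
#' @slot chains integer, number of chains (>= 2 so the Gelman-Rubin
#'   diagnostic is defined).
#' @slot iterations integer, post burn-in iterations per chain.
#' @slot burnin integer, burn-in iterations discarded per chain.
#' @slot thin integer, thinning interval.
#' @slot seed integer, master seed controlling initial values and the
#'   per-chain RNG streams; identical settings reproduce identical draws.
#' @export
setClass("McmcSettings", representation(
  chains = "integer", iterations = "integer", burnin = "integer",
  thin = "integer", seed = "integer"
))

setValidity("McmcSettings", function(object) {
  msgs <- character(0)
  if (object@chains < 2L)
    msgs <- c(msgs, "at least 2 chains are required")
  if (object@iterations < 1L) msgs <- c(msgs, "iterations must be >= 1")
  if (object@burnin < 0L) msgs <- c(msgs, "burnin must be >= 0")
  if (object@thin < 1L) msgs <- c(msgs, "thin must be >= 1")
  if (is.na(object@seed)) msgs <- c(msgs, "seed must be an integer")
  if (length(msgs)) msgs else TRUE
})

#' Construct McmcSettings
#'
#' Defaults follow the reference analysis: 3 chains of 100,000 iterations
#' each after burn-in. Scale `iterations` down for exploratory work; the
#' scenario quantiles of interest are stable well below the default.
#'
#' @param chains number of chains (>= 2).
#' @param iterations post burn-in iterations per chain.
#' @param burnin burn-in iterations.
#' @param thin thinning interval.
#' @param seed integer master seed.
#' @return An [McmcSettings-class] object.
#' @export
McmcSettings <- function(chains = 3, iterations = 100000, burnin = 10000,
                         thin = 1, seed = 1) {
  new("McmcSettings", chains = as.integer(chains),
      iterations = as.integer(iterations), burnin = as.integer(burnin),
      thin = as.integer(thin), seed = as.integer(seed))
}

#' A point in the latent-parameter space of the hierarchical model
#'
#' Used by [logJoint()] to evaluate the unnormalised posterior log-density.
#' Structural consistency (vector lengths) is enforced here; values outside
#' the parameter support are permitted and make [logJoint()] return `-Inf`.
#'
#' @slot pi numeric, overall prevalence.
#' @slot V numeric length-`B`, block random effects on the logit scale.
#' @slot sigma numeric, random-effect standard deviation.
#' @slot lambda numeric, mean number of fruit infested per pest.
#' @slot O numeric length-`B`, fruit infested per pest in each block
#'   (positive integers when inside the support).
#' @slot tau numeric, areal trap encounter rate per season.
#' @slot delta numeric, per-fruit inspection sensitivity.
#' @export
setClass("LatentState", representation(
  pi = "numeric", V = "numeric", sigma = "numeric", lambda = "numeric",
  O = "numeric", tau = "numeric", delta = "numeric"
))

setValidity("LatentState", function(object) {
  msgs <- character(0)
  if (length(object@V) != length(object@O))
    msgs <- c(msgs, "V and O must have the same length (one per block)")
  for (nm in c("pi", "sigma", "lambda", "tau", "delta"))
    if (length(slot(object, nm)) != 1L)
      msgs <- c(msgs, paste(nm, "must be a scalar"))
  if (length(msgs)) msgs else TRUE
})

#' Construct a LatentState
#'
#' @param pi overall prevalence.
#' @param V block random effects (logit scale), length `B`.
#' @param sigma random-effect standard deviation.
#' @param lambda mean fruit infested per pest.
#' @param O fruit infested per pest, per block, length `B`.
#' @param tau areal trap encounter rate.
#' @param delta inspection sensitivity.
#' @return A [LatentState-class] object.
#' @export
LatentState <- function(pi, V, sigma, lambda, O, tau, delta) {
  new("LatentState", pi = pi, V = as.numeric(V), sigma = sigma,
      lambda = lambda, O = as.numeric(O), tau = tau, delta = delta)
}

#' Beta distribution parameters
#'
#' @slot alpha,beta numeric shape parameters, both strictly positive.
#' @export
setClass("BetaParams", representation(alpha = "numeric", beta = "numeric"))

setValidity("BetaParams", function(object) {
  if (length(object@alpha) != 1L || length(object@beta) != 1L)
    return("alpha and beta must be scalars")
  if (!is.finite(object@alpha) || object@alpha <= 0 ||
      !is.finite(object@beta) || object@beta <= 0)
    return("alpha and beta must be finite and > 0")
  TRUE
})

#' Construct BetaParams
#'
#' @param alpha,beta shape parameters (> 0).
#' @return A [BetaParams-class] object.
#' @export
BetaParams <- function(alpha, beta) new("BetaParams", alpha = alpha, beta = beta)

#' Posterior sample from the hierarchical prevalence model
#'
#' Container returned by [samplePosterior()]: the per-chain draws of the
#' monitored quantities together with the design, priors and sampler
#' settings that produced them.
#'
#' @slot draws a [coda::mcmc.list] with one [coda::mcmc] matrix per chain;
#'   columns are the monitored quantities (`pi`, `lambda`, `tau`, `delta`
#'   unless fixed, `sigma` when block effects are active, and `pi_i[b]`).
#' @slot design the [OrchardDesign-class] fitted.
#' @slot priors the [PriorSpec-class] used.
#' @slot data the [SurveillanceData-class] fitted.
#' @slot settings the [McmcSettings-class] used.
#' @slot blockEffects logical, whether the logit-normal block random-effect
#'   layer was included.
#' @slot fixedDelta numeric, the value delta was fixed at (`NA` when delta
#'   was sampled from its Beta prior).
#' @slot fixedSigma numeric, the value sigma was fixed at (`NA` when
#'   1/sigma was sampled from its uniform prior).
#' @slot multipleDetections logical, whether the multiple-detection trap
#'   likelihood (rate \eqn{P_i \tau D_i}) was used instead of the
#'   single-capture form.
#' @export
setClass("PrevalenceFit", representation(
  draws = "ANY", design = "OrchardDesign", priors = "PriorSpec",
  data = "SurveillanceData", settings = "McmcSettings",
  blockEffects = "logical", fixedDelta = "numeric", fixedSigma = "numeric",
  multipleDetections = "logical"
))

#' Simulated validation dataset with known truth
#'
#' Produced by [generateDataset()] under the gamma-Poisson generator, which
#' is deliberately a different formulation from the fitted hierarchical
#' model: pest counts are Poisson, per-pest fecundity is a single
#' gamma-distributed intensity, and the observation draws are exact
#' Binomials rather than the model's Poisson approximations.
#'
#' @slot pests integer length-`B`, true pests per block.
#' @slot lambdaO numeric, the realised gamma-distributed Poisson intensity
#'   for fruit infested per pest (one draw per dataset).
#' @slot infested integer length-`B`, true infested fruit per block.
#' @slot prevalence numeric length-`B`, true prevalence per block.
#' @slot orchardPrevalence numeric, mean true prevalence over all blocks.
#' @slot data the generated [SurveillanceData-class] observations.
#' @slot design the [OrchardDesign-class] used.
#' @slot pestIntensity numeric, the Poisson intensity of pests per block.
#' @slot deltaTrue,tauTrue numeric, the sensitivity and encounter rate used
#'   for the observation draws.
#' @slot seed integer, the seed that reproduces the dataset.
#' @export
setClass("SimulatedDataset", representation(
  pests = "integer", lambdaO = "numeric", infested = "integer",
  prevalence = "numeric", orchardPrevalence = "numeric",
  data = "SurveillanceData", design = "OrchardDesign",
  pestIntensity = "numeric", deltaTrue = "numeric", tauTrue = "numeric",
  seed = "integer"
))

setValidity("SimulatedDataset", function(object) {
  B <- object@design@B
  msgs <- character(0)
  if (length(object@pests) != B || length(object@infested) != B ||
      length(object@prevalence) != B)
    msgs <- c(msgs, "truth vectors must have length B")
  if (any(object@prevalence < 0) || any(object@prevalence > 1))
    msgs <- c(msgs, "prevalence must lie in [0, 1]")
  if (any(object@data@x > object@pests))
    msgs <- c(msgs, "trap catches cannot exceed the number of pests")
  if (any(object@data@y > object@design@n * object@design@C))
    msgs <- c(msgs, "detections cannot exceed fruit inspected")
  if (length(msgs)) msgs else TRUE
})

#' A named scenario: design, priors, data mode and sampler settings
#'
#' @slot name character scenario identifier (used in output tables).
#' @slot design an [OrchardDesign-class].
#' @slot priors a [PriorSpec-class].
#' @slot data a [SurveillanceData-class]; [ScenarioConfig()] fills in
#'   all-zero observations when none are supplied.
#' @slot settings an [McmcSettings-class].
#' @slot blockEffects character, `"auto"`, `"on"` or `"off"` (see
#'   [samplePosterior()]).
#' @slot multipleDetections logical, trap-likelihood variant flag.
#' @export
setClass("ScenarioConfig", representation(
  name = "character", design = "OrchardDesign", priors = "PriorSpec",
  data = "SurveillanceData", settings = "McmcSettings",
  blockEffects = "character", multipleDetections = "logical"
))

#' Construct a ScenarioConfig
#'
#' @param name scenario identifier.
#' @param design an [OrchardDesign-class].
#' @param priors a [PriorSpec-class].
#' @param data observations; `NULL` (default) means the operational
#'   all-zero "clean" data mode.
#' @param settings an [McmcSettings-class].
#' @param blockEffects `"auto"`, `"on"` or `"off"`.
#' @param multipleDetections use the multiple-detection trap likelihood.
#' @return A [ScenarioConfig-class] object.
#' @export
ScenarioConfig <- function(name, design, priors = PriorSpec(), data = NULL,
                           settings = McmcSettings(),
                           blockEffects = "auto",
                           multipleDetections = FALSE) {
  if (is.null(data)) data <- allZeroData(design)
  validateData(data, design)
  new("ScenarioConfig", name = as.character(name), design = design,
      priors = priors, data = data, settings = settings,
      blockEffects = match.arg(blockEffects, c("auto", "on", "off")),
      multipleDetections = isTRUE(multipleDetections))
}
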