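#' Probability that an individual pest is captured by in-field traps
#'
#' Over the season in which fruit are vulnerable to infestation, a pest in a
#' block with trap density `D` encounters (and is caught by) a trap with
#' probability \eqn{p(c) = 1 - \exp(-\tau D)}, where \eqn{\tau} is the
#' effective area searched per trap per season.
#'
#' @param tau areal encounter rate per season (>= 0).
#' @param D trap density (traps per unit area, >= 0).
#' @return The capture probability in `[0, 1)`; 0 exactly when
#'   `tau * D == 0`. Vectorised over both arguments.
#' @seealso [estimateTau()], the inverse transformation.
#' @examples
#' captureProbability(0.1, 10)   # 1 - exp(-1)
#' @export
captureProbability <- function(tau, D) {
  if (any(tau < 0) || any(D < 0))
    stop("tau and D must be non-negative")
  -expm1(-tau * D)
}

#' Poisson rate for infested-fruit detections in consignment samples
#'
#' The number of infested fruit detected across `C` consignment samples of
#' size `n`, inspected with per-fruit sensitivity `delta` from a block with
#' prevalence `piBlock`, is well approximated as Poisson with rate
#' \eqn{\mu = \delta n C \pi}. The approximation (Poisson limit of the
#' Binomial for `n * C` large relative to \eqn{\delta\pi}) is conservative.
#'
#' @param delta per-fruit inspection sensitivity in `[0, 1]`.
#' @param n pieces per consignment sample (>= 0).
#' @param C number of consignment samples (>= 0).
#' @param piBlock block prevalence in `[0, 1]`.
#' @return The detection rate \eqn{\delta n C \pi}, linear in each argument.
#' @examples
#' consignmentDetectionRate(0.9, 600, 100, 1e-4)  # 5.4
#' @export
consignmentDetectionRate <- function(delta, n, C, piBlock) {
  if (any(delta < 0) || any(delta > 1))
    stop("delta must lie in [0, 1]")
  if (any(piBlock < 0) || any(piBlock > 1))
    stop("piBlock must lie in [0, 1]")
  if (any(n < 0) || any(C < 0))
    stop("n and C must be non-negative")
  delta * n * C * piBlock
}

#' Block-level prevalence from the overall prevalence and a random effect
#'
#' Blocks within an orchard are related through a logit-normal random
#' effect: \eqn{\mathrm{logit}(\pi_i) = \mathrm{logit}(\pi) + V_i}.
#'
#' @param pi overall prevalence, strictly inside `(0, 1)`.
#' @param V block random effect on the logit scale (finite).
#' @return The block prevalence \eqn{\pi_i \in (0, 1)}; equals `pi` when
#'   `V = 0`. Vectorised over `V`.
#' @examples
#' blockPrevalence(1e-4, 1)
#' @export
blockPrevalence <- function(pi, V) {
  if (any(pi <= 0) || any(pi >= 1))
    stop("pi must lie strictly inside (0, 1)")
  if (any(!is.finite(V)))
    stop("V must be finite")
  stats::plogis(stats::qlogis(pi) + V)
}

#' Derived infested-fruit and pest counts for a block
#'
#' The number of infested fruit in a block and the number of pests that
#' produced them are derived (not sampled) quantities:
#' \eqn{I_i = \pi_i N} and \eqn{P_i = I_i / O_i}, where \eqn{O_i} is the
#' number of fruit infested per pest. Both are continuous; the Poisson trap
#' likelihood accepts a continuous rate.
#'
#' @param piBlock block prevalence in `[0, 1]`.
#' @param N fruit per block.
#' @param O fruit infested per pest (>= 1; zero would make the pest count
#'   undefined).
#' @return A list with components `I` (infested fruit) and `P` (pests),
#'   both non-negative.
#' @examples
#' derivedQuantities(1e-5, 1e7, 25)  # I = 100, P = 4
#' @export
derivedQuantities <- function(piBlock, N, O) {
  if (any(O < 1))
    stop("O must be >= 1")
  I <- piBlock * N
  list(I = I, P = I / O)
}

## Log-pmf of a Poisson truncated to {1, 2, ...}.
.dpois_trunc1_log <- function(k, lambda) {
  stats::dpois(k, lambda, log = TRUE) -
    stats::ppois(0, lambda, lower.tail = FALSE, log.p = TRUE)
}

.dunif_log <- function(x, lower, upper) {
  ifelse(x >= lower & x <= upper, -log(upper - lower), -Inf)
}

#' Unnormalised log-density of the full posterior
#'
#' Evaluates, at a [LatentState-class], the sum of every factor of the
#' joint model: the Poisson trap likelihood for `x_i` at rate
#' \eqn{P_i\,p(c_i)} (or \eqn{P_i \tau D_i} under the multiple-detection
#' variant), the Poisson consignment likelihood for `y_i` at rate
#' \eqn{\delta n C_i \pi_i}, the truncated-Poisson model for \eqn{O_i} at
#' intensity \eqn{\lambda}, the normal random-effect density of \eqn{V_i},
#' and the log prior densities of \eqn{\pi}, \eqn{\lambda}, \eqn{\tau},
#' \eqn{\delta} and \eqn{1/\sigma}. Returns `-Inf` whenever the state is
#' outside the parameter support.
#'
#' @param state a [LatentState-class].
#' @param data a [SurveillanceData-class].
#' @param design an [OrchardDesign-class].
#' @param priors a [PriorSpec-class].
#' @param multipleDetections logical; if `TRUE` the trap likelihood uses
#'   the multiple-detection rate \eqn{P_i \tau D_i} appropriate for devices
#'   that can detect the same individual repeatedly.
#' @return The scalar log-density (possibly `-Inf`).
#' @export
logJoint <- function(state, data, design, priors,
                     multipleDetections = FALSE) {
  stopifnot(is(state, "LatentState"), is(data, "SurveillanceData"),
            is(design, "OrchardDesign"), is(priors, "PriorSpec"))
  validateData(data, design)
  B <- design@B
  if (length(state@V) != B)
    stop("state has ", length(state@V), " blocks but design has ", B)

  ## support checks: outside support the density is zero, not an error
  if (state@pi <= 0 || state@pi >= 1) return(-Inf)
  if (state@delta < 0 || state@delta > 1) return(-Inf)
  if (state@sigma <= 0) return(-Inf)
  if (any(state@O < 1) || any(state@O != round(state@O))) return(-Inf)
  if (any(!is.finite(state@V))) return(-Inf)

  ## priors (on 1/sigma itself, matching its uniform prior)
  lp <- stats::dbeta(state@pi, priors@piAlpha, priors@piBeta, log = TRUE) +
    .dunif_log(state@lambda, priors@lambdaLower, priors@lambdaUpper) +
    .dunif_log(state@tau, priors@tauLower, priors@tauUpper) +
    stats::dbeta(state@delta, priors@deltaAlpha, priors@deltaBeta,
                 log = TRUE) +
    .dunif_log(1 / state@sigma, priors@invSigmaLower, priors@invSigmaUpper)
  if (!is.finite(lp)) return(-Inf)

  ## hierarchical layers
  lp <- lp + sum(stats::dnorm(state@V, 0, state@sigma, log = TRUE))
  lp <- lp + sum(.dpois_trunc1_log(state@O, state@lambda))

  ## likelihood
  pi_i <- blockPrevalence(state@pi, state@V)
  dq <- derivedQuantities(pi_i, design@N, state@O)
  trap_rate <- if (multipleDetections) {
    dq$P * state@tau * design@D
  } else {
    dq$P * captureProbability(state@tau, design@D)
  }
  lp <- lp + sum(stats::dpois(data@x, trap_rate, log = TRUE))
  cons_rate <- consignmentDetectionRate(state@delta, design@n, design@C,
                                        pi_i)
  lp <- lp + sum(stats::dpois(data@y, cons_rate, log = TRUE))
  if (is.nan(lp)) -Inf else lp
}
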