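#' Beta prior with a given mean and coefficient of variation
#'
#' Constructs the Beta distribution whose mean is exactly `p` and whose
#' coefficient of variation (standard deviation over mean) is exactly `cv`:
#' \deqn{\hat\alpha = (1 - p)/CV^2 - p, \qquad
#'       \hat\beta = (1 - p)\hat\alpha / p.}
#' Holding the CV constant while varying `p` gives a family of priors of
#' constant relative precision, the construction used for the
#' single-consignment (status quo) analysis.
#'
#' @param p target mean prevalence, in `(0, 1)`.
#' @param cv target coefficient of variation (> 0). Must satisfy
#'   `cv^2 < (1 - p)/p`, otherwise no Beta distribution exists
#'   (\eqn{\hat\alpha \le 0}).
#' @return A [BetaParams-class] with the requested moments.
#' @examples
#' betaPriorFromCV(0.1, 1)   # Beta(0.8, 7.2)
#' @export
betaPriorFromCV <- function(p, cv) {
  if (p <= 0 || p >= 1) stop("p must lie strictly inside (0, 1)")
  if (cv <= 0) stop("cv must be > 0")
  alpha <- (1 - p) / cv^2 - p
  if (alpha <= 0)
    stop("cv too large for mean p: no Beta distribution has these moments")
  BetaParams(alpha = alpha, beta = (1 - p) * alpha / p)
}

#' Conjugate Beta posterior after a consignment inspection
#'
#' With `y` detections in a random (or well-mixed) sample of `n` fruit and
#' prior \eqn{p \sim Beta(\alpha, \beta)}, the posterior is
#' \eqn{Beta(\alpha + y,\; n - y + \beta)}.
#'
#' @param prior a [BetaParams-class].
#' @param n sample size (>= 0).
#' @param y detections, `0 <= y <= n`.
#' @return The posterior [BetaParams-class].
#' @examples
#' betaPosteriorUpdate(BetaParams(1, 1), 600, 0)  # Beta(1, 601)
#' @export
betaPosteriorUpdate <- function(prior, n, y) {
  stopifnot(is(prior, "BetaParams"))
  if (n < 0) stop("n must be >= 0")
  if (y < 0 || y > n) stop("y must satisfy 0 <= y <= n")
  BetaParams(alpha = prior@alpha + y, beta = n - y + prior@beta)
}

#' Probability that a consignment sample detects an infestation
#'
#' The acceptance-sampling detection probability for a random sample of `n`
#' fruit, prevalence `prevalence` and per-fruit inspection sensitivity
#' `delta`: \eqn{1 - (1 - \delta\,\pi)^n}. With `n = 600`, perfect
#' sensitivity and prevalence 0.5% this exceeds 95%, the standard
#' design-prevalence calculation behind the 600-piece sample.
#'
#' @param n sample size (>= 0).
#' @param prevalence infestation prevalence in `[0, 1]`.
#' @param delta per-fruit inspection sensitivity in `[0, 1]`.
#' @return The detection probability, non-decreasing in every argument.
#' @examples
#' detectionProbability(600, 0.005, 1)   # 0.9506
#' @export
detectionProbability <- function(n, prevalence, delta) {
  if (any(n < 0)) stop("n must be >= 0")
  if (any(prevalence < 0) || any(prevalence > 1))
    stop("prevalence must lie in [0, 1]")
  if (any(delta < 0) || any(delta > 1))
    stop("delta must lie in [0, 1]")
  1 - (1 - delta * prevalence)^n
}

#' Estimate the areal trap encounter rate from a capture probability
#'
#' Inverts the capture-probability relation
#' \eqn{p(c) = 1 - e^{-\tau D}} to
#' \eqn{\hat\tau = -\log(1 - p(c)) / D}, allowing an observed per-season
#' (or per-day) capture probability at a known trap density to be turned
#' into an encounter-rate estimate for use as a prior.
#'
#' @param captureProb observed capture probability in `[0, 1)`.
#' @param D trap density (> 0).
#' @return The estimated areal rate \eqn{\hat\tau \ge 0}; the exact inverse
#'   of [captureProbability()].
#' @examples
#' estimateTau(0.013, 6)  # daily-scale example: ~0.00218
#' @export
estimateTau <- function(captureProb, D) {
  if (any(captureProb < 0) || any(captureProb >= 1))
    stop("captureProb must lie in [0, 1)")
  if (any(D <= 0)) stop("D must be > 0")
  -log1p(-captureProb) / D
}

#' Prior-to-posterior table for clean single-consignment samples
#'
#' For each prior mean prevalence, builds the constant-CV Beta prior,
#' applies the conjugate update for a clean (zero-detection) sample of `n`
#' fruit at perfect sensitivity, and reports prior and posterior means and
#' 95th percentiles. This is the "status quo" analysis: it shows that a
#' single 600-piece sample only meaningfully sharpens belief when the prior
#' prevalence is high, and is negligible once the prior is already low.
#'
#' @param priorMeans numeric vector of prior mean prevalences in `(0, 1)`.
#' @param cv coefficient of variation held constant across the range.
#' @param n sample size of the single clean consignment sample.
#' @return A `data.frame` with columns `prior_mean`, `prior_q95`,
#'   `posterior_mean`, `posterior_q95`.
#' @examples
#' statusQuoCurve(c(1e-4, 1e-3, 1e-2, 1e-1), cv = 1)
#' @export
statusQuoCurve <- function(priorMeans, cv, n = 600) {
  rows <- lapply(priorMeans, function(p) {
    prior <- betaPriorFromCV(p, cv)
    post <- betaPosteriorUpdate(prior, n, 0)
    data.frame(prior_mean = betaMean(prior),
               prior_q95 = betaQuantile(prior, 0.95),
               posterior_mean = betaMean(post),
               posterior_q95 = betaQuantile(post, 0.95))
  })
  do.call(rbind, rows)
}
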