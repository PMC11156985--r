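#' Generate a validation dataset with known truth
#'
#' Simulates an orchard under a gamma-Poisson generator that deliberately
#' differs from the fitted hierarchical model, so that parameter-recovery
#' checks probe the inference rather than echoing its own likelihood:
#' \itemize{
#'   \item one per-pest infestation intensity \eqn{\lambda_O \sim
#'     Gamma(shape, scale)} is drawn per dataset (an orchard-wide
#'     fecundity);
#'   \item pests per block \eqn{P_i \sim Poisson(\mu)} with `pestIntensity`
#'     \eqn{\mu};
#'   \item infested fruit per block is the sum of a \eqn{Poisson(\lambda_O)}
#'     draw per pest, capped at the `N` fruit available;
#'   \item trap catches are exact Binomials,
#'     \eqn{x_i \sim Bin(P_i, 1 - e^{-\tau D_i})};
#'   \item consignment detections are exact Binomials,
#'     \eqn{y_i \sim Bin(n C_i, \delta\,\pi_i)} with \eqn{\pi_i} the true
#'     block prevalence.
#' }
#'
#' @param pestIntensity Poisson intensity of pests per block (the
#'   validation study spans 0.5-100).
#' @param design an [OrchardDesign-class]; the reference validation design
#'   is 10 blocks, 10 consignment samples and 5 traps per block,
#'   \eqn{10^7} fruit per block.
#' @param deltaTrue true per-fruit inspection sensitivity used for the
#'   observation draws; default 0.5, the mean of the medium Beta(50, 50)
#'   sensitivity prior.
#' @param tauTrue true areal encounter rate; default 0.01, the midpoint of
#'   the low \eqn{U(0.0075, 0.0125)} prior.
#' @param gammaShape,gammaScale shape and scale of the fecundity
#'   distribution (defaults 15 and 2, mean 30 fruit infested per pest).
#' @param seed integer; identical seeds reproduce identical datasets.
#' @return A [SimulatedDataset-class].
#' @examples
#' sim <- generateDataset(5, OrchardDesign(B = 10, D = 5, C = 10), seed = 1)
#' sim
#' @export
generateDataset <- function(pestIntensity, design = OrchardDesign(
                              B = 10, D = 5, C = 10),
                            deltaTrue = 0.5, tauTrue = 0.01,
                            gammaShape = 15, gammaScale = 2, seed = 1) {
  stopifnot(is(design, "OrchardDesign"))
  if (pestIntensity < 0) stop("pestIntensity must be >= 0")
  if (gammaShape <= 0 || gammaScale <= 0)
    stop("gamma parameters must be > 0")
  if (deltaTrue < 0 || deltaTrue > 1) stop("deltaTrue must lie in [0, 1]")
  if (tauTrue < 0) stop("tauTrue must be >= 0")

  set.seed(as.integer(seed))
  B <- design@B
  lambdaO <- stats::rgamma(1, shape = gammaShape, scale = gammaScale)
  pests <- stats::rpois(B, pestIntensity)
  infested <- vapply(pests, function(p)
    if (p == 0L) 0 else sum(stats::rpois(p, lambdaO)), numeric(1))
  infested <- pmin(infested, design@N)
  prevalence <- infested / design@N
  x <- stats::rbinom(B, pests, captureProbability(tauTrue, design@D))
  y <- stats::rbinom(B, round(design@n * design@C), deltaTrue * prevalence)

  new("SimulatedDataset", pests = as.integer(pests), lambdaO = lambdaO,
      infested = as.integer(infested), prevalence = prevalence,
      orchardPrevalence = mean(prevalence),
      data = SurveillanceData(x = x, y = y), design = design,
      pestIntensity = pestIntensity, deltaTrue = deltaTrue,
      tauTrue = tauTrue, seed = as.integer(seed))
}

#' Relative error of a prevalence estimate
#'
#' \deqn{(\hat\pi - \pi_{true}) / \pi_{true}}
#'
#' @param estimate estimated prevalence.
#' @param truth true prevalence (> 0).
#' @return The signed relative error; zero iff `estimate == truth`.
#' @examples
#' relativeError(2e-6, 1e-6)   # 1
#' @export
relativeError <- function(estimate, truth) {
  if (any(truth <= 0)) stop("truth must be > 0")
  (estimate - truth) / truth
}

#' Simulation-based parameter recovery study
#'
#' Generates datasets over a grid of pest intensities, fits the
#' hierarchical model to each, and pairs the orchard-mean true prevalence
#' with the posterior-mean estimate. Reproducible from `settings@seed`:
#' each dataset and its fit derive their seeds from the master seed.
#'
#' @param intensities numeric grid of pest Poisson intensities (the
#'   reference study spans 0.5-100).
#' @param reps datasets per intensity.
#' @param design an [OrchardDesign-class] (default: the validation design
#'   of 10 blocks, 5 traps and 10 consignment samples per block).
#' @param priors a [PriorSpec-class] used for fitting.
#' @param settings an [McmcSettings-class]; `settings@seed` is the master
#'   seed.
#' @param deltaTrue,tauTrue generator truth passed to [generateDataset()].
#' @param gammaShape,gammaScale fecundity distribution passed to
#'   [generateDataset()].
#' @return A `data.frame` with one row per dataset: `intensity`, `rep`,
#'   `seed`, `truth` (orchard-mean true prevalence), `estimate`
#'   (posterior mean of the orchard prevalence), `estimate_q95`, and
#'   `relative_error` (`NA` when the realised truth is exactly zero).
#' @export
recoveryStudy <- function(intensities, reps = 3,
                          design = OrchardDesign(B = 10, D = 5, C = 10),
                          priors = PriorSpec(), settings = McmcSettings(),
                          deltaTrue = 0.5, tauTrue = 0.01,
                          gammaShape = 15, gammaScale = 2) {
  master <- settings@seed %% 100000000L
  grid <- expand.grid(rep = seq_len(reps), intensity = intensities)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    dseed <- master + 101L * i
    sim <- generateDataset(grid$intensity[i], design = design,
                           deltaTrue = deltaTrue, tauTrue = tauTrue,
                           gammaShape = gammaShape, gammaScale = gammaScale,
                           seed = dseed)
    fitSettings <- McmcSettings(chains = settings@chains,
                                iterations = settings@iterations,
                                burnin = settings@burnin,
                                thin = settings@thin, seed = dseed + 1L)
    fit <- samplePosterior(design, priors, sim@data, fitSettings)
    op <- orchardPrevalence(fit)
    est <- mean(op)
    data.frame(intensity = grid$intensity[i], rep = grid$rep[i],
               seed = dseed, truth = sim@orchardPrevalence,
               estimate = est,
               estimate_q95 = stats::quantile(op, 0.95, names = FALSE),
               relative_error = if (sim@orchardPrevalence > 0)
                 relativeError(est, sim@orchardPrevalence) else NA_real_)
  })
  do.call(rbind, rows)
}
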