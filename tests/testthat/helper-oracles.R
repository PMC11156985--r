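# Independent reference implementations used as oracles. These are coded
# from the model definition directly (explicit log-density algebra, sums
# and sorts) and never call the package functions they check.

# Term-by-term unnormalised log posterior, written out factor by factor.
ref_log_joint <- function(state, data, design, priors,
                          multipleDetections = FALSE) {
  logit <- function(p) log(p) - log(1 - p)
  ilogit <- function(z) 1 / (1 + exp(-z))
  lbeta_log <- function(x, a, b)
    (a - 1) * log(x) + (b - 1) * log(1 - x) - lbeta(a, b)
  pois_log <- function(k, r) {
    if (r == 0) return(if (k == 0) 0 else -Inf)
    k * log(r) - r - lgamma(k + 1)
  }
  lp <- lbeta_log(state@pi, priors@piAlpha, priors@piBeta) +
    lbeta_log(state@delta, priors@deltaAlpha, priors@deltaBeta) -
    log(priors@lambdaUpper - priors@lambdaLower) -
    log(priors@tauUpper - priors@tauLower) -
    log(priors@invSigmaUpper - priors@invSigmaLower)
  for (i in seq_len(design@B)) {
    v <- state@V[i]
    lp <- lp - 0.5 * log(2 * base::pi * state@sigma^2) -
      v^2 / (2 * state@sigma^2)
    o <- state@O[i]
    lp <- lp + o * log(state@lambda) - state@lambda - lgamma(o + 1) -
      log(1 - exp(-state@lambda))
    p_i <- ilogit(logit(state@pi) + v)
    P <- p_i * design@N / o
    r_trap <- if (multipleDetections) P * state@tau * design@D[i]
              else P * (1 - exp(-state@tau * design@D[i]))
    lp <- lp + pois_log(data@x[i], r_trap)
    lp <- lp + pois_log(data@y[i],
                        state@delta * design@n * design@C[i] * p_i)
  }
  lp
}

# Textbook potential scale reduction factor from a list of chains.
ref_psrf <- function(chains) {
  m <- length(chains)
  n <- length(chains[[1]])
  means <- vapply(chains, mean, numeric(1))
  W <- mean(vapply(chains, function(ch)
    sum((ch - mean(ch))^2) / (n - 1), numeric(1)))
  B <- n / (m - 1) * sum((means - mean(means))^2)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Empirical quantile by sorting and linear interpolation between order
# statistics (h = (n-1)p + 1).
ref_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# A random state inside the parameter support, plus consistent data, for
# property sweeps.
random_valid_case <- function() {
  B <- sample(1:4, 1)
  design <- OrchardDesign(B = B, N = 1e7,
                          D = sample(0:10, B, replace = TRUE),
                          C = sample(0:20, B, replace = TRUE))
  priors <- PriorSpec(tau = sample(c("low", "high"), 1),
                      delta = sample(c("low", "medium", "high"), 1))
  lambda <- runif(1, priors@lambdaLower, priors@lambdaUpper)
  state <- LatentState(
    pi = runif(1, 1e-6, 0.9),
    V = rnorm(B, 0, 1.5),
    sigma = 1 / runif(1, 0.05, 1),
    lambda = lambda,
    O = pmax(1, rpois(B, lambda)),
    tau = runif(1, priors@tauLower, priors@tauUpper),
    delta = rbeta(1, priors@deltaAlpha, priors@deltaBeta))
  data <- SurveillanceData(
    x = ifelse(design@D > 0, rpois(B, 1), 0L),
    y = ifelse(design@C > 0, rpois(B, 1), 0L))
  list(state = state, data = data, design = design, priors = priors)
}

# Compact sampler settings for tests that only need a rough posterior.
fast_settings <- function(iterations = 4000, seed = 1, chains = 2,
                          burnin = 1000)
  McmcSettings(chains = chains, iterations = iterations, burnin = burnin,
               seed = seed)

# Monte-Carlo standard error of an empirical quantile from batch means:
# the pooled draws are cut into consecutive batches, the quantile computed
# per batch, and the spread of batch quantiles scaled by sqrt(batches).
mcse_quantile <- function(draws, p, batches = 30) {
  idx <- cut(seq_along(draws), batches, labels = FALSE)
  qs <- tapply(draws, idx, function(v) quantile(v, p, names = FALSE))
  sd(qs) / sqrt(length(qs))
}
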