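## JAGS model construction ---------------------------------------------------

## Assembles the JAGS program for the hierarchical prevalence model. The
## trap and consignment likelihood loops are emitted only for blocks that
## actually have traps / consignment samples (a BUGS `for (j in 1:0)` loop
## would iterate, so empty loops must be omitted, and a Poisson node with
## rate exactly 0 is not allowed).
.jags_model_string <- function(blockEffects, fixDelta, fixSigma,
                               multipleDetections, hasTraps, hasCons) {
  lines <- c(
    "model {",
    "  pi ~ dbeta(pi_alpha, pi_beta)",
    "  lambda ~ dunif(lambda_lower, lambda_upper)",
    "  tau ~ dunif(tau_lower, tau_upper)",
    if (is.null(fixDelta))
      "  delta ~ dbeta(delta_alpha, delta_beta)"
    else
      "  delta <- delta_fixed",
    if (blockEffects) {
      if (is.null(fixSigma)) c(
        "  inv_sigma ~ dunif(inv_sigma_lower, inv_sigma_upper)",
        "  sigma <- 1 / inv_sigma"
      ) else
        "  sigma <- sigma_fixed"
    },
    "  for (i in 1:B) {",
    if (blockEffects)
      "    V[i] ~ dnorm(0, pow(sigma, -2))"
    else
      "    V[i] <- 0",
    "    logit(pi_i[i]) <- logit(pi) + V[i]",
    "    O[i] ~ dpois(lambda) T(1,)",
    "    I[i] <- pi_i[i] * N",
    "    P[i] <- I[i] / O[i]",
    "  }",
    if (hasTraps) c(
      "  for (j in 1:n_trap) {",
      if (multipleDetections)
        "    x_obs[j] ~ dpois(P[trap_idx[j]] * tau * D[trap_idx[j]])"
      else
        "    x_obs[j] ~ dpois(P[trap_idx[j]] * (1 - exp(-tau * D[trap_idx[j]])))",
      "  }"
    ),
    if (hasCons) c(
      "  for (j in 1:n_cons) {",
      "    y_obs[j] ~ dpois(delta * n * C[cons_idx[j]] * pi_i[cons_idx[j]])",
      "  }"
    ),
    "}"
  )
  paste(lines, collapse = "\n")
}

## Independent prior draws used as chain starting values; overdispersed by
## construction, and guaranteed inside the support so the initial
## log-density is finite.
.prior_inits <- function(priors, B, blockEffects, fixDelta, fixSigma,
                         chainSeed) {
  set.seed(chainSeed)
  inits <- list(
    pi = stats::rbeta(1, priors@piAlpha, priors@piBeta),
    lambda = stats::runif(1, priors@lambdaLower, priors@lambdaUpper),
    tau = stats::runif(1, priors@tauLower, priors@tauUpper)
  )
  inits$O <- pmax(1, stats::rpois(B, inits$lambda))
  if (is.null(fixDelta))
    inits$delta <- stats::rbeta(1, priors@deltaAlpha, priors@deltaBeta)
  if (blockEffects && is.null(fixSigma)) {
    ## avoid an extreme sigma = 1/u start when u is tiny
    inits$inv_sigma <- stats::runif(1, max(priors@invSigmaLower, 0.05),
                                    priors@invSigmaUpper)
    inits$V <- stats::rnorm(B, 0, 1)
  } else if (blockEffects) {
    inits$V <- stats::rnorm(B, 0, fixSigma)
  }
  inits$.RNG.name <- "base::Mersenne-Twister"
  inits$.RNG.seed <- chainSeed
  inits
}

#' Sample the posterior of the hierarchical prevalence model
#'
#' Fits, by Gibbs sampling via JAGS, the joint model in which per-pest
#' infestation counts are truncated Poisson with uniform-prior intensity
#' \eqn{\lambda}, block prevalences are logit-normal around the overall
#' prevalence \eqn{\pi}, trap catches are Poisson at rate
#' \eqn{P_i (1 - e^{-\tau D_i})}, and consignment detections are Poisson at
#' rate \eqn{\delta n C_i \pi_i}. Chains start at independent prior draws
#' and are fully reproducible from `settings@seed`.
#'
#' @param design an [OrchardDesign-class].
#' @param priors a [PriorSpec-class].
#' @param data a [SurveillanceData-class] consistent with `design`;
#'   defaults to all-zero (clean) observations.
#' @param settings an [McmcSettings-class].
#' @param blockEffects `"auto"` (default), `"on"` or `"off"`. The
#'   logit-normal block random effect codifies the relatedness of multiple
#'   blocks within one orchard; with a single block it is unidentifiable
#'   (only \eqn{\mathrm{logit}(\pi) + V_1} enters the likelihood) and the
#'   heavy-tailed \eqn{\sigma = 1/U(0,1)} prior would dominate the
#'   inference, so `"auto"` includes the layer only when `B > 1`.
#' @param fixDelta optional scalar in `[0, 1]`: treat the inspection
#'   sensitivity as known rather than Beta-distributed.
#' @param fixSigma optional positive scalar: fix the random-effect standard
#'   deviation (useful for degenerate-limit checks with `fixSigma` near 0).
#' @param multipleDetections if `TRUE`, use the trap likelihood rate
#'   \eqn{P_i \tau D_i} suitable for devices that can detect the same pest
#'   repeatedly.
#' @return A [PrevalenceFit-class] holding the monitored draws (`pi`,
#'   `lambda`, `tau`, `delta` unless fixed, `sigma` when the random-effect
#'   scale is sampled, and the block prevalences `pi_i[b]`).
#' @examples
#' \donttest{
#' design <- OrchardDesign(B = 2, D = 5, C = 10)
#' fit <- samplePosterior(design, PriorSpec(),
#'                        settings = McmcSettings(iterations = 2000,
#'                                                burnin = 500, seed = 1))
#' summarizePosterior(fit)
#' }
#' @export
samplePosterior <- function(design, priors = PriorSpec(),
                            data = allZeroData(design),
                            settings = McmcSettings(),
                            blockEffects = c("auto", "on", "off"),
                            fixDelta = NULL, fixSigma = NULL,
                            multipleDetections = FALSE) {
  stopifnot(is(design, "OrchardDesign"), is(priors, "PriorSpec"),
            is(data, "SurveillanceData"), is(settings, "McmcSettings"))
  validateData(data, design)
  blockEffects <- match.arg(blockEffects)
  useRE <- switch(blockEffects, auto = design@B > 1L, on = TRUE,
                  off = FALSE)
  if (!is.null(fixDelta))
    stopifnot(length(fixDelta) == 1L, fixDelta >= 0, fixDelta <= 1)
  if (!is.null(fixSigma))
    stopifnot(length(fixSigma) == 1L, fixSigma > 0)

  trap_idx <- which(design@D > 0)
  cons_idx <- which(design@C > 0)
  hasTraps <- length(trap_idx) > 0L
  hasCons <- length(cons_idx) > 0L

  jdata <- list(B = design@B, N = design@N,
                pi_alpha = priors@piAlpha, pi_beta = priors@piBeta,
                lambda_lower = priors@lambdaLower,
                lambda_upper = priors@lambdaUpper,
                tau_lower = priors@tauLower, tau_upper = priors@tauUpper)
  if (is.null(fixDelta)) {
    jdata$delta_alpha <- priors@deltaAlpha
    jdata$delta_beta <- priors@deltaBeta
  } else jdata$delta_fixed <- fixDelta
  if (useRE) {
    if (is.null(fixSigma)) {
      jdata$inv_sigma_lower <- priors@invSigmaLower
      jdata$inv_sigma_upper <- priors@invSigmaUpper
    } else jdata$sigma_fixed <- fixSigma
  }
  if (hasTraps) {
    jdata$D <- design@D
    jdata$trap_idx <- trap_idx
    jdata$n_trap <- length(trap_idx)
    jdata$x_obs <- data@x[trap_idx]
  }
  if (hasCons) {
    jdata$n <- design@n
    jdata$C <- design@C
    jdata$cons_idx <- cons_idx
    jdata$n_cons <- length(cons_idx)
    jdata$y_obs <- data@y[cons_idx]
  }

  baseSeed <- settings@seed %% 1000000000L
  inits <- lapply(seq_len(settings@chains), function(k)
    .prior_inits(priors, design@B, useRE, fixDelta, fixSigma,
                 baseSeed + 1000L * k))

  monitors <- c("pi", "lambda", "tau",
                if (is.null(fixDelta)) "delta",
                if (useRE && is.null(fixSigma)) "sigma",
                "pi_i")
  modelStr <- .jags_model_string(useRE, fixDelta, fixSigma,
                                 multipleDetections, hasTraps, hasCons)

  model <- tryCatch(
    rjags::jags.model(textConnection(modelStr), data = jdata,
                      inits = inits, n.chains = settings@chains,
                      quiet = TRUE),
    error = function(e) {
      stop("JAGS model initialisation failed: ", conditionMessage(e),
           "\ninitial states were:\n",
           paste(utils::capture.output(utils::str(inits)), collapse = "\n"),
           call. = FALSE)
    })
  if (settings@burnin > 0)
    update(model, settings@burnin, progress.bar = "none")
  draws <- rjags::coda.samples(model, variable.names = monitors,
                               n.iter = settings@iterations,
                               thin = settings@thin,
                               progress.bar = "none")
  ## a length-1 monitored vector is reported without its index
  draws <- lapply(draws, function(ch) {
    cn <- colnames(ch)
    cn[cn == "pi_i"] <- "pi_i[1]"
    colnames(ch) <- cn
    ch
  })
  draws <- coda::as.mcmc.list(lapply(draws, coda::as.mcmc))

  new("PrevalenceFit", draws = draws, design = design, priors = priors,
      data = data, settings = settings, blockEffects = useRE,
      fixedDelta = if (is.null(fixDelta)) NA_real_ else fixDelta,
      fixedSigma = if (is.null(fixSigma)) NA_real_ else fixSigma,
      multipleDetections = isTRUE(multipleDetections))
}

## Gelman-Rubin ---------------------------------------------------------------

## Plain between/within-chain potential scale reduction factor:
## sqrt(((n-1)/n * W + B/n) / W). No degrees-of-freedom correction.
.psrf <- function(mat) {
  n <- nrow(mat)
  m <- ncol(mat)
  if (m < 2L) stop("at least 2 chains are required")
  if (n < 2L) stop("chains must contain at least 2 draws")
  W <- mean(apply(mat, 2, stats::var))
  Bv <- n * stats::var(colMeans(mat))
  if (W == 0) return(if (Bv == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + Bv / n) / W)
}

#' @describeIn gelmanRubin chains supplied as an iterations x chains matrix.
#' @export
setMethod("gelmanRubin", "matrix", function(object, ...) .psrf(object))

#' @describeIn gelmanRubin chains supplied as a list of equal-length
#'   numeric vectors.
#' @export
setMethod("gelmanRubin", "list", function(object, ...) {
  lens <- lengths(object)
  if (length(unique(lens)) != 1L)
    stop("all chains must have equal length")
  .psrf(do.call(cbind, object))
})

#' @describeIn gelmanRubin one value per monitored quantity of a fit (or a
#'   single value when `parameter` is given).
#' @param parameter optional quantity name, e.g. `"lambda"`.
#' @export
setMethod("gelmanRubin", "PrevalenceFit", function(object,
                                                   parameter = NULL, ...) {
  draws <- object@draws
  params <- colnames(draws[[1]])
  if (!is.null(parameter)) {
    if (!parameter %in% params)
      stop("unknown parameter: ", parameter)
    params <- parameter
  }
  res <- vapply(params, function(p)
    .psrf(sapply(draws, function(ch) as.vector(ch[, p]))), numeric(1))
  if (!is.null(parameter)) unname(res) else res
})

## Summaries ------------------------------------------------------------------

#' @describeIn orchardPrevalence draws of the production-system prevalence:
#'   the block-level prevalence draws `pi_i[b]` pooled over every block and
#'   chain.
#' @export
setMethod("orchardPrevalence", "PrevalenceFit", function(object, ...) {
  cols <- grep("^pi_i\\[", colnames(object@draws[[1]]), value = TRUE)
  unlist(lapply(object@draws, function(ch)
    as.vector(ch[, cols])), use.names = FALSE)
})

.summary_row <- function(v, probs) {
  qs <- stats::quantile(v, probs, names = FALSE, type = 7)
  names(qs) <- paste0("q", formatC(100 * probs, format = "fg"))
  c(mean = mean(v), qs)
}

#' @describeIn summarizePosterior pooled-chain means and empirical
#'   quantiles (linear interpolation between order statistics) for every
#'   monitored quantity, plus the orchard-level prevalence pooled over all
#'   blocks; per-quantity Gelman-Rubin factor and effective sample size
#'   (the latter diagnostic only).
#' @param probs quantile levels to report.
#' @return A `data.frame` with one row per quantity: `mean`, one column per
#'   quantile, `rhat` and `ess`.
#' @export
setMethod("summarizePosterior", "PrevalenceFit",
          function(object, probs = c(0.025, 0.5, 0.95, 0.975), ...) {
  draws <- object@draws
  params <- colnames(draws[[1]])
  rows <- lapply(params, function(p) {
    v <- unlist(lapply(draws, function(ch) as.vector(ch[, p])),
                use.names = FALSE)
    .summary_row(v, probs)
  })
  rhat <- gelmanRubin(object)
  ess <- vapply(params, function(p)
    sum(vapply(draws, function(ch)
      unname(coda::effectiveSize(ch[, p])), numeric(1))), numeric(1))

  op <- orchardPrevalence(object)
  op_chains <- lapply(draws, function(ch) {
    cols <- grep("^pi_i\\[", colnames(ch), value = TRUE)
    as.vector(ch[, cols])
  })
  rows <- c(rows, list(.summary_row(op, probs)))
  out <- as.data.frame(do.call(rbind, rows))
  out$rhat <- c(unname(rhat), .psrf(do.call(cbind, op_chains)))
  out$ess <- c(unname(ess), NA_real_)
  out <- cbind(quantity = c(params, "orchard_prevalence"), out)
  rownames(out) <- NULL
  out
})

#' @describeIn summarizePosterior plain draws as a list of equal-length
#'   chains of one quantity: pooled mean and quantiles.
#' @export
setMethod("summarizePosterior", "list",
          function(object, probs = c(0.025, 0.5, 0.95, 0.975), ...) {
  if (!length(object) || !all(lengths(object) > 0))
    stop("chains must be non-empty")
  v <- unlist(object, use.names = FALSE)
  as.data.frame(as.list(.summary_row(v, probs)), check.names = FALSE)
})

#' @describeIn summarizePosterior a single chain as a numeric vector.
#' @export
setMethod("summarizePosterior", "numeric",
          function(object, probs = c(0.025, 0.5, 0.95, 0.975), ...) {
  summarizePosterior(list(object), probs = probs)
})

#' @describeIn exportChains one row per retained draw, one column per
#'   monitored quantity, with `chain` and `iteration` identifier columns.
#' @export
setMethod("exportChains", "PrevalenceFit", function(object, path, ...) {
  tabs <- lapply(seq_along(object@draws), function(k) {
    m <- as.matrix(object@draws[[k]])
    data.frame(chain = k, iteration = seq_len(nrow(m)), m,
               check.names = FALSE)
  })
  out <- do.call(rbind, tabs)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
})
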