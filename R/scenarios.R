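#' Run a single named scenario
#'
#' Fits the hierarchical model for the scenario's design, priors and data
#' and returns one row per monitored quantity (plus the pooled
#' orchard-level prevalence) with the scenario identifier, the headline
#' design parameters, posterior mean and 95th percentile, and the
#' Gelman-Rubin factor. Runs whose largest monitored R-hat exceeds 1.2 are
#' flagged in the `converged` column rather than dropped.
#'
#' @param config a [ScenarioConfig-class].
#' @return A `data.frame` with columns `scenario`, `quantity`, `B`, `N`,
#'   `n`, `traps`, `consignments`, `delta_mean`, `tau_lower`, `tau_upper`,
#'   `seed`, `mean`, `q95`, `rhat`, `converged`.
#' @export
runScenario <- function(config) {
  stopifnot(is(config, "ScenarioConfig"))
  fit <- samplePosterior(config@design, config@priors, config@data,
                         config@settings,
                         blockEffects = config@blockEffects,
                         multipleDetections = config@multipleDetections)
  s <- summarizePosterior(fit, probs = 0.95)
  pr <- config@priors
  converged <- all(is.finite(s$rhat)) && max(s$rhat) <= 1.2
  data.frame(
    scenario = config@name, quantity = s$quantity,
    B = config@design@B, N = config@design@N, n = config@design@n,
    traps = mean(config@design@D), consignments = mean(config@design@C),
    delta_mean = pr@deltaAlpha / (pr@deltaAlpha + pr@deltaBeta),
    tau_lower = pr@tauLower, tau_upper = pr@tauUpper,
    seed = config@settings@seed,
    mean = s$mean, q95 = s$q95, rhat = s$rhat,
    converged = converged, row.names = NULL)
}

#' Run a grid of scenarios
#'
#' Runs every configuration and concatenates the rows. When `masterSeed`
#' is given, each scenario's seed is derived reproducibly from it
#' (`masterSeed + index`), so a rerun with the same master seed produces a
#' byte-identical table. Individual failures are logged to stderr and the
#' grid continues.
#'
#' @param configs a list of [ScenarioConfig-class] objects.
#' @param masterSeed optional integer master seed.
#' @param path optional CSV output path; written with [utils::write.csv()].
#' @return The combined `data.frame` (invisibly when `path` is given).
#' @export
runGrid <- function(configs, masterSeed = NULL, path = NULL) {
  if (!length(configs)) stop("at least one scenario config is required")
  rows <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    if (!is.null(masterSeed)) {
      st <- cfg@settings
      cfg@settings <- McmcSettings(st@chains, st@iterations, st@burnin,
                                   st@thin,
                                   seed = as.integer(masterSeed) + i)
    }
    rows[[i]] <- tryCatch(runScenario(cfg), error = function(e) {
      message("scenario '", cfg@name, "' failed: ", conditionMessage(e))
      NULL
    })
  }
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Built-in scenario bundles
#'
#' Pre-assembled grids covering the reference scenario analyses, all with
#' \eqn{10^7} fruit per block and all-zero (clean) observations:
#' \describe{
#'   \item{`trap-density`}{a single block with 0-10 traps, low vs high
#'     encounter rate, no consignment sampling.}
#'   \item{`trap-blocks`}{10 traps per block, 1-10 blocks, low vs high
#'     encounter rate, no consignment sampling.}
#'   \item{`consignment-number`}{a single block, 1-100 clean 600-piece
#'     consignment samples, low/medium/high inspection sensitivity, no
#'     traps.}
#'   \item{`consignment-blocks`}{100 clean consignment samples per block,
#'     1-10 blocks, low/medium/high sensitivity, no traps.}
#'   \item{`combined-single-trap`}{a single block with one trap
#'     (\eqn{\tau \sim U(0.0075, 0.015)}) and 0-100 clean consignment
#'     samples at each sensitivity level.}
#'   \item{`combined-ten-traps`}{as above with ten traps.}
#' }
#'
#' @param name bundle name (see Details).
#' @param settings an [McmcSettings-class] applied to every scenario in
#'   the bundle.
#' @return A list of [ScenarioConfig-class] objects suitable for
#'   [runGrid()].
#' @export
scenarioBundle <- function(name = c("trap-density", "trap-blocks",
                                    "consignment-number",
                                    "consignment-blocks",
                                    "combined-single-trap",
                                    "combined-ten-traps"),
                           settings = McmcSettings()) {
  name <- match.arg(name)
  cfg <- function(id, design, priors)
    ScenarioConfig(id, design, priors, settings = settings)
  combinedTau <- c(0.0075, 0.015)
  switch(name,
    "trap-density" = {
      grid <- expand.grid(D = 0:10, tau = c("low", "high"),
                          stringsAsFactors = FALSE)
      lapply(seq_len(nrow(grid)), function(i)
        cfg(sprintf("trap-density_D%d_tau-%s", grid$D[i], grid$tau[i]),
            OrchardDesign(B = 1, D = grid$D[i], C = 0),
            PriorSpec(tau = grid$tau[i])))
    },
    "trap-blocks" = {
      grid <- expand.grid(B = 1:10, tau = c("low", "high"),
                          stringsAsFactors = FALSE)
      lapply(seq_len(nrow(grid)), function(i)
        cfg(sprintf("trap-blocks_B%d_tau-%s", grid$B[i], grid$tau[i]),
            OrchardDesign(B = grid$B[i], D = 10, C = 0),
            PriorSpec(tau = grid$tau[i])))
    },
    "consignment-number" = {
      grid <- expand.grid(C = c(1, 2, 5, 10, 20, 50, 100),
                          delta = c("low", "medium", "high"),
                          stringsAsFactors = FALSE)
      lapply(seq_len(nrow(grid)), function(i)
        cfg(sprintf("consignment-number_C%d_delta-%s", grid$C[i],
                    grid$delta[i]),
            OrchardDesign(B = 1, D = 0, C = grid$C[i]),
            PriorSpec(delta = grid$delta[i])))
    },
    "consignment-blocks" = {
      grid <- expand.grid(B = 1:10, delta = c("low", "medium", "high"),
                          stringsAsFactors = FALSE)
      lapply(seq_len(nrow(grid)), function(i)
        cfg(sprintf("consignment-blocks_B%d_delta-%s", grid$B[i],
                    grid$delta[i]),
            OrchardDesign(B = grid$B[i], D = 0, C = 100),
            PriorSpec(delta = grid$delta[i])))
    },
    "combined-single-trap" = ,
    "combined-ten-traps" = {
      D <- if (name == "combined-single-trap") 1 else 10
      grid <- expand.grid(C = c(0, 1, 2, 5, 10, 20, 50, 100),
                          delta = c("low", "medium", "high"),
                          stringsAsFactors = FALSE)
      lapply(seq_len(nrow(grid)), function(i)
        cfg(sprintf("%s_C%d_delta-%s", name, grid$C[i], grid$delta[i]),
            OrchardDesign(B = 1, D = D, C = grid$C[i]),
            PriorSpec(tau = combinedTau, delta = grid$delta[i])))
    })
}
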