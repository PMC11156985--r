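#' Read a scenario configuration file
#'
#' Parses a JSON or YAML scenario description into a
#' [ScenarioConfig-class]. Format (YAML shown; JSON is isomorphic):
#'
#' ```yaml
#' name: ten-blocks-clean
#' design: {B: 10, N: 1.0e7, D: 5, C: 10, n: 600}
#' priors: {tau: low, delta: medium, lambda: [20, 30], pi: [1, 1]}
#' data: {x: [0, ...], y: [0, ...]}    # optional; omitted = all-zero
#' settings: {chains: 3, iterations: 30000, burnin: 5000, seed: 1}
#' blockEffects: auto                   # optional
#' multipleDetections: false            # optional
#' ```
#'
#' `priors.tau` may be a named level (`low`/`high`) or `[lower, upper]`;
#' `priors.delta` a named level (`low`/`medium`/`high`) or
#' `[alpha, beta]`.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return A [ScenarioConfig-class].
#' @export
readScenarioConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)

  d <- raw$design
  if (is.null(d)) stop("config is missing the 'design' section")
  design <- OrchardDesign(B = d$B %||% 1,
                          N = d$N %||% 10e6,
                          D = d$D %||% 0,
                          C = d$C %||% 0,
                          n = d$n %||% 600)
  p <- raw$priors %||% list()
  priors <- PriorSpec(tau = .num_or(p$tau, "low"),
                      delta = .num_or(p$delta, "medium"),
                      lambda = p$lambda %||% c(20, 30),
                      pi = p$pi %||% c(1, 1),
                      invSigma = p$invSigma %||% c(0, 1))
  s <- raw$settings %||% list()
  settings <- McmcSettings(chains = s$chains %||% 3,
                           iterations = s$iterations %||% 100000,
                           burnin = s$burnin %||% 10000,
                           thin = s$thin %||% 1,
                           seed = s$seed %||% 1)
  data <- if (!is.null(raw$data))
    SurveillanceData(x = raw$data$x, y = raw$data$y)
  ScenarioConfig(name = raw$name %||% basename(path),
                 design = design, priors = priors, data = data,
                 settings = settings,
                 blockEffects = raw$blockEffects %||% "auto",
                 multipleDetections = raw$multipleDetections %||% FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.num_or <- function(x, default) {
  if (is.null(x)) default
  else if (is.character(x)) x
  else as.numeric(unlist(x))
}

#' Export a simulated dataset as CSV with a JSON metadata sidecar
#'
#' Writes the per-block truth and observations to `path` and the scalar
#' generator settings (seed included) to `paste0(path, ".meta.json")`.
#'
#' @param sim a [SimulatedDataset-class].
#' @param path output CSV path.
#' @return Invisibly, the CSV path.
#' @export
exportDataset <- function(sim, path) {
  stopifnot(is(sim, "SimulatedDataset"))
  tab <- data.frame(block = seq_len(sim@design@B), pests = sim@pests,
                    infested = sim@infested, prevalence = sim@prevalence,
                    trap_density = sim@design@D,
                    consignments = sim@design@C,
                    x = sim@data@x, y = sim@data@y)
  utils::write.csv(tab, path, row.names = FALSE)
  meta <- list(seed = sim@seed, pest_intensity = sim@pestIntensity,
               lambda_O = sim@lambdaO, delta_true = sim@deltaTrue,
               tau_true = sim@tauTrue, N = sim@design@N, n = sim@design@n,
               orchard_prevalence = sim@orchardPrevalence)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a recovery-study table as CSV with a JSON metadata sidecar
#'
#' @param table the `data.frame` returned by [recoveryStudy()].
#' @param path output CSV path.
#' @param masterSeed the master seed the study was run under, recorded in
#'   `paste0(path, ".meta.json")`.
#' @return Invisibly, the CSV path.
#' @export
exportRecoveryTable <- function(table, path, masterSeed) {
  utils::write.csv(table, path, row.names = FALSE)
  jsonlite::write_json(list(master_seed = as.integer(masterSeed)),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
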