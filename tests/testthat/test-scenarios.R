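test_that("named prior levels resolve to the documented hyperparameters", {
  low <- PriorSpec(tau = "low")
  expect_equal(c(low@tauLower, low@tauUpper), c(0.0075, 0.0125))
  high <- PriorSpec(tau = "high")
  expect_equal(c(high@tauLower, high@tauUpper), c(0.075, 0.125))
  expect_equal(c(PriorSpec(delta = "low")@deltaAlpha,
                 PriorSpec(delta = "low")@deltaBeta), c(10, 90))
  expect_equal(c(PriorSpec(delta = "medium")@deltaAlpha,
                 PriorSpec(delta = "medium")@deltaBeta), c(50, 50))
  expect_equal(c(PriorSpec(delta = "high")@deltaAlpha,
                 PriorSpec(delta = "high")@deltaBeta), c(90, 10))
  def <- PriorSpec()
  expect_equal(c(def@lambdaLower, def@lambdaUpper), c(20, 30))
  expect_equal(c(def@piAlpha, def@piBeta), c(1, 1))
  expect_equal(c(def@invSigmaLower, def@invSigmaUpper), c(0, 1))
})

test_that("scenario bundles reproduce the reference designs", {
  st <- fast_settings(100)
  td <- scenarioBundle("trap-density", st)
  expect_length(td, 22)  # D 0..10 x tau low/high
  expect_true(all(vapply(td, function(c) c@design@B == 1L, logical(1))))
  expect_true(all(vapply(td, function(c) sum(c@design@C) == 0, logical(1))))
  expect_setequal(vapply(td, function(c) c@design@D[1], numeric(1)), 0:10)
  expect_true(all(vapply(td, function(c) c@design@N == 10e6, logical(1))))

  tb <- scenarioBundle("trap-blocks", st)
  expect_length(tb, 20)  # B 1..10 x tau low/high
  expect_setequal(vapply(tb, function(c) c@design@B, integer(1)), 1:10)
  expect_true(all(vapply(tb, function(c) all(c@design@D == 10), logical(1))))

  cn <- scenarioBundle("consignment-number", st)
  expect_length(cn, 21)  # 7 consignment counts x 3 sensitivities
  expect_true(all(vapply(cn, function(c) sum(c@design@D) == 0, logical(1))))
  expect_true(max(vapply(cn, function(c) c@design@C[1], numeric(1))) == 100)

  cb <- scenarioBundle("consignment-blocks", st)
  expect_length(cb, 30)  # B 1..10 x 3 sensitivities
  expect_true(all(vapply(cb, function(c) all(c@design@C == 100),
                         logical(1))))

  # combined bundles use the wider encounter-rate range
  cs <- scenarioBundle("combined-single-trap", st)
  expect_true(all(vapply(cs, function(c)
    c@priors@tauLower == 0.0075 && c@priors@tauUpper == 0.015,
    logical(1))))
  expect_true(all(vapply(cs, function(c) all(c@design@D == 1), logical(1))))
  ct <- scenarioBundle("combined-ten-traps", st)
  expect_true(all(vapply(ct, function(c) all(c@design@D == 10),
                         logical(1))))
  # all bundles run on clean (all-zero) data
  expect_true(all(vapply(c(td, tb, cn, cb, cs, ct), function(c)
    all(c@data@x == 0L) && all(c@data@y == 0L), logical(1))))
})

test_that("scenario configs round-trip through JSON and YAML", {
  cfg_list <- list(
    name = "roundtrip",
    design = list(B = 3, N = 1e7, D = c(1, 2, 3), C = c(4, 5, 6), n = 600),
    priors = list(tau = "high", delta = c(90, 10), lambda = c(20, 30)),
    data = list(x = c(0, 1, 0), y = c(2, 0, 0)),
    settings = list(chains = 2, iterations = 500, burnin = 10, seed = 99),
    blockEffects = "on")
  jpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg_list, jpath, auto_unbox = TRUE, digits = NA)
  ypath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg_list, ypath)

  for (path in c(jpath, ypath)) {
    cfg <- readScenarioConfig(path)
    expect_s4_class(cfg, "ScenarioConfig")
    expect_equal(cfg@name, "roundtrip")
    expect_equal(cfg@design@B, 3L)
    expect_equal(cfg@design@D, c(1, 2, 3))
    expect_equal(cfg@priors@tauUpper, 0.125)
    expect_equal(cfg@priors@deltaAlpha, 90)
    expect_equal(cfg@data@x, c(0L, 1L, 0L))
    expect_equal(cfg@settings@seed, 99L)
    expect_equal(cfg@blockEffects, "on")
  }
  # omitted data section means the clean all-zero mode
  cfg_list$data <- NULL
  yaml::write_yaml(cfg_list, ypath)
  cfg0 <- readScenarioConfig(ypath)
  expect_true(all(cfg0@data@x == 0L) && all(cfg0@data@y == 0L))
  expect_error(readScenarioConfig("no/such/file.yaml"), "not found")
})

test_that("a grid of one scenario matches the single-scenario run", {
  cfg <- ScenarioConfig("single", OrchardDesign(B = 1, C = 10),
                        settings = fast_settings(1500, seed = 8))
  one <- runScenario(cfg)
  grid <- runGrid(list(cfg))
  expect_equal(grid, one)
  expect_true(all(one$converged))
  expect_true("orchard_prevalence" %in% one$quantity)
})

test_that("grid reruns under one master seed are byte-identical", {
  cfgs <- list(
    ScenarioConfig("a", OrchardDesign(B = 1, C = 10),
                   settings = fast_settings(800)),
    ScenarioConfig("b", OrchardDesign(B = 1, D = 5, C = 0),
                   PriorSpec(tau = "high"),
                   settings = fast_settings(800)))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  runGrid(cfgs, masterSeed = 400, path = p1)
  runGrid(cfgs, masterSeed = 400, path = p2)
  expect_identical(readLines(p1), readLines(p2))
  tab <- read.csv(p1)
  # per-scenario seeds derive from the master seed
  expect_equal(unique(tab$seed), c(401L, 402L))
})

test_that("the command-line wrapper emits the status-quo table as CSV", {
  cli <- system.file("cli", "previnfer.R", package = "previnfer")
  expect_true(nzchar(cli))
  out <- withr::local_tempfile(fileext = ".csv")
  rscript <- file.path(R.home("bin"), "Rscript")
  res <- system2(rscript, c(cli, "statusquo", "--means", "1e-4,1e-2,0.1",
                            "--cv", "1", "--out", out),
                 stdout = TRUE, stderr = TRUE,
                 env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":")))
  expect_true(file.exists(out))
  tab <- read.csv(out)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$posterior_q95,
               statusQuoCurve(c(1e-4, 1e-2, 0.1), cv = 1)$posterior_q95,
               tolerance = 1e-10)
})
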