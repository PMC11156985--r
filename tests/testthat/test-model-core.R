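test_that("captureProbability follows 1 - exp(-tau D)", {
  expect_identical(captureProbability(0, 5), 0)
  expect_equal(captureProbability(0.1, 10), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(captureProbability(0.1, 10), 0.632121, tolerance = 1e-6)
  expect_equal(captureProbability(10, 10), 1, tolerance = 1e-12)
  expect_identical(captureProbability(0.5, 0), 0)
  expect_error(captureProbability(-1, 5), "non-negative")
  expect_error(captureProbability(0.1, -2), "non-negative")
})

test_that("capture probability and encounter-rate estimator are inverses", {
  taus <- c(1e-4, 0.0075, 0.01, 0.125, 1)
  Ds <- c(0.1, 1, 5, 10)
  for (tau in taus) for (D in Ds) {
    pc <- captureProbability(tau, D)
    expect_equal(estimateTau(pc, D), tau, tolerance = 1e-9)
  }
  # and the other direction
  for (p in c(0, 0.013, 0.5, 0.99)) for (D in Ds)
    expect_equal(captureProbability(estimateTau(p, D), D), p,
                 tolerance = 1e-12)
})

test_that("consignment detection rate is the product delta*n*C*pi", {
  expect_equal(consignmentDetectionRate(0.9, 600, 100, 1e-4), 5.4,
               tolerance = 1e-12)
  expect_equal(consignmentDetectionRate(0.5, 600, 1, 0.005), 1.5,
               tolerance = 1e-12)
  expect_identical(consignmentDetectionRate(0.7, 600, 0, 0.01), 0)
  # exact linearity in the consignment count
  for (C in c(1, 7, 100))
    expect_identical(consignmentDetectionRate(0.3, 600, C, 2e-5),
                     C * consignmentDetectionRate(0.3, 600, 1, 2e-5))
  expect_error(consignmentDetectionRate(1.2, 600, 1, 0.1), "delta")
  expect_error(consignmentDetectionRate(0.5, 600, 1, 1.1), "piBlock")
})

test_that("block prevalence shifts the overall prevalence on the logit scale", {
  expect_identical(blockPrevalence(0.5, 0), 0.5)
  # hand evaluation of inverse-logit(logit(1e-4) + 1)
  expect_equal(blockPrevalence(1e-4, 1), 2.7181e-4, tolerance = 1e-3)
  expect_equal(blockPrevalence(1e-4, 1),
               1 / (1 + exp(-(log(1e-4 / (1 - 1e-4)) + 1))),
               tolerance = 1e-12)
  # identity at V = 0 for any pi
  for (p in c(1e-7, 0.01, 0.5, 0.99))
    expect_equal(blockPrevalence(p, 0), p, tolerance = 1e-12)
  # monotone in V
  V <- sort(rnorm(20))
  expect_true(all(diff(blockPrevalence(0.01, V)) > 0))
  expect_error(blockPrevalence(0, 1), "inside")
  expect_error(blockPrevalence(1, 1), "inside")
})

test_that("derived infested-fruit and pest counts follow I = pi*N, P = I/O", {
  expect_equal(derivedQuantities(0, 1e7, 25), list(I = 0, P = 0))
  dq <- derivedQuantities(1e-5, 1e7, 25)
  expect_equal(dq$I, 100)
  expect_equal(dq$P, 4)
  dq1 <- derivedQuantities(0.3, 1000, 1)
  expect_equal(dq1$I, dq1$P)
  expect_error(derivedQuantities(0.1, 1e7, 0), ">= 1")
})

test_that("logJoint returns -Inf outside the parameter support", {
  d <- OrchardDesign(B = 2, D = c(5, 5), C = c(10, 10))
  pr <- PriorSpec()
  ok <- LatentState(pi = 1e-4, V = c(0, 0), sigma = 2, lambda = 25,
                    O = c(25, 25), tau = 0.01, delta = 0.5)
  dat <- allZeroData(d)
  expect_true(is.finite(logJoint(ok, dat, d, pr)))
  bad <- function(...) {
    st <- ok
    args <- list(...)
    for (nm in names(args)) slot(st, nm) <- args[[nm]]
    logJoint(st, dat, d, pr)
  }
  expect_identical(bad(pi = 1.5), -Inf)
  expect_identical(bad(pi = 0), -Inf)
  expect_identical(bad(delta = -0.1), -Inf)
  expect_identical(bad(sigma = -1), -Inf)
  expect_identical(bad(O = c(0, 25)), -Inf)   # zero fruit per pest
  expect_identical(bad(O = c(25.5, 25)), -Inf) # non-integer
  expect_identical(bad(lambda = 50), -Inf)     # outside uniform prior
  expect_identical(bad(tau = 1), -Inf)
  expect_identical(bad(sigma = 0.5), -Inf)     # 1/sigma outside U(0,1)
  # dimension mismatch is an error, not -Inf
  st3 <- LatentState(pi = 1e-4, V = c(0, 0, 0), sigma = 2, lambda = 25,
                     O = c(25, 25, 25), tau = 0.01, delta = 0.5)
  expect_error(logJoint(st3, dat, d, pr), "blocks")
})

test_that("logJoint equals an independently coded term-by-term sum", {
  d <- OrchardDesign(B = 1, D = 5, C = 10)
  pr <- PriorSpec()
  st <- LatentState(pi = 0.5, V = 0, sigma = 2, lambda = 25, O = 25,
                    tau = 0.01, delta = 0.5)
  dat <- allZeroData(d)
  expect_equal(logJoint(st, dat, d, pr), ref_log_joint(st, dat, d, pr),
               tolerance = 1e-10)

  set.seed(41)
  for (i in 1:100) {
    cs <- random_valid_case()
    expect_equal(logJoint(cs$state, cs$data, cs$design, cs$priors),
                 ref_log_joint(cs$state, cs$data, cs$design, cs$priors),
                 tolerance = 1e-8)
    expect_equal(
      logJoint(cs$state, cs$data, cs$design, cs$priors,
               multipleDetections = TRUE),
      ref_log_joint(cs$state, cs$data, cs$design, cs$priors,
                    multipleDetections = TRUE),
      tolerance = 1e-8)
  }
})

test_that("one extra trap catch changes logJoint by log(rate)", {
  d <- OrchardDesign(B = 1, D = 2, C = 0)
  pr <- PriorSpec()
  st <- LatentState(pi = 1e-6, V = 0, sigma = 2, lambda = 25, O = 25,
                    tau = 0.01, delta = 0.5)
  rate <- derivedQuantities(blockPrevalence(st@pi, 0), d@N, st@O)$P *
    captureProbability(st@tau, d@D)
  expect_lt(rate, 1)
  l0 <- logJoint(st, SurveillanceData(0, 0), d, pr)
  l1 <- logJoint(st, SurveillanceData(1, 0), d, pr)
  expect_equal(l1 - l0, log(rate), tolerance = 1e-10)
})

test_that("domain types enforce their invariants", {
  expect_error(OrchardDesign(B = 0), "B")
  expect_error(OrchardDesign(B = 2, D = c(-1, 0)), "D")
  expect_error(PriorSpec(lambda = c(30, 20)), "lambdaLower")
  expect_error(PriorSpec(pi = c(0, 1)), "pi")
  expect_error(SurveillanceData(x = c(0, -1), y = c(0, 0)), "x")
  d <- OrchardDesign(B = 2, D = c(0, 5), C = c(1, 1))
  expect_error(validateData(SurveillanceData(x = c(1, 0), y = c(0, 0)), d),
               "no traps")
  expect_error(validateData(SurveillanceData(x = c(0, 0), y = c(601, 0)), d),
               "exceeds")
  expect_true(validateData(allZeroData(d), d))
})
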