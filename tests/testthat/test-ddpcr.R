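# Poisson droplet correction, positivity calling and normalization.

test_that("Poisson correction matches the closed form and is monotone", {
  expect_identical(poissonConcentration(0, 20000), 0)
  # independent closed-form evaluation: lambda = -ln(1 - 100/20000)
  expect_equal(poissonConcentration(100, 20000, 0.00085),
               -log(1 - 100 / 20000) / 0.00085, tolerance = 1e-12)
  expect_equal(poissonConcentration(100, 20000), 5.897, tolerance = 1e-3)

  k <- 0:500
  conc <- poissonConcentration(k, 20000)
  expect_true(all(diff(conc) > 0))

  # continuity in total: nearby totals give nearby concentrations
  expect_equal(poissonConcentration(100, 20000),
               poissonConcentration(100, 20001), tolerance = 1e-4)

  expect_error(poissonConcentration(10, 10), "saturated")
  expect_error(poissonConcentration(0, 0), "total")
  expect_error(poissonConcentration(-1, 100), "positives")
  expect_error(poissonConcentration(5, 100, dropletVolume = 0), "dropletVolume")
})

test_that("simulated droplet counts round-trip through the Poisson correction", {
  v <- 0.85e-3
  n <- 20000
  set.seed(101)
  for (c0 in c(0.05, 0.2, 1, 3, 10)) {
    pPos <- 1 - exp(-c0 * v)
    k <- rbinom(1, n, pPos)
    cHat <- poissonConcentration(k, n, v)
    # 3 binomial SEs on the positive fraction, propagated through
    # dc/dp = 1 / ((1 - p) v)
    tol <- 3 * sqrt(pPos * (1 - pPos) / n) / ((1 - pPos) * v)
    expect_lt(abs(cHat - c0), tol)
  }
})

test_that("positivity rules reproduce the rerun and two-of-three decisions", {
  one <- function(k, n = 20000) data.frame(positives = k, total = n)

  # single positive droplet cannot be trusted: rerun twice
  r <- classifySample(one(1))
  expect_identical(r@status, "rerun_required")
  expect_true("single_droplet" %in% r@qcFlags)

  # two of three positive runs: positive, mean of the positive concentrations
  runs <- data.frame(positives = c(1, 0, 2), total = rep(20000, 3))
  r <- classifySample(runs)
  expect_identical(r@status, "positive")
  expect_equal(r@finalConcentration,
               mean(poissonConcentration(c(1, 2), 20000)))

  # one of three positive: negative
  expect_identical(
    classifySample(data.frame(positives = c(1, 0, 0),
                              total = rep(20000, 3)))@status, "negative")

  # clean single runs
  expect_identical(classifySample(one(0, 15000))@status, "negative")
  expect_equal(classifySample(one(0, 15000))@finalConcentration, 0)
  r <- classifySample(one(5))
  expect_identical(r@status, "positive")
  expect_equal(r@finalConcentration, poissonConcentration(5, 20000))

  # droplet QC: a lone low-droplet run must be rerun and is flagged
  r <- classifySample(one(5, 8000))
  expect_identical(r@status, "rerun_required")
  expect_true("low_droplets" %in% r@qcFlags)
  # a passing replacement run rescues the sample
  r <- classifySample(data.frame(positives = c(5, 5),
                                 total = c(8000, 20000)))
  expect_identical(r@status, "positive")

  # two passing runs that disagree: one more rerun
  expect_identical(
    classifySample(data.frame(positives = c(0, 3),
                              total = rep(20000, 2)))@status,
    "rerun_required")

  expect_error(classifySample(data.frame()), "one technical run")
})

test_that("positivity calls are invariant to the order of technical runs", {
  runs <- data.frame(positives = c(1, 0, 2), total = c(20000, 18244, 21000))
  base <- classifySample(runs)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    r <- classifySample(runs[perm, ])
    expect_identical(r@status, base@status)
    expect_equal(r@finalConcentration, base@finalConcentration)
  }
})

test_that("normalization scales reaction concentration to the raw sample", {
  expect_equal(normalizeConcentration(1, 1, 1, 1, 1), 1)
  # 0.5 copies/uL, 20 uL reaction, 6 uL template, 100 uL elution, 0.5 L
  expect_equal(normalizeConcentration(0.5, 20, 6, 100, 0.5),
               0.5 * 20 / 6 * 100 / 0.5, tolerance = 1e-12)
  expect_equal(normalizeConcentration(0.5, 20, 6, 100, 0.5), 333.3,
               tolerance = 1e-3)
  expect_equal(normalizeConcentration(0, 20, 6, 100, 2), 0)
  expect_equal(waterMlToGrams(500), 500)
  expect_error(normalizeConcentration(1, 0, 6, 100, 1), "positive")
  expect_error(normalizeConcentration(1, 20, 6, 100, 0), "positive")
})

test_that("LoQ estimation finds a planted breakpoint and never extrapolates", {
  # exactly proportional ladder: no deviation anywhere
  flat <- dilutionSeries(10^(3:-2), as.list(2 * 10^(3:-2)))
  loq <- estimateLoq(flat)
  expect_true(is.na(loq))
  expect_true(isTRUE(attr(loq, "belowRange")))

  # proportional down to 10, inflated 3-fold underneath
  expected <- 10^(3:-2)
  measured <- lapply(expected, function(e)
    rep(2 * e * ifelse(e < 10, 3, 1), 3))
  s <- dilutionSeries(expected, measured)
  expect_equal(estimateLoq(s), 10)
  expect_true(estimateLoq(s) %in% expected)

  expect_error(estimateLoq(dilutionSeries(c(100, 10, 1),
                                          as.list(c(200, 20, 2)))),
               "at least 4")
  expect_error(dilutionSeries(c(1, 10, 100, 1000),
                              as.list(rep(1, 4))),
               "decreasing")
  expect_error(estimateLoq(s, deviationTolerance = 1.5), "deviationTolerance")
})
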