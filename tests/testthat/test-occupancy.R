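# Multi-method occupancy likelihood, fitting and AIC ranking.

test_that("site likelihood matches hand values and brute-force enumeration", {
  expect_equal(siteLikelihood(matrix(1, 2, 2), 1, 1, 1), 1)
  expect_equal(siteLikelihood(matrix(0, 2, 2), 0, 0.5, 0.5), 1)
  # closed form 0.2 + 0.8 (0.3 + 0.7 * 0.4 * 0.6)^2
  expect_equal(siteLikelihood(matrix(0, 2, 2), 0.8, 0.7, c(0.6, 0.4)),
               0.3752192, tolerance = 1e-9)

  # latent-state enumeration oracle on random histories and parameters
  set.seed(21)
  for (i in 1:25) {
    y <- matrix(sample(c(0, 1, NA), 4, replace = TRUE,
                       prob = c(0.4, 0.4, 0.2)), 2, 2)
    psi <- runif(1); theta <- runif(1)
    p <- matrix(runif(4), 2, 2)
    expect_equal(siteLikelihood(y, psi, theta, p),
                 bruteForceSiteLikelihood(y, psi, theta, p),
                 tolerance = 1e-12)
  }

  expect_error(siteLikelihood(matrix(0, 2, 2), 0.5, 0.5, matrix(0.5, 3, 2)),
               "dimensions")
  expect_error(siteLikelihood(matrix(0, 2, 2), 1.5, 0.5, 0.5), "0, 1")
})

test_that("site likelihood is a probability distribution over complete histories", {
  set.seed(5)
  for (i in 1:20) {
    psi <- runif(1); theta <- runif(1)
    p <- matrix(runif(4), 2, 2)
    tot <- sum(vapply(allCompleteHistories(),
                      function(y) siteLikelihood(y, psi, theta, p),
                      numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-10)
  }
})

test_that("missing cells marginalize: likelihood with NA equals the sum over completions", {
  set.seed(9)
  for (i in 1:10) {
    psi <- runif(1); theta <- runif(1)
    p <- matrix(runif(4), 2, 2)
    y <- matrix(sample(c(0, 1), 4, replace = TRUE), 2, 2)
    y[sample(4, 1)] <- NA
    cell <- which(is.na(y))
    y0 <- y; y0[cell] <- 0
    y1 <- y; y1[cell] <- 1
    expect_equal(siteLikelihood(y, psi, theta, p),
                 siteLikelihood(y0, psi, theta, p) +
                   siteLikelihood(y1, psi, theta, p),
                 tolerance = 1e-12)
  }
})

test_that("the sixteen model variants have the advertised parameter counts", {
  specs <- allModelSpecs()
  expect_length(specs, 16L)
  expect_length(unique(vapply(specs, modelLabel, character(1))), 16L)
  ks <- vapply(specs, nParameters, integer(1))
  expect_true(all(ks >= 3L & ks <= 8L))
  expect_identical(nParameters(occuModelSpec()), 3L)
  expect_identical(nParameters(occuModelSpec(psi = "by_location",
                                             theta = "by_location",
                                             p = "by_method_and_location")),
                   8L)
})

test_that("with occupancy and availability fixed at 1, p-hat equals the detection fraction", {
  set.seed(33)
  for (i in 1:15) {
    S <- sample(6:14, 1)
    y <- array(rbinom(S * 4, 1, runif(1, 0.25, 0.75)), dim = c(S, 2, 2))
    h <- makeHistory(y, S)
    f <- fitOccupancy(h, occuModelSpec(p = "by_method"),
                      fixed = c(psi = 1, theta = 1))
    obs <- c(p_water = mean(y[, , 1]), p_sediment = mean(y[, , 2]))
    expect_equal(estimates(f)[names(obs)], obs, tolerance = 1e-6)
    expect_identical(nParameters(f), 2L)
  }
})

test_that("fits are invariant under permutation of site order", {
  set.seed(41)
  y <- array(rbinom(20 * 4, 1, 0.5), dim = c(20, 2, 2))
  loc <- sample(c("near_shore", "mid_lake"), 20, replace = TRUE)
  h1 <- detectionHistory(y, location = loc)
  perm <- sample(20)
  h2 <- detectionHistory(y[perm, , , drop = FALSE], location = loc[perm])
  spec <- occuModelSpec(p = "by_method_and_location")
  f1 <- fitOccupancy(h1, spec)
  f2 <- fitOccupancy(h2, spec)
  expect_equal(logLikelihood(f1), logLikelihood(f2), tolerance = 1e-6)
  expect_equal(estimates(f1), estimates(f2), tolerance = 1e-4)
})

test_that("fit recovers generating parameters on a large simulated survey", {
  cfg <- lakeConfig(nSites = 200, p = c(water = 0.9, sediment = 0.4),
                    seed = 2024)
  d <- generateDataset(cfg)
  h <- binarizeDetections(classifyReplicates(d$runs), species = "perch")
  f <- fitOccupancy(h, occuModelSpec(p = "by_method"))
  expect_true(f@converged)
  expect_lt(abs(estimates(f)[["p_water"]] - 0.9), 0.05)
  expect_lt(abs(estimates(f)[["p_sediment"]] - 0.4), 0.05)
  expect_true(all(estimates(f) >= 0 & estimates(f) <= 1))
})

test_that("log-likelihood is monotone in model nesting", {
  set.seed(55)
  y <- array(rbinom(30 * 4, 1, 0.4), dim = c(30, 2, 2))
  h <- detectionHistory(y, location = rep(c("near_shore", "mid_lake"), 15))
  small <- fitOccupancy(h, occuModelSpec(p = "constant"))
  big <- fitOccupancy(h, occuModelSpec(p = "by_method_and_location"))
  expect_gte(logLikelihood(big), logLikelihood(small) - 1e-6)
})

test_that("AIC ranking is sorted, normalized and consistent with the formula", {
  set.seed(66)
  y <- array(rbinom(25 * 4, 1, 0.5), dim = c(25, 2, 2))
  h <- detectionHistory(y, location = rep(c("near_shore", "mid_lake"),
                                          c(13, 12)))
  r <- rankModels(h, allModelSpecs()[c(1, 2, 5, 9)])
  tb <- rankingTable(r)
  expect_equal(tb$AIC, -2 * tb$logLik + 2 * tb$K)
  expect_false(is.unsorted(tb$AIC))
  expect_equal(tb$deltaAIC[1], 0)
  expect_equal(sum(tb$weight), 1, tolerance = 1e-12)
  expect_s4_class(bestFit(r), "OccuFit")
  expect_identical(modelLabel(modelSpec(bestFit(r))), tb$model[1])
  expect_error(rankModels(h, allModelSpecs()[1]), "two model specs")
})

test_that("boundary estimates are snapped, flagged and their SEs withheld", {
  # every observation positive: p is estimated at the upper bound
  h <- makeHistory(rep(1, 10 * 4), 10)
  f <- fitOccupancy(h, occuModelSpec(p = "constant"),
                    fixed = c(psi = 1, theta = 1))
  expect_identical(unname(estimates(f)["p"]), 1)
  expect_true("p" %in% f@boundaryFlags)
  expect_true(is.na(standardErrors(f)["p"]))
})
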