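# Synthetic lake surveys: schema, determinism, latent-truth invariants.

test_that("the generated survey has the field-design schema and is seed-deterministic", {
  cfg <- lakeConfig(seed = 42)
  d <- generateDataset(cfg)
  reps <- classifyReplicates(d$runs)
  # 14 sites x 2 occasions x 2 methods per species
  expect_identical(nrow(d$truth), 14L * 2L * 2L * 2L)
  for (sp in c("perch", "rudd"))
    expect_identical(sum(reps$species == sp), 56L)
  expect_identical(sort(unique(d$runs$location)),
                   c("mid_lake", "near_shore"))
  expect_equal(sum(d$truth$location == "near_shore"), nrow(d$truth) / 2)

  d2 <- generateDataset(lakeConfig(seed = 42))
  expect_identical(d$runs, d2$runs)
  expect_identical(d$truth, d2$truth)
  d3 <- generateDataset(lakeConfig(seed = 43))
  expect_false(identical(d$runs, d3$runs))
})

test_that("latent truth is hierarchical and concentrations attach to detections only", {
  d <- generateDataset(lakeConfig(psi = 0.7, theta = 0.8,
                                  p = c(water = 0.5, sediment = 0.5),
                                  nSites = 40, seed = 8))
  tr <- d$truth
  expect_true(all(tr$available <= tr$occupied))
  expect_true(all(tr$detected <= tr$available))
  expect_true(all((tr$trueConcentration > 0) == (tr$detected == 1)))
})

test_that("perfect detection yields an all-positive survey", {
  d <- generateDataset(lakeConfig(psi = 1, theta = 1, p = 1, seed = 3))
  reps <- classifyReplicates(d$runs)
  expect_true(all(reps$status == "positive"))
  h <- binarizeDetections(reps, species = "perch")
  expect_true(all(detectionArray(h) == 1))
  expect_equal(naiveOccupancy(h), 1)
})

test_that("droplet counts round-trip the generating concentration distribution", {
  cfg <- lakeConfig(nSites = 300, p = 1, seed = 12, species = "perch")
  d <- generateDataset(cfg)
  reps <- classifyReplicates(d$runs)
  key <- function(x) paste(x$site, x$occasion, x$method)
  tr <- d$truth[match(key(reps), key(d$truth)), ]
  pos <- reps$status == "positive"
  expect_identical(pos, tr$detected == 1L)
  # per-replicate Poisson-corrected concentration tracks the planted one;
  # restrict to levels where the binomial droplet error is small
  quant <- pos & tr$trueConcentration >= 0.5
  logRatio <- log10(reps$concentration[quant] /
                      tr$trueConcentration[quant])
  expect_lt(abs(mean(logRatio)), 0.05)
  expect_gt(cor(log10(reps$concentration[pos]),
                log10(tr$trueConcentration[pos])), 0.9)
})

test_that("single-positive-droplet replicates are emitted with two rerun runs", {
  # tiny concentrations make single-droplet runs common
  d <- generateDataset(lakeConfig(nSites = 120, p = 1,
                                  concMeanLog10 = log10(0.02),
                                  concSdLog10 = 0.1, seed = 5,
                                  species = "perch"))
  runCounts <- table(interaction(d$runs$site, d$runs$occasion,
                                 d$runs$method, drop = TRUE))
  expect_true(any(runCounts == 3))
  expect_true(all(runCounts %in% c(1L, 3L)))
  firstRuns <- d$runs[d$runs$run == 1L, ]
  rerun <- interaction(firstRuns$site[firstRuns$positives == 1L],
                       firstRuns$occasion[firstRuns$positives == 1L],
                       firstRuns$method[firstRuns$positives == 1L])
  expect_identical(sort(as.character(rerun)),
                   sort(names(runCounts[runCounts == 3])))
})

test_that("synthetic dilution ladders plant a recoverable LoQ", {
  flat <- generateDilutionSeries(inflationBelow = 1, seed = 2)
  expect_true(isTRUE(attr(estimateLoq(flat), "belowRange")))

  s <- generateDilutionSeries(trueLoq = 10, steps = 6, topExpected = 1000,
                              inflationBelow = 3, seed = 31)
  expect_equal(estimateLoq(s), 10)

  s1 <- generateDilutionSeries(seed = 9)
  s2 <- generateDilutionSeries(seed = 9)
  expect_identical(s1@measured, s2@measured)
})

test_that("model selection prefers the generating structure on large surveys", {
  hits <- 0L
  for (seed in 1:5) {
    d <- generateDataset(lakeConfig(nSites = 200, species = "perch",
                                    p = c(water = 0.9, sediment = 0.4),
                                    seed = 100 + seed))
    h <- binarizeDetections(classifyReplicates(d$runs), species = "perch")
    tb <- rankingTable(rankModels(h))
    genRow <- tb[tb$model == modelLabel(occuModelSpec(p = "by_method")), ]
    if (genRow$deltaAIC <= 2) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
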