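## Synthetic lake surveys with known latent truth.
##
## The generator mirrors the structure the analysis assumes: latent
## occupancy and availability, method- and location-dependent detection,
## log-normal concentrations for detected replicates, and binomial droplet
## counts at ~20,000 droplets per reaction. Every pipeline stage can
## therefore be validated against a known ground truth.

#' Configuration of a synthetic lake survey
#'
#' Defaults emulate the field design of a small-lake eDNA survey: 14 sites
#' per lake (7 near-shore, 7 mid-lake), 2 biological replicates (occasions)
#' of each of 2 sampling methods (water, sediment), two species assays.
#' Detected replicates receive a log-normal concentration (default mean
#' 0.3 copies/uL, sd 0.5 log10 units, spanning the 0.05-7 copies/uL range
#' typical of positive lake samples); droplet totals are Poisson around
#' `dropletsMean`, floored at 10001 so QC passes unless configured
#' otherwise.
#'
#' @param lake lake name.
#' @param nSites number of sites; locations are balanced near-shore /
#'   mid-lake (first half near-shore).
#' @param occasions biological replicates per site and method.
#' @param species assay names.
#' @param psi,theta latent occupancy and availability probabilities.
#' @param p detection probability: a scalar, a named vector by method
#'   (`water`, `sediment`), or a methods x locations matrix with dimnames
#'   (`water`/`sediment` x `near_shore`/`mid_lake`).
#' @param concMeanLog10,concSdLog10 log10 mean and sd of the positive
#'   concentration distribution (copies/uL of reaction).
#' @param dropletsMean mean accepted droplets per run (>= 10000).
#' @param dropletsFloor minimum droplets per run; default 10001 keeps all
#'   runs above the QC threshold.
#' @param dropletVolume droplet volume in uL.
#' @param seed integer seed.
#' @return list of class `lakeConfig`.
#' @export
lakeConfig <- function(lake = "Lake_A", nSites = 14, occasions = 2,
                       species = c("perch", "rudd"),
                       psi = 1, theta = 1,
                       p = c(water = 0.64, sediment = 0.93),
                       concMeanLog10 = log10(0.3), concSdLog10 = 0.5,
                       dropletsMean = 20000, dropletsFloor = 10001,
                       dropletVolume = 0.85e-3, seed = 1) {
  stopifnot(nSites >= 1, occasions >= 1, psi >= 0, psi <= 1,
            theta >= 0, theta <= 1, dropletsMean >= 10000)
  pm <- .expandPMatrix(p)
  structure(list(lake = lake, nSites = as.integer(nSites),
                 occasions = as.integer(occasions), species = species,
                 psi = psi, theta = theta, p = pm,
                 concMeanLog10 = concMeanLog10, concSdLog10 = concSdLog10,
                 dropletsMean = dropletsMean,
                 dropletsFloor = as.integer(dropletsFloor),
                 dropletVolume = dropletVolume, seed = as.integer(seed)),
            class = "lakeConfig")
}

# normalize p to a methods x locations matrix
.expandPMatrix <- function(p) {
  if (is.matrix(p)) {
    stopifnot(all(rownames(p) %in% .METHODS),
              all(colnames(p) %in% .LOCATIONS))
    pm <- p[.METHODS, .LOCATIONS]
  } else if (!is.null(names(p))) {
    stopifnot(all(names(p) %in% .METHODS))
    pm <- matrix(p[.METHODS], 2L, 2L,
                 dimnames = list(.METHODS, .LOCATIONS))
  } else {
    stopifnot(length(p) == 1L)
    pm <- matrix(p, 2L, 2L, dimnames = list(.METHODS, .LOCATIONS))
  }
  stopifnot(all(pm >= 0 & pm <= 1))
  pm
}

#' Generate a synthetic lake survey with ground truth
#'
#' Draws the latent states, assigns log-normal concentrations to detected
#' replicates, converts each concentration to a binomial droplet count
#' (`positives ~ Binomial(total, 1 - exp(-c v))`), and emits one
#' technical-run row per reaction in the replicate-table layout. A run
#' with exactly one positive droplet triggers two simulated reruns of the
#' same extract, mirroring the lab protocol, so the downstream
#' two-of-three rule is exercised. Fully reproducible for a fixed seed.
#'
#' The detection probability `p` is the probability that a replicate
#' yields a positive call, with every sensitivity loss already folded in;
#' the concentration model therefore describes the levels of detected
#' samples. Concentrations for detected replicates are drawn from the
#' log-normal conditioned on producing a positive call (rejection
#' sampling), so the latent detection indicator and the downstream
#' positivity call coincide exactly and recovery tests have a clean
#' ground truth.
#'
#' @param config a [lakeConfig()] list.
#' @return list with `runs` (data.frame: lake, site, location, method,
#'   occasion, species, run, positives, total, concentration) and `truth`
#'   (data.frame of latent occupancy, availability, detection and true
#'   concentration per site x occasion x method x species).
#' @examples
#' d <- generateDataset(lakeConfig(seed = 7))
#' head(d$runs)
#' @export
generateDataset <- function(config) {
  stopifnot(inherits(config, "lakeConfig"))
  .withSeed(config$seed, .generateDatasetImpl(config))
}

.generateDatasetImpl <- function(config) {
  nS <- config$nSites
  nJ <- config$occasions
  loc <- rep(.LOCATIONS, c(ceiling(nS / 2), floor(nS / 2)))
  v <- config$dropletVolume

  runs <- list()
  truth <- list()
  for (sp in config$species) {
    z <- stats::rbinom(nS, 1L, config$psi)
    for (site in seq_len(nS)) {
      for (j in seq_len(nJ)) {
        a <- z[site] * stats::rbinom(1L, 1L, config$theta)
        for (m in .METHODS) {
          d <- a * stats::rbinom(1L, 1L, config$p[m, loc[site]])
          drawRun <- function(runIdx, pPos) {
            total <- max(stats::rpois(1L, config$dropletsMean),
                         config$dropletsFloor)
            k <- min(stats::rbinom(1L, total, pPos), total - 1L)
            data.frame(lake = config$lake, site = site,
                       location = loc[site], method = m, occasion = j,
                       species = sp, run = runIdx, positives = k,
                       total = total,
                       concentration = poissonConcentration(k, total, v),
                       stringsAsFactors = FALSE)
          }
          drawReplicate <- function(conc) {
            r <- drawRun(1L, 1 - exp(-conc * v))
            if (r$positives == 1L)  # lab protocol: rerun twice
              r <- rbind(r, drawRun(2L, 1 - exp(-conc * v)),
                         drawRun(3L, 1 - exp(-conc * v)))
            r
          }
          if (d == 1L) {
            # the latent indicator says this replicate IS a detection, so
            # the emitted droplet counts must classify positive: the
            # concentration is drawn from the log-normal conditioned on
            # detectability (rejection sampling)
            for (attempt in seq_len(1000L)) {
              conc <- 10^stats::rnorm(1L, config$concMeanLog10,
                                      config$concSdLog10)
              r <- drawReplicate(conc)
              status <- classifySample(r[, c("positives", "total")],
                                       dropletVolume = v)@status
              if (status == "positive") break
            }
            if (status != "positive")
              stop("could not realise a detectable concentration; ",
                   "concMeanLog10 is far below the assay's reach")
          } else {
            conc <- 0
            r <- drawReplicate(0)
          }
          runs[[length(runs) + 1L]] <- r
          truth[[length(truth) + 1L]] <- data.frame(
            lake = config$lake, site = site, location = loc[site],
            method = m, occasion = j, species = sp,
            occupied = z[site], available = a, detected = d,
            trueConcentration = conc, stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(runs = do.call(rbind, runs), truth = do.call(rbind, truth))
}

#' Classify every biological replicate of a run table
#'
#' Applies [classifySample()] to each (lake, site, method, occasion,
#' species) group of technical runs and returns one replicate-level record
#' per group, ready for [binarizeDetections()].
#'
#' @param runs run-level `data.frame` as produced by [generateDataset()]
#'   or read by [readReplicateTable()].
#' @param qcMinDroplets,dropletVolume passed to [classifySample()].
#' @return `data.frame` with columns lake, site, location, method,
#'   occasion, species, status, concentration, qcFlags.
#' @export
classifyReplicates <- function(runs, qcMinDroplets = 10000,
                               dropletVolume = 0.85e-3) {
  need <- c("lake", "site", "location", "method", "occasion", "species",
            "positives", "total")
  if (!is.data.frame(runs) || !all(need %in% names(runs)))
    stop("runs must contain columns: ", paste(need, collapse = ", "))
  key <- interaction(runs$lake, runs$site, runs$method, runs$occasion,
                     runs$species, drop = TRUE)
  groups <- split(runs, key)
  out <- lapply(groups, function(g) {
    call <- classifySample(g[, c("positives", "total")], qcMinDroplets,
                           dropletVolume)
    data.frame(lake = g$lake[1L], site = g$site[1L],
               location = g$location[1L], method = g$method[1L],
               occasion = g$occasion[1L], species = g$species[1L],
               status = call@status,
               concentration = call@finalConcentration,
               qcFlags = paste(call@qcFlags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$lake, res$species, res$site, res$occasion, res$method), ]
}

#' Generate a synthetic dilution series with a planted LoQ
#'
#' Measured concentrations are proportional to the nominal ladder (with
#' multiplicative log-normal noise) down to `trueLoq`, and systematically
#' inflated by `inflationBelow` underneath it — the bend that the LoQ
#' estimator is meant to find.
#'
#' @param trueLoq the planted breakpoint, on the expected-concentration
#'   scale; should coincide with one of the ladder steps.
#' @param steps number of dilution steps (>= 4); default 6.
#' @param topExpected highest nominal concentration; steps descend from it
#'   in factors of 10.
#' @param inflationBelow multiplicative bias applied below `trueLoq`
#'   (> 1); 1 plants no deviation at all.
#' @param replicates measurements per step (default 3).
#' @param proportionality measured/expected ratio in the quantitative
#'   range.
#' @param noiseSdLog10 sd of the multiplicative measurement noise, log10
#'   units.
#' @param seed integer seed.
#' @return a [DilutionSeries-class].
#' @examples
#' estimateLoq(generateDilutionSeries(trueLoq = 10, seed = 3))
#' @export
generateDilutionSeries <- function(trueLoq = 10, steps = 6,
                                   topExpected = 1000, inflationBelow = 3,
                                   replicates = 3, proportionality = 2,
                                   noiseSdLog10 = 0.02, seed = 1) {
  stopifnot(steps >= 4, inflationBelow >= 1, replicates >= 1)
  expected <- topExpected * 10^(-(seq_len(steps) - 1L))
  measured <- .withSeed(seed, lapply(expected, function(e) {
    bias <- if (e < trueLoq) inflationBelow else 1
    proportionality * e * bias *
      10^stats::rnorm(replicates, 0, noiseSdLog10)
  }))
  dilutionSeries(expected, measured)
}
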