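## Survey-design simulation: how many sites and replicates are enough?

#' Design criteria for the minimum-effort search
#'
#' A whole-survey false negative (an "empty history": zero detections at
#' every site although the target is present) is the failure mode the
#' design must avoid. The criterion is that its probability rounds to
#' 0.0 percent, i.e. is at most `emptyHistoryTolerance` (default 1e-3).
#' The precision of the detection-probability estimate is tracked as a
#' diagnostic via `seTolerance` (default 0.05) but does not gate the
#' search.
#'
#' @param emptyHistoryTolerance maximum acceptable empty-history
#'   probability, in (0, 1).
#' @param seTolerance reference bound for the analytic standard error of
#'   the detection-probability estimate, in (0, 1).
#' @param nSims Monte-Carlo simulations per evaluated design (default
#'   10000).
#' @param seed integer seed for Monte-Carlo mode.
#' @return list of class `designCriteria`.
#' @export
designCriteria <- function(emptyHistoryTolerance = 1e-3, seTolerance = 0.05,
                           nSims = 10000, seed = 1) {
  stopifnot(emptyHistoryTolerance > 0, emptyHistoryTolerance < 1,
            seTolerance > 0, seTolerance < 1, nSims >= 1)
  structure(list(emptyHistoryTolerance = emptyHistoryTolerance,
                 seTolerance = seTolerance, nSims = as.integer(nSims),
                 seed = as.integer(seed)),
            class = "designCriteria")
}

#' Simulate a detection history under known parameters
#'
#' Draws per-site occupancy `Bern(psi)`, per-replicate availability
#' `Bern(theta)` and detection `Bern(p)` conditional on the latent states:
#' the generative model behind the occupancy likelihood, for one sampling
#' method.
#'
#' @param psi,theta,p probabilities in \[0, 1\].
#' @param sites,replicates positive counts (replicates are the repeated
#'   surveys per site).
#' @param seed integer seed; the draw is reproducible.
#' @return a [DetectionHistory-class] with dimensions
#'   `sites x replicates x 1`.
#' @examples
#' simulateHistory(1, 1, 0.5, sites = 10, replicates = 2, seed = 42)
#' @export
simulateHistory <- function(psi, theta, p, sites, replicates, seed = 1) {
  stopifnot(psi >= 0, psi <= 1, theta >= 0, theta <= 1, p >= 0, p <= 1,
            sites >= 1, replicates >= 1)
  y <- .withSeed(seed, {
    z <- stats::rbinom(sites, 1L, psi)
    a <- matrix(stats::rbinom(sites * replicates, 1L, theta),
                sites, replicates) * z
    matrix(stats::rbinom(sites * replicates, 1L, p),
           sites, replicates) * a
  })
  detectionHistory(array(y, dim = c(sites, replicates, 1L)))
}

#' Probability of an all-zero survey
#'
#' Closed form for the probability that a survey of `sites` sites with
#' `replicates` replicates each records no detection anywhere:
#' `prod over sites of [(1 - psi) + psi ((1 - theta) + theta (1 - p))^k]`.
#' With `psi = theta = 1` this reduces to `(1 - p)^(k s)`. Computed in log
#' space; monotone decreasing in each of `p`, `replicates`, `sites`.
#'
#' @param p detection probability.
#' @param replicates replicates per site (k).
#' @param sites number of sites (s).
#' @param psi,theta occupancy and availability; both default to 1, the
#'   worst-case surveillance assumption that the target is present and
#'   available everywhere.
#' @return probability in \[0, 1\].
#' @examples
#' emptyHistoryProbability(p = 0.21, replicates = 5, sites = 6)
#' @export
emptyHistoryProbability <- function(p, replicates, sites, psi = 1,
                                    theta = 1) {
  stopifnot(p >= 0, p <= 1, psi >= 0, psi <= 1, theta >= 0, theta <= 1,
            replicates >= 1, sites >= 1)
  perReplicateMiss <- (1 - theta) + theta * (1 - p)
  perSite <- (1 - psi) + psi * perReplicateMiss^replicates
  if (perSite == 0) return(0)
  exp(sites * log(perSite))
}

#' Monte-Carlo diagnostics for one candidate design
#'
#' Simulates `nSims` surveys at the given design and reports the observed
#' fraction of empty (all-zero) surveys, the distribution of false-negative
#' site counts (occupied-and-available sites that were never detected), the
#' analytic empty-history probability, and the analytic standard error of
#' the detection-probability estimate `sqrt(p (1 - p) / (s k))`.
#'
#' @param p,replicates,sites the design under evaluation.
#' @param criteria a [designCriteria()] list (supplies `nSims` and `seed`).
#' @param psi,theta occupancy and availability, default 1.
#' @return list with `emptyFraction`, `emptyProbAnalytic`,
#'   `falseNegativeSites` (integer vector of length `nSims`),
#'   `seEstimate`, `nSims`.
#' @export
evaluateDesign <- function(p, replicates, sites, criteria = designCriteria(),
                           psi = 1, theta = 1) {
  nSims <- criteria$nSims
  sims <- .withSeed(criteria$seed, {
    # detections per site collapse to Binomial draws; a site is a false
    # negative when it is occupied with >= 1 available replicate yet
    # records no detection
    vapply(seq_len(nSims), function(i) {
      z <- stats::rbinom(sites, 1L, psi)
      nAvail <- stats::rbinom(sites, replicates, theta) * z
      nDet <- stats::rbinom(sites, nAvail, p)
      c(empty = as.numeric(all(nDet == 0L)),
        falseNeg = sum(nAvail > 0L & nDet == 0L))
    }, numeric(2))
  })
  emptyFraction <- mean(sims["empty", ] == 1)
  falseNeg <- as.integer(sims["falseNeg", ])
  list(emptyFraction = emptyFraction,
       emptyProbAnalytic = emptyHistoryProbability(p, replicates, sites,
                                                   psi, theta),
       falseNegativeSites = falseNeg,
       seEstimate = sqrt(p * (1 - p) / (sites * replicates)),
       nSims = nSims)
}

#' Minimum number of sites for reliable detection
#'
#' Searches linearly upward in the number of sites for the smallest design
#' whose empty-history probability (analytic mode) or observed empty
#' fraction over `nSims` simulations (Monte-Carlo mode) does not exceed
#' `emptyHistoryTolerance`. The analytic SE of the detection-probability
#' estimate at the returned design is reported as a precision diagnostic.
#'
#' @param p detection probability per replicate.
#' @param replicates replicates per site.
#' @param criteria a [designCriteria()] list.
#' @param mode `"analytic"` or `"monte_carlo"`.
#' @param psi,theta occupancy and availability, default 1.
#' @param maxSites search cap (default 200); reaching it yields a result
#'   with `minSites = NA`, not an error.
#' @return a [DesignResult-class].
#' @examples
#' minimumDesign(p = 0.21, replicates = 5) # 6 sites
#' @export
minimumDesign <- function(p, replicates, criteria = designCriteria(),
                          mode = c("analytic", "monte_carlo"),
                          psi = 1, theta = 1, maxSites = 200) {
  mode <- match.arg(mode)
  stopifnot(p >= 0, p <= 1, replicates >= 1)
  for (s in seq_len(maxSites)) {
    emptyFrac <- if (mode == "analytic") {
      emptyHistoryProbability(p, replicates, s, psi, theta)
    } else {
      # per-cell seed stream so each (sites, replicates) cell is
      # independently reproducible
      cellCriteria <- criteria
      cellCriteria$seed <- criteria$seed + 1009L * s + replicates
      evaluateDesign(p, replicates, s, cellCriteria, psi,
                     theta)$emptyFraction
    }
    if (emptyFrac <= criteria$emptyHistoryTolerance)
      return(new("DesignResult", p = p, replicates = as.integer(replicates),
                 minSites = as.integer(s), emptyFraction = emptyFrac,
                 seEstimate = sqrt(p * (1 - p) / (s * replicates)),
                 mode = mode))
  }
  new("DesignResult", p = p, replicates = as.integer(replicates),
      minSites = NA_integer_, emptyFraction = NA_real_,
      seEstimate = NA_real_, mode = mode)
}

#' Minimum-sites table over a grid of detection probabilities and replicates
#'
#' Evaluates [minimumDesign()] over the cross of `pValues` and
#' `replicateValues`; the rows draw the familiar sites-versus-p curves,
#' one per replicate count.
#'
#' @param pValues detection probabilities (non-empty).
#' @param replicateValues replicate counts (non-empty).
#' @param criteria a [designCriteria()] list.
#' @param ... passed to [minimumDesign()].
#' @return `data.frame` with columns `p`, `replicates`, `minSites`,
#'   `emptyFraction`, `seEstimate`, `mode`.
#' @examples
#' designGrid(seq(0.1, 0.9, by = 0.2), c(2, 4))
#' @export
designGrid <- function(pValues, replicateValues,
                       criteria = designCriteria(), ...) {
  stopifnot(length(pValues) >= 1, length(replicateValues) >= 1)
  grid <- expand.grid(p = pValues, replicates = replicateValues)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    r <- minimumDesign(grid$p[i], grid$replicates[i], criteria, ...)
    data.frame(p = r@p, replicates = r@replicates, minSites = r@minSites,
               emptyFraction = r@emptyFraction, seEstimate = r@seEstimate,
               mode = r@mode)
  })
  do.call(rbind, rows)
}
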