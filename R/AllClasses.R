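#' @import methods
NULL

.LOCATIONS <- c("near_shore", "mid_lake")
.METHODS <- c("water", "sediment")

## ---------------------------------------------------------------------------
## PositivityCall: the final call for one biological replicate after QC,
## rerun and two-of-three rules have been applied to its technical runs.
## ---------------------------------------------------------------------------

#' PositivityCall class
#'
#' The outcome of applying droplet-count quality control and the
#' rerun/two-of-three positivity rules to the technical ddPCR runs of a
#' single biological replicate.
#'
#' @slot status one of `"positive"`, `"negative"`, `"rerun_required"`.
#' @slot finalConcentration copies/uL of reaction; mean over the positive
#'   contributing runs for a positive call, 0 for a negative call, `NA`
#'   when a rerun is required.
#' @slot runsUsed `data.frame` of the runs that informed the call
#'   (columns `positives`, `total`, `concentration`).
#' @slot qcFlags character vector, subset of
#'   `c("low_droplets", "single_droplet")`.
#'
#' @seealso [classifySample()]
#' @export
setClass("PositivityCall",
  representation(
    status = "character",
    finalConcentration = "numeric",
    runsUsed = "data.frame",
    qcFlags = "character"
  )
)

setValidity("PositivityCall", function(object) {
  msg <- character()
  if (length(object@status) != 1L ||
      !object@status %in% c("positive", "negative", "rerun_required"))
    msg <- c(msg, "status must be positive, negative or rerun_required")
  if (!all(object@qcFlags %in% c("low_droplets", "single_droplet")))
    msg <- c(msg, "unknown qc flag")
  if (length(object@status) == 1L) {
    if (identical(object@status, "positive") &&
        !isTRUE(object@finalConcentration > 0))
      msg <- c(msg, "positive call requires finalConcentration > 0")
    if (identical(object@status, "negative") &&
        !isTRUE(object@finalConcentration == 0))
      msg <- c(msg, "negative call requires finalConcentration == 0")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## DilutionSeries: expected vs measured concentrations down a dilution ladder.
## ---------------------------------------------------------------------------

#' DilutionSeries class
#'
#' An ordered dilution ladder: expected (nominal) concentrations, strictly
#' decreasing, each with one or more measured replicate concentrations from
#' ddPCR. Used to estimate the limit of quantification (LoQ).
#'
#' @slot expected numeric vector of nominal concentrations, strictly
#'   decreasing.
#' @slot measured list of numeric vectors, one per step, each with at least
#'   one replicate measurement in copies/uL.
#'
#' @seealso [dilutionSeries()], [estimateLoq()]
#' @export
setClass("DilutionSeries",
  representation(expected = "numeric", measured = "list")
)

setValidity("DilutionSeries", function(object) {
  msg <- character()
  if (length(object@expected) != length(object@measured))
    msg <- c(msg, "expected and measured must have the same length")
  if (length(object@expected) >= 2L && any(diff(object@expected) >= 0))
    msg <- c(msg, "expected concentrations must be strictly decreasing")
  if (any(object@expected <= 0))
    msg <- c(msg, "expected concentrations must be positive")
  if (any(!vapply(object@measured, function(m)
        is.numeric(m) && length(m) >= 1L && all(m >= 0), logical(1))))
    msg <- c(msg, "each step needs >= 1 non-negative measured value")
  if (length(msg)) msg else TRUE
})

#' Construct a DilutionSeries
#'
#' @param expected strictly decreasing nominal concentrations.
#' @param measured list of numeric replicate measurements (copies/uL), one
#'   element per step; a numeric matrix with one row per step is also
#'   accepted.
#' @return a [DilutionSeries-class] object.
#' @examples
#' dilutionSeries(10^(3:-2), as.list(2 * 10^(3:-2)))
#' @export
dilutionSeries <- function(expected, measured) {
  if (is.matrix(measured))
    measured <- lapply(seq_len(nrow(measured)), function(i) measured[i, ])
  new("DilutionSeries", expected = as.numeric(expected), measured = measured)
}

## ---------------------------------------------------------------------------
## DetectionHistory: the S x J x M presence/absence array the occupancy
## likelihood consumes. Values 0, 1 or NA (missing, e.g. QC-excluded).
## ---------------------------------------------------------------------------

#' DetectionHistory class
#'
#' A site x occasion x method binary detection array with missing-value
#' support, plus a per-site location covariate. This is the data object of
#' the multi-method occupancy model: rows are sampling sites (the sampling
#' units), occasions are repeated biological replicates, and methods are
#' the sampling media (water, sediment).
#'
#' @slot y 3-d array, sites x occasions x methods, values in \{0, 1, NA\}.
#' @slot location character vector, one of `"near_shore"`, `"mid_lake"`
#'   per site.
#' @slot lake,species optional single-string metadata.
#'
#' @seealso [detectionHistory()], [binarizeDetections()], [fitOccupancy()]
#' @export
setClass("DetectionHistory",
  representation(
    y = "array",
    location = "character",
    lake = "character",
    species = "character"
  )
)

setValidity("DetectionHistory", function(object) {
  msg <- character()
  d <- dim(object@y)
  if (length(d) != 3L)
    msg <- c(msg, "y must be a sites x occasions x methods array")
  else {
    if (any(d < 1L)) msg <- c(msg, "all dimensions must be >= 1")
    if (length(object@location) != d[1L])
      msg <- c(msg, "location covariate must have one entry per site")
  }
  v <- object@y[!is.na(object@y)]
  if (!all(v %in% c(0, 1)))
    msg <- c(msg, "y values must be 0, 1 or NA")
  if (!all(object@location %in% .LOCATIONS))
    msg <- c(msg, sprintf("location must be one of: %s",
                          paste(.LOCATIONS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a DetectionHistory
#'
#' @param y sites x occasions x methods array over \{0, 1, NA\}. Method
#'   dimnames default to `c("water", "sediment")` when the array has two
#'   unnamed method slices.
#' @param location per-site location covariate (`"near_shore"` /
#'   `"mid_lake"`); defaults to `"near_shore"` everywhere, for designs
#'   without a location effect.
#' @param lake,species optional metadata strings.
#' @return a [DetectionHistory-class] object.
#' @examples
#' y <- array(rbinom(14 * 2 * 2, 1, 0.5), dim = c(14, 2, 2))
#' h <- detectionHistory(y, location = rep(c("near_shore", "mid_lake"), 7))
#' naiveOccupancy(h)
#' @export
detectionHistory <- function(y, location = NULL, lake = NA_character_,
                             species = NA_character_) {
  y <- as.array(y)
  if (length(dim(y)) != 3L)
    stop("y must be a 3-d array (sites x occasions x methods)")
  storage.mode(y) <- "double"
  dn <- dimnames(y)
  if (is.null(dn)) dn <- vector("list", 3L)
  if (is.null(dn[[1L]])) dn[[1L]] <- as.character(seq_len(dim(y)[1L]))
  if (is.null(dn[[2L]])) dn[[2L]] <- paste0("occ", seq_len(dim(y)[2L]))
  if (is.null(dn[[3L]]))
    dn[[3L]] <- if (dim(y)[3L] == 2L) .METHODS else
      paste0("method", seq_len(dim(y)[3L]))
  dimnames(y) <- dn
  if (is.null(location)) location <- rep("near_shore", dim(y)[1L])
  new("DetectionHistory", y = y, location = as.character(location),
      lake = lake, species = species)
}

## ---------------------------------------------------------------------------
## OccuModelSpec: covariate structure of (psi, theta, p).
## ---------------------------------------------------------------------------

.PSI_STRUCTURES <- c("constant", "by_location")
.THETA_STRUCTURES <- c("constant", "by_location")
.P_STRUCTURES <- c("constant", "by_method", "by_location",
                   "by_method_and_location")

#' OccuModelSpec class
#'
#' The covariate structure of a single-season multi-method occupancy model:
#' whether large-scale occupancy (psi), availability (theta) and detection
#' probability (p) are constant or vary with site location and/or sampling
#' method. The full cross of allowed structures yields 16 model variants.
#'
#' @slot psi `"constant"` or `"by_location"`.
#' @slot theta `"constant"` or `"by_location"`.
#' @slot p one of `"constant"`, `"by_method"`, `"by_location"`,
#'   `"by_method_and_location"`.
#'
#' @seealso [occuModelSpec()], [allModelSpecs()], [nParameters()]
#' @export
setClass("OccuModelSpec",
  representation(psi = "character", theta = "character", p = "character")
)

setValidity("OccuModelSpec", function(object) {
  msg <- character()
  if (!identical(length(object@psi), 1L) ||
      !object@psi %in% .PSI_STRUCTURES)
    msg <- c(msg, "psi structure must be constant or by_location")
  if (!identical(length(object@theta), 1L) ||
      !object@theta %in% .THETA_STRUCTURES)
    msg <- c(msg, "theta structure must be constant or by_location")
  if (!identical(length(object@p), 1L) || !object@p %in% .P_STRUCTURES)
    msg <- c(msg, "invalid p structure")
  if (length(msg)) msg else TRUE
})

#' Construct an occupancy model specification
#'
#' @param psi,theta `"constant"` or `"by_location"`.
#' @param p `"constant"`, `"by_method"`, `"by_location"` or
#'   `"by_method_and_location"`.
#' @return an [OccuModelSpec-class] object.
#' @examples
#' occuModelSpec(p = "by_method")
#' @export
occuModelSpec <- function(psi = "constant", theta = "constant",
                          p = "constant") {
  new("OccuModelSpec", psi = psi, theta = theta, p = p)
}

#' All sixteen model variants
#'
#' Enumerates the full cross of structures for psi (2), theta (2) and p
#' (4): sixteen single-season multi-method model variants.
#'
#' @return list of 16 [OccuModelSpec-class] objects.
#' @export
allModelSpecs <- function() {
  grid <- expand.grid(p = .P_STRUCTURES, theta = .THETA_STRUCTURES,
                      psi = .PSI_STRUCTURES, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    occuModelSpec(psi = grid$psi[i], theta = grid$theta[i], p = grid$p[i]))
}

## ---------------------------------------------------------------------------
## OccuFit: maximum-likelihood estimates of one model variant.
## ---------------------------------------------------------------------------

#' OccuFit class
#'
#' Maximum-likelihood fit of one multi-method occupancy model variant.
#' Estimates live on the probability scale; standard errors come from the
#' inverse observed information via the delta method and are unreliable for
#' boundary-flagged parameters.
#'
#' @slot spec the [OccuModelSpec-class] that was fitted.
#' @slot estimates named numeric, probabilities in \[0, 1\].
#' @slot standardErrors named numeric, `NA` where unreliable.
#' @slot logLik maximized log-likelihood.
#' @slot aic `-2 logLik + 2 K`.
#' @slot nParameters K, the number of free parameters.
#' @slot converged logical.
#' @slot boundaryFlags names of parameters estimated at 0 or 1.
#' @slot naivePsi fraction of sites with at least one detection.
#'
#' @seealso [fitOccupancy()], [rankModels()]
#' @export
setClass("OccuFit",
  representation(
    spec = "OccuModelSpec",
    estimates = "numeric",
    standardErrors = "numeric",
    logLik = "numeric",
    aic = "numeric",
    nParameters = "integer",
    converged = "logical",
    boundaryFlags = "character",
    naivePsi = "numeric"
  )
)

setValidity("OccuFit", function(object) {
  msg <- character()
  if (any(object@estimates < 0 | object@estimates > 1, na.rm = TRUE))
    msg <- c(msg, "estimates must lie in [0, 1]")
  if (length(object@aic) == 1L && length(object@logLik) == 1L &&
      is.finite(object@aic) &&
      abs(object@aic - (-2 * object@logLik + 2 * object@nParameters)) > 1e-8)
    msg <- c(msg, "aic must equal -2 logLik + 2 K")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## OccuRanking: AIC table over a set of fitted variants.
## ---------------------------------------------------------------------------

#' OccuRanking class
#'
#' AIC ranking of a set of fitted occupancy model variants: a table sorted
#' by ascending AIC (ties broken by fewer parameters) with delta-AIC and
#' Akaike weights, plus the underlying fits.
#'
#' @slot table `data.frame` with columns `model`, `K`, `logLik`, `AIC`,
#'   `deltaAIC`, `weight`, `converged`.
#' @slot fits list of [OccuFit-class], in table order.
#'
#' @seealso [rankModels()], [bestFit()]
#' @export
setClass("OccuRanking",
  representation(table = "data.frame", fits = "list")
)

setValidity("OccuRanking", function(object) {
  msg <- character()
  tb <- object@table
  need <- c("model", "K", "logLik", "AIC", "deltaAIC", "weight")
  if (!all(need %in% names(tb)))
    msg <- c(msg, "ranking table is missing required columns")
  else if (nrow(tb)) {
    if (is.unsorted(tb$AIC)) msg <- c(msg, "table must be sorted by AIC")
    if (abs(tb$deltaAIC[1L]) > 1e-10)
      msg <- c(msg, "top row must have deltaAIC 0")
    if (abs(sum(tb$weight) - 1) > 1e-12)
      msg <- c(msg, "Akaike weights must sum to 1")
  }
  if (length(object@fits) != nrow(tb))
    msg <- c(msg, "one fit per table row required")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## DesignResult: minimum-effort answer for one (p, replicates) query.
## ---------------------------------------------------------------------------

#' DesignResult class
#'
#' The minimum number of sampling sites needed for a target detection
#' probability and replicate count, together with the empty-history
#' (whole-survey false negative) probability achieved and a precision
#' diagnostic for the detection-probability estimate.
#'
#' @slot p assumed per-replicate detection probability.
#' @slot replicates replicates per site (k).
#' @slot minSites smallest site count meeting the criterion; `NA` when the
#'   search cap was reached with no feasible design.
#' @slot emptyFraction empty-history probability (analytic) or observed
#'   fraction (Monte Carlo) at `minSites`.
#' @slot seEstimate analytic standard error of the detection-probability
#'   estimate at the returned design, `sqrt(p (1 - p) / (s k))`.
#' @slot mode `"analytic"` or `"monte_carlo"`.
#'
#' @seealso [minimumDesign()], [designGrid()]
#' @export
setClass("DesignResult",
  representation(
    p = "numeric",
    replicates = "integer",
    minSites = "integer",
    emptyFraction = "numeric",
    seEstimate = "numeric",
    mode = "character"
  )
)

setValidity("DesignResult", function(object) {
  msg <- character()
  if (!object@mode %in% c("analytic", "monte_carlo"))
    msg <- c(msg, "mode must be analytic or monte_carlo")
  if (!is.na(object@minSites) && object@minSites < 1L)
    msg <- c(msg, "minSites must be >= 1")
  if (length(msg)) msg else TRUE
})
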