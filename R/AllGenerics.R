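## Generics and simple accessor/show methods for the core classes.

#' Number of free parameters of a model specification
#'
#' K = number of psi levels + theta levels + p levels implied by the
#' covariate structure (location has two levels, method two levels).
#'
#' @param object an [OccuModelSpec-class] or [OccuFit-class].
#' @return integer parameter count.
#' @export
setGeneric("nParameters", function(object) standardGeneric("nParameters"))

#' @rdname nParameters
#' @export
setMethod("nParameters", "OccuModelSpec", function(object) {
  np <- c(constant = 1L, by_location = 2L)[object@psi] +
    c(constant = 1L, by_location = 2L)[object@theta] +
    c(constant = 1L, by_method = 2L, by_location = 2L,
      by_method_and_location = 4L)[object@p]
  unname(np)
})

#' @rdname nParameters
#' @export
setMethod("nParameters", "OccuFit", function(object) object@nParameters)

#' Compact label of a model specification
#'
#' @param object an [OccuModelSpec-class].
#' @return single string such as `"psi(.) theta(.) p(method)"`.
#' @export
setGeneric("modelLabel", function(object) standardGeneric("modelLabel"))

#' @rdname modelLabel
#' @export
setMethod("modelLabel", "OccuModelSpec", function(object) {
  lab <- function(s) switch(s,
    constant = ".", by_location = "loc", by_method = "method",
    by_method_and_location = "method*loc")
  sprintf("psi(%s) theta(%s) p(%s)",
          lab(object@psi), lab(object@theta), lab(object@p))
})

#' Accessors for DetectionHistory
#'
#' `detectionArray` returns the sites x occasions x methods array,
#' `siteLocations` the per-site location covariate, and `nSites`,
#' `nOccasions`, `nMethods` the dimensions.
#'
#' @param object a [DetectionHistory-class].
#' @return array, character vector or integer as appropriate.
#' @name DetectionHistory-accessors
NULL

#' @rdname DetectionHistory-accessors
#' @export
setGeneric("detectionArray", function(object) standardGeneric("detectionArray"))

#' @rdname DetectionHistory-accessors
#' @export
setMethod("detectionArray", "DetectionHistory", function(object) object@y)

#' @rdname DetectionHistory-accessors
#' @export
setGeneric("siteLocations", function(object) standardGeneric("siteLocations"))

#' @rdname DetectionHistory-accessors
#' @export
setMethod("siteLocations", "DetectionHistory", function(object) {
  structure(object@location, names = dimnames(object@y)[[1L]])
})

#' @rdname DetectionHistory-accessors
#' @export
setGeneric("nSites", function(object) standardGeneric("nSites"))

#' @rdname DetectionHistory-accessors
#' @export
setMethod("nSites", "DetectionHistory", function(object) dim(object@y)[1L])

#' @rdname DetectionHistory-accessors
#' @export
setGeneric("nOccasions", function(object) standardGeneric("nOccasions"))

#' @rdname DetectionHistory-accessors
#' @export
setMethod("nOccasions", "DetectionHistory", function(object) dim(object@y)[2L])

#' @rdname DetectionHistory-accessors
#' @export
setGeneric("nMethods", function(object) standardGeneric("nMethods"))

#' @rdname DetectionHistory-accessors
#' @export
setMethod("nMethods", "DetectionHistory", function(object) dim(object@y)[3L])

#' Accessors for OccuFit
#'
#' @param object an [OccuFit-class].
#' @return named numeric (`estimates`, `standardErrors`), numeric scalar
#'   (`logLikelihood`, `aic`) or [OccuModelSpec-class] (`modelSpec`).
#' @name OccuFit-accessors
NULL

#' @rdname OccuFit-accessors
#' @export
setGeneric("estimates", function(object) standardGeneric("estimates"))

#' @rdname OccuFit-accessors
#' @export
setMethod("estimates", "OccuFit", function(object) object@estimates)

#' @rdname OccuFit-accessors
#' @export
setGeneric("standardErrors", function(object) standardGeneric("standardErrors"))

#' @rdname OccuFit-accessors
#' @export
setMethod("standardErrors", "OccuFit", function(object) object@standardErrors)

#' @rdname OccuFit-accessors
#' @export
setGeneric("logLikelihood", function(object) standardGeneric("logLikelihood"))

#' @rdname OccuFit-accessors
#' @export
setMethod("logLikelihood", "OccuFit", function(object) object@logLik)

#' @rdname OccuFit-accessors
#' @export
setGeneric("aic", function(object) standardGeneric("aic"))

#' @rdname OccuFit-accessors
#' @export
setMethod("aic", "OccuFit", function(object) object@aic)

#' @rdname OccuFit-accessors
#' @export
setGeneric("modelSpec", function(object) standardGeneric("modelSpec"))

#' @rdname OccuFit-accessors
#' @export
setMethod("modelSpec", "OccuFit", function(object) object@spec)

#' Accessors for OccuRanking
#'
#' `rankingTable` returns the AIC table; `bestFit` the top-ranked
#' [OccuFit-class].
#'
#' @param object an [OccuRanking-class].
#' @name OccuRanking-accessors
#' @return `data.frame` or [OccuFit-class].
NULL

#' @rdname OccuRanking-accessors
#' @export
setGeneric("rankingTable", function(object) standardGeneric("rankingTable"))

#' @rdname OccuRanking-accessors
#' @export
setMethod("rankingTable", "OccuRanking", function(object) object@table)

#' @rdname OccuRanking-accessors
#' @export
setGeneric("bestFit", function(object) standardGeneric("bestFit"))

#' @rdname OccuRanking-accessors
#' @export
setMethod("bestFit", "OccuRanking", function(object) object@fits[[1L]])

## show methods -------------------------------------------------------------

setMethod("show", "PositivityCall", function(object) {
  cat("PositivityCall:", object@status, "\n")
  cat("  final concentration:",
      format(object@finalConcentration, digits = 4), "copies/uL\n")
  cat("  runs used:", nrow(object@runsUsed), "\n")
  if (length(object@qcFlags))
    cat("  qc flags:", paste(object@qcFlags, collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "DilutionSeries", function(object) {
  cat("DilutionSeries with", length(object@expected), "steps\n")
  cat("  expected:", paste(format(object@expected, digits = 3),
                           collapse = " > "), "\n")
  cat("  replicates per step:",
      paste(vapply(object@measured, length, integer(1)), collapse = ", "),
      "\n")
  invisible(NULL)
})

setMethod("show", "DetectionHistory", function(object) {
  d <- dim(object@y)
  cat(sprintf("DetectionHistory: %d sites x %d occasions x %d methods\n",
              d[1L], d[2L], d[3L]))
  if (!is.na(object@lake) || !is.na(object@species))
    cat("  lake:", object@lake, " species:", object@species, "\n")
  cat("  detections:", sum(object@y == 1, na.rm = TRUE), "of",
      sum(!is.na(object@y)), "observations",
      sprintf("(%d missing)\n", sum(is.na(object@y))))
  cat("  naive occupancy:",
      format(naiveOccupancy(object), digits = 3), "\n")
  invisible(NULL)
})

setMethod("show", "OccuModelSpec", function(object) {
  cat("OccuModelSpec:", modelLabel(object),
      sprintf("(K = %d)\n", nParameters(object)))
  invisible(NULL)
})

setMethod("show", "OccuFit", function(object) {
  cat("OccuFit:", modelLabel(object@spec), "\n")
  cat(sprintf("  logLik = %.4f  AIC = %.4f  K = %d  converged: %s\n",
              object@logLik, object@aic, object@nParameters,
              object@converged))
  est <- data.frame(
    estimate = round(object@estimates, 4),
    se = round(object@standardErrors, 4)
  )
  rownames(est) <- names(object@estimates)
  print(est)
  if (length(object@boundaryFlags))
    cat("  at boundary:", paste(object@boundaryFlags, collapse = ", "),
        "(SEs unreliable)\n")
  invisible(NULL)
})

setMethod("show", "OccuRanking", function(object) {
  cat("OccuRanking of", nrow(object@table), "model variants\n")
  tb <- object@table
  tb$logLik <- round(tb$logLik, 3)
  tb$AIC <- round(tb$AIC, 3)
  tb$deltaAIC <- round(tb$deltaAIC, 3)
  tb$weight <- round(tb$weight, 4)
  print(tb, row.names = FALSE)
  invisible(NULL)
})

setMethod("show", "DesignResult", function(object) {
  cat(sprintf("DesignResult (%s): p = %.3g, k = %d\n",
              object@mode, object@p, object@replicates))
  if (is.na(object@minSites))
    cat("  no feasible design within the search cap\n")
  else
    cat(sprintf("  minimum sites: %d (empty-history prob %.3g, SE(p-hat) %.3g)\n",
                object@minSites, object@emptyFraction, object@seEstimate))
  invisible(NULL)
})
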