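## Limit of quantification from a dilution ladder.

#' Estimate the limit of quantification from a dilution series
#'
#' Below the LoQ, measured ddPCR concentrations stop tracking the nominal
#' dilution: the measured trend bends away from proportionality. The
#' estimator works on log10-log10 axes: a local-regression smoother
#' (`loess`, default span 0.75, degree 2) is fitted to the mean measured
#' concentration per step, and a proportional reference line of slope one
#' is anchored by the median measured/expected ratio over the top (most
#' concentrated) half of the ladder. Scanning from the top of the ladder
#' down, the LoQ is the smallest expected concentration whose smoothed
#' measurement still stays within `deviationTolerance` relative deviation
#' of the reference line; all steps below it deviate. When no step
#' deviates, the LoQ is below the tested range and `NA` is returned (with
#' attribute `belowRange = TRUE`).
#'
#' @param series a [DilutionSeries-class] with at least 4 steps.
#' @param deviationTolerance maximum tolerated relative deviation from
#'   proportionality, in (0, 1); default 0.5 (50 percent).
#' @param span `loess` span; default 0.75.
#' @return LoQ on the expected-concentration scale, or `NA` with attribute
#'   `belowRange = TRUE` when the whole ladder is proportional. The result
#'   is always one of the tested steps: the estimator never extrapolates.
#' @examples
#' s <- generateDilutionSeries(trueLoq = 10, seed = 1)
#' estimateLoq(s)
#' @export
estimateLoq <- function(series, deviationTolerance = 0.5, span = 0.75) {
  stopifnot(is(series, "DilutionSeries"))
  validObject(series)
  if (length(series@expected) < 4L)
    stop("at least 4 dilution steps are required to estimate the LoQ")
  if (deviationTolerance <= 0 || deviationTolerance >= 1)
    stop("deviationTolerance must lie in (0, 1)")

  x <- log10(series@expected)
  meanMeasured <- vapply(series@measured, mean, numeric(1))
  if (any(meanMeasured <= 0))
    stop("mean measured concentration must be positive at every step")
  y <- log10(meanMeasured)

  sm <- stats::loess(y ~ x, span = span, degree = 2,
                     surface = "direct",
                     control = stats::loess.control(iterations = 1))
  smoothed <- stats::predict(sm, x)

  # proportional reference: slope-1 line anchored on the upper half of the
  # ladder, where the assay is assumed quantitative
  top <- seq_len(max(2L, ceiling(length(x) / 2)))
  refIntercept <- stats::median(y[top] - x[top])
  deviation <- abs(10^(smoothed - (x + refIntercept)) - 1)

  deviates <- deviation > deviationTolerance
  if (!any(deviates)) {
    out <- NA_real_
    attr(out, "belowRange") <- TRUE
    return(out)
  }
  firstBad <- which(deviates)[1L]
  if (firstBad == 1L)
    stop("measured trend deviates already at the highest step; ",
         "the ladder does not cover the quantitative range")
  series@expected[firstBad - 1L]
}
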