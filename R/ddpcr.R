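## Droplet digital PCR quantification and positivity calling.

#' Poisson-corrected target concentration from droplet counts
#'
#' In ddPCR the reaction is partitioned into ~20,000 nanodroplets; template
#' molecules distribute over droplets approximately as a Poisson process.
#' The per-droplet mean copy number is therefore
#' `lambda = -log(1 - k/n)` for `k` positive out of `n` accepted droplets,
#' and the reaction concentration is `lambda / dropletVolume` copies/uL.
#'
#' @param positives number of positive droplets (k).
#' @param total number of accepted droplets (n), > 0.
#' @param dropletVolume droplet volume in uL; default 0.85e-3 (0.85 nL, the
#'   nominal QX200 partition volume).
#' @return concentration in copies/uL of reaction; 0 when `positives` is 0.
#'   Vectorized over `positives` and `total`.
#' @examples
#' poissonConcentration(100, 20000) # ~5.9 copies/uL
#' @export
poissonConcentration <- function(positives, total, dropletVolume = 0.85e-3) {
  if (any(dropletVolume <= 0)) stop("dropletVolume must be > 0")
  if (any(total <= 0)) stop("invalid run: total droplets must be > 0")
  if (any(positives < 0) || any(positives > total))
    stop("positives must lie in [0, total]")
  if (any(positives == total))
    stop("saturated run: all droplets positive, concentration unquantifiable")
  -log1p(-positives / total) / dropletVolume
}

#' Classify a biological replicate from its technical ddPCR runs
#'
#' Applies droplet quality control and the rerun/positivity rules used for
#' low-level eDNA detections:
#' \itemize{
#'   \item runs with fewer than `qcMinDroplets` accepted droplets are
#'     dropped (flag `low_droplets`); if no run passes QC the sample needs
#'     a rerun;
#'   \item a single passing run with exactly one positive droplet is not
#'     trusted: the sample must be rerun twice (flag `single_droplet`);
#'   \item with three (or more) final runs the sample is positive iff at
#'     least two runs have a positive droplet; the final concentration is
#'     the mean Poisson-corrected concentration of the positive runs;
#'   \item a single passing run with two or more positive droplets is
#'     positive with its own concentration; with zero positives, negative;
#'   \item two runs must agree (both positive or both negative), otherwise
#'     one more rerun is required.
#' }
#'
#' @param runs `data.frame` with columns `positives` and `total` (one row
#'   per technical run); a `concentration` column is recomputed from the
#'   droplet counts.
#' @param qcMinDroplets minimum accepted droplets per run (default 10000).
#' @param dropletVolume droplet volume in uL, passed to
#'   [poissonConcentration()].
#' @return a [PositivityCall-class].
#' @examples
#' classifySample(data.frame(positives = c(1, 0, 2),
#'                           total = rep(20000, 3)))
#' @export
classifySample <- function(runs, qcMinDroplets = 10000,
                           dropletVolume = 0.85e-3) {
  if (!is.data.frame(runs) || nrow(runs) == 0L)
    stop("at least one technical run is required")
  if (!all(c("positives", "total") %in% names(runs)))
    stop("runs must have columns 'positives' and 'total'")
  flags <- character()
  if (any(runs$total < qcMinDroplets)) flags <- c(flags, "low_droplets")
  ok <- runs[runs$total >= qcMinDroplets, , drop = FALSE]
  if (nrow(ok) == 0L)
    return(new("PositivityCall", status = "rerun_required",
               finalConcentration = NA_real_, runsUsed = ok,
               qcFlags = flags))
  ok$concentration <- poissonConcentration(ok$positives, ok$total,
                                           dropletVolume)
  pos <- ok$positives >= 1L

  if (nrow(ok) == 1L) {
    if (ok$positives == 1L)
      return(new("PositivityCall", status = "rerun_required",
                 finalConcentration = NA_real_, runsUsed = ok,
                 qcFlags = unique(c(flags, "single_droplet"))))
    status <- if (ok$positives >= 2L) "positive" else "negative"
    conc <- if (status == "positive") ok$concentration else 0
    return(new("PositivityCall", status = status,
               finalConcentration = conc, runsUsed = ok, qcFlags = flags))
  }

  if (nrow(ok) == 2L && sum(pos) == 1L)
    return(new("PositivityCall", status = "rerun_required",
               finalConcentration = NA_real_, runsUsed = ok,
               qcFlags = flags))

  if (sum(pos) >= 2L)
    return(new("PositivityCall", status = "positive",
               finalConcentration = mean(ok$concentration[pos]),
               runsUsed = ok, qcFlags = flags))
  new("PositivityCall", status = "negative", finalConcentration = 0,
      runsUsed = ok, qcFlags = flags)
}

#' Normalize a reaction concentration to the original sample
#'
#' Scales a ddPCR reaction concentration (copies/uL) back through the
#' template and extract volumes to gene copies per gram of sediment or per
#' litre (or gram) of water:
#' `conc * reactionVolume / templateVolume * elutionVolume / sampleAmount`.
#' One mL of water is treated as one gram, so water and sediment levels can
#' share a copies-per-gram axis.
#'
#' @param concReaction concentration in copies/uL of reaction.
#' @param reactionVolume ddPCR reaction volume in uL (default 20).
#' @param templateVolume template volume added to the reaction, uL
#'   (default 6).
#' @param elutionVolume DNA extract elution volume, uL (default 100).
#' @param sampleAmount amount of raw sample extracted, in g (sediment) or
#'   L (water); water volumes in mL can be converted with [waterMlToGrams()].
#' @return copies per gram (or per litre), same length as `concReaction`.
#' @examples
#' normalizeConcentration(0.5, 20, 6, 100, 0.5) # copies per litre
#' @export
normalizeConcentration <- function(concReaction, reactionVolume = 20,
                                   templateVolume = 6, elutionVolume = 100,
                                   sampleAmount = 1) {
  if (any(reactionVolume <= 0) || any(templateVolume <= 0) ||
      any(elutionVolume <= 0) || any(sampleAmount <= 0))
    stop("volumes and sample amount must be positive")
  if (any(concReaction < 0)) stop("concentration must be non-negative")
  concReaction * reactionVolume / templateVolume * elutionVolume /
    sampleAmount
}

#' Convert a water volume in mL to the equivalent mass in grams
#'
#' @param ml water volume in mL.
#' @return mass in grams (1 mL = 1 g).
#' @export
waterMlToGrams <- function(ml) ml
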