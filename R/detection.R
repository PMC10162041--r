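## From classified replicates to detection histories and summary statistics.

#' Build a detection history from classified replicate records
#'
#' Turns replicate-level positivity calls into the site x occasion x
#' method array the occupancy model consumes. Biological replicate `r` of
#' water and of sediment at a site form occasion `r`, so each occasion
#' carries one observation per method (the multi-method encoding).
#' Replicates whose status is `rerun_required` (unresolved QC failures)
#' become missing values, never zeros.
#'
#' @param records `data.frame` with columns `lake`, `site`, `location`,
#'   `method` (`"water"`/`"sediment"`), `occasion` (biological replicate
#'   index), `species` and `status` (`"positive"`, `"negative"`,
#'   `"rerun_required"`).
#' @param lake,species which lake/species stratum to extract; may be
#'   omitted when `records` covers a single stratum.
#' @return a [DetectionHistory-class]; sites ordered by site identifier.
#' @examples
#' d <- generateDataset(lakeConfig(seed = 1))
#' h <- binarizeDetections(classifyReplicates(d$runs),
#'                         lake = "Lake_A", species = "perch")
#' @export
binarizeDetections <- function(records, lake = NULL, species = NULL) {
  need <- c("lake", "site", "location", "method", "occasion", "species",
            "status")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("records must contain columns: ", paste(need, collapse = ", "))
  if (nrow(records) == 0L) stop("no records supplied")
  if (is.null(lake)) {
    lake <- unique(records$lake)
    if (length(lake) != 1L) stop("records span several lakes; pass `lake`")
  }
  if (is.null(species)) {
    species <- unique(records$species)
    if (length(species) != 1L)
      stop("records span several species; pass `species`")
  }
  rec <- records[records$lake == lake & records$species == species, ,
                 drop = FALSE]
  if (nrow(rec) == 0L) stop("no records for this lake/species")

  key <- interaction(rec$site, rec$method, rec$occasion, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (site, method, occasion) records: data integrity error")

  sites <- sort(unique(rec$site))
  occasions <- sort(unique(rec$occasion))
  methods <- intersect(.METHODS, unique(rec$method))
  if (length(methods) == 0L) methods <- sort(unique(rec$method))

  y <- array(NA_real_, dim = c(length(sites), length(occasions),
                               length(methods)),
             dimnames = list(as.character(sites),
                             paste0("occ", occasions), methods))
  loc <- rep(NA_character_, length(sites))
  for (i in seq_len(nrow(rec))) {
    s <- match(rec$site[i], sites)
    j <- match(rec$occasion[i], occasions)
    m <- match(rec$method[i], methods)
    y[s, j, m] <- switch(rec$status[i],
                         positive = 1, negative = 0,
                         rerun_required = NA_real_,
                         stop("unknown status: ", rec$status[i]))
    sLoc <- as.character(rec$location[i])
    if (!is.na(loc[s]) && loc[s] != sLoc)
      stop("location must be constant within a site")
    loc[s] <- sLoc
  }
  detectionHistory(y, location = loc, lake = as.character(lake),
                   species = as.character(species))
}

#' Naive occupancy
#'
#' Fraction of surveyed sites with at least one detection over all
#' occasions and methods, ignoring imperfect detection. Sites with only
#' missing observations are still counted in the denominator.
#'
#' @param history a [DetectionHistory-class].
#' @return fraction in \[0, 1\].
#' @export
naiveOccupancy <- function(history) {
  stopifnot(is(history, "DetectionHistory"))
  y <- history@y
  if (all(is.na(y))) stop("all observations missing: naive occupancy undefined")
  detected <- apply(y, 1L, function(v) any(v == 1, na.rm = TRUE))
  mean(detected)
}

#' Detection-rate summary by method and location
#'
#' Per-method (and per-method-by-location) fraction of non-missing
#' replicates with a detection, plus the per-site agreement between the
#' two methods (detected by both, one, or neither).
#'
#' @param history a [DetectionHistory-class].
#' @return list with elements `byMethod` (data.frame: method, detections,
#'   replicates, fraction), `byMethodLocation` (adds a location column)
#'   and `siteAgreement` (named counts: `both`, plus one `<method>_only`
#'   entry per method, and `neither`).
#' @export
detectionRateSummary <- function(history) {
  stopifnot(is(history, "DetectionHistory"))
  y <- history@y
  methods <- dimnames(y)[[3L]]
  loc <- history@location

  frac <- function(v) {
    n <- sum(!is.na(v))
    data.frame(detections = sum(v == 1, na.rm = TRUE), replicates = n,
               fraction = if (n) sum(v == 1, na.rm = TRUE) / n else NA_real_)
  }
  byMethod <- do.call(rbind, lapply(seq_along(methods), function(m)
    cbind(method = methods[m], frac(y[, , m]))))

  byMethodLocation <- do.call(rbind, lapply(seq_along(methods), function(m) {
    do.call(rbind, lapply(unique(loc), function(l)
      cbind(method = methods[m], location = l,
            frac(y[loc == l, , m, drop = FALSE]))))
  }))

  perSite <- vapply(seq_along(methods), function(m)
    apply(y[, , m, drop = FALSE], 1L,
          function(v) any(v == 1, na.rm = TRUE)),
    logical(dim(y)[1L]))
  perSite <- matrix(perSite, nrow = dim(y)[1L])
  agreement <- c(both = sum(rowSums(perSite) == ncol(perSite)),
                 stats::setNames(
                   vapply(seq_along(methods), function(m)
                     sum(perSite[, m] & rowSums(perSite) == 1L), integer(1)),
                   paste0(methods, "_only")),
                 neither = sum(rowSums(perSite) == 0L))

  list(byMethod = byMethod, byMethodLocation = byMethodLocation,
       siteAgreement = agreement)
}

#' Kruskal-Wallis rank test across groups of eDNA concentrations
#'
#' Tie-corrected Kruskal-Wallis H with the chi-square approximation, as
#' used for comparing eDNA levels across locations or sample types. Being
#' rank-based, the result is invariant under any strictly monotone
#' transformation of the pooled values (log10(x+1), exp, square root),
#' so the choice of plotting transformation does not affect it.
#'
#' @param groups list of at least two numeric vectors (one per group),
#'   each with at least one value.
#' @return list with `H` (the tie-corrected statistic), `df`
#'   (groups - 1) and `pValue`. When every pooled value is identical, H
#'   is 0 and a warning is raised.
#' @examples
#' kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
kruskalWallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("at least two groups are required")
  if (any(vapply(groups, length, integer(1)) < 1L))
    stop("every group needs at least one value")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep.int(seq_along(groups),
                      vapply(groups, length, integer(1))))
  if (length(unique(x)) == 1L) {
    warning("all values identical across groups; H = 0")
    return(list(H = 0, df = length(groups) - 1L, pValue = 1))
  }
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       pValue = unname(kt$p.value))
}
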