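## Plain-text input/output: replicate tables and detection-history files.

#' Read / write a droplet-run table
#'
#' Minimal CSV round trip for run-level droplet counts with columns
#' `sample_id`, `assay`, `positives`, `total` and (recomputed on read)
#' `concentration`.
#'
#' @param file path to a CSV file.
#' @param dropletVolume droplet volume in uL for the Poisson correction.
#' @return `readDropletRuns`: a `data.frame`; `writeDropletRuns`: the file
#'   path, invisibly.
#' @export
readDropletRuns <- function(file, dropletVolume = 0.85e-3) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("sample_id", "assay", "positives", "total")
  if (!all(need %in% names(x)))
    stop("droplet-run table must contain columns: ",
         paste(need, collapse = ", "))
  x$concentration <- poissonConcentration(x$positives, x$total,
                                          dropletVolume)
  x
}

#' @rdname readDropletRuns
#' @param runs `data.frame` of runs to write.
#' @export
writeDropletRuns <- function(runs, file) {
  utils::write.csv(runs, file, row.names = FALSE)
  invisible(file)
}

#' Read a replicate-level survey table
#'
#' Reads a CSV in the layout of a deposited lake-survey table: one row per
#' technical ddPCR run with columns `lake`, `site`, `location`,
#' `sample_type` (or `method`), `replicate` (or `occasion`), `species`,
#' `positives`, `total` and optionally `run` and `concentration`. Column
#' aliases are normalized; the concentration is recomputed from the
#' droplet counts.
#'
#' @param file path to a CSV file.
#' @param dropletVolume droplet volume in uL.
#' @return run-level `data.frame` accepted by [classifyReplicates()].
#' @export
readReplicateTable <- function(file, dropletVolume = 0.85e-3) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE)
  alias <- c(sample_type = "method", replicate = "occasion")
  for (a in names(alias))
    if (a %in% names(x) && !alias[[a]] %in% names(x))
      names(x)[names(x) == a] <- alias[[a]]
  need <- c("lake", "site", "location", "method", "occasion", "species",
            "positives", "total")
  if (!all(need %in% names(x)))
    stop("replicate table must contain columns: ",
         paste(need, collapse = ", "))
  if (!"run" %in% names(x)) x$run <- 1L
  x$concentration <- poissonConcentration(x$positives, x$total,
                                          dropletVolume)
  x
}

#' @rdname readReplicateTable
#' @param runs run-level `data.frame` to write (written with `sample_type`
#'   and `replicate` column names).
#' @export
writeReplicateTable <- function(runs, file) {
  out <- runs
  names(out)[names(out) == "method"] <- "sample_type"
  names(out)[names(out) == "occasion"] <- "replicate"
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}

#' Write / read a detection history as a wide CSV
#'
#' One row per site with a `site` and `location` column followed by one
#' `occ<j>_<method>` column per occasion x method cell; missing
#' observations are written as `-`, in the style of occupancy-software
#' input files.
#'
#' @param history a [DetectionHistory-class].
#' @param file path to a CSV file.
#' @return `writeDetectionHistory`: the file path, invisibly;
#'   `readDetectionHistory`: a [DetectionHistory-class].
#' @export
writeDetectionHistory <- function(history, file) {
  stopifnot(is(history, "DetectionHistory"))
  y <- history@y
  d <- dim(y)
  cols <- list(site = dimnames(y)[[1L]], location = history@location)
  for (j in seq_len(d[2L])) for (m in seq_len(d[3L])) {
    v <- y[, j, m]
    cols[[paste0("occ", j, "_", dimnames(y)[[3L]][m])]] <-
      ifelse(is.na(v), "-", as.character(v))
  }
  utils::write.csv(as.data.frame(cols, stringsAsFactors = FALSE), file,
                   row.names = FALSE)
  invisible(file)
}

#' @rdname writeDetectionHistory
#' @export
readDetectionHistory <- function(file) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE,
                       colClasses = "character")
  obsCols <- grep("^occ[0-9]+_", names(x), value = TRUE)
  if (length(obsCols) == 0L) stop("no occ<j>_<method> columns found")
  occ <- as.integer(sub("^occ([0-9]+)_.*$", "\\1", obsCols))
  meth <- sub("^occ[0-9]+_", "", obsCols)
  J <- max(occ)
  methods <- unique(meth[order(match(meth, .METHODS))])
  y <- array(NA_real_, dim = c(nrow(x), J, length(methods)),
             dimnames = list(x$site, paste0("occ", seq_len(J)), methods))
  for (i in seq_along(obsCols)) {
    v <- x[[obsCols[i]]]
    v[v == "-"] <- NA
    y[, occ[i], match(meth[i], methods)] <- as.numeric(v)
  }
  detectionHistory(y, location = x$location)
}
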