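## Maximum-likelihood fitting and AIC ranking of the model variants.

.LOGIT_BOUND <- stats::qlogis(1 - 1e-6)  # probabilities clamped to [1e-6, 1-1e-6]

.clampLogit <- function(x) pmin(pmax(x, -.LOGIT_BOUND), .LOGIT_BOUND)

# Run expr with a temporary RNG state; the caller's stream is untouched.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Fit a multi-method occupancy model by maximum likelihood
#'
#' Maximizes the summed log [siteLikelihood()] over sites on the logit
#' scale, with several optimization restarts (one start at the empirical
#' detection frequencies plus `nStarts` fixed-seed random starts; the best
#' log-likelihood is kept). Probabilities are clamped to
#' \[1e-6, 1 - 1e-6\] so boundary estimates cannot overflow the logit.
#' Standard errors come from the inverse observed information via the
#' delta method; estimates within 1e-4 of 0 or 1 are reported as exactly
#' 0 or 1, flagged as boundary estimates, and their standard errors set to
#' `NA` (a curvature-based error is meaningless at a bound).
#'
#' Parameters can be held fixed (e.g. `fixed = c(psi = 1, theta = 1)` when
#' the target is known to be present and available everywhere); fixed
#' parameters are excluded from the optimization and from the parameter
#' count K.
#'
#' @param history a [DetectionHistory-class] with at least 2 sites.
#' @param spec an [OccuModelSpec-class]; default: everything constant.
#' @param fixed named numeric of probabilities to hold fixed; names must be
#'   structure parameter names (`psi`, `theta`, `p_water`, ...).
#' @param nStarts number of random restarts beyond the empirical start.
#' @param startSeed seed for the fixed random-start stream.
#' @return an [OccuFit-class]. Non-convergence after all starts yields a
#'   fit flagged `converged = FALSE`, not an error.
#' @examples
#' h <- simulateHistory(psi = 1, theta = 1, p = 0.6, sites = 30,
#'                      replicates = 2, seed = 1)
#' fitOccupancy(h, occuModelSpec(), fixed = c(psi = 1, theta = 1))
#' @export
fitOccupancy <- function(history, spec = occuModelSpec(), fixed = NULL,
                         nStarts = 5, startSeed = 20230) {
  stopifnot(is(history, "DetectionHistory"), is(spec, "OccuModelSpec"))
  y <- history@y
  if (all(is.na(y))) stop("all observations missing: nothing to fit")
  if (dim(y)[1L] < 2L) stop("at least 2 sites are required")

  methods <- dimnames(y)[[3L]]
  J <- dim(y)[2L]
  collapsed <- .collapseHistory(history)
  parNames <- .paramNames(spec, methods)

  fixed <- fixed[names(fixed) %in% parNames]
  freeNames <- setdiff(parNames, names(fixed))
  K <- length(freeNames)
  if (K == 0L) stop("all parameters fixed: nothing to estimate")

  fullProbs <- function(freeLogit) {
    probs <- stats::plogis(.clampLogit(freeLogit))
    names(probs) <- freeNames
    c(probs, fixed)
  }
  objective <- function(freeLogit)
    .negLogLik(fullProbs(freeLogit), spec, collapsed, J, methods)

  # empirical start: naive occupancy for psi/theta, per-method detection
  # frequency for p, everything pulled off the bounds
  naive <- naiveOccupancy(history)
  squeeze <- function(x) pmin(pmax(x, 0.05), 0.95)
  pFreq <- vapply(seq_along(methods), function(m)
    mean(y[, , m] == 1, na.rm = TRUE), numeric(1))
  pFreq[is.nan(pFreq)] <- 0.5
  empirical <- vapply(freeNames, function(nm) {
    if (startsWith(nm, "psi")) squeeze(naive)
    else if (startsWith(nm, "theta")) 0.8
    else {
      m <- methods[vapply(methods, function(mm)
        grepl(paste0("^p_", mm), nm), logical(1))]
      if (length(m) == 1L) squeeze(pFreq[match(m, methods)])
      else squeeze(mean(pFreq))
    }
  }, numeric(1))

  starts <- rbind(stats::qlogis(empirical),
                  .withSeed(startSeed, matrix(stats::qlogis(
                    stats::runif(nStarts * K, 0.05, 0.95)), nStarts, K)))

  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::nlminb(starts[s, ], objective,
                    lower = -.LOGIT_BOUND, upper = .LOGIT_BOUND,
                    control = list(rel.tol = 1e-12, x.tol = 1e-12,
                                   iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective - 1e-12) best <- fit
  }
  if (is.null(best))
    stop("optimization failed at every starting point")

  estLogit <- .clampLogit(best$par)
  est <- stats::plogis(estLogit)
  names(est) <- freeNames

  # nlminb reports "false convergence" when parameters sit on the clamped
  # logit bounds, which is the expected outcome for boundary estimates;
  # accept the fit as converged when every interior parameter is at a
  # stationary point of the objective
  converged <- best$convergence == 0
  if (!converged) {
    atBound <- abs(estLogit) >= .LOGIT_BOUND - 1e-6
    if (all(atBound)) {
      converged <- TRUE
    } else {
      eps <- 1e-5
      grad <- vapply(which(!atBound), function(i) {
        up <- dn <- estLogit
        up[i] <- up[i] + eps
        dn[i] <- dn[i] - eps
        (objective(up) - objective(dn)) / (2 * eps)
      }, numeric(1))
      converged <- all(abs(grad) < 1e-3 * (1 + abs(best$objective)))
    }
  }

  # observed information on the logit scale; delta method to probabilities
  se <- rep(NA_real_, K)
  hess <- tryCatch(stats::optimHess(estLogit, objective),
                   error = function(e) NULL)
  if (!is.null(hess)) {
    cov <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(cov)) {
      v <- diag(cov)
      okVar <- is.finite(v) & v >= 0
      se[okVar] <- sqrt(v[okVar]) * est[okVar] * (1 - est[okVar])
    }
  }
  names(se) <- freeNames

  boundary <- freeNames[est < 1e-4 | est > 1 - 1e-4]
  est[est < 1e-4] <- 0
  est[est > 1 - 1e-4] <- 1
  se[freeNames %in% boundary] <- NA_real_

  logLik <- -best$objective
  new("OccuFit", spec = spec, estimates = est, standardErrors = se,
      logLik = logLik, aic = -2 * logLik + 2 * K,
      nParameters = as.integer(K), converged = converged,
      boundaryFlags = boundary, naivePsi = naive)
}

#' Rank occupancy model variants by AIC
#'
#' Fits every supplied specification to the same detection history and
#' ranks the fits by ascending AIC (ties broken by fewer parameters).
#' Reports delta-AIC and Akaike weights
#' `exp(-delta/2) / sum(exp(-delta/2))`; the weight ratio between the two
#' top rows is the evidence ratio of the best model over the runner-up.
#' Unconverged fits are retained in the table and flagged.
#'
#' @param history a [DetectionHistory-class].
#' @param specs list of [OccuModelSpec-class]; defaults to the full set of
#'   sixteen variants from [allModelSpecs()].
#' @param ... passed to [fitOccupancy()].
#' @return an [OccuRanking-class].
#' @examples
#' h <- simulateHistory(psi = 1, theta = 1, p = 0.6, sites = 30,
#'                      replicates = 2, seed = 1)
#' rankModels(h, allModelSpecs()[1:4])
#' @export
rankModels <- function(history, specs = allModelSpecs(), ...) {
  if (length(specs) < 2L) stop("at least two model specs are required")
  fits <- lapply(specs, function(sp) fitOccupancy(history, sp, ...))
  aics <- vapply(fits, aic, numeric(1))
  ks <- vapply(fits, nParameters, integer(1))
  ord <- order(aics, ks)
  fits <- fits[ord]
  aics <- aics[ord]
  delta <- aics - aics[1L]
  w <- exp(-delta / 2)
  w <- w / sum(w)
  tb <- data.frame(
    model = vapply(fits, function(f) modelLabel(f@spec), character(1)),
    K = vapply(fits, nParameters, integer(1)),
    logLik = vapply(fits, logLikelihood, numeric(1)),
    AIC = aics,
    deltaAIC = delta,
    weight = w,
    converged = vapply(fits, function(f) f@converged, logical(1)),
    stringsAsFactors = FALSE
  )
  new("OccuRanking", table = tb, fits = fits)
}
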