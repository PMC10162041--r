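## Single-season multi-method occupancy likelihood.
##
## Latent structure per site i: occupancy z_i ~ Bern(psi); given z_i = 1,
## availability a_ij ~ Bern(theta) at each occasion j; given a_ij = 1 each
## method m detects with probability p_jm. Marginalizing the latent states
## gives the site likelihood below. Missing observations contribute a
## factor of 1 (missing at random).

#' Likelihood of one site's detection history
#'
#' Computes
#' `psi * prod_j [ theta * prod_m p^y (1-p)^(1-y) + (1-theta) * I(occasion j all zero) ] + (1-psi) * I(site all zero)`
#' where the products run over non-missing cells and the indicators ask
#' that no non-missing cell of the occasion (or site) is a detection.
#'
#' @param ySite occasions x methods matrix over \{0, 1, NA\}.
#' @param psi large-scale occupancy probability.
#' @param theta availability (small-scale occupancy) probability.
#' @param p occasions x methods matrix of detection probabilities (a
#'   scalar or a length-M vector is recycled across occasions).
#' @return the probability of the observed history, in \[0, 1\].
#' @examples
#' y <- matrix(0, 2, 2)
#' siteLikelihood(y, psi = 0.8, theta = 0.7, p = c(0.6, 0.4))
#' @export
siteLikelihood <- function(ySite, psi, theta, p) {
  ySite <- as.matrix(ySite)
  if (length(p) == 1L) p <- matrix(p, nrow(ySite), ncol(ySite))
  if (is.null(dim(p)) && length(p) == ncol(ySite))
    p <- matrix(p, nrow(ySite), ncol(ySite), byrow = TRUE)
  p <- as.matrix(p)
  if (!all(dim(p) == dim(ySite)))
    stop("p must match the dimensions of ySite")
  if (anyNA(c(psi, theta)) || psi < 0 || psi > 1 || theta < 0 || theta > 1 ||
      any(p < 0 | p > 1))
    stop("probabilities must lie in [0, 1]")

  J <- nrow(ySite)
  occ <- numeric(J)
  for (j in seq_len(J)) {
    obs <- !is.na(ySite[j, ])
    detTerm <- prod(ifelse(ySite[j, obs] == 1, p[j, obs], 1 - p[j, obs]))
    allZero <- as.numeric(!any(ySite[j, obs] == 1))
    occ[j] <- theta * detTerm + (1 - theta) * allZero
  }
  siteAllZero <- as.numeric(!any(ySite == 1, na.rm = TRUE))
  psi * prod(occ) + (1 - psi) * siteAllZero
}

## Internal vectorized log-likelihood ---------------------------------------

# Collapse a DetectionHistory into unique (location, pattern) groups so the
# likelihood cost does not grow with the number of sites. Precomputes the
# pieces the vectorized likelihood needs: the observation mask, per-occasion
# and per-site all-zero indicators, and group counts.
.collapseHistory <- function(history) {
  y <- history@y
  S <- dim(y)[1L]
  J <- dim(y)[2L]
  M <- dim(y)[3L]
  pat <- vapply(seq_len(S), function(i) {
    v <- as.vector(y[i, , ])
    paste(ifelse(is.na(v), "-", v), collapse = "")
  }, character(1))
  key <- paste(history@location, pat, sep = "|")
  idx <- !duplicated(key)
  G <- sum(idx)
  yG <- array(y[idx, , , drop = FALSE], dim = c(G, J, M))
  mask <- 1 - is.na(yG)
  y0 <- yG
  y0[is.na(y0)] <- 0
  occasionZero <- matrix(1, G, J)
  for (j in seq_len(J))
    occasionZero[, j] <-
      as.numeric(rowSums(matrix(y0[, j, ] == 1 & mask[, j, ] == 1, G)) == 0)
  list(
    ySites = lapply(which(idx), function(i) matrix(y[i, , ], J, M)),
    y0 = y0, mask = mask, occasionZero = occasionZero,
    siteZero = as.numeric(apply(occasionZero, 1L, prod) == 1),
    location = history@location[idx],
    locIdx = match(history@location[idx], .LOCATIONS),
    counts = as.vector(table(factor(key, levels = key[idx]))),
    G = G, J = J, M = M
  )
}

# Per-site probability parameters implied by a spec and parameter vector.
# prob: named list psi[loc], theta[loc], p[loc, method] (all expanded).
.expandParams <- function(probs, spec, methods) {
  psi <- switch(spec@psi,
    constant = c(near_shore = probs[["psi"]], mid_lake = probs[["psi"]]),
    by_location = c(near_shore = probs[["psi_near_shore"]],
                    mid_lake = probs[["psi_mid_lake"]]))
  theta <- switch(spec@theta,
    constant = c(near_shore = probs[["theta"]], mid_lake = probs[["theta"]]),
    by_location = c(near_shore = probs[["theta_near_shore"]],
                    mid_lake = probs[["theta_mid_lake"]]))
  pMat <- matrix(NA_real_, 2L, length(methods),
                 dimnames = list(.LOCATIONS, methods))
  for (loc in .LOCATIONS) for (m in methods) {
    pMat[loc, m] <- switch(spec@p,
      constant = probs[["p"]],
      by_method = probs[[paste0("p_", m)]],
      by_location = probs[[paste0("p_", loc)]],
      by_method_and_location = probs[[paste0("p_", m, "_", loc)]])
  }
  list(psi = psi, theta = theta, p = pMat)
}

# Names of the free parameters of a spec (before removing fixed ones).
.paramNames <- function(spec, methods) {
  c(switch(spec@psi, constant = "psi",
           by_location = paste0("psi_", .LOCATIONS)),
    switch(spec@theta, constant = "theta",
           by_location = paste0("theta_", .LOCATIONS)),
    switch(spec@p,
           constant = "p",
           by_method = paste0("p_", methods),
           by_location = paste0("p_", .LOCATIONS),
           by_method_and_location = as.vector(outer(
             methods, .LOCATIONS, function(m, l) paste0("p_", m, "_", l)))))
}

# Negative log-likelihood over collapsed site groups, on the probability
# scale (a named vector including any fixed values). Vectorized across
# groups; algebraically identical to summing log siteLikelihood() per site.
.negLogLik <- function(probs, spec, collapsed, J, methods) {
  expanded <- .expandParams(as.list(probs), spec, methods)
  G <- collapsed$G
  M <- collapsed$M
  psiG <- expanded$psi[collapsed$locIdx]
  thetaG <- expanded$theta[collapsed$locIdx]
  pGM <- expanded$p[collapsed$locIdx, , drop = FALSE]          # G x M
  pArr <- aperm(array(pGM, dim = c(G, M, J)), c(1L, 3L, 2L))   # G x J x M
  # log detection term per cell, 0 where missing
  cellLog <- collapsed$mask *
    (collapsed$y0 * log(pArr) + (1 - collapsed$y0) * log1p(-pArr))
  detTerm <- exp(apply(cellLog, c(1L, 2L), sum))               # G x J
  occ <- thetaG * detTerm + (1 - thetaG) * collapsed$occasionZero
  prodOcc <- exp(rowSums(log(pmax(occ, 1e-300))))
  L <- psiG * prodOcc + (1 - psiG) * collapsed$siteZero
  -sum(collapsed$counts * log(pmax(L, 1e-300)))
}
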