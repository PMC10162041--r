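# Small constructors shared across test files.

# S x J x M history from a vector/array of 0/1/NA values
makeHistory <- function(values, S, J = 2, M = 2, location = NULL) {
  detectionHistory(array(values, dim = c(S, J, M)), location = location)
}

# every complete J x M binary history (rows of the returned list)
allCompleteHistories <- function(J = 2, M = 2) {
  cells <- J * M
  lapply(seq_len(2^cells) - 1L, function(i) {
    bits <- as.integer(intToBits(i))[seq_len(cells)]
    matrix(bits, J, M)
  })
}

# independent brute-force site likelihood: marginalize the latent states
# by explicit enumeration (occupancy z, availability a_j per occasion)
bruteForceSiteLikelihood <- function(y, psi, theta, p) {
  J <- nrow(y)
  M <- ncol(y)
  if (length(p) == 1L) p <- matrix(p, J, M)
  if (is.null(dim(p))) p <- matrix(p, J, M, byrow = TRUE)
  total <- 0
  for (z in 0:1) {
    availGrid <- expand.grid(rep(list(0:1), J))
    for (r in seq_len(nrow(availGrid))) {
      a <- as.integer(availGrid[r, ])
      prob <- ifelse(z == 1, psi, 1 - psi)
      for (j in seq_len(J)) {
        pa <- if (z == 1) ifelse(a[j] == 1, theta, 1 - theta)
              else ifelse(a[j] == 1, 0, 1)
        prob <- prob * pa
        for (m in seq_len(M)) {
          if (is.na(y[j, m])) next
          pd <- if (a[j] == 1) ifelse(y[j, m] == 1, p[j, m], 1 - p[j, m])
                else ifelse(y[j, m] == 1, 0, 1)
          prob <- prob * pd
        }
      }
      total <- total + prob
    }
  }
  total
}
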