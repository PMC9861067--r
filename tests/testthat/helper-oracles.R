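# Independent literal oracles, deliberately written with explicit loops so
# they share no code path with the vectorised implementations they check.

# Three-branch anti-diagonal mean (edge / bulk / edge) of an L x K matrix.
reconstruct_literal <- function(Y) {
  L <- nrow(Y); K <- ncol(Y); N <- L + K - 1
  stopifnot(L <= K)
  x <- numeric(N)
  for (t in seq_len(N)) {
    if (t <= L - 1) {
      x[t] <- mean(vapply(1:t, function(j) Y[j, t - j + 1], numeric(1)))
    } else if (t <= K) {
      x[t] <- mean(vapply(1:L, function(j) Y[j, t - j + 1], numeric(1)))
    } else {
      x[t] <- mean(vapply((t - K + 1):L, function(j) Y[j, t - j + 1], numeric(1)))
    }
  }
  x
}

# One ADMM sweep (Wiener-filter mode updates in order, then the
# power-spectrum-centroid frequency update per mode) on the mirror-extended
# half spectrum, starting from zero modes and zero centre frequencies.
vmd_first_iteration_literal <- function(x, k, alpha, dc) {
  N <- length(x)
  h <- floor(N / 2)
  fm <- c(rev(x[1:h]), x, rev(x[(h + 1):N]))
  Tt <- length(fm)
  nh <- floor(Tt / 2) + 1
  om <- (0:(nh - 1)) / Tt
  fhat <- stats::fft(fm)[1:nh]
  u <- matrix(0 + 0i, nh, k)
  w <- rep(0, k)
  for (j in 1:k) {
    for (b in 1:nh) {
      others <- 0 + 0i
      for (i in 1:k) if (i != j) others <- others + u[b, i]
      u[b, j] <- (fhat[b] - others) / (1 + 2 * alpha * (om[b] - w[j])^2)
    }
    if (!(dc && j == 1)) {
      num <- 0; den <- 0
      for (b in 1:nh) {
        p <- Mod(u[b, j])^2
        num <- num + om[b] * p
        den <- den + p
      }
      w[j] <- num / den
    }
  }
  list(u = u, w = w)
}
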