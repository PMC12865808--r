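# Independent brute-force oracles (direct summation, no FFT) used to check
# the wavelet-coherence implementation on small inputs.

oracle_cwt <- function(x, fs, periods_s, omega0 = 6) {
  n <- length(x)
  dt <- 1 / fs
  ff <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  scales <- periods_s / ff
  coef <- matrix(0i, length(scales), n)
  for (i in seq_along(scales)) {
    s <- scales[i]
    K <- ceiling(6 * s / dt)
    for (t in seq_len(n)) {
      acc <- 0i
      for (j in seq(-K, K)) {
        tt <- t + j
        if (tt >= 1 && tt <= n) {
          u <- j * dt / s
          psi <- pi^(-1 / 4) * exp(1i * omega0 * u - u^2 / 2)
          acc <- acc + x[tt] * Conj(psi)
        }
      }
      coef[i, t] <- acc * sqrt(dt / s)
    }
  }
  coef
}

oracle_smooth_time_row <- function(v, sigma) {
  n <- length(v)
  out <- v
  K <- max(1, ceiling(4 * max(sigma, 1e-8)))
  for (t in seq_len(n)) {
    wsum <- 0
    acc <- 0
    for (j in seq(-K, K)) {
      tt <- t + j
      if (tt >= 1 && tt <= n) {
        w <- exp(-j^2 / (2 * max(sigma, 1e-8)^2))
        wsum <- wsum + w
        acc <- acc + w * v[tt]
      }
    }
    out[t] <- acc / wsum
  }
  out
}

oracle_smooth_scale <- function(M, periods_s, octaves = 0.6) {
  ns <- nrow(M)
  if (ns < 2) return(M)
  dj <- mean(diff(log2(periods_s)))
  m <- octaves / dj
  if (m <= 1) return(M)
  k <- floor((m - 1) / 2)
  r <- (m - (2 * k + 1)) / 2
  w <- c(r, rep(1, 2 * k + 1), r)
  off <- seq(-(k + 1), k + 1)
  out <- M
  for (i in seq_len(ns)) {
    acc <- 0 * M[1, ]
    wsum <- 0
    for (q in seq_along(off)) {
      src <- i + off[q]
      if (src >= 1 && src <= ns) {
        acc <- acc + w[q] * M[src, ]
        wsum <- wsum + w[q]
      }
    }
    out[i, ] <- acc / wsum
  }
  out
}

oracle_wtc <- function(x, y, fs, periods_s, omega0 = 6) {
  ff <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  scales <- periods_s / ff
  Wx <- oracle_cwt(x, fs, periods_s, omega0)
  Wy <- oracle_cwt(y, fs, periods_s, omega0)
  sm <- function(P) {
    for (i in seq_len(nrow(P)))
      P[i, ] <- oracle_smooth_time_row(P[i, ], scales[i] * fs / sqrt(2))
    oracle_smooth_scale(P, periods_s)
  }
  smc <- function(P) {
    re <- sm(Re(P)); im <- sm(Im(P))
    re + 1i * im
  }
  sxx <- sm((abs(Wx)^2) / scales)
  syy <- sm((abs(Wy)^2) / scales)
  sxy <- smc((Wx * Conj(Wy)) / scales)
  (abs(sxy)^2) / (sxx * syy)
}
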