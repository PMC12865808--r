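# Morlet wavelet transform coherence with adaptive period band and
# cone-of-influence exclusion.
#
# Conventions (all config-exposed): analytic Morlet mother with omega0 = 6;
# scale s = period * (omega0 + sqrt(2 + omega0^2)) / (4*pi); smoothing is a
# Gaussian in time with SD s/sqrt(2) followed by a 0.6-octave boxcar across
# scale; the cone of influence uses the e-folding time sqrt(2)*s.

morlet_fourier_factor <- function(omega0 = 6) {
  4 * pi / (omega0 + sqrt(2 + omega0^2))
}

# Per-grid cache of kernel FFTs and edge-normalization factors. Cohort-scale
# runs reuse one (n, fs, periods) grid thousands of times; the kernels only
# depend on the grid, so they are computed once.
.wtc_cache <- new.env(parent = emptyenv())

grid_key <- function(tag, n, fs, periods, omega0 = 6) {
  paste(tag, n, format(fs, digits = 12), omega0,
        paste(format(range(periods), digits = 12), collapse = ","),
        length(periods), sep = "|")
}

cache_get_or_set <- function(key, builder) {
  if (!exists(key, envir = .wtc_cache, inherits = FALSE)) {
    if (length(ls(.wtc_cache)) > 32) rm(list = ls(.wtc_cache), envir = .wtc_cache)
    assign(key, builder(), envir = .wtc_cache)
  }
  get(key, envir = .wtc_cache, inherits = FALSE)
}

#' Adaptive period range for a segment
#'
#' The analysis band runs from \code{min_period_s} up to one quarter of the
#' segment duration, guaranteeing at least four cycles of the slowest
#' analysed fluctuation. A 300-s segment therefore yields the band
#' (8, 75) s, i.e. approximately 0.0133-0.125 Hz.
#'
#' @param duration_s segment duration in seconds.
#' @param min_period_s shortest analysed period (default 8 s).
#' @return Numeric length-2: (pmin_s, pmax_s).
#' @export
adaptive_period_range <- function(duration_s, min_period_s = 8) {
  if (duration_s / 4 < min_period_s)
    stop_input(sprintf(
      "segment too short: duration/4 = %.2f s < minimum period %.2f s",
      duration_s / 4, min_period_s))
  c(min_period_s, duration_s / 4)
}

#' Logarithmic period grid
#'
#' @param band length-2 period band (s).
#' @param voices_per_octave scale resolution (default 12).
#' @return Increasing vector of periods covering the band, endpoints included.
#' @export
period_grid <- function(band, voices_per_octave = 12) {
  if (band[1] > band[2]) stop_input("invalid period band")
  if (abs(band[2] - band[1]) < 1e-12) return(band[1])
  dj <- 1 / voices_per_octave
  k <- seq(0, log2(band[2] / band[1]), by = dj)
  p <- band[1] * 2^k
  if (p[length(p)] < band[2] * (1 - 1e-12)) p <- c(p, band[2])
  p
}

#' Continuous wavelet transform with the analytic Morlet wavelet
#'
#' Correlates the series with time-sampled analytic Morlet wavelets
#' \eqn{\psi(u) = \pi^{-1/4} e^{i\omega_0 u} e^{-u^2/2}} at the scales
#' corresponding to \code{periods_s}, using FFT convolution on a zero-padded
#' buffer (identical to direct correlation with the truncated kernel; the
#' kernel is supported on +/- 6 scale SDs).
#'
#' @param x real time series (finite values).
#' @param fs sampling rate (Hz).
#' @param periods_s vector of analysed periods (s), increasing.
#' @param omega0 Morlet nondimensional frequency (default 6).
#' @return A \code{cwt_result}: list with complex \code{coef}
#'   (periods x time), \code{periods_s}, \code{scales}, per-time
#'   \code{coi_period_s}, \code{fs}, \code{omega0}.
#' @export
morlet_cwt <- function(x, fs, periods_s, omega0 = 6) {
  if (anyNA(x) || !all(is.finite(x))) stop_input("input series contains NA/Inf")
  n <- length(x)
  dt <- 1 / fs
  ff <- morlet_fourier_factor(omega0)
  scales <- periods_s / ff
  kmax <- ceiling(6 * max(scales) / dt)
  L <- next_fft_len(n + kmax)
  kern <- cache_get_or_set(grid_key("cwt", n, fs, periods_s, omega0), function() {
    G <- matrix(0i, L, length(scales))
    norm_c <- pi^(-1 / 4)
    for (i in seq_along(scales)) {
      s <- scales[i]
      K <- ceiling(6 * s / dt)
      j <- seq(-K, K)
      u <- j * dt / s
      psi <- norm_c * exp(1i * omega0 * u - u^2 / 2) * sqrt(dt / s)
      g <- complex(length.out = L)
      g[(j %% L) + 1] <- psi
      G[, i] <- g
    }
    Conj(stats::mvfft(G))
  })
  X <- fft(c(x, numeric(L - n)))
  coef <- t(stats::mvfft(X * kern, inverse = TRUE) / L)[, seq_len(n), drop = FALSE]
  dist <- pmin(seq_len(n) - 1, n - seq_len(n)) * dt
  structure(list(coef = coef, periods_s = periods_s, scales = scales,
                 coi_period_s = ff * dist / sqrt(2), fs = fs, n = n,
                 omega0 = omega0),
            class = "cwt_result")
}

# ---- smoothing operators ---------------------------------------------------

# Gaussian smoothing along time, one SD per row (in samples); edges are
# renormalized over the in-range part of the truncated (+/- 4 SD) kernel.
# All rows share one FFT length so the whole matrix is smoothed with two
# mvfft calls; kernel FFTs and edge norms are cached per grid.
smooth_time <- function(M, sigma_samples, cache_tag = NULL) {
  n <- ncol(M)
  ns <- nrow(M)
  kmax <- max(1L, ceiling(4 * max(sigma_samples)))
  L <- next_fft_len(n + 2 * kmax + 1)
  key <- grid_key(paste0("smt", ns), n, L, sigma_samples)
  kern <- cache_get_or_set(key, function() {
    G <- matrix(0, L, ns)
    for (i in seq_len(ns)) {
      sig <- max(sigma_samples[i], 1e-8)
      K <- max(1L, ceiling(4 * sig))
      j <- seq(-K, K)
      g <- numeric(L)
      g[(j %% L) + 1] <- exp(-j^2 / (2 * sig^2))
      G[, i] <- g
    }
    Gf <- Conj(stats::mvfft(G))
    ones <- fft(c(rep(1, n), numeric(L - n)))
    norm <- t(Re(stats::mvfft(ones * Gf, inverse = TRUE) / L))[, seq_len(n),
                                                              drop = FALSE]
    list(Gf = Gf, norm = norm)
  })
  conv_mat <- function(A) {
    Ap <- rbind(t(A), matrix(0, L - n, ns))
    t(Re(stats::mvfft(stats::mvfft(Ap) * kern$Gf, inverse = TRUE) / L))[,
      seq_len(n), drop = FALSE]
  }
  if (is.complex(M)) {
    (conv_mat(Re(M)) + 1i * conv_mat(Im(M))) / kern$norm
  } else {
    conv_mat(M) / kern$norm
  }
}

# boxcar smoothing across scales (rows), width in octaves; fractional end
# weights, renormalized where the window is truncated by the grid edge.
smooth_scale <- function(M, periods_s, octaves = 0.6) {
  ns <- nrow(M)
  if (ns < 2 || octaves <= 0) return(M)
  dj <- mean(diff(log2(periods_s)))
  m <- octaves / dj
  if (m <= 1) return(M)
  k <- floor((m - 1) / 2)
  r <- (m - (2 * k + 1)) / 2
  w <- c(r, rep(1, 2 * k + 1), r)
  off <- seq(-(k + 1), k + 1)
  out <- 0 * M
  norm <- numeric(ns)
  for (q in seq_along(off)) {
    src <- seq_len(ns) + off[q]
    ok <- src >= 1 & src <= ns
    out[ok, ] <- out[ok, ] + w[q] * M[src[ok], , drop = FALSE]
    norm[ok] <- norm[ok] + w[q]
  }
  out / norm
}

smoothed_power <- function(cw) {
  P <- (abs(cw$coef)^2) / cw$scales
  smooth_scale(smooth_time(P, cw$scales * cw$fs / sqrt(2)), cw$periods_s)
}

smoothed_cross <- function(cx, cy) {
  P <- (cx$coef * Conj(cy$coef)) / cx$scales
  smooth_scale(smooth_time(P, cx$scales * cx$fs / sqrt(2)), cx$periods_s)
}

#' Wavelet transform coherence of two transforms
#'
#' \deqn{R^2 = \frac{|S(s^{-1} W_{xy})|^2}
#'   {S(s^{-1}|W_x|^2) \, S(s^{-1}|W_y|^2)}}
#' with the smoothing operator \eqn{S} described in the file header. Values
#' are bounded in [0, 1] (Cauchy-Schwarz under the common smoothing weights)
#' and are exactly 1 for identical inputs.
#'
#' @param cx,cy \code{cwt_result}s on identical grids.
#' @param sxx,syy optional precomputed smoothed auto-power matrices (reused
#'   heavily by the surrogate module).
#' @return A \code{wtc_matrix}: list with \code{coherence} (periods x time),
#'   \code{periods_s}, \code{coi_mask} (TRUE = outside the cone, i.e. valid),
#'   \code{coi_period_s}, \code{fs}.
#' @export
compute_wtc <- function(cx, cy, sxx = NULL, syy = NULL) {
  if (!identical(cx$periods_s, cy$periods_s) || cx$n != cy$n ||
      cx$fs != cy$fs)
    stop_input("CWT grids do not match")
  if (is.null(sxx)) sxx <- smoothed_power(cx)
  if (is.null(syy)) syy <- smoothed_power(cy)
  sxy <- smoothed_cross(cx, cy)
  coh <- (abs(sxy)^2) / (sxx * syy)
  coh <- pmin(pmax(coh, 0), 1)
  mask <- outer(cx$periods_s, cx$coi_period_s, "<=")
  structure(list(coherence = coh, periods_s = cx$periods_s,
                 coi_mask = mask, coi_period_s = cx$coi_period_s, fs = cx$fs),
            class = "wtc_matrix")
}

#' Average coherence over a period band outside the cone of influence
#'
#' Arithmetic mean over all time-scale cells whose period lies inside
#' \code{band} and which fall outside the cone of influence. Excluded cells
#' are removed, not zero-filled.
#'
#' @param wtc a \code{wtc_matrix}.
#' @param band length-2 period band (s); defaults to the full grid.
#' @return List: \code{wtc_value} (NA when no valid cell),
#'   \code{n_valid_cells}, and \code{reason} (NULL or
#'   \code{"fully inside COI"}).
#' @export
mask_and_average <- function(wtc, band = range(wtc$periods_s)) {
  inband <- wtc$periods_s >= band[1] - 1e-9 & wtc$periods_s <= band[2] + 1e-9
  if (!any(inband)) stop_input("band outside the computed period grid")
  sel <- wtc$coi_mask & inband
  nv <- sum(sel)
  if (nv == 0)
    return(list(wtc_value = NA_real_, n_valid_cells = 0L,
                reason = "fully inside COI"))
  list(wtc_value = mean(wtc$coherence[sel]), n_valid_cells = as.integer(nv),
       reason = NULL)
}

#' Enumerate ROI pairs
#'
#' All unordered pairs with repetition: homologous pairs first (in ROI
#' order), then cross pairs in upper-triangle order. For the canonical four
#' ROIs (IFGl, IFGr, TPJl, TPJr) this yields the 10 pairs IFGl_IFGl,
#' IFGr_IFGr, TPJl_TPJl, TPJr_TPJr, IFGl_IFGr, IFGl_TPJl, IFGl_TPJr,
#' IFGr_TPJl, IFGr_TPJr, TPJl_TPJr.
#'
#' @param rois ordered character vector of ROI labels.
#' @return Data frame with label, roi1, roi2.
#' @export
enumerate_roi_pairs <- function(rois = c("IFGl", "IFGr", "TPJl", "TPJr")) {
  if (length(rois) == 0) stop_input("need at least one ROI")
  k <- length(rois)
  r1 <- rois; r2 <- rois
  if (k > 1) {
    idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    r1 <- c(rois, rois[idx[, 1]])
    r2 <- c(rois, rois[idx[, 2]])
  }
  data.frame(label = paste(r1, r2, sep = "_"), roi1 = r1, roi2 = r2,
             stringsAsFactors = FALSE)
}

# ROI signals: mean of good channels per ROI; NULL if the ROI has no good one
roi_signals <- function(mat, channel_roi, bad_channel = NULL) {
  rois <- unique(channel_roi)
  out <- list()
  for (r in rois) {
    cols <- which(channel_roi == r)
    if (!is.null(bad_channel)) cols <- cols[!bad_channel[cols]]
    out[[r]] <- if (length(cols) == 0) NULL else
      rowMeans(mat[, cols, drop = FALSE])
  }
  out
}

#' Dyad-level synchrony table
#'
#' For each phase of a (preprocessed or synthetic) recording: averages HbO
#' across each ROI's good channels, splits the phase into equal intervals,
#' applies the adaptive period range to the interval duration, computes WTC
#' between the partners' ROI signals, and averages over the band outside the
#' cone of influence. Heterologous pairs are computed in both directions
#' (A.roi1 with B.roi2 and A.roi2 with B.roi1) and averaged. One row per
#' dyad x ROI pair x phase x interval.
#'
#' @param recording a \code{dyad_recording} (or an object with the same
#'   shape holding preprocessed HbO).
#' @param quality optional list \code{list(A=, B=)} of logical bad-channel
#'   vectors (per channel, in column order).
#' @param intervals_per_phase number of equal intervals (default 2).
#' @param min_period_s shortest analysed period (default 8 s).
#' @param voices_per_octave scale resolution (default 12).
#' @param signal \code{"hbo"} (default) or \code{"hbr"} for the
#'   supplementary-style rerun.
#' @return Data frame: dyad_id, roi_pair, phase, interval, wtc_value,
#'   n_valid_cells, excluded_reason.
#' @export
dyad_synchrony <- function(recording, quality = NULL,
                           intervals_per_phase = 2, min_period_s = 8,
                           voices_per_octave = 12, signal = c("hbo", "hbr")) {
  signal <- match.arg(signal)
  pairs <- enumerate_roi_pairs(recording$rois)
  interval_names <- if (intervals_per_phase == 2) c("first", "second") else
    paste0("interval", seq_len(intervals_per_phase))
  rows <- list()
  for (ph in names(recording$phases)) {
    phx <- recording$phases[[ph]]
    n <- phx$n
    cut <- floor(seq(0, n, length.out = intervals_per_phase + 1))
    for (iv in seq_len(intervals_per_phase)) {
      idx <- (cut[iv] + 1):cut[iv + 1]
      dur <- length(idx) / recording$fs
      band <- adaptive_period_range(dur, min_period_s)
      periods <- period_grid(band, voices_per_octave)
      cws <- list()
      pows <- list()
      for (p in c("A", "B")) {
        sig <- roi_signals(phx[[signal]][[p]][idx, , drop = FALSE],
                           recording$channel_roi,
                           if (!is.null(quality)) quality[[p]] else NULL)
        cws[[p]] <- lapply(sig, function(x)
          if (is.null(x)) NULL else morlet_cwt(x, recording$fs, periods))
        pows[[p]] <- lapply(cws[[p]], function(cw)
          if (is.null(cw)) NULL else smoothed_power(cw))
      }
      pair_value <- function(rA, rB) {
        if (is.null(cws$A[[rA]]) || is.null(cws$B[[rB]])) return(NULL)
        w <- compute_wtc(cws$A[[rA]], cws$B[[rB]],
                         sxx = pows$A[[rA]], syy = pows$B[[rB]])
        mask_and_average(w, band)
      }
      for (k in seq_len(nrow(pairs))) {
        r1 <- pairs$roi1[k]; r2 <- pairs$roi2[k]
        if (r1 == r2) {
          res <- pair_value(r1, r2)
        } else {
          a <- pair_value(r1, r2)
          b <- pair_value(r2, r1)
          res <- if (is.null(a) || is.null(b)) NULL else {
            vals <- c(a$wtc_value, b$wtc_value)
            if (all(is.na(vals))) {
              list(wtc_value = NA_real_, n_valid_cells = 0L,
                   reason = "fully inside COI")
            } else {
              list(wtc_value = mean(vals, na.rm = TRUE),
                   n_valid_cells = a$n_valid_cells + b$n_valid_cells,
                   reason = NULL)
            }
          }
        }
        if (is.null(res))
          res <- list(wtc_value = NA_real_, n_valid_cells = 0L,
                      reason = "bad ROI")
        rows[[length(rows) + 1]] <- data.frame(
          dyad_id = recording$dyad_id,
          roi_pair = pairs$label[k],
          phase = ph,
          interval = interval_names[iv],
          wtc_value = res$wtc_value,
          n_valid_cells = res$n_valid_cells,
          excluded_reason = res$reason %||% NA_character_,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}
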