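# Simplified fNIRS preprocessing chain:
#   intensity -> optical density -> motion detection -> spline correction
#   -> wavelet despiking -> zero-phase band-pass -> modified Beer-Lambert.
# Every threshold is exposed; no step changes series length or sampling rate.

#' Default extinction coefficients (760 / 850 nm)
#'
#' Molar extinction coefficients (cm^-1 M^-1) of oxy- and deoxyhemoglobin at
#' the two standard measurement wavelengths; rows = wavelengths (760, 850),
#' columns = (HbO, HbR).
#' @return 2x2 numeric matrix.
#' @export
extinction_default <- function() {
  matrix(c(1486.5865, 3843.707,
           2526.391, 1798.643),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("wl760", "wl850"), c("HbO", "HbR")))
}

#' Convert raw intensity to optical density
#'
#' \eqn{OD(t) = -\log_{10}(I(t) / \bar I)} per channel, where \eqn{\bar I} is
#' the channel's mean intensity.
#'
#' @param intensity numeric matrix (time x channels), strictly positive.
#' @return Matrix of optical-density changes, same shape.
#' @export
intensity_to_od <- function(intensity) {
  intensity <- as.matrix(intensity)
  bad <- which(intensity <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_input(sprintf(
      "nonpositive intensity at sample %d, channel %s",
      bad[1, 1], colnames(intensity)[bad[1, 2]] %||% as.character(bad[1, 2])))
  means <- colMeans(intensity)
  -log10(sweep(intensity, 2, means, "/"))
}

#' Detect motion artifacts
#'
#' A sample is flagged when the signal range (max - min) within a centred
#' moving window exceeds \code{sd_factor} times a robust channel noise SD
#' (MAD of the first differences, scaled to the SD of the undifferenced
#' noise) or \code{amp_thresh} in absolute value; flags are dilated to the
#' full window. Estimating the noise level from first differences keeps the
#' threshold insensitive to the artifacts being detected.
#'
#' @param od matrix (time x channels) of optical density (or any signal).
#' @param fs sampling rate (Hz).
#' @param window_s moving-window length in seconds (>= 2 samples).
#' @param sd_factor multiple of the robust channel SD.
#' @param amp_thresh absolute amplitude threshold.
#' @return Logical matrix, same shape as \code{od}; TRUE = artifact.
#' @export
detect_motion <- function(od, fs, window_s = 1, sd_factor = 13.5,
                          amp_thresh = 0.4) {
  od <- as.matrix(od)
  w <- max(2L, round(window_s * fs))
  n <- nrow(od)
  mask <- matrix(FALSE, n, ncol(od), dimnames = dimnames(od))
  half <- floor(w / 2)
  for (j in seq_len(ncol(od))) {
    x <- od[, j]
    s <- mad(diff(x)) / sqrt(2)
    if (s == 0) s <- sd(x)
    # rolling range via cummax trick on windows
    rng <- vapply(seq_len(n), function(i) {
      idx <- max(1, i - half):min(n, i + half)
      diff(range(x[idx]))
    }, 0)
    hit <- rng > sd_factor * s | rng > amp_thresh
    if (any(hit)) {
      flag <- rep(FALSE, n)
      for (i in which(hit)) flag[max(1, i - half):min(n, i + half)] <- TRUE
      mask[, j] <- flag
    }
  }
  mask
}

#' Spline-based motion correction
#'
#' Within each flagged segment, a smoothing spline is fitted to the artifact
#' trend and subtracted; the residual segment is re-anchored by adding the
#' linear interpolation between the clean samples bordering the segment, so
#' the corrected segment joins its neighbours without discontinuity.
#' Unflagged samples pass through unchanged. A fully flagged channel is left
#' untouched and reported as bad.
#'
#' @param od matrix (time x channels).
#' @param mask logical matrix from \code{\link{detect_motion}}.
#' @param smoothing spline tracking parameter in (0, 1]: 0 fits a straight
#'   line through the segment, values near 1 track the artifact closely
#'   (mapped to the equivalent degrees of freedom of
#'   \code{\link[stats]{smooth.spline}}); default 0.99.
#' @return List with \code{od} (corrected matrix) and \code{bad_channels}
#'   (character or integer ids of fully flagged channels).
#' @export
spline_correct <- function(od, mask, smoothing = 0.99) {
  od <- as.matrix(od)
  if (!all(dim(mask) == dim(od))) stop_input("mask shape must match data")
  out <- od
  bad <- c()
  n <- nrow(od)
  for (j in seq_len(ncol(od))) {
    m <- mask[, j]
    if (!any(m)) next
    if (all(m)) {
      bad <- c(bad, colnames(od)[j] %||% j)
      next
    }
    x <- od[, j]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      seg <- x[i0:i1]
      len <- length(seg)
      if (len >= 8) {
        dfree <- max(2, min(len - 1, 2 + smoothing * (len - 2)))
        fit <- tryCatch(
          smooth.spline(seq_len(len), seg, df = dfree)$y,
          error = function(e) stats::fitted(lm(seg ~ seq_len(len))))
      } else fit <- seg
      resid <- seg - fit
      # force zero residual at both segment ends so the corrected segment
      # joins its neighbours continuously
      ramp <- resid[1] + (resid[len] - resid[1]) *
        (seq_len(len) - 1) / max(len - 1, 1)
      resid <- resid - ramp
      left <- if (i0 > 1) x[i0 - 1] else x[i1 + 1]
      right <- if (i1 < n) x[i1 + 1] else x[i0 - 1]
      anchor <- seq(left, right, length.out = len + 2)[2:(len + 1)]
      out[i0:i1, j] <- resid + anchor
    }
  }
  list(od = out, bad_channels = bad)
}

# --- minimal periodized Daubechies-4 DWT (no wavelet package on board) -----

.db4_lo <- c(0.48296291314469025, 0.836516303737469,
             0.22414386804185735, -0.12940952255092145)
.db4_hi <- c(-0.12940952255092145, -0.22414386804185735,
             0.836516303737469, -0.48296291314469025)

dwt_step <- function(x, filt) {
  n <- length(x)
  idx <- outer(seq(1, n, by = 2) - 1, seq_along(filt) - 1, "+") %% n + 1
  as.numeric(matrix(x[idx], ncol = length(filt)) %*% filt)
}

idwt_step <- function(approx, detail) {
  n <- 2 * length(approx)
  x <- numeric(n)
  for (k in seq_along(approx)) {
    pos <- (2 * (k - 1) + seq_along(.db4_lo) - 1) %% n + 1
    x[pos] <- x[pos] + approx[k] * .db4_lo + detail[k] * .db4_hi
  }
  x
}

# full periodized pyramid; n must be padded to a power of two by the caller
dwt_pyramid <- function(x, levels) {
  details <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    d <- dwt_step(a, .db4_hi)
    a <- dwt_step(a, .db4_lo)
    details[[l]] <- d
  }
  list(approx = a, details = details)
}

idwt_pyramid <- function(pyr) {
  a <- pyr$approx
  for (l in rev(seq_along(pyr$details))) a <- idwt_step(a, pyr$details[[l]])
  a
}

#' Wavelet despiking
#'
#' Discrete (periodized Daubechies-4) wavelet decomposition per channel;
#' detail coefficients whose magnitude exceeds \code{iqr_factor} times the
#' interquartile range of their level are zeroed, and the signal is
#' reconstructed. Spiky transients live in a few large detail coefficients
#' and are attenuated, while smooth slow components pass through.
#'
#' @param od matrix (time x channels).
#' @param iqr_factor coefficients with |coef - median| beyond
#'   \code{iqr_factor} x IQR of their level are zeroed; \code{Inf} disables
#'   thresholding.
#' @return Filtered matrix, same shape.
#' @export
wavelet_filter <- function(od, iqr_factor = 1.5) {
  od <- as.matrix(od)
  n <- nrow(od)
  n2 <- 2^ceiling(log2(n))
  levels <- max(1L, floor(log2(n2)) - 3L)
  out <- od
  for (j in seq_len(ncol(od))) {
    x <- od[, j]
    xp <- c(x, rev(x))[seq_len(n2)] # reflect-pad to dyadic length
    if (n2 > 2 * n) xp <- rep(c(x, rev(x)), length.out = n2)
    pyr <- dwt_pyramid(xp, levels)
    if (is.finite(iqr_factor)) {
      pyr$details <- lapply(pyr$details, function(d) {
        iqr <- stats::IQR(d)
        if (iqr == 0) return(d)
        d[abs(d - median(d)) > iqr_factor * iqr] <- 0
        d
      })
    }
    out[, j] <- idwt_pyramid(pyr)[seq_len(n)]
  }
  out
}

#' Zero-phase band-pass filter
#'
#' Frequency-domain filtering with a raised-cosine transition band (10% of
#' each cutoff), applied to the FFT of the (reflect-padded, detrended)
#' signal; exactly zero phase. The default band 0.01-0.5 Hz removes drift,
#' cardiac and most respiratory energy while preserving the hemodynamic band.
#'
#' @param od matrix (time x channels).
#' @param fs sampling rate (Hz).
#' @param low_hz,high_hz band edges; \code{0 <= low_hz < high_hz <= fs/2}.
#' @return Filtered matrix, same shape.
#' @export
bandpass <- function(od, fs, low_hz = 0.01, high_hz = 0.5) {
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz <= fs / 2))
    stop_input("invalid band: need 0 <= low_hz < high_hz <= Nyquist")
  od <- as.matrix(od)
  n <- nrow(od)
  np <- next_fft_len(2 * n)
  freq <- seq(0, np - 1) / np * fs
  freq <- pmin(freq, fs - freq)
  gain <- cosine_gain(freq, low_hz, high_hz)
  out <- od
  for (j in seq_len(ncol(od))) {
    x <- od[, j]
    mu <- mean(x)
    xp <- c(x - mu, rev(x - mu), numeric(np - 2 * n))
    y <- Re(fft(fft(xp) * gain, inverse = TRUE)) / np
    out[, j] <- y[seq_len(n)] + if (low_hz == 0) mu else 0
  }
  out
}

# raised-cosine band gain with 10% transition width around each cutoff
cosine_gain <- function(freq, low_hz, high_hz) {
  g <- rep(1, length(freq))
  if (low_hz > 0) {
    tw <- 0.1 * low_hz
    lo0 <- low_hz - tw
    ramp <- freq > lo0 & freq < low_hz
    g[freq <= lo0] <- 0
    g[ramp] <- 0.5 * (1 - cos(pi * (freq[ramp] - lo0) / tw))
  }
  tw <- 0.1 * high_hz
  hi1 <- high_hz + tw
  ramp <- freq > high_hz & freq < hi1
  g[freq >= hi1] <- 0
  g[ramp] <- 0.5 * (1 + cos(pi * (freq[ramp] - high_hz) / tw))
  g
}

#' Modified Beer-Lambert transform
#'
#' Solves, per sample and channel, the 2x2 system
#' \deqn{\Delta OD_\lambda = (\epsilon_{HbO,\lambda}\Delta HbO +
#'   \epsilon_{HbR,\lambda}\Delta HbR) \, d \, DPF_\lambda}
#' for the concentration changes \eqn{(\Delta HbO, \Delta HbR)}.
#'
#' @param od760,od850 matrices (time x channels) of optical-density changes
#'   at the two wavelengths.
#' @param dpf length-2 differential pathlength factors.
#' @param extinction 2x2 extinction matrix (rows = wavelengths,
#'   cols = HbO/HbR); must be invertible.
#' @param distance_cm source-detector separation (cm).
#' @return List with matrices \code{hbo} and \code{hbr} (molar units; multiply
#'   by 1e6 for micromolar).
#' @export
mbll <- function(od760, od850, dpf = c(6, 6),
                 extinction = extinction_default(), distance_cm = 3) {
  if (any(dpf <= 0) || distance_cm <= 0)
    stop_input("dpf and distance must be > 0")
  A <- extinction * (distance_cm * dpf) # row-wise scaling
  if (abs(det(A)) < 1e-12) stop_input("extinction matrix is singular")
  Ainv <- solve(A)
  hbo <- Ainv[1, 1] * od760 + Ainv[1, 2] * od850
  hbr <- Ainv[2, 1] * od760 + Ainv[2, 2] * od850
  list(hbo = hbo, hbr = hbr)
}

#' Channel quality assessment and exclusion bookkeeping
#'
#' A channel is bad when its intensity coefficient of variation exceeds
#' \code{cv_thresh}, when it is flat (zero variance), or when it saturates.
#' An ROI is bad when all of its channels are bad, and a dyad is excluded
#' for an ROI pair when either member's ROI involved in the pair is bad —
#' which is what produces differing per-ROI-pair sample sizes downstream.
#'
#' @param intensity matrix (time x channels) of raw intensity (one
#'   wavelength, or the elementwise minimum quality over wavelengths can be
#'   obtained by calling twice and OR-ing).
#' @param channel_roi character vector mapping each column to its ROI.
#' @param cv_thresh coefficient-of-variation threshold (default 0.15).
#' @param saturation intensity ceiling regarded as sensor saturation.
#' @return List with logical \code{bad_channel} (per column), logical
#'   \code{bad_roi} (per ROI), and the \code{cv} values.
#' @export
channel_quality <- function(intensity, channel_roi, cv_thresh = 0.15,
                            saturation = Inf) {
  if (cv_thresh <= 0) stop_input("cv_thresh must be > 0")
  intensity <- as.matrix(intensity)
  mu <- colMeans(intensity)
  s <- apply(intensity, 2, sd)
  cv <- ifelse(mu > 0, s / mu, Inf)
  flat <- s < 1e-12
  sat <- apply(intensity, 2, max) >= saturation
  bad <- cv > cv_thresh | flat | sat
  rois <- unique(channel_roi)
  bad_roi <- vapply(rois, function(r) all(bad[channel_roi == r]), TRUE)
  list(bad_channel = setNames(bad, colnames(intensity)),
       bad_roi = setNames(bad_roi, rois), cv = cv)
}

#' Run the full preprocessing chain for one participant
#'
#' Fixed order: intensity -> OD -> motion detection -> spline correction ->
#' wavelet despiking -> band-pass -> MBLL. Returns HbO/HbR plus quality
#' flags; series length and sampling rate are never changed.
#'
#' @param raw list with matrices \code{wl760} and \code{wl850}
#'   (time x channels, both wavelengths for every channel).
#' @param fs sampling rate (Hz).
#' @param channel_roi ROI label per channel.
#' @param params list of chain parameters; see defaults in the function
#'   signature of the individual steps.
#' @return List with \code{hbo}, \code{hbr} (micromolar), \code{quality}
#'   (from \code{\link{channel_quality}}), \code{mask} and
#'   \code{bad_channels}.
#' @export
preprocess_participant <- function(raw, fs, channel_roi,
                                   params = list()) {
  p <- modifyList(list(window_s = 1, sd_factor = 13.5, amp_thresh = 0.4,
                       smoothing = 0.99, iqr_factor = 1.5,
                       low_hz = 0.01, high_hz = 0.5,
                       dpf = c(6, 6), distance_cm = 3,
                       cv_thresh = 0.15), params)
  q1 <- channel_quality(raw$wl760, channel_roi, p$cv_thresh)
  q2 <- channel_quality(raw$wl850, channel_roi, p$cv_thresh)
  quality <- list(bad_channel = q1$bad_channel | q2$bad_channel,
                  bad_roi = q1$bad_roi | q2$bad_roi,
                  cv = pmax(q1$cv, q2$cv))
  ods <- lapply(raw[c("wl760", "wl850")], intensity_to_od)
  bad_from_spline <- c()
  for (wl in names(ods)) {
    mask <- detect_motion(ods[[wl]], fs, p$window_s, p$sd_factor, p$amp_thresh)
    sc <- spline_correct(ods[[wl]], mask, p$smoothing)
    bad_from_spline <- union(bad_from_spline, sc$bad_channels)
    x <- wavelet_filter(sc$od, p$iqr_factor)
    ods[[wl]] <- bandpass(x, fs, p$low_hz, p$high_hz)
  }
  hb <- mbll(ods$wl760, ods$wl850, p$dpf, distance_cm = p$distance_cm)
  list(hbo = hb$hbo * 1e6, hbr = hb$hbr * 1e6,
       quality = quality, bad_channels = bad_from_spline)
}
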