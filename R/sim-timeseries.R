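# Synthetic dyadic hemodynamic time series with tunable cross-brain coupling.

#' Band-limited Gaussian noise
#'
#' White Gaussian noise restricted (by hard FFT masking) to the Fourier bins
#' whose period lies inside \code{band_s}, rescaled to unit SD. Used for the
#' shared and independent low-frequency components of the generator, so that
#' all of the component's power lies inside the analysis band.
#'
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @param band_s length-2 period band (seconds), low < high.
#' @return Numeric vector of length \code{n} with SD 1.
#' @export
bandlimited_noise <- function(n, fs, band_s) {
  x <- rnorm(n)
  xf <- fft(x)
  freq <- seq(0, n - 1) / n * fs
  freq <- pmin(freq, fs - freq) # two-sided
  keep <- freq >= 1 / band_s[2] & freq <= 1 / band_s[1]
  if (!any(keep)) stop_input("period band contains no Fourier bin at this length")
  xf[!keep] <- 0i
  y <- Re(fft(xf, inverse = TRUE)) / n
  s <- sd(y)
  if (s == 0) stop_input("degenerate band-limited component")
  y / s
}

# 1/f (power ~ f^-slope) background noise, unit SD
one_over_f_noise <- function(n, fs, slope) {
  x <- rnorm(n)
  xf <- fft(x)
  freq <- seq(0, n - 1) / n * fs
  freq <- pmin(freq, fs - freq)
  w <- ifelse(freq > 0, freq^(-slope / 2), 0)
  y <- Re(fft(xf * w, inverse = TRUE)) / n
  y / sd(y)
}

# physiological sinusoids with per-call random phases and frequency jitter
physio_component <- function(n, fs, comps) {
  t <- seq_len(n) / fs
  y <- numeric(n)
  for (i in seq_len(nrow(comps))) {
    f <- comps$center_freq_hz[i] + comps$jitter[i] * rnorm(1)
    y <- y + comps$amplitude[i] * sin(2 * pi * f * t + runif(1, 0, 2 * pi))
  }
  y
}

# sparse motion artifacts: boxcar excursions of given amplitude/duration
motion_spikes <- function(n, fs, rate_per_min, amp, duration_s) {
  y <- numeric(n)
  k <- rpois(1, rate_per_min * n / fs / 60)
  if (k > 0) {
    w <- max(1L, round(duration_s * fs))
    for (j in seq_len(k)) {
      at <- sample.int(n, 1)
      idx <- at:min(n, at + w - 1L)
      y[idx] <- y[idx] + amp * sample(c(-1, 1), 1)
    }
  }
  y
}

#' Generate one dyad's multi-channel hemodynamic recording
#'
#' Builds two participants' HbO (and companion HbR) series for every phase of
#' the plan. Each ROI of each participant carries a latent low-frequency
#' component \eqn{\kappa g + \sqrt{1-\kappa^2} h}, where \eqn{g} is shared
#' across the dyad (one component per dyad, common to all ROIs) and \eqn{h}
#' is participant- and ROI-specific; both are band-limited to the configured
#' coupling period band. Channels within an ROI share its latent component and
#' add white channel noise, 1/f background, narrowband physiological
#' sinusoids, and (optionally) motion artifacts. \eqn{\kappa} therefore tunes
#' the cross-brain coherence inside the analysis band directly.
#'
#' @param config a \code{\link{sim_config}}.
#' @param dyad_index positive integer; also selects the RNG substream.
#' @param kappa coupling strength in [0, 1].
#' @return A \code{dyad_recording}: list with dyad_id, fs, channel/ROI map and
#'   per-phase HbO/HbR matrices (time x channel) for participants A and B.
#' @export
generate_dyad_timeseries <- function(config, dyad_index, kappa) {
  assert_scalar(kappa, "kappa", 0, 1)
  if (any(config$coupling_period_band_s[2] > config$phase_plan$duration_s / 4))
    stop_input("coupling band incompatible with phase durations")
  fs <- config$sampling_rate_hz
  nroi <- length(config$rois)
  cpr <- config$channels_per_roi
  nch <- nroi * cpr
  channel_roi <- rep(config$rois, each = cpr)
  channels <- paste0(channel_roi, "_", rep(seq_len(cpr), nroi))

  phases <- with_seed(substream_seed(config$seed, dyad_index), {
    out <- list()
    for (i in seq_len(nrow(config$phase_plan))) {
      ph <- config$phase_plan$phase[i]
      n <- round(config$phase_plan$duration_s[i] * fs)
      g <- bandlimited_noise(n, fs, config$coupling_period_band_s)
      hbo <- list()
      hbr <- list()
      for (p in c("A", "B")) {
        m <- matrix(0, n, nch, dimnames = list(NULL, channels))
        for (r in seq_len(nroi)) {
          h <- bandlimited_noise(n, fs, config$coupling_period_band_s)
          latent <- kappa * g + sqrt(1 - kappa^2) * h
          for (c in seq_len(cpr)) {
            ch <- (r - 1) * cpr + c
            sig <- latent
            if (config$channel_noise_sd > 0)
              sig <- sig + config$channel_noise_sd * rnorm(n)
            if (config$background_amp > 0)
              sig <- sig + config$background_amp *
                one_over_f_noise(n, fs, config$background_slope)
            if (nrow(config$noise_components) > 0 &&
                any(config$noise_components$amplitude > 0))
              sig <- sig + physio_component(n, fs, config$noise_components)
            if (config$motion_rate_per_min > 0)
              sig <- sig + motion_spikes(n, fs, config$motion_rate_per_min,
                                         config$motion_amp,
                                         config$motion_duration_s)
            m[, ch] <- sig
          }
        }
        hbo[[p]] <- m
        # HbR: anticorrelated companion signal carried for the HbR rerun switch
        hbr[[p]] <- -0.4 * m + 0.05 * matrix(rnorm(n * nch), n, nch)
        colnames(hbr[[p]]) <- channels
      }
      out[[ph]] <- list(n = n, duration_s = config$phase_plan$duration_s[i],
                        hbo = hbo, hbr = hbr)
    }
    out
  })

  structure(list(
    dyad_id = sprintf("dyad%03d", dyad_index),
    dyad_index = dyad_index,
    fs = fs,
    rois = config$rois,
    channels = channels,
    channel_roi = channel_roi,
    kappa = kappa,
    phases = phases
  ), class = "dyad_recording")
}

#' @export
print.dyad_recording <- function(x, ...) {
  cat(sprintf("dyad_recording %s: %d channels (%s), fs = %.2f Hz, kappa = %.2f\n",
              x$dyad_id, length(x$channels),
              paste(x$rois, collapse = "/"), x$fs, x$kappa))
  for (ph in names(x$phases))
    cat(sprintf("  %s: %d samples (%.0f s)\n", ph, x$phases[[ph]]$n,
                x$phases[[ph]]$duration_s))
  invisible(x)
}

#' Synthesize two-wavelength raw intensities from a recording
#'
#' Inverts the modified Beer-Lambert transform: the recording's HbO/HbR
#' series (micromolar units) are mapped to optical-density changes at 760 and
#' 850 nm with the package's extinction coefficients, and converted to raw
#' intensities around a constant baseline, \eqn{I = I_0 10^{-\Delta OD}}.
#' Feeding the result through the preprocessing chain recovers the
#' concentrations, which is how the pipeline is exercised end-to-end.
#'
#' @param recording a \code{dyad_recording}.
#' @param baseline baseline intensity (arbitrary units).
#' @param dpf differential pathlength factors for the two wavelengths.
#' @param distance_cm source-detector separation.
#' @return Nested list: phase -> participant -> list(wl760, wl850) matrices.
#' @export
simulate_raw_intensity <- function(recording, baseline = 1000,
                                   dpf = c(6, 6), distance_cm = 3) {
  E <- extinction_default()
  out <- list()
  for (ph in names(recording$phases)) {
    phx <- recording$phases[[ph]]
    out[[ph]] <- list()
    for (p in c("A", "B")) {
      hbo <- phx$hbo[[p]] * 1e-6 # micromolar -> molar
      hbr <- phx$hbr[[p]] * 1e-6
      od760 <- (E[1, 1] * hbo + E[1, 2] * hbr) * distance_cm * dpf[1]
      od850 <- (E[2, 1] * hbo + E[2, 2] * hbr) * distance_cm * dpf[2]
      out[[ph]][[p]] <- list(wl760 = baseline * 10^(-od760),
                             wl850 = baseline * 10^(-od850))
    }
  }
  out
}
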