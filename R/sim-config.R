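# Simulation configuration and structural parameters for synthetic cohorts.

#' Default phase plan
#'
#' Two recording phases: a manipulation (video-watching) phase and a free
#' interaction (conversation) phase, each 600 s long and analysed as two
#' 5-minute intervals. The pre-onset windows (282 s and 60 s) extend the
#' behavioural annotation window backwards so that laughter occurring between
#' tasks is credited to the subsequent phase; they are not part of the neural
#' recording.
#'
#' @return A data frame with columns \code{phase}, \code{duration_s},
#'   \code{preonset_s}.
#' @export
default_phase_plan <- function() {
  data.frame(
    phase = c("manipulation", "free_interaction"),
    duration_s = c(600, 600),
    preonset_s = c(282, 60),
    stringsAsFactors = FALSE
  )
}

#' Condition cells of the 2x2 design
#'
#' Laughter (yes/no) crossed with Social context (yes/no). Cell labels are
#' \code{"L_S"}, \code{"L_NS"}, \code{"NL_S"}, \code{"NL_NS"}.
#' @return Character vector of the four cell labels.
#' @export
condition_cells <- function() c("L_S", "L_NS", "NL_S", "NL_NS")

#' Simulation configuration for a synthetic dyadic cohort
#'
#' Bundles every tunable of the synthetic-data generator. Defaults emulate
#' the study conditions the analysis is designed for: 7.81 Hz sampling,
#' 16 channels per participant grouped four per region of interest (bilateral
#' IFG and TPJ), two 600-s phases, low-frequency cross-brain coupling confined
#' to the 8-75 s period band, and physiological nuisance components (cardiac
#' ~1 Hz, respiratory ~0.25 Hz, Mayer waves ~0.1 Hz) on top of 1/f background
#' noise. The default coupling strength is 0 in every cell: empirically, real
#' dyads in this paradigm do not exceed chance-level synchrony, so the neutral
#' cohort carries no genuine cross-brain coupling unless you ask for it.
#'
#' @param n_dyads_per_condition dyads per design cell (default 2).
#' @param sampling_rate_hz sampling rate in Hz (default 7.81).
#' @param phase_plan data frame with \code{phase}, \code{duration_s},
#'   \code{preonset_s}; see \code{\link{default_phase_plan}}.
#' @param rois character vector of ROI labels.
#' @param channels_per_roi channels per ROI (default 4).
#' @param coupling_period_band_s length-2 numeric, period band (seconds) of
#'   the shared cross-brain component; must lie within [8, 75] and satisfy
#'   \code{band[2] <= duration_s / 4} for every phase.
#' @param coupling_strength named numeric vector of kappa in [0,1] per
#'   condition cell (see \code{\link{condition_cells}}), or a single number
#'   recycled to all cells.
#' @param noise_components data frame with \code{center_freq_hz},
#'   \code{amplitude}, \code{jitter} for narrowband physiological sinusoids.
#' @param background_slope spectral exponent of the 1/f background
#'   (power ~ f^-slope).
#' @param background_amp SD of the 1/f background component.
#' @param channel_noise_sd SD of white channel noise.
#' @param motion_rate_per_min expected motion artifacts per minute per
#'   channel (default 0; the clean default passes the quality gate).
#' @param motion_amp,motion_duration_s amplitude and duration of injected
#'   motion artifacts.
#' @param laughter_targets data frame of calibration targets for dyad-union
#'   laughter totals (seconds) per cell and phase; see
#'   \code{\link{default_laughter_targets}}.
#' @param mean_bout_s,bout_sdlog mean laughter-bout duration (s) and log-SD of
#'   the log-normal bout-duration distribution.
#' @param seed master integer seed; per-dyad substreams are derived with
#'   \code{\link{substream_seed}}.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n_dyads_per_condition = 2,
                       sampling_rate_hz = 7.81,
                       phase_plan = default_phase_plan(),
                       rois = c("IFGl", "IFGr", "TPJl", "TPJr"),
                       channels_per_roi = 4,
                       coupling_period_band_s = c(8, 75),
                       coupling_strength = 0,
                       noise_components = data.frame(
                         center_freq_hz = c(1.0, 0.25, 0.1),
                         amplitude = c(0.3, 0.2, 0.3),
                         jitter = c(0.05, 0.02, 0.01)
                       ),
                       background_slope = 1,
                       background_amp = 0.5,
                       channel_noise_sd = 0.5,
                       motion_rate_per_min = 0,
                       motion_amp = 5,
                       motion_duration_s = 0.5,
                       laughter_targets = default_laughter_targets(),
                       mean_bout_s = 2.5,
                       bout_sdlog = 0.6,
                       seed = 1L) {
  assert_scalar(n_dyads_per_condition, "n_dyads_per_condition", 1)
  assert_scalar(sampling_rate_hz, "sampling_rate_hz", 1e-6)
  if (!is.data.frame(phase_plan) ||
      !all(c("phase", "duration_s", "preonset_s") %in% names(phase_plan)))
    stop_input("`phase_plan` needs columns phase, duration_s, preonset_s")
  if (any(phase_plan$duration_s <= 0) || any(phase_plan$preonset_s < 0))
    stop_input("phase durations must be > 0 and pre-onsets >= 0")
  if (length(coupling_period_band_s) != 2 ||
      coupling_period_band_s[1] >= coupling_period_band_s[2] ||
      coupling_period_band_s[1] < 8 || coupling_period_band_s[2] > 75)
    stop_input("`coupling_period_band_s` must be (low, high) within [8, 75]")
  if (any(coupling_period_band_s[2] > phase_plan$duration_s / 4))
    stop_input("coupling band upper bound exceeds duration/4 for some phase; ",
               "the coherence band would not fit the segment")
  cells <- condition_cells()
  if (length(coupling_strength) == 1)
    coupling_strength <- setNames(rep(coupling_strength, 4), cells)
  if (!all(cells %in% names(coupling_strength)))
    stop_input("`coupling_strength` must name all cells ", paste(cells, collapse = ", "))
  if (any(coupling_strength < 0 | coupling_strength > 1))
    stop_input("coupling strengths (kappa) must lie in [0, 1]")
  if (motion_rate_per_min < 0) stop_input("`motion_rate_per_min` must be >= 0")
  assert_scalar(channels_per_roi, "channels_per_roi", 1)

  structure(list(
    n_dyads_per_condition = as.integer(n_dyads_per_condition),
    sampling_rate_hz = sampling_rate_hz,
    phase_plan = phase_plan,
    rois = rois,
    channels_per_roi = as.integer(channels_per_roi),
    coupling_period_band_s = coupling_period_band_s,
    coupling_strength = coupling_strength[cells],
    noise_components = noise_components,
    background_slope = background_slope,
    background_amp = background_amp,
    channel_noise_sd = channel_noise_sd,
    motion_rate_per_min = motion_rate_per_min,
    motion_amp = motion_amp,
    motion_duration_s = motion_duration_s,
    laughter_targets = laughter_targets,
    mean_bout_s = mean_bout_s,
    bout_sdlog = bout_sdlog,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d dyads per cell (x4 cells), fs = %.2f Hz\n",
              x$n_dyads_per_condition, x$sampling_rate_hz))
  cat(sprintf("  ROIs: %s (%d channels each)\n",
              paste(x$rois, collapse = ", "), x$channels_per_roi))
  cat(sprintf("  coupling band %.0f-%.0f s, kappa: %s\n",
              x$coupling_period_band_s[1], x$coupling_period_band_s[2],
              paste(sprintf("%s=%.2f", names(x$coupling_strength),
                            x$coupling_strength), collapse = " ")))
  cat(sprintf("  phases: %s\n",
              paste(sprintf("%s (%gs + %gs pre-onset)", x$phase_plan$phase,
                            x$phase_plan$duration_s, x$phase_plan$preonset_s),
                    collapse = ", ")))
  invisible(x)
}

#' Structural (mediation) parameters for outcome generation
#'
#' Linear paths of the two-equation mediation structure: treatment ->
#' mediator (\code{a_path}), mediator -> outcome (\code{b_path}) and the
#' direct treatment -> outcome path (\code{c_prime}). The neutral defaults
#' (a = b = 0, c' = 0.5) emulate a regime with direct treatment effects on
#' outcomes but no synchrony-mediated pathway.
#'
#' @param a_path,b_path,c_prime linear path coefficients.
#' @param sd_mediator_noise,sd_outcome_noise residual SDs (> 0).
#' @return An object of class \code{structural_params}.
#' @export
structural_params <- function(a_path = 0, b_path = 0, c_prime = 0.5,
                              sd_mediator_noise = 0.05,
                              sd_outcome_noise = 0.5) {
  if (sd_mediator_noise <= 0 || sd_outcome_noise <= 0)
    stop_input("noise SDs must be > 0")
  structure(list(a_path = a_path, b_path = b_path, c_prime = c_prime,
                 sd_mediator_noise = sd_mediator_noise,
                 sd_outcome_noise = sd_outcome_noise),
            class = "structural_params")
}

#' Session timeline implied by a phase plan
#'
#' Lays phases out sequentially: each phase occupies
#' \code{[start, start + duration)} with its pre-onset window
#' \code{[start - preonset, start)} immediately before it, so that the gap
#' between two tasks belongs to the following phase's extended window.
#'
#' @param phase_plan data frame as in \code{\link{sim_config}}.
#' @return Data frame with phase, start_s, end_s, preonset_s.
#' @export
phase_timeline <- function(phase_plan) {
  t0 <- 0
  out <- phase_plan
  out$start_s <- NA_real_
  out$end_s <- NA_real_
  for (i in seq_len(nrow(out))) {
    t0 <- t0 + out$preonset_s[i]
    out$start_s[i] <- t0
    out$end_s[i] <- t0 + out$duration_s[i]
    t0 <- out$end_s[i]
  }
  out[, c("phase", "start_s", "end_s", "preonset_s")]
}
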