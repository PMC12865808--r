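# Synthetic laughter annotation tracks.

#' Default laughter calibration targets
#'
#' Mean dyad-union laughter totals (seconds) per condition cell and phase that
#' the bout generator is calibrated to. The values are the per-cell means of
#' the study design the generator emulates: laughter peaks in the
#' Laughter+Social manipulation cell (135 s) and is nearly absent in the
#' No-Laughter+No-Social manipulation cell (0.52 s), while free-interaction
#' laughter is similar across cells (~50 s).
#'
#' @return Data frame with columns cell, phase, target_total_s.
#' @export
default_laughter_targets <- function() {
  data.frame(
    cell = rep(condition_cells(), 2),
    phase = rep(c("manipulation", "free_interaction"), each = 4),
    target_total_s = c(135.00, 51.20, 36.10, 0.52,
                       51.20, 47.60, 50.20, 50.40),
    stringsAsFactors = FALSE
  )
}

#' Per-participant bout rate reaching a dyad-union coverage target
#'
#' For two independent participants whose laughter bouts form a Poisson
#' process with rate \eqn{\lambda} and i.i.d. positive durations with mean
#' \eqn{\mu}, the stationary coverage of one track is
#' \eqn{p = 1 - e^{-\lambda\mu}} (Boolean-model coverage) and the dyad-union
#' coverage is \eqn{1-(1-p)^2}. Inverting these gives the rate that makes the
#' expected union total in a window of length \code{window_s} equal to
#' \code{target_s}.
#'
#' @param target_s desired mean dyad-union laughter total (s).
#' @param window_s window length (s).
#' @param mean_bout_s mean bout duration (s).
#' @return Bout onset rate per second per participant.
#' @export
laughter_rate_for_target <- function(target_s, window_s, mean_bout_s) {
  if (target_s < 0 || window_s <= 0 || mean_bout_s <= 0)
    stop_input("laughter calibration inputs must be nonnegative (window, bout > 0)")
  u <- min(target_s / window_s, 0.999)
  p <- 1 - sqrt(1 - u)
  -log(1 - p) / mean_bout_s
}

# merge sorted intervals; half-open convention, touching intervals merge
merge_interval_df <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  iv <- iv[order(iv$onset_s), , drop = FALSE]
  on <- iv$onset_s
  off <- iv$offset_s
  keep_on <- on[1]
  keep_off <- off[1]
  res_on <- c()
  res_off <- c()
  for (i in seq_along(on)[-1]) {
    if (on[i] <= keep_off) {
      keep_off <- max(keep_off, off[i])
    } else {
      res_on <- c(res_on, keep_on)
      res_off <- c(res_off, keep_off)
      keep_on <- on[i]
      keep_off <- off[i]
    }
  }
  data.frame(onset_s = c(res_on, keep_on), offset_s = c(res_off, keep_off))
}

#' Generate laughter bouts for both members of a dyad
#'
#' Bout onsets follow a homogeneous Poisson process inside the extended phase
#' window (task interval plus pre-onset), durations are log-normal with mean
#' \code{config$mean_bout_s}, and overlapping bouts of one participant are
#' merged. The per-cell rate is calibrated with
#' \code{\link{laughter_rate_for_target}} so that the expected dyad-union
#' total matches the configured target for that cell and phase.
#'
#' @param config a \code{\link{sim_config}}.
#' @param condition condition cell label (see \code{\link{condition_cells}}).
#' @param phase phase label present in the phase plan.
#' @param seed integer seed for this dyad's annotation stream.
#' @return List with elements \code{A} and \code{B}, each a data frame of
#'   non-overlapping \code{(onset_s, offset_s)} intervals in session time
#'   (the extended window spans \code{[start - preonset, end)}).
#' @export
generate_laughter_bouts <- function(config, condition, phase, seed) {
  tl <- phase_timeline(config$phase_plan)
  row <- tl[tl$phase == phase, ]
  if (nrow(row) != 1) stop_input("unknown phase: ", phase)
  tg <- config$laughter_targets
  hit <- tg[tg$cell == condition & tg$phase == phase, ]
  if (nrow(hit) != 1)
    stop_input("no laughter target for cell ", condition, ", phase ", phase)
  w0 <- row$start_s - row$preonset_s
  w1 <- row$end_s
  W <- w1 - w0
  rate <- laughter_rate_for_target(hit$target_total_s, W, config$mean_bout_s)
  meanlog <- log(config$mean_bout_s) - config$bout_sdlog^2 / 2

  with_seed(seed, {
    tracks <- lapply(c(A = 1, B = 2), function(p) {
      k <- rpois(1, rate * W)
      if (k == 0)
        return(data.frame(onset_s = numeric(0), offset_s = numeric(0)))
      on <- w0 + sort(runif(k, 0, W))
      dur <- rlnorm(k, meanlog, config$bout_sdlog)
      off <- pmin(on + dur, w1)
      iv <- data.frame(onset_s = on, offset_s = off)
      merge_interval_df(iv[iv$offset_s > iv$onset_s, , drop = FALSE])
    })
    tracks
  })
}
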