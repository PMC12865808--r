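# Pseudo-dyad surrogate null for interbrain synchrony.
#
# Each participant is paired with randomly selected non-partners; the WTC
# matrices of those pairings are averaged elementwise and then reduced with
# the same band/COI averaging as real dyads (matrix-then-scalar order).

#' Surrogate sampling plan
#'
#' @param n_surrogates partners per participant (default 100).
#' @param seed integer seed.
#' @param exclude_self,exclude_partner exclusion rules (both default TRUE).
#' @return List of class \code{surrogate_plan}.
#' @export
surrogate_plan <- function(n_surrogates = 100, seed = 1L,
                           exclude_self = TRUE, exclude_partner = TRUE) {
  if (n_surrogates < 1) stop_input("n_surrogates must be >= 1")
  structure(list(n_surrogates = as.integer(n_surrogates),
                 seed = as.integer(seed),
                 exclude_self = exclude_self,
                 exclude_partner = exclude_partner),
            class = "surrogate_plan")
}

#' Sample surrogate partners for one participant
#'
#' Seeded sample from the pool after removing the participant and their true
#' partner. When fewer eligible partners than \code{n_surrogates} remain, the
#' sample is drawn with replacement and flagged.
#'
#' @param participant_id id of the participant being matched.
#' @param pool character vector of all candidate participant ids.
#' @param plan a \code{\link{surrogate_plan}}.
#' @param true_partner id of the participant's real partner.
#' @return Character vector of partner ids; attribute
#'   \code{"with_replacement"} records whether replacement was needed.
#' @export
sample_partners <- function(participant_id, pool, plan, true_partner = NULL) {
  elig <- pool
  if (plan$exclude_self) elig <- setdiff(elig, participant_id)
  if (plan$exclude_partner && !is.null(true_partner))
    elig <- setdiff(elig, true_partner)
  if (length(elig) == 0) stop_input("empty surrogate pool after exclusions")
  replace <- length(elig) < plan$n_surrogates
  out <- with_seed(substream_seed(plan$seed, hash_id(participant_id)), {
    if (!replace && length(elig) == plan$n_surrogates) elig[sample.int(length(elig))] else
      sample(elig, plan$n_surrogates, replace = replace)
  })
  attr(out, "with_replacement") <- replace
  out
}

# stable small hash of a participant id for substream derivation
hash_id <- function(id) {
  sum(utf8ToInt(as.character(id)) * seq_along(utf8ToInt(as.character(id)))) %% 100000L
}

#' Pseudo-dyad synchrony value for one participant
#'
#' Computes the WTC matrix between the participant's ROI signal and each
#' surrogate partner's signal (series truncated to the shorter length),
#' averages the coherence matrices elementwise across partners, and applies
#' the band/COI average. Signals must share the sampling rate.
#'
#' @param x participant's ROI time series.
#' @param partner_signals list of surrogate partners' ROI time series.
#' @param fs sampling rate (Hz).
#' @param min_period_s,voices_per_octave band construction parameters.
#' @return List: wtc_value, n_valid_cells, n_partners, band.
#' @export
pseudo_dyad_value <- function(x, partner_signals, fs, min_period_s = 8,
                              voices_per_octave = 12) {
  if (length(partner_signals) == 0) stop_input("no surrogate partners")
  nmin <- min(length(x), vapply(partner_signals, length, 0L))
  band <- adaptive_period_range(nmin / fs, min_period_s)
  periods <- period_grid(band, voices_per_octave)
  cx <- morlet_cwt(x[seq_len(nmin)], fs, periods)
  sxx <- smoothed_power(cx)
  acc <- NULL
  wt <- NULL
  for (ps in partner_signals) {
    cy <- morlet_cwt(ps[seq_len(nmin)], fs, periods)
    w <- compute_wtc(cx, cy, sxx = sxx)
    if (is.null(acc)) {
      acc <- w$coherence
      wt <- w
    } else acc <- acc + w$coherence
  }
  wt$coherence <- acc / length(partner_signals)
  res <- mask_and_average(wt, band)
  c(res, list(n_partners = length(partner_signals), band = band))
}

#' Surrogate synchrony table for a cohort
#'
#' Mirrors the real synchrony table: for every participant, phase, interval
#' and ROI pair, the pseudo-dyad value against \code{n_surrogates} random
#' non-partners (pool = all participants of the same phase, unrestricted by
#' condition). For heterologous pairs both cross-assignments are averaged,
#' as for real dyads.
#'
#' @param recordings list of \code{dyad_recording}s.
#' @param plan a \code{\link{surrogate_plan}}.
#' @param roi_pairs optional subset of pair labels (default: all).
#' @param intervals_per_phase,min_period_s,voices_per_octave as in
#'   \code{\link{dyad_synchrony}}.
#' @param signal \code{"hbo"} or \code{"hbr"}.
#' @return Data frame like \code{\link{dyad_synchrony}}'s with
#'   \code{is_surrogate = TRUE}; one row per participant x pair x phase x
#'   interval (the participant's dyad id is retained, participant in
#'   \code{participant}).
#' @export
pseudo_dyad_table <- function(recordings, plan = surrogate_plan(),
                              roi_pairs = NULL, intervals_per_phase = 2,
                              min_period_s = 8, voices_per_octave = 12,
                              signal = c("hbo", "hbr")) {
  signal <- match.arg(signal)
  rois <- recordings[[1]]$rois
  pairs <- enumerate_roi_pairs(rois)
  if (!is.null(roi_pairs)) pairs <- pairs[pairs$label %in% roi_pairs, ]
  fs <- recordings[[1]]$fs
  # participant registry: id, dyad, member, recording index
  reg <- do.call(rbind, lapply(seq_along(recordings), function(i) {
    data.frame(pid = paste0(recordings[[i]]$dyad_id, "_", c("A", "B")),
               dyad_id = recordings[[i]]$dyad_id, member = c("A", "B"),
               idx = i, stringsAsFactors = FALSE)
  }))
  phases <- names(recordings[[1]]$phases)
  interval_names <- if (intervals_per_phase == 2) c("first", "second") else
    paste0("interval", seq_len(intervals_per_phase))

  get_roi_sig <- function(row, ph, idx_range) {
    rec <- recordings[[row$idx]]
    roi_signals(rec$phases[[ph]][[signal]][[row$member]][idx_range, , drop = FALSE],
                rec$channel_roi)
  }

  rows <- list()
  for (ph in phases) {
    n <- recordings[[1]]$phases[[ph]]$n
    cut <- floor(seq(0, n, length.out = intervals_per_phase + 1))
    for (iv in seq_len(intervals_per_phase)) {
      idx <- (cut[iv] + 1):cut[iv + 1]
      band <- adaptive_period_range(length(idx) / fs, min_period_s)
      periods <- period_grid(band, voices_per_octave)
      # precompute CWT + smoothed power for every participant and ROI
      cw <- list()
      pw <- list()
      for (k in seq_len(nrow(reg))) {
        sig <- get_roi_sig(reg[k, ], ph, idx)
        cw[[reg$pid[k]]] <- lapply(sig, morlet_cwt, fs = fs, periods_s = periods)
        pw[[reg$pid[k]]] <- lapply(cw[[reg$pid[k]]], smoothed_power)
      }
      avg_coh <- function(pid, partner_pids, roi_a, roi_b) {
        acc <- NULL
        for (q in partner_pids) {
          w <- compute_wtc(cw[[pid]][[roi_a]], cw[[q]][[roi_b]],
                           sxx = pw[[pid]][[roi_a]], syy = pw[[q]][[roi_b]])
          acc <- if (is.null(acc)) w$coherence else acc + w$coherence
        }
        list(coh = acc / length(partner_pids), tmpl = w)
      }
      for (k in seq_len(nrow(reg))) {
        pid <- reg$pid[k]
        partner <- reg$pid[reg$dyad_id == reg$dyad_id[k] & reg$pid != pid]
        partners <- sample_partners(pid, reg$pid, plan, true_partner = partner)
        for (j in seq_len(nrow(pairs))) {
          r1 <- pairs$roi1[j]; r2 <- pairs$roi2[j]
          a <- avg_coh(pid, partners, r1, r2)
          coh <- a$coh
          if (r1 != r2) coh <- (coh + avg_coh(pid, partners, r2, r1)$coh) / 2
          wt <- a$tmpl
          wt$coherence <- coh
          res <- mask_and_average(wt, band)
          rows[[length(rows) + 1]] <- data.frame(
            dyad_id = reg$dyad_id[k], participant = pid,
            roi_pair = pairs$label[j], phase = ph,
            interval = interval_names[iv],
            wtc_value = res$wtc_value, n_valid_cells = res$n_valid_cells,
            excluded_reason = res$reason %||% NA_character_,
            is_surrogate = TRUE, stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Compare real and surrogate synchrony
#'
#' Bayesian two-group comparison (Gaussian model with a +/-0.5-coded group
#' indicator, no random term) of real versus pseudo-dyad synchrony values;
#' delegates to \code{\link{fit_hierarchical}}.
#'
#' @param real,surrogate numeric vectors of synchrony values.
#' @param priors optional \code{\link{ds_priors}}.
#' @param ... passed to \code{\link{fit_hierarchical}}.
#' @return The fitted \code{posterior_summary}; the group-difference row is
#'   named \code{"group1"} and a convenience element \code{difference} holds
#'   its posterior mean and 95% interval (real minus surrogate).
#' @export
real_vs_surrogate <- function(real, surrogate, priors = NULL, ...) {
  real <- real[is.finite(real)]
  surrogate <- surrogate[is.finite(surrogate)]
  if (length(real) < 2 || length(surrogate) < 2)
    stop_input("need at least 2 values per group")
  dat <- data.frame(
    y = c(real, surrogate),
    group = factor(rep(c("surrogate", "real"), c(length(surrogate), length(real))),
                   levels = c("surrogate", "real"))
  )
  if (var(dat$y) < 1e-14)
    warning("degenerate variance in real-vs-surrogate comparison")
  fit <- fit_hierarchical(y ~ group, dat, priors = priors, ...)
  d <- fit$draws[, "group1"]
  fit$difference <- c(mean = mean(d), eti(d))
  fit
}
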