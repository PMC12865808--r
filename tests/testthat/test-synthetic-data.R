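# Synthetic cohort generator: determinism, coupling structure, calibration.

short_cfg <- function(...) {
  sim_config(n_dyads_per_condition = 1,
             phase_plan = data.frame(phase = "manipulation",
                                     duration_s = 300, preonset_s = 60),
             rois = c("IFGl", "TPJl"), channels_per_roi = 2, ...)
}

test_that("identical config and seed give bitwise-identical output", {
  cfg <- short_cfg(seed = 21)
  expect_identical(generate_dyad_timeseries(cfg, 3, 0.4),
                   generate_dyad_timeseries(cfg, 3, 0.4))
  expect_identical(generate_laughter_bouts(cfg, "L_S", "manipulation", 99),
                   generate_laughter_bouts(cfg, "L_S", "manipulation", 99))
  sp <- structural_params(a_path = 0.3, b_path = 0.2)
  expect_identical(generate_outcomes(sp, c(0, 1, 0, 1), seed = 5),
                   generate_outcomes(sp, c(0, 1, 0, 1), seed = 5))
})

test_that("full coupling with no noise duplicates the in-band signal", {
  cfg <- short_cfg(channel_noise_sd = 0, background_amp = 0,
                   noise_components = data.frame(center_freq_hz = numeric(0),
                                                 amplitude = numeric(0),
                                                 jitter = numeric(0)),
                   seed = 4)
  rec <- generate_dyad_timeseries(cfg, 1, 1)
  expect_equal(rec$phases$manipulation$hbo$A,
               rec$phases$manipulation$hbo$B, tolerance = 1e-12)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(coupling_period_band_s = c(8, 200)), "within")
  expect_error(sim_config(phase_plan = data.frame(phase = "p", duration_s = 100,
                                                  preonset_s = 0)),
               "duration/4")
  expect_error(sim_config(coupling_strength = 1.2), "0, 1")
  cfg <- short_cfg(seed = 1)
  expect_error(generate_dyad_timeseries(cfg, 1, 1.5), "kappa")
})

test_that("band-limited components concentrate their power in the band", {
  set.seed(8)
  fs <- 7.81
  n <- 2343
  x <- bandlimited_noise(n, fs, c(8, 75))
  spec <- Mod(fft(x))^2 / n
  freq <- seq(0, n - 1) / n * fs
  freq <- pmin(freq, fs - freq)
  inband <- freq >= 1 / 75 & freq <= 1 / 8
  expect_gte(sum(spec[inband]) / sum(spec[freq > 0]), 0.8)
})

test_that("laughter bout generation respects windows and calibration logic", {
  cfg <- short_cfg(seed = 13)
  tl <- phase_timeline(cfg$phase_plan)
  tr <- generate_laughter_bouts(cfg, "L_S", "manipulation", 7)
  for (p in c("A", "B")) {
    iv <- tr[[p]]
    expect_true(all(iv$onset_s < iv$offset_s))
    expect_true(all(iv$onset_s >= tl$start_s - tl$preonset_s))
    expect_true(all(iv$offset_s <= tl$end_s))
    if (nrow(iv) > 1) # non-overlap after merging
      expect_true(all(diff(as.vector(t(iv))) > 0))
  }
  # zero target -> zero rate -> empty tracks
  cfg0 <- short_cfg(seed = 13,
                    laughter_targets = data.frame(cell = "L_S",
                                                  phase = "manipulation",
                                                  target_total_s = 0))
  tr0 <- generate_laughter_bouts(cfg0, "L_S", "manipulation", 7)
  expect_equal(nrow(tr0$A) + nrow(tr0$B), 0)
  expect_error(laughter_rate_for_target(-5, 100, 2), "nonnegative")
  # closed-form rate is increasing in the target
  rates <- vapply(c(1, 50, 135), laughter_rate_for_target,
                  0, window_s = 882, mean_bout_s = 2.5)
  expect_true(all(diff(rates) > 0))
})

test_that("outcome generator reproduces the structural model", {
  sp0 <- structural_params(a_path = 0, b_path = 0, c_prime = 0,
                           sd_mediator_noise = 1, sd_outcome_noise = 1)
  tr <- rep(c(0, 1), 250)
  out <- generate_outcomes(sp0, tr, seed = 2)
  expect_lt(abs(cor(out$treatment, out$liking_raw)), 0.1)

  sp <- structural_params(a_path = 0.5, b_path = 0.4, c_prime = 0.2,
                          sd_mediator_noise = 1e-12,
                          sd_outcome_noise = 1e-12)
  out2 <- generate_outcomes(sp, c(0, 1), seed = 2)
  expect_equal(diff(out2$liking_raw), 0.2 + 0.5 * 0.4, tolerance = 1e-9)
})

test_that("cohorts are balanced, tracked, and clean by default", {
  cfg <- sim_config(n_dyads_per_condition = 2,
                    phase_plan = data.frame(phase = "manipulation",
                                            duration_s = 300, preonset_s = 60),
                    rois = c("IFGl", "TPJl"), channels_per_roi = 2,
                    coupling_strength = c(L_S = 0.8, L_NS = 0.4,
                                          NL_S = 0.2, NL_NS = 0),
                    seed = 31)
  co <- generate_cohort(cfg, structural_params(sd_mediator_noise = 1e-9))
  expect_length(co$recordings, 8)
  expect_equal(nrow(co$outcomes), 16)
  expect_equal(unname(table(co$ground_truth$cell)[condition_cells()]),
               rep(2L, 4), ignore_attr = TRUE)
  # bookkeeping: recorded kappa matches ground truth and the cell values
  ks <- vapply(co$recordings, `[[`, 0, "kappa")
  expect_equal(ks, co$ground_truth$kappa)
  expect_equal(co$ground_truth$kappa, co$ground_truth$kappa_cell,
               tolerance = 1e-6)
  # quality gate: every participant of the default cohort passes
  for (rec in co$recordings[1:2]) {
    raw <- simulate_raw_intensity(rec)
    for (p in c("A", "B")) {
      q <- channel_quality(raw$manipulation[[p]]$wl760, rec$channel_roi)
      expect_equal(sum(q$bad_channel), 0L)
    }
  }
})
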