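# Wavelet transform coherence: band construction, transform, smoothing,
# averaging, ROI pair bookkeeping.

test_that("adaptive period range follows the duration/4 rule", {
  expect_equal(adaptive_period_range(300), c(8, 75))
  expect_equal(1 / adaptive_period_range(300), c(0.125, 1 / 75),
               tolerance = 1e-12)
  expect_equal(adaptive_period_range(32), c(8, 8))
  expect_error(adaptive_period_range(20), "too short")
})

test_that("ROI pair enumeration matches the canonical ordering", {
  p4 <- enumerate_roi_pairs(c("IFGl", "IFGr", "TPJl", "TPJr"))
  expect_equal(p4$label,
               c("IFGl_IFGl", "IFGr_IFGr", "TPJl_TPJl", "TPJr_TPJr",
                 "IFGl_IFGr", "IFGl_TPJl", "IFGl_TPJr", "IFGr_TPJl",
                 "IFGr_TPJr", "TPJl_TPJr"))
  expect_equal(nrow(enumerate_roi_pairs(c("A", "B"))), 3)
  expect_equal(nrow(enumerate_roi_pairs("A")), 1)
})

test_that("Morlet CWT basics: zeros, linearity, peak localization", {
  fs <- 7.81
  periods <- period_grid(c(8, 75), 12)
  n <- 2343
  z <- morlet_cwt(numeric(n), fs, periods)
  expect_true(all(abs(z$coef) == 0))
  expect_error(morlet_cwt(c(1, NA, 3), fs, periods), "NA")

  t <- seq_len(n) / fs
  x <- sin(2 * pi * t / 30)
  cw <- morlet_cwt(x, fs, periods)
  mid <- round(n / 2)
  peak <- which.max(abs(cw$coef[, mid]))
  target <- which.min(abs(periods - 30))
  expect_lte(abs(peak - target), 1)

  cw2 <- morlet_cwt(2 * x, fs, periods)
  expect_equal(cw2$coef, 2 * cw$coef, tolerance = 1e-12)
})

test_that("coherence is 1 for identical signals, bounded, symmetric and
           scale invariant", {
  set.seed(42)
  fs <- 7.81
  n <- 1200
  periods <- period_grid(adaptive_period_range(n / fs), 12)
  x <- as.numeric(arima.sim(list(ar = 0.95), n))
  y <- as.numeric(arima.sim(list(ar = 0.95), n))
  cx <- morlet_cwt(x, fs, periods)
  cy <- morlet_cwt(y, fs, periods)

  self <- compute_wtc(cx, cx)
  expect_lt(max(abs(self$coherence - 1)), 1e-6)

  w_xy <- compute_wtc(cx, cy)
  w_yx <- compute_wtc(cy, cx)
  expect_true(all(w_xy$coherence >= 0 & w_xy$coherence <= 1))
  expect_lt(max(abs(w_xy$coherence - w_yx$coherence)), 1e-10)

  cx3 <- morlet_cwt(3.7 * x, fs, periods)
  w_scaled <- compute_wtc(cx3, cy)
  expect_lt(max(abs(w_scaled$coherence - w_xy$coherence)), 1e-8)
})

test_that("FFT implementation matches the brute-force oracle on toy signals", {
  set.seed(9)
  fs <- 4
  n <- 64
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n)
  periods <- period_grid(c(2, 8), 6)
  cx <- morlet_cwt(x, fs, periods)
  expect_lt(max(abs(cx$coef - oracle_cwt(x, fs, periods))), 1e-6)
  w <- compute_wtc(cx, morlet_cwt(y, fs, periods))
  expect_lt(max(abs(w$coherence - oracle_wtc(x, y, fs, periods))), 1e-6)
})

test_that("band/COI averaging counts and excludes correctly", {
  periods <- c(10, 20, 40)
  n <- 6
  fake <- structure(list(
    coherence = matrix(0.5, 3, n), periods_s = periods,
    coi_mask = matrix(TRUE, 3, n), coi_period_s = rep(100, n), fs = 1),
    class = "wtc_matrix")
  res <- mask_and_average(fake)
  expect_equal(res$wtc_value, 0.5)
  expect_equal(res$n_valid_cells, 3L * n)

  fake$coi_mask[] <- FALSE
  res2 <- mask_and_average(fake)
  expect_true(is.na(res2$wtc_value))
  expect_equal(res2$reason, "fully inside COI")

  fake$coherence <- matrix(rep(c(0, 1), length.out = 3 * n), 3, n)
  fake$coi_mask <- matrix(rep(c(TRUE, FALSE), length.out = 3 * n), 3, n)
  fake$coi_mask[] <- TRUE
  expect_equal(mask_and_average(fake)$wtc_value, 0.5)
})

test_that("coherence localizes a shared periodic component", {
  set.seed(7)
  fs <- 7.81
  n <- 2343
  t <- seq_len(n) / fs
  periods <- period_grid(c(8, 75), 12)
  for (P in c(10, 30, 60)) {
    shared <- sin(2 * pi * t / P)
    x <- shared + 0.8 * rnorm(n)
    y <- shared + 0.8 * rnorm(n)
    w <- compute_wtc(morlet_cwt(x, fs, periods), morlet_cwt(y, fs, periods))
    prof <- vapply(seq_along(periods), function(i) {
      sel <- w$coi_mask[i, ]
      if (!any(sel)) return(NA_real_)
      mean(w$coherence[i, sel])
    }, 0)
    peak <- which.max(prof)
    expect_lte(abs(peak - which.min(abs(periods - P))), 2)
  }
})

test_that("lagged and independent signals behave as expected in the band", {
  set.seed(11)
  fs <- 7.81
  n <- 2343
  periods <- period_grid(c(8, 75), 12)
  x <- bandlimited_noise(n, fs, c(8, 75)) + 0.1 * rnorm(n)
  shift <- round(2 * fs)
  y <- c(x[-(seq_len(shift))], x[seq_len(shift)])
  w <- compute_wtc(morlet_cwt(x, fs, periods), morlet_cwt(y, fs, periods))
  expect_gt(mask_and_average(w)$wtc_value, 0.9)

  z <- rnorm(n)
  w0 <- compute_wtc(morlet_cwt(rnorm(n), fs, periods), morlet_cwt(z, fs, periods))
  v0 <- mask_and_average(w0)$wtc_value
  expect_gt(v0, 0)
  expect_lt(v0, 0.75)
})

test_that("dyad synchrony emits one row per pair, phase and interval", {
  cfg <- sim_config(n_dyads_per_condition = 1,
                    phase_plan = data.frame(
                      phase = c("manipulation", "free_interaction"),
                      duration_s = c(600, 600), preonset_s = c(282, 60)),
                    seed = 5)
  rec <- generate_dyad_timeseries(cfg, 1, 0.5)
  syn <- dyad_synchrony(rec)
  expect_equal(nrow(syn), 2 * 2 * 10)
  expect_true(all(is.finite(syn$wtc_value)))
  expect_true(all(syn$wtc_value >= 0 & syn$wtc_value <= 1))
  expect_setequal(unique(syn$interval), c("first", "second"))
})

test_that("identical partner signals give coherence ~1; bad ROI rows are
           flagged", {
  cfg <- sim_config(n_dyads_per_condition = 1,
                    phase_plan = data.frame(phase = "manipulation",
                                            duration_s = 300, preonset_s = 10),
                    rois = c("IFGl", "TPJl"), channels_per_roi = 2,
                    channel_noise_sd = 0, background_amp = 0,
                    noise_components = data.frame(center_freq_hz = numeric(0),
                                                  amplitude = numeric(0),
                                                  jitter = numeric(0)),
                    seed = 3)
  rec <- generate_dyad_timeseries(cfg, 1, 1) # kappa = 1, no noise
  syn <- dyad_synchrony(rec, intervals_per_phase = 1)
  hom <- syn[syn$roi_pair == "IFGl_IFGl", ]
  expect_gt(hom$wtc_value, 1 - 1e-6)

  quality <- list(A = c(FALSE, FALSE, TRUE, TRUE), B = rep(FALSE, 4))
  syn2 <- dyad_synchrony(rec, quality = quality, intervals_per_phase = 1)
  expect_true(all(is.na(syn2$wtc_value[grepl("TPJl", syn2$roi_pair)])))
  expect_true(all(!is.na(syn2$wtc_value[syn2$roi_pair == "IFGl_IFGl"])))
  expect_equal(unique(syn2$excluded_reason[grepl("TPJl", syn2$roi_pair)]),
               "bad ROI")
})
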