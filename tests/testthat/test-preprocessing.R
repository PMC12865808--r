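# Preprocessing chain: OD conversion, motion handling, despiking, filtering,
# Beer-Lambert inversion and quality gating.

test_that("optical density conversion", {
  I <- matrix(100, 50, 2)
  expect_true(all(intensity_to_od(I) == 0))

  I2 <- matrix(100, 200, 1)
  I2[100, 1] <- 50
  od <- intensity_to_od(I2)
  expect_equal(od[100, 1], log10(2), tolerance = 0.01)

  I3 <- I2; I3[5, 1] <- 0
  expect_error(intensity_to_od(I3), "nonpositive intensity at sample 5")
})

test_that("motion detection flags steps and is monotone in its threshold", {
  set.seed(2)
  fs <- 7.81
  x <- matrix(rnorm(500, 0, 0.01), ncol = 1)
  expect_equal(sum(detect_motion(x, fs)), 0)

  x2 <- x
  x2[250:500, 1] <- x2[250:500, 1] + 10 * sd(x)
  m <- detect_motion(x2, fs, sd_factor = 5, amp_thresh = Inf)
  expect_true(any(m[245:255, 1]))

  n_low <- sum(detect_motion(x2, fs, sd_factor = 3, amp_thresh = Inf))
  n_high <- sum(detect_motion(x2, fs, sd_factor = 8, amp_thresh = Inf))
  expect_gte(n_low, n_high)
})

test_that("spline correction removes transient excursions smoothly", {
  set.seed(3)
  n <- 600
  noise_sd <- 0.01
  x <- matrix(rnorm(n, 0, noise_sd), ncol = 1)
  mask <- matrix(FALSE, n, 1)
  out0 <- spline_correct(x, mask)
  expect_identical(out0$od, x)

  x2 <- x
  art <- 300:360
  x2[art, 1] <- x2[art, 1] + 0.5 # boxcar excursion
  mask[295:365, 1] <- TRUE
  out <- spline_correct(x2, mask)
  expect_lt(sd(out$od[, 1]), sd(x2[, 1]))
  # no discontinuity at the segment boundaries beyond local noise level
  jumps <- c(abs(out$od[295, 1] - out$od[294, 1]),
             abs(out$od[366, 1] - out$od[365, 1]))
  expect_true(all(jumps < 6 * noise_sd))

  mask_all <- matrix(TRUE, n, 1)
  out_bad <- spline_correct(x2, mask_all)
  expect_identical(out_bad$od, x2)
  expect_length(out_bad$bad_channels, 1)
})

test_that("wavelet despiking attenuates spikes and preserves slow waves", {
  set.seed(4)
  fs <- 7.81
  n <- 1000
  x <- matrix(rnorm(n, 0, 0.05), ncol = 1)
  expect_lt(max(abs(wavelet_filter(x, Inf) - x)), 1e-10)

  spike <- x
  spike[500, 1] <- spike[500, 1] + 2
  filtered <- wavelet_filter(spike, 1.5)
  expect_lt(abs(filtered[500, 1]), 0.5 * 2)

  t <- seq_len(n) / fs
  slow <- matrix(sin(2 * pi * t / 20), ncol = 1)
  out <- wavelet_filter(slow, 1.5)
  mid <- 200:800
  expect_equal(sd(out[mid, 1]), sd(slow[mid, 1]), tolerance = 0.05)
})

test_that("zero-phase band-pass keeps the band and kills what is outside", {
  fs <- 7.81
  n <- 4000
  t <- seq_len(n) / fs
  hi <- matrix(sin(2 * pi * 1.0 * t), ncol = 1)
  out_hi <- bandpass(hi, fs, 0.01, 0.5)
  expect_lt(sd(out_hi[500:3500, 1]), 0.1 * sd(hi[500:3500, 1]))

  lo <- matrix(sin(2 * pi * 0.05 * t), ncol = 1)
  out_lo <- bandpass(lo, fs, 0.01, 0.5)
  expect_equal(sd(out_lo[500:3500, 1]), sd(lo[500:3500, 1]), tolerance = 0.05)

  expect_true(all(bandpass(matrix(0, 100, 1), fs) == 0))
  expect_error(bandpass(hi, fs, 0.5, 0.1), "invalid band")
})

test_that("Beer-Lambert inversion solves the 2x2 system exactly", {
  z <- matrix(0, 10, 1)
  hb0 <- mbll(z, z)
  expect_true(all(hb0$hbo == 0) && all(hb0$hbr == 0))

  res <- mbll(matrix(0.3, 1, 1), matrix(0.1, 1, 1), dpf = c(1, 1),
              extinction = diag(2), distance_cm = 1)
  expect_equal(c(res$hbo, res$hbr), c(0.3, 0.1))

  res2 <- mbll(matrix(1, 1, 1), matrix(1, 1, 1), dpf = c(1, 1),
               extinction = matrix(c(2, 1, 1, 3), 2, byrow = TRUE),
               distance_cm = 1)
  expect_equal(c(res2$hbo, res2$hbr), c(0.4, 0.2))

  expect_error(mbll(z, z, extinction = matrix(1, 2, 2)), "singular")

  # round trip: forward-generate OD from known concentrations and invert
  set.seed(5)
  hbo <- matrix(rnorm(50), ncol = 1)
  hbr <- matrix(rnorm(50), ncol = 1)
  E <- extinction_default()
  d <- 3; dpf <- c(6, 6)
  od760 <- (E[1, 1] * hbo + E[1, 2] * hbr) * d * dpf[1]
  od850 <- (E[2, 1] * hbo + E[2, 2] * hbr) * d * dpf[2]
  back <- mbll(od760, od850, dpf = dpf, distance_cm = d)
  expect_lt(max(abs(back$hbo - hbo)), 1e-10)
  expect_lt(max(abs(back$hbr - hbr)), 1e-10)
})

test_that("channel quality gates flat channels and cascades to ROI pairs", {
  set.seed(6)
  I <- matrix(1000 + rnorm(16 * 400, 0, 5), 400, 16)
  roi <- rep(c("IFGl", "IFGr", "TPJl", "TPJr"), each = 4)
  q <- channel_quality(I, roi)
  expect_equal(sum(q$bad_channel), 0L)

  I2 <- I
  I2[, roi == "TPJl"] <- 1000 # flat
  q2 <- channel_quality(I2, roi)
  expect_true(q2$bad_roi[["TPJl"]])
  expect_false(any(q2$bad_roi[c("IFGl", "IFGr", "TPJr")]))

  # monotone: lowering the threshold never reduces bad channels
  I3 <- matrix(1000 * exp(rnorm(8 * 400, 0, 0.12)), 400, 8)
  roi3 <- rep(c("IFGl", "TPJl"), each = 4)
  n_tight <- sum(channel_quality(I3, roi3, cv_thresh = 0.05)$bad_channel)
  n_loose <- sum(channel_quality(I3, roi3, cv_thresh = 0.3)$bad_channel)
  expect_gte(n_tight, n_loose)
})

test_that("the full chain preserves length and recovers concentrations", {
  cfg <- sim_config(n_dyads_per_condition = 1,
                    phase_plan = data.frame(phase = "manipulation",
                                            duration_s = 300, preonset_s = 60),
                    rois = c("IFGl", "TPJl"), channels_per_roi = 2, seed = 17)
  rec <- generate_dyad_timeseries(cfg, 1, 0.5)
  raw <- simulate_raw_intensity(rec)
  pp <- preprocess_participant(raw$manipulation$A, rec$fs, rec$channel_roi)
  truth <- rec$phases$manipulation$hbo$A
  expect_equal(dim(pp$hbo), dim(truth))
  expect_equal(sum(pp$quality$bad_channel), 0L)
  # recovered HbO tracks the band-passed ground truth
  ref <- bandpass(truth, rec$fs, 0.01, 0.5)
  cors <- vapply(seq_len(ncol(truth)), function(j) cor(pp$hbo[, j], ref[, j]), 0)
  expect_true(all(cors > 0.6))
})
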