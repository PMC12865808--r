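# Laughter annotation algebra: parsing, unions, phase assignment,
# relative durations.

test_that("annotation parsing validates, sorts and merges", {
  f <- tempfile(fileext = ".tsv")
  df <- data.frame(participant = c("p1", "p1", "p1", "p2"),
                   tier = "laughter",
                   onset_s = c(5, 0, 20, 3),
                   offset_s = c(12, 10, 25, 9))
  write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
  tracks <- parse_annotations(f)
  expect_named(tracks, c("p1", "p2"))
  # (0,10) and (5,12) merge; (20,25) stays
  expect_equal(tracks$p1$onset_s, c(0, 20))
  expect_equal(tracks$p1$offset_s, c(12, 25))
  expect_equal(nrow(tracks$p2), 1)

  bad <- df; bad$offset_s[2] <- -1
  write.table(bad, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(parse_annotations(f), "row\\(s\\) 2")

  write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(parse_annotations(f, participants = "p1"), "unknown participant")
})

test_that("dyad union adds non-overlapping time and merges overlap", {
  a <- data.frame(onset_s = 0, offset_s = 10)
  b <- data.frame(onset_s = 5, offset_s = 15)
  u <- dyad_union(a, b)
  expect_equal(u$intervals, data.frame(onset_s = 0, offset_s = 15))
  expect_equal(u$total_s, 15)

  a2 <- data.frame(onset_s = 0, offset_s = 5)
  b2 <- data.frame(onset_s = 10, offset_s = 12)
  expect_equal(dyad_union(a2, b2)$total_s, 7)

  # idempotence and commutativity
  expect_equal(dyad_union(a, a)$total_s, 10)
  expect_equal(dyad_union(a, b), dyad_union(b, a))
})

test_that("phase assignment clips to extended windows and routes gap
           laughter to the subsequent phase", {
  w1 <- phase_window("manipulation", start_s = 100, end_s = 400,
                     preonset_s = 50)
  w2 <- phase_window("free_interaction", start_s = 430, end_s = 700,
                     preonset_s = 30)
  ws <- list(w1, w2)

  inside <- data.frame(onset_s = 200, offset_s = 210)
  out <- assign_to_phase(inside, ws)
  expect_equal(out$manipulation, data.frame(onset_s = 200, offset_s = 210))
  expect_equal(nrow(out$free_interaction), 0)

  # straddles the end of phase 1 and the pre-onset of phase 2
  strad <- data.frame(onset_s = 395, offset_s = 410)
  out2 <- assign_to_phase(strad, ws)
  expect_equal(out2$manipulation, data.frame(onset_s = 395, offset_s = 400))
  expect_equal(out2$free_interaction, data.frame(onset_s = 400, offset_s = 410))

  # between-task laughter (in the gap 400..430) goes to the next phase
  gap <- data.frame(onset_s = 405, offset_s = 420)
  out3 <- assign_to_phase(gap, ws)
  expect_equal(nrow(out3$manipulation), 0)
  expect_equal(out3$free_interaction, data.frame(onset_s = 405, offset_s = 420))

  # outside everything -> dropped and accounted for
  outside <- data.frame(onset_s = 10, offset_s = 20)
  out4 <- assign_to_phase(outside, ws)
  expect_equal(nrow(out4$manipulation) + nrow(out4$free_interaction), 0)
  expect_equal(attr(out4, "dropped_s"), 10)

  expect_error(assign_to_phase(inside, list(w2, w1)), "out of order")
})

test_that("relative duration normalizes by the extended window length", {
  w <- phase_window("manipulation", start_s = 0, end_s = 300, preonset_s = 0)
  expect_equal(relative_duration(data.frame(onset_s = 10, offset_s = 40), w), 0.1)
  expect_equal(relative_duration(data.frame(onset_s = numeric(0),
                                            offset_s = numeric(0)), w), 0)
  wp <- phase_window("manipulation", start_s = 50, end_s = 300, preonset_s = 50)
  full <- data.frame(onset_s = 0, offset_s = 300)
  expect_equal(relative_duration(full, wp), 1)
})

test_that("per-dyad behavior table: clipping bounds and rate-0 zeros", {
  plan <- data.frame(phase = c("manipulation", "free_interaction"),
                     duration_s = c(300, 300), preonset_s = c(60, 30))
  ann <- data.frame(
    dyad_id = "d1",
    participant = c("d1_A", "d1_A", "d1_B"),
    tier = "laughter",
    onset_s = c(10, 100, 50),
    offset_s = c(30, 150, 120))
  b <- dyad_behavior(ann, plan)
  expect_equal(nrow(b), 1)
  expect_true(b$lbmp >= 0 && b$lbmp <= 1)
  expect_lte(b$total_manipulation_s, 300 + 60)
  # union by hand: (10,30) + (50,150) = 120 s in a 360-s extended window
  expect_equal(b$total_manipulation_s, 120)
  expect_equal(b$lbmp, 120 / 360)
  expect_equal(b$lbfi, 0)

  # dyads without any bouts appear with exact zeros
  b2 <- dyad_behavior(ann[0, ], plan, dyad_ids = c("d1", "d2"))
  expect_equal(b2$lbmp, c(0, 0))
  expect_equal(b2$lbfi, c(0, 0))
})
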