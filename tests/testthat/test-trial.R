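test_that("the 48-trial schedule has the published structure", {
  sch <- build_schedule()
  expect_equal(nrow(sch), 48)
  expect_equal(sch$font_logmar[1], 1.5)
  expect_equal(sch$viewing[1], "Clear")
  expect_equal(sch$font_logmar[2], 1.5)
  expect_equal(sch$viewing[2], "High")
  # every (font, viewing) class occurs exactly twice (counting oracle)
  tally <- table(sch$font_logmar, sch$viewing)
  expect_true(all(tally == 2))
  # sentences consumed once each
  expect_identical(anyDuplicated(sch$sentence_id), 0L)
  # difficulty monotone within each pass of 24
  for (half in list(1:24, 25:48)) {
    expect_true(all(diff(sch$font_logmar[half]) <= 0))
    for (f in unique(sch$font_condition[half])) {
      rows <- sch[half, ][sch$font_condition[half] == f, ]
      expect_identical(rows$viewing, c("Clear", "High", "Medium", "Low"))
    }
  }
  expect_error(build_schedule(sprintf("S%02d", 1:47)), "48")
  expect_error(build_schedule(rep("a", 48)), "distinct")
})

test_that("noise-free gaze traces land exactly on the programmed fixations", {
  lines_px <- data.frame(x_start = c(100, 100), x_end = c(500, 500),
                         y = c(300, 400))
  tr <- simulate_gaze_trace(lines_px, fixations_per_line = 3, fixation_ms = 100,
                            saccade_ms = 0, noise_sd_deg = 0, rate_hz = 300)
  expect_setequal(unique(tr$x_px), c(100, 300, 500))
  expect_setequal(unique(tr$y_px), c(300, 400))
  # sample interval is 1000/300 ms
  expect_equal(unique(round(diff(tr$t_ms), 9)), 1000 / 300)
  expect_true(all(diff(tr$t_ms) > 0))
})

test_that("gaze jitter reproduces the tracker precision within 5%", {
  lines_px <- data.frame(x_start = 200, x_end = 200, y = 300)
  tr <- simulate_gaze_trace(lines_px, fixations_per_line = 1,
                            fixation_ms = 40000, saccade_ms = 0,
                            noise_sd_deg = 0.14, rate_hz = 300, seed = 4)
  d <- display_model()
  expect_gt(nrow(tr), 1e4)
  expect_equal(sd(px_to_deg(tr$x_px - 200, d, "x")), 0.14, tolerance = 0.05)
  expect_equal(sd(px_to_deg(tr$y_px - 300, d, "y")), 0.14, tolerance = 0.05)
  # deterministic given the seed
  tr2 <- simulate_gaze_trace(lines_px, fixations_per_line = 1,
                             fixation_ms = 40000, saccade_ms = 0,
                             noise_sd_deg = 0.14, rate_hz = 300, seed = 4)
  expect_identical(tr, tr2)
})

test_that("fill_gaps repairs traces like the naive oracle", {
  tr <- scripted_trace(list(list(0, 0, 100), list(2, 2, 100)), dt_ms = 10)
  # one missing sample between (0,0) and (2,2): linear midpoint
  tr$valid[10] <- FALSE
  tr$x_px[10] <- tr$y_px[10] <- NA
  filled <- fill_gaps(tr)
  expect_equal(filled$x_px[10], 1)
  expect_equal(filled$y_px[10], 1)
  # untouched when nothing is invalid
  ok <- scripted_trace(list(list(5, 6, 50)))
  expect_identical(fill_gaps(ok), ok)
  # long interior gap repeats the last valid value; leading gap repeats the
  # first valid value; trailing gap repeats the last
  set.seed(31)
  big <- scripted_trace(list(list(0, 0, 400)), dt_ms = 10)
  big$x_px <- runif(nrow(big), 0, 100); big$y_px <- runif(nrow(big), 0, 100)
  big$valid[c(1:3, 12:28, 38:40)] <- FALSE
  expect_equal(fill_gaps(big, max_interp_ms = 100),
               oracle_fill_gaps(big, max_interp_ms = 100))
  # short interior gaps interpolate in both implementations
  small <- big
  small$valid <- TRUE
  small$valid[c(7, 20:23)] <- FALSE
  expect_equal(fill_gaps(small, max_interp_ms = 100),
               oracle_fill_gaps(small, max_interp_ms = 100))
  all_bad <- scripted_trace(list(list(0, 0, 50)))
  all_bad$valid <- FALSE
  expect_error(fill_gaps(all_bad), "no valid samples")
})

test_that("a scripted trial yields the scripted reading time exactly", {
  d <- display_model()
  cdot <- phosim:::center_dot_px(d)
  tdot <- phosim:::top_dot_px(d)
  gaze <- scripted_trace(list(
    list(cdot[1], cdot[2], 600),    # Start + Pre-Stimulus hold
    list(400, 300, 3500),           # Reading (away from both dots)
    list(tdot[1], tdot[2], 500)))   # advance dwell
  spec <- list(index = 1L, font_logmar = 1.5, viewing = "Clear",
               sentence_id = "S01")
  rec <- run_trial(spec, gaze, n_words = 11, errors = 2)
  expect_true(rec$complete)
  # hold completes 500 ms after the first center sample (t = 0 -> 500);
  # the dwell window starts when gaze reaches the top dot at t = 4100
  expect_equal(rec$phase_times[["reading"]], 500)
  expect_equal(rec$t_reading, (4100 + 350 - 350 - 500) / 1000)
  expect_equal(rec$t_reading, 3.6)
  expect_equal(rec$n, 11)
  expect_equal(rec$e, 2)
  # the End phase appends the 2000 ms intertrial pause on the clock
  expect_equal(rec$phase_times[["end"]] - rec$phase_times[["dwell"]],
               350 + 2000)
})

test_that("a dwell shorter than 350 ms does not trigger the End phase", {
  d <- display_model()
  cdot <- phosim:::center_dot_px(d)
  tdot <- phosim:::top_dot_px(d)
  gaze <- scripted_trace(list(
    list(cdot[1], cdot[2], 600),
    list(400, 300, 1000),
    list(tdot[1], tdot[2], 340),    # too short
    list(400, 300, 500)))
  spec <- list(index = 1L, font_logmar = 1.5, viewing = "Clear",
               sentence_id = "S01")
  rec <- run_trial(spec, gaze, n_words = 10, errors = 0)
  expect_false(rec$complete)
  expect_true(is.na(rec$t_reading))
})

test_that("trials that never start or never finish are incomplete", {
  spec <- list(index = 1L, font_logmar = 1.5, viewing = "Clear",
               sentence_id = "S01")
  never_center <- scripted_trace(list(list(10, 10, 1000)))
  expect_false(run_trial(spec, never_center, 10, 0)$complete)
  d <- display_model()
  cdot <- phosim:::center_dot_px(d)
  no_dwell <- scripted_trace(list(list(cdot[1], cdot[2], 600),
                                  list(400, 300, 800)))
  expect_false(run_trial(spec, no_dwell, 10, 0)$complete)
  expect_error(run_trial(spec, never_center, 10, 12), "errors")
})

test_that("gaze-contingent rendering runs during Reading and counts frames", {
  d <- display_model()
  s <- generate_sentence(seed = 4)
  stim <- rasterize_sentence(s, 1.5, d)
  pat <- get_pattern("Low", 1L)
  lines_px <- data.frame(x_start = c(500, 500, 500), x_end = c(1400, 1400, 1400),
                         y = c(430, 540, 650))
  gaze <- simulate_trial_gaze(lines_px, d, fixations_per_line = 2,
                              fixation_ms = 120, seed = 7)
  spec <- list(index = 2L, font_logmar = 1.5, viewing = "Low",
               sentence_id = "S02")
  seen <- 0L
  rec <- run_trial(spec, gaze, n_words = 10, errors = 1, stimulus = stim,
                   pattern = pat, display = d, render_every = 50L,
                   frame_sink = function(fr, t) {
                     seen <<- seen + 1L
                     stopifnot(all(fr >= 0 & fr <= 1))
                   })
  expect_true(rec$complete)
  expect_gt(rec$n_frames, 0)
  expect_identical(seen, rec$n_frames)
  expect_error(run_trial(spec, gaze, 10, 1, stimulus = NULL, pattern = pat,
                         display = d, render_every = 10L), "no stimulus")
})

test_that("simulated full-trial gaze drives the state machine to completion", {
  d <- display_model()
  lines_px <- data.frame(x_start = 600, x_end = 1300, y = 540)
  gaze <- simulate_trial_gaze(lines_px, d, fixations_per_line = 3,
                              fixation_ms = 200, seed = 3)
  spec <- list(index = 1L, font_logmar = 1.2, viewing = "Clear",
               sentence_id = "S01")
  rec <- run_trial(spec, gaze, n_words = 12, errors = 0)
  expect_true(rec$complete)
  expect_gt(rec$t_reading, 0)
})
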