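test_that("sampling a uniform or black image returns the constant", {
  img <- matrix(0.37, 40, 40)
  for (sig in c(0.8, 2.5, 7)) {
    expect_equal(sample_phosphene_brightness(img, c(20, 20), sig), 0.37,
                 tolerance = 1e-12)
  }
  expect_equal(sample_phosphene_brightness(img * 0, c(20, 20), 3), 0)
  expect_error(sample_phosphene_brightness(img, c(20, 20), 0), "positive")
  expect_error(sample_phosphene_brightness(1:5, c(1, 1), 1), "matrix")
})

test_that("sampling agrees with the dense discrete-sum oracle to 1e-6", {
  set.seed(5)
  step <- matrix(0, 64, 64); step[, 33:64] <- 1   # half black / half white
  noise <- matrix(runif(64 * 64), 64, 64)
  for (img in list(step, noise)) {
    for (k in 1:12) {
      c_px <- runif(2, -4, 68)   # includes off-image centers
      sig <- runif(1, 0.6, 6)
      expect_equal(sample_phosphene_brightness(img, c_px, sig),
                   oracle_gauss_sample(img, c_px[1], c_px[2], sig),
                   tolerance = 1e-6)
    }
  }
  # filter centered on the step edge sees about half white
  expect_equal(sample_phosphene_brightness(step, c(32.5, 32), 4), 0.5,
               tolerance = 0.02)
})

test_that("off-image filters renormalize or vanish", {
  img <- matrix(1, 32, 32)
  # center outside, support partially in-bounds: still averages the white
  expect_equal(sample_phosphene_brightness(img, c(-1, 16), 2), 1,
               tolerance = 1e-12)
  # support fully off-screen: zero
  expect_equal(sample_phosphene_brightness(img, c(-50, 16), 2), 0)
})

test_that("splat adds a peak-normalized Gaussian and matches the oracle", {
  fr <- matrix(0, 48, 48)
  out <- splat_phosphene(fr, c(24, 24), 3, 0.6)
  expect_equal(out[24, 24], 0.6, tolerance = 1e-12)  # exact center increment
  expect_equal(out, oracle_splat_add(fr, 24, 24, 3, 0.6), tolerance = 1e-12)
  # amplitude 0 leaves the frame unchanged
  expect_identical(splat_phosphene(fr, c(24, 24), 3, 0), fr)
  expect_error(splat_phosphene(fr, c(24, 24), 3, 1.5), "amplitude")
  expect_error(splat_phosphene(fr, c(24, 24), -1, 0.5), "positive")
})

test_that("additive splats saturate at the display maximum", {
  fr <- matrix(0, 32, 32)
  one <- splat_phosphene(fr, c(16, 16), 2.5, 0.7)
  two <- splat_phosphene(one, c(16, 16), 2.5, 0.7)
  expect_equal(two[16, 16], 1.4, tolerance = 1e-12)        # pre-clip additive
  expect_equal(clip_frame(two)[16, 16], 1)                 # saturates at 1
  expect_true(all(clip_frame(two) <= 1) && all(clip_frame(two) >= 0))
})

test_that("pre-clip splat integral approximates 2*pi*sigma^2*amplitude", {
  fr <- matrix(0, 120, 120)
  sig <- 5; amp <- 0.4
  out <- splat_phosphene(fr, c(60, 60), sig, amp)
  expect_equal(sum(out), 2 * pi * sig^2 * amp, tolerance = 0.012)
})

test_that("render_frame reproduces the naive double-loop renderer (64x64)", {
  set.seed(8)
  d <- toy_display(64)                      # 16 px/deg both axes
  stim <- matrix(runif(64 * 64), 64, 64)
  pat <- toy_pattern(x_deg = c(-1.2, 0, 0.9, 1.6, -0.4, 2.3),
                     y_deg = c(0.5, 0, -1.1, 1.2, -1.8, -2.6),
                     sigma_deg = c(0.1, 0.15, 0.2, 0.12, 0.3, 0.08))
  gaze <- c(33, 30)
  out <- render_frame(stim, pat, gaze, d)
  xs <- gaze[1] + pat$phosphenes$x_deg * 16
  ys <- gaze[2] + pat$phosphenes$y_deg * 16
  expect_equal(out, oracle_render(stim, xs, ys, pat$phosphenes$sigma_deg * 16),
               tolerance = 1e-6)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("black in, black out; uniform white lights every phosphene fully", {
  d <- toy_display(64)
  pat <- toy_pattern(x_deg = c(-1, 0, 1), y_deg = c(0, 0.5, -1),
                     sigma_deg = c(0.2, 0.25, 0.15))
  black <- matrix(0, 64, 64)
  expect_true(all(render_frame(black, pat, c(32, 32), d) == 0))
  white <- matrix(1, 64, 64)
  out <- render_frame(white, pat, c(32, 32), d)
  # phosphene centers land on integer pixels here; each sampled amplitude is
  # 1, so the frame saturates to exactly 1 at every center
  xs <- 32 + pat$phosphenes$x_deg * 16
  ys <- 32 + pat$phosphenes$y_deg * 16
  for (k in seq_along(xs)) expect_equal(out[ys[k], xs[k]], 1)
  expect_true(all(out <= 1))
})

test_that("phosphene order does not change the rendered frame", {
  set.seed(9)
  d <- toy_display(64)
  stim <- matrix(runif(64 * 64), 64, 64)
  pat <- toy_pattern(runif(8, -1.5, 1.5), runif(8, -1.5, 1.5),
                     runif(8, 0.08, 0.3))
  perm <- pat
  perm$phosphenes <- pat$phosphenes[sample(8), ]
  a <- render_frame(stim, pat, c(32, 32), d)
  b <- render_frame(stim, perm, c(32, 32), d)
  # additive composition commutes up to floating-point summation order
  expect_lt(max(abs(a - b)), 1e-12)
})

test_that("stimulus edits outside every filter's reach do not alter the frame", {
  set.seed(10)
  d <- toy_display(64)
  stim <- matrix(runif(64 * 64), 64, 64)
  pat <- toy_pattern(c(-0.5, 0.4), c(0.3, -0.2), c(0.1, 0.15))
  base <- render_frame(stim, pat, c(20, 20), d)
  edited <- stim
  edited[60:64, 60:64] <- 1   # far corner, beyond 3 sigma of both filters
  expect_identical(render_frame(edited, pat, c(20, 20), d), base)
})

test_that("a pointwise-brighter stimulus never renders darker", {
  set.seed(12)
  d <- toy_display(64)
  stim <- matrix(runif(64 * 64, 0, 0.6), 64, 64)
  brighter <- pmin(stim + matrix(runif(64 * 64, 0, 0.4), 64, 64), 1)
  pat <- toy_pattern(runif(6, -1.5, 1.5), runif(6, -1.5, 1.5),
                     runif(6, 0.08, 0.3))
  a <- render_frame(stim, pat, c(32, 32), d)
  b <- render_frame(brighter, pat, c(32, 32), d)
  expect_true(all(b - a >= -1e-12))
})

test_that("rendering is equivariant to integer gaze+stimulus translations", {
  set.seed(13)
  d <- toy_display(96)
  stim <- matrix(0, 96, 96)
  stim[40:56, 40:56] <- matrix(runif(17 * 17), 17, 17)
  pat <- toy_pattern(c(-0.6, 0, 0.5), c(0.2, -0.4, 0), c(0.1, 0.15, 0.12))
  gaze <- c(48, 48); dx <- 7L; dy <- -3L
  shifted <- matrix(0, 96, 96)
  shifted[(40 + dy):(56 + dy), (40 + dx):(56 + dx)] <- stim[40:56, 40:56]
  a <- render_frame(stim, pat, gaze, d)
  b <- render_frame(shifted, pat, gaze + c(dx, dy), d)
  # compare on the interior where both supports are fully in-bounds
  rows <- 20:76; cols <- 20:76
  expect_equal(b[rows + dy, cols + dx], a[rows, cols], tolerance = 1e-9)
})

test_that("off-screen gaze and phosphenes are dropped gracefully", {
  d <- toy_display(64)
  stim <- matrix(1, 64, 64)
  pat <- toy_pattern(c(0, 30), c(0, 0), c(0.2, 0.2))  # second is far off-screen
  out <- render_frame(stim, pat, c(-200, 32), d)       # gaze off-screen too
  expect_true(all(out == 0))
  expect_error(render_frame(matrix(0, 10, 10), pat, c(5, 5), d), "dimensions")
})

test_that("frames round trip through 8-bit PNG within quantization", {
  set.seed(14)
  fr <- matrix(runif(32 * 32), 32, 32)
  f <- tempfile(fileext = ".png")
  write_frame_png(fr, f)
  back <- read_frame_png(f)
  expect_equal(dim(back), dim(fr))
  expect_lt(max(abs(back - fr)), 1 / 255)
  unlink(f)
})
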