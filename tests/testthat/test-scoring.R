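test_that("reading accuracy matches hand-evaluated examples", {
  expect_equal(reading_accuracy(data.frame(n = c(11, 11), e = c(0, 0))), 1)
  expect_equal(reading_accuracy(data.frame(n = c(11, 11), e = c(1, 3))),
               (10 / 11 + 8 / 11) / 2)
  expect_equal(reading_accuracy(data.frame(n = 10, e = 10)), 0)
  expect_error(reading_accuracy(data.frame(n = 0, e = 0)), "positive")
  expect_error(reading_accuracy(data.frame(n = 5, e = 7)), "0 <= e <= n")
})

test_that("reading speed matches hand-evaluated examples in WPM", {
  expect_equal(reading_speed(data.frame(n = 10, e = 0, t = 10)), 60)
  expect_equal(reading_speed(data.frame(n = 8, e = 8, t = 4)), 0)
  expect_equal(reading_speed(data.frame(n = c(11, 11), e = c(1, 3),
                                        t = c(10, 16))), 45)
  expect_error(reading_speed(data.frame(n = 5, e = 0, t = 0)), "positive")
  expect_error(reading_speed(data.frame(n = 5, e = 0)), "t column")
})

test_that("MNREAD acuity reduces to the classic formula", {
  expect_equal(reading_acuity_mnread(rep(1, 6)), 1.0)
  expect_equal(reading_acuity_mnread(rep(0, 6)), 1.5)
  expect_equal(reading_acuity_mnread(c(1, 1, 1, 0, 0, 0)), 1.3)
  # the alternative base-plus-step parameterization also reaches 1.0 when
  # everything is read (base sits one step above the largest font)
  expect_equal(reading_acuity_mnread(rep(1, 6), weight_first = TRUE), 1.0)
  expect_equal(reading_acuity_mnread(rep(0, 6), weight_first = TRUE), 1.6)
  # clipping flags out-of-range values
  g <- reading_acuity_mnread(rep(1, 6), clip_to_range = TRUE)
  expect_false(attr(g, "out_of_range"))
  expect_error(reading_acuity_mnread(c(1.2, rep(0, 5))), "0, 1")
  expect_error(reading_acuity_mnread(rep(1, 5)), "length")
  expect_error(reading_acuity_mnread(rep(1, 3), sizes = c(1.0, 1.2, 1.1)),
               "ordered")
})

test_that("gamma is monotone: more correct reading never worsens acuity", {
  set.seed(41)
  for (k in 1:20) {
    a <- runif(6)
    i <- sample(6, 1)
    better <- a
    better[i] <- min(1, a[i] + runif(1, 0, 1 - a[i]))
    expect_lte(reading_acuity_mnread(better), reading_acuity_mnread(a) + 1e-12)
  }
})

test_that("logistic acuity recovers noise-free parameters to 1e-6", {
  sizes <- font_ladder()
  a <- 1 / (1 + exp(-12 * (sizes - 1.26)))
  fit <- reading_acuity_logistic(a, sizes)
  expect_false(fit$degenerate)
  expect_true(fit$converged)
  expect_equal(fit$midpoint_logmar, 1.26, tolerance = 1e-6)
  expect_equal(fit$k, 12, tolerance = 1e-4)
  expect_equal(fit$slope_pct_per_logmar, 25 * fit$k)
  expect_equal(predict(fit, 1.26), 0.5, tolerance = 1e-5)
})

test_that("data symmetric about a size have that size as midpoint", {
  sizes <- font_ladder()
  a <- 1 / (1 + exp(-20 * (sizes - 1.25)))
  expect_equal(a[sizes == 1.2] + a[sizes == 1.3], 1)
  fit <- reading_acuity_logistic(a, sizes)
  expect_equal(fit$midpoint_logmar, 1.25, tolerance = 1e-6)
})

test_that("degenerate accuracy data are flagged without a midpoint", {
  fit_hi <- reading_acuity_logistic(rep(0.9, 6))
  expect_true(fit_hi$degenerate)
  expect_true(is.na(fit_hi$midpoint_logmar))
  fit_lo <- reading_acuity_logistic(rep(0.2, 6))
  expect_true(fit_lo$degenerate)
  expect_error(reading_acuity_logistic(c(0.2, 0.9), sizes = c(1.0, 1.1)),
               "at least 3")
  expect_error(reading_acuity_logistic(c(0.2, 0.9, 1.4),
                                       sizes = c(1, 1.1, 1.2)), "0, 1")
})

test_that("logistic midpoint on step-like data sits within one font step of gamma", {
  sizes <- font_ladder()
  a <- c(1, 1, 1, 1, 0, 0)   # sharp step between 1.2 and 1.1
  fit <- reading_acuity_logistic(a, sizes)
  gamma <- reading_acuity_mnread(a, sizes)
  expect_lt(abs(fit$midpoint_logmar - gamma), 0.1 + 1e-9)
})

test_that("acuity surplus reproduces the hand-evaluated pairs", {
  out <- acuity_surplus(c(1.07, 1.26, 1.48), c(1757, 1029, 522))
  expect_equal(out$pairs$observed, c(0.19, 0.22))
  expect_equal(out$pairs$expected,
               0.5 * log10(c(1757 / 1029, 1029 / 522)))
  expect_equal(out$pairs$surplus, c(0.074, 0.073), tolerance = 1e-2)
  expect_equal(out$mean_surplus_display, 0.07)
  # zero surplus when observations match the sampling expectation
  ac <- c(1.0, 1.0 + 0.5 * log10(2))
  expect_equal(acuity_surplus(ac, c(1000, 500))$mean_surplus, 0,
               tolerance = 1e-12)
  expect_error(acuity_surplus(c(1, 1.2), c(100, 200)), "densest first")
  expect_error(acuity_surplus(c(1, 1.2), c(100)), "length")
})

test_that("score_trials pools classes and scores per viewing condition", {
  sizes <- font_ladder()
  log <- expand.grid(font_logmar = sizes, viewing = c("Clear", "Low"),
                     rep = 1:2, stringsAsFactors = FALSE)
  log$n_words <- 11L
  # Clear reads everything; Low fails below 1.3
  log$errors <- ifelse(log$viewing == "Clear", 0L,
                       ifelse(log$font_logmar >= 1.3, 0L, 11L))
  log$t_reading_s <- 5
  sc <- score_trials(log)
  bv <- sc$by_viewing
  expect_equal(bv$gamma[bv$viewing == "Clear"], 1.0)
  expect_equal(bv$gamma[bv$viewing == "Low"], 1.5 - 0.2)
  expect_true(bv$degenerate_fit[bv$viewing == "Clear"])
  expect_false(bv$degenerate_fit[bv$viewing == "Low"])
  expect_true(abs(bv$logistic_midpoint[bv$viewing == "Low"] - 1.25) < 0.05)
  cl <- sc$by_class
  expect_true(all(cl$n_obs == 2))
  expect_equal(cl$beta[cl$viewing == "Clear" & cl$font_logmar == 1.5],
               60 * 11 / 5)
  expect_error(score_trials(log[, setdiff(names(log), "errors")]), "columns")
})
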