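# Reading-performance scoring: generalized MNREAD mathematics.  Per trial
# class (font f x viewing v) with N repeated observations of (n words, e
# missed, t seconds):
#   accuracy  alpha = (1/N) sum (n - e) / n
#   speed     beta  = (1/N) sum (n - e) / t        (reported in words/min)
#   acuity    gamma = base size + sum of step-weighted accuracies
# plus the logistic-midpoint acuity with asymptotes fixed at 0 and 100%.

check_obs <- function(observations, need_t = FALSE) {
  stopifnot(is.data.frame(observations), all(c("n", "e") %in% names(observations)))
  if (nrow(observations) < 1L) stop("at least one observation is required")
  if (any(observations$n <= 0)) stop("word count n must be positive")
  if (any(observations$e < 0 | observations$e > observations$n))
    stop("errors e must satisfy 0 <= e <= n")
  if (need_t) {
    if (!"t" %in% names(observations)) stop("observations need a t column (seconds)")
    if (any(observations$t <= 0)) stop("reading time t must be positive")
  }
  invisible(observations)
}

#' Reading accuracy for one trial class
#'
#' Mean over the class's observations of the fraction of words read
#' correctly, `(n - e) / n`.
#'
#' @param observations data frame with columns `n` (words shown) and `e`
#'   (words missed) for the repeated observations of one (font, viewing)
#'   class.
#' @return Accuracy in \[0, 1\].
#' @examples
#' reading_accuracy(data.frame(n = c(11, 11), e = c(1, 3)))  # 0.8182
#' @export
reading_accuracy <- function(observations) {
  check_obs(observations)
  mean((observations$n - observations$e) / observations$n)
}

#' Reading speed for one trial class
#'
#' Mean over the class's observations of correctly read words per unit
#' time, `(n - e) / t`, reported in words per minute.  The reading time `t`
#' is the Reading-phase duration and excludes the advance dwell by
#' construction of the trial record.
#'
#' @param observations data frame with columns `n`, `e`, and `t` (seconds).
#' @return Speed in words per minute.
#' @examples
#' reading_speed(data.frame(n = 10, e = 0, t = 10))  # 60 WPM
#' @export
reading_speed <- function(observations) {
  check_obs(observations, need_t = TRUE)
  60 * mean((observations$n - observations$e) / observations$t)
}

#' MNREAD reading acuity from per-font accuracies
#'
#' The sum of accuracies across font sizes, weighted by the (negative)
#' size step to the previous font, measures how many size intervals below
#' the base size the subject effectively read:
#' `gamma = base + sum_f step_f * alpha_f` over fonts 2..K, where `step_f =
#' size_f - size_(f-1)`.  The largest font carries no step weight, so
#' perfect reading of a 1.5 -> 1.0 ladder yields exactly the smallest
#' tested size (1.0), and reading nothing yields the base (1.5).  With the
#' standard six-font, -0.1-step ladder and one observation per class this
#' reduces to the classic published formula.  Set `weight_first = TRUE` for
#' the alternative base-plus-step parameterization in which all fonts carry
#' a step and the base sits one step above the largest font.
#'
#' @param alphas accuracies ordered largest font first.
#' @param sizes font sizes in logMAR, same order (default the standard
#'   ladder).
#' @param weight_first give the largest font a step weight too (with the
#'   base shifted one step up).
#' @param clip_to_range clip the result into the tested range and attach an
#'   `out_of_range` attribute.
#' @return Reading acuity gamma in logMAR.
#' @examples
#' reading_acuity_mnread(rep(1, 6))  # 1.0 (reads everything)
#' reading_acuity_mnread(rep(0, 6))  # 1.5 (reads nothing)
#' @export
reading_acuity_mnread <- function(alphas, sizes = font_ladder(),
                                  weight_first = FALSE, clip_to_range = FALSE) {
  if (any(!is.finite(alphas)) || any(alphas < 0 | alphas > 1))
    stop("accuracies must lie in [0, 1]")
  if (length(alphas) != length(sizes)) stop("alphas and sizes differ in length")
  if (length(sizes) >= 2 && any(diff(sizes) > 0))
    stop("sizes must be ordered largest (base) to smallest")
  steps <- diff(sizes)                    # negative steps, fonts 2..K
  if (weight_first) {
    first_step <- if (length(steps)) steps[1] else -0.1
    base <- sizes[1] - first_step
    gamma <- base + sum(c(first_step, steps) * alphas)
  } else {
    base <- sizes[1]
    gamma <- base + sum(steps * alphas[-1])
  }
  if (clip_to_range) {
    lo <- min(sizes); hi <- base
    out <- gamma < lo | gamma > hi
    gamma <- min(max(gamma, lo), hi)
    attr(gamma, "out_of_range") <- out
  }
  gamma
}

#' Logistic reading acuity (midpoint of a psychometric fit)
#'
#' Fits `alpha(size) = 1 / (1 + exp(-k (size - m)))` to per-font accuracies
#' by least squares with the asymptotes fixed at 0 and 100%.  The midpoint
#' `m` is the 50%-performance acuity; the slope is reported as the maximum
#' derivative of the fitted curve in percentage points per logMAR
#' (`25 k`).  Initialization: `m` at the 50% crossing of the linearly
#' interpolated data, `k` at 10 per logMAR; bounded optimization to
#' tolerance 1e-10.  Degenerate data (all accuracies on one side of 50%)
#' yield no midpoint and are flagged.
#'
#' @param alphas accuracies in \[0, 1\].
#' @param sizes font sizes in logMAR (>= 3 values).
#' @return An object of class `logistic_acuity_fit` with elements
#'   `midpoint_logmar`, `slope_pct_per_logmar`, `k`, `converged`,
#'   `degenerate`, `data`.
#' @examples
#' a <- 1 / (1 + exp(-12 * (font_ladder() - 1.26)))
#' fit <- reading_acuity_logistic(a)
#' fit$midpoint_logmar   # 1.26
#' @export
reading_acuity_logistic <- function(alphas, sizes = font_ladder()) {
  if (length(alphas) != length(sizes)) stop("alphas and sizes differ in length")
  keep <- is.finite(alphas) & is.finite(sizes)
  alphas <- alphas[keep]; sizes <- sizes[keep]
  if (length(alphas) < 3L) stop("at least 3 font sizes with finite accuracy are required")
  if (any(alphas < 0 | alphas > 1)) stop("accuracies must lie in [0, 1]")
  dat <- data.frame(size = sizes, alpha = alphas)
  degenerate <- all(alphas >= 0.5) || all(alphas <= 0.5)
  if (degenerate) {
    return(structure(list(midpoint_logmar = NA_real_,
                          slope_pct_per_logmar = NA_real_, k = NA_real_,
                          converged = FALSE, degenerate = TRUE, data = dat),
                     class = "logistic_acuity_fit"))
  }
  ord <- order(sizes)
  m0 <- approx(alphas[ord], sizes[ord], xout = 0.5, ties = mean)$y
  if (!is.finite(m0)) m0 <- mean(range(sizes))
  sse <- function(par) {
    pred <- 1 / (1 + exp(-par[2] * (sizes - par[1])))
    sum((pred - alphas)^2)
  }
  opt <- optim(c(m0, 10), sse, method = "L-BFGS-B",
               lower = c(min(sizes) - 2, 0.01), upper = c(max(sizes) + 2, 500),
               control = list(factr = 1e-10 / .Machine$double.eps, maxit = 500))
  structure(list(midpoint_logmar = opt$par[1],
                 slope_pct_per_logmar = 25 * opt$par[2],
                 k = opt$par[2],
                 converged = opt$convergence == 0,
                 degenerate = FALSE, data = dat),
            class = "logistic_acuity_fit")
}

#' @export
print.logistic_acuity_fit <- function(x, ...) {
  if (x$degenerate)
    cat("<logistic_acuity_fit> degenerate data: no 50% crossing in range\n")
  else
    cat(sprintf("<logistic_acuity_fit> midpoint %.3f logMAR, slope %.0f %%/logMAR (%s)\n",
                x$midpoint_logmar, x$slope_pct_per_logmar,
                if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.logistic_acuity_fit <- function(object, ...) {
  c(midpoint = object$midpoint_logmar, k = object$k)
}

#' @export
predict.logistic_acuity_fit <- function(object, newdata = object$data$size, ...) {
  if (object$degenerate) stop("degenerate fit has no curve")
  sizes <- if (is.data.frame(newdata)) newdata$size else newdata
  1 / (1 + exp(-object$k * (sizes - object$midpoint_logmar)))
}

#' @export
plot.logistic_acuity_fit <- function(x, ...) {
  plot(x$data$size, 100 * x$data$alpha, xlab = "print size (logMAR)",
       ylab = "reading accuracy (%)", ylim = c(0, 100), pch = 16, ...)
  if (!x$degenerate) {
    s <- seq(min(x$data$size) - 0.2, max(x$data$size) + 0.2, length.out = 200)
    graphics::lines(s, 100 * predict(x, s))
    graphics::abline(v = x$midpoint_logmar, lty = 2)
  }
  invisible(x)
}

#' Acuity surplus over the sampling-density expectation
#'
#' For adjacent pairs of density tiers (ordered by decreasing phosphene
#' count), compares the observed acuity difference against the expected
#' improvement `0.5 log10(count ratio)` from the two-dimensional sampling
#' argument.  A positive surplus means acuity improved more with count than
#' sampling density alone predicts.
#'
#' @param acuities logMAR acuities ordered densest tier first.
#' @param counts matching total phosphene counts (decreasing).
#' @return List with `pairs` (data frame: observed, expected, surplus per
#'   adjacent pair) and `mean_surplus` (also rounded to 2 decimals for
#'   display as `mean_surplus_display`).
#' @examples
#' acuity_surplus(c(1.07, 1.26, 1.48), c(1757, 1029, 522))
#' @export
acuity_surplus <- function(acuities, counts) {
  if (length(acuities) != length(counts)) stop("acuities and counts differ in length")
  if (length(acuities) < 2L) stop("at least two tiers are required")
  if (any(diff(counts) >= 0)) stop("counts must be ordered densest first")
  i <- seq_len(length(acuities) - 1L)
  observed <- acuities[i + 1L] - acuities[i]
  expected <- expected_acuity_gain(counts[i], counts[i + 1L])
  pairs <- data.frame(from = counts[i], to = counts[i + 1L],
                      observed = observed, expected = expected,
                      surplus = observed - expected)
  list(pairs = pairs,
       mean_surplus = mean(pairs$surplus),
       mean_surplus_display = round(mean(pairs$surplus), 2))
}

#' Score a trial log into the per-class performance table
#'
#' Pools trial records by (font, viewing) class and computes accuracy and
#' speed per class, then MNREAD and logistic acuities per viewing
#' condition.
#'
#' @param log data frame with columns `font_logmar`, `viewing`, `n_words`,
#'   `errors`, `t_reading_s` (the trial-log CSV format).
#' @return An object of class `reading_scores`: list with `by_class` (alpha,
#'   beta per class), `by_viewing` (gamma, logistic midpoint and slope), and
#'   the input grid metadata.
#' @export
score_trials <- function(log) {
  need <- c("font_logmar", "viewing", "n_words", "errors", "t_reading_s")
  if (!all(need %in% names(log)))
    stop("trial log must have columns ", paste(need, collapse = ", "))
  sizes <- sort(unique(log$font_logmar), decreasing = TRUE)
  views <- unique(log$viewing)
  by_class <- do.call(rbind, lapply(views, function(v) {
    do.call(rbind, lapply(sizes, function(s) {
      obs <- log[log$viewing == v & log$font_logmar == s, ]
      if (nrow(obs) == 0L) return(NULL)
      o <- data.frame(n = obs$n_words, e = obs$errors, t = obs$t_reading_s)
      data.frame(viewing = v, font_logmar = s, n_obs = nrow(o),
                 alpha = reading_accuracy(o),
                 beta = reading_speed(o), stringsAsFactors = FALSE)
    }))
  }))
  by_viewing <- do.call(rbind, lapply(views, function(v) {
    cl <- by_class[by_class$viewing == v, ]
    cl <- cl[order(-cl$font_logmar), ]
    fit <- reading_acuity_logistic(cl$alpha, cl$font_logmar)
    data.frame(viewing = v,
               gamma = reading_acuity_mnread(cl$alpha, cl$font_logmar),
               logistic_midpoint = fit$midpoint_logmar,
               logistic_slope = fit$slope_pct_per_logmar,
               degenerate_fit = fit$degenerate, stringsAsFactors = FALSE)
  }))
  structure(list(by_class = by_class, by_viewing = by_viewing,
                 sizes = sizes, viewings = views),
            class = "reading_scores")
}

#' @export
print.reading_scores <- function(x, ...) {
  cat("<reading_scores>\n")
  cat("Per viewing condition:\n")
  print(x$by_viewing, row.names = FALSE, digits = 4)
  invisible(x)
}
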