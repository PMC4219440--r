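# Trial scheduling, synthetic gaze traces, and the four-phase trial state
# machine.  The engine runs entirely on a simulated clock (sample
# timestamps), so runs are exact and reproducible.

#' Font ladder and viewing conditions
#'
#' Six print sizes from 1.5 down to 1.0 logMAR in 0.1 steps, and four
#' viewing conditions: text in the clear (control) followed by the three
#' phosphene tiers in decreasing count.
#'
#' @return Numeric vector (font ladder) / character vector (conditions).
#' @export
font_ladder <- function() seq(1.5, 1.0, by = -0.1)

#' @rdname font_ladder
#' @export
viewing_conditions <- function() c("Clear", "High", "Medium", "Low")

#' Build the 48-trial schedule
#'
#' One block of 48 trials: two passes over all combinations of six font
#' sizes (largest first) by four viewing conditions (Clear, then High,
#' Medium, Low phosphene patterns), so each (font, viewing) class occurs
#' exactly twice and difficulty increases in steps within each pass.
#' Sentences are consumed in order, each shown exactly once.
#'
#' @param sentence_ids exactly 48 distinct sentence identifiers.
#' @return Data frame with one row per trial: `index`, `repetition`,
#'   `font_condition` (1-6), `font_logmar`, `viewing_condition` (1-4),
#'   `viewing`, `sentence_id`.
#' @export
build_schedule <- function(sentence_ids = sprintf("S%02d", 1:48)) {
  sentence_ids <- as.character(sentence_ids)
  if (length(sentence_ids) != 48L || anyDuplicated(sentence_ids))
    stop("exactly 48 distinct sentence ids are required")
  fonts <- font_ladder()
  views <- viewing_conditions()
  grid <- expand.grid(viewing_condition = seq_along(views),
                      font_condition = seq_along(fonts),
                      repetition = 1:2)
  data.frame(index = seq_len(nrow(grid)),
             repetition = grid$repetition,
             font_condition = grid$font_condition,
             font_logmar = fonts[grid$font_condition],
             viewing_condition = grid$viewing_condition,
             viewing = views[grid$viewing_condition],
             sentence_id = sentence_ids,
             stringsAsFactors = FALSE)
}

#' Simulate a reading gaze trace
#'
#' Emulates the scanpath of a reader: a left-to-right sequence of fixations
#' along each line's baseline, top line first, with brief saccadic
#' transitions between fixations and isotropic Gaussian jitter on every
#' sample (the instrument's precision).  Samples arrive at the tracker rate
#' on a simulated clock.  Deterministic given `seed`.
#'
#' @param lines_px data frame with one row per text line: `x_start`,
#'   `x_end`, `y` (pixels).
#' @param fixations_per_line fixations distributed evenly along each line.
#' @param fixation_ms dwell per fixation.
#' @param saccade_ms transition time between fixations (linear motion).
#' @param noise_sd_deg per-axis Gaussian jitter, degrees (tracker precision).
#' @param rate_hz sampling rate.
#' @param display a [display_model()] (converts jitter to pixels).
#' @param seed integer seed.
#' @param t0_ms timestamp of the first sample.
#' @return Data frame `t_ms`, `x_px`, `y_px`, `valid`.
#' @export
simulate_gaze_trace <- function(lines_px, fixations_per_line = 5,
                                fixation_ms = 250, saccade_ms = 30,
                                noise_sd_deg = 0.14, rate_hz = 300,
                                display = display_model(), seed = 1L,
                                t0_ms = 0) {
  stopifnot(all(c("x_start", "x_end", "y") %in% names(lines_px)),
            fixations_per_line > 0, fixation_ms > 0, rate_hz > 0,
            noise_sd_deg >= 0)
  fix <- do.call(rbind, lapply(seq_len(nrow(lines_px)), function(i) {
    xs <- seq(lines_px$x_start[i], lines_px$x_end[i],
              length.out = fixations_per_line)
    data.frame(x = xs, y = lines_px$y[i])
  }))
  dt <- 1000 / rate_hz
  path <- list(); t <- t0_ms
  for (i in seq_len(nrow(fix))) {
    n_fix <- max(1L, round(fixation_ms / dt))
    seg <- data.frame(t_ms = t + dt * (seq_len(n_fix) - 1L),
                      x_px = fix$x[i], y_px = fix$y[i])
    path[[length(path) + 1L]] <- seg
    t <- t + n_fix * dt
    if (i < nrow(fix) && saccade_ms > 0) {
      n_sac <- max(1L, round(saccade_ms / dt))
      frac <- seq_len(n_sac) / (n_sac + 1)
      path[[length(path) + 1L]] <- data.frame(
        t_ms = t + dt * (seq_len(n_sac) - 1L),
        x_px = fix$x[i] + frac * (fix$x[i + 1L] - fix$x[i]),
        y_px = fix$y[i] + frac * (fix$y[i + 1L] - fix$y[i]))
      t <- t + n_sac * dt
    }
  }
  out <- do.call(rbind, path)
  if (noise_sd_deg > 0) {
    out <- local_seed(seed, {
      out$x_px <- out$x_px + rnorm(nrow(out), 0, deg_to_px(noise_sd_deg, display, "x"))
      out$y_px <- out$y_px + rnorm(nrow(out), 0, deg_to_px(noise_sd_deg, display, "y"))
      out
    })
  }
  out$valid <- TRUE
  rownames(out) <- NULL
  out
}

# a steady fixation segment at one point (no jitter unless noise_sd_deg > 0)
fixation_segment <- function(x_px, y_px, duration_ms, rate_hz = 300, t0_ms = 0,
                             noise_sd_deg = 0, display = display_model(),
                             seed = 1L) {
  dt <- 1000 / rate_hz
  n <- max(1L, round(duration_ms / dt))
  seg <- data.frame(t_ms = t0_ms + dt * (seq_len(n) - 1L),
                    x_px = x_px, y_px = y_px, valid = TRUE)
  if (noise_sd_deg > 0) {
    seg <- local_seed(seed, {
      seg$x_px <- seg$x_px + rnorm(n, 0, deg_to_px(noise_sd_deg, display, "x"))
      seg$y_px <- seg$y_px + rnorm(n, 0, deg_to_px(noise_sd_deg, display, "y"))
      seg
    })
  }
  seg
}

#' Fill gaps in a gaze trace
#'
#' Invalid samples (blinks, lost tracking) are repaired the way a
#' gaze-position server degrades gracefully: interior gaps no longer than
#' `max_interp_ms` are linearly interpolated across; longer interior gaps
#' and trailing gaps repeat the last valid position; leading gaps repeat
#' the first valid position.  Timestamps are untouched.
#'
#' @param trace data frame `t_ms`, `x_px`, `y_px`, `valid`.
#' @param max_interp_ms longest gap to interpolate across.
#' @return The trace with all samples valid.
#' @export
fill_gaps <- function(trace, max_interp_ms = 100) {
  stopifnot(all(c("t_ms", "x_px", "y_px", "valid") %in% names(trace)))
  if (!any(trace$valid)) stop("gaze trace contains no valid samples")
  if (all(trace$valid)) return(trace)
  good <- which(trace$valid)
  runs <- rle(trace$valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (k in seq_along(runs$values)) {
    if (runs$values[k]) next
    i0 <- starts[k]; i1 <- ends[k]
    prev <- if (i0 > 1L) i0 - 1L else NA_integer_
    nxt <- if (i1 < nrow(trace)) i1 + 1L else NA_integer_
    gap_ms <- if (!is.na(prev) && !is.na(nxt)) trace$t_ms[nxt] - trace$t_ms[prev] else Inf
    idx <- i0:i1
    if (is.na(prev)) {                       # leading gap
      trace$x_px[idx] <- trace$x_px[nxt]; trace$y_px[idx] <- trace$y_px[nxt]
    } else if (is.na(nxt) || gap_ms > max_interp_ms) {  # trailing or long gap
      trace$x_px[idx] <- trace$x_px[prev]; trace$y_px[idx] <- trace$y_px[prev]
    } else {                                 # short interior gap
      trace$x_px[idx] <- approx(trace$t_ms[c(prev, nxt)],
                                trace$x_px[c(prev, nxt)], trace$t_ms[idx])$y
      trace$y_px[idx] <- approx(trace$t_ms[c(prev, nxt)],
                                trace$y_px[c(prev, nxt)], trace$t_ms[idx])$y
    }
    trace$valid[idx] <- TRUE
  }
  trace
}

# screen anchor points for the task dots
center_dot_px <- function(display) c(display$width_px / 2, display$height_px / 2)
top_dot_px <- function(display) c(display$width_px / 2, 0.07 * display$height_px)

#' Default trial-engine timing and tolerance parameters
#'
#' Pre-stimulus hold 500 ms; advance dwell 350 ms on the top-center dot;
#' 2000 ms intertrial pause; 2 degree fixation tolerance radius.
#'
#' @return Named list of parameters.
#' @export
trial_params <- function() {
  list(pre_stimulus_ms = 500, dwell_ms = 350, intertrial_ms = 2000,
       fixation_tolerance_deg = 2, rate_hz = 300)
}

in_tolerance <- function(x_px, y_px, dot_px, tol_deg, display) {
  dx <- px_to_deg(x_px - dot_px[1], display, "x")
  dy <- px_to_deg(y_px - dot_px[2], display, "y")
  dx * dx + dy * dy <= tol_deg^2
}

# first index at which `flag` has been TRUE continuously for >= hold_ms
# (by timestamps), or NA
dwell_complete_at <- function(t_ms, flag, hold_ms) {
  start <- NA_real_
  for (i in seq_along(flag)) {
    if (flag[i]) {
      if (is.na(start)) start <- t_ms[i]
      if (t_ms[i] - start >= hold_ms) return(i)
    } else start <- NA_real_
  }
  NA_integer_
}

#' Run one trial of the reading task
#'
#' Advances the four-phase state machine (Start, Pre-Stimulus, Reading,
#' End) over a gaze trace on the simulated clock.  The Start phase waits
#' for gaze to enter the tolerance window of the central dot; the
#' Pre-Stimulus phase requires a continuous hold there; the Reading phase
#' begins when the hold completes and ends when gaze has dwelt continuously
#' for the advance-dwell duration inside the tolerance window of the
#' top-center dot.  The recorded reading time excludes that dwell, and the
#' End phase appends the intertrial pause.  During Reading, frames can be
#' rendered gaze-contingently every `render_every`-th sample (clear-viewing
#' trials bypass the phosphene renderer).
#'
#' @param spec one row of [build_schedule()] (or any list with
#'   `font_logmar`, `viewing`, `sentence_id`, `index`).
#' @param gaze gaze trace (`t_ms`, `x_px`, `y_px`, `valid`); invalid
#'   samples are repaired with [fill_gaps()].
#' @param n_words,errors reading outcome for the sentence: words shown and
#'   words missed (scored externally; the engine does not recognize speech).
#' @param stimulus optional stimulus frame (needed only when rendering).
#' @param pattern a [generate_pattern()] result, or NULL for clear viewing.
#' @param display a [display_model()].
#' @param params timing parameters, see [trial_params()].
#' @param render_every render a frame every this many Reading-phase samples
#'   (0 = never).
#' @param frame_sink optional `function(frame, t_ms)` receiving each
#'   rendered frame.
#' @return A `trial_record`: list with `spec`, `phase_times` (ms), `t_reading`
#'   (seconds), `n`, `e`, `n_frames`, `complete`.
#' @export
run_trial <- function(spec, gaze, n_words, errors,
                      stimulus = NULL, pattern = NULL,
                      display = display_model(), params = trial_params(),
                      render_every = 0L, frame_sink = NULL) {
  if (errors < 0 || errors > n_words) stop("errors must be in [0, n_words]")
  gaze <- fill_gaps(gaze)
  tol <- params$fixation_tolerance_deg
  cdot <- center_dot_px(display); tdot <- top_dot_px(display)
  at_center <- in_tolerance(gaze$x_px, gaze$y_px, cdot, tol, display)
  t <- gaze$t_ms

  record <- function(reading_start = NA, dwell_start = NA, end_at = NA,
                     complete = FALSE, n_frames = 0L, start_at = NA) {
    t_reading <- if (complete) (dwell_start - reading_start) / 1000 else NA_real_
    structure(list(spec = spec,
                   phase_times = c(start = start_at,
                                   reading = reading_start,
                                   dwell = dwell_start,
                                   end = end_at),
                   t_reading = t_reading, n = n_words, e = errors,
                   n_frames = n_frames, complete = complete),
              class = "trial_record")
  }

  # Start + Pre-Stimulus: continuous hold at the central dot
  first_at <- which(at_center)[1]
  if (is.na(first_at)) return(record(complete = FALSE))
  hold_idx <- dwell_complete_at(t, at_center, params$pre_stimulus_ms)
  if (is.na(hold_idx)) return(record(start_at = t[first_at], complete = FALSE))
  reading_start <- t[hold_idx]

  # Reading: watch for the advance dwell on the top-center dot
  reading <- which(t > reading_start)
  if (length(reading) == 0L) return(record(start_at = t[first_at], complete = FALSE))
  at_top <- in_tolerance(gaze$x_px[reading], gaze$y_px[reading], tdot, tol, display)
  dwell_idx_rel <- dwell_complete_at(t[reading], at_top, params$dwell_ms)
  n_frames <- 0L
  if (render_every > 0L && !is.null(pattern) && spec$viewing != "Clear") {
    if (is.null(stimulus)) stop("rendering requested but no stimulus frame given")
    upto <- if (is.na(dwell_idx_rel)) length(reading) else dwell_idx_rel
    for (k in seq(1L, upto, by = render_every)) {
      i <- reading[k]
      fr <- render_frame(stimulus, pattern, c(gaze$x_px[i], gaze$y_px[i]), display)
      n_frames <- n_frames + 1L
      if (!is.null(frame_sink)) frame_sink(fr, t[i])
    }
  }
  if (is.na(dwell_idx_rel))
    return(record(reading_start = reading_start, start_at = t[first_at],
                  complete = FALSE, n_frames = n_frames))
  dwell_end <- t[reading[dwell_idx_rel]]
  dwell_start <- dwell_end - params$dwell_ms
  record(reading_start = reading_start, dwell_start = dwell_start,
         end_at = dwell_end + params$intertrial_ms, complete = TRUE,
         n_frames = n_frames, start_at = t[first_at])
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> trial %s (%s, %.1f logMAR): %s, n=%d e=%d t=%.2fs\n",
              as.character(x$spec$index), x$spec$viewing, x$spec$font_logmar,
              if (x$complete) "complete" else "incomplete",
              x$n, x$e, x$t_reading))
  invisible(x)
}

#' Compose a full-trial gaze trace
#'
#' Concatenates the segments a cooperative subject produces: a steady
#' fixation on the central dot long enough to complete the pre-stimulus
#' hold, the reading scanpath over the laid-out text, and a final dwell on
#' the top-center advance dot.
#'
#' @param lines_px text-line geometry as in [simulate_gaze_trace()].
#' @param display a [display_model()].
#' @param params see [trial_params()].
#' @param fixations_per_line,fixation_ms,noise_sd_deg passed to the scanpath
#'   generator.
#' @param seed integer seed.
#' @return Gaze trace data frame.
#' @export
simulate_trial_gaze <- function(lines_px, display = display_model(),
                                params = trial_params(),
                                fixations_per_line = 5, fixation_ms = 250,
                                noise_sd_deg = 0.14, seed = 1L) {
  rate <- params$rate_hz
  cdot <- center_dot_px(display); tdot <- top_dot_px(display)
  hold <- fixation_segment(cdot[1], cdot[2],
                           params$pre_stimulus_ms + 200, rate,
                           t0_ms = 0, noise_sd_deg = min(noise_sd_deg, 0.1),
                           display = display, seed = seed)
  t1 <- max(hold$t_ms) + 1000 / rate
  read <- simulate_gaze_trace(lines_px, fixations_per_line, fixation_ms,
                              noise_sd_deg = noise_sd_deg, rate_hz = rate,
                              display = display, seed = seed + 1L, t0_ms = t1)
  t2 <- max(read$t_ms) + 1000 / rate
  dwell <- fixation_segment(tdot[1], tdot[2], params$dwell_ms + 150, rate,
                            t0_ms = t2, noise_sd_deg = min(noise_sd_deg, 0.1),
                            display = display, seed = seed + 2L)
  rbind(hold, read, dwell)
}
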