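# MNREAD-style sentence fixtures and their rasterization.  The published
# chart sentences are licensed content and are not embedded; a generator
# produces pseudo-sentences satisfying the same structural constraints
# (exactly 60 characters including spaces, 10-13 words, three lines broken
# as evenly as possible without hyphenation), and user-supplied sentence
# files can be validated against the same invariants.

#' Default lexicon for the sentence generator
#'
#' Simple, common English words (2-8 letters) of the register used by
#' graded reading charts.  Sentences built from it are pseudo-sentences:
#' structurally valid reading stimuli without guaranteed syntax.
#'
#' @return Character vector of lowercase words.
#' @export
default_lexicon <- function() {
  c("at", "be", "by", "do", "go", "he", "in", "is", "it", "me", "my", "no",
    "of", "on", "so", "to", "up", "we", "and", "big", "boy", "can", "car",
    "cat", "day", "dog", "eat", "for", "fun", "get", "had", "has", "her",
    "him", "his", "hot", "man", "mom", "new", "not", "now", "old", "one",
    "our", "out", "own", "ran", "red", "run", "saw", "she", "sun", "the",
    "too", "two", "was", "wet", "you", "ball", "bird", "blue", "book",
    "came", "come", "dark", "door", "down", "farm", "fast", "fish", "food",
    "from", "game", "gave", "girl", "goes", "gone", "good", "grew", "hand",
    "have", "help", "here", "home", "into", "jump", "kind", "lake", "like",
    "long", "look", "made", "make", "many", "milk", "more", "most", "near",
    "nest", "nice", "over", "park", "play", "rain", "read", "ride", "road",
    "room", "sang", "seen", "side", "sing", "some", "song", "soon", "stay",
    "take", "tall", "that", "them", "then", "they", "this", "time", "tree",
    "very", "walk", "want", "warm", "week", "went", "were", "what", "when",
    "wind", "with", "your", "about", "after", "again", "apple", "early",
    "every", "found", "front", "going", "grass", "great", "green", "happy",
    "house", "large", "later", "little", "lunch", "night", "other", "plays",
    "right", "small", "started", "store", "summer", "their", "there",
    "these", "thing", "think", "three", "today", "under", "water", "where",
    "white", "window", "winter", "yellow", "garden", "mother", "father",
    "friend", "school", "always", "around", "basket", "before", "better",
    "family", "flower", "liked", "morning", "picture", "playing", "walked",
    "wanted", "watched", "evening", "animals", "brother", "children")
}

SENTENCE_CHARS <- 60L
SENTENCE_WORDS_MIN <- 10L
SENTENCE_WORDS_MAX <- 13L

#' Generate an MNREAD-like pseudo-sentence
#'
#' Draws words from the lexicon to build a sentence of exactly 60
#' characters including spaces and 10 to 13 words, the structural
#' constraints of standardized continuous-text acuity sentences.  The first
#' word is capitalized.  Candidates are additionally required to lay out on
#' three lines whose widest line fits the default display at the largest
#' tested size (1.5 logMAR) in the default typeface, mirroring the fact
#' that chart sentences are typographically constrained to fit the chart.
#' Deterministic given `seed`.
#'
#' @param seed integer seed.
#' @param lexicon word list (lowercase, word lengths <= 10).
#' @param check_width enforce the largest-size fit constraint (needs a
#'   graphics device once per session to measure glyph advances).
#' @param max_tries bounded search; error if no candidate found.
#' @return An object of class `sentence_stimulus`: list with `text`,
#'   `words`, `char_count`, `lines`.
#' @examples
#' \donttest{
#' s <- generate_sentence(seed = 1)
#' s$char_count  # 60
#' }
#' @export
generate_sentence <- function(seed = 1L, lexicon = default_lexicon(),
                              check_width = TRUE, max_tries = 4000L) {
  if (length(lexicon) == 0L) stop("lexicon must be non-empty")
  if (any(nchar(lexicon) > 10L)) stop("lexicon word lengths must be <= 10")
  by_len <- split(lexicon, nchar(lexicon))
  local_seed(seed, {
    for (try in seq_len(max_tries)) {
      k <- sample(SENTENCE_WORDS_MIN:SENTENCE_WORDS_MAX, 1L)
      letters_needed <- SENTENCE_CHARS - (k - 1L)  # spaces between words
      words <- character(0)
      remaining <- letters_needed
      ok <- TRUE
      for (i in seq_len(k)) {
        left <- k - i  # words still to place after this one
        # keep the remainder fillable: each later word needs 2-8 letters
        lo <- max(2L, remaining - 8L * left)
        hi <- min(8L, remaining - 2L * left)
        if (i == k) { lo <- remaining; hi <- remaining }
        lens <- as.integer(names(by_len))
        lens <- lens[lens >= lo & lens <= hi]
        if (length(lens) == 0L) { ok <- FALSE; break }
        len <- if (length(lens) == 1L) lens else sample(lens, 1L)
        pool <- by_len[[as.character(len)]]
        w <- if (length(pool) == 1L) pool else sample(pool, 1L)
        words <- c(words, w)
        remaining <- remaining - len
      }
      if (!ok || remaining != 0L) next
      words[1] <- paste0(toupper(substr(words[1], 1, 1)), substr(words[1], 2, nchar(words[1])))
      sent <- new_sentence(words)
      if (check_width && !sentence_fits(sent)) next
      return(sent)
    }
    stop("could not generate a valid sentence from this lexicon within the search bound")
  })
}

new_sentence <- function(words) {
  text <- paste(words, collapse = " ")
  structure(list(text = text, words = words, char_count = nchar(text),
                 lines = layout_three_lines(words)),
            class = "sentence_stimulus")
}

#' @export
print.sentence_stimulus <- function(x, ...) {
  cat(sprintf("<sentence_stimulus> %d chars, %d words\n", x$char_count, length(x$words)))
  cat(paste0("  ", x$lines, collapse = "\n"), "\n")
  invisible(x)
}

#' Break a sentence into three balanced lines
#'
#' Partitions the word sequence into three contiguous groups minimizing the
#' longest line's character count (spaces included), with no hyphenation.
#' Ties prefer the more top-heavy split (longer first, then second, line).
#' The search is exhaustive over the two break points (at most a few dozen
#' partitions for chart-length sentences).
#'
#' @param words character vector of words (>= 3), or a `sentence_stimulus`.
#' @return Character vector of three lines.
#' @export
layout_three_lines <- function(words) {
  if (inherits(words, "sentence_stimulus")) words <- words$words
  n <- length(words)
  if (n < 3L) stop("need at least three words for a three-line layout")
  best <- NULL
  for (i in 1:(n - 2L)) for (j in (i + 1L):(n - 1L)) {
    lines <- c(paste(words[1:i], collapse = " "),
               paste(words[(i + 1L):j], collapse = " "),
               paste(words[(j + 1L):n], collapse = " "))
    len <- nchar(lines)
    key <- c(max(len), -len[1], -len[2])  # minimize max; tie: top-heavy
    if (is.null(best) || lex_less(key, best$key)) best <- list(key = key, lines = lines)
  }
  best$lines
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Validate sentences against the chart constraints
#'
#' @param texts character vector of candidate sentences (one per element).
#' @return Data frame with the text, character and word counts, and a
#'   `valid` flag (60 characters, 10-13 words, single spaces).
#' @export
validate_sentences <- function(texts) {
  words <- strsplit(texts, " ", fixed = TRUE)
  nw <- lengths(words)
  nc <- nchar(texts)
  clean <- !grepl("  ", texts, fixed = TRUE) & !grepl("-", texts, fixed = TRUE)
  data.frame(text = texts, char_count = nc, word_count = nw,
             valid = nc == SENTENCE_CHARS & nw >= SENTENCE_WORDS_MIN &
               nw <= SENTENCE_WORDS_MAX & clean,
             stringsAsFactors = FALSE)
}

# ---- typeface metrics and rasterization ------------------------------------

# The default typeface is R's built-in Hershey serif vector font (a
# Times-class stroke face available on every R installation), drawn with
# stroke width of one MAR, the classic optotype stroke convention, and
# condensed horizontally by a fixed factor.  The Hershey face has a small
# x-height relative to its em, so at a given x-height its natural advance
# (~1.19 x-heights per character of running text) is far wider than the
# print-chart convention; the condensation brings the mean advance to
# ~0.77 x-heights per character so that a 60-character three-line chart
# sentence (widest line >= 20 characters) spans at most the display's 43
# degrees at the largest tested size.  The factor is part of the typeface
# definition, fixed a priori, not fitted per sentence.

hershey_vfont <- c("serif", "plain")
HERSHEY_CONDENSE <- 0.65

# Measure, once per session, the Hershey serif advance width of each
# printable character we use, and the ink height of a lowercase x, in
# device units per unit cex.  strwidth()/strheight() report Hershey
# metrics in nominal units that differ from rendered ink by a constant
# device scale (~0.70 here), so the relative per-character advances from
# strwidth() are rescaled by an ink measurement of a reference string.
# Needs a throwaway bitmap device.
hershey_metrics <- function() {
  if (!is.null(.phosim_cache$hershey)) return(.phosim_cache$hershey)
  chars <- c(letters, LETTERS, " ", ".", ",", "'")
  f <- tempfile(fileext = ".png")
  grDevices::png(f, width = 400, height = 400, type = "cairo")
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 400), ylim = c(400, 0), xaxs = "i", yaxs = "i")
  cex_ref <- 10
  adv <- vapply(chars, function(ch)
    graphics::strwidth(ch, units = "user", cex = cex_ref, vfont = hershey_vfont), 0)
  ref <- "the quick brown fox"
  adv_ref <- sum(adv[strsplit(ref, "")[[1]]]) / cex_ref
  grDevices::dev.off(); unlink(f)
  cex_cal <- 15
  ink <- measure_ink(ref, cex_cal, lwd = 2,
                     width_px = ceiling(adv_ref * cex_cal) + 200L,
                     height_px = 300L)
  if (ink[["w"]] == 0) stop("Hershey metric calibration render produced no ink")
  scale <- ink[["w"]] / (adv_ref * cex_cal)
  xh <- measure_ink("x", cex_cal, lwd = 2, 300L, 300L)[["h"]] / cex_cal
  # adv_per_cex is the advance of the typeface as used, i.e. condensed
  .phosim_cache$hershey <- list(adv_per_cex = adv / cex_ref * scale * HERSHEY_CONDENSE,
                                xheight_per_cex = xh, chars = chars)
  .phosim_cache$hershey
}

string_advance_per_cex <- function(s) {
  m <- hershey_metrics()
  cs <- strsplit(s, "")[[1]]
  unknown <- setdiff(cs, m$chars)
  if (length(unknown))
    stop(sprintf("no advance metric for character(s): %s",
                 paste(unique(unknown), collapse = " ")))
  sum(m$adv_per_cex[cs])
}

# Measure the ink height (px) of a rendered string at a given cex/lwd on a
# canvas of the given size; used for x-height calibration.
measure_ink <- function(txt, cex, lwd, width_px, height_px) {
  f <- tempfile(fileext = ".png")
  on.exit(unlink(f))
  grDevices::png(f, width = width_px, height = height_px, type = "cairo", bg = "black")
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, width_px), ylim = c(height_px, 0),
                        xaxs = "i", yaxs = "i")
  graphics::text(width_px / 2, height_px / 2, txt, col = "white",
                 vfont = hershey_vfont, cex = cex, lwd = lwd, adj = c(0.5, 0.5))
  grDevices::dev.off()
  img <- png::readPNG(f)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  ink <- which(img > 0.5, arr.ind = TRUE)
  if (nrow(ink) == 0L) return(c(h = 0, w = 0))
  c(h = diff(range(ink[, 1])) + 1, w = diff(range(ink[, 2])) + 1)
}

# cex that renders a lowercase x with ink height target_px at stroke width
# lwd.  Secant iteration on bitmap measurements; cached per (target, lwd).
calibrate_cex <- function(target_px, lwd) {
  key <- sprintf("cex_%.1f_%.1f", target_px, lwd)
  if (!is.null(.phosim_cache[[key]])) return(.phosim_cache[[key]])
  canvas <- max(64L, ceiling(4 * target_px + 4 * lwd))
  # ink height grows ~linearly in cex with a stroke-width offset; secant
  # iteration on bitmap measurements to within half a pixel
  cex1 <- max(0.2, target_px / hershey_metrics()$xheight_per_cex)
  h1 <- measure_ink("x", cex1, lwd, canvas, canvas)[["h"]]
  if (h1 == 0) stop("calibration render produced no ink")
  cex <- cex2 <- max(0.2, cex1 * target_px / h1)
  for (i in 1:6) {
    h2 <- measure_ink("x", cex2, lwd, canvas, canvas)[["h"]]
    cex <- cex2
    if (abs(h2 - target_px) <= 0.5) break
    step <- if (h2 != h1) (target_px - h2) * (cex2 - cex1) / (h2 - h1)
            else (target_px - h2) * cex2 / h2
    cex1 <- cex2; h1 <- h2
    cex2 <- max(0.2, cex2 + step)
  }
  .phosim_cache[[key]] <- cex
  cex
}

# does the widest laid-out line of `sentence` fit the display at 1.5 logMAR?
sentence_fits <- function(sentence, logmar = 1.5, display = display_model(),
                          margin = 0.995) {
  xh_px <- deg_to_px(logmar_to_xheight_deg(logmar), display, axis = "y")
  cex <- xh_px / hershey_metrics()$xheight_per_cex
  widths <- vapply(sentence$lines, string_advance_per_cex, 0) * cex
  max(widths) <= display$width_px * margin
}

#' Rasterize a sentence stimulus at a logMAR size
#'
#' Renders the three-line sentence white-on-black at the requested print
#' size: the lowercase x-height equals `5 * 10^logmar` arcmin converted to
#' pixels with the display's vertical scale, calibrated against the
#' rendered bitmap to within one pixel.  Lines are centered horizontally
#' and stacked about the screen center with a baseline spacing of
#' `line_spacing` x-heights.  The typeface is the built-in Hershey serif
#' stroke font, condensed horizontally by a fixed factor so chart-format
#' sentences fit the display at the largest tested size, with stroke width
#' of one MAR (the optotype convention, split evenly across the
#' condensation).  Text that would overflow the display raises an error
#' rather than clipping.
#'
#' @param sentence a `sentence_stimulus` (or character vector of 3 lines).
#' @param logmar print size in logMAR.
#' @param display a [display_model()].
#' @param line_spacing baseline-to-baseline distance in x-heights.
#' @return A frame (numeric matrix in \[0, 1\]) of the display's dimensions,
#'   with attributes `xheight_px` (calibrated target) and `logmar`.
#' @export
rasterize_sentence <- function(sentence, logmar, display = display_model(),
                               line_spacing = 2.2) {
  lines <- if (inherits(sentence, "sentence_stimulus")) sentence$lines
           else as.character(sentence)
  stop_if_not_finite(logmar, "logmar")
  xh_px <- deg_to_px(logmar_to_xheight_deg(logmar), display, axis = "y")
  mar_px <- xh_px / 5
  # stroke-width compromise under condensation: rendering at MAR/sqrt(c)
  # leaves vertical strokes at MAR*sqrt(c) and horizontal at MAR/sqrt(c)
  # after the horizontal resample, centred on the optotype convention
  lwd <- max(1, mar_px / sqrt(HERSHEY_CONDENSE))
  cex <- calibrate_cex(xh_px, lwd)
  widths <- vapply(lines, string_advance_per_cex, 0) * cex  # condensed widths
  block_h <- (length(lines) - 1) * line_spacing * xh_px + 3 * xh_px
  if (max(widths) > display$width_px || block_h > display$height_px)
    stop(sprintf("text overflows the display at %.2f logMAR (line %.0f px wide, limit %d)",
                 logmar, max(widths), display$width_px))
  # render at natural advance on a wide off-screen canvas, then condense
  nat_w <- as.integer(ceiling(max(widths) / HERSHEY_CONDENSE) + 8 * ceiling(lwd))
  f <- tempfile(fileext = ".png")
  on.exit(unlink(f))
  grDevices::png(f, width = nat_w, height = display$height_px,
                 type = "cairo", bg = "black")
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, nat_w),
                        ylim = c(display$height_px, 0), xaxs = "i", yaxs = "i")
  yc <- display$height_px / 2
  ys <- yc + (seq_along(lines) - (length(lines) + 1) / 2) * line_spacing * xh_px
  for (i in seq_along(lines))
    graphics::text(nat_w / 2, ys[i], lines[i], col = "white",
                   vfont = hershey_vfont, cex = cex, lwd = lwd,
                   adj = c(0.5, 0.5))
  grDevices::dev.off()
  img <- png::readPNG(f)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img <- resample_width(img, as.integer(round(nat_w * HERSHEY_CONDENSE)))
  if (ncol(img) > display$width_px) {  # trim canvas padding symmetrically
    cut <- ncol(img) - display$width_px
    img <- img[, (cut %/% 2 + 1):(cut %/% 2 + display$width_px), drop = FALSE]
  }
  frame <- matrix(0, display$height_px, display$width_px)
  x0 <- as.integer(round((display$width_px - ncol(img)) / 2))
  frame[, x0 + seq_len(ncol(img))] <- img
  structure(pmin(pmax(frame, 0), 1), xheight_px = xh_px, logmar = logmar)
}

# linear horizontal resampling of an image matrix to out_w columns
resample_width <- function(img, out_w) {
  in_w <- ncol(img)
  x <- (seq_len(out_w) - 0.5) * in_w / out_w + 0.5  # 1-based source centers
  j0 <- pmax(1L, pmin(in_w - 1L, as.integer(floor(x))))
  w <- pmin(1, pmax(0, x - j0))
  img[, j0, drop = FALSE] * rep(1 - w, each = nrow(img)) +
    img[, j0 + 1L, drop = FALSE] * rep(w, each = nrow(img))
}

#' Measure the rendered x-height at a logMAR size
#'
#' Renders a lone lowercase x exactly as [rasterize_sentence()] would and
#' returns the ink height of its bitmap in pixels.  Used to verify the size
#' calibration.
#'
#' @inheritParams rasterize_sentence
#' @return Ink height in pixels.
#' @export
measured_xheight_px <- function(logmar, display = display_model()) {
  xh_px <- deg_to_px(logmar_to_xheight_deg(logmar), display, axis = "y")
  mar_px <- max(1, xh_px / 5)
  cex <- calibrate_cex(xh_px, mar_px)
  canvas <- max(64L, ceiling(4 * xh_px))
  measure_ink("x", cex, mar_px, canvas, canvas)[["h"]]
}
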