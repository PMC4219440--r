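# Scripted reader observer: supplies the word-level outcomes (words missed,
# reading pace) that a human subject would produce, so the full pipeline can
# run end to end on synthetic data.  The engine itself never scores speech.

#' Default reader-model parameters
#'
#' Word recognition follows a logistic psychometric function of print size
#' with asymptotes 0 and 1: `p(correct) = 1 / (1 + exp(-k (size - m_v)))`,
#' with the 50% threshold `m_v` per viewing condition set to the acuities
#' the three density tiers support (High 1.07, Medium 1.26, Low 1.48
#' logMAR; clear text is always read) and a common slope of 300 %/logMAR
#' (`k = 12`).  Fluent pace per condition is the words-per-minute plateau;
#' pace slows as recognition degrades, and below `give_up_p` the reader
#' declares the sentence unreadable (all words missed, short declaration
#' time).
#'
#' @return Named list of parameters.
#' @export
reader_params <- function() {
  list(threshold_logmar = c(Clear = -Inf, High = 1.07, Medium = 1.26, Low = 1.48),
       slope_k = 12,
       fluent_wpm = c(Clear = 170, High = 59, Medium = 45, Low = 30),
       slowdown = 2.5,       # pace multiplier at p -> 0
       give_up_p = 0.05,
       declare_s = 3)
}

#' Simulate a reader's outcome for one trial
#'
#' Draws the number of missed words from a binomial with the psychometric
#' recognition probability, and a reading time from the condition's pace.
#' Deterministic given `seed`.
#'
#' @param n_words words in the sentence.
#' @param font_logmar print size.
#' @param viewing `"Clear"`, `"High"`, `"Medium"` or `"Low"`.
#' @param params see [reader_params()].
#' @param seed integer seed.
#' @return List with `e` (words missed), `reading_s` (target reading time,
#'   seconds), `p` (word recognition probability), `declared` (unreadable).
#' @export
simulate_reader <- function(n_words, font_logmar, viewing,
                            params = reader_params(), seed = 1L) {
  m <- params$threshold_logmar[[viewing]]
  p <- if (is.infinite(m) && m < 0) 1
       else 1 / (1 + exp(-params$slope_k * (font_logmar - m)))
  local_seed(seed, {
    if (p < params$give_up_p) {
      list(e = n_words, reading_s = params$declare_s, p = p, declared = TRUE)
    } else {
      e <- rbinom(1, n_words, 1 - p)
      per_word <- 60 / params$fluent_wpm[[viewing]]
      pace <- per_word * (1 + params$slowdown * (1 - p))
      jitter <- exp(rnorm(1, 0, 0.08))
      list(e = e, reading_s = max(0.5, n_words * pace * jitter),
           p = p, declared = FALSE)
    }
  })
}
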