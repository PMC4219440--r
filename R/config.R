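# Run configuration, artifact writing, and the end-to-end synthetic
# experiment orchestrator.

#' Default run configuration
#'
#' Display geometry (1920x1080, 43x25 degrees at 65 cm), the standard font
#' ladder, named seeds for every source of randomness, and rendering/layout
#' options.  All seeds are recorded in the output artifacts so a run is
#' fully reproducible.
#'
#' @return Named list (class `phosim_config`).
#' @export
default_config <- function() {
  structure(list(
    display = list(width_px = 1920L, height_px = 1080L,
                   width_deg = 43, height_deg = 25,
                   reference_distance_cm = 65),
    seeds = list(pattern = 1L, sentences = 100L, gaze = 200L, reader = 300L),
    font_ladder = font_ladder(),
    line_spacing = 2.2,
    fixations_per_line = 5,
    noise_sd_deg = 0.14,
    render_every = 0L,
    output_dir = "phosim-out"),
    class = "phosim_config")
}

config_display <- function(config) do.call(display_model, config$display)

#' Load and save run configurations
#'
#' YAML or JSON, chosen by file extension.  Omitted fields take defaults;
#' unknown top-level fields are an error (strict mode), and validation
#' errors name the offending field.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return `load_config()` returns a `phosim_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw)) raw <- list()
  defaults <- default_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(unclass(defaults), raw)
  validate_config(structure(cfg, class = "phosim_config"))
}

#' @rdname load_config
#' @param config a `phosim_config`.
#' @export
save_config <- function(config, path) {
  obj <- unclass(config)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::write_yaml(obj, path)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

validate_config <- function(config) {
  d <- config$display
  for (f in c("width_px", "height_px", "width_deg", "height_deg", "reference_distance_cm"))
    if (!is.numeric(d[[f]]) || d[[f]] <= 0)
      stop(sprintf("config field display.%s must be a positive number", f))
  for (f in names(config$seeds))
    if (!is.numeric(config$seeds[[f]]))
      stop(sprintf("config field seeds.%s must be an integer", f))
  if (any(diff(config$font_ladder) >= 0))
    stop("config field font_ladder must decrease from the base size")
  config
}

#' Run the full synthetic reading experiment
#'
#' The complete pipeline on synthetic inputs: builds the 48-trial schedule,
#' generates sentences and the three phosphene patterns, simulates a
#' reader's word-level outcomes and a plausible gaze trace for every trial,
#' advances the trial state machine on the simulated clock, and scores the
#' resulting log.  Identical config (including seeds) reproduces identical
#' output.
#'
#' @param config a `phosim_config`.
#' @param progress print a line per trial.
#' @return List with `log` (trial-log data frame), `scores`
#'   ([score_trials()] result), `records`, `patterns`, `sentences`,
#'   `config`.
#' @export
run_experiment <- function(config = default_config(), progress = FALSE) {
  display <- config_display(config)
  profile <- default_profile()
  patterns <- lapply(c(High = "High", Medium = "Medium", Low = "Low"),
                     generate_pattern, profile = profile,
                     seed = config$seeds$pattern)
  sentences <- lapply(1:48, function(i)
    generate_sentence(seed = config$seeds$sentences + i))
  schedule <- build_schedule()
  params <- trial_params()
  records <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    spec <- schedule[i, ]
    sent <- sentences[[i]]
    outcome <- simulate_reader(length(sent$words), spec$font_logmar,
                               spec$viewing, seed = config$seeds$reader + i)
    lines_px <- lines_geometry(sent, spec$font_logmar, display,
                               config$line_spacing)
    # pace the scanpath so the Reading phase lasts about the reader's time
    n_fix <- 3 * config$fixations_per_line
    fix_ms <- max(40, 1000 * outcome$reading_s / n_fix)
    gaze <- simulate_trial_gaze(lines_px, display, params,
                                fixations_per_line = config$fixations_per_line,
                                fixation_ms = fix_ms,
                                noise_sd_deg = config$noise_sd_deg,
                                seed = config$seeds$gaze + 10L * i)
    stim <- NULL
    if (config$render_every > 0L && spec$viewing != "Clear")
      stim <- rasterize_sentence(sent, spec$font_logmar, display,
                                 config$line_spacing)
    pattern <- if (spec$viewing == "Clear") NULL else patterns[[spec$viewing]]
    records[[i]] <- run_trial(spec, gaze, n_words = length(sent$words),
                              errors = outcome$e, stimulus = stim,
                              pattern = pattern, display = display,
                              params = params,
                              render_every = config$render_every)
    if (progress)
      cat(sprintf("trial %2d %-6s %.1f logMAR: e=%2d t=%.2fs\n", i,
                  spec$viewing, spec$font_logmar, outcome$e,
                  records[[i]]$t_reading))
  }
  log <- trial_log(records)
  list(log = log, scores = score_trials(log), records = records,
       patterns = patterns, sentences = sentences, config = config)
}

# approximate on-screen geometry of the laid-out lines (for gaze simulation)
lines_geometry <- function(sentence, logmar, display, line_spacing = 2.2) {
  xh_px <- deg_to_px(logmar_to_xheight_deg(logmar), display, axis = "y")
  cex <- xh_px / hershey_metrics()$xheight_per_cex
  widths <- vapply(sentence$lines, string_advance_per_cex, 0) * cex
  yc <- display$height_px / 2
  k <- length(sentence$lines)
  ys <- yc + (seq_len(k) - (k + 1) / 2) * line_spacing * xh_px
  data.frame(x_start = (display$width_px - widths) / 2,
             x_end = (display$width_px + widths) / 2,
             y = ys)
}

#' Flatten trial records into the trial-log table
#'
#' @param records list of `trial_record`s.
#' @return Data frame with columns `trial`, `font_condition`, `font_logmar`,
#'   `viewing_condition`, `viewing`, `sentence_id`, `n_words`, `errors`,
#'   `t_reading_s`, `complete`.
#' @export
trial_log <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(trial = r$spec$index,
               font_condition = r$spec$font_condition,
               font_logmar = r$spec$font_logmar,
               viewing_condition = r$spec$viewing_condition,
               viewing = r$spec$viewing,
               sentence_id = r$spec$sentence_id,
               n_words = r$n, errors = r$e,
               t_reading_s = r$t_reading,
               complete = r$complete, stringsAsFactors = FALSE)
  }))
}

#' Write run artifacts with a content manifest
#'
#' Writes the trial log (CSV), the score table (CSV) and summary (JSON),
#' each phosphene pattern (JSON), a copy of the configuration, and a
#' manifest of md5 content hashes over all written files.
#'
#' @param run a [run_experiment()] result.
#' @param dir output directory (created if needed).
#' @return The manifest (named md5 vector), invisibly; also written as
#'   `manifest.json`.
#' @export
write_run_artifacts <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  files <- character(0)
  p <- function(f) file.path(dir, f)
  write.csv(run$log, p("trial_log.csv"), row.names = FALSE)
  files <- c(files, "trial_log.csv")
  write.csv(run$scores$by_class, p("scores_by_class.csv"), row.names = FALSE)
  files <- c(files, "scores_by_class.csv")
  jsonlite::write_json(list(by_viewing = run$scores$by_viewing,
                            seeds = run$config$seeds),
                       p("scores_summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, "scores_summary.json")
  for (tier in names(run$patterns)) {
    f <- sprintf("pattern_%s.json", tolower(tier))
    write_pattern_json(run$patterns[[tier]], p(f))
    files <- c(files, f)
  }
  save_config(run$config, p("config.yaml"))
  files <- c(files, "config.yaml")
  hashes <- tools::md5sum(file.path(dir, files))
  names(hashes) <- files
  jsonlite::write_json(as.list(hashes), p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(hashes)
}

#' Verify a run directory against its manifest
#'
#' @param dir a directory written by [write_run_artifacts()].
#' @return Logical vector per manifest entry (TRUE = hash matches);
#'   attribute `ok` is TRUE when all match.
#' @export
verify_manifest <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  current <- tools::md5sum(file.path(dir, names(mf)))
  ok <- unname(current) == unlist(mf)
  names(ok) <- names(mf)
  attr(ok, "ok") <- all(ok, na.rm = FALSE) && !any(is.na(ok))
  ok
}
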