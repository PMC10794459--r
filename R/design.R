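#' Task design configuration
#'
#' Builds the configuration object describing the 2AFC orientation-identification
#' experiment: the two task variants (temporal and spatial), the four standard
#' orientations, the method-of-constant-stimuli offset sets, run/repeat counts,
#' and the Gabor stimulus and timing parameters. Defaults reproduce the study
#' design: five runs of ten repeats of seven offset levels (350 trials per
#' orientation condition), distinct offset sets for cardinal (0/90 deg) and
#' oblique (-45/+45 deg) standards, 1 cyc/deg gratings in a Gaussian envelope
#' (space constant 1.33 deg, truncated at +/-4 deg) at 40% contrast, 300 ms
#' presentations with a 500 ms ISI (temporal task) and 8 deg eccentricity
#' (spatial task), viewed at 60 cm.
#'
#' Orientations are measured in degrees anticlockwise from horizontal = 0 deg;
#' the two obliques are labelled -45 and +45. Because every analysis treats the
#' two obliques symmetrically, whether obliques are referenced to horizontal or
#' vertical is inert; the convention is recorded in the
#' `orientation_reference` field.
#'
#' Timing fields (stimulus duration, ISI, response-to-trial delay) are carried
#' as metadata for record-keeping and serialisation; no real-time presentation
#' is simulated.
#'
#' @param tasks Character vector of task names, subset of
#'   `c("temporal", "spatial")`.
#' @param standard_orientations Numeric, the standard orientations in degrees.
#' @param cardinal_offsets,oblique_offsets Seven strictly increasing positive
#'   orientation offsets (degrees) used for cardinal / oblique standards.
#' @param repeats_per_level Presentations of each offset level per run.
#' @param runs_per_condition Runs per orientation condition.
#' @param grating_sf Grating spatial frequency, cycles per degree.
#' @param envelope_space_constant Gaussian envelope space constant, degrees.
#' @param envelope_truncation Envelope truncation radius, degrees.
#' @param contrast_fraction Michelson contrast as a fraction of the maximum
#'   available, in (0, 1].
#' @param stimulus_duration_ms,isi_ms,response_delay_ms Timings, milliseconds.
#' @param eccentricity_deg Centre eccentricity of the two stimuli on the
#'   spatial task, degrees.
#' @param viewing_distance_cm Nominal viewing distance, cm.
#' @param response_keys Named character vector mapping the first/left and
#'   second/right response to keys.
#' @param orientation_reference Free-text note recording the angular
#'   convention.
#'
#' @return A list of class `"design_config"`.
#' @examples
#' cfg <- design_config()
#' offsets_for(cfg, 90)   # cardinal offset set
#' offsets_for(cfg, -45)  # oblique offset set
#' @export
design_config <- function(tasks = c("temporal", "spatial"),
                          standard_orientations = c(0, 90, -45, 45),
                          cardinal_offsets = c(0.71, 1.43, 2.14, 2.86, 3.57, 4.29, 5.00),
                          oblique_offsets = c(3.57, 7.14, 10.70, 14.29, 17.80, 21.42, 25.00),
                          repeats_per_level = 10,
                          runs_per_condition = 5,
                          grating_sf = 1,
                          envelope_space_constant = 1.33,
                          envelope_truncation = 4,
                          contrast_fraction = 0.40,
                          stimulus_duration_ms = 300,
                          isi_ms = 500,
                          response_delay_ms = 800,
                          eccentricity_deg = 8,
                          viewing_distance_cm = 60,
                          response_keys = c(first = "F", second = "J"),
                          orientation_reference = "degrees anticlockwise from horizontal = 0") {
  tasks <- match.arg(tasks, c("temporal", "spatial"), several.ok = TRUE)
  check_offsets <- function(x, what) {
    if (length(x) != 7L || any(x <= 0) || any(diff(x) <= 0)) {
      stop(what, " must contain exactly 7 strictly increasing positive values",
           call. = FALSE)
    }
  }
  check_offsets(cardinal_offsets, "cardinal_offsets")
  check_offsets(oblique_offsets, "oblique_offsets")
  stopifnot(
    repeats_per_level >= 1, runs_per_condition >= 1,
    grating_sf > 0, envelope_space_constant > 0, envelope_truncation > 0,
    contrast_fraction > 0, contrast_fraction <= 1,
    viewing_distance_cm > 0
  )
  structure(
    list(
      tasks = tasks,
      standard_orientations = standard_orientations,
      cardinal_offsets = cardinal_offsets,
      oblique_offsets = oblique_offsets,
      repeats_per_level = as.integer(repeats_per_level),
      runs_per_condition = as.integer(runs_per_condition),
      grating_sf = grating_sf,
      envelope_space_constant = envelope_space_constant,
      envelope_truncation = envelope_truncation,
      contrast_fraction = contrast_fraction,
      stimulus_duration_ms = stimulus_duration_ms,
      isi_ms = isi_ms,
      response_delay_ms = response_delay_ms,
      eccentricity_deg = eccentricity_deg,
      viewing_distance_cm = viewing_distance_cm,
      response_keys = response_keys,
      orientation_reference = orientation_reference
    ),
    class = "design_config"
  )
}

#' @export
print.design_config <- function(x, ...) {
  cat("<design_config>\n")
  cat("  tasks:           ", paste(x$tasks, collapse = ", "), "\n")
  cat("  orientations:    ", paste(x$standard_orientations, collapse = ", "), "deg\n")
  cat("  cardinal offsets:", paste(format(x$cardinal_offsets), collapse = " "), "deg\n")
  cat("  oblique offsets: ", paste(format(x$oblique_offsets), collapse = " "), "deg\n")
  cat("  runs x repeats:  ", x$runs_per_condition, "x", x$repeats_per_level,
      "x 7 levels =", x$runs_per_condition * x$repeats_per_level * 7,
      "trials/condition\n")
  cat("  stimulus:        ", x$grating_sf, "cyc/deg, sigma", x$envelope_space_constant,
      "deg, contrast", x$contrast_fraction, "\n")
  invisible(x)
}

#' Classify a standard orientation as cardinal or oblique
#'
#' Horizontal (0 deg) and vertical (90 deg) standards are cardinal; the
#' +/-45 deg standards are oblique. The split matters because thresholds for
#' obliques are several-fold larger (the oblique effect), so the two classes
#' use different offset sets.
#'
#' @param orientation_deg Numeric orientation(s) in degrees.
#' @return Character vector, `"cardinal"` or `"oblique"`.
#' @export
orientation_class <- function(orientation_deg) {
  ifelse(orientation_deg %% 90 == 0, "cardinal", "oblique")
}

#' Offset levels for a standard orientation
#'
#' @param config A [design_config()].
#' @param orientation_deg A standard orientation present in the config.
#' @return Numeric vector of 7 positive offsets (degrees).
#' @export
offsets_for <- function(config, orientation_deg) {
  assert_orientation(config, orientation_deg)
  if (orientation_class(orientation_deg) == "cardinal") {
    config$cardinal_offsets
  } else {
    config$oblique_offsets
  }
}

assert_orientation <- function(config, orientation_deg) {
  if (!orientation_deg %in% config$standard_orientations) {
    stop("unknown standard orientation ", orientation_deg,
         "; allowed: {", paste(config$standard_orientations, collapse = ", "),
         "}", call. = FALSE)
  }
  invisible(TRUE)
}

position_levels <- function(task) {
  if (task == "temporal") c("first", "second") else c("left", "right")
}

#' Build a constant-stimuli trial schedule
#'
#' Generates the ordered list of trial stubs for one orientation condition of
#' one task: `n_runs` runs, each containing `repeats_per_level` presentations
#' of each of the 7 offset levels in seeded random order. The offset sign
#' (comparison clockwise vs anticlockwise of the standard) and the position of
#' the standard (first/second interval on the temporal task, left/right
#' location on the spatial task) are drawn independently per trial. Response
#' fields are left `NA`; [simulate_responses()] or real data fill them in.
#'
#' @param config A [design_config()].
#' @param task `"temporal"` or `"spatial"`.
#' @param standard_orientation One of `config$standard_orientations`.
#' @param n_runs Number of runs (default `config$runs_per_condition`).
#' @param participant_id,session,session_order Identifiers stamped on each row.
#' @param seed Optional integer seed; the schedule is a pure function of it.
#'
#' @return A tibble with one row per trial: `participant_id`, `session`,
#'   `session_order`, `task`, `standard_orientation_deg`, `offset_deg`,
#'   `offset_sign`, `standard_position`, `run_index`, `trial_index`,
#'   `response`, `correct`.
#' @examples
#' sched <- build_trial_schedule(design_config(), "temporal", 0, seed = 1)
#' nrow(sched)  # 350
#' @export
build_trial_schedule <- function(config, task, standard_orientation,
                                 n_runs = config$runs_per_condition,
                                 participant_id = "P01", session = "web",
                                 session_order = 1L, seed = NULL) {
  task <- match.arg(task, c("temporal", "spatial"))
  assert_orientation(config, standard_orientation)
  stopifnot(n_runs >= 1)
  offsets <- offsets_for(config, standard_orientation)
  positions <- position_levels(task)
  n_per_run <- config$repeats_per_level * length(offsets)

  one_run <- function(run) {
    offs <- sample(rep(offsets, each = config$repeats_per_level))
    tibble::tibble(
      participant_id = participant_id,
      session = session,
      session_order = as.integer(session_order),
      task = task,
      standard_orientation_deg = standard_orientation,
      offset_deg = offs,
      offset_sign = sample(c(-1L, 1L), n_per_run, replace = TRUE),
      standard_position = sample(positions, n_per_run, replace = TRUE),
      run_index = as.integer(run),
      trial_index = seq_len(n_per_run),
      response = NA_character_,
      correct = NA
    )
  }
  with_seed_if(seed, dplyr::bind_rows(lapply(seq_len(n_runs), one_run)))
}
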