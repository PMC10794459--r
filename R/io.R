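trial_columns <- c("participant_id", "session", "session_order", "task",
                   "standard_orientation_deg", "offset_deg", "offset_sign",
                   "standard_position", "run_index", "trial_index",
                   "response", "correct")

#' Write trial records to CSV
#'
#' One row per trial, fixed header, comma-separated, UTF-8, '.' decimal
#' separator — the single interchange format for schedules and completed
#' trials.
#'
#' @param trials Trial tibble (see [build_trial_schedule()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  missing_cols <- setdiff(trial_columns, names(trials))
  if (length(missing_cols)) {
    stop("trial table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(trials), trial_columns)
  readr::write_csv(trials[, c(trial_columns, extra)], path, progress = FALSE)
  invisible(path)
}

#' Read trial records from CSV
#'
#' Validates the documented schema; unknown columns are preserved. Malformed
#' rows (non-numeric offsets, unknown sessions/tasks, inconsistent
#' correctness) are rejected with their row numbers.
#'
#' @param path CSV file with the [write_trials()] header.
#' @return A validated trial tibble with a `.row` column for provenance.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(trial_columns, names(raw))
  if (length(missing_cols)) {
    stop("trial file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw$.row <- seq_len(nrow(raw))
  raw$correct <- as.logical(raw$correct)
  bad <- which(!is.finite(raw$offset_deg) | raw$offset_deg <= 0 |
                 !raw$offset_sign %in% c(-1, 1) |
                 !raw$task %in% c("temporal", "spatial"))
  if (length(bad)) {
    stop("malformed trial row(s): ", paste(utils::head(bad, 10), collapse = ", "),
         call. = FALSE)
  }
  answered <- !is.na(raw$response) & !is.na(raw$correct)
  inconsistent <- which(answered &
                          (raw$response == raw$standard_position) != raw$correct)
  if (length(inconsistent)) {
    stop("correct flag contradicts response/standard_position at row(s): ",
         paste(utils::head(inconsistent, 10), collapse = ", "), call. = FALSE)
  }
  raw
}

#' Write / read a threshold table
#'
#' @param thresholds Threshold tibble from [fit_thresholds()].
#' @param path CSV path.
#' @return The path (write) or tibble (read).
#' @export
write_thresholds <- function(thresholds, path) {
  readr::write_csv(thresholds, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("participant_id", "session", "task", "standard_orientation_deg",
            "threshold")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("threshold file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab
}

#' Serialise a design configuration
#'
#' Round-trips a [design_config()] through a YAML file; an empty or partial
#' file reproduces the default study design.
#'
#' @param config A design_config.
#' @param path YAML file path.
#' @return The path (write) or a design_config (read).
#' @export
write_design_config <- function(config, path) {
  stopifnot(inherits(config, "design_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_design_config
#' @export
read_design_config <- function(path) {
  vals <- if (file.exists(path)) yaml::read_yaml(path) else list()
  vals <- vals %||% list()
  if (!is.null(vals$response_keys)) vals$response_keys <- unlist(vals$response_keys)
  vals <- vals[names(vals) %in% names(formals(design_config))]
  do.call(design_config, vals)
}

#' Write an analysis report bundle
#'
#' Serialises a results bundle to a directory: the threshold table as CSV,
#' ANOVA and agreement summaries as structured text (full precision plus a
#' rounded human-readable table), and optional figures (threshold boxplots
#' and Bland–Altman plots).
#'
#' @param results A list with any of `thresholds`, `anova` (an `"rm_anova"`),
#'   `agreement` (tibble from [evaluate_agreement()]), `learning` (from
#'   [learning_check()]).
#' @param dir Output directory (created if absent).
#' @param plots Write PDF figures as well.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(results, dir, plots = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir, call. = FALSE)
  written <- character()
  add <- function(p) written <<- c(written, p)

  thr <- results$thresholds %||%
    tibble::tibble(participant_id = character(), session = character(),
                   session_order = integer(), task = character(),
                   standard_orientation_deg = double(), threshold = double(),
                   se_threshold = double())
  p <- file.path(dir, "thresholds.csv")
  readr::write_csv(thr, p, progress = FALSE); add(p)

  lines <- character()
  if (!is.null(results$anova)) {
    e <- results$anova$effects
    lines <- c(lines, "== Repeated-measures ANOVA ==",
               readr::format_csv(e), "")
  }
  if (!is.null(results$agreement)) {
    ag <- results$agreement
    lines <- c(lines, "== Web vs lab agreement ==", readr::format_csv(ag), "",
               "rounded:",
               utils::capture.output(print(
                 dplyr::mutate(ag, dplyr::across(dplyr::where(is.numeric),
                                                 ~round(.x, 3))))), "")
  }
  if (!is.null(results$learning)) {
    lines <- c(lines, "== Learning check ==",
               paste0("first/second mean ratio: ", results$learning$ratio),
               results$learning$direction, "")
  }
  p <- file.path(dir, "summary.txt")
  writeLines(lines, p); add(p)

  if (plots && nrow(thr) > 0) {
    gp <- ggplot2::ggplot(thr, ggplot2::aes(
      x = factor(.data$standard_orientation_deg), y = .data$threshold,
      fill = .data$task)) +
      ggplot2::geom_boxplot() +
      ggplot2::facet_wrap(~session) +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "standard orientation (deg)", y = "threshold (deg)")
    p <- file.path(dir, "thresholds_boxplot.pdf")
    ggplot2::ggsave(p, gp, width = 7, height = 4); add(p)
  }
  invisible(written)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a pipeline invocation: the design
#' configuration snapshot, the master seed, package version, and the input
#' and output file lists.
#'
#' @param dir Directory for `manifest.yaml`.
#' @param config A design_config.
#' @param seed Master seed used.
#' @param inputs,outputs Character vectors of file paths.
#' @param extra Named list of additional fields.
#' @return Path to the manifest, invisibly.
#' @export
write_manifest <- function(dir, config, seed, inputs = character(),
                           outputs = character(), extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- c(list(
    package = "visagree",
    version = as.character(utils::packageVersion("visagree")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config = unclass(config),
    inputs = as.list(inputs),
    outputs = as.list(outputs)
  ), extra)
  p <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, p)
  invisible(p)
}
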