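#' Synthetic observer population configuration
#'
#' Defines the generative model for a simulated two-session (web/lab)
#' reliability study. Each participant's log threshold in a condition is
#'
#' \deqn{\log a_{i,s,c} = \mu_c + S_i + E_{i,s} + \varepsilon_{i,s,c}}
#'
#' with a condition mean `mu_c` per (task, orientation class), a shared
#' subject effect `S_i` (SD `sigma_subject`), a session-specific effect
#' `E_{i,s}` (SD `sigma_session`, shared across conditions within a session)
#' and a residual `eps` (SD `sigma_resid`). Thresholds are therefore
#' log-normal — positive by construction, with variability proportional to
#' magnitude, which is the structure the log-scale Bland–Altman analysis
#' assumes. For a single condition, the true intraclass correlation between
#' sessions is
#'
#' \deqn{ICC = \sigma_S^2 / (\sigma_S^2 + \sigma_E^2 + \sigma_\varepsilon^2).}
#'
#' Either pass `icc` (the session SDs are derived, split equally between
#' `sigma_session` and `sigma_resid`) or pass both SDs explicitly.
#'
#' Condition means default to geometric-mean thresholds of 1.2 deg
#' (temporal/cardinal), 6 deg (temporal/oblique), 1.8 deg (spatial/cardinal)
#' and 9 deg (spatial/oblique): a several-fold cardinal advantage (the oblique
#' effect) and a temporal-task advantage, each threshold comfortably inside
#' its condition's offset range. Slopes follow a Weber-like rule,
#' `|b| = slope_ratio * a`, so psychometric functions have similar shape on a
#' log-offset axis across conditions.
#'
#' @param n_participants Number of simulated participants.
#' @param icc True single-condition ICC in `[0, 1)`; ignored when both session
#'   SDs are given.
#' @param sigma_subject Between-subject SD of log thresholds.
#' @param sigma_session,sigma_resid Session-effect and residual SDs of log
#'   thresholds; both `NULL` (default) derives them from `icc`.
#' @param mean_log_thresholds Tibble with columns `task`, `class`, `mu` giving
#'   the mean log threshold per task x orientation class.
#' @param slope_ratio Slope magnitude as a fraction of the threshold.
#' @param session_bias Multiplicative lab/web threshold bias (1 = none);
#'   applied to the lab session.
#' @param learning_gain Multiplicative factor applied to second-session
#'   thresholds (1 = no learning; 0.8 = 20% improvement).
#' @param seed Optional integer seed stamped into the config and used by
#'   [draw_population()].
#'
#' @return A list of class `"observer_population"`.
#' @export
observer_population <- function(n_participants = 18,
                                icc = 0.9,
                                sigma_subject = 0.35,
                                sigma_session = NULL,
                                sigma_resid = NULL,
                                mean_log_thresholds = default_mean_log_thresholds(),
                                slope_ratio = 0.3,
                                session_bias = 1,
                                learning_gain = 1,
                                seed = NULL) {
  stopifnot(n_participants >= 1, sigma_subject >= 0, slope_ratio > 0,
            session_bias > 0, learning_gain > 0)
  if (is.null(sigma_session) != is.null(sigma_resid)) {
    stop("supply both sigma_session and sigma_resid, or neither", call. = FALSE)
  }
  if (is.null(sigma_session)) {
    stopifnot(icc >= 0, icc < 1)
    if (icc == 0 && sigma_subject > 0) {
      stop("icc = 0 with sigma_subject > 0 requires infinite session noise; ",
           "set sigma_subject = 0 instead", call. = FALSE)
    }
    within_var <- if (sigma_subject == 0) 0 else sigma_subject^2 * (1 - icc) / icc
    sigma_session <- sqrt(within_var / 2)
    sigma_resid <- sqrt(within_var / 2)
  }
  stopifnot(sigma_session >= 0, sigma_resid >= 0)
  req <- c("task", "class", "mu")
  if (!all(req %in% names(mean_log_thresholds))) {
    stop("mean_log_thresholds needs columns task, class, mu", call. = FALSE)
  }
  tot <- sigma_subject^2 + sigma_session^2 + sigma_resid^2
  structure(
    list(
      n_participants = as.integer(n_participants),
      sigma_subject = sigma_subject,
      sigma_session = sigma_session,
      sigma_resid = sigma_resid,
      true_icc = if (tot == 0) 1 else sigma_subject^2 / tot,
      mean_log_thresholds = tibble::as_tibble(mean_log_thresholds),
      slope_ratio = slope_ratio,
      session_bias = session_bias,
      learning_gain = learning_gain,
      seed = seed
    ),
    class = "observer_population"
  )
}

#' Default condition means for the synthetic population
#'
#' Geometric-mean thresholds (degrees) per task x orientation class, chosen so
#' cardinal thresholds are several-fold smaller than oblique and temporal
#' smaller than spatial.
#'
#' @return Tibble with columns `task`, `class`, `mu` (mean log threshold).
#' @export
default_mean_log_thresholds <- function() {
  tibble::tibble(
    task  = c("temporal", "temporal", "spatial", "spatial"),
    class = c("cardinal", "oblique", "cardinal", "oblique"),
    mu    = log(c(1.2, 6, 1.8, 9))
  )
}

#' Draw a population of synthetic observers
#'
#' Realises the random-effects model of [observer_population()]: one true
#' threshold and slope per participant x session x task x orientation.
#' Session order is counterbalanced (the first half of participants do web
#' first). The optional `session_bias` multiplies lab thresholds and
#' `learning_gain` multiplies second-session thresholds.
#'
#' @param popcfg An [observer_population()].
#' @param config A [design_config()] supplying tasks and orientations.
#' @param sessions Character vector of sessions to draw (default web and lab).
#' @param seed Optional seed overriding `popcfg$seed`.
#'
#' @return A tibble with one row per participant x session x task x
#'   orientation: `participant_id`, `session`, `session_order`, `task`,
#'   `standard_orientation_deg`, `orientation_class`, `threshold_true`,
#'   `slope_true`.
#' @export
draw_population <- function(popcfg, config = design_config(),
                            sessions = c("web", "lab"), seed = NULL) {
  stopifnot(inherits(popcfg, "observer_population"))
  seed <- seed %||% popcfg$seed
  n <- popcfg$n_participants
  ids <- sprintf("P%02d", seq_len(n))
  grid <- tidyr::expand_grid(
    participant_id = ids,
    session = sessions,
    task = config$tasks,
    standard_orientation_deg = config$standard_orientations
  )
  grid$orientation_class <- orientation_class(grid$standard_orientation_deg)
  grid <- dplyr::left_join(
    grid,
    dplyr::rename(popcfg$mean_log_thresholds, orientation_class = "class"),
    by = c("task", "orientation_class")
  )
  # web first for the first half of participants, lab first for the rest
  web_first <- stats::setNames(seq_len(n) <= ceiling(n / 2), ids)
  grid$session_order <- ifelse(
    (grid$session == "web") == web_first[grid$participant_id], 1L, 2L)

  with_seed_if(seed, {
    subj <- stats::setNames(stats::rnorm(n, 0, popcfg$sigma_subject), ids)
    sess_key <- paste(grid$participant_id, grid$session)
    usess <- unique(sess_key)
    sess_eff <- stats::setNames(
      stats::rnorm(length(usess), 0, popcfg$sigma_session), usess)
    eps <- stats::rnorm(nrow(grid), 0, popcfg$sigma_resid)
    log_a <- grid$mu + subj[grid$participant_id] + sess_eff[sess_key] + eps
    log_a <- log_a +
      ifelse(grid$session == "lab", log(popcfg$session_bias), 0) +
      ifelse(grid$session_order == 2L, log(popcfg$learning_gain), 0)
    grid$threshold_true <- unname(exp(log_a))
    grid$slope_true <- popcfg$slope_ratio * grid$threshold_true
    grid$mu <- NULL
    grid[, c("participant_id", "session", "session_order", "task",
             "standard_orientation_deg", "orientation_class",
             "threshold_true", "slope_true")]
  })
}

#' Probability correct under the logistic psychometric model
#'
#' The probability of a correct 2AFC response at orientation offset `x` for an
#' observer with threshold `a` and slope magnitude `b`:
#' `p = 0.5 + 0.5 / (1 + exp(-(x - a) / b))`. This is the percent-correct
#' logistic (see [logistic_pct()]) divided by 100, written with the
#' monotone-increasing sign convention; it rises from 0.5 (chance) to 1 and
#' equals exactly 0.75 at `x = a`.
#'
#' @param offset_deg Orientation offset(s), degrees, `>= 0`.
#' @param threshold Threshold `a` (deg), the 75%-correct offset.
#' @param slope Slope magnitude `b` (deg), `> 0`.
#' @return Probability in `[0.5, 1]`, vectorised over all arguments.
#' @examples
#' p_correct(2.5, threshold = 2.5, slope = 1)  # 0.75
#' @export
p_correct <- function(offset_deg, threshold, slope) {
  stopifnot(all(offset_deg >= 0), all(threshold > 0), all(slope > 0))
  0.5 + 0.5 / (1 + exp(-(offset_deg - threshold) / slope))
}

#' Simulate 2AFC responses for a scheduled set of trials
#'
#' Fills the response fields of a trial schedule by Bernoulli draws from each
#' observer's psychometric function: trial `t` is correct with probability
#' [p_correct()] at its offset, given the observer's true threshold and slope
#' for that (participant, session, task, orientation). The recorded `response`
#' is the standard's position when correct and the other position otherwise.
#'
#' @param population A tibble from [draw_population()] (or any table with
#'   `participant_id`, `session`, `task`, `standard_orientation_deg`,
#'   `threshold_true`, `slope_true`).
#' @param schedule Trial stubs from [build_trial_schedule()].
#' @param seed Optional integer seed.
#' @return The schedule with `response` and `correct` filled in.
#' @export
simulate_responses <- function(population, schedule, seed = NULL) {
  key <- c("participant_id", "session", "task", "standard_orientation_deg")
  merged <- dplyr::left_join(
    schedule,
    population[, c(key, "threshold_true", "slope_true")],
    by = key
  )
  if (anyNA(merged$threshold_true)) {
    bad <- unique(merged[is.na(merged$threshold_true), key])
    stop("no observer model for scheduled condition(s): ",
         paste(apply(bad, 1, paste, collapse = "/"), collapse = "; "),
         call. = FALSE)
  }
  with_seed_if(seed, {
    p <- p_correct(merged$offset_deg, merged$threshold_true, merged$slope_true)
    correct <- stats::runif(nrow(merged)) < p
    out <- schedule
    out$correct <- correct
    out$response <- ifelse(
      correct, out$standard_position,
      other_position(out$task, out$standard_position))
    out
  })
}

other_position <- function(task, position) {
  pairs <- c(first = "second", second = "first", left = "right", right = "left")
  unname(pairs[position])
}

#' Simulate a complete synthetic study at the trial level
#'
#' Draws a population, schedules every (participant, session, task,
#' orientation) condition with the configured runs and repeats, and simulates
#' all responses. This is the full data-generating loop a real study would
#' produce, usable to exercise collation, fitting, exclusion, group inference
#' and agreement end to end.
#'
#' @param popcfg An [observer_population()].
#' @param config A [design_config()].
#' @param sessions Sessions to simulate; use `"web"` alone for the web-only
#'   group experiment.
#' @param seed Integer seed controlling population draw, schedules and
#'   responses.
#' @return A list with `population` (true parameters) and `trials` (completed
#'   trial records).
#' @export
simulate_study <- function(popcfg, config = design_config(),
                           sessions = c("web", "lab"), seed = NULL) {
  seeds <- derive_seeds(seed, 3)
  population <- draw_population(popcfg, config, sessions, seed = seeds[[1]])
  conds <- unique(population[, c("participant_id", "session", "session_order",
                                 "task", "standard_orientation_deg")])
  sched_seeds <- derive_seeds(seeds[[2]], nrow(conds))
  schedules <- purrr::pmap(
    list(conds$participant_id, conds$session, conds$session_order,
         conds$task, conds$standard_orientation_deg, sched_seeds),
    function(pid, sess, ord, task, orient, s) {
      build_trial_schedule(config, task, orient,
                           participant_id = pid, session = sess,
                           session_order = ord, seed = s)
    }
  )
  schedule <- dplyr::bind_rows(schedules)
  trials <- simulate_responses(population, schedule, seed = seeds[[3]])
  list(population = population, trials = trials)
}
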