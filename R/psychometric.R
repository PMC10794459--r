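#' Percent-correct logistic psychometric function
#'
#' The two-parameter logistic used throughout the package, in its printed
#' form: `y = 50 + 50 / (1 + exp((x - a) / b))`, where `x` is the orientation
#' offset (deg), `a` the curve midpoint — the threshold, since the curve
#' passes through 75% correct exactly at `x = a` — and `b` the slope. As
#' printed, the curve is monotone *increasing* (chance 50% up to 100%) only
#' when `b < 0`; the fitting routine therefore works with the slope magnitude
#' internally and [fit_logistic()] stores `b` with its fitted (negative) sign
#' alongside the magnitude.
#'
#' @param offset_deg Offset(s) `x` in degrees.
#' @param a Midpoint/threshold (deg).
#' @param b Slope (deg); negative for an increasing curve.
#' @return Percent correct in `(0, 100)`.
#' @examples
#' logistic_pct(2.5, a = 2.5, b = -1)  # 75
#' @export
logistic_pct <- function(offset_deg, a, b) {
  50 + 50 / (1 + exp((offset_deg - a) / b))
}

#' Collate trials into psychometric data
#'
#' Aggregates trial records into proportion correct per offset level for each
#' condition (participant x session x task x standard orientation), pooling
#' across runs and across clockwise/anticlockwise offset signs. The counts per
#' level are the sufficient statistics for the least-squares fit, so any
#' split or ordering of runs yields identical downstream results.
#'
#' @param trials Tibble of completed trial records (see
#'   [build_trial_schedule()] for the schema); `correct` must be filled in.
#' @return A tibble with one row per condition x offset level:
#'   key columns, `offset_deg`, `n_trials`, `n_correct`, `pct_correct`.
#' @export
collate_trials <- function(trials) {
  if (is.null(trials) || nrow(trials) == 0) {
    stop("no trials to collate", call. = FALSE)
  }
  if (anyNA(trials$correct)) {
    stop("trials contain unanswered rows (correct is NA); complete or drop ",
         "them before collating", call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(trials, .data$participant_id, .data$session,
                    .data$session_order, .data$task,
                    .data$standard_orientation_deg, .data$offset_deg),
    n_trials = dplyr::n(),
    n_correct = sum(.data$correct),
    .groups = "drop"
  )
  out$pct_correct <- 100 * out$n_correct / out$n_trials
  dplyr::arrange(out, .data$participant_id, .data$session, .data$task,
                 .data$standard_orientation_deg, .data$offset_deg)
}

#' Fit the logistic psychometric function by least squares
#'
#' Fits [logistic_pct()] to one condition's proportion-correct data by
#' unweighted least squares on the percent scale, minimising
#' `sum((pct_observed - y(x; a, b))^2)` over the midpoint `a` and slope.
#' Internally the curve is parameterised as
#' `y = 50 + 50 / (1 + exp(-(x - a) / beta))` with `beta > 0`, which is the
#' printed form with `b = -beta` and removes the sign ambiguity. The start
#' values are deterministic and scale-aware: `a0` is the offset where the
#' observed proportions cross 75% (linear interpolation, clamped to the tested
#' range) and `beta0` a quarter of the offset range. Optimisation uses
#' Levenberg–Marquardt ([minpack.lm::nlsLM()]) with a Nelder–Mead fallback;
#' failures set `converged = FALSE` rather than raising.
#'
#' The threshold standard error is the asymptotic (Jacobian-based)
#' least-squares standard error of `a`; `se_boot()` offers a trial-resampling
#' alternative via `bootstrap_se()`.
#'
#' @param data A tibble with columns `offset_deg` and `pct_correct` (and
#'   optionally counts), one row per offset level, for a single condition.
#' @return An object of class `"psychometric_fit"`: a list with `a`
#'   (threshold, deg), `b` (slope with fitted sign; negative), `slope_mag`
#'   (`|b|`), `se_threshold`, `rss`, `converged`, `reached_threshold`
#'   (maximum observed proportion >= 75 and `a` within the tested offsets),
#'   `n_levels`, `offset_range`, and the input `data`.
#' @examples
#' x <- c(0.71, 1.43, 2.14, 2.86, 3.57, 4.29, 5)
#' d <- tibble::tibble(offset_deg = x, pct_correct = logistic_pct(x, 2.5, -0.8))
#' fit <- fit_logistic(d)
#' fit$a  # 2.5
#' @export
fit_logistic <- function(data) {
  if (!all(c("offset_deg", "pct_correct") %in% names(data))) {
    stop("data needs columns offset_deg and pct_correct", call. = FALSE)
  }
  data <- dplyr::arrange(tibble::as_tibble(data), .data$offset_deg)
  x <- data$offset_deg
  y <- data$pct_correct
  if (length(unique(x)) < 3) {
    stop("at least 3 distinct offset levels are required", call. = FALSE)
  }
  if (any(!is.finite(y))) stop("non-finite proportions", call. = FALSE)

  a0 <- interp_crossing(x, y, 75)
  beta0 <- diff(range(x)) / 4
  n_trials <- if ("n_trials" %in% names(data)) data$n_trials else NULL
  fit <- tryCatch(
    {
      m <- minpack.lm::nlsLM(
        y ~ 50 + 50 / (1 + exp(-(x - a) / beta)),
        start = list(a = a0, beta = beta0),
        lower = c(a = -Inf, beta = 1e-8),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
      cf <- stats::coef(m)
      list(a = unname(cf["a"]), beta = unname(cf["beta"]),
           rss = sum(stats::resid(m)^2), ok = TRUE)
    },
    error = function(e) NULL
  )
  if (is.null(fit)) fit <- fit_logistic_nm(x, y, a0, beta0)
  if (!is.null(fit)) {
    fit$se <- threshold_se(x, y, fit$a, fit$beta, n_trials)
  }

  if (is.null(fit)) {
    res <- list(a = NA_real_, b = NA_real_, slope_mag = NA_real_,
                se_threshold = NA_real_, rss = NA_real_, converged = FALSE,
                reached_threshold = FALSE, n_levels = length(x),
                offset_range = range(x), data = data)
  } else {
    reached <- max(y) >= 75 && fit$a >= min(x) && fit$a <= max(x)
    res <- list(a = fit$a, b = -fit$beta, slope_mag = fit$beta,
                se_threshold = fit$se, rss = fit$rss, converged = TRUE,
                reached_threshold = reached, n_levels = length(x),
                offset_range = range(x), data = data)
  }
  structure(res, class = "psychometric_fit")
}

# linear interpolation of the first crossing of `level`, clamped to range(x)
interp_crossing <- function(x, y, level) {
  if (all(y < level)) return(max(x))
  if (all(y >= level)) return(min(x))
  i <- which(y >= level)[1]
  if (i == 1) return(min(x))
  x0 <- x[i - 1]; x1 <- x[i]; y0 <- y[i - 1]; y1 <- y[i]
  if (y1 == y0) return((x0 + x1) / 2)
  min(max(x0 + (level - y0) * (x1 - x0) / (y1 - y0), min(x)), max(x))
}

# Nelder-Mead fallback on the same least-squares objective
fit_logistic_nm <- function(x, y, a0, beta0) {
  obj <- function(p) {
    beta <- exp(p[2])
    sum((y - (50 + 50 / (1 + exp(-(x - p[1]) / beta))))^2)
  }
  opt <- tryCatch(
    stats::optim(c(a0, log(beta0)), obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12)),
    error = function(e) NULL
  )
  if (is.null(opt) || opt$convergence != 0) return(NULL)
  list(a = opt$par[1], beta = exp(opt$par[2]), rss = opt$value, ok = TRUE)
}

# analytic Jacobian of the increasing-form logistic at (a, beta)
logistic_jacobian <- function(x, a, beta) {
  z <- exp(-(x - a) / beta)
  denom <- (1 + z)^2
  cbind(a = -50 * z / (beta * denom),
        beta = -50 * z * (x - a) / (beta^2 * denom))
}

# Asymptotic SE of the threshold from the least-squares Jacobian. When
# per-level trial counts are known the error variance per level is the
# model-based binomial variance (sandwich form, robust to the strong
# heteroscedasticity of proportions near the upper asymptote); otherwise the
# homoscedastic residual-variance form.
threshold_se <- function(x, y, a, beta, n_trials = NULL) {
  J <- logistic_jacobian(x, a, beta)
  tryCatch({
    JtJ_inv <- solve(crossprod(J))
    if (!is.null(n_trials)) {
      p_hat <- pmin(pmax((50 + 50 / (1 + exp(-(x - a) / beta))) / 100,
                         1 / (4 * n_trials)), 1 - 1 / (4 * n_trials))
      V <- 100^2 * p_hat * (1 - p_hat) / n_trials
      cov_a <- (JtJ_inv %*% crossprod(J * V, J) %*% JtJ_inv)[1, 1]
    } else {
      s2 <- sum((y - (50 + 50 / (1 + exp(-(x - a) / beta))))^2) /
        max(length(x) - 2, 1)
      cov_a <- s2 * JtJ_inv[1, 1]
    }
    # ill-conditioned Jacobians can push the variance numerically negative
    if (!is.finite(cov_a) || cov_a < 0) NA_real_ else sqrt(cov_a)
  }, error = function(e) NA_real_)
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("<psychometric_fit>\n")
  if (x$converged) {
    cat(sprintf("  threshold a = %.3f deg (SE %.3f), slope |b| = %.3f deg\n",
                x$a, x$se_threshold, x$slope_mag))
    cat(sprintf("  RSS = %.3f over %d levels; reached threshold: %s\n",
                x$rss, x$n_levels, x$reached_threshold))
  } else {
    cat("  did not converge\n")
  }
  invisible(x)
}

#' Predicted percent correct from a fit
#'
#' @param object A `"psychometric_fit"`.
#' @param newdata Optional tibble with `offset_deg`; defaults to the fitted
#'   levels.
#' @param ... Unused.
#' @return Numeric percent-correct predictions.
#' @export
predict.psychometric_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$offset_deg else newdata$offset_deg
  logistic_pct(x, object$a, object$b)
}

#' Bootstrap standard error of the threshold
#'
#' Resamples trials within each offset level (parametric binomial resampling
#' of the per-level counts), refits, and returns the SD of the bootstrap
#' threshold estimates. An alternative to the asymptotic SE when per-level
#' counts are small.
#'
#' @param fit A converged `"psychometric_fit"` whose data carry `n_trials`.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Optional seed.
#' @return Bootstrap SE of the threshold (numeric scalar).
#' @export
bootstrap_se <- function(fit, n_boot = 200, seed = NULL) {
  stopifnot(inherits(fit, "psychometric_fit"), fit$converged)
  d <- fit$data
  if (!"n_trials" %in% names(d)) {
    stop("bootstrap requires per-level trial counts (n_trials)", call. = FALSE)
  }
  with_seed_if(seed, {
    a_star <- replicate(n_boot, {
      k <- stats::rbinom(nrow(d), d$n_trials, d$pct_correct / 100)
      b <- d
      b$pct_correct <- 100 * k / d$n_trials
      f <- fit_logistic(b)
      if (f$converged) f$a else NA_real_
    })
    stats::sd(a_star, na.rm = TRUE)
  })
}

#' Fit thresholds for every condition in a trial set
#'
#' Convenience wrapper: collates trials and fits the logistic per condition,
#' returning a long-format threshold table suitable for [rm_anova()],
#' [evaluate_agreement()] and [apply_exclusion()].
#'
#' @param trials Completed trial records, or pre-collated data from
#'   [collate_trials()].
#' @return A tibble with one row per condition: key columns, `threshold`,
#'   `slope`, `se_threshold`, `rss`, `converged`, `reached_threshold`,
#'   `max_pct`.
#' @export
fit_thresholds <- function(trials) {
  collated <- if ("pct_correct" %in% names(trials)) trials else collate_trials(trials)
  keys <- c("participant_id", "session", "session_order", "task",
            "standard_orientation_deg")
  nested <- tidyr::nest(dplyr::group_by(collated, dplyr::across(dplyr::all_of(keys))))
  fits <- purrr::map(nested$data, fit_logistic)
  out <- nested[keys]
  out$threshold <- purrr::map_dbl(fits, "a")
  out$slope <- purrr::map_dbl(fits, "b")
  out$se_threshold <- purrr::map_dbl(fits, "se_threshold")
  out$rss <- purrr::map_dbl(fits, "rss")
  out$converged <- purrr::map_lgl(fits, "converged")
  out$reached_threshold <- purrr::map_lgl(fits, "reached_threshold")
  out$max_pct <- purrr::map_dbl(nested$data, ~max(.x$pct_correct))
  dplyr::ungroup(out)
}

#' Apply the threshold-performance exclusion rule
#'
#' A condition "reaches threshold" when its maximum observed proportion
#' correct across offset levels is at least 75% *and* the logistic fit
#' converged with a threshold inside the tested offset range. A participant is
#' excluded when any required condition fails (including conditions that are
#' simply missing). The operationalisation via the in-range fitted threshold
#' is a package decision; the criterion itself is the 75%-correct performance
#' floor.
#'
#' @param thresholds Output of [fit_thresholds()].
#' @param required_conditions Tibble of `task` x `standard_orientation_deg`
#'   combinations each participant must pass per session; defaults to the
#'   full 2 x 4 design.
#' @return A list with `included` (character participant ids), `excluded`,
#'   and `report`: a tibble of failing (participant, session, task,
#'   orientation) rows with a `reason`.
#' @export
apply_exclusion <- function(thresholds,
                            required_conditions = NULL) {
  cfg <- design_config()
  if (is.null(required_conditions)) {
    required_conditions <- tidyr::expand_grid(
      task = cfg$tasks, standard_orientation_deg = cfg$standard_orientations)
  }
  sessions <- unique(thresholds$session)
  required <- tidyr::expand_grid(
    participant_id = unique(thresholds$participant_id),
    session = sessions
  )
  required <- tidyr::expand_grid(required, required_conditions)

  merged <- dplyr::left_join(
    required, thresholds,
    by = c("participant_id", "session", "task", "standard_orientation_deg"))
  merged$reason <- dplyr::case_when(
    is.na(merged$converged) ~ "condition missing",
    merged$max_pct < 75 ~ "below 75% correct at every offset",
    !merged$converged ~ "fit did not converge",
    !merged$reached_threshold ~ "threshold outside tested offset range",
    TRUE ~ NA_character_
  )
  report <- merged[!is.na(merged$reason),
                   c("participant_id", "session", "task",
                     "standard_orientation_deg", "reason")]
  all_ids <- unique(thresholds$participant_id)
  excluded <- unique(report$participant_id)
  list(
    included = setdiff(all_ids, excluded),
    excluded = excluded,
    report = tibble::as_tibble(report)
  )
}
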