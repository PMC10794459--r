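#' Intraclass correlation ICC(2,1) with 95% confidence interval
#'
#' Single-measurement, absolute-agreement intraclass correlation under the
#' two-way random-effects model (Shrout–Fleiss ICC(2,1); McGraw–Wong case
#' 2A). From the two-way ANOVA mean squares — rows/subjects `MSR`, columns/
#' raters `MSC`, residual `MSE` — the estimate is
#'
#' \deqn{ICC = \frac{MSR - MSE}{MSR + (k-1) MSE + \frac{k}{n}(MSC - MSE)}}
#'
#' with the standard F-based confidence interval (Satterthwaite degrees of
#' freedom for the rater stratum).
#'
#' @param x Numeric matrix, n subjects x k raters/sessions, no missing cells;
#'   or a data frame coercible to one.
#' @param conf Confidence level (default 0.95).
#' @return A list with `estimate`, `ci_low`, `ci_high`, `conf`, the mean
#'   squares `msr`, `msc`, `mse`, and `n`, `k`.
#' @examples
#' m <- cbind(web = c(1, 2, 4, 6), lab = c(1.2, 2.1, 3.6, 6.4))
#' icc21(m)$estimate
#' @export
icc21 <- function(x, conf = 0.95) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing cells are not allowed; no imputation", call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters", call. = FALSE)

  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((x - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))

  est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  alpha <- 1 - conf
  fj <- msc / mse
  a <- (k * est) / (n * (1 - est))
  b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
  v <- ((a * fj + b)^2) /
    ((a^2 * fj^2) / (k - 1) + b^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)

  list(estimate = est, ci_low = lower, ci_high = upper, conf = conf,
       msr = msr, msc = msc, mse = mse, n = n, k = k)
}

#' Bland–Altman agreement analysis on log-transformed thresholds
#'
#' Assesses agreement between paired web and lab threshold measurements on
#' the log scale (appropriate when variability is proportional to magnitude).
#' Differences are `d_i = log(lab_i) - log(web_i)` (natural log); the antilog
#' of their mean is the mean ratio (lab/web; values above 1 mean larger
#' thresholds in the lab), and the antilogged `mean(d) +/- 1.96 SD(d)` are
#' the ratio-scale limits of agreement expected to contain ~95% of lab/web
#' ratios. A Shapiro–Wilk test checks the normality assumption on the log
#' differences; failure (p < 0.05) triggers a warning but the limits are
#' still reported, flagged.
#'
#' @param web,lab Positive paired threshold vectors (same length, >= 3 pairs).
#' @param z Multiplier for the limits of agreement (default 1.96).
#' @return A list of class `"bland_altman"`: `mean_ratio`, `loa_low`,
#'   `loa_high`, `mean_log_diff`, `sd_log_diff`, `shapiro_w`, `shapiro_p`,
#'   `normality_ok`, `n_pairs`, and `points` (tibble of per-pair `mean_log`,
#'   `diff_log` coordinates for plotting).
#' @export
bland_altman_log <- function(web, lab, z = 1.96) {
  stopifnot(length(web) == length(lab))
  if (length(web) < 3) stop("need at least 3 pairs", call. = FALSE)
  bad <- which(!(web > 0 & lab > 0))
  if (length(bad)) {
    stop("non-positive threshold in pair(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  d <- log(lab) - log(web)
  m <- mean(d); s <- stats::sd(d)
  # shapiro.test is defined for 3..5000 observations; degenerate or larger
  # samples skip the check (at n > 5000 any test of normality is moot anyway)
  sw <- if (length(unique(round(d, 12))) > 1 && length(d) <= 5000) {
    stats::shapiro.test(d)
  } else {
    list(statistic = NA_real_, p.value = NA_real_)
  }
  normality_ok <- !is.finite(sw$p.value) || sw$p.value >= 0.05
  if (is.finite(sw$p.value) && !normality_ok) {
    warning("log differences deviate from normality (Shapiro-Wilk p = ",
            signif(sw$p.value, 3), "); limits of agreement reported anyway",
            call. = FALSE)
  }
  structure(
    list(mean_ratio = exp(m),
         loa_low = exp(m - z * s), loa_high = exp(m + z * s),
         mean_log_diff = m, sd_log_diff = s,
         shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
         normality_ok = normality_ok, n_pairs = length(d),
         points = tibble::tibble(mean_log = (log(web) + log(lab)) / 2,
                                 diff_log = d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (log scale, n = %d): mean ratio (lab/web) %.3f, LoA [%.3f, %.3f]\n",
    x$n_pairs, x$mean_ratio, x$loa_low, x$loa_high))
  if (is.finite(x$shapiro_p)) {
    cat(sprintf("  Shapiro-Wilk on log differences: W = %.3f, p = %.3g%s\n",
                x$shapiro_w, x$shapiro_p,
                if (x$normality_ok) "" else " [violated]"))
  }
  invisible(x)
}

#' Median absolute ratio between paired measurements
#'
#' A scale-free typical-error metric: for each pair,
#' `r_i = exp(|log(lab_i) - log(web_i)|)`, the factor by which the two
#' measurements differ regardless of direction (always >= 1). Returns the
#' median and interquartile range across pairs.
#'
#' @inheritParams bland_altman_log
#' @return A list with `median`, `iqr`, and the per-pair `ratios`.
#' @export
median_absolute_ratio <- function(web, lab) {
  stopifnot(length(web) == length(lab), all(web > 0), all(lab > 0))
  r <- exp(abs(log(lab) - log(web)))
  list(median = stats::median(r), iqr = stats::IQR(r), ratios = r)
}

#' Check for learning effects between first and second sessions
#'
#' Computes the antilog of the mean of `log(threshold_first) -
#' log(threshold_second)` across all participant-conditions. A ratio near 1
#' indicates no order effect; a ratio above 1 means thresholds were higher
#' (worse) in whichever session a participant completed first, i.e.
#' performance improved with practice.
#'
#' @param thresholds Long threshold table containing both sessions with
#'   `session_order` recorded (1 = first, 2 = second).
#' @return A list with `ratio` (first/second, antilogged mean),
#'   `direction` (text convention), and `n_pairs`.
#' @export
learning_check <- function(thresholds) {
  need <- c("participant_id", "session", "session_order", "task",
            "standard_orientation_deg", "threshold")
  if (!all(need %in% names(thresholds)) || anyNA(thresholds$session_order)) {
    stop("threshold table must record session_order for both sessions",
         call. = FALSE)
  }
  keys <- c("participant_id", "task", "standard_orientation_deg")
  wide <- tidyr::pivot_wider(
    thresholds[, c(keys, "session_order", "threshold")],
    names_from = "session_order", values_from = "threshold",
    names_prefix = "s")
  if (!all(c("s1", "s2") %in% names(wide)) || anyNA(wide$s1) || anyNA(wide$s2)) {
    stop("each participant-condition needs thresholds for both session orders",
         call. = FALSE)
  }
  d <- log(wide$s1) - log(wide$s2)
  list(ratio = exp(mean(d)),
       direction = "ratio > 1: higher thresholds in the first session (improvement with practice)",
       n_pairs = length(d))
}

#' Minimum sample size for an ICC reliability study
#'
#' Walter–Eliasziw–Donner F-based minimum number of subjects needed to
#' distinguish an acceptable reliability `icc_null` from an expected
#' reliability `icc_alt` with `k_ratings` ratings per subject — the
#' computation underlying the standard reliability sample-size tables.
#' `alpha` is the (one-sided) significance level of the test of
#' `H0: ICC = icc_null` against `ICC > icc_null`, matching how those tables
#' are built. The result is rounded up to an integer.
#'
#' @param icc_null Acceptable (null) reliability, in `[0, 1)`.
#' @param icc_alt Expected (alternative) reliability, `> icc_null`, `< 1`.
#' @param k_ratings Ratings (sessions x conditions) per subject, `>= 2`.
#' @param alpha Significance level (one-sided).
#' @param power Target power.
#' @return Minimum number of subjects (integer).
#' @examples
#' sample_size_icc(0.50, 0.75, k_ratings = 8)  # 15
#' @export
sample_size_icc <- function(icc_null, icc_alt, k_ratings, alpha = 0.05,
                            power = 0.80) {
  if (!(icc_null >= 0 && icc_null < icc_alt && icc_alt < 1)) {
    stop("need 0 <= icc_null < icc_alt < 1 (power is unattainable otherwise)",
         call. = FALSE)
  }
  stopifnot(k_ratings >= 2, alpha > 0, alpha < 1, power > 0, power < 1)
  k <- k_ratings
  z_a <- stats::qnorm(1 - alpha)
  z_b <- stats::qnorm(power)
  c0 <- (1 + k * icc_null / (1 - icc_null)) /
    (1 + k * icc_alt / (1 - icc_alt))
  n <- 1 + 2 * (z_a + z_b)^2 * k / (log(c0)^2 * (k - 1))
  as.integer(ceiling(n))
}

#' Full web-vs-lab agreement analysis per task
#'
#' Runs the complete agreement battery on a two-session threshold table,
#' separately per task: ICC(2,1) with 95% CI on the raw thresholds (the 4
#' orientation conditions of each participant entering as separate subjects,
#' i.e. one threshold pair per participant x orientation), log-scale
#' Bland–Altman (mean ratio lab/web, limits of agreement, Shapiro–Wilk),
#' and the median absolute ratio with IQR.
#'
#' @param thresholds Long threshold table with `web` and `lab` sessions.
#' @param by `"task"` (default) to analyse each task separately, or
#'   `"pooled"` for one analysis over all conditions.
#' @return A tibble with one row per analysis unit and columns `task`,
#'   `n_pairs`, `icc`, `icc_low`, `icc_high`, `mean_ratio`, `loa_low`,
#'   `loa_high`, `median_abs_ratio`, `mar_iqr`, `shapiro_w`, `shapiro_p`,
#'   `normality_ok`.
#' @export
evaluate_agreement <- function(thresholds, by = c("task", "pooled")) {
  by <- match.arg(by)
  need <- c("participant_id", "session", "task", "standard_orientation_deg",
            "threshold")
  stopifnot(all(need %in% names(thresholds)))
  wide <- tidyr::pivot_wider(
    thresholds[, need],
    names_from = "session", values_from = "threshold")
  if (!all(c("web", "lab") %in% names(wide))) {
    stop("threshold table must contain both 'web' and 'lab' sessions",
         call. = FALSE)
  }
  if (anyNA(wide$web) || anyNA(wide$lab)) {
    miss <- wide[is.na(wide$web) | is.na(wide$lab), ]
    stop("missing session threshold for: ",
         paste(utils::head(paste(miss$participant_id, miss$task,
                                 miss$standard_orientation_deg, sep = "/"), 5),
               collapse = "; "), call. = FALSE)
  }
  groups <- if (by == "task") split(wide, wide$task) else list(pooled = wide)
  purrr::imap_dfr(groups, function(g, nm) {
    ic <- icc21(cbind(web = g$web, lab = g$lab))
    ba <- bland_altman_log(g$web, g$lab)
    mar <- median_absolute_ratio(g$web, g$lab)
    tibble::tibble(
      task = nm, n_pairs = nrow(g),
      icc = ic$estimate, icc_low = ic$ci_low, icc_high = ic$ci_high,
      mean_ratio = ba$mean_ratio, loa_low = ba$loa_low, loa_high = ba$loa_high,
      median_abs_ratio = mar$median, mar_iqr = mar$iqr,
      shapiro_w = ba$shapiro_w, shapiro_p = ba$shapiro_p,
      normality_ok = ba$normality_ok
    )
  })
}
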