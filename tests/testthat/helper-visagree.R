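# Shared fixtures, all built in code.

cardinal_offsets <- c(0.71, 1.43, 2.14, 2.86, 3.57, 4.29, 5.00)
oblique_offsets <- c(3.57, 7.14, 10.70, 14.29, 17.80, 21.42, 25.00)

# noiseless samples of the increasing logistic at given offsets
noiseless_psych_data <- function(a, slope, offsets = cardinal_offsets) {
  tibble::tibble(offset_deg = offsets,
                 pct_correct = 50 + 50 / (1 + exp(-(offsets - a) / slope)))
}

# a balanced 2x4 threshold table with log-normal cells
random_threshold_table <- function(n = 6, sd_log = 0.3,
                                   tasks = c("temporal", "spatial"),
                                   orients = c(-45, 0, 45, 90),
                                   session = "web") {
  tab <- tidyr::expand_grid(participant_id = sprintf("P%02d", seq_len(n)),
                            task = tasks, standard_orientation_deg = orients)
  mu <- log(ifelse(tab$standard_orientation_deg %% 90 == 0, 1.5, 7)) +
    ifelse(tab$task == "temporal", -0.2, 0.2)
  tab$threshold <- exp(stats::rnorm(nrow(tab), mu, sd_log))
  tab$session <- session
  tab$session_order <- 1L
  tab
}

# brute-force sums of squares for the balanced two-way within design,
# written as explicit loops so it shares nothing with rm_anova()
anova_ss_oracle <- function(tab) {
  ids <- sort(unique(tab$participant_id))
  tasks <- sort(unique(tab$task))
  orients <- sort(unique(tab$standard_orientation_deg))
  n <- length(ids); tk <- length(tasks); ok <- length(orients)
  y <- array(NA_real_, c(n, tk, ok))
  for (r in seq_len(nrow(tab))) {
    y[match(tab$participant_id[r], ids), match(tab$task[r], tasks),
      match(tab$standard_orientation_deg[r], orients)] <- tab$threshold[r]
  }
  g <- mean(y)
  ss <- list(subject = 0, task = 0, orientation = 0, interaction = 0,
             task_err = 0, orientation_err = 0, total = 0)
  for (i in seq_len(n)) ss$subject <- ss$subject + tk * ok * (mean(y[i, , ]) - g)^2
  for (t in seq_len(tk)) ss$task <- ss$task + n * ok * (mean(y[, t, ]) - g)^2
  for (o in seq_len(ok)) ss$orientation <- ss$orientation + n * tk * (mean(y[, , o]) - g)^2
  for (t in seq_len(tk)) for (o in seq_len(ok)) {
    ss$interaction <- ss$interaction +
      n * (mean(y[, t, o]) - mean(y[, t, ]) - mean(y[, , o]) + g)^2
  }
  for (i in seq_len(n)) for (t in seq_len(tk)) {
    ss$task_err <- ss$task_err +
      ok * (mean(y[i, t, ]) - mean(y[i, , ]) - mean(y[, t, ]) + g)^2
  }
  for (i in seq_len(n)) for (o in seq_len(ok)) {
    ss$orientation_err <- ss$orientation_err +
      tk * (mean(y[i, , o]) - mean(y[i, , ]) - mean(y[, , o]) + g)^2
  }
  ss$total <- sum((y - g)^2)
  ss$interaction_err <- ss$total - ss$subject - ss$task - ss$orientation -
    ss$interaction - ss$task_err - ss$orientation_err
  ss
}

# direct mean squares for the n x k two-way (subjects x raters) layout,
# via explicit loops
icc_ms_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x); g <- mean(x)
  ssr <- ssc <- sse <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(x[i, ]) - g)^2
  for (j in seq_len(k)) ssc <- ssc + n * (mean(x[, j]) - g)^2
  for (i in seq_len(n)) for (j in seq_len(k)) {
    sse <- sse + (x[i, j] - mean(x[i, ]) - mean(x[, j]) + g)^2
  }
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)))
}

# two-session table of drawn (not fitted) log thresholds for one condition
draw_log_threshold_pairs <- function(n, icc, seed) {
  cfg <- design_config(tasks = "temporal", standard_orientations = 0)
  pop <- observer_population(n, icc = icc)
  tab <- draw_population(pop, cfg, seed = seed)
  wide <- tidyr::pivot_wider(
    tab[, c("participant_id", "session", "threshold_true")],
    names_from = "session", values_from = "threshold_true")
  log(cbind(web = wide$web, lab = wide$lab))
}
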