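#' Two-way repeated-measures ANOVA on a threshold table
#'
#' Classical within-subjects decomposition for the balanced 2 (task) x 4
#' (orientation) design: sums of squares for subjects, each main effect, the
#' interaction, and the matching subject-by-effect error strata. Each within
#' effect gets a Mauchly sphericity test and a Greenhouse–Geisser epsilon
#' computed from the orthonormal-contrast covariance matrix of the
#' subject-level data; `p_reported` uses the Greenhouse–Geisser-corrected
#' degrees of freedom when Mauchly's test rejects sphericity at
#' `sphericity_alpha` and the uncorrected ones otherwise (both p values are
#' always retained). Effect size is partial eta squared,
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param thresholds Long threshold table (see [fit_thresholds()]) with
#'   columns `participant_id`, `task`, `standard_orientation_deg`,
#'   `threshold`; one row per cell.
#' @param session Optional session label to filter on (e.g. `"web"`); `NULL`
#'   uses the table as given.
#' @param sphericity_alpha Significance level of Mauchly's test that triggers
#'   the Greenhouse–Geisser correction.
#' @return An object of class `"rm_anova"`: a list with `effects` (tibble:
#'   one row per effect with `ss`, `df`, `ms`, `ss_error`, `df_error`,
#'   `ms_error`, `F`, `p_uncorrected`, `gg_epsilon`, `df_corrected`,
#'   `df_error_corrected`, `p_gg`, `p_reported`, `peta2`), `mauchly` (tibble
#'   with `W`, `chisq`, `df`, `p` per within effect), `ss_subject`,
#'   `ss_total`, `n`, and the cell means.
#' @export
rm_anova <- function(thresholds, session = NULL, sphericity_alpha = 0.05) {
  tab <- thresholds
  if (!is.null(session)) tab <- tab[tab$session == session, ]
  need <- c("participant_id", "task", "standard_orientation_deg", "threshold")
  if (!all(need %in% names(tab))) {
    stop("threshold table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tasks <- sort(unique(tab$task))
  orients <- sort(unique(tab$standard_orientation_deg))
  ids <- sort(unique(tab$participant_id))
  n <- length(ids); t_k <- length(tasks); o_k <- length(orients)

  full <- tidyr::expand_grid(participant_id = ids, task = tasks,
                             standard_orientation_deg = orients)
  merged <- dplyr::left_join(full, tab,
                             by = c("participant_id", "task",
                                    "standard_orientation_deg"))
  if (anyNA(merged$threshold)) {
    miss <- merged[is.na(merged$threshold),
                   c("participant_id", "task", "standard_orientation_deg")]
    stop("unbalanced design; missing cells: ",
         paste(utils::head(apply(miss, 1, paste, collapse = "/"), 10),
               collapse = "; "), call. = FALSE)
  }
  if (nrow(tab) != n * t_k * o_k) {
    stop("duplicate rows per (participant, task, orientation) cell",
         call. = FALSE)
  }

  # cell matrix, columns task-major then orientation
  merged <- dplyr::arrange(merged, .data$participant_id, .data$task,
                           .data$standard_orientation_deg)
  Y <- matrix(merged$threshold, nrow = n, byrow = TRUE)
  grand <- mean(Y)
  m_subj <- rowMeans(Y)
  cell_means <- colMeans(Y)
  M <- matrix(cell_means, nrow = t_k, byrow = TRUE,
              dimnames = list(tasks, orients))
  m_task <- rowMeans(M)
  m_orient <- colMeans(M)

  ss_subject <- t_k * o_k * sum((m_subj - grand)^2)
  ss_task <- n * o_k * sum((m_task - grand)^2)
  ss_orient <- n * t_k * sum((m_orient - grand)^2)
  inter_dev <- sweep(sweep(M, 1, m_task), 2, m_orient) + grand
  ss_inter <- n * sum(inter_dev^2)

  # subject x task means (averaged over orientation), etc.
  subj_task <- t(sapply(seq_len(n), function(i)
    rowMeans(matrix(Y[i, ], nrow = t_k, byrow = TRUE))))
  subj_orient <- t(sapply(seq_len(n), function(i)
    colMeans(matrix(Y[i, ], nrow = t_k, byrow = TRUE))))
  # subject-by-effect interaction strata: sum over (y_it - y_i. - y_.t + y_..)^2
  ss_task_err <- o_k * sum((sweep(sweep(subj_task, 1, m_subj), 2, m_task) + grand)^2)
  ss_orient_err <- t_k * sum((sweep(sweep(subj_orient, 1, m_subj), 2, m_orient) + grand)^2)
  ss_total <- sum((Y - grand)^2)
  ss_inter_err <- ss_total - ss_subject - ss_task - ss_orient - ss_inter -
    ss_task_err - ss_orient_err

  dfs <- list(task = t_k - 1, orientation = o_k - 1,
              interaction = (t_k - 1) * (o_k - 1))
  df_err <- list(task = (n - 1) * (t_k - 1),
                 orientation = (n - 1) * (o_k - 1),
                 interaction = (n - 1) * (t_k - 1) * (o_k - 1))
  sss <- list(task = ss_task, orientation = ss_orient, interaction = ss_inter)
  sse <- list(task = ss_task_err, orientation = ss_orient_err,
              interaction = ss_inter_err)

  # orthonormal contrast projections for sphericity diagnostics
  proj <- list(
    task = kronecker(orth_contrasts(t_k), matrix(1 / o_k, o_k, 1)),
    orientation = kronecker(matrix(1 / t_k, t_k, 1), orth_contrasts(o_k)),
    interaction = kronecker(orth_contrasts(t_k), orth_contrasts(o_k))
  )

  effects <- purrr::map_dfr(c("task", "orientation", "interaction"), function(e) {
    D <- Y %*% proj[[e]]
    d <- ncol(D)
    S <- stats::cov(D)
    eps <- gg_epsilon(S)
    mau <- mauchly_from_cov(S, n)
    Fval <- (sss[[e]] / dfs[[e]]) / (sse[[e]] / df_err[[e]])
    p_unc <- stats::pf(Fval, dfs[[e]], df_err[[e]], lower.tail = FALSE)
    p_gg <- stats::pf(Fval, eps * dfs[[e]], eps * df_err[[e]], lower.tail = FALSE)
    corrected <- is.finite(mau$p) && mau$p < sphericity_alpha
    tibble::tibble(
      effect = e, ss = sss[[e]], df = dfs[[e]], ms = sss[[e]] / dfs[[e]],
      ss_error = sse[[e]], df_error = df_err[[e]],
      ms_error = sse[[e]] / df_err[[e]],
      F = Fval, p_uncorrected = p_unc,
      gg_epsilon = eps, df_corrected = eps * dfs[[e]],
      df_error_corrected = eps * df_err[[e]], p_gg = p_gg,
      sphericity_violated = corrected,
      p_reported = if (corrected) p_gg else p_unc,
      peta2 = sss[[e]] / (sss[[e]] + sse[[e]]),
      mauchly_W = mau$W, mauchly_chisq = mau$chisq,
      mauchly_df = mau$df, mauchly_p = mau$p
    )
  })

  structure(
    list(effects = effects,
         mauchly = effects[, c("effect", "mauchly_W", "mauchly_chisq",
                               "mauchly_df", "mauchly_p")],
         ss_subject = ss_subject, df_subject = n - 1,
         ss_total = ss_total, n = n,
         cell_means = M),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (", x$n, " participants)\n", sep = "")
  e <- x$effects
  for (i in seq_len(nrow(e))) {
    cat(sprintf(
      "  %-12s F(%.2f, %.2f) = %.2f, p = %.3g, partial eta2 = %.2f%s\n",
      e$effect[i],
      if (e$sphericity_violated[i]) e$df_corrected[i] else e$df[i],
      if (e$sphericity_violated[i]) e$df_error_corrected[i] else e$df_error[i],
      e$F[i], e$p_reported[i], e$peta2[i],
      if (e$sphericity_violated[i]) " [GG-corrected]" else ""))
  }
  invisible(x)
}

# orthonormal polynomial-free contrasts (normalised Helmert), k x (k-1)
orth_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

# Greenhouse-Geisser epsilon from the contrast-projected covariance
gg_epsilon <- function(S) {
  d <- ncol(S)
  if (d == 1) return(1)
  eps <- sum(diag(S))^2 / (d * sum(S^2))
  min(max(eps, 1 / d), 1)
}

# Mauchly's W and its chi-square approximation from the projected covariance
mauchly_from_cov <- function(S, n) {
  d <- ncol(S)
  if (d == 1) return(list(W = 1, chisq = 0, df = 0, p = 1))
  df <- d * (d + 1) / 2 - 1
  if (n - 1 < d) {
    # singular covariance: W undefined; flag and let epsilon carry the burden
    return(list(W = NA_real_, chisq = NA_real_, df = df, p = NA_real_))
  }
  W <- det(S) / (sum(diag(S)) / d)^d
  f <- 1 - (2 * d^2 + d + 2) / (6 * d * (n - 1))
  chisq <- -(n - 1) * f * log(W)
  list(W = W, chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Mauchly's test of sphericity for a within-subject factor
#'
#' Tests whether the variances of all pairwise level differences are equal,
#' the assumption under which uncorrected repeated-measures F tests are
#' exact. Operates on the n x k matrix of subject-by-level scores. A factor
#' with two levels has a single difference, so sphericity holds trivially
#' (`W = 1, p = 1`).
#'
#' @param Y Numeric matrix, subjects in rows, factor levels in columns.
#' @return A list with `W`, `chisq`, `df`, `p`, and `gg_epsilon` for the
#'   factor.
#' @export
mauchly_test <- function(Y) {
  Y <- as.matrix(Y)
  k <- ncol(Y)
  if (k < 2) stop("factor needs at least 2 levels", call. = FALSE)
  D <- Y %*% orth_contrasts(k)
  S <- stats::cov(D)
  out <- mauchly_from_cov(S, nrow(Y))
  out$gg_epsilon <- gg_epsilon(S)
  out
}

#' Bonferroni-corrected paired comparisons with effect sizes
#'
#' Paired t tests between condition cells of a threshold table, with p values
#' multiplied by the number of comparisons (capped at 1). Cells are labelled
#' `"task:orientation"`. Two Cohen's d conventions are reported: `d_av`, the
#' mean difference divided by the average of the two condition SDs (the
#' default headline value), and `d_z`, the mean difference divided by the SD
#' of the paired differences. Zero-variance differences leave the effect size
#' undefined (`NA`) with a flag.
#'
#' @param thresholds Long threshold table.
#' @param comparisons List of length-2 character vectors of cell labels, e.g.
#'   `list(c("temporal:0", "spatial:0"))`; `NULL` compares all task pairs at
#'   matched orientation plus all orientation pairs within task.
#' @param session Optional session filter.
#' @param m Number of comparisons for the Bonferroni factor; defaults to
#'   `length(comparisons)`.
#' @return Tibble: one row per comparison with `t`, `df`, `p`, `p_adjusted`,
#'   `mean_diff`, `d_av`, `d_z`, `degenerate`.
#' @export
pairwise_bonferroni <- function(thresholds, comparisons = NULL, session = NULL,
                                m = NULL) {
  tab <- thresholds
  if (!is.null(session)) tab <- tab[tab$session == session, ]
  tab$cell <- paste(tab$task, tab$standard_orientation_deg, sep = ":")
  cells <- unique(tab$cell)
  if (is.null(comparisons)) {
    prs <- utils::combn(sort(cells), 2, simplify = FALSE)
    keep <- purrr::map_lgl(prs, function(p) {
      a <- strsplit(p[1], ":")[[1]]; b <- strsplit(p[2], ":")[[1]]
      a[1] == b[1] || a[2] == b[2]   # same task or same orientation
    })
    comparisons <- prs[keep]
  }
  m <- m %||% length(comparisons)
  wide <- tidyr::pivot_wider(tab[, c("participant_id", "cell", "threshold")],
                             names_from = "cell", values_from = "threshold")
  purrr::map_dfr(comparisons, function(pr) {
    if (!all(pr %in% names(wide))) {
      stop("unknown cell label(s): ",
           paste(setdiff(pr, names(wide)), collapse = ", "), call. = FALSE)
    }
    x <- wide[[pr[1]]]; y <- wide[[pr[2]]]
    diffs <- x - y
    sd_d <- stats::sd(diffs)
    degenerate <- sd_d == 0
    if (degenerate && mean(diffs) == 0) {
      tt <- list(statistic = 0, parameter = length(diffs) - 1, p.value = 1)
    } else {
      tt <- stats::t.test(x, y, paired = TRUE)
    }
    sd_av <- (stats::sd(x) + stats::sd(y)) / 2
    tibble::tibble(
      comparison = paste(pr[1], "vs", pr[2]),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, p_adjusted = min(tt$p.value * m, 1),
      mean_diff = mean(diffs),
      d_av = if (sd_av > 0) mean(diffs) / sd_av else NA_real_,
      d_z = if (!degenerate) mean(diffs) / sd_d else if (mean(diffs) == 0) 0 else NA_real_,
      degenerate = degenerate
    )
  })
}
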