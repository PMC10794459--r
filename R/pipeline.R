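#' Run a complete synthetic reliability study
#'
#' End-to-end convenience wrapper: draws a synthetic population, simulates
#' every trial of the constant-stimuli design for the requested sessions,
#' collates and fits psychometric functions, applies the 75%-correct
#' exclusion rule, and (when both sessions are present) runs the group
#' ANOVA, agreement battery and learning check.
#'
#' @param n_participants Number of simulated participants.
#' @param icc True single-condition ICC of the generative model.
#' @param sessions `c("web", "lab")` for a reliability study, `"web"` for the
#'   web-only group experiment.
#' @param seed Master integer seed; every stage derives its stream from it.
#' @param config A [design_config()].
#' @param popcfg An [observer_population()]; overrides `n_participants`/`icc`
#'   when given.
#' @param exclude Apply the exclusion rule before inference (default TRUE).
#' @param keep_trials Keep the (large) trial table in the result.
#' @return A list of class `"visagree_study"`: `population`, `thresholds`
#'   (post-exclusion), `thresholds_all`, `exclusion`, and — where computable —
#'   `anova` (web session), `agreement`, `learning`; plus `trials` if
#'   `keep_trials`.
#' @export
run_synthetic_study <- function(n_participants = 18, icc = 0.9,
                                sessions = c("web", "lab"), seed = NULL,
                                config = design_config(), popcfg = NULL,
                                exclude = TRUE, keep_trials = FALSE) {
  popcfg <- popcfg %||% observer_population(n_participants, icc = icc)
  sim <- simulate_study(popcfg, config, sessions, seed = seed)
  thresholds_all <- fit_thresholds(sim$trials)
  excl <- apply_exclusion(thresholds_all)
  thresholds <- if (exclude) {
    thresholds_all[thresholds_all$participant_id %in% excl$included, ]
  } else {
    thresholds_all
  }
  out <- list(population = sim$population,
              thresholds = thresholds,
              thresholds_all = thresholds_all,
              exclusion = excl,
              seed = seed, config = config, popcfg = popcfg)
  if (keep_trials) out$trials <- sim$trials

  web <- thresholds[thresholds$session == "web", ]
  if (nrow(web) > 0 && length(unique(web$participant_id)) >= 3) {
    out$anova <- tryCatch(rm_anova(web), error = function(e) NULL)
  }
  if (all(c("web", "lab") %in% sessions)) {
    both <- thresholds
    ok_ids <- names(which(table(unique(both[, c("participant_id", "session")])$participant_id) == 2))
    both <- both[both$participant_id %in% ok_ids, ]
    if (length(ok_ids) >= 3) {
      out$agreement <- tryCatch(evaluate_agreement(both), error = function(e) NULL)
      out$learning <- tryCatch(learning_check(both), error = function(e) NULL)
    }
  }
  structure(out, class = "visagree_study")
}

#' @export
print.visagree_study <- function(x, ...) {
  cat("<visagree_study>\n")
  cat("  participants:", length(unique(x$thresholds_all$participant_id)),
      "(", length(x$exclusion$excluded), "excluded )\n")
  cat("  sessions:    ", paste(unique(x$thresholds_all$session), collapse = ", "), "\n")
  if (!is.null(x$anova)) {
    cat("  web ANOVA:\n")
    print(x$anova)
  }
  if (!is.null(x$agreement)) {
    ag <- x$agreement
    for (i in seq_len(nrow(ag))) {
      cat(sprintf("  %s: ICC(2,1) %.2f [%.2f, %.2f], mean ratio %.2f, LoA [%.2f, %.2f]\n",
                  ag$task[i], ag$icc[i], ag$icc_low[i], ag$icc_high[i],
                  ag$mean_ratio[i], ag$loa_low[i], ag$loa_high[i]))
    }
  }
  invisible(x)
}
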