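test_that("collation pools runs and signs into per-level counts", {
  cfg <- design_config()
  obs <- tibble::tibble(participant_id = "P01", session = "web",
                        session_order = 1L, task = "temporal",
                        standard_orientation_deg = 0,
                        threshold_true = 2, slope_true = 0.6)
  sched <- build_trial_schedule(cfg, "temporal", 0, n_runs = 5, seed = 31)
  trials <- simulate_responses(obs, sched, seed = 32)
  col <- collate_trials(trials)
  expect_equal(nrow(col), 7)
  expect_true(all(col$n_trials == 50))    # 5 runs x 10 repeats
  expect_equal(col$offset_deg, cardinal_offsets)

  one_run <- collate_trials(trials[trials$run_index == 1, ])
  expect_true(all(one_run$n_trials == 10))

  all_right <- dplyr::mutate(trials, correct = TRUE,
                             response = standard_position)
  expect_true(all(collate_trials(all_right)$pct_correct == 100))

  expect_error(collate_trials(trials[0, ]), "no trials")
  expect_error(collate_trials(sched), "NA")
})

test_that("noiseless logistic data are recovered exactly and hit 75 at a", {
  for (a in c(1.8, 2.5, 4.2)) {
    d <- noiseless_psych_data(a, slope = 0.8)
    f <- fit_logistic(d)
    expect_true(f$converged)
    expect_equal(f$a, a, tolerance = 1e-6)
    expect_equal(f$slope_mag, 0.8, tolerance = 1e-5)
    expect_lt(f$b, 0)   # printed-form slope sign
    # the defining property of the threshold
    expect_equal(logistic_pct(f$a, f$a, f$b), 75, tolerance = 1e-9)
    expect_equal(unname(predict(f, tibble::tibble(offset_deg = f$a))), 75,
                 tolerance = 1e-9)
  }
})

test_that("threshold estimation is scale-equivariant and order-invariant", {
  withr::with_seed(77, {
    k <- rbinom(7, 50, p_correct(cardinal_offsets, 2.5, 0.75))
  })
  d <- tibble::tibble(offset_deg = cardinal_offsets, n_trials = 50,
                      pct_correct = 100 * k / 50)
  f <- fit_logistic(d)
  for (c_scale in c(0.5, 4)) {
    fs <- fit_logistic(dplyr::mutate(d, offset_deg = offset_deg * c_scale))
    expect_equal(fs$a, c_scale * f$a, tolerance = 1e-4)
    expect_equal(fs$slope_mag, c_scale * f$slope_mag, tolerance = 1e-4)
  }
  shuffled <- withr::with_seed(3, d[sample(7), ])
  expect_equal(fit_logistic(shuffled)$a, f$a, tolerance = 1e-10)
})

test_that("the optimiser beats a dense grid search on random datasets", {
  rss_of <- function(a, beta, x, y) {
    sum((y - (50 + 50 / (1 + exp(-(x - a) / beta))))^2)
  }
  withr::with_seed(123, {
    for (rep in 1:20) {
      a_true <- runif(1, 1, 4.5)
      b_true <- runif(1, 0.3, 1.5)
      k <- rbinom(7, 25, p_correct(cardinal_offsets, a_true, b_true))
      d <- tibble::tibble(offset_deg = cardinal_offsets,
                          pct_correct = 100 * k / 25)
      f <- fit_logistic(d)
      expect_true(f$converged)
      grid <- expand.grid(a = seq(0.1, 6, length.out = 60),
                          beta = seq(0.05, 3, length.out = 60))
      best <- min(mapply(rss_of, grid$a, grid$beta,
                         MoreArgs = list(x = d$offset_deg, y = d$pct_correct)))
      expect_lte(f$rss, best + 1e-8)
    }
  })
})

test_that("threshold SE is calibrated for binomial sampling noise", {
  # binomial trials at the design's per-level count; the +/- 2 SE interval
  # should cover the generating threshold in the vast majority of replicates
  withr::with_seed(202, {
    hits <- replicate(1500, {
      k <- rbinom(7, 50, p_correct(oblique_offsets, 10, 3))
      f <- fit_logistic(tibble::tibble(offset_deg = oblique_offsets,
                                       n_trials = 50,
                                       pct_correct = 100 * k / 50))
      f$converged && is.finite(f$se_threshold) &&
        abs(f$a - 10) <= 2 * f$se_threshold
    })
    expect_gte(mean(hits), 0.93)
  })
})

test_that("degenerate inputs are rejected or flagged, never fatal", {
  expect_error(fit_logistic(noiseless_psych_data(2, 0.5)[1:2, ]),
               "at least 3")
  bad <- noiseless_psych_data(2, 0.5)
  bad$pct_correct[3] <- NaN
  expect_error(fit_logistic(bad), "non-finite")
  # flat data: fit must return rather than raise, flagged appropriately
  flat <- tibble::tibble(offset_deg = cardinal_offsets,
                         pct_correct = rep(50, 7))
  f <- fit_logistic(flat)
  expect_s3_class(f, "psychometric_fit")
  expect_false(f$reached_threshold)
})

test_that("bootstrap SE is close to the asymptotic SE on well-behaved data", {
  withr::with_seed(55, {
    k <- rbinom(7, 50, p_correct(oblique_offsets, 10, 3))
  })
  d <- tibble::tibble(offset_deg = oblique_offsets, n_trials = 50,
                      pct_correct = 100 * k / 50)
  f <- fit_logistic(d)
  se_b <- bootstrap_se(f, n_boot = 100, seed = 8)
  expect_gt(se_b, 0.2 * f$se_threshold)
  expect_lt(se_b, 5 * f$se_threshold)
})

test_that("the exclusion rule flags participants that never reach 75%", {
  cfg <- design_config()
  pop <- observer_population(2, icc = 0.9)
  sim <- simulate_study(pop, cfg, sessions = "web", seed = 61)
  thr <- fit_thresholds(sim$trials)
  res <- apply_exclusion(thr)
  expect_setequal(c(res$included, res$excluded), c("P01", "P02"))

  # force one condition of P01 to chance: all proportions below 75
  chance <- thr
  bad_rows <- chance$participant_id == "P01" & chance$task == "temporal" &
    chance$standard_orientation_deg == 0
  chance$max_pct[bad_rows] <- 60
  res2 <- apply_exclusion(chance)
  expect_true("P01" %in% res2$excluded)
  expect_true(any(res2$report$participant_id == "P01" &
                    res2$report$task == "temporal" &
                    res2$report$standard_orientation_deg == 0))

  # an observer whose oblique threshold lies beyond the largest offset
  far <- tibble::tibble(participant_id = "P99", session = "web",
                        session_order = 1L, task = "spatial",
                        standard_orientation_deg = 45,
                        threshold_true = 60, slope_true = 18)
  sched <- build_trial_schedule(cfg, "spatial", 45, participant_id = "P99",
                                seed = 62)
  thr_far <- fit_thresholds(simulate_responses(far, sched, seed = 63))
  res3 <- apply_exclusion(thr_far)
  expect_true("P99" %in% res3$excluded)
  expect_true(any(res3$report$standard_orientation_deg == 45 &
                    res3$report$participant_id == "P99"))
  # missing conditions are failures, not silent passes
  expect_true(any(res3$report$reason == "condition missing"))
})

test_that("full-loop parameter recovery stays within 15% median error", {
  study <- run_synthetic_study(10, sessions = "web", seed = 303,
                               exclude = FALSE)
  merged <- dplyr::inner_join(
    study$thresholds_all, study$population,
    by = c("participant_id", "session", "task", "standard_orientation_deg"))
  ok <- merged$converged
  expect_gt(mean(ok), 0.95)
  rel_err <- abs(merged$threshold[ok] - merged$threshold_true[ok]) /
    merged$threshold_true[ok]
  expect_lt(median(rel_err), 0.15)
})
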