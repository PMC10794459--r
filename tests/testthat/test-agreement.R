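test_that("ICC(2,1) recovers perfect, null, and hand-checked agreement", {
  # identical columns over heterogeneous rows: perfect agreement
  x <- cbind(c(1, 3, 7, 2, 9), c(1, 3, 7, 2, 9))
  expect_equal(icc21(x)$estimate, 1)

  # independent noise: ICC near zero
  withr::with_seed(13, {
    z <- cbind(rnorm(500), rnorm(500))
    expect_lt(abs(icc21(z)$estimate), 0.1)
  })

  # 6 x 2 matrix against the direct mean-squares oracle and a fixed
  # reference computed independently for this exact matrix
  m <- matrix(c(4.2, 3.9, 6.1, 6.5, 1.2, 1.4, 8.0, 7.1, 2.5, 2.9, 5.0, 5.6),
              ncol = 2, byrow = TRUE)
  r <- icc21(m)
  ms <- icc_ms_oracle(m)
  expect_equal(r$msr, ms$msr, tolerance = 1e-12)
  expect_equal(r$msc, ms$msc, tolerance = 1e-12)
  expect_equal(r$mse, ms$mse, tolerance = 1e-12)
  direct <- (ms$msr - ms$mse) /
    (ms$msr + (2 - 1) * ms$mse + 2 * (ms$msc - ms$mse) / 6)
  expect_equal(r$estimate, direct, tolerance = 1e-12)
  expect_equal(r$estimate, 0.975124378109453, tolerance = 1e-12)
  expect_equal(r$ci_low, 0.8377750456, tolerance = 1e-8)
  expect_equal(r$ci_high, 0.9964731864, tolerance = 1e-8)

  expect_error(icc21(rbind(c(1, NA), c(2, 3))), "missing")
  expect_error(icc21(matrix(1:2, 1, 2)), "at least 2")
})

test_that("ICC point estimates and CIs recover the generative reliability", {
  withr::with_seed(97, {
    for (true_icc in c(0.5, 0.75, 0.9)) {
      res <- t(replicate(120, {
        S <- rnorm(30, 0, sqrt(true_icc))
        x <- S + matrix(rnorm(60, 0, sqrt(1 - true_icc)), 30, 2)
        r <- icc21(x)
        c(est = r$estimate, covered = r$ci_low <= true_icc & true_icc <= r$ci_high)
      }))
      expect_lt(abs(mean(res[, "est"]) - true_icc), 0.07)
      expect_gte(mean(res[, "covered"]), 0.9)
    }
  })
})

test_that("log Bland-Altman reports ratios with the lab/web orientation", {
  web <- c(2, 4, 1.5, 6, 3)
  # identity: ratio 1, degenerate limits
  ba <- bland_altman_log(web, web)
  expect_equal(ba$mean_ratio, 1)
  expect_equal(ba$loa_low, 1)
  expect_equal(ba$loa_high, 1)

  # doubled lab thresholds: ratio exactly 2 (values > 1 mean lab larger)
  ba2 <- bland_altman_log(web, 2 * web)
  expect_equal(ba2$mean_ratio, 2)

  # scale invariance: common rescaling changes nothing
  withr::with_seed(19, {
    lab <- web * exp(rnorm(5, 0, 0.2))
    a <- bland_altman_log(web, lab)
    b <- bland_altman_log(10 * web, 10 * lab)
    expect_equal(a$mean_ratio, b$mean_ratio)
    expect_equal(a$loa_low, b$loa_low)
    expect_equal(a$loa_high, b$loa_high)
    # swapping labels inverts the ratio and swaps/inverts the limits
    sw <- bland_altman_log(lab, web)
    expect_equal(sw$mean_ratio, 1 / a$mean_ratio)
    expect_equal(sw$loa_low, 1 / a$loa_high)
    expect_equal(sw$loa_high, 1 / a$loa_low)
  })

  expect_error(bland_altman_log(c(1, 2), c(1, 2)), "at least 3")
  expect_error(bland_altman_log(c(1, -2, 3), c(1, 2, 3)), "pair")
})

test_that("limits of agreement contain ~95% of pairs under Gaussian noise", {
  withr::with_seed(23, {
    web <- exp(rnorm(1e4, log(3), 0.5))
    lab <- web * exp(rnorm(1e4, 0, 0.25))
    ba <- bland_altman_log(web, lab)
    ratio <- lab / web
    inside <- mean(ratio >= ba$loa_low & ratio <= ba$loa_high)
    expect_lt(abs(inside - 0.95), 0.01)
  })
})

test_that("non-normal log differences warn but still report limits", {
  withr::with_seed(29, {
    web <- exp(rnorm(50, 1, 0.3))
    lab <- web * exp(rexp(50) - 0.3)   # strongly skewed differences
    expect_warning(ba <- bland_altman_log(web, lab), "normality")
    expect_false(ba$normality_ok)
    expect_true(is.finite(ba$loa_low) && is.finite(ba$loa_high))
  })
})

test_that("median absolute ratio is a symmetric error metric at least 1", {
  web <- c(2, 4, 1.5, 6)
  mar <- median_absolute_ratio(web, web)
  expect_equal(mar$median, 1)
  expect_equal(mar$iqr, 0)

  # reciprocal ratios fold onto the same absolute ratio
  mar2 <- median_absolute_ratio(c(1, 1, 1, 1), c(2, 0.5, 2, 0.5))
  expect_equal(mar2$median, 2)
  expect_equal(mar2$iqr, 0)
  expect_true(all(mar2$ratios >= 1))

  # Monte-Carlo check against the closed form for Gaussian log noise:
  # |d| ~ half-normal, median exp(sigma * sqrt(2) * qnorm(0.75))
  withr::with_seed(31, {
    n <- 1e4
    web <- exp(rnorm(n, 0, 0.2))
    lab <- exp(rnorm(n, 0, 0.2))
    mar3 <- median_absolute_ratio(web, lab)
    expect_equal(mar3$median, exp(0.2 * sqrt(2) * qnorm(0.75)),
                 tolerance = 0.02)
  })
})

test_that("learning check returns first/second ratios under its convention", {
  pop <- observer_population(18, icc = 0.9)
  tab <- draw_population(pop, seed = 83)
  tab$threshold <- tab$threshold_true
  lc <- learning_check(tab)
  expect_equal(lc$n_pairs, 18 * 8)
  expect_lt(abs(lc$ratio - 1), 0.1)
  # across replicates the null order-effect ratio centres tightly on 1
  ratios <- vapply(1:20, function(r) {
    t2 <- draw_population(pop, seed = 830 + r)
    t2$threshold <- t2$threshold_true
    learning_check(t2)$ratio
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.02)

  # 20% second-session improvement: first/second ratio 1/0.8 = 1.25
  pop_l <- observer_population(30, sigma_subject = 0.3, sigma_session = 0,
                               sigma_resid = 0, learning_gain = 0.8)
  tab_l <- draw_population(pop_l, seed = 89)
  tab_l$threshold <- tab_l$threshold_true
  expect_equal(learning_check(tab_l)$ratio, 1.25, tolerance = 1e-10)

  # identical sessions: exactly 1
  pop_0 <- observer_population(10, sigma_subject = 0.3, sigma_session = 0,
                               sigma_resid = 0)
  tab_0 <- draw_population(pop_0, seed = 97)
  tab_0$threshold <- tab_0$threshold_true
  expect_equal(learning_check(tab_0)$ratio, 1)

  no_order <- dplyr::mutate(tab, session_order = NA_integer_)
  expect_error(learning_check(no_order), "session_order")
})

test_that("the reliability sample-size planner matches its F-based formula", {
  expect_identical(sample_size_icc(0.50, 0.75, k_ratings = 8), 15L)
  # more ratings never demand more subjects
  ns <- vapply(2:10, function(k) sample_size_icc(0.50, 0.75, k), integer(1))
  expect_true(all(diff(ns) <= 0))
  expect_error(sample_size_icc(0.8, 0.5, 2), "unattainable")
  expect_error(sample_size_icc(0.5, 0.5, 2), "unattainable")

  # Monte-Carlo power oracle: at the returned n, a one-sided test of
  # ICC <= icc_null (via the matching-level CI bound) rejects in >= 80%
  n_req <- sample_size_icc(0.2, 0.8, k_ratings = 3)
  withr::with_seed(101, {
    rej <- replicate(300, {
      S <- rnorm(n_req, 0, sqrt(0.8))
      x <- S + matrix(rnorm(n_req * 3, 0, sqrt(0.2)), n_req, 3)
      icc21(x, conf = 0.90)$ci_low > 0.2
    })
    expect_gte(mean(rej), 0.80)
  })
})

test_that("the per-task agreement battery produces a coherent summary", {
  study_thr <- withr::with_seed(107, {
    pop <- observer_population(18, icc = 0.9)
    tab <- draw_population(pop)
    tab$threshold <- tab$threshold_true
    tab
  })
  # the normality check can fire at its 5% rate on perfectly log-normal data
  ag <- suppressWarnings(evaluate_agreement(study_thr))
  expect_setequal(ag$task, c("temporal", "spatial"))
  expect_equal(ag$n_pairs, c(72, 72), ignore_attr = TRUE)
  expect_true(all(ag$loa_low <= ag$mean_ratio & ag$mean_ratio <= ag$loa_high))
  expect_true(all(ag$median_abs_ratio >= 1))
  expect_true(all(ag$icc > 0.5))   # strong true reliability should show

  pooled <- suppressWarnings(evaluate_agreement(study_thr, by = "pooled"))
  expect_equal(nrow(pooled), 1)
  expect_equal(pooled$n_pairs, 144)

  web_only <- study_thr[study_thr$session == "web", ]
  expect_error(evaluate_agreement(web_only), "both 'web' and 'lab'")
})
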