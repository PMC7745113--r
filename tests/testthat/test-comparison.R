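make_pairs <- function(obs, pred, tau = NULL) {
  n <- length(obs)
  list(
    predicted = tibble::tibble(run = seq_len(n), yield_pct = pred),
    observed = if (is.null(tau)) {
      tibble::tibble(run = seq_len(n), yield_pct = obs)
    } else {
      tibble::tibble(run = seq_len(n), yield_pct = obs, tau_min = tau)
    }
  )
}

test_that("identical predictions give unit slopes and zero differences", {
  obs <- c(4, 8, 12, 18, 30, 45, 60, 80)
  p <- make_pairs(obs, obs)
  res <- parity_analysis(p$predicted, p$observed)
  g <- glance(res)
  expect_equal(g$slope_low, 1, tolerance = 1e-12)
  expect_equal(g$slope_high, 1, tolerance = 1e-12)
  expect_true(all(res$pairs$difference == 0))
})

test_that("constructed two-segment data recover the planted slopes exactly", {
  obs <- c(2, 5, 9, 14, 19, 25, 33, 48, 62, 85)
  pred <- ifelse(obs < 20, obs * 0.85, obs * 1.31)
  p <- make_pairs(obs, pred)
  res <- parity_analysis(p$predicted, p$observed, crossover = 20)
  g <- glance(res)
  expect_equal(g$slope_low, 0.85, tolerance = 1e-10)
  expect_equal(g$slope_high, 1.31, tolerance = 1e-10)
  expect_equal(res$slopes$intercept, c(0, 0), tolerance = 1e-9)

  # slopes are invariant under reordering of the pairs
  perm <- c(7, 2, 9, 1, 10, 4, 3, 8, 5, 6)
  res_shuf <- parity_analysis(p$predicted[perm, ], p$observed[rev(perm), ])
  expect_equal(res_shuf$slopes$slope, res$slopes$slope, tolerance = 1e-12)
})

test_that("a crossover above all observations leaves one global segment", {
  obs <- c(3, 6, 10, 15)
  pred <- c(4, 5, 12, 14)
  p <- make_pairs(obs, pred)
  res <- parity_analysis(p$predicted, p$observed, crossover = 99)
  expect_true(is.na(res$slopes$slope[res$slopes$segment == "high"]))
  global <- unname(coef(lm(pred ~ obs))[2])
  expect_equal(res$slopes$slope[res$slopes$segment == "low"], global,
               tolerance = 1e-12)
})

test_that("replicated observations are averaged before pairing", {
  obs3 <- tibble::tibble(run = rep(1:3, each = 3),
                         yield_pct = c(9, 10, 11, 29, 30, 31, 59, 60, 61))
  pred <- tibble::tibble(run = 1:3, yield_pct = c(10, 30, 60))
  res <- parity_analysis(pred, obs3)
  expect_equal(res$pairs$observed, c(10, 30, 60))
  expect_true(all(res$pairs$difference == 0))
})

test_that("error-versus-residence-time summaries match hand computation", {
  obs <- c(10, 20, 40, 60)
  pred <- c(12.4, 18, 45, 79.1)
  tau <- c(2, 4, 9, 30)
  p <- make_pairs(obs, pred, tau)
  res <- parity_analysis(p$predicted, p$observed, crossover = 20)
  tab <- error_vs_residence_time(res, short_tau = 5, long_tau = 8)
  expect_equal(tab$abs_difference, c(2.4, 2, 5, 19.1))
  s <- attr(tab, "summary")
  expect_equal(s$min_abs_error_short_tau, 2)
  expect_equal(s$max_abs_error_long_tau, 19.1)
  # a monotone-increasing error profile peaks at the largest tau
  expect_identical(which.max(tab$abs_difference), nrow(tab))
  # empty long bin yields an absent (NA) summary
  s2 <- attr(error_vs_residence_time(res, long_tau = 100), "summary")
  expect_true(is.na(s2$max_abs_error_long_tau))
})

test_that("mismatched or undersized inputs are rejected", {
  p <- make_pairs(c(10, 20, 30), c(11, 19, 33))
  expect_error(parity_analysis(p$predicted[1:2, ], p$observed),
               "same condition set")
  expect_error(parity_analysis(p$predicted[1, ], p$observed[1, ]), "at least two")
  expect_error(parity_analysis(dplyr::select(p$predicted, -yield_pct),
                               p$observed), "lacks column")
  res <- parity_analysis(p$predicted, p$observed)
  expect_error(error_vs_residence_time(res), "no residence times")
})
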