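test_that("factorial designs have the right runs, balance and generator", {
  full <- build_design(kind = "full")
  expect_identical(nrow(full), 32L)
  expect_identical(nrow(dplyr::distinct(full[c("A", "B", "C", "D", "E")])), 32L)
  frac <- build_design(kind = "fractional")
  expect_identical(nrow(frac), 16L)
  expect_equal(frac$E, frac$A * frac$B * frac$C * frac$D) # E = ABCD
  for (l in c("A", "B", "C", "D", "E")) {
    expect_equal(sum(full[[l]]), 0)
    expect_equal(sum(frac[[l]]), 0)
  }
  # natural-unit mapping hits exactly the configured levels
  ft <- default_factor_table(default_cfg)
  expect_equal(sort(unique(full$ID_mm)), c(ft$low[2], ft$high[2]))
  expect_equal(sort(unique(full$chi)), c(ft$low[5], ft$high[5]))
  # replicates triple the rows without new conditions
  rep3 <- build_design(kind = "fractional", replicates = 3)
  expect_identical(nrow(rep3), 48L)
  expect_identical(nrow(dplyr::distinct(rep3[c("A", "B", "C", "D", "E")])), 16L)
})

test_that("contrast effects agree with least-squares coefficients", {
  d <- build_design(kind = "full")
  # degenerate responses
  expect_true(all(estimate_effects(d, rep(3, 32))$effect == 0))
  eff_b <- estimate_effects(d, d$B)
  expect_equal(eff_b$effect[eff_b$term == "B"], 2)
  expect_true(all(abs(eff_b$effect[eff_b$term != "B"]) < 1e-12))

  # random response: effects = 2 x regression coefficients on coded contrasts
  set.seed(5)
  y <- rnorm(32)
  eff <- estimate_effects(d, y)
  X <- sapply(eff$term, function(tm) {
    Reduce(`*`, lapply(strsplit(tm, "")[[1]], function(l) d[[l]]))
  })
  beta <- coef(lm(y ~ X))[-1]
  expect_equal(eff$effect, unname(2 * beta[match(eff$term, colnames(X))]),
               tolerance = 1e-10)
})

test_that("fractional effects absorb their aliases", {
  # with I = ABCDE, the AB contrast of the half fraction carries AB + CDE
  full <- build_design(kind = "full")
  frac <- build_design(kind = "fractional")
  model <- function(d) {
    0.3 * d$A * d$B + 0.2 * d$C * d$D * d$E + 0.1 * d$A
  }
  eff_full <- estimate_effects(full, model(full), terms = c("A", "AB"))
  eff_frac <- estimate_effects(frac, model(frac), terms = c("A", "AB"))
  expect_equal(eff_full$effect[eff_full$term == "AB"], 2 * 0.3)
  expect_equal(eff_frac$effect[eff_frac$term == "AB"], 2 * (0.3 + 0.2))
  expect_equal(eff_frac$effect[eff_frac$term == "A"], 2 * 0.1)
})

test_that("Lenth screening matches a hand evaluation and its degenerate cases", {
  e <- c(10, 0.1, -0.12, 0.08, 0.11, -0.09, 0.1)
  tbl <- tibble::tibble(term = paste0("t", 1:7), effect = e,
                        coefficient = e / 2, sign = sign(e))
  tbl <- dplyr::arrange(tbl, abs(effect))
  tbl$rank <- 1:7
  tbl$half_normal_quantile <- qnorm(0.5 + 0.5 * (tbl$rank - 0.5) / 7)
  class(tbl) <- c("effect_table", class(tbl))
  scr <- lenth_screen(tbl, alpha = 0.05)
  # hand: s0 = 1.5*0.1, PSE = 1.5*median{|e| < 0.375} = 0.15,
  # margin = t_{0.975, 7/3} * 0.15 -> only the effect of 10 exceeds it
  expect_equal(scr$pse[1], 0.15)
  expect_identical(scr$term[scr$significant], "t1") # the |effect| = 10 term

  zero <- estimate_effects(build_design(kind = "full"), rep(1, 32))
  expect_false(any(lenth_screen(zero)$significant))
  expect_error(lenth_screen(zero[1:5, ]), "at least 7")

  # the family-wise simultaneous margin is strictly wider than the
  # individual one, and still flags the dominant effect here
  sme <- lenth_screen(tbl, margin = "simultaneous")
  expect_gt(sme$margin[1], scr$margin[1])
  expect_identical(sme$term[sme$significant], "t1")
})

test_that("planted main effects are always detected over seeded repetitions", {
  d <- build_design(kind = "full")
  set.seed(42)
  res <- replicate(50, {
    y <- 0.3 * d$A + 0.5 * d$B - 0.4 * d$C + 0.4 * d$D + rnorm(32, sd = 0.02)
    s <- lenth_screen(estimate_effects(d, y))
    flagged <- s$term[s$significant]
    c(power = all(c("A", "B", "C", "D") %in% flagged),
      false_flags = length(setdiff(flagged, c("A", "B", "C", "D"))))
  })
  expect_true(all(res["power", ] == 1)) # the planted set is never missed
  # the individual-error margin admits occasional false flags (by design,
  # ~2% per null term); they stay rare
  expect_lt(mean(res["false_flags", ]), 0.75)
})

test_that("factorial model fitting recovers exact models and honest summaries", {
  d <- build_design(kind = "full")
  y_exact <- 10^(0.8 + 0.3 * d$A - 0.2 * d$C + 0.05 * d$B * d$D)
  fit <- fit_factorial_model(d, y_exact, terms = c("A", "C", "BD"))
  expect_equal(unname(fit$coefficients), c(0.3, -0.2, 0.05), tolerance = 1e-10)
  expect_equal(fit$intercept, 0.8, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # noisy data: predicted R2 <= adjusted R2 <= R2
  set.seed(9)
  y_noisy <- 10^(0.8 + 0.3 * d$A - 0.2 * d$C + rnorm(32, sd = 0.1))
  fit_n <- fit_factorial_model(d, y_noisy, terms = c("A", "B", "C", "D"))
  g <- glance(fit_n)
  expect_lte(g$adj.r.squared, g$r.squared)
  expect_lte(g$pred.r.squared, g$adj.r.squared)
  expect_identical(nrow(tidy(fit_n)), 5L)

  # replicated designs: zero pure error for noise-free replicates,
  # positive pure error and a lack-of-fit F once noise enters
  d3 <- build_design(kind = "fractional", replicates = 3)
  y_rep <- 10^(0.5 + 0.2 * d3$A)
  g0 <- glance(fit_factorial_model(d3, y_rep, terms = c("A", "B")))
  expect_equal(g0$ms.pure.error, 0)
  set.seed(10)
  y_rep_n <- y_rep * exp(rnorm(nrow(d3), sd = 0.05))
  g1 <- glance(fit_factorial_model(d3, y_rep_n, terms = c("A", "B")))
  expect_gt(g1$ms.pure.error, 0)
  expect_true(is.finite(g1$f.lack.of.fit))

  # aliased terms on the half fraction are reported, not silently dropped
  frac <- build_design(kind = "fractional")
  expect_error(
    fit_factorial_model(frac, 10^frac$A, terms = c("A", "BCDE")),
    "rank deficient"
  )
})

test_that("surface prediction differentiates the published-style interaction model", {
  m <- coded_model(1.09, c(D = 0.13, E = 0.013, DE = 0.047))
  s <- predict_surface(m, c("D", "E"), n = 3)
  # E-slope of log10 yield at the two temperature levels
  slope_at <- function(dlev) {
    sl <- dplyr::filter(s, .data$D == dlev)
    (sl$log10_yield[sl$E == 1] - sl$log10_yield[sl$E == -1]) / 2
  }
  expect_equal(abs(slope_at(-1)), abs(0.013 - 0.047), tolerance = 1e-12)
  expect_equal(abs(slope_at(1)), 0.013 + 0.047, tolerance = 1e-12)
  # centre of the design returns the back-transformed intercept
  centre <- dplyr::filter(predict_surface(m, c("D", "E"), n = 3),
                          .data$D == 0, .data$E == 0)
  expect_equal(centre$yield_pct, 10^1.09)

  # no interaction -> parallel slices
  m0 <- coded_model(1, c(D = 0.2, E = 0.1))
  s0 <- predict_surface(m0, c("D", "E"), n = 5)
  slopes <- sapply(unique(s0$D), function(dl) {
    sl <- dplyr::filter(s0, .data$D == dl)
    coef(lm(sl$log10_yield ~ sl$E))[2]
  })
  expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-12)
  expect_warning(predict_surface(m0, c("D", "E"), range = c(-2, 2)),
                 "extrapolates")
})
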