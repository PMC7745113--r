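#' Default two-level factor table for the screening design
#'
#' Factors in fixed order A..E: tubing length (m), inner diameter (mm),
#' total flow rate (mL min^-1), bath temperature (degC) and feed mole ratio
#' DMF-DMA : M4MAA, with the low/high levels of the screening study.
#'
#' @param config A [flow_config()]; levels come from its `factors` block.
#' @return A tibble `factor`, `code`, `column`, `low`, `high`.
#' @export
default_factor_table <- function(config = flow_config()) {
  f <- config$factors
  tibble(
    factor = c("length", "inner_diameter", "flow_rate", "temperature", "molar_ratio"),
    code = c("A", "B", "C", "D", "E"),
    column = c("L_m", "ID_mm", "Q_mL_min", "T_C", "chi"),
    low = purrr::map_dbl(c("length", "inner_diameter", "flow_rate",
                           "temperature", "molar_ratio"), ~ f[[.x]]$low),
    high = purrr::map_dbl(c("length", "inner_diameter", "flow_rate",
                            "temperature", "molar_ratio"), ~ f[[.x]]$high)
  )
}

#' Build a two-level factorial design
#'
#' Generates the full \eqn{2^5} design (32 runs, every level combination
#' once) or the resolution-V half fraction \eqn{2^{5-1}} with generator
#' E = ABCD (16 runs; two-way interactions are aliased only with three-way
#' interactions).  Coded columns are -1/+1 in standard (Yates) order;
#' natural-unit columns are mapped from the factor table.
#'
#' @param factors A factor table from [default_factor_table()].
#' @param kind `"full"` or `"fractional"`.
#' @param replicates Number of replicates of each run (rows are repeated
#'   with a `replicate` index).
#' @return A tibble with `run`, coded columns `A`..`E`, natural-unit
#'   columns (`L_m`, `ID_mm`, `Q_mL_min`, `T_C`, `chi`) and `replicate`.
#' @examples
#' nrow(build_design(kind = "full")) # 32
#' nrow(build_design(kind = "fractional")) # 16
#' @export
build_design <- function(factors = default_factor_table(),
                         kind = c("full", "fractional"),
                         replicates = 1) {
  kind <- match.arg(kind)
  if (!all(factors$low < factors$high)) abort("factor lows must be below highs")
  if (nrow(factors) != 5) abort("the screening design uses exactly five factors")
  if (replicates < 1) abort("replicates must be >= 1")

  if (kind == "full") {
    coded <- expand.grid(A = c(-1, 1), B = c(-1, 1), C = c(-1, 1),
                         D = c(-1, 1), E = c(-1, 1))
  } else {
    coded <- expand.grid(A = c(-1, 1), B = c(-1, 1), C = c(-1, 1), D = c(-1, 1))
    coded$E <- coded$A * coded$B * coded$C * coded$D # generator E = ABCD
  }
  coded <- as_tibble(coded)

  natural <- purrr::map2_dfc(factors$code, seq_len(5), function(code, i) {
    x <- coded[[code]]
    centre <- (factors$high[i] + factors$low[i]) / 2
    half <- (factors$high[i] - factors$low[i]) / 2
    setNames(tibble(centre + half * x), factors$column[i])
  })

  base <- dplyr::bind_cols(tibble(run = seq_len(nrow(coded))), coded, natural)
  out <- tidyr::crossing(base, replicate = seq_len(replicates))
  dplyr::arrange(out, .data$run, .data$replicate)
}

# contrast column for a term string such as "A", "BD", "ABC"
term_contrast <- function(design, term) {
  letters_used <- strsplit(term, "")[[1]]
  bad <- setdiff(letters_used, c("A", "B", "C", "D", "E"))
  if (length(bad) > 0) abort(paste0("unknown factor code(s): ", paste(bad, collapse = ", ")))
  Reduce(`*`, lapply(letters_used, function(l) design[[l]]))
}

all_terms <- function(order = 2) {
  main <- c("A", "B", "C", "D", "E")
  terms <- main
  if (order >= 2) {
    terms <- c(terms, combn(main, 2, paste, collapse = ""))
  }
  if (order >= 3) {
    for (k in 3:min(order, 5)) terms <- c(terms, combn(main, k, paste, collapse = ""))
  }
  terms
}

#' Estimate factorial effects from contrasts
#'
#' For each requested term the effect is the mean response at the +1 level
#' of its contrast minus the mean at the -1 level; the regression
#' coefficient is half the effect.  Half-normal quantiles are assigned by
#' rank of |effect| for screening plots.
#'
#' @param design A design tibble from [build_design()] (coded columns
#'   `A`..`E`).
#' @param response Numeric response, one value per design row.
#' @param terms Character vector of terms (`"A"`, `"BD"`, ...), or
#'   `"two_way"` (default: all main effects and two-way interactions) or
#'   `"all"` (all 31 effects).
#' @return An `effect_table` tibble: `term`, `effect`, `coefficient`,
#'   `sign`, `rank`, `half_normal_quantile`.
#' @export
estimate_effects <- function(design, response, terms = "two_way") {
  if (length(response) != nrow(design)) {
    abort("response must have one value per design row")
  }
  if (any(!is.finite(response))) abort("response contains non-finite values")
  if (identical(terms, "two_way")) terms <- all_terms(2)
  if (identical(terms, "all")) terms <- all_terms(5)

  eff <- purrr::map_dbl(terms, function(tm) {
    x <- term_contrast(design, tm)
    mean(response[x > 0]) - mean(response[x < 0])
  })
  out <- tibble(
    term = terms,
    effect = eff,
    coefficient = eff / 2,
    sign = sign(eff)
  )
  out <- dplyr::arrange(out, abs(.data$effect))
  m <- nrow(out)
  out$rank <- seq_len(m)
  out$half_normal_quantile <- qnorm(0.5 + 0.5 * (out$rank - 0.5) / m)
  class(out) <- c("effect_table", class(out))
  out
}

#' Lenth's pseudo-standard-error screening of unreplicated effects
#'
#' Implements Lenth's method for judging effect significance without
#' replicate error: \eqn{s_0 = 1.5 \cdot \mathrm{median}|e|}, the
#' pseudo-standard error \eqn{PSE = 1.5 \cdot \mathrm{median}\{|e| :
#' |e| < 2.5 s_0\}}, and margin of error
#' \eqn{ME = t_{1-\alpha/2, d/3} \cdot PSE} with `d` the number of effects.
#' Effects with \eqn{|e| > ME} are flagged.
#'
#' @param effects An `effect_table` from [estimate_effects()] (>= 7 effects
#'   for a stable PSE).
#' @param alpha Significance level.
#' @param margin `"individual"` (default) uses the margin of error `ME`,
#'   which controls the per-effect error rate; `"simultaneous"` uses the
#'   family-wise simultaneous margin `SME` with quantile
#'   \eqn{\gamma = (1 + (1-\alpha)^{1/d})/2}.
#' @return The input with columns `pse`, `margin`, `significant` added.
#' @examples
#' d <- build_design(kind = "full")
#' y <- 0.5 * d$B + rnorm(32, sd = 0.01)
#' lenth_screen(estimate_effects(d, y))
#' @export
lenth_screen <- function(effects, alpha = 0.05,
                         margin = c("individual", "simultaneous")) {
  margin_kind <- match.arg(margin)
  if (!inherits(effects, "effect_table")) {
    abort("effects must come from estimate_effects()")
  }
  d <- nrow(effects)
  if (d < 7) abort("need at least 7 effects for a stable pseudo-standard error")
  e <- abs(effects$effect)
  if (all(e == 0)) {
    effects$pse <- 0
    effects$margin <- 0
    effects$significant <- FALSE
    return(effects)
  }
  s0 <- 1.5 * median(e)
  pse <- 1.5 * median(e[e < 2.5 * s0])
  q <- if (margin_kind == "individual") {
    1 - alpha / 2
  } else {
    (1 + (1 - alpha)^(1 / d)) / 2
  }
  margin <- qt(q, df = d / 3) * pse
  effects$pse <- pse
  effects$margin <- margin
  effects$significant <- e > margin
  effects
}

# response transform used by the factorial model: log10 of percent yield
# with a 0.01% floor guarding degenerate zero-yield runs
log10_yield <- function(y, floor = 0.01) log10(pmax(y, floor))

#' Fit the coded-unit log10-yield factorial model
#'
#' Least squares on the coded contrasts of \eqn{\log_{10}} percent yield
#' (floored at 0.01% before the transform).  Returns the fitted model plus
#' ANOVA-style summaries: model F and p, R^2, adjusted R^2, predicted R^2
#' from PRESS, and - for replicated designs - pure error and the
#' lack-of-fit F test.
#'
#' @param design A design tibble from [build_design()].
#' @param response Percent yield per design row (> 0 after flooring).
#' @param terms Character vector of retained terms in `A`..`E` coding
#'   (e.g. `c("A","B","C","D")`); interaction parents are not added
#'   automatically.
#' @param transform `"log10"` (default) or `"identity"`.
#' @param floor Yield floor (percent) applied before the log transform.
#' @return A `doe_fit` object; see [tidy.doe_fit()], [glance.doe_fit()],
#'   [predict_surface()].
#' @export
fit_factorial_model <- function(design, response, terms = c("A", "B", "C", "D"),
                                transform = c("log10", "identity"),
                                floor = 0.01) {
  transform <- match.arg(transform)
  if (length(response) != nrow(design)) {
    abort("response must have one value per design row")
  }
  y <- if (transform == "log10") log10_yield(response, floor) else response
  X <- purrr::map_dfc(terms, function(tm) setNames(tibble(term_contrast(design, tm)), tm))
  dat <- dplyr::bind_cols(tibble(.y = y), X)

  qrX <- qr(cbind(1, as.matrix(X)))
  if (qrX$rank < ncol(X) + 1) {
    abort(paste0(
      "design cannot estimate all requested terms (rank deficient); ",
      "aliased terms among: ", paste(terms, collapse = ", ")
    ))
  }

  fml <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", terms), collapse = " + ")))
  fit <- lm(fml, data = dat)

  res <- stats::residuals(fit)
  h <- lm.influence(fit)$hat
  press <- sum((res / (1 - h))^2)
  sst <- sum((y - mean(y))^2)
  sse <- sum(res^2)
  p <- length(terms)
  n <- length(y)
  r2 <- 1 - sse / sst
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  pred_r2 <- 1 - press / sst

  # model F computed directly (summary.lm warns on exact fits)
  df_res <- n - p - 1
  model_f <- if (sse > 0) ((sst - sse) / p) / (sse / df_res) else Inf
  model_p <- pf(model_f, p, df_res, lower.tail = FALSE)

  # replicate structure: pure error and lack of fit
  cond <- apply(design[, c("A", "B", "C", "D", "E")], 1, paste, collapse = "/")
  n_cond <- length(unique(cond))
  pure <- NULL
  if (n_cond < n) {
    ybar <- stats::ave(y, cond)
    ss_pe <- sum((y - ybar)^2)
    df_pe <- n - n_cond
    ss_lof <- max(sse - ss_pe, 0)
    df_lof <- n_cond - p - 1
    ms_pe <- ss_pe / df_pe
    if (df_lof > 0 && ms_pe > 0) {
      f_lof <- (ss_lof / df_lof) / ms_pe
      p_lof <- pf(f_lof, df_lof, df_pe, lower.tail = FALSE)
    } else {
      f_lof <- NA_real_
      p_lof <- NA_real_
    }
    pure <- list(ss_pure_error = ss_pe, ms_pure_error = ms_pe, df_pure_error = df_pe,
                 f_lack_of_fit = f_lof, p_lack_of_fit = p_lof)
  }

  structure(
    list(
      lm = fit, terms = terms, transform = transform, floor = floor,
      design = design, response = response,
      intercept = unname(coef(fit)[1]),
      coefficients = setNames(unname(coef(fit)[-1]), terms),
      r_squared = r2, adj_r_squared = adj_r2, pred_r_squared = pred_r2,
      press = press, model_f = model_f, model_p = model_p,
      pure = pure
    ),
    class = "doe_fit"
  )
}

#' @export
print.doe_fit <- function(x, ...) {
  cat("<doe_fit>", x$transform, "percent-yield model in coded units\n")
  cat(sprintf("  intercept %.4g; terms: %s\n", x$intercept,
              paste(sprintf("%s=%.3g", x$terms, x$coefficients), collapse = ", ")))
  cat(sprintf("  R2 = %.3f, adj R2 = %.3f, pred R2 = %.3f\n",
              x$r_squared, x$adj_r_squared, x$pred_r_squared))
  invisible(x)
}

#' Per-term summary of a factorial model
#'
#' @param x A `doe_fit`.
#' @param ... Unused.
#' @return A tibble `term`, `estimate` (coded-unit coefficient),
#'   `std.error`, `statistic`, `p.value`; the intercept row first.
#' @export
tidy.doe_fit <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  tibble(
    term = c("(Intercept)", x$terms),
    estimate = unname(s[, 1]),
    std.error = unname(s[, 2]),
    statistic = unname(s[, 3]),
    p.value = unname(s[, 4])
  )
}

#' Model-level summary of a factorial model
#'
#' @param x A `doe_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `r.squared`, `adj.r.squared`,
#'   `pred.r.squared`, `press`, model `statistic` and `p.value`, and (for
#'   replicated designs) `ms.pure.error`, `f.lack.of.fit`, `p.lack.of.fit`.
#' @export
glance.doe_fit <- function(x, ...) {
  out <- tibble(
    r.squared = x$r_squared, adj.r.squared = x$adj_r_squared,
    pred.r.squared = x$pred_r_squared, press = x$press,
    statistic = x$model_f, p.value = x$model_p,
    ms.pure.error = NA_real_, f.lack.of.fit = NA_real_,
    p.lack.of.fit = NA_real_
  )
  if (!is.null(x$pure)) {
    out$ms.pure.error <- x$pure$ms_pure_error
    out$f.lack.of.fit <- x$pure$f_lack_of_fit
    out$p.lack.of.fit <- x$pure$p_lack_of_fit
  }
  out
}

#' Construct a coded-unit model from known coefficients
#'
#' Builds the same kind of object [fit_factorial_model()] returns, from an
#' intercept and named coded-unit coefficients (interactions as e.g.
#' `"DE"`), for evaluating published or hypothesised models.
#'
#' @param intercept Intercept on the transformed (log10 percent-yield)
#'   scale.
#' @param coefficients Named numeric vector of coded-unit coefficients.
#' @param transform `"log10"` or `"identity"`.
#' @return A `doe_model` object usable by [predict_surface()].
#' @examples
#' m <- coded_model(1.09, c(D = 0.13, E = 0.013, DE = 0.047))
#' @export
coded_model <- function(intercept, coefficients, transform = "log10") {
  if (is.null(names(coefficients)) || any(names(coefficients) == "")) {
    abort("coefficients must be a named vector")
  }
  structure(
    list(intercept = intercept, coefficients = coefficients,
         terms = names(coefficients), transform = transform),
    class = "doe_model"
  )
}

predict_coded <- function(model, newdata) {
  eta <- rep(model$intercept, nrow(newdata))
  for (tm in model$terms) {
    x <- Reduce(`*`, lapply(strsplit(tm, "")[[1]], function(l) newdata[[l]]))
    eta <- eta + model$coefficients[[tm]] * x
  }
  eta
}

#' Predicted yield surface over two coded factors
#'
#' Evaluates a fitted (or constructed) coded-unit model on a grid over two
#' factors with all remaining factors at the design centre (coded 0), and
#' back-transforms to percent yield.  Points beyond the coded range
#' \eqn{[-1, 1]} trigger a warning (extrapolation).
#'
#' @param model A `doe_fit` or [coded_model()].
#' @param factors Two factor codes, e.g. `c("D", "E")`.
#' @param n Grid resolution per axis.
#' @param range Coded range of each axis.
#' @return A tibble with the two coded factors, `log10_yield` (or the
#'   untransformed prediction) and `yield_pct`.
#' @export
predict_surface <- function(model, factors = c("D", "E"), n = 21,
                            range = c(-1, 1)) {
  if (length(factors) != 2) abort("factors must name exactly two codes")
  if (min(range) < -1 || max(range) > 1) {
    warn("requested range extrapolates beyond the coded design region [-1, 1]")
  }
  if (inherits(model, "doe_fit")) {
    model <- coded_model(model$intercept, model$coefficients, model$transform)
  }
  grid <- tidyr::crossing(
    !!factors[1] := seq(range[1], range[2], length.out = n),
    !!factors[2] := seq(range[1], range[2], length.out = n)
  )
  full <- grid
  for (l in setdiff(c("A", "B", "C", "D", "E"), factors)) full[[l]] <- 0
  eta <- predict_coded(model, full)
  grid$log10_yield <- eta
  grid$yield_pct <- if (model$transform == "log10") 10^eta else eta
  grid
}
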