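#' Parity analysis of predicted versus observed yields
#'
#' Pairs per-condition predicted (simulator) and observed (campaign mean)
#' yields, splits the pairs at an observed-yield crossover (default 20%),
#' and fits one ordinary-least-squares line of predicted on observed per
#' segment (free intercepts).  Slopes below/above one indicate
#' under-/over-estimation by the simulator.
#'
#' @param predicted A data frame with the condition columns (`run` or the
#'   natural-unit columns) and a predicted `yield_pct`.
#' @param observed A data frame with the same condition identifiers,
#'   `yield_pct` (replicates are averaged) and, if available, `tau_min`.
#' @param by Column(s) identifying a condition in both inputs.
#' @param crossover Observed-yield threshold (percent) splitting the two
#'   segments.
#' @return A `parity_result`: `pairs` (tibble with `predicted`, `observed`,
#'   `difference = predicted - observed`, `segment`, `tau_min`), per-segment
#'   `slopes` (slope, intercept, n; `NA` for a segment with fewer than two
#'   points), and the `crossover` used.  [tidy()] returns the pairs,
#'   [glance()] the slopes and extreme differences.
#' @examples
#' obs <- tibble::tibble(run = 1:6, yield_pct = c(5, 10, 15, 30, 50, 70))
#' pred <- tibble::tibble(run = 1:6, yield_pct = c(5, 10, 15, 30, 50, 70) * 1.2)
#' parity_analysis(pred, obs)
#' @export
parity_analysis <- function(predicted, observed, by = "run", crossover = 20) {
  for (nm in c(by, "yield_pct")) {
    if (!nm %in% names(predicted)) abort(paste0("predicted lacks column ", nm))
    if (!nm %in% names(observed)) abort(paste0("observed lacks column ", nm))
  }
  has_tau <- "tau_min" %in% names(observed)
  obs <- dplyr::summarise(
    dplyr::group_by(observed, dplyr::across(dplyr::all_of(by))),
    observed = mean(.data$yield_pct),
    tau_min = if (has_tau) mean(.data$tau_min) else NA_real_,
    .groups = "drop"
  )
  pred <- dplyr::select(predicted, dplyr::all_of(by), predicted = "yield_pct")
  pairs <- dplyr::inner_join(pred, obs, by = by)
  if (nrow(pairs) < nrow(pred) || nrow(pairs) < nrow(obs)) {
    abort("predicted and observed must cover the same condition set")
  }
  if (nrow(pairs) < 2) abort("need at least two paired conditions")

  pairs <- dplyr::mutate(
    pairs,
    difference = .data$predicted - .data$observed,
    segment = ifelse(.data$observed < crossover, "low", "high")
  )

  fit_segment <- function(d) {
    if (nrow(d) < 2) {
      return(tibble(slope = NA_real_, intercept = NA_real_, n = nrow(d)))
    }
    co <- coef(lm(predicted ~ observed, data = d))
    tibble(slope = unname(co[2]), intercept = unname(co[1]), n = nrow(d))
  }
  slopes <- dplyr::bind_rows(
    low = fit_segment(dplyr::filter(pairs, .data$segment == "low")),
    high = fit_segment(dplyr::filter(pairs, .data$segment == "high")),
    .id = "segment"
  )

  structure(list(pairs = pairs, slopes = slopes, crossover = crossover, by = by),
            class = "parity_result")
}

#' @export
print.parity_result <- function(x, ...) {
  cat("<parity_result>", nrow(x$pairs), "paired conditions, crossover at",
      x$crossover, "%\n")
  print(x$slopes)
  invisible(x)
}

#' @export
tidy.parity_result <- function(x, ...) x$pairs

#' @export
glance.parity_result <- function(x, ...) {
  s <- x$slopes
  tibble(
    slope_low = s$slope[s$segment == "low"],
    slope_high = s$slope[s$segment == "high"],
    crossover = x$crossover,
    n_pairs = nrow(x$pairs),
    max_abs_difference = max(abs(x$pairs$difference)),
    min_abs_difference = min(abs(x$pairs$difference))
  )
}

#' Absolute prediction error versus residence time
#'
#' @param parity A `parity_result` whose pairs carry `tau_min`.
#' @param short_tau,long_tau Bin edges in minutes: the summary reports the
#'   smallest absolute error among short runs (`tau < short_tau`) and the
#'   largest among long runs (`tau > long_tau`).
#' @return A tibble sorted by `tau_min` with `abs_difference`, carrying a
#'   `summary` attribute (a tibble with `min_abs_error_short_tau`,
#'   `max_abs_error_long_tau`; a value is `NA` when its bin is empty).
#' @export
error_vs_residence_time <- function(parity, short_tau = 5, long_tau = 8) {
  if (!inherits(parity, "parity_result")) abort("parity must be a parity_result")
  p <- parity$pairs
  if (all(is.na(p$tau_min))) {
    abort("pairs carry no residence times; supply tau_min in the observed table")
  }
  out <- dplyr::arrange(
    dplyr::transmute(p, tau_min = .data$tau_min,
                     abs_difference = abs(.data$difference),
                     observed = .data$observed, predicted = .data$predicted),
    .data$tau_min
  )
  short <- out$abs_difference[out$tau_min < short_tau]
  long <- out$abs_difference[out$tau_min > long_tau]
  attr(out, "summary") <- tibble(
    min_abs_error_short_tau = if (length(short) > 0) min(short) else NA_real_,
    max_abs_error_long_tau = if (length(long) > 0) max(long) else NA_real_
  )
  out
}
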