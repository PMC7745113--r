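#' Half-normal plot of factorial effects
#'
#' @param object An `effect_table`, ideally after [lenth_screen()].
#' @param ... Unused.
#' @return A ggplot: |effect| against half-normal quantiles, labelled, with
#'   significant effects (when screened) highlighted and the Lenth margin
#'   shown as a reference line.
#' @export
autoplot.effect_table <- function(object, ...) {
  d <- dplyr::mutate(object, abs_effect = abs(.data$effect),
                     direction = ifelse(.data$sign >= 0, "positive", "negative"))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$half_normal_quantile,
                                       y = .data$abs_effect)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$direction), size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$term), hjust = -0.4, size = 3) +
    ggplot2::scale_colour_manual(values = c(positive = "#E69F00",
                                            negative = "#0072B2")) +
    ggplot2::labs(x = "half-normal quantile", y = "|effect|",
                  colour = "correlation with yield") +
    ggplot2::theme_minimal()
  if ("margin" %in% names(d)) {
    p <- p + ggplot2::geom_hline(yintercept = d$margin[1], linetype = "dashed")
  }
  p
}

#' Startup transient of a reactor simulation
#'
#' @param object A `reactor_sim`.
#' @param ... Unused.
#' @return A ggplot of outlet yield versus residence-time multiples.
#' @export
autoplot.reactor_sim <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$multiple, y = .data$yield_pct)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$steady$multiple, linetype = "dotted") +
    ggplot2::labs(x = "residence-time multiples", y = "outlet yield (%)") +
    ggplot2::theme_minimal()
}

#' Arrhenius plot of a kinetic fit
#'
#' @param object An `arrhenius_fit`.
#' @param ... Unused.
#' @return A ggplot of ln k against 1/T with the fitted line.
#' @export
autoplot.arrhenius_fit <- function(object, ...) {
  d <- dplyr::mutate(object$rate_constants, inv_t = 1 / .data$temperature,
                     ln_k = log(.data$k))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$inv_t, y = .data$ln_k)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40", linewidth = 0.5) +
    ggplot2::labs(x = "1 / T (1/K)", y = "ln k") +
    ggplot2::theme_minimal()
}

#' Parity plot of predicted versus observed yields
#'
#' @param object A `parity_result`.
#' @param ... Unused.
#' @return A ggplot with the identity line and the per-segment fits.
#' @export
autoplot.parity_result <- function(object, ...) {
  p <- ggplot2::ggplot(object$pairs,
                       ggplot2::aes(x = .data$observed, y = .data$predicted,
                                    colour = .data$segment)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$crossover, linetype = "dotted") +
    ggplot2::labs(x = "observed yield (%)", y = "predicted yield (%)") +
    ggplot2::theme_minimal()
  for (i in seq_len(nrow(object$slopes))) {
    s <- object$slopes[i, ]
    if (!is.na(s$slope)) {
      p <- p + ggplot2::geom_abline(slope = s$slope, intercept = s$intercept,
                                    linetype = "dashed", colour = "grey40")
    }
  }
  p
}

#' Transient axial yield profiles
#'
#' @param sim A `reactor_sim`.
#' @param multiples Residence-time multiples to draw.
#' @return A ggplot of yield along the reactor length per startup time.
#' @export
plot_transient_profiles <- function(sim, multiples = c(0, 0.5, 1, 5)) {
  d <- transient_profiles(sim, multiples)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$z, y = .data$yield_pct,
                                  colour = factor(.data$multiple))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "axial position (m)", y = "mixing-cup yield (%)",
                  colour = "t / tau") +
    ggplot2::theme_minimal()
}

#' Interaction surface of a coded model
#'
#' @param model A `doe_fit` or [coded_model()].
#' @param factors Two factor codes.
#' @param n Grid resolution.
#' @return A filled-contour ggplot of predicted percent yield.
#' @export
plot_surface <- function(model, factors = c("D", "E"), n = 41) {
  d <- predict_surface(model, factors, n)
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[factors[1]]],
                                  y = .data[[factors[2]]],
                                  z = .data$yield_pct)) +
    ggplot2::geom_contour_filled() +
    ggplot2::labs(x = paste0(factors[1], " (coded)"),
                  y = paste0(factors[2], " (coded)"),
                  fill = "yield (%)") +
    ggplot2::theme_minimal()
}
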