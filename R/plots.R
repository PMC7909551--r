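#' Plot a visual predictive check
#'
#' Observed concentrations overlaid on the simulated percentile bands,
#' faceted is not possible (bands are per subject's own dose history), so
#' observations are plotted against time with the per-observation simulated
#' 5th/50th/95th percentiles as ribbons of vertical segments.
#'
#' @param object An `amik_vpc` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot amik_vpc
#' @export
autoplot.amik_vpc <- function(object, ...) {
  b <- object$bands
  ggplot2::ggplot(b, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_linerange(
      ggplot2::aes(ymin = .data$p5, ymax = .data$p95),
      colour = "grey70", linewidth = 1.5, alpha = 0.6
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$p50), colour = "grey40",
                        shape = 3) +
    ggplot2::geom_point(ggplot2::aes(y = .data$obs, colour = .data$inside)) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#2c7fb8", `FALSE` = "#d7301f"),
      name = "inside 5-95 band"
    ) +
    ggplot2::labs(
      x = "Time since first dose (h)",
      y = "Amikacin concentration (mg/L)",
      title = sprintf("Visual predictive check (%.1f%% inside band)",
                      object$inclusion_pct)
    ) +
    ggplot2::theme_minimal()
}

#' Plot observed versus predicted concentrations
#'
#' @param object An `npag_fit` object.
#' @param cohort The cohort the fit was built on.
#' @param ... Unused.
#' @return A ggplot of observed vs individual-posterior and population
#'   predictions with the identity line.
#' @method autoplot npag_fit
#' @export
autoplot.npag_fit <- function(object, cohort, ...) {
  p <- predictions(object, cohort)
  long <- tidyr::pivot_longer(
    p, c("pop_pred", "ind_pred"),
    names_to = "kind", values_to = "pred"
  ) |>
    dplyr::mutate(kind = dplyr::recode(.data$kind,
                                       pop_pred = "population",
                                       ind_pred = "individual posterior"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pred, y = .data$obs)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~kind) +
    ggplot2::labs(
      x = "Predicted concentration (mg/L)",
      y = "Observed concentration (mg/L)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a PTA grid
#'
#' Joint attainment versus dose, one line per creatinine clearance, faceted
#' by dosing interval, for a chosen MIC; the 90% decision threshold is drawn
#' as a horizontal reference.
#'
#' @param object An `amik_pta_grid` from [pta_table()].
#' @param mic Which MIC to display (defaults to the smallest in the grid).
#' @param threshold Reference threshold (%), default 90.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot amik_pta_grid
#' @export
autoplot.amik_pta_grid <- function(object, mic = NULL, threshold = 90, ...) {
  if (is.null(mic)) mic <- min(object$mic)
  df <- dplyr::filter(object, .data$mic == .env$mic)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose, y = .data$joint_pct,
                                   colour = factor(.data$ccr),
                                   group = .data$ccr)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~interval,
                        labeller = ggplot2::labeller(
                          interval = function(x) paste0("q", x, "h")
                        )) +
    ggplot2::labs(
      x = "Dose (mg)", y = "Joint PTA (%)",
      colour = "CCr (mL/min)",
      title = sprintf("Joint target attainment, MIC %g mg/L", mic)
    ) +
    ggplot2::theme_minimal()
}
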