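#' Plot an individual concentration-time profile
#'
#' Drug concentration (log scale) and target inhibition over time.
#'
#' @param object A `tmdd_profile` from [simulate_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tmdd_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("time", "conc_drug", "inhibition")],
    cols = c("conc_drug", "inhibition"),
    names_to = "variable", values_to = "value")
  long$variable <- factor(long$variable, c("conc_drug", "inhibition"),
                          c("drug concentration (ng/mL)", "inhibition (%)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time / 168, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (weeks)", y = NULL) +
    ggplot2::theme_bw()
}

#' Plot visual predictive check bands
#'
#' Observed percentiles (points and dashed lines) over the simulated
#' median and its 90% prediction interval, per observation type.
#'
#' @param object A `tmdd_vpc` from [vpc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tmdd_vpc <- function(object, ...) {
  object$type <- factor(object$cmt, c(CMT_DRUG, CMT_SVAP1, CMT_ACT),
                        c("drug concentration", "sVAP-1 concentration",
                          "VAP-1 activity"))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time / 168)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_p50_lo,
                                      ymax = .data$sim_p50_hi),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$sim_p50)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p50), colour = "blue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p5), colour = "red",
                       linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p95), colour = "red",
                       linetype = 2) +
    ggplot2::facet_wrap(~type, scales = "free_y") +
    ggplot2::labs(x = "scheduled time (weeks)", y = "log observation") +
    ggplot2::theme_bw()
}

#' Plot the concentration-effect relationship
#'
#' @param object A `tmdd_curve` from [concentration_effect_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tmdd_curve <- function(object, ...) {
  ic50 <- attr(object, "ic50_ng_mL")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$conc,
                                       y = .data$inhibition)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = ic50, linetype = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "drug plasma concentration (ng/mL)",
                  y = "VAP-1 inhibition (%)") +
    ggplot2::theme_bw()
}

#' Dose-response summary plot
#'
#' Median and 5th/95th percentile of the average 24 h inhibition versus
#' dose from a population simulation.
#'
#' @param pop Stacked [simulate_population()] output (several doses).
#' @return A ggplot object.
#' @export
plot_dose_response <- function(pop) {
  sm <- population_summary(pop)
  sm <- sm[sm$metric == "avg_inhibition_24h", ]
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$dose_mg)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p5, ymax = .data$p95),
                         fill = "grey85") +
    ggplot2::geom_line(ggplot2::aes(y = .data$p50), colour = "blue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "daily dose (mg)",
                  y = "average 24 h VAP-1 inhibition (%)") +
    ggplot2::theme_bw()
}
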