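# ggplot2 visualisations for records, fits, agreement and class contrasts.

#' Plot an IVGTT record
#'
#' Glucose and insulin time courses in facetted panels, with the baselines
#' as dashed references.
#'
#' @param object An [ivgtt_dataset].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ivgtt_dataset <- function(object, ...) {
  meta <- ivgtt_meta(object)
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("glucose_mM", "insulin_pM"),
                              names_to = "analyte", values_to = "value")
  base <- tibble(analyte = c("glucose_mM", "insulin_pM"),
                 value = c(meta$G_b, meta$I_b))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(data = base,
                        ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~analyte, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(glucose_mM = "glucose (mM)",
                            insulin_pM = "insulin (pM)"))) +
    ggplot2::labs(x = "time (min)", y = NULL,
                  title = paste("IVGTT record:", meta$subject_id))
}

# dense fitted curves for overlay plots
fitted_curves <- function(fit, n = 241) {
  if (fit$model == "SDM") {
    tt <- seq(0, max(fit$residuals$time_min), length.out = n)
    sim <- simulate_sdm(fit$params, fit$G_b, fit$I_b, tt,
                        h = fit$options$h)
    tidyr::pivot_longer(sim, c("glucose_mM", "insulin_pM"),
                        names_to = "analyte", values_to = "fitted")
  } else {
    tt <- seq(fit$options$t_start, max(fit$residuals$time_min),
              length.out = n)
    sim <- simulate_mm(fit$params, fit$insulin_input, fit$G_b, fit$I_b, tt,
                       t_start = fit$options$t_start, h = fit$options$h)
    dplyr::mutate(sim, analyte = "glucose_mM",
                  fitted = .data$glucose_mM)[c("time_min", "analyte", "fitted")]
  }
}

#' Plot a fitted model over the observations
#'
#' Observed concentrations (points) with the fitted model trajectory
#' (line); for the Minimal Model only the glucose panel is modelled and the
#' interpolated insulin input is shown instead.
#'
#' @param object An `sdm_fit` or `mm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sdm_fit <- function(object, ...) {
  obs <- dplyr::mutate(object$residuals,
                       analyte = paste0(.data$analyte,
                                        ifelse(.data$analyte == "glucose",
                                               "_mM", "_pM")))
  crv <- fitted_curves(object)
  ggplot2::ggplot(crv, ggplot2::aes(x = .data$time_min)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::geom_point(data = obs, ggplot2::aes(y = .data$observed)) +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL,
                  title = sprintf("%s fit: %s", object$model,
                                  object$subject_id))
}

#' @rdname autoplot.sdm_fit
#' @export
autoplot.mm_fit <- function(object, ...) {
  obs <- dplyr::mutate(object$residuals, analyte = "glucose_mM")
  crv <- fitted_curves(object)
  ins <- tibble(
    time_min = seq(min(object$insulin_input$knot_times),
                   max(object$insulin_input$knot_times), length.out = 241)
  )
  ins$fitted <- object$insulin_input$fun(ins$time_min)
  ins$analyte <- "insulin_input_pM"
  ggplot2::ggplot(dplyr::bind_rows(crv, ins),
                  ggplot2::aes(x = .data$time_min)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::geom_point(data = obs, ggplot2::aes(y = .data$observed)) +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL,
                  title = sprintf("MM fit: %s", object$subject_id))
}

#' Bland-Altman agreement plot
#'
#' Per-subject log ratio `ln(K_xgI / S_I)` against the pair mean, with the
#' bias and the 95% limits of agreement.
#'
#' @param object A [bland_altman_log()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  bias <- attr(object, "bias")
  lim <- attr(object, "limits")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$pair_mean, y = .data$log_ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = bias) +
    ggplot2::geom_hline(yintercept = lim, linetype = "dashed") +
    ggplot2::labs(x = "pair mean of (K_xgI, S_I)",
                  y = "ln(K_xgI / S_I)",
                  title = "Bland-Altman agreement (log ratios)")
}

#' Class-wise index panel plot
#'
#' Per-BMI-class distribution of an index from the panel.
#'
#' @param object An [index_panel] tibble.
#' @param index Column to plot, default `"K_xgI"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.index_panel <- function(object, index = "K_xgI", ...) {
  stopifnot(index %in% names(object))
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$bmi_class, y = .data[[index]])) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "BMI class", y = index,
                  title = paste(index, "by BMI class"))
}
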