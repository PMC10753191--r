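#' Plot a torque trace
#'
#' Torque against time with the stimulation window shaded and, for eccentric
#' traces, the rotation onset marked.
#'
#' @param object A [force_trace()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.force_trace <- function(object, ...) {
  meta <- trace_meta(object)
  g <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$torque_Nm)) +
    ggplot2::annotate("rect", xmin = meta$stim_onset_s, xmax = meta$stim_end_s,
                      ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "steelblue") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "torque (N m)",
                  title = sprintf("%s %s (%s nerve)", meta$subject_id,
                                  meta$trace_kind, meta$nerve_target))
  if (!is.null(meta$rotation_onset_s)) {
    g <- g + ggplot2::geom_vline(xintercept = meta$rotation_onset_s,
                                 linetype = "dashed", colour = "firebrick")
  }
  g
}

#' @export
plot.force_trace <- function(x, ...) print(autoplot.force_trace(x, ...))

#' Plot a normalised eccentric-contraction decrement series
#'
#' Plateau torque as a percentage of the protocol maximum against contraction
#' number, the standard decrement display.
#'
#' @param object An `ecd_result` from [ecd_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ecd_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$k, y = .data$normalised_pct)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$accepted)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4), guide = "none") +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = "contraction number", y = "% of maximum tetanic torque",
                  title = sprintf("%s: final decrement %.1f%%",
                                  object$subject_id, object$final_decrement_pct))
}

#' Plot fibre-type composition by genotype
#'
#' Per-subject mean reporting-class percentages as points over group bars.
#'
#' @param subject_comp Output of [subject_composition()] with an added
#'   `genotype` column (or subject ids encoding genotype joined beforehand).
#' @return A ggplot object.
#' @export
plot_composition <- function(subject_comp) {
  if (!"genotype" %in% names(subject_comp)) {
    abort("subject_comp needs a genotype column")
  }
  ggplot2::ggplot(subject_comp,
                  ggplot2::aes(x = .data$reporting_class, y = .data$mean_pct,
                               fill = .data$genotype)) +
    ggplot2::stat_summary(fun = mean, geom = "col",
                          position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.8), size = 1) +
    ggplot2::labs(x = NULL, y = "% of fibres (subject mean over images)")
}

#' Display a classification threshold plot
#'
#' ROI mean fluorescence scatter for a channel pair with the fitted cutoffs,
#' mirroring the interactive thresholding plots of the reference workflow.
#'
#' @param measurements ROI table from [measure_rois()].
#' @param thresholds Threshold table from [auto_thresholds()].
#' @param x,y Channel names among `"slow"`, `"fast"`, `"regen"`.
#' @return A ggplot object.
#' @export
plot_thresholds <- function(measurements, thresholds, x = "fast", y = "slow") {
  tv <- threshold_vector(thresholds)
  col_of <- c(slow = "mean_slow", fast = "mean_fast", regen = "mean_regen")
  ggplot2::ggplot(measurements,
                  ggplot2::aes(x = .data[[col_of[[x]]]], y = .data[[col_of[[y]]]])) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = tv[[x]], colour = "firebrick") +
    ggplot2::geom_hline(yintercept = tv[[y]], colour = "firebrick") +
    ggplot2::labs(x = paste0(x, " ROI mean"), y = paste0(y, " ROI mean"))
}
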