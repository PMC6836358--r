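# ggplot2 displays for recordings and result objects.

#' Plot a waveform recording
#'
#' Stacked channel panels (flow, Paw, Pes, Edi) over an optional time
#' window, with detected breath onsets and occlusions marked when a breath
#' table is supplied.
#'
#' @param object A [as_recording()] object.
#' @param breaths Optional breath table ([detect_occlusions()]).
#' @param window Optional `c(t0, t1)` time window in seconds.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pocc_recording
#' @export
autoplot.pocc_recording <- function(object, breaths = NULL, window = NULL,
                                    ...) {
  df <- as_tibble(object)
  if (!is.null(window)) {
    df <- filter(df, .data$time >= window[1], .data$time <= window[2])
  }
  channels <- intersect(c("flow", "paw", "pes", "edi"), names(df))
  long <- tidyr::pivot_longer(df[, c("time", channels)], -"time",
                              names_to = "channel", values_to = "value")
  long$channel <- factor(long$channel, levels = channels,
                         labels = toupper(channels))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time,
                                          y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel),
                        scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
  if (!is.null(breaths) && nrow(breaths) > 0) {
    fs <- rec_rate(object)
    marks <- mutate(breaths, onset_time = (.data$start - 1) / fs)
    if (!is.null(window)) {
      marks <- filter(marks, .data$onset_time >= window[1],
                      .data$onset_time <= window[2])
    }
    p <- p + ggplot2::geom_vline(
      data = marks,
      ggplot2::aes(xintercept = .data$onset_time,
                   color = .data$occluded),
      linewidth = 0.3, alpha = 0.6
    ) +
      ggplot2::scale_color_manual(
        values = c(`FALSE` = "grey60", `TRUE` = "red"),
        labels = c(`FALSE` = "breath", `TRUE` = "occlusion"),
        name = NULL
      )
  }
  p
}

#' Bland-Altman plot of a repeated-measures agreement analysis
#'
#' @param object A [bland_altman_repeated()] object.
#' @param ... Unused.
#' @return A ggplot object: per-pair ratio (predicted/measured, log scale)
#'   against the measured value, with the bias and within-patient limits.
#' @method autoplot pocc_agreement
#' @export
autoplot.pocc_agreement <- function(object, ...) {
  d <- object$data
  lim <- 1.96 * object$la_pct_within / 196  # log-scale half-width
  ggplot2::ggplot(d, ggplot2::aes(x = .data$measured,
                                  y = exp(.data$d_log),
                                  color = .data$patient)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias_ratio) +
    ggplot2::geom_hline(yintercept = object$bias_ratio * exp(c(-lim, lim)),
                        linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::guides(color = "none") +
    ggplot2::labs(x = "measured (cm H2O)", y = "predicted / measured")
}

#' ROC curve of a discrimination analysis
#'
#' @param object A [discrimination()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pocc_roc
#' @export
autoplot.pocc_roc <- function(object, ...) {
  tab <- object$cutoffs
  ggplot2::ggplot(tab, ggplot2::aes(x = 100 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::coord_equal(xlim = c(0, 100), ylim = c(0, 100)) +
    ggplot2::labs(
      x = "100 - specificity (%)", y = "sensitivity (%)",
      title = sprintf("AUROC %.3f (threshold %g cm H2O)",
                      object$auroc, object$threshold)
    )
}

#' Distribution of cross-validated discrimination and factors
#'
#' @param object A [cross_validate()] object.
#' @param ... Unused.
#' @return A ggplot object: boxplots of the per-repetition AUROCs.
#' @method autoplot pocc_crossval
#' @export
autoplot.pocc_crossval <- function(object, ...) {
  res <- object$results
  aucs <- grep("^auroc", names(res), value = TRUE)
  long <- tidyr::pivot_longer(res[, c("rep", aucs)], -"rep",
                              names_to = "metric", values_to = "auroc")
  long$metric <- sub("^auroc_", "", long$metric)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$auroc)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::labs(x = NULL, y = "AUROC per repetition")
}
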