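#' Grand-average ERP plot by condition
#'
#' Averages retained epochs per condition at one channel and plots the
#' waveform with the P300 and LPP analysis windows shaded.
#'
#' @param epochs An `epoch_set`.
#' @param channel Channel to display.
#' @return A ggplot object.
#' @export
plot_erp <- function(epochs, channel = "Cz") {
  ch <- match(channel, epochs$channels)
  if (is.na(ch)) abort(paste0("Unknown channel: ", channel))
  keep <- !epochs$mask$rejected
  df <- purrr::map_dfr(unique(epochs$trials$condition), function(cond) {
    idx <- keep & epochs$trials$condition == cond
    tibble(condition = cond, time_ms = epochs$time_ms,
           uv = colMeans(epochs$data[idx, ch, , drop = FALSE], dims = 1))
  })
  win <- erp_windows()
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$uv,
                                   colour = .data$condition)) +
    ggplot2::annotate("rect", xmin = win$p300[1], xmax = win$p300[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.08) +
    ggplot2::annotate("rect", xmin = win$lpp[1], xmax = win$lpp[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.08) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time from picture onset (ms)",
                  y = "Amplitude (µV)",
                  title = paste("Grand-average ERP at", channel)) +
    ggplot2::theme_minimal()
}

#' E difference scores by emotion
#'
#' One point per participant, jittered, with the zero (neutral) reference
#' line, facetted by modality (and channel where present).
#'
#' @param escores A long E-score table (e.g. `run$escores`).
#' @return A ggplot object.
#' @export
plot_escores <- function(escores) {
  df <- escores
  df$panel <- ifelse(is.na(df$channel), df$modality,
                     paste(df$modality, df$channel))
  ggplot2::ggplot(df, ggplot2::aes(.data$emotion, .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "red", size = 2) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "E (emotion - neutral)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.classifier_report <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(df, c("accuracy", "auc"),
                              names_to = "metric", values_to = "value")
  ref <- tibble(metric = c("accuracy", "auc"), chance = c(50, 0.5))
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$fold), .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(data = ref, ggplot2::aes(yintercept = .data$chance),
                        linetype = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Fold", y = NULL,
                  title = paste(attr(object, "modality"),
                                attr(object, "emotion"), sep = " / ")) +
    ggplot2::theme_minimal()
}
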