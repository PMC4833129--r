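# Figures for signals and recovery summaries.

#' Plot a signal set against b-value
#'
#' @param signal A signal tibble.
#' @return A ggplot: signal vs b, one point per measurement, colored by
#'   shell.
#' @export
plot_signal <- function(signal) {
  stopifnot("signal" %in% names(signal))
  ggplot2::ggplot(signal,
                  ggplot2::aes(x = .data$b, y = .data$signal,
                               colour = factor(.data$shell))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "b (s/mm²)", y = "normalized signal",
                  colour = "shell") +
    ggplot2::theme_minimal()
}

# long-format recovery summary per (metric, truth level) for one SNR
recovery_summary_long <- function(results, snr) {
  res <- results[results$snr == snr, , drop = FALSE]
  if (nrow(res) == 0) abort("no records at the requested `snr`.")
  spec <- list(
    ICVF = c(est = "icvf_est", truth = "icvf_true"),
    ODI  = c(est = "odi_est",  truth = "odi_true"),
    FISO = c(est = "fiso_est", truth = "fiso_true")
  )
  res$fiso_true <- 0   # fixed by the study design
  purrr::imap_dfr(spec, function(cols, metric) {
    res %>%
      group_by(.data$protocol,
               truth = .data[[cols[["truth"]]]]) %>%
      summarise(mean = mean(.data[[cols[["est"]]]], na.rm = TRUE),
                sd = stats::sd(.data[[cols[["est"]]]], na.rm = TRUE),
                .groups = "drop") %>%
      mutate(metric = metric)
  })
}

#' Recovery summary figure for one SNR level
#'
#' One panel per (metric, ground-truth level): protocol means as dots,
#' standard deviations as error bars, the ground truth as a dashed line.
#' Pooling follows [aggregate_results()]: across trials, orientations and
#' the other truth parameters.
#'
#' @param results A results tibble from [run_experiment()].
#' @param snr The SNR level to display.
#' @return A ggplot object.
#' @export
plot_recovery_summary <- function(results, snr) {
  if (nrow(results) == 0 || length(unique(results$protocol)) == 0) {
    abort("`results` must contain at least one protocol.")
  }
  summ <- recovery_summary_long(results, snr)
  summ$panel <- sprintf("%s = %.2f", summ$metric, summ$truth)
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$protocol, y = .data$mean)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$truth),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd), width = 0.25) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "estimate (mean ± sd)",
                  title = sprintf("SNR_b0 = %s", format(snr))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Render one recovery figure per SNR level
#'
#' Writes one figure file per SNR level present in `results`; regeneration
#' from the same results is deterministic.
#'
#' @param results A results tibble from [run_experiment()].
#' @param dir Output directory (created if needed).
#' @param format `"pdf"` or `"png"`.
#' @param width,height Device size in inches.
#' @return Character vector of the files written, invisibly.
#' @export
render_summary_figures <- function(results, dir, format = c("pdf", "png"),
                                   width = 8, height = 6) {
  format <- arg_match(format)
  if (nrow(results) == 0 || length(unique(results$protocol)) == 0) {
    abort("`results` must contain at least one protocol.")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  snrs <- sort(unique(results$snr))
  files <- vapply(snrs, function(s) {
    label <- if (is.infinite(s)) "Inf" else format(s)
    f <- file.path(dir, sprintf("recovery_snr_%s.%s", label, format))
    p <- plot_recovery_summary(results, s)
    ggplot2::ggsave(f, p, width = width, height = height)
    f
  }, character(1))
  invisible(files)
}
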