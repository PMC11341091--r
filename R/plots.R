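#' Tidiers for popdprime objects
#'
#' broom-style [generics::tidy()] and [generics::glance()] methods:
#' `tidy.evoked_set()` returns one row per (event, neuron) response;
#' `tidy.fa_fit()` one row per (neuron, factor) loading;
#' `glance.fa_fit()` one-row model summary; `glance.task_report()` the
#' headline statistics of a pipeline run.
#'
#' @param x Object to tidy.
#' @param ... Unused.
#' @name tidy_popdprime
NULL

#' Psychometric curve plot
#'
#' Behavioral d-prime against target SNR (finite SNRs on a linear axis,
#' the pure-tone condition at the right edge).
#'
#' @param behavior Output of [psychometric_table()] (optionally with a
#'   `session` column).
#' @return A ggplot object.
#' @export
plot_psychometric <- function(behavior) {
  b <- dplyr::mutate(behavior,
                     snr_plot = ifelse(is.finite(.data$snr_db), .data$snr_db,
                                       max(.data$snr_db[is.finite(.data$snr_db)], 0) + 10),
                     snr_lab = ifelse(is.finite(.data$snr_db),
                                      as.character(.data$snr_db), "Inf"))
  p <- ggplot2::ggplot(b, ggplot2::aes(x = .data$snr_plot, y = .data$dprime))
  if ("session" %in% names(b)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(group = .data$session), alpha = 0.4)
  } else {
    p <- p + ggplot2::geom_line()
  }
  p +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(b$snr_plot),
                                labels = unique(b$snr_lab)) +
    ggplot2::labs(x = "Target SNR (dB)", y = "Behavioral d-prime") +
    ggplot2::theme_minimal()
}

#' Population activity in the dDR plane
#'
#' Single-trial responses of two classes projected onto the signal and
#' noise axes.
#'
#' @param space A `ddr_space`.
#' @param responses_a,responses_b Trials x neurons matrices.
#' @param labels Class labels for the legend.
#' @return A ggplot object.
#' @export
plot_ddr_projection <- function(space, responses_a, responses_b,
                                labels = c("a", "b")) {
  Ap <- as.matrix(responses_a) %*% t(space$proj)
  Bp <- as.matrix(responses_b) %*% t(space$proj)
  if (ncol(Ap) < 2) abort("The dDR space is 1-D; nothing to plot.")
  df <- dplyr::bind_rows(
    tibble(signal = Ap[, 1], noise = Ap[, 2], class = labels[1]),
    tibble(signal = Bp[, 1], noise = Bp[, 2], class = labels[2])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$signal, y = .data$noise,
                                   color = .data$class)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::stat_ellipse() +
    ggplot2::labs(x = "Signal axis", y = "Noise axis") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_decoding autoplot method for decoding tables.
#' @export
autoplot.decoding_tbl <- function(object, ...) plot_decoding(object, ...)

#' Decoding improvement by pair category
#'
#' Normalized engagement-related change in population d-prime
#' (\eqn{(a - p)/(a + p)}) per stimulus pair, grouped by task relevance.
#'
#' @param results A `decoding_tbl`.
#' @param metric Column to display.
#' @param object A `decoding_tbl` (autoplot method).
#' @param ... Passed through.
#' @return A ggplot object.
#' @export
plot_decoding <- function(results, metric = "delta_norm", ...) {
  ggplot2::ggplot(results, ggplot2::aes(x = .data$category,
                                        y = .data[[metric]])) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}

#' Simulated vs actual selective enhancement per ablation model
#'
#' @param simulated Named list of per-model numeric vectors (per session).
#' @param actual Actual per-session values.
#' @return A ggplot object.
#' @export
plot_model_performance <- function(simulated, actual) {
  df <- purrr::imap(simulated, function(v, m) {
    tibble(model = m, simulated = v, actual = actual)
  }) |> dplyr::bind_rows() |>
    dplyr::mutate(model = factor(.data$model, levels = sim_models()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$actual, y = .data$simulated)) +
    ggplot2::geom_abline(linetype = 2, color = "grey50") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "Actual selective enhancement",
                  y = "Simulated selective enhancement") +
    ggplot2::theme_minimal()
}
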