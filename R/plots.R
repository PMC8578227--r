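# ggplot2 graphics for records, cohorts and training runs.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the heart-rate distribution of a cohort
#'
#' Histogram of per-record heart rates with the clinical normal band
#' (60-99 bpm) filled differently from the bradycardic / tachycardic
#' tails, and boundary lines at 60 and 100 bpm.
#'
#' @param features tibble with a `heart_rate` column.
#' @param binwidth histogram bin width in bpm.
#' @return a ggplot.
#' @export
plot_hr_distribution <- function(features, binwidth = 2) {
  df <- dplyr::filter(features, !is.na(.data$heart_rate))
  df$band <- ifelse(df$heart_rate >= 60 & df$heart_rate < 100,
                    "normal (60-99)", "outside normal range")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$heart_rate,
                                   fill = .data$band)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            colour = "grey30", linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = c(60, 100), linetype = 2) +
    ggplot2::scale_fill_manual(values = c("normal (60-99)" = "steelblue",
                                          "outside normal range" = "firebrick"),
                               name = NULL) +
    ggplot2::labs(x = "heart rate (bpm)", y = "records") +
    ggplot2::theme_minimal()
}

#' Plot the QT/RR relationship
#'
#' One point per record; the squared Pearson correlation is annotated.
#' With a `cohort` column the cohorts are coloured separately (e.g. real
#' vs generated).
#'
#' @param features tibble with `qt_interval` and `rr_mean` (or
#'   `rr_interval`) columns, optionally a `cohort` column.
#' @return a ggplot.
#' @export
plot_qt_rr <- function(features) {
  rr <- features[["rr_mean"]] %||% features[["rr_interval"]]
  df <- tibble::tibble(rr = rr, qt = features$qt_interval,
                       cohort = features[["cohort"]] %||% "cohort")
  df <- dplyr::filter(df, !is.na(.data$rr), !is.na(.data$qt))
  r2 <- stats::cor(df$rr, df$qt)^2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rr, y = .data$qt,
                                   colour = .data$cohort)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.2, vjust = 1.5,
                      label = sprintf("r^2 == %.2f", r2), parse = TRUE) +
    ggplot2::labs(x = "RR interval (ms)", y = "QT interval (ms)") +
    ggplot2::theme_minimal()
}

#' Plot an ECG record
#'
#' Stacked lead traces of the 12-lead view (derived on the fly for an
#' 8-channel record).
#'
#' @param object an [ecg8()] or `ecg12` object.
#' @param leads leads to draw (default all 12).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ecg8 <- function(object, leads = NULL, ...) {
  autoplot.ecg12(derive_12_from_8(object), leads = leads, ...)
}

#' @rdname autoplot.ecg8
#' @export
autoplot.ecg12 <- function(object, leads = NULL, ...) {
  s <- object$samples
  if (is.null(leads)) leads <- rownames(s)
  t_s <- (seq_len(ncol(s)) - 1) / object$sampling_rate
  df <- tidyr::pivot_longer(
    tibble::as_tibble(cbind(time = t_s, as.data.frame(t(s[leads, ,
                                                          drop = FALSE])))),
    -"time", names_to = "lead", values_to = "uv")
  df$lead <- factor(df$lead, levels = leads)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$uv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$lead), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "amplitude (µV)") +
    ggplot2::theme_minimal()
}

#' Plot a training run's loss history
#'
#' Critic Wasserstein estimate, gradient penalty and generator loss over
#' update steps.
#'
#' @param object a `gan_train_state`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gan_train_state <- function(object, ...) {
  h <- object$history
  df <- dplyr::bind_rows(
    tibble::tibble(step = h$step[h$kind == "critic"],
                   value = h$wasserstein[h$kind == "critic"],
                   series = "Wasserstein estimate"),
    tibble::tibble(step = h$step[h$kind == "critic"],
                   value = h$penalty[h$kind == "critic"],
                   series = "gradient penalty"),
    tibble::tibble(step = h$step[h$kind == "generator"],
                   value = h$loss[h$kind == "generator"],
                   series = "generator loss"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$series), ncol = 1,
                        scales = "free_y") +
    ggplot2::labs(x = "update step", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cohort summary
#'
#' Mean with the 2.5-97.5 percentile span per feature.
#'
#' @param object a `cohort_summary`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cohort_summary <- function(object, ...) {
  s <- dplyr::filter(object$stats, !.data$flagged)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$mean, y = .data$feature)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$pct_2_5,
                                          xmax = .data$pct_97_5)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$feature), scales = "free",
                        ncol = 2) +
    ggplot2::labs(x = "value (ms / bpm / µV)", y = NULL) +
    ggplot2::theme_minimal()
}
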