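#' Plot kinetic flux traces
#'
#' OCR and ECAR against time, one line per well, colored by group, with
#' injection boundaries marked when a schedule is attached.
#'
#' @param object A `flux_traces` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flux_traces
#' @export
autoplot.flux_traces <- function(object, ...) {
  long <- object |>
    tibble::as_tibble() |>
    tidyr::pivot_longer(c("ocr", "ecar"), names_to = "rate",
                        values_to = "value") |>
    dplyr::mutate(rate = dplyr::recode(.data$rate,
                                       ocr = "OCR (pmol O2/min)",
                                       ecar = "ECAR (mpH/min)"))
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$time_min, y = .data$value,
    group = .data$well, colour = .data$group
  )) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~rate, scales = "free_y") +
    ggplot2::labs(x = "Time (min)", y = NULL, colour = "Population")
  sched <- attr(object, "schedule")
  if (!is.null(sched)) {
    inj <- sched$first_index[-1]
    times <- vapply(inj, function(i) {
      min(object$time_min[object$measurement == i])
    }, numeric(1))
    p <- p + ggplot2::geom_vline(xintercept = times, linetype = "dashed",
                                 colour = "grey50")
  }
  p
}

#' Plot per-group flux metric summaries
#'
#' Bar plot of group means with mean +/- sd error bars, faceted by metric.
#'
#' @param summary Output of [summarize_groups()].
#' @return A ggplot object.
#' @export
plot_metric_summary <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(
    x = .data$group, y = .data$mean, fill = .data$group
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd
    ), width = 0.3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean ± sd") +
    ggplot2::guides(fill = "none")
}

#' Plot pathway mean-z trajectories
#'
#' @param object A `pathway_trajectory` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pathway_trajectory
#' @export
autoplot.pathway_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$population, y = .data$mean_z,
    group = .data$pathway, colour = .data$pathway
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "Average z-score", colour = "Pathway")
}

#' Correlation volcano plot
#'
#' Pearson r against -log10 BH-adjusted p, colored by sign class, with the
#' significance level and the +/- r threshold marked — the scatter used to
#' read off which panel genes track a flux metric.
#'
#' @param object A `correlation_result` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot correlation_result
#' @export
autoplot.correlation_result <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  thr <- attr(object, "r_threshold") %||% 0.5
  d <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$r))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$r, y = -log10(.data$p_adj), colour = .data$sign_class
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(alpha), colour = "black") +
    ggplot2::geom_vline(xintercept = c(-thr, thr), linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(
      positive = "#e05c8a", negative = "#4477c9", weak = "grey60"
    )) +
    ggplot2::xlim(-1, 1) +
    ggplot2::labs(x = "Pearson R", y = expression(-log[10] ~ "adjusted p"),
                  colour = NULL)
}

#' @method tidy correlation_result
#' @export
tidy.correlation_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @method glance correlation_result
#' @export
glance.correlation_result <- function(x, ...) {
  alpha <- attr(x, "alpha") %||% 0.05
  tibble::tibble(
    n_genes = nrow(x),
    n_positive = sum(x$sign_class == "positive", na.rm = TRUE),
    n_negative = sum(x$sign_class == "negative", na.rm = TRUE),
    n_weak = sum(x$sign_class == "weak", na.rm = TRUE),
    n_significant = sum(x$p_adj < alpha, na.rm = TRUE),
    n_excluded = sum(!is.na(x$excluded_reason))
  )
}

#' Write per-well metrics and group summaries to TSV
#'
#' @param metrics A `flux_metrics` tibble.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly; writes `well_metrics.tsv` and
#'   `group_summary.tsv`.
#' @export
write_flux_metrics <- function(metrics, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(tibble::as_tibble(metrics),
                   file.path(dir, "well_metrics.tsv"))
  readr::write_tsv(summarize_groups(metrics),
                   file.path(dir, "group_summary.tsv"))
  invisible(dir)
}
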