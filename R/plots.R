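#' Plot the degree distribution of a differential network
#'
#' Bar chart of node degrees with hubs highlighted and the percentile
#' cutoff drawn as a dashed line.
#'
#' @param object A `diff_net`.
#' @param percentile Hub percentile (default 80).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.diff_net <- function(object, percentile = 80, ...) {
  hubs <- identify_hubs(object, percentile = percentile)
  tbl <- hubs$degree_table
  ggplot2::ggplot(tbl, ggplot2::aes(
    x = stats::reorder(.data$gene, .data$degree),
    y = .data$degree, fill = .data$is_hub)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = hubs$degree_cutoff, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick"),
                               name = "hub") +
    ggplot2::labs(x = NULL, y = "differential links",
                  title = sprintf("Differential co-expression degrees (Z ≥ %.3g)",
                                  object$z_threshold))
}

#' Plot cross-cohort degree agreement
#'
#' @param object A `net_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.net_comparison <- function(object, ...) {
  ggplot2::ggplot(object$degrees,
                  ggplot2::aes(x = .data$degree_a, y = .data$degree_b)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$gene), vjust = -0.6, size = 3) +
    ggplot2::labs(x = "degree (discovery)", y = "degree (validation)",
                  title = sprintf("Degree rank correlation = %.2f",
                                  object$degree_rank_correlation))
}

#' Kaplan-Meier curves by group
#'
#' @param tbl A [survival_table()].
#' @param ... Unused.
#' @return A ggplot object with one survival step function per group.
#' @export
plot_km <- function(tbl, ...) {
  km <- km_estimate(tbl)
  start <- dplyr::distinct(km, .data$group)
  start$time <- 0; start$survival <- 1
  curves <- dplyr::bind_rows(
    start[c("group", "time", "survival")],
    km[c("group", "time", "survival")])
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$survival,
                                       colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "overall survival", colour = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
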