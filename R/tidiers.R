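#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a differential network into its edge table
#' @param x A `diff_net`.
#' @param ... Unused.
#' @return A tibble (gene_a, gene_b, rho_T, rho_C, z_T, z_C, Z).
#' @exportS3Method generics::tidy
#' @export
tidy.diff_net <- function(x, ...) x$edges

#' @rdname tidy.diff_net
#' @exportS3Method generics::glance
#' @export
glance.diff_net <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$nodes), n_edges = nrow(x$edges),
                 z_threshold = x$z_threshold, density = x$density,
                 n_T = x$n_T, n_C = x$n_C)
}

#' Tidy a hub report into its degree table
#' @param x A `hub_report`.
#' @param ... Unused.
#' @return A tibble (gene, degree, is_hub).
#' @exportS3Method generics::tidy
#' @export
tidy.hub_report <- function(x, ...) x$degree_table

#' @rdname tidy.hub_report
#' @exportS3Method generics::glance
#' @export
glance.hub_report <- function(x, ...) {
  tibble::tibble(n_hubs = length(x$hubs), percentile = x$percentile,
                 degree_cutoff = x$degree_cutoff,
                 n_connected = nrow(x$degree_table))
}

#' Tidy a fuzzy C-means fit
#' @param x An `fcm_fit`.
#' @param ... Unused.
#' @return One row per subject: memberships, hard cluster, and tag when
#'   [tag_clusters()] has been applied.
#' @exportS3Method generics::tidy
#' @export
tidy.fcm_fit <- function(x, ...) {
  out <- dplyr::bind_cols(tibble::tibble(subject = x$subjects),
                          tibble::as_tibble(x$membership),
                          tibble::tibble(cluster = x$hard_labels))
  if (!is.null(x$subject_tags)) out$tag <- x$subject_tags
  out
}

#' @rdname tidy.fcm_fit
#' @exportS3Method generics::glance
#' @export
glance.fcm_fit <- function(x, ...) {
  tibble::tibble(n_subjects = length(x$subjects),
                 n_clusters = ncol(x$membership),
                 objective = utils::tail(x$objective, 1),
                 iterations = x$iterations, converged = x$converged)
}

#' Tidy survival test results
#' @param x A `logrank_result` or `hr_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @exportS3Method generics::tidy
#' @export
tidy.logrank_result <- function(x, ...) {
  tibble::tibble(chi_square = x$chi_square, df = x$df, p = x$p)
}

#' @rdname tidy.logrank_result
#' @exportS3Method generics::tidy
#' @export
tidy.hr_result <- function(x, ...) {
  tibble::tibble(hr = x$hr, ci_lower = x$ci_lower, ci_upper = x$ci_upper,
                 numerator = x$numerator, denominator = x$denominator, p = x$p)
}

#' Tidy a cross-cohort comparison into its degree table
#' @param x A `net_comparison`.
#' @param ... Unused.
#' @return A tibble (gene, degree_a, degree_b).
#' @exportS3Method generics::tidy
#' @export
tidy.net_comparison <- function(x, ...) x$degrees

#' @rdname tidy.net_comparison
#' @exportS3Method generics::glance
#' @export
glance.net_comparison <- function(x, ...) {
  ov <- x$hub_overlap
  tibble::tibble(degree_rank_correlation = x$degree_rank_correlation,
                 min_degree = x$min_degree,
                 hubs_only_a = length(ov$only_a),
                 hubs_shared = length(ov$shared),
                 hubs_only_b = length(ov$only_b))
}

#' One-row summary of a pipeline run
#' @param x A `lect_run_report` from [run_discovery_validation()].
#' @param ... Unused.
#' @return A one-row tibble of the headline quantities each stage computed.
#' @exportS3Method generics::glance
#' @export
glance.lect_run_report <- function(x, ...) {
  s <- x$stages
  out <- tibble::tibble(
    genes_kept = s$preprocess_discovery$genes_kept,
    n_edges = s$differential_network$n_edges,
    density = s$differential_network$density,
    n_hubs = length(s$differential_network$hubs$hubs),
    n_de_flagged = s$differential_expression$n_flagged)
  if (!is.null(s$validation)) {
    out$validation_threshold <- s$validation$threshold
    out$degree_rank_correlation <- s$validation$comparison$degree_rank_correlation
    out$shared_hubs <- length(s$validation$comparison$hub_overlap$shared)
  }
  if (!is.null(s$survival)) {
    out$logrank_p <- s$survival$logrank$p
    out$hazard_ratio <- s$survival$hazard_ratio$hr
  }
  out
}
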