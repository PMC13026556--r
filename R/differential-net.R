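#' Fisher Z-transformation of a correlation coefficient
#'
#' `atanh(rho)`, the variance-stabilizing transform whose sampling
#' distribution is approximately normal with variance 1/(n - 3). Values
#' within 1e-15 of +/-1 are clamped so the transform stays finite.
#'
#' @param rho Correlation coefficient(s) in \[-1, 1\].
#' @return Transformed value(s), same length as `rho`.
#' @export
fisher_z <- function(rho) {
  if (any(abs(rho) > 1)) stop("|rho| must not exceed 1", call. = FALSE)
  eps <- 1e-15
  atanh(pmin(pmax(rho, -1 + eps), 1 - eps))
}

#' Differential co-expression z-score for one gene pair
#'
#' The two condition-specific correlations are Fisher-transformed and their
#' difference standardized by the pooled Fisher variance:
#' \deqn{Z = \frac{z_T - z_C}{\sqrt{1/(n_T-3) + 1/(n_C-3)}}}
#' Positive Z means the pair is more strongly co-expressed in the tumor
#' cohort than in the control cohort.
#'
#' @param rho_tumor,rho_control Spearman coefficients in the two conditions.
#' @param n_tumor,n_control Sample counts of the two cohorts (each > 3).
#' @param spearman_correction If `TRUE`, uses the 1.06/(n - 3) asymptotic
#'   variance appropriate for Spearman coefficients instead of the plain
#'   Fisher 1/(n - 3). Default `FALSE`.
#' @return The z-score (vectorized over the correlations).
#' @export
differential_zscore <- function(rho_tumor, rho_control, n_tumor, n_control,
                                spearman_correction = FALSE) {
  if (n_tumor <= 3 || n_control <= 3) {
    stop("both cohorts need more than 3 samples", call. = FALSE)
  }
  kappa <- if (spearman_correction) 1.06 else 1
  denom <- sqrt(kappa / (n_tumor - 3) + kappa / (n_control - 3))
  (fisher_z(rho_tumor) - fisher_z(rho_control)) / denom
}

# Full per-pair differential table for two aligned correlation matrices.
differential_pairs <- function(corr_tumor, corr_control,
                               spearman_correction = FALSE) {
  stopifnot(inherits(corr_tumor, "corr_mat"), inherits(corr_control, "corr_mat"))
  if (!identical(rownames(corr_tumor), rownames(corr_control))) {
    stop("the two correlation matrices must share the same genes in the same order",
         call. = FALSE)
  }
  genes <- rownames(corr_tumor)
  n_t <- attr(corr_tumor, "n_samples")
  n_c <- attr(corr_control, "n_samples")
  idx <- which(upper.tri(corr_tumor), arr.ind = TRUE)
  rho_t <- corr_tumor[idx]
  rho_c <- corr_control[idx]
  tibble::tibble(
    gene_a = genes[idx[, 1]],
    gene_b = genes[idx[, 2]],
    rho_T = rho_t,
    rho_C = rho_c,
    z_T = fisher_z(rho_t),
    z_C = fisher_z(rho_c),
    Z = differential_zscore(rho_t, rho_c, n_t, n_c,
                            spearman_correction = spearman_correction)
  )
}

#' Build the differential co-expression network
#'
#' Scores every gene pair with [differential_zscore()] and keeps edges whose
#' Z reaches `z_threshold` (inclusive), i.e. pairs whose co-expression
#' increases significantly in the tumor condition. With `positive_only =
#' TRUE` (the default) an edge additionally requires a positive tumor
#' correlation, excluding negative-to-less-negative changes.
#'
#' @param corr_tumor,corr_control `corr_mat` objects over the same gene set
#'   in the same order.
#' @param z_threshold Retention threshold on Z (default 3).
#' @param positive_only Require `rho_T > 0` for retained edges (default TRUE).
#' @param spearman_correction Passed to [differential_zscore()].
#' @return A list of class `diff_net`: `nodes`, `edges` (tibble gene_a,
#'   gene_b, rho_T, rho_C, z_T, z_C, Z), `z_threshold`, `n_T`, `n_C`,
#'   `density` (edges / possible pairs) and `pairs` (the full unthresholded
#'   pair table, used for density matching).
#' @export
build_differential_network <- function(corr_tumor, corr_control,
                                       z_threshold = 3,
                                       positive_only = TRUE,
                                       spearman_correction = FALSE) {
  pairs <- differential_pairs(corr_tumor, corr_control,
                              spearman_correction = spearman_correction)
  candidate <- if (positive_only) dplyr::filter(pairs, .data$rho_T > 0) else pairs
  edges <- dplyr::filter(candidate, .data$Z >= z_threshold)
  nodes <- rownames(corr_tumor)
  n_pairs <- length(nodes) * (length(nodes) - 1) / 2
  structure(list(nodes = nodes,
                 edges = dplyr::arrange(edges, dplyr::desc(.data$Z)),
                 z_threshold = z_threshold,
                 n_T = attr(corr_tumor, "n_samples"),
                 n_C = attr(corr_control, "n_samples"),
                 density = nrow(edges) / n_pairs,
                 positive_only = positive_only,
                 pairs = pairs),
            class = "diff_net")
}

#' @export
print.diff_net <- function(x, ...) {
  cat(sprintf(
    "# Differential co-expression network: %d nodes, %d edges (Z >= %.4g, density %.4f)\n",
    length(x$nodes), nrow(x$edges), x$z_threshold, x$density))
  cat(sprintf("# cohorts: n_T = %d, n_C = %d\n", x$n_T, x$n_C))
  print(x$edges, n = 5)
  invisible(x)
}

#' Density-matched threshold for a validation network
#'
#' For cross-cohort validation the second differential comparison is
#' thresholded not at a fixed Z but at the value that makes its edge density
#' most comparable to a reference network's. Candidate thresholds are the
#' distinct Z values observed in the second comparison; the one minimizing
#' the absolute density difference is chosen, with ties broken toward the
#' higher (stricter) threshold.
#'
#' @param reference A `diff_net` with at least one edge.
#' @param corr_tumor,corr_control Correlation matrices of the second
#'   comparison.
#' @param positive_only,spearman_correction Passed through to
#'   [build_differential_network()].
#' @return A list with `threshold` (the chosen Z cutoff) and `network` (the
#'   resulting `diff_net`).
#' @export
match_density_threshold <- function(reference, corr_tumor, corr_control,
                                    positive_only = reference$positive_only,
                                    spearman_correction = FALSE) {
  stopifnot(inherits(reference, "diff_net"))
  if (nrow(reference$edges) == 0L) {
    stop("reference network has no edges; density matching is undefined", call. = FALSE)
  }
  pairs <- differential_pairs(corr_tumor, corr_control,
                              spearman_correction = spearman_correction)
  candidate <- if (positive_only) dplyr::filter(pairs, .data$rho_T > 0) else pairs
  n_genes <- nrow(corr_tumor)
  n_pairs <- n_genes * (n_genes - 1) / 2
  # candidate thresholds, high to low, so ties resolve to the stricter cut
  thresholds <- sort(unique(candidate$Z), decreasing = TRUE)
  densities <- vapply(thresholds,
                      function(t) sum(candidate$Z >= t) / n_pairs,
                      numeric(1))
  best <- which.min(abs(densities - reference$density))
  thr <- thresholds[best]
  net <- build_differential_network(corr_tumor, corr_control,
                                    z_threshold = thr,
                                    positive_only = positive_only,
                                    spearman_correction = spearman_correction)
  list(threshold = thr, network = net)
}

#' Node degrees of a differential network
#'
#' @param net A `diff_net`.
#' @param include_isolated Include nodes with no edge (degree 0)?
#' @return A tibble (gene, degree) sorted by decreasing degree.
#' @export
node_degrees <- function(net, include_isolated = FALSE) {
  stopifnot(inherits(net, "diff_net"))
  counts <- table(factor(c(net$edges$gene_a, net$edges$gene_b), levels = net$nodes))
  tbl <- tibble::tibble(gene = names(counts), degree = as.integer(counts))
  if (!include_isolated) tbl <- dplyr::filter(tbl, .data$degree > 0)
  dplyr::arrange(tbl, dplyr::desc(.data$degree), .data$gene)
}

#' Identify hub genes by degree percentile
#'
#' Hubs are the nodes whose degree falls at or above the given percentile of
#' the network's degree distribution. The distribution is taken over
#' connected nodes (degree >= 1); the cutoff is the nearest-rank percentile
#' of the distinct degree values, so a single dominant node is called alone
#' even when many leaves tie below it, and a degree-regular network makes
#' every connected node a hub.
#'
#' @param net A `diff_net` with at least one edge.
#' @param percentile Percentile of the degree distribution (default 80).
#' @return A list of class `hub_report`: `degree_table` (tibble gene,
#'   degree, is_hub), `percentile`, `degree_cutoff`, `hubs` (character).
#' @export
identify_hubs <- function(net, percentile = 80) {
  stopifnot(inherits(net, "diff_net"))
  deg <- node_degrees(net, include_isolated = FALSE)
  if (nrow(deg) == 0L) stop("network has no edges; no degree distribution", call. = FALSE)
  stopifnot(percentile >= 0, percentile <= 100)
  levels <- sort(unique(deg$degree))
  k <- max(1L, ceiling(percentile / 100 * length(levels)))
  cutoff <- levels[k]
  deg <- dplyr::mutate(deg, is_hub = .data$degree >= cutoff)
  structure(list(degree_table = deg,
                 percentile = percentile,
                 degree_cutoff = cutoff,
                 hubs = deg$gene[deg$is_hub]),
            class = "hub_report")
}

#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf("# Hub report: %d hub(s) at the %.4gth degree percentile (degree >= %d)\n",
              length(x$hubs), x$percentile, x$degree_cutoff))
  cat("# ", paste(x$hubs, collapse = ", "), "\n")
  invisible(x)
}

#' Cross-cohort network agreement
#'
#' Compares two differential networks built over (partly) shared genes:
#' the Spearman correlation of node degrees over shared genes that reach
#' `min_degree` links in at least one network, and the overlap of the two
#' hub sets.
#'
#' @param net_a,net_b `diff_net` objects (e.g. discovery and validation).
#' @param min_degree Only genes with at least this many links in one of the
#'   networks enter the rank correlation (default 5).
#' @param percentile Hub percentile applied to both networks (default 80).
#' @return A list of class `net_comparison`: `degree_rank_correlation`,
#'   `degrees` (tibble gene, degree_a, degree_b), `hub_overlap` (list
#'   only_a / shared / only_b), and the two `hub_report`s.
#' @export
compare_networks <- function(net_a, net_b, min_degree = 5, percentile = 80) {
  stopifnot(inherits(net_a, "diff_net"), inherits(net_b, "diff_net"))
  shared <- intersect(net_a$nodes, net_b$nodes)
  deg_a <- node_degrees(net_a, include_isolated = TRUE)
  deg_b <- node_degrees(net_b, include_isolated = TRUE)
  degs <- dplyr::inner_join(
    dplyr::rename(deg_a, degree_a = "degree"),
    dplyr::rename(deg_b, degree_b = "degree"),
    by = "gene")
  degs <- dplyr::filter(degs, .data$gene %in% shared,
                        pmax(.data$degree_a, .data$degree_b) >= min_degree)
  if (nrow(degs) < 3L) {
    stop("fewer than 3 shared genes reach min_degree; rank correlation undefined",
         call. = FALSE)
  }
  rho <- stats::cor(degs$degree_a, degs$degree_b, method = "spearman")
  hubs_a <- identify_hubs(net_a, percentile = percentile)
  hubs_b <- identify_hubs(net_b, percentile = percentile)
  structure(list(
    degree_rank_correlation = rho,
    degrees = degs,
    hub_overlap = list(only_a = setdiff(hubs_a$hubs, hubs_b$hubs),
                       shared = intersect(hubs_a$hubs, hubs_b$hubs),
                       only_b = setdiff(hubs_b$hubs, hubs_a$hubs)),
    hubs_a = hubs_a,
    hubs_b = hubs_b,
    min_degree = min_degree), class = "net_comparison")
}

#' @export
print.net_comparison <- function(x, ...) {
  cat(sprintf("# Network comparison: degree rank correlation %.3f (min degree %d)\n",
              x$degree_rank_correlation, x$min_degree))
  ov <- x$hub_overlap
  cat(sprintf("# hubs: %d only in A, %d shared, %d only in B\n",
              length(ov$only_a), length(ov$shared), length(ov$only_b)))
  if (length(ov$shared)) cat("# shared hubs:", paste(ov$shared, collapse = ", "), "\n")
  invisible(x)
}

#' Export a network edge list as TSV
#' @param net A `diff_net` or `coexpr_net`.
#' @param path Output path.
#' @return `net`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  edges <- if (inherits(net, "diff_net")) {
    dplyr::select(net$edges, "gene_a", "gene_b", "rho_T", "rho_C", "Z")
  } else if (inherits(net, "coexpr_net")) {
    net$edges
  } else stop("not a network object", call. = FALSE)
  readr::write_tsv(edges, path, progress = FALSE)
  invisible(net)
}

#' Export a network as GraphML
#'
#' Minimal GraphML with node ids and, for differential networks, the
#' per-edge correlations and z-score as edge attributes.
#'
#' @param net A `diff_net` or `coexpr_net`.
#' @param path Output path.
#' @return `net`, invisibly.
#' @export
write_graphml <- function(net, path) {
  if (inherits(net, "diff_net")) {
    nodes <- net$nodes
    edges <- net$edges
    keys <- c(rho_T = "double", rho_C = "double", Z = "double")
  } else if (inherits(net, "coexpr_net")) {
    nodes <- net$nodes
    edges <- net$edges
    keys <- c(rho = "double")
  } else stop("not a network object", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    sprintf('  <key id="%s" for="edge" attr.name="%s" attr.type="%s"/>',
            names(keys), names(keys), keys),
    '  <graph edgedefault="undirected">'), con)
  writeLines(sprintf('    <node id="%s"/>', nodes), con)
  for (i in seq_len(nrow(edges))) {
    writeLines(sprintf('    <edge source="%s" target="%s">',
                       edges$gene_a[i], edges$gene_b[i]), con)
    for (k in names(keys)) {
      writeLines(sprintf('      <data key="%s">%.10g</data>', k, edges[[k]][i]), con)
    }
    writeLines('    </edge>', con)
  }
  writeLines(c('  </graph>', '</graphml>'), con)
  invisible(net)
}
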