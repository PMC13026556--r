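#' Run the full discovery / validation pipeline
#'
#' Orchestrates the analysis end to end: panel subsetting, the 500-count
#' low-expression filter, median-of-ratios + log2 normalization, per-condition
#' Spearman matrices, the differential co-expression network (tumor vs
#' control) with degree-percentile hub calling, per-gene differential
#' expression annotation, and — when a validation cohort is supplied — a
#' density-matched validation network with cross-cohort degree agreement and
#' hub overlap. When a clinical table is supplied, subjects are stratified on
#' the marker genes (fuzzy C-means low/high tagging, or four-way median
#' splits) and compared by Kaplan-Meier / log-rank with a Mantel-Haenszel
#' hazard ratio.
#'
#' @param discovery,control `lect_expr` raw-count matrices (e.g. a tumor
#'   cohort and a healthy-tissue cohort).
#' @param validation Optional second tumor cohort (`lect_expr`), thresholded
#'   by density matching against the discovery network.
#' @param panel Optional `lect_panel`; matrices are subset to it first.
#' @param clinical Optional tibble with columns `subject_id`, `os_months`,
#'   `event`; subject ids must match discovery sample ids.
#' @param markers Genes used for stratification; defaults to the two
#'   highest-degree hubs (shared hubs when a validation cohort is present).
#' @param min_total Count filter threshold (default 500).
#' @param z_threshold Differential z-score threshold (default 3).
#' @param hub_percentile Degree percentile for hub calling (default 80).
#' @param fc_threshold,alpha Differential-expression call thresholds.
#' @param min_degree Degree restriction for the cross-cohort rank
#'   correlation (default 5).
#' @param stratify_method `"fcm"` (two fuzzy clusters tagged low/high) or
#'   `"median"` (four median-split groups; the survival contrast is then
#'   lo/lo vs hi/hi).
#' @param seed Seed driving the fuzzy C-means initialization.
#' @return A list of class `lect_run_report`; see the `stages` element for
#'   per-stage objects and [glance.lect_run_report()] for the one-row
#'   summary.
#' @export
run_discovery_validation <- function(discovery, control, validation = NULL,
                                     panel = NULL, clinical = NULL,
                                     markers = NULL,
                                     min_total = 500, z_threshold = 3,
                                     hub_percentile = 80,
                                     fc_threshold = 1.5, alpha = 0.05,
                                     min_degree = 5,
                                     stratify_method = c("fcm", "median"),
                                     seed = 1L) {
  stratify_method <- match.arg(stratify_method)
  stages <- list()

  prep <- function(mat, label) {
    if (!is.null(panel)) mat <- subset_to_panel(mat, panel)
    filtered <- filter_low_expression(mat, min_total = min_total)
    stages[[paste0("preprocess_", label)]] <<- list(
      genes_in = nrow(mat), genes_kept = nrow(filtered),
      removed = attr(filtered, "removed_genes"))
    normalize_log2(filtered)
  }
  disc <- prep(discovery, "discovery")
  ctrl <- prep(control, "control")

  shared <- intersect(disc$gene, ctrl$gene)
  if (length(shared) < 2L) stop("discovery stage: fewer than 2 shared genes", call. = FALSE)
  align <- function(x) new_expr_from(x, expr_values(x)[shared, , drop = FALSE])
  disc <- align(disc); ctrl <- align(ctrl)

  corr_d <- spearman_matrix(disc)
  corr_c <- spearman_matrix(ctrl)
  net <- build_differential_network(corr_d, corr_c, z_threshold = z_threshold)
  hubs <- identify_hubs(net, percentile = hub_percentile)
  de <- differential_expression(disc, ctrl, fc_threshold = fc_threshold, alpha = alpha)
  hub_de <- dplyr::mutate(
    dplyr::filter(de, .data$gene %in% hubs$hubs),
    status = ifelse(.data$flag_de, "upregulated", "unchanged"))
  stages$differential_network <- list(network = net, hubs = hubs,
                                      n_edges = nrow(net$edges),
                                      density = net$density)
  stages$differential_expression <- list(table = de, hub_annotation = hub_de,
                                         n_flagged = sum(de$flag_de))

  comparison <- NULL
  if (!is.null(validation)) {
    vali <- prep(validation, "validation")
    shared_v <- intersect(vali$gene, ctrl$gene)
    vali <- new_expr_from(vali, expr_values(vali)[shared_v, , drop = FALSE])
    ctrl_v <- new_expr_from(ctrl, expr_values(ctrl)[shared_v, , drop = FALSE])
    matched <- match_density_threshold(net, spearman_matrix(vali),
                                       spearman_matrix(ctrl_v))
    comparison <- compare_networks(net, matched$network,
                                   min_degree = min_degree,
                                   percentile = hub_percentile)
    stages$validation <- list(threshold = matched$threshold,
                              network = matched$network,
                              comparison = comparison)
  }

  surv <- NULL
  if (!is.null(clinical)) {
    if (is.null(markers)) {
      pool <- if (!is.null(comparison) && length(comparison$hub_overlap$shared) >= 2) {
        comparison$hub_overlap$shared
      } else hubs$hubs
      ranked <- dplyr::filter(node_degrees(net), .data$gene %in% pool)
      if (nrow(ranked) < 2L) stop("fewer than 2 hub markers available", call. = FALSE)
      markers <- ranked$gene[1:2]
    }
    surv <- stratify_and_test(disc, clinical, markers,
                              method = stratify_method, seed = seed)
    stages$survival <- surv
  }

  structure(list(stages = stages,
                 markers = markers,
                 parameters = list(min_total = min_total, z_threshold = z_threshold,
                                   hub_percentile = hub_percentile,
                                   fc_threshold = fc_threshold, alpha = alpha,
                                   min_degree = min_degree,
                                   stratify_method = stratify_method),
                 seed = seed),
            class = "lect_run_report")
}

# Stratify discovery subjects on marker expression and compare survival.
stratify_and_test <- function(norm_expr, clinical, markers, method, seed) {
  miss <- setdiff(markers, norm_expr$gene)
  if (length(miss)) stop("marker gene(s) absent after filtering: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  x <- t(expr_values(norm_expr)[markers, , drop = FALSE])
  common <- intersect(rownames(x), as.character(clinical$subject_id))
  if (length(common) < 4L) stop("fewer than 4 subjects with clinical follow-up", call. = FALSE)
  clin <- clinical[match(common, as.character(clinical$subject_id)), ]
  x <- x[common, , drop = FALSE]

  if (method == "fcm") {
    fit <- tag_clusters(fuzzy_cmeans(x, centers = 2, seed = seed), x)
    group <- fit$subject_tags
  } else {
    df <- median_split_groups(as.data.frame(x), markers)
    group <- df$group
    fit <- NULL
  }
  tbl <- survival_table(common, clin$os_months, clin$event, group)
  test_tbl <- tbl
  if (method == "median") {
    test_tbl <- dplyr::filter(tbl, .data$group %in% c("lo/lo", "hi/hi"))
  }
  lr <- logrank_test(test_tbl)
  hr <- hazard_ratio(test_tbl)
  list(markers = markers, method = method, fit = fit,
       table = tbl, km = km_estimate(tbl),
       logrank = lr, hazard_ratio = hr,
       group_sizes = table(tbl$group))
}

#' @export
print.lect_run_report <- function(x, ...) {
  s <- x$stages
  cat("# Differential co-expression run\n")
  for (nm in grep("^preprocess_", names(s), value = TRUE)) {
    cat(sprintf("#  %s: %d -> %d genes after count filter\n",
                sub("preprocess_", "", nm), s[[nm]]$genes_in, s[[nm]]$genes_kept))
  }
  cat(sprintf("#  differential network: %d edges (density %.4f), hubs: %s\n",
              s$differential_network$n_edges, s$differential_network$density,
              paste(s$differential_network$hubs$hubs, collapse = ", ")))
  cat(sprintf("#  DE-flagged genes: %d\n", s$differential_expression$n_flagged))
  if (!is.null(s$validation)) {
    cat(sprintf("#  validation: threshold %.3f, degree rank corr %.3f, shared hubs: %s\n",
                s$validation$threshold,
                s$validation$comparison$degree_rank_correlation,
                paste(s$validation$comparison$hub_overlap$shared, collapse = ", ")))
  }
  if (!is.null(s$survival)) {
    cat(sprintf("#  survival (%s on %s): log-rank p = %.4g, HR = %.4g [%.4g, %.4g]\n",
                s$survival$method, paste(s$survival$markers, collapse = "+"),
                s$survival$logrank$p, s$survival$hazard_ratio$hr,
                s$survival$hazard_ratio$ci_lower, s$survival$hazard_ratio$ci_upper))
  }
  invisible(x)
}
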