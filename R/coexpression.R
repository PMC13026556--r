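#' Pairwise Spearman correlation matrix
#'
#' Spearman's rank correlation for every gene pair, using average (fractional)
#' ranks for ties. A gene with constant values across samples has no defined
#' rank correlation; its off-diagonal entries are set to 0 with a warning
#' rather than propagating `NA`.
#'
#' @param x A `lect_expr` in normalized log2 units with at least 4 samples
#'   and 2 genes (the differential z-score downstream needs n - 3 > 0).
#' @return A symmetric matrix of class `corr_mat` with unit diagonal and
#'   attributes `n_samples` and `condition`.
#' @export
spearman_matrix <- function(x) {
  stopifnot(inherits(x, "lect_expr"))
  mat <- expr_values(x)
  if (ncol(mat) < 4L) stop("at least 4 samples are required", call. = FALSE)
  if (nrow(mat) < 2L) stop("at least 2 genes are required", call. = FALSE)
  constant <- apply(mat, 1, function(v) max(v) == min(v))
  rho <- suppressWarnings(stats::cor(t(mat), method = "spearman"))
  if (any(constant)) {
    warning(sum(constant), " constant gene(s) assigned rho = 0: ",
            paste(utils::head(rownames(mat)[constant], 5), collapse = ", "),
            call. = FALSE)
    rho[constant, ] <- 0
    rho[, constant] <- 0
  }
  diag(rho) <- 1
  structure(rho,
            n_samples = ncol(mat),
            condition = expr_condition(x),
            class = c("corr_mat", "matrix", "array"))
}

#' Build a positive-link co-expression network
#'
#' One undirected edge per gene pair whose Spearman coefficient exceeds
#' `min_rho`; negative links are dropped by construction with the default
#' threshold of 0. All genes remain as nodes, including isolated ones.
#'
#' @param corr A `corr_mat` from [spearman_matrix()].
#' @param min_rho Minimum correlation for an edge (default 0, i.e. any
#'   strictly positive link).
#' @return A list of class `coexpr_net` with elements `nodes` (character),
#'   `edges` (tibble: gene_a, gene_b, rho), `condition`, `n_samples`.
#' @export
build_coexpression_network <- function(corr, min_rho = 0) {
  stopifnot(inherits(corr, "corr_mat"))
  genes <- rownames(corr)
  idx <- which(upper.tri(corr) & corr > min_rho, arr.ind = TRUE)
  edges <- tibble::tibble(
    gene_a = genes[idx[, 1]],
    gene_b = genes[idx[, 2]],
    rho = corr[idx]
  )
  structure(list(nodes = genes,
                 edges = dplyr::arrange(edges, dplyr::desc(.data$rho)),
                 condition = attr(corr, "condition"),
                 n_samples = attr(corr, "n_samples")),
            class = "coexpr_net")
}

#' @export
print.coexpr_net <- function(x, ...) {
  cat(sprintf("# Co-expression network [%s]: %d nodes, %d positive edges\n",
              x$condition %||% "?", length(x$nodes), nrow(x$edges)))
  print(x$edges, n = 5)
  invisible(x)
}

#' Write a correlation matrix as TSV
#' @param corr A `corr_mat`.
#' @param path Output path.
#' @return `corr`, invisibly.
#' @export
write_corr_matrix <- function(corr, path) {
  stopifnot(inherits(corr, "corr_mat"))
  tbl <- tibble::as_tibble(unclass(corr), .name_repair = "minimal")
  readr::write_tsv(dplyr::bind_cols(tibble::tibble(gene = rownames(corr)), tbl),
                   path, progress = FALSE)
  invisible(corr)
}
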