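#' Per-gene log2 fold change between two conditions
#'
#' The difference of per-gene mean expression on the log2 scale
#' (tumor minus control); both inputs must already be log2-normalized.
#'
#' @param mat_tumor,mat_control `lect_expr` objects in `normalized_log2`
#'   units over the same gene set.
#' @return A tibble (gene, log2FC).
#' @export
log2_fold_change <- function(mat_tumor, mat_control) {
  stopifnot(inherits(mat_tumor, "lect_expr"), inherits(mat_control, "lect_expr"))
  if (expr_units(mat_tumor) != "normalized_log2" ||
      expr_units(mat_control) != "normalized_log2") {
    stop("fold changes are defined on normalized log2 values", call. = FALSE)
  }
  vt <- expr_values(mat_tumor)
  vc <- expr_values(mat_control)
  if (!identical(rownames(vt), rownames(vc))) {
    stop("gene sets (and order) must match between conditions", call. = FALSE)
  }
  tibble::tibble(gene = rownames(vt),
                 log2FC = unname(rowMeans(vt) - rowMeans(vc)))
}

#' Differential expression with a fold-change and FDR criterion
#'
#' Per-gene two-sample t-test on log2-normalized values (Welch by default),
#' Benjamini-Hochberg adjustment across the tested genes, and the
#' conjunctive call: a gene is flagged differentially expressed only when
#' `|log2FC| >= fc_threshold` *and* `adj_p < alpha`.
#'
#' @param mat_tumor,mat_control `lect_expr` objects in `normalized_log2`
#'   units over the same gene set, each with at least 2 samples.
#' @param fc_threshold Absolute log2 fold-change threshold (default 1.5).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param var_equal Use the pooled-variance t-test instead of Welch
#'   (default `FALSE`).
#' @return A tibble (gene, log2FC, raw_p, adj_p, flag_de) of class
#'   `de_result`.
#' @export
differential_expression <- function(mat_tumor, mat_control,
                                    fc_threshold = 1.5, alpha = 0.05,
                                    var_equal = FALSE) {
  fc <- log2_fold_change(mat_tumor, mat_control)
  vt <- expr_values(mat_tumor)
  vc <- expr_values(mat_control)
  if (ncol(vt) < 2L || ncol(vc) < 2L) {
    stop("each condition needs at least 2 samples for a t-test", call. = FALSE)
  }
  raw_p <- vapply(seq_len(nrow(vt)), function(i) {
    a <- vt[i, ]; b <- vc[i, ]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      # degenerate: identical-variance-free groups; equal means <=> p = 1
      return(if (mean(a) == mean(b)) 1 else 0)
    }
    stats::t.test(a, b, var.equal = var_equal)$p.value
  }, numeric(1))
  out <- dplyr::mutate(fc,
    raw_p = raw_p,
    adj_p = stats::p.adjust(raw_p, method = "BH"),
    flag_de = abs(.data$log2FC) >= fc_threshold & .data$adj_p < alpha)
  attr(out, "fc_threshold") <- fc_threshold
  attr(out, "alpha") <- alpha
  class(out) <- c("de_result", class(out))
  out
}
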