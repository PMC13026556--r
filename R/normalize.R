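#' Remove lowly expressed genes
#'
#' Drops genes whose total count summed across samples is strictly below
#' `min_total`; a gene whose row sum equals the threshold is retained. The
#' operation is idempotent and preserves gene order.
#'
#' @param x A `lect_expr` in raw counts.
#' @param min_total Minimum total count across samples (default 500).
#' @return The filtered `lect_expr`; removed genes are reported via a message
#'   and stored in the `removed_genes` attribute.
#' @export
filter_low_expression <- function(x, min_total = 500) {
  stopifnot(inherits(x, "lect_expr"))
  if (expr_units(x) != "raw_counts") {
    stop("low-expression filtering applies to raw counts", call. = FALSE)
  }
  mat <- expr_values(x)
  keep <- rowSums(mat) >= min_total
  if (!any(keep)) stop("all genes fall below the count filter", call. = FALSE)
  removed <- rownames(mat)[!keep]
  if (length(removed)) {
    message("filtered ", length(removed), " gene(s) with total count < ",
            min_total, ": ", paste(utils::head(removed, 10), collapse = ", "))
  }
  out <- new_expr_from(x, mat[keep, , drop = FALSE])
  attr(out, "removed_genes") <- removed
  out
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling constants computed by the median-of-ratios scheme:
#' each count is divided by its gene's geometric mean across samples, and a
#' sample's factor is the median of those ratios over the reference genes.
#' Reference genes are those with no zero count in any sample, so the
#' geometric mean is finite.
#'
#' @param x A `lect_expr` in raw counts.
#' @return A named numeric vector of positive factors, one per sample.
#' @export
estimate_size_factors <- function(x) {
  stopifnot(inherits(x, "lect_expr"))
  if (expr_units(x) != "raw_counts") stop("size factors need raw counts", call. = FALSE)
  mat <- expr_values(x)
  ref <- rowSums(mat == 0) == 0L
  if (!any(ref)) {
    stop("no reference gene: every gene has a zero count in some sample", call. = FALSE)
  }
  logmat <- log(mat[ref, , drop = FALSE])
  geo <- rowMeans(logmat)
  sf <- apply(exp(logmat - geo), 2, stats::median)
  if (any(sf <= 0)) stop("non-positive size factor encountered", call. = FALSE)
  sf
}

#' Size-factor normalization and log2 transform
#'
#' Divides each sample's counts by its size factor and applies
#' `log2(x + pseudo_count)`. With the default pseudo-count of 1, zero counts
#' map to zero and the transform is monotone within each sample.
#'
#' @param x A `lect_expr` in raw counts.
#' @param size_factors Named per-sample factors; defaults to
#'   [estimate_size_factors()] on `x`.
#' @param pseudo_count Offset added before the log (default 1).
#' @return A `lect_expr` with units `"normalized_log2"`.
#' @export
normalize_log2 <- function(x, size_factors = estimate_size_factors(x),
                           pseudo_count = 1) {
  stopifnot(inherits(x, "lect_expr"))
  if (expr_units(x) != "raw_counts") stop("input must be raw counts", call. = FALSE)
  mat <- expr_values(x)
  if (length(size_factors) != ncol(mat)) {
    stop("size factors do not match the number of samples", call. = FALSE)
  }
  if (!is.null(names(size_factors)) &&
      !identical(names(size_factors), colnames(mat))) {
    if (!setequal(names(size_factors), colnames(mat))) {
      stop("size factor names do not match sample ids", call. = FALSE)
    }
    size_factors <- size_factors[colnames(mat)]
  }
  if (any(size_factors <= 0)) stop("size factors must be positive", call. = FALSE)
  norm <- sweep(mat, 2, size_factors, "/")
  new_expr_from(x, log2(norm + pseudo_count), units = "normalized_log2")
}
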