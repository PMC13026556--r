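#' Construct an expression matrix
#'
#' An expression matrix is a tibble with a `gene` column of unique symbols
#' followed by one numeric column per sample, tagged with the condition it
#' came from (e.g. `"tumor"`, `"control"`) and its units: `"raw_counts"`
#' straight off a quantifier, or `"normalized_log2"` after size-factor
#' normalization and log2 transform (see [normalize_log2()]).
#'
#' @param values A numeric matrix (genes x samples, rownames = gene symbols)
#'   or a data frame whose first column holds gene symbols.
#' @param condition Condition label attached to all samples of this matrix.
#' @param units Either `"raw_counts"` or `"normalized_log2"`.
#' @return A tibble of class `lect_expr` with attributes `condition` and
#'   `units`.
#' @export
expr_matrix <- function(values, condition, units = "raw_counts") {
  units <- match.arg(units, c("raw_counts", "normalized_log2"))
  if (is.data.frame(values)) {
    genes <- as.character(values[[1]])
    mat <- as.matrix(values[, -1, drop = FALSE])
  } else {
    mat <- as.matrix(values)
    genes <- rownames(mat)
  }
  if (is.null(genes) || anyNA(genes)) {
    stop("gene symbols are required as rownames or a first column", call. = FALSE)
  }
  storage.mode(mat) <- "double"
  if (nrow(mat) == 0L || ncol(mat) == 0L) stop("empty expression matrix", call. = FALSE)
  if (anyNA(mat)) stop("expression matrix contains missing values", call. = FALSE)
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    message("collapsing ", length(dup), " duplicated gene row(s) by sum: ",
            paste(utils::head(dup, 5), collapse = ", "))
    mat <- rowsum(mat, group = genes, reorder = FALSE)
    genes <- rownames(mat)
  }
  if (units == "raw_counts" && any(mat < 0)) {
    stop("raw counts must be non-negative", call. = FALSE)
  }
  if (is.null(colnames(mat))) colnames(mat) <- paste0("S", seq_len(ncol(mat)))
  out <- tibble::tibble(gene = genes)
  out <- dplyr::bind_cols(out, tibble::as_tibble(mat))
  structure(out,
            condition = as.character(condition)[1],
            units = units,
            class = c("lect_expr", class(out)))
}

#' @rdname expr_matrix
#' @param x A `lect_expr` object.
#' @export
expr_values <- function(x) {
  stopifnot(inherits(x, "lect_expr"))
  mat <- as.matrix(x[, -1, drop = FALSE])
  rownames(mat) <- x$gene
  mat
}

#' @rdname expr_matrix
#' @export
expr_condition <- function(x) attr(x, "condition")

#' @rdname expr_matrix
#' @export
expr_units <- function(x) attr(x, "units")

#' @rdname expr_matrix
#' @export
expr_samples <- function(x) colnames(x)[-1]

# Rebuild a lect_expr from a plain matrix, keeping metadata of a template.
new_expr_from <- function(template, mat, units = expr_units(template)) {
  expr_matrix(mat, condition = expr_condition(template), units = units)
}

#' Read an expression matrix from a delimited file
#'
#' Expects genes in rows (first column = gene symbol) and a header row of
#' sample identifiers; the delimiter (tab or comma) is sniffed by `readr`.
#' Duplicate gene rows are collapsed by summation, since counts are additive.
#'
#' @param path Path to a TSV/CSV file.
#' @param condition Condition label to attach.
#' @param units Units of the stored values (default `"raw_counts"`).
#' @return A [expr_matrix()] tibble.
#' @export
load_expression <- function(path, condition, units = "raw_counts") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- readr::read_delim(path, delim = sniff_delim(path), show_col_types = FALSE,
                           progress = FALSE)
  if (ncol(tbl) < 2L) stop("expected a gene column plus at least one sample", call. = FALSE)
  num <- tbl[, -1, drop = FALSE]
  if (anyNA(num)) stop("missing values in expression file: ", path, call. = FALSE)
  bad <- !vapply(num, is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric expression column(s): ",
         paste(names(num)[bad], collapse = ", "), call. = FALSE)
  }
  expr_matrix(tbl, condition = condition, units = units)
}

#' Write an expression matrix to a TSV file
#'
#' @param x A `lect_expr` object.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "lect_expr"))
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(x)
}

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' @export
print.lect_expr <- function(x, ...) {
  cat(sprintf("# Expression matrix: %d genes x %d samples [%s, %s]\n",
              nrow(x), ncol(x) - 1L, expr_condition(x), expr_units(x)))
  NextMethod()
}
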