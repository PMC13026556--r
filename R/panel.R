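#' Read a gene panel
#'
#' A panel is a two-column delimited file mapping gene symbols to one of the
#' three lectin families: `siglec`, `galectin` or `ctype` (C-type lectin).
#' Symbols must be unique and family labels must come from that set.
#'
#' @param path Path to a two-column TSV/CSV (symbol, family). A header row is
#'   detected and skipped when its second field is not a valid family label.
#' @return A tibble of class `lect_panel` with columns `gene` and `family`
#'   (factor with levels siglec, galectin, ctype).
#' @seealso [subset_to_panel()]
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  tbl <- readr::read_delim(path, delim = sniff_delim(path), col_names = FALSE,
                           col_types = "cc", progress = FALSE)
  if (ncol(tbl) < 2L) stop("panel file needs two columns: symbol, family", call. = FALSE)
  names(tbl)[1:2] <- c("gene", "family")
  if (nrow(tbl) > 0 && tolower(tbl$family[1]) == "family") tbl <- tbl[-1, ]
  panel(tbl$gene, tbl$family)
}

#' Construct a gene panel from vectors
#'
#' @param gene Character vector of unique gene symbols.
#' @param family Family label per gene: `"siglec"`, `"galectin"` or `"ctype"`.
#' @return A `lect_panel` tibble.
#' @export
panel <- function(gene, family) {
  gene <- as.character(gene)
  family <- as.character(family)
  if (length(gene) == 0L) stop("panel is empty", call. = FALSE)
  if (length(gene) != length(family)) stop("gene/family length mismatch", call. = FALSE)
  bad <- setdiff(unique(family), panel_families())
  if (length(bad)) {
    stop("unknown family label(s): ", paste(bad, collapse = ", "),
         " (expected siglec, galectin or ctype)", call. = FALSE)
  }
  if (anyDuplicated(gene)) {
    stop("duplicate gene symbol(s) in panel: ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(gene = gene,
                        family = factor(family, levels = panel_families()))
  structure(out, class = c("lect_panel", class(out)))
}

panel_families <- function() c("siglec", "galectin", "ctype")

#' Write a panel to a two-column TSV
#' @param x A `lect_panel`.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_panel <- function(x, path) {
  stopifnot(inherits(x, "lect_panel"))
  readr::write_tsv(tibble::tibble(gene = x$gene, family = as.character(x$family)),
                   path, col_names = FALSE, progress = FALSE)
  invisible(x)
}

#' Restrict an expression matrix to a gene panel
#'
#' Keeps exactly the panel genes present in the matrix, in panel order.
#' Panel genes absent from the matrix are recorded in the `missing_genes`
#' attribute (retrievable with [missing_genes()]) and reported via a message.
#'
#' @param x A `lect_expr` matrix (raw counts or normalized).
#' @param panel A `lect_panel`.
#' @return The subsetted `lect_expr`; errors if no panel gene is present.
#' @export
subset_to_panel <- function(x, panel) {
  stopifnot(inherits(x, "lect_expr"), inherits(panel, "lect_panel"))
  present <- panel$gene[panel$gene %in% x$gene]
  missing <- setdiff(panel$gene, x$gene)
  if (length(present) == 0L) {
    stop("no panel gene found in the expression matrix", call. = FALSE)
  }
  if (length(missing)) {
    message(length(missing), " panel gene(s) absent from the matrix: ",
            paste(utils::head(missing, 10), collapse = ", "))
  }
  mat <- expr_values(x)[present, , drop = FALSE]
  out <- new_expr_from(x, mat)
  attr(out, "missing_genes") <- missing
  out
}

#' @rdname subset_to_panel
#' @export
missing_genes <- function(x) attr(x, "missing_genes") %||% character(0)
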