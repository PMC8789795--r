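#' Expression matrices
#'
#' A `tcsp_expr` object is a gene-by-sample matrix of non-negative finite
#' values tagged with its unit, either `"counts"` (raw reads) or `"cpm"`
#' (counts per million). Gene identifiers are case-sensitive symbol strings;
#' no aliasing is attempted. All model construction and deconvolution
#' operate on the CPM scale.
#'
#' @param values numeric matrix with unique rownames (genes) and colnames
#'   (samples); all entries finite and `>= 0`.
#' @param unit `"counts"` or `"cpm"`.
#' @return A `tcsp_expr` object.
#' @export
expression_matrix <- function(values, unit = c("counts", "cpm")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) {
    tcsp_error("tcsp_input_error", "`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    tcsp_error("tcsp_input_error", "expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    tcsp_error("tcsp_input_error", "duplicate gene identifiers in expression matrix")
  }
  if (anyDuplicated(colnames(values))) {
    tcsp_error("tcsp_input_error", "duplicate sample identifiers in expression matrix")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    tcsp_error("tcsp_input_error", "expression values must be finite and non-negative")
  }
  structure(list(values = values, unit = unit), class = "tcsp_expr")
}

#' @export
print.tcsp_expr <- function(x, ...) {
  cat(sprintf(
    "<tcsp_expr> %d genes x %d samples [%s]\n",
    nrow(x$values), ncol(x$values), x$unit
  ))
  invisible(x)
}

#' @export
dim.tcsp_expr <- function(x) dim(x$values)

genes <- function(m) rownames(m$values)
samples <- function(m) colnames(m$values)

#' Read a gene-by-sample count table
#'
#' Expects a tab-separated file with a header row; the first column holds
#' gene symbols, remaining columns numeric read counts. Duplicate gene rows
#' are collapsed by summation (counts are additive) with a warning.
#'
#' @param path path to a TSV count table.
#' @param sep field separator, tab by default.
#' @return A `tcsp_expr` with `unit = "counts"`.
#' @export
read_counts_table <- function(path, sep = "\t") {
  if (!file.exists(path)) {
    tcsp_error("tcsp_input_error", sprintf("file not found: %s", path))
  }
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, comment.char = "", quote = ""),
    error = function(e) {
      tcsp_error("tcsp_input_error",
                 sprintf("malformed table %s: %s", path, conditionMessage(e)))
    }
  )
  if (nrow(df) == 0L || ncol(df) < 2L) {
    tcsp_error("tcsp_input_error", sprintf("empty or column-less table: %s", path))
  }
  gene <- as.character(df[[1L]])
  vals <- df[-1L]
  bad_col <- !vapply(vals, is.numeric, logical(1))
  if (any(bad_col)) {
    tcsp_error("tcsp_input_error",
               sprintf("non-numeric count column(s): %s",
                       paste(colnames(vals)[bad_col], collapse = ", ")))
  }
  m <- as.matrix(vals)
  if (any(!is.finite(m))) {
    row <- which(rowSums(!is.finite(m)) > 0)[1L]
    tcsp_error("tcsp_input_error",
               sprintf("non-finite count at data line %d (gene %s)", row, gene[row]))
  }
  if (any(m < 0)) {
    row <- which(rowSums(m < 0) > 0)[1L]
    tcsp_error("tcsp_input_error",
               sprintf("negative count at data line %d (gene %s)", row, gene[row]))
  }
  if (anyDuplicated(gene)) {
    dup <- unique(gene[duplicated(gene)])
    tcsp_warn("tcsp_duplicate_gene_warning",
              sprintf("%d duplicated gene id(s) collapsed by sum: %s",
                      length(dup), paste(utils::head(dup, 5), collapse = ", ")))
    m <- rowsum(m, group = gene, reorder = FALSE)
  } else {
    rownames(m) <- gene
  }
  expression_matrix(m, unit = "counts")
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_counts_table()]: gene symbols in the first column
#' (`gene`), one column per sample, full double precision.
#'
#' @param m a `tcsp_expr`.
#' @param path output path.
#' @export
write_expression_table <- function(m, path) {
  stopifnot(inherits(m, "tcsp_expr"))
  df <- data.frame(gene = genes(m), as.data.frame(m$values, check.names = FALSE),
                   check.names = FALSE)
  write_tsv_precise(df, path)
}

#' Counts-per-million normalization
#'
#' `cpm(g, s) = count(g, s) / total(s) * 1e6`; every sample column sums to
#' one million. Scale-invariant per sample by construction.
#'
#' @param m a `tcsp_expr` with `unit = "counts"`.
#' @return A `tcsp_expr` with `unit = "cpm"`.
#' @export
compute_cpm <- function(m) {
  stopifnot(inherits(m, "tcsp_expr"))
  if (m$unit != "counts") {
    tcsp_error("tcsp_input_error", "compute_cpm expects a counts matrix")
  }
  totals <- colSums(m$values)
  if (any(totals <= 0)) {
    bad <- colnames(m$values)[totals <= 0]
    tcsp_error("tcsp_degenerate_sample_error",
               sprintf("sample(s) with zero total counts: %s",
                       paste(bad, collapse = ", ")))
  }
  expression_matrix(sweep(m$values, 2L, totals, "/") * 1e6, unit = "cpm")
}
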