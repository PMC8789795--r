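# Signature model serialization: a TSV of genes x five subtype columns with
# a structured '#'-prefixed header recording the format version, the filter
# parameters and the per-gene audit trail. Round trips are lossless at full
# double precision.

SHEM_FORMAT_VERSION <- 1L

fmt_value <- function(x) {
  if (is.numeric(x)) paste(sprintf("%.17g", x), collapse = ",")
  else paste(as.character(x), collapse = ",")
}

#' Write a signature model to a TSV file
#'
#' @param model a `tcsp_shem`.
#' @param path output path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "tcsp_shem"))
  params <- model$provenance$params
  hdr <- c(
    sprintf("#tcsp_shem\tversion\t%d", SHEM_FORMAT_VERSION),
    vapply(names(params), function(k) {
      type <- if (is.numeric(params[[k]])) {
        if (is.integer(params[[k]])) "int" else "num"
      } else "chr"
      sprintf("#param\t%s\t%s\t%s", k, type, fmt_value(params[[k]]))
    }, character(1))
  )
  audit <- model$provenance$audit
  if (!is.null(audit) && nrow(audit)) {
    hdr <- c(hdr,
             paste0("#audit_cols\t", paste(colnames(audit), collapse = "\t")),
             vapply(seq_len(nrow(audit)), function(i) {
               row <- audit[i, ]
               vals <- vapply(seq_along(row), function(j) {
                 v <- row[[j]]
                 if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
               }, character(1))
               paste0("#audit\t", paste(vals, collapse = "\t"))
             }, character(1)))
  }
  df <- data.frame(gene = model$gene_ids,
                   as.data.frame(model$S, check.names = FALSE),
                   check.names = FALSE)
  write_tsv_precise(df, path, header_lines = hdr)
}

#' Read a signature model from a TSV file
#'
#' @param path a file produced by [write_model()].
#' @return A `tcsp_shem`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) {
    tcsp_error("tcsp_input_error", sprintf("file not found: %s", path))
  }
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  if (!length(hdr) || !startsWith(hdr[1L], "#tcsp_shem\t")) {
    tcsp_error("tcsp_model_format_error", "missing #tcsp_shem header line")
  }
  ver_fields <- strsplit(hdr[1L], "\t", fixed = TRUE)[[1L]]
  ver <- suppressWarnings(as.integer(ver_fields[3L]))
  if (is.na(ver) || ver != SHEM_FORMAT_VERSION) {
    tcsp_error("tcsp_model_version_error",
               sprintf("unsupported model format version: %s", ver_fields[3L]))
  }
  params <- list()
  for (h in hdr[startsWith(hdr, "#param\t")]) {
    f <- strsplit(h, "\t", fixed = TRUE)[[1L]]
    raw <- strsplit(f[4L], ",", fixed = TRUE)[[1L]]
    params[[f[2L]]] <- switch(f[3L],
      int = as.integer(raw), num = as.numeric(raw), raw)
  }
  audit <- NULL
  cols_line <- hdr[startsWith(hdr, "#audit_cols\t")]
  if (length(cols_line)) {
    acols <- strsplit(cols_line[1L], "\t", fixed = TRUE)[[1L]][-1L]
    rows <- hdr[startsWith(hdr, "#audit\t")]
    fields <- strsplit(rows, "\t", fixed = TRUE)
    # a trailing empty field (e.g. a blank removal reason) is dropped by
    # strsplit; pad back to the declared width
    fields <- lapply(fields, function(f) {
      c(f, rep("", length(acols) + 1L - length(f)))
    })
    mat <- do.call(rbind, fields)[, -1L, drop = FALSE]
    audit <- as.data.frame(mat, stringsAsFactors = FALSE)
    colnames(audit) <- acols
    for (nc in c("rank_value", "cv", "max_cpm", "background_score")) {
      if (nc %in% acols) {
        v <- audit[[nc]]
        v[v == "NA"] <- NA
        audit[[nc]] <- as.numeric(v)
      }
    }
  }
  body <- lines[!is_hdr]
  con <- textConnection(body)
  on.exit(close(con))
  df <- utils::read.table(con, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  missing <- setdiff(SUBTYPES, colnames(df))
  if (length(missing)) {
    tcsp_error("tcsp_model_format_error",
               sprintf("model file missing subtype column(s): %s",
                       paste(missing, collapse = ", ")))
  }
  S <- as.matrix(df[, SUBTYPES, drop = FALSE])
  storage.mode(S) <- "double"
  rownames(S) <- df$gene
  new_signature_model(S, params, audit)
}
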