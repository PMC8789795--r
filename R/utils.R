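# Internal helpers: classed conditions, local RNG scoping, TSV plumbing.

SUBTYPES <- c("N", "A", "EX", "EM", "CM")

tcsp_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "tcsp_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

tcsp_warn <- function(class, message, ...) {
  warning(structure(
    class = c(class, "tcsp_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    tcsp_error("tcsp_parameter_error", "`seed` must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic stream of sub-seeds below 2^31, derived from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# Fixed-format TSV writer: full double precision, no quoting, LF endings.
# Used everywhere so that identical inputs give byte-identical files.
write_tsv_precise <- function(df, path, header_lines = character(0)) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(header_lines)) {
    writeLines(header_lines, con, sep = "\n")
  }
  writeLines(paste(colnames(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    rows <- do.call(paste, c(unname(as.list(out)), list(sep = "\t")))
    writeLines(rows, con, sep = "\n")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
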