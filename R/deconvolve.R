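#' @name deconvolve
#' @title Bulk deconvolution into T-cell subtype fractions
#' @description
#' A bulk expression profile is modeled as the linear mixture `B = S * F`:
#' `B` is the sample's CPM vector over the signature genes, `S` the
#' gene-by-five signature matrix, and `F` the mRNA fractions of the five
#' subtypes. Both sides are first normalized per gene by the maximum of the
#' five signature columns, then `F` is estimated by linear epsilon-SVR with
#' no intercept; negative coefficients are clipped to zero and the result
#' reported on a 0-100 scale. The five estimates are not forced to sum to
#' 100: tumor and stroma may dominate the sample, so the subtypes need not
#' explain all of it.
NULL

#' Align a sample to a signature model
#'
#' Orders the sample's CPM values by the model's gene order. Model genes
#' absent from the sample are imputed as 0 (with a warning) so that `S`
#' stays fixed across a cohort and estimates remain comparable between
#' samples.
#'
#' @param sample_cpm a `tcsp_expr` with `unit = "cpm"`.
#' @param model a `tcsp_shem`.
#' @param sample_id which sample column to align (default: first).
#' @param coverage_floor error below this matched fraction of model genes.
#' @return list with `B` (named vector over model genes), `coverage`
#'   (matched fraction), `missing` (unmatched model genes).
#' @export
align_to_model <- function(sample_cpm, model, sample_id = NULL,
                           coverage_floor = 0.5) {
  stopifnot(inherits(sample_cpm, "tcsp_expr"), inherits(model, "tcsp_shem"))
  if (sample_cpm$unit != "cpm") {
    tcsp_error("tcsp_input_error", "sample must be on the CPM scale")
  }
  sample_id <- sample_id %||% samples(sample_cpm)[1L]
  if (!sample_id %in% samples(sample_cpm)) {
    tcsp_error("tcsp_input_error", sprintf("unknown sample: %s", sample_id))
  }
  g <- model$gene_ids
  hit <- match(g, genes(sample_cpm))
  B <- numeric(length(g))
  names(B) <- g
  B[!is.na(hit)] <- sample_cpm$values[hit[!is.na(hit)], sample_id]
  coverage <- mean(!is.na(hit))
  if (coverage < coverage_floor) {
    tcsp_error("tcsp_coverage_error",
               sprintf("sample %s matches only %d/%d model genes (floor %.2f)",
                       sample_id, sum(!is.na(hit)), length(g), coverage_floor))
  }
  if (anyNA(hit)) {
    tcsp_warn("tcsp_coverage_warning",
              sprintf("sample %s: %d model gene(s) absent, imputed as 0",
                      sample_id, sum(is.na(hit))))
  }
  list(B = B, coverage = coverage, missing = g[is.na(hit)])
}

#' Normalize a sample vector and signature matrix to the per-gene model max
#'
#' Each gene's divisor is the maximum of its five signature values, so every
#' row of the normalized signature has maximum exactly 1 and the sample is
#' expressed on the same relative scale.
#'
#' @param B named CPM vector over the model genes (from [align_to_model()]).
#' @param model a `tcsp_shem`.
#' @return list with `B_norm` and `S_norm`.
#' @export
normalize_to_model_max <- function(B, model) {
  stopifnot(inherits(model, "tcsp_shem"))
  d <- apply(model$S, 1L, max)
  if (any(d <= 0)) {
    tcsp_error("tcsp_model_error", "model gene with non-positive subtype maximum")
  }
  list(B_norm = B / d, S_norm = model$S / d)
}

#' Estimate subtype mRNA fractions for one aligned, normalized sample
#'
#' Regresses `B_norm` on the columns of `S_norm` with linear epsilon-SVR
#' (no intercept) over a small sweep of regularization strengths, keeping
#' the fit with minimal residual norm; negative coefficients are clipped to
#' zero and the result scaled by 100.
#'
#' @param B_norm normalized sample vector.
#' @param S_norm normalized signature matrix (genes x 5).
#' @param epsilon SVR insensitive-tube half width (normalized-CPM units).
#' @param C_grid regularization strengths swept; minimal-residual fit wins
#'   (first on ties).
#' @param sample_id label carried into the result.
#' @return A `tcsp_estimate`: `raw` (five values, 0-100 scale), `sum`,
#'   `normalized` (sum-normalized fractions, `NA` when `sum == 0`),
#'   `genes_used`, and `fit` diagnostics (residual norm, chosen C, clipping,
#'   rank-deficiency flag).
#' @export
estimate_fractions <- function(B_norm, S_norm, epsilon = 0.001,
                               C_grid = c(0.1, 1, 10), sample_id = "sample") {
  S_norm <- as.matrix(S_norm)
  if (length(B_norm) != nrow(S_norm)) {
    tcsp_error("tcsp_input_error", "B and S have incompatible shapes")
  }
  if (nrow(S_norm) < ncol(S_norm)) {
    tcsp_error("tcsp_input_error", "need at least as many genes as subtypes")
  }
  if (any(!is.finite(B_norm)) || any(!is.finite(S_norm))) {
    tcsp_error("tcsp_input_error", "non-finite deconvolution input")
  }
  rank_deficient <- qr(S_norm)$rank < ncol(S_norm)
  if (rank_deficient) {
    tcsp_warn("tcsp_rank_warning",
              "signature matrix is rank deficient; estimates may be unstable")
  }
  best <- NULL
  for (C in C_grid) {
    fit <- svr_linear(S_norm, B_norm, C = C, epsilon = epsilon)
    resid <- sqrt(sum((S_norm %*% fit$w - B_norm)^2))
    if (is.null(best) || resid < best$resid) {
      best <- list(w = fit$w, resid = resid, C = C, converged = fit$converged)
    }
  }
  w <- best$w
  clipped <- w < 0
  raw <- pmax(w, 0) * 100
  names(raw) <- colnames(S_norm) %||% SUBTYPES
  if (any(raw > 100)) {
    tcsp_warn("tcsp_scale_warning",
              sprintf("sample %s: estimate(s) above 100: %s", sample_id,
                      paste(names(raw)[raw > 100], collapse = ", ")))
  }
  total <- sum(raw)
  normalized <- if (total > 0) raw / total else {
    structure(rep(NA_real_, length(raw)), names = names(raw))
  }
  structure(list(
    sample_id = sample_id,
    raw = raw,
    sum = total,
    normalized = normalized,
    normalization_defined = total > 0,
    genes_used = nrow(S_norm),
    fit = list(
      residual_norm = best$resid,
      solver = sprintf("linear epsilon-SVR (dual CD), epsilon=%g, C=%g",
                       epsilon, best$C),
      C = best$C,
      n_clipped = sum(clipped),
      converged = best$converged,
      rank_deficient = rank_deficient
    )
  ), class = "tcsp_estimate")
}

#' @export
print.tcsp_estimate <- function(x, ...) {
  cat(sprintf("<tcsp_estimate> %s: %s; sum=%.2f\n", x$sample_id,
              paste(sprintf("%s=%.2f", names(x$raw), x$raw), collapse = " "),
              x$sum))
  invisible(x)
}

#' Sum-normalize a subtype estimate
#'
#' Divides each raw estimate by their total, yielding fractions in `[0, 1]`
#' summing to 1. Undefined (all-`NA`, flagged via the `"undefined"`
#' attribute and a warning) when the total is zero — never silently 0.
#'
#' @param e a `tcsp_estimate`.
#' @return named numeric vector of length 5.
#' @export
sum_normalize <- function(e) {
  stopifnot(inherits(e, "tcsp_estimate"))
  if (e$sum <= 0) {
    tcsp_warn("tcsp_undefined_normalization_warning",
              sprintf("sample %s: all subtype estimates are zero; normalization undefined",
                      e$sample_id))
    return(structure(rep(NA_real_, 5L), names = names(e$raw), undefined = TRUE))
  }
  e$raw / e$sum
}

#' Composite subtype ratio
#'
#' Ratio of two raw subtype estimates, e.g. the effector-memory-normalized
#' exhaustion readout `EX/EM`. Invariant under sum-normalization. Undefined
#' (`NA`, flagged) when the denominator estimate is zero.
#'
#' @param e a `tcsp_estimate`.
#' @param numerator,denominator subtype ids.
#' @return single number, or flagged `NA` when undefined.
#' @export
composite_ratio <- function(e, numerator = "EX", denominator = "EM") {
  stopifnot(inherits(e, "tcsp_estimate"))
  if (!numerator %in% names(e$raw) || !denominator %in% names(e$raw)) {
    tcsp_error("tcsp_parameter_error", "unknown subtype id in ratio")
  }
  num <- e$raw[[numerator]]
  den <- e$raw[[denominator]]
  if (den == 0) {
    tcsp_warn("tcsp_undefined_ratio_warning",
              sprintf("sample %s: %s/%s undefined (numerator %.4g, denominator 0)",
                      e$sample_id, numerator, denominator, num))
    return(structure(NA_real_, undefined = TRUE, numerator = num, denominator = den))
  }
  num / den
}

#' Deconvolve every sample of a cohort
#'
#' Runs [align_to_model()], [normalize_to_model_max()] and
#' [estimate_fractions()] per sample and assembles the standard estimates
#' table.
#'
#' @param expr a `tcsp_expr` (counts or CPM; counts are converted).
#' @param model a `tcsp_shem`.
#' @param epsilon,C_grid,coverage_floor passed through to the stages.
#' @return data.frame with columns `sample, N, A, EX, EM, CM, Sum,
#'   genes_used`; the per-sample `tcsp_estimate` objects are attached as
#'   the `"estimates"` attribute.
#' @export
estimate_subtypes <- function(expr, model, epsilon = 0.001,
                              C_grid = c(0.1, 1, 10), coverage_floor = 0.5) {
  stopifnot(inherits(expr, "tcsp_expr"), inherits(model, "tcsp_shem"))
  if (expr$unit == "counts") expr <- compute_cpm(expr)
  ids <- samples(expr)
  ests <- lapply(ids, function(s) {
    al <- align_to_model(expr, model, sample_id = s,
                         coverage_floor = coverage_floor)
    nm <- normalize_to_model_max(al$B, model)
    estimate_fractions(nm$B_norm, nm$S_norm, epsilon = epsilon,
                       C_grid = C_grid, sample_id = s)
  })
  names(ests) <- ids
  raw <- t(vapply(ests, function(e) e$raw, numeric(5L)))
  df <- data.frame(sample = ids, raw,
                   Sum = vapply(ests, function(e) e$sum, numeric(1)),
                   genes_used = vapply(ests, function(e) e$genes_used, numeric(1)),
                   row.names = NULL, check.names = FALSE,
                   stringsAsFactors = FALSE)
  attr(df, "estimates") <- ests
  df
}

#' Write an estimates table as TSV
#'
#' @param df output of [estimate_subtypes()].
#' @param path output path.
#' @param normalized also include sum-normalized columns (`N_frac`, ...).
#' @param ratios character vector of composite ratios to append, e.g.
#'   `"EX/EM"`.
#' @export
write_estimates <- function(df, path, normalized = FALSE, ratios = character(0)) {
  ests <- attr(df, "estimates")
  out <- df
  if (normalized && !is.null(ests)) {
    nm <- t(vapply(ests, function(e) suppressWarnings(sum_normalize(e)), numeric(5L)))
    colnames(nm) <- paste0(SUBTYPES, "_frac")
    out <- cbind(out, nm)
  }
  for (r in ratios) {
    parts <- strsplit(r, "/", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) {
      tcsp_error("tcsp_parameter_error", sprintf("bad ratio spec: %s", r))
    }
    out[[r]] <- vapply(ests, function(e) {
      as.numeric(suppressWarnings(composite_ratio(e, parts[1L], parts[2L])))
    }, numeric(1))
  }
  write_tsv_precise(out, path)
}
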