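#' Labeled reference profiles
#'
#' Bundles a CPM expression matrix of sorted/stimulated T-cell reference
#' libraries with a subtype label per sample. The five subtypes are naive
#' (`N`), activated (`A`), exhausted (`EX`), effector memory (`EM`) and
#' central memory (`CM`). Every subtype needs at least two replicate
#' libraries; the within-subtype coefficient of variation is undefined
#' otherwise.
#'
#' @param matrix_cpm a `tcsp_expr` with `unit = "cpm"`.
#' @param labels named character vector mapping each sample id to one of
#'   `N, A, EX, EM, CM`.
#' @return A `tcsp_reference` object.
#' @export
reference_profiles <- function(matrix_cpm, labels) {
  stopifnot(inherits(matrix_cpm, "tcsp_expr"))
  if (matrix_cpm$unit != "cpm") {
    tcsp_error("tcsp_input_error", "reference profiles must be on the CPM scale")
  }
  smp <- samples(matrix_cpm)
  if (is.null(names(labels)) || !setequal(names(labels), smp) ||
      length(labels) != length(smp)) {
    tcsp_error("tcsp_label_error",
               "labels must name every reference sample exactly once")
  }
  labels <- labels[smp]
  if (!all(labels %in% SUBTYPES)) {
    tcsp_error("tcsp_label_error",
               sprintf("unknown subtype label(s): %s",
                       paste(setdiff(labels, SUBTYPES), collapse = ", ")))
  }
  n_rep <- table(factor(labels, levels = SUBTYPES))
  if (any(n_rep < 2L)) {
    tcsp_error("tcsp_label_error",
               sprintf("subtype(s) with fewer than 2 replicates: %s",
                       paste(SUBTYPES[n_rep < 2L], collapse = ", ")))
  }
  structure(list(matrix = matrix_cpm, labels = labels), class = "tcsp_reference")
}

#' @export
print.tcsp_reference <- function(x, ...) {
  tab <- table(factor(x$labels, levels = SUBTYPES))
  cat(sprintf("<tcsp_reference> %d genes; replicates: %s\n",
              nrow(x$matrix$values),
              paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  invisible(x)
}

#' Tumor background panel
#'
#' A CPM matrix over cancer cell lines (CCLE-style) with a disease-origin
#' string per cell line, used to strip signature genes that are broadly
#' expressed outside T cells.
#'
#' @param matrix_cpm a `tcsp_expr` with `unit = "cpm"` (genes x cell lines).
#' @param origins named character vector mapping cell-line ids to a
#'   tissue/disease-origin string.
#' @return A `tcsp_background_panel` object.
#' @export
background_panel <- function(matrix_cpm, origins) {
  stopifnot(inherits(matrix_cpm, "tcsp_expr"))
  lines <- samples(matrix_cpm)
  if (is.null(names(origins)) || !setequal(names(origins), lines)) {
    tcsp_error("tcsp_label_error", "origins must name every cell line exactly once")
  }
  structure(list(matrix = matrix_cpm, origins = origins[lines]),
            class = "tcsp_background_panel")
}

ref_subtype_means <- function(ref) {
  vapply(SUBTYPES, function(t) {
    rowMeans(ref$matrix$values[, ref$labels == t, drop = FALSE])
  }, numeric(nrow(ref$matrix$values)))
}

#' Rank genes by log fold difference for one subtype
#'
#' For each gene, computes
#' `log2((mean CPM in subtype + pseudocount) / (mean CPM over all other
#' subtypes' samples + pseudocount))` and sorts descending. Ties are broken
#' lexicographically by gene id (C locale) so the ranking is deterministic.
#'
#' @param ref a `tcsp_reference`.
#' @param subtype one of `N, A, EX, EM, CM`.
#' @param pseudocount positive CPM offset guarding against zero means.
#' @return data.frame with columns `gene`, `log2_fold`, sorted descending.
#' @export
rank_genes <- function(ref, subtype, pseudocount = 1) {
  stopifnot(inherits(ref, "tcsp_reference"))
  if (!subtype %in% SUBTYPES) {
    tcsp_error("tcsp_parameter_error", sprintf("unknown subtype: %s", subtype))
  }
  if (!any(ref$labels == subtype)) {
    tcsp_error("tcsp_label_error", sprintf("no samples labeled %s", subtype))
  }
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    tcsp_error("tcsp_parameter_error", "pseudocount must be positive")
  }
  v <- ref$matrix$values
  in_t <- ref$labels == subtype
  mu_in <- rowMeans(v[, in_t, drop = FALSE])
  mu_out <- rowMeans(v[, !in_t, drop = FALSE])
  lfd <- log2((mu_in + pseudocount) / (mu_out + pseudocount))
  ord <- order(-lfd, rownames(v), method = "radix")
  data.frame(gene = rownames(v)[ord], log2_fold = lfd[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

# Within-subtype replicate CV (sd with n-1 denominator over mean; Inf when
# the replicate mean is zero) and max replicate CPM, for a set of genes.
subtype_gene_stats <- function(ref, subtype, gene_ids) {
  v <- ref$matrix$values[gene_ids, ref$labels == subtype, drop = FALSE]
  mu <- rowMeans(v)
  sdv <- apply(v, 1L, stats::sd)
  cv <- ifelse(mu > 0, sdv / mu, Inf)
  list(cv = cv, max_cpm = apply(v, 1L, max), mean = mu)
}

#' Gate a ranked gene list on variability and abundance
#'
#' Walks the ranked list in order and skips any gene whose within-subtype
#' replicate CV exceeds `cv_max` or whose maximum replicate CPM falls below
#' `cpm_min`, stopping once `n_target` genes are accepted. Returns fewer
#' than `n_target` (with a warning) if the list is exhausted first.
#'
#' @param ranked output of [rank_genes()] for the same subtype.
#' @param ref the `tcsp_reference` the ranking came from.
#' @param subtype the subtype being modeled.
#' @param cv_max maximum allowed replicate coefficient of variation.
#' @param cpm_min minimum required maximum replicate CPM.
#' @param n_target number of genes to accept.
#' @return list with `genes` (accepted, in rank order) and `audit`
#'   (one row per examined gene: gate values, status and skip reason).
#' @export
gate_genes <- function(ranked, ref, subtype, cv_max = 0.25, cpm_min = 15,
                       n_target = 10L) {
  stopifnot(inherits(ref, "tcsp_reference"), is.data.frame(ranked))
  if (!is.numeric(n_target) || n_target < 1) {
    tcsp_error("tcsp_parameter_error", "n_target must be >= 1")
  }
  st <- subtype_gene_stats(ref, subtype, ranked$gene)
  pass <- st$cv <= cv_max & st$max_cpm >= cpm_min
  acc <- which(cumsum(pass) <= n_target & pass)
  n_examined <- if (length(acc) >= n_target) acc[n_target] else nrow(ranked)
  idx <- seq_len(n_examined)
  status <- ifelse(pass[idx], "kept", "removed")
  reason <- rep("", n_examined)
  reason[st$cv[idx] > cv_max] <- "cv_gate"
  reason[st$max_cpm[idx] < cpm_min & reason == ""] <- "cpm_gate"
  audit <- data.frame(
    gene = ranked$gene[idx], subtype = subtype,
    rank_value = ranked$log2_fold[idx],
    cv = st$cv[idx], max_cpm = st$max_cpm[idx],
    background_score = NA_real_, status = status, reason = reason,
    row.names = NULL, stringsAsFactors = FALSE
  )
  genes_kept <- ranked$gene[idx][pass[idx]]
  if (length(genes_kept) < n_target) {
    tcsp_warn("tcsp_gate_warning",
              sprintf("subtype %s: only %d of %d requested genes passed the gates",
                      subtype, length(genes_kept), n_target))
  }
  list(genes = genes_kept, audit = audit)
}

new_signature_model <- function(S, params, audit) {
  if (any(!is.finite(S)) || any(S < 0)) {
    tcsp_error("tcsp_model_error", "signature entries must be finite and non-negative")
  }
  if (nrow(S) && any(apply(S, 1L, max) <= 0)) {
    tcsp_error("tcsp_model_error", "every signature gene needs a positive subtype maximum")
  }
  structure(list(gene_ids = rownames(S), S = S,
                 provenance = list(params = params, audit = audit)),
            class = "tcsp_shem")
}

#' @export
print.tcsp_shem <- function(x, ...) {
  cat(sprintf("<tcsp_shem> %d genes x 5 subtypes (%s)\n",
              length(x$gene_ids), paste(SUBTYPES, collapse = ", ")))
  invisible(x)
}

#' Assemble the preliminary signature model
#'
#' The model rows are the union of the per-subtype gene selections (first
#' occurrence kept, in subtype order `N, A, EX, EM, CM`); `S[g, t]` is the
#' mean reference CPM of gene `g` over subtype `t`'s replicate libraries.
#'
#' @param ref a `tcsp_reference`.
#' @param selections named list (one entry per subtype) of [gate_genes()]
#'   results, or plain character vectors of gene ids.
#' @param params filter parameters to record in provenance.
#' @return A `tcsp_shem` signature model.
#' @export
build_preliminary_model <- function(ref, selections, params = list()) {
  stopifnot(inherits(ref, "tcsp_reference"))
  if (!setequal(names(selections), SUBTYPES)) {
    tcsp_error("tcsp_parameter_error", "selections must cover exactly the five subtypes")
  }
  sel_genes <- lapply(SUBTYPES, function(t) {
    s <- selections[[t]]
    if (is.list(s)) s$genes else s
  })
  names(sel_genes) <- SUBTYPES
  union_genes <- unique(unlist(sel_genes, use.names = FALSE))
  if (length(union_genes) == 0L) {
    tcsp_error("tcsp_model_error", "no genes selected for any subtype")
  }
  means <- ref_subtype_means(ref)
  S <- means[union_genes, , drop = FALSE]
  audits <- lapply(SUBTYPES, function(t) {
    s <- selections[[t]]
    if (is.list(s)) s$audit else NULL
  })
  audit <- do.call(rbind, audits[!vapply(audits, is.null, logical(1))])
  if (is.null(audit)) {
    audit <- data.frame(
      gene = union_genes,
      subtype = vapply(union_genes, function(g) {
        paste(SUBTYPES[vapply(sel_genes, function(s) g %in% s, logical(1))],
              collapse = "+")
      }, character(1)),
      rank_value = NA_real_, cv = NA_real_, max_cpm = NA_real_,
      background_score = NA_real_, status = "kept", reason = "",
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  new_signature_model(S, params, audit)
}

default_excluded_origins <- function() {
  c("haematopoietic", "lymphoid", "leukemia", "lymphoma", "myeloma")
}

#' Filter signature genes against a tumor background panel
#'
#' For each model gene, the background score is the mean CPM over retained
#' panel cell lines divided by the gene's maximum across the five model
#' columns; genes with score `>= threshold` are removed (inclusive bound).
#' Cell lines whose origin contains any `excluded_origins` substring
#' (case-insensitive) are dropped before averaging, so immune-derived lines
#' do not mask genuine T-cell genes. Model genes absent from the panel are
#' kept with score 0 and logged.
#'
#' @param model a `tcsp_shem`.
#' @param panel a `tcsp_background_panel`.
#' @param threshold removal bound on the normalized background score.
#' @param excluded_origins substrings identifying immune-derived cell lines.
#' @return The filtered `tcsp_shem`, provenance updated gene-by-gene.
#' @export
filter_background <- function(model, panel, threshold = 0.2,
                              excluded_origins = default_excluded_origins()) {
  stopifnot(inherits(model, "tcsp_shem"), inherits(panel, "tcsp_background_panel"))
  if (!is.numeric(threshold) || threshold <= 0 || !is.finite(threshold)) {
    tcsp_error("tcsp_parameter_error", "threshold must be a finite positive number")
  }
  origin_lc <- tolower(panel$origins)
  excluded <- rep(FALSE, length(origin_lc))
  for (pat in tolower(excluded_origins)) {
    excluded <- excluded | grepl(pat, origin_lc, fixed = TRUE)
  }
  retained <- panel$matrix$values[, !excluded, drop = FALSE]
  if (ncol(retained) == 0L) {
    tcsp_error("tcsp_parameter_error", "no background cell lines left after origin exclusion")
  }
  g <- model$gene_ids
  in_panel <- g %in% rownames(retained)
  if (any(!in_panel)) {
    tcsp_warn("tcsp_panel_coverage_warning",
              sprintf("%d model gene(s) absent from background panel, kept with score 0",
                      sum(!in_panel)))
  }
  bg_mean <- numeric(length(g))
  bg_mean[in_panel] <- rowMeans(retained[g[in_panel], , drop = FALSE])
  score <- bg_mean / apply(model$S, 1L, max)
  keep <- score < threshold
  audit <- model$provenance$audit
  hit <- match(audit$gene, g)
  known <- !is.na(hit) & audit$status == "kept"
  audit$background_score[known] <- score[hit[known]]
  removed <- logical(nrow(audit))
  removed[known] <- !keep[hit[known]]
  audit$status[removed] <- "removed"
  audit$reason[removed] <- "background"
  params <- model$provenance$params
  params$bg_threshold <- threshold
  params$excluded_origins <- excluded_origins
  if (!any(keep)) {
    tcsp_error("tcsp_model_error", "background filter removed every signature gene")
  }
  new_signature_model(model$S[keep, , drop = FALSE], params, audit)
}

#' Build the five subtype signature models end-to-end
#'
#' Composes [rank_genes()] and [gate_genes()] per subtype,
#' [build_preliminary_model()], then [filter_background()]. Fully
#' deterministic given its inputs and parameters.
#'
#' @param ref a `tcsp_reference`.
#' @param panel a `tcsp_background_panel`, or `NULL` to skip background
#'   filtering.
#' @param pseudocount,cv_max,cpm_min,n_target,bg_threshold,excluded_origins
#'   stage parameters; see the stage functions for meanings.
#' @return A `tcsp_shem`.
#' @export
build_shems <- function(ref, panel = NULL, pseudocount = 1, cv_max = 0.25,
                        cpm_min = 15, n_target = 10L, bg_threshold = 0.2,
                        excluded_origins = default_excluded_origins()) {
  selections <- lapply(SUBTYPES, function(t) {
    ranked <- rank_genes(ref, t, pseudocount = pseudocount)
    gate_genes(ranked, ref, t, cv_max = cv_max, cpm_min = cpm_min,
               n_target = n_target)
  })
  names(selections) <- SUBTYPES
  params <- list(pseudocount = pseudocount, cv_max = cv_max,
                 cpm_min = cpm_min, n_target = as.integer(n_target))
  model <- build_preliminary_model(ref, selections, params)
  if (!is.null(panel)) {
    model <- filter_background(model, panel, threshold = bg_threshold,
                               excluded_origins = excluded_origins)
  }
  model
}
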