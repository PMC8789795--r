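#' Feature tables for biomarker modeling
#'
#' @param x numeric matrix, samples x features, with rownames and colnames.
#' @param labels binary response per sample (0/1, logical, or a two-level
#'   factor), named by sample.
#' @param survival optional data.frame with columns `sample`, `time`
#'   (positive) and `event` (0/1 right-censoring indicator).
#' @return A `tcsp_features` object.
#' @export
feature_table <- function(x, labels, survival = NULL) {
  if (!is.matrix(x) || !is.numeric(x) || is.null(rownames(x))) {
    tcsp_error("tcsp_input_error", "x must be a numeric matrix with sample rownames")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    tcsp_error("tcsp_input_error", "feature table contains missing or non-finite values")
  }
  if (is.null(names(labels)) || !all(rownames(x) %in% names(labels))) {
    tcsp_error("tcsp_label_error", "labels must name every sample")
  }
  labels <- labels[rownames(x)]
  if (is.factor(labels) || is.character(labels)) {
    lv <- sort(unique(as.character(labels)))
    if (length(lv) != 2L) {
      tcsp_error("tcsp_label_error", "labels must be binary")
    }
    labels <- as.integer(as.character(labels) == lv[2L])
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    tcsp_error("tcsp_label_error", "labels must be binary")
  }
  names(labels) <- rownames(x)
  if (!is.null(survival)) {
    need <- c("sample", "time", "event")
    if (!all(need %in% colnames(survival))) {
      tcsp_error("tcsp_input_error", "survival needs columns sample, time, event")
    }
    if (any(survival$time <= 0)) {
      tcsp_error("tcsp_input_error", "survival times must be positive")
    }
  }
  structure(list(x = x, labels = labels, survival = survival),
            class = "tcsp_features")
}

#' @export
print.tcsp_features <- function(x, ...) {
  cat(sprintf("<tcsp_features> %d samples x %d features (%d positive)\n",
              nrow(x$x), ncol(x$x), sum(x$labels)))
  invisible(x)
}

#' Assemble subtype-estimate features
#'
#' Turns per-sample subtype estimates into a feature table with 5 columns
#' (`raw` or `normalized` mode) or 10 (`both`). Standardization is not
#' baked in here: the bootstrap harness standardizes inside each resample
#' to avoid train/test leakage; use [standardize_features()] for
#' whole-cohort use.
#'
#' @param estimates output of [estimate_subtypes()] (its `"estimates"`
#'   attribute is used), or a list of `tcsp_estimate` objects.
#' @param labels,survival as in [feature_table()].
#' @param mode `"raw"`, `"normalized"` or `"both"`.
#' @return A `tcsp_features` object.
#' @export
assemble_features <- function(estimates, labels, mode = c("raw", "normalized", "both"),
                              survival = NULL) {
  mode <- match.arg(mode)
  ests <- if (is.data.frame(estimates)) attr(estimates, "estimates") else estimates
  if (is.null(ests) || !length(ests)) {
    tcsp_error("tcsp_input_error", "no subtype estimates supplied")
  }
  ids <- vapply(ests, function(e) e$sample_id, character(1))
  raw <- t(vapply(ests, function(e) e$raw, numeric(5L)))
  rownames(raw) <- ids
  if (mode %in% c("normalized", "both")) {
    undef <- !vapply(ests, function(e) isTRUE(e$normalization_defined), logical(1))
    if (any(undef)) {
      tcsp_error("tcsp_assembly_error",
                 sprintf("sample(s) with undefined sum-normalization: %s",
                         paste(ids[undef], collapse = ", ")))
    }
    nm <- t(vapply(ests, function(e) e$normalized, numeric(5L)))
    colnames(nm) <- paste0(SUBTYPES, "_frac")
    rownames(nm) <- ids
  }
  x <- switch(mode, raw = raw, normalized = nm, both = cbind(raw, nm))
  feature_table(x, labels, survival)
}

#' Standardize feature columns to zero mean, unit variance
#'
#' @param ft a `tcsp_features` object.
#' @return The same object with standardized columns (constant columns are
#'   left centered at 0).
#' @export
standardize_features <- function(ft) {
  stopifnot(inherits(ft, "tcsp_features"))
  ft$x <- standardize_matrix(ft$x)
  ft
}

standardize_matrix <- function(x, center = NULL, scale = NULL) {
  center <- center %||% colMeans(x)
  scale <- scale %||% apply(x, 2L, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  sweep(sweep(x, 2L, center), 2L, scale, "/")
}

#' Gene-expression features for gene-set biomarkers
#'
#' One feature per listed gene present in the matrix, valued
#' `log2(CPM + 1)`. Genes absent from the matrix are dropped with a
#' warning; zero overlap is an error.
#'
#' @param expr a `tcsp_expr` with `unit = "cpm"`.
#' @param gene_list character vector of gene symbols.
#' @param labels,survival as in [feature_table()].
#' @return A `tcsp_features` object.
#' @export
extract_geneset_features <- function(expr, gene_list, labels, survival = NULL) {
  stopifnot(inherits(expr, "tcsp_expr"))
  if (expr$unit != "cpm") {
    tcsp_error("tcsp_input_error", "gene-set features require CPM input")
  }
  present <- gene_list[gene_list %in% genes(expr)]
  if (!length(present)) {
    tcsp_error("tcsp_input_error", "no listed gene present in the expression matrix")
  }
  if (length(present) < length(gene_list)) {
    tcsp_warn("tcsp_geneset_warning",
              sprintf("%d listed gene(s) absent: %s",
                      length(gene_list) - length(present),
                      paste(setdiff(gene_list, present), collapse = ", ")))
  }
  x <- t(log2(expr$values[present, , drop = FALSE] + 1))
  feature_table(x, labels, survival)
}

#' Projection + classifier specification
#'
#' @param projection one of `"none"`, `"pca"` (principal components),
#'   `"ica"` (independent components), `"kpca"` (RBF kernel principal
#'   components).
#' @param classifier one of `"adaboost"`, `"knn"`, `"rf"` (random forest),
#'   `"svm"` (linear support-vector machine).
#' @param hyperparameters optional named list overriding the documented
#'   defaults (`k = 5`, `C = 1`, `n_stumps = 50`, `n_tree = 64`,
#'   `max_depth = 4`, `n_components` = number of features).
#' @return A `tcsp_model_spec`.
#' @export
model_spec <- function(projection = "none", classifier = "knn",
                       hyperparameters = list()) {
  if (!projection %in% PROJECTIONS) {
    tcsp_error("tcsp_parameter_error", sprintf("unknown projection: %s", projection))
  }
  if (!classifier %in% CLASSIFIERS) {
    tcsp_error("tcsp_parameter_error", sprintf("unknown classifier: %s", classifier))
  }
  structure(list(projection = projection, classifier = classifier,
                 hyperparameters = hyperparameters),
            class = "tcsp_model_spec")
}

#' The full 4 x 4 projection-by-classifier grid
#' @return list of 16 `tcsp_model_spec`s, projections varying slowest.
#' @export
default_model_grid <- function() {
  grid <- list()
  for (p in PROJECTIONS) for (cl in CLASSIFIERS) {
    grid[[length(grid) + 1L]] <- model_spec(p, cl)
  }
  grid
}

#' Bootstrap out-of-bag evaluation of one model specification
#'
#' For each of `n_boot` iterations (seeds derived from the master seed),
#' samples are drawn with replacement to form the bag; bags containing a
#' single class are redrawn (counted). Features are standardized with
#' bag statistics, the projection and classifier are fitted on the bag, and
#' the out-of-bag samples are scored in `[0, 1]`. Each sample's final score
#' is the mean over its out-of-bag appearances, and one ROC/AUC is computed
#' from those mean scores — the same per-sample score vector later
#' thresholded at 0.5 for survival stratification.
#'
#' @param features a `tcsp_features`.
#' @param spec a `tcsp_model_spec`.
#' @param n_boot bootstrap iterations.
#' @param seed master seed.
#' @return A `tcsp_biomarker_result` with per-sample `scores`,
#'   `oob_counts`, `roc`, `auc`, `spec`, `n_boot`, `seed`, `redraws`, and
#'   `never_oob` (flagged samples with no out-of-bag appearance).
#' @export
bootstrap_oob_evaluate <- function(features, spec, n_boot = 200L, seed = 1L) {
  stopifnot(inherits(features, "tcsp_features"), inherits(spec, "tcsp_model_spec"))
  if (n_boot < 1L) tcsp_error("tcsp_parameter_error", "n_boot must be >= 1")
  y <- features$labels
  if (length(unique(y)) < 2L) {
    tcsp_error("tcsp_label_error", "both classes must be present")
  }
  n <- nrow(features$x)
  iter_seeds <- derive_seeds(seed, n_boot)
  score_sum <- numeric(n)
  score_cnt <- integer(n)
  redraws <- 0L
  hp <- spec$hyperparameters
  for (b in seq_len(n_boot)) {
    res <- with_seed(iter_seeds[b], {
      bag <- sample.int(n, n, replace = TRUE)
      tries <- 0L
      while (length(unique(y[bag])) < 2L && tries < 100L) {
        bag <- sample.int(n, n, replace = TRUE)
        tries <- tries + 1L
      }
      oob <- setdiff(seq_len(n), unique(bag))
      if (!length(oob)) {
        list(oob = integer(0), scores = numeric(0), tries = tries)
      } else {
        xb <- features$x[bag, , drop = FALSE]
        ctr <- colMeans(xb)
        scl <- apply(xb, 2L, stats::sd)
        scl[scl == 0 | !is.finite(scl)] <- 1
        xb <- standardize_matrix(xb, ctr, scl)
        xo <- standardize_matrix(features$x[oob, , drop = FALSE], ctr, scl)
        proj <- fit_projection(spec$projection, xb, hp$n_components)
        zb <- apply_projection(proj, xb)
        zo <- apply_projection(proj, xo)
        clf <- fit_classifier(spec$classifier, zb, y[bag], hp)
        sc <- pmin(pmax(as.numeric(predict_score(clf, zo)), 0), 1)
        list(oob = oob, scores = sc, tries = tries)
      }
    })
    redraws <- redraws + res$tries
    score_sum[res$oob] <- score_sum[res$oob] + res$scores
    score_cnt[res$oob] <- score_cnt[res$oob] + 1L
  }
  never <- score_cnt == 0L
  if (any(never)) {
    tcsp_warn("tcsp_oob_warning",
              sprintf("%d sample(s) never out-of-bag after %d iterations",
                      sum(never), n_boot))
  }
  scores <- ifelse(never, NA_real_, score_sum / pmax(score_cnt, 1L))
  names(scores) <- rownames(features$x)
  ok <- !is.na(scores)
  rr <- roc_auc(scores[ok], y[ok])
  structure(list(scores = scores, oob_counts = score_cnt, roc = rr$roc,
                 auc = rr$auc, spec = spec, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), redraws = redraws,
                 never_oob = names(scores)[never]),
            class = "tcsp_biomarker_result")
}

#' @export
print.tcsp_biomarker_result <- function(x, ...) {
  cat(sprintf("<tcsp_biomarker_result> %s + %s: AUC %.3f (%d bootstraps)\n",
              x$spec$projection, x$spec$classifier, x$auc, x$n_boot))
  invisible(x)
}

#' Select the best model over a specification grid
#'
#' Evaluates every spec with [bootstrap_oob_evaluate()] under the same
#' master seed (so all specs see identical bootstrap bags) and returns the
#' result with maximal out-of-bag AUC; ties go to the earlier grid entry.
#'
#' @param features a `tcsp_features`.
#' @param grid list of `tcsp_model_spec`s.
#' @param n_boot,seed as in [bootstrap_oob_evaluate()].
#' @return The winning `tcsp_biomarker_result`; all AUCs are attached as
#'   the `"grid_aucs"` attribute.
#' @export
select_best_model <- function(features, grid = default_model_grid(),
                              n_boot = 200L, seed = 1L) {
  if (!length(grid)) tcsp_error("tcsp_parameter_error", "empty model grid")
  results <- lapply(grid, function(sp) {
    bootstrap_oob_evaluate(features, sp, n_boot = n_boot, seed = seed)
  })
  aucs <- vapply(results, function(r) r$auc, numeric(1))
  best <- results[[which.max(aucs)]]
  attr(best, "grid_aucs") <- aucs
  best
}

#' ROC curve and AUC by the rank (Mann-Whitney) identity
#'
#' AUC equals the probability that a random positive outscores a random
#' negative, ties counted one half.
#'
#' @param scores numeric scores.
#' @param labels binary labels (1 = positive).
#' @return list with `roc` (data.frame `threshold`, `fpr`, `tpr`, monotone
#'   from (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    tcsp_error("tcsp_label_error", "both classes required for ROC")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[labels == 1L] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[labels == 0L] >= t), numeric(1))
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' One-sided Mann-Whitney U test
#'
#' `U` counts pairs where an `a` value exceeds a `b` value (ties count one
#' half). For `length(a) + length(b) <= 12` the p-value is exact, by full
#' enumeration of all group assignments of the pooled values; larger
#' samples use the normal approximation with tie-corrected variance and a
#' continuity correction.
#'
#' @param a,b numeric samples.
#' @param alternative `"greater"` (a tends larger) or `"less"`.
#' @return list with `U`, `p`, `method`.
#' @export
mann_whitney_one_sided <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) {
    tcsp_error("tcsp_input_error", "both groups must be non-empty")
  }
  na <- length(a)
  nb <- length(b)
  u_stat <- function(av, bv) {
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  U <- u_stat(a, b)
  if (na + nb <= 12L) {
    pooled <- c(a, b)
    combos <- utils::combn(na + nb, na)
    us <- apply(combos, 2L, function(idx) u_stat(pooled[idx], pooled[-idx]))
    p <- if (alternative == "greater") mean(us >= U) else mean(us <= U)
    return(list(U = U, p = p, method = "exact enumeration"))
  }
  N <- na + nb
  ties <- table(c(a, b))
  mu <- na * nb / 2
  sigma <- sqrt(na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1))))
  z <- if (alternative == "greater") (U - mu - 0.5) / sigma else (U - mu + 0.5) / sigma
  p <- if (alternative == "greater") stats::pnorm(z, lower.tail = FALSE)
       else stats::pnorm(z)
  list(U = U, p = p, method = "normal approximation with tie correction")
}

#' Threshold out-of-bag scores and run a two-group log-rank test
#'
#' Samples with mean out-of-bag score `>= threshold` are biomarker
#' positive. Kaplan-Meier curves are estimated per group with right
#' censoring; group difference is tested with the log-rank test. When one
#' group is empty the result is flagged and no test is run.
#'
#' @param result a `tcsp_biomarker_result`.
#' @param survival data.frame with columns `sample`, `time`, `event`.
#' @param threshold positivity cutoff on the mean out-of-bag score.
#' @return list with `groups` (named logical, TRUE = positive),
#'   `statistic` (log-rank chi-square), `p_value`, `km` (a
#'   `survival::survfit` object), `flag`.
#' @export
stratify_and_logrank <- function(result, survival, threshold = 0.5) {
  stopifnot(inherits(result, "tcsp_biomarker_result"))
  ids <- names(result$scores)
  if (!all(ids %in% survival$sample)) {
    tcsp_error("tcsp_input_error", "survival data must cover every scored sample")
  }
  sv <- survival[match(ids, survival$sample), ]
  pos <- result$scores >= threshold
  if (all(pos, na.rm = TRUE) || !any(pos, na.rm = TRUE)) {
    tcsp_warn("tcsp_stratification_warning",
              "all samples fall in one biomarker group; no log-rank test")
    return(list(groups = pos, statistic = NA_real_, p_value = NA_real_,
                km = NULL, flag = "single_group"))
  }
  group <- factor(ifelse(pos, "positive", "negative"),
                  levels = c("negative", "positive"))
  sd_fit <- survival::survdiff(survival::Surv(sv$time, sv$event) ~ group)
  km <- survival::survfit(survival::Surv(sv$time, sv$event) ~ group)
  p <- stats::pchisq(sd_fit$chisq, df = 1L, lower.tail = FALSE)
  list(groups = pos, statistic = unname(sd_fit$chisq), p_value = p,
       km = km, flag = NA_character_)
}
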