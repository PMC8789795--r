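toy_estimates <- function(n = 12, seed = 2, ex_shift = 0) {
  # deconvolve mixtures with known composition against the toy signature
  model <- toy_model()
  set.seed(seed)
  labels <- setNames(rep(c(0L, 1L), length.out = n), sprintf("p%02d", 1:n))
  ests <- lapply(seq_len(n), function(i) {
    f <- runif(5, 0.02, 0.15)
    if (labels[i] == 1L) f[3] <- f[3] + ex_shift  # exhausted elevated in responders
    B <- as.vector(model$S %*% f)
    names(B) <- model$gene_ids
    deconvolve_vector(B, model, sample_id = names(labels)[i])
  })
  list(estimates = ests, labels = labels)
}

test_that("assemble_features yields 5 or 10 columns and standardizes cleanly", {
  te <- toy_estimates()
  ft_raw <- assemble_features(te$estimates, te$labels, mode = "raw")
  expect_identical(colnames(ft_raw$x), subtypes)
  ft_both <- assemble_features(te$estimates, te$labels, mode = "both")
  expect_equal(ncol(ft_both$x), 10L)
  expect_identical(colnames(ft_both$x)[6:10], paste0(subtypes, "_frac"))

  std <- standardize_features(ft_both)
  expect_equal(unname(colMeans(std$x)), rep(0, 10))
  expect_equal(unname(apply(std$x, 2, var)), rep(1, 10))

  # undefined normalization must name the offending sample
  zero <- deconvolve_vector(rep(0, 15), toy_model(), sample_id = "bad1")
  err <- expect_error(
    assemble_features(c(te$estimates, list(zero)),
                      c(te$labels, bad1 = 0L), mode = "both"),
    class = "tcsp_assembly_error")
  expect_match(conditionMessage(err), "bad1")
  # raw mode tolerates the zero sample
  expect_silent(assemble_features(c(te$estimates, list(zero)),
                                  c(te$labels, bad1 = 0L), mode = "raw"))
})

test_that("extract_geneset_features uses log2(CPM+1) and drops absent genes", {
  v <- matrix(c(3, 7, 15, 31, 1, 0), nrow = 3,
              dimnames = list(c("PDCD1", "LAG3", "HAVCR2"), c("s1", "s2")))
  expr <- expression_matrix(v, unit = "cpm")
  labels <- c(s1 = 0L, s2 = 1L)
  ft <- extract_geneset_features(expr, c("PDCD1", "LAG3", "HAVCR2"), labels)
  expect_equal(ncol(ft$x), 3L)
  expect_equal(ft$x["s1", "PDCD1"], 2)

  expect_warning(
    ft2 <- extract_geneset_features(expr, c("PDCD1", "LAG3", "MISSING"), labels),
    class = "tcsp_geneset_warning")
  expect_equal(ncol(ft2$x), 2L)
  expect_error(extract_geneset_features(expr, c("NOPE"), labels),
               class = "tcsp_input_error")

  # doubling expression shifts log features by +1; standardized unchanged
  # 2*(v+1) = (2v+1)+1, so features of 2v+1 sit exactly one log2 unit higher
  ftx <- extract_geneset_features(expression_matrix(2 * v + 1, unit = "cpm"),
                                  c("PDCD1", "LAG3"), labels)
  base <- extract_geneset_features(expr, c("PDCD1", "LAG3"), labels)
  expect_equal(ftx$x, base$x + 1)
  expect_equal(standardize_features(ftx)$x, standardize_features(base)$x)
})

test_that("roc_auc equals exhaustive pair counting and honors tie rules", {
  expect_equal(roc_auc(c(0.2, 0.8), c(0, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.4, 6), c(0, 1, 0, 1, 1, 0))$auc, 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), class = "tcsp_label_error")

  set.seed(21)
  for (i in 1:50) {
    scores <- round(runif(6), 1)  # rounding forces ties
    labels <- sample(c(0, 0, 1, 1, sample(0:1, 2, replace = TRUE)))
    if (length(unique(labels)) < 2) next
    rr <- roc_auc(scores, labels)
    expect_identical(rr$auc, auc_pair_oracle(scores, labels))
    expect_true(all(diff(rr$roc$fpr) >= 0) && all(diff(rr$roc$tpr) >= 0))
    expect_equal(rr$roc$fpr[1], 0)
    expect_equal(rr$roc$tpr[nrow(rr$roc)], 1)
  }
})

test_that("one-sided Mann-Whitney matches enumeration and wilcox.test", {
  r <- mann_whitney_one_sided(c(4, 5, 6), c(1, 2, 3), "greater")
  expect_equal(r$p, 1 / 20)
  expect_equal(r$U, 9)
  expect_match(r$method, "exact")

  # symmetric null: identical groups
  same <- mann_whitney_one_sided(c(1, 2, 3), c(1, 2, 3), "greater")
  expect_gte(same$p, 0.5)

  # complement identity at the observed U (no ties)
  a <- c(2.3, 4.1, 0.5)
  b <- c(1.1, 3.3, 5.5, 0.2)
  pg <- mann_whitney_one_sided(a, b, "greater")$p
  pl <- mann_whitney_one_sided(a, b, "less")$p
  expect_gte(pg + pl, 1)

  # exact path agrees with wilcox.test's exact p
  set.seed(33)
  for (i in 1:20) {
    a <- round(rnorm(4), 2)
    b <- round(rnorm(5), 2)
    if (any(outer(a, b, "=="))) next
    expect_equal(mann_whitney_one_sided(a, b, "greater")$p,
                 suppressWarnings(wilcox.test(a, b, alternative = "greater",
                                              exact = TRUE)$p.value))
  }

  # large-sample path approximates wilcox.test's corrected normal p
  set.seed(34)
  a <- rnorm(20, 0.5)
  b <- rnorm(15)
  ours <- mann_whitney_one_sided(a, b, "greater")
  ref <- wilcox.test(a, b, alternative = "greater", exact = FALSE, correct = TRUE)
  expect_match(ours$method, "normal")
  expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
  expect_error(mann_whitney_one_sided(numeric(0), b), class = "tcsp_input_error")
})

test_that("separated classes give near-perfect AUC for every classifier", {
  n <- 20
  labels <- setNames(rep(c(0L, 1L), each = n / 2), sprintf("s%02d", 1:n))
  set.seed(6)
  x <- matrix(rnorm(n * 2), n, 2, dimnames = list(names(labels), c("f1", "f2")))
  x[labels == 1L, 1] <- x[labels == 1L, 1] + 10  # 10-sigma separation
  sep <- feature_table(x, labels)
  for (clf in c("knn", "svm", "adaboost", "rf")) {
    res <- bootstrap_oob_evaluate(sep, model_spec("none", clf),
                                  n_boot = 200, seed = 4)
    expect_gte(res$auc, 0.99)
    expect_true(all(res$scores >= 0 & res$scores <= 1))
  }
})

test_that("every projection runs and preserves separability", {
  n <- 24
  labels <- setNames(rep(c(0L, 1L), each = n / 2), sprintf("s%02d", 1:n))
  set.seed(14)
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(names(labels), paste0("f", 1:5)))
  x[labels == 1L, ] <- x[labels == 1L, ] + 4
  ft <- feature_table(x, labels)
  for (proj in c("none", "pca", "ica", "kpca")) {
    res <- bootstrap_oob_evaluate(ft, model_spec(proj, "knn"), n_boot = 60, seed = 2)
    expect_gte(res$auc, 0.95)
  }
})

test_that("out-of-bag bookkeeping matches the bootstrap exclusion rate", {
  n <- 30
  labels <- setNames(rep(c(0L, 1L), each = n / 2), sprintf("s%02d", 1:n))
  set.seed(7)
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(names(labels), letters[1:3]))
  ft <- feature_table(x, labels)
  n_boot <- 200
  res <- bootstrap_oob_evaluate(ft, model_spec("none", "knn"),
                                n_boot = n_boot, seed = 11)
  p_oob <- (1 - 1 / n)^n
  frac <- sum(res$oob_counts) / (n * n_boot)
  se <- sqrt(p_oob * (1 - p_oob) / (n * n_boot))
  expect_lte(abs(frac - p_oob), 3 * se)
  expect_true(all(res$oob_counts >= 1))
  expect_length(res$never_oob, 0)
})

test_that("results are reproducible per seed and model selection is an argmax", {
  te <- toy_estimates(n = 16, ex_shift = 0.4)
  ft <- assemble_features(te$estimates, te$labels, mode = "raw")
  r1 <- bootstrap_oob_evaluate(ft, model_spec("pca", "svm"), n_boot = 40, seed = 9)
  r2 <- bootstrap_oob_evaluate(ft, model_spec("pca", "svm"), n_boot = 40, seed = 9)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$auc, r2$auc)

  grid <- list(model_spec("none", "knn"), model_spec("none", "svm"),
               model_spec("pca", "knn"))
  best <- select_best_model(ft, grid, n_boot = 40, seed = 9)
  aucs <- vapply(grid, function(sp) {
    bootstrap_oob_evaluate(ft, sp, n_boot = 40, seed = 9)$auc
  }, numeric(1))
  expect_equal(attr(best, "grid_aucs"), aucs)
  expect_equal(best$auc, max(aucs))
  expect_identical(best$spec, grid[[which.max(aucs)]])

  # identical specs tie -> first occurrence wins
  twice <- select_best_model(ft, list(model_spec("none", "knn"),
                                      model_spec("none", "knn")),
                             n_boot = 20, seed = 9)
  expect_identical(twice$spec, model_spec("none", "knn"))
  expect_error(select_best_model(ft, list()), class = "tcsp_parameter_error")
})

test_that("log-rank stratification matches hand computation", {
  # 4 samples, all events, alternating groups by score threshold 0.5:
  # hand tally of observed-minus-expected gives chi-square 8/13
  scores <- c(p1 = 0.9, p2 = 0.1, p3 = 0.8, p4 = 0.2)
  res <- structure(list(scores = scores, oob_counts = rep(10L, 4),
                        roc = NULL, auc = 0.5,
                        spec = model_spec(), n_boot = 10L, seed = 1L,
                        redraws = 0L, never_oob = character(0)),
                   class = "tcsp_biomarker_result")
  surv <- data.frame(sample = c("p1", "p2", "p3", "p4"),
                     time = c(1, 2, 3, 4), event = 1)
  lr <- stratify_and_logrank(res, surv)
  expect_identical(unname(lr$groups), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(lr$statistic, 8 / 13, tolerance = 1e-9)
  expect_equal(lr$p_value, pchisq(8 / 13, 1, lower.tail = FALSE), tolerance = 1e-9)

  # identical survival in both groups: statistic 0, p = 1
  surv_same <- data.frame(sample = names(scores),
                          time = c(5, 5, 9, 9), event = c(1, 1, 0, 0))
  lr2 <- stratify_and_logrank(res, surv_same)
  expect_equal(lr2$statistic, 0, tolerance = 1e-12)
  expect_equal(lr2$p_value, 1, tolerance = 1e-12)

  # degenerate stratification flags and skips the test
  res$scores[] <- 0.9
  expect_warning(lr3 <- stratify_and_logrank(res, surv),
                 class = "tcsp_stratification_warning")
  expect_identical(lr3$flag, "single_group")
  expect_true(is.na(lr3$statistic))
})

test_that("elevated exhausted/EM signal is recovered end-to-end", {
  te <- toy_estimates(n = 24, seed = 15, ex_shift = 0.3)
  ft <- assemble_features(te$estimates, te$labels, mode = "raw")
  best <- select_best_model(ft, list(model_spec("none", "knn"),
                                     model_spec("pca", "svm")),
                            n_boot = 60, seed = 3)
  expect_gte(best$auc, 0.85)
})
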