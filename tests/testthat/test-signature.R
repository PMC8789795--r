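make_ref <- function(values, labels) {
  reference_profiles(expression_matrix(values, unit = "cpm"), labels)
}

test_that("rank_genes computes log2 fold differences with deterministic ties", {
  # gene hi: 100 in EX vs 10 elsewhere; gene mid: 50 vs 25; zz/aa tie at 0
  v <- rbind(
    hi  = rep(10, 10), mid = rep(25, 10), zz = rep(40, 10), aa = rep(40, 10)
  )
  colnames(v) <- paste0(rep(subtypes, each = 2), "_", 1:2)
  ex_cols <- startsWith(colnames(v), "EX")
  v["hi", ex_cols] <- 100
  v["mid", ex_cols] <- 50
  ref <- make_ref(v, setNames(rep(subtypes, each = 2), colnames(v)))
  ranked <- rank_genes(ref, "EX", pseudocount = 1)
  expect_equal(ranked$log2_fold[ranked$gene == "hi"], log2(101 / 11))
  expect_lt(ranked$log2_fold[ranked$gene == "mid"], log2(101 / 11))
  expect_identical(ranked$gene[1:2], c("hi", "mid"))
  # identical means in all subtypes -> fold 0; tie broken by gene id
  expect_equal(ranked$log2_fold[ranked$gene == "zz"], 0)
  expect_identical(ranked$gene[3:4], c("aa", "zz"))
  expect_error(rank_genes(ref, "XX"), class = "tcsp_parameter_error")
  expect_error(rank_genes(ref, "EX", pseudocount = 0), class = "tcsp_parameter_error")
})

test_that("gate_genes enforces the CV and abundance gates in rank order", {
  # EX has three replicates; plant gate failures among high-fold genes
  n_rep <- c(N = 2, A = 2, EX = 3, EM = 2, CM = 2)
  ids <- unlist(mapply(function(t, k) paste0(t, "_", seq_len(k)), names(n_rep), n_rep))
  labels <- setNames(rep(names(n_rep), n_rep), ids)
  v <- matrix(10, nrow = 14, ncol = length(ids),
              dimnames = list(sprintf("c%02d", 1:14), ids))
  ex_cols <- labels == "EX"
  # 12 candidates elevated in EX, ranked roughly c01 > c02 > ... by fold;
  # c13/c14 stay at baseline (fold 0)
  for (i in 1:12) v[i, ex_cols] <- 105 - 5 * i
  v["c03", ex_cols] <- c(10, 20, 400)           # huge CV -> cv_gate
  v["c05", ex_cols] <- c(14, 14, 14)            # max CPM 14 < 15 -> cpm_gate
  v["c05", !ex_cols] <- 0.5                     # keeps its fold high (~3.3)
  v["c07", ex_cols] <- c(100, 220, 30)          # CV 0.82 -> cv_gate
  ref <- make_ref(v, labels)
  ranked <- rank_genes(ref, "EX")
  res <- gate_genes(ranked, ref, "EX", n_target = 8)
  expect_length(res$genes, 8)
  expect_false(any(c("c03", "c05", "c07") %in% res$genes))
  expect_identical(res$genes, gate_oracle(ref, "EX", n_target = 8))
  expect_setequal(res$audit$status[res$audit$gene %in% c("c03", "c05", "c07")],
                  "removed")
  expect_identical(res$audit$reason[res$audit$gene == "c05"], "cpm_gate")
  expect_identical(res$audit$reason[res$audit$gene == "c03"], "cv_gate")
  expect_equal(sum(res$audit$status == "kept") + sum(res$audit$status == "removed"),
               nrow(res$audit))

  # explicit threshold examples
  v2 <- rbind(x = c(10, 20, rep(5, 8)), y = rep(30, 10))
  colnames(v2) <- paste0(rep(subtypes, each = 2), "_", 1:2)
  two_rep <- make_ref(v2, setNames(rep(subtypes, each = 2), colnames(v2)))
  ranked2 <- rank_genes(two_rep, "N")
  expect_warning(res2 <- gate_genes(ranked2, two_rep, "N", n_target = 2),
                 class = "tcsp_gate_warning")
  expect_false("x" %in% res2$genes)  # CV = sd/mean = 7.07/15 = 0.471 > 0.25

  expect_error(gate_genes(ranked, ref, "EX", n_target = 0),
               class = "tcsp_parameter_error")
})

test_that("gates are monotone in their thresholds", {
  cfg <- acceptance_config(seed = 7, n_genes = 200L, markers_per_subtype = 6L)
  ref <- generate_reference(cfg)
  ranked <- rank_genes(ref, "EX")
  strict <- suppressWarnings(
    gate_genes(ranked, ref, "EX", cv_max = 0.15, cpm_min = 30, n_target = 1000))
  relaxed <- suppressWarnings(
    gate_genes(ranked, ref, "EX", cv_max = 0.25, cpm_min = 15, n_target = 1000))
  expect_true(all(strict$genes %in% relaxed$genes))
})

test_that("build_preliminary_model takes replicate means over the union", {
  v <- rbind(
    gA1 = c(100, 120, rep(10, 8)), gA2 = c(50, 70, rep(5, 8)),
    gB1 = c(rep(8, 2), 200, 240, rep(8, 6)), gB2 = c(rep(4, 2), 30, 50, rep(4, 6))
  )
  colnames(v) <- paste0(rep(subtypes, each = 2), "_", 1:2)
  ref <- make_ref(v, setNames(rep(subtypes, each = 2), colnames(v)))
  sel <- list(N = c("gA1", "gA2"), A = c("gB1", "gB2"),
              EX = c("gA1"), EM = c("gA1"), CM = c("gA1"))
  model <- build_preliminary_model(ref, sel)
  # gene selected by several subtypes appears exactly once
  expect_identical(model$gene_ids, c("gA1", "gA2", "gB1", "gB2"))
  expect_equal(model$S["gA1", "N"], 110)
  expect_equal(model$S["gA2", "N"], 60)
  expect_equal(model$S["gB1", "A"], 220)
  expect_equal(model$S["gB2", "A"], 40)
  expect_equal(model$S["gB1", "N"], 8)

  # duplicated replicate leaves the means unchanged
  v2 <- cbind(v, N_3 = v[, "N_1"])
  ref2 <- make_ref(v2, setNames(c(rep(subtypes, each = 2), "N"), colnames(v2)))
  expect_equal(build_preliminary_model(ref2, sel)$S["gA2", "A"],
               model$S["gA2", "A"])

  expect_error(build_preliminary_model(ref, list(N = "gA1")),
               class = "tcsp_parameter_error")
})

test_that("filter_background applies the inclusive score threshold", {
  model <- toy_model()
  # panel: g01 at 25 CPM (score 25/100 = 0.25), g04 at exactly 20 CPM
  # (score 20/100 = 0.2, inclusive bound), g07 at 11.9 (score 0.119), others 0
  lines <- sprintf("cl%02d", 1:4)
  pv <- matrix(0, nrow = 15, ncol = 4, dimnames = list(rownames(toy_signature()), lines))
  pv["g01", ] <- 25
  pv["g04", ] <- 20
  pv["g07", ] <- 11.9
  pv["g10", ] <- c(400, 0, 0, 0)  # only expressed in the immune line
  origins <- setNames(c("haematopoietic_and_lymphoid_tissue", "lung", "ovary", "skin"),
                      lines)
  panel <- background_panel(expression_matrix(pv, unit = "cpm"), origins)
  filtered <- filter_background(model, panel, threshold = 0.2)
  expect_false("g01" %in% filtered$gene_ids)   # 0.25 >= 0.2 -> removed
  expect_false("g04" %in% filtered$gene_ids)   # exactly 0.2 -> removed
  expect_true("g07" %in% filtered$gene_ids)    # 0.119/0.6... below threshold
  expect_true("g10" %in% filtered$gene_ids)    # immune line excluded from mean

  audit <- filtered$provenance$audit
  expect_identical(audit$reason[audit$gene == "g01"], "background")
  expect_equal(audit$background_score[audit$gene == "g01"], 0.25)
  score <- background_score_oracle(model, panel, c("haematopoietic", "lymphoid"))
  expect_equal(audit$background_score[match(model$gene_ids, audit$gene)],
               unname(score))

  # genes absent from the panel are kept with score 0
  small_panel <- background_panel(
    expression_matrix(pv[1:3, , drop = FALSE], unit = "cpm"), origins)
  expect_warning(kept <- filter_background(model, small_panel),
                 class = "tcsp_panel_coverage_warning")
  a2 <- kept$provenance$audit
  expect_equal(a2$background_score[a2$gene == "g12"], 0)
  expect_true("g12" %in% kept$gene_ids)

  expect_error(filter_background(model, panel, threshold = 0),
               class = "tcsp_parameter_error")

  # raising the threshold never removes a previously kept gene
  loose <- filter_background(model, panel, threshold = 0.3)
  expect_true(all(filtered$gene_ids %in% loose$gene_ids))
})

test_that("build_shems recovers planted markers and is deterministic", {
  cfg <- acceptance_config(seed = 31, n_genes = 160L, markers_per_subtype = 5L,
                           n_tumor_genes = 20L)
  ref <- generate_reference(cfg)
  bg <- generate_background(cfg)
  model <- build_shems(ref, bg$panel)
  expect_setequal(model$gene_ids, names(attr(ref, "markers")))

  # contaminated markers are removed by the background filter
  cfg2 <- acceptance_config(seed = 31, n_genes = 160L, markers_per_subtype = 5L,
                            n_tumor_genes = 20L, contaminated_markers = 3L)
  bg2 <- generate_background(cfg2)
  model2 <- build_shems(ref, bg2$panel)
  expect_length(bg2$contaminated, 3L)
  expect_false(any(bg2$contaminated %in% model2$gene_ids))
  expect_setequal(model2$gene_ids, setdiff(names(attr(ref, "markers")), bg2$contaminated))

  # byte-identical model files on identical inputs
  f1 <- tempfile(); f2 <- tempfile()
  write_model(model, f1)
  write_model(build_shems(generate_reference(cfg), bg$panel), f2)
  expect_identical(readLines(f1), readLines(f2))
})
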