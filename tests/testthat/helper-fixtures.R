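# Small in-code fixtures shared across test files.

subtypes <- c("N", "A", "EX", "EM", "CM")

# Reference with two identical replicates per subtype, so subtype means are
# exact and deterministic (CV = 0 everywhere).
exact_reference <- function(S) {
  cols <- do.call(cbind, lapply(subtypes, function(t) {
    cbind(S[, t], S[, t])
  }))
  colnames(cols) <- paste0(rep(subtypes, each = 2L), "_", 1:2)
  labels <- setNames(rep(subtypes, each = 2L), colnames(cols))
  reference_profiles(expression_matrix(cols, unit = "cpm"), labels)
}

# 15-gene toy signature: three private markers per subtype at 100/80/60 CPM
# over a baseline of 1.
toy_signature <- function() {
  g <- sprintf("g%02d", 1:15)
  S <- matrix(1, 15, 5, dimnames = list(g, subtypes))
  for (t in seq_along(subtypes)) {
    S[(3 * t - 2):(3 * t), t] <- c(100, 80, 60)
  }
  S
}

toy_model <- function() {
  S <- toy_signature()
  ref <- exact_reference(S)
  sel <- lapply(seq_along(subtypes), function(t) rownames(S)[(3 * t - 2):(3 * t)])
  names(sel) <- subtypes
  build_preliminary_model(ref, sel)
}

# Deconvolve a single CPM vector against a model, returning the estimate.
deconvolve_vector <- function(B, model, ...) {
  nm <- normalize_to_model_max(B, model)
  estimate_fractions(nm$B_norm, nm$S_norm, ...)
}

write_counts_fixture <- function(path, values) {
  df <- data.frame(gene = rownames(values), values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# The shared "acceptance world": the synthetic conditions the validation
# experiments state — 8/3/6/5/3 replicate libraries, 10 planted markers per
# subtype over 500 nulls, 8-fold marker elevation, depth 1e6. Dispersion is
# 0.01 so that planted markers are genuinely "low CV" relative to the 0.25
# gate (the generator default 0.1 puts every gene's expected CV at ~0.32).
acceptance_config <- function(seed = 101L, ...) {
  synthesis_config(seed = seed, dispersion = 0.01, ...)
}
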