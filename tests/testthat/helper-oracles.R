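# Independent oracles, kept outside the package on purpose: each one solves
# the same problem as an implementation path by a different algorithm.

# Lawson-Hanson active-set non-negative least squares: the brute-force
# reference the SVR deconvolution is compared against.
nnls_oracle <- function(A, b, tol = 1e-10, max_iter = 200L) {
  p <- ncol(A)
  P <- logical(p)
  x <- numeric(p)
  w <- as.vector(crossprod(A, b - A %*% x))
  for (it in seq_len(max_iter)) {
    if (all(P) || max(w[!P]) <= tol) break
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      s <- numeric(p)
      s[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      s[is.na(s)] <- 0
      if (all(s[P] > tol)) {
        x <- s
        break
      }
      q <- P & (s <= tol)
      alpha <- min(x[q] / (x[q] - s[q]))
      x <- x + alpha * (s - x)
      P[P & (x <= tol)] <- FALSE
      x[!P] <- 0
    }
    w <- as.vector(crossprod(A, b - A %*% x))
  }
  x
}

# AUC by exhaustive positive-negative pair counting (ties one half).
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# Brute-force re-evaluation of every signature gate for one subtype:
# recompute fold ranking, CV and max CPM with plain loops and walk the
# gates independently of gate_genes().
gate_oracle <- function(ref, subtype, pseudocount = 1, cv_max = 0.25,
                        cpm_min = 15, n_target = 10L) {
  v <- ref$matrix$values
  in_t <- ref$labels == subtype
  lfd <- numeric(nrow(v))
  for (i in seq_len(nrow(v))) {
    lfd[i] <- log2((mean(v[i, in_t]) + pseudocount) /
                   (mean(v[i, !in_t]) + pseudocount))
  }
  ord <- order(-lfd, rownames(v), method = "radix")
  chosen <- character(0)
  for (i in ord) {
    reps <- v[i, in_t]
    cv <- if (mean(reps) > 0) sd(reps) / mean(reps) else Inf
    if (cv > cv_max || max(reps) < cpm_min) next
    chosen <- c(chosen, rownames(v)[i])
    if (length(chosen) == n_target) break
  }
  chosen
}

# Background-filter oracle: per-gene score recomputed with loops.
background_score_oracle <- function(model, panel, excluded_origins) {
  keep_line <- !vapply(tolower(panel$origins), function(o) {
    any(vapply(tolower(excluded_origins), grepl, logical(1), x = o, fixed = TRUE))
  }, logical(1))
  vapply(model$gene_ids, function(g) {
    if (!g %in% rownames(panel$matrix$values)) return(0)
    mean(panel$matrix$values[g, keep_line]) / max(model$S[g, ])
  }, numeric(1))
}
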