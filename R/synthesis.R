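#' Synthetic-world configuration
#'
#' Describes a seeded synthetic dataset emulating the statistical structure
#' of the reference T-cell libraries, the tumor background, and count-level
#' mixtures: subtype-specific marker genes elevated `marker_fold`-fold over
#' a shared log-normal baseline, negative-binomial replicate noise at a
#' stated sequencing depth, and background profiles expressing a disjoint
#' "tumor" gene set and none of the markers (unless contamination is
#' requested).
#'
#' @param n_genes total genes; markers occupy `5 * markers_per_subtype` of
#'   them, `n_tumor_genes` of the remaining null genes are elevated in the
#'   background.
#' @param markers_per_subtype planted marker genes per subtype.
#' @param marker_fold expected fold elevation of a marker in its own subtype.
#' @param replicates named integer vector of replicate libraries per subtype
#'   (defaults to the 8/3/6/5/3 design of the reference data).
#' @param background_profiles number of bulk tumor (CD45-negative) profiles.
#' @param n_cell_lines background panel cell lines (two of which are
#'   immune-derived and subject to origin exclusion).
#' @param n_tumor_genes null genes elevated in tumor background.
#' @param depth expected total counts per library.
#' @param dispersion negative-binomial overdispersion of replicate counts
#'   (`0` = Poisson).
#' @param contaminated_markers number of exhausted-subtype markers also
#'   planted into the retained background cell lines (exercises the
#'   background filter).
#' @param seed mandatory integer seed; everything downstream is
#'   bit-reproducible given it.
#' @return A `tcsp_synthesis_config`.
#' @export
synthesis_config <- function(n_genes = 550L, markers_per_subtype = 10L,
                             marker_fold = 8,
                             replicates = c(N = 8L, A = 3L, EX = 6L, EM = 5L, CM = 3L),
                             background_profiles = 3L, n_cell_lines = 12L,
                             n_tumor_genes = 50L, depth = 1e6,
                             dispersion = 0.1, contaminated_markers = 0L,
                             seed) {
  if (missing(seed)) tcsp_error("tcsp_parameter_error", "seed is mandatory")
  if (5L * markers_per_subtype > n_genes) {
    tcsp_error("tcsp_config_error",
               "markers_per_subtype x 5 exceeds n_genes")
  }
  if (marker_fold <= 1) {
    tcsp_error("tcsp_config_error", "marker_fold must exceed 1")
  }
  if (any(c(n_genes, markers_per_subtype, depth, background_profiles,
            n_cell_lines, n_tumor_genes, replicates) <= 0) || dispersion < 0) {
    tcsp_error("tcsp_config_error", "counts parameters must be positive")
  }
  if (!setequal(names(replicates), SUBTYPES)) {
    tcsp_error("tcsp_config_error", "replicates must name the five subtypes")
  }
  structure(list(
    n_genes = as.integer(n_genes),
    markers_per_subtype = as.integer(markers_per_subtype),
    marker_fold = marker_fold,
    replicates = replicates[SUBTYPES],
    background_profiles = as.integer(background_profiles),
    n_cell_lines = as.integer(n_cell_lines),
    n_tumor_genes = as.integer(n_tumor_genes),
    depth = depth,
    dispersion = dispersion,
    contaminated_markers = as.integer(contaminated_markers),
    seed = as.integer(seed)
  ), class = "tcsp_synthesis_config")
}

# The deterministic "world" behind a config: gene names, marker layout,
# shared baseline, expected CPM per subtype and per background profile.
synthesis_world <- function(cfg) {
  mps <- cfg$markers_per_subtype
  marker_genes <- unlist(lapply(SUBTYPES, function(t) sprintf("mk%s%02d", t, seq_len(mps))))
  n_null <- cfg$n_genes - length(marker_genes)
  null_genes <- sprintf("null%04d", seq_len(n_null))
  gene_ids <- c(marker_genes, null_genes)
  sds <- derive_seeds(cfg$seed, 4L)
  baseline <- with_seed(sds[1L], stats::rlnorm(cfg$n_genes, meanlog = log(40), sdlog = 0.8))
  names(baseline) <- gene_ids
  # markers must clear the abundance gate comfortably
  baseline[marker_genes] <- pmax(baseline[marker_genes], 25)
  marker_of <- rep(NA_character_, cfg$n_genes)
  names(marker_of) <- gene_ids
  marker_of[marker_genes] <- rep(SUBTYPES, each = mps)
  # subtype expected CPM: baseline everywhere, fold-elevated own markers,
  # zero on tumor-only genes
  tumor_genes <- null_genes[seq_len(min(cfg$n_tumor_genes, n_null))]
  exp_subtype <- vapply(SUBTYPES, function(t) {
    p <- baseline
    p[marker_genes] <- baseline[marker_genes] # markers at baseline in other subtypes
    p[!is.na(marker_of) & marker_of == t] <-
      baseline[!is.na(marker_of) & marker_of == t] * cfg$marker_fold
    p[tumor_genes] <- 0
    p / sum(p) * 1e6
  }, numeric(cfg$n_genes))
  rownames(exp_subtype) <- gene_ids
  # bulk tumor background: baseline on nulls, elevated tumor genes, no markers
  bg_jitter <- with_seed(sds[2L], matrix(
    stats::rlnorm(cfg$n_genes * cfg$background_profiles, meanlog = 0, sdlog = 0.3),
    nrow = cfg$n_genes))
  exp_background <- vapply(seq_len(cfg$background_profiles), function(j) {
    p <- baseline * bg_jitter[, j]
    p[marker_genes] <- 0
    p[tumor_genes] <- p[tumor_genes] * cfg$marker_fold
    p / sum(p) * 1e6
  }, numeric(cfg$n_genes))
  rownames(exp_background) <- gene_ids
  colnames(exp_background) <- sprintf("bg%02d", seq_len(cfg$background_profiles))
  list(gene_ids = gene_ids, marker_genes = marker_genes,
       null_genes = null_genes, tumor_genes = tumor_genes,
       baseline = baseline, marker_of = marker_of,
       expected_subtype_cpm = exp_subtype,
       expected_background_cpm = exp_background,
       seeds = sds)
}

# NB (or Poisson) counts around an expected CPM profile at a given depth.
draw_counts <- function(expected_cpm, depth, dispersion) {
  mu <- expected_cpm / 1e6 * depth
  if (dispersion > 0) {
    stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  } else {
    stats::rpois(length(mu), lambda = mu)
  }
}

#' Generate a labeled synthetic reference set
#'
#' Draws replicate count libraries for the five subtypes around the
#' config's expected profiles, computes CPM, and returns a
#' `tcsp_reference`. The raw counts and the expected (noise-free) CPM
#' profiles are attached as attributes `"counts"` and `"expected_cpm"`;
#' the planted marker layout as `"markers"`.
#'
#' @param cfg a `tcsp_synthesis_config`.
#' @return A `tcsp_reference`.
#' @export
generate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "tcsp_synthesis_config"))
  world <- synthesis_world(cfg)
  n_rep <- cfg$replicates
  ids <- unlist(lapply(SUBTYPES, function(t) sprintf("%s_rep%d", t, seq_len(n_rep[[t]]))))
  labels <- rep(SUBTYPES, times = n_rep)
  names(labels) <- ids
  counts <- with_seed(world$seeds[3L], {
    vapply(seq_along(ids), function(j) {
      draw_counts(world$expected_subtype_cpm[, labels[j]], cfg$depth, cfg$dispersion)
    }, numeric(cfg$n_genes))
  })
  dimnames(counts) <- list(world$gene_ids, ids)
  cm <- expression_matrix(counts, unit = "counts")
  ref <- reference_profiles(compute_cpm(cm), labels)
  attr(ref, "counts") <- cm
  attr(ref, "expected_cpm") <- world$expected_subtype_cpm
  attr(ref, "markers") <- world$marker_of[!is.na(world$marker_of)]
  ref
}

#' Generate a synthetic tumor background panel and bulk background profiles
#'
#' The panel holds non-immune cancer cell lines expressing the baseline and
#' the tumor gene set (never the subtype markers, except the optional
#' contaminated exhausted markers), plus two immune-derived lines — which
#' do express markers — whose origin strings match the default exclusion
#' list. Bulk CD45-negative profiles for mixtures are returned as expected
#' CPM vectors.
#'
#' @param cfg a `tcsp_synthesis_config`.
#' @return list with `panel` (a `tcsp_background_panel`),
#'   `profiles` (gene x profile expected-CPM matrix),
#'   `contaminated` (ids of markers planted into the panel).
#' @export
generate_background <- function(cfg) {
  stopifnot(inherits(cfg, "tcsp_synthesis_config"))
  world <- synthesis_world(cfg)
  n_lines <- cfg$n_cell_lines
  tumor_origins <- c("lung", "ovary", "skin", "breast", "colon")
  n_immune <- min(2L, n_lines - 1L)
  origins <- c(rep_len(tumor_origins, n_lines - n_immune),
               rep("haematopoietic_and_lymphoid_tissue", n_immune))
  line_ids <- sprintf("line%02d", seq_len(n_lines))
  names(origins) <- line_ids
  contaminated <- character(0)
  if (cfg$contaminated_markers > 0L) {
    ex_markers <- names(world$marker_of)[!is.na(world$marker_of) & world$marker_of == "EX"]
    contaminated <- utils::head(ex_markers, cfg$contaminated_markers)
  }
  counts <- with_seed(world$seeds[4L], {
    vapply(seq_len(n_lines), function(j) {
      p <- world$baseline
      if (origins[j] == "haematopoietic_and_lymphoid_tissue") {
        # immune-derived line: expresses markers like a T cell would
        mk <- !is.na(world$marker_of)
        p[mk] <- p[mk] * cfg$marker_fold
      } else {
        p[names(world$marker_of)[!is.na(world$marker_of)]] <- 0
        p[world$tumor_genes] <- p[world$tumor_genes] * cfg$marker_fold
        if (length(contaminated)) {
          # half the own-subtype elevation: clears the 0.2 score bound
          p[contaminated] <- world$baseline[contaminated] * cfg$marker_fold / 2
        }
      }
      draw_counts(p / sum(p) * 1e6, cfg$depth, cfg$dispersion)
    }, numeric(cfg$n_genes))
  })
  dimnames(counts) <- list(world$gene_ids, line_ids)
  panel <- background_panel(compute_cpm(expression_matrix(counts, unit = "counts")),
                            origins)
  list(panel = panel, profiles = world$expected_background_cpm,
       contaminated = contaminated)
}

#' Mixture specification
#'
#' @param components gene x component matrix of expected CPM profiles.
#' @param fractions non-negative mixing fractions summing to 1 (within
#'   `1e-9`).
#' @param depth total counts to draw.
#' @param seed integer seed.
#' @return A `tcsp_mixture_spec`.
#' @export
mixture_spec <- function(components, fractions, depth = 1e6, seed) {
  if (missing(seed)) tcsp_error("tcsp_parameter_error", "seed is mandatory")
  components <- as.matrix(components)
  if (length(fractions) != ncol(components)) {
    tcsp_error("tcsp_spec_error", "one fraction per component required")
  }
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    tcsp_error("tcsp_spec_error", "fractions must be non-negative and sum to 1")
  }
  structure(list(components = components, fractions = fractions,
                 depth = depth, seed = as.integer(seed)),
            class = "tcsp_mixture_spec")
}

#' Draw a count-level mixture with known ground truth
#'
#' The expected mixture CPM is the convex combination of the component CPM
#' profiles; counts are drawn multinomially at the stated depth from that
#' distribution — statistically equivalent to subsampling reads from the
#' component libraries in the given proportions. True fractions travel
#' along as the `"true_fractions"` attribute.
#'
#' @param spec a `tcsp_mixture_spec`.
#' @param sample_id column name of the drawn sample.
#' @return A one-sample `tcsp_expr` with `unit = "counts"`.
#' @export
mix_counts <- function(spec, sample_id = "mix") {
  stopifnot(inherits(spec, "tcsp_mixture_spec"))
  p <- as.vector(spec$components %*% spec$fractions)
  p <- p / sum(p)
  counts <- with_seed(spec$seed,
                      stats::rmultinom(1L, size = spec$depth, prob = p))
  dimnames(counts) <- list(rownames(spec$components), sample_id)
  m <- expression_matrix(counts, unit = "counts")
  attr(m, "true_fractions") <- spec$fractions
  m
}

#' Default exhausted-into-background titration series
#'
#' The eleven read fractions of the in-silico exhaustion titration:
#' 0, 1, 2, 5, 8, 12, 17, 25, 50, 75 and 100 percent.
#' @export
titration_fractions <- function() {
  c(0, 0.01, 0.02, 0.05, 0.08, 0.12, 0.17, 0.25, 0.50, 0.75, 1.00)
}

#' Build a titration of an exhausted profile into tumor background
#'
#' One count-level mixture per fraction, each drawn at `depth` with a seed
#' derived from the master seed.
#'
#' @param exhausted_profile expected-CPM vector of the pure exhausted
#'   library.
#' @param background_profile expected-CPM vector of the CD45-negative
#'   background.
#' @param fractions series of exhausted read fractions.
#' @param depth counts per mixture.
#' @param seed master seed.
#' @return list with `counts` (a `tcsp_expr`, one column per fraction) and
#'   `truth` (data.frame `sample`, `fraction`).
#' @export
make_titration <- function(exhausted_profile, background_profile,
                           fractions = titration_fractions(),
                           depth = 1e6, seed) {
  if (missing(seed)) tcsp_error("tcsp_parameter_error", "seed is mandatory")
  if (length(exhausted_profile) != length(background_profile)) {
    tcsp_error("tcsp_spec_error", "profiles must share the gene universe")
  }
  comp <- cbind(EX = exhausted_profile, BG = background_profile)
  seeds <- derive_seeds(seed, length(fractions))
  cols <- lapply(seq_along(fractions), function(i) {
    sp <- mixture_spec(comp, c(fractions[i], 1 - fractions[i]),
                       depth = depth, seed = seeds[i])
    mix_counts(sp, sample_id = sprintf("titr_%03d", round(fractions[i] * 100)))
  })
  counts <- do.call(cbind, lapply(cols, function(m) m$values))
  m <- expression_matrix(counts, unit = "counts")
  list(counts = m,
       truth = data.frame(sample = colnames(counts), fraction = fractions,
                          stringsAsFactors = FALSE))
}
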