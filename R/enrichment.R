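# Gene-set and annotation statistics over pattern gene weights: rank-based
# (Wilcoxon / AUC) set enrichment, list-overlap (hypergeometric) enrichment,
# evolutionary-era contribution, and dosage-sensitivity summaries.

#' Rank enrichment of a gene set in one pattern's weights
#'
#' One-sided Wilcoxon rank-sum test of the amplitudes of set genes against
#' the complement (alternative: set genes ranked higher). The effect size is
#' the AUC `U / (n_set * n_background)` — the probability that a random set
#' gene outranks a random background gene, with midranks for ties.
#' [stats::wilcox.test()] supplies the p-value (exact for small untied
#' samples, normal approximation with continuity correction otherwise);
#' Bonferroni adjustment is across the K patterns.
#'
#' @param decomp A `pattern_decomposition`.
#' @param gene_set Character vector of gene ids.
#' @param pattern Pattern index or name.
#' @param min_set Minimum set genes present in the decomposition.
#' @return One-row data frame: `pattern`, `auc`, `p`, `p_adjusted`,
#'   `n_set`, `n_background`.
#' @export
rank_enrichment <- function(decomp, gene_set, pattern, min_set = 5) {
  stopifnot(inherits(decomp, "pattern_decomposition"))
  k <- resolve_pattern(decomp, pattern)
  genes <- rownames(decomp$A)
  in_set <- genes %in% gene_set
  n1 <- sum(in_set)
  n2 <- sum(!in_set)
  if (n1 < min_set) stop("only ", n1, " set genes present (need >= ", min_set, ")")
  if (n2 < 1) stop("empty background after matching")
  a <- decomp$A[, k]
  r <- rank(a)
  U <- sum(r[in_set]) - n1 * (n1 + 1) / 2
  auc <- U / (n1 * n2)
  p <- stats::wilcox.test(a[in_set], a[!in_set], alternative = "greater")$p.value
  data.frame(pattern = colnames(decomp$A)[k], auc = auc, p = p,
             p_adjusted = min(1, decomp$K * p),
             n_set = n1, n_background = n2, stringsAsFactors = FALSE)
}

#' Rank enrichment of a gene set across all patterns
#'
#' Applies [rank_enrichment()] to every pattern and returns the table
#' sorted by decreasing AUC; `p_adjusted` is Bonferroni across K.
#'
#' @inheritParams rank_enrichment
#' @return Data frame with one row per pattern, sorted by `auc`.
#' @export
enrichment_profile <- function(decomp, gene_set, min_set = 5) {
  rows <- lapply(seq_len(decomp$K), function(k) {
    rank_enrichment(decomp, gene_set, k, min_set = min_set)
  })
  tab <- do.call(rbind, rows)
  tab[order(-tab$auc), , drop = FALSE]
}

#' Hypergeometric overlap enrichment of two gene lists
#'
#' Upper-tail hypergeometric probability of observing at least the actual
#' overlap between a top-gene list and an annotation set drawn from a
#' common universe, plus the fold over the expected overlap.
#'
#' @param top_genes Character vector (subset of `universe`).
#' @param annotation_set Character vector (subset of `universe`).
#' @param universe Character vector of all candidate genes.
#' @return One-row data frame: `overlap`, `expected`, `fold`, `p`.
#' @export
overlap_enrichment <- function(top_genes, annotation_set, universe) {
  if (!length(universe)) stop("empty universe")
  if (!length(top_genes)) stop("empty top gene list")
  universe <- unique(universe)
  top_genes <- unique(top_genes)
  annotation_set <- unique(annotation_set)
  if (!all(top_genes %in% universe)) stop("top_genes must be a subset of the universe")
  if (!all(annotation_set %in% universe)) stop("annotation_set must be a subset of the universe")
  k <- length(intersect(top_genes, annotation_set))
  m <- length(annotation_set)
  N <- length(universe)
  n_top <- length(top_genes)
  expected <- n_top * m / N
  p <- stats::phyper(k - 1, m, N - m, n_top, lower.tail = FALSE)
  data.frame(overlap = k, expected = expected,
             fold = if (expected > 0) k / expected else NA_real_, p = p)
}

#' Evolutionary-era contribution to pattern gene weights
#'
#' Summarizes each pattern's amplitude distribution per gene-age era
#' (1 = ancient .. 5 = primate-specific) and tests era-1 against era-5
#' amplitudes with a two-sided Wilcoxon rank-sum test, reporting the
#' direction of the difference. Conserved dynamic programs are expected to
#' weight ancient genes; individual-specific signatures weight recent ones.
#'
#' @param decomp A `pattern_decomposition`.
#' @param era_map Named integer vector, gene id -> era in 1..5.
#' @param class_labels Optional per-pattern labels (e.g. from
#'   [classify_patterns()]) carried into the output.
#' @param min_per_era Minimum genes per tested era stratum.
#' @return List with `summary` (pattern x era mean/median amplitude and
#'   counts) and `tests` (per pattern: mean amplitudes of eras 1 and 5,
#'   `direction` = sign of era1 - era5 mean difference, Wilcoxon `p`).
#' @export
era_contribution <- function(decomp, era_map, class_labels = NULL,
                             min_per_era = 5) {
  stopifnot(inherits(decomp, "pattern_decomposition"))
  genes <- rownames(decomp$A)
  era <- era_map[genes]
  if (sum(!is.na(era)) == 0) stop("era_map covers none of the decomposition genes")
  eras_present <- table(era)
  if (sum(eras_present >= min_per_era) < 2) {
    stop("need >= 2 eras with >= ", min_per_era, " genes each")
  }
  i1 <- which(era == 1)
  i5 <- which(era == 5)
  if (length(i1) < min_per_era || length(i5) < min_per_era) {
    stop("era 1 and era 5 strata must each have >= ", min_per_era, " genes")
  }
  pats <- colnames(decomp$A)
  summ <- do.call(rbind, lapply(seq_along(pats), function(k) {
    a <- decomp$A[, k]
    do.call(rbind, lapply(sort(unique(era[!is.na(era)])), function(e) {
      v <- a[which(era == e)]
      data.frame(pattern = pats[k], era = e, n = length(v),
                 mean_amplitude = mean(v), median_amplitude = stats::median(v))
    }))
  }))
  tests <- do.call(rbind, lapply(seq_along(pats), function(k) {
    a <- decomp$A[, k]
    d <- mean(a[i1]) - mean(a[i5])
    p <- if (all(a[i1] == a[i1][1]) && all(a[i5] == a[i1][1])) 1 else
      stats::wilcox.test(a[i1], a[i5])$p.value
    data.frame(pattern = pats[k], mean_era1 = mean(a[i1]), mean_era5 = mean(a[i5]),
               direction = sign(d), p = p, stringsAsFactors = FALSE)
  }))
  if (!is.null(class_labels)) tests$label <- class_labels
  list(summary = summ, tests = tests)
}

#' Dosage-sensitivity summary of top pattern genes
#'
#' For each pattern, takes the top `ceiling(top_frac * G)` genes by
#' amplitude (ties broken by gene order) and reports the mean
#' probability-of-haploinsufficiency (pHaplo) over those with a score;
#' genes lacking scores are excluded and counted.
#'
#' @param decomp A `pattern_decomposition`.
#' @param phaplo_map Named numeric vector, gene id -> pHaplo in `[0, 1]`;
#'   must cover at least half the genes.
#' @param top_frac Fraction of genes per pattern (default 0.01).
#' @return Data frame: `pattern`, `n_top`, `n_scored`, `n_missing`,
#'   `mean_phaplo`.
#' @export
dosage_sensitivity_summary <- function(decomp, phaplo_map, top_frac = 0.01) {
  stopifnot(inherits(decomp, "pattern_decomposition"))
  genes <- rownames(decomp$A)
  covered <- sum(genes %in% names(phaplo_map))
  if (covered < length(genes) / 2) {
    stop("pHaplo scores cover fewer than half the genes")
  }
  n_top <- ceiling(top_frac * length(genes))
  out <- do.call(rbind, lapply(seq_len(decomp$K), function(k) {
    ord <- order(-decomp$A[, k], seq_along(genes))
    top <- genes[ord[seq_len(n_top)]]
    ph <- phaplo_map[top]
    scored <- !is.na(ph)
    if (!any(scored)) stop("no scored genes among the top of pattern ", k)
    data.frame(pattern = colnames(decomp$A)[k], n_top = n_top,
               n_scored = sum(scored), n_missing = sum(!scored),
               mean_phaplo = mean(ph[scored]), stringsAsFactors = FALSE)
  }))
  out
}
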