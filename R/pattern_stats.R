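# Classification and embedding of latent patterns: ANOVA of pattern weights
# against the experimental design separates dynamic trajectory modules from
# cell line- and donor-specific signatures.

resolve_pattern <- function(decomp, pattern) {
  if (is.character(pattern)) {
    idx <- match(pattern, colnames(decomp$A))
    if (is.na(idx)) stop("unknown pattern: ", pattern)
    return(idx)
  }
  p <- as.integer(pattern)
  if (p < 1 || p > decomp$K) stop("pattern index out of range 1..", decomp$K)
  p
}

#' Classify patterns as dynamic versus line/donor-specific
#'
#' For each pattern, the sample weights (a row of `P`) are analyzed by a
#' main-effects ANOVA on `line + day + condition` (type II sums of squares);
#' day and condition are treated as factors. Significance is gated at a
#' Bonferroni-adjusted threshold `alpha / K`. A pattern is labeled
#' `line-specific` when the line effect carries the largest partial eta
#' squared and is significant while day and condition are not; it is
#' promoted to `donor-specific` when all replicate lines of the owning donor
#' have mean weights above the 90th percentile of the other lines' mean
#' weights and each carries at least half the top line's mean weight (so a
#' module private to one line is not promoted merely because every other
#' line is near zero). A pattern is `dynamic` when day and/or condition dominate and
#' are significant, and `unresolved` otherwise. The owner of a specific
#' pattern is the line (or donor) with the largest mean weight.
#'
#' @param decomp A `pattern_decomposition`.
#' @param metadata Sample metadata data frame (`sample_id`, `line_id`,
#'   `donor_id`, `condition`, `day`) covering every column of `P`.
#' @param alpha Significance level before the Bonferroni adjustment across
#'   the K patterns.
#' @return Data frame with one row per pattern: p-values and partial eta
#'   squared for line, day and condition, `label` in `dynamic`,
#'   `line-specific`, `donor-specific`, `unresolved`, and `owner` (line or
#'   donor id; `NA` for non-specific patterns).
#' @export
classify_patterns <- function(decomp, metadata, alpha = 0.01) {
  stopifnot(inherits(decomp, "pattern_decomposition"))
  metadata <- as.data.frame(metadata)
  ids <- colnames(decomp$P)
  if (!all(ids %in% metadata$sample_id)) {
    stop("metadata does not cover all samples of the decomposition")
  }
  meta <- metadata[match(ids, metadata$sample_id), ]
  design <- data.frame(line = factor(meta$line_id),
                       day = factor(meta$day),
                       condition = factor(meta$condition))
  keep <- vapply(design, function(f) nlevels(droplevels(f)) >= 2, logical(1))
  if (!all(keep)) {
    warning("dropping single-level factor(s): ",
            paste(names(design)[!keep], collapse = ", "))
  }
  terms_used <- names(design)[keep]
  if (!length(terms_used)) stop("no design factor has >= 2 levels")
  K <- decomp$K
  thr <- alpha / K
  out <- data.frame(pattern = rownames(decomp$P),
                    p_line = NA_real_, p_day = NA_real_, p_condition = NA_real_,
                    eta2_line = NA_real_, eta2_day = NA_real_,
                    eta2_condition = NA_real_,
                    label = "unresolved", owner = NA_character_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    w <- decomp$P[k, ]
    dat <- cbind(design[keep], w = w)
    pv <- stats::setNames(rep(NA_real_, 3), c("line", "day", "condition"))
    eta <- pv
    if (stats::sd(w) > 0) {
      fml <- stats::reformulate(terms_used, response = "w")
      fit <- stats::lm(fml, data = dat)
      an <- car::Anova(fit, type = 2)
      ss <- an[["Sum Sq"]]
      names(ss) <- rownames(an)
      ss_res <- ss[["Residuals"]]
      for (tm in terms_used) {
        pv[tm] <- an[tm, "Pr(>F)"]
        eta[tm] <- ss[[tm]] / (ss[[tm]] + ss_res)
      }
    }
    pv[is.na(pv) & names(pv) %in% terms_used] <- 1
    out$p_line[k] <- pv[["line"]]; out$p_day[k] <- pv[["day"]]
    out$p_condition[k] <- pv[["condition"]]
    out$eta2_line[k] <- eta[["line"]]; out$eta2_day[k] <- eta[["day"]]
    out$eta2_condition[k] <- eta[["condition"]]
    eta_ok <- eta[terms_used]
    if (all(is.na(eta_ok))) next
    dominant <- terms_used[which.max(eta_ok)]
    sig <- function(tm) tm %in% terms_used && !is.na(pv[[tm]]) && pv[[tm]] < thr
    if (dominant == "line" && sig("line") && !sig("day") && !sig("condition")) {
      line_means <- tapply(w, design$line, mean)
      owner_line <- names(line_means)[which.max(line_means)]
      owner_donor <- meta$donor_id[match(owner_line, meta$line_id)]
      donor_lines <- unique(meta$line_id[meta$donor_id == owner_donor])
      other <- line_means[!names(line_means) %in% donor_lines]
      # promotion needs every replicate line of the donor elevated above the
      # other lines AND carrying at least half the top line's signal; the
      # second guard keeps a private single-line module from being promoted
      # just because the non-owner means are all near zero
      promote <- length(donor_lines) >= 2 && length(other) > 0 &&
        all(line_means[donor_lines] > stats::quantile(other, 0.9)) &&
        all(line_means[donor_lines] >= 0.5 * max(line_means[donor_lines]))
      if (promote) {
        out$label[k] <- "donor-specific"
        out$owner[k] <- owner_donor
      } else {
        out$label[k] <- "line-specific"
        out$owner[k] <- owner_line
      }
    } else if (dominant %in% c("day", "condition") && (sig("day") || sig("condition"))) {
      out$label[k] <- "dynamic"
    }
  }
  out
}

#' Hierarchically cluster pattern weights
#'
#' Distance is `1 - Pearson r` between rows of `P`; zero-variance rows are
#' placed at distance 1 from everything (with a warning). Average linkage;
#' the dendrogram leaves are deterministically ordered tightest-cluster
#' first (children with lower merge height come first, ties broken by
#' smallest pattern index).
#'
#' @param decomp A `pattern_decomposition` with `K >= 2`.
#' @param linkage Linkage method for [stats::hclust()].
#' @return The `hclust` object with the deterministic leaf order applied.
#' @export
cluster_patterns <- function(decomp, linkage = "average") {
  stopifnot(inherits(decomp, "pattern_decomposition"))
  if (decomp$K < 2) stop("clustering requires K >= 2")
  P <- decomp$P
  sds <- apply(P, 1, stats::sd)
  if (any(sds == 0)) warning("zero-variance pattern row(s): ",
                             paste(rownames(P)[sds == 0], collapse = ", "),
                             "; distance to them set to 1")
  cors <- suppressWarnings(stats::cor(t(P)))
  cors[!is.finite(cors)] <- 0
  diag(cors) <- 1
  hc <- stats::hclust(stats::as.dist(1 - cors), method = linkage)
  hc$order <- deterministic_leaf_order(hc$merge, hc$height)
  hc
}

# leaf order: depth-first with the lower-height (tighter) child first,
# ties by smallest contained leaf index
deterministic_leaf_order <- function(merge, height) {
  h_of <- function(node) if (node < 0) 0 else height[node]
  rec <- function(node) {
    if (node < 0) return(-node)
    ch <- merge[node, ]
    sub <- lapply(ch, rec)
    o <- order(vapply(ch, h_of, numeric(1)), vapply(sub, min, numeric(1)))
    unlist(sub[o])
  }
  rec(nrow(merge))
}

#' Classical MDS embedding of pattern gene amplitudes
#'
#' Torgerson multidimensional scaling of the distance `1 - Pearson r`
#' between the amplitude columns of `A`. Coordinates are centered at the
#' origin; if the double-centered matrix supports fewer informative
#' dimensions than requested, missing coordinates are zero-padded and
#' flagged.
#'
#' @param decomp A `pattern_decomposition` with `K >= dims + 1`.
#' @param dims Number of embedding dimensions.
#' @return List with `coords` (K x dims), `eig` (eigenvalues) and
#'   `n_informative` (number of positive eigenvalues used).
#' @export
mds_amplitudes <- function(decomp, dims = 2) {
  stopifnot(inherits(decomp, "pattern_decomposition"))
  if (decomp$K < dims + 1) stop("mds requires K >= dims + 1")
  cors <- suppressWarnings(stats::cor(decomp$A))
  cors[!is.finite(cors)] <- 0
  diag(cors) <- 1
  d <- stats::as.dist(1 - cors)
  fit <- suppressWarnings(stats::cmdscale(d, k = dims, eig = TRUE))
  pts <- fit$points
  n_informative <- ncol(pts)
  if (n_informative < dims) {
    pts <- cbind(pts, matrix(0, nrow(pts), dims - n_informative))
  }
  rownames(pts) <- colnames(decomp$A)
  colnames(pts) <- paste0("dim", seq_len(dims))
  list(coords = pts, eig = fit$eig, n_informative = n_informative)
}

#' Correlate pattern gene weights with an external per-gene score
#'
#' Pearson correlation of every amplitude column with a supplied score
#' vector (e.g. knockout differential-expression statistics) over the
#' shared genes, with two-sided p-values.
#'
#' @param decomp A `pattern_decomposition`.
#' @param gene_scores Named numeric vector of per-gene scores.
#' @param min_genes Minimum shared genes (default 10).
#' @return Data frame: `pattern`, `r`, `p`, `n`.
#' @export
correlate_weights_with_scores <- function(decomp, gene_scores, min_genes = 10) {
  stopifnot(inherits(decomp, "pattern_decomposition"))
  shared <- intersect(rownames(decomp$A), names(gene_scores))
  if (length(shared) < min_genes) {
    stop("fewer than ", min_genes, " genes shared between scores and decomposition")
  }
  s <- gene_scores[shared]
  if (stats::sd(s) == 0) stop("constant score vector: correlation undefined")
  A <- decomp$A[shared, , drop = FALSE]
  res <- lapply(seq_len(ncol(A)), function(k) {
    a <- A[, k]
    if (stats::sd(a) == 0) return(c(r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(a, s)
    c(r = unname(ct$estimate), p = ct$p.value)
  })
  data.frame(pattern = colnames(A),
             r = vapply(res, `[[`, numeric(1), "r"),
             p = vapply(res, `[[`, numeric(1), "p"),
             n = length(shared), stringsAsFactors = FALSE)
}
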