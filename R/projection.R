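# Transfer learning: estimate pattern weights of external samples against a
# fixed amplitude space (nonnegative least squares), or project into a fixed
# PCA loading space, with permutation significance for projected signatures.

new_values_matrix <- function(new_study) {
  if (inherits(new_study, "expression_study")) new_study$values else as.matrix(new_study)
}

# shared preparation of a projection: gene matching + scaling
prepare_projection <- function(decomp, new_study, min_genes, external_scaling) {
  Xn <- new_values_matrix(new_study)
  shared <- intersect(rownames(decomp$A), rownames(Xn))
  if (length(shared) < min_genes) {
    stop("gene intersection (", length(shared), ") below the required minimum of ",
         min_genes)
  }
  sc <- decomp$row_scaling[shared]
  As <- decomp$A[shared, , drop = FALSE] / sc
  Xn <- Xn[shared, , drop = FALSE]
  zero <- colSums(abs(Xn)) == 0
  if (any(zero)) stop("all-zero sample(s): ", paste(colnames(Xn)[zero], collapse = ", "))
  Xs <- switch(external_scaling,
               row = Xn / sc,
               zscore = {
                 mu <- rowMeans(Xn)
                 sd <- apply(Xn, 1, stats::sd)
                 sd[sd == 0] <- 1
                 (Xn - mu) / sd
               },
               none = Xn,
               stop("external_scaling must be 'row', 'zscore' or 'none'"))
  list(As = As, Xs = Xs, shared = shared, sc = sc,
       external_scaling = external_scaling)
}

solve_weights <- function(As, Xs) {
  AtA <- crossprod(As)
  B <- crossprod(As, Xs) # K x n
  W <- matrix(0, ncol(As), ncol(Xs))
  for (j in seq_len(ncol(Xs))) W[, j] <- nnls_solve(AtA, B[, j])
  W
}

#' Project external samples into a fixed amplitude space
#'
#' Matches the external matrix to the decomposition on the shared gene
#' space, applies the decomposition's stored per-gene scaling (or per-row
#' z-scaling for cross-platform data such as promoter-level ChIP signal),
#' and solves one exact nonnegative least-squares problem per sample:
#' `w = argmin ||x - A w||^2, w >= 0` (Lawson-Hanson active set).
#'
#' @param decomp A `pattern_decomposition`.
#' @param new_study An [expression_study()] or genes x samples matrix on a
#'   comparable scale.
#' @param min_genes Minimum size of the gene intersection (default 50).
#' @param external_scaling `"row"` (divide by the decomposition's stored
#'   per-gene scaling; default), `"zscore"` (per-row z-scale the external
#'   matrix; for cross-platform signal), or `"none"`.
#' @return Object of class `projection_result`: `weights` (K x samples,
#'   nonnegative), `residual_fraction` (per-sample `||x - Aw||^2 / ||x||^2`),
#'   `genes_used`.
#' @export
project_nnls <- function(decomp, new_study, min_genes = 50,
                         external_scaling = "row") {
  stopifnot(inherits(decomp, "pattern_decomposition"))
  prep <- prepare_projection(decomp, new_study, min_genes, external_scaling)
  W <- solve_weights(prep$As, prep$Xs)
  fitted <- prep$As %*% W
  res <- colSums((prep$Xs - fitted)^2) / colSums(prep$Xs^2)
  dimnames(W) <- list(rownames(decomp$P), colnames(prep$Xs))
  structure(list(weights = W,
                 residual_fraction = stats::setNames(res, colnames(prep$Xs)),
                 genes_used = length(prep$shared),
                 p_perm = NULL, n_perm = 0L, seed = NA_integer_),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("projection_result: %d patterns x %d samples (%d genes used)\n",
              nrow(x$weights), ncol(x$weights), x$genes_used))
  cat(sprintf("  median residual fraction %.3f\n", stats::median(x$residual_fraction)))
  invisible(x)
}

#' Permutation test for a projected signature
#'
#' Tests whether the focal group of external samples carries more of a
#' target pattern than the background group. The statistic is the
#' difference of mean projected weights (focal minus background); the null
#' is built by permuting the gene identifiers of the external data rows
#' before projection, which destroys the signature-specific gene alignment
#' while preserving each sample's value distribution.
#'
#' @inheritParams project_nnls
#' @param focal Logical vector over external samples (TRUE = focal), or a
#'   character vector of focal sample ids.
#' @param target_pattern Pattern index or name.
#' @param n_perm Number of permutations (values below 100 warn).
#' @param seed Integer seed for the permutations.
#' @param scheme `"genes"` (default) permutes the gene identifiers of the
#'   external rows before projection, testing signature-specific gene
#'   alignment; it assumes the external rows are exchangeable under the
#'   null. `"labels"` permutes the focal/background assignment instead,
#'   testing group difference given the observed projections.
#' @return List: `p_value` (`(1 + #{null >= observed}) / (n_perm + 1)`),
#'   `observed`, `null` (permutation statistics), `n_perm`, `seed`,
#'   `weights` (observed projection weights).
#' @export
projection_permutation_test <- function(decomp, new_study, focal, target_pattern,
                                        n_perm = 10000, seed = 1, min_genes = 50,
                                        external_scaling = "row",
                                        scheme = c("genes", "labels")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(decomp, "pattern_decomposition"))
  prep <- prepare_projection(decomp, new_study, min_genes, external_scaling)
  n <- ncol(prep$Xs)
  if (is.character(focal)) focal <- colnames(prep$Xs) %in% focal
  focal <- as.logical(focal)
  if (length(focal) != n) stop("focal must align with the external samples")
  if (!any(focal)) stop("empty focal group")
  if (all(focal)) stop("empty background group")
  if (n_perm < 100) warning("n_perm < 100 gives a coarse p-value floor of ",
                            signif(1 / (n_perm + 1), 3))
  tp <- resolve_pattern(decomp, target_pattern)
  stat_of <- function(W) mean(W[tp, focal]) - mean(W[tp, !focal])
  AtA <- crossprod(prep$As)
  solve_all <- function(B) {
    W <- matrix(0, ncol(prep$As), n)
    for (j in seq_len(n)) W[, j] <- nnls_solve(AtA, B[, j])
    W
  }
  W_obs <- solve_all(crossprod(prep$As, prep$Xs))
  observed <- stat_of(W_obs)
  G <- nrow(prep$Xs)
  null <- with_seed(seed, if (scheme == "genes") {
    # permute the gene identifiers of the raw external rows, then apply each
    # slot's training scaling: the data travel, the per-slot scaling stays
    raw_rows <- if (prep$external_scaling == "row") prep$Xs * prep$sc else prep$Xs
    rescale <- if (prep$external_scaling == "row") function(M) M / prep$sc else identity
    vapply(seq_len(n_perm), function(i) {
      perm <- sample.int(G)
      stat_of(solve_all(crossprod(prep$As, rescale(raw_rows[perm, , drop = FALSE]))))
    }, numeric(1))
  } else {
    w <- W_obs[tp, ]
    vapply(seq_len(n_perm), function(i) {
      f <- sample(focal)
      mean(w[f]) - mean(w[!f])
    }, numeric(1))
  })
  dimnames(W_obs) <- list(rownames(decomp$P), colnames(prep$Xs))
  list(p_value = (1 + sum(null >= observed)) / (n_perm + 1),
       observed = observed, null = null, n_perm = as.integer(n_perm),
       seed = as.integer(seed), target_pattern = rownames(decomp$P)[tp],
       weights = W_obs)
}

#' Fit a PCA model on an expression study
#'
#' Gene-centered singular value decomposition. Loadings columns are
#' orthonormal; each component's sign is fixed so its largest-magnitude
#' loading is positive (deterministic across platforms). Scores are
#' `t(loadings) %*% (x - center)`.
#'
#' @param study An [expression_study()] or genes x samples matrix.
#' @param n_components Number of components, at most `min(genes, samples - 1)`.
#' @return List with `model` (class `pca_model`: `loadings`, `center`,
#'   `explained_variance_fraction`) and `scores` (components x samples).
#' @export
pca_fit <- function(study, n_components) {
  X <- new_values_matrix(study)
  if (ncol(X) < 2) stop("PCA requires at least 2 samples")
  maxc <- min(nrow(X), ncol(X) - 1)
  if (n_components < 1 || n_components > maxc) {
    stop("n_components must lie in 1..", maxc)
  }
  center <- rowMeans(X)
  C <- X - center
  sv <- svd(C)
  L <- sv$u[, seq_len(n_components), drop = FALSE]
  scores <- (diag(sv$d, length(sv$d)) %*% t(sv$v))[seq_len(n_components), , drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(n_components)) {
    s <- sign(L[which.max(abs(L[, j])), j])
    if (s < 0) {
      L[, j] <- -L[, j]
      scores[j, ] <- -scores[j, ]
    }
  }
  ev <- sv$d^2
  dimnames(L) <- list(rownames(X), paste0("PC", seq_len(n_components)))
  dimnames(scores) <- list(colnames(L), colnames(X))
  model <- structure(list(loadings = L, center = stats::setNames(center, rownames(X)),
                          explained_variance_fraction = ev[seq_len(n_components)] / sum(ev)),
                     class = "pca_model")
  list(model = model, scores = scores)
}

#' Project new samples into a fitted PCA space
#'
#' Matches genes, centers with the model's stored per-gene means restricted
#' to the intersection, and returns the raw loading inner products (no
#' re-orthonormalization on the restricted gene set; the intersection
#' fraction is reported so comparability can be judged).
#'
#' @param model A `pca_model` from [pca_fit()].
#' @param new_study An [expression_study()] or genes x samples matrix.
#' @param min_genes Minimum gene intersection (default 50).
#' @return List with `scores` (components x samples), `genes_used` and
#'   `fraction_of_model_genes`.
#' @export
pca_project <- function(model, new_study, min_genes = 50) {
  stopifnot(inherits(model, "pca_model"))
  Xn <- new_values_matrix(new_study)
  shared <- intersect(rownames(model$loadings), rownames(Xn))
  if (length(shared) < min_genes) {
    stop("gene intersection (", length(shared), ") below the required minimum of ",
         min_genes)
  }
  L <- model$loadings[shared, , drop = FALSE]
  scores <- t(L) %*% (Xn[shared, , drop = FALSE] - model$center[shared])
  list(scores = scores, genes_used = length(shared),
       fraction_of_model_genes = length(shared) / nrow(model$loadings))
}
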