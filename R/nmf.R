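# Multi-restart consensus nonnegative matrix factorization. A single run is
# Frobenius-loss NMF by multiplicative updates on the row-scaled expression
# matrix; the consensus step pools pattern-weight vectors across restarts,
# clusters them by correlation, takes cluster medians as the consensus P and
# refits amplitudes by nonnegative least squares.

MU_EPS <- 1e-10

# per-gene scaling used before factorization (sd; constant rows get 1)
row_scaling_of <- function(X) {
  s <- apply(X, 1, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  s
}

# normalize each P row to max 1, moving the compensating scale into A;
# then order patterns by descending P-row variance (ties: first-sample
# weight, then index) for reproducible labeling
normalize_decomposition <- function(A, P) {
  m <- apply(P, 1, max)
  m[m == 0] <- 1
  P <- P / m
  A <- sweep(A, 2, m, "*")
  v <- apply(P, 1, stats::var)
  ord <- order(-v, -P[, 1], seq_len(nrow(P)))
  list(A = A[, ord, drop = FALSE], P = P[ord, , drop = FALSE])
}

new_pattern_decomposition <- function(A, P, objective_trace, restart_stability,
                                      row_scaling, converged, seed) {
  K <- ncol(A)
  dimnames(A) <- list(rownames(A), paste0("P", seq_len(K)))
  dimnames(P) <- list(paste0("P", seq_len(K)), colnames(P))
  structure(list(A = A, P = P, K = K, objective_trace = objective_trace,
                 restart_stability = restart_stability,
                 row_scaling = row_scaling, converged = converged, seed = seed),
            class = "pattern_decomposition")
}

#' @export
print.pattern_decomposition <- function(x, ...) {
  cat(sprintf("pattern_decomposition: %d genes x %d samples, K = %d\n",
              nrow(x$A), ncol(x$P), x$K))
  cat(sprintf("  final objective %.4g after %d iterations%s\n",
              utils::tail(x$objective_trace, 1), length(x$objective_trace),
              if (isTRUE(x$converged)) "" else " (not converged)"))
  if (!all(is.na(x$restart_stability))) {
    cat("  restart stability:", paste(sprintf("%.2f", x$restart_stability),
                                      collapse = " "), "\n")
  }
  invisible(x)
}

#' Single-run NMF by multiplicative updates
#'
#' Factorizes the row-scaled expression matrix as `X ~ A P` with `A, P >= 0`
#' under the Frobenius loss, using the standard multiplicative updates (a
#' small epsilon in the denominators guards division by zero). The objective
#' is non-increasing across iterations; the run stops when the relative
#' objective change drops below `tol` or `max_iter` is reached. Each gene
#' row is divided by its standard deviation before factorization (stored in
#' `row_scaling` and reused by projections) so high expressors do not
#' dominate the loss; reported amplitudes are mapped back to the original
#' scale, so `A %*% P` approximates the input values.
#'
#' @param study An [expression_study()] (or a plain nonnegative matrix).
#' @param K Rank, `1 <= K <= min(genes, samples)`.
#' @param seed Integer seed for the uniform random initialization.
#' @param max_iter Maximum multiplicative-update iterations.
#' @param tol Relative objective-change convergence threshold.
#' @return A `pattern_decomposition`: amplitudes `A` (genes x K, original
#'   scale), pattern weights `P` (K x samples, each row max-normalized to
#'   1), `objective_trace`, `row_scaling`, `converged`.
#' @export
nmf_factorize <- function(study, K, seed = 1, max_iter = 2000, tol = 1e-6) {
  X <- if (inherits(study, "expression_study")) study$values else as.matrix(study)
  if (anyNA(X) || any(!is.finite(X))) stop("NaN or non-finite values in input")
  if (any(X < 0)) stop("input must be nonnegative")
  if (K < 1 || K > min(dim(X))) {
    stop("K must lie in 1..min(genes, samples) = ", min(dim(X)))
  }
  G <- nrow(X); S <- ncol(X)
  sc <- row_scaling_of(X)
  Xs <- X / sc
  if (all(Xs == 0)) {
    A <- matrix(0, G, K, dimnames = list(rownames(X), NULL))
    P <- matrix(0, K, S, dimnames = list(NULL, colnames(X)))
    return(new_pattern_decomposition(A, P, objective_trace = 0,
                                     restart_stability = rep(NA_real_, K),
                                     row_scaling = sc, converged = TRUE,
                                     seed = seed))
  }
  init <- with_seed(seed, list(A = matrix(stats::runif(G * K, 0.1, 1), G, K),
                               P = matrix(stats::runif(K * S, 0.1, 1), K, S)))
  A <- init$A
  P <- init$P
  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    A <- A * (Xs %*% t(P)) / (A %*% (P %*% t(P)) + MU_EPS)
    P <- P * (t(A) %*% Xs) / ((t(A) %*% A) %*% P + MU_EPS)
    obj <- sum((Xs - A %*% P)^2)
    trace <- c(trace, obj)
    if (is.finite(prev) && (prev - obj) <= tol * max(prev, MU_EPS)) {
      converged <- TRUE
      break
    }
    prev <- obj
  }
  norm <- normalize_decomposition(A, P)
  A <- norm$A * sc
  dimnames(A) <- list(rownames(X), NULL)
  colnames(norm$P) <- colnames(X)
  new_pattern_decomposition(A, norm$P, objective_trace = trace,
                            restart_stability = rep(NA_real_, K),
                            row_scaling = stats::setNames(sc, rownames(X)),
                            converged = converged, seed = seed)
}

#' Consensus NMF across random restarts
#'
#' Runs [nmf_factorize()] from `n_restarts` distinct sub-seeds, pools every
#' restart's pattern-weight vectors, clusters them by correlation (average
#' linkage, merge threshold r >= 0.7), and reports the element-wise medians
#' of the `K` largest clusters as the consensus pattern weights. Amplitudes
#' are then refit against the consensus weights by exact nonnegative least
#' squares per gene. `restart_stability` is the fraction of restarts that
#' contributed at least one pattern to each consensus cluster.
#'
#' @inheritParams nmf_factorize
#' @param n_restarts Number of random restarts (>= 1; 1 reduces to a single
#'   [nmf_factorize()] run).
#' @param seed Master seed; restart sub-seeds are derived from it.
#' @return A `pattern_decomposition` with `restart_stability` populated.
#' @export
consensus_decompose <- function(study, K, n_restarts = 30, seed = 1,
                                max_iter = 2000, tol = 1e-6) {
  if (n_restarts < 1) stop("n_restarts must be >= 1")
  X <- if (inherits(study, "expression_study")) study$values else as.matrix(study)
  sub_seeds <- as.integer((as.numeric(seed) * 1009 + seq_len(n_restarts) * 9973) %%
                            2147483647)
  fits <- lapply(sub_seeds, function(s) {
    nmf_factorize(study, K, seed = s, max_iter = max_iter, tol = tol)
  })
  if (n_restarts == 1) {
    fit <- fits[[1]]
    fit$restart_stability <- rep(1, K)
    fit$seed <- seed
    return(fit)
  }
  pool <- do.call(rbind, lapply(fits, function(f) f$P))
  restart_id <- rep(seq_len(n_restarts), each = K)
  # correlation distance between pooled pattern-weight vectors
  cors <- suppressWarnings(stats::cor(t(pool)))
  cors[!is.finite(cors)] <- 0 # zero-variance patterns: maximally distant
  d <- stats::as.dist(1 - cors)
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, h = 0.3)
  sizes <- table(cl)
  if (length(sizes) < K) cl <- stats::cutree(hc, k = K)
  sizes <- sort(table(cl), decreasing = TRUE)
  keep <- as.integer(names(sizes)[seq_len(K)])
  P_cons <- t(vapply(keep, function(cid) {
    apply(pool[cl == cid, , drop = FALSE], 2, stats::median)
  }, numeric(ncol(pool))))
  stability <- vapply(keep, function(cid) {
    length(unique(restart_id[cl == cid])) / n_restarts
  }, numeric(1))
  sc <- fits[[1]]$row_scaling
  Xs <- X / sc
  # max-normalize consensus rows, refit amplitudes on the scaled matrix
  m <- apply(P_cons, 1, max)
  m[m == 0] <- 1
  P_cons <- P_cons / m
  A_s <- nnls_refit_amplitudes(Xs, P_cons)
  norm <- normalize_decomposition(A_s, P_cons)
  ordv <- apply(P_cons, 1, stats::var)
  stability <- stability[order(-ordv, -P_cons[, 1], seq_len(nrow(P_cons)))]
  A <- norm$A * sc
  colnames(norm$P) <- colnames(X)
  rownames(A) <- rownames(X)
  obj <- sum((Xs - (A / sc) %*% norm$P)^2)
  new_pattern_decomposition(A, norm$P, objective_trace = obj,
                            restart_stability = stability,
                            row_scaling = stats::setNames(sc, rownames(X)),
                            converged = all(vapply(fits, `[[`, logical(1), "converged")),
                            seed = seed)
}

#' Relative reconstruction error of a decomposition
#'
#' `||X - A P||_F / ||X||_F` on the original value scale.
#'
#' @param decomp A `pattern_decomposition`.
#' @param study The study (or matrix) it was fit to.
#' @return Scalar relative Frobenius error.
#' @export
reconstruction_error <- function(decomp, study) {
  X <- if (inherits(study, "expression_study")) study$values else as.matrix(study)
  sqrt(sum((X - decomp$A %*% decomp$P)^2)) / sqrt(sum(X^2))
}

#' Rank-selection diagnostics over a range of K
#'
#' Runs [consensus_decompose()] for each candidate rank and tabulates the
#' relative reconstruction error and the mean and minimum per-pattern
#' restart stability. The recommended rank is the largest K whose *minimum*
#' stability stays at or above `stability_threshold`: past the true rank,
#' restarts stop agreeing on at least one of the extra patterns, and the
#' weakest pattern's stability collapses well before the mean does.
#'
#' @inheritParams consensus_decompose
#' @param K_range Integer vector of candidate ranks.
#' @param stability_threshold Minimum per-pattern restart stability.
#' @return List with `table` (data frame: K, reconstruction_error,
#'   mean_stability, min_stability) and `recommended_K`.
#' @export
select_rank <- function(study, K_range, n_restarts = 10, seed = 1,
                        stability_threshold = 0.8, max_iter = 2000, tol = 1e-6) {
  if (!length(K_range)) stop("K_range must be nonempty")
  K_range <- sort(unique(as.integer(K_range)))
  rows <- lapply(K_range, function(K) {
    fit <- consensus_decompose(study, K, n_restarts = n_restarts, seed = seed,
                               max_iter = max_iter, tol = tol)
    data.frame(K = K,
               reconstruction_error = reconstruction_error(fit, study),
               mean_stability = mean(fit$restart_stability),
               min_stability = min(fit$restart_stability))
  })
  tab <- do.call(rbind, rows)
  ok <- tab$K[tab$min_stability >= stability_threshold]
  recommended <- if (length(ok)) max(ok) else tab$K[which.max(tab$min_stability)]
  list(table = tab, recommended_K = recommended)
}

#' Match estimated patterns to reference patterns
#'
#' Finds the one-to-one assignment between the columns of two amplitude
#' matrices that maximizes total cosine similarity (exact search with
#' branch-and-bound; columns must agree in number and gene order).
#'
#' @param A_ref,A_est Amplitude matrices (genes x K).
#' @return List with `assignment` (index into `A_est` columns for each
#'   reference column), `cosines` (matched cosine per reference column) and
#'   `mean_cosine`.
#' @export
match_patterns <- function(A_ref, A_est) {
  stopifnot(nrow(A_ref) == nrow(A_est), ncol(A_ref) == ncol(A_est))
  K <- ncol(A_ref)
  nr <- sqrt(colSums(A_ref^2)); nr[nr == 0] <- 1
  ne <- sqrt(colSums(A_est^2)); ne[ne == 0] <- 1
  C <- crossprod(A_ref, A_est) / outer(nr, ne) # K x K cosine matrix
  best <- list(score = -Inf, perm = integer(K))
  ub_tail <- rev(cumsum(rev(apply(C, 1, max)))) # upper bound for remaining rows
  assign_rec <- function(i, used, acc, perm) {
    if (i > K) {
      if (acc > best$score) best <<- list(score = acc, perm = perm)
      return()
    }
    if (acc + ub_tail[i] <= best$score) return()
    ord <- order(C[i, ], decreasing = TRUE)
    for (j in ord) {
      if (!used[j]) {
        used[j] <- TRUE
        perm[i] <- j
        assign_rec(i + 1L, used, acc + C[i, j], perm)
        used[j] <- FALSE
      }
    }
  }
  assign_rec(1L, rep(FALSE, K), 0, integer(K))
  list(assignment = best$perm,
       cosines = C[cbind(seq_len(K), best$perm)],
       mean_cosine = best$score / K)
}
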