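# Shared fixture builders: everything is generated in code at test time.

# wrap planted factors as a pattern_decomposition (unit row scaling unless a
# study is supplied, in which case the study's per-gene sd is stored so
# projections behave exactly as they would after a fit on that study)
truth_decomp <- function(truth, study = NULL) {
  sc <- if (is.null(study)) rep(1, nrow(truth$A_true)) else
    apply(study$values, 1, stats::sd)
  sc[sc == 0] <- 1
  K <- ncol(truth$A_true)
  structure(list(A = truth$A_true, P = truth$P_true, K = K,
                 objective_trace = 0, restart_stability = rep(1, K),
                 row_scaling = stats::setNames(sc, rownames(truth$A_true)),
                 converged = TRUE, seed = 1L),
            class = "pattern_decomposition")
}

# wrap arbitrary A (genes x K) and P (K x samples) matrices
make_decomp <- function(A, P) {
  if (is.null(rownames(A))) rownames(A) <- paste0("g", seq_len(nrow(A)))
  if (is.null(colnames(P))) colnames(P) <- paste0("s", seq_len(ncol(P)))
  colnames(A) <- rownames(P) <- paste0("P", seq_len(ncol(A)))
  structure(list(A = A, P = P, K = ncol(A), objective_trace = 0,
                 restart_stability = rep(1, ncol(A)),
                 row_scaling = stats::setNames(rep(1, nrow(A)), rownames(A)),
                 converged = TRUE, seed = 1L),
            class = "pattern_decomposition")
}

# minimal expression study around a value matrix; metadata filled from a
# single-line single-condition design unless given
toy_study <- function(values, meta = NULL, scale = "rpkm") {
  if (is.null(rownames(values))) rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("s", seq_len(ncol(values)))
  if (is.null(meta)) {
    meta <- data.frame(sample_id = colnames(values), line_id = "L1",
                       donor_id = "D1", condition = "SR",
                       day = seq_len(ncol(values)), replicate = "r1")
  }
  expression_study(values, meta, scale = scale)
}

# small, fast study configuration used by module-level tests
small_sim_config <- function(...) {
  sim_config(n_genes = 400,
             lines = c(L1 = "D1", L2 = "D1", L3 = "D2", L4 = "D3"),
             k_dynamic = 3, k_line = 2, discordant_line = NULL,
             set_sizes = c(ra_like = 40, krab_like = 30),
             n_population_donors = 8, ...)
}

# brute-force NNLS oracle: enumerate every active set, solve the equality-
# constrained least squares, keep the feasible KKT point with lowest loss
nnls_bruteforce <- function(A, b) {
  K <- ncol(A)
  best <- NULL
  best_loss <- Inf
  for (mask in 0:(2^K - 1)) {
    on <- which(bitwAnd(mask, 2^(seq_len(K) - 1)) > 0)
    x <- numeric(K)
    if (length(on)) {
      sol <- tryCatch(qr.solve(A[, on, drop = FALSE], b), error = function(e) NULL)
      if (is.null(sol) || any(!is.finite(sol))) next
      x[on] <- sol
    }
    if (any(x < -1e-9)) next
    loss <- sum((b - A %*% x)^2)
    if (loss < best_loss - 1e-12) {
      best <- pmax(x, 0)
      best_loss <- loss
    }
  }
  best
}
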