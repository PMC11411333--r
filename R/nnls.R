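# Nonnegative least squares by the Lawson-Hanson active-set method, run in
# normal-equation form: all solves share the K x K cross-product, so
# projecting many samples (or permutations) against one amplitude matrix
# costs one small solve per active-set change. Exact solution, finite
# termination.

#' Solve min ||b - A x||^2 subject to x >= 0 from normal equations
#'
#' @param AtA Crossproduct `t(A) %*% A` (K x K, symmetric PSD).
#' @param Atb Vector `t(A) %*% b`.
#' @param tol Dual-feasibility tolerance, scaled internally by the problem
#'   magnitude.
#' @return Nonnegative solution vector of length K satisfying the KKT
#'   conditions (gradient approximately 0 on the support, >= 0 off it).
#' @export
nnls_solve <- function(AtA, Atb, tol = 1e-10) {
  n <- length(Atb)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  scale <- max(abs(Atb), diag(AtA), 1)
  tol <- tol * scale
  w <- Atb # negative gradient at x = 0
  outer_max <- 10L * n + 10L
  it <- 0L
  while (it < outer_max) {
    it <- it + 1L
    cand <- which(!passive & w > tol)
    if (!length(cand)) break
    j <- cand[which.max(w[cand])]
    passive[j] <- TRUE
    repeat {
      p <- which(passive)
      s <- numeric(n)
      App <- AtA[p, p, drop = FALSE]
      # tiny ridge guards rank-deficient active sets
      s[p] <- as.numeric(solve(App + diag(1e-12 * scale, length(p)), Atb[p]))
      if (all(s[p] > 0)) {
        x <- s
        break
      }
      neg <- passive & s <= 0
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol / scale] <- FALSE
      x[!passive] <- 0
    }
    w <- Atb - as.numeric(AtA %*% x)
  }
  x[x < 0] <- 0
  x
}

#' KKT residuals of a nonnegative least-squares solution
#'
#' For `min ||b - A x||^2, x >= 0` the optimum satisfies: `x >= 0`;
#' gradient `g = AtA x - Atb >= 0` wherever `x = 0`; and `g ~ 0` wherever
#' `x > 0`.
#'
#' @param AtA,Atb Normal-equation inputs as in [nnls_solve()].
#' @param x Candidate solution.
#' @return List with `max_primal` (most negative entry of `x`),
#'   `max_dual` (most negative gradient on the zero set) and
#'   `max_complementarity` (largest `|g|` on the support), all on the scale
#'   of the inputs.
#' @export
nnls_kkt <- function(AtA, Atb, x) {
  g <- as.numeric(AtA %*% x) - Atb
  on <- x > 0
  list(max_primal = max(0, -min(x)),
       max_dual = if (any(!on)) max(0, -min(g[!on])) else 0,
       max_complementarity = if (any(on)) max(abs(g[on])) else 0)
}

# Row-wise NNLS refit of amplitudes against fixed pattern weights:
# A[g, ] = argmin_a>=0 || X[g, ] - a' P ||^2 for every gene g.
nnls_refit_amplitudes <- function(X, P) {
  DtD <- P %*% t(P)
  B <- P %*% t(X) # K x G
  A <- matrix(0, nrow(X), nrow(P))
  for (g in seq_len(nrow(X))) A[g, ] <- nnls_solve(DtD, B[, g])
  dimnames(A) <- list(rownames(X), rownames(P))
  A
}
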