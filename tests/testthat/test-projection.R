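test_that("a basis-vector sample recovers a single pattern weight", {
  set.seed(61)
  A <- matrix(rexp(200 * 3, 0.5), 200, 3)
  P <- matrix(runif(3 * 6), 3, 6, dimnames = list(NULL, paste0("s", 1:6)))
  dec <- make_decomp(A, P)
  for (j in 1:3) {
    x <- matrix(A[, j], dimnames = list(rownames(dec$A), list("new")))
    w <- project_nnls(dec, x)$weights[, 1]
    expect_gt(w[j], 0)
    expect_true(all(w[-j] < 1e-8 * w[j]))
  }
})

test_that("self-projection of a noiseless simulation recovers planted weights", {
  cfg <- small_sim_config(noise = list(family = "lognormal", sigma = 0),
                          baseline = 0, seed = 63)
  sim <- simulate_study(cfg)
  dec <- truth_decomp(sim$truth, sim$study)
  pr <- project_nnls(dec, sim$study)
  expect_true(all(pr$weights >= 0))
  expect_true(all(pr$residual_fraction >= 0 & pr$residual_fraction <= 1))
  rr <- vapply(seq_len(ncol(pr$weights)), function(j) {
    cor(pr$weights[, j], sim$truth$P_true[, j])
  }, numeric(1))
  expect_true(all(rr >= 0.99))
})

test_that("tiny-instance NNLS matches the brute-force KKT oracle and pracma", {
  skip_if_not_installed("pracma")
  set.seed(67)
  for (rep in 1:25) {
    G <- 5; K <- 2
    A <- matrix(rexp(G * K), G, K)
    b <- if (rep %% 2 == 0) rexp(G) else as.numeric(A %*% c(2, 0)) + rnorm(G, 0, 0.3)
    x_pkg <- nnls_solve(crossprod(A), crossprod(A, b))
    x_oracle <- nnls_bruteforce(A, b)
    x_pracma <- pracma::lsqnonneg(A, b)$x
    expect_lt(max(abs(x_pkg - x_oracle)), 1e-6)
    expect_lt(max(abs(x_pkg - x_pracma)), 1e-6)
  }
})

test_that("every NNLS projection satisfies the KKT conditions", {
  set.seed(71)
  sim <- simulate_study(small_sim_config(seed = 5))
  dec <- truth_decomp(sim$truth, sim$study)
  prep_A <- dec$A / dec$row_scaling
  pr <- project_nnls(dec, sim$study)
  AtA <- crossprod(prep_A)
  scale <- max(diag(AtA))
  for (j in seq_len(ncol(pr$weights))) {
    x <- sim$study$values[, j] / dec$row_scaling
    kkt <- nnls_kkt(AtA, crossprod(prep_A, x)[, 1], pr$weights[, j])
    expect_lt(kkt$max_dual / scale, 1e-8)
    expect_lt(kkt$max_complementarity / scale, 1e-8)
  }
})

test_that("projection is equivariant to consistent gene reordering", {
  set.seed(73)
  sim <- simulate_study(small_sim_config(seed = 6))
  dec <- truth_decomp(sim$truth, sim$study)
  pr1 <- project_nnls(dec, sim$study)
  ord <- sample(nrow(sim$study$values))
  shuffled <- expression_study(sim$study$values[ord, ], sim$study$samples,
                               sim$study$scale)
  pr2 <- project_nnls(dec, shuffled)
  expect_equal(pr1$weights, pr2$weights, tolerance = 1e-10)
})

test_that("projection contracts are enforced", {
  set.seed(79)
  A <- matrix(rexp(300), 100, 3)
  dec <- make_decomp(A, matrix(runif(9), 3, dimnames = list(NULL, paste0("s", 1:3))))
  few <- matrix(rexp(10 * 2), 10, 2,
                dimnames = list(rownames(dec$A)[1:10], c("a", "b")))
  expect_error(project_nnls(dec, few), "below the required minimum")
  expect_silent(project_nnls(dec, few, min_genes = 5))
  zero <- matrix(0, 100, 1, dimnames = list(rownames(dec$A), "z"))
  expect_error(project_nnls(dec, zero), "all-zero sample")
})

test_that("permutation p respects its floor and flags planted signatures", {
  sim <- simulate_study(small_sim_config(seed = 83))
  dec <- truth_decomp(sim$truth, sim$study)
  ext <- simulate_external_dataset(sim$truth, "tissue-like", 24, seed = 2)
  kd <- which(sim$truth$module_class == "donor")[1]
  focal <- ext$samples$donor_id == sim$truth$module_owner[kd]
  pt <- projection_permutation_test(dec, ext, focal, kd, n_perm = 199, seed = 3)
  expect_gte(pt$p_value, 1 / 200)
  expect_lt(pt$p_value, 0.01)
  # the label-permutation scheme agrees on a strong planted signal
  pl <- projection_permutation_test(dec, ext, focal, kd, n_perm = 199, seed = 3,
                                    scheme = "labels")
  expect_lt(pl$p_value, 0.05)

  expect_error(projection_permutation_test(dec, ext, rep(FALSE, 24), kd),
               "empty focal")
  expect_error(projection_permutation_test(dec, ext, rep(TRUE, 24), kd),
               "empty background")
  expect_warning(projection_permutation_test(dec, ext, focal, kd, n_perm = 50,
                                             seed = 1), "n_perm < 100")
})

test_that("PCA explains a single varying gene and projects self consistently", {
  set.seed(89)
  X <- matrix(5, 60, 8, dimnames = list(paste0("g", 1:60), paste0("s", 1:8)))
  X[1, ] <- 5 + seq(0, 7)
  fit <- pca_fit(X, 2)
  expect_gt(fit$model$explained_variance_fraction[1], 0.999)

  Y <- matrix(rexp(60 * 8), 60, 8, dimnames = dimnames(X))
  f2 <- pca_fit(Y, 3)
  self <- pca_project(f2$model, Y, min_genes = 10)
  expect_lt(max(abs(self$scores - f2$scores)), 1e-10)
  expect_equal(self$fraction_of_model_genes, 1)
  # loadings orthonormal, explained fractions non-increasing in [0, 1]
  expect_equal(crossprod(f2$model$loadings), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  ev <- f2$model$explained_variance_fraction
  expect_true(all(diff(ev) <= 0) && all(ev >= 0 & ev <= 1))
  expect_error(pca_fit(Y, 9), "n_components")
})

test_that("pca_project is linear: constant offsets shift scores by L^T offset", {
  set.seed(97)
  Y <- matrix(rexp(80 * 6), 80, 6, dimnames = list(paste0("g", 1:80), paste0("s", 1:6)))
  fit <- pca_fit(Y, 2)
  offset <- rnorm(80)
  shifted <- Y + offset
  s2 <- pca_project(fit$model, shifted, min_genes = 10)$scores
  expected <- fit$scores + as.numeric(crossprod(fit$model$loadings, offset))
  expect_equal(s2, expected, tolerance = 1e-10)
})

test_that("planted 2-factor subspace is found and cross-condition ranking survives", {
  set.seed(101)
  # two planted orthogonal-ish factors + small noise
  G <- 300; S <- 24
  L1 <- rexp(G); L2 <- rexp(G)
  t1 <- rnorm(S); t2 <- rnorm(S)
  X <- outer(L1, t1) + outer(L2, t2) + matrix(rnorm(G * S, 0, 0.05), G, S)
  X <- X - min(X)
  dimnames(X) <- list(paste0("g", 1:G), paste0("s", 1:S))
  fit <- pca_fit(X, 2)
  # principal angle between estimated and planted 2-D subspaces < 5 degrees
  Qp <- qr.Q(qr(cbind(L1, L2)))
  sv <- svd(crossprod(fit$model$loadings, Qp))$d
  angle <- acos(min(sv)) * 180 / pi
  expect_lt(angle, 5)

  # line ranking transfers between conditions in a simulated panel
  sim <- simulate_study(sim_config(seed = 103))
  meta <- sim$study$samples
  nsb <- meta$condition == "NSB"
  sr <- meta$condition == "SR"
  s_nsb <- expression_study(sim$study$values[, nsb], meta[nsb, ], sim$study$scale)
  s_sr <- expression_study(sim$study$values[, sr], meta[sr, ], sim$study$scale)
  fit_nsb <- pca_fit(s_nsb, 3)
  # which PC tracks the planted donor-D1 module? pick by correlation in-fit
  d1 <- sim$truth$P_true[which(sim$truth$module_class == "donor")[1], nsb]
  pc <- which.max(abs(cor(t(fit_nsb$scores), d1)))
  proj <- pca_project(fit_nsb$model, s_sr)$scores[pc, ]
  rank_sr <- rank(tapply(proj, meta$line_id[sr], mean))
  in_fit <- fit_nsb$scores[pc, ]
  rank_nsb <- rank(tapply(in_fit, meta$line_id[nsb], mean))
  expect_gte(cor(rank_sr, rank_nsb, method = "spearman"), 0.8)
})
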