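make_design_meta <- function(lines = c(L1 = "D1", L2 = "D1", L3 = "D2", L4 = "D3"),
                             conditions = c("SR", "NSB", "BMP4"),
                             days = c(2, 4, 6)) {
  meta <- expand.grid(day = days, condition = conditions, line_id = names(lines),
                      stringsAsFactors = FALSE)
  meta$donor_id <- unname(lines[meta$line_id])
  meta$replicate <- "r1"
  meta$sample_id <- sprintf("%s_%s_d%d", meta$line_id, meta$condition, meta$day)
  meta[, c("sample_id", "line_id", "donor_id", "condition", "day", "replicate")]
}

test_that("planted line, donor, and dynamic weight rows are labeled correctly", {
  set.seed(31)
  meta <- make_design_meta()
  n <- nrow(meta)
  # line module private to L3; donor module on D1 (lines L1+L2); day trend
  w_line <- ifelse(meta$line_id == "L3", 1, 0) + rnorm(n, 0, 0.05)
  w_donor <- ifelse(meta$donor_id == "D1", 1, 0) + rnorm(n, 0, 0.05)
  w_dyn <- (meta$day / 6) + rnorm(n, 0, 0.05)
  P <- rbind(pmax(w_line, 0), pmax(w_donor, 0), pmax(w_dyn, 0))
  colnames(P) <- meta$sample_id
  dec <- make_decomp(matrix(1, 20, 3), P)
  cls <- classify_patterns(dec, meta)
  expect_equal(cls$label, c("line-specific", "donor-specific", "dynamic"))
  expect_equal(cls$owner, c("L3", "D1", NA))
  expect_true(cls$eta2_day[3] > cls$eta2_line[3])
})

test_that("constant weights give p ~ 1 and an unresolved label", {
  meta <- make_design_meta()
  P <- matrix(0.7, 2, nrow(meta), dimnames = list(NULL, meta$sample_id))
  dec <- make_decomp(matrix(1, 5, 2), P)
  cls <- classify_patterns(dec, meta)
  expect_equal(cls$label, rep("unresolved", 2))
  expect_true(all(cls$p_line == 1))
})

test_that("single-level factors are dropped with a warning", {
  meta <- make_design_meta(conditions = "SR")
  set.seed(1)
  P <- matrix(runif(nrow(meta)), 1, dimnames = list(NULL, meta$sample_id))
  dec <- make_decomp(matrix(1, 5, 1), P)
  expect_warning(classify_patterns(dec, meta), "single-level")
})

test_that("ANOVA p-values agree with a brute-force permutation F-null", {
  set.seed(41)
  meta <- make_design_meta(lines = c(L1 = "D1", L2 = "D2"),
                           conditions = c("SR", "NSB"), days = c(2, 4))
  n <- nrow(meta) # 8 samples
  w <- 0.25 * (meta$line_id == "L2") + rnorm(n, 0, 0.3)
  P <- matrix(pmax(w, 0), 1, dimnames = list(NULL, meta$sample_id))
  dec <- make_decomp(matrix(1, 5, 1), P)
  cls <- classify_patterns(dec, meta)

  # oracle: permutation distribution of the line F statistic
  f_line <- function(y) {
    full <- lm(y ~ line + day + condition,
               data = data.frame(line = meta$line_id, day = factor(meta$day),
                                 condition = meta$condition))
    drop <- update(full, . ~ . - line)
    an <- anova(drop, full)
    an$F[2]
  }
  y <- P[1, ]
  f_obs <- f_line(y)
  n_perm <- 2000
  f_null <- vapply(seq_len(n_perm), function(i) f_line(sample(y)), numeric(1))
  p_perm <- (1 + sum(f_null >= f_obs)) / (n_perm + 1)
  mc_sd <- sqrt(p_perm * (1 - p_perm) / n_perm)
  expect_lt(abs(cls$p_line - p_perm), 4 * mc_sd + 0.02)
})

test_that("pattern clustering orders merges by correlation distance", {
  s <- seq(0, 1, length.out = 12)
  P <- rbind(s, -s + 1, c(rep(0, 6), rep(1, 6)))
  P <- P + matrix(runif(36, 0, 1e-4), 3) # break exact ties deterministically
  colnames(P) <- paste0("s", 1:12)
  dec <- make_decomp(matrix(1, 5, 3), P)
  hc <- cluster_patterns(dec)
  # hand-computed distances: d(1,2) = 1 - (-1) = 2, the largest; the
  # anticorrelated pair therefore merges last, and the final average-linkage
  # height is mean(d(2,1), d(2,3))
  D <- as.matrix(1 - cor(t(P)))
  expect_equal(D[1, 2], 2, tolerance = 0.01)
  expect_equal(max(hc$height), mean(c(D[2, 1], D[2, 3])), tolerance = 1e-8)
  first <- hc$merge[1, ]
  expect_false(all(sort(-first) == c(1, 2)))

  # duplicated rows merge first at height 0
  P2 <- rbind(s, s, c(rep(0, 6), rep(1, 6)))
  colnames(P2) <- paste0("s", 1:12)
  dec2 <- make_decomp(matrix(1, 5, 3), P2)
  hc2 <- cluster_patterns(dec2)
  expect_equal(sort(-hc2$merge[1, ]), c(1, 2))
  expect_equal(hc2$height[1], 0, tolerance = 1e-12)

  # K = 2 gives a single merge
  dec3 <- make_decomp(matrix(1, 5, 2), P[1:2, ])
  expect_equal(nrow(cluster_patterns(dec3)$merge), 1L)

  # zero-variance row warns
  P4 <- rbind(s, rep(0.5, 12)); colnames(P4) <- paste0("s", 1:12)
  expect_warning(cluster_patterns(make_decomp(matrix(1, 5, 2), P4)),
                 "zero-variance")
})

test_that("MDS reproduces pairwise distances and collapses identical columns", {
  set.seed(51)
  A <- matrix(rexp(60), 20, 3)
  dec <- make_decomp(A, matrix(runif(12), 3, dimnames = list(NULL, paste0("s", 1:4))))
  md <- mds_amplitudes(dec, dims = 2)
  # three points always embed exactly in 2-D
  din <- as.matrix(1 - cor(A))
  dout <- as.matrix(dist(md$coords))
  expect_equal(unname(dout), unname(din), tolerance = 1e-8)
  expect_equal(colMeans(md$coords), c(dim1 = 0, dim2 = 0), tolerance = 1e-10)

  # identical amplitude columns land on identical coordinates
  A2 <- cbind(A[, 1], A[, 1], A[, 2], A[, 3])
  dec2 <- make_decomp(A2, matrix(runif(16), 4, dimnames = list(NULL, paste0("s", 1:4))))
  md2 <- mds_amplitudes(dec2, dims = 2)
  expect_equal(md2$coords[1, ], md2$coords[2, ], tolerance = 1e-8)

  expect_error(mds_amplitudes(dec, dims = 3), "K >= dims")
})

test_that("first MDS dimension separates dynamic from line-specific patterns", {
  sim <- simulate_study(sim_config(seed = 23))
  dec <- truth_decomp(sim$truth)
  md <- mds_amplitudes(dec, dims = 2)
  lab <- sim$truth$module_class == "dynamic"
  # silhouette > 0 on dimension 1: within-class spread below between-class gap
  x <- md$coords[, 1]
  sil <- vapply(seq_along(x), function(i) {
    a <- mean(abs(x[i] - x[lab == lab[i]][-which(which(lab == lab[i]) == i)]))
    b <- mean(abs(x[i] - x[lab != lab[i]]))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
})

test_that("gene-weight correlations find self and planted signals, reject nulls", {
  sim <- simulate_study(small_sim_config(seed = 29))
  dec <- truth_decomp(sim$truth)
  genes <- rownames(dec$A)

  # self-correlation
  cw <- correlate_weights_with_scores(dec, setNames(dec$A[, 2], genes))
  expect_equal(cw$r[2], 1, tolerance = 1e-12)

  # independent scores stay inside the 3/sqrt(G) null band
  set.seed(1)
  null_scores <- setNames(rnorm(length(genes)), genes)
  cw0 <- correlate_weights_with_scores(dec, null_scores)
  expect_true(all(abs(cw0$r) < 3 / sqrt(length(genes))))

  # planted: amplitudes of one module plus noise peak at that module
  sc <- setNames(dec$A[, 4] + rnorm(length(genes), 0, 0.5), genes)
  cw1 <- correlate_weights_with_scores(dec, sc)
  expect_equal(which.max(cw1$r), 4L)

  expect_error(correlate_weights_with_scores(dec, setNames(rep(1, 400), genes)),
               "constant score")
  expect_error(correlate_weights_with_scores(dec, null_scores[1:5]), "fewer than")
})
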