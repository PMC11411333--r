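test_that("extreme and uniform rankings give AUC 1 and ~0.5", {
  set.seed(111)
  A <- matrix(rexp(400), 100, 4, dimnames = list(paste0("g", 1:100), NULL))
  dec <- make_decomp(A, matrix(runif(16), 4, dimnames = list(NULL, paste0("s", 1:4))))
  top <- rownames(A)[order(-A[, 2])][1:10]
  er <- rank_enrichment(dec, top, 2)
  expect_equal(er$auc, 1)
  expect_lt(er$p_adjusted, 1e-6)

  # uniform amplitudes: AUC exactly 0.5 by midranks
  Au <- matrix(1, 100, 2, dimnames = list(paste0("g", 1:100), NULL))
  du <- make_decomp(Au, matrix(runif(8), 2, dimnames = list(NULL, paste0("s", 1:4))))
  pu <- enrichment_profile(du, paste0("g", 1:15))
  expect_equal(pu$auc, rep(0.5, 2))

  expect_error(rank_enrichment(dec, c("g1", "zz"), 1), "set genes present")
})

test_that("AUC equals brute-force pair counting with midranks for ties", {
  set.seed(113)
  for (rep in 1:5) {
    G <- 150
    a <- sample(c(rexp(G - 40), rep(c(0, 1.5), 20))) # ties included
    genes <- paste0("g", 1:G)
    A <- matrix(a, G, 1, dimnames = list(genes, NULL))
    dec <- make_decomp(A, matrix(runif(4), 1, dimnames = list(NULL, paste0("s", 1:4))))
    set_genes <- sample(genes, 25)
    er <- rank_enrichment(dec, set_genes, 1)
    in_set <- genes %in% set_genes
    wins <- 0
    for (i in which(in_set)) {
      wins <- wins + sum(a[i] > a[!in_set]) + 0.5 * sum(a[i] == a[!in_set])
    }
    expect_equal(er$auc, wins / (sum(in_set) * sum(!in_set)))
  }
})

test_that("null sets give centered AUCs and uniform p-values", {
  set.seed(127)
  G <- 300
  A <- matrix(rexp(G), G, 1, dimnames = list(paste0("g", 1:G), NULL))
  dec <- make_decomp(A, matrix(runif(4), 1, dimnames = list(NULL, paste0("s", 1:4))))
  draws <- replicate(200, {
    er <- rank_enrichment(dec, sample(rownames(A), 30), 1)
    c(er$auc, er$p)
  })
  expect_lt(abs(mean(draws[1, ]) - 0.5), 0.02)
  expect_gt(suppressWarnings(ks.test(draws[2, ], "punif"))$p.value, 0.001)
})

test_that("enrichment statistics are invariant to column rescaling and gene order", {
  set.seed(131)
  sim <- simulate_study(small_sim_config(seed = 7))
  dec <- truth_decomp(sim$truth)
  ra <- sim$truth$set_membership$ra_like
  base <- enrichment_profile(dec, ra)

  dec2 <- dec
  dec2$A <- sweep(dec$A, 2, c(3, 0.2, 7, 1, 0.5), "*")
  expect_equal(enrichment_profile(dec2, ra)$auc, base$auc)

  ord <- sample(nrow(dec$A))
  dec3 <- dec
  dec3$A <- dec$A[ord, ]
  dec3$row_scaling <- dec$row_scaling[ord]
  prof3 <- enrichment_profile(dec3, ra)
  expect_equal(prof3$auc, base$auc)
  expect_equal(prof3$p, base$p)
})

test_that("planted sets light up exactly their target modules", {
  # RA-like set targeted at exactly 2 of 5 modules via an explicit map
  hits <- matrix(0L, 10, 5)
  for (s in 1:10) {
    cfg <- small_sim_config(seed = 300 + s,
                            set_target_modules = list(ra_like = c(`4` = 1, `5` = 1)))
    sim <- simulate_study(cfg)
    prof <- enrichment_profile(truth_decomp(sim$truth),
                               sim$truth$set_membership$ra_like)
    idx <- as.integer(sub("M", "", prof$pattern))
    hits[s, idx] <- as.integer(prof$p_adjusted < 0.05)
  }
  rate <- colMeans(hits)
  expect_true(all(rate[4:5] >= 0.9))
  expect_true(all(rate[1:3] <= 0.1))
})

test_that("hypergeometric overlap matches the exact combinatorial oracle", {
  universe <- paste0("g", 1:100)
  set10 <- universe[1:10]
  top20 <- universe[c(1:8, 30:41)] # overlap 8
  oe <- overlap_enrichment(top20, set10, universe)
  expect_equal(oe$overlap, 8)
  # oracle: tail sum of the hypergeometric pmf via choose()
  p_oracle <- sum(vapply(8:10, function(k) {
    choose(10, k) * choose(90, 20 - k) / choose(100, 20)
  }, numeric(1)))
  expect_equal(oe$p, p_oracle, tolerance = 1e-12)

  disjoint <- overlap_enrichment(universe[50:60], universe[1:10], universe)
  expect_equal(disjoint$fold, 0)
  expect_equal(disjoint$p, 1)

  same <- overlap_enrichment(set10, set10, universe)
  expect_equal(same$fold, 10)
  expect_equal(same$p, choose(90, 0) * choose(10, 10) / choose(100, 10),
               tolerance = 1e-12)

  expect_error(overlap_enrichment(character(0), set10, universe), "empty top")
  expect_error(overlap_enrichment(c("nope"), set10, universe), "subset")
})

test_that("era contributions have planted directions; unlabeled eras are null", {
  sim <- simulate_study(sim_config(seed = 137))
  dec <- truth_decomp(sim$truth)
  ec <- era_contribution(dec, sim$truth$era, class_labels = sim$truth$module_class)
  dyn <- ec$tests$label == "dynamic"
  expect_true(all(ec$tests$direction[dyn] == 1))
  expect_true(all(ec$tests$direction[!dyn] == -1))
  expect_true(all(ec$tests$p < 0.01))

  # era labels shuffled independently of amplitudes: p roughly uniform
  set.seed(2)
  ps <- replicate(60, {
    shuffled <- setNames(sample(sim$truth$era), names(sim$truth$era))
    era_contribution(dec, shuffled)$tests$p[1]
  })
  expect_gt(mean(ps > 0.05), 0.8)

  # all-equal amplitudes: difference 0, p = 1
  Au <- matrix(1, 2000, 2, dimnames = list(names(sim$truth$era), NULL))
  du <- make_decomp(Au, matrix(runif(8), 2, dimnames = list(NULL, paste0("s", 1:4))))
  ecu <- era_contribution(du, sim$truth$era)
  expect_true(all(ecu$tests$direction == 0))
  expect_true(all(ecu$tests$p == 1))

  few <- setNames(rep(c(1L, 5L), c(3, 3)), rownames(dec$A)[1:6])
  expect_error(era_contribution(dec, few), ">= 5 genes")
})

test_that("top-fraction arithmetic and pHaplo means are exact", {
  genes <- paste0("g", sprintf("%04d", 1:1000))
  set.seed(139)
  A <- matrix(rexp(2000), 1000, 2, dimnames = list(genes, NULL))
  dec <- make_decomp(A, matrix(runif(8), 2, dimnames = list(NULL, paste0("s", 1:4))))
  ph <- setNames(rep(0.5, 1000), genes)
  ds <- dosage_sensitivity_summary(dec, ph, top_frac = 0.01)
  expect_equal(ds$n_top, rep(10L, 2), ignore_attr = TRUE)
  expect_equal(ds$mean_phaplo, rep(0.5, 2))

  # missing scores are excluded and counted
  ph2 <- ph[-match(rownames(A)[order(-A[, 1])][1:3], names(ph))]
  ds2 <- dosage_sensitivity_summary(dec, ph2, top_frac = 0.01)
  expect_equal(ds2$n_missing[1], 3)
  expect_equal(ds2$n_scored[1], 7)
  expect_error(dosage_sensitivity_summary(dec, ph[1:100]), "fewer than half")
})
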