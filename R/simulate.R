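#' Simulation configuration for a stem-cell differentiation panel
#'
#' Describes a synthetic multi-line differentiation study: a panel of PSC
#' lines (some sharing a donor), profiled across culture conditions
#' (self-renewal `SR`, neural induction `NSB`, mesendoderm induction `BMP4`)
#' and days, whose expression is generated from planted nonnegative latent
#' modules. Dynamic modules follow parametric day/condition trajectories
#' shared by all lines; line/donor modules are constant over day and
#' condition within the owning line(s) and absent elsewhere. One line may be
#' "discordant": it carries a private module its donor's other line lacks,
#' emulating an epigenetically driven signature that is absent from the
#' donor's other cells and tissue.
#'
#' @param n_genes Number of genes.
#' @param lines Named character vector mapping line id to donor id.
#' @param n_replicates Replicates per line x condition x day cell.
#' @param conditions Subset of `c("SR", "NSB", "BMP4")`.
#' @param days Ordered positive integers.
#' @param k_dynamic Number of dynamic trajectory modules (shapes cycle over
#'   a decaying, early-sigmoid, late-sigmoid and rising curve library).
#' @param k_line Number of stable line/donor modules (the private module of
#'   `discordant_line`, when set, occupies the last of these slots).
#' @param discordant_line Line id receiving a private module, or `NULL`.
#' @param amplitude_sparsity Fraction of genes with zero loading per module.
#' @param set_sizes Named sizes of the planted gene sets (`ra_like`,
#'   `krab_like`).
#' @param set_target_modules Named list mapping each planted set to a named
#'   numeric vector `module index -> loading strength`. `NULL` derives the
#'   default: the RA-like set loads into every line/donor module with graded
#'   strength (private module strongest); the KRAB-like set loads uniformly
#'   into every line/donor module.
#' @param era_probs 3 x 5 matrix of evolutionary-era assignment
#'   probabilities, rows `dynamic`, `line`, `none` (gene's dominant module
#'   class), columns eras 1 (ancient) .. 5 (primate-specific). `NULL` uses a
#'   default where dynamic-dominated genes skew ancient and line-dominated
#'   genes skew recent.
#' @param noise List with `family` (`"lognormal"` or `"negative-binomial"`),
#'   `sigma` (log-scale sd for lognormal) and `dispersion` (NB dispersion,
#'   `size = 1/dispersion`).
#' @param baseline Mean expression floor added to every gene before noise;
#'   the expected level of genes loading on no module.
#' @param amplitude_shift Multiplier converting a planted set's strength
#'   into the additive amplitude boost of its genes in the target module.
#' @param phenotype_link List with `slope`, `intercept`, `sigma` linking the
#'   planted per-line RA-activity score to the per-line phenotype (e.g. the
#'   proportion of hindbrain-marker-high cells after retinoic acid).
#' @param n_population_donors Extra unrelated donors added to the kinship
#'   panel (used by tissue-like external datasets).
#' @param kinship_mean,kinship_sd Mean and sd of simulated off-diagonal
#'   relatedness between distinct donors.
#' @param seed Integer seed; the whole simulation is a deterministic
#'   function of the configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       lines = c(L1 = "D1", L2 = "D1", L3 = "D2",
                                 L4 = "D2", L5 = "D3", L6 = "D4"),
                       n_replicates = 1,
                       conditions = c("SR", "NSB", "BMP4"),
                       days = c(2, 4, 6),
                       k_dynamic = 5,
                       k_line = 3,
                       discordant_line = "L4",
                       amplitude_sparsity = 0.7,
                       set_sizes = c(ra_like = 100, krab_like = 80),
                       set_target_modules = NULL,
                       era_probs = NULL,
                       noise = list(family = "lognormal", sigma = 0.25, dispersion = 0.1),
                       baseline = 0.2,
                       amplitude_shift = 5,
                       phenotype_link = list(slope = 0.3, intercept = 0.1, sigma = 0.05),
                       n_population_donors = 20,
                       kinship_mean = 0.15,
                       kinship_sd = 0.08,
                       seed = 1) {
  stopifnot(n_genes >= 1, n_replicates >= 1, k_dynamic >= 0, k_line >= 0,
            k_dynamic + k_line >= 1, length(lines) >= 1, length(days) >= 1)
  if (!all(conditions %in% c("SR", "NSB", "BMP4"))) {
    stop("conditions must be a subset of SR, NSB, BMP4")
  }
  if (amplitude_sparsity < 0 || amplitude_sparsity >= 1) {
    stop("amplitude_sparsity must lie in [0, 1)")
  }
  if (!is.null(discordant_line) && !discordant_line %in% names(lines)) {
    stop("discordant_line '", discordant_line, "' is not one of the configured lines")
  }
  if (!is.null(discordant_line) && k_line < 1) stop("discordant_line requires k_line >= 1")
  if (is.null(era_probs)) {
    era_probs <- rbind(dynamic = c(0.60, 0.20, 0.10, 0.06, 0.04),
                       line    = c(0.04, 0.06, 0.10, 0.20, 0.60),
                       none    = rep(0.2, 5))
  }
  if (any(abs(rowSums(era_probs) - 1) > 1e-8)) stop("era_probs rows must sum to 1")
  if (phenotype_link$sigma < 0) stop("phenotype sigma must be >= 0")
  structure(list(n_genes = n_genes, lines = lines, n_replicates = n_replicates,
                 conditions = conditions, days = sort(days),
                 k_dynamic = k_dynamic, k_line = k_line,
                 discordant_line = discordant_line,
                 amplitude_sparsity = amplitude_sparsity,
                 set_sizes = set_sizes, set_target_modules = set_target_modules,
                 era_probs = era_probs, noise = noise, baseline = baseline,
                 amplitude_shift = amplitude_shift,
                 phenotype_link = phenotype_link,
                 n_population_donors = n_population_donors,
                 kinship_mean = kinship_mean, kinship_sd = kinship_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# ---- module layout -------------------------------------------------------

# Dynamic shape library: four parametric curves over the normalized day axis,
# each tied to a condition scope. Shapes repeat (with alternating induction
# condition) when k_dynamic > 4 so that repeated curves stay linearly
# independent in weight space.
dynamic_shape_table <- function(k_dynamic) {
  if (k_dynamic == 0) return(list())
  base <- list(
    list(label = "pluripotency-decay", curve = "decay",  condition = "all"),
    list(label = "NSB-early",          curve = "early",  condition = "NSB"),
    list(label = "NSB-late",           curve = "late",   condition = "NSB"),
    list(label = "BMP4-rising",        curve = "rising", condition = "BMP4"),
    list(label = "BMP4-early",         curve = "early",  condition = "BMP4"),
    list(label = "BMP4-late",          curve = "late",   condition = "BMP4"),
    list(label = "NSB-rising",         curve = "rising", condition = "NSB"))
  if (k_dynamic > length(base)) {
    warning("k_dynamic > ", length(base),
            ": dynamic shapes repeat and are no longer separately identifiable")
  }
  lapply(seq_len(k_dynamic), function(i) base[[(i - 1L) %% length(base) + 1L]])
}

dynamic_weight <- function(curve, condition_scope, condition, t) {
  # t in [0, 1] over the day axis
  if (curve == "decay") {
    return(if (condition == "SR") 1 - 0.15 * t else exp(-1.8 * t))
  }
  if (condition_scope != "all" && condition != condition_scope) return(0.05)
  switch(curve,
         early  = exp(-((t - 0.4) / 0.25)^2), # transient early wave
         late   = 1 / (1 + exp(-8 * (t - 0.7))),
         rising = 0.1 + 0.9 * t,
         stop("unknown curve: ", curve))
}

# Owners of the stable modules: donor-level modules for multi-donor line
# pairs first, then single-line modules; the discordant line's private
# module takes the final slot.
line_module_layout <- function(config) {
  lines <- config$lines
  donors <- split(names(lines), lines)
  donors <- donors[order(names(donors))]
  k <- config$k_line
  if (k == 0) return(list())
  has_private <- !is.null(config$discordant_line)
  n_public <- k - as.integer(has_private)
  cand <- list()
  for (d in names(donors)) {
    if (length(donors[[d]]) >= 2) {
      cand[[length(cand) + 1L]] <- list(class = "donor", owner = d, lines = donors[[d]])
    }
  }
  multi <- unlist(lapply(donors[vapply(donors, length, 1L) >= 2], identity))
  for (l in sort(names(lines))) {
    if (!l %in% multi) {
      cand[[length(cand) + 1L]] <- list(class = "line", owner = l, lines = l)
    }
  }
  if (n_public > length(cand)) {
    # fall back to plain line modules for remaining slots
    for (l in sort(names(lines))) {
      if (length(cand) >= n_public) break
      cand[[length(cand) + 1L]] <- list(class = "line", owner = l, lines = l)
    }
  }
  out <- cand[seq_len(n_public)]
  if (has_private) {
    out[[k]] <- list(class = "private", owner = config$discordant_line,
                     lines = config$discordant_line)
  }
  out
}

default_set_targets <- function(config, layout) {
  k_dyn <- config$k_dynamic
  idx_line <- k_dyn + seq_along(layout)
  if (length(idx_line) == 0) return(list())
  cls <- vapply(layout, `[[`, character(1), "class")
  # RA-like: graded strengths across stable modules, private strongest
  ra <- seq(0.4, 0.8, length.out = max(1L, length(idx_line)))
  ra[cls == "private"] <- 1.2
  names(ra) <- idx_line
  krab <- rep(0.6, length(idx_line))
  names(krab) <- idx_line
  targets <- list(ra_like = ra, krab_like = krab)
  targets[names(config$set_sizes)]
}

# ---- main generator ------------------------------------------------------

#' Simulate a differentiation study with planted ground truth
#'
#' Builds nonnegative amplitudes `A_true` (genes x K) and pattern weights
#' `P_true` (K x samples) from the configuration, then emits an expression
#' matrix `X = (A_true P_true + baseline)` perturbed by the configured noise
#' family (multiplicative lognormal with mean preserved, or
#' negative-binomial counts). Planted gene sets receive boosted amplitudes
#' in their target modules; per-gene evolutionary era and haploinsufficiency
#' scores are drawn conditional on each gene's dominant module class; the
#' per-line phenotype is a noisy linear function of the planted per-line
#' RA-activity score; the donor kinship matrix covers the study donors plus
#' a simulated background population.
#'
#' @param config A [sim_config()].
#' @return List with `study` (an [expression_study()]) and `truth` (class
#'   `ground_truth`: `A_true`, `P_true`, `module_class`, `module_owner`,
#'   `module_label`, `set_membership`, `era`, `phaplo`, `phenotype`,
#'   `line_score`, `kinship`, `donor_of`, `config`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_study_impl(config))
}

simulate_study_impl <- function(config) {
  G <- config$n_genes
  genes <- sprintf("g%04d", seq_len(G))
  shapes <- dynamic_shape_table(config$k_dynamic)
  layout <- line_module_layout(config)
  K <- config$k_dynamic + length(layout)

  module_class <- c(rep("dynamic", config$k_dynamic),
                    vapply(layout, `[[`, character(1), "class"))
  module_owner <- c(rep(NA_character_, config$k_dynamic),
                    vapply(layout, `[[`, character(1), "owner"))
  module_label <- c(vapply(shapes, `[[`, character(1), "label"),
                    vapply(layout, function(m) paste0(m$class, ":", m$owner), character(1)))
  names(module_class) <- names(module_owner) <- names(module_label) <-
    paste0("M", seq_len(K))

  # amplitudes: sparse nonnegative loadings
  A <- matrix(0, G, K, dimnames = list(genes, names(module_class)))
  n_active <- max(1L, round((1 - config$amplitude_sparsity) * G))
  for (k in seq_len(K)) {
    act <- sample.int(G, n_active)
    A[act, k] <- stats::rgamma(n_active, shape = 2, rate = 0.4)
  }

  # planted gene sets, disjoint, boosted in their target modules
  set_sizes <- config$set_sizes
  set_membership <- list()
  if (length(set_sizes)) {
    pool <- sample(genes, sum(set_sizes))
    off <- 0L
    for (s in names(set_sizes)) {
      set_membership[[s]] <- pool[off + seq_len(set_sizes[[s]])]
      off <- off + set_sizes[[s]]
    }
  }
  targets <- config$set_target_modules
  if (is.null(targets)) targets <- default_set_targets(config, layout)
  for (s in names(targets)) {
    tg <- targets[[s]]
    for (i in seq_along(tg)) {
      m <- as.integer(names(tg)[i])
      gidx <- set_membership[[s]]
      A[gidx, m] <- stats::rgamma(length(gidx), shape = 2, rate = 0.4) +
        config$amplitude_shift * tg[i]
    }
  }

  # dominant module class per gene drives era / pHaplo annotation
  dom <- apply(A, 1, function(a) if (all(a == 0)) 0L else which.max(a))
  dom_class <- ifelse(dom == 0L, "none",
                      ifelse(module_class[pmax(dom, 1L)] == "dynamic", "dynamic", "line"))
  era <- integer(G)
  for (cl in c("dynamic", "line", "none")) {
    idx <- which(dom_class == cl)
    if (length(idx)) {
      era[idx] <- sample.int(5, length(idx), replace = TRUE,
                             prob = config$era_probs[cl, ])
    }
  }
  names(era) <- genes
  phaplo <- numeric(G)
  phaplo[dom_class == "dynamic"] <- stats::rbeta(sum(dom_class == "dynamic"), 13, 7)
  phaplo[dom_class == "line"] <- stats::rbeta(sum(dom_class == "line"), 7, 13)
  phaplo[dom_class == "none"] <- stats::rbeta(sum(dom_class == "none"), 10, 10)
  names(phaplo) <- genes

  # kinship over study donors + background population
  study_donors <- sort(unique(unname(config$lines)))
  pop_donors <- if (config$n_population_donors > 0) {
    sprintf("POP%02d", seq_len(config$n_population_donors))
  } else character(0)
  all_donors <- c(study_donors, pop_donors)
  nd <- length(all_donors)
  kin <- matrix(0, nd, nd, dimnames = list(all_donors, all_donors))
  up <- upper.tri(kin)
  vals <- stats::rnorm(sum(up), config$kinship_mean, config$kinship_sd)
  kin[up] <- pmin(pmax(vals, 0), 0.9)
  kin <- kin + t(kin)
  diag(kin) <- 1

  # sample grid and pattern weights
  meta <- expand.grid(replicate = paste0("r", seq_len(config$n_replicates)),
                      day = config$days, condition = config$conditions,
                      line_id = names(config$lines),
                      stringsAsFactors = FALSE)
  meta <- meta[, c("line_id", "condition", "day", "replicate")]
  meta$donor_id <- unname(config$lines[meta$line_id])
  meta$sample_id <- sprintf("%s_%s_d%d_%s", meta$line_id, meta$condition,
                            meta$day, meta$replicate)
  meta <- meta[, c("sample_id", "line_id", "donor_id", "condition", "day", "replicate")]
  S <- nrow(meta)
  drange <- range(config$days)
  tnorm <- if (drange[1] == drange[2]) rep(0, S) else
    (meta$day - drange[1]) / (drange[2] - drange[1])
  P <- matrix(0, K, S, dimnames = list(names(module_class), meta$sample_id))
  for (k in seq_len(config$k_dynamic)) {
    sh <- shapes[[k]]
    P[k, ] <- vapply(seq_len(S), function(s) {
      dynamic_weight(sh$curve, sh$condition, meta$condition[s], tnorm[s])
    }, numeric(1))
  }
  for (i in seq_along(layout)) {
    P[config$k_dynamic + i, meta$line_id %in% layout[[i]]$lines] <- 1
  }

  # expression with configured noise family
  mu <- A %*% P + config$baseline
  fam <- config$noise$family
  if (fam == "lognormal") {
    sg <- config$noise$sigma
    X <- if (sg == 0) mu else
      mu * exp(matrix(stats::rnorm(G * S, 0, sg), G, S) - sg^2 / 2)
    scale <- "rpkm"
  } else if (fam == "negative-binomial") {
    disp <- config$noise$dispersion
    X <- matrix(stats::rnbinom(G * S, mu = mu, size = 1 / max(disp, 1e-8)), G, S)
    scale <- "counts"
  } else stop("unknown noise family: ", fam)
  dimnames(X) <- dimnames(mu)

  # planted per-line RA activity: summed RA-like strengths of the stable
  # modules covering each line; phenotype is a noisy linear function of it
  line_score <- stats::setNames(numeric(length(config$lines)), names(config$lines))
  ra_tg <- targets[["ra_like"]]
  if (!is.null(ra_tg)) {
    for (i in seq_along(ra_tg)) {
      m <- as.integer(names(ra_tg)[i])
      li <- m - config$k_dynamic
      if (li >= 1 && li <= length(layout)) {
        ln <- layout[[li]]$lines
        line_score[ln] <- line_score[ln] + ra_tg[i]
      }
    }
  }
  pl <- config$phenotype_link
  phenotype <- pl$intercept + pl$slope * line_score +
    stats::rnorm(length(line_score), 0, pl$sigma)
  names(phenotype) <- names(line_score)

  truth <- structure(list(A_true = A, P_true = P, module_class = module_class,
                          module_owner = module_owner, module_label = module_label,
                          set_membership = set_membership, era = era, phaplo = phaplo,
                          phenotype = phenotype, line_score = line_score,
                          kinship = kin, donor_of = config$lines, config = config),
                     class = "ground_truth")
  study <- expression_study(X, meta, scale = scale)
  list(study = study, truth = truth)
}

#' Simulate an external dataset for projection testing
#'
#' Generates projection targets with known relations to the planted modules:
#' `tissue-like` samples (e.g. postmortem brain) carry the genetic
#' line/donor-module signal of their assigned donor, scaled by kinship, but
#' never the private (epigenetic) module; `celltype-like` samples express
#' random subsets of the dynamic modules; `promoter-signal` columns emulate
#' a repressive chromatin mark (H3K9me3-like) anticorrelated with a chosen
#' stable module's amplitudes.
#'
#' @param truth A `ground_truth` from [simulate_study()].
#' @param kind One of `"tissue-like"`, `"celltype-like"`, `"promoter-signal"`.
#' @param n_samples Number of external samples (0 gives an empty study with
#'   a valid gene header).
#' @param seed Integer seed.
#' @param target_module For `promoter-signal`: module index to anticorrelate
#'   with; defaults to the private module, else the first stable module.
#' @param signal_sd Lognormal noise sd of the external data.
#' @return An [expression_study()]; tissue-like metadata records the
#'   assigned donor in `donor_id`.
#' @export
simulate_external_dataset <- function(truth, kind, n_samples, seed = 1,
                                      target_module = NULL, signal_sd = 0.25) {
  stopifnot(inherits(truth, "ground_truth"))
  kinds <- c("tissue-like", "celltype-like", "promoter-signal")
  if (!kind %in% kinds) stop("unknown kind '", kind, "'; use one of: ",
                             paste(kinds, collapse = ", "))
  with_seed(seed, simulate_external_impl(truth, kind, n_samples,
                                         target_module, signal_sd))
}

simulate_external_impl <- function(truth, kind, n_samples, target_module,
                                   signal_sd) {
  A <- truth$A_true
  K <- ncol(A)
  G <- nrow(A)
  cls <- truth$module_class
  base <- truth$config$baseline
  if (n_samples == 0) {
    X <- matrix(numeric(0), G, 0, dimnames = list(rownames(A), character(0)))
    meta <- data.frame(sample_id = character(0), line_id = character(0),
                       donor_id = character(0), condition = character(0),
                       day = integer(0), replicate = character(0))
    return(expression_study(X, meta, scale = "rpkm"))
  }
  if (kind == "tissue-like") {
    donors <- rownames(truth$kinship)
    # round-robin so every donor is represented once n_samples >= n_donors
    assigned <- if (n_samples >= length(donors)) {
      c(donors, sample(donors, n_samples - length(donors), replace = TRUE))
    } else {
      sample(donors, n_samples)
    }
    W <- matrix(0, K, n_samples)
    W[cls == "dynamic", ] <- stats::runif(sum(cls == "dynamic") * n_samples, 0, 0.3)
    for (k in which(cls %in% c("line", "donor"))) {
      own_donor <- if (cls[k] == "donor") truth$module_owner[k] else
        unname(truth$donor_of[truth$module_owner[k]])
      W[k, ] <- truth$kinship[assigned, own_donor]
    }
    # private (epigenetically driven) modules leave no trace in tissue
    mu <- A %*% W + base
    X <- mu * exp(matrix(stats::rnorm(G * n_samples, 0, signal_sd), G, n_samples) -
                    signal_sd^2 / 2)
    ids <- sprintf("tissue_%03d", seq_len(n_samples))
    dimnames(X) <- list(rownames(A), ids)
    meta <- data.frame(sample_id = ids, line_id = assigned, donor_id = assigned,
                       condition = "other", day = 0, replicate = "r1")
    return(expression_study(X, meta, scale = "rpkm"))
  }
  if (kind == "celltype-like") {
    dyn <- which(cls == "dynamic")
    if (!length(dyn)) stop("celltype-like samples require dynamic modules")
    W <- matrix(0.02, K, n_samples)
    for (j in seq_len(n_samples)) {
      on <- sample(dyn, min(length(dyn), sample(1:2, 1)))
      W[on, j] <- stats::runif(length(on), 0.7, 1)
    }
    W[cls != "dynamic", ] <- 0
    mu <- A %*% W + base
    X <- mu * exp(matrix(stats::rnorm(G * n_samples, 0, signal_sd), G, n_samples) -
                    signal_sd^2 / 2)
    ids <- sprintf("cell_%03d", seq_len(n_samples))
    dimnames(X) <- list(rownames(A), ids)
    meta <- data.frame(sample_id = ids, line_id = "external", donor_id = "external",
                       condition = "other", day = 0, replicate = "r1")
    return(expression_study(X, meta, scale = "rpkm"))
  }
  # promoter-signal: repressive mark anticorrelated with one stable module
  if (is.null(target_module)) {
    target_module <- if (any(cls == "private")) which(cls == "private")[1] else
      which(cls != "dynamic")[1]
    if (is.na(target_module)) stop("no stable module available for promoter-signal")
  }
  a <- A[, target_module]
  a <- a / max(a)
  mu <- pmax(1 - 0.8 * a, 0.05)
  X <- matrix(0, G, n_samples)
  for (j in seq_len(n_samples)) {
    X[, j] <- mu * exp(stats::rnorm(G, 0, signal_sd) - signal_sd^2 / 2)
  }
  ids <- sprintf("mark_%03d", seq_len(n_samples))
  dimnames(X) <- list(rownames(A), ids)
  meta <- data.frame(sample_id = ids, line_id = "chip", donor_id = "chip",
                     condition = "other", day = 0, replicate = "r1")
  expression_study(X, meta, scale = "rpkm")
}

#' Write a simulated study and its ground truth to a directory
#'
#' Emits `expression.tsv`, `metadata.tsv`, `gene_sets.gmt`,
#' `annotations.tsv` (era, pHaplo), `phenotype.tsv`, `kinship.tsv` and
#' `truth.json` (module classes/owners and the planted per-line scores);
#' `A_true.tsv` / `P_true.tsv` hold the planted factors.
#'
#' @param sim Result of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- sim$truth
  write_expression(sim$study, file.path(dir, "expression.tsv"),
                   file.path(dir, "metadata.tsv"))
  if (length(tr$set_membership)) {
    write_gmt(tr$set_membership, file.path(dir, "gene_sets.gmt"))
  }
  write_tsv_full(data.frame(gene_id = names(tr$era), era = tr$era,
                            phaplo = tr$phaplo),
                 file.path(dir, "annotations.tsv"))
  write_tsv_full(data.frame(line_id = names(tr$phenotype),
                            phenotype = tr$phenotype,
                            ra_activity = tr$line_score),
                 file.path(dir, "phenotype.tsv"))
  write_kinship(tr$kinship, file.path(dir, "kinship.tsv"))
  write_tsv_full(data.frame(gene_id = rownames(tr$A_true), tr$A_true,
                            check.names = FALSE),
                 file.path(dir, "A_true.tsv"))
  write_tsv_full(data.frame(pattern = rownames(tr$P_true), tr$P_true,
                            check.names = FALSE),
                 file.path(dir, "P_true.tsv"))
  jsonlite::write_json(list(module_class = as.list(tr$module_class),
                            module_owner = as.list(tr$module_owner),
                            module_label = as.list(tr$module_label),
                            line_score = as.list(tr$line_score),
                            donor_of = as.list(tr$donor_of),
                            seed = tr$config$seed),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
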