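# Links pattern-level statistics to phenotypes and donor structure:
# enrichment-phenotype regression, donor intraclass correlation, and
# kinship-signature association.

#' Associate per-line scores with a per-line phenotype
#'
#' Pearson correlation and least-squares line between a per-line score
#' (e.g. retinoic-acid gene-set enrichment in each line's specific pattern)
#' and a per-line phenotype (e.g. the proportion of hindbrain-marker-high
#' cells after RA treatment), over the lines present in both.
#'
#' @param per_line_scores Named numeric vector, line id -> score.
#' @param phenotypes Named numeric vector, line id -> phenotype, or a data
#'   frame with columns `line_id` and `phenotype`.
#' @return List of class `association_result`: `r`, `r_squared`,
#'   `p_two_sided`, `n`, `slope`, `intercept`.
#' @export
phenotype_association <- function(per_line_scores, phenotypes) {
  if (is.data.frame(phenotypes)) {
    phenotypes <- stats::setNames(phenotypes$phenotype, phenotypes$line_id)
  }
  shared <- intersect(names(per_line_scores), names(phenotypes))
  if (length(shared) < 3) stop("need >= 3 lines with both score and phenotype")
  x <- as.numeric(per_line_scores[shared])
  y <- as.numeric(phenotypes[shared])
  if (stats::sd(x) == 0) stop("constant scores: correlation undefined")
  if (stats::sd(y) == 0) stop("constant phenotypes: correlation undefined")
  ct <- stats::cor.test(x, y)
  fit <- stats::lm(y ~ x)
  structure(list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
                 p_two_sided = ct$p.value, n = length(shared),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1])),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("association: r = %.3f (R^2 = %.3f), p = %.3g, n = %d\n",
              x$r, x$r_squared, x$p_two_sided, x$n))
  cat(sprintf("  fit: phenotype = %.3g * score + %.3g\n", x$slope, x$intercept))
  invisible(x)
}

#' One-way random-effects intraclass correlation, ICC(1)
#'
#' Estimates the proportion of score variance attributable to the grouping
#' factor (donor of origin) by the method of moments:
#' `ICC = (MSB - MSW) / (MSB + (k0 - 1) MSW)` with the standard
#' unbalanced-design group size `k0 = (N - sum(k_i^2) / N) / (n_groups - 1)`.
#'
#' @param scores Numeric vector (e.g. one principal component's sample
#'   scores).
#' @param donor_labels Grouping factor aligned with `scores`.
#' @return List of class `icc_result`: `icc`, `ms_between`, `ms_within`,
#'   `n_groups`, `group_sizes`.
#' @export
donor_icc <- function(scores, donor_labels) {
  if (length(scores) != length(donor_labels)) {
    stop("scores and donor_labels must align")
  }
  g <- factor(donor_labels)
  sizes <- table(g)
  n_groups <- nlevels(g)
  if (n_groups < 2) stop("need >= 2 donors")
  if (!any(sizes >= 2)) stop("all donors are singletons: within-donor variance undefined")
  N <- length(scores)
  gm <- mean(scores)
  means <- tapply(scores, g, mean)
  ssb <- sum(sizes * (means - gm)^2)
  ssw <- sum((scores - means[g])^2)
  msb <- ssb / (n_groups - 1)
  msw <- ssw / (N - n_groups)
  k0 <- (N - sum(sizes^2) / N) / (n_groups - 1)
  icc <- if (msb + (k0 - 1) * msw == 0) NA_real_ else
    (msb - msw) / (msb + (k0 - 1) * msw)
  structure(list(icc = icc, ms_between = msb, ms_within = msw,
                 n_groups = n_groups, group_sizes = as.integer(sizes)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(1) = %.3f over %d groups (MSB = %.3g, MSW = %.3g)\n",
              x$icc, x$n_groups, x$ms_between, x$ms_within))
  invisible(x)
}

#' Correlate kinship to a reference donor with projected signature strength
#'
#' Tests whether individuals genetically closer to a reference donor carry
#' more of that donor's projected signature: Pearson correlation between
#' the kinship-to-reference vector (the reference itself excluded) and the
#' per-individual signature strength, with a permutation p-value obtained
#' by shuffling the individual labels of the strength vector.
#'
#' @param kinship Square labeled symmetric relatedness matrix covering the
#'   reference donor and every individual.
#' @param reference_donor Row/column name of the reference donor.
#' @param signature_strengths Named numeric vector, individual -> projected
#'   signature strength.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @param alternative `"greater"` (default: strength increases with
#'   relatedness) or `"two.sided"`.
#' @return List: `r`, `slope`, `intercept`, `n`, `p_perm`, `n_perm`.
#' @export
kinship_signature_correlation <- function(kinship, reference_donor,
                                          signature_strengths, n_perm = 1000,
                                          seed = 1, alternative = "greater") {
  if (!reference_donor %in% rownames(kinship)) {
    stop("reference donor '", reference_donor, "' missing from kinship matrix")
  }
  ind <- setdiff(names(signature_strengths), reference_donor)
  miss <- setdiff(ind, rownames(kinship))
  if (length(miss)) stop("kinship matrix missing individuals: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  if (length(ind) < 3) stop("need >= 3 individuals besides the reference")
  x <- kinship[ind, reference_donor]
  y <- as.numeric(signature_strengths[ind])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant kinship or strength vector: correlation undefined")
  }
  r <- stats::cor(x, y)
  fit <- stats::lm(y ~ x)
  stat <- if (alternative == "two.sided") abs else identity
  null <- with_seed(seed, vapply(seq_len(n_perm),
                                 function(i) stats::cor(x, sample(y)), numeric(1)))
  p <- (1 + sum(stat(null) >= stat(r))) / (n_perm + 1)
  list(r = r, slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n = length(ind),
       p_perm = p, n_perm = as.integer(n_perm))
}
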