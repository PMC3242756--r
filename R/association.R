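## Marginal and epistatic linear-model association tests.
##
## Marginal model:   y = mu + b*x + e,              test b   (df = n - 2)
## Epistasis model:  y = mu + b1*x1 + b2*x2
##                         + b12*x1*x2 + e,         test b12 (df = n - 4)
##
## Genotypes are additively coded (0/1 haploid, 0/1/2 diploid); the
## interaction predictor is the product of the additive codes.  Missing
## data are handled by pairwise complete cases; p-values come from the t
## distribution.

.as_geno_values <- function(g) {
  if (inherits(g, "genotype_matrix")) g$values else as.matrix(g)
}

.as_pair_matrix <- function(pairs) {
  if (inherits(pairs, "pair_subset")) pairs <- pairs$pairs
  pairs <- as.matrix(pairs)
  if (length(pairs) == 0) pairs <- matrix(integer(0), ncol = 2)
  storage.mode(pairs) <- "integer"
  pairs
}

#' Single-SNP marginal association test
#'
#' OLS of phenotype on an intercept and one additive-coded genotype;
#' two-sided t-test on the slope with `n_used - 2` df.  Rows with a
#' missing genotype or phenotype are dropped.  A genotype that is
#' constant on the complete cases, or a phenotype with zero residual
#' variance, yields missing statistics (flagged via `note`), not an
#' error.
#'
#' @param x genotype vector.
#' @param y phenotype vector.
#' @return list of class `marginal_result`: `beta`, `se`, `t_stat`,
#'   `df`, `p_value`, `n_used`, `note`.
#' @export
marginal_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  cc <- !is.na(x) & !is.na(y)
  n <- sum(cc)
  if (n < 3) stop("need at least 3 complete cases")
  x <- x[cc]; y <- y[cc]
  sxx <- sum((x - mean(x))^2)
  res <- list(beta = NA_real_, se = NA_real_, t_stat = NA_real_,
              df = n - 2, p_value = NA_real_, n_used = n, note = NULL)
  if (sxx <= 0) {
    res$note <- "constant genotype"
    class(res) <- "marginal_result"
    return(res)
  }
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  beta <- sxy / sxx
  rss <- syy - beta * sxy
  if (rss < 0) rss <- 0
  sigma2 <- rss / (n - 2)
  res$beta <- beta
  if (sigma2 > 0) {
    res$se <- sqrt(sigma2 / sxx)
    res$t_stat <- beta / res$se
    res$p_value <- 2 * stats::pt(-abs(res$t_stat), n - 2)
  } else {
    res$note <- "zero residual variance"
  }
  class(res) <- "marginal_result"
  res
}

#' Marginal scan over all SNPs of a genotype matrix
#'
#' Vectorized equivalent of [marginal_test()] applied to every SNP
#' column, with per-SNP pairwise complete cases.
#'
#' @param g a [genotype_matrix()] (or plain matrix).
#' @param y phenotype vector, one entry per sample.
#' @return data.frame with columns `snp_id`, `beta`, `se`, `t_stat`,
#'   `p_value`, `n_used`.
#' @export
marginal_scan <- function(g, y) {
  G <- .as_geno_values(g)
  if (length(y) != nrow(G)) stop("phenotype length must match sample count")
  vy <- !is.na(y)
  y0 <- ifelse(vy, y, 0)
  M <- (!is.na(G)) * vy            # valid indicator per cell
  G0 <- G; G0[is.na(G0)] <- 0
  G0 <- G0 * vy
  nj <- colSums(M)
  sx <- colSums(G0)
  sxx <- colSums(G0 * G0)
  sy <- colSums(M * y0)
  syy <- colSums(M * y0 * y0)
  sxy <- colSums(G0 * y0)
  sxx_c <- sxx - sx * sx / nj
  sxy_c <- sxy - sx * sy / nj
  syy_c <- syy - sy * sy / nj
  beta <- ifelse(sxx_c > 0, sxy_c / sxx_c, NA_real_)
  rss <- pmax(syy_c - beta * sxy_c, 0)
  df <- nj - 2
  sigma2 <- rss / df
  se <- ifelse(!is.na(beta) & sigma2 > 0 & df > 0, sqrt(sigma2 / sxx_c), NA_real_)
  t_stat <- beta / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  data.frame(snp_id = if (inherits(g, "genotype_matrix")) g$snp_ids else
               colnames(G) %||% paste0("snp_", seq_len(ncol(G))),
             beta = beta, se = se, t_stat = t_stat, p_value = p,
             n_used = as.integer(nj), stringsAsFactors = FALSE)
}

#' Two-locus epistasis test
#'
#' OLS of phenotype on `(1, x1, x2, x1*x2)`; two-sided t-test on the
#' product-term coefficient with `n_used - 4` df.  Rank-deficient
#' designs (e.g. identical SNPs, or a missing genotype combination
#' making the product collinear) yield missing statistics.
#'
#' @param x1,x2 genotype vectors.
#' @param y phenotype vector.
#' @return list of class `epistasis_result`: `beta12`, `se`, `t_stat`,
#'   `df`, `p_value`, `n_used`, `note`.
#' @export
epistasis_test <- function(x1, x2, y) {
  if (length(x1) != length(y) || length(x2) != length(y)) {
    stop("x1, x2 and y must have equal length")
  }
  G <- cbind(x1, x2)
  r <- epi_scan_cpp(G, as.numeric(y), matrix(c(1L, 2L), nrow = 1))
  r <- unname(r[1, ])
  res <- list(beta12 = r[1], se = r[2], t_stat = r[3], df = r[4],
              p_value = r[5], n_used = as.integer(r[6]),
              note = if (is.na(r[5])) "degenerate design" else NULL)
  class(res) <- "epistasis_result"
  res
}

#' Epistasis scan over a SNP-pair subset
#'
#' Batched version of [epistasis_test()]: one row per pair, numerically
#' identical to the per-pair test, in the order of the pair list.
#' Degenerate pairs are flagged with missing statistics; the scan never
#' aborts on a single bad pair.
#'
#' @param g a [genotype_matrix()].
#' @param y phenotype vector.
#' @param pairs a [pair_subset()] or 2-column matrix of SNP indices.
#' @param trait_id label written into the result rows.
#' @return data.frame with columns `trait_id`, `snp1_id`, `snp2_id`,
#'   `beta12`, `t_stat`, `p_value`, `n_used`.
#' @export
epistasis_scan <- function(g, y, pairs, trait_id = "trait") {
  G <- .as_geno_values(g)
  pm <- .as_pair_matrix(pairs)
  ids <- if (inherits(g, "genotype_matrix")) g$snp_ids else
    colnames(G) %||% paste0("snp_", seq_len(ncol(G)))
  if (nrow(pm) == 0) {
    return(data.frame(trait_id = character(0), snp1_id = character(0),
                      snp2_id = character(0), beta12 = numeric(0),
                      t_stat = numeric(0), p_value = numeric(0),
                      n_used = integer(0), stringsAsFactors = FALSE))
  }
  if (max(pm) > ncol(G) || min(pm) < 1) stop("pair indices out of range")
  r <- epi_scan_cpp(G, as.numeric(y), pm)
  data.frame(trait_id = trait_id,
             snp1_id = ids[pm[, 1]], snp2_id = ids[pm[, 2]],
             beta12 = r[, "beta12"], t_stat = r[, "t_stat"],
             p_value = r[, "p_value"], n_used = as.integer(r[, "n_used"]),
             stringsAsFactors = FALSE)
}

#' Minimum p-value of a result table
#'
#' The per-trait test statistic of the whole framework: the smallest
#' non-missing interaction p-value over the trait's pair subset.  An
#' empty table or one with only missing p-values returns 1.0 (so such
#' traits can never be hits) with an `all_missing` attribute set.
#'
#' @param tab result data.frame with a `p_value` column (or a bare
#'   numeric vector of p-values).
#' @return single numeric p-value.
#' @export
min_p <- function(tab) {
  p <- if (is.data.frame(tab)) tab$p_value else as.numeric(tab)
  p <- p[!is.na(p)]
  if (length(p) == 0) {
    es_log("min_p: empty or all-missing subset, returning 1.0")
    return(structure(1.0, all_missing = TRUE))
  }
  min(p)
}

#' Variance explained by the interaction term
#'
#' `R^2` of the full two-locus model (with the product term) minus
#' `R^2` of the additive-only model, in percent.  Non-negative by
#' nesting; missing for degenerate designs.
#'
#' @param x1,x2 genotype vectors.
#' @param y phenotype vector.
#' @return percent increase in explained variance (numeric scalar).
#' @export
variance_explained_delta_r2 <- function(x1, x2, y) {
  cc <- stats::complete.cases(x1, x2, y)
  if (sum(cc) < 5) return(NA_real_)
  x1 <- x1[cc]; x2 <- x2[cc]; y <- y[cc]
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) return(NA_real_)
  r2 <- function(X) {
    fit <- stats::lm.fit(X, y)
    if (fit$rank < ncol(X)) return(NA_real_)
    1 - sum(fit$residuals^2) / ss_tot
  }
  r2_red <- r2(cbind(1, x1, x2))
  r2_full <- r2(cbind(1, x1, x2, x1 * x2))
  if (is.na(r2_red) || is.na(r2_full)) return(NA_real_)
  max(0, (r2_full - r2_red)) * 100
}

#' Dominance-adjusted epistasis test
#'
#' Adds heterozygote indicator terms for each diploid SNP to the
#' two-locus model: OLS of `y` on `(1, x1, het(x1), x2, het(x2),
#' x1*x2)` with `het(x) = 1` iff `x == 1`; two-sided t-test on the
#' product term with `n_used - 6` df.  When a SNP has no heterozygotes
#' on the complete cases the dominance terms are inestimable and the
#' function falls back to [epistasis_test()] (flagged via `note`).
#'
#' @param x1,x2 diploid genotype vectors (0/1/2).
#' @param y phenotype vector.
#' @return list of class `epistasis_result`.
#' @export
epistasis_test_dominance <- function(x1, x2, y) {
  cc <- stats::complete.cases(x1, x2, y)
  if (sum(cc) < 7) stop("need at least 7 complete cases for the dominance model")
  x1c <- x1[cc]; x2c <- x2[cc]; yc <- y[cc]
  h1 <- as.numeric(x1c == 1); h2 <- as.numeric(x2c == 1)
  if (sum(h1) == 0 || sum(h2) == 0) {
    res <- epistasis_test(x1, x2, y)
    res$note <- "no heterozygote class; fell back to the additive epistasis model"
    return(res)
  }
  X <- cbind(1, x1c, h1, x2c, h2, x1c * x2c)
  n <- length(yc)
  res <- list(beta12 = NA_real_, se = NA_real_, t_stat = NA_real_,
              df = n - 6, p_value = NA_real_, n_used = n, note = NULL)
  class(res) <- "epistasis_result"
  fit <- stats::lm.fit(X, yc)
  if (fit$rank < ncol(X) || n <= 6) {
    res$note <- "rank-deficient dominance design"
    return(res)
  }
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - 6)
  XtX_inv <- chol2inv(chol(crossprod(X)))
  if (sigma2 <= 0) {
    res$note <- "zero residual variance"
    return(res)
  }
  res$beta12 <- unname(fit$coefficients[6])
  res$se <- sqrt(sigma2 * XtX_inv[6, 6])
  res$t_stat <- res$beta12 / res$se
  res$p_value <- 2 * stats::pt(-abs(res$t_stat), n - 6)
  res
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' 1-df chi-square test of observed diploid genotype counts against the
#' expectation from the observed allele frequency.  Monomorphic input
#' returns p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return p-value.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("need at least one genotype")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  if (p <= 0 || q <= 0) return(1)
  expected <- n * c(p^2, 2 * p * q, q^2)
  stat <- sum((c(n_AA, n_Aa, n_aa) - expected)^2 / expected)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}
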