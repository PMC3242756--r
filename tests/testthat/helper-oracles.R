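# Independent oracles and small fixture builders used across tests.

# Full OLS of y on (1, x1, x2, x1*x2) via explicit normal equations on a
# materialized design matrix -- an implementation route deliberately
# different from the package's accumulation kernel.
oracle_epistasis <- function(x1, x2, y) {
  cc <- complete.cases(x1, x2, y)
  x1 <- x1[cc]; x2 <- x2[cc]; y <- y[cc]
  X <- cbind(1, x1, x2, x1 * x2)
  XtX <- crossprod(X)
  XtX_inv <- solve(XtX)
  beta <- XtX_inv %*% crossprod(X, y)
  resid <- y - X %*% beta
  df <- length(y) - 4L
  sigma2 <- sum(resid^2) / df
  se <- sqrt(sigma2 * XtX_inv[4, 4])
  t_stat <- beta[4] / se
  list(beta12 = beta[4], se = se, t_stat = t_stat, df = df,
       p_value = 2 * pt(-abs(t_stat), df))
}

# Simple-regression closed form for the marginal model.
oracle_marginal <- function(x, y) {
  cc <- complete.cases(x, y)
  x <- x[cc]; y <- y[cc]
  beta <- cov(x, y) / var(x)
  resid <- y - mean(y) - beta * (x - mean(x))
  df <- length(x) - 2L
  se <- sqrt(sum(resid^2) / df / sum((x - mean(x))^2))
  t_stat <- beta / se
  list(beta = beta, se = se, t_stat = t_stat, df = df,
       p_value = 2 * pt(-abs(t_stat), df))
}

rand_geno <- function(n, S, ploidy = "haploid", miss_frac = 0) {
  vals <- if (ploidy == "haploid") {
    matrix(rbinom(n * S, 1, 0.5), n)
  } else {
    matrix(rbinom(n * S, 2, runif(S, 0.2, 0.5)[rep(seq_len(S), each = n)]), n)
  }
  if (miss_frac > 0) {
    vals[runif(length(vals)) < miss_frac] <- NA
  }
  genotype_matrix(vals, ploidy = ploidy)
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
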