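test_that("marginal test matches the closed-form simple regression", {
  r <- marginal_test(c(0, 0, 1, 1), c(0, 1, 1, 2))
  expect_equal(r$beta, 1)
  expect_equal(r$se, sqrt(0.5), tolerance = 1e-12)
  expect_equal(r$t_stat, sqrt(2), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, 2 * pt(-sqrt(2), 2), tolerance = 1e-12)

  ## degenerate cases flag missing p rather than erroring
  expect_true(is.na(marginal_test(c(0, 1, 0, 1), rep(3, 4))$p_value))
  expect_true(is.na(marginal_test(rep(1, 5), rnorm(5))$p_value))

  ## exchangeability: jointly permuting rows changes nothing
  set.seed(7)
  x <- rbinom(40, 1, 0.5); y <- rnorm(40)
  perm <- sample(40)
  a <- marginal_test(x, y); b <- marginal_test(x[perm], y[perm])
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$beta, b$beta)
})

test_that("marginal scan agrees with per-SNP tests under missing data", {
  set.seed(11)
  g <- rand_geno(60, 15, "diploid", miss_frac = 0.05)
  y <- rnorm(60); y[c(3, 9)] <- NA
  sc <- marginal_scan(g, y)
  for (j in c(1, 4, 15)) {
    ref <- marginal_test(g$values[, j], y)
    expect_equal(sc$beta[j], ref$beta, tolerance = 1e-10)
    expect_equal(sc$p_value[j], ref$p_value, tolerance = 1e-10)
    expect_equal(sc$n_used[j], ref$n_used)
  }
})

test_that("epistasis test recovers planted interactions and nulls", {
  set.seed(21)
  ## balanced 2x2 haploid design, two replicates per cell, tiny noise
  x1 <- rep(c(0, 0, 1, 1), 2); x2 <- rep(c(0, 1), 4)
  y <- x1 * x2 + rnorm(8, sd = 1e-6)
  r <- epistasis_test(x1, x2, y)
  expect_equal(r$beta12, 1, tolerance = 1e-4)
  expect_lt(r$p_value, 1e-10)

  ## purely additive signal: no interaction
  y2 <- x1 + x2 + rnorm(8, sd = 1e-6)
  expect_lt(abs(epistasis_test(x1, x2, y2)$beta12), 1e-4)

  ## rank-deficient designs are flagged, not fatal
  expect_true(is.na(epistasis_test(x1, x1, rnorm(8))$p_value))
})

test_that("scan kernel equals the normal-equations oracle and lm()", {
  set.seed(31)
  for (i in 1:50) {
    n <- 50
    ploidy <- if (i %% 2) "haploid" else "diploid"
    g <- rand_geno(n, 2, ploidy, miss_frac = if (i %% 3 == 0) 0.06 else 0)
    x1 <- g$values[, 1]; x2 <- g$values[, 2]
    y <- rnorm(n)
    r <- epistasis_test(x1, x2, y)
    o <- oracle_epistasis(x1, x2, y)
    expect_equal(r$beta12, o$beta12, tolerance = 1e-10)
    expect_equal(r$se, o$se, tolerance = 1e-10)
    expect_equal(r$t_stat, o$t_stat, tolerance = 1e-10)
    expect_equal(r$p_value, o$p_value, tolerance = 1e-10)
  }
  ## cross-check one instance against R's lm machinery
  set.seed(32)
  x1 <- rbinom(50, 1, 0.5); x2 <- rbinom(50, 1, 0.5); y <- rnorm(50)
  fit <- summary(lm(y ~ x1 * x2))$coefficients
  r <- epistasis_test(x1, x2, y)
  expect_equal(r$beta12, unname(fit["x1:x2", "Estimate"]), tolerance = 1e-10)
  expect_equal(r$p_value, unname(fit["x1:x2", "Pr(>|t|)"]), tolerance = 1e-10)
})

test_that("batched scan equals the per-pair test and handles empty subsets", {
  set.seed(41)
  g <- rand_geno(50, 12, "haploid", miss_frac = 0.04)
  y <- rnorm(50)
  sub <- all_pairs(12)
  tab <- epistasis_scan(g, y, sub, trait_id = "t")
  expect_equal(nrow(tab), 66L)
  pick <- sample(66, 20)
  for (r in pick) {
    pm <- sub$pairs[r, ]
    ref <- epistasis_test(g$values[, pm[1]], g$values[, pm[2]], y)
    expect_equal(tab$p_value[r], ref$p_value, tolerance = 1e-12)
    expect_equal(tab$beta12[r], ref$beta12, tolerance = 1e-12)
  }
  empty <- epistasis_scan(g, y, pair_subset(matrix(integer(0), ncol = 2)))
  expect_equal(nrow(empty), 0L)
})

test_that("interaction p-values are invariant to affine y and allele relabeling", {
  set.seed(51)
  g <- rand_geno(60, 2, "diploid")
  x1 <- g$values[, 1]; x2 <- g$values[, 2]
  y <- rnorm(60)
  base <- epistasis_test(x1, x2, y)
  aff <- epistasis_test(x1, x2, 3.7 * y - 2)
  expect_equal(aff$p_value, base$p_value, tolerance = 1e-10)
  flip <- epistasis_test(2 - x1, x2, y)
  expect_equal(flip$p_value, base$p_value, tolerance = 1e-8)
  expect_equal(flip$beta12, -base$beta12, tolerance = 1e-8)

  m <- marginal_test(x1, y)
  mf <- marginal_test(2 - x1, y)
  expect_equal(mf$p_value, m$p_value, tolerance = 1e-10)
  expect_equal(mf$beta, -m$beta, tolerance = 1e-10)
})

test_that("p-values are uniform under the complete null", {
  set.seed(61)
  g <- rand_geno(80, 50, "haploid")
  pm <- replicate(100, marginal_scan(g, rnorm(80))$p_value)
  ks_m <- suppressWarnings(ks.test(as.vector(pm), "punif"))
  expect_lt(unname(ks_m$statistic), 0.05)

  sub <- all_pairs(50)
  pe <- unlist(lapply(1:10, function(i) {
    epistasis_scan(g, rnorm(80), sub)$p_value
  }))
  ks_e <- suppressWarnings(ks.test(pe[!is.na(pe)], "punif"))
  expect_lt(unname(ks_e$statistic), 0.05)
})

test_that("min_p summarizes a result table with the degenerate convention", {
  tab <- data.frame(p_value = c(0.3, 0.01, 0.5))
  expect_equal(min_p(tab), 0.01)
  expect_equal(min_p(data.frame(p_value = 0.2)), 0.2)
  allna <- data.frame(p_value = c(NA_real_, NA_real_))
  expect_equal(as.numeric(min_p(allna)), 1.0)
  expect_true(isTRUE(attr(min_p(allna), "all_missing")))
  expect_equal(as.numeric(min_p(data.frame(p_value = numeric(0)))), 1.0)
})

test_that("interaction term's added variance follows the nested-model algebra", {
  ## noise-free pure interaction on the balanced 2x2 design
  x1 <- rep(c(0, 0, 1, 1), 5); x2 <- rep(c(0, 1), 10)
  expect_equal(variance_explained_delta_r2(x1, x2, x1 * x2),
               100 / 3, tolerance = 1e-8)
  expect_equal(variance_explained_delta_r2(x1, x2, x1 + x2), 0, tolerance = 1e-8)
  set.seed(71)
  for (i in 1:20) {
    y <- rnorm(20)
    expect_gte(variance_explained_delta_r2(x1, x2, y), 0)
  }
})

test_that("dominance-adjusted model matches a full OLS fit and falls back cleanly", {
  set.seed(81)
  x1 <- rbinom(100, 2, 0.4); x2 <- rbinom(100, 2, 0.5)
  y <- 0.3 * x1 + 0.5 * (x1 == 1) + 0.8 * x1 * x2 + rnorm(100)
  r <- epistasis_test_dominance(x1, x2, y)
  h1 <- as.numeric(x1 == 1); h2 <- as.numeric(x2 == 1)
  fit <- summary(lm(y ~ x1 + h1 + x2 + h2 + I(x1 * x2)))$coefficients
  expect_equal(r$beta12, unname(fit["I(x1 * x2)", "Estimate"]), tolerance = 1e-10)
  expect_equal(r$p_value, unname(fit["I(x1 * x2)", "Pr(>|t|)"]), tolerance = 1e-10)
  expect_equal(r$df, 100 - 6)

  ## additive + dominance but no interaction: beta12 near zero
  y2 <- 0.5 * x1 + 0.7 * (x2 == 1) + rnorm(100, sd = 0.05)
  expect_lt(abs(epistasis_test_dominance(x1, x2, y2)$beta12), 0.1)

  ## no heterozygotes in x1 -> fallback to the additive epistasis model
  x1h <- rep(c(0, 2), 50)
  rf <- epistasis_test_dominance(x1h, x2, y)
  expect_match(rf$note, "fell back")
  expect_equal(rf$p_value, epistasis_test(x1h, x2, y)$p_value)
})

test_that("Hardy-Weinberg chi-square test matches expected-count algebra", {
  expect_equal(hwe_test(25, 50, 25), 1)
  ## no heterozygotes at p = 0.5: chi-square equals n
  expect_equal(hwe_test(50, 0, 50), pchisq(100, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(hwe_test(10, 0, 0), 1)   # monomorphic
})
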