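test_that("per-sample centering removes array means and respects missingness", {
  e <- expression_matrix(matrix(c(1, 2, 3,   5, NA, 7), nrow = 3,
                                dimnames = list(paste0("t", 1:3), c("s1", "s2"))))
  ce <- center_samples(e)
  expect_equal(unname(ce$values[, "s1"]), c(-1, 0, 1))
  expect_equal(unname(ce$values[, "s2"]), c(-1, NA, 1))
  ## idempotence on an already-centered matrix
  expect_equal(center_samples(ce)$values, ce$values)

  e2 <- expression_matrix(matrix(c(1, 2, NA, NA), 2))
  expect_error(center_samples(e2), "no non-missing")
})

test_that("trait missingness filter is inclusive at the threshold", {
  v <- rbind(rep(1, 10),
             c(rep(1, 8), NA, NA),
             c(rep(1, 9), NA))
  e <- expression_matrix(v, trait_ids = c("full", "eight", "nine"))
  kept <- filter_traits_yeast(e, 0.9)$trait_ids
  expect_setequal(kept, c("full", "nine"))
})

test_that("normal quantile transform matches the inverse-normal oracle", {
  expect_equal(normal_quantile_transform(7.3), 0)   # qnorm(0.5)
  expect_equal(normal_quantile_transform(c(1, 2, 3)),
               qnorm(c(0.5, 1.5, 2.5) / 3))
  ## m = 2 non-missing, then the missing slot becomes 0
  expect_equal(normal_quantile_transform(c(5, NA, 9)),
               c(qnorm(0.25), 0, qnorm(0.75)))
  expect_error(normal_quantile_transform(c(NA_real_, NA)), "all-missing")
  ## Blom convention via the offset argument
  expect_equal(normal_quantile_transform(1:4, offset = 3/8),
               qnorm(((1:4) - 3/8) / (4 + 1/4)))
})

test_that("transformed traits share one value multiset, zero mean, antisymmetry", {
  set.seed(42)
  for (i in 1:20) {
    a <- rnorm(50); b <- rexp(50)
    ta <- normal_quantile_transform(a)
    tb <- normal_quantile_transform(b)
    expect_equal(sort(ta), sort(tb))            # shared template
    expect_equal(mean(ta), 0, tolerance = 1e-12)
    expect_equal(normal_quantile_transform(-a), -ta)   # rank reversal
  }
  expect_equal(sort(normal_quantile_transform(rnorm(30))), nqt_template(30))
})

test_that("MAF filtering is strict and idempotent", {
  ## diploid counts AA=50, Aa=40, aa=10 -> allele freq 0.3
  x <- c(rep(0, 50), rep(1, 40), rep(2, 10))
  g <- genotype_matrix(cbind(a = x), "diploid")
  expect_equal(unname(snp_maf(g)), 0.3)
  expect_equal(n_snps(filter_snps_maf(g, 0.20)), 1L)

  ## haploid boundary: MAF exactly 0.05 is dropped at maf_min = 0.05
  h <- genotype_matrix(cbind(a = c(rep(0, 95), rep(1, 5)),
                             b = rep(0, 100)), "haploid")
  expect_equal(unname(snp_maf(h)), c(0.05, 0))
  expect_equal(n_snps(filter_snps_maf(h, 0.05)), 0L)
  expect_equal(n_snps(filter_snps_maf(h, 0.04)), 1L)

  g2 <- rand_geno(80, 20, "diploid")
  once <- filter_snps_maf(g2, 0.25)
  twice <- filter_snps_maf(once, 0.25)
  expect_identical(once$values, twice$values)
})

test_that("human trait selection applies mean, SD and association-count filters", {
  ## mean filter: grand mean of (1, 3) is 2 -> only trait 2 passes
  e <- expression_matrix(rbind(rep(1, 6) + 0.6 * scale(rnorm(6))[, 1],
                               rep(3, 6) + 0.6 * scale(rnorm(6))[, 1]),
                         trait_ids = c("low", "high"))
  mp <- matrix(1, 2, 5)
  kept <- select_traits_human(e, mp, preprocess_config(marginal_count_p = 1e-5))
  expect_equal(kept$trait_ids, "high")

  ## SD boundary: exactly 0.5 passes
  v <- scale(rnorm(20))[, 1] * 0.5 + 10
  e2 <- expression_matrix(rbind(v, rep(0, 20)), trait_ids = c("sd05", "flat"))
  k2 <- select_traits_human(e2, matrix(1, 2, 3), preprocess_config())
  expect_equal(k2$trait_ids, "sd05")

  ## association counts (0, 3, 9) among mean/SD survivors: average 4 ->
  ## only the 9-count trait
  base <- scale(rnorm(12))[, 1] + 5
  e3 <- expression_matrix(rbind(base, base + 0.01, base - 0.01,
                                scale(rnorm(12))[, 1]),
                          trait_ids = c("c0", "c3", "c9", "low"))
  mp3 <- matrix(1, 4, 10)
  mp3[2, 1:3] <- 1e-8
  mp3[3, 1:9] <- 1e-8
  mp3[4, ] <- 1e-8   # high count but fails the mean filter
  k3 <- select_traits_human(e3, mp3, preprocess_config())
  expect_equal(k3$trait_ids, "c9")
})

test_that("SNP-gene mapping extends gene bodies and excludes multi-gene SNPs", {
  ## boundary arithmetic: pos 500 is exactly at start - window of [1000, 2000]
  g <- genotype_matrix(matrix(rbinom(9, 1, 0.5), 3),
                       "haploid",
                       snp_ids = c("edge", "far", "offchrom"),
                       chrom = c("1", "1", "2"),
                       pos = c(500L, 10000L, 1500L))
  genes <- data.frame(gene_id = "G1", chrom = "1", start = 1000L, end = 2000L)
  map <- map_snps_to_genes(g, genes, window_bp = 1000L)
  expect_equal(map$gene_id[map$snp_id == "edge"], "G1")
  expect_false("far" %in% map$snp_id)      # beyond end + window
  expect_false("offchrom" %in% map$snp_id) # other chromosome

  ## multi-gene exclusion with overlapping extended bodies
  g2 <- genotype_matrix(matrix(rbinom(6, 1, 0.5), 3),
                        "haploid", snp_ids = c("unique", "multi"),
                        chrom = c("1", "1"), pos = c(1200L, 1900L))
  genes2 <- data.frame(gene_id = c("G1", "G2"), chrom = c("1", "1"),
                       start = c(1000L, 1800L), end = c(2000L, 2600L))
  map2 <- map_snps_to_genes(g2, genes2, window_bp = 100L)
  expect_equal(map2$gene_id[map2$snp_id == "unique"], "G1")
  expect_false("multi" %in% map2$snp_id)
})
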