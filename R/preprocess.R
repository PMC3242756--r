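## Trait and SNP filtering, normalization, quantile transformation and
## SNP-to-gene mapping.

#' Preprocessing configuration
#'
#' @param min_nonmissing_frac minimum fraction of non-missing values a
#'   trait must have to be kept (yeast-style filter; default 0.90).
#' @param maf_min minor-allele-frequency floor; SNPs with MAF strictly
#'   greater than this are kept.
#' @param sd_min minimum trait standard deviation (human-style trait
#'   selection; default 0.5, inclusive).
#' @param marginal_count_p p-value defining a "marginal association"
#'   when counting associations per trait (default 1e-5).
#' @param gene_window_bp bp added on both sides of a gene body when
#'   mapping SNPs to genes (default 1000).
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(min_nonmissing_frac = 0.90, maf_min = 0.20,
                              sd_min = 0.5, marginal_count_p = 1e-5,
                              gene_window_bp = 1000L) {
  stopifnot(min_nonmissing_frac >= 0, min_nonmissing_frac <= 1,
            maf_min >= 0, maf_min < 0.5, sd_min >= 0, gene_window_bp >= 0)
  structure(list(min_nonmissing_frac = min_nonmissing_frac,
                 maf_min = maf_min, sd_min = sd_min,
                 marginal_count_p = marginal_count_p,
                 gene_window_bp = as.integer(gene_window_bp)),
            class = "preprocess_config")
}

#' Center each sample (array) at its mean
#'
#' Subtracts from every sample column its mean over non-missing entries,
#' emulating per-array mean normalization.  Missing entries stay
#' missing.
#'
#' @param e an [expression_matrix()].
#' @return the centered `expression_matrix`.
#' @export
center_samples <- function(e) {
  v <- e$values
  nn <- colSums(!is.na(v))
  if (any(nn == 0)) {
    stop("sample(s) with no non-missing expression values: ",
         paste(e$sample_ids[nn == 0], collapse = ", "))
  }
  mu <- colMeans(v, na.rm = TRUE)
  e$values <- sweep(v, 2, mu, `-`)
  e
}

#' Drop traits with too many missing values
#'
#' Keeps traits whose fraction of non-missing values is at least
#' `min_nonmissing_frac` (inclusive).
#'
#' @param e an [expression_matrix()].
#' @param min_nonmissing_frac threshold in `[0, 1]`.
#' @return the filtered `expression_matrix`.
#' @export
filter_traits_yeast <- function(e, min_nonmissing_frac = 0.90) {
  frac <- rowMeans(!is.na(e$values))
  keep <- frac >= min_nonmissing_frac
  es_log("filter_traits_yeast: kept %d / %d traits", sum(keep), length(keep))
  expression_matrix(e$values[keep, , drop = FALSE],
                    trait_ids = e$trait_ids[keep],
                    sample_ids = e$sample_ids,
                    trait_gene = e$trait_gene[keep])
}

#' Rank-based inverse normal (quantile) transform
#'
#' Non-missing values are replaced by `qnorm((r - offset) / (m - 2*offset + 1))`
#' where `r` is the 1-based ascending rank (ties averaged) and `m` the
#' number of non-missing values; with the default `offset = 0.5` this is
#' `qnorm((r - 0.5) / m)`.  Missing values are then set to 0 (the
#' transformed median), so that after transformation every trait with
#' the same `m` carries the identical value multiset — the property that
#' lets one permutation set serve as the null for all traits.
#'
#' @param v numeric vector, missing allowed.
#' @param offset rank offset; 0.5 gives the `(r - 0.5)/m` convention,
#'   3/8 the Blom convention.
#' @return transformed numeric vector of the same length.
#' @export
normal_quantile_transform <- function(v, offset = 0.5) {
  ok <- !is.na(v)
  m <- sum(ok)
  if (m == 0) stop("cannot quantile-transform an all-missing vector")
  r <- rank(v[ok], ties.method = "average")
  out <- numeric(length(v))
  out[ok] <- stats::qnorm((r - offset) / (m - 2 * offset + 1))
  out[!ok] <- 0
  out
}

#' Quantile-transform every trait of an expression matrix
#'
#' @param e an [expression_matrix()].
#' @param offset see [normal_quantile_transform()].
#' @return the transformed `expression_matrix` (no missing values).
#' @export
transform_expression <- function(e, offset = 0.5) {
  e$values <- t(apply(e$values, 1, normal_quantile_transform, offset = offset))
  dimnames(e$values) <- list(e$trait_ids, e$sample_ids)
  e
}

#' Shared post-transform phenotype template
#'
#' The sorted value vector every fully observed quantile-transformed
#' trait consists of: `qnorm(((1:n) - offset) / (n - 2*offset + 1))`.
#'
#' @param n number of samples.
#' @param offset see [normal_quantile_transform()].
#' @return numeric vector of length `n`.
#' @export
nqt_template <- function(n, offset = 0.5) {
  stats::qnorm((seq_len(n) - offset) / (n - 2 * offset + 1))
}

#' Per-SNP minor allele frequency
#'
#' Allele frequency is the mean genotype over non-missing calls divided
#' by the homozygote dose (1 haploid, 2 diploid), folded to `<= 0.5`.
#'
#' @param g a [genotype_matrix()].
#' @return numeric vector of MAFs (NaN for all-missing SNPs).
#' @export
snp_maf <- function(g) {
  f <- colMeans(g$values, na.rm = TRUE) / ploidy_dose(g)
  pmin(f, 1 - f)
}

#' Drop SNPs at or below a minor-allele-frequency floor
#'
#' Keeps SNPs with MAF strictly greater than `maf_min`.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min MAF floor (strict inequality).
#' @return the filtered `genotype_matrix`.
#' @export
filter_snps_maf <- function(g, maf_min) {
  maf <- snp_maf(g)
  keep <- !is.na(maf) & maf > maf_min
  es_log("filter_snps_maf: kept %d / %d SNPs at MAF > %g",
         sum(keep), length(keep), maf_min)
  genotype_matrix(g$values[, keep, drop = FALSE], ploidy = g$ploidy,
                  snp_ids = g$snp_ids[keep], sample_ids = g$sample_ids,
                  chrom = g$chrom[keep], pos = g$pos[keep])
}

#' Select expressed, variable, moderately associated traits
#'
#' Keeps traits passing all of: (1) trait mean above the grand mean of
#' trait means; (2) trait standard deviation at least `sd_min`;
#' (3) among traits surviving (1) and (2), a count of marginal
#' associations (`p < marginal_count_p` across SNPs) at least the
#' average such count.
#'
#' @param e an [expression_matrix()].
#' @param marginal_p traits x SNPs matrix of marginal-test p-values,
#'   row-aligned with `e`.
#' @param cfg a [preprocess_config()].
#' @return the selected `expression_matrix`.
#' @export
select_traits_human <- function(e, marginal_p, cfg = preprocess_config()) {
  if (nrow(marginal_p) != nrow(e$values)) {
    stop("marginal_p must have one row per trait")
  }
  mu <- rowMeans(e$values, na.rm = TRUE)
  sds <- apply(e$values, 1, stats::sd, na.rm = TRUE)
  surv <- mu > mean(mu) & sds >= cfg$sd_min
  cnt <- rowSums(marginal_p < cfg$marginal_count_p, na.rm = TRUE)
  keep <- surv & cnt >= mean(cnt[surv])
  if (!any(surv)) keep <- surv
  es_log("select_traits_human: kept %d / %d traits", sum(keep), length(keep))
  expression_matrix(e$values[keep, , drop = FALSE],
                    trait_ids = e$trait_ids[keep],
                    sample_ids = e$sample_ids,
                    trait_gene = e$trait_gene[keep])
}

#' Map SNPs to single genes by position
#'
#' A SNP maps to a gene when its position falls within the gene body
#' extended by `window_bp` on both sides (1-based closed intervals, same
#' chromosome).  SNPs overlapping two or more genes are excluded; SNPs
#' overlapping none are absent from the map.
#'
#' @param g a [genotype_matrix()] carrying `chrom` and `pos`.
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`,
#'   `end` (1-based, closed, `start <= end`).
#' @param window_bp bp extension on each side (default 1000).
#' @return data.frame of class `snp_gene_map` with columns `snp_id`,
#'   `gene_id`, one row per uniquely mapped SNP.
#' @export
map_snps_to_genes <- function(g, genes, window_bp = 1000L) {
  if (is.null(g$chrom) || is.null(g$pos)) {
    stop("genotype matrix lacks chrom/pos metadata needed for mapping")
  }
  if (any(genes$start > genes$end)) stop("gene intervals with start > end")
  snps <- GenomicRanges::GRanges(as.character(g$chrom),
                                 IRanges::IRanges(g$pos, g$pos))
  ext <- GenomicRanges::GRanges(as.character(genes$chrom),
                                IRanges::IRanges(pmax(1L, genes$start - window_bp),
                                                 genes$end + window_bp))
  nhit <- GenomicRanges::countOverlaps(snps, ext)
  ov <- GenomicRanges::findOverlaps(snps, ext)
  one <- which(nhit == 1)
  keep <- S4Vectors::queryHits(ov) %in% one
  map <- data.frame(snp_id = g$snp_ids[S4Vectors::queryHits(ov)[keep]],
                    gene_id = as.character(genes$gene_id)[S4Vectors::subjectHits(ov)[keep]],
                    stringsAsFactors = FALSE)
  es_log("map_snps_to_genes: %d mapped, %d excluded as multi-gene, %d unmapped",
         nrow(map), sum(nhit > 1), sum(nhit == 0))
  class(map) <- c("snp_gene_map", "data.frame")
  map
}
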