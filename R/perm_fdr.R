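## Shared-permutation null construction, quantile cutoffs and FDR
## estimation.
##
## Because every quantile-transformed trait carries the identical value
## multiset, the null distribution of the per-trait minimum p-value is
## built once, from K permutations of the shared template vector, and
## reused for every trait.

#' Generate a reproducible set of phenotype permutations
#'
#' @param n number of samples.
#' @param K number of permutations.
#' @param seed RNG seed; the same seed yields the identical set.
#' @return object of class `permutation_set`: list with `perms`
#'   (K x n integer matrix, each row a permutation of `1:n`), `n`,
#'   `K`, `seed`.
#' @export
make_permutations <- function(n, K, seed = 1L) {
  stopifnot(n >= 2, K >= 1)
  perms <- with_seed(seed, {
    m <- matrix(0L, nrow = K, ncol = n)
    for (k in seq_len(K)) m[k, ] <- sample.int(n)
    m
  })
  structure(list(perms = perms, n = as.integer(n), K = as.integer(K),
                 seed = seed), class = "permutation_set")
}

#' Per-strategy minimum p-value for one phenotype
#'
#' Applies the strategy to the phenotype (MM/MG rebuild their subset
#' from a fresh marginal scan of this phenotype; ALL/ST and the control
#' strategies use their fixed, phenotype-independent subset supplied in
#' `context`), runs the epistasis scan over the subset and returns the
#' minimum p-value.
#'
#' @param g a [genotype_matrix()].
#' @param y phenotype vector (typically quantile-transformed).
#' @param cfg a [strategy_config()].
#' @param context list with, as needed: `subset` (a [pair_subset()],
#'   for ALL/ST/MM0/MG0/ST0; for ALL it defaults to all pairs).
#' @return list with `min_p` and `n_pairs`.
#' @export
strategy_min_p <- function(g, y, cfg, context = list()) {
  sub <- switch(cfg$kind,
    MM = mm_subset(marginal_scan(g, y)$p_value, cfg),
    MG = mg_subset(marginal_scan(g, y)$p_value, cfg, n_snps = n_snps(g)),
    {
      s <- context$subset
      if (is.null(s)) {
        if (cfg$kind == "ALL") s <- all_pairs(n_snps(g)) else
          stop("strategy ", cfg$kind, " needs a fixed subset in context$subset")
      }
      s
    })
  pm <- .as_pair_matrix(sub)
  mp <- if (nrow(pm) == 0) 1.0 else
    epi_scan_min_p_cpp(g$values, as.numeric(y), pm)
  list(min_p = mp, n_pairs = nrow(pm))
}

#' Null distribution of the minimum p-value under shared permutations
#'
#' For each permutation the shared template vector is reordered, the
#' strategy is re-applied to this permuted phenotype (a fresh marginal
#' scan and subset for MM/MG; the fixed subset for ALL/ST and the
#' controls) and the minimum interaction p-value over the resulting
#' subset is recorded.  An empty subset in a permutation contributes
#' 1.0.  The K values serve as the null for every quantile-transformed
#' trait.
#'
#' @param g a [genotype_matrix()].
#' @param cfg a [strategy_config()].
#' @param perms a [make_permutations()] set over the sample count.
#' @param template the shared post-transform value vector, see
#'   [nqt_template()].
#' @param context see [strategy_min_p()].
#' @return numeric vector of K null minimum p-values in `[0, 1]`.
#' @export
null_min_p <- function(g, cfg, perms, template, context = list()) {
  if (length(template) != n_samples(g)) {
    stop("template length must equal the sample count")
  }
  if (perms$n != n_samples(g)) stop("permutation set built for a different n")
  vapply(seq_len(perms$K), function(k) {
    strategy_min_p(g, template[perms$perms[k, ]], cfg, context)$min_p
  }, numeric(1))
}

#' Quantile cutoff from the permutation null
#'
#' Returns the r-th smallest null value, where r is `round(q * K)`; the
#' convention under which q = 0.001 with K = 10,000 and q = 0.01 with
#' K = 1,000 both select the 10th smallest value.
#'
#' @param null_values numeric vector of K null minimum p-values.
#' @param q quantile level in `(0, 1]` with `q * K >= 1`.
#' @return the cutoff p-value.
#' @export
quantile_cutoff <- function(null_values, q) {
  K <- length(null_values)
  stopifnot(q > 0, q <= 1)
  r <- round(q * K)
  if (r < 1) stop("insufficient permutations: q * K < 1")
  sort(null_values)[r]
}

#' Count traits with at least one significant interaction
#'
#' @param observed_min_p per-trait observed minimum p-values.
#' @param cutoff p-value cutoff (inclusive `<=`).
#' @return integer hit count.
#' @export
count_hits <- function(observed_min_p, cutoff) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  sum(observed_min_p <= cutoff, na.rm = TRUE)
}

#' Expected-false-positives FDR estimate
#'
#' The cutoff is chosen so that `q * n_traits` traits are expected to
#' pass under the null; the FDR estimate is that expectation divided by
#' the observed hit count, capped at 1.  Undefined (NA) when there are
#' no hits.
#'
#' @param q quantile level used for the cutoff.
#' @param n_traits number of traits scanned.
#' @param hits observed hit count.
#' @return list of class `fdr_estimate`: `q`, `n_traits`, `hits`,
#'   `expected_fp`, `fdr`.
#' @export
estimate_fdr <- function(q, n_traits, hits) {
  stopifnot(hits >= 0)
  expected_fp <- q * n_traits
  fdr <- if (hits == 0) NA_real_ else min(1, expected_fp / hits)
  structure(list(q = q, n_traits = n_traits, hits = hits,
                 expected_fp = expected_fp, fdr = fdr),
            class = "fdr_estimate")
}

#' Significance of a strategy relative to its random controls
#'
#' The proportion of control strategies with FDR as low or lower than
#' the candidate's.  Undefined control FDRs (no hits) count as 1.0 so
#' the candidate is never unfairly favored; an undefined candidate FDR
#' returns NA.
#'
#' @param strategy_fdr the candidate strategy's FDR estimate.
#' @param control_fdrs vector of control-strategy FDR estimates.
#' @return proportion in `[0, 1]`.
#' @export
compare_to_controls <- function(strategy_fdr, control_fdrs) {
  if (length(control_fdrs) < 1) stop("need at least one control FDR")
  if (is.na(strategy_fdr)) {
    es_log("compare_to_controls: candidate FDR undefined (no hits)")
    return(NA_real_)
  }
  control_fdrs[is.na(control_fdrs)] <- 1.0
  mean(control_fdrs <= strategy_fdr)
}

#' FDR along a grid of quantile levels
#'
#' @param observed_min_p per-trait observed minimum p-values.
#' @param null_values permutation null minimum p-values.
#' @param q_grid quantile levels, each with `q * K >= 1`.
#' @return data.frame with columns `q`, `cutoff`, `hits`,
#'   `expected_fp`, `fdr`.
#' @export
fdr_curve <- function(observed_min_p, null_values, q_grid) {
  rows <- lapply(q_grid, function(q) {
    cutoff <- quantile_cutoff(null_values, q)
    hits <- count_hits(observed_min_p, cutoff)
    est <- estimate_fdr(q, length(observed_min_p), hits)
    data.frame(q = q, cutoff = cutoff, hits = hits,
               expected_fp = est$expected_fp, fdr = est$fdr)
  })
  do.call(rbind, rows)
}

#' Full strategy evaluation: observed min-p, shared null, cutoff, FDR
#'
#' Quantile-transforms every trait (optional), computes each trait's
#' observed minimum interaction p-value under the strategy, builds the
#' shared permutation null from the common template, applies the
#' quantile cutoff and estimates the FDR.
#'
#' @param g a [genotype_matrix()].
#' @param e an [expression_matrix()] over the same samples.
#' @param cfg a [strategy_config()].
#' @param K number of permutations.
#' @param q quantile level for the cutoff.
#' @param seed RNG seed for the permutation set.
#' @param context see [strategy_min_p()].
#' @param transform quantile-transform traits first (default TRUE).
#' @return object of class `fdr_report`: list with `q`, `cutoff`,
#'   `n_traits`, `hits`, `expected_fp`, `fdr`, `observed_min_p`,
#'   `null_min_p`, `cfg`.
#' @export
fdr_report <- function(g, e, cfg, K = 1000, q = 0.001, seed = 1L,
                       context = list(), transform = TRUE) {
  if (!identical(g$sample_ids, e$sample_ids)) {
    stop("samples not aligned; run align_samples() first")
  }
  if (transform) e <- transform_expression(e)
  n <- n_samples(g)
  template <- nqt_template(n)
  perms <- make_permutations(n, K, seed)
  es_log("fdr_report: strategy %s, %d traits, %d SNPs, K = %d",
         cfg$kind, nrow(e$values), n_snps(g), K)
  null <- null_min_p(g, cfg, perms, template, context)
  observed <- vapply(seq_len(nrow(e$values)), function(t) {
    strategy_min_p(g, e$values[t, ], cfg, context)$min_p
  }, numeric(1))
  names(observed) <- e$trait_ids
  cutoff <- quantile_cutoff(null, q)
  hits <- count_hits(observed, cutoff)
  est <- estimate_fdr(q, length(observed), hits)
  structure(list(q = q, cutoff = cutoff, n_traits = length(observed),
                 hits = hits, expected_fp = est$expected_fp, fdr = est$fdr,
                 observed_min_p = observed, null_min_p = null, cfg = cfg),
            class = "fdr_report")
}

#' @export
print.fdr_report <- function(x, ...) {
  cat(sprintf("fdr_report (%s): %d traits, cutoff %.3g (q = %g)\n",
              x$cfg$kind, x$n_traits, x$cutoff, x$q))
  cat(sprintf("  hits %d, expected FP %.3g, FDR %s\n", x$hits, x$expected_fp,
              if (is.na(x$fdr)) "undefined (no hits)" else sprintf("%.3f", x$fdr)))
  invisible(x)
}
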