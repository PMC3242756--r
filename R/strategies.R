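## SNP-pair subset strategies: MM (both SNPs marginally associated),
## MG (at least one marginally associated), ST (genes connected in a
## protein-interaction network), their matched random controls
## (MM0/MG0/ST0) and the exhaustive all-pairs baseline.

#' Strategy configuration
#'
#' @param kind one of `"MM"`, `"MG"`, `"ST"`, `"MM0"`, `"MG0"`,
#'   `"ST0"`, `"ALL"`.
#' @param marginal_threshold p-value cutoff defining "marginally
#'   associated" (inclusive `<=`); exactly one of this and `top_k` for
#'   MM/MG/MM0/MG0.
#' @param top_k alternative parameterization: the k SNPs with smallest
#'   marginal p (ties broken by ascending SNP index).
#' @param string_score_min network-score floor for ST (strict `>`).
#' @param n_control_pairs target SNP-pair count for ST0 size-matching.
#' @param seed RNG seed for the control strategies.
#' @return a list of class `strategy_config`.
#' @export
strategy_config <- function(kind = c("MM", "MG", "ST", "MM0", "MG0", "ST0", "ALL"),
                            marginal_threshold = NULL, top_k = NULL,
                            string_score_min = NULL, n_control_pairs = NULL,
                            seed = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("MM", "MG", "MM0", "MG0")) {
    if (is.null(marginal_threshold) == is.null(top_k)) {
      stop("exactly one of marginal_threshold / top_k must be set for ", kind)
    }
  }
  if (kind == "ST" && is.null(string_score_min)) {
    stop("string_score_min must be set for ST")
  }
  structure(list(kind = kind, marginal_threshold = marginal_threshold,
                 top_k = top_k, string_score_min = string_score_min,
                 n_control_pairs = n_control_pairs, seed = seed),
            class = "strategy_config")
}

#' Construct a SNP-pair subset
#'
#' Pairs are stored with the smaller index first, deduplicated and
#' sorted; self-pairs are an error.
#'
#' @param pairs 2-column matrix of SNP indices (may have 0 rows).
#' @param provenance optional [strategy_config()] recording how the
#'   subset was built.
#' @return an object of class `pair_subset` with elements `pairs`
#'   (integer matrix, columns `i`, `j`) and `provenance`.
#' @export
pair_subset <- function(pairs, provenance = NULL) {
  pairs <- as.matrix(pairs)
  if (length(pairs) == 0) {
    pairs <- matrix(integer(0), ncol = 2)
  } else {
    storage.mode(pairs) <- "integer"
    if (ncol(pairs) != 2) stop("pairs must have two columns")
    if (any(pairs[, 1] == pairs[, 2])) stop("self-pairs are not allowed")
    if (any(pairs < 1)) stop("pair indices must be positive")
    swap <- pairs[, 1] > pairs[, 2]
    if (any(swap)) pairs[swap, ] <- pairs[swap, 2:1]
    pairs <- unique(pairs)
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  }
  colnames(pairs) <- c("i", "j")
  structure(list(pairs = pairs, provenance = provenance), class = "pair_subset")
}

#' @export
print.pair_subset <- function(x, ...) {
  kind <- if (!is.null(x$provenance)) x$provenance$kind else "?"
  cat(sprintf("pair_subset: %d SNP pairs (strategy %s)\n", nrow(x$pairs), kind))
  invisible(x)
}

#' Number of pairs in a subset
#' @param s a `pair_subset`.
#' @return integer count.
#' @export
subset_size <- function(s) nrow(s$pairs)

#' Number of unordered pairs of n items
#'
#' Exact count `n*(n-1)/2` as a double (counts above 2^31 are
#' representable exactly well beyond genome scale).
#'
#' @param n item count.
#' @return numeric count.
#' @export
n_pairs <- function(n) as.numeric(n) * (n - 1) / 2

#' All unordered SNP pairs
#'
#' @param n_snps number of SNPs.
#' @return a [pair_subset()] with `n_pairs(n_snps)` rows.
#' @export
all_pairs <- function(n_snps) {
  if (n_snps < 2) return(pair_subset(matrix(integer(0), ncol = 2),
                                     strategy_config("ALL")))
  n <- as.integer(n_snps)
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2:n)
  pair_subset(cbind(i, j), strategy_config("ALL"))
}

#' SNPs selected by a marginal-association criterion
#' @noRd
marginal_snp_set <- function(marginal_p, cfg) {
  if (!is.null(cfg$marginal_threshold)) {
    s <- which(!is.na(marginal_p) & marginal_p <= cfg$marginal_threshold)
  } else {
    k <- min(cfg$top_k, sum(!is.na(marginal_p)))
    s <- order(marginal_p, na.last = TRUE)[seq_len(k)]   # stable: ties by index
  }
  sort(s)
}

#' Marginal-by-marginal (MM) pair subset
#'
#' All pairs within the set S of marginally associated SNPs (both ends
#' in S).
#'
#' @param marginal_p per-SNP marginal p-values (index-aligned with the
#'   genotype matrix).
#' @param cfg a [strategy_config()] carrying `marginal_threshold` or
#'   `top_k`.
#' @return a [pair_subset()].
#' @export
mm_subset <- function(marginal_p, cfg) {
  s <- marginal_snp_set(marginal_p, cfg)
  if (length(s) < 2) {
    es_log("mm_subset: |S| = %d, empty subset", length(s))
    return(pair_subset(matrix(integer(0), ncol = 2), cfg))
  }
  ap <- all_pairs(length(s))$pairs
  pair_subset(cbind(s[ap[, 1]], s[ap[, 2]]), cfg)
}

#' Marginal-by-genomewide (MG) pair subset
#'
#' All pairs with at least one end in the set S of marginally
#' associated SNPs; always a superset of the MM subset at equal
#' configuration.
#'
#' @inheritParams mm_subset
#' @param n_snps total number of SNPs.
#' @return a [pair_subset()].
#' @export
mg_subset <- function(marginal_p, cfg, n_snps = length(marginal_p)) {
  s <- marginal_snp_set(marginal_p, cfg)
  if (length(s) == 0 || n_snps < 2) {
    return(pair_subset(matrix(integer(0), ncol = 2), cfg))
  }
  within <- if (length(s) >= 2) {
    ap <- all_pairs(length(s))$pairs
    cbind(s[ap[, 1]], s[ap[, 2]])
  } else matrix(integer(0), ncol = 2)
  others <- setdiff(seq_len(n_snps), s)
  cross <- if (length(others)) {
    cbind(rep(s, each = length(others)), rep(others, times = length(s)))
  } else matrix(integer(0), ncol = 2)
  pair_subset(rbind(within, cross), cfg)
}

#' Network (ST) pair subset
#'
#' For every network edge with score strictly above `score_min`, all
#' SNP pairs with one SNP mapped to each endpoint gene; union over
#' edges, deduplicated.  Trait-independent.
#'
#' @param net an `interaction_network` (see [read_network()]).
#' @param map a `snp_gene_map` (see [map_snps_to_genes()]).
#' @param score_min score floor (strict `>`).
#' @param snp_ids SNP identifiers defining pair indices (the genotype
#'   matrix column order).
#' @return a [pair_subset()].
#' @export
st_subset <- function(net, map, score_min, snp_ids) {
  cfg <- strategy_config("ST", string_score_min = score_min)
  keep <- net$score > score_min
  idx <- match(map$snp_id, snp_ids)
  ok <- !is.na(idx)
  by_gene <- split(idx[ok], map$gene_id[ok])
  out <- vector("list", sum(keep))
  kk <- which(keep)
  for (q in seq_along(kk)) {
    e <- kk[q]
    sa <- by_gene[[net$gene_a[e]]]
    sb <- by_gene[[net$gene_b[e]]]
    if (is.null(sa) || is.null(sb)) next
    out[[q]] <- cbind(rep(sa, each = length(sb)), rep(sb, times = length(sa)))
  }
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0) {
    return(pair_subset(matrix(integer(0), ncol = 2), cfg))
  }
  pair_subset(out, cfg)
}

#' Matched random control subsets (MM0, MG0, ST0)
#'
#' Controls discard the information the candidate strategy uses while
#' keeping its multiplicity: MM0/MG0 run the marginal scan against a
#' freshly drawn standard-normal phenotype and apply the same
#' threshold/top-k rule; ST0 draws gene pairs uniformly (without
#' replacement) from unordered pairs of network nodes — ignoring the
#' edges — until the mapped SNP-pair count first reaches
#' `target_pairs`, then maps them to SNP pairs.  Controls depend only
#' on the seed, never on the measured phenotypes.
#'
#' @param kind `"MM0"`, `"MG0"` or `"ST0"`.
#' @param cfg the candidate strategy's [strategy_config()] (threshold /
#'   top_k reused for MM0/MG0).
#' @param g a [genotype_matrix()] (MM0/MG0).
#' @param net,map,snp_ids network context (ST0), as in [st_subset()].
#' @param target_pairs SNP-pair count to match (ST0), typically
#'   `subset_size(st_subset(...))`.
#' @param seed RNG seed; same seed, same subset.
#' @return a [pair_subset()].
#' @export
control_subset <- function(kind = c("MM0", "MG0", "ST0"), cfg, g = NULL,
                           net = NULL, map = NULL, snp_ids = NULL,
                           target_pairs = NULL, seed = 1L) {
  kind <- match.arg(kind)
  ccfg <- strategy_config(kind,
                          marginal_threshold = cfg$marginal_threshold,
                          top_k = cfg$top_k,
                          n_control_pairs = target_pairs, seed = seed)
  if (kind %in% c("MM0", "MG0")) {
    if (is.null(g)) stop("MM0/MG0 controls need the genotype matrix")
    y0 <- with_seed(seed, stats::rnorm(n_samples(g)))
    mp <- marginal_scan(g, y0)$p_value
    sub <- if (kind == "MM0") mm_subset(mp, ccfg) else
      mg_subset(mp, ccfg, n_snps = n_snps(g))
    sub$provenance <- ccfg
    return(sub)
  }
  ## ST0
  if (is.null(net) || is.null(map) || is.null(snp_ids) || is.null(target_pairs)) {
    stop("ST0 controls need net, map, snp_ids and target_pairs")
  }
  nodes <- network_nodes(net)
  m <- length(nodes)
  if (m < 2) return(pair_subset(matrix(integer(0), ncol = 2), ccfg))
  gp <- all_pairs(m)$pairs
  ord <- with_seed(seed, sample.int(nrow(gp)))
  idx <- match(map$snp_id, snp_ids)
  ok <- !is.na(idx)
  by_gene <- split(idx[ok], map$gene_id[ok])
  acc <- list(); total <- 0; used <- 0
  for (r in ord) {
    used <- used + 1
    sa <- by_gene[[nodes[gp[r, 1]]]]
    sb <- by_gene[[nodes[gp[r, 2]]]]
    if (is.null(sa) || is.null(sb)) next
    acc[[length(acc) + 1]] <- cbind(rep(sa, each = length(sb)),
                                    rep(sb, times = length(sa)))
    total <- total + length(sa) * length(sb)
    if (total >= target_pairs) break
  }
  if (total < target_pairs) {
    warning("ST0: only ", total, " SNP pairs available for a target of ",
            target_pairs, "; using all")
  }
  pm <- do.call(rbind, acc)
  if (is.null(pm)) pm <- matrix(integer(0), ncol = 2)
  pair_subset(pm, ccfg)
}
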