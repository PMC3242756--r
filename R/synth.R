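## Synthetic genotypes, phenotypes, gene maps and networks with known
## ground truth.
##
## Haploid mode emulates a two-parent cross: each individual's genotype
## row is a two-state Markov chain along the marker order, switching
## parental origin between adjacent markers with probability
## `recomb_prob` — block LD with a single knob.  Diploid mode draws
## per-SNP allele frequencies uniformly from `maf_range` and genotypes
## Binomial(2, f) under Hardy-Weinberg, independent across SNPs.

#' Simulation configuration
#'
#' @param n_individuals sample count (default 112, a typical cross
#'   panel).
#' @param n_snps marker count.
#' @param ploidy `"haploid"` or `"diploid"`.
#' @param recomb_prob per-adjacent-marker switch probability in
#'   `[0, 0.5]` (haploid LD knob).
#' @param maf_range allele-frequency range for diploid draws.
#' @param n_traits number of expression traits.
#' @param marginal_effects data.frame (`trait`, `snp`, `beta`) of
#'   planted single-SNP effects; NULL for none.
#' @param epistatic_pairs data.frame (`trait`, `snp1`, `snp2`,
#'   `beta12`) of planted interactions; NULL for none.
#' @param noise_sd residual standard deviation (> 0).
#' @param network list `n_genes`, `n_edges`, `causal_enrichment`
#'   (fraction of true epistatic gene pairs forcibly included as
#'   high-score edges).
#' @param seed RNG seed; identical configuration gives bit-identical
#'   output.  Genotypes, phenotypes and annotation use the seed with
#'   fixed offsets (0, 1, 2) so the three draws are independent.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_individuals = 112L, n_snps = 100L,
                              ploidy = c("haploid", "diploid"),
                              recomb_prob = 0.1, maf_range = c(0.2, 0.5),
                              n_traits = 100L, marginal_effects = NULL,
                              epistatic_pairs = NULL, noise_sd = 1,
                              network = list(n_genes = 20L, n_edges = 30L,
                                             causal_enrichment = 0.5),
                              seed = 1L) {
  ploidy <- match.arg(ploidy)
  stopifnot(recomb_prob >= 0, recomb_prob <= 0.5, noise_sd > 0,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  if (!is.null(marginal_effects)) {
    stopifnot(all(c("trait", "snp", "beta") %in% names(marginal_effects)),
              all(marginal_effects$snp >= 1 & marginal_effects$snp <= n_snps),
              all(marginal_effects$trait >= 1 & marginal_effects$trait <= n_traits))
  }
  if (!is.null(epistatic_pairs)) {
    stopifnot(all(c("trait", "snp1", "snp2", "beta12") %in% names(epistatic_pairs)),
              all(epistatic_pairs$snp1 >= 1 & epistatic_pairs$snp1 <= n_snps),
              all(epistatic_pairs$snp2 >= 1 & epistatic_pairs$snp2 <= n_snps),
              all(epistatic_pairs$snp1 != epistatic_pairs$snp2),
              all(epistatic_pairs$trait >= 1 & epistatic_pairs$trait <= n_traits))
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_snps = as.integer(n_snps), ploidy = ploidy,
                 recomb_prob = recomb_prob, maf_range = maf_range,
                 n_traits = as.integer(n_traits),
                 marginal_effects = marginal_effects,
                 epistatic_pairs = epistatic_pairs, noise_sd = noise_sd,
                 network = network, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate genotypes
#'
#' @param cfg a [simulation_config()].
#' @return a [genotype_matrix()] with snp ids `snp_###`, chromosome
#'   `"1"` and positions spaced 2 kb apart.
#' @export
simulate_genotypes <- function(cfg) {
  n <- cfg$n_individuals; S <- cfg$n_snps
  vals <- with_seed(cfg$seed, {
    if (cfg$ploidy == "haploid") {
      start <- stats::rbinom(n, 1, 0.5)
      if (S > 1) {
        switches <- matrix(stats::rbinom(n * (S - 1), 1, cfg$recomb_prob),
                           nrow = n)
        t(apply(cbind(start, switches), 1, cumsum)) %% 2
      } else {
        matrix(start, ncol = 1)
      }
    } else {
      f <- stats::runif(S, cfg$maf_range[1], cfg$maf_range[2])
      vapply(seq_len(S), function(j) stats::rbinom(n, 2, f[j]),
             numeric(n))
    }
  })
  vals <- matrix(as.numeric(vals), nrow = n)
  genotype_matrix(vals, ploidy = cfg$ploidy,
                  snp_ids = sprintf("snp_%04d", seq_len(S)),
                  sample_ids = sprintf("ind_%04d", seq_len(n)),
                  chrom = rep("1", S), pos = seq_len(S) * 2000L)
}

#' Simulate phenotypes with planted effects
#'
#' Each trait is the sum of its planted marginal terms `beta * x`, its
#' planted interaction terms `beta12 * x1 * x2`, and Gaussian noise;
#' traits without planted effects are pure noise (null traits).
#' Phenotypes are emitted raw (pre-transform) so the pipeline's
#' quantile transform is always exercised downstream.
#'
#' @param g a [genotype_matrix()] from [simulate_genotypes()].
#' @param cfg the same [simulation_config()].
#' @return list with `expression` (an [expression_matrix()]) and
#'   `truth` (list `marginal`, `epistatic`: the planted-effect tables).
#' @export
simulate_phenotypes <- function(g, cfg) {
  n <- n_samples(g); Tn <- cfg$n_traits
  Y <- with_seed(cfg$seed + 1L,
                 matrix(stats::rnorm(Tn * n, sd = cfg$noise_sd), nrow = Tn))
  if (!is.null(cfg$marginal_effects)) {
    me <- cfg$marginal_effects
    for (r in seq_len(nrow(me))) {
      Y[me$trait[r], ] <- Y[me$trait[r], ] + me$beta[r] * g$values[, me$snp[r]]
    }
  }
  if (!is.null(cfg$epistatic_pairs)) {
    ep <- cfg$epistatic_pairs
    for (r in seq_len(nrow(ep))) {
      Y[ep$trait[r], ] <- Y[ep$trait[r], ] +
        ep$beta12[r] * g$values[, ep$snp1[r]] * g$values[, ep$snp2[r]]
    }
  }
  e <- expression_matrix(Y, trait_ids = sprintf("trait_%04d", seq_len(Tn)),
                         sample_ids = g$sample_ids)
  list(expression = e,
       truth = list(marginal = cfg$marginal_effects,
                    epistatic = cfg$epistatic_pairs))
}

#' Simulate gene annotation: SNP-gene map, intervals and a network
#'
#' SNPs are partitioned into contiguous gene blocks (every SNP maps to
#' exactly one gene).  The network draws edges uniformly over gene
#' pairs, then forcibly includes a `causal_enrichment` fraction of the
#' true epistatic gene pairs as high-score edges.  Scores: causal edges
#' Uniform(700, 999), background Uniform(150, 699), so a score floor of
#' ~700 separates them.
#'
#' @param g a [genotype_matrix()] from [simulate_genotypes()].
#' @param cfg the same [simulation_config()].
#' @param truth optional truth list from [simulate_phenotypes()] (used
#'   for causal enrichment; omit for a signal-free network).
#' @return list with `map` (snp_gene_map), `genes` (gene interval
#'   data.frame) and `network` (interaction_network).
#' @export
simulate_annotation <- function(g, cfg, truth = NULL) {
  S <- n_snps(g); ng <- min(cfg$network$n_genes, S)  # no empty gene blocks
  stopifnot(ng >= 2)
  block <- sort(rep_len(seq_len(ng), S))          # contiguous partition
  map <- data.frame(snp_id = g$snp_ids,
                    gene_id = sprintf("gene_%03d", block),
                    stringsAsFactors = FALSE)
  class(map) <- c("snp_gene_map", "data.frame")
  genes <- do.call(rbind, lapply(seq_len(ng), function(b) {
    p <- g$pos[block == b]
    data.frame(gene_id = sprintf("gene_%03d", b), chrom = "1",
               start = min(p) - 500L, end = max(p) + 500L,
               stringsAsFactors = FALSE)
  }))
  ## causal gene pairs: genes hosting the two SNPs of a planted interaction
  causal <- NULL
  if (!is.null(truth$epistatic) && nrow(truth$epistatic) > 0) {
    ga <- block[truth$epistatic$snp1]
    gb <- block[truth$epistatic$snp2]
    keep <- ga != gb
    causal <- unique(cbind(pmin(ga[keep], gb[keep]), pmax(ga[keep], gb[keep])))
  }
  net <- with_seed(cfg$seed + 2L, {
    gp <- all_pairs(ng)$pairs
    key <- gp[, 1] * (ng + 1) + gp[, 2]
    edge_a <- integer(0); edge_b <- integer(0); score <- numeric(0)
    if (!is.null(causal) && nrow(causal) > 0 && cfg$network$causal_enrichment > 0) {
      n_in <- round(cfg$network$causal_enrichment * nrow(causal))
      if (n_in > 0) {
        pick <- sample.int(nrow(causal), n_in)
        edge_a <- causal[pick, 1]; edge_b <- causal[pick, 2]
        score <- stats::runif(n_in, 700, 999)
      }
    }
    ckey <- edge_a * (ng + 1) + edge_b
    avail <- which(!(key %in% ckey))
    n_bg <- max(0, min(cfg$network$n_edges - length(edge_a), length(avail)))
    if (n_bg > 0) {
      pick <- sample(avail, n_bg)
      edge_a <- c(edge_a, gp[pick, 1]); edge_b <- c(edge_b, gp[pick, 2])
      score <- c(score, stats::runif(n_bg, 150, 699))
    }
    interaction_network(sprintf("gene_%03d", edge_a),
                        sprintf("gene_%03d", edge_b), score)
  })
  list(map = map, genes = genes, network = net)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_phenotypes()] and [simulate_annotation()] in order.
#'
#' @param cfg a [simulation_config()].
#' @return list with `genotypes`, `expression`, `truth`, `map`,
#'   `genes`, `network`, `config`.
#' @export
simulate_dataset <- function(cfg) {
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  ann <- simulate_annotation(g, cfg, ph$truth)
  list(genotypes = g, expression = ph$expression, truth = ph$truth,
       map = ann$map, genes = ann$genes, network = ann$network, config = cfg)
}
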