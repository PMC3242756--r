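## Containers and file I/O.
##
## Genotype TSV dialect: samples as rows, SNPs as columns, header row of
## SNP ids, first column the sample id, missing coded "NA" (matches the
## PLINK .raw orientation).  Coordinates throughout the package are
## 1-based, fully closed intervals.

#' Construct a genotype matrix
#'
#' Additive-coded genotypes for `n` individuals at `S` SNPs.  Haploid
#' values are 0/1 (parental origin in a cross), diploid values 0/1/2
#' (minor-allele dose).  Missing calls are `NA`.
#'
#' @param values numeric matrix, individuals in rows, SNPs in columns.
#' @param ploidy `"haploid"` or `"diploid"`.
#' @param snp_ids,sample_ids identifiers; default to the dimnames.
#' @param chrom,pos optional per-SNP chromosome label and 1-based
#'   base-pair position.
#' @return an object of class `genotype_matrix`: a list with elements
#'   `values`, `snp_ids`, `sample_ids`, `chrom`, `pos`, `ploidy`.
#' @export
genotype_matrix <- function(values, ploidy = c("haploid", "diploid"),
                            snp_ids = colnames(values),
                            sample_ids = rownames(values),
                            chrom = NULL, pos = NULL) {
  ploidy <- match.arg(ploidy)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(snp_ids)) snp_ids <- paste0("snp_", seq_len(ncol(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(values)))
  snp_ids <- as.character(snp_ids)
  sample_ids <- as.character(sample_ids)
  if (length(snp_ids) != ncol(values)) {
    stop("length of snp_ids does not match the number of SNP columns")
  }
  if (length(sample_ids) != nrow(values)) {
    stop("length of sample_ids does not match the number of sample rows")
  }
  if (anyDuplicated(snp_ids)) {
    stop("duplicated SNP ids: ", paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample ids: ", paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  allowed <- if (ploidy == "haploid") c(0, 1) else c(0, 1, 2)
  bad <- !is.na(values) & !(values %in% allowed)
  if (any(bad)) {
    stop("genotype values outside {", paste(allowed, collapse = ","),
         "} for ploidy ", ploidy)
  }
  if (!is.null(chrom) && length(chrom) != length(snp_ids)) {
    stop("chrom must have one entry per SNP")
  }
  if (!is.null(pos) && length(pos) != length(snp_ids)) {
    stop("pos must have one entry per SNP")
  }
  dimnames(values) <- list(sample_ids, snp_ids)
  structure(list(values = values, snp_ids = snp_ids, sample_ids = sample_ids,
                 chrom = chrom, pos = pos, ploidy = ploidy),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%s)\n",
              nrow(x$values), ncol(x$values), x$ploidy))
  invisible(x)
}

#' Number of SNPs / samples in a genotype matrix
#' @param g a `genotype_matrix`.
#' @return integer count.
#' @export
n_snps <- function(g) ncol(g$values)

#' @rdname n_snps
#' @export
n_samples <- function(g) nrow(g$values)

#' Allele dose corresponding to a homozygote (1 for haploid, 2 diploid)
#' @noRd
ploidy_dose <- function(g) if (g$ploidy == "haploid") 1 else 2

#' Construct an expression matrix
#'
#' @param values numeric matrix, traits in rows, samples in columns.
#' @param trait_ids,sample_ids identifiers; default to dimnames.
#' @param trait_gene optional per-trait gene identifier.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, trait_ids = rownames(values),
                              sample_ids = colnames(values),
                              trait_gene = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(trait_ids)) trait_ids <- paste0("trait_", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(values)))
  trait_ids <- as.character(trait_ids)
  sample_ids <- as.character(sample_ids)
  if (length(trait_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("identifier lengths inconsistent with matrix dimensions")
  }
  if (anyDuplicated(trait_ids)) {
    stop("duplicated trait ids: ", paste(unique(trait_ids[duplicated(trait_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  if (!is.null(trait_gene) && length(trait_gene) != length(trait_ids)) {
    stop("trait_gene must have one entry per trait")
  }
  dimnames(values) <- list(trait_ids, sample_ids)
  structure(list(values = values, trait_ids = trait_ids,
                 sample_ids = sample_ids, trait_gene = trait_gene),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d traits x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read genotypes from a TSV or PLINK .raw-style file
#'
#' The TSV dialect has samples as rows, a header row of SNP ids and the
#' sample id in the first column.  PLINK `.raw` files carry the six
#' leading pedigree columns (FID IID PAT MAT SEX PHENOTYPE) followed by
#' additive-coded SNP columns named `snp_allele`; the allele suffix is
#' stripped and IID is used as the sample id.  Missing genotypes ("NA")
#' map to `NA`.
#'
#' @param path file path.
#' @param format `"tsv"` or `"plink_raw"`.
#' @param ploidy optional; when `NULL`, inferred from the value range
#'   (any 2 observed implies diploid, otherwise haploid).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "plink_raw"), ploidy = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                            fill = FALSE)
    if (ncol(df) < 2) stop("genotype TSV needs a sample-id column plus >=1 SNP column")
    sample_ids <- as.character(df[[1]])
    snp_ids <- colnames(df)[-1]
    vals <- as.matrix(df[, -1, drop = FALSE])
  } else {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE, fill = FALSE)
    lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(lead %in% colnames(df)[seq_len(6)])) {
      stop("not a PLINK .raw header (expected FID IID PAT MAT SEX PHENOTYPE)")
    }
    sample_ids <- as.character(df[["IID"]])
    keep <- setdiff(colnames(df), lead)
    snp_ids <- sub("_[^_]*$", "", keep)
    vals <- as.matrix(df[, keep, drop = FALSE])
  }
  suppressWarnings(storage.mode(vals) <- "double")
  obs <- vals[!is.na(vals)]
  if (length(obs) && !all(obs %in% c(0, 1, 2))) {
    stop("genotype values outside {0,1,2} in ", path)
  }
  if (is.null(ploidy)) {
    ploidy <- if (any(obs == 2)) "diploid" else "haploid"
  }
  g <- genotype_matrix(vals, ploidy = ploidy, snp_ids = snp_ids,
                       sample_ids = sample_ids)
  es_log("read_genotypes: %d samples x %d SNPs (%s) from %s",
         n_samples(g), n_snps(g), g$ploidy, path)
  g
}

#' Read an expression matrix from TSV
#'
#' Traits as rows (trait id in the first column), samples as header
#' columns.  Non-numeric cells become `NA`.
#'
#' @param path file path.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          fill = FALSE)
  if (nrow(df) == 0) stop("no traits in expression file: ", path)
  trait_ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  e <- expression_matrix(vals, trait_ids = trait_ids,
                         sample_ids = colnames(df)[-1])
  es_log("read_expression: %d traits x %d samples from %s",
         nrow(e$values), ncol(e$values), path)
  e
}

#' Read a gene-pair interaction network from TSV
#'
#' Expects columns `gene_a`, `gene_b`, `score` (STRING-style confidence).
#' Edges are undirected: duplicate (a,b)/(b,a) rows are collapsed keeping
#' the maximum score; self-loops are dropped with a warning.
#'
#' @param path file path.
#' @return a data.frame of class `interaction_network` with columns
#'   `gene_a`, `gene_b` (lexicographically ordered within a row) and
#'   `score`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, fill = FALSE)
  need <- c("gene_a", "gene_b", "score")
  if (!all(need %in% colnames(df))) {
    stop("network TSV must have columns gene_a, gene_b, score")
  }
  if (!is.numeric(df$score)) stop("non-numeric network scores in ", path)
  if (any(!is.finite(df$score))) stop("non-finite network scores in ", path)
  interaction_network(df$gene_a, df$gene_b, df$score)
}

#' Construct an interaction network from edge vectors
#'
#' @param gene_a,gene_b character endpoints.
#' @param score numeric confidence per edge.
#' @return data.frame of class `interaction_network`.
#' @export
interaction_network <- function(gene_a, gene_b, score) {
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  score <- as.numeric(score)
  loop <- gene_a == gene_b
  if (any(loop)) {
    warning(sum(loop), " self-loop edge(s) dropped")
    gene_a <- gene_a[!loop]; gene_b <- gene_b[!loop]; score <- score[!loop]
  }
  a <- pmin(gene_a, gene_b)
  b <- pmax(gene_a, gene_b)
  key <- paste(a, b, sep = "\r")
  score <- vapply(split(score, key), max, numeric(1))
  keys <- names(score)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  net <- data.frame(gene_a = vapply(parts, `[`, "", 1),
                    gene_b = vapply(parts, `[`, "", 2),
                    score = unname(score),
                    stringsAsFactors = FALSE)
  net <- net[order(net$gene_a, net$gene_b), , drop = FALSE]
  rownames(net) <- NULL
  class(net) <- c("interaction_network", "data.frame")
  net
}

#' Node set of an interaction network
#' @param net an `interaction_network`.
#' @return sorted character vector of gene ids.
#' @export
network_nodes <- function(net) sort(unique(c(net$gene_a, net$gene_b)))

#' Restrict genotypes and expression to their shared samples
#'
#' Both objects are subset to the intersection of their sample ids, in
#' the order the ids appear in the genotype matrix.  Idempotent.
#'
#' @param g a [genotype_matrix()].
#' @param e an [expression_matrix()].
#' @return list with elements `genotypes` and `expression`.
#' @export
align_samples <- function(g, e) {
  common <- intersect(g$sample_ids, e$sample_ids)
  if (length(common) == 0) stop("no samples shared between genotypes and expression")
  if (length(common) < 3) stop("fewer than 3 shared samples; cannot analyse")
  gi <- match(common, g$sample_ids)
  ei <- match(common, e$sample_ids)
  g2 <- genotype_matrix(g$values[gi, , drop = FALSE], ploidy = g$ploidy,
                        snp_ids = g$snp_ids, sample_ids = common,
                        chrom = g$chrom, pos = g$pos)
  e2 <- expression_matrix(e$values[, ei, drop = FALSE], trait_ids = e$trait_ids,
                          sample_ids = common, trait_gene = e$trait_gene)
  es_log("align_samples: %d shared samples", length(common))
  list(genotypes = g2, expression = e2)
}

#' Write / read an epistasis result table
#'
#' TSV with a header; numeric columns serialized at 12 significant
#' digits so that `read_results(write_results(t))` reproduces `t` to
#' that precision.
#'
#' @param tab result data.frame as produced by [epistasis_scan()].
#' @param path output file path.
#' @return `write_results` invisibly returns `path`; `read_results`
#'   returns the data.frame.
#' @export
write_results <- function(tab, path) {
  out <- tab
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), "NA", formatC(x, digits = 12, format = "g"))
  })
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write results to ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (cn in intersect(c("beta12", "t_stat", "p_value"), colnames(df))) {
    df[[cn]] <- as.numeric(df[[cn]])
  }
  if ("n_used" %in% colnames(df)) df$n_used <- as.integer(df$n_used)
  df
}
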