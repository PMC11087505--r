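#' Read a SNP-to-gene map
#'
#' Expects a TSV with a header and columns `chrom`, `pos`, `gene` (extra
#' columns ignored). Each row assigns the SNP at (chrom, pos) to a gene; a
#' SNP may be listed under several genes (overlapping annotation) and a gene
#' set can be encoded by listing its members' SNPs under one set id.
#'
#' @param path path to the TSV.
#' @return data.frame with columns chrom, pos, gene.
#' @export
read_gene_map <- function(path) {
  gm <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "gene")
  if (!all(need %in% names(gm)))
    stop("gene map must have columns: ", paste(need, collapse = ", "))
  gm$pos <- as.integer(gm$pos)
  gm[, need]
}

#' Build a gene-to-SNP index over the effective variants
#'
#' @param gene_map data.frame from [read_gene_map()] (columns chrom, pos,
#'   gene), or a named list of integer SNP indices (passed through after
#'   validation).
#' @param counts the effective [allelic_counts()] the indices refer to.
#' @return named list of integer SNP index vectors, one per gene; genes with
#'   no effective SNP are absent. Carries per-gene total reads as the
#'   `total_reads` attribute.
#' @export
build_gene_index <- function(gene_map, counts) {
  N <- nrow(counts$variants)
  if (is.list(gene_map) && !is.data.frame(gene_map)) {
    idx <- lapply(gene_map, as.integer)
    if (any(unlist(idx) < 1L) || any(unlist(idx) > N))
      stop("gene index refers to SNPs outside the filtered set")
  } else {
    key_snp <- paste(counts$variants$chrom, counts$variants$pos)
    key_map <- paste(gene_map$chrom, gene_map$pos)
    hit <- match(key_map, key_snp)
    ok <- !is.na(hit)
    idx <- split(hit[ok], gene_map$gene[ok])
    idx <- lapply(idx, function(v) sort(unique(v)))
  }
  idx <- idx[lengths(idx) > 0L]
  if (length(idx) == 0L) stop("empty gene index: no gene maps to an effective SNP")
  attr(idx, "total_reads") <- vapply(idx, function(v) sum(counts$d[v]), 0)
  idx
}

#' Gene-to-SNP map from a GTF annotation
#'
#' Optional helper for when no TSV map is available: assigns each SNP to the
#' gene(s) whose exon intervals (1-based, inclusive) contain its position.
#'
#' @param gtf_path path to a GTF file.
#' @param counts [allelic_counts()] holding the SNP positions to assign.
#' @param feature GTF feature type to use (default `"exon"`).
#' @param attribute attribute naming the gene (default `"gene_id"`).
#' @return data.frame with columns chrom, pos, gene (the [read_gene_map()]
#'   layout).
#' @export
gene_map_from_gtf <- function(gtf_path, counts, feature = "exon",
                              attribute = "gene_id") {
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("GenomicRanges", quietly = TRUE))
    stop("gene_map_from_gtf requires the rtracklayer and GenomicRanges packages")
  gtf <- rtracklayer::import(gtf_path, format = "gtf")
  gtf <- gtf[gtf$type == feature]
  if (length(gtf) == 0L) stop("no '", feature, "' rows in GTF")
  gene <- S4Vectors::mcols(gtf)[[attribute]]
  if (is.null(gene)) stop("GTF lacks attribute '", attribute, "'")
  v <- counts$variants
  snps <- GenomicRanges::GRanges(v$chrom,
                                 IRanges::IRanges(v$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(snps, gtf, ignore.strand = TRUE)
  if (length(hits) == 0L) stop("no SNP overlaps any ", feature, " interval")
  out <- unique(data.frame(
    chrom = v$chrom[S4Vectors::queryHits(hits)],
    pos = v$pos[S4Vectors::queryHits(hits)],
    gene = gene[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Gene-level donor abundance
#'
#' Re-fits the donor proportions on one gene's SNPs with the allele-frequency
#' parameters held fixed at the supplied (globally estimated or default)
#' values. The result reflects the product of each donor's cell share and
#' its relative expression of the gene, so genes expressed equally across
#' donors return a vector close to the global proportions.
#'
#' @param counts_g,G_g counts and genotypes restricted to the gene's SNPs.
#' @param theta allele-frequency parameters, held fixed.
#' @param tol,max_iter EM controls, see [em_fit()].
#' @return named donor-proportion vector phi_g.
#' @export
gene_abundance <- function(counts_g, G_g, theta = c(0.01, 0.5, 0.99),
                           tol = 1e-8, max_iter = 2000L) {
  fit <- em_fit(counts_g, G_g, theta_mode = "fixed", theta0 = theta,
                tol = tol, max_iter = max_iter)
  fit$phi
}

#' Likelihood-ratio test for donor-differential expression of one gene
#'
#' Compares the likelihood of the gene's allelic counts under the global
#' donor proportions (null: the gene is expressed equally by all donors,
#' so its SNPs follow the global mixture) against the gene-specific
#' proportions (alternative). The statistic lambda = -2 log(L0/L1) is
#' referred to a chi-square distribution with K - 1 degrees of freedom
#' (the simplex dimension) for a one-tailed p-value. Both likelihoods are
#' evaluated on the identical SNP subset and theta.
#'
#' @param counts_g,G_g counts and genotypes restricted to the gene's SNPs.
#' @param phi_global global donor proportions (null model).
#' @param phi_g gene-level donor proportions (alternative model), typically
#'   from [gene_abundance()].
#' @param theta allele-frequency parameters shared by both models.
#' @return list with `lambda` (clipped at 0) and `p`.
#' @export
lrt_gene <- function(counts_g, G_g, phi_global, phi_g,
                     theta = c(0.01, 0.5, 0.99)) {
  stop_if_misaligned(G_g, counts_g)
  K <- length(G_g$donors)
  mu <- donor_allele_means(G_g, theta)
  ll0 <- suppressMessages(pool_loglik(counts_g, mu, phi_global))
  ll1 <- suppressMessages(pool_loglik(counts_g, mu, phi_g))
  lambda <- max(0, 2 * (ll1 - ll0))
  list(lambda = lambda,
       p = stats::pchisq(lambda, df = K - 1, lower.tail = FALSE))
}

#' Scan all genes for donor-differential expression
#'
#' For every gene with at least `min_reads` total reads over its effective
#' SNPs, estimates the gene-level donor abundance, computes the
#' likelihood-ratio statistic against the global proportions, and adjusts
#' p-values across tested genes by Benjamini-Hochberg. Genes below the read
#' threshold are listed untested with a reason. The default threshold of 32
#' reads marks where gene-level quantification becomes reliable.
#'
#' @param counts,G effective-filtered counts and genotypes (aligned).
#' @param gene_index named list of SNP indices from [build_gene_index()].
#' @param phi_global global donor proportions; estimated by [em_fit()] on all
#'   effective SNPs when NULL.
#' @param theta allele-frequency parameters, held fixed for every gene fit.
#' @param min_reads minimum per-gene total reads to test (default 32).
#' @return data.frame sorted by p-value: gene, n_snps, total_reads, one
#'   `phi_<donor>` column per donor, lambda, pval, fdr, tested, reason.
#' @export
deg_scan <- function(counts, G, gene_index, phi_global = NULL,
                     theta = c(0.01, 0.5, 0.99), min_reads = 32) {
  stop_if_misaligned(G, counts)
  if (length(gene_index) == 0L) stop("empty gene index")
  K <- length(G$donors)
  if (is.null(phi_global))
    phi_global <- em_fit(counts, G, theta_mode = "fixed", theta0 = theta)$phi
  phi_global <- check_phi(phi_global, K = K)

  rows <- lapply(names(gene_index), function(g) {
    idx <- gene_index[[g]]
    cg <- subset_variants(counts, idx)
    gg <- subset_variants(G, idx)
    total <- sum(cg$d)
    base <- data.frame(gene = g, n_snps = length(idx), total_reads = total,
                       stringsAsFactors = FALSE)
    phim <- matrix(NA_real_, 1, K,
                   dimnames = list(NULL, paste0("phi_", G$donors)))
    if (total < min_reads)
      return(cbind(base, phim, lambda = NA_real_, pval = NA_real_,
                   tested = FALSE, reason = "below min_reads"))
    contrast <- any(apply(gg$G, 1, function(x) length(unique(x)) >= 2L))
    if (!contrast)
      return(cbind(base, phim, lambda = NA_real_, pval = NA_real_,
                   tested = FALSE, reason = "no informative SNP"))
    phi_g <- gene_abundance(cg, gg, theta)
    lr <- lrt_gene(cg, gg, phi_global, phi_g, theta)
    phim[1, ] <- phi_g
    cbind(base, phim, lambda = lr$lambda, pval = lr$p,
          tested = TRUE, reason = "")
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  out$fdr[out$tested] <- stats::p.adjust(out$pval[out$tested], method = "BH")
  out[order(!out$tested, out$pval), , drop = FALSE]
}
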