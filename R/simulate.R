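#' Simulation configuration
#'
#' Bundles the generative settings shared by the synthetic-data functions:
#' K donors with Hardy-Weinberg genotypes at N SNPs, pooled binomial allelic
#' counts at Poisson depths, optional cell-level counts, doublet injection
#' and donor-specific per-gene expression multipliers.
#'
#' @param K number of donors (>= 2 for deconvolution).
#' @param N number of SNPs to simulate (all effective by construction).
#' @param phi true donor proportions (default uniform).
#' @param theta true allele-frequency parameters (default (0.01, 0.5, 0.99)).
#' @param maf_range population minor-allele-frequency range; per-SNP ALT
#'   frequency is drawn Uniform over it (default (0.05, 0.5)).
#' @param depth_mean mean per-SNP Poisson depth in the pooled sample
#'   (default 50).
#' @param n_cells optional cell count for cell-level simulation.
#' @param doublet_rate doublet fraction in \[0, 0.4\] for [inject_doublets()].
#' @param seed integer seed; mandatory, every generator call is reproducible
#'   from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(K, N, phi = rep(1 / K, K),
                       theta = c(0.01, 0.5, 0.99),
                       maf_range = c(0.05, 0.5), depth_mean = 50,
                       n_cells = NULL, doublet_rate = 0, seed) {
  stopifnot(K >= 2L, N >= 1L, depth_mean > 0,
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            doublet_rate >= 0, doublet_rate <= 0.4)
  if (missing(seed)) stop("sim_config requires an explicit seed")
  phi <- check_phi(phi, K = K)
  theta <- check_theta(theta)
  structure(list(K = as.integer(K), N = as.integer(N), phi = phi,
                 theta = theta, maf_range = maf_range,
                 depth_mean = depth_mean,
                 n_cells = if (is.null(n_cells)) NULL else as.integer(n_cells),
                 doublet_rate = doublet_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate donor genotypes under Hardy-Weinberg equilibrium
#'
#' For each SNP a population ALT frequency q is drawn from the configured
#' MAF range and each donor's genotype category is Binomial(2, q). Rows
#' without genotype contrast (all donors identical) carry no demultiplexing
#' information and are resampled, so every returned row is informative.
#'
#' @param cfg a [sim_config()].
#' @param seed overrides `cfg$seed`.
#' @return a [genotype_matrix()] with donors named `donor1..donorK`.
#' @export
simulate_genotypes <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  K <- cfg$K; N <- cfg$N
  G <- matrix(NA_integer_, N, K)
  todo <- seq_len(N)
  while (length(todo)) {
    q <- stats::runif(length(todo), cfg$maf_range[1], cfg$maf_range[2])
    draw <- matrix(stats::rbinom(length(todo) * K, 2L, rep(q, K)),
                   nrow = length(todo), ncol = K)
    G[todo, ] <- draw
    ok <- apply(G[todo, , drop = FALSE], 1,
                function(g) length(unique(g)) >= 2L)
    todo <- todo[!ok]
  }
  vt <- variant_table(chrom = rep("chrS", N), pos = seq_len(N),
                      ref = rep("A", N), alt = rep("G", N),
                      id = sprintf("snp%d", seq_len(N)))
  genotype_matrix(vt, sprintf("donor%d", seq_len(K)), G)
}

#' Simulate pooled bulk allelic counts
#'
#' The generative mirror of the deconvolution model: per-SNP depth is
#' Poisson with the configured mean, and the ALT count is Binomial with the
#' donor-averaged ALT rate mu_i' phi.
#'
#' @param cfg a [sim_config()].
#' @param G a [genotype_matrix()], typically from [simulate_genotypes()].
#' @param seed overrides `cfg$seed`.
#' @return list with `counts` (an [allelic_counts()]) and `phi_true`.
#' @export
simulate_bulk <- function(cfg, G, seed = cfg$seed) {
  set.seed(seed)
  mu <- donor_allele_means(G, cfg$theta)
  p <- as.vector(mu %*% cfg$phi)
  N <- nrow(G$G)
  d <- stats::rpois(N, cfg$depth_mean)
  a <- stats::rbinom(N, d, p)
  list(counts = allelic_counts(G$variants, a, d), phi_true = cfg$phi)
}

#' Simulate cell-level allelic counts with donor labels
#'
#' Each cell is assigned a donor with probability phi; its per-SNP depth is
#' Poisson with mean `depth_mean / n_cells` (so the pseudo-bulk total depth
#' matches [simulate_bulk()]), and its ALT counts are Binomial with that
#' donor's ALT rate. Labels are returned for truth-side counting.
#'
#' @param cfg a [sim_config()] with `n_cells` set.
#' @param G a [genotype_matrix()].
#' @param seed overrides `cfg$seed`.
#' @return a [cell_allelic_counts()] with per-cell `labels` (donor names).
#' @export
simulate_cells <- function(cfg, G, seed = cfg$seed) {
  if (is.null(cfg$n_cells)) stop("cfg$n_cells must be set for simulate_cells")
  set.seed(seed)
  C <- cfg$n_cells; N <- nrow(G$G); K <- cfg$K
  labels <- sample(G$donors, C, replace = TRUE, prob = cfg$phi)
  mu <- donor_allele_means(G, cfg$theta)
  cell_rate <- cfg$depth_mean / C
  D <- matrix(stats::rpois(N * C, cell_rate), N, C)
  MU <- mu[, match(labels, G$donors), drop = FALSE]
  A <- matrix(stats::rbinom(N * C, D, MU), N, C)
  cell_allelic_counts(G$variants, sprintf("cell%d", seq_len(C)),
                      Matrix::Matrix(A, sparse = TRUE),
                      Matrix::Matrix(D, sparse = TRUE), labels = labels)
}

#' Inject synthetic doublets into cell-level counts
#'
#' Merges randomly chosen cell pairs into single barcodes (counts summed),
#' so that the requested fraction of the resulting barcodes are doublets.
#' Reads are conserved exactly: pseudo-bulk aggregation before and after
#' injection is identical, which is why pooled-read deconvolution is immune
#' to doublets while per-cell (singlet-labelled) counting is distorted.
#'
#' @param cc a [cell_allelic_counts()].
#' @param rate doublet fraction of the output barcodes, in \[0, 0.5).
#' @param seed integer seed.
#' @return a [cell_allelic_counts()]; merged barcodes are named
#'   `bc1+bc2` and labelled `"doublet:<donorA>+<donorB>"`.
#' @export
inject_doublets <- function(cc, rate, seed) {
  stopifnot(inherits(cc, "cell_allelic_counts"), rate >= 0, rate < 0.5)
  if (rate == 0) return(cc)
  set.seed(seed)
  C <- length(cc$cells)
  n_d <- round(rate * C / (1 + rate))
  if (2L * n_d > C) stop("doublet rate too high for the cell count")
  if (n_d == 0L) return(cc)
  picked <- sample.int(C, 2L * n_d)
  first <- picked[seq_len(n_d)]
  second <- picked[n_d + seq_len(n_d)]
  keep <- setdiff(seq_len(C), picked)
  A <- cbind(cc$A[, keep, drop = FALSE],
             cc$A[, first, drop = FALSE] + cc$A[, second, drop = FALSE])
  D <- cbind(cc$D[, keep, drop = FALSE],
             cc$D[, first, drop = FALSE] + cc$D[, second, drop = FALSE])
  cells <- c(cc$cells[keep], paste0(cc$cells[first], "+", cc$cells[second]))
  labels <- if (is.null(cc$labels)) NULL else
    c(cc$labels[keep],
      paste0("doublet:", cc$labels[first], "+", cc$labels[second]))
  cell_allelic_counts(cc$variants, cells, A, D, labels = labels)
}

#' Down-sample pooled read counts
#'
#' Per SNP, the retained depth is Binomial(d_i, fraction) and the retained
#' ALT count is Hypergeometric (sampling reads without replacement), so
#' `a <= d` holds exactly and expected totals scale by `fraction`.
#'
#' @param counts an [allelic_counts()].
#' @param fraction retained read fraction in (0, 1\].
#' @param seed integer seed.
#' @return an [allelic_counts()].
#' @export
subsample_reads <- function(counts, fraction, seed) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(counts)
  set.seed(seed)
  N <- length(counts$d)
  d2 <- stats::rbinom(N, counts$d, fraction)
  a2 <- stats::rhyper(N, m = counts$a, n = counts$d - counts$a, k = d2)
  allelic_counts(counts$variants, a2, d2)
}

#' Simulate pooled counts with donor-specific gene expression effects
#'
#' SNPs are grouped into genes; within gene g the effective donor
#' proportions are tilted by expression multipliers,
#' phi_g = (w_g * phi) / sum(w_g * phi), and counts are drawn as in
#' [simulate_bulk()] under phi_g. Null genes (all multipliers 1) are
#' distributionally identical to the global model.
#'
#' @param cfg a [sim_config()]; `cfg$N` must equal the number of SNPs
#'   covered by `gene_index`.
#' @param G a [genotype_matrix()].
#' @param gene_index named list of SNP index vectors (disjoint).
#' @param w numeric n_genes x K matrix of expression multipliers, rows in
#'   `gene_index` order (default all 1: every gene null).
#' @param gene_depths optional per-gene total read counts; when given, each
#'   gene's reads are split across its SNPs multinomially (uniform), instead
#'   of per-SNP Poisson depths. Used to target exact read budgets.
#' @param seed overrides `cfg$seed`.
#' @return list with `counts`, `truth` (data.frame: gene, is_null, one `w_*`
#'   column per donor, phi_g columns) and `gene_index`.
#' @export
simulate_deg <- function(cfg, G, gene_index,
                         w = matrix(1, length(gene_index), cfg$K),
                         gene_depths = NULL, seed = cfg$seed) {
  stopifnot(nrow(w) == length(gene_index), ncol(w) == cfg$K)
  set.seed(seed)
  mu <- donor_allele_means(G, cfg$theta)
  N <- nrow(G$G)
  a <- integer(N); d <- integer(N)
  phis <- matrix(NA_real_, length(gene_index), cfg$K)
  for (g in seq_along(gene_index)) {
    idx <- gene_index[[g]]
    phi_g <- w[g, ] * cfg$phi
    phi_g <- phi_g / sum(phi_g)
    phis[g, ] <- phi_g
    p <- as.vector(mu[idx, , drop = FALSE] %*% phi_g)
    if (is.null(gene_depths)) {
      dg <- stats::rpois(length(idx), cfg$depth_mean)
    } else {
      dg <- as.vector(stats::rmultinom(1, gene_depths[g],
                                       rep(1, length(idx))))
    }
    d[idx] <- dg
    a[idx] <- stats::rbinom(length(idx), dg, p)
  }
  truth <- data.frame(gene = names(gene_index),
                      is_null = apply(w, 1, function(x) all(x == x[1])),
                      stringsAsFactors = FALSE)
  truth <- cbind(truth,
                 stats::setNames(as.data.frame(w), paste0("w_", G$donors)),
                 stats::setNames(as.data.frame(phis),
                                 paste0("phi_", G$donors)))
  list(counts = allelic_counts(G$variants, a, d),
       truth = truth, gene_index = gene_index)
}

#' Evenly sized gene blocks over simulated SNPs
#'
#' Convenience constructor: assigns consecutive SNPs to genes of
#' `snps_per_gene` SNPs each.
#'
#' @param N total SNP count (multiple of `snps_per_gene`).
#' @param snps_per_gene SNPs per gene.
#' @return named list of SNP index vectors (`gene1`, `gene2`, ...).
#' @export
block_gene_index <- function(N, snps_per_gene) {
  stopifnot(N %% snps_per_gene == 0L)
  n_genes <- N %/% snps_per_gene
  stats::setNames(
    split(seq_len(N), rep(seq_len(n_genes), each = snps_per_gene)),
    sprintf("gene%d", seq_len(n_genes)))
}
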