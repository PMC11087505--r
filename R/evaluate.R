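#' Jensen-Shannon divergence between two compositions
#'
#' JSD(p, q) = KL(p||m)/2 + KL(q||m)/2 with m = (p + q)/2, logarithms base 2
#' so the value is bounded in \[0, 1\] (0 for identical compositions, 1 for
#' disjoint supports). Zero entries contribute 0 (0 log 0 := 0). Vectors off
#' the simplex by more than 1e-6 are renormalized with a warning.
#'
#' @param p,q non-negative vectors of equal length.
#' @return scalar in \[0, 1\].
#' @export
jsd <- function(p, q) {
  if (length(p) != length(q)) stop("jsd: length mismatch")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    warning("jsd: input off the simplex; renormalizing")
  p <- check_phi(p, renormalize = TRUE)
  q <- check_phi(q, renormalize = TRUE)
  m <- (p + q) / 2
  kl <- function(x, y) {
    nz <- x > 0
    sum(x[nz] * log2(x[nz] / y[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Compositional accuracy of an estimated donor abundance
#'
#' @param truth,est donor-proportion vectors of equal length (K >= 2).
#' @return list with `jsd`, `r` (Pearson correlation across donor entries)
#'   and `r2`; `r` is NA when either composition is constant (correlation
#'   undefined).
#' @export
composition_accuracy <- function(truth, est) {
  if (length(truth) < 2L) stop("Pearson r needs at least two donors")
  truth <- as.numeric(truth); est <- as.numeric(est)
  r <- if (stats::sd(truth) == 0 || stats::sd(est) == 0) NA_real_
       else stats::cor(truth, est)
  list(jsd = jsd(truth, est), r = r, r2 = r^2)
}

# One recovery replicate at the reference study conditions: K = 4 donors at
# proportions (0.4, 0.3, 0.2, 0.1), N = 2000 effective SNPs, Poisson(50)
# depth, fixed theta.
recovery_instance <- function(seed, K = 4, phi = c(0.4, 0.3, 0.2, 0.1),
                              N = 2000, depth_mean = 50,
                              theta = c(0.01, 0.5, 0.99)) {
  cfg <- sim_config(K = K, N = N, phi = phi, theta = theta,
                    depth_mean = depth_mean, seed = seed)
  G <- simulate_genotypes(cfg)
  sim <- simulate_bulk(cfg, G, seed = seed + 1L)
  list(cfg = cfg, G = G, counts = sim$counts, phi_true = sim$phi_true)
}

#' Run a predefined validation experiment
#'
#' Orchestrates simulate -> fit -> metric loops for the standard synthetic
#' validations, reporting the mean and SD over the supplied seeds
#' (technique-repeat style):
#'
#' * `"recovery"`: parameter recovery at the reference conditions; rows
#'   report JSD and Pearson r^2 between true and estimated proportions.
#' * `"coverage"`: recovery after down-sampling reads to each fraction in
#'   `fractions`; reports JSD and -log10(JSD) per fraction.
#' * `"doublets"`: cell-level simulation with doublets injected at each rate
#'   in `rates`; reports pooled-fit JSD (flat in rate) and the JSD of naive
#'   singlet-label counting (grows with rate).
#' * `"deg_null"`: rejection rate of the gene-level LRT at `alpha` on null
#'   genes.
#' * `"deg_power"`: LRT power for a 2-fold donor multiplier, binned by
#'   per-gene total reads.
#'
#' @param preset one of `"recovery"`, `"coverage"`, `"doublets"`,
#'   `"deg_null"`, `"deg_power"`.
#' @param seeds integer vector of seeds (>= 2 for an SD column).
#' @param fractions,rates,alpha preset-specific settings.
#' @param n_genes genes per condition in the DEG presets.
#' @return data.frame, one row per condition: condition, metric, mean, sd,
#'   n_replicates.
#' @export
run_experiment <- function(preset = c("recovery", "coverage", "doublets",
                                      "deg_null", "deg_power"),
                           seeds = 1:3,
                           fractions = c(0.01, 0.05, 0.1, 0.5, 1),
                           rates = c(0.05, 0.1, 0.2, 0.4),
                           alpha = 0.05, n_genes = 200) {
  preset <- match.arg(preset)
  agg <- function(condition, metric, values)
    data.frame(condition = condition, metric = metric,
               mean = mean(values),
               sd = if (length(values) >= 2L) stats::sd(values) else NA_real_,
               n_replicates = length(values), stringsAsFactors = FALSE)

  if (preset == "recovery") {
    res <- vapply(seeds, function(s) {
      inst <- recovery_instance(s)
      fit <- em_fit(inst$counts, inst$G)
      acc <- composition_accuracy(inst$phi_true, fit$phi)
      c(acc$jsd, acc$r2)
    }, numeric(2))
    return(rbind(agg("recovery", "jsd", res[1, ]),
                 agg("recovery", "r2", res[2, ])))
  }

  if (preset == "coverage") {
    rows <- lapply(fractions, function(f) {
      js <- vapply(seeds, function(s) {
        inst <- recovery_instance(s)
        cts <- subsample_reads(inst$counts, f, seed = s + 7L)
        fit <- em_fit(cts, inst$G)
        jsd(inst$phi_true, fit$phi)
      }, 0)
      rbind(agg(sprintf("fraction=%g", f), "jsd", js),
            agg(sprintf("fraction=%g", f), "neg_log10_jsd",
                -log10(pmax(js, 1e-12))))
    })
    return(do.call(rbind, rows))
  }

  if (preset == "doublets") {
    rows <- lapply(rates, function(r) {
      m <- vapply(seeds, function(s) {
        cfg <- sim_config(K = 4, N = 500, phi = c(0.4, 0.3, 0.2, 0.1),
                          depth_mean = 2000, n_cells = 1000, seed = s)
        G <- simulate_genotypes(cfg)
        cc <- simulate_cells(cfg, G, seed = s + 1L)
        cc2 <- inject_doublets(cc, r, seed = s + 2L)
        fit <- em_fit(pseudobulk(cc2), G)
        bulk_jsd <- jsd(cfg$phi, fit$phi)
        lab <- singlet_label_proportions(cc2, G$donors)
        c(bulk_jsd, jsd(cfg$phi, lab))
      }, numeric(2))
      rbind(agg(sprintf("rate=%g", r), "bulk_jsd", m[1, ]),
            agg(sprintf("rate=%g", r), "singlet_count_jsd", m[2, ]))
    })
    return(do.call(rbind, rows))
  }

  if (preset == "deg_null") {
    rej <- vapply(seeds, function(s) {
      snps_per_gene <- 5L
      cfg <- sim_config(K = 4, N = n_genes * snps_per_gene,
                        phi = c(0.4, 0.3, 0.2, 0.1), depth_mean = 25,
                        seed = s)
      G <- simulate_genotypes(cfg)
      gi <- block_gene_index(cfg$N, snps_per_gene)
      sim <- simulate_deg(cfg, G, gi, seed = s + 1L)
      tab <- deg_scan(sim$counts, G, gi, phi_global = cfg$phi,
                      theta = cfg$theta, min_reads = 32)
      mean(tab$pval[tab$tested] < alpha)
    }, 0)
    return(agg(sprintf("null, alpha=%g", alpha), "rejection_rate", rej))
  }

  # deg_power: 2-fold multiplier on donor 1, binned by per-gene reads
  bins <- list(c(8, 16), c(16, 32), c(32, 64), c(64, 128))
  rows <- lapply(bins, function(bn) {
    pow <- vapply(seeds, function(s) {
      power_at_reads(bn[1], bn[2], n_genes = n_genes, seed = s,
                     alpha = alpha)
    }, 0)
    agg(sprintf("reads %g-%g", bn[1], bn[2]), "power", pow)
  })
  do.call(rbind, rows)
}

#' Donor proportions by naive singlet-label counting
#'
#' Counts each barcode's reads toward its (single) donor label; doublet
#' barcodes are dropped when `drop_doublets`, or split evenly between their
#' two constituent donors otherwise. This is the cell-level counting that
#' doublets distort, in contrast to pooled-read deconvolution.
#'
#' @param cc a labelled [cell_allelic_counts()].
#' @param donors donor name vector fixing the output order.
#' @param drop_doublets discard doublet barcodes (default TRUE).
#' @return named donor-proportion vector.
#' @export
singlet_label_proportions <- function(cc, donors, drop_doublets = TRUE) {
  if (is.null(cc$labels)) stop("cell counts carry no donor labels")
  reads <- Matrix::colSums(cc$D)
  tot <- stats::setNames(numeric(length(donors)), donors)
  singlet <- !startsWith(cc$labels, "doublet:")
  sums <- tapply(reads[singlet], cc$labels[singlet], sum)
  tot[names(sums)] <- sums
  if (!drop_doublets && any(!singlet)) {
    pairs <- sub("^doublet:", "", cc$labels[!singlet])
    halves <- strsplit(pairs, "+", fixed = TRUE)
    for (i in seq_along(halves))
      for (dn in halves[[i]])
        tot[dn] <- tot[dn] + reads[!singlet][i] / 2
  }
  tot / sum(tot)
}

power_at_reads <- function(lo, hi, n_genes, seed, alpha = 0.05,
                           K = 4, phi = c(0.4, 0.3, 0.2, 0.1),
                           snps_per_gene = 5L, fold = 2) {
  cfg <- sim_config(K = K, N = n_genes * snps_per_gene, phi = phi,
                    depth_mean = 25, seed = seed)
  G <- simulate_genotypes(cfg)
  gi <- block_gene_index(cfg$N, snps_per_gene)
  w <- matrix(1, n_genes, K); w[, 1] <- fold
  set.seed(seed + 13L)
  depths <- sample(seq(lo, hi - 1L), n_genes, replace = TRUE)
  sim <- simulate_deg(cfg, G, gi, w = w, gene_depths = depths,
                      seed = seed + 1L)
  tab <- deg_scan(sim$counts, G, gi, phi_global = cfg$phi,
                  theta = cfg$theta, min_reads = 0)
  mean(tab$pval[tab$tested] < alpha)
}
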