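test_that("lambda is zero with p = 1 when gene and global proportions agree", {
  G <- make_gm(rbind(c(0L, 2L), c(1L, 2L)))
  cts <- make_counts(c(30L, 40L), c(100L, 80L))
  phi <- c(0.3, 0.7)
  lr <- lrt_gene(cts, G, phi_global = phi, phi_g = phi)
  expect_equal(lr$lambda, 0)
  expect_equal(lr$p, 1)
})

test_that("lambda equals twice the log-likelihood difference by definition", {
  G <- make_gm(rbind(c(0L, 2L), c(1L, 0L), c(2L, 1L)))
  cts <- make_counts(c(20L, 10L, 50L), c(60L, 45L, 70L))
  theta <- c(0.01, 0.5, 0.99)
  mu <- donor_allele_means(G, theta)
  phi0 <- c(0.3, 0.7)
  phi1 <- gene_abundance(cts, G, theta)
  lr <- lrt_gene(cts, G, phi0, phi1, theta)
  expect_equal(lr$lambda,
               2 * (pool_loglik(cts, mu, phi1) - pool_loglik(cts, mu, phi0)),
               tolerance = 1e-10)
  expect_equal(lr$p, pchisq(lr$lambda, df = 1, lower.tail = FALSE))
})

test_that("gene abundance matches the closed-form inversion on one K=2 SNP", {
  # genotypes (0, 2), a/d = 0.5: phi_g = ((0.99-0.5)/0.98, (0.5-0.01)/0.98)
  G <- make_gm(matrix(c(0L, 2L), 1))
  cts <- make_counts(50L, 100L)
  phi_g <- gene_abundance(cts, G, tol = 1e-12, max_iter = 50000)
  expect_equal(unname(phi_g), c(0.5, 0.5), tolerance = 1e-6)
  # it deviates from a skewed global phi, and the LRT notices
  lr <- lrt_gene(cts, G, phi_global = c(0.3, 0.7), phi_g = phi_g)
  expect_gt(lr$lambda, 0)
  expect_lt(lr$p, 1)
})

test_that("a 2-fold donor multiplier tilts phi_g by w*phi / sum(w*phi)", {
  cfg <- sim_config(K = 3, N = 400, phi = c(0.5, 0.3, 0.2),
                    depth_mean = 200, seed = 31)
  G <- simulate_genotypes(cfg)
  gi <- list(gene1 = seq_len(400))
  w <- matrix(c(2, 1, 1), 1)
  sim <- simulate_deg(cfg, G, gi, w = w, seed = 32)
  phi_g <- gene_abundance(sim$counts, G, cfg$theta)
  expected <- c(2, 1, 1) * cfg$phi / sum(c(2, 1, 1) * cfg$phi)
  expect_equal(unname(phi_g), expected, tolerance = 0.02)
})

test_that("deg_scan thresholds by reads, reports reasons, and orders FDR", {
  cfg <- sim_config(K = 4, N = 40 * 5, phi = c(0.4, 0.3, 0.2, 0.1),
                    depth_mean = 25, seed = 41)
  G <- simulate_genotypes(cfg)
  gi <- block_gene_index(cfg$N, 5L)
  sim <- simulate_deg(cfg, G, gi, seed = 42)
  tab <- deg_scan(sim$counts, G, gi, phi_global = cfg$phi,
                  theta = cfg$theta, min_reads = 32)
  expect_setequal(tab$gene, names(gi))
  expect_true(all(tab$total_reads[tab$tested] >= 32))
  expect_true(all(tab$reason[!tab$tested] == "below min_reads"))
  tt <- tab[tab$tested, ]
  expect_true(all(tt$lambda >= 0))
  expect_true(all(tt$pval >= 0 & tt$pval <= 1))
  expect_true(all(tt$fdr >= tt$pval - 1e-12))
  expect_false(is.unsorted(tt$pval))          # sorted by p
  expect_false(is.unsorted(tt$fdr))           # BH is monotone in p
  phis <- as.matrix(tt[, paste0("phi_", G$donors)])
  expect_equal(unname(rowSums(phis)), rep(1, nrow(tt)), tolerance = 1e-6)

  tab0 <- deg_scan(sim$counts, G, gi, phi_global = cfg$phi,
                   theta = cfg$theta, min_reads = 0)
  expect_true(all(tab0$tested))               # min_reads = 0 tests every gene
  expect_error(deg_scan(sim$counts, G, list(), phi_global = cfg$phi),
               "empty gene index")
})

test_that("null-simulated genes give roughly uniform p-values", {
  cfg <- sim_config(K = 4, N = 300 * 5, phi = c(0.4, 0.3, 0.2, 0.1),
                    depth_mean = 25, seed = 51)
  G <- simulate_genotypes(cfg)
  gi <- block_gene_index(cfg$N, 5L)
  sim <- simulate_deg(cfg, G, gi, seed = 52)
  tab <- deg_scan(sim$counts, G, gi, phi_global = cfg$phi,
                  theta = cfg$theta, min_reads = 64)
  p <- tab$pval[tab$tested]
  expect_gt(length(p), 200)
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.04)
})

test_that("gene maps resolve SNPs from TSV and from GTF exons", {
  cts <- make_counts(a = c(10L, 20L, 30L, 5L), d = c(40L, 50L, 60L, 30L))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tgene",
               "1\t1\tGENEA", "1\t2\tGENEA", "1\t3\tGENEB",
               "1\t999\tGENEC"), tsv)
  gi <- build_gene_index(read_gene_map(tsv), cts)
  expect_equal(names(gi), c("GENEA", "GENEB"))   # GENEC has no effective SNP
  expect_equal(gi$GENEA, c(1L, 2L))
  expect_equal(unname(attr(gi, "total_reads")["GENEA"]), 90)

  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("1", "src", "exon", "1", "2", ".", "+", ".",
          'gene_id "GENEA"; transcript_id "T1";', sep = "\t"),
    paste("1", "src", "exon", "3", "4", ".", "-", ".",
          'gene_id "GENEB"; transcript_id "T2";', sep = "\t")), gtf)
  gm <- gene_map_from_gtf(gtf, cts)
  gi2 <- build_gene_index(gm, cts)
  expect_equal(gi2$GENEA, c(1L, 2L))
  expect_equal(gi2$GENEB, c(3L, 4L))
})
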