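# Small in-code fixtures shared across the suite.

tiny_variants <- function(n, chrom = "1") {
  variant_table(chrom = rep(chrom, n), pos = seq_len(n),
                ref = rep("A", n), alt = rep("G", n),
                id = sprintf("rs%d", seq_len(n)))
}

make_gm <- function(G, donors = sprintf("d%d", seq_len(ncol(G)))) {
  genotype_matrix(tiny_variants(nrow(G)), donors, G)
}

make_counts <- function(a, d) allelic_counts(tiny_variants(length(a)), a, d)

# A literal 3-donor VCF exercising the GT parsing corners: phased calls,
# half-calls, haploid calls, a multiallelic row, an indel and a symbolic ALT.
write_fixture_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "alice", "bob", "carol", sep = "\t"),
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t1|0\t0|1\t0/0",
    "1\t300\trs3\tG\tA,T\t.\tPASS\t.\tGT\t0/1\t0/2\t1/2",
    "1\t400\trs4\tT\tC\t.\tPASS\t.\tGT\t./1\t1\t1/1",
    "1\t500\trs5\tAT\tA\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t600\trs6\tG\t<DEL>\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t700\trs7\tA\tC\t.\tPASS\t.\tGT\t1/1\t0/0\t0/1"
  ), path)
  path
}

# Deterministic bulk instance at the reference study conditions, shared by
# several tests (K = 4 donors at (0.4, 0.3, 0.2, 0.1), Poisson(50) depth).
bulk_instance <- function(seed, N = 2000, K = 4,
                          phi = c(0.4, 0.3, 0.2, 0.1), depth_mean = 50) {
  cfg <- sim_config(K = K, N = N, phi = phi, depth_mean = depth_mean,
                    seed = seed)
  G <- simulate_genotypes(cfg)
  sim <- simulate_bulk(cfg, G, seed = seed + 1L)
  list(cfg = cfg, G = G, counts = sim$counts, phi_true = sim$phi_true)
}

random_simplex <- function(K) {
  x <- stats::rexp(K)
  x / sum(x)
}
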