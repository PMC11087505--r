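# demuxbulk

Donor deconvolution of multiplexed bulk RNA-seq from expressed allelic
counts.

When cells from several genotyped donors are pooled, cultured and sequenced
as a single bulk RNA-seq library — a standard design for removing batch
effects in iPSC differentiation and organoid studies — the reads from the
different donors are mixed. At biallelic SNPs where the donors carry
different genotypes, however, the pooled ALT/REF read counts still encode
each donor's share of the library. demuxbulk is for analysts running such
multiplexed experiments who need per-donor read compositions from bulk data,
and per-donor expression differences, without any cell-level information.

## Model

For SNP *i* and donor *k* with genotype category *t* ∈ {0, 1, 2}
(hom-ref / het / hom-alt), the expected ALT-read fraction is
μ<sub>ik</sub> = θ<sub>t</sub>, with θ = (θ₀, θ₁, θ₂) defaulting to
(0.01, 0.5, 0.99). With unknown donor proportions φ on the K-simplex, each
read is ALT with probability μᵢᵀφ, giving the binomial-mixture
log-likelihood

ℓ(φ, θ) = Σᵢ [ aᵢ log(μᵢᵀφ) + (dᵢ − aᵢ) log(1 − μᵢᵀφ) ]

over the *effective* SNPs (genotype contrast between ≥2 donors, ≥100 pooled
reads, >5% minor-allele fraction; all thresholds adjustable). `em_fit()`
maximizes ℓ by EM, optionally learning θ adaptively. For a gene *g*, the
same fit on its SNPs yields a gene-level abundance φ_g, and
λ = −2 log(L₀/L₁) comparing the global and gene-level proportions is
referred to χ²(K−1) for a one-tailed p-value — a likelihood-ratio test for
donor-differential expression, with Benjamini–Hochberg FDR across genes.

## Worked example

Simulate a 4-donor pool at proportions (0.4, 0.3, 0.2, 0.1) with 2000
effective SNPs at Poisson(50) depth, deconvolve it, then scan 400 genes of
which the first 40 carry a 4-fold expression increase in donor 1:

```r
library(demuxbulk)

cfg  <- sim_config(K = 4, N = 2000, phi = c(0.4, 0.3, 0.2, 0.1),
                   depth_mean = 50, seed = 42)
G    <- simulate_genotypes(cfg)
pool <- simulate_bulk(cfg, G)
fit  <- em_fit(pool$counts, G)
fit
#> demux_fit: K=4 donors, 108 EM iterations (converged)
#> phi:   donor1=0.4033  donor2=0.3027  donor3=0.1980  donor4=0.0960
#> theta: (0.0100, 0.5000, 0.9900)   logLik: -55342.402
```

The estimated composition matches the simulated truth to a Jensen–Shannon
divergence of 4.2e-05 (`composition_accuracy(pool$phi_true, fit$phi)`,
Pearson r² = 0.9999): each φ entry is each donor's share of the pooled
reads.

```r
gi <- block_gene_index(2000, 5)                 # 400 genes, 5 SNPs each
w  <- matrix(1, 400, 4); w[1:40, 1] <- 4        # donor-1 up-regulation
deg_sim <- simulate_deg(cfg, G, gi, w = w, gene_depths = rep(400L, 400),
                        seed = 43)
tab <- deg_scan(deg_sim$counts, G, gi, phi_global = fit$phi,
                theta = fit$theta)
head(tab[, c("gene", "total_reads", "phi_donor1", "lambda", "pval", "fdr")], 3)
#>   gene total_reads phi_donor1 lambda     pval      fdr
#>  gene7         400      0.810   93.2 4.60e-20 1.84e-17
#> gene18         400      0.769   67.4 1.56e-14 3.12e-12
#> gene13         400      0.708   65.8 3.41e-14 4.55e-12
```

`phi_donor1` rises from the global 0.40 toward 4·0.4/(4·0.4 + 0.6) ≈ 0.73
for the perturbed genes. At FDR < 0.05 the scan reports 35 genes, all among
the 40 truly perturbed, and no false positives.

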