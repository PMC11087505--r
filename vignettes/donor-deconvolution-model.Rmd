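---
title: "The demuxbulk model: donor deconvolution of pooled bulk RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The demuxbulk model: donor deconvolution of pooled bulk RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demuxbulk)
```

## The problem

Multiplexed designs culture and sequence cells from several genetically
distinct donors in one library, removing batch effects at the cost of mixing
the donors' reads. In single-cell data each cell can be assigned back to its
donor using genotype differences as natural barcodes; in *bulk* RNA-seq
there are no cells to assign, but the pooled allelic counts at SNPs where
donors carry different genotypes still encode each donor's share of the
reads. demuxbulk recovers that share, and flags genes whose per-donor
abundance deviates from the global composition — evidence of differential
expression between donors.

## The model

Consider $N$ effective biallelic SNPs: sites with genotype contrast between
at least two of the $K$ pooled donors, adequate pooled coverage, and a
non-trivial minor-allele read fraction. Donor $k$'s genotype at SNP $i$ is a
category $t \in \{0, 1, 2\}$ (hom-ref BB, het AB, hom-alt AA), and each
category emits ALT reads at a globally shared rate
$\boldsymbol\theta = (\theta_0, \theta_1, \theta_2)$, nominally $(0, 0.5, 1)$
but defaulting to $(0.01, 0.5, 0.99)$ to absorb sequencing and genotyping
error. The donor's expected ALT fraction is the lookup
$\mu_{i,k} = \theta_{t(i,k)}$.

Each read at SNP $i$ originates from donor $k$ with probability $\phi_k$,
the unknown donor proportion. Marginalizing the read origin, an ALT read
occurs with probability $\boldsymbol\mu_i^\top \boldsymbol\phi$, so with
$a_i$ ALT reads out of $d_i$ the log-likelihood is

$$\ell(\boldsymbol\phi, \boldsymbol\theta) = \sum_{i=1}^N \Big[
a_i \log(\boldsymbol\mu_i^\top \boldsymbol\phi) +
(d_i - a_i) \log(1 - \boldsymbol\mu_i^\top \boldsymbol\phi) \Big],$$

a binomial mixture over donors. The binomial coefficient is constant in
$\boldsymbol\phi$ and omitted, so traces are comparable between fits on the
same data but not across data sets.

`em_fit()` maximizes $\ell$ by EM. The E-step computes read-origin
responsibilities — for ALT reads $r^A_{i,k} \propto \phi_k \mu_{i,k}$, for
REF reads $r^B_{i,k} \propto \phi_k (1 - \mu_{i,k})$; reads of the same
allele at one SNP are exchangeable, so the per-read latent variables
collapse to count-weighted responsibilities without approximation. The
M-step sets $\phi_k$ to donor $k$'s share of the total read mass. In
adaptive mode $\theta_t$ is re-estimated as the ALT fraction of the read
mass assigned to donor–SNP pairs of genotype category $t$, clipped to
$[10^{-4}, 1-10^{-4}]$ to keep the likelihood finite and re-sorted to
preserve $\theta_0 < \theta_1 < \theta_2$ (resolving label switching between
the hom-ref and hom-alt categories). Every iteration provably increases the
likelihood; the fit records the trace and asserts nothing weaker.

### Identifiability and symmetries

$\boldsymbol\phi$ is identified as long as no two donors share genotypes at
every effective SNP. The model is equivariant under donor permutation and,
when $\theta$ is symmetric ($\theta_0 = 1 - \theta_2$, $\theta_1 = 0.5$),
invariant under flipping REF/ALT labels at any SNP. The estimate depends on
the counts only through the per-SNP proportions and total mass: scaling all
counts by a constant changes the sharpness of the likelihood but not its
maximizer. These symmetries are asserted as tests on every fit.

## Gene-level abundance and the LRT

Restricting the fit to one gene's SNPs yields $\boldsymbol\phi_g$, which
reflects the product of each donor's cell share and its relative expression
of that gene. Under equal expression, $\boldsymbol\phi_g \approx
\boldsymbol\phi$; a deviation indicates donor-differential expression.
`lrt_gene()` compares the null likelihood $L_0$ (gene counts under the
global $\boldsymbol\phi$) with the alternative $L_1$ (under
$\boldsymbol\phi_g$) on the identical SNP subset and $\theta$:
$\lambda = -2\log(L_0/L_1)$, referred to $\chi^2_{K-1}$ (the simplex has
$K - 1$ free coordinates) for a one-tailed p-value. $\lambda$ is clipped at
zero; since the alternative MLE nests the null, negative values can arise
only from finite convergence tolerance.

Design choices here, where the procedure was genuinely open:

* $\theta$ is frozen at the globally estimated (or default) value for all
  gene-level fits. Per-gene SNP counts are far too small to re-learn a
  three-parameter error model, and a shared $\theta$ keeps $L_0$ and $L_1$
  comparable.
* Multiple testing uses Benjamini–Hochberg across tested genes.
* Genes with fewer than `min_reads = 32` total reads are reported untested:
  below roughly that coverage, gene-level composition estimates are too
  noisy to interpret, and the LRT has essentially no power there anyway. A
  gene *set* is handled by mapping the union of its members' SNPs to one id.
* Only the global $K-1$-df test is provided; no per-donor contrasts.

The test is mildly conservative at moderate coverage (empirical size
0.03–0.045 at $\alpha = 0.05$ for $K = 4$ and ~125 reads/gene in the
calibration runs) because the gene-level MLE can sit on the simplex
boundary, where the usual $\chi^2$ asymptotics overstate the null spread.
The conservatism is systematic: with thousands of null genes a
Kolmogorov–Smirnov test has enough power to detect it for some generator
seeds. It errs on the safe side — reported p-values are, if anything, too
large — and is a property of the $\chi^2$ reference, not of the EM
convergence tolerance (tightening the gene fits to `tol = 1e-12` leaves the
p-value distribution unchanged).

## What the synthetic generator emulates

The `simulate` functions generate data with exactly the statistical
structure the model assumes, so that recovery, coverage, doublet and DEG
experiments can run without any external download:

* **Genotypes** (`simulate_genotypes`): per SNP a population ALT frequency
  $q \sim \mathrm{Uniform}(0.05, 0.5)$ and Hardy–Weinberg categories
  $\mathrm{Binomial}(2, q)$ per donor; rows without genotype contrast are
  resampled so every simulated SNP is effective. Real panels have linkage
  disequilibrium, relatedness and shared haplotypes — none of which the
  generator reproduces; users can substitute a real multi-donor VCF.
* **Pooled counts** (`simulate_bulk`): depths $d_i \sim$ Poisson with the
  configured mean, ALT counts binomial at rate
  $\boldsymbol\mu_i^\top\boldsymbol\phi$.
* **Cells** (`simulate_cells`): donor labels drawn from $\boldsymbol\phi$,
  per-cell depths Poisson at `depth_mean / n_cells` so the pseudo-bulk
  matches the bulk generator's total coverage.
* **Doublets** (`inject_doublets`): uniformly random cell pairs merged by
  summing their columns, so that the requested fraction of output barcodes
  are doublets. Reads are conserved exactly; only higher-order multiplets
  (not modelled) or biased pairing could break the pooled invariance.
* **Down-sampling** (`subsample_reads`): retained depth binomial, retained
  ALT count hypergeometric (without replacement), keeping $a_i \le d_i$
  exactly and conserving expected totals.
* **DEG structure** (`simulate_deg`): per-gene expression multipliers
  $w_{g,k}$ tilt the effective proportions to
  $w_{g,k}\phi_k / \sum_j w_{g,j}\phi_j$. Optional per-gene read budgets are
  split multinomially across the gene's SNPs, used to place genes in exact
  total-read bins for the power experiment.

Because the generator *is* the model, passing recovery tests demonstrates
correctness of the estimator, not robustness to real-data violations:
allele-specific expression, RNA editing, mapping bias toward the reference
allele, genotype errors correlated across donors, and ambient RNA are all
absent. The adaptive-$\theta$ mode absorbs globally shared allelic bias but
not SNP-specific effects.

## Reference study conditions and numerical choices

The validation experiments use fixed conditions chosen to represent a
realistic pooled experiment at desk scale: $K = 4$ donors at proportions
$(0.4, 0.3, 0.2, 0.1)$, $N = 2000$ effective SNPs, Poisson(50) pooled depth
(~100k reads), $\theta$ fixed at its default. Calibration and power runs
use 5 SNPs per gene — typical of the expressed-SNP density of a
well-covered gene — with Poisson(25) per-SNP depth for calibration
(~125 reads/gene) and per-gene read budgets of 8–128 for the power bins;
1000–2000 genes per condition keep Monte-Carlo error on rejection rates
near 0.5%.

* Convergence: `tol = 1e-6` on the log-likelihood increment,
  `max_iter = 1000` for global fits (typically ~100 iterations); gene-level
  fits use `tol = 1e-8`, `max_iter = 2000` since small-SNP likelihoods can
  be flat near the simplex boundary. Reference-oracle comparisons tighten
  to `tol = 1e-12`.
* Initialization: $\boldsymbol\phi^0$ uniform (no donor favored),
  $\theta^0 = (0.01, 0.5, 0.99)$. The likelihood in $\boldsymbol\phi$ at
  fixed $\theta$ is concave, so the fixed-mode EM finds the global optimum;
  adaptive mode is a genuinely non-convex joint fit, where the symmetric
  start and the ordering constraint have been sufficient in practice.
* Mixture rates are clamped to $[10^{-12}, 1-10^{-12}]$ before logs; the
  event is reported, and cannot occur with the default $\theta$ clip.
* JSD is computed in base 2 so it is bounded in $[0, 1]$; accuracy
  thresholds on a bounded scale (e.g. 0.2 for "reasonably accurate"
  gene-level composition) are then interpretable.
* Pearson $r$ is computed across the $K$ donor-proportion pairs, and both
  $r$ and $r^2$ are reported, labelled explicitly.

## Limitations

* Deconvolution needs $K \ge 2$ and genotype contrast; monozygotic twins or
  clones are indistinguishable.
* No confidence intervals on $\boldsymbol\phi$ are provided.
* Gene-level results inherit SNP-to-gene mapping quality; overlapping genes
  double-count shared SNPs.
* The doublet experiments demonstrate the *pooled* invariance (bit-identical
  pseudo-bulk before and after injection). The cell-level counting error
  shown alongside grows with the doublet rate through read loss when
  doublet barcodes are dropped; systematic misassignment by a cell-level
  demultiplexer — the dominant effect in real single-cell pipelines — is
  outside this package's scope.
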