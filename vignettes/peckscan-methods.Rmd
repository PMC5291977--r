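---
title: "Mapping count-valued pecking behaviour in a divergent-line F2 cross: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping count-valued pecking behaviour in a divergent-line F2 cross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peckscan)
```

## The design and the inference chain

Two White-Leghorn lines divergently selected for feather pecking (HFP
= high, LFP = low) found a large F2 cross: 5 sires and 10 dams per
line produce 10 F1 families by reciprocal crossing, 10 F1 sires are
each mated to 8 F1 hens, and 960 F2 offspring hatch in four groups.
Each hen contributes three counts — feather pecks delivered (FPD),
aggressive pecks delivered (APD) and received (APR) — standardised to
a 420-minute observation window, plus chip genotypes.

`peckscan` chains six stages over this design: SNP QC, single-marker
Poisson GWAS, genome-wide and FDR multiple-testing control, an
F_ST-based selection-signature meta-analysis, SNP-cluster
construction, and cluster-restricted differential-expression
enrichment. This vignette explains each model, its assumptions, and
the numerical decisions behind the implementation.

## The count model

Counts are overdispersed relative to Gaussian assumptions and
heavily skewed, so association is tested in a Poisson GLM with log
link and *no random effects*:

$$\eta_{ijm} = H_j + S_i + D_i + b_m x_{im}$$

with fixed hatch ($H_j$), sire ($S_i$) and dam ($D_i$) effects and
$x_{im} \in \{0,1,2\}$ the minor-allele dosage at SNP $m$. Fitting the
family structure as fixed effects (rather than a random family effect
in a GLMM) sidesteps the poorly characterised behaviour of
approximate-likelihood GLMM tests while still absorbing the
between-family component of population stratification. The dominance
model adds $\tilde b_m z_{im}$ with $z$ the heterozygosity indicator;
the reported dominance p-value is the Wald test of $\tilde b_m = 0$.

Implementation notes:

* Fitting is IRLS through `stats::glm.fit`, warm-started per SNP from
  the covariate-only fit (typically 2–3 iterations), with deviance
  tolerance `1e-8` and a 100-iteration cap.
* Because each F1 dam is mated to a single sire, the dam factor spans
  the sire factor; a pivoted QR drops the aliased columns once so
  every per-SNP design is full rank.
* *Separation* (a factor level whose hens all have zero counts) drives
  a coefficient to $-\infty$ while the relative deviance still
  "converges" (around $\hat\beta \approx -18$ in practice); fits with
  any $|\hat\beta| > 15$ or a standard error above 100 on the log-rate
  scale are therefore flagged and report `NA` p-values.
* The 420-minute standardisation enters as a log-exposure offset
  `log(minutes / 420)`, never by rescaling the counts — scaled counts
  are not integers and have no Poisson likelihood.
* The Wald z at these sample sizes is mildly conservative (null z SD
  ≈ 0.97 at 960 hens with ~84 nuisance parameters; about 4% of null
  p-values fall below 0.05 rather than 5%). This is a property of the
  Wald test with small counts, shared by `stats::glm`; a
  likelihood-ratio alternative would calibrate slightly better but
  the Wald default matches standard GLM reporting.

## Multiple testing

Genome-wide correction is the Šidák-type
$p_{gw} = 1 - (1 - p)^{\#SNP}$, computed as `-expm1(n * log1p(-p))` so
nominal p-values down to 1e-300 survive without underflow. At the
chip's post-QC density (29,376 SNPs) the genome-wide 0.05 level
corresponds to a nominal $p \approx 1.746 \times 10^{-6}$. Because
this correction is conservative, a relaxed nominal level
$p \le 5\times10^{-5}$ (and a weak level $5\times10^{-4}$ for cluster
bounds) is carried through the pipeline.

FDR control uses Storey q-values implemented in-package: $\hat\pi_0$
is estimated on the grid $\lambda = 0.05, 0.10, \ldots, 0.95$ with a
cubic smoothing spline extrapolated to $\lambda = 1$; below 100
p-values the single-point estimate at $\lambda = 0.5$ is used instead
(a spline through 19 noisy points is not meaningful there). With
$\hat\pi_0 = 1$ the procedure reduces exactly to Benjamini–Hochberg,
which the tests exploit as an independent oracle. The largest q-value
among the declared significant SNPs estimates the proportion of false
positives among them.

## Selection signatures and Fisher's combined test

The founder lines diverged under 11 generations of selection, so loci
controlling the selected behaviour should show allele-frequency
divergence beyond drift. The package quantifies divergence by the
two-population Weir–Cockerham $\hat\theta$ (diploid moment estimator;
negative finite-sample estimates are preserved) and attaches
permutation p-values by shuffling line labels:
$p = (1 + \#\{\theta_{perm} \ge \theta_{obs}\}) / (n_{perm} + 1)$.

Two properties of this stand-in deserve note. First, it is a generic
differentiation scan, not a reproduction of any particular selection
experiment's test — externally computed selection p-values can be
supplied as a TSV and are then used verbatim. Second, $\hat\theta$ on
discrete genotype data takes few distinct values, so permutation ties
are common (5–20% of permutations at 30 individuals per line) and the
conservative `>=` counting makes the null p-values stochastically
*larger* than uniform. They remain valid at every level; they are
simply not KS-uniform.

GWAS and selection evidence are combined per SNP by Fisher's method,
$\chi^2_{2k} = -2\sum_i \ln p_i$ with $k = 2$ studies (4 df). The two
sources are independent in the relevant sense — one uses founder-line
frequencies, the other F2 genotype–phenotype covariance — and a null
simulation in `scripts/acceptance.R` confirms a correlation near zero
between the two p-value sets. Zero p-values are floored at 1e-300
before logs (the permutation p has a positive floor anyway). The
classical sharpening property — the combined p beats the better
input — holds for equal inputs below $p \approx 0.28$; for unequal
pairs near that boundary the combined p can exceed the smaller input
(e.g. Fisher(0.2, 0.27) ≈ 0.21), which is expected behaviour, not a
defect.

## Cluster identification

A causative mutation should be in LD with several SNPs, so isolated
significant SNPs are weaker evidence than groups. Clusters are built
per chromosome by chaining: consecutive significant SNPs
($p \le 5\times10^{-5}$) at most 3 Mb apart join one chain, chains
with at least two SNPs become seeds, the midpoint is the centre of the
seed's span, and the bounds are the outermost weakly significant SNPs
($p \le 5\times10^{-4}$; the thresholds are nested, so seed SNPs
qualify) within ±1.5 Mb of the midpoint.

Decisions where the rule is under-specified:

* "Maximum distance of 3 Mb between them" is read as
  consecutive-pair chaining (transitive), not a pairwise diameter —
  the natural reading for more than two SNPs.
* The midpoint uses significant members only, not weak ones.
* Interval membership is inclusive at both bounds (bounds are SNP
  positions).
* Lengths in Mb are rounded *half-up* to two decimals (base R's
  `round` is half-to-even, which changes boundary cases).
* A chain may span more than the ±1.5 Mb window (three or more chained
  SNPs can cover > 3 Mb); the bounds are then truncated to the window
  and a warning is emitted rather than silently widening the cluster.
* Cluster numbering is by (chromosome, start) per trait.

One behaviour of the chain rule matters for interpretation: in an F2,
within-family co-segregation with family-random phase inflates the
association variance of SNPs on a QTL's chromosome tens of Mb away,
so besides the cluster at the QTL the scan genuinely produces weaker
*echo* clusters elsewhere on the same chromosome. The cluster tests
therefore assert chromosome-level localisation and a 3 Mb proximity
for most clusters, not that every cluster contains a causal variant —
which is also the right reading of any real cluster table from this
design.

## LD profiling

Pairwise $r^2$ within 5 Mb is estimated from unphased dosages by an
EM estimator of the four two-locus haplotype frequencies (the only
ambiguous configuration, the double heterozygote, is split by the
current frequency estimates; convergence at `1e-10` or 1,000
iterations). On data without double heterozygotes EM equals direct
haplotype counting exactly, which the tests assert. $r^2 = D^2 /
(p_A q_A p_B q_B)$; pairs with a monomorphic locus are skipped (the
correlation is undefined), not counted as zero. The decay profile
bins pairs at the distances (0, 0.025], …, (3, 5] Mb and reports the
distribution of $r^2$ per bin.

## Differential expression and enrichment

Brain expression from 9 hens per line (quantile-normalised, log2) is
compared probe-wise by a Welch t-test with Satterthwaite degrees of
freedom, restricted to probes whose genomic midpoint falls inside an
FPD_meta cluster; Bonferroni correction uses that in-cluster probe
count only, which is the point of restricting the test set. Fold
change is $2^{|\Delta|}$ with direction Up when the HFP mean is
larger. Probe intervals arrive 0-based half-open (BED convention) and
are reduced to a 1-based midpoint; SNP coordinates are 1-based
throughout. The enrichment profile compares the fraction of
significant probes (at corrected p ≤ 0.1, 0.05, 0.01) inside each
cluster with chromosome- and genome-wide fractions; cis-acting
regulation under a cluster predicts enrichment that strengthens as
the threshold tightens.

## The synthetic-data generator

The generator emulates the statistical structure every downstream
stage assumes; its defaults are the study design (5 + 10 founders per
line, 10 F1 sires × 8 dams, 960 F2 in 4 hatches, 29,376-SNP map on
the nine large autosomes by default, 9 expression samples per line).
Key modelling choices:

* **Founder divergence.** Per-SNP line frequencies follow a
  Balding–Nichols model around ancestral frequencies ~ U(0.1, 0.9).
  The beta parameter is calibrated numerically (fixed-seed Monte
  Carlo + root finding, memoised) so the *mean per-SNP*
  Weir–Cockerham F_ST between the lines matches
  `founder_divergence`. That mean saturates near ~0.55 under these
  ancestral frequencies — fixed loci drop out of the estimator — so
  higher targets fall back to maximal divergence.
* **Within-line LD.** Founder haplotypes are drawn by a first-order
  Markov process whose adjacent-SNP allele correlation is
  `exp(-d / founder_ld_scale_bp)` (default 1 Mb), preserving the
  marginal frequencies. Without it an F2 from
  linkage-equilibrium founders has no short-range LD structure at
  all, and the LD-decay profile and cluster halos cannot exist.
* **Selective sweeps.** QTL receive a between-line frequency shift
  (`qtl_freq_shift`, 1 = fixed difference) that decays into the
  flanks with scale `qtl_sweep_scale_bp` (default 1 Mb), emulating
  hitchhiking — this is what gives a selected QTL its locally
  divergent halo and makes the selection scan and the cluster rule
  informative.
* **Recombination.** Gametes form under Haldane's model (no
  interference) at `cm_per_mb` (default 1 cM/Mb; the true genetic map
  of the cross is not modelled). Founder, F1 and F2 haplotypes are
  tracked, so Mendelian consistency is testable exactly.
* **Phenotypes.** $\eta$ = baseline + hatch + sire + dam + QTL
  effects; counts are Poisson($e^\eta$), with an optional
  negative-binomial switch for robustness experiments. Hatch effects
  are fixed constants, sire/dam effects i.i.d. Gaussian — mirroring
  the fixed-effect analysis model while generating real
  stratification. The FPD-like trait carries the QTL; APD/APR share
  the covariate structure but are generated null.
* **Expression.** Probes get Gaussian log2 baselines; a configurable
  fraction of probes inside designated intervals receives a line mean
  shift (cis effect), so in-cluster enrichment is recoverable by
  construction.

What the generator does *not* emulate: 11 generations of truncation
selection (the sweep shift is a one-parameter summary of its
outcome), social interaction / indirect genetic effects on the
counts, genotyping error and missingness patterns of a real chip, and
microarray normalisation artefacts. Passing tests therefore show the
inference chain is correct and calibrated under the design's
statistical structure — not that any biological conclusion about real
hens follows.

## Problem sizes used in tests and the acceptance script

The test suite and `scripts/acceptance.R` run the chain at reduced
sizes chosen to keep a desktop run in the minutes range while leaving
the statistical properties measurable: null calibration on 2,000 SNPs
(960 hens) plus 200 reduced null replicates (480 hens, 100 SNPs) for
the family-wise error rate; the power ordering of the meta-analysis
over 20 simulated studies of 300 SNPs; effect recovery for a common
QTL (MAF 0.45, b = 0.3) over 50 replicates; cluster localisation on
600 SNPs over six 30-Mb chromosomes. The `analysis/` drivers run a
6,000-SNP version of the full study on the real chromosome-length
map. All stages scale linearly in SNP count, so the same code runs
the full 29,376-SNP design unchanged.

## Known limitations

* Single-marker tests inherit all F2 long-range LD effects; clusters
  localise to chromosome arms, not genes.
* The Poisson model ignores residual overdispersion beyond the fitted
  fixed effects; with several strong unmodelled QTL the genome-wide
  null inflates (visible in the generator at implausibly large effect
  sizes). The study-scale defaults keep per-QTL effects small, where
  the calibration tests show the null is clean.
* Permutation selection p-values are conservative under heavy ties
  (small panels); they never overstate significance.
* The q-value $\hat\pi_0$ spline follows the standard recipe; for
  p-value sets with extreme signal fractions the BH-equivalent
  $\pi_0 = 1$ override is available and exact.
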