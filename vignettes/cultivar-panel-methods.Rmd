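---
title: "Models and methods for F1 cultivar panel genomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for F1 cultivar panel genomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the models each stage fits, the assumptions they lean on, the tunable
parameters that matter, and the places where a design choice was genuinely
open and had to be made. Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The data model

All stages operate on a `genotype_data` container: a biallelic variant
table (1-based positions, strictly increasing within chromosome), sample
metadata (`sample_id`, `release_year`, `line_type`), an ALT-dosage matrix
with entries in {0, 1, 2} = {REF/REF, heterozygous, ALT/ALT}, and — when
every VCF genotype is `|`-separated — a phased haplotype matrix whose rows
2i−1 and 2i are the two gametes of sample i. Missing genotypes are
rejected at ingestion rather than imputed: panels of this kind are imputed
upstream by dedicated software, and silently mean-imputing inside an
analysis package would blur that provenance. Multiallelic records are
dropped (not split) with a logged count; no splitting rule would be
canonical for the downstream dosage coding.

## Kinship and population structure

The additive relationship matrix uses VanRaden's method 1 with
panel-estimated allele frequencies: per site, dosages are centred by 2p̂
and the cross-product is scaled by 2Σp̂(1−p̂). The dominance matrix uses
the classical dominance-deviation coding {0,1,2} → {−2p̂², 2p̂q̂, −2q̂²}
scaled by Σ(2p̂q̂)². Both treat the panel itself as the base population —
the natural choice when no pedigree base exists.

Per-chromosome matrices are combined with chromosome-length weights,
`K = Σ_c K_c l_c / Σ_c l_c`. The length-weighted sum prevents chromosomes
with inflated variant counts (introgression drag regions) from dominating
genome-wide relatedness. The division by `Σ l_c` is a deliberate
normalisation choice: principal components and GBLUP fits are invariant to
any global positive rescaling of `K` (the variance component absorbs it),
so normalising changes nothing downstream while keeping the matrix on the
conventional kinship scale. `integrate_kinship(..., normalize = FALSE)`
gives the literal weighted sum. When true assembly lengths are not
supplied, the maximum variant position per chromosome stands in for `l_c`.

Structure analysis is *PCA of the kinship matrix treated as a data
matrix*: column-centre `K`, take the SVD, and report left singular vectors
scaled by singular values. This is what `prcomp(K)` computes and differs
from an uncentred eigendecomposition of `K`; the package replicates the
former deliberately and fixes each component's sign by making its
largest-magnitude loading positive, so scores are reproducible across
linear-algebra backends.

## Phenotype aggregation

Records from multiple cropping seasons and years are reduced to one value
per cultivar by REML:

    value ~ 0 + cultivar + (1 | season) + (1 | season:year)

with cultivar fixed and the two environmental terms random, fitted by
`lme4::lmer`. Cultivar estimates are reported centred (sum-to-zero): only
differences between cultivars matter to the downstream kernel models, and
differences are invariant to the contrast convention. A random term whose
grouping factor has a single level is dropped and its variance reported as
0, so a single-environment data set degrades gracefully to per-cultivar
means. Incidence traits (proportions of affected fruit) are transformed
with the empirical logit `ln((p + 0.5/n)/(1 − p + 0.5/n))` *before*
fitting — the transform-first order is an assumption; the per-plot count
`n` falls back to a configurable pseudo-count (default 20) when no count
column exists.

A design-of-experiment note: a variance component carried by a factor with
k levels is estimated with k−1 degrees of freedom, so a 2-season trial
gives its season variance ~χ²₁ sampling error (the median REML estimate of
a true variance 1 is then ≈ 0.45) and no estimator can recover it within
±30% in median. The parameter-recovery tests therefore use a balanced
6-season × 4-year design, where 5 and ~23 degrees of freedom make the
±30% check meaningful.

## GBLUP genomic prediction

The kernel model is `y = 1μ + Σ_k u_k + ε`, `u_k ~ N(0, K_k σ²_k)`,
`ε ~ N(0, I σ²_ε)`, with one kernel (additive) or two (additive +
dominance). The default REML path profiles the residual variance out and
maximises the restricted likelihood over the log variance ratios
γ_k = σ²_k/σ²_ε — a 0.5-spaced grid on [−10, 10] followed by local
refinement for one kernel, a coarse-grid multistart plus Nelder–Mead
(relative tolerance 1e−12) for several. Random effects come from
Henderson's equations, evaluated as û_k = γ̂_k K_k[·, obs] H⁻¹(y − 1μ̂)
with H the scaled covariance of the observed block, so samples *without*
phenotypes receive predictions through their kinship with the phenotyped
block. A kernel whose smallest eigenvalue is below −1e−6 is rejected as
non-PSD.

The Gibbs path samples the same model on each kernel's eigenbasis
(u_k = U_k α_k with independent prior α ~ N(0, λ σ²_k)), using
scaled-inverse-χ² priors with 5 prior degrees of freedom and prior scales
that split an a-priori R² of 0.5 equally across kernels; defaults are
15 000 iterations, 5 000 burn-in, thinning 5. Variance components and
fitted values are posterior means. For unphenotyped samples the Gibbs path
predicts by plug-in BLUP at the posterior-mean variances rather than
augmenting the sampler with missing phenotypes; the posterior-mean
prediction is the same quantity and the result object keeps the exact
shape of the REML path.

Cross-validation draws balanced random fold assignments per replicate from
a single seed, and the *same* assignments are reused for every model
specification so that model comparisons are paired. Accuracy is the
Pearson correlation between predicted and observed values pooled over all
held-out samples of a replicate; per-fold correlations at n/2 would be
noisier, and pooling is the documented default. Replicates with constant
predictions are recorded as undefined and excluded with a logged count.
Fits inside CV are Cholesky-based on the ≤150-sample training subsets;
pre-caching kernel eigendecompositions across replicates was considered
and rejected — at these problem sizes the whole 2-fold × 100-replicate run
takes seconds and the cache would only add state.

## Mixed-model GWAS

Each variant is tested in `y = Sτ + Xβ + a + ε` with `a ~ N(0, K σ²_g)`,
where `S` is the ALT-dosage column, `X` an intercept plus optional PC
scores, and `K` the integrated additive kinship — the only genome-wide
relationship matrix the pipeline builds. The kinship is eigendecomposed
once; rotating `y`, `X` and all dosage columns by the eigenvectors makes
the covariance diagonal, after which the ML likelihood profiled over the
variance ratio costs a weighted least-squares solve per evaluation. The
ratio is re-optimised under *every* per-variant full model as well as
under the null (a 41-point grid on log-ratio ∈ [−12, 12] plus Brent
refinement to 1e−8), so `2(LL_full − LL_null)` is an exact ML likelihood
ratio referred to χ²₁. A fixed-ratio approximation
(`reoptimize = FALSE`) is available for speed. Monomorphic variants are
skipped with a logged count; rank-deficient covariates are an error.
Negative eigenvalues of `K` are clipped at zero.

FDR control defaults to Benjamini–Hochberg; Storey q-values with the
fixed-λ estimate π̂₀ = min(1, mean(p > 0.5)/0.5) are selectable, since
either convention is defensible for this kind of scan. The decision object
reports the p-value threshold that exactly reproduces the significant set.

## Selection signatures

Windows slide in variant-site counts (default 500 sites per window, step
100), per chromosome, on the *full panel's* site set regardless of which
sample subset is being summarised — so the π track of a subpanel and of
the whole panel share one window frame and their ratio or difference is
well defined. Trailing windows shorter than the window size are reported
with their true site counts, marked partial, and excluded from percentile
ranking.

Per site, diversity is the unbiased allele-frequency form
π̂ = (n/(n−1))·2p̂(1−p̂) with n the number of allele copies, which equals
the mean pairwise difference per site among the sampled copies (the test
suite checks this identity against direct enumeration to 1e−12). ROD is
the windowwise ratio π_All/π_sub; windows with π_sub = 0 are undefined and
excluded from ranking rather than clamped — a division by zero carries no
rank information. The heterozygosity statistic is H = H_exp − H_obs
(Hardy–Weinberg expectation minus observed heterozygote fraction), so
heterozygote *excess* is negative H, and the between-panel indicator
H_All − H_sub is large and positive where the subpanel is excessively
heterozygous; the sign convention is chosen exactly so that a donor
segment kept heterozygous in recent hybrids produces a positive peak.
Percentile flagging uses the linear-interpolation quantile
(`stats::quantile`, type 7) over defined full windows and flags values
greater than or equal to it; ties at the threshold are all flagged.

LD decay pairs variants up to 3 Mb apart within chromosomes, bins pairs by
distance (default 10-kb bins), and averages r². Genotype mode squares the
Pearson correlation of dosage vectors; haplotype mode computes
r² = D²/(p_A p_a p_B p_b) from phased two-locus haplotype frequencies.
The two coincide exactly on fully homozygous samples, where phase carries
no extra information. The half-decay distance is the first crossing of
half the maximum bin mean, linearly interpolated between bin midpoints;
it is reported as `NA` when the binned curve never reaches half its
maximum within the distance limit (a flat curve has no half-decay point,
and inventing one would be misleading). MAF-filter the input first: r²
among rare variants is noise-dominated.

LD pruning is a greedy left-to-right scan dropping a variant whose r² with
any retained variant among the previous 1000 *sites* strictly exceeds
0.99. The window unit follows the pruning tool whose options these
defaults mirror — sites, not base pairs — with `window_unit = "bp"`
available because the ambiguity is real.

## The simulator: what it emulates, and what it does not

The generator is a forward-in-time caricature of a decades-long hybrid
breeding program, built to reproduce the *statistical* features the
analysis stages assume, not any particular genealogy:

* **Narrow germplasm with decaying LD.** Founder inbreds are mosaics of a
  small ancestral haplotype pool (default 3 haplotypes, segment lengths
  exponential with mean 1 Mb). Two sites on one ancestral segment are
  strongly correlated, two sites on different segments only weakly, so
  panel LD decays with physical distance on the Mb scale. Independent
  per-site founder draws — the obvious simpler model — produce *zero*
  founder LD and hence a panel whose LD curve has nothing to decay from.
* **A release-year gradient in relatedness.** A pool of 60 inbred lines
  advances one generation per 10 calendar years: truncation selection on
  a 100-QTL selection trait keeps the top 70%, pairs are crossed, and each
  offspring is instantly re-inbred (a doubled-haploid gamete). Drift plus
  directional selection move allele frequencies steadily, so cultivars
  sampled from the pool of their release generation carry a PC1 that
  tracks release year. With selection off (`year_trend = 0`) the gradient
  is drift-only and weaker.
* **F1 cultivars.** An F1 is the cross of two distinct pool inbreds — its
  two haplotypes *are* the parental lines, which the test suite exploits
  as an exact invariant. Pure-line cultivars (default 3 of 150) are single
  pool inbreds and stay perfectly homozygous.
* **Introgression segments.** From an onset year, a configurable fraction
  of new F1s carry a donor haplotype across a region; `keep_heterozygous`
  puts it on exactly one gamete (resistance-gene style, driving
  heterozygosity excess), otherwise on both (sweep style). Donor-specific
  alleles (absent from the founder pool) arise per site with probability
  `donor_divergence`; the region's variant density is inflated by
  1 + 10·divergence; and crossovers falling inside the region are
  discarded, mimicking linkage drag. Carriers are drawn among F1s only, so
  the pure-line invariant survives.
* **Phenotypes.** `y = μ + Σ a_j x_j + Σ d_j 1[x_j = 1] + season +
  season:year + residual` on a balanced cultivar × season × year grid,
  with true per-cultivar genetic values returned for recovery tests. For
  randomly placed QTL, effect sizes are rescaled so the realised sample
  variance of the additive (dominance) values equals the configured
  variance exactly — the clean way to pin heritability in a finite panel;
  explicitly placed QTL with explicit effects are used verbatim.

Meiosis draws one crossover per chromosome per gamete on average (Poisson,
uniform position) — a deliberate simplification standing in for a real
genetic map. What the simulator does **not** emulate: sequence-level
reads and genotyping error, realistic chromosome-specific recombination
maps, epistasis, pedigree loops or shared parents across release years,
multi-allelic variation, and genotype-by-environment interaction beyond
the additive season terms. Consequently, passing tests demonstrate that
the estimators recover the truth of *this* generative model at desk
scale; they do not certify performance on the full complexity of real
resequencing panels.

One invariant deserves its footnote: "panel allele frequencies match
founder frequencies under neutrality" only holds when the cultivars are
drawn from an *undrifted* pool, because drift across generations
legitimately moves frequencies. The test conditions on that regime by
setting the generation interval longer than the year range.

## Numerical choices, degenerate inputs, reproducibility

* Variance-ratio optimisations run on the log scale over [−10, 10] (REML)
  or [−12, 12] (GWAS); likelihood evaluations that fail Cholesky or give
  non-positive quadratic forms return −∞ and are skipped by the grid.
* LRT statistics are floored at 0 (the full-model optimum can fall a
  rounding error below the null's), so p-values stay in (0, 1].
* A MAF threshold of exactly the boundary is retained (≥, not >), matching
  the convention that `--maf 0.05` keeps a 5% site.
* Dosage {0,1,2} counts ALT alleles; the heterozygosity indicator is
  1 iff dosage = 1. REF/ALT label swaps leave kinship, π, H and r²
  invariant, and the tests assert it.
* Every stochastic function takes an explicit seed and restores the RNG
  state (`withr::with_seed`); identical configuration + seed gives
  bit-identical output, which the pipeline turns into byte-identical
  output files (manifests carry parameters, seed and checksums, never
  timestamps).
* Problem sizes in the tests and the acceptance script are scaled-down
  study analogues: panels of 50–300 cultivars, 10⁴-ish variants,
  2-fold × 5–100-replicate CV, and 20-seed medians for stochastic
  properties. Selection-scan windows in the acceptance script use 150/30
  sites rather than the 500/100 pipeline default because a 500-site window
  at desk-scale density spans a quarter chromosome; the window must stay
  small relative to the signal region for the ranking to mean anything.

## Known limitations

* The GWAS fits one variant at a time; no multi-locus or haplotype-based
  association, no fine-mapping.
* The Gibbs path is provided for fidelity to Bayesian kernel-regression
  practice; it is slower than REML and the package's default inference is
  deliberately the deterministic path.
* `read_vcf` expects a finished, imputed VCF; depth- or quality-based
  site filtering belongs upstream.
* Sweep detection by composite likelihood (SweepFinder-style CLR) is out
  of scope; ROD and the H indicator are the implemented scans.
* Chromosome lengths default to the last variant position when no
  assembly lengths are given, which slightly shortens the weight of
  sparsely covered chromosome ends.
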