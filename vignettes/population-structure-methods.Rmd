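---
title: "Methods: population structure, differentiation and its cost in power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population structure, differentiation and its cost in power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popstruct)
```

popstruct analyzes within-country genetic structure in pooled multi-study SNP
cohorts and quantifies what that structure costs a case-control association
study. This vignette is the package's own account of the models and the
numerical choices behind each stage, and of what the test suite does and does
not demonstrate.

## The synthetic cohort and the Balding–Nichols model

No suitable cohort of this kind is publicly distributable, so the package is
developed and validated against a generator with known ground truth. Each SNP
receives an ancestral minor allele frequency $p \sim U(0.05, 0.5)$ by
default; subpopulation $k$ with drift parameter $F_k \in [0,1)$ draws its
frequency from the Balding–Nichols distribution

$$p_k \sim \mathrm{Beta}\left(p\,\frac{1-F_k}{F_k},\; (1-p)\,\frac{1-F_k}{F_k}\right),$$

which has mean $p$ and variance $F_k\,p(1-p)$; $F_k = 0$ is handled exactly
as $p_k = p$. Genotypes are $\mathrm{Binomial}(2, p_k)$. Under this model two
subpopulations diverged by $F_1$ and $F_2$ have an expected Hudson $F_{st}$
of $(F_1+F_2)/2$ regardless of the ancestral-frequency distribution, because
the expected numerator $ (F_1+F_2)\,p(1-p)$ and denominator $2\,p(1-p)$ carry
the same $p(1-p)$ factor. The test suite checks the estimator against this
expectation computed by numerical integration over the Beta mixture, not
against a re-implementation of the estimator.

Defaults place six subpopulations on a south-north latitude axis
(55.5°–67.5°N) with $F_k$ rising from 5×10⁻⁴ to 5×10⁻³, giving pairwise
$F_{st}$ between ~5×10⁻⁴ and ~4×10⁻³ — the magnitudes reported for
within-country structure in northern Europe, with the admixture source
($F = 0.02$) at roughly the divergence of a neighbouring country's isolate
population. SNPs sit at uniform 50 kb spacing (configurable; the ROH filters
are bp-denominated, so tests that plant 2 Mb/100-SNP runs use 20 kb spacing)
on one or more synthetic autosomes. Study labels are assigned round-robin
within subpopulation so platform and geography are unconfounded unless
`confound_study_geography = TRUE` deliberately confounds them.

Planted artifacts exercise specific QC stages: duplicate, parent-offspring
and full-sib pairs (Mendelian transmission) for the relatedness filter;
allele-level admixture ($\mathrm{Binomial}(2, \alpha p_{src} + (1-\alpha)p_k)$)
for the ancestry exclusion; per-study missingness and strand flips (genotypes
recoded $2-g$ in one study) for the call-rate and one-vs-rest filters; and
homozygous runs (a doubled haplotype drawn from subpopulation frequencies)
for the ROH scanner. Each injection draws from a sub-stream derived from the
master seed by a fixed offset, so injections are order-independent and a
fixed seed reproduces the dataset byte for byte.

What the generator does **not** emulate: linkage disequilibrium and
recombination (SNPs are exchangeable draws, so LD pruning is validated on
separately constructed correlated blocks, not on the cohort), phased
haplotypes, genotyping-intensity artifacts beyond missingness/flips, and the
X chromosome. Passing tests therefore demonstrate correctness of the
estimators under the stated sampling models, not robustness to every failure
mode of real array data.

## Merging and SNP/sample QC

Datasets are restricted to the SNPs of the largest (reference) dataset
present in all others. Allele pairs are reconciled against the reference:
identical pairs pass, swapped pairs have dosages recoded $2-g$, and
complementary-strand labels are normalized — except A/T and C/G pairs, which
are their own complements and cannot be checked; they are dropped whenever
labels disagree. Irreconcilable SNPs are dropped and counted separately from
the threshold filters.

The four SNP filters are applied to the same starting set: call rate ≥ 0.95
within **every** study; MAF ≥ 0.01 and the Hardy-Weinberg exact test
(p ≥ 10⁻⁶) on **all studies combined**; and a 1-df allelic chi-square
comparing each study against the pooled rest, flagging a SNP when any
comparison gives p < 10⁻⁶. The exact HWE test (rather than the asymptotic
chi-square) is used because at p thresholds of 10⁻⁶ the asymptotic tail is
unreliable; it is computed by the standard recurrence over heterozygote
counts conditional on allele counts, summing probabilities no greater than
the observed configuration (ties admitted with a 10⁻¹⁰ relative buffer).
The one-vs-rest statistic is the allelic (allele-count) chi-square, chosen
for consistency with the power-simulation statistic; degenerate tables give
p = 1. The QC report carries, per filter, both the total SNPs removed and
those removed *solely* by that filter, and the two accountings are checked
for mutual consistency.

Relatedness uses method-of-moments IBD estimation from IBS counts. The
expected IBS-given-IBD probabilities involve monomials $p^aq^b$ of the true
allele frequency; plugging in sample frequencies biases $\hat\pi$ upward, so
unbiased falling-factorial estimators
($\widehat{p^2q^2} = x(x{-}1)y(y{-}1)/[n]_4$ with $x$, $y$ the allele counts)
replace them. State probabilities are truncated into $[0,1]$ and
renormalized; $\hat\pi = P(2) + P(1)/2$. Pairs with fewer than 100
informative SNPs are flagged unreliable. Removal is greedy: the pair with
the largest $\hat\pi$ above 0.20 loses its higher-missingness member (tie:
higher index) until no pair violates — the tool the field uses leaves this
tie-break unspecified, so it is fixed and documented here. Sample
missingness (> 2%, strict) is evaluated on the post-SNP-QC marker set,
after relatedness removal. With only ~10³ SNPs $\hat\pi$ has sampling noise
of a few hundredths plus truncation-induced positive bias, so thresholding
at 0.20 needs a few thousand markers to be reliable; the calibration test
(50 unrelated and 50 parent-offspring pairs at 10⁴ SNPs, means within
±0.02) documents the regime in which the estimator is trusted.

## LD pruning

Within each chromosome a 200-SNP window advances in 25-SNP steps over the
surviving SNPs; within a window, while any pair exceeds $r^2 = 0.2$
(squared Pearson correlation of dosages over pairwise-complete samples;
zero-variance columns define $r^2 = 0$), the first violating pair in scan
order loses one member: higher missingness, then lower MAF, then larger
position. The full sweep runs twice — the second pass catches LD straddling
the first pass's window boundaries. The removal rule is the package's own
deterministic choice (the field's standard tool leaves its internal order
unspecified); correctness is checked against an exhaustive small-window
oracle applying the same rule.

## PCA, ancestry exclusion and projection

Columns are Patterson-normalized: centered by mean dosage and scaled by
$\sqrt{\hat p(1-\hat p)}$ with the shrunk estimate
$\hat p = (1+\sum g)/(2+2n)$; missing entries become 0 after centering and
so sit at the column mean. Eigendecomposition of the sample-sample
covariance gives eigenvalues equal to squared singular values over $n-1$;
each component is oriented so its largest-magnitude SNP weight is positive,
making runs reproducible. Projection of external samples applies the stored
center/scale and SNP weights — a training sample projects onto its own score
to machine precision, and an all-missing sample lands exactly at the origin.

Ancestry exclusion is a configurable half-plane in the (PC1, PC2) plane
(unit normal + offset, strict inequality; boundary samples are kept): the
published analyses draw such a cutoff empirically, so the package treats it
as data, never a constant. Remaining outliers are removed by the
nearest-neighbor rule: for $k = 1..5$, each sample's distance to its $k$-th
nearest neighbor (in normalized-genotype space by default) is standardized
and samples with $z > 4$ are removed, accumulating over $k$ — the sweep over
higher $k$ exists because two co-located outliers hide each other at
$k = 1$. Distances are computed once on the full sample set per $k$.

Geography is summarized by OLS regressions of a PC on latitude, longitude,
and the increment $\Delta R^2$ of adding longitude to the latitude model;
binary ancestry annotations are related to PCs by logistic regression with
Nagelkerke's rescaled $R^2_N = (1-(L_0/L_1)^{2/n})/(1-L_0^{2/n})$, where a
residual deviance of zero (perfect separation) is reported as a failure
rather than a number.

## Pairwise F_st and the genomic-control translation

The Hudson estimator is combined across SNPs as a ratio of averages
$\sum_j N_j / \sum_j D_j$ — averaging per-SNP ratios is biased on
heterogeneous data, and a regression test asserts the implementation
computes the former. SNPs enter a pair's estimate when both groups have at
least two genotyped samples and the pooled pair is polymorphic. Negative
estimates are reported as computed but floored at zero for the λ
translation, clustering and MDS. Standard errors come from a block jackknife
over contiguous SNP blocks. Groups below a configurable minimum size
(default 20) are excluded with a warning, because F_st at these magnitudes
is meaningless for a dozen samples.

The expected genomic-control inflation of a fully stratified study of
$n$ samples is the exact linear map $\lambda = 1 + n F_{st}$; the shipped
reference table of published national-area values confirms the translation
reproduces every printed λ within rounding (±0.005). Clustering of the
F_st matrix uses complete linkage (the default of the standard hierarchical
clustering routine) on the zero-floored matrix treated as distances, and the
MDS is classical scaling (double-centered $-D^2/2$, negative eigenvalues
truncated), with a residual stress reported.

## Runs of homozygosity

Every contiguous 20-SNP window is homozygous when it contains at most one
heterozygote; missing genotypes count as neither heterozygous nor homozygous
(the window still spans 20 SNPs). A SNP is a segment candidate when at least
10% (inclusive — "at least" is read as ≥) of the windows covering it are
homozygous; maximal candidate runs become segments bounded by their first
and last candidate SNP, then filtered to ≥ 1 Mb, ≥ 50 SNPs and ≤ 5%
heterozygotes. Chromosomes shorter than the window produce no calls, with a
warning. Calls are invariant to allele orientation, and the scanner is
required to agree exactly with a brute-force enumeration oracle on fixtures
up to 500 SNPs.

The inbreeding coefficient is $F = (O_{hom}-E_{hom})/(N-E_{hom})$ with
$E_{hom} = \sum_j\left(1 - 2p_j(1-p_j)\tfrac{A_j}{A_j-1}\right)$ over the
sample's non-missing SNPs ($A_j$ = alleles behind $\hat p_j$). Segment
counts are modelled by log-link Poisson regression on latitude (continuous)
or group (categorical, configurable baseline), always adjusting for source
study because studies differ in both platform and sampling geography;
group-coefficient p-values are Bonferroni-adjusted (configurable) across
groups.

## Power under genomic inflation

Case allele frequency follows from the allelic odds ratio,
$p_1 = \mathrm{OR}\,p_0/(1-p_0+\mathrm{OR}\,p_0)$. Per replicate the risk
allele count is binomial at the allele level (2N draws — HWE is implicitly
assumed, matching the 1-df allelic statistic), the chi-square is computed
from the 2×2 allele table, **divided by λ**, and compared with the
$\chi^2_1$ critical value at 5×10⁻⁸; deflating the statistic is
algebraically identical to inflating the critical value, and a test asserts
that identity. Degenerate tables count as non-rejections. Power is the
rejection fraction over 10,000 replicates (Monte-Carlo SE ≈ 0.4 pp near
80% power) with an exact binomial CI, cross-checked against the noncentral
chi-square closed form with noncentrality
$(p_1-p_2)^2/\left[\bar p(1-\bar p)\left(\tfrac{1}{2n_1}+\tfrac{1}{2n_2}\right)\right]$.

```{r power, eval = FALSE}
simulate_power(power_scenario(maf_controls = 0.16, odds_ratio = 2,
                              lambda_gc = 2, seed = 1))$power
power_closed_form(maf_controls = 0.16, odds_ratio = 2, lambda_gc = 2)
```

## Problem sizes, tolerances and limitations

The test suite validates at sizes chosen to make Monte-Carlo bounds sharp
while keeping the full run around a quarter of a minute: F_st recovery on
10⁵ SNPs (within 3 jackknife SEs of the integrated expectation), HWE
against enumeration to 12 significant digits for n ≤ 200, π̂ classes at
5×10⁴ SNPs (±0.05) and calibration at 10⁴ SNPs (±0.02 on means over 50
pairs), PCA projection at 10⁻⁸, the ROH oracle on ≤ 500-SNP fixtures, and
the Poisson latitude coefficient at n = 5000 (±0.02 around a planted 0.20).
The analysis drivers under `analysis/` run a 600-sample × 8000-SNP cohort,
a deliberately modest size that still separates all planted structure.

Known limitations: the pipeline assumes biallelic autosomal SNPs in PLINK 1
format (no VCF, dosages or PLINK 2); $\hat\pi$ and F_st both treat SNPs as
independent, so heavy LD inflates their effective precision; the
nearest-neighbor outlier removal is not iterated jointly with the PCA (the
explicit cutoff plus NN sweep replaces the iterative outlier loop some PCA
tools apply); ancestry exclusion happens before neighbor-based outlier
removal, and the reverse order would give slightly different removals; and
the power simulation covers the allelic test only, not covariate-adjusted
logistic models.
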