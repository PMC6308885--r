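---
title: "Methods: partitioned species-genetic diversity correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioned species-genetic diversity correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgdcpart)
```

# Rationale

Species-genetic diversity correlations (SGDCs) measure the covariation
between the genetic diversity of a focal species and the diversity of its
surrounding community. In a network of discrete habitat patches, drift and
migration are expected to shape allelic diversity and species richness in
parallel, so a *neutrally driven* SGDC should strengthen when loci under
selection are removed from the SNP panel, and weaken (or invert) when only
putatively selected loci are used. `sgdcpart` operationalizes this
contrast: it partitions a post-QC SNP panel into five datasets using two
complementary outlier scans, then estimates site-level (alpha) and
landscape-level (beta) SGDCs for each dataset with parametric, Mantel and
subset-randomization tests.

The five datasets are: DS1, every post-QC locus; DS4, the union of the two
scans' outlier flags; DS5, their intersection; DS2 = DS1 minus DS4; DS3 =
DS1 minus DS5. Under neutral drivers one expects the richness alpha-SGDC
ordering r(DS2) >= r(DS1) >= r(DS4) on average, since DS2 is the cleanest
neutral panel and DS4 the most contaminated by selected loci. The test
suite checks this ordering as a 20-seed average on synthetic data, not per
replicate: in any single replicate the simulated selective gradient can by
chance correlate with connectivity, pulling the outlier datasets along.

# Quality control

`apply_qc()` runs eight steps in a fixed order: (1) genotypes under
`min_genotype_depth` reads (default 10) become missing; (2) loci with mean
depth over non-missing genotypes above `max_mean_locus_depth` (50) are
dropped as paralog-prone; (3) loci with a missing fraction at or above
`max_locus_missing` (0.40; a stricter 0.30 preset exists) are dropped; (4)
minor allele frequency below `min_maf` (0.04), computed from allele counts
over non-missing genotypes only, drops a locus; (5) only biallelic variant
records are kept, judged from the record's allele list rather than from
observed dosages; (6) observed heterozygosity above `max_obs_het` (0.5)
drops a locus (a paralog screen); (7) individuals genotyped at fewer than
`min_call_rate` (0.40) of loci are removed; (8) populations left with
fewer than `min_per_population` (4) individuals are removed. Steps 3 and 4
do not commute — MAF changes when the denominator changes — so the order
is fixed and the report records the counts surviving each step. Boundary
behaviour at the 40% thresholds is strict-less for retention (a locus with
exactly 40% missing data is dropped; an individual with exactly 40% call
rate is kept).

Hardy-Weinberg departures are *reported*, never used to drop loci. The
per-locus test compares observed genotype counts to their expectation at
the sample allele frequency with a chi-square discrepancy, and builds the
null by re-pairing the 2n observed allele copies into n genotypes; the
p-value uses the add-one rule (b+1)/(m+1). These permutation p-values are
discrete and conservative by construction, so the suite checks validity
(P(p <= t) <= t) and exact agreement with Levene's conditional pairing
distribution rather than raw Kolmogorov-Smirnov uniformity, which a tied
discrete statistic cannot satisfy against a continuous reference.

# Outlier scans

**Structure scan** (`pca_scan`). Dosages are standardized per locus
(centered at 2p-hat, scaled by sqrt(2 p-hat (1-p-hat)); missing entries
mean-imputed after centering), the leading k components are taken from an
SVD, and each locus is scored by the z-statistics of its regression on the
k component scores. The squared Mahalanobis distance of each z-vector is
computed with a minimum-covariance-determinant (MCD) estimate, rescaled by
the genomic inflation factor lambda = median(D^2)/median(chi-square_k),
referred to a chi-square(k) upper tail, and thresholded at a 10% FDR via
Benjamini-Hochberg. Two numerical choices matter here:

* *Robust covariance at every k.* Classical moments break the lambda
  calibration as soon as genuine outliers exist — in a synthetic scenario
  with ~13% clinal loci and k = 1, the classical variance is inflated by
  the outliers and lambda collapses to ~0.07, silently flagging nothing or
  everything. Univariate MCD restores lambda to ~1.2-1.4, so MCD is used
  for all k (seeded, hence deterministic), with classical moments only as
  an error fallback.
* *Scree elbow convention* (`choose_k`). The maximum-distance-to-chord
  rule locates the corner where the scree plateau begins; the number of
  structured components is the point *before* that corner, so a
  one-dominant-then-flat spectrum yields k = 1. A perfectly flat spectrum
  yields k = 1 with a warning. The scree values are returned so the choice
  can be overridden — scree reading is ultimately manual judgement, and
  the scan accepts any k.

**Genotype-environment scan** (`rda_scan`). Individual dosages (missing
values imputed to the locus's modal genotype — a different convention from
the PCA scan, each mirroring its reference method) are regressed on the
site-level predictors replicated per individual, and the fitted values are
eigen-decomposed into constrained axes (redundancy analysis, via
`vegan::rda`). Individuals, not site means, are the observation unit; the
environment is constant within a site. Each axis is tested by an
ANOVA-like permutation of predictor rows across individuals with forward
conditioning on earlier axes (`vegan::anova.cca(by = "axis")`). Retained
axes are those significant at `alpha` (0.05) up to the eigenvalue scree
elbow; when scree and significance disagree the intersection is used, and
`axes = n` overrides both, since the two criteria have no canonical
precedence. Loadings on retained axes are standardized to z-scores and a
locus is flagged outside [Q1 - 2 IQR, Q3 + 2 IQR] on any retained axis.
The "twice the interquartile range" convention is ambiguous about its
anchor; the quartile-anchored Tukey-fence reading is the default and a
median-anchored variant plus the multiplier are config options. Each
retained axis also reports its most strongly correlated predictor.

Before the scan, `prescreen_environment()` iteratively removes the
variable with the most pairwise |r| > 0.7 partners (ties: larger mean |r|,
then name order), and `vif_check()` verifies variance inflation factors
(warning above 5, infinite VIF reported for exact collinearity).
Categorical predictors enter as 0/1 indicators (a two-level factor
contributes one column).

# Diversity measures

Expected heterozygosity is the plug-in estimator He = 1 - sum(p-hat^2)
averaged over loci with at least four genotyped individuals at the site
(the threshold below which the estimate was judged unstable; it is an
argument). The small-sample 2n/(2n-1) correction is off by default to
match the convention of the gstudio-style tools that produced the
packaged reference table; it is available as a flag. Sites where a locus
fails the minimum are skipped for that locus only, and a site with no
qualifying locus reports `NA`, never 0.

The Cavalli-Sforza chord distance is implemented as
D = (2/pi) sqrt(2 (1 - (1/L) sum_l sum_u sqrt(X_lu Y_lu))) — the
per-locus allele-sharing terms averaged *inside* the radical. The source
formula in the motivating literature is typographically garbled, so the
normalization was fixed by its verifiable consequences: identical
profiles give 0, a single opposite-fixed locus gives (2/pi) sqrt(2)
(~0.900), and a half-identical pair gives 2/pi (~0.637), all asserted in
the tests; the variant averaging outside the radical is available via
`average = "outside"`. Loci lacking a defined frequency in either site of
a pair are dropped pairwise.

Community indices: richness S counts species with positive pooled
biomass; Shannon H' uses natural logs on biomass shares; Pielou
J = H'/ln S is `NA` when S = 1. Bray-Curtis runs on log10(x+1) biomass
through `vegan::vegdist`; the denominator is total transformed abundance
per site (the standard quantitative form). Reading the denominator as a
species *count* would make the index independent of the abundances being
transformed, so that reading was rejected for internal consistency.

# SGDC inference

Alpha-SGDCs are Pearson correlations tested with the exact t transform on
n-2 degrees of freedom. The default tail is one-sided positive: the
motivating prediction is directional (more connectivity, more of both
diversities), and the package's fixture-derived p-values (0.095 for
r = 0.334 at n = 17) are consistent with that convention; `tail =
"two.sided"` is available. Beta-SGDCs use a Mantel test over the
n(n-1)/2 site pairs with joint row/column permutations and the add-one
rule; the implementation is package-owned and cross-checked against
`vegan::mantel` in the tests.

`subset_randomization()` asks whether the SGDC of an outlier dataset
could arise by chance from a reference panel: it draws 999 (configurable)
equal-size locus subsets from the reference, recomputes the SGDC for
each — per-site He for alpha, a full chord-distance matrix per subset for
beta, with the per-pair allele-sharing terms precomputed once so the cost
is a row-mean per subset — and locates the observed value in that null.
The conventional tails are lower for alpha (are outlier SGDCs unusually
low?) and upper for beta. Degenerate draws (reference = outlier set)
return p = 1 by the as-or-more-extreme counting rule, which the tests
assert.

`compare_marker_panels()` correlates two per-site diversity vectors and
greedily removes the site whose exclusion most increases r while the gain
exceeds a threshold (default 0.05, at most 3 sites). On the packaged
table this flags exactly the two sites whose SNP diversity is
conspicuously low against the AFLP panel (S21, then S6), moving r from
0.70 to 0.90.

# The synthetic scenario

The generator emulates a fragmented wetland metapopulation. Per site i, a
connectivity c_i in [0,1] sets the drift concentration theta_i =
theta_min + c_i (theta_max - theta_min); neutral locus frequencies are
Beta-distributed around an ancestral frequency drawn uniform on
[0.05, 0.95], so poorly connected sites drift further and lose
heterozygosity. Adaptive loci follow logit(p_il) = logit(pbar_l) +
b (E_i - mean E) + N(0, 0.3) along an environmental gradient E that is
independent of connectivity by default. Frequencies are clipped to
[0.01, 0.99] so the realized MAF spectrum stays compatible with the
MAF >= 0.04 filter. Genotypes are Binomial(2, p_il); depth is negative
binomial with mean 30 (the scale of a typical GBS run) and dispersion 5;
genotypes are masked missing at rate 0.05. Community richness is
round(10 + 10 c_i + N(0, 1.5)) clipped to [2, 40], species identities are
drawn with Gaussian niche weights along the connectivity gradient (width
0.35) so compositional similarity decays along it, and biomass is
log-normal (sdlog 1). The environment table carries E, nuisance variables
at correlations {0.9, 0.5, 0.3, 0} with E — one above the 0.7 prescreen
threshold by design — and a two-level categorical. Defaults mirror the
study scale (17 sites, 9 individuals/site, 1480 + 229 loci).

What the generator does *not* emulate: linkage (loci are independent),
explicit migration or spatial coalescent structure, allele-frequency
spectra skewed toward rare variants, locus-specific depth biases, and any
coupling between selection and connectivity. Passing tests therefore
demonstrate that the machinery recovers the structure it assumes, not
that real GBS data meet those assumptions.

Reproducibility: each stage seeds its own stream deterministically from
the master seed (offsets for site drivers, genotypes, community,
environment), so stages are reproducible individually and jointly, and
`run_sgdc_pipeline` is byte-identical across runs of the same config.

# Problem sizes and limitations

The test suite and acceptance script use deliberately scaled problem
sizes chosen to exercise every code path at desk-scale cost: PCA null
calibration at 500 loci x 100 individuals; Mantel type-I over 200
replicates of 199 permutations; subset-randomization null over 100
replicates of 99 subsets; the dataset-ordering property over 20 seeds of
a 17-site, 6-individual, 460-locus scenario; the end-to-end acceptance
run at 17 x 9 with 690 loci, 499 axis permutations and 199 subsets.
Production analyses would raise the permutation counts (9,999 for axis
tests and Mantel, 999 subsets) — the defaults of the respective
functions.

Known limitations: no latent-factor genotype-environment methods, no
haplotype- or LD-based scans, no rarefaction of richness, no
variance-partitioning of SGDCs into shared environmental drivers, and no
handling of ploidy other than diploid. The VCF reader accepts
coordinate-free placeholder contigs (as produced by reference-free GBS
pipelines) but does not parse phased multiallelic genotypes beyond
flagging the record for exclusion.
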