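---
title: "Methods: population structure and stratified GWAS from low-coverage genotype panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population structure and stratified GWAS from low-coverage genotype panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcpopgen)
```

## The problem

Genotyping a mosquito population by whole-genome sequencing at a mean
depth of a few reads per site is cheap enough to run on hundreds of
specimens, but every per-genotype call is uncertain: at depth 3 a
heterozygote is regularly read as a homozygote, and many sites have no
reads at all. `lcpopgen` implements the complete analysis chain that
makes such panels usable for two questions asked at microgeographic
scale (collection points 2–3 km apart):

1. is there detectable population stratification between collection
   sites, and
2. are any SNPs associated with binary behavioural phenotypes (indoor
   vs outdoor biting; blood-seeking at dusk vs dawn), once collection
   site is controlled for?

The chain is: genotype- and site-level QC → posterior-gated genotype
imputation → LD-decay-informed marker pruning → permutation-tested
FST, PCA and k-means stratification → continuity-corrected
Cochran–Mantel–Haenszel (CMH) association with gene-adjacency
annotation. A Balding–Nichols simulator generates statistically
matched synthetic panels, with a truth sidecar, so that every stage is
testable without any sequencing data.

## Quality control

**Genotype-level masking.** A genotype is queued for imputation when
`DP < 5` or `GQ < 20` (`mask_low_confidence()`). Both thresholds are
strict inequalities and exposed as arguments.

**Site-level filters** (`site_filters()`) come in three modes whose
boundary semantics follow the working rules of this kind of pipeline
literally, because the rules are quoted with strict inequalities in
both directions:

| mode | keep rule |
|---|---|
| `pre_imputation`  | MAF ≥ 0.1 and MD ≤ 0.5 |
| `post_imputation` | MAF > 0.1, MD < 0.3, within-stratum HWE p ≥ 0.001 |
| `raw`             | MAF > 0.1, MD < 0.8, ≥ 15 non-missing genotypes in every stratum, within-stratum HWE p ≥ 0.001 |

A site at MAF exactly 0.1 therefore survives the pre-imputation filter
but not the post-imputation one. Each removed site is attributed to
the first failed rule in the fixed order MAF → MD → stratum support →
HWE, so per-rule counts sum to the total. The raw-mode global MD
ceiling and the per-stratum support rule are both enforced, since
either reading of the rule is defensible and the conjunction is the
conservative one.

**Hardy–Weinberg testing** is the conditional exact test on the
heterozygote count given the allele counts (two-sided, summing the
probabilities of all configurations no more probable than the observed
one; no mid-p). It is evaluated *within* collection-site strata: a
deficit of heterozygotes in the pooled panel that disappears within
sites is the signature of a Wahlund effect, i.e. of real structure,
and must not delete the informative sites. The implementation uses the
standard probability recurrence across heterozygote counts; the test
suite checks it against direct log-factorial enumeration to 1e-12 for
up to 100 diploids.

## Imputation with a posterior gate

The imputer is a deliberately simple, site-independent frequency-prior
EM refiner (`em_site_frequency()`, `genotype_posteriors()`): per site,
the alternative-allele frequency is estimated by EM over genotype
posteriors formed from the phred likelihoods `10^(-PL/10)` and a
Hardy–Weinberg prior, and each masked genotype receives the posterior
triple `GP`. This is *not* a haplotype imputer — it shares no
information across sites — and we document that as a genuine
limitation rather than hiding it: panels imputed by an external
haplotype-aware tool can be ingested through `read_panel_vcf()`, whose
`GP` field then bypasses the EM step entirely and flows through the
same acceptance gate.

The gate (`apply_imputation()`) accepts a masked genotype only when
`max(GP) ≥ 0.95`; otherwise the genotype becomes missing, and — a
decision the pipeline needs but the usual description leaves open —
*failed-gate genotypes count as missing data* in the subsequent
post-imputation MD filter. EM starts from the frequency implied by the
likelihood-maximizing calls (falling back to 0.5), converges when the
frequency moves < 1e-8, and labels all-flat-PL sites with a warning
rather than inventing information.

## LD decay and pruning

Pairwise LD is the squared Pearson correlation of dosage vectors over
complete pairs (`pairwise_r2()`). Averages are taken in forty 500-bp
distance bins spanning 20 kb, with half-open bin assignment
`ceiling(d / 500)` (`bin_ld_by_distance()`). The decay model

$$\hat Y = \beta_0 + \beta_1 \frac{1}{\ln x}$$

is linear in the transformed predictor `1/ln(x)` and is fitted by least
squares (`fit_decay()`). The logarithm is natural: with coefficients of
the magnitude seen in mosquito panels (β0 ≈ −0.40, β1 ≈ 4.76), a
base-10 reading would put the r² = 0.1 crossing near 10^9.5 bp, beyond
any chromosome, while the natural-log reading gives ≈ 13.6 kb —
consistent with the window size such pipelines actually adopt (14 kb,
the crossing rounded up to the kb).

`solve_crossing()` inverts the fitted curve in closed form,
`x* = exp(β1 / (t − β0))`, and alternatively root-finds the crossing of
the pointwise 95% confidence band for the mean response (the band is
the standard linear-model construction on the transformed predictor;
nothing in the decay model prescribes a particular band, so the choice
is exposed via `conf_level`). Pruning (`prune_ld()`) is the greedy
left-to-right windowed scan: a marker is dropped when its r² with any
retained marker within the window exceeds the threshold. The pruning
statistic is pairwise r² with threshold 0.1 — taken from the
window-selection criterion ("average r² between 0.1 and 0.05") since
no separate pruning threshold is stated — and both window and
threshold are plain arguments.

## FST, permutation testing and stratification

Per-SNP FST uses the identity-by-state formula

$$F_{ST} = \frac{GS - GT}{1 - GT}$$

with `GT` the IBS probability of two alleles from the pooled sample and
`GS` the IBS probability within groups (`snp_fst()`). Two deliberate
estimator decisions deserve attention:

**Group weighting in GS.** The formula does not say how groups combine
into `GS`. We default to weighting each group by its observed allele
count, which puts `GS` on the same footing as the allele-count-weighted
pooled `GT`. The seemingly innocuous alternative — an unweighted mean
over groups — interacts pathologically with unbalanced designs: for a
160-vs-39 comparison with genuine divergence F = 0.04, the expected
unweighted ratio is ≈ 0.0006 (Monte-Carlo over Balding–Nichols
frequencies), because the asymmetry between unweighted `GS` and
weighted `GT` cancels almost the whole signal, and a permutation test
built on it loses the ability to detect structure the design plainly
contains. The unweighted variant remains available
(`weighting = "unweighted"`) for balanced designs, where the two
coincide.

**IBS versus variance components.** The IBS ratio is a descriptive
statistic, not an unbiased estimator of the divergence parameter: at
two groups its expectation is roughly half the nominal Balding–Nichols
F, plus a finite-sample term of order `pq/2n`. That bias is shared by
the permutation null, so significance testing with it is sound; but
*parameter recovery* is not, and for that purpose the package provides
the Weir–Cockerham (1984) variance-components estimator
(`mean_fst(..., estimator = "wc")`, aggregated as a ratio of sums),
which recovers nominal F within Monte-Carlo tolerance in the test
suite at 5,000 SNPs.

`fst_permutation()` shuffles group labels (unrestricted across stage
and behaviour labels; a restricted shuffle would only be needed if
those covariates structured the panel, which the simulator does not
plant) and uses the add-one convention
`p = (1 + #\{permuted ≥ observed\}) / (1 + n_perm)`: with 10,000
permutations the smallest attainable p-value is 1/10001 ≈ 1.0e-4.
Per-SNP p-values receive Benjamini–Hochberg correction, and SNPs with
q ≤ 0.05 are flagged stratification-informative. The permutation
engine batches label shuffles into matrix products, so the full-scale
run (199 samples × 5,000 SNPs × 10,000 permutations) takes seconds.

PCA (`pca_panel()`) mean-imputes missing dosages per SNP,
standardizes, and eigendecomposes; it is normally run on the
informative-SNP subset, but the subset is an argument, not hard-wired.
k-means runs on the top two components by default (the visualized
space; configurable). `optimal_k_twss()` encodes the elbow rule
verbally stated for such analyses: the optimal k is the smallest k
whose relative TWSS improvement to k+1 falls below δ = 0.10 while the
improvement into k is at least δ. The plateau threshold δ is exposed;
0.10 matches the "difference in percentage" bar-plot reading of the
rule. Monotonicity of TWSS in k is enforced by warm-starting each k
from the previous solution with its worst-fitted point split off, so a
poorly initialized restart can never report an increase. The
cluster-by-site association uses the plain Pearson chi-square
(`contingency_chi2()`), df = (r−1)(c−1), no continuity correction.

## Stratified association testing

`build_tables()` tallies, per SNP and per collection-site stratum, the
2×2 allele-count table of case/control × reference/alternative
(heterozygotes contribute one allele to each column; missing genotypes
contribute nothing). `cmh_test()` evaluates the continuity-corrected
CMH statistic

$$\chi^2_{MH} = \frac{\left(\left|\sum_i a_i -
\frac{(a_i+b_i)(a_i+c_i)}{n_i}\right| - \tfrac12\right)^2}
{\sum_i \frac{(a_i+b_i)(a_i+c_i)(b_i+d_i)(c_i+d_i)}{n_i^3 - n_i^2}}$$

against χ²(1). Two numerical details: strata with `n ≤ 1` (or a zero
variance term) contribute zero to both sums, and the ½ correction is
applied only when the summed deviation reaches ½ — the Yates-style
guard used by reference implementations — so the statistic equals the
formula above for every non-null table while near-null tables are not
pushed to a spurious positive value. `correct = FALSE` disables the
correction. The continuity-corrected test is conservative by
construction; the suite verifies one-sided type-I control for the
corrected statistic and two-sided calibration for the uncorrected one
under the synthetic null.

Phenotype dichotomies: cases are indoor-biting samples for the biting
phenotype, and dusk-captured samples for the blood-seeking phenotype.
The dusk window is 18:00–22:00 (`classify_capture_window()`): the two
printed descriptions of the window disagree ("06:00 and 22:00" versus
"06:00 to 10:00 PM"), and we adopt the evening reading, since a
16-hour "dusk" spanning daylight is an evident typo and the
complementary dawn window (02:00–06:00) only makes sense against an
evening counterpart.

Significant SNPs (BH-adjusted p < 0.05) are annotated with genes
within 10 kb on the same scaffold (`annotate_adjacent_genes()`,
distance 0 inside the gene body, else distance to the nearer end).
The 10-kb-each-way default follows the behaviour that reproduces
published adjacency lists, which include a gene 9,199 bp away; the
stricter 5-kb reading is available by setting `max_dist = 5000`.

## The synthetic-data generator

`simulate_panel()` emulates the statistical structure of the study
inputs, not the sequencing process:

- **Structure**: K subpopulations (default 3, one per collection site,
  with sample sizes 95/60/166 matching the Brazilian panel) with
  Balding–Nichols Beta-distributed allele frequencies around ancestral
  frequencies drawn uniformly from (0.1, 0.5]. The default divergence
  F = 0.002 sits in the microgeographic range (pairwise FST
  0.0005–0.0027); long-range comparisons use F = 0.04.
- **Sequencing evidence**: per-genotype depth Poisson(λ), allele reads
  binomial with 1% base error, PL as rescaled phred likelihoods with a
  zero minimum, GQ as the gap between the two smallest PL entries,
  calls likelihood-maximizing. λ defaults to 3: the mean depth of the
  emulated study is not reported, and 3 is what "extreme low-coverage"
  sequencing of multiplexed 60-sample runs delivers in practice.
  Zero-depth genotypes have a flat PL and are emitted missing rather
  than tie-broken.
- **Phenotypes**: two independent dichotomies (indoor/outdoor,
  dusk/dawn), balanced within strata. Causal SNPs shift the allele
  frequency by ±`causal_effect`/2 between cases and controls within
  every stratum — exactly the kind of effect the CMH statistic
  measures.
- **Physical structure**: SNPs on 20 synthetic scaffolds with uniform
  sorted positions, so all forty LD distance bins are populated.
  Optional first-order haplotype copying with per-bp decay rate
  `ld_rate` plants distance-decaying LD for exercising the decay fit;
  it is off by default to keep the null model simple.
- **Truth sidecar**: subpopulation frequencies, true dosages, causal
  indices, phenotype labels — the reference for accuracy and power
  checks.

What the generator does *not* emulate — haplotype structure from
recombination and demography, reference bias, batch effects, related
individuals, multi-allelic and indel sites — bounds what passing tests
mean: they demonstrate the statistical machinery is correct under its
stated model, not that any particular field dataset satisfies that
model.

## Problem sizes and numerical choices

The test suite and the acceptance script run simulations at desk
scale, chosen to make Monte-Carlo tolerances meaningful: 5,000 SNPs
and 50–100 samples per group for FST parameter recovery (±30% of
nominal F), 2,000 SNPs × 300 samples for the type-I check (99%
binomial bounds around 0.05), 10,000 permutations for the permutation
floor (1/10001), 1,000 random table sets for the CMH cross-check
(1e-6), and full enumeration for the HWE (n ≤ 100, 1e-12) and BH
(lists ≤ 6) comparisons. EM converges at 1e-8 on the frequency; the
decay fit requires ≥ 3 defined bins and refuses singular designs; the
permutation p-value can never be 0 by construction; monomorphic pooled
sites have undefined FST and are excluded from genome-wide means with
a reported count.

## Known limitations

- The internal imputer ignores LD between sites; its accuracy property
  (better than the always-major-genotype baseline) is deliberately
  weak, and real pipelines should feed externally imputed GP fields
  through the ingestion path.
- The IBS FST is reported because it is the printed form of the
  statistic this pipeline reproduces; for estimation use the WC
  option.
- The greedy pruner is order-dependent by construction (deterministic
  for a given panel); it audits cleanly against its own rule but is
  not an optimal subset selection.
- The elbow rule for k is a heuristic with an explicit δ; for weakly
  separated clusters (relative TWSS gains near δ) it is sensitive to
  that choice, which is why δ is an argument and the TWSS curve is
  returned for inspection.
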