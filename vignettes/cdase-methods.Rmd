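---
title: "Methods: condition-dependent allele-specific expression in cdase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: condition-dependent allele-specific expression in cdase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdase)
```

## The measurement model

cdase works on allelic read counts at heterozygous transcribed SNPs: for
SNP *s*, sample *i*, condition *c*, a pair (ref, alt) of read counts
whose ratio ref/(ref+alt) estimates the relative expression of the two
alleles. Because both alleles are measured inside the same cell
population, the comparison is internally controlled: *trans* factors,
environment and sequencing depth act on both alleles alike, and a
departure from 0.5 implicates a *cis*-regulatory difference between the
two haplotypes. A *change* of the ratio between a control and a
treatment condition in the same individual additionally implicates an
environmentally responsive *cis* effect (a genotype-by-environment
interaction). The package takes the counts as given; upstream concerns —
alignment, variant calling, mapping-bias removal — are assumed solved by
the count producer, and the only bias handled here is diagnostic (see
the simulator section).

Under the null of balanced expression the reference count at depth *n*
is Binomial(*n*, 0.5). This is the working assumption of both SNP-wise
tests; biological overdispersion (e.g. random monoallelic expression,
cell-composition noise) is *not* modelled by the tests, which is why the
simulator can generate overdispersed data to quantify the consequences.

## Stages, parameters, defaults

**Informative-site filter** (`filter_thresholds()`): ≥ 30 total reads,
≥ 3 reads per allele, minor-allele share ≥ 1%, autosomes only. These are
the standard coverage criteria for ASE scans at this sequencing depth;
all are inclusive ("at least"), and each is exposed because deeper or
shallower designs warrant different values. The 1% rule is evaluated on
the minor allele only — the major allele satisfies it whenever the minor
one does — and therefore binds only at depths above 300, where 3 reads
fall below 1%. Filters apply per (sample, condition) record; a SNP is
tested in a condition as soon as one sample passes there.

**SNP-wise static ASE** (`scan_static_ase()`): exact binomial p-values
per sample, Fisher's method across samples (χ² with 2k df), BH FDR per
condition across its tested SNPs. Significance defaults to FDR ≤ 0.05.
Samples failing the filter contribute nothing, not even degrees of
freedom.

**SNP-wise cd-ASE** (`scan_cd_ase()`): candidates are SNPs with
significant static ASE in ≥ 1 condition — the preselection keeps the
multiple-testing burden proportional to loci that can show a change at
all. Each sample informative in both conditions of a contrast yields a
2×2 Fisher exact test; combination and FDR as above, per contrast. Two
reporting columns need a per-sample criterion the combined test does not
give: `n_sig_samples` counts samples with *unadjusted* per-sample
p ≤ 0.05 (`per_sample_alpha`), and `ge3_samples_flag` marks SNPs with at
least three such samples. Both are descriptive flags, not filters: the
per-sample threshold is a reporting convention, so it is exposed and the
≥ 3-samples rule never removes rows.

**Gene-wise ASE** (`scan_gene_ase()`): observations are SNP × sample
pairs of a gene (only SNPs mapping to exactly one gene). Each
observation's exact p becomes z = Φ⁻¹(1 − p/2) ≥ 0, and the gene
statistic is the weighted Stouffer sum S = Σwᵢzᵢ/√(Σwᵢ²) with
wᵢ = √depthᵢ (configurable to equal weights to check sensitivity to the
weighting). Folding the sign away makes S a pure imbalance score: SNPs
of the same gene whose reference alleles sit on opposite haplotypes
still reinforce rather than cancel. The cost is that S is no longer
directional, which the empirical null accounts for by construction. The
null redraws every observation with its depth (static: Binomial(n, 0.5))
or its margins (conditional: hypergeometric) fixed, n_resamples = 10,000
by default (≥ 100 enforced), and the empirical p uses the add-one rule
(1 + #{S₀ ≥ S})/(n + 1) — unbiased under the null and never zero, so BH
downstream is safe. Genes need ≥ 2 contributing SNPs. The conditional
mode is restricted to genes with static ASE at ≥ 1 SNP, mirroring the
SNP-wise preselection.

**Haplotype verification** (`haplotype_ratios()`,
`compare_ratios_across_conditions()`): with an explicit phase table
(which allele of each SNP lies on H1), reads are pooled per haplotype
across the locus's SNPs for each heterozygous (H1H2) sample and
condition. Condition shifts are tested by paired t-tests against the
control with Bonferroni correction over the contrasts. A Dunnett
many-to-one procedure is the classical choice here; we use paired
t-tests because the same individuals are measured in every condition —
the pairing removes between-individual haplotype-ratio variance, which a
group-means ANOVA ignores — and Bonferroni over three contrasts is only
marginally more conservative than the multivariate-t allowance while
keeping the machinery minimal. The contrast set is identical.

## Numerical choices

- **Two-sidedness.** Exact tests use the minimum-likelihood convention
  (sum of probabilities of all outcomes no more probable than the
  observed one) with a relative tie tolerance of 1e−7 — the convention
  of `binom.test()`/`fisher.test()`, against which the implementation is
  cross-checked in the tests. A `double_tail` alternative (twice the
  smaller tail, capped at 1) is available for sensitivity analysis.
- **Probability tables.** P-values come from `dbinom`/`dhyper`
  probability tables computed once per depth or margin set and cached;
  this is what makes ~10⁷ exact-test evaluations per gene scan feasible.
- **Zero p-values.** Exact p-values are strictly positive, but clamping
  (`p_floor = 1e−300`) guards the log in Fisher's method and the normal
  quantile in the z conversion against underflow; a p of exactly 0 in
  user-supplied input is clamped with a warning.
- **Degenerate cases.** A 2×2 table with an empty condition row is a
  precondition error (the sample is uninformative); a table whose
  margins admit a single outcome has p = 1. Zero-variance paired
  differences in the haplotype comparison are reported as p = 1 (all
  differences zero) or the smallest positive double with a
  `degenerate` flag, rather than a meaningless t statistic.
- **Determinism.** Scans sort observations canonically before any
  computation, so results are invariant to input row order; all
  resampling derives from one configured seed (per-unit derived seeds
  inside the gene scan), making every scan bit-reproducible; result
  writers render doubles with 17 significant digits so repeated runs are
  byte-identical and values survive a read/write round trip exactly.
- **Discreteness and calibration checks.** Exact-test p-values are
  discrete and conservative: P(p ≤ t) ≤ t with equality exactly on the
  achievable values. The suite therefore checks per-sample calibration
  on randomized (Stevens) p-values — drawn uniformly between consecutive
  achievable values — which are exactly Uniform(0,1) iff the test is
  calibrated; a raw KS test on discrete p-values would reject any
  correct exact test merely for its discreteness.

## What the simulator emulates — and what it does not

`simulate_counts()` emulates the post-alignment count structure of a
stimulated-cohort design: by default 20 individuals, conditions C, D, L,
LD (vehicle control, dexamethasone, LPS, and their combination),
heterozygosity drawn once per individual × SNP (het_prob = 0.5, a
typical cohort heterozygote frequency at ascertained variable sites) and
held across conditions, read depths Negative-Binomial(mean 100,
size 5) — a realistic dispersion for mRNA-seq site coverage, leaving a
fair fraction of records below the 30-read filter — and effect classes
null / static ASE (ratio 0.7) / cd-ASE (0.5 in control, 0.65 in affected
treatments). Classes attach to genes by default (all SNPs of a gene
share the class), since *cis*-regulatory effects are haplotype-coherent;
a per-SNP mode exists for focused tests. Counts are beta-binomial with
mean μ and intra-class correlation ρ (α = μ(1−ρ)/ρ, β = (1−μ)(1−ρ)/ρ) —
an orthogonal parameterization of location and overdispersion — pure
binomial at ρ = 0, plus an additive reference bias shifting every mean
toward the reference allele (default 0; the mean null ratio is the
standard mapping-bias diagnostic). A small fraction of SNPs is placed on
chromosome X and a small fraction annotated to two genes, so the
exclusion rules are exercised.

Not emulated: read-level artefacts (the scalar ref_bias is the only
alignment-bias proxy), linkage between the allelic configurations of
neighbouring SNPs (each SNP's phase orientation is effectively
independent; counts from SNPs of the same gene are statistically
independent given the class, whereas real reads spanning two SNPs are
correlated), genotyping error, and sample-level covariates. Passing
tests therefore demonstrate that the statistics do what they claim under
the stated sampling model — not that real data meet that model; the ρ
and ref_bias dials exist precisely to probe departures.

## Design decisions that were genuinely open

- The gene statistic is described in the underlying methodology only as
  a meta-analytic combination of SNP-wise effects; the depth-weighted
  Stouffer sum over SNP × sample observations with margin-preserving
  resampling is this package's concrete instantiation. Pooling samples
  and SNPs into one observation set (rather than combining per-sample
  gene scores afterwards) keeps the null simple and exact; per-sample
  gene statistics are still reported as diagnostics.
- Whether the per-sample counts behind `n_sig_samples` should use raw or
  adjusted p-values is not fixed by the method's description; raw
  p ≤ 0.05 is the default, as adjusted per-sample values would conflate
  the SNP-level FDR with the sample-level evidence count.
- BH is applied within each condition (static) and within each contrast
  (cd and gene scans): each condition/contrast is reported as its own
  family.
- Autosome status is decided by an explicit chromosome-name list
  (default "1"–"18", the pig autosomes) rather than by pattern matching,
  since unplaced scaffolds must fall out as non-autosomal.
- Calibration runs pass `candidates =` explicitly to `scan_cd_ase()`:
  under a global null the static preselection (correctly) leaves no
  candidates, so type-I-error measurement of the cd test itself requires
  bypassing it. The preselection contract is tested separately.

## Problem sizes

The test suite and the acceptance script size their simulations to keep
a full run in minutes on one core while leaving the assertions
well-powered: exact-test oracles are exhaustive (all binomial outcomes
to depth 200; all 2×2 margins to 40), null calibration uses 2,000 SNPs ×
10 samples at depth 100, gene-level calibration 500 two-SNP genes at
10,000 resamples, and the end-to-end acceptance run 2,000 SNPs / 500
genes / 20 individuals / 4 conditions with 2,000 resamples in the gene
stage. These are deliberate analysis choices, stated here so they can be
scaled up when more stringent checks are wanted.

## Known limitations

- The SNP-wise tests are plain binomial / Fisher exact: overdispersed
  counts (ρ > 0) inflate their type-I error, and the package offers
  diagnosis (simulate at ρ > 0) but not an overdispersion-robust test.
- The gene-level resampling null treats observations as independent;
  correlation between nearby SNPs covered by the same reads inflates S
  relative to its null, making gene-level p-values anticonservative in
  proportion to that correlation.
- Haplotype ratios double-count reads spanning two phased SNPs, since
  the input is per-SNP counts; this is shared by any per-SNP pooling
  scheme.
- Phase is always an explicit input; the package neither infers
  diplotypes nor checks them against the counts.
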