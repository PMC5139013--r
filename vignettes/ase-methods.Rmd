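---
title: "Methods: allele-specific expression calling and differential allelic imbalance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific expression calling and differential allelic imbalance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aseflow)
```

## The problem

At a heterozygous SNP inside a transcribed region, RNA-seq reads carry
either the reference (REF) or the alternative (ALT) allele, and the
reference ratio REF/(REF + ALT) estimates the relative transcriptional
output of the two haplotypes. Balanced expression gives 0.5;
cis-regulatory variation, imprinting, or nonsense-mediated decay push it
away from 0.5 (allele-specific expression, ASE); a cohort-wide excess of
ratios above 0.5 is the signature of reference-mapping bias, because reads
carrying the ALT allele mismatch the reference genome and align slightly
less well. This package implements the full analysis path for a two-tissue
cardiac design — an atrial cohort with a binary clinical label
(postoperative atrial fibrillation) and a ventricular cohort sampled at
paired baseline/post-ischemia timepoints — but every stage is generic.

## Allele counting

Counting is deliberately conservative and transparent:

* Only uniquely mapped reads are used. A read is unique when its `NH` tag
  equals 1; when the tag is absent, mapping quality above a threshold
  (default MAPQ > 0, with MAPQ 255 treated as unavailable) stands in. The
  criterion is configurable because "unique mapping" is reported by
  aligners in both ways.
* The base at the SNP is located by walking the CIGAR string: `M`/`=`/`X`
  consume read and reference, `I`/`S` consume read only, `D`/`N` consume
  reference only; a deletion or splice junction spanning the SNP
  contributes nothing. Coordinates are 1-based throughout (VCF convention).
* Duplicate reads are kept by default (`remove_duplicates = FALSE`) and
  base quality is ignored by default (`min_base_quality = 0`); both are
  flags, since neither a duplicate policy nor a base-quality cutoff is part
  of the canonical cascade.
* Strand is ignored: both strands count toward the same allele.
* Reads overlapping two heterozygous SNPs count once per SNP; per-SNP
  totals are therefore not additive across SNPs.

## The filter cascade

Six stages, in order, each reported with SNPs/reads in and out:

1. at least one heterozygous individual;
2. at least `min_reads = 15` REF+ALT+OTHER reads per (SNP, individual)
   record — the minimum is applied per record, not to the pooled total,
   because pooled totals in real cohorts are in the thousands and a pooled
   rule would be vacuous (a `min_reads_scope = "pooled"` option exists);
3. exact Hardy–Weinberg equilibrium on the cohort's array genotypes at
   p > 1e-5. The test conditions on the observed allele counts; each
   compatible heterozygote count has probability proportional to its
   multinomial weight times 2^het, and the two-sided p sums configurations
   no more probable than the observed one. A chi-square variant is
   available behind `hwe_method = "chisq"`;
4. genotyping rate above 95%, computed across all genotyped individuals
   (not only heterozygotes);
5. mappability score of 1 (an input annotation; computing it is upstream);
6. genotyping-error test: the overall error rate `e` is the ratio of
   OTHER-allele counts to all counts over every record entering the
   cascade, and each SNP's pooled OTHER count is tested against `e` by a
   two-sided exact binomial test; SNPs rejecting at p < 0.05 are excluded
   as likely genotyping errors or random monoallelic expression. `e` is
   estimated on the full input table rather than the stage-5 survivors so
   the estimate stays a property of the dataset (and the test cannot
   become self-referential when few SNPs survive). The error test pools
   counts per SNP across individuals; a per-record variant would conflate
   the test with coverage.

With every threshold at its degenerate extreme the cascade is the
identity on heterozygous records, and the eligible set is invariant to
the ordering of individuals.

## ASE calling

Three engines share one interface (`call_ase()`):

* `binomial`: exact two-sided binomial test of the pooled REF count
  against 0.5, minimum-likelihood two-sided convention (sum of outcomes no
  more probable than the observed one).
* `nb_aggregate`: the exact conditional negative-binomial test applied to
  the pooled counts with a fixed dispersion of 0.1.
* `nb_individual` (default): per-individual counts with per-SNP estimated
  dispersion.

The NB test treats the SNP's REF and ALT totals as sums of n
per-individual NB counts with common mean and dispersion `phi`; each total
is then NB with size `n/phi`, and conditioning on the pooled total `T`
gives the split distribution (a beta-binomial with shape `n/phi` on both
sides). The two-sided p sums split probabilities no larger than the
observed one. As `phi -> 0` this converges to the exact binomial test;
the implementation switches to the binomial below `phi = 1e-12`.

**Dispersion.** The per-SNP moment estimator works on the conditional
scale: with each individual's total as exposure and the pooled ratio as the
fitted rate, the Pearson statistic over the 2n cells has expectation
`(n - 1) + rho (sum t - n)`, where `rho` is the intraclass correlation of
the per-individual REF/ALT split. The moment estimate of `rho` is
translated to the NB dispersion by `phi = 2 rho / (1 - rho)` (the split of
two equal-mean NB counts given their total is beta-binomial with
`rho = 1/(2/phi + 1)`). This calibrates correctly in both regimes: for
unconditionally NB counts it recovers `phi`, and under pure binomial
sampling it clamps to zero. Estimates are clamped to [0, 10]; a single
heterozygote cannot identify dispersion and falls back to the fixed value
0.1 with a flag.

Within `call_ase()` the per-SNP estimates are additionally moderated:
signed moment estimates (clamping at zero *before* averaging would bias
everything upward) are shrunk toward their cross-SNP median with prior
weight `prior_df = 20` against the per-SNP degrees of freedom, then
clamped. This is the same empirical-Bayes idea count-model packages use
for tagwise dispersion; unshrunk plug-ins are noisy at typical cohort
sizes and make the exact test needlessly conservative. `prior_df = 0`
disables moderation.

Raw p-values are adjusted by Benjamini–Hochberg across SNPs and
significance is `p_fdr < 0.05` by default — FDR control avoids overcalling
ASE given tens of thousands of eligible SNPs.

**Bias diagnostics.** Among significant SNPs, the counts of ratios above
and below 0.5 (exact ties excluded from both sides) feed a two-sided
binomial skew test, and mean ratios are tabulated by pooled-depth bin
(default [15,30), [30,60), [60,120), [120,Inf)) since residual reference
bias concentrates at low depth.

## Cross-tissue sharing

Both result tables are restricted to the SNPs eligible in both tissues and
partitioned into shared / A-only / B-only at the chosen significance scale
(`"fdr"` default; `"raw"` exposed because overlap reporting conventions
differ). The permutation null re-draws random subsets of both observed set
sizes from the eligible SNPs (drawing both sets is symmetric in the
tissues and conservative; a single-set variant exists) and the p-value is
`(1 + #{null >= obs}) / (B + 1)`, floored at `1/(B+1)` so it is never
zero; B defaults to 10,000. Direction concordance is the fraction of SNPs
whose ratios fall on the same side of 0.5 in both tissues (ties carry no
direction and are excluded); groups are compared by Fisher's exact test on
the concordant/discordant split.

## Differential ASE

The differential engine is a beta-binomial likelihood-ratio test on
per-individual REF counts, parameterised by mean `mu` and intraclass
correlation `rho` (`alpha = mu(1-rho)/rho`, `beta = (1-mu)(1-rho)/rho`),
chosen because it models the allelic ratio directly and absorbs
between-individual overdispersion. The LRT compares group-specific means
against a common mean on 1 df; `rho` is estimated once, under the
group-specific model, and held fixed in the common-mean fit. Re-estimating
`rho` under the null would let overdispersion absorb the group difference
— with one record per group that collapses the test entirely, whereas the
shared-`rho` version reduces exactly to the two-proportion binomial LRT.

Numerical choices: `mu` is constrained to `[1e-6, 1 - 1e-6]` and `rho` to
`[0, 0.995]`; optimisation is bounded quasi-Newton (L-BFGS-B) from two
starting correlations (0.005, 0.1), keeping the better optimum;
non-convergence is flagged, never silent; with a single record `rho` is
pinned to 0 and flagged non-estimable. Groups with one heterozygote are
tested but flagged `low_confidence` — a lone extreme ratio is
indistinguishable from a genotyping error, and such hits are reported
rather than filtered because single-heterozygote hits are part of what the
analysis surfaces.

The paired test treats timepoint as a fixed effect with shared `rho`,
dropping individuals missing a timepoint; a full per-individual
random-effects model is out of scope, and since each pair conditions on
the same heterozygote the fixed-effect comparison captures the within-pair
contrast of interest.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes:
HWE genotypes at MAFs drawn from (0.05, 0.5] with missing calls;
negative-binomial per-heterozygote depth (mean 30, shape 2 — real site
coverage is overdispersed); OTHER reads drawn first as
Binomial(depth, error rate 0.005) so the error rate is a per-base
probability; the remaining reads split REF/ALT by a beta-binomial with
mean `clamp(true ratio + ref_bias, 1e-6, 1 - 1e-6)` (an additive bias
shift is easier to reason about near 0.5 than a multiplicative one) and
correlation 0.01; 10% of SNPs carry ASE with ratios in (0.65, 0.9)
mirrored below 0.5 with probability 1/2. The default design mirrors the
study conditions: 62 atrial individuals of whom 21 carry the clinical
label (34%), 76 ventricular individuals sampled at two paired timepoints,
disjoint cohorts. Truth ledgers accompany every table so downstream tests
never re-derive ground truth.

What it does **not** emulate: read-level artefacts (no FASTQ/SAM
synthesis; counts are generated directly, and a small static SAM fixture
exercises the counting code), alignment-induced bias correlated with
sequence context, linkage between SNPs, gene structure (SNPs are
independent), or covariate structure (age, comorbidities). Passing tests
on synthetic data therefore demonstrate the statistical machinery —
calibration, power, reproducibility — not robustness to alignment
artefacts in real data.

Calibration experiments in the tests and acceptance script use the null
configuration (all true ratios 0.5, no reference bias, zero
overdispersion, MAFs in (0.3, 0.5) so pooled depths exceed 500) with
~1000 SNPs and a 62-individual cohort; recovery experiments use 50 seeded
replicates at 200 individuals; permutation checks use 1000 eligible SNPs,
set sizes 100/100 and B = 10,000. These sizes make every distributional
check tight while keeping the default test run fast.

## Known limitations

* The NB engine uses per-SNP moment dispersions with median-target
  moderation, not full empirical-Bayes shrinkage with a mean-dispersion
  trend; SNP-specific dispersion structure beyond the shared median is
  only captured through the per-SNP component.
* The genotyping-error test assumes a single global error rate; locus-
  specific error (e.g. mapping into paralogues) is only caught indirectly.
* No phasing: ASE is detected per SNP, not per haplotype, and gene-level
  aggregation is out of scope.
* The paired test conditions on timepoint as a fixed effect; individual-
  level random effects are not modelled.
* No covariate adjustment in the differential comparisons.
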