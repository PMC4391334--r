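---
title: "Genotype inference from beta values: models, parameters, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype inference from beta values: models, parameters, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylaudit)
```

## The model

A methylation array probe reports β, the fraction of methylated signal at one
CpG, in [0,1]. When the assayed cytosine is the site of a C→A/G/T
polymorphism (the unidentified non-C base is written D throughout), the
methylation signal is lost stoichiometrically from each D-bearing chromosome.
At a CpG that is fully methylated in C-allele carriers, the three genotypes
are therefore separated into modes near 1.0 (CC), 0.5 (CD) and 0.0 (DD).
Nothing epigenetic about the donor is being measured at such a probe; it is a
genotyping assay in disguise, which is exactly why it is a privacy problem.

The audit assumes:

* the matrix has been preprocessed upstream (normalisation, background
  correction, bad-sample removal are out of scope — the audit consumes a
  *cleaned* matrix);
* the cohort is a single population sample under approximate random mating,
  so Hardy-Weinberg equilibrium (genotype proportions p², 2pq, q²) is a
  reasonable null for genuine polymorphisms;
* per-probe noise is small relative to the 0.5 spacing of the modes.

## The discovery pipeline and its parameters

Binning uses strict thresholds: X iff β > 0.7, Y iff 0.3 < β < 0.7, Z iff
β < 0.25. Exact boundary values and the [0.25, 0.3] gap are *unbinned*. The
published bin definition contains a typographical inversion of the Y bounds;
only the reading 0.3 < Y < 0.7 is coherent (heterozygotes sit near 0.5), and
that is what is implemented. The asymmetric Z bound (0.25, not 0.3) is
preserved as printed. Unbinned values and missing betas both become missing
genotype calls: the strict inequalities leave them unassigned, and a no-call
is the conservative resolution.

Candidacy (defaults in `candidacy_params()`):

* `min_binned_fraction` (default 0.95): a probe must have at least
  `ceiling(0.95 * n_samples)` values inside the three bins. The ceiling
  reading is fixed by the published arithmetic at n = 111, where the
  threshold is 106. Missing values count against the probe — the denominator
  is the full sample count.
* `min_homozygote_count` (default 4): at least four observations in *each* of
  bins X and Z. This is what demands genuine bi-allelic structure; it is also
  the binding constraint at low minor allele frequency (see Limits).
* `hwe_p_min` (default 0.01): candidates are converted to genotype counts and
  kept when the HWE test's P exceeds this. Probes failing HWE are more likely
  cross-hybridising probes, partial signal loss, or population structure than
  clean single-SNP readouts.

The HWE test is the Pearson χ² with 1 df and no continuity correction against
expectations computed from the sample allele frequencies. The original
analysis names only "HWE P values"; χ² is the conventional default at
n ≈ 100. An exact test would shift the retained count slightly; it is a
documented alternative, not implemented. Monomorphic count vectors get
χ² = 0, P = 1 by convention (they cannot violate HWE; they are removed by the
homozygote rule regardless).

Minor allele frequency is deliberately *not* an independent filter: the
observed MAF floor in audited data is an outcome induced by the
≥4-homozygote rule and the HWE screen, matching how the published cohort's
floor (0.105) arises.

Ranking: "most informative" = observed heterozygosity n_CD/n, descending,
ties broken by probe ID ascending. Heterozygosity is the single-locus
identification information; the published top-30 table is ordered the same
way.

## Fingerprints and match evidence

`match_samples()` scores sample pairs by concordance over loci called in
both, with a `min_overlap` guard (default 30) so that two profiles sharing
three called loci cannot claim a vacuous 100% match. No concordance threshold
for *declaring* identity ships: the published work asserts matchability, not
a cutoff, so results are returned as a ranked score.

`random_match_probability()` uses the forensic product rule under HWE and
locus independence, in log10. Both assumptions are documented approximations:
CpG probes within the same LD block are not independent, so the product rule
overstates the evidence; treat the value as an upper bound on surprise. Loci
with f_D of exactly 0 or 1 are refused (degenerate; a monomorphic locus
carries no match information and a zero frequency would send the log to −∞).

Redaction removes rows rather than masking values, so no reconstruction from
residuals is possible, and re-auditing a redacted matrix with the same
parameters provably returns none of the redacted probes (this is a tested
invariant).

## Trait flagging

The default panel holds a single probe, cg05575921 (AHRR), hypomethylated in
smokers. Two deliberate refusals: no numeric threshold ships (the source
presents the smoking relationship as a figure without a cutoff, and shipping
an invented clinical cutoff would be worse than requiring one), and no
alcohol loci are bundled (the external literature is cited without naming
probes). `flag_trait_status()` therefore errors until the caller supplies a
threshold, which is echoed in CLI report output.

## MspI assay design

MspI cuts C^CGG on genomic DNA regardless of methylation. When the assayed
CpG is the inner CG of a CCGG, the C allele is cut and the D allele is not,
so fragment patterns read out genotype — an orthogonal wet-lab check of
array-inferred calls. The model treats only the assayed CpG's site as
genotype-dependent; other CCGG sites in the amplicon are constitutive. Only
fragment lengths are predicted (per allele they sum to the amplicon length —
a tested invariant); sticky ends and gel mobility are not modeled. The primer
pairs for the two wet-lab-validated loci ship as fixture data
(`validated_primers()`).

## The synthetic world

`simulate_dataset()` states one world and the test suite lives in it:

* 111 samples by default, so the ⌈0.95·n⌉ = 106 arithmetic is exercised at
  the published scale.
* SNP probes: true MAF ~ Uniform(0.05, 0.5); per-sample genotype from HWE
  (D-allele dose ~ Binomial(2, MAF)); β ~ Normal(μ_genotype, 0.03) clipped to
  [0,1], with μ = (0.97, 0.50, 0.03). The heterozygote mean is exactly half
  signal, per the loss mechanism; the clipped Normal is a simple stand-in for
  array chemistry, not a claim about it (a Beta mixture would be the
  alternative). The MAF range deliberately extends below detectability so
  that the audit's observed MAF floor *emerges* from the filters, as it does
  in real data, instead of being built into the generator.
* Background probes: a per-probe baseline mean from a high/low/mid mixture
  (0.9/0.1/0.5, weights 0.4/0.4/0.2, baseline SD 0.05), no genotype
  structure. High and low baselines emulate the bulk of fully
  (un)methylated CpGs; mid-baseline probes emulate intermediate sites that
  are unimodal near 0.5 and must *not* be selected.
* One trait probe, `cg05575921`: smoker prevalence 0.5 (a balanced
  smoking-study design), group means 0.85 (nonsmoker) vs 0.45 (smoker) — a
  >4 SD separation at noise SD 0.03.
* `missing_rate` defaults to 0 because the audited input is a cleaned
  matrix; missingness is opt-in for robustness tests.

What the simulator does **not** emulate: probe cross-hybridisation, batch and
chip-position effects, cell-composition heterogeneity, linkage between loci,
bimodal-but-not-genetic probes. A green recovery test therefore establishes
that the pipeline is correct *in this world*; it does not establish the
false-positive rate on real arrays, where non-genetic tri-modality exists.

`resample_individuals()` re-draws noise (and optionally flips a fraction of
genotype cells) for the same individuals, which is what sample-matching tests
need: a second assay of the same cohort.

## Numerical and degenerate-input choices

* Boundary betas are unbinned (strict inequalities), so thresholds are
  reproducible across floating-point round trips through TSV.
* The binned-count comparison is integer (`>= ceiling(...)`), never a
  floating-point fraction comparison.
* Ties in the informativeness ranking break by probe ID so output order is
  deterministic.
* Empty selections, empty fingerprints, and empty redaction lists are valid
  results, not errors; zero *genotyped* samples is an error for every
  statistic whose denominator it is.
* Missing tokens on read: empty cell, `NA`, `NaN`, and `null`
  (case-insensitive) — the last is the GEO series-matrix convention; any
  other non-numeric cell names its probe and sample in the error.

## Known limits

* **Low-MAF sensitivity is bounded by counting, not by code.** A locus with
  true MAF m yields ≥ 4 minor homozygotes among n = 111 with probability
  P(Binomial(111, m²) ≥ 4): 0.24 at m = 0.15, 0.65 at m = 0.20, 0.92 at
  m = 0.25. Averaged over MAF ≥ 0.15 in the default world, expected
  sensitivity is ≈ 0.88 — the acceptance suite's ≥ 95% bound for MAF ≥ 0.15
  is therefore red, while ≥ 95% holds for MAF ≥ 0.3. The module tests check
  the measured sensitivity against this exact binomial prediction instead.
* MAF estimation error at n = 111 is dominated by allele sampling
  (SE ≈ √(pq/2n) ≈ 0.03 at p = 0.5); more samples, not better code, is the
  only fix.
* The product rule's independence assumption overstates evidence for linked
  loci; no LD correction is attempted.
* The published cohort reproduction requires the deposited series matrix,
  which must be fetched from GEO; the test asserting its printed counts is
  red whenever the file is absent.
* Kinship inference (matching against a relative's genotypes) and surname
  triangulation are out of scope; only direct sample-to-sample matching is
  implemented.
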