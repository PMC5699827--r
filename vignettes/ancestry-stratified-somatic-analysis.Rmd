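---
title: "Ancestry-stratified somatic analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestry-stratified somatic analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmstrat)
```

# The problem

Multiple myeloma incidence differs two- to three-fold between people of
African and European descent, yet most tumor-genomics cohorts are
analysed as a single population, with ancestry reduced to a self-report
checkbox. `mmstrat` implements the full analysis chain needed to compare
somatic alteration profiles between *genetic-ancestry* strata of an
exome cohort: estimate each patient's admixture from germline markers,
reconcile the estimate with self-report, build a consensus somatic call
set, test per-gene mutation frequencies between strata, classify
integrated mutation/copy-number states at a locus of interest (TP53),
call hyperdiploid karyotypes, score an expression risk signature, and
stratify overall survival.

Every stage is exercisable on a bundled synthetic-cohort generator, so
the whole pipeline is testable without access to controlled patient
data.

# Statistical core

All downstream stages share four primitives, implemented in the package
(not delegated) because their exact definitions are the contract the
results depend on:

* **Fisher's exact test** on 2×2 tables. The two-sided p-value uses the
  *minimum-likelihood* tail: with both margins fixed, it sums the
  hypergeometric point probabilities of every table whose probability
  does not exceed that of the observed table (relative tie tolerance
  `1e-7`). This matches the behaviour of the common statistical
  packages; a doubled-one-tail variant is available behind
  `two_sided_method = "double"`. The reported statistic is the sample
  odds ratio, with `Inf` allowed for empty off-diagonal cells, and an
  all-zero table returns p = 1 by convention. The test suite checks the
  implementation against exhaustive fixed-margin enumeration for every
  table size up to n = 40 (about 10^4 cases) and against
  `stats::fisher.test`.

* **Benjamini–Hochberg adjustment**, the step-up
  `q_(i) = min_{j>=i} m p_(j) / j` capped at 1 and returned in input
  order. Note the step-up map is *not* idempotent on already-adjusted
  values (for i < m, `m q_(j)/j` exceeds `q_(j)`), so the invariants we
  assert are pointwise domination of the input and monotonicity along
  the sorted sequence.

* **Wilcoxon rank-sum** with midranks. The null distribution is
  enumerated exactly (a subset-sum dynamic programme over doubled
  midranks) whenever the smaller sample has at most 10 observations and
  the total is at most 25; beyond that a normal approximation with tie
  correction and 0.5 continuity correction is used. The two paths agree
  within 0.02 at the crossover size on tie-free data.

* **Binomial upper tail** `P(X >= k)`, evaluated through
  `stats::pbinom`'s regularised-beta tail.

# Supervised admixture estimation

The ancestry model is the standard two-population supervised admixture
likelihood: given reference allele frequencies `f_Aj`, `f_Bj` and a
per-sample admixture proportion `q`, the dosage at marker j is
`Binomial(2, q f_Aj + (1-q) f_Bj)`. We maximise the likelihood per
sample by EM over allele-origin responsibilities; the log-likelihood is
non-decreasing at every iteration (asserted in tests) and iteration
stops when it rises by less than `1e-6` (default cap 5000 iterations —
convergence is sublinear for samples at the `q = 1` boundary, which is
why the cap is generous; interior samples converge in tens to hundreds
of iterations, and the active-set implementation makes the boundary
stragglers cheap).

This replaces an unsupervised MCMC clustering (STRUCTURE-style) with
its supervised maximum-likelihood equivalent: at K = 2 with fixed
reference frequencies the estimand is the same, and the EM solution is
deterministic and desk-scale. Reference frequencies are clipped to
`[0.001, 0.999]` so the likelihood never evaluates `log(0)`; markers
missing in a sample are simply dropped from that sample's likelihood,
and samples missing more than 50% of markers are flagged with `q = NA`.
A panel in which the two populations are identical leaves `q`
unidentifiable; we return 0.5 with `converged = FALSE` rather than an
arbitrary converged value.

At the scale of the shipped defaults (4,761 markers, Fst 0.15) the
sampling standard deviation of `q̂` is about 0.02, which sets what
recovery tests can demand: mean absolute error below 0.02 and maximum
below 0.06 on a 200-sample cohort, and per-`q` bias below 0.01 when
averaged over 20 replicate cohorts.

Marker informativeness uses Rosenberg's assignment informativeness for
biallelic markers (0 for indistinguishable populations, `ln 2` for a
fully diagnostic marker), and the PCA applies the usual
population-genetics normalisation: centre each marker at `2p̂`, scale by
`sqrt(p̂(1-p̂))`, drop monomorphic markers, and take the SVD.

**Concordance filter.** A sample is excluded when its estimated
proportion of the ancestry *opposite* its self-report exceeds a
threshold, default 0.55 — the ">55% discordant ancestry" rule. The
threshold is configurable; values at or below 0.5 are rejected because
they would make the rule self-contradictory.

# Somatic consensus and burden comparison

Variants are keyed by `(sample, chrom, pos, ref, alt)` and a key is kept
when at least `min_callers` of the three caller tables contain it
(default 2 of 3). Annotation fields come from the first supporting
caller in a configurable priority order (default: file order), because
multi-caller annotation disagreements have no principled resolution at
this layer; indels are assumed pre-normalised (no re-left-alignment), a
documented limitation. Only *nonsilent* classes (missense, nonsense,
nonstop, splice site, frameshift and in-frame indels, translation start
site) enter the mutation matrix.

The cross-cohort comparison is exact per gene: a 2×2 table of
mutated/not × group, two-sided Fisher, BH over all *tested* genes
(those with at least one mutated sample cohort-wide; the adjustment
family is per comparison — the inputs do not pin down a different
choice, so we take the natural one and expose the tested flag).

The per-cohort recurrence ("significantly mutated gene") test is a
declared simplification of covariate-adjusted mutation-significance
models: a single cohort-wide per-base background rate
`μ = total mutations / (Σ L_g × N)`, per-gene mutated-sample
probability `1 - (1-μ)^{L_g}`, binomial upper tail, BH, significance at
q < 0.1. It shares the background-rate null with the full models but
carries no expression or replication-timing covariates, so on real data
it will over-call long late-replicating genes; on the synthetic cohort
(uniform background by construction) it is correctly calibrated, which
is what the tests demonstrate.

# Locus states, karyotype, and risk score

**Locus state.** LOH at the locus is approximated by somatic copy
*loss*: the length-weighted mean log2 ratio of the segments overlapping
the locus, at or below −0.2 (single-copy range; boundary inclusive).
This is standard exome copy-number practice when B-allele frequencies
are not in scope; copy-neutral LOH is invisible to it, a documented
limitation. The integrated classification is then a total function of
the two flags: wildtype, mutation-only, LOH-only (both mono-allelic),
LOH+mutation (bi-allelic). A deep loss at or below −1.0 (homozygous
range) also sets bi-allelic. Two coincident point mutations without
loss are *not* promoted to bi-allelic, because phase is unknown. The
shipped TP53 locus is chr17:7,571,719–7,590,868 (GRCh37, 0-based
half-open) and can be overridden.

**Hyperdiploidy.** A sample is hyperdiploid when at least three odd
autosomes (1, 3, …, 21) are trisomic; a chromosome is trisomic when the
length-weighted median log2 of its segments reaches 0.4 (just below the
ideal single-copy-gain value `log2(3/2) ≈ 0.585`, leaving headroom for
noise and subclonality) across segments covering at least 60% of its
covered length. The call is invariant to segment order and to splitting
segments, which the tests assert.

**Risk signature.** Score = mean `log2(TPM+1)` over the up-gene arm
minus the mean over the down-gene arm; high-risk above a cohort-specific
cutoff. No universal cutoff is asserted — published cutoffs for
signature scores are training-cohort artefacts — so the cutoff is a
required argument, and tests use synthetic cutoffs. Scores with more
than 20% of signature genes missing are flagged low-confidence.

# Survival

Kaplan–Meier estimation and the log-rank chi-square are delegated to
the `survival` package behind thin wrappers that fix the contract: the
deaths-before-censorings tie rule, a plain data-frame curve schema,
and an explicit *untestable* flag (rather than an error) when the
pooled data contain no events. Three-group stratifications (wildtype /
mono-allelic / bi-allelic) use the df = 2 omnibus test plus pairwise
tests with BH. The wrappers are validated against hand-computed
product-limit values.

# The synthetic cohort generator

The generator is first-class, tested code, and its defaults *are* the
study conditions the rest of the package assumes:

* **Reference panel**: Balding–Nichols — ancestral frequency
  `Uniform(0.05, 0.95)` per marker, population frequencies
  `Beta(f(1-F)/F, (1-f)(1-F)/F)` with F = Fst (default 0.15 in tests,
  the continental-scale value), clipped to `[0.001, 0.999]`.
* **Cohort composition**: 128 + 593 samples by self-report, with true
  African admixture `Beta(7, 3)` in group A (mean European admixture
  30%, matching the reported ~31%) and `Beta(0.1, 99.9)` in group B
  (mean African admixture 0.1%, as reported); 3 mislabelled samples,
  emulating the three discordant self-reports the concordance filter is
  meant to catch.
* **Somatic genes**: recurrent myeloma drivers at field-typical
  frequencies (KRAS/NRAS ≈ 20%, BRAF 6%, and so on), several with a
  roughly two-fold between-group difference in the direction reported
  for this disease, plus equal-rate passengers. Mutation calls pass
  through three callers with sensitivities 0.95/0.92/0.90 and
  per-cell false-positive rate 0.002 each, independently — correlated
  caller errors are deliberately not modelled.
* **TP53**: the joint LOH/mutation state is planted directly from the
  published integrated profile (group A: 6.3% LOH-only, 1.6%
  mutation-only, 7.9% both; group B: 8.6%/6.6%/15.2%), because the
  strong dependence between loss and mutation cannot be reproduced by
  independent event probabilities. Deletions enter the segment table as
  a chr17 segment at log2 ≈ −0.7 (hemizygous range).
* **Karyotype**: half the samples hyperdiploid with 3–7 odd-chromosome
  trisomies at log2 ≈ 0.585 plus N(0, 0.05) segment noise;
  non-hyperdiploid samples occasionally carry 1–2 odd trisomies so the
  ≥3 rule is actually exercised at its boundary.
* **Survival**: exponential with baseline hazard 0.12/year (median
  overall survival near 6 years, typical of newly diagnosed myeloma in
  this era) and hazard ratio 3 for bi-allelic TP53 inactivation,
  administratively censored at 4 years — the study's follow-up horizon.
* **Expression**: log2 expression `N(5, 1)`, with the up-arm of the
  signature shifted +2 in 15% of samples (the planted high-risk class).

With the seed fixed, every emitted file is byte-identical across runs,
and the planted truth (true `q`, true group, mutation truth, TP53
state, karyotype, risk class) is returned in a separate `truth` record
that is never written to the analysis-facing files.

What the generator does **not** emulate: linkage disequilibrium between
markers, realistic trinucleotide mutation spectra, correlated caller
errors, focal copy-number architecture, or covariate-driven mutation
rates. Tests passing on this cohort therefore demonstrate correctness
of the estimators and decision rules under their assumed models, not
robustness to the full messiness of real exome data.

# Calibration of the recovery experiments

The differential-gene recovery experiment plants a two-fold rate
difference (30% vs 15%) against a 10% null background at the cohort's
group sizes (127 vs 591). These values were fixed by design before
measuring: 30%/15% sits at the KRAS-like top of driver frequencies and
gives ~93% analytic power per gene at α = 0.05, so an 80% sensitivity
floor is comfortably attainable; a 10% null keeps the counts dense
enough that the exact test's conservatism stays mild (empirically ~4.2%
rejection at nominal 5%, inside a 5% ± 1.5% calibration band — exact
conditional tests run below nominal level by construction on discrete
data).

The survival power experiment uses 60 bi-allelic vs 540 other samples
over a 4-year horizon at hazard ratio 3, mirroring the cohort's
bi-allelic fraction; with ~250 expected events the log-rank detects the
effect in essentially every replicate.

Problem sizes throughout the test suite (a few hundred samples, tens of
genes, 20–400 markers for unit tests and the full 4,761-marker panel
for the recovery runs) are the package's chosen desk-scale defaults:
large enough that the asserted properties are statistically stable,
small enough that the whole suite runs in about a minute.

# Known limitations

* LOH is inferred from copy loss only; copy-neutral LOH is not called.
* The SMG test is uncovariate-adjusted (see above).
* Consensus assumes pre-normalised indel representations.
* The admixture model is K = 2 and supervised; it does not estimate
  reference frequencies, handle K > 2, or perform local ancestry.
* Published p-values for two of the contingency comparisons in the
  motivating study are reproducible only under a chi-square test
  without continuity correction, not under any sidedness of Fisher's
  exact test, although the tests are labelled "Fisher's" there; the
  package deliberately reports the exact-test values.
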