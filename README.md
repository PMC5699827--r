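# mmstrat — ancestry-stratified somatic analysis of myeloma cohorts

Multiple myeloma is two to three times more common in people of African
descent than in people of European descent, yet tumor-genomics cohorts
are usually analysed as one population, with ancestry reduced to a
self-report field. `mmstrat` is an R toolkit for asking whether the
*somatic* genome of the tumor differs between *genetic*-ancestry strata
of an exome cohort. It is aimed at cancer-genomics analysts working
with cohort-level exome data: germline genotypes at ancestry-informative
markers, multi-caller somatic call tables, copy-number segments,
expression matrices, and clinical follow-up.

## What it computes

* **Genetic ancestry.** Per-sample admixture proportion `q` under the
  supervised two-population model `g_j ~ Binomial(2, q f_Aj + (1-q) f_Bj)`,
  maximised by EM (deterministic, monotone log-likelihood); Rosenberg
  marker informativeness `I_n`; genotype PCA with the usual
  `(g - 2p̂)/√(p̂(1-p̂))` normalisation; and a concordance filter that
  excludes samples whose estimated opposite-ancestry fraction exceeds
  55%.
* **Somatic consensus.** The 2-of-3 caller rule keyed on
  `(sample, chrom, pos, ref, alt)`, effect classification over the MAF
  vocabulary, and the gene × sample nonsilent mutation matrix.
* **Differential mutation frequency.** Per-gene two-sided Fisher's
  exact test (minimum-likelihood tail, implemented in-package and
  enumeration-verified) between strata with Benjamini–Hochberg
  adjustment; a simplified background-rate binomial recurrence (SMG)
  test at q < 0.1; Wilcoxon association between mutation status and
  percent European ancestry; per-sample burden summaries.
* **Integrated locus state.** TP53-style classification from consensus
  mutations plus segment copy loss (length-weighted mean log2 ≤ −0.2):
  wildtype / mutation-only / LOH-only (mono-allelic) / LOH+mutation
  (bi-allelic, as is deep loss ≤ −1.0), with group tabulation and
  per-row exact tests.
* **Karyotype and risk.** Hyperdiploidy = trisomy (length-weighted
  median log2 ≥ 0.4) of at least three odd autosomes; expression risk
  score = mean log2(TPM+1) over an up-gene arm minus a down-gene arm.
* **Survival.** Kaplan–Meier curves and log-rank tests (omnibus and
  BH-adjusted pairwise) across locus-state or ancestry strata.
* **Synthetic cohorts.** A seeded generator (Balding–Nichols panel,
  admixed genotypes, three noisy callers, planted TP53 states,
  trisomies, risk signature, exponential survival tied to bi-allelic
  TP53 loss) that produces every input file the pipeline consumes plus
  the planted truth, so the entire chain is testable without controlled
  data.

`run_pipeline()` orchestrates all stages from one config and writes
provenance-stamped TSVs plus an aggregate `report.json`; a thin
command-line wrapper lives at `inst/scripts/mmpipe.R`.

## Worked example

```r
library(mmstrat)

panel  <- simulate_reference_panel(n_markers = 2000, fst = 0.15, seed = 7)
cohort <- simulate_cohort(panel, cohort_config(n_A = 60, n_B = 140, seed = 7))

est  <- estimate_admixture(cohort$genotypes, panel)
filt <- concordance_filter(cohort$samples, est, threshold = 0.55)
nrow(filt$excluded)
#> [1] 3
head(filt$excluded$reason, 2)
#> [1] "self-reported B with 62.2% opposite-population ancestry (> 55%)"
#> [2] "self-reported A with 57.7% opposite-population ancestry (> 55%)"
```

The three planted mislabelled samples are caught by the >55% rule. The
somatic side, on the retained samples:

```r
cons <- merge_callers(cohort$caller_calls, min_callers = 2)
mm   <- build_mutation_matrix(cons, filt$kept$sample)
mm
#> mutation_matrix: 31 genes x 197 samples, 410 nonsilent calls

groups <- setNames(filt$kept$self_report, filt$kept$sample)
cmp <- per_gene_fisher(mm, groups)
head(cmp[order(cmp$p), c("gene","count_A","count_B","freq_A","freq_B","p","q")], 3)
#>      gene count_A count_B    freq_A     freq_B            p           q
#> 30   RYR1      19      15 0.3333333 0.10714286 0.0003082872 0.009556904
#> 14  PSG06       5       0 0.0877193 0.00000000 0.0017822936 0.027625551
#> 5  FAM46C      12      13 0.2105263 0.09285714 0.0331687334 0.342743578
```

`RYR1` is one of the generator's planted two-fold-difference genes and
comes out on top (q < 0.05); `freq_A`/`freq_B` are per-stratum mutated
fractions. The integrated TP53 state and its survival impact:

```r
st <- locus_states(cons, cohort$segments, filt$kept$sample)
tabulate_states(st, groups)
#>       category count_A     pct_A count_B     pct_B         p
#> 1     Wildtype      45 78.947368     104 74.285714 0.5842982
#> 2 Mono-allelic       6 10.526316      18 12.857143 0.8113949
#> 3   Bi-allelic       6 10.526316      18 12.857143 0.8113949
#> 4          LOH       5  8.771930      10  7.142857 0.7684242
#> 5     Mutation       1  1.754386       8  5.714286 0.4515108
#> 6 LOH+Mutation       6 10.526316      18 12.857143 0.8113949

strata <- ifelse(st$bi_allelic, "bi_allelic",
                 ifelse(st$mono_allelic, "mono_allelic", "wildtype"))
lr <- logrank_test(filt$kept$time_years, filt$kept$event, strata)
lr$test
#> logrank (two.sided): statistic = 13.27, p = 0.001314
```

The generator plants a three-fold death hazard for bi-allelic TP53
inactivation; the df = 2 log-rank finds it (p ≈ 0.001) at this modest
cohort size. Rows of the state table overlap by design — Mono-allelic
and Bi-allelic are roll-ups of the event rows beneath them.

## Vignette

`vignettes/ancestry-stratified-somatic-analysis.Rmd` documents the
models, every tunable threshold with its default and rationale, what
the synthetic generator does and does not emulate, and the package's
design choices and limitations.
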