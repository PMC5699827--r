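# Shared fixture builders.  Everything is generated in code at test
# time; nothing is read from disk except the shipped locus definition.

# a small cohort for integration-style tests
small_cohort <- function(seed = 11, n_A = 30, n_B = 50, n_markers = 400,
                         mislabel_count = 2, ...) {
  panel <- simulate_reference_panel(n_markers, fst = 0.15, seed = seed)
  simulate_cohort(panel, cohort_config(n_A = n_A, n_B = n_B,
                                       mislabel_count = mislabel_count,
                                       seed = seed, ...))
}

# brute-force minimum-likelihood two-sided Fisher p by direct
# enumeration over all tables with the observed margins, with point
# probabilities computed from factorial ratios (independent of dhyper)
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  prob <- function(x) {
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) +
          lfactorial(n - c1) - lfactorial(n) - lfactorial(x) -
          lfactorial(r1 - x) - lfactorial(c1 - x) -
          lfactorial(r2 - c1 + x))
  }
  ps <- vapply(lo:hi, prob, numeric(1))
  sum(ps[ps <= prob(a) * (1 + 1e-7)])
}

# simple caller table builder
toy_calls <- function(sample, gene, pos, vc = "Missense_Mutation",
                      chrom = 1, ref = "A", alt = "T") {
  data.frame(sample = sample, gene = gene, chrom = chrom, pos = pos,
             ref = ref, alt = alt, variant_classification = vc,
             stringsAsFactors = FALSE)
}

# segment row helper (0-based half-open)
seg_row <- function(sample, chrom, start, end, log2) {
  data.frame(sample = sample, chrom = chrom, start = start, end = end,
             log2 = log2, stringsAsFactors = FALSE)
}
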