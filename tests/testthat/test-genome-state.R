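# Locus loss, allelic-state classification, hyperdiploidy, risk score.

tp53 <- list(chrom = 17, start = 7571719, end = 7590868)

test_that("locus loss uses the length-weighted mean, boundary inclusive", {
  locus <- list(chrom = 17, start = 7000000, end = 8000000)
  seg <- rbind(seg_row("s1", 17, 6000000, 9000000, -1.0),
               seg_row("s2", 17, 6000000, 9000000, 0.0),
               # two equal-length overlapping segments: mean -0.2
               seg_row("s3", 17, 7000000, 7500000, -0.5),
               seg_row("s3", 17, 7500000, 8000000, 0.1),
               seg_row("s4", 3, 1, 2e6, -2))
  res <- suppressWarnings(
    call_locus_loss(seg, locus, samples = c("s1", "s2", "s3", "s4")))
  expect_equal(res$loss, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(res$locus_log2[res$sample == "s3"], -0.2, tolerance = 1e-9)
  expect_true(res$deep_loss[res$sample == "s1"])
  # s4 has no overlapping segment: no-call, treated as no loss
  expect_true(res$no_call[res$sample == "s4"])
  expect_warning(call_locus_loss(seg, tp53,
                                 samples = c("s1", "s4")), "no segment")
  expect_error(call_locus_loss(seg, list(chrom = 17, start = 5, end = 2)),
               "locus")
})

test_that("the allelic-state truth table matches the integrated scheme", {
  res <- classify_locus_state(mutated = c(FALSE, TRUE, FALSE, TRUE),
                              loss = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(res$state, c("wildtype", "mutation_only", "loh_only",
                            "loh_plus_mutation"))
  expect_equal(res$mono_allelic, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(res$bi_allelic, c(FALSE, FALSE, FALSE, TRUE))
  # bi-allelic and mono-allelic are mutually exclusive by construction
  expect_false(any(res$mono_allelic & res$bi_allelic))
  # deep (homozygous-range) loss promotes to bi-allelic
  deep <- classify_locus_state(FALSE, TRUE, deep_loss = TRUE)
  expect_equal(deep$state, "loh_only")
  expect_true(deep$bi_allelic)
  expect_false(deep$mono_allelic)
})

test_that("tabulate_states reproduces planted group frequencies", {
  co <- small_cohort(seed = 59, n_A = 127, n_B = 591, n_markers = 20,
                     caller_sensitivity = c(1, 1, 1),
                     caller_fpr = c(0, 0, 0), mislabel_count = 0)
  cons <- merge_callers(co$caller_calls, 2)
  st <- locus_states(cons, co$segments, co$samples$sample)
  # with noiseless callers the classified states equal the planted truth
  expect_equal(setNames(st$state, st$sample),
               co$truth$tp53_state[st$sample])
  groups <- setNames(co$samples$self_report, co$samples$sample)
  tab <- tabulate_states(st, groups)
  truth_a <- co$truth$tp53_state[co$samples$self_report == "A"]
  expect_equal(tab$count_A[tab$category == "LOH+Mutation"],
               sum(truth_a == "loh_plus_mutation"))
  expect_equal(tab$count_A[tab$category == "Wildtype"],
               sum(truth_a == "wildtype"))
  # roll-up identity: every non-wildtype sample is mono- or bi-allelic
  expect_equal(tab$count_A[tab$category == "Mono-allelic"] +
                 tab$count_A[tab$category == "Bi-allelic"] +
                 tab$count_A[tab$category == "Wildtype"],
               sum(co$samples$self_report == "A"))
  expect_error(tabulate_states(st, groups[-1]), "group")
})

test_that("tabulate_states reproduces the published LOH+Mutation row", {
  # 10/127 vs 90/591 is the published LOH+Mutation comparison
  states <- data.frame(
    sample = sprintf("s%03d", 1:718),
    state = c(rep("loh_plus_mutation", 10), rep("wildtype", 117),
              rep("loh_plus_mutation", 90), rep("wildtype", 501)),
    stringsAsFactors = FALSE)
  states$mono_allelic <- FALSE
  states$bi_allelic <- states$state == "loh_plus_mutation"
  groups <- setNames(rep(c("A", "B"), c(127, 591)), states$sample)
  tab <- tabulate_states(states, groups)
  row <- tab[tab$category == "LOH+Mutation", ]
  expect_equal(round(row$pct_A, 1), 7.9)
  expect_equal(round(row$pct_B, 1), 15.2)
  expect_equal(round(row$p, 2), 0.03)
})

test_that("hyperdiploidy requires three trisomic odd autosomes", {
  base <- function(s) do.call(rbind, lapply(1:22, function(ch)
    seg_row(s, ch, 0, 5e7, 0)))
  tri <- function(seg, chroms) {
    seg$log2[seg$chrom %in% chroms] <- 0.58
    seg
  }
  seg <- rbind(tri(base("hrd"), c(3, 5, 7)),
               tri(base("two"), c(3, 5)),
               tri(base("even"), c(2, 4, 6)))
  k <- call_hyperdiploidy(seg)
  expect_equal(k$karyotype[k$sample == "hrd"], "hyperdiploid")
  expect_equal(k$trisomic_chroms[k$sample == "hrd"], "3,5,7")
  expect_equal(k$karyotype[k$sample == "two"], "nonhyperdiploid")
  expect_equal(k$karyotype[k$sample == "even"], "nonhyperdiploid")
})

test_that("hyperdiploidy is invariant to segment order and splitting", {
  co <- small_cohort(seed = 61, n_A = 15, n_B = 15, n_markers = 20)
  k1 <- call_hyperdiploidy(co$segments)
  shuf <- co$segments[sample(nrow(co$segments)), ]
  k2 <- call_hyperdiploidy(shuf, samples = k1$sample)
  expect_equal(k1, k2)
  # split every segment in two adjoining halves with the same log2
  s <- co$segments
  mid <- floor((s$start + s$end) / 2)
  ok <- mid > s$start & mid < s$end
  split_seg <- rbind(
    transform(s[ok, ], end = mid[ok]),
    transform(s[ok, ], start = mid[ok]),
    s[!ok, ])
  k3 <- call_hyperdiploidy(split_seg, samples = k1$sample)
  expect_equal(k1, k3)
})

test_that("hyperdiploidy calls recover the planted karyotype", {
  co <- small_cohort(seed = 67, n_A = 50, n_B = 50, n_markers = 20)
  k <- call_hyperdiploidy(co$segments)
  expect_equal(setNames(k$karyotype == "hyperdiploid", k$sample),
               co$truth$hyperdiploid[k$sample])
})

test_that("risk score behaves under symmetry, scaling, and planting", {
  up <- c("U1", "U2"); dn <- c("D1", "D2")
  # identical expression in both arms: score 0
  tpm <- matrix(100, 4, 3, dimnames = list(c(up, dn), c("a", "b", "c")))
  rs <- risk_score(tpm, up, dn, cutoff = 0.5)
  expect_equal(rs$scores$score, rep(0, 3))
  expect_false(any(rs$scores$high_risk))
  # doubling all TPM leaves the score nearly unchanged at high TPM
  tpm2 <- tpm; tpm2[up, ] <- 800; tpm2[dn, ] <- 200
  s1 <- risk_score(tpm2, up, dn, 0)$scores$score
  s2 <- risk_score(tpm2 * 2, up, dn, 0)$scores$score
  expect_equal(s1, s2, tolerance = 5e-3)
  # missing signature genes flag low confidence
  expect_warning(risk_score(tpm[-1, ], up, dn, 0), "low-confidence")
  expect_error(risk_score(tpm[c("D1", "D2"), ], up, dn, 0),
               "at least one up")
})

test_that("planted high-risk samples separate by score (AUROC > 0.95)", {
  co <- small_cohort(seed = 73, n_A = 60, n_B = 60, n_markers = 20)
  up <- grep("^UPG", rownames(co$tpm), value = TRUE)
  dn <- grep("^DNG", rownames(co$tpm), value = TRUE)
  rs <- risk_score(co$tpm, up, dn, cutoff = 1)
  score <- setNames(rs$scores$score, rs$scores$sample)
  truth <- co$truth$risk_high[names(score)]
  # AUROC via the rank-sum identity
  r <- rank(score)
  auc <- (sum(r[truth]) - sum(truth) * (sum(truth) + 1) / 2) /
    (sum(truth) * sum(!truth))
  expect_gt(auc, 0.95)
})
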