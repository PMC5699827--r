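# Differential mutation-frequency testing and burden summaries.

matrix_from_counts <- function(count_a, n_a, count_b, n_b,
                               gene = "GENE") {
  ind <- matrix(0L, nrow = length(gene), ncol = n_a + n_b,
                dimnames = list(gene,
                                sprintf("s%03d", seq_len(n_a + n_b))))
  for (g in seq_along(gene)) {
    ind[g, seq_len(count_a[g])] <- 1L
    ind[g, n_a + seq_len(count_b[g])] <- 1L
  }
  structure(list(counts = ind, indicator = ind > 0,
                 sample_totals = colSums(ind)),
            class = "mutation_matrix")
}

test_that("per_gene_fisher reproduces a hand-built 2x2 comparison", {
  mm <- matrix_from_counts(2, 127, 39, 591, gene = "TP53")
  groups <- setNames(rep(c("A", "B"), c(127, 591)),
                     colnames(mm$counts))
  res <- per_gene_fisher(mm, groups)
  expect_equal(res$p, fisher_exact(c(2, 125, 39, 552))$p_value)
  expect_equal(res$freq_A, 2 / 127)
  expect_equal(res$direction, "B_higher")
  expect_equal(res$q, res$p)  # single tested gene
})

test_that("per_gene_fisher handles equal groups, untested genes, order", {
  mm <- matrix_from_counts(c(5, 0, 3), 30, c(5, 0, 9), 30,
                           gene = c("G1", "G0", "G2"))
  groups <- setNames(rep(c("A", "B"), c(30, 30)), colnames(mm$counts))
  res <- per_gene_fisher(mm, groups)
  expect_equal(res$p[res$gene == "G1"], 1)  # identical counts, equal n
  expect_true(is.na(res$p[res$gene == "G0"]))
  expect_false(res$tested[res$gene == "G0"])
  # q-values computed only over tested genes
  expect_equal(sum(!is.na(res$q)), 2)
  # gene order invariance
  mm2 <- mm
  perm <- c(3, 1, 2)
  mm2$counts <- mm$counts[perm, ]; mm2$indicator <- mm$indicator[perm, ]
  res2 <- per_gene_fisher(mm2, groups)
  expect_equal(res2[match(res$gene, res2$gene), -1], res[, -1],
               ignore_attr = TRUE)
  # direction always agrees with the frequency difference
  expect_true(all(res$direction[res$tested] ==
    ifelse(res$freq_A > res$freq_B, "A_higher",
           ifelse(res$freq_B > res$freq_A, "B_higher",
                  "none"))[res$tested]))
})

test_that("smg_binomial follows the background-rate null", {
  # no mutations anywhere: all p = 1
  mm0 <- matrix_from_counts(c(0, 0), 10, c(0, 0), 10, c("G1", "G2"))
  s0 <- smg_binomial(mm0, c(G1 = 1000, G2 = 2000))
  expect_true(all(s0$p == 1))
  # a zero-count gene keeps p = 1 even with background signal
  mm <- matrix_from_counts(c(8, 0), 20, c(8, 0), 20, c("G1", "G2"))
  s <- smg_binomial(mm, c(G1 = 1500, G2 = 1500))
  expect_equal(s$p[s$gene == "G2"], 1)
  expect_lt(s$p[s$gene == "G1"], 1)
  # doubling the length with fixed counts weakly increases p
  s2 <- smg_binomial(mm, c(G1 = 3000, G2 = 1500))
  expect_gte(s2$p[s2$gene == "G1"], s$p[s$gene == "G1"])
  expect_error(smg_binomial(mm, c(G1 = 1500)), "missing gene lengths")
})

test_that("smg_binomial recovers a planted driver and spares the null", {
  # planted driver mutated 10x above a uniform background
  hits <- 0L
  for (s in 1:10) {
    set.seed(300 + s)
    n <- 200
    genes <- c("DRIVER", sprintf("N%02d", 1:40))
    L <- setNames(rep(1500, length(genes)), genes)
    rate <- c(0.20, rep(0.02, 40))
    ind <- matrix(rbinom(length(genes) * n, 1, rate), nrow = length(genes),
                  dimnames = list(genes, sprintf("s%d", 1:n)))
    mm <- structure(list(counts = ind, indicator = ind > 0,
                         sample_totals = colSums(ind)),
                    class = "mutation_matrix")
    res <- smg_binomial(mm, L)
    hits <- hits + (res$significant[res$gene == "DRIVER"])
  }
  expect_gte(hits, 9)
})

test_that("mutation-ancestry association detects planted enrichment", {
  set.seed(71)
  n <- 500
  eur <- c(runif(400, 0.9, 1), runif(100, 0, 0.7))
  names(eur) <- sprintf("s%03d", 1:n)
  ind <- setNames(rep(FALSE, n), names(eur))
  ind[sample(which(eur > 0.95), 20)] <- TRUE
  res <- mutation_ancestry_association(ind, q_african = 1 - eur)
  expect_false(res$untestable)
  expect_lt(res$test$p_value, 0.05)
  expect_equal(res$frac_mutated_high_european, 1)
  # zero mutated samples are untestable, not an error
  res0 <- mutation_ancestry_association(setNames(rep(FALSE, n),
                                                 names(eur)), 1 - eur)
  expect_true(res0$untestable)
})

test_that("random mutation placement is null-calibrated", {
  set.seed(72)
  ps <- vapply(1:200, function(i) {
    eur <- runif(80)
    names(eur) <- sprintf("s%02d", 1:80)
    ind <- setNames(seq_along(eur) %in% sample(80, 15), names(eur))
    mutation_ancestry_association(ind, 1 - eur)$test$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("burden_summary compares per-sample totals", {
  mm <- matrix_from_counts(c(5, 4), 10, c(5, 4), 10, c("G1", "G2"))
  groups <- setNames(rep(c("A", "B"), c(10, 10)), colnames(mm$counts))
  bs <- burden_summary(mm, groups)
  expect_equal(bs$summary$mean[1], bs$summary$mean[2])
  expect_gte(bs$test$p_value, 0.99)
  # single-group input violates the precondition
  expect_error(burden_summary(mm, setNames(rep("A", 20),
                                           colnames(mm$counts))),
               "two")
})

test_that("equal-rate cohorts show balanced burden", {
  co <- small_cohort(seed = 47, n_A = 300, n_B = 300, n_markers = 20,
                     gene_spec = {
                       gs <- default_gene_spec(); gs$rate_B <- gs$rate_A; gs
                     })
  cons <- merge_callers(co$caller_calls, 2)
  mm <- build_mutation_matrix(cons, co$samples$sample)
  groups <- setNames(co$truth$true_group, names(co$truth$true_group))
  bs <- burden_summary(mm, groups)
  pooled <- mean(mm$sample_totals)
  expect_lt(abs(diff(bs$summary$mean)), 0.1 * pooled)
})
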