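# Marker informativeness, PCA, supervised admixture EM, concordance
# filter.

test_that("informativeness matches the closed form", {
  expect_equal(marker_informativeness(data.frame(f_A = 0.4, f_B = 0.4)), 0)
  expect_equal(marker_informativeness(data.frame(f_A = 1, f_B = 0)), log(2))
  # independent numeric evaluation at (0.8, 0.2)
  p1 <- 0.8; p2 <- 0.2; pb <- 0.5
  direct <- -(pb * log(pb) + (1 - pb) * log(1 - pb)) +
    (p1 * log(p1) + (1 - p1) * log(1 - p1) +
       p2 * log(p2) + (1 - p2) * log(1 - p2)) / 2
  expect_equal(marker_informativeness(data.frame(f_A = 0.8, f_B = 0.2)),
               direct)
  expect_error(marker_informativeness(data.frame(f_A = NA, f_B = 0.3)),
               "finite")
})

test_that("select_aims ranks by informativeness with positional ties", {
  pan <- data.frame(marker = c("m1", "m2"), chrom = c(1, 1),
                    pos = c(100, 200), f_A = c(0.6, 1), f_B = c(0.4, 0))
  expect_equal(select_aims(pan, top_k = 1)$marker, "m2")
  expect_equal(nrow(select_aims(pan, top_k = 2)), 2)
  # markers with identical frequencies are excluded at min_in > 0
  pan2 <- rbind(pan, data.frame(marker = "m3", chrom = 2, pos = 1,
                                f_A = 0.5, f_B = 0.5))
  expect_false("m3" %in% select_aims(pan2, min_in = 0)$marker)
  expect_error(select_aims(pan, top_k = 5), "top_k")
  expect_error(select_aims(pan, top_k = 1, min_in = 0.1), "exactly one")
})

test_that("genotype PCA separates simulated populations", {
  pan <- simulate_reference_panel(600, fst = 0.15, seed = 31)
  cfg <- cohort_config(n_A = 40, n_B = 60,
                       admixture_beta_A = c(1e6, 1),
                       admixture_beta_B = c(1, 1e6),
                       mislabel_count = 0, seed = 31)
  co <- simulate_cohort(pan, cfg)
  pca <- genotype_pca(co$genotypes)
  grp <- co$truth$true_group[rownames(pca$coords)]
  a <- pca$coords[grp == "A", 1]; b <- pca$coords[grp == "B", 1]
  # zero overlap on PC1
  expect_true(max(range(a)) < min(range(b)) ||
                min(range(a)) > max(range(b)))
  # duplicated samples land on identical coordinates
  G2 <- cbind(co$genotypes, DUP = co$genotypes[, 1])
  p2 <- genotype_pca(G2)
  expect_equal(unname(p2$coords["DUP", ]),
               unname(p2$coords[colnames(co$genotypes)[1], ]),
               tolerance = 1e-8)
  # eigenvalues are descending and bounded by the total variance
  expect_true(all(diff(pca$eigenvalues) <= 1e-8))
  expect_error(genotype_pca(matrix(1, 5, 5)), "no variance")
})

test_that("PCA coordinates are sample-order invariant up to sign", {
  co <- small_cohort(seed = 17, n_A = 15, n_B = 15, n_markers = 200)
  p1 <- genotype_pca(co$genotypes, n_pc = 2)
  perm <- sample(ncol(co$genotypes))
  p2 <- genotype_pca(co$genotypes[, perm], n_pc = 2)
  for (k in 1:2) {
    v1 <- p1$coords[rownames(p2$coords), k]
    expect_true(isTRUE(all.equal(v1, p2$coords[, k], tolerance = 1e-6)) ||
                  isTRUE(all.equal(v1, -p2$coords[, k], tolerance = 1e-6)))
  }
})

test_that("EM log-likelihood is non-decreasing over iterations", {
  co <- small_cohort(seed = 23, n_A = 5, n_B = 5, n_markers = 150)
  lls <- sapply(1:12, function(k)
    estimate_admixture(co$genotypes, co$panel, max_iter = k,
                       tol = 0)$loglik)
  expect_true(all(diff(t(lls)) >= -1e-8))
})

test_that("admixture estimation recovers pure and planted proportions", {
  pan <- simulate_reference_panel(4761, fst = 0.15, seed = 41)
  # pure-population limit
  cfg <- cohort_config(n_A = 5, n_B = 2, admixture_beta_A = c(1e7, 1),
                       mislabel_count = 0, seed = 41)
  co <- simulate_cohort(pan, cfg)
  est <- estimate_admixture(co$genotypes, pan)
  qa <- est$q[co$truth$true_group[est$sample] == "A"]
  expect_true(all(qa >= 0.97))  # sampling sd of q-hat is ~0.02 at Fst 0.15
  expect_gte(mean(qa), 0.99)
  expect_true(all(est$converged))
})

test_that("a flat panel leaves q unidentifiable at 0.5, unconverged", {
  pan <- data.frame(marker = sprintf("m%d", 1:50), chrom = 1,
                    pos = 1:50, f_A = 0.4, f_B = 0.4)
  G <- matrix(rbinom(100, 2, 0.4), nrow = 50,
              dimnames = list(pan$marker, c("s1", "s2")))
  est <- estimate_admixture(G, pan)
  expect_equal(est$q, c(0.5, 0.5))
  expect_false(any(est$converged))
})

test_that("swapping the reference populations reflects q to 1 - q", {
  co <- small_cohort(seed = 29, n_A = 10, n_B = 10, n_markers = 300)
  est <- estimate_admixture(co$genotypes, co$panel)
  swapped <- co$panel
  names(swapped)[names(swapped) == "f_A"] <- ".tmp"
  names(swapped)[names(swapped) == "f_B"] <- "f_A"
  names(swapped)[names(swapped) == ".tmp"] <- "f_B"
  est2 <- estimate_admixture(co$genotypes, swapped)
  expect_equal(est$q, 1 - est2$q, tolerance = 1e-4)
})

test_that("q estimates are nearly unbiased across the admixture range", {
  pan <- simulate_reference_panel(4761, fst = 0.15, seed = 53)
  qs <- seq(0.1, 0.9, by = 0.1)
  bias <- matrix(NA_real_, nrow = 20, ncol = length(qs))
  for (s in 1:20) {
    set.seed(1000 + s)
    pi <- outer(pan$f_A, qs) + outer(pan$f_B, 1 - qs)
    G <- matrix(rbinom(length(pi), 2, pi), nrow = nrow(pan),
                dimnames = list(pan$marker, paste0("s", seq_along(qs))))
    bias[s, ] <- estimate_admixture(G, pan)$q - qs
  }
  expect_lt(max(abs(colMeans(bias))), 0.01)
})

test_that("missing genotypes are handled marker-wise", {
  co <- small_cohort(seed = 37, n_A = 8, n_B = 8, n_markers = 400)
  G <- co$genotypes
  G[sample(length(G), length(G) * 0.2)] <- NA
  est <- estimate_admixture(G, co$panel)
  expect_true(all(est$frac_markers_used < 1))
  err <- abs(est$q - co$truth$q_true[est$sample])
  expect_lt(mean(err), 0.1)
  # a sample missing beyond the threshold is flagged
  G[seq(1, 400 * 0.6), 1] <- NA
  est2 <- estimate_admixture(G, co$panel)
  expect_true(is.na(est2$q[1]))
})

test_that("concordance filter applies the >55% opposite-ancestry rule", {
  samples <- data.frame(sample = c("s1", "s2", "s3"),
                        self_report = c("B", "A", "A"))
  est <- data.frame(sample = c("s1", "s2", "s3"),
                    q = c(0.60, 0.70, 0.30))
  f <- concordance_filter(samples, est, threshold = 0.55)
  expect_equal(f$excluded$sample, c("s1", "s3"))  # s1: B with 60% A;
  expect_equal(f$kept$sample, "s2")               # s3: A with 70% B
  expect_match(f$excluded$reason[1], "opposite")
  # threshold 1.0 excludes nothing
  f2 <- concordance_filter(samples, est, threshold = 1.0)
  expect_equal(nrow(f2$excluded), 0)
  expect_error(concordance_filter(samples, est, threshold = 0.4),
               "threshold")
  expect_error(concordance_filter(samples, est[-1, ]), "every sample")
})
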