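# Cross-cohort differential mutation-frequency testing, a simplified
# background-rate recurrence (SMG) test, mutation-vs-ancestry
# association, and per-sample burden summaries.

check_two_groups <- function(groups, samples) {
  g <- groups[samples]
  unl <- samples[is.na(g)]
  if (length(unl)) {
    warning(length(unl), " sample(s) without a group label excluded",
            call. = FALSE)
  }
  g <- g[!is.na(g)]
  lev <- sort(unique(as.character(g)))
  if (length(lev) != 2)
    stop("exactly two non-empty groups are required (got ",
         length(lev), ")")
  list(labels = as.character(g), levels = lev)
}

#' Per-gene cross-cohort Fisher comparison
#'
#' For each gene with at least one mutated sample cohort-wide, tests
#' the 2x2 table (mutated / not x group) with the two-sided exact test
#' and adjusts over all tested genes by Benjamini-Hochberg.  Genes with
#' no mutations in either group are reported untested (`p = NA`).
#'
#' @param mm A [build_mutation_matrix()] object.
#' @param groups Named vector mapping sample id to one of two group
#'   labels; samples without a label are excluded with a warning.
#' @return Data.frame with one row per gene: counts, frequencies, odds
#'   ratio, `p`, `q` (BH over tested genes), `direction`
#'   (which group has the higher frequency), `tested`.
#' @export
per_gene_fisher <- function(mm, groups) {
  stopifnot(inherits(mm, "mutation_matrix"))
  gi <- check_two_groups(groups, colnames(mm$indicator))
  ind <- mm$indicator[, colnames(mm$indicator) %in%
                        names(groups)[!is.na(groups)], drop = FALSE]
  g <- as.character(groups[colnames(ind)])
  a_lab <- gi$levels[1]; b_lab <- gi$levels[2]
  in_a <- g == a_lab
  n_a <- sum(in_a); n_b <- sum(!in_a)
  count_a <- rowSums(ind[, in_a, drop = FALSE])
  count_b <- rowSums(ind[, !in_a, drop = FALSE])
  tested <- (count_a + count_b) > 0
  p <- or <- rep(NA_real_, nrow(ind))
  for (i in which(tested)) {
    ft <- fisher_exact(c(count_a[i], n_a - count_a[i],
                         count_b[i], n_b - count_b[i]))
    p[i] <- ft$p_value
    or[i] <- ft$statistic
  }
  q <- rep(NA_real_, nrow(ind))
  q[tested] <- bh_adjust(p[tested])
  freq_a <- count_a / n_a
  freq_b <- count_b / n_b
  data.frame(gene = rownames(ind),
             count_A = count_a, n_A = n_a,
             count_B = count_b, n_B = n_b,
             freq_A = freq_a, freq_B = freq_b,
             odds_ratio = or, p = p, q = q,
             direction = ifelse(freq_a > freq_b, "A_higher",
                                ifelse(freq_b > freq_a, "B_higher", "none")),
             tested = tested,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simplified significantly-mutated-gene test
#'
#' Background-rate recurrence test: the cohort-wide per-base nonsilent
#' mutation rate is `mu = total nonsilent mutations / (sum_g L_g * N)`;
#' under the null a gene of coding length `L_g` mutates a sample with
#' probability `1 - (1 - mu)^L_g`, and the per-gene p-value is the
#' binomial upper tail of the observed mutated-sample count among `N`
#' samples.  This is a declared simplification of covariate-adjusted
#' mutation-significance models: it shares the background-rate null but
#' carries no per-gene covariates.
#'
#' @param mm A [build_mutation_matrix()] object.
#' @param gene_lengths Named numeric vector of coding lengths (bp)
#'   covering every gene in the matrix.
#' @param q_cutoff Significance cutoff on the BH-adjusted q (default
#'   0.1).
#' @param samples Optional subset of sample ids (e.g. one cohort).
#' @return Data.frame per gene: `length_bp`, `observed` mutated
#'   samples, `expected` under the background, `p`, `q`, `significant`.
#' @export
smg_binomial <- function(mm, gene_lengths, q_cutoff = 0.1,
                         samples = NULL) {
  stopifnot(inherits(mm, "mutation_matrix"))
  counts <- mm$counts
  ind <- mm$indicator
  if (!is.null(samples)) {
    counts <- counts[, colnames(counts) %in% samples, drop = FALSE]
    ind <- ind[, colnames(ind) %in% samples, drop = FALSE]
  }
  genes <- rownames(counts)
  miss <- setdiff(genes, names(gene_lengths))
  if (length(miss))
    stop("missing gene lengths for: ", paste(utils::head(miss, 5),
                                             collapse = ", "))
  L <- gene_lengths[genes]
  if (any(L <= 0)) stop("gene lengths must be positive")
  N <- ncol(counts)
  mu <- sum(counts) / (sum(L) * N)
  obs <- rowSums(ind)
  if (mu == 0) {
    p <- rep(1, length(genes))
  } else {
    p_gene <- 1 - (1 - mu)^L
    p <- binomial_tail(obs, N, p_gene)
  }
  q <- bh_adjust(p)
  data.frame(gene = genes, length_bp = as.numeric(L), observed = obs,
             expected = N * (if (mu == 0) 0 else 1 - (1 - mu)^L),
             p = p, q = q, significant = q < q_cutoff,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Association between a gene's mutation status and ancestry
#'
#' Compares the percent European ancestry (`1 - q_A`) of mutated versus
#' non-mutated samples with the Wilcoxon rank-sum test, and reports the
#' fraction of mutated samples with European ancestry above
#' `high_cutoff`.
#'
#' @param indicator Named logical vector: mutation status per sample.
#' @param q_african Named numeric vector: proportion of African
#'   ancestry per sample (the estimate of [estimate_admixture()]).
#' @param high_cutoff European-ancestry threshold for the reported
#'   fraction (default 0.95).
#' @return A list: `test` (an `mm_test`, or NULL), `untestable`,
#'   `n_mutated`, `frac_mutated_high_european`.
#' @export
mutation_ancestry_association <- function(indicator, q_african,
                                          high_cutoff = 0.95) {
  common <- intersect(names(indicator), names(q_african))
  if (length(common) == 0) stop("no samples shared between inputs")
  ind <- indicator[common]
  eur <- 1 - q_african[common]
  keep <- !is.na(ind) & !is.na(eur)
  ind <- ind[keep]; eur <- eur[keep]
  n_mut <- sum(ind)
  if (n_mut < 1 || n_mut == length(ind)) {
    return(list(test = NULL, untestable = TRUE, n_mutated = n_mut,
                frac_mutated_high_european = NA_real_))
  }
  list(test = wilcoxon_rank_sum(eur[ind], eur[!ind]),
       untestable = FALSE, n_mutated = n_mut,
       frac_mutated_high_european = mean(eur[ind] > high_cutoff))
}

#' Per-group nonsilent mutation burden summary
#'
#' Summarises per-sample nonsilent totals by group and compares the two
#' groups with the Wilcoxon rank-sum test.
#'
#' @param mm A [build_mutation_matrix()] object.
#' @param groups Named vector mapping sample id to one of two labels.
#' @return A list: `summary` data.frame (per-group n, mean, median) and
#'   `test` (an `mm_test`).
#' @export
burden_summary <- function(mm, groups) {
  stopifnot(inherits(mm, "mutation_matrix"))
  gi <- check_two_groups(groups, names(mm$sample_totals))
  tot <- mm$sample_totals[!is.na(groups[names(mm$sample_totals)])]
  g <- as.character(groups[names(tot)])
  lev <- gi$levels
  s <- do.call(rbind, lapply(lev, function(l) data.frame(
    group = l, n = sum(g == l), mean = mean(tot[g == l]),
    median = stats::median(tot[g == l]), stringsAsFactors = FALSE)))
  list(summary = s,
       test = wilcoxon_rank_sum(tot[g == lev[1]], tot[g == lev[2]]))
}
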