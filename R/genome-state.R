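# Copy-number-aware locus-state classification (the integrated TP53
# scheme), hyperdiploidy karyotyping from segment tables, and
# expression risk-signature scoring.

#' TP53 locus coordinates (GRCh37)
#'
#' Reads the shipped locus definition (`chr17`, 0-based half-open
#' interval) from `inst/extdata`; override by supplying your own file
#' with columns `chrom`, `start`, `end`.
#'
#' @param file Optional path to an alternative locus TSV.
#' @return A list with `chrom`, `start`, `end`.
#' @export
tp53_locus <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "tp53_locus_grch37.tsv",
                        package = "mmstrat")
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  list(chrom = d$chrom[1], start = d$start[1], end = d$end[1])
}

check_locus <- function(locus) {
  if (!all(c("chrom", "start", "end") %in% names(locus)) ||
      !is.finite(locus$start) || !is.finite(locus$end) ||
      locus$start >= locus$end)
    stop("locus must be a list(chrom, start, end) with start < end")
  locus
}

#' Copy-loss call at a locus from segment data
#'
#' The per-sample locus log2 ratio is the length-weighted mean of all
#' segments overlapping the locus (0-based half-open coordinates);
#' loss is called when it is at or below `loss_threshold`, deep
#' (homozygous-range) loss at or below `deep_threshold`.  Samples with
#' no overlapping segment are no-calls, treated as no loss with a
#' warning.
#'
#' @param segments Segment data.frame: `sample`, `chrom`, `start`,
#'   `end`, `log2`.
#' @param locus `list(chrom, start, end)`, 0-based half-open.
#' @param loss_threshold,deep_threshold log2 thresholds (defaults -0.2
#'   and -1.0, inclusive).
#' @param samples Optional sample universe; defaults to the samples in
#'   `segments`.
#' @return Data.frame per sample: `locus_log2`, `loss`, `deep_loss`,
#'   `no_call`.
#' @export
call_locus_loss <- function(segments, locus, loss_threshold = -0.2,
                            deep_threshold = -1.0, samples = NULL) {
  locus <- check_locus(locus)
  if (is.null(samples)) samples <- unique(segments$sample)
  seg <- segments[segments$chrom == locus$chrom, , drop = FALSE]
  ov_w <- pmin(seg$end, locus$end) - pmax(seg$start, locus$start)
  seg <- seg[ov_w > 0, , drop = FALSE]
  ov_w <- ov_w[ov_w > 0]
  wsum <- tapply(ov_w * seg$log2, seg$sample, sum)
  wtot <- tapply(ov_w, seg$sample, sum)
  l2 <- stats::setNames(rep(NA_real_, length(samples)), samples)
  hit <- intersect(samples, names(wsum))
  l2[hit] <- wsum[hit] / wtot[hit]
  no_call <- is.na(l2)
  if (any(no_call))
    warning(sum(no_call), " sample(s) with no segment overlapping the ",
            "locus: treated as no loss", call. = FALSE)
  data.frame(sample = samples, locus_log2 = as.numeric(l2),
             loss = !is.na(l2) & l2 <= loss_threshold,
             deep_loss = !is.na(l2) & l2 <= deep_threshold,
             no_call = no_call, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Classify the allelic state of a locus
#'
#' Integrated mutation/copy-loss scheme: no event = `wildtype`;
#' mutation without loss = `mutation_only`; loss without mutation =
#' `loh_only`; both = `loh_plus_mutation`.  `mutation_only` and
#' `loh_only` are mono-allelic; `loh_plus_mutation` is bi-allelic, as
#' is any deep (homozygous-range) loss.  Two coincident point mutations
#' without copy loss are not promoted to bi-allelic (phase unknown).
#'
#' @param mutated,loss Logical vectors (recycled to common length).
#' @param deep_loss Logical vector; deep deletion forces `bi_allelic`.
#' @return Data.frame: `state`, `mono_allelic`, `bi_allelic`.
#' @export
classify_locus_state <- function(mutated, loss, deep_loss = FALSE) {
  n <- max(length(mutated), length(loss), length(deep_loss))
  mutated <- rep_len(as.logical(mutated), n)
  loss <- rep_len(as.logical(loss), n)
  deep_loss <- rep_len(as.logical(deep_loss), n)
  state <- ifelse(mutated & loss, "loh_plus_mutation",
           ifelse(mutated, "mutation_only",
           ifelse(loss, "loh_only", "wildtype")))
  bi <- (mutated & loss) | deep_loss
  mono <- (mutated | loss) & !bi
  data.frame(state = state, mono_allelic = mono, bi_allelic = bi,
             stringsAsFactors = FALSE)
}

#' Per-sample locus state from consensus calls and segments
#'
#' Convenience wrapper: a sample is `mutated` when it carries a
#' nonsilent consensus variant in `gene`, `loss`/`deep_loss` come from
#' [call_locus_loss()], and the state from [classify_locus_state()].
#'
#' @param consensus Consensus table ([merge_callers()]).
#' @param segments Segment table.
#' @param samples Sample universe.
#' @param gene Gene symbol (default `"TP53"`).
#' @param locus Locus coordinates; defaults to [tp53_locus()].
#' @param ... Passed to [call_locus_loss()].
#' @return Data.frame per sample: `sample`, `state`, `mono_allelic`,
#'   `bi_allelic`, `locus_log2`.
#' @export
locus_states <- function(consensus, segments, samples, gene = "TP53",
                         locus = tp53_locus(), ...) {
  eff <- classify_effect(consensus$variant_classification,
                         on_unknown = "silent")
  mut_samples <- unique(consensus$sample[consensus$gene == gene &
                                           eff == "nonsilent"])
  loss <- call_locus_loss(segments, locus, samples = samples, ...)
  mutated <- samples %in% mut_samples
  st <- classify_locus_state(mutated, loss$loss, loss$deep_loss)
  cbind(data.frame(sample = samples, stringsAsFactors = FALSE), st,
        locus_log2 = loss$locus_log2)
}

#' Tabulate locus states by group with per-row exact tests
#'
#' Produces the integrated-profile layout: rows `Wildtype`,
#' `Mono-allelic`, `Bi-allelic`, `LOH`, `Mutation`, `LOH+Mutation`
#' (the first three are roll-ups, so rows overlap by design), with
#' per-group counts and percentages and a two-sided Fisher p per row.
#'
#' @param states Output of [locus_states()] (needs `sample`, `state`,
#'   `mono_allelic`, `bi_allelic`).
#' @param groups Named vector mapping sample id to one of two labels.
#' @return Data.frame with one row per category.
#' @export
tabulate_states <- function(states, groups) {
  g <- as.character(groups[states$sample])
  if (anyNA(g)) stop("every sample needs a group label")
  lev <- sort(unique(g))
  if (length(lev) != 2 || any(table(g) == 0))
    stop("two non-empty groups are required")
  flags <- list(
    "Wildtype" = states$state == "wildtype",
    "Mono-allelic" = states$mono_allelic,
    "Bi-allelic" = states$bi_allelic,
    "LOH" = states$state == "loh_only",
    "Mutation" = states$state == "mutation_only",
    "LOH+Mutation" = states$state == "loh_plus_mutation")
  n_a <- sum(g == lev[1]); n_b <- sum(g == lev[2])
  rows <- lapply(names(flags), function(nm) {
    f <- flags[[nm]]
    a <- sum(f & g == lev[1]); b <- sum(f & g == lev[2])
    data.frame(category = nm, count_A = a, pct_A = 100 * a / n_a,
               count_B = b, pct_B = 100 * b / n_b,
               p = fisher_exact(c(a, n_a - a, b, n_b - b))$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- stats::setNames(c(n_a, n_b), lev)
  out
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

#' Hyperdiploidy karyotype call from copy-number segments
#'
#' For each odd autosome (1, 3, ..., 21) the chromosome-level log2
#' ratio is the length-weighted median of its segments; the chromosome
#' is trisomic when that median reaches `gain_threshold` and the
#' gained segments cover at least `min_gain_coverage` of the
#' chromosome's covered length.  A sample is hyperdiploid when at
#' least `min_trisomies` odd autosomes are trisomic.
#'
#' @param segments Segment data.frame.
#' @param gain_threshold log2 gain threshold (default 0.4, just below
#'   the ideal single-copy-gain value `log2(3/2) = 0.585`).
#' @param min_gain_coverage Minimum fraction of covered length at or
#'   above the threshold (default 0.6).
#' @param min_trisomies Odd-chromosome trisomy count defining
#'   hyperdiploidy (default 3).
#' @param samples Optional sample universe; samples with no segments
#'   are returned as no-calls (`karyotype = NA`).
#' @return Data.frame per sample: `n_odd_trisomies`,
#'   `trisomic_chroms` (comma-separated), `karyotype`.
#' @export
call_hyperdiploidy <- function(segments, gain_threshold = 0.4,
                               min_gain_coverage = 0.6,
                               min_trisomies = 3, samples = NULL) {
  if (is.null(samples)) samples <- unique(segments$sample)
  odd <- seq(1, 21, by = 2)
  seg <- segments[segments$chrom %in% odd, , drop = FALSE]
  seg$w <- seg$end - seg$start
  res <- lapply(samples, function(s) {
    ss <- seg[seg$sample == s, , drop = FALSE]
    if (nrow(ss) == 0 && !s %in% segments$sample)
      return(data.frame(sample = s, n_odd_trisomies = NA_integer_,
                        trisomic_chroms = NA_character_,
                        karyotype = NA_character_,
                        stringsAsFactors = FALSE))
    tri <- vapply(odd, function(ch) {
      cs <- ss[ss$chrom == ch, , drop = FALSE]
      if (nrow(cs) == 0) return(FALSE)
      wm <- weighted_median(cs$log2, cs$w)
      cov_gain <- sum(cs$w[cs$log2 >= gain_threshold]) / sum(cs$w)
      wm >= gain_threshold && cov_gain >= min_gain_coverage
    }, logical(1))
    data.frame(sample = s, n_odd_trisomies = sum(tri),
               trisomic_chroms = paste(odd[tri], collapse = ","),
               karyotype = if (sum(tri) >= min_trisomies) "hyperdiploid"
                           else "nonhyperdiploid",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Expression risk-signature score
#'
#' Score per sample = mean `log2(TPM + 1)` over the up-regulated
#' signature genes minus the mean over the down-regulated genes;
#' samples above `cutoff` are flagged high-risk.  When more than
#' `max_missing` of the signature genes are absent from the matrix the
#' scores are flagged low-confidence.  Optional group / karyotype
#' vectors add high-risk frequency tables with per-table exact tests.
#'
#' @param tpm Gene x sample TPM matrix.
#' @param up_genes,down_genes Signature gene sets (at least one of
#'   each must be present in the matrix).
#' @param cutoff High-risk score cutoff (cohort-specific; no universal
#'   default is asserted).
#' @param groups,karyotype Optional named vectors over samples.
#' @param max_missing Maximum tolerated missing-signature fraction.
#' @return A list: `scores` data.frame (`sample`, `score`,
#'   `high_risk`), `low_confidence`, `missing_genes`, and (when
#'   requested) `by_group` / `by_karyotype` frequency tables with a
#'   Fisher p.
#' @export
risk_score <- function(tpm, up_genes, down_genes, cutoff,
                       groups = NULL, karyotype = NULL,
                       max_missing = 0.2) {
  tpm <- as.matrix(tpm)
  up <- intersect(up_genes, rownames(tpm))
  dn <- intersect(down_genes, rownames(tpm))
  if (length(up) == 0 || length(dn) == 0)
    stop("need at least one up and one down signature gene in the matrix")
  missing <- setdiff(c(up_genes, down_genes), rownames(tpm))
  frac_missing <- length(missing) / (length(up_genes) + length(down_genes))
  low_conf <- frac_missing > max_missing
  if (low_conf)
    warning(sprintf("%.0f%% of signature genes missing: scores are %s",
                    100 * frac_missing, "low-confidence"), call. = FALSE)
  lg <- log2(tpm + 1)
  score <- colMeans(lg[up, , drop = FALSE]) -
    colMeans(lg[dn, , drop = FALSE])
  scores <- data.frame(sample = colnames(tpm), score = as.numeric(score),
                       high_risk = score > cutoff,
                       stringsAsFactors = FALSE, row.names = NULL)
  out <- list(scores = scores, low_confidence = low_conf,
              missing_genes = missing)
  freq_table <- function(strata) {
    s <- as.character(strata[scores$sample])
    keep <- !is.na(s)
    lev <- sort(unique(s[keep]))
    tab <- do.call(rbind, lapply(lev, function(l) {
      hr <- sum(scores$high_risk[keep][s[keep] == l])
      n <- sum(s[keep] == l)
      data.frame(stratum = l, n = n, high_risk = hr,
                 pct_high_risk = 100 * hr / n, stringsAsFactors = FALSE)
    }))
    if (length(lev) == 2) {
      attr(tab, "fisher_p") <- fisher_exact(c(
        tab$high_risk[1], tab$n[1] - tab$high_risk[1],
        tab$high_risk[2], tab$n[2] - tab$high_risk[2]))$p_value
    }
    tab
  }
  if (!is.null(groups)) out$by_group <- freq_table(groups)
  if (!is.null(karyotype)) out$by_karyotype <- freq_table(karyotype)
  out
}
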