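# Seeded generator for a synthetic admixed two-population myeloma-like
# cohort.  It produces every file the analysis pipeline consumes --
# reference panel, germline dosages, sample sheet, three noisy caller
# tables, copy-number segments, TPM matrix -- together with the planted
# truth needed to score recovery.  Truth never appears in the
# analysis-facing files.

# GRCh37 autosome lengths (bp), chr1..chr22
GRCH37_AUTOSOME_LENGTHS <- c(
  249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
  159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
  115169878, 107349540, 102531392,  90354753,  81195210,  78077248,
   59128983,  63025520,  48129895,  51304566)

NONSILENT_CLASSES <- c("Missense_Mutation", "Nonsense_Mutation",
                       "Nonstop_Mutation", "Splice_Site",
                       "Frame_Shift_Del", "Frame_Shift_Ins",
                       "In_Frame_Del", "In_Frame_Ins",
                       "Translation_Start_Site")
SILENT_CLASSES <- c("Silent", "Intron", "3'UTR", "5'UTR",
                    "5'Flank", "3'Flank", "IGR", "RNA")

#' Simulate a two-population reference allele-frequency panel
#'
#' Balding-Nichols model: each marker draws an ancestral frequency
#' `f_anc ~ Uniform(0.05, 0.95)` and, independently for each of the two
#' populations, a population frequency from
#' `Beta(f_anc (1-F)/F, (1-f_anc)(1-F)/F)` with `F` the fixation index.
#' Frequencies are clipped to `[0.001, 0.999]` so the admixture
#' likelihood never evaluates `log(0)`.
#'
#' @param n_markers Number of biallelic markers (>= 1).
#' @param fst Fixation index in (0, 1) separating the two populations.
#' @param seed Optional integer seed; when given the panel is
#'   reproducible byte-for-byte.
#' @return A data.frame with columns `marker`, `chrom`, `pos` (1-based),
#'   `f_A`, `f_B`.
#' @export
simulate_reference_panel <- function(n_markers, fst, seed = NULL) {
  if (n_markers < 1) stop("n_markers must be >= 1")
  if (!is.finite(fst) || fst <= 0 || fst >= 1)
    stop("fst must lie strictly inside (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  f_anc <- stats::runif(n_markers, 0.05, 0.95)
  s1 <- f_anc * (1 - fst) / fst
  s2 <- (1 - f_anc) * (1 - fst) / fst
  clip <- function(p) pmin(pmax(p, 0.001), 0.999)
  chrom <- sort(rep_len(1:22, n_markers))
  pos <- integer(n_markers)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- 1e5 + seq_along(idx) * 5e4
  }
  data.frame(marker = sprintf("mk%06d", seq_len(n_markers)),
             chrom = chrom, pos = pos,
             f_A = clip(stats::rbeta(n_markers, s1, s2)),
             f_B = clip(stats::rbeta(n_markers, s1, s2)),
             stringsAsFactors = FALSE)
}

#' Default somatic gene specification
#'
#' Per-gene coding length and nonsilent mutation probability in each
#' self-report group (A = the African-ancestry group, B = the
#' European-ancestry group).  The defaults mix recurrent myeloma driver
#' genes at field-typical frequencies -- some with a two-fold
#' between-group rate difference -- with equal-rate passenger genes.
#' TP53 is absent here because its mutations and deletions are planted
#' jointly through `tp53_spec` (see [cohort_config()]).
#'
#' @param n_passengers Number of equal-rate passenger genes to append.
#' @param passenger_rate Shared passenger mutation probability.
#' @return A data.frame with columns `gene`, `chrom`, `start`,
#'   `length_bp`, `rate_A`, `rate_B`.
#' @export
default_gene_spec <- function(n_passengers = 20, passenger_rate = 0.05) {
  drivers <- data.frame(
    gene   = c("KRAS", "NRAS", "BRAF", "FAM46C", "DIS3", "IRF4",
               "RYR1", "BCL7A", "PTCHD3", "AUTS2"),
    chrom  = c(12, 1, 7, 1, 13, 6, 19, 12, 10, 7),
    start  = c(25358180, 115247085, 140419127, 118148556, 73333880,
               391739, 38924340, 122456912, 27687558, 69063905),
    length_bp = c(567, 570, 2301, 1176, 2877, 1356, 15117, 630, 2313, 3759),
    rate_A = c(0.23, 0.20, 0.06, 0.126, 0.11, 0.02, 0.30, 0.10, 0.08, 0.06),
    rate_B = c(0.22, 0.19, 0.06, 0.083, 0.11, 0.07, 0.15, 0.05, 0.04, 0.03),
    stringsAsFactors = FALSE)
  if (n_passengers > 0) {
    pg <- data.frame(
      gene = sprintf("PSG%02d", seq_len(n_passengers)),
      chrom = rep_len(c(2:5, 8, 9, 11, 14:16, 18, 20:22), n_passengers),
      start = 3e7 + seq_len(n_passengers) * 2e6,
      length_bp = 1500,
      rate_A = passenger_rate, rate_B = passenger_rate,
      stringsAsFactors = FALSE)
    drivers <- rbind(drivers, pg)
  }
  drivers
}

#' Generator configuration for a synthetic cohort
#'
#' Defaults emulate the study conditions of an exome cohort of 128
#' self-reported African-American and 593 self-reported Caucasian
#' myeloma cases: African admixture `q ~ Beta(7, 3)` in group A (mean
#' European admixture 30%) and `q ~ Beta(0.1, 99.9)` in group B (mean
#' African admixture 0.1%); three mislabelled samples; joint TP53
#' LOH/mutation state frequencies matching the published integrated
#' profile; half the cohort hyperdiploid; exponential survival with a
#' three-fold hazard for bi-allelic TP53 loss, censored at 4 years of
#' follow-up.
#'
#' @param n_A,n_B Samples per self-report group.
#' @param admixture_beta_A,admixture_beta_B `c(alpha, beta)` of the Beta
#'   distribution of true African admixture per group.
#' @param mislabel_count Number of samples whose self-report is swapped
#'   relative to their true ancestral group.
#' @param gene_spec Data.frame as returned by [default_gene_spec()].
#' @param silent_rate Per-gene-sample probability of an additional
#'   silent (non-coding-impact) call.
#' @param caller_sensitivity,caller_fpr Length-3 vectors: probability a
#'   caller re-emits a true call, and its per-(gene, sample)
#'   false-positive probability.
#' @param tp53_spec Named list `A`/`B`, each a vector of joint state
#'   probabilities `loh_only`, `mutation_only`, `loh_plus_mutation`
#'   (the remainder is wildtype).
#' @param deletion_log2 log2 ratio planted for a hemizygous TP53 loss.
#' @param hyperdiploid_fraction Fraction of samples planted with >= 3
#'   odd-chromosome trisomies.
#' @param trisomy_log2 log2 ratio planted for a whole-chromosome gain.
#' @param segment_noise_sd SD of the log2 noise on background segments.
#' @param survival_baseline_hazard Baseline exponential hazard
#'   (events/year).
#' @param survival_hazard_ratio_biallelic Hazard ratio for bi-allelic
#'   TP53 inactivation.
#' @param censor_horizon Administrative censoring time (years).
#' @param n_signature_genes Up- and down-regulated genes per arm of the
#'   expression risk signature.
#' @param risk_high_fraction Fraction of samples planted as high-risk.
#' @param risk_shift_log2 log2 expression shift of the up-arm in
#'   high-risk samples.
#' @param seed Integer seed; fixed seed implies byte-identical output.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_A = 128, n_B = 593,
                          admixture_beta_A = c(7, 3),
                          admixture_beta_B = c(0.1, 99.9),
                          mislabel_count = 3,
                          gene_spec = default_gene_spec(),
                          silent_rate = 0.02,
                          caller_sensitivity = c(0.95, 0.92, 0.90),
                          caller_fpr = c(0.002, 0.002, 0.002),
                          tp53_spec = list(
                            A = c(loh_only = 0.063, mutation_only = 0.016,
                                  loh_plus_mutation = 0.079),
                            B = c(loh_only = 0.086, mutation_only = 0.066,
                                  loh_plus_mutation = 0.152)),
                          deletion_log2 = -0.7,
                          hyperdiploid_fraction = 0.5,
                          trisomy_log2 = log2(3 / 2),
                          segment_noise_sd = 0.05,
                          survival_baseline_hazard = 0.12,
                          survival_hazard_ratio_biallelic = 3,
                          censor_horizon = 4,
                          n_signature_genes = 10,
                          risk_high_fraction = 0.15,
                          risk_shift_log2 = 2,
                          seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(unlist(cfg$tp53_spec), cfg$caller_sensitivity, cfg$caller_fpr,
             cfg$hyperdiploid_fraction, cfg$risk_high_fraction,
             cfg$silent_rate,
             cfg$gene_spec$rate_A, cfg$gene_spec$rate_B)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(sapply(cfg$tp53_spec, sum) > 1))
    stop("tp53_spec state probabilities must sum to at most 1 per group")
  if (cfg$mislabel_count > cfg$n_A + cfg$n_B)
    stop("mislabel_count exceeds the number of samples")
  if (length(cfg$caller_sensitivity) != 3 || length(cfg$caller_fpr) != 3)
    stop("exactly three callers are simulated")
  structure(cfg, class = "cohort_config")
}

# age-of-onset band probabilities per group (AA then CA), bands
# 25-39 ... 90-99; group A uses 18/127 in the 70-79 band
AGE_BANDS <- c("25-39", "40-49", "50-59", "60-69", "70-79", "80-89", "90-99")
AGE_PROBS_A <- c(4, 14, 27, 49, 18, 14, 1) / 127
AGE_PROBS_B <- c(10, 27, 145, 224, 132, 48, 5) / 591

random_alleles <- function(n) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  list(ref = ref, alt = unname(alt))
}

make_calls <- function(sample_id, gene, gene_spec_row) {
  n <- length(sample_id)
  al <- random_alleles(n)
  data.frame(
    sample = sample_id, gene = gene,
    chrom = gene_spec_row$chrom,
    pos = gene_spec_row$start +
      sample.int(max(gene_spec_row$length_bp, 2L), n, replace = TRUE),
    ref = al$ref, alt = al$alt,
    variant_classification = sample(
      NONSILENT_CLASSES, n, replace = TRUE,
      prob = c(0.62, 0.10, 0.01, 0.07, 0.08, 0.05, 0.03, 0.03, 0.01)),
    stringsAsFactors = FALSE)
}

#' Simulate a full synthetic cohort
#'
#' Draws, per sample, a true ancestral group and admixture proportion,
#' genotypes at the panel markers (`Binomial(2, q f_A + (1-q) f_B)`),
#' an age-of-onset band, nonsilent somatic mutations per gene at the
#' group rate, a joint TP53 LOH/mutation state, copy-number segments
#' (background noise, planted TP53 deletions, planted odd-chromosome
#' trisomies), an expression matrix carrying a planted high-risk
#' signature, and exponential survival with an elevated hazard for
#' bi-allelic TP53 inactivation.  Three caller tables re-emit the true
#' calls subject to per-caller sensitivity and add false positives at
#' the per-caller false-positive rate.
#'
#' @param panel Reference panel from [simulate_reference_panel()].
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `panel`,
#'   `genotypes` (marker x sample dosage matrix), `samples` (sample
#'   sheet), `caller_calls` (list of 3 MAF-like data.frames),
#'   `segments`, `tpm`, and `truth` (planted parameters; never written
#'   to the analysis-facing files).
#' @export
simulate_cohort <- function(panel, config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_A <- config$n_A; n_B <- config$n_B; n <- n_A + n_B
  ids <- sprintf("MM%04d", seq_len(n))
  true_group <- rep(c("A", "B"), c(n_A, n_B))

  q <- numeric(n)
  q[true_group == "A"] <- stats::rbeta(n_A, config$admixture_beta_A[1],
                                       config$admixture_beta_A[2])
  q[true_group == "B"] <- stats::rbeta(n_B, config$admixture_beta_B[1],
                                       config$admixture_beta_B[2])

  self_report <- true_group
  mislabelled <- character(0)
  if (config$mislabel_count > 0) {
    flip <- sample.int(n, config$mislabel_count)
    self_report[flip] <- ifelse(true_group[flip] == "A", "B", "A")
    mislabelled <- ids[flip]
  }

  # germline dosages, markers x samples
  pi <- outer(panel$f_A, q) + outer(panel$f_B, 1 - q)
  G <- matrix(stats::rbinom(length(pi), 2L, pi), nrow = nrow(panel),
              dimnames = list(panel$marker, ids))

  age_band <- character(n)
  age_band[true_group == "A"] <- sample(AGE_BANDS, n_A, TRUE, AGE_PROBS_A)
  age_band[true_group == "B"] <- sample(AGE_BANDS, n_B, TRUE, AGE_PROBS_B)

  # --- somatic truth per gene ------------------------------------------
  gs <- config$gene_spec
  mut_truth <- matrix(FALSE, nrow = nrow(gs), ncol = n,
                      dimnames = list(gs$gene, ids))
  for (g in seq_len(nrow(gs))) {
    r <- ifelse(true_group == "A", gs$rate_A[g], gs$rate_B[g])
    mut_truth[g, ] <- stats::runif(n) < r
  }

  # --- TP53 joint state -------------------------------------------------
  tp53_state <- character(n)
  for (grp in c("A", "B")) {
    idx <- which(true_group == grp)
    pr <- config$tp53_spec[[grp]]
    pw <- c(1 - sum(pr), pr)
    tp53_state[idx] <- sample(c("wildtype", names(pr)), length(idx),
                              replace = TRUE, prob = pw)
  }
  tp53_mut <- tp53_state %in% c("mutation_only", "loh_plus_mutation")
  tp53_del <- tp53_state %in% c("loh_only", "loh_plus_mutation")
  tp53_biallelic <- tp53_state == "loh_plus_mutation"

  locus <- tp53_locus()
  tp53_row <- data.frame(chrom = locus$chrom, start = locus$start,
                         length_bp = locus$end - locus$start)

  true_calls <- list()
  for (g in seq_len(nrow(gs))) {
    who <- ids[mut_truth[g, ]]
    if (length(who))
      true_calls[[length(true_calls) + 1L]] <-
        make_calls(who, gs$gene[g], gs[g, ])
  }
  if (any(tp53_mut))
    true_calls[[length(true_calls) + 1L]] <-
      make_calls(ids[tp53_mut], "TP53", tp53_row)
  # silent background calls, exercised by effect classification
  for (g in seq_len(nrow(gs))) {
    who <- ids[stats::runif(n) < config$silent_rate]
    if (length(who)) {
      cal <- make_calls(who, gs$gene[g], gs[g, ])
      cal$variant_classification <- sample(SILENT_CLASSES, nrow(cal),
                                           replace = TRUE)
      true_calls[[length(true_calls) + 1L]] <- cal
    }
  }
  true_calls <- do.call(rbind, true_calls)

  # --- three noisy callers ---------------------------------------------
  caller_names <- c("caller1", "caller2", "caller3")
  all_genes <- rbind(gs[, c("gene", "chrom", "start", "length_bp")],
                     cbind(gene = "TP53", tp53_row))
  caller_calls <- lapply(seq_len(3), function(k) {
    keep <- stats::runif(nrow(true_calls)) < config$caller_sensitivity[k]
    calls <- true_calls[keep, , drop = FALSE]
    n_cells <- n * nrow(all_genes)
    n_fp <- stats::rbinom(1L, n_cells, config$caller_fpr[k])
    if (n_fp > 0) {
      cell <- sample.int(n_cells, n_fp)
      gi <- (cell - 1L) %/% n + 1L
      si <- (cell - 1L) %% n + 1L
      fp <- do.call(rbind, lapply(seq_len(n_fp), function(i)
        make_calls(ids[si[i]], all_genes$gene[gi[i]], all_genes[gi[i], ])))
      calls <- rbind(calls, fp)
    }
    calls <- calls[order(calls$sample, calls$chrom, calls$pos), ]
    rownames(calls) <- NULL
    calls
  })
  names(caller_calls) <- caller_names

  # --- copy-number segments --------------------------------------------
  hrd <- stats::runif(n) < config$hyperdiploid_fraction
  odd_chroms <- seq(1, 21, by = 2)
  trisomies <- vector("list", n)
  seg_list <- vector("list", n)
  for (i in seq_len(n)) {
    k <- if (hrd[i]) sample(3:7, 1) else
      sample(0:2, 1, prob = c(0.7, 0.2, 0.1))
    tri <- sort(sample(odd_chroms, k))
    trisomies[[i]] <- tri
    log2v <- stats::rnorm(22, 0, config$segment_noise_sd)
    log2v[tri] <- log2v[tri] + config$trisomy_log2
    seg <- data.frame(sample = ids[i], chrom = 1:22, start = 0L,
                      end = GRCH37_AUTOSOME_LENGTHS,
                      log2 = round(log2v, 4), stringsAsFactors = FALSE)
    if (tp53_del[i]) {
      del_start <- 7e6L; del_end <- 85e5L
      ch17 <- seg[seg$chrom == 17, ]
      base <- ch17$log2
      seg <- seg[seg$chrom != 17, ]
      seg <- rbind(seg, data.frame(
        sample = ids[i], chrom = 17L,
        start = c(0L, del_start, del_end),
        end = c(del_start, del_end, GRCH37_AUTOSOME_LENGTHS[17]),
        log2 = round(c(base, config$deletion_log2 +
                         stats::rnorm(1, 0, config$segment_noise_sd),
                       base), 4)))
    }
    seg_list[[i]] <- seg
  }
  segments <- do.call(rbind, seg_list)
  segments <- segments[order(segments$sample, segments$chrom,
                             segments$start), ]
  rownames(segments) <- NULL

  # --- expression risk signature ---------------------------------------
  m <- config$n_signature_genes
  sig_up <- sprintf("UPG%02d", seq_len(m))
  sig_down <- sprintf("DNG%02d", seq_len(m))
  other <- sprintf("EXP%02d", seq_len(30))
  expr_genes <- c(sig_up, sig_down, other)
  risk_high <- stats::runif(n) < config$risk_high_fraction
  lg <- matrix(stats::rnorm(length(expr_genes) * n, 5, 1),
               nrow = length(expr_genes),
               dimnames = list(expr_genes, ids))
  lg[sig_up, risk_high] <- lg[sig_up, risk_high] + config$risk_shift_log2
  tpm <- round(2^lg, 3)

  # --- survival ---------------------------------------------------------
  hz <- config$survival_baseline_hazard *
    config$survival_hazard_ratio_biallelic^tp53_biallelic
  t_event <- stats::rexp(n, hz)
  event <- as.integer(t_event <= config$censor_horizon)
  time <- round(pmin(t_event, config$censor_horizon), 4)
  time[time <= 0] <- 1e-4

  samples <- data.frame(sample = ids, self_report = self_report,
                        age_band = age_band, time_years = time,
                        event = event, stringsAsFactors = FALSE)

  truth <- list(
    q_true = stats::setNames(q, ids),
    true_group = stats::setNames(true_group, ids),
    mislabelled = mislabelled,
    gene_rates = gs,
    differential_genes = gs$gene[gs$rate_A != gs$rate_B],
    mutation_truth = mut_truth,
    tp53_state = stats::setNames(tp53_state, ids),
    tp53_biallelic = stats::setNames(tp53_biallelic, ids),
    hyperdiploid = stats::setNames(hrd, ids),
    trisomies = stats::setNames(trisomies, ids),
    risk_high = stats::setNames(risk_high, ids),
    config = unclass(config))

  structure(list(panel = panel, genotypes = G, samples = samples,
                 caller_calls = caller_calls, segments = segments,
                 tpm = tpm, truth = truth),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to analysis-facing files
#'
#' Emits `panel.tsv`, `genotypes.tsv` (markers x samples),
#' `sample_sheet.tsv`, `caller1.maf.tsv` .. `caller3.maf.tsv`,
#' `segments.seg` (0-based half-open), `tpm.tsv`, and `manifest.json`
#' (generator configuration and seed).  Planted truth is not written.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  utils::write.table(cohort$panel, p("panel.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gt <- data.frame(marker = rownames(cohort$genotypes), cohort$genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(gt, p("genotypes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$samples, p("sample_sheet.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (k in seq_along(cohort$caller_calls))
    utils::write.table(cohort$caller_calls[[k]],
                       p(sprintf("caller%d.maf.tsv", k)), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$segments, p("segments.seg"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tp <- data.frame(gene = rownames(cohort$tpm), cohort$tpm,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tp, p("tpm.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- cohort$truth$config
  cfg$gene_spec <- NULL
  jsonlite::write_json(list(generator = "mmstrat::simulate_cohort",
                            seed = cfg$seed, config = cfg),
                       p("manifest.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(vapply(c("panel.tsv", "genotypes.tsv", "sample_sheet.tsv",
                     "caller1.maf.tsv", "caller2.maf.tsv",
                     "caller3.maf.tsv", "segments.seg", "tpm.tsv",
                     "manifest.json"), p, character(1)))
}
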