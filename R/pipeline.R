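# End-to-end orchestration: ancestry -> consensus -> burden ->
# locus state / karyotype / risk -> survival, from one configuration.
# Stages communicate through files; every output carries a provenance
# header and the aggregate report is a single JSON.

#' Pipeline configuration
#'
#' Collects input paths and analysis thresholds.  Relative paths are
#' interpreted from the caller's working directory.
#'
#' @param sample_sheet,panel,genotypes,segments,tpm Input file paths.
#' @param callers Character vector of caller MAF-like TSV paths (the
#'   consensus rule is `min_callers` of `length(callers)`).
#' @param group_a,group_b Self-report labels (ancestry A / B).
#' @param concordance_threshold Discordance exclusion threshold.
#' @param min_callers Consensus support requirement.
#' @param loss_threshold,deep_loss_threshold,gain_threshold log2
#'   thresholds for locus loss, deep loss, and chromosome gain.
#' @param smg_q SMG significance cutoff on q.
#' @param fisher_alpha Per-gene comparison significance level.
#' @param locus_gene,locus Locus of interest for state classification.
#' @param risk_up,risk_down,risk_cutoff Expression signature gene sets
#'   and high-risk cutoff (risk scoring is skipped when either set is
#'   NULL).
#' @param seed Seed recorded in every output header.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sample_sheet, panel, genotypes, callers,
                            segments, tpm = NULL,
                            group_a = "A", group_b = "B",
                            concordance_threshold = 0.55,
                            min_callers = 2L,
                            loss_threshold = -0.2,
                            deep_loss_threshold = -1.0,
                            gain_threshold = 0.4,
                            smg_q = 0.1, fisher_alpha = 0.05,
                            locus_gene = "TP53", locus = NULL,
                            risk_up = NULL, risk_down = NULL,
                            risk_cutoff = 0, seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full ancestry-stratified somatic analysis
#'
#' Executes the stages in dependency order: ancestry estimation and the
#' self-report concordance filter; multi-caller consensus and the
#' mutation matrix; cross-cohort per-gene comparison, per-cohort SMG
#' test, and burden summary; locus-state classification and
#' group tabulation; hyperdiploidy karyotyping; optional risk-signature
#' scoring; Kaplan-Meier / log-rank survival stratified by locus state
#' and by group.  Each output TSV carries a header with the package
#' version, seed, and configuration fingerprint; `report.json`
#' aggregates the results.  Any stage failure aborts with the stage
#' name.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  cfg_json <- jsonlite::toJSON(config[!vapply(config, is.null,
                                              logical(1))],
                               auto_unbox = TRUE, digits = NA)
  chash <- fnv1a_hash(as.character(cfg_json))
  emit <- function(x, name)
    write_tsv_report(x, file.path(out_dir, name), config$seed, chash)
  report <- list(package_version =
                   as.character(utils::packageVersion("mmstrat")),
                 seed = config$seed, config_hash = chash)

  # --- ancestry ---------------------------------------------------------
  anc <- run_stage("ancestry", {
    sheet <- read_sample_sheet(config$sample_sheet)
    panel <- read_panel(config$panel)
    G <- read_genotypes(config$genotypes)
    est <- estimate_admixture(G, panel)
    pca <- genotype_pca(G, n_pc = 4)
    filt <- concordance_filter(sheet, est, config$concordance_threshold,
                               config$group_a, config$group_b)
    emit(est, "ancestry_estimates.tsv")
    emit(data.frame(sample = rownames(pca$coords), pca$coords),
         "pca_coordinates.tsv")
    list(sheet = sheet, est = est, filt = filt)
  })
  kept <- anc$filt$kept
  report$n_samples <- nrow(anc$sheet)
  report$n_excluded_discordant <- nrow(anc$filt$excluded)
  report$excluded <- anc$filt$excluded$sample
  groups <- stats::setNames(kept$self_report, kept$sample)

  # --- consensus --------------------------------------------------------
  cons <- run_stage("consensus", {
    callsets <- lapply(config$callers, read_maf)
    names(callsets) <- sub("\\..*$", "", basename(config$callers))
    cc <- merge_callers(callsets, config$min_callers)
    emit(cc, "consensus_calls.tsv")
    cc
  })
  mm <- run_stage("mutation_matrix", {
    m <- build_mutation_matrix(cons, samples = kept$sample)
    cnt <- data.frame(gene = rownames(m$counts), m$counts,
                      check.names = FALSE)
    emit(cnt, "mutation_matrix.tsv")
    m
  })

  # --- burden comparison ------------------------------------------------
  report$burden <- run_stage("burden_compare", {
    cmp <- per_gene_fisher(mm, groups)
    cmp <- cmp[order(cmp$p), ]
    emit(cmp, "gene_comparison.tsv")
    bs <- burden_summary(mm, groups)
    list(n_genes_tested = sum(cmp$tested),
         significant_genes =
           cmp$gene[!is.na(cmp$p) & cmp$p < config$fisher_alpha],
         burden_means = stats::setNames(bs$summary$mean, bs$summary$group),
         burden_p = bs$test$p_value)
  })

  # --- genome state -----------------------------------------------------
  gs <- run_stage("genome_state", {
    seg <- read_seg(config$segments)
    locus <- if (is.null(config$locus)) tp53_locus() else config$locus
    st <- locus_states(cons, seg, samples = kept$sample,
                       gene = config$locus_gene, locus = locus,
                       loss_threshold = config$loss_threshold,
                       deep_threshold = config$deep_loss_threshold)
    emit(st, "locus_states.tsv")
    tab <- tabulate_states(st, groups)
    emit(tab, "locus_state_table.tsv")
    kar <- call_hyperdiploidy(seg, config$gain_threshold,
                              samples = kept$sample)
    emit(kar, "karyotype.tsv")
    list(states = st, tab = tab, karyotype = kar)
  })
  report$locus_state_table <- gs$tab
  report$karyotype_frequencies <-
    as.list(table(gs$karyotype$karyotype, useNA = "no"))

  # --- risk signature ---------------------------------------------------
  if (!is.null(config$risk_up) && !is.null(config$risk_down) &&
      !is.null(config$tpm)) {
    report$risk <- run_stage("risk_score", {
      tpm <- read_tpm(config$tpm)
      kar <- stats::setNames(gs$karyotype$karyotype, gs$karyotype$sample)
      rs <- risk_score(tpm, config$risk_up, config$risk_down,
                       config$risk_cutoff, groups = groups,
                       karyotype = kar)
      emit(rs$scores, "risk_scores.tsv")
      list(pct_high_risk = 100 * mean(rs$scores$high_risk),
           by_group = rs$by_group,
           by_group_p = attr(rs$by_group, "fisher_p"))
    })
  }

  # --- survival ---------------------------------------------------------
  if (all(c("time_years", "event") %in% names(kept))) {
    report$survival <- run_stage("survival", {
      st <- gs$states
      cls <- ifelse(st$bi_allelic, "bi_allelic",
                    ifelse(st$mono_allelic, "mono_allelic", "wildtype"))
      names(cls) <- st$sample
      strata <- cls[kept$sample]
      lr <- logrank_test(kept$time_years, kept$event, strata)
      pw <- logrank_pairwise(kept$time_years, kept$event, strata)
      lr_group <- logrank_test(kept$time_years, kept$event,
                               kept$self_report)
      km <- do.call(rbind, lapply(split(seq_len(nrow(kept)), strata),
        function(ix) {
          cur <- km_estimate(kept$time_years[ix], kept$event[ix])
          cbind(stratum = strata[ix][1], as.data.frame(cur))
        }))
      emit(km, "km_curves.tsv")
      emit(pw, "logrank_pairwise.tsv")
      list(locus_state_logrank_p =
             if (lr$untestable) NA else lr$test$p_value,
           locus_state_logrank_chisq =
             if (lr$untestable) NA else lr$test$statistic,
           group_logrank_p =
             if (lr_group$untestable) NA else lr_group$test$p_value,
           pairwise = pw)
    })
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
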