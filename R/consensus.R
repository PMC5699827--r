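# Multi-caller somatic consensus and the gene x sample mutation matrix.

#' Merge somatic call tables under an m-of-n consensus rule
#'
#' Variants are keyed by `(sample, chrom, pos, ref, alt)`; a key is
#' retained when it appears in at least `min_callers` of the supplied
#' callsets (the study rule is 2 of 3).  Annotation fields (`gene`,
#' `variant_classification`) are taken from the first supporting caller
#' in `priority` order; a `callers` column records provenance.
#' Duplicate keys within one callset are deduplicated with a warning;
#' rows with malformed positions (missing, non-numeric, or < 1) are
#' rejected with a message.
#'
#' @param callsets Named list of MAF-like data.frames with columns
#'   `sample`, `gene`, `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `variant_classification`.
#' @param min_callers Minimum number of supporting callers (1..length).
#' @param priority Caller names in annotation-precedence order;
#'   defaults to the list order.
#' @return Consensus data.frame sorted by `(sample, chrom, pos)` with
#'   `callers` (comma-separated) and `n_callers` columns.
#' @export
merge_callers <- function(callsets, min_callers = 2L,
                          priority = names(callsets)) {
  if (is.null(names(callsets)))
    names(callsets) <- paste0("caller", seq_along(callsets))
  if (is.null(priority)) priority <- names(callsets)
  if (min_callers < 1 || min_callers > length(callsets))
    stop("min_callers must lie in 1..", length(callsets))
  req <- c("sample", "gene", "chrom", "pos", "ref", "alt",
           "variant_classification")
  cleaned <- lapply(names(callsets), function(nm) {
    cs <- callsets[[nm]]
    miss <- setdiff(req, names(cs))
    if (length(miss))
      stop("callset '", nm, "' lacks columns: ", paste(miss, collapse = ", "))
    pos <- suppressWarnings(as.numeric(cs$pos))
    bad <- is.na(pos) | pos < 1 | pos != round(pos)
    if (any(bad)) {
      message(sum(bad), " row(s) with malformed position rejected from '",
              nm, "'")
      cs <- cs[!bad, , drop = FALSE]
    }
    key <- paste(cs$sample, cs$chrom, cs$pos, cs$ref, cs$alt, sep = "\r")
    if (anyDuplicated(key)) {
      warning("duplicate variant keys in callset '", nm,
              "' deduplicated (first kept)", call. = FALSE)
      cs <- cs[!duplicated(key), , drop = FALSE]
      key <- key[!duplicated(key)]
    }
    cs$.key <- key
    cs$.caller <- nm
    cs[, c(req, ".key", ".caller")]
  })
  combined <- do.call(rbind, cleaned)
  if (is.null(combined) || nrow(combined) == 0) {
    out <- data.frame(sample = character(), gene = character(),
                      chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      variant_classification = character(),
                      callers = character(), n_callers = integer(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  support <- split(combined$.caller, combined$.key)
  n_sup <- lengths(support)
  keep_keys <- names(support)[n_sup >= min_callers]
  # annotation row: first supporting caller in priority order
  combined$.rank <- match(combined$.caller, priority)
  combined <- combined[order(combined$.key, combined$.rank), ]
  first <- combined[!duplicated(combined$.key), ]
  out <- first[first$.key %in% keep_keys, req, drop = FALSE]
  keyed <- first$.key[first$.key %in% keep_keys]
  out$callers <- vapply(support[keyed], function(s)
    paste(priority[sort(match(s, priority))], collapse = ","), character(1))
  out$n_callers <- n_sup[keyed]
  out$pos <- as.integer(out$pos)
  out <- out[order(out$sample, out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

#' Classify a MAF variant label as silent or nonsilent
#'
#' Case-folded lookup against the MAF vocabulary.  Nonsilent covers the
#' coding-impact classes (missense, nonsense, nonstop, splice site,
#' frameshift and in-frame indels, translation start site); silent
#' covers synonymous and non-coding classes.
#'
#' @param labels Character vector of `variant_classification` labels.
#' @param on_unknown `"reject"` (default) maps unknown labels to `NA`
#'   with a message; `"silent"` buckets them as silent.
#' @return Character vector in `{"nonsilent", "silent"}` (possibly NA).
#' @export
classify_effect <- function(labels, on_unknown = c("reject", "silent")) {
  on_unknown <- match.arg(on_unknown)
  lab <- tolower(labels)
  out <- rep(NA_character_, length(lab))
  out[lab %in% tolower(NONSILENT_CLASSES)] <- "nonsilent"
  out[lab %in% tolower(SILENT_CLASSES)] <- "silent"
  unk <- is.na(out) & !is.na(labels)
  if (any(unk)) {
    if (on_unknown == "silent") {
      out[unk] <- "silent"
    } else {
      message(sum(unk), " variant(s) with unknown classification rejected: ",
              paste(unique(labels[unk]), collapse = ", "))
    }
  }
  out
}

#' Build the gene x sample nonsilent mutation matrix
#'
#' Each cell counts the nonsilent consensus variants of a (gene,
#' sample) pair; the indicator view is `count > 0`.  Samples with no
#' variants appear as all-zero columns.  Variants for samples absent
#' from `samples` are skipped with a message.
#'
#' @param consensus Consensus table from [merge_callers()].
#' @param samples Character vector of sample ids (matrix columns).
#' @param genes Optional character vector of genes (matrix rows);
#'   defaults to the genes present in the consensus table.
#' @param on_unknown Passed to [classify_effect()].
#' @return A list of class `mutation_matrix`: `counts`, `indicator`,
#'   `sample_totals` (per-sample nonsilent counts).
#' @export
build_mutation_matrix <- function(consensus, samples, genes = NULL,
                                  on_unknown = "reject") {
  if (length(samples) == 0) stop("sample list must be non-empty")
  eff <- classify_effect(consensus$variant_classification, on_unknown)
  ns <- consensus[!is.na(eff) & eff == "nonsilent", , drop = FALSE]
  if (is.null(genes)) genes <- sort(unique(ns$gene))
  if (length(genes) == 0) genes <- character(0)
  unknown <- setdiff(unique(ns$sample), samples)
  if (length(unknown)) {
    message(length(unknown), " sample(s) absent from the sample list ",
            "skipped: ", paste(utils::head(unknown, 5), collapse = ", "))
    ns <- ns[ns$sample %in% samples, , drop = FALSE]
  }
  ns <- ns[ns$gene %in% genes, , drop = FALSE]
  counts <- matrix(0L, nrow = length(genes), ncol = length(samples),
                   dimnames = list(genes, samples))
  if (nrow(ns) > 0) {
    tab <- table(factor(ns$gene, levels = genes),
                 factor(ns$sample, levels = samples))
    counts[] <- as.integer(tab)
  }
  structure(list(counts = counts, indicator = counts > 0,
                 sample_totals = colSums(counts)),
            class = "mutation_matrix")
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf("mutation_matrix: %d genes x %d samples, %d nonsilent calls\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}
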