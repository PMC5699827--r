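# Readers and writers for the pipeline's tab-separated dialects.
# All readers tolerate "#"-prefixed provenance header lines.

read_tsv_file <- function(path, what) {
  if (!file.exists(path))
    stop("missing ", what, " file: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                    check.names = FALSE)
}

#' Read a sample sheet TSV
#'
#' Expected columns: `sample`, `self_report`, and optionally
#' `age_band`, `time_years`, `event`.
#' @param path File path.
#' @return Data.frame.
#' @export
read_sample_sheet <- function(path) {
  d <- read_tsv_file(path, "sample sheet")
  if (!all(c("sample", "self_report") %in% names(d)))
    stop("sample sheet needs `sample` and `self_report` columns")
  d
}

#' Read a reference allele-frequency panel TSV
#' @param path File path (columns `marker`, `chrom`, `pos`, `f_A`, `f_B`).
#' @return Data.frame.
#' @export
read_panel <- function(path) {
  d <- read_tsv_file(path, "reference panel")
  if (!all(c("marker", "f_A", "f_B") %in% names(d)))
    stop("panel needs `marker`, `f_A`, `f_B` columns")
  d
}

#' Read a genotype dosage TSV (markers x samples)
#' @param path File path; first column `marker`, remaining columns one
#'   per sample with 0/1/2 dosages.
#' @return Numeric matrix with marker rownames.
#' @export
read_genotypes <- function(path) {
  d <- read_tsv_file(path, "genotype")
  G <- as.matrix(d[, -1, drop = FALSE])
  rownames(G) <- d[[1]]
  storage.mode(G) <- "numeric"
  G
}

#' Read a MAF-like somatic call TSV
#' @param path File path.
#' @return Data.frame with the variant-call columns.
#' @export
read_maf <- function(path) {
  d <- read_tsv_file(path, "somatic call")
  req <- c("sample", "gene", "chrom", "pos", "ref", "alt",
           "variant_classification")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("call table lacks columns: ", paste(miss, collapse = ", "))
  d
}

#' Read a SEG copy-number table (0-based half-open)
#' @param path File path.
#' @return Data.frame with `sample`, `chrom`, `start`, `end`, `log2`.
#' @export
read_seg <- function(path) {
  d <- read_tsv_file(path, "segment")
  req <- c("sample", "chrom", "start", "end", "log2")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("segment table lacks columns: ", paste(miss, collapse = ", "))
  if (any(d$start >= d$end)) stop("segments must satisfy start < end")
  d
}

#' Read a gene x sample TPM matrix TSV
#' @param path File path; first column gene ids.
#' @return Numeric matrix with gene rownames.
#' @export
read_tpm <- function(path) {
  d <- read_tsv_file(path, "TPM")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "numeric"
  m
}

# 32-bit FNV-1a over a string, rendered as 8 hex digits; used to stamp
# outputs with a config fingerprint without a heavyweight digest
# dependency.
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  p <- 16777619
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply in double precision via 16-bit split
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a TSV with a provenance header
#'
#' Prepends `#`-prefixed lines recording the package version, the run
#' seed, and a configuration fingerprint, then the table.
#'
#' @param x Data.frame.
#' @param path Output path.
#' @param seed Run seed recorded in the header.
#' @param config_hash Configuration fingerprint string.
#' @return Invisibly, `path`.
#' @export
write_tsv_report <- function(x, path, seed = NA, config_hash = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# mmstrat %s", as.character(utils::packageVersion("mmstrat"))),
    sprintf("# seed: %s", seed),
    sprintf("# config: %s", config_hash)), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
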