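# Marker informativeness, genotype PCA, supervised two-population
# admixture estimation, and the self-report concordance filter.

xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

#' Rosenberg informativeness for assignment (K = 2)
#'
#' For a biallelic marker with population allele frequencies `p1`, `p2`
#' and mean `pbar = (p1 + p2)/2`,
#' `In = sum_alleles [ -pbar_j ln pbar_j + sum_i (p_ij / 2) ln p_ij ]`
#' with the `0 ln 0 := 0` convention.  `In` is 0 when the populations
#' are indistinguishable at the marker and `ln 2` for a fully diagnostic
#' marker (frequencies 1 and 0).
#'
#' @param panel Reference panel data.frame with columns `f_A`, `f_B`
#'   (see [simulate_reference_panel()]).
#' @return Numeric vector of per-marker informativeness values, named by
#'   marker when the panel carries a `marker` column.
#' @export
marker_informativeness <- function(panel) {
  p1 <- panel$f_A; p2 <- panel$f_B
  if (anyNA(p1) || anyNA(p2) || any(!is.finite(c(p1, p2))))
    stop("allele frequencies must be finite and non-missing")
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1))
    stop("allele frequencies must lie in [0, 1]")
  pbar <- (p1 + p2) / 2
  In <- (-xlogx(pbar) - xlogx(1 - pbar)) +
    (xlogx(p1) + xlogx(1 - p1) + xlogx(p2) + xlogx(1 - p2)) / 2
  In <- pmax(In, 0)  # guard tiny negative rounding
  if (!is.null(panel$marker)) names(In) <- panel$marker
  In
}

#' Select ancestry-informative markers
#'
#' Ranks markers by Rosenberg informativeness (descending, ties broken
#' by chromosome then position ascending) and returns the top `top_k`,
#' or all markers exceeding `min_in`.
#'
#' @param panel Reference panel data.frame.
#' @param top_k Number of markers to keep (mutually exclusive with
#'   `min_in`).
#' @param min_in Minimum informativeness (exclusive bound).
#' @return The selected subset of `panel`, with an `In` column appended,
#'   in rank order.
#' @export
select_aims <- function(panel, top_k = NULL, min_in = NULL) {
  if (is.null(top_k) == is.null(min_in))
    stop("give exactly one of `top_k` or `min_in`")
  In <- marker_informativeness(panel)
  out <- panel
  out$In <- as.numeric(In)
  out <- out[order(-out$In, out$chrom, out$pos), ]
  if (!is.null(top_k)) {
    if (top_k < 1 || top_k > nrow(out))
      stop("top_k must lie in [1, panel size]")
    out <- out[seq_len(top_k), ]
  } else {
    out <- out[out$In > min_in, ]
  }
  if (nrow(out) == 0) stop("no markers selected")
  rownames(out) <- NULL
  out
}

#' Genotype principal-component analysis
#'
#' Eigenanalysis of the dosage matrix after the standard
#' population-genetics normalisation: each marker is centred by twice
#' its sample allele frequency `2 p-hat` and scaled by
#' `sqrt(p-hat (1 - p-hat))`; monomorphic markers are dropped and
#' missing dosages are imputed to the marker mean before normalisation.
#'
#' @param G Dosage matrix (markers x samples, values 0/1/2 or NA).
#' @param n_pc Number of leading components to return.
#' @return A list of class `genotype_pca`: `coords` (samples x
#'   components), `eigenvalues` (descending, sample-covariance scale),
#'   and `n_markers_used`.
#' @export
genotype_pca <- function(G, n_pc = 10) {
  G <- as.matrix(G)
  if (ncol(G) < 2 || nrow(G) < 2)
    stop("need at least 2 samples and 2 markers")
  # impute missing dosages to the marker mean
  if (anyNA(G)) {
    mu <- rowMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 1]]
  }
  phat <- rowMeans(G) / 2
  keep <- phat > 0 & phat < 1 & apply(G, 1, stats::var) > 0
  if (!any(keep)) stop("no variance: all markers are monomorphic")
  G <- G[keep, , drop = FALSE]
  phat <- phat[keep]
  X <- (G - 2 * phat) / sqrt(phat * (1 - phat))
  sv <- svd(t(X))  # samples x markers
  k <- min(n_pc, length(sv$d))
  coords <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  dimnames(coords) <- list(colnames(G), paste0("PC", seq_len(k)))
  structure(list(coords = coords,
                 eigenvalues = sv$d^2 / (ncol(G) - 1),
                 n_markers_used = nrow(G)),
            class = "genotype_pca")
}

#' Supervised two-population admixture estimation
#'
#' Per-sample maximum-likelihood estimate of the admixture proportion
#' `q` (fraction of ancestry from population A) under the binomial
#' model `g_j ~ Binomial(2, q f_Aj + (1-q) f_Bj)` with the reference
#' frequencies held fixed.  Maximisation is by EM over allele-origin
#' responsibilities; the log-likelihood is non-decreasing at every
#' iteration.  Markers missing in a sample are skipped for that sample.
#' A panel with `f_A = f_B` everywhere leaves `q` unidentifiable: the
#' estimate is returned as 0.5 with `converged = FALSE`.
#'
#' @param G Dosage matrix (markers x samples), rownames matching
#'   `panel$marker`.
#' @param panel Reference panel with `marker`, `f_A`, `f_B`.
#' @param tol Convergence tolerance on the per-sample log-likelihood
#'   increase.
#' @param max_iter Maximum EM iterations.
#' @param max_missing Maximum tolerated per-sample missing-marker
#'   fraction; beyond it the sample is flagged and `q` is `NA`.
#' @return A data.frame with one row per sample: `sample`, `q`,
#'   `loglik`, `n_iter`, `converged`, `n_markers_used`,
#'   `frac_markers_used`.
#' @export
estimate_admixture <- function(G, panel, tol = 1e-6, max_iter = 5000L,
                               max_missing = 0.5) {
  G <- as.matrix(G)
  common <- intersect(rownames(G), panel$marker)
  if (length(common) == 0)
    stop("no markers shared between genotypes and panel")
  G <- G[common, , drop = FALSE]
  pj <- panel[match(common, panel$marker), ]
  clip <- function(p) pmin(pmax(p, 0.001), 0.999)
  fA <- clip(pj$f_A); fB <- clip(pj$f_B)
  M <- length(common); N <- ncol(G)

  obs <- !is.na(G)
  Gz <- G; Gz[!obs] <- 0
  m_i <- colSums(obs)
  usable <- m_i > 0 & (1 - m_i / M) <= max_missing
  flat <- max(abs(fA - fB)) < 1e-12

  q <- rep(0.5, N)
  ll_prev <- rep(-Inf, N)
  n_iter <- integer(N)
  converged <- rep(FALSE, N)
  active <- which(usable & !flat)
  it <- 0L
  while (length(active) && it < max_iter) {
    it <- it + 1L
    qa <- q[active]
    piM <- outer(fA, qa) + outer(fB, 1 - qa)
    Ga <- Gz[, active, drop = FALSE]
    oa <- obs[, active, drop = FALSE]
    wA_der <- outer(fA, qa) / piM             # P(origin A | derived allele)
    wA_anc <- outer(1 - fA, qa) / (1 - piM)   # P(origin A | ancestral allele)
    num <- colSums(oa * (Ga * wA_der + (2 - Ga) * wA_anc))
    q_new <- num / (2 * m_i[active])
    ll <- colSums(oa * (Ga * log(piM) + (2 - Ga) * log(1 - piM)))
    delta <- ll - ll_prev[active]
    newly <- is.finite(ll_prev[active]) & delta < tol
    converged[active[newly]] <- TRUE
    n_iter[active] <- it
    ll_prev[active] <- ll
    q[active[!newly]] <- q_new[!newly]
    active <- active[!newly]
  }
  piM <- outer(fA, q) + outer(fB, 1 - q)
  ll <- colSums(obs * (Gz * log(piM) + (2 - Gz) * log(1 - piM)))
  if (any(!is.finite(ll[usable])))
    stop("non-finite likelihood; check panel frequencies")
  q[!usable] <- NA_real_
  ll[!usable] <- NA_real_
  data.frame(sample = colnames(G), q = q, loglik = ll, n_iter = n_iter,
             converged = converged & usable,
             n_markers_used = m_i, frac_markers_used = m_i / M,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Concordance filter between self-report and estimated ancestry
#'
#' A sample is excluded when its estimated proportion of the ancestry
#' OPPOSITE its self-reported group exceeds `threshold` (default 0.55,
#' the ">55%" discordance rule): a self-reported group-B sample with
#' `q > threshold` ancestry A, or a self-reported group-A sample with
#' `1 - q > threshold` ancestry B.
#'
#' @param samples Sample sheet with columns `sample` and `self_report`.
#' @param estimates Output of [estimate_admixture()] (`q` = proportion
#'   of ancestry A).
#' @param threshold Exclusion threshold in `(0.5, 1]`.
#' @param group_a,group_b Self-report labels corresponding to ancestral
#'   populations A and B.
#' @return A list with data.frames `kept` and `excluded`; `excluded`
#'   carries a per-sample `reason` string.  Samples with missing `q`
#'   are kept but flagged in `no_estimate`.
#' @export
concordance_filter <- function(samples, estimates, threshold = 0.55,
                               group_a = "A", group_b = "B") {
  if (!is.finite(threshold) || threshold <= 0.5 || threshold > 1)
    stop("threshold must lie in (0.5, 1]")
  m <- merge(samples, estimates[, c("sample", "q")], by = "sample",
             sort = FALSE)
  if (nrow(m) < nrow(samples))
    stop("every sample needs an ancestry estimate")
  bad_label <- !m$self_report %in% c(group_a, group_b)
  if (any(bad_label))
    stop("unknown self-report labels: ",
         paste(unique(m$self_report[bad_label]), collapse = ", "))
  opposite <- ifelse(m$self_report == group_a, 1 - m$q, m$q)
  excl <- !is.na(opposite) & opposite > threshold
  reason <- sprintf(
    "self-reported %s with %.1f%% opposite-population ancestry (> %.0f%%)",
    m$self_report, 100 * opposite, 100 * threshold)
  list(kept = m[!excl, setdiff(names(m), "q"), drop = FALSE],
       excluded = cbind(m[excl, , drop = FALSE],
                        reason = reason[excl])[, , drop = FALSE],
       no_estimate = m$sample[is.na(m$q)])
}
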