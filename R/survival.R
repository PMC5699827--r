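# Kaplan-Meier estimation and log-rank stratification.  The
# product-limit fit and the O-E chi-square are delegated to the
# survival package; these wrappers fix the tie convention
# (deaths-before-censorings, the survfit default), the return schema,
# and the untestable-input contract, and are checked against
# hand-computed product-limit values in the test suite.

check_survival_input <- function(time, event) {
  if (length(time) == 0) stop("at least one record is required")
  if (anyNA(time) || any(!is.finite(time)) || any(time <= 0))
    stop("times must be positive and finite")
  ev <- as.integer(event)
  if (anyNA(ev) || !all(ev %in% c(0L, 1L)))
    stop("event must be 0/1 (censored/death)")
  ev
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times,
#' with deaths resolved before censorings at tied times.
#'
#' @param time Positive follow-up times (years).
#' @param event Event indicator: 1 = death, 0 = censored.
#' @return Data.frame of class `km_curve`: `time` (distinct observed
#'   times, ascending), `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
km_estimate <- function(time, event) {
  event <- check_survival_input(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Log-rank test across survival strata
#'
#' Standard observed-minus-expected chi-square over the pooled event
#' times with the hypergeometric variance, `df = #groups - 1`.  When
#' the pooled data contain no events the comparison is untestable and
#' is returned flagged rather than as an error.
#'
#' @param time,event As in [km_estimate()].
#' @param group Stratum label per record (>= 2 distinct values).
#' @return A list: `test` (an `mm_test` with the chi-square statistic,
#'   or NULL), `df`, `untestable`.
#' @export
logrank_test <- function(time, event, group) {
  event <- check_survival_input(time, event)
  group <- as.character(group)
  if (length(unique(group)) < 2)
    stop("at least two strata are required")
  if (sum(event) == 0)
    return(list(test = NULL, df = length(unique(group)) - 1L,
                untestable = TRUE))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(unique(group)) - 1L
  p <- stats::pchisq(sd$chisq, df, lower.tail = FALSE)
  list(test = mm_test(sd$chisq, p, "logrank", "two.sided"),
       df = df, untestable = FALSE)
}

#' Pairwise log-rank tests with BH correction
#'
#' Runs [logrank_test()] on every pair of strata (the companion to the
#' omnibus df = k-1 test) and adjusts the pairwise p-values by
#' Benjamini-Hochberg.
#'
#' @inheritParams logrank_test
#' @return Data.frame: `group1`, `group2`, `statistic`, `p`, `q`.
#' @export
logrank_pairwise <- function(time, event, group) {
  group <- as.character(group)
  lev <- sort(unique(group))
  if (length(lev) < 2) stop("at least two strata are required")
  pairs <- utils::combn(lev, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    sel <- group %in% pairs[, k]
    lr <- logrank_test(time[sel], event[sel], group[sel])
    data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
               statistic = if (lr$untestable) NA_real_ else
                 lr$test$statistic,
               p = if (lr$untestable) NA_real_ else lr$test$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bh_adjust(out$p[ok])
  out
}
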