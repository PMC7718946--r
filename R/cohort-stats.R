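#' Kaplan-Meier product-limit estimator
#'
#' At each distinct event time `t`, the survival probability is multiplied by
#' `1 - d(t)/n(t)` where `d(t)` counts events and `n(t)` the samples still at
#' risk. Observations censored at an event time are counted at risk for that
#' time (the event-before-censor tie convention), `S(0) = 1` and the curve is
#' non-increasing.
#'
#' @param time non-negative follow-up times.
#' @param event logical; `TRUE` = event observed, `FALSE` = censored.
#' @return data.frame `time`, `n_risk`, `n_event`, `n_censor`, `survival`,
#'   one row per distinct event or censoring time.
#' @export
km_estimate <- function(time, event) {
  if (length(time) != length(event)) stop("time/event length mismatch")
  if (any(time < 0)) stop("negative follow-up time")
  event <- as.logical(event)
  times <- sort(unique(time))
  n <- length(time)
  surv <- 1
  out <- data.frame(time = times, n_risk = NA_integer_, n_event = NA_integer_,
                    n_censor = NA_integer_, survival = NA_real_)
  for (i in seq_along(times)) {
    t <- times[i]
    at_risk <- sum(time >= t)
    d <- sum(time == t & event)
    c <- sum(time == t & !event)
    if (d > 0) surv <- surv * (1 - d / at_risk)
    out$n_risk[i] <- at_risk
    out$n_event[i] <- d
    out$n_censor[i] <- c
    out$survival[i] <- surv
  }
  out
}

#' Two-group log-rank test
#'
#' The standard 1-df log-rank statistic: at each distinct event time the
#' observed events in group 1 are compared with the hypergeometric
#' expectation given the risk sets, and `(O - E)^2 / V` is referred to the
#' upper tail of a chi-square with one degree of freedom. Invariant to
#' relabeling of the two groups.
#'
#' @param time,event as in [km_estimate()].
#' @param group two-level factor/character per sample.
#' @return list with `chi_square`, `p_value`, `observed` and `expected`
#'   (events per group).
#' @export
logrank_test <- function(time, event, group) {
  if (length(unique(group)) != 2L) stop("exactly two groups required")
  event <- as.logical(event)
  if (sum(event) == 0L) stop("log-rank test undefined with zero events")
  g <- as.integer(factor(group))
  etimes <- sort(unique(time[event]))
  O <- E <- V <- 0
  for (t in etimes) {
    n1 <- sum(time >= t & g == 1L)
    n2 <- sum(time >= t & g == 2L)
    nt <- n1 + n2
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & g == 1L)
    O <- O + d1
    E <- E + d * n1 / nt
    if (nt > 1L) V <- V + d * (n1 / nt) * (n2 / nt) * (nt - d) / (nt - 1)
  }
  if (V == 0) return(list(chi_square = 0, p_value = 1,
                          observed = c(O, sum(event) - O),
                          expected = c(E, sum(event) - E)))
  chi <- (O - E)^2 / V
  list(chi_square = chi, p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
       observed = c(O, sum(event) - O), expected = c(E, sum(event) - E))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric enumeration with the probability-mass definition of
#' the two-sided p-value: the sum of the probabilities of every table with
#' the same margins whose probability does not exceed that of the observed
#' table (within a relative tolerance of 1e-12, to make the <= comparison
#' robust to floating-point noise). A zero margin gives p = 1 by convention,
#' with a warning.
#'
#' @param table 2x2 matrix of non-negative counts, or the four counts
#'   `a, b, c, d` (row-wise).
#' @return two-sided p-value.
#' @export
fisher_exact <- function(table) {
  if (!is.matrix(table)) {
    if (length(table) != 4L) stop("need a 2x2 matrix or 4 counts")
    table <- matrix(table, 2L, byrow = TRUE)
  }
  if (any(table < 0) || any(table != round(table))) stop("counts must be non-negative integers")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  n <- a + b + c + d
  if (n == 0) stop("empty table")
  r1 <- a + b; c1 <- a + c
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) {
    warning("degenerate margin; p = 1 by convention")
    return(1)
  }
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  x <- lo:hi
  logp <- lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1)
  p_obs <- logp[x == a]
  sum(exp(logp[logp <= p_obs + 1e-12]))
}

#' Relative quantification by the delta-delta-Ct method
#'
#' Fold change of a target transcript relative to a housekeeping gene and a
#' reference sample:
#' `fold = 2^-[(Ct_target,s - Ct_hk,s) - (Ct_target,ref - Ct_hk,ref)]`.
#' The reference sample's fold change is exactly 1.
#'
#' @param ct numeric matrix of Ct values, genes x samples.
#' @param target target gene (rowname).
#' @param housekeeping housekeeping gene (rowname); must be finite for every
#'   sample.
#' @param reference reference sample (colname).
#' @return named fold-change vector per sample.
#' @export
delta_delta_ct <- function(ct, target, housekeeping, reference) {
  if (!target %in% rownames(ct)) stop("target '", target, "' not in Ct table")
  if (!housekeeping %in% rownames(ct)) stop("housekeeping '", housekeeping, "' not in Ct table")
  if (!reference %in% colnames(ct)) stop("reference sample '", reference, "' not in Ct table")
  hk <- ct[housekeeping, ]
  if (any(!is.finite(hk)))
    stop("missing housekeeping Ct for sample(s): ",
         paste(colnames(ct)[!is.finite(hk)], collapse = ", "))
  dct <- ct[target, ] - hk
  ddct <- dct - dct[reference]
  2^(-ddct)
}
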