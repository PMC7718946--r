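#' Score a single-dose drug screen by the response-ratio rule
#'
#' For each drug, well replicates are averaged, viability is converted to
#' response (`100 - viability`, clamped at 0 from below) and the ratio of the
#' mean MYC-high response to the mean MYC-low response is computed. A drug is
#' a hit when the ratio exceeds 2 (a twofold larger response in the MYC-high
#' models). Drugs are ranked by descending ratio, ties broken by drug ID.
#'
#' Response, not raw viability, is the numerator and denominator: only under
#' that reading does "ratio > 2" select drugs to which the MYC-high lines are
#' *more sensitive*; a viability ratio would invert the rule.
#'
#' When the MYC-low mean response falls below `epsilon` (inert drugs in
#' resistant lines), the ratio is reported against `epsilon` and flagged
#' `unstable`. Drugs with no usable response in either group are skipped with
#' a warning.
#'
#' @param table a [drug_response_table()].
#' @param groups a [phenotype_labels()] over the cell lines (positive class
#'   = MYC-high).
#' @param hit_threshold ratio above which a drug is a hit (default 2).
#' @param epsilon denominator guard, percentage points of response.
#' @return data.frame of class `ScreenResultTable`: `drug_id`,
#'   `mean_response_high`, `mean_response_low`, `ratio`, `rank`, `is_hit`,
#'   `unstable`, ordered by rank.
#' @export
score_single_dose_screen <- function(table, groups, hit_threshold = 2,
                                     epsilon = 1) {
  stopifnot(inherits(table, "DrugResponseTable"),
            inherits(groups, "PhenotypeLabels"))
  if (is.null(groups$sample_ids)) {
    if (length(groups$labels) != length(table$cell_line_ids))
      stop("positional groups length != number of cell lines")
    lab <- groups$labels
  } else {
    m <- match(table$cell_line_ids, groups$sample_ids)
    if (anyNA(m)) stop("cell lines missing from groups: ",
                       paste(table$cell_line_ids[is.na(m)], collapse = ", "))
    lab <- groups$labels[m]
  }
  high <- lab == groups$class_names[1L]
  if (!any(high) || all(high)) stop("each group needs at least one line")

  avg <- average_replicates(table)$mean
  resp <- 100 - avg
  resp[!is.na(resp) & resp < 0] <- 0
  mh <- rowMeans(resp[, high, drop = FALSE], na.rm = TRUE)
  ml <- rowMeans(resp[, !high, drop = FALSE], na.rm = TRUE)
  usable <- is.finite(mh) & is.finite(ml)
  if (!all(usable))
    warning("skipping ", sum(!usable), " drug(s) with no usable response: ",
            paste(utils::head(table$drug_ids[!usable], 5L), collapse = ", "))
  unstable <- usable & ml < epsilon
  denom <- ifelse(unstable, epsilon, ml)
  ratio <- ifelse(usable, mh / denom, NA_real_)

  res <- data.frame(drug_id = table$drug_ids,
                    mean_response_high = mh, mean_response_low = ml,
                    ratio = ratio, is_hit = !is.na(ratio) & ratio > hit_threshold,
                    unstable = unstable, row.names = NULL,
                    stringsAsFactors = FALSE)[usable, ]
  res <- res[order(-res$ratio, res$drug_id, method = "radix"), ]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  class(res) <- c("ScreenResultTable", "data.frame")
  res
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `v(d) = bottom + (top - bottom)/(1 + (d/gi50)^hill)`
#' by Levenberg-Marquardt (via `minpack.lm::nlsLM`), with the midpoint
#' parametrized as `log(gi50)` for stability. Initialization: `top = max v`,
#' `bottom = min v`, `gi50` at the dose nearest the half-range crossing,
#' and a multi-start over Hill seeds (0.5, 1, 2) to avoid local minima.
#' Bounds: `bottom >= 0`, `hill` in \[0.1, 10\].
#'
#' Two midpoints are reported: the relative GI50 (the fitted inflection) and
#' the absolute GI50 (the dose at which the fitted curve crosses 50% of
#' control), the latter censored at the maximum tested dose when the curve
#' never reaches 50%.
#'
#' @param doses >= 4 distinct positive doses (nM).
#' @param viabilities viability (% of control) per dose.
#' @return `DoseResponseFit` list: `bottom`, `top`, `gi50` (relative),
#'   `hill`, `gi50_abs`, `gi50_censored`, `rss`, `converged`.
#' @export
fit_4pl <- function(doses, viabilities) {
  if (length(doses) != length(viabilities)) stop("doses/viabilities length mismatch")
  ok <- is.finite(doses) & is.finite(viabilities)
  doses <- doses[ok]; viabilities <- viabilities[ok]
  if (any(doses <= 0)) stop("doses must be positive")
  if (length(unique(doses)) < 4L) stop("need >= 4 distinct doses, got ",
                                       length(unique(doses)))
  df <- data.frame(d = doses, v = viabilities)
  top0 <- max(df$v); bot0 <- min(df$v)
  if (top0 - bot0 < 1e-8) {
    # flat series: the constant is the exact least-squares fit; no midpoint
    # exists, so the absolute GI50 is censored at the panel edge
    m <- mean(df$v)
    return(structure(list(bottom = m, top = m, gi50 = NA_real_,
                          hill = NA_real_,
                          gi50_abs = if (m >= 50) max(doses) else min(doses),
                          gi50_censored = TRUE,
                          rss = sum((df$v - m)^2), converged = TRUE),
                     class = "DoseResponseFit"))
  }
  half <- (top0 + bot0) / 2
  g0 <- df$d[which.min(abs(df$v - half))]

  best <- NULL
  for (h0 in c(0.5, 1, 2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ bottom + (top - bottom) / (1 + exp(hill * (log(d) - lg))),
        data = df,
        start = list(bottom = max(bot0, 0), top = top0, lg = log(g0), hill = h0),
        lower = c(bottom = 0, top = -Inf, lg = -Inf, hill = 0.1),
        upper = c(bottom = Inf, top = Inf, lg = Inf, hill = 10),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-8) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(bottom = NA_real_, top = NA_real_, gi50 = NA_real_,
                          hill = NA_real_, gi50_abs = NA_real_,
                          gi50_censored = NA, rss = NA_real_,
                          converged = FALSE),
                     class = "DoseResponseFit"))
  }
  cf <- stats::coef(best$fit)
  bottom <- unname(cf["bottom"]); top <- unname(cf["top"])
  gi50 <- exp(unname(cf["lg"])); hill <- unname(cf["hill"])
  # absolute GI50: fitted viability = 50% of control
  gi50_abs <- NA_real_; censored <- FALSE
  if ((bottom - 50) * (top - 50) < 0) {
    frac <- (top - 50) / (50 - bottom)       # (d/gi50)^hill at the crossing
    gi50_abs <- gi50 * frac^(1 / hill)
    if (gi50_abs > max(doses)) { gi50_abs <- max(doses); censored <- TRUE }
  } else {
    gi50_abs <- max(doses); censored <- TRUE
  }
  structure(list(bottom = bottom, top = top, gi50 = gi50, hill = hill,
                 gi50_abs = gi50_abs, gi50_censored = censored,
                 rss = best$rss, converged = TRUE),
            class = "DoseResponseFit")
}

#' @export
print.DoseResponseFit <- function(x, ...) {
  cat(sprintf("4PL fit: bottom=%.3g top=%.3g GI50=%.4g hill=%.3g (abs GI50 %.4g%s)\n",
              x$bottom, x$top, x$gi50, x$hill, x$gi50_abs,
              if (isTRUE(x$gi50_censored)) ", censored" else ""))
  invisible(x)
}

#' Normalized area under a dose-response curve
#'
#' Trapezoidal integral of `viability / 100` over `log10(dose)`, normalized
#' by the log10 dose span, so the value lies in \[0,1\] with 1 = completely
#' resistant. Duplicate doses are averaged before integration; the result is
#' invariant to rescaling all doses by a constant.
#'
#' @param doses >= 2 positive doses.
#' @param viabilities viability (% of control) per dose.
#' @return AUC in \[0,1\].
#' @export
dose_response_auc <- function(doses, viabilities) {
  if (any(doses <= 0)) stop("doses must be positive")
  if (length(doses) != length(viabilities)) stop("length mismatch")
  v <- tapply(viabilities, doses, mean)
  d <- as.numeric(names(v))
  ord <- order(d)
  d <- d[ord]; v <- unname(v[ord])
  if (length(d) < 2L) stop("need >= 2 distinct doses")
  x <- log10(d)
  area <- sum(diff(x) * (utils::head(v, -1L) + utils::tail(v, -1L)) / 2)
  area / (diff(range(x)) * 100)
}

#' Stratify a cell-line panel into a sensitive-quartile phenotype
#'
#' The boundary is the 25th percentile (linear-interpolation, type-7
#' quantile) of the sensitivity metric, oriented so that lower values mean
#' more sensitive when `lower_is_sensitive`. Lines at or beyond the boundary
#' on the sensitive side (ties included) form the sensitive set; the
#' complement is the comparison class of the emitted phenotype.
#'
#' @param values named numeric vector of the metric per cell line (e.g.
#'   GI50 or screen AUC).
#' @param lower_is_sensitive orientation of the metric.
#' @param quartile fraction defining the sensitive tail (default 0.25).
#' @return `SensitivityPhenotype` list: `boundary`, `sensitive_set`,
#'   `labels` (a [phenotype_labels()] with classes sensitive/resistant).
#' @export
quartile_stratify <- function(values, lower_is_sensitive = TRUE,
                              quartile = 0.25) {
  if (is.null(names(values))) stop("values must be named by cell line")
  if (length(values) < 4L) stop("need >= 4 lines to stratify")
  if (any(!is.finite(values))) stop("metric values must be finite")
  if (length(unique(values)) == 1L)
    stop("all metric values identical; no stratification possible")
  if (lower_is_sensitive) {
    boundary <- stats::quantile(values, quartile, type = 7, names = FALSE)
    sens <- names(values)[values <= boundary]
  } else {
    boundary <- stats::quantile(values, 1 - quartile, type = 7, names = FALSE)
    sens <- names(values)[values >= boundary]
  }
  structure(list(boundary = boundary, sensitive_set = sens,
                 labels = phenotype_labels(
                   ifelse(names(values) %in% sens, "sensitive", "resistant"),
                   class_names = c("sensitive", "resistant"),
                   sample_ids = names(values))),
            class = "SensitivityPhenotype")
}

#' Correlate two sensitivity metrics across a panel
#'
#' Pearson correlation (two-sided p from the t transform) and least-squares
#' regression line, computed on log10-transformed values by default (the
#' usual scale for GI50 comparisons).
#'
#' @param gi50_a,gi50_b paired metric vectors (>= 3 finite pairs).
#' @param log10_transform correlate log10 values (default `TRUE`).
#' @return list with `r`, `p_value`, `slope`, `intercept`, `n`.
#' @export
correlate_sensitivities <- function(gi50_a, gi50_b, log10_transform = TRUE) {
  if (length(gi50_a) != length(gi50_b)) stop("length mismatch")
  ok <- is.finite(gi50_a) & is.finite(gi50_b)
  a <- gi50_a[ok]; b <- gi50_b[ok]
  if (length(a) < 3L) stop("need >= 3 paired finite values")
  if (log10_transform) {
    if (any(a <= 0 | b <= 0)) stop("log10 transform needs positive values")
    a <- log10(a); b <- log10(b)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in one of the vectors")
  ct <- stats::cor.test(a, b, method = "pearson")
  fit <- stats::lm(b ~ a)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]), n = length(a))
}
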