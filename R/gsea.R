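#' Rank genes by signal-to-noise ratio between two phenotype classes
#'
#' The default GSEA ranking metric: per gene,
#' `score = (mu_pos - mu_neg) / (sd_pos + sd_neg)`, where each class SD is
#' floored at `max(0.2 * |mu_class|, 0.2)` so that near-constant genes do not
#' produce unbounded scores. Genes are sorted by descending score; ties are
#' broken by gene ID ascending so the ranking is deterministic across
#' platforms. If either class has fewer than 2 samples the metric falls back
#' to the difference of class means, with a warning.
#'
#' @param matrix an [expression_matrix()].
#' @param labels a [phenotype_labels()]; positional when `sample_ids` is
#'   `NULL`, ID-joined otherwise. The first class name is the positive class.
#' @return data.frame `gene`, `score`, ordered descending by score; of class
#'   `RankedList`.
#' @export
rank_genes_snr <- function(matrix, labels) {
  idx <- align_labels(matrix, labels)
  scores <- snr_scores(unclass(matrix), idx$pos, idx$neg, warn_fallback = TRUE)
  ord <- order(-scores, rownames(matrix), method = "radix")
  structure(data.frame(gene = rownames(matrix)[ord], score = scores[ord],
                       stringsAsFactors = FALSE),
            class = c("RankedList", "data.frame"))
}

# map PhenotypeLabels onto matrix columns -> list(pos = idx, neg = idx)
align_labels <- function(matrix, labels) {
  stopifnot(inherits(labels, "PhenotypeLabels"))
  if (is.null(labels$sample_ids)) {
    if (length(labels$labels) != ncol(matrix))
      stop("positional phenotype has ", length(labels$labels),
           " labels but matrix has ", ncol(matrix), " samples")
    lab <- labels$labels
  } else {
    m <- match(colnames(matrix), labels$sample_ids)
    if (anyNA(m))
      stop("samples missing from phenotype: ",
           paste(utils::head(colnames(matrix)[is.na(m)], 5L), collapse = ", "))
    lab <- labels$labels[m]
  }
  pos <- which(lab == labels$class_names[1L])
  neg <- which(lab == labels$class_names[2L])
  if (length(pos) < 1L || length(neg) < 1L)
    stop("each class needs at least one sample")
  list(pos = pos, neg = neg)
}

# vectorized SNR over genes for one split; falls back to mean difference
# when a class has < 2 samples
snr_scores <- function(x, pos, neg, warn_fallback = FALSE) {
  mu_p <- rowMeans(x[, pos, drop = FALSE])
  mu_n <- rowMeans(x[, neg, drop = FALSE])
  if (length(pos) < 2L || length(neg) < 2L) {
    if (warn_fallback)
      warning("a class has < 2 samples; using difference of means")
    return(mu_p - mu_n)
  }
  sd_p <- sqrt(rowSums((x[, pos, drop = FALSE] - mu_p)^2) / (length(pos) - 1L))
  sd_n <- sqrt(rowSums((x[, neg, drop = FALSE] - mu_n)^2) / (length(neg) - 1L))
  sd_p <- pmax(sd_p, pmax(0.2 * abs(mu_p), 0.2))
  sd_n <- pmax(sd_n, pmax(0.2 * abs(mu_n), 0.2))
  (mu_p - mu_n) / (sd_p + sd_n)
}

#' Enrichment score of a gene set on a ranked list
#'
#' The weighted Kolmogorov-Smirnov running-sum statistic: walking the ranked
#' list, hits increment the sum by `|score|^p / sum(|score_hits|^p)` and
#' misses decrement it by `1 / (N - N_hit)`. The ES is the signed maximum
#' deviation from zero; the leading edge is the hit genes at or before the
#' extremum (at or after it for negative ES). `weight_p = 0` is the classic
#' unweighted KS statistic, `weight_p = 1` the weighted default.
#'
#' @param ranked a `RankedList` from [rank_genes_snr()], or any data.frame
#'   with `gene` and `score` ordered descending.
#' @param geneset a [gene_set()]; must hit the ranked list in at least one
#'   gene and must not cover it entirely.
#' @param weight_p 0 (classic) or 1 (weighted).
#' @return list with `es`, `running_sum` (length-N vector) and
#'   `leading_edge` (character vector of genes).
#' @export
enrichment_score <- function(ranked, geneset, weight_p = 1) {
  stopifnot(is.data.frame(ranked), all(c("gene", "score") %in% names(ranked)))
  hit <- ranked$gene %in% geneset$genes
  n <- length(hit); nh <- sum(hit)
  if (nh == 0L) stop("gene set '", geneset$name, "' has no overlap with the ranked list")
  if (nh == n) stop("gene set '", geneset$name,
                    "' covers the entire ranked list; miss penalty undefined")
  w <- abs(ranked$score)^weight_p
  inc <- numeric(n)
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (n - nh)
  running <- cumsum(inc)
  i_max <- which.max(running); i_min <- which.min(running)
  # positive extreme wins a tie (within float tolerance) so the sign is
  # deterministic across summation orders
  pos_wins <- abs(running[i_max]) >= abs(running[i_min]) - 1e-12
  es <- if (pos_wins) running[i_max] else running[i_min]
  leading <- if (pos_wins) ranked$gene[seq_len(i_max)][hit[seq_len(i_max)]]
             else ranked$gene[i_min:n][hit[i_min:n]]
  list(es = es, running_sum = running, leading_edge = leading)
}

# O(N_hit) enrichment score from sorted |score|^p weights and hit positions.
# Used for permutation nulls; agrees with the full walk (property-tested).
es_fast <- function(w_all, hit_pos, n) {
  hit_pos <- sort.int(hit_pos)
  nh <- length(hit_pos)
  cw <- cumsum(w_all[hit_pos])
  cw <- cw / cw[nh]
  miss_before <- (hit_pos - seq_len(nh)) / (n - nh)
  top <- cw - miss_before                         # just after each hit
  bottom <- c(0, cw[-nh]) - miss_before           # just before each hit
  hi <- max(top); lo <- min(bottom)
  if (abs(hi) >= abs(lo) - 1e-12) hi else lo
}

#' Gene set enrichment analysis with a permutation null
#'
#' Computes the observed enrichment score per gene set, a permutation null,
#' nominal p-values with add-one smoothing, normalized enrichment scores
#' (ES divided by the mean absolute null ES of matching sign) and tail-ratio
#' FDR q-values over the pooled normalized null.
#'
#' The permutation scheme follows standard guidance "depending on sample
#' size": with `perm_type = "auto"`, phenotype relabeling is used when both
#' classes have at least 7 samples, otherwise gene-set resampling of equal
#' size on the observed ranking. Both modes can be forced.
#'
#' @inheritParams rank_genes_snr
#' @param genesets named list of [gene_set()].
#' @param n_perm number of permutations (>= 10).
#' @param seed RNG seed; results are a pure function of inputs and seed.
#' @param weight_p 0 (classic) or 1 (weighted, default).
#' @param perm_type `"auto"`, `"phenotype"` or `"gene_set"`.
#' @param min_size,max_size sets whose overlap with the matrix falls outside
#'   this range are skipped (reported in the `skipped` attribute). Defaults
#'   5/500 suit synthetic collections (the Broad tool defaults to 15/500).
#' @return data.frame of class `EnrichmentTable`: one row per analyzed set
#'   with `set`, `size`, `es`, `nes`, `p_nominal`, `fdr_q`, `leading_edge`
#'   (comma-joined), plus `mode`, `perm_type`, `n_perm`, `seed` attributes
#'   and a `skipped` attribute naming filtered sets.
#' @export
gsea <- function(matrix, labels, genesets, n_perm = 1000L, seed = 1L,
                 weight_p = 1, perm_type = c("auto", "phenotype", "gene_set"),
                 min_size = 5L, max_size = 500L) {
  perm_type <- match.arg(perm_type)
  if (n_perm < 10L) stop("n_perm must be >= 10")
  idx <- align_labels(matrix, labels)
  x <- unclass(matrix)
  n_genes <- nrow(x)

  sizes <- vapply(genesets, function(s) sum(s$genes %in% rownames(x)), integer(1L))
  keep <- sizes >= min_size & sizes <= max_size & sizes < n_genes
  skipped <- names(genesets)[!keep]
  genesets <- genesets[keep]
  if (length(genesets) == 0L) stop("no gene set passes the size filter")

  if (perm_type == "auto")
    perm_type <- if (min(length(idx$pos), length(idx$neg)) >= 7L)
      "phenotype" else "gene_set"

  obs_scores <- snr_scores(x, idx$pos, idx$neg)
  obs_ord <- order(-obs_scores, rownames(x), method = "radix")
  ranked <- data.frame(gene = rownames(x)[obs_ord], score = obs_scores[obs_ord],
                       stringsAsFactors = FALSE)

  obs <- lapply(genesets, enrichment_score, ranked = ranked, weight_p = weight_p)
  es_obs <- vapply(obs, `[[`, numeric(1L), "es")

  null_es <- withr::with_seed(seed, {
    if (perm_type == "phenotype") {
      n_samp <- ncol(x)
      n_pos <- length(idx$pos)
      hit_sets <- lapply(genesets, function(s) rownames(x) %in% s$genes)
      vapply(seq_len(n_perm), function(p) {
        perm <- sample.int(n_samp)
        sc <- snr_scores(x, perm[seq_len(n_pos)], perm[-seq_len(n_pos)])
        ord <- order(-sc, rownames(x), method = "radix")
        w <- abs(sc[ord])^weight_p
        pos_of <- integer(n_genes); pos_of[ord] <- seq_len(n_genes)
        vapply(hit_sets, function(h) es_fast(w, pos_of[which(h)], n_genes),
               numeric(1L))
      }, numeric(length(genesets)))
    } else {
      w_obs <- abs(ranked$score)^weight_p
      vapply(seq_len(n_perm), function(p) {
        vapply(sizes[keep], function(s)
          es_fast(w_obs, sample.int(n_genes, s), n_genes), numeric(1L))
      }, numeric(length(genesets)))
    }
  })
  null_es <- matrix(null_es, nrow = length(genesets))

  p_nom <- nes <- rep(NA_real_, length(genesets))
  null_nes <- vector("list", length(genesets))
  for (i in seq_along(genesets)) {
    nulls <- null_es[i, ]
    same <- nulls[sign(nulls) == sign(es_obs[i]) & nulls != 0]
    m <- length(same)
    p_nom[i] <- (sum(abs(same) >= abs(es_obs[i])) + 1) / (m + 1)
    pos_mean <- mean(nulls[nulls > 0]); neg_mean <- mean(abs(nulls[nulls < 0]))
    nes[i] <- if (es_obs[i] >= 0) es_obs[i] / pos_mean else es_obs[i] / neg_mean
    nn <- rep(NA_real_, length(nulls))
    nn[nulls > 0] <- nulls[nulls > 0] / pos_mean
    nn[nulls < 0] <- nulls[nulls < 0] / neg_mean
    null_nes[[i]] <- nn[!is.na(nn)]
  }
  pool <- unlist(null_nes)
  fdr_q <- fdr_tail_ratio(nes, pool)

  res <- data.frame(
    set = names(genesets), size = sizes[keep], es = es_obs, nes = nes,
    p_nominal = p_nom, fdr_q = fdr_q,
    leading_edge = vapply(obs, function(o)
      paste(o$leading_edge, collapse = ","), character(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "mode") <- if (weight_p == 0) "classic" else "weighted"
  attr(res, "perm_type") <- perm_type
  attr(res, "n_perm") <- n_perm
  attr(res, "seed") <- seed
  attr(res, "skipped") <- skipped
  class(res) <- c("EnrichmentTable", "data.frame")
  res
}

# GSEA tail-ratio FDR over pooled normalized null scores, clamped to [0,1]
# and monotonized within each sign (BH-style step-up: a more extreme NES
# never gets a larger q than a less extreme one).
fdr_tail_ratio <- function(nes, pool) {
  q <- rep(NA_real_, length(nes))
  n_pool_pos <- sum(pool > 0); n_pool_neg <- sum(pool < 0)
  n_obs_pos <- sum(nes > 0, na.rm = TRUE); n_obs_neg <- sum(nes < 0, na.rm = TRUE)
  for (i in seq_along(nes)) {
    if (is.na(nes[i])) next
    if (nes[i] >= 0) {
      num <- if (n_pool_pos > 0) sum(pool >= nes[i]) / n_pool_pos else 1
      den <- sum(nes >= nes[i], na.rm = TRUE) / max(n_obs_pos, 1L)
    } else {
      num <- if (n_pool_neg > 0) sum(pool <= nes[i]) / n_pool_neg else 1
      den <- sum(nes <= nes[i], na.rm = TRUE) / max(n_obs_neg, 1L)
    }
    q[i] <- min(1, max(0, num / den))
  }
  for (sgn in c(1, -1)) {
    sel <- which(!is.na(nes) & sign(nes) == sgn)
    if (length(sel) < 2L) next
    ord <- sel[order(-abs(nes[sel]))]          # most extreme first
    q[ord] <- rev(cummin(rev(q[ord])))
  }
  q
}

#' Adjust p-values for multiple testing
#'
#' Validating wrapper around the standard step-up procedures
#' (Benjamini-Hochberg or Benjamini-Yekutieli).
#'
#' @param pvals numeric vector in \[0,1\].
#' @param method `"BH"` or `"BY"`.
#' @return adjusted values, monotone, in \[0,1\].
#' @export
adjust_pvalues <- function(pvals, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0,1]")
  stats::p.adjust(pvals, method = method)
}

#' Intersect enriched gene sets across two analyses
#'
#' A set is shared when it passes the FDR threshold in both results with the
#' same enrichment direction (ES sign).
#'
#' @param results_a,results_b [gsea()] result tables over a shared set-name
#'   universe.
#' @param q_threshold FDR q cutoff (conventionally 0.25).
#' @return list with `shared` (set names), `n_a`, `n_b` (per-input pass
#'   counts, for Venn reporting).
#' @export
intersect_enriched <- function(results_a, results_b, q_threshold = 0.25) {
  pass <- function(r) r$set[!is.na(r$fdr_q) & r$fdr_q < q_threshold]
  pa <- pass(results_a); pb <- pass(results_b)
  shared <- intersect(pa, pb)
  if (length(shared) > 0L) {
    sa <- sign(results_a$es[match(shared, results_a$set)])
    sb <- sign(results_b$es[match(shared, results_b$set)])
    shared <- shared[sa == sb]
  }
  list(shared = shared, n_a = length(pa), n_b = length(pb))
}

#' Write a GSEA result table as TSV
#' @param results an `EnrichmentTable` from [gsea()].
#' @param path destination.
#' @export
write_enrichment_table <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
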