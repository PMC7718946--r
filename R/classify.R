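#' Row-scale an expression matrix to zero mean, unit variance
#'
#' ClustVis-style "variance scaling": each gene row is centered and divided
#' by its SD. Zero-variance rows are dropped with a warning (they carry no
#' clustering information and make the z-score undefined).
#'
#' @param values numeric matrix, genes x samples.
#' @return scaled matrix, possibly with fewer rows.
#' @export
scale_rows <- function(values) {
  mu <- rowMeans(values)
  sd <- apply(values, 1L, stats::sd)
  zero <- sd == 0 | is.na(sd)
  if (any(zero)) {
    warning("dropping ", sum(zero), " zero-variance row(s): ",
            paste(utils::head(rownames(values)[zero], 5L), collapse = ", "))
    values <- values[!zero, , drop = FALSE]
    mu <- mu[!zero]; sd <- sd[!zero]
  }
  (values - mu) / sd
}

#' Cluster samples by a gene signature
#'
#' Subsets the matrix to the signature genes present, row-scales them to unit
#' variance, and clusters the samples by agglomerative hierarchical
#' clustering with Euclidean distance and Ward linkage (`ward.D2`, the Ward
#' criterion on squared Euclidean distances as in current ClustVis/hclust).
#' The tree is cut into `k` clusters.
#'
#' @param matrix an [expression_matrix()].
#' @param signature a [gene_set()].
#' @param k number of clusters to cut (default 2: a high/low dichotomy).
#' @param scale_rows row-scale before distances (disable to cluster raw
#'   log2 values).
#' @return `ClusterAssignment`: list with `signature_name`, `sample_ids`,
#'   `cluster` (integer per sample, 1..k), `k`, `scaled` (the scaled
#'   signature submatrix), `n_missing_genes`, `hclust` (the tree).
#' @export
cluster_by_signature <- function(matrix, signature, k = 2L, scale_rows = TRUE) {
  stopifnot(inherits(signature, "GeneSet"))
  if (k > ncol(matrix)) stop("k = ", k, " exceeds n_samples = ", ncol(matrix))
  present <- intersect(signature$genes, rownames(matrix))
  n_missing <- length(signature$genes) - length(present)
  if (n_missing > 0L)
    message("signature '", signature$name, "': ", n_missing,
            " gene(s) absent from matrix, dropped")
  if (length(present) < 2L)
    stop("signature '", signature$name, "' has ", length(present),
         " usable gene(s) in the matrix; need >=2")
  sub <- matrix[present, , drop = FALSE]
  class(sub) <- "matrix"
  if (scale_rows) sub <- scale_rows(sub)
  if (nrow(sub) < 2L)
    stop("signature '", signature$name,
         "' has <2 informative genes after zero-variance drop")
  d <- stats::dist(t(sub), method = "euclidean")
  hc <- stats::hclust(d, method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  structure(list(signature_name = signature$name,
                 sample_ids = colnames(matrix),
                 cluster = cl, k = k, scaled = sub,
                 n_missing_genes = n_missing, hclust = hc),
            class = "ClusterAssignment")
}

#' Call the MYC-high cluster(s)
#'
#' The high cluster is the one with the largest mean row-scaled signature
#' expression. With `secondary_threshold` set, any further cluster whose mean
#' scaled expression exceeds the threshold is also included — the escape
#' hatch for a cluster with incomplete but elevated target-gene expression
#' that belongs with the high group. An exact tie between cluster means is
#' broken toward the cluster containing the lexicographically smallest
#' sample ID, with a warning.
#'
#' @param assignment a [cluster_by_signature()] result.
#' @param secondary_threshold numeric or `NULL` (off, the default). When set
#'   (conventionally 0), clusters other than the argmax whose mean scaled
#'   expression exceeds it are unioned in.
#' @return character vector of MYC-high sample IDs.
#' @export
call_high_cluster <- function(assignment, secondary_threshold = NULL) {
  stopifnot(inherits(assignment, "ClusterAssignment"))
  means <- vapply(seq_len(assignment$k), function(ci)
    mean(assignment$scaled[, assignment$cluster == ci, drop = FALSE]),
    numeric(1L))
  top <- max(means)
  cand <- which(means == top)
  if (length(cand) > 1L) {
    warning("exact tie between cluster means; breaking toward the cluster ",
            "with the smallest sample ID")
    firsts <- vapply(cand, function(ci)
      min(assignment$sample_ids[assignment$cluster == ci]), character(1L))
    cand <- cand[which.min(firsts)]
  }
  high <- cand
  if (!is.null(secondary_threshold)) {
    extra <- setdiff(which(means > secondary_threshold), high)
    high <- sort(c(high, extra))
  }
  assignment$sample_ids[assignment$cluster %in% high]
}

#' Consensus MYC-high calls across signatures
#'
#' A sample is "common MYC-high" when every signature calls it high: the
#' consensus is the set intersection across the per-signature call sets.
#' Pairwise and triple overlap counts are emitted for Venn-style reporting.
#'
#' @param per_signature_high named list of character vectors (sample IDs
#'   called high per signature).
#' @return `MycCallSet`: list with `per_signature_high`, `consensus_high`,
#'   `counts` (per-signature sizes), `venn` (named overlap counts for every
#'   non-empty signature combination).
#' @export
consensus_calls <- function(per_signature_high) {
  if (length(per_signature_high) < 1L) stop("need at least one signature")
  if (is.null(names(per_signature_high)) || any(!nzchar(names(per_signature_high))))
    stop("per_signature_high must be a named list")
  consensus <- Reduce(intersect, per_signature_high)
  if (length(consensus) == 0L)
    warning("consensus MYC-high set is empty")
  sig_names <- names(per_signature_high)
  venn <- list()
  for (m in seq_along(sig_names)) {
    for (combo in utils::combn(sig_names, m, simplify = FALSE)) {
      venn[[paste(combo, collapse = "&")]] <-
        length(Reduce(intersect, per_signature_high[combo]))
    }
  }
  structure(list(per_signature_high = per_signature_high,
                 consensus_high = sort(consensus),
                 counts = vapply(per_signature_high, length, integer(1L)),
                 venn = unlist(venn)),
            class = "MycCallSet")
}

#' @export
print.MycCallSet <- function(x, ...) {
  cat("MycCallSet:", length(x$consensus_high), "consensus-high of signatures [",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "]\n")
  invisible(x)
}

#' Classify a cohort by a panel of MYC signatures
#'
#' Convenience wrapper: clusters by each signature, calls the high cluster,
#' and intersects across signatures.
#'
#' @inheritParams cluster_by_signature
#' @param signatures named list of [gene_set()].
#' @param secondary_threshold passed to [call_high_cluster()].
#' @return a [consensus_calls()] `MycCallSet`.
#' @export
classify_myc <- function(matrix, signatures, k = 2L,
                         secondary_threshold = NULL, scale_rows = TRUE) {
  calls <- lapply(signatures, function(sig) {
    a <- cluster_by_signature(matrix, sig, k = k, scale_rows = scale_rows)
    call_high_cluster(a, secondary_threshold = secondary_threshold)
  })
  consensus_calls(calls)
}
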