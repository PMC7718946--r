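#' Construct and validate an expression matrix
#'
#' The working representation of a log2 expression matrix is a plain numeric
#' matrix with gene IDs as rownames and sample IDs as colnames, the same
#' convention used throughout limma-style workflows. This constructor checks
#' the invariants every downstream stage relies on: unique gene and sample
#' IDs, dimensions matching the ID lists, and numeric (finite or `NA`) values.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids,sample_ids optional character vectors; default to the
#'   dimnames of `values`.
#' @return a validated numeric matrix of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample IDs are required (as dimnames or arguments)")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stop("length of gene_ids (", length(gene_ids), ") != nrow (", nrow(values), ")")
  if (length(sample_ids) != ncol(values))
    stop("length of sample_ids (", length(sample_ids), ") != ncol (", ncol(values), ")")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene IDs: ", paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs: ", paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (any(is.infinite(values)))
    stop("expression values must be finite or NA")
  dimnames(values) <- list(gene_ids, sample_ids)
  class(values) <- c("ExpressionMatrix", class(values))
  values
}

#' Construct a gene set
#'
#' @param name non-empty set name.
#' @param genes character vector of gene IDs; duplicates are removed,
#'   empty strings dropped.
#' @param description free-text description (GMT column 2).
#' @return object of class `GeneSet`: list with `name`, `genes`, `description`.
#' @export
gene_set <- function(name, genes, description = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("gene set name must be a non-empty string")
  genes <- unique(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L)
    stop("gene set '", name, "' has no genes")
  structure(list(name = name, genes = genes, description = description),
            class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat("GeneSet '", x$name, "': ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Construct binary phenotype labels
#'
#' Two-class sample labels in the style of a CLS phenotype file. The first
#' class name is the "positive" class (the class whose up-regulated genes get
#' positive ranking scores in [rank_genes_snr()]).
#'
#' @param labels character vector of class assignments, one per sample.
#' @param class_names length-2 character vector, positive class first.
#'   Defaults to the unique labels in order of first appearance.
#' @param sample_ids optional sample IDs; `NULL` means positional matching
#'   (the CLS convention).
#' @return object of class `PhenotypeLabels`.
#' @export
phenotype_labels <- function(labels, class_names = NULL, sample_ids = NULL) {
  labels <- as.character(labels)
  if (is.null(class_names)) class_names <- unique(labels)
  class_names <- as.character(class_names)
  if (length(class_names) != 2L)
    stop("exactly two classes are required, got ", length(class_names))
  if (!all(labels %in% class_names))
    stop("labels contain values outside class_names: ",
         paste(setdiff(labels, class_names), collapse = ", "))
  if (!all(class_names %in% labels))
    stop("each class needs at least one sample; missing: ",
         paste(setdiff(class_names, labels), collapse = ", "))
  if (!is.null(sample_ids)) {
    sample_ids <- as.character(sample_ids)
    if (length(sample_ids) != length(labels))
      stop("sample_ids and labels differ in length")
    if (anyDuplicated(sample_ids)) stop("duplicate sample IDs in phenotype")
  }
  structure(list(sample_ids = sample_ids, labels = labels,
                 class_names = class_names),
            class = "PhenotypeLabels")
}

#' @export
print.PhenotypeLabels <- function(x, ...) {
  n <- table(factor(x$labels, levels = x$class_names))
  cat("PhenotypeLabels: ", paste(x$class_names, n, sep = "=", collapse = ", "),
      if (is.null(x$sample_ids)) " (positional)" else " (ID-joined)", "\n", sep = "")
  invisible(x)
}

#' Construct a drug-response table
#'
#' Viability measurements (% of vehicle control) for a panel of drugs against
#' a panel of cell lines, with an optional replicate dimension. Stored as a
#' 3-d array drug x line x replicate; missing wells are `NA` and are excluded
#' (with their effective n) from every downstream mean.
#'
#' @param viability numeric matrix (drug x line) or 3-d array
#'   (drug x line x replicate).
#' @param drug_ids,cell_line_ids character IDs; default to dimnames.
#' @param dose single positive dose (nM) at which the screen was run, or `NA`.
#' @return object of class `DrugResponseTable`.
#' @export
drug_response_table <- function(viability, drug_ids = NULL, cell_line_ids = NULL,
                                dose = NA_real_) {
  if (is.matrix(viability)) {
    viability <- array(viability, dim = c(dim(viability), 1L),
                       dimnames = c(dimnames(viability), list(NULL)))
  }
  if (!is.array(viability) || length(dim(viability)) != 3L)
    stop("`viability` must be a matrix or 3-d array (drug x line x replicate)")
  if (is.null(drug_ids)) drug_ids <- dimnames(viability)[[1L]]
  if (is.null(cell_line_ids)) cell_line_ids <- dimnames(viability)[[2L]]
  if (is.null(drug_ids) || is.null(cell_line_ids))
    stop("drug and cell-line IDs are required")
  drug_ids <- as.character(drug_ids); cell_line_ids <- as.character(cell_line_ids)
  if (anyDuplicated(drug_ids)) stop("duplicate drug IDs")
  if (anyDuplicated(cell_line_ids)) stop("duplicate cell-line IDs")
  if (length(drug_ids) != dim(viability)[1L] ||
      length(cell_line_ids) != dim(viability)[2L])
    stop("viability dimensions do not match ID lists")
  if (any(viability < 0, na.rm = TRUE)) {
    bad <- which(viability < 0, arr.ind = TRUE)[1L, ]
    stop("negative viability at drug '", drug_ids[bad[1L]], "', line '",
         cell_line_ids[bad[2L]], "'")
  }
  if (!is.na(dose) && dose <= 0) stop("dose must be positive")
  dimnames(viability) <- list(drug_ids, cell_line_ids, NULL)
  structure(list(drug_ids = drug_ids, cell_line_ids = cell_line_ids,
                 viability = viability, dose = dose),
            class = "DrugResponseTable")
}

#' @export
print.DrugResponseTable <- function(x, ...) {
  cat("DrugResponseTable: ", length(x$drug_ids), " drugs x ",
      length(x$cell_line_ids), " lines x ", dim(x$viability)[3L],
      " replicate(s); dose ", x$dose, " nM\n", sep = "")
  invisible(x)
}

#' Average the replicate dimension of a drug-response table
#'
#' Replicates are never averaged implicitly; call this when a per-well mean
#' is wanted. Missing wells are excluded and the effective replicate count is
#' returned alongside the means.
#'
#' @param table a [drug_response_table()].
#' @return list with `mean` (drug x line matrix) and `n` (effective
#'   replicate count per well).
#' @export
average_replicates <- function(table) {
  stopifnot(inherits(table, "DrugResponseTable"))
  v <- table$viability
  m <- apply(v, c(1L, 2L), function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
  n <- apply(v, c(1L, 2L), function(x) sum(!is.na(x)))
  list(mean = m, n = n)
}
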