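#' Read a gene x sample expression matrix
#'
#' Supports two dialects: plain tab-delimited (header row = sample IDs, first
#' column = gene ID) and GCT version #1.2 (two header lines, then
#' NAME/Description columns). Values are taken to be on log2 scale.
#'
#' Duplicate gene rows are collapsed by taking the per-sample maximum, with a
#' warning naming the genes (the usual convention when several probes map to
#' one symbol). Duplicate sample IDs are a hard error. Gene IDs are matched
#' case-sensitively by default; `case_fold = TRUE` upper-cases them so that
#' murine symbols ("Myc") align with human ones ("MYC").
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"gct"`.
#' @param case_fold upper-case gene IDs on read (cross-species matching).
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "gct"),
                                   case_fold = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("malformed header in ", path, ": need >=2 columns")
    genes <- as.character(df[[1L]])
    vals <- as.matrix(df[, -1L, drop = FALSE])
    samples <- colnames(df)[-1L]
  } else {
    lines <- readLines(path, n = 3L)
    if (length(lines) < 3L) stop("malformed GCT: fewer than 3 lines")
    if (trimws(lines[1L]) != "#1.2")
      stop("malformed GCT header (line 1): expected '#1.2', got '", lines[1L], "'")
    dims <- suppressWarnings(as.integer(strsplit(lines[2L], "\t")[[1L]]))
    if (length(dims) < 2L || anyNA(dims[1:2]))
      stop("malformed GCT dimensions line (line 2): '", lines[2L], "'")
    df <- utils::read.delim(path, header = TRUE, sep = "\t", skip = 2L,
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 3L) stop("malformed GCT column header: need NAME, Description, samples")
    if (nrow(df) != dims[1L])
      stop("GCT declares ", dims[1L], " rows but file has ", nrow(df), " data rows")
    if (ncol(df) - 2L != dims[2L])
      stop("GCT declares ", dims[2L], " samples but file has ", ncol(df) - 2L)
    genes <- as.character(df[[1L]])
    vals <- as.matrix(df[, -(1:2), drop = FALSE])
    samples <- colnames(df)[-(1:2)]
  }
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(vals), nrow(vals)))) &
                   !is.na(vals), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop("non-numeric expression value at row ", bad[1L, 1L], ", sample '",
           samples[bad[1L, 2L]], "'")
    vals <- matrix(as.numeric(vals), nrow(vals), dimnames = dimnames(vals))
  }
  if (anyDuplicated(samples))
    stop("duplicate sample ID(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (case_fold) genes <- toupper(genes)
  if (anyDuplicated(genes)) {
    dups <- unique(genes[duplicated(genes)])
    warning("collapsing ", length(dups), " duplicated gene ID(s) by max: ",
            paste(utils::head(dups, 5L), collapse = ", "))
    vals <- rowsum_max(vals, genes)
    genes <- rownames(vals)
  }
  expression_matrix(vals, gene_ids = genes, sample_ids = samples)
}

# per-group maximum over rows, preserving first-appearance order
rowsum_max <- function(vals, groups) {
  ord <- unique(groups)
  out <- matrix(NA_real_, length(ord), ncol(vals), dimnames = list(ord, colnames(vals)))
  for (g in ord) {
    rows <- vals[groups == g, , drop = FALSE]
    out[g, ] <- suppressWarnings(apply(rows, 2L, max, na.rm = TRUE))
    out[g, is.infinite(out[g, ])] <- NA_real_
  }
  out
}

#' Write an expression matrix
#'
#' TSV writer is the round-trip inverse of [read_expression_matrix()]:
#' UTF-8, LF line endings, full `format(..., digits = 17)` precision.
#'
#' @param x an [expression_matrix()].
#' @param path destination.
#' @param dialect `"tsv"` or `"gct"`.
#' @export
write_expression_matrix <- function(x, path, dialect = c("tsv", "gct")) {
  dialect <- match.arg(dialect)
  fmt <- function(v) vapply(v, function(z) if (is.na(z)) "NA" else
    format(z, digits = 17, scientific = FALSE, trim = TRUE), character(1L))
  body <- apply(x, 1L, fmt)
  body <- if (is.matrix(body)) t(body) else matrix(body, nrow = nrow(x))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (dialect == "tsv") {
    writeLines(c(paste(c("gene_id", colnames(x)), collapse = "\t"),
                 paste(rownames(x), apply(body, 1L, paste, collapse = "\t"),
                       sep = "\t")),
               con, sep = "\n")
  } else {
    writeLines(c("#1.2",
                 paste(nrow(x), ncol(x), sep = "\t"),
                 paste(c("NAME", "Description", colnames(x)), collapse = "\t"),
                 paste(rownames(x), "na",
                       apply(body, 1L, paste, collapse = "\t"), sep = "\t")),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then tab-separated gene IDs. Empty
#' gene fields are dropped and duplicate genes within a set deduplicated.
#'
#' @param path GMT file.
#' @param case_fold upper-case gene IDs on read.
#' @return named list of [gene_set()] objects, in file order.
#' @export
read_gmt <- function(path, case_fold = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has ", length(f), " fields; need >=3")
    genes <- f[-(1:2)]
    if (case_fold) genes <- toupper(genes)
    sets[[i]] <- gene_set(f[1L], genes, description = f[2L])
  }
  names(sets) <- vapply(sets, `[[`, character(1L), "name")
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set name(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets
}

#' Write a GMT gene-set collection
#' @param sets list of [gene_set()] objects.
#' @param path destination.
#' @export
write_gmt <- function(sets, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(vapply(sets, function(s)
    paste(c(s$name, if (nzchar(s$description)) s$description else "na", s$genes),
          collapse = "\t"), character(1L)), con, sep = "\n")
  invisible(path)
}

#' Read a CLS phenotype file
#'
#' Categorical CLS: line 1 `n_samples n_classes 1`, line 2
#' `# name_pos name_neg`, line 3 space-separated labels. Labels may be given
#' either as the class names or as 0/1 indices into the name line. Matching
#' to an expression matrix is positional (the CLS convention); use
#' [read_phenotype_tsv()] for an ID-joined phenotype.
#'
#' @param path CLS file.
#' @return a [phenotype_labels()] (positional, `sample_ids = NULL`).
#' @export
read_cls <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3L) stop("CLS file needs 3 lines, got ", length(lines))
  hdr <- strsplit(lines[1L], "\\s+")[[1L]]
  n_declared <- as.integer(hdr[1L])
  n_classes <- as.integer(hdr[2L])
  if (is.na(n_declared) || is.na(n_classes))
    stop("malformed CLS counts line: '", lines[1L], "'")
  if (n_classes != 2L) stop("two classes required, CLS declares ", n_classes)
  namef <- strsplit(sub("^#\\s*", "", lines[2L]), "\\s+")[[1L]]
  if (length(namef) != 2L)
    stop("CLS class-name line must name 2 classes, got ", length(namef))
  lab <- strsplit(lines[3L], "\\s+")[[1L]]
  if (length(lab) != n_declared)
    stop("CLS declares ", n_declared, " labels but ", length(lab), " given")
  if (all(lab %in% c("0", "1"))) lab <- namef[as.integer(lab) + 1L]
  if (length(unique(lab)) != 2L)
    stop("two classes required; labels contain ", length(unique(lab)))
  phenotype_labels(lab, class_names = namef)
}

#' Write a CLS phenotype file
#' @param labels a [phenotype_labels()].
#' @param path destination.
#' @export
write_cls <- function(labels, path) {
  stopifnot(inherits(labels, "PhenotypeLabels"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(length(labels$labels), 2L, 1L),
               paste("#", labels$class_names[1L], labels$class_names[2L]),
               paste(labels$labels, collapse = " ")),
             con, sep = "\n")
  invisible(path)
}

#' Read an ID-joined phenotype TSV
#'
#' Two columns `sample_id`, `label`; the explicit alternative to positional
#' CLS matching when sample order is not guaranteed.
#'
#' @param path TSV with header.
#' @param class_names optional explicit class order (positive first).
#' @return a [phenotype_labels()] carrying sample IDs.
#' @export
read_phenotype_tsv <- function(path, class_names = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% colnames(df)))
    stop("phenotype TSV needs columns sample_id, label")
  phenotype_labels(df$label, class_names = class_names,
                   sample_ids = df$sample_id)
}

#' Read a single-dose drug-response table
#'
#' Header row of cell-line IDs, first column the drug ID, one row per
#' drug (repeated drug rows are stacked into a replicate dimension).
#' `NA` cells are kept as missing wells; negative or non-numeric entries are
#' errors with coordinates.
#'
#' @param path TSV file.
#' @param dose screen dose in nM (annotation only).
#' @return a [drug_response_table()].
#' @export
read_drug_table <- function(path, dose = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("malformed drug table: need drug column + >=1 line")
  drugs_raw <- as.character(df[[1L]])
  lines_ids <- colnames(df)[-1L]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals) & vals != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-numeric viability at drug '", drugs_raw[bad[1L, 1L]],
         "', line '", lines_ids[bad[1L, 2L]], "'")
  if (any(num < 0, na.rm = TRUE)) {
    b <- which(num < 0, arr.ind = TRUE)[1L, ]
    stop("negative viability at drug '", drugs_raw[b[1L]], "', line '",
         lines_ids[b[2L]], "'")
  }
  drugs <- unique(drugs_raw)
  n_rep <- max(table(drugs_raw))
  arr <- array(NA_real_, dim = c(length(drugs), length(lines_ids), n_rep),
               dimnames = list(drugs, lines_ids, NULL))
  for (d in drugs) {
    rows <- num[drugs_raw == d, , drop = FALSE]
    arr[d, , seq_len(nrow(rows))] <- t(rows)
  }
  if (anyNA(arr))
    message("drug table has ", sum(is.na(arr)),
            " missing well(s); excluded from downstream means")
  drug_response_table(arr, dose = dose)
}

#' Write a drug-response table (replicates stacked as repeated rows)
#' @param table a [drug_response_table()].
#' @param path destination.
#' @export
write_drug_table <- function(table, path) {
  stopifnot(inherits(table, "DrugResponseTable"))
  fmt <- function(z) if (is.na(z)) "NA" else
    format(z, digits = 17, scientific = FALSE, trim = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  out <- paste(c("drug_id", table$cell_line_ids), collapse = "\t")
  for (r in seq_len(dim(table$viability)[3L])) {
    sl <- table$viability[, , r, drop = FALSE]
    keep <- apply(sl[, , 1L, drop = FALSE], 1L, function(x) !all(is.na(x)))
    for (d in which(keep)) {
      out <- c(out, paste(c(table$drug_ids[d],
                            vapply(sl[d, , 1L], fmt, character(1L))),
                          collapse = "\t"))
    }
  }
  writeLines(out, con, sep = "\n")
  invisible(path)
}
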