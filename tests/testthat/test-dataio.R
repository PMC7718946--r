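test_that("expression TSV round-trips bit-exactly and preserves file order", {
  x <- expression_matrix(matrix(c(1.25, -3.75, 5.5, 0.125, 2.2, 1/3),
                                3, 2, dimnames = list(c("MYC", "ODC1", "CAD"),
                                                      c("sA", "sB"))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(x, path)
  y <- read_expression_matrix(path)
  expect_identical(rownames(y), c("MYC", "ODC1", "CAD"))
  expect_identical(colnames(y), c("sA", "sB"))
  expect_identical(unclass(y), unclass(x))
})

test_that("duplicate gene rows collapse by max with a warning", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "MYC\t5.0\t1.0", "MYC\t7.0\t0.5",
               "ODC1\t2\t2"), path)
  expect_warning(y <- read_expression_matrix(path), "collaps")
  expect_equal(unname(y["MYC", ]), c(7.0, 1.0))
  expect_equal(nrow(y), 2L)
})

test_that("duplicate sample IDs are a hard error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts1", "MYC\t5\t6"), path)
  expect_error(read_expression_matrix(path), "duplicate sample")
})

test_that("GCT dialect validates declared dimensions and round-trips values", {
  path <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.2", "5\t4", "NAME\tDescription\ta\tb\tc\td",
               "g1\tna\t1\t2\t3\t4", "g2\tna\t5\t6\t7\t8",
               "g3\tna\t9\t10\t11\t12"), path)
  expect_error(read_expression_matrix(path, dialect = "gct"), "3 data rows")

  x <- expression_matrix(matrix(rnorm(6), 3, 2,
                                dimnames = list(paste0("g", 1:3), c("a", "b"))))
  write_expression_matrix(x, path, dialect = "gct")
  y <- read_expression_matrix(path, dialect = "gct")
  expect_equal(unclass(y), unclass(x))
})

test_that("case folding aligns murine and human symbols", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "Myc\t1\t2", "Odc1\t3\t4"), path)
  y <- read_expression_matrix(path, case_fold = TRUE)
  expect_identical(rownames(y), c("MYC", "ODC1"))
})

test_that("GMT parsing dedups genes, keeps file order, flags short lines", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA\tB\tB", "S2\tdesc2\tC\t\tD"), path)
  sets <- read_gmt(path)
  expect_identical(names(sets), c("S1", "S2"))
  expect_setequal(sets$S1$genes, c("A", "B"))
  expect_setequal(sets$S2$genes, c("C", "D"))   # empty field dropped

  writeLines(c("S1\tdesc\tA", "BAD\tonlydesc"), path)
  expect_error(read_gmt(path), "line 2")

  writeLines(character(0), path)
  expect_length(read_gmt(path), 0L)

  sets2 <- list(gene_set("S1", c("A", "B"), "d1"), gene_set("S2", "C"))
  write_gmt(sets2, path)
  rt <- read_gmt(path)
  expect_setequal(rt[[1]]$genes, c("A", "B"))
  expect_identical(rt[[1]]$description, "d1")
})

test_that("CLS parsing validates structure and count, both label styles", {
  path <- withr::local_tempfile(fileext = ".cls")
  writeLines(c("4 2 1", "# high low", "high high low low"), path)
  ph <- read_cls(path)
  expect_identical(ph$labels, c("high", "high", "low", "low"))
  expect_identical(ph$class_names, c("high", "low"))

  writeLines(c("4 2 1", "# high low", "0 0 1 1"), path)
  expect_identical(read_cls(path)$labels, c("high", "high", "low", "low"))

  writeLines(c("4 2 1", "# high low", "high high low"), path)
  expect_error(read_cls(path), "4 labels but 3")

  writeLines(c("3 2 1", "# high low", "high high high"), path)
  expect_error(read_cls(path), "two classes")

  ph2 <- phenotype_labels(c("a", "b", "a"), c("a", "b"))
  write_cls(ph2, path)
  expect_identical(read_cls(path)$labels, c("a", "b", "a"))
})

test_that("drug table reader handles replicates, NA wells and bad cells", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("drug_id\tL1\tL2\tL3\tL4",
               "d1\t10\t20\t30\t40",
               "d2\t50\t60\t70\t80"), path)
  tab <- read_drug_table(path)
  expect_identical(dim(tab$viability), c(2L, 4L, 1L))

  writeLines(c("drug_id\tL1\tL2",
               "d1\t10\t20", "d1\t12\t22", "d2\t5\tNA"), path)
  expect_message(tab <- read_drug_table(path), "missing well")
  expect_identical(dim(tab$viability)[3L], 2L)
  avg <- average_replicates(tab)
  expect_equal(avg$mean["d1", "L1"], 11)
  expect_equal(avg$n["d2", "L2"], 0L)

  writeLines(c("drug_id\tL1", "d1\t-5"), path)
  expect_error(read_drug_table(path), "negative viability.*d1")

  writeLines(c("drug_id\tL1", "d1\toops"), path)
  expect_error(read_drug_table(path), "non-numeric.*d1.*L1")
})

test_that("drug table TSV round-trips through writer and reader", {
  arr <- array(c(10, 20, 30, 40, 11, 21, 31, 41), c(2, 2, 2),
               dimnames = list(c("d1", "d2"), c("L1", "L2"), NULL))
  tab <- drug_response_table(arr, dose = 600)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_drug_table(tab, path)
  rt <- read_drug_table(path, dose = 600)
  expect_equal(rt$viability, tab$viability)
  expect_identical(rt$drug_ids, tab$drug_ids)
})
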