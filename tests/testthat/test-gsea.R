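test_that("signal-to-noise scores follow the floored-SD formula", {
  x <- expression_matrix(matrix(c(2, 2, 0, 0,      # pos=(2,2), neg=(0,0)
                                  1, 1, 1, 1),     # identical classes
                                2, 4, byrow = TRUE,
                                dimnames = list(c("gA", "gB"), paste0("s", 1:4))))
  lab <- phenotype_labels(c("pos", "pos", "neg", "neg"), c("pos", "neg"))
  r <- rank_genes_snr(x, lab)
  # SD floors: pos max(0.2*2, 0.2)=0.4, neg max(0, 0.2)=0.2 -> 2/0.6
  expect_equal(r$score[r$gene == "gA"], 2 / 0.6, tolerance = 1e-12)
  expect_equal(r$score[r$gene == "gB"], 0)

  # antisymmetry under label swap
  lab2 <- phenotype_labels(c("pos", "pos", "neg", "neg"), c("neg", "pos"))
  r2 <- rank_genes_snr(x, lab2)
  expect_equal(r2$score[match(r$gene, r2$gene)], -r$score)
})

test_that("ranking breaks score ties by gene ID and rejects empty classes", {
  x <- expression_matrix(matrix(rep(c(3, 3, 1, 1), 3), 3, 4, byrow = TRUE,
                                dimnames = list(c("z", "a", "m"), paste0("s", 1:4))))
  lab <- phenotype_labels(c("p", "p", "n", "n"), c("p", "n"))
  r <- rank_genes_snr(x, lab)
  expect_identical(r$gene, c("a", "m", "z"))
  expect_error(phenotype_labels(c("p", "p"), c("p", "n")), "at least one sample")
})

test_that("extreme-placement gene sets reach ES of +1 and -1", {
  ranked <- data.frame(gene = paste0("g", 1:4), score = c(3, 2, -1, -2))
  top <- enrichment_score(ranked, gene_set("top", c("g1", "g2")), weight_p = 0)
  expect_equal(top$es, 1)
  expect_setequal(top$leading_edge, c("g1", "g2"))
  bot <- enrichment_score(ranked, gene_set("bot", c("g3", "g4")), weight_p = 0)
  expect_equal(bot$es, -1)
  expect_setequal(bot$leading_edge, c("g3", "g4"))
})

test_that("enrichment score matches the explicit-walk oracle on random cases", {
  withr::with_seed(31, {
    for (rep in 1:50) {
      n <- sample(5:40, 1)
      scores <- sort(rnorm(n), decreasing = TRUE)
      ranked <- data.frame(gene = sprintf("g%03d", 1:n), score = scores)
      nh <- sample(seq_len(n - 1L), 1)
      hits <- sort(sample(n, nh))
      gs <- gene_set("S", ranked$gene[hits])
      for (p in c(0, 1)) {
        got <- enrichment_score(ranked, gs, weight_p = p)$es
        want <- oracle_es(scores, seq_len(n) %in% hits, p = p)
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  })
})

test_that("weighted ES agrees with an independent reference implementation", {
  skip_if_not_installed("fgsea")
  withr::with_seed(77, {
    for (rep in 1:20) {
      n <- sample(20:100, 1)
      scores <- sort(rnorm(n), decreasing = TRUE)
      ranked <- data.frame(gene = sprintf("g%03d", 1:n), score = scores)
      hits <- sort(sample(n, sample(3:10, 1)))
      es_pkg <- enrichment_score(ranked, gene_set("S", ranked$gene[hits]),
                                 weight_p = 1)$es
      es_ref <- fgsea::calcGseaStat(stats::setNames(scores, ranked$gene),
                                    selectedStats = hits, gseaParam = 1)
      expect_equal(es_pkg, es_ref, tolerance = 1e-9)
    }
  })
})

test_that("ES is bounded, sign-consistent with NES, and p never zero", {
  co <- simulate_cohort(cohort_sim_config(n_samples = 40L, n_genes = 300L,
                                          seed = 8))
  lab <- phenotype_labels(ifelse(co$truth_high, "high", "low"),
                          c("high", "low"),
                          sample_ids = colnames(co$expression))
  sets <- c(co$signatures,
            random_gene_sets(rownames(co$expression), 5, 30, seed = 2))
  res <- gsea(co$expression, lab, sets, n_perm = 100, seed = 4)
  expect_true(all(res$es >= -1 & res$es <= 1))
  expect_true(all(res$p_nominal > 0 & res$p_nominal <= 1))
  expect_true(all(is.na(res$fdr_q) | (res$fdr_q >= 0 & res$fdr_q <= 1)))
  expect_true(all(sign(res$nes) == sign(res$es) | res$es == 0))
})

test_that("classic-mode ES is invariant to monotone rescaling of scores", {
  ranked <- data.frame(gene = paste0("g", 1:10),
                       score = sort(rnorm(10), decreasing = TRUE))
  gs <- gene_set("S", ranked$gene[c(2, 5, 9)])
  a <- enrichment_score(ranked, gs, weight_p = 0)$es
  ranked2 <- transform(ranked, score = score * 100 + 5)
  b <- enrichment_score(ranked2, gs, weight_p = 0)$es
  expect_equal(a, b)
})

test_that("degenerate gene sets are rejected", {
  ranked <- data.frame(gene = paste0("g", 1:5), score = 5:1)
  expect_error(enrichment_score(ranked, gene_set("all", paste0("g", 1:5))),
               "entire ranked list")
  expect_error(enrichment_score(ranked, gene_set("none", "zzz")), "no overlap")
})

test_that("gsea is deterministic given the seed and respects size filters", {
  co <- simulate_cohort(cohort_sim_config(n_samples = 30L, n_genes = 200L,
                                          signature_sizes = c(20L, 20L, 20L),
                                          seed = 6))
  lab <- phenotype_labels(ifelse(co$truth_high, "high", "low"),
                          c("high", "low"), colnames(co$expression))
  sets <- c(co$signatures, random_gene_sets(rownames(co$expression), 3, 10,
                                            seed = 1),
            list(tiny = gene_set("tiny", rownames(co$expression)[1:2])))
  a <- gsea(co$expression, lab, sets, n_perm = 50, seed = 9)
  b <- gsea(co$expression, lab, sets, n_perm = 50, seed = 9)
  expect_identical(a, b)
  expect_identical(attr(a, "skipped"), "tiny")
})

test_that("planted signatures enrich in the high phenotype across seeds", {
  ok <- vapply(1:5, function(s) {
    co <- simulate_cohort(cohort_sim_config(n_samples = 60L, n_genes = 500L,
                                            seed = s))
    lab <- phenotype_labels(ifelse(co$truth_high, "high", "low"),
                            c("high", "low"), colnames(co$expression))
    sets <- c(co$signatures,
              random_gene_sets(rownames(co$expression), 10, 50, seed = s))
    res <- gsea(co$expression, lab, sets, n_perm = 500, seed = s)
    planted <- res[res$set %in% names(co$signatures), ]
    all(planted$nes > 0 & planted$fdr_q < 0.25)
  }, logical(1))
  expect_true(all(ok))
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  expect_equal(adjust_pvalues(rep(1, 4), "BH"), rep(1, 4))
  expect_equal(adjust_pvalues(0.04, "BH"), 0.04)
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0,1")
})

test_that("enriched-set intersection respects threshold and ES sign", {
  ra <- data.frame(set = c("s1", "s2", "s3", "s4"),
                   es = c(0.5, 0.6, -0.4, 0.2),
                   fdr_q = c(0.01, 0.1, 0.2, 0.5))
  rb <- data.frame(set = c("s1", "s2", "s3", "s4"),
                   es = c(0.4, -0.5, -0.3, 0.1),
                   fdr_q = c(0.02, 0.05, 0.1, 0.01))
  out <- intersect_enriched(ra, rb, q_threshold = 0.25)
  expect_setequal(out$shared, c("s1", "s3"))   # s2 excluded: opposite sign
  expect_identical(out$n_a, 3L)
  expect_length(intersect_enriched(ra, rb, q_threshold = 1e-9)$shared, 0L)
})
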