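test_that("ratio statistic follows the stated response arithmetic", {
  # high viabilities (20, 40) -> responses (80, 60), mean 70
  # low viabilities (70, 70) -> mean response 30; ratio 70/30 -> hit
  v <- matrix(c(20, 40, 70, 70,
                60, 60, 60, 60), 2, 4, byrow = TRUE,
              dimnames = list(c("dA", "dB"), c("h1", "h2", "l1", "l2")))
  tab <- drug_response_table(v, dose = 600)
  grp <- phenotype_labels(c("MYC_high", "MYC_high", "MYC_low", "MYC_low"),
                          c("MYC_high", "MYC_low"),
                          sample_ids = colnames(v))
  res <- score_single_dose_screen(tab, grp)
  a <- res[res$drug_id == "dA", ]
  expect_equal(a$mean_response_high, 70)
  expect_equal(a$mean_response_low, 30)
  expect_equal(a$ratio, 70 / 30)
  expect_true(a$is_hit)
  b <- res[res$drug_id == "dB", ]
  expect_equal(b$ratio, 1)
  expect_false(b$is_hit)
  expect_identical(res$rank, 1:2)   # dA ranks first by descending ratio
})

test_that("hit calls are invariant to a common response scale factor", {
  withr::with_seed(10, {
    resp <- matrix(runif(40, 5, 45), 10, 4,
                   dimnames = list(sprintf("d%02d", 1:10), c("h1", "h2", "l1", "l2")))
  })
  grp <- phenotype_labels(c("MYC_high", "MYC_high", "MYC_low", "MYC_low"),
                          c("MYC_high", "MYC_low"),
                          sample_ids = c("h1", "h2", "l1", "l2"))
  r1 <- score_single_dose_screen(drug_response_table(100 - resp), grp)
  r2 <- score_single_dose_screen(drug_response_table(100 - resp * 0.5), grp)
  expect_equal(r1$ratio, r2$ratio)
  expect_identical(r1$is_hit, r2$is_hit)
})

test_that("near-zero low-group response triggers the epsilon guard", {
  v <- matrix(c(50, 50, 99.9, 99.9), 1, 4,
              dimnames = list("d1", c("h1", "h2", "l1", "l2")))
  grp <- phenotype_labels(c("MYC_high", "MYC_high", "MYC_low", "MYC_low"),
                          c("MYC_high", "MYC_low"), sample_ids = colnames(v))
  res <- score_single_dose_screen(drug_response_table(v), grp)
  expect_true(res$unstable)
  expect_equal(res$ratio, 50 / 1)   # denominator replaced by epsilon = 1
})

test_that("hit calling recovers any planted hit set exactly at zero noise", {
  truth <- c(A = TRUE, B = TRUE, C = FALSE, D = FALSE, E = FALSE)
  for (ratio in c(2.1, 3, 5)) {
    sim <- simulate_screen(screen_sim_config(n_drugs = 30L, n_hits = 7L,
                                             hit_ratio = ratio,
                                             replicate_cv = 0, seed = 17),
                           truth)
    res <- score_single_dose_screen(sim$table, sim$groups)
    expect_setequal(res$drug_id[res$is_hit],
                    names(sim$hit_truth)[sim$hit_truth])
  }
})

test_that("noiseless 4PL parameters are recovered near-exactly", {
  d <- 10^seq(-2, 2, length.out = 7) * 10
  v <- four_pl(d, bottom = 0, top = 100, gi50 = 10, hill = 1)
  fit <- fit_4pl(d, v)
  expect_true(fit$converged)
  expect_equal(fit$gi50, 10, tolerance = 1e-6)
  expect_equal(fit$top, 100, tolerance = 1e-5)
  expect_equal(fit$bottom, 0, tolerance = 1e-4)
  expect_equal(fit$hill, 1, tolerance = 1e-6)
  expect_equal(fit$gi50_abs, 10, tolerance = 1e-5)
  expect_false(fit$gi50_censored)
})

test_that("4PL fit is invariant to the order of dose points", {
  withr::with_seed(5, {
    d <- 10^seq(-1, 2, length.out = 7)
    v <- four_pl(d, 5, 95, 3, 1.5) * (1 + rnorm(7, 0, 0.02))
    perm <- sample(7)
  })
  f1 <- fit_4pl(d, v)
  f2 <- fit_4pl(d[perm], v[perm])
  expect_equal(f1$gi50, f2$gi50, tolerance = 1e-8)
  expect_equal(f1$rss, f2$rss, tolerance = 1e-10)
})

test_that("flat 100% viability censors the absolute GI50 at the top dose", {
  d <- 10^seq(0, 3, length.out = 7)
  fit <- fit_4pl(d, rep(100, 7))
  expect_true(fit$gi50_censored)
  expect_equal(fit$gi50_abs, max(d))
})

test_that("fewer than four distinct doses is an error", {
  expect_error(fit_4pl(c(1, 10, 100), c(90, 50, 10)), ">= 4 distinct")
  expect_error(fit_4pl(c(1, 1, 10, 10), c(90, 91, 50, 49)), ">= 4 distinct")
})

test_that("median relative GI50 error stays below 10% on noisy curves", {
  errs <- vapply(1:100, function(s) {
    d <- 10^seq(-2, 2, length.out = 7) * 10   # spans gi50 x 1/100 .. x 100
    dr <- simulate_dose_response(d, bottom = 0, top = 100, gi50 = 10, hill = 1,
                                 noise_cv = 0.02, seed = s)
    abs(fit_4pl(dr$dose, dr$viability)$gi50 - 10) / 10
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})

test_that("dose-response AUC hits its analytic anchors", {
  d <- 10^seq(0, 3, length.out = 9)
  expect_equal(dose_response_auc(d, rep(100, 9)), 1)
  expect_equal(dose_response_auc(d, rep(0, 9)), 0)
  # step curve: 100% over the first half of the log span -> AUC ~ 0.5
  dd <- 10^seq(0, 4, length.out = 401)
  vv <- ifelse(log10(dd) <= 2, 100, 0)
  expect_equal(dose_response_auc(dd, vv), 0.5, tolerance = 0.01)
  # invariance to a common dose scale factor
  withr::with_seed(2, v <- runif(9, 0, 100))
  expect_equal(dose_response_auc(d, v), dose_response_auc(d * 1e3, v))
  # duplicate doses are averaged
  expect_equal(dose_response_auc(c(1, 1, 10), c(80, 120, 50)),
               dose_response_auc(c(1, 10), c(100, 50)))
})

test_that("quartile stratification uses type-7 quantiles with tie inclusion", {
  v <- stats::setNames(1:8, paste0("L", 1:8))
  s <- quartile_stratify(v, lower_is_sensitive = TRUE)
  expect_setequal(s$sensitive_set, c("L1", "L2"))
  expect_equal(s$boundary, stats::quantile(1:8, 0.25, type = 7, names = FALSE))

  ties <- stats::setNames(c(1, 1, 1, 1, 5, 6, 7, 8), paste0("L", 1:8))
  st <- quartile_stratify(ties)
  expect_setequal(st$sensitive_set, c("L1", "L2", "L3", "L4"))

  flip <- quartile_stratify(v, lower_is_sensitive = FALSE)
  expect_setequal(flip$sensitive_set, c("L7", "L8"))

  # sensitive set and complement partition the panel
  lab <- s$labels
  expect_setequal(lab$sample_ids, names(v))
  expect_identical(sort(unique(lab$labels)), c("resistant", "sensitive"))
  expect_error(quartile_stratify(stats::setNames(rep(2, 5), paste0("L", 1:5))),
               "identical")
})

test_that("sensitivity correlation recovers exact and null relationships", {
  x <- stats::setNames(10^seq(0, 2, length.out = 10), paste0("L", 1:10))
  r <- correlate_sensitivities(x, x^2)     # log10: y = 2x
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_equal(r$slope, 2, tolerance = 1e-10)
  rneg <- correlate_sensitivities(x, 1 / x)
  expect_equal(rneg$r, -1, tolerance = 1e-12)

  # null distribution of r at n = 38: |r| > 0.32 in about 5% of sims
  withr::with_seed(123, {
    rs <- vapply(1:1000, function(i)
      correlate_sensitivities(rnorm(38), rnorm(38), log10_transform = FALSE)$r,
      numeric(1))
  })
  expect_lt(abs(mean(rs)), 0.02)
  expect_lt(abs(mean(abs(rs) > 0.32) - 0.05), 0.025)
  expect_error(correlate_sensitivities(rep(1, 5), 1:5, log10_transform = FALSE),
               "zero variance")
})
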