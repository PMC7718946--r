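#' Configuration for the end-to-end synthetic analysis
#'
#' Bundles the simulation configs and analysis parameters for
#' [run_full_analysis()]. The defaults mirror the analysis surfaces of a
#' two-cohort MYC stratification study: two tumor cohorts (n = 80 and
#' n = 150, 10% MYC-high), a 129-drug single-dose screen on a 2+2 cell-line
#' panel with 10 planted hits, and a 38-line multidose panel whose MYC-high
#' members have left-shifted dose-response curves.
#'
#' @param cohorts list of [cohort_sim_config()], one per tumor cohort.
#' @param screen a [screen_sim_config()].
#' @param n_screen_lines_high,n_screen_lines_low cell lines per group in the
#'   single-dose screen panel.
#' @param panel a [cohort_sim_config()] for the multidose cell-line panel
#'   (expression used for the sensitivity-quartile enrichment).
#' @param gi50_low_lines,gi50_high_lines relative GI50 (nM) of MYC-low and
#'   MYC-high panel lines; the default tenfold left-shift plants the
#'   sensitivity signal.
#' @param doses dose series (nM) for the panel curves (seven-point
#'   half-log dilution by default).
#' @param dose_noise_cv multiplicative noise CV on panel viabilities.
#' @param k clusters to cut per signature.
#' @param secondary_threshold passed to [call_high_cluster()].
#' @param n_perm,weight_p,perm_type GSEA settings.
#' @param q_threshold FDR q cutoff for calling a set enriched (default 0.25).
#' @param n_decoys,decoy_size random decoy sets added to the enrichment
#'   collection alongside the planted signatures.
#' @param quartile sensitive-quartile fraction.
#' @param seed master seed; every stage derives its own seed from it.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(cohorts = list(cohort_sim_config(n_samples = 80L),
                                           cohort_sim_config(n_samples = 150L)),
                            screen = screen_sim_config(),
                            n_screen_lines_high = 2L, n_screen_lines_low = 2L,
                            panel = cohort_sim_config(n_samples = 38L,
                                                      frac_myc_high = 0.25),
                            gi50_low_lines = 100, gi50_high_lines = 10,
                            doses = 10^seq(-0.5, 2.5, by = 0.5),
                            dose_noise_cv = 0.05,
                            k = 2L, secondary_threshold = NULL,
                            n_perm = 1000L, weight_p = 1,
                            perm_type = "auto", q_threshold = 0.25,
                            n_decoys = 30L, decoy_size = 50L,
                            quartile = 0.25, seed = 1L) {
  if (q_threshold <= 0 || q_threshold >= 1) stop("q_threshold must be in (0,1)")
  structure(as.list(environment()), class = "PipelineConfig")
}

# deterministic per-stage seed derivation, kept below 2^31
derive_seed <- function(seed, stage) {
  (as.integer(seed) * 1009L + as.integer(stage) * 7919L) %% 2000000000L
}

#' Run the full MYC-stratification analysis end-to-end
#'
#' Simulate (or accept) the cohorts, classify MYC-high samples per signature
#' and by consensus, test enrichment of the signature collection in the
#' consensus-high phenotype of each cohort, intersect the enriched sets
#' across cohorts, score the single-dose screen, build the
#' sensitivity-quartile phenotype from fitted panel GI50s and test its
#' enrichment, and compute the survival and subtype-association statistics
#' for the first cohort. Deterministic given the config seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, the simulated inputs and
#'   the JSON report are written there in the package's file formats.
#' @return `ReportBundle` list with elements `consensus` (per-cohort calls,
#'   Venn counts, precision/recall vs truth), `enrichment` (per-cohort
#'   tables + `shared` intersection), `screen` (hit table + recovery vs
#'   planted truth), `quartile` (boundary, sensitive lines, enrichment
#'   table), `survival` (log-rank on consensus calls), `subtype` (Fisher
#'   test), and `provenance`.
#' @export
run_full_analysis <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  t0 <- Sys.time()
  stage_log <- function(name, ...) {
    message(sprintf("[%s] %s (%.1fs elapsed)", name, paste0(...),
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  ## cohorts: simulate, classify, enrich ------------------------------------
  ## one decoy collection shared across cohorts, like a fixed signature
  ## database applied to every dataset
  universe <- sprintf("G%05d",
                      seq_len(min(vapply(config$cohorts, `[[`, numeric(1L),
                                         "n_genes"))))
  decoys <- random_gene_sets(universe, config$n_decoys, config$decoy_size,
                             seed = derive_seed(config$seed, 100L))
  cohort_reports <- list()
  enr_tables <- list()
  for (i in seq_along(config$cohorts)) {
    cfg <- config$cohorts[[i]]
    cfg$seed <- derive_seed(config$seed, i)
    cohort <- simulate_cohort(cfg)
    stage_log("simulate", "cohort ", i, ": ", cfg$n_genes, " genes x ",
              cfg$n_samples, " samples")

    calls <- classify_myc(cohort$expression, cohort$signatures, k = config$k,
                          secondary_threshold = config$secondary_threshold)
    truth_ids <- names(cohort$truth_high)[cohort$truth_high]
    tp <- length(intersect(calls$consensus_high, truth_ids))
    precision <- if (length(calls$consensus_high) > 0)
      tp / length(calls$consensus_high) else NA_real_
    recall <- tp / length(truth_ids)
    stage_log("classify", "cohort ", i, ": ", length(calls$consensus_high),
              " consensus-high (precision ", round(precision, 3),
              ", recall ", round(recall, 3), ")")

    collection <- c(cohort$signatures, decoys)
    n_cons <- length(calls$consensus_high)
    if (n_cons == 0L || n_cons == ncol(cohort$expression)) {
      message("cohort ", i, ": consensus call set is ",
              if (n_cons == 0L) "empty" else "the whole cohort",
              "; skipping enrichment")
      enr <- data.frame(set = character(), size = integer(), es = numeric(),
                        nes = numeric(), p_nominal = numeric(),
                        fdr_q = numeric(), leading_edge = character())
    } else {
      labels <- phenotype_labels(
        ifelse(colnames(cohort$expression) %in% calls$consensus_high,
               "MYC_high", "rest"),
        class_names = c("MYC_high", "rest"),
        sample_ids = colnames(cohort$expression))
      enr <- gsea(cohort$expression, labels, collection,
                  n_perm = config$n_perm, seed = derive_seed(config$seed, 200L + i),
                  weight_p = config$weight_p, perm_type = config$perm_type)
      stage_log("gsea", "cohort ", i, ": ", nrow(enr), " sets, ",
                attr(enr, "perm_type"), " permutation x ", config$n_perm)
    }

    enr_tables[[i]] <- enr
    cohort_reports[[i]] <- list(
      n_samples = cfg$n_samples,
      consensus_high = calls$consensus_high,
      per_signature_counts = as.list(calls$counts),
      venn = as.list(calls$venn),
      precision = precision, recall = recall,
      enrichment = as.data.frame(enr))
    if (i == 1L) first_cohort <- list(cohort = cohort, calls = calls)
  }

  shared <- if (length(enr_tables) >= 2L)
    intersect_enriched(enr_tables[[1L]], enr_tables[[2L]],
                       q_threshold = config$q_threshold)
  else list(shared = character(), n_a = NA_integer_, n_b = NA_integer_)

  ## single-dose screen ------------------------------------------------------
  line_truth <- stats::setNames(
    rep(c(TRUE, FALSE), c(config$n_screen_lines_high, config$n_screen_lines_low)),
    sprintf("LINE_%02d", seq_len(config$n_screen_lines_high +
                                   config$n_screen_lines_low)))
  scfg <- config$screen
  scfg$seed <- derive_seed(config$seed, 300L)
  screen_sim <- simulate_screen(scfg, line_truth)
  screen_res <- score_single_dose_screen(screen_sim$table, screen_sim$groups)
  called_hits <- sort(screen_res$drug_id[screen_res$is_hit])
  planted_hits <- sort(names(screen_sim$hit_truth)[screen_sim$hit_truth])
  stage_log("screen", length(called_hits), " hits of ", scfg$n_drugs,
            " drugs (", length(planted_hits), " planted)")

  ## multidose panel: GI50 fits, quartile phenotype, enrichment --------------
  pcfg <- config$panel
  pcfg$seed <- derive_seed(config$seed, 400L)
  panel <- simulate_cohort(pcfg)
  gi50_true <- ifelse(panel$truth_high, config$gi50_high_lines,
                      config$gi50_low_lines)
  gi50_fit <- vapply(seq_along(gi50_true), function(j) {
    dr <- simulate_dose_response(config$doses, bottom = 0, top = 100,
                                 gi50 = gi50_true[j], hill = 1,
                                 noise_cv = config$dose_noise_cv,
                                 seed = derive_seed(config$seed, 500L + j))
    fit_4pl(dr$dose, dr$viability)$gi50
  }, numeric(1L))
  names(gi50_fit) <- colnames(panel$expression)
  strat <- quartile_stratify(gi50_fit, lower_is_sensitive = TRUE,
                             quartile = config$quartile)
  quartile_enr <- gsea(panel$expression, strat$labels,
                       c(panel$signatures, decoys),
                       n_perm = config$n_perm,
                       seed = derive_seed(config$seed, 700L),
                       weight_p = config$weight_p, perm_type = config$perm_type)
  stage_log("quartile", length(strat$sensitive_set), " sensitive of ",
            pcfg$n_samples, " lines")

  ## survival + subtype association on cohort 1 ------------------------------
  surv <- first_cohort$cohort$survival
  call_group <- ifelse(surv$sample_id %in% first_cohort$calls$consensus_high,
                       "MYC_high", "MYC_low")
  lr <- logrank_test(surv$time, surv$event, call_group)
  km <- lapply(split(seq_len(nrow(surv)), call_group), function(ii)
    km_estimate(surv$time[ii], surv$event[ii]))
  subtype <- first_cohort$cohort$subtype[surv$sample_id]
  tab <- matrix(c(sum(call_group == "MYC_high" & subtype == "squamous"),
                  sum(call_group == "MYC_high" & subtype != "squamous"),
                  sum(call_group == "MYC_low" & subtype == "squamous"),
                  sum(call_group == "MYC_low" & subtype != "squamous")),
                2L, byrow = TRUE)
  fisher_p <- fisher_exact(tab)
  stage_log("stats", "log-rank p = ", signif(lr$p_value, 3),
            ", Fisher p = ", signif(fisher_p, 3))

  report <- list(
    schema_version = "1.0",
    consensus = cohort_reports,
    enrichment_shared = list(shared = shared$shared,
                             n_pass_a = shared$n_a, n_pass_b = shared$n_b,
                             q_threshold = config$q_threshold),
    screen = list(hits = called_hits, planted = planted_hits,
                  n_hits = length(called_hits),
                  exact_recovery = identical(called_hits, planted_hits),
                  table = as.data.frame(screen_res)),
    quartile = list(boundary = strat$boundary,
                    sensitive = sort(strat$sensitive_set),
                    enrichment = as.data.frame(quartile_enr)),
    survival = list(chi_square = lr$chi_square, p_value = lr$p_value,
                    km = km),
    subtype = list(table = as.vector(t(tab)), fisher_p = fisher_p),
    provenance = list(package_version = as.character(utils::packageVersion("mycstrat")),
                      seed = config$seed,
                      n_perm = config$n_perm, weight_p = config$weight_p,
                      k = config$k, q_threshold = config$q_threshold,
                      quartile = config$quartile))
  class(report) <- "ReportBundle"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_expression_matrix(first_cohort$cohort$expression,
                            file.path(out_dir, "cohort1_expression.tsv"))
    write_gmt(first_cohort$cohort$signatures,
              file.path(out_dir, "signatures.gmt"))
    write_drug_table(screen_sim$table, file.path(out_dir, "screen.tsv"))
    write_myc_calls(first_cohort$calls, file.path(out_dir, "cohort1_calls.tsv"))
    write_report_json(report, file.path(out_dir, "report.json"))
  }
  report
}

#' Write consensus MYC calls as TSV
#'
#' One row per sample: `sample_id`, one high/low column per signature, and a
#' 0/1 consensus column.
#'
#' @param calls a [consensus_calls()] `MycCallSet`.
#' @param path destination.
#' @export
write_myc_calls <- function(calls, path) {
  stopifnot(inherits(calls, "MycCallSet"))
  samples <- sort(unique(unlist(calls$per_signature_high)))
  samples <- union(samples, calls$consensus_high)
  df <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  for (sig in names(calls$per_signature_high))
    df[[sig]] <- ifelse(samples %in% calls$per_signature_high[[sig]],
                        "high", "low")
  df$consensus <- as.integer(samples %in% calls$consensus_high)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a report bundle to JSON
#'
#' Deterministic for a given report: no timestamps, fixed numeric formatting.
#'
#' @param report a `ReportBundle` from [run_full_analysis()].
#' @param path destination.
#' @export
write_report_json <- function(report, path) {
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
  writeLines(json, con <- file(path, open = "wb"), sep = "\n")
  close(con)
  invisible(path)
}
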