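#' Configuration for a synthetic tumor cohort
#'
#' The generator plants the structure the downstream analysis assumes: a
#' minority of samples ("MYC-high", default 10% as in pancreatic cohorts
#' where roughly one in ten tumors shows coordinate MYC-target activation)
#' with signature genes shifted upwards, worse survival (proportional-hazards
#' exponential times), and enrichment of a binary "squamous" subtype label.
#'
#' @param n_genes total genes in the matrix.
#' @param n_samples cohort size.
#' @param frac_myc_high fraction of truth-high samples (exactly
#'   `round(frac * n)` are planted).
#' @param effect_size shift (in units of `noise_sd`) added to signature genes
#'   in high samples.
#' @param noise_sd per-gene Gaussian noise SD on the log2 scale.
#' @param signature_sizes sizes of the MYC target signatures (three lists of
#'   50 by default, standing in for the two hallmark MYC-target collections
#'   plus a direct-target list).
#' @param signature_overlap fraction of each signature shared pairwise: a
#'   common core of `round(overlap * size)` genes is sampled first and shared
#'   by all signatures, mirroring the real overlap of MYC target lists.
#' @param hazard_ratio hazard of the high group relative to the low group.
#' @param median_survival_low median survival of the low group, in days.
#' @param censor_quantile administrative censoring horizon expressed as a
#'   quantile of the low-group event distribution; the default 0.7 censors
#'   about 30% of low-group samples.
#' @param subtype_enrichment probability that a high sample carries the
#'   "squamous" label.
#' @param subtype_baseline probability that a low sample carries it.
#' @param seed RNG seed; the cohort is a pure function of (config, seed).
#' @return a `CohortSimConfig` list.
#' @export
cohort_sim_config <- function(n_genes = 2000L, n_samples = 80L,
                              frac_myc_high = 0.10, effect_size = 1.5,
                              noise_sd = 1.0,
                              signature_sizes = c(50L, 50L, 50L),
                              signature_overlap = 0.2,
                              hazard_ratio = 2.0,
                              median_survival_low = 600,
                              censor_quantile = 0.7,
                              subtype_enrichment = 0.75,
                              subtype_baseline = 0.15,
                              seed = 1L) {
  if (frac_myc_high <= 0 || frac_myc_high >= 1) stop("frac_myc_high must be in (0,1)")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  if (signature_overlap < 0 || signature_overlap >= 1)
    stop("signature_overlap must be in [0,1)")
  structure(as.list(environment()), class = "CohortSimConfig")
}

#' Simulate a tumor cohort with planted MYC-high structure
#'
#' Background expression is gene-wise Normal(0, `noise_sd`); every gene in the
#' union of the signatures is shifted by `+effect_size * noise_sd` in the
#' truth-high samples. Survival times are exponential with the low-group rate
#' scaled by `hazard_ratio` for high samples, administratively censored at a
#' fixed horizon. The subtype label is Bernoulli with the enriched
#' probability in high samples.
#'
#' @param config a [cohort_sim_config()].
#' @return a `SyntheticCohort` list: `expression` ([expression_matrix()]),
#'   `truth_high` (logical per sample), `signatures` (named list of
#'   [gene_set()]), `survival` (data.frame sample_id/time/event/group),
#'   `subtype` (character per sample), `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "CohortSimConfig"))
  if (sum(config$signature_sizes) > config$n_genes)
    stop("signature sizes (", sum(config$signature_sizes),
         ") exceed n_genes (", config$n_genes, ")")
  withr::with_seed(config$seed, {
    ng <- config$n_genes; ns <- config$n_samples
    genes <- sprintf("G%05d", seq_len(ng))
    samples <- sprintf("S%03d", seq_len(ns))
    n_high <- round(config$frac_myc_high * ns)
    if (n_high < 1L) stop("frac_myc_high too small: no high samples at n = ", ns)
    truth <- rep(FALSE, ns)
    truth[sample.int(ns, n_high)] <- TRUE

    # shared core first, then disjoint unique remainders
    core_n <- round(config$signature_overlap * min(config$signature_sizes))
    pool <- sample(genes)
    core <- pool[seq_len(core_n)]
    used <- core_n
    sigs <- list()
    for (i in seq_along(config$signature_sizes)) {
      uniq_n <- config$signature_sizes[i] - core_n
      uniq <- pool[used + seq_len(uniq_n)]
      used <- used + uniq_n
      sigs[[paste0("MYC_SIG_", i)]] <-
        gene_set(paste0("MYC_SIG_", i), c(core, uniq),
                 description = "planted MYC target signature")
    }

    expr <- matrix(stats::rnorm(ng * ns, 0, config$noise_sd), ng, ns,
                   dimnames = list(genes, samples))
    sig_union <- unique(unlist(lapply(sigs, `[[`, "genes")))
    expr[sig_union, truth] <- expr[sig_union, truth] +
      config$effect_size * config$noise_sd

    rate_low <- log(2) / config$median_survival_low
    rate <- ifelse(truth, rate_low * config$hazard_ratio, rate_low)
    t_event <- stats::rexp(ns, rate)
    horizon <- stats::qexp(config$censor_quantile, rate_low)
    event <- t_event <= horizon
    time <- pmin(t_event, horizon)

    p_sq <- ifelse(truth, config$subtype_enrichment, config$subtype_baseline)
    subtype <- ifelse(stats::runif(ns) < p_sq, "squamous", "nonsquamous")

    list(expression = expression_matrix(expr),
         truth_high = stats::setNames(truth, samples),
         signatures = sigs,
         survival = data.frame(sample_id = samples, time = time,
                               event = event,
                               group = ifelse(truth, "MYC_high", "MYC_low"),
                               stringsAsFactors = FALSE),
         subtype = stats::setNames(subtype, samples),
         config = config)
  })
}

#' Random decoy gene sets drawn from a gene universe
#'
#' Used to pad enrichment collections with null sets of the same size as the
#' planted signatures.
#'
#' @param genes gene universe.
#' @param n number of sets.
#' @param size genes per set.
#' @param seed RNG seed.
#' @return named list of [gene_set()].
#' @export
random_gene_sets <- function(genes, n, size, seed = 1L) {
  withr::with_seed(seed, {
    sets <- lapply(seq_len(n), function(i)
      gene_set(sprintf("DECOY_%03d", i), sample(genes, size),
               description = "random decoy set"))
    stats::setNames(sets, vapply(sets, `[[`, character(1L), "name"))
  })
}

#' Configuration for a synthetic single-dose drug screen
#'
#' Defaults mirror a 129-compound library screened at one dose against a
#' small panel, with hits planted as drugs whose mean response in the
#' MYC-high lines is `hit_ratio` times the response in the low lines.
#'
#' @param n_drugs library size.
#' @param n_hits number of planted hits.
#' @param hit_ratio planted true ratio of mean responses (must exceed the
#'   hit threshold of 2 for the screen statistic to have a recoverable
#'   signal; enforced > 0 only, so non-hit planting is possible).
#' @param baseline_response mean response (% of control, 100 - viability) of
#'   low lines for every drug and of high lines for non-hits.
#' @param replicate_cv coefficient of variation of multiplicative replicate
#'   noise on the response scale.
#' @param n_replicates replicates per drug x line.
#' @param dose screen dose in nM (annotation; the screen is single-dose).
#' @param seed RNG seed.
#' @return a `ScreenSimConfig` list.
#' @export
screen_sim_config <- function(n_drugs = 129L, n_hits = 10L, hit_ratio = 3.0,
                              baseline_response = 20, replicate_cv = 0.1,
                              n_replicates = 3L, dose = 600, seed = 1L) {
  if (n_hits > n_drugs) stop("n_hits cannot exceed n_drugs")
  if (hit_ratio <= 0) stop("hit_ratio must be > 0")
  if (hit_ratio * baseline_response > 100)
    stop("hit_ratio * baseline_response = ", hit_ratio * baseline_response,
         " exceeds 100% response; lower baseline_response")
  structure(as.list(environment()), class = "ScreenSimConfig")
}

#' Simulate a single-dose drug screen with planted hits
#'
#' The generator works in response space (100 - viability): non-hit drugs get
#' equal mean response in both groups, hit drugs get `hit_ratio x` the
#' baseline response in the MYC-high group. Multiplicative Gaussian noise
#' with CV `replicate_cv` is applied per well and responses converted back to
#' viability, clipped at 0 from below.
#'
#' @param config a [screen_sim_config()].
#' @param truth_labels named logical vector per cell line (`TRUE` =
#'   MYC-high); needs at least one line in each group.
#' @return list with `table` (a [drug_response_table()]), `hit_truth`
#'   (named logical per drug) and `groups` (a [phenotype_labels()]).
#' @export
simulate_screen <- function(config, truth_labels) {
  stopifnot(inherits(config, "ScreenSimConfig"))
  if (is.null(names(truth_labels))) stop("truth_labels must be named by cell line")
  truth_labels <- stats::setNames(as.logical(truth_labels), names(truth_labels))
  if (all(truth_labels)) stop("need at least one MYC-low line")
  if (!any(truth_labels)) stop("need at least one MYC-high line")
  withr::with_seed(config$seed, {
    drugs <- sprintf("DRUG_%03d", seq_len(config$n_drugs))
    hit_truth <- stats::setNames(rep(FALSE, config$n_drugs), drugs)
    hit_truth[sample.int(config$n_drugs, config$n_hits)] <- TRUE
    lines_ids <- names(truth_labels)
    resp_mean <- matrix(config$baseline_response, config$n_drugs,
                        length(lines_ids), dimnames = list(drugs, lines_ids))
    resp_mean[hit_truth, truth_labels] <-
      config$baseline_response * config$hit_ratio
    arr <- array(NA_real_,
                 dim = c(config$n_drugs, length(lines_ids), config$n_replicates),
                 dimnames = list(drugs, lines_ids, NULL))
    for (r in seq_len(config$n_replicates)) {
      noise <- if (config$replicate_cv > 0)
        1 + stats::rnorm(length(resp_mean), 0, config$replicate_cv) else 1
      resp <- resp_mean * noise
      arr[, , r] <- pmax(0, 100 - resp)
    }
    list(table = drug_response_table(arr, dose = config$dose),
         hit_truth = hit_truth,
         groups = phenotype_labels(
           ifelse(truth_labels, "MYC_high", "MYC_low"),
           class_names = c("MYC_high", "MYC_low"),
           sample_ids = lines_ids))
  })
}

#' Four-parameter logistic dose-response model
#'
#' `v(d) = bottom + (top - bottom) / (1 + (d / gi50)^hill)`; at `d = gi50`
#' the curve sits halfway between top and bottom (relative GI50), and with
#' `hill > 0` viability falls with dose.
#'
#' @param dose dose vector (nM), positive.
#' @param bottom,top lower/upper viability asymptotes (% of control).
#' @param gi50 inflection dose (nM).
#' @param hill Hill slope.
#' @return fitted viability at each dose.
#' @export
four_pl <- function(dose, bottom, top, gi50, hill) {
  bottom + (top - bottom) / (1 + (dose / gi50)^hill)
}

#' Simulate a noisy dose-response series
#'
#' @param doses positive dose vector, at least 4 points if the series is to
#'   be fitted afterwards.
#' @param bottom,top,gi50,hill 4PL parameters (see [four_pl()]).
#' @param noise_cv multiplicative noise CV; 0 gives the exact curve.
#' @param seed RNG seed.
#' @return data.frame with `dose` and `viability`.
#' @export
simulate_dose_response <- function(doses, bottom = 0, top = 100, gi50 = 10,
                                   hill = 1, noise_cv = 0, seed = 1L) {
  if (any(doses <= 0)) stop("doses must be positive")
  withr::with_seed(seed, {
    v <- four_pl(doses, bottom, top, gi50, hill)
    if (noise_cv > 0) v <- v * (1 + stats::rnorm(length(v), 0, noise_cv))
    data.frame(dose = doses, viability = pmax(0, v))
  })
}
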