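#' Configuration for the spectral-count simulator
#'
#' Describes the count-generating process of a paired two-group shotgun
#' proteomics experiment: per-protein expected per-sample counts drawn from a
#' long-tailed log-normal law, Poisson sampling per sample (the log-normal
#' layer supplies the over-dispersion typical of spectral counts), a planted
#' fraction of differential proteins whose expected counts are multiplied by
#' `de_fold` in one group, and a per-sample Bernoulli detection dropout whose
#' probability decreases with the expected count — which is what produces
#' proteins identified in only one group.
#'
#' @param n_proteins number of proteins in the simulated universe.
#' @param n_cases number of paired cases; the matrix gets `n_cases` PT plus
#'   `n_cases` LT columns. Default 7, the size of a paired FFPE discovery
#'   set.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-sample expected count of a protein in PT.
#' @param lt_depth_factor multiplicative depth advantage of the LT group
#'   (> 1 reproduces a deeper metastasis proteome).
#' @param de_fraction proportion of proteins planted as differential, in
#'   \[0, 1\]; exactly `round(de_fraction * n_proteins)` proteins are
#'   planted.
#' @param de_fold multiplicative effect (> 1) applied to the expected counts
#'   of a planted protein in its enriched group.
#' @param de_lt_share probability that a planted protein is LT-enriched
#'   (default 0.7, mirroring the predominance of metastasis-enriched
#'   candidates).
#' @param dropout list describing the detection-dropout rule:
#'   `list(type = "none")` or `list(type = "expcount", max = , scale = )`
#'   where the per-sample dropout probability is
#'   `max * exp(-lambda / scale)` for expected count `lambda`.
#' @param length_meanlog,length_sdlog log-normal parameters of protein
#'   length in amino acids (truncated below at 50).
#' @param length_coupling if `TRUE`, expected counts are additionally scaled
#'   by `length / 400` (longer proteins yield more spectra); default
#'   `FALSE`, so the NSAF length correction is exercised both ways.
#' @param seed integer seed; together with the config it fully determines
#'   the output.
#' @return validated list of class `"count_sim_config"`.
#' @export
count_sim_config <- function(n_proteins, n_cases = 7,
                             baseline_meanlog = log(2.5),
                             baseline_sdlog = 1.2,
                             lt_depth_factor = 1.25,
                             de_fraction = 0.03, de_fold = 4,
                             de_lt_share = 0.7,
                             dropout = list(type = "expcount", max = 0.85,
                                            scale = 8),
                             length_meanlog = log(400),
                             length_sdlog = 0.45,
                             length_coupling = FALSE,
                             seed = 1) {
  check_pos(n_proteins, "n_proteins", int = TRUE)
  check_pos(n_cases, "n_cases", int = TRUE)
  check_prob(de_fraction, "de_fraction")
  check_prob(de_lt_share, "de_lt_share")
  if (de_fold <= 1) stop_config("'de_fold' must be > 1")
  check_pos(lt_depth_factor, "lt_depth_factor")
  if (!is.list(dropout) || !dropout$type %in% c("none", "expcount"))
    stop_config("'dropout' must be list(type = 'none') or list(type = 'expcount', max =, scale =)")
  if (dropout$type == "expcount") {
    check_prob(dropout$max, "dropout$max")
    check_pos(dropout$scale, "dropout$scale")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 n_cases = as.integer(n_cases),
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 lt_depth_factor = lt_depth_factor,
                 de_fraction = de_fraction, de_fold = de_fold,
                 de_lt_share = de_lt_share, dropout = dropout,
                 length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog,
                 length_coupling = length_coupling,
                 seed = as.integer(seed)),
            class = "count_sim_config")
}

#' Simulate a paired spectral-count matrix with planted differential proteins
#'
#' @param config a [count_sim_config()].
#' @return list with `matrix` (a [count_matrix()]), `annotation` (an
#'   [annotation_table()] of simulated lengths) and `truth` (class
#'   `"simulation_truth"`: data.frame `de` of planted accessions with
#'   direction and fold, plus the config).
#' @examples
#' sim <- simulate_counts(count_sim_config(n_proteins = 500, seed = 42))
#' sim$matrix
#' head(sim$truth$de)
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "count_sim_config"))
  with_seed(config$seed, {
    n <- config$n_proteins
    m <- config$n_cases
    acc <- sprintf("SP%05d", seq_len(n))
    lengths <- pmax(50L, as.integer(round(
      stats::rlnorm(n, config$length_meanlog, config$length_sdlog))))
    lambda_pt <- stats::rlnorm(n, config$baseline_meanlog,
                               config$baseline_sdlog)
    if (config$length_coupling) lambda_pt <- lambda_pt * lengths / 400
    lambda_lt <- lambda_pt * config$lt_depth_factor

    n_de <- round(config$de_fraction * n)
    de_idx <- if (n_de > 0) sample.int(n, n_de) else integer(0)
    de_dir <- character(0)
    if (n_de > 0) {
      lt_up <- stats::runif(n_de) < config$de_lt_share
      de_dir <- ifelse(lt_up, "LT", "PT")
      lambda_lt[de_idx[lt_up]] <- lambda_lt[de_idx[lt_up]] * config$de_fold
      lambda_pt[de_idx[!lt_up]] <- lambda_pt[de_idx[!lt_up]] * config$de_fold
    }

    draw_group <- function(lambda) {
      counts <- matrix(stats::rpois(n * m, rep(lambda, m)), nrow = n)
      if (config$dropout$type == "expcount") {
        p_drop <- config$dropout$max * exp(-lambda / config$dropout$scale)
        drop <- matrix(stats::runif(n * m) < rep(p_drop, m), nrow = n)
        counts[drop] <- 0L
      }
      counts
    }
    pt <- draw_group(lambda_pt)
    lt <- draw_group(lambda_lt)
    counts <- cbind(pt, lt)
    dimnames(counts) <- list(acc, c(sprintf("PT_c%d", seq_len(m)),
                                    sprintf("LT_c%d", seq_len(m))))
    mat <- count_matrix(counts,
                        group = rep(c("PT", "LT"), each = m),
                        case = rep(sprintf("c%d", seq_len(m)), 2L))
    truth <- structure(list(
      de = data.frame(accession = acc[de_idx], direction = de_dir,
                      fold = rep(config$de_fold, n_de),
                      stringsAsFactors = FALSE),
      config = config), class = "simulation_truth")
    list(matrix = mat,
         annotation = annotation_table(acc, lengths,
                                       symbol = sub("^SP", "GENE", acc)),
         truth = truth)
  })
}

#' Count-simulator configuration calibrated to a two-group FFPE discovery set
#'
#' Returns a [count_sim_config()] whose dropout and abundance parameters were
#' calibrated by simulation so that the identification Venn partition of the
#' generated matrices matches a paired PT/LT FFPE discovery experiment:
#' roughly 2,600-3,000 proteins identified per group with about half the
#' union shared (target fractions 19.6% PT-only / 29.6% LT-only / 50.8%
#' shared). The frozen parameters ship as a plain-text fixture in
#' `inst/extdata/calibrated_count_config.json`.
#'
#' @param seed seed for the returned config.
#' @param n_proteins universe size (default as calibrated).
#' @param de_fraction,de_fold planted-effect overrides.
#' @return a [count_sim_config()].
#' @export
calibrated_count_config <- function(seed = 1, n_proteins = NULL,
                                    de_fraction = 0.03, de_fold = 4) {
  path <- system.file("extdata", "calibrated_count_config.json",
                      package = "speccount", mustWork = TRUE)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  count_sim_config(
    n_proteins = if (is.null(n_proteins)) p$n_proteins else n_proteins,
    n_cases = p$n_cases,
    baseline_meanlog = p$baseline_meanlog, baseline_sdlog = p$baseline_sdlog,
    lt_depth_factor = p$lt_depth_factor,
    de_fraction = de_fraction, de_fold = de_fold,
    dropout = list(type = "expcount", max = p$dropout_max,
                   scale = p$dropout_scale),
    seed = seed)
}

#' Configuration for the patient-cohort simulator
#'
#' Describes a surgical cohort with liver-metastasis outcomes generated from
#' a proportional-hazards model. A fraction of patients present with
#' synchronous liver metastasis (present at resection; they get no liver-RFS
#' time and are excluded from survival analyses downstream). For the rest,
#' time to liver recurrence is exponential with hazard
#' `baseline_rate * exp(marker_log_hr * positive + size_log_hr * (size >= size_cutoff))`,
#' administratively censored; whether a patient ends up "metachronous" or
#' "none" is an outcome of this race, so planted hazard ratios naturally
#' enrich marker-positives among metachronous patients.
#'
#' @param n_patients cohort size (default 70).
#' @param p_synchronous probability of synchronous metastasis at baseline
#'   (default 8/70).
#' @param marker_name symbol of the simulated immunohistochemistry marker.
#' @param marker_positive_rate named numeric: positivity probability for
#'   `synchronous` patients (set at baseline) and `baseline` for everyone
#'   else; the metachronous-vs-none split emerges from the hazard model.
#' @param baseline_rate exponential hazard of liver recurrence per month for
#'   marker-negative, small-tumor patients.
#' @param marker_log_hr,size_log_hr planted log hazard ratios.
#' @param size_cutoff tumor-size threshold (mm) carrying `size_log_hr`.
#' @param censoring `list(type = "uniform", min =, max =)` months, or
#'   `list(type = "point", at =)`, or `list(type = "exponential", rate =)`;
#'   administrative censoring of both liver-RFS and OS.
#' @param os_rate exponential hazard of death per month (independent of the
#'   recurrence process; kept simple since OS is not the planted endpoint).
#' @param ki67_meanlog,ki67_sdlog,size_meanlog,size_sdlog log-normal
#'   covariate laws (Ki-67 %, tumor size mm).
#' @param invasion_rates named probabilities for `lymph_node`, `vascular`,
#'   `lymphatic`.
#' @param seed integer seed.
#' @return validated list of class `"cohort_sim_config"`.
#' @export
cohort_sim_config <- function(n_patients = 70, p_synchronous = 8 / 70,
                              marker_name = "M1",
                              marker_positive_rate = c(synchronous = 0.875,
                                                       baseline = 0.40),
                              baseline_rate = 5e-4,
                              marker_log_hr = log(6.19),
                              size_log_hr = log(4.63),
                              size_cutoff = 42,
                              censoring = list(type = "uniform", min = 6,
                                               max = 240),
                              os_rate = 2e-3,
                              ki67_meanlog = log(4), ki67_sdlog = 1.1,
                              size_meanlog = log(25), size_sdlog = 0.65,
                              invasion_rates = c(lymph_node = 0.17,
                                                 vascular = 0.45,
                                                 lymphatic = 0.30),
                              seed = 1) {
  check_pos(n_patients, "n_patients", int = TRUE)
  check_prob(p_synchronous, "p_synchronous")
  for (nm in c("synchronous", "baseline"))
    check_prob(marker_positive_rate[[nm]], paste0("marker_positive_rate$", nm))
  check_pos(baseline_rate, "baseline_rate")
  check_pos(os_rate, "os_rate")
  check_pos(size_cutoff, "size_cutoff")
  if (!is.list(censoring) ||
      !censoring$type %in% c("uniform", "point", "exponential"))
    stop_config("'censoring' must be a list with type uniform/point/exponential")
  if (censoring$type == "uniform") {
    check_pos(censoring$min, "censoring$min"); check_pos(censoring$max, "censoring$max")
    if (censoring$min >= censoring$max)
      stop_config("censoring window must have min < max")
  }
  if (censoring$type == "point") check_pos(censoring$at, "censoring$at")
  if (censoring$type == "exponential") check_pos(censoring$rate, "censoring$rate")
  for (nm in c("lymph_node", "vascular", "lymphatic"))
    check_prob(invasion_rates[[nm]], paste0("invasion_rates$", nm))
  structure(list(n_patients = as.integer(n_patients),
                 p_synchronous = p_synchronous, marker_name = marker_name,
                 marker_positive_rate = marker_positive_rate,
                 baseline_rate = baseline_rate,
                 marker_log_hr = marker_log_hr, size_log_hr = size_log_hr,
                 size_cutoff = size_cutoff, censoring = censoring,
                 os_rate = os_rate,
                 ki67_meanlog = ki67_meanlog, ki67_sdlog = ki67_sdlog,
                 size_meanlog = size_meanlog, size_sdlog = size_sdlog,
                 invasion_rates = invasion_rates, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Simulate a surgical cohort with planted hazard ratios
#'
#' @param config a [cohort_sim_config()].
#' @return list with `cohort` (a cohort table, see [read_cohort()] for the
#'   schema) and `truth` (class `"simulation_truth"`: `planted_hrs`, a named
#'   vector of the true hazard ratios, plus the config).
#' @examples
#' sim <- simulate_cohort(cohort_sim_config(n_patients = 70, seed = 7))
#' table(sim$cohort$group)
#' sim$truth$planted_hrs
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  with_seed(config$seed, {
    n <- config$n_patients
    sync <- stats::runif(n) < config$p_synchronous
    ki67 <- pmin(100, round(stats::rlnorm(n, config$ki67_meanlog,
                                          config$ki67_sdlog), 1))
    size <- pmax(5, round(stats::rlnorm(n, config$size_meanlog,
                                        config$size_sdlog)))
    lymph_node <- as.integer(stats::runif(n) < config$invasion_rates[["lymph_node"]])
    vascular <- as.integer(stats::runif(n) < config$invasion_rates[["vascular"]])
    lymphatic <- as.integer(stats::runif(n) < config$invasion_rates[["lymphatic"]])
    marker <- as.integer(stats::runif(n) < ifelse(
      sync, config$marker_positive_rate[["synchronous"]],
      config$marker_positive_rate[["baseline"]]))

    hazard <- config$baseline_rate *
      exp(config$marker_log_hr * marker +
          config$size_log_hr * (size >= config$size_cutoff))
    t_event <- stats::rexp(n, hazard)
    t_cens <- switch(config$censoring$type,
      uniform = stats::runif(n, config$censoring$min, config$censoring$max),
      point = rep(config$censoring$at, n),
      exponential = stats::rexp(n, config$censoring$rate))
    # month-resolution follow-up, kept strictly positive
    rfs_time <- pmax(round(pmin(t_event, t_cens), 1), 1e-3)
    rfs_event <- as.integer(t_event <= t_cens)
    group <- ifelse(sync, "synchronous",
                    ifelse(rfs_event == 1, "metachronous", "none"))
    rfs_time[sync] <- NA_real_
    rfs_event[sync] <- NA_integer_

    t_death <- stats::rexp(n, config$os_rate)
    os_time <- pmax(round(pmin(t_death, t_cens), 1), 1e-3)
    death <- as.integer(t_death <= t_cens)

    grade <- sample(c("G1", "G2", "G3"), n, replace = TRUE,
                    prob = c(0.50, 0.42, 0.08))
    stage <- ifelse(sync, "IV",
                    sample(c("I", "II", "III"), n, replace = TRUE,
                           prob = c(0.45, 0.40, 0.15)))
    cohort <- data.frame(
      patient_id = sprintf("PT%03d", seq_len(n)),
      group = group,
      gender = sample(c("male", "female"), n, replace = TRUE),
      age = pmin(90, pmax(20, round(stats::rnorm(n, 55, 15)))),
      function_type = sample(c("NF", "insulinoma", "gastrinoma",
                               "glucagonoma"),
                             n, replace = TRUE,
                             prob = c(0.70, 0.24, 0.04, 0.02)),
      who_grade = grade,
      ki67 = ki67,
      mitotic_count = stats::rpois(n, 1.5),
      tumor_size = size,
      lymph_node_metastasis = lymph_node,
      vascular_invasion = vascular,
      lymphatic_invasion = lymphatic,
      enets_stage = stage,
      liver_met_at_diagnosis = as.integer(sync),
      liver_rfs_months = rfs_time,
      liver_recurrence = rfs_event,
      os_months = os_time,
      death = death,
      stringsAsFactors = FALSE)
    cohort[[paste0("marker_", config$marker_name)]] <- marker
    truth <- structure(list(
      planted_hrs = c(marker = exp(config$marker_log_hr),
                      size_ge_cutoff = exp(config$size_log_hr)),
      config = config), class = "simulation_truth")
    list(cohort = as_cohort_table(cohort), truth = truth)
  })
}
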