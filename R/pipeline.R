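#' Two-stage pipeline configuration
#'
#' Bundles everything needed to run the discovery (spectral counting) and
#' validation (clinicopathological survival) stages end to end. Each stage
#' takes exactly one input source: real files, a simulation config, or — for
#' the discovery stage — published per-group identification set sizes when
#' only presence lists are available ("printed-set mode").
#'
#' @param discovery one of: `list(counts =, sample_map =, lengths = | fasta =)`
#'   (paths), `list(simulate = count_sim_config(...))`, or
#'   `list(set_sizes = c(n_pt, n_lt, n_shared))`.
#' @param clinical one of: `list(cohort = path)` or
#'   `list(simulate = cohort_sim_config(...))`, plus `marker` (marker symbol
#'   to validate; defaults to the simulated marker where applicable).
#' @param f,rsc_threshold,alpha,correction,mode,spi_min,nsaf_ratio_min
#'   discovery-stage parameters, see [spectral_dea()].
#' @param landmark_months,ties,gate_alpha validation-stage parameters, see
#'   [liver_rfs_analysis()].
#' @param seed integer master seed; simulation configs without their own
#'   seed inherit it.
#' @param out_dir report directory, or `NULL` to skip writing.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(discovery = NULL, clinical = NULL,
                            f = 0.5, rsc_threshold = 1, alpha = 0.05,
                            correction = "none", mode = "pooled",
                            spi_min = NULL, nsaf_ratio_min = NULL,
                            landmark_months = 120, ties = "efron",
                            gate_alpha = 0.05,
                            seed = 1, out_dir = NULL) {
  check_pos(f, "f"); check_pos(rsc_threshold, "rsc_threshold")
  check_prob(alpha, "alpha"); check_prob(gate_alpha, "gate_alpha")
  if (!is.null(discovery)) {
    src <- intersect(names(discovery), c("counts", "simulate", "set_sizes"))
    if (length(src) != 1L)
      stop_config("discovery input must be exactly one of counts/simulate/set_sizes")
  }
  if (!is.null(clinical)) {
    src <- intersect(names(clinical), c("cohort", "simulate"))
    if (length(src) != 1L)
      stop_config("clinical input must be exactly one of cohort/simulate")
  }
  structure(list(discovery = discovery, clinical = clinical,
                 spectral = list(f = f, rsc_threshold = rsc_threshold,
                                 alpha = alpha, correction = correction,
                                 mode = mode, spi_min = spi_min,
                                 nsaf_ratio_min = nsaf_ratio_min),
                 survival = list(landmark_months = landmark_months,
                                 ties = ties, gate_alpha = gate_alpha),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file mirrors the arguments of [pipeline_config()]; nested
#' `discovery$simulate` / `clinical$simulate` blocks are passed to
#' [count_sim_config()] / [cohort_sim_config()].
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (!is.null(raw$discovery$simulate))
    raw$discovery$simulate <- do.call(count_sim_config, raw$discovery$simulate)
  if (!is.null(raw$clinical$simulate))
    raw$clinical$simulate <- do.call(cohort_sim_config, raw$clinical$simulate)
  do.call(pipeline_config, raw)
}

#' Run the discovery stage
#'
#' Resolves the configured input (files, simulation, or printed set sizes),
#' fits [spectral_dea()], and writes a report: `differential.tsv` with
#' columns accession, symbol, n_PT, n_LT, Rsc, fold_change, direction, G, p,
#' q, NSAF_PT, NSAF_LT, SpI, selected; `selected.tsv` (sorted candidates);
#' `venn.tsv`; and a JSON summary echoing the config and seed. In
#' printed-set mode only the Venn partition is computed.
#'
#' @param config a [pipeline_config()] with a `discovery` block.
#' @return list with `fit` (NULL in printed-set mode), `venn`, `selected`,
#'   `truth` (when simulated) and `report_dir`.
#' @export
run_discovery <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  d <- config$discovery
  if (is.null(d)) stop_config("no discovery input configured")
  sp <- config$spectral
  truth <- NULL
  if (!is.null(d$set_sizes)) {
    s <- as.numeric(d$set_sizes)
    venn <- venn_from_sizes(s[1L], s[2L], s[3L])
    message(sprintf("[discovery] printed-set mode: union %d", venn$total))
    res <- list(fit = NULL, venn = venn, selected = NULL, truth = NULL)
  } else {
    if (!is.null(d$simulate)) {
      sim_cfg <- d$simulate
      if (is.null(sim_cfg$seed)) sim_cfg$seed <- config$seed
      sim <- simulate_counts(sim_cfg)
      mat <- sim$matrix; ann <- sim$annotation; truth <- sim$truth
    } else {
      mat <- read_count_table(d$counts, d$sample_map)
      ann <- if (!is.null(d$fasta)) lengths_from_fasta(d$fasta)
             else if (!is.null(d$lengths)) read_annotation(d$lengths)
    }
    fit <- spectral_dea(mat, ann, f = sp$f,
                        rsc_threshold = sp$rsc_threshold, alpha = sp$alpha,
                        correction = sp$correction, mode = sp$mode,
                        spi_min = sp$spi_min,
                        nsaf_ratio_min = sp$nsaf_ratio_min)
    sel <- summary(fit)
    message(sprintf(
      "[discovery] %d proteins (PT-only %d, LT-only %d, shared %d); |Rsc|>%g & p<%g -> %d selected (%d PT, %d LT)",
      fit$venn$total, fit$venn$PT_only, fit$venn$LT_only, fit$venn$shared,
      sp$rsc_threshold, sp$alpha, nrow(sel),
      sum(sel$direction == "PT"), sum(sel$direction == "LT")))
    res <- list(fit = fit, venn = fit$venn, selected = sel, truth = truth)
  }
  if (!is.null(config$out_dir)) {
    dir <- file.path(config$out_dir, "discovery")
    report <- list(
      config = config_echo(config),
      venn = data.frame(partition = c("PT_only", "LT_only", "shared", "total"),
                        n = c(res$venn$PT_only, res$venn$LT_only,
                              res$venn$shared, res$venn$total),
                        pct = c(res$venn$pct_PT_only, res$venn$pct_LT_only,
                                res$venn$pct_shared, 100)))
    if (!is.null(res$fit)) {
      report$differential <- res$fit$table
      report$selected <- res$selected
    }
    write_report(report, dir)
    res$report_dir <- dir
  }
  res
}

#' Run the validation stage
#'
#' Loads or simulates the cohort, writes a three-group comparison of every
#' clinicopathological factor (chi-square/exact test for categorical
#' factors, Kruskal-Wallis for continuous ones), then runs the
#' marker-stratified liver-RFS analysis of [liver_rfs_analysis()]:
#' synchronous-metastasis patients excluded, ROC/Youden cutoffs for Ki-67
#' and tumor size, Kaplan-Meier + log-rank by marker positivity, univariate
#' Cox screening and the multivariate model over univariately significant
#' covariates.
#'
#' @param config a [pipeline_config()] with a `clinical` block.
#' @return list with `cohort`, `group_comparison`, `rfs` (a
#'   [liver_rfs_analysis()] result), `truth` (when simulated) and
#'   `report_dir`.
#' @export
run_validation <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cl <- config$clinical
  if (is.null(cl)) stop_config("no clinical input configured")
  truth <- NULL
  if (!is.null(cl$simulate)) {
    sim_cfg <- cl$simulate
    if (is.null(sim_cfg$seed)) sim_cfg$seed <- config$seed
    sim <- simulate_cohort(sim_cfg)
    cohort <- sim$cohort; truth <- sim$truth
    marker <- if (!is.null(cl$marker)) cl$marker else sim_cfg$marker_name
  } else {
    cohort <- read_cohort(cl$cohort)
    marker <- cl$marker
  }
  if (is.null(marker)) stop_config("no marker specified for validation")
  gc_tab <- cohort_group_comparison(cohort)
  sv <- config$survival
  rfs <- liver_rfs_analysis(cohort, marker,
                            landmark_months = sv$landmark_months,
                            ties = sv$ties, gate_alpha = sv$gate_alpha)
  message(sprintf(
    "[validation] n=%d (groups %s); marker %s; %d excluded, %d events; log-rank p = %s",
    nrow(cohort),
    paste(table(factor(cohort$group,
                       c("synchronous", "metachronous", "none"))),
          collapse = "/"),
    marker, rfs$n_excluded, rfs$n_events,
    if (is.null(rfs$logrank)) "NA" else format(rfs$logrank$p, digits = 3)))
  res <- list(cohort = cohort, group_comparison = gc_tab, rfs = rfs,
              truth = truth)
  if (!is.null(config$out_dir)) {
    dir <- file.path(config$out_dir, "validation")
    km_tabs <- lapply(rfs$km, function(k) if (!is.null(k)) k$table)
    report <- list(config = config_echo(config),
                   group_comparison = gc_tab,
                   univariate = rfs$univariate)
    if (!is.null(rfs$multivariate))
      report$multivariate <- rfs$multivariate$table
    for (lev in names(km_tabs))
      if (!is.null(km_tabs[[lev]]))
        report[[paste0("km_", lev)]] <- km_tabs[[lev]]
    report$tests <- list(
      logrank = if (!is.null(rfs$logrank)) unclass(rfs$logrank),
      landmark = rfs$landmark,
      ki67_cutoff = rfs$ki67_cutoff, size_cutoff = rfs$size_cutoff)
    write_report(report, dir)
    res$report_dir <- dir
  }
  res
}

#' @rdname run_discovery
#' @export
run_pipeline <- function(config) {
  out <- list()
  if (!is.null(config$discovery)) out$discovery <- run_discovery(config)
  if (!is.null(config$clinical)) out$validation <- run_validation(config)
  out
}

#' Compare clinicopathological factors across metastasis groups
#'
#' One row per factor with the p-value of the appropriate three-group test:
#' [contingency_test()] (chi-square, exact fallback when any expected cell
#' is below 5) for categorical factors and marker positivity,
#' [rank_test()] (Kruskal-Wallis) for continuous ones.
#'
#' @param cohort a cohort table.
#' @return data.frame with `factor`, `test`, `p`.
#' @export
cohort_group_comparison <- function(cohort) {
  g <- factor(cohort$group, c("synchronous", "metachronous", "none"))
  cat_p <- function(v) {
    tab <- table(v, g)
    ct <- contingency_test(tab, method = "auto")
    c(test = ct$method, p = ct$p)
  }
  num_p <- function(v) {
    rt <- rank_test(v, g)
    c(test = rt$method, p = rt$p)
  }
  rows <- list(
    gender = cat_p(cohort$gender),
    age = num_p(cohort$age),
    function_type = cat_p(cohort$function_type),
    who_grade = cat_p(cohort$who_grade),
    ki67 = num_p(cohort$ki67),
    mitotic_count = num_p(cohort$mitotic_count),
    tumor_size = num_p(cohort$tumor_size),
    lymph_node_metastasis = cat_p(cohort$lymph_node_metastasis),
    vascular_invasion = cat_p(cohort$vascular_invasion),
    lymphatic_invasion = cat_p(cohort$lymphatic_invasion),
    enets_stage = cat_p(cohort$enets_stage))
  for (m in grep("^marker_", names(cohort), value = TRUE))
    rows[[m]] <- cat_p(cohort[[m]])
  data.frame(factor = names(rows),
             test = vapply(rows, `[[`, character(1), "test"),
             p = as.numeric(vapply(rows, `[[`, character(1), "p")),
             row.names = NULL, stringsAsFactors = FALSE)
}

config_echo <- function(config) {
  e <- unclass(config)
  e$discovery <- echo_block(e$discovery)
  e$clinical <- echo_block(e$clinical)
  e$out_dir <- NULL  # report content must not depend on where it is written
  e
}

echo_block <- function(b) {
  if (!is.null(b$simulate)) b$simulate <- unclass(b$simulate)
  b
}
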