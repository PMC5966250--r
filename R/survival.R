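#' Kaplan-Meier product-limit estimate
#'
#' Thin, validated wrapper around [survival::survfit()] returning a plain
#' step-function table. Subjects censored at an event time remain at risk for
#' the event at that time (the standard convention). The curve is
#' right-continuous: S(t) at an event time already includes the drop.
#'
#' @param times follow-up times (months, > 0).
#' @param events event indicator (0 = censored, 1 = event).
#' @return object of class `"km_curve"`: data.frame with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`, `greenwood_se`.
#' @examples
#' km <- km_estimate(c(5, 10, 15, 20), c(1, 1, 0, 1))
#' survival_at(km, c(5, 10, 20))  # 0.75 0.50 0.00
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop_config("empty survival input")
  if (length(times) != length(events))
    stop_config("'times' and 'events' must have equal length")
  if (any(is.na(times)) || any(times <= 0))
    stop_config("all times must be positive and non-missing")
  if (!all(events %in% c(0, 1)))
    stop_config("'events' must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  tab <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv,
                    greenwood_se = fit$surv * fit$std.err)
  structure(list(table = tab, n = length(times), n_events = sum(events)),
            class = "km_curve")
}

#' @rdname km_estimate
#' @param curve a `km_curve`.
#' @param t times at which to read the step function (S(t) = 1 before the
#'   first event; beyond the last follow-up time the last value is carried
#'   forward).
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  tab <- curve$table
  if (nrow(tab) == 0L) return(rep(1, length(t)))
  sf <- stats::stepfun(tab$time, c(1, tab$surv))
  sf(t)
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d\n", x$n, x$n_events))
  print(utils::head(x$table, 10L))
  if (nrow(x$table) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x$table) - 10L))
  invisible(x)
}

#' Log-rank test
#'
#' Standard (O - E)^2 / V chi-square comparison of survival between groups
#' via [survival::survdiff()], df = number of groups - 1. The degenerate
#' all-censored case (no events anywhere) is reported as statistic 0, p = 1.
#'
#' @inheritParams km_estimate
#' @param group group labels, at least two non-empty groups.
#' @return list of class `"log_rank"`: `chisq`, `df`, `p`.
#' @export
log_rank <- function(times, events, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2L)
    stop_config("log-rank test needs at least two groups")
  if (any(table(group) == 0L))
    stop_config("every group must be non-empty")
  if (length(unique(c(length(times), length(events), length(group)))) != 1L)
    stop_config("'times', 'events' and 'group' must have equal length")
  if (sum(events) == 0) {
    out <- list(chisq = 0, df = nlevels(group) - 1L, p = 1)
  } else {
    sd <- survival::survdiff(survival::Surv(times, events) ~ group)
    df <- nlevels(group) - 1L
    out <- list(chisq = unname(sd$chisq), df = df,
                p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
  }
  structure(out, class = "log_rank")
}

#' @export
print.log_rank <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.4g\n",
              x$chisq, x$df, x$p))
  invisible(x)
}

#' Cox proportional-hazards fit with diagnostics
#'
#' Fits [survival::coxph()] (Efron tie handling by default, Breslow
#' optional) and returns hazard ratios with Wald 95% confidence intervals
#' and p-values. Constant covariates are dropped from the fit and flagged
#' (their HR is undefined). Monotone partial likelihood (perfect
#' separation), which would otherwise surface as an absurd hazard ratio, is
#' detected from the coxph convergence warnings and from runaway
#' coefficients, and flagged per covariate.
#'
#' @param covariates data.frame or matrix of numeric covariates (columns are
#'   model terms; binary factors must be coded 0/1 upstream).
#' @inheritParams km_estimate
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return object of class `"cox_fit"`: `$table` with `term`, `coef`, `HR`,
#'   `se`, `lower`, `upper`, `p`, `flag`; plus `loglik`, `n`, `n_events`,
#'   `converged`.
#' @export
cox_fit <- function(covariates, times, events, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  if (any(is.na(covariates)))
    stop_config("missing covariate values are not allowed")
  if (sum(events) == 0)
    stop_config("no events: the Cox partial likelihood is degenerate (all subjects censored)")
  if (length(times) != nrow(covariates))
    stop_config("covariate rows must match the number of subjects")
  terms <- names(covariates)
  constant <- vapply(covariates, function(v) length(unique(v)) == 1L, logical(1))
  fit_terms <- terms[!constant]
  warn_msgs <- character(0)
  fit <- NULL
  if (length(fit_terms) > 0L) {
    dat <- cbind(covariates[fit_terms], .time = times, .event = events)
    fml <- stats::as.formula(paste(
      "survival::Surv(.time, .event) ~",
      paste(sprintf("`%s`", fit_terms), collapse = " + ")))
    fit <- withCallingHandlers(
      survival::coxph(fml, data = dat, ties = ties),
      warning = function(w) {
        warn_msgs <<- c(warn_msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  tab <- data.frame(term = terms, coef = NA_real_, HR = NA_real_,
                    se = NA_real_, lower = NA_real_, upper = NA_real_,
                    p = NA_real_, flag = "", stringsAsFactors = FALSE)
  tab$flag[constant] <- "constant covariate: HR not identifiable"
  if (!is.null(fit)) {
    i <- match(fit_terms, terms)
    cf <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    tab$coef[i] <- cf
    tab$HR[i] <- exp(cf)
    tab$se[i] <- se
    tab$lower[i] <- exp(cf - stats::qnorm(0.975) * se)
    tab$upper[i] <- exp(cf + stats::qnorm(0.975) * se)
    tab$p[i] <- 2 * stats::pnorm(-abs(cf / se))
    runaway <- abs(cf) > 13 | se > 1e3
    sep_warn <- any(grepl("converged before variable|infinite", warn_msgs))
    if (any(runaway) || sep_warn) {
      j <- i[runaway | sep_warn]
      tab$flag[j] <- paste0(tab$flag[j],
        "possible monotone likelihood (separation): HR unreliable")
    }
  }
  structure(list(table = tab,
                 loglik = if (is.null(fit)) NA_real_ else fit$loglik[2L],
                 n = length(times), n_events = sum(events),
                 ties = ties,
                 converged = is.null(fit) ||
                   !any(grepl("did not converge", warn_msgs)),
                 warnings = warn_msgs),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$n_events))
  tab <- x$table
  tab$`HR (95% CI)` <- ifelse(is.na(tab$HR), "-",
    sprintf("%.*g (%.*g-%.*g)", digits, tab$HR, digits, tab$lower,
            digits, tab$upper))
  print(tab[, c("term", "HR (95% CI)", "p", "flag")], row.names = FALSE)
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) {
  stats::setNames(object$table$coef, object$table$term)
}

#' ROC analysis with Youden-optimal cutoff
#'
#' Builds the empirical ROC curve of a continuous marker against a binary
#' outcome, classifying "positive" when `value >= cutoff` (the convention
#' behind rules like tumor size >= 42 mm). The AUC is the area under the
#' empirical ROC polygon, equal to the Mann-Whitney probability with ties
#' counted 1/2; its p-value against AUC = 0.5 comes from the two-sided
#' Mann-Whitney U test. The reported cutoff maximizes Youden's
#' J = sensitivity + specificity - 1 over the observed-value midpoints (plus
#' the all-positive boundary), ties broken toward the lower cutoff.
#'
#' @param values numeric marker values.
#' @param outcome binary outcome (0/1); both classes must be present.
#' @return list of class `"roc_cutoff"`: `auc`, `cutoff`, `sensitivity`,
#'   `specificity`, `youden`, `p`, and the swept `curve` data.frame.
#' @examples
#' roc_cutoff(c(1, 2, 4, 3, 5), c(0, 0, 0, 1, 1))
#' @export
roc_cutoff <- function(values, outcome) {
  if (length(values) != length(outcome))
    stop_config("'values' and 'outcome' must have equal length")
  if (any(is.na(values)) || any(is.na(outcome)))
    stop_config("missing marker values or outcomes are not allowed")
  if (!all(outcome %in% c(0, 1)) || length(unique(outcome)) < 2L)
    stop_config("'outcome' must be 0/1 with both classes present")
  pos <- values[outcome == 1]
  neg <- values[outcome == 0]
  u <- sort(unique(values))
  cand <- c(u[1L], if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2)
  sens <- vapply(cand, function(cc) mean(pos >= cc), numeric(1))
  spec <- vapply(cand, function(cc) mean(neg < cc), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1L]  # candidates ascend, so first = lowest cutoff
  # empirical ROC polygon over thresholds (>= v), plus the (0,0) corner
  thr <- c(Inf, rev(u))
  tpr <- vapply(thr, function(cc) mean(pos >= cc), numeric(1))
  fpr <- vapply(thr, function(cc) mean(neg >= cc), numeric(1))
  tpr <- c(tpr, 1); fpr <- c(fpr, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  p <- suppressWarnings(stats::wilcox.test(pos, neg)$p.value)
  structure(list(auc = auc, cutoff = cand[best], sensitivity = sens[best],
                 specificity = spec[best], youden = j[best], p = p,
                 curve = data.frame(cutoff = cand, sensitivity = sens,
                                    specificity = spec, youden = j)),
            class = "roc_cutoff")
}

#' @export
print.roc_cutoff <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (p = %.3g vs 0.5)\n", x$auc, x$p))
  cat(sprintf("Youden-optimal cutoff (>=): %g (sens %.3f, spec %.3f)\n",
              x$cutoff, x$sensitivity, x$specificity))
  invisible(x)
}

#' Contingency-table and rank tests for cohort comparisons
#'
#' `contingency_test()` compares categorical variables across groups:
#' Pearson's chi-square (no Yates correction by default) or Fisher's exact
#' test. `method = "auto"` uses chi-square unless any expected cell is below
#' 5, in which case it falls back to the exact test (valid for r x c
#' tables); `"fisher_2x2"` insists on a 2x2 table and errors otherwise.
#' `rank_test()` compares a continuous variable across groups:
#' Mann-Whitney U for two groups, Kruskal-Wallis for three or more
#' (`method = "auto"` picks by group count).
#'
#' @param table matrix of non-negative integer counts (categories x groups).
#' @param method see Details.
#' @param yates apply Yates continuity correction to the 2x2 chi-square.
#' @return list: `p`, `method`, and for chi-square `statistic` and `df`.
#' @export
contingency_test <- function(table,
                             method = c("auto", "chi2", "fisher_2x2", "exact"),
                             yates = FALSE) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (any(table < 0) || any(!is_wholenumber(table)))
    stop_config("contingency table must contain non-negative integers")
  if (method == "fisher_2x2" && !all(dim(table) == c(2L, 2L)))
    stop_config("method 'fisher_2x2' requires a 2x2 table, got %dx%d",
                nrow(table), ncol(table))
  if (method == "auto") {
    expected <- outer(rowSums(table), colSums(table)) / sum(table)
    method <- if (any(expected < 5)) "exact" else "chi2"
  }
  if (method == "chi2") {
    ct <- suppressWarnings(stats::chisq.test(table, correct = yates))
    list(p = unname(ct$p.value), statistic = unname(ct$statistic),
         df = unname(ct$parameter), method = "chi2")
  } else {
    # large sparse r x c tables can exhaust the network-algorithm workspace;
    # fall back to the hybrid approximation, then to chi-square
    ft <- tryCatch(stats::fisher.test(table),
                   error = function(e) tryCatch(
                     stats::fisher.test(table, hybrid = TRUE),
                     error = function(e2) NULL))
    if (!is.null(ft))
      list(p = unname(ft$p.value), method = "fisher_exact")
    else {
      ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
      list(p = unname(ct$p.value), statistic = unname(ct$statistic),
           df = unname(ct$parameter), method = "chi2_fallback")
    }
  }
}

#' @rdname contingency_test
#' @param values numeric vector.
#' @param groups group labels.
#' @export
rank_test <- function(values, groups,
                      method = c("auto", "mann_whitney", "kruskal_wallis")) {
  method <- match.arg(method)
  groups <- as.factor(as.character(groups))
  k <- nlevels(groups)
  if (k < 2L) stop_config("rank test needs at least two groups")
  if (method == "auto")
    method <- if (k == 2L) "mann_whitney" else "kruskal_wallis"
  if (method == "mann_whitney") {
    if (k != 2L) stop_config("Mann-Whitney requires exactly two groups")
    ht <- suppressWarnings(
      stats::wilcox.test(values[groups == levels(groups)[1L]],
                         values[groups == levels(groups)[2L]]))
  } else {
    ht <- stats::kruskal.test(values, groups)
  }
  list(p = unname(ht$p.value), method = method)
}

#' Marker-stratified liver recurrence-free survival analysis
#'
#' The validation-stage workflow for one immunohistochemistry marker.
#' Patients with synchronous liver metastasis (metastasis already present at
#' resection) have no liver-RFS time and are excluded first. The remaining
#' cohort is analyzed as: Kaplan-Meier liver-RFS per positivity stratum with
#' a log-rank comparison and landmark survival read off the step function
#' (default 120 months, i.e. 10-year liver RFS); ROC/Youden cutoff discovery
#' dichotomizing Ki-67 and tumor size against the recurrence outcome;
#' univariate Cox screening of every covariate; and a multivariate Cox model
#' over the covariates with univariate Wald p below `gate_alpha`.
#'
#' @param cohort a cohort table from [read_cohort()] / [as_cohort_table()].
#' @param marker marker symbol (column `marker_<symbol>` must exist).
#' @param landmark_months time(s) at which landmark survival is reported.
#' @param ties Cox tie handling, `"efron"` (default) or `"breslow"`.
#' @param gate_alpha univariate p threshold for entry into the multivariate
#'   model, default 0.05.
#' @param ki67_cutoff,size_cutoff dichotomization cutoffs; `NULL` (default)
#'   discovers them by [roc_cutoff()] against the recurrence outcome.
#' @param force_covariates covariate names always entered into the
#'   multivariate model regardless of their univariate p.
#' @return object of class `"liver_rfs"`.
#' @export
liver_rfs_analysis <- function(cohort, marker, landmark_months = 120,
                               ties = "efron", gate_alpha = 0.05,
                               ki67_cutoff = NULL, size_cutoff = NULL,
                               force_covariates = NULL) {
  stopifnot(inherits(cohort, "cohort_table") || is.data.frame(cohort))
  mcol <- paste0("marker_", marker)
  if (!mcol %in% names(cohort))
    stop_config("marker column '%s' not found; available markers: %s", mcol,
                paste(grep("^marker_", names(cohort), value = TRUE),
                      collapse = ", "))
  n_excluded <- sum(cohort$group == "synchronous")
  d <- cohort[cohort$group != "synchronous", , drop = FALSE]
  if (nrow(d) == 0L) stop_config("no patients left after excluding synchronous metastasis")
  times <- d$liver_rfs_months
  events <- d$liver_recurrence
  if (any(is.na(times)) || any(is.na(events)))
    stop_config("missing liver-RFS time or event flag in non-synchronous patients")
  any_events <- sum(events) > 0

  roc <- list(ki67 = NULL, tumor_size = NULL)
  if (any_events) {
    if (is.null(ki67_cutoff)) {
      roc$ki67 <- roc_cutoff(d$ki67, events)
      ki67_cutoff <- roc$ki67$cutoff
    }
    if (is.null(size_cutoff)) {
      roc$tumor_size <- roc_cutoff(d$tumor_size, events)
      size_cutoff <- roc$tumor_size$cutoff
    }
  }

  pos <- d[[mcol]] == 1
  strata <- list()
  landmark <- list()
  for (lev in c("negative", "positive")) {
    sel <- if (lev == "positive") pos else !pos
    if (sum(sel) == 0L) { strata[lev] <- list(NULL); next }
    strata[[lev]] <- km_estimate(times[sel], events[sel])
    landmark[[lev]] <- stats::setNames(
      survival_at(strata[[lev]], landmark_months),
      paste0("S_", landmark_months, "m"))
  }
  empty_stratum <- any(vapply(strata, is.null, logical(1))) ||
    length(strata) < 2L
  logrank <- if (!empty_stratum)
    log_rank(times, events, ifelse(pos, "positive", "negative"))

  covs <- data.frame(
    functioning = as.integer(d$function_type != "NF"),
    grade_G2G3 = as.integer(d$who_grade %in% c("G2", "G3")),
    grade_G3 = as.integer(d$who_grade == "G3"),
    lymph_node_metastasis = d$lymph_node_metastasis,
    vascular_invasion = d$vascular_invasion,
    lymphatic_invasion = d$lymphatic_invasion,
    stage_III_IV = as.integer(d$enets_stage %in% c("III", "IV")))
  if (!is.null(ki67_cutoff))
    covs[[sprintf("ki67_ge_%g", ki67_cutoff)]] <- as.integer(d$ki67 >= ki67_cutoff)
  if (!is.null(size_cutoff))
    covs[[sprintf("size_ge_%gmm", size_cutoff)]] <- as.integer(d$tumor_size >= size_cutoff)
  covs[[marker]] <- as.integer(pos)

  uni <- NULL; multi <- NULL
  if (any_events) {
    uni_rows <- lapply(names(covs), function(term) {
      fit <- cox_fit(covs[term], times, events, ties = ties)
      fit$table
    })
    uni <- do.call(rbind, uni_rows)
    pass <- uni$term[!is.na(uni$p) & uni$p < gate_alpha & uni$flag == ""]
    pass <- union(pass, intersect(force_covariates, names(covs)))
    if (length(pass) >= 1L)
      multi <- cox_fit(covs[pass], times, events, ties = ties)
  }

  structure(list(marker = marker, n = nrow(d), n_excluded = n_excluded,
                 n_events = sum(events),
                 ki67_cutoff = ki67_cutoff, size_cutoff = size_cutoff,
                 roc = roc, km = strata, landmark = landmark,
                 logrank = logrank, empty_stratum = empty_stratum,
                 univariate = uni, multivariate = multi,
                 gate_alpha = gate_alpha,
                 landmark_months = landmark_months),
            class = "liver_rfs")
}

#' @export
print.liver_rfs <- function(x, ...) {
  cat(sprintf("Liver recurrence-free survival analysis: marker %s\n", x$marker))
  cat(sprintf("  %d patients analyzed (%d synchronous excluded), %d recurrences\n",
              x$n, x$n_excluded, x$n_events))
  if (!is.null(x$ki67_cutoff))
    cat(sprintf("  cutoffs: Ki-67 >= %g%%, tumor size >= %g mm\n",
                x$ki67_cutoff, x$size_cutoff))
  for (lev in names(x$landmark))
    cat(sprintf("  %s stratum: %s = %.1f%%\n", lev,
                names(x$landmark[[lev]])[1L], 100 * x$landmark[[lev]][[1L]]))
  if (!is.null(x$logrank))
    cat(sprintf("  log-rank p = %.4g\n", x$logrank$p))
  if (!is.null(x$multivariate)) {
    cat("  multivariate model:\n")
    print(x$multivariate)
  }
  invisible(x)
}

#' Plot marker-stratified Kaplan-Meier curves
#' @param x a `liver_rfs` result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.liver_rfs <- function(x, ...) {
  cols <- c(negative = "steelblue", positive = "firebrick")
  graphics::plot(NA, xlim = c(0, max(vapply(x$km, function(k)
                   if (is.null(k)) 0 else max(k$table$time), numeric(1)))),
                 ylim = c(0, 1), xlab = "Months after resection",
                 ylab = "Liver recurrence-free survival", ...)
  for (lev in names(x$km)) {
    k <- x$km[[lev]]
    if (is.null(k)) next
    graphics::lines(stats::stepfun(k$table$time, c(1, k$table$surv)),
                    do.points = FALSE, col = cols[[lev]])
  }
  graphics::legend("bottomleft", legend = names(x$km),
                   col = cols[names(x$km)], lty = 1, bty = "n")
  invisible(x)
}
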