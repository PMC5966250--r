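#' Spectral-counting differential expression analysis
#'
#' The central fitting function of the discovery stage. Counts are pooled
#' within each tissue group (primary tumor PT vs liver metastasis LT), and
#' for every protein the function computes the pseudo-count-corrected log2
#' ratio Rsc ([compute_rsc()]), the fold change `2^|Rsc|`, a likelihood-ratio
#' [g_test()] p-value with its BH-adjusted q-value, per-group NSAF relative
#' abundances ([compute_nsaf()], when lengths are supplied), and the spectral
#' index ([compute_spi()]). Candidates are flagged by the strict gate
#' `|Rsc| > rsc_threshold & p < alpha`.
#'
#' In the non-default `mode = "per_case"`, Rsc is instead the mean of
#' per-case Rsc values computed from each case's paired PT/LT columns (cases
#' lacking either column are skipped); the G-test, NSAF and SpI remain
#' pooled. This paired variant down-weights a single dominant case but has no
#' closed-form null, so selection still uses the pooled G-test p.
#'
#' @param x a [count_matrix()].
#' @param annotation optional [annotation_table()] with sequence lengths
#'   (required for NSAF; without it NSAF columns are NA).
#' @param f pseudo-count for Rsc, default 0.5.
#' @param rsc_threshold,alpha selection gate, defaults 1 and 0.05 (strict
#'   inequalities).
#' @param correction G-test variant, `"none"` (default) or `"williams"`.
#' @param mode `"pooled"` (default) or `"per_case"`.
#' @param spi_min,nsaf_ratio_min optional secondary screens passed to
#'   [select_candidates()].
#' @return object of class `"spectral_dea"`; the per-protein table is in
#'   `$table` (also via `as.data.frame()`), the Venn partition in `$venn`.
#' @seealso [select_candidates()], [venn_summary()]
#' @examples
#' cfg <- count_sim_config(n_proteins = 200, n_cases = 7, de_fraction = 0.1,
#'                         de_fold = 4, seed = 1)
#' sim <- simulate_counts(cfg)
#' fit <- spectral_dea(sim$matrix, sim$annotation)
#' fit
#' head(summary(fit))
#' @export
spectral_dea <- function(x, annotation = NULL, f = 0.5, rsc_threshold = 1,
                         alpha = 0.05, correction = c("none", "williams"),
                         mode = c("pooled", "per_case"),
                         spi_min = NULL, nsaf_ratio_min = NULL) {
  correction <- match.arg(correction)
  mode <- match.arg(mode)
  pooled <- pool_counts(x, f = f)
  pc <- pooled$counts
  if (mode == "pooled") {
    rsc <- compute_rsc(pc$n_PT, pc$n_LT, pooled$t_PT, pooled$t_LT, f = f)
  } else {
    rsc <- per_case_rsc(x, f = f)
  }
  gt <- g_test(pc$n_PT, pc$n_LT, pooled$t_PT, pooled$t_LT,
               correction = correction)
  spi <- compute_spi(x)
  if (!is.null(annotation)) {
    nsaf_pt <- compute_nsaf(stats::setNames(pc$n_PT, pc$accession), annotation)
    nsaf_lt <- compute_nsaf(stats::setNames(pc$n_LT, pc$accession), annotation)
    symbol <- annotation$symbol[match(pc$accession, annotation$accession)]
  } else {
    nsaf_pt <- nsaf_lt <- rep(NA_real_, nrow(pc))
    symbol <- rep(NA_character_, nrow(pc))
  }
  tab <- data.frame(
    accession = pc$accession, symbol = symbol,
    n_PT = pc$n_PT, n_LT = pc$n_LT,
    Rsc = rsc, fold_change = 2^abs(rsc),
    direction = ifelse(rsc > 0, "LT", ifelse(rsc < 0, "PT", "none")),
    G = gt$G, p = gt$p, q = stats::p.adjust(gt$p, method = "BH"),
    NSAF_PT = as.numeric(nsaf_pt), NSAF_LT = as.numeric(nsaf_lt),
    SpI = as.numeric(spi),
    stringsAsFactors = FALSE)
  tab$selected <- abs(tab$Rsc) > rsc_threshold & tab$p < alpha
  if (!is.null(spi_min))
    tab$selected <- tab$selected & !is.na(tab$SpI) & abs(tab$SpI) >= spi_min
  if (!is.null(nsaf_ratio_min)) {
    lo <- pmin(tab$NSAF_PT, tab$NSAF_LT); hi <- pmax(tab$NSAF_PT, tab$NSAF_LT)
    tab$selected <- tab$selected & (lo == 0 | hi / lo >= nsaf_ratio_min)
  }
  structure(list(
    table = tab, venn = venn_summary(x),
    params = list(f = f, rsc_threshold = rsc_threshold, alpha = alpha,
                  correction = correction, mode = mode,
                  spi_min = spi_min, nsaf_ratio_min = nsaf_ratio_min),
    totals = list(t_PT = pooled$t_PT, t_LT = pooled$t_LT),
    n_samples = table(attr(x, "samples")$group)),
    class = "spectral_dea")
}

# mean of per-case Rsc over cases with both a PT and an LT sample,
# each case using its own column totals
per_case_rsc <- function(x, f) {
  s <- attr(x, "samples")
  if (all(is.na(s$case)))
    stop_config("per-case mode requires case IDs on the samples")
  cases <- unique(stats::na.omit(s$case))
  per <- matrix(NA_real_, nrow(x), length(cases),
                dimnames = list(rownames(x), cases))
  for (cs in cases) {
    pt_col <- s$sample[s$case == cs & s$group == "PT"]
    lt_col <- s$sample[s$case == cs & s$group == "LT"]
    if (length(pt_col) != 1L || length(lt_col) != 1L) next
    n_pt <- x[, pt_col]; n_lt <- x[, lt_col]
    per[, cs] <- compute_rsc(n_pt, n_lt, sum(n_pt), sum(n_lt), f = f)
  }
  rowMeans(per, na.rm = TRUE)
}

#' @export
print.spectral_dea <- function(x, ...) {
  p <- x$params
  cat("Spectral-counting differential expression\n")
  cat(sprintf("  samples: %d PT + %d LT; pooled depth %d (PT) / %d (LT)\n",
              x$n_samples[["PT"]], x$n_samples[["LT"]],
              x$totals$t_PT, x$totals$t_LT))
  cat(sprintf("  proteins: %d (PT only %d, LT only %d, shared %d)\n",
              x$venn$total, x$venn$PT_only, x$venn$LT_only, x$venn$shared))
  cat(sprintf("  gate: |Rsc| > %g and G-test p < %g (f = %g, %s mode)\n",
              p$rsc_threshold, p$alpha, p$f, p$mode))
  sel <- x$table[x$table$selected, ]
  cat(sprintf("  selected: %d (%d PT-overexpressed, %d LT-overexpressed)\n",
              nrow(sel), sum(sel$direction == "PT"),
              sum(sel$direction == "LT")))
  invisible(x)
}

#' @export
summary.spectral_dea <- function(object, ...) {
  sel <- select_candidates(object$table,
                           rsc_threshold = object$params$rsc_threshold,
                           alpha = object$params$alpha)
  sel
}

#' @export
as.data.frame.spectral_dea <- function(x, ...) x$table

#' @export
coef.spectral_dea <- function(object, ...) {
  stats::setNames(object$table$Rsc, object$table$accession)
}

#' Volcano-style plot of a spectral DEA fit
#'
#' Rsc against -log10 G-test p, with the selection gate drawn and selected
#' proteins highlighted.
#' @param x a `spectral_dea` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.spectral_dea <- function(x, ...) {
  tab <- x$table
  graphics::plot(tab$Rsc, -log10(tab$p),
                 xlab = "Rsc (log2 LT/PT)", ylab = "-log10 p (G-test)",
                 pch = 20, col = ifelse(tab$selected, "firebrick", "grey60"),
                 ...)
  graphics::abline(v = c(-1, 1) * x$params$rsc_threshold, lty = 2)
  graphics::abline(h = -log10(x$params$alpha), lty = 2)
  invisible(x)
}
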