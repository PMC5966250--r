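#' Pool spectral counts within tissue groups
#'
#' Sums each protein's counts over all samples of a group and records the
#' group grand totals. These pooled quantities (n_PT, n_LT, t_PT, t_LT) are
#' the inputs of the Rsc log-ratio and the G-test.
#'
#' @param x a [count_matrix()] with at least one sample in each group.
#' @param f pseudo-count (> 0) carried along for downstream Rsc computation.
#' @return list of class `"pooled_counts"`: `counts` (data.frame with
#'   `accession`, `n_PT`, `n_LT`), `t_PT`, `t_LT`, `f`.
#' @export
pool_counts <- function(x, f = 0.5) {
  stopifnot(inherits(x, "count_matrix"))
  check_pos(f, "f")
  grp <- attr(x, "samples")$group
  if (!all(c("PT", "LT") %in% grp))
    stop_config("both groups need at least one sample; present: %s",
                paste(unique(grp), collapse = ", "))
  n_pt <- as.integer(rowSums(x[, grp == "PT", drop = FALSE]))
  n_lt <- as.integer(rowSums(x[, grp == "LT", drop = FALSE]))
  structure(list(
    counts = data.frame(accession = rownames(x), n_PT = n_pt, n_LT = n_lt,
                        stringsAsFactors = FALSE),
    t_PT = sum(n_pt), t_LT = sum(n_lt), f = f),
    class = "pooled_counts")
}

#' Spectral-count log2 ratio (Rsc)
#'
#' The base-2 log fold change between groups from pooled spectral counts,
#' with a pseudo-count f keeping proteins identified in only one group
#' finite:
#'
#' \deqn{Rsc = \log_2\frac{n_{LT}+f}{n_{PT}+f} +
#'       \log_2\frac{t_{PT}-n_{PT}+f}{t_{LT}-n_{LT}+f}}
#'
#' The second term normalizes for unequal sequencing depth between the
#' groups. Sign convention: positive Rsc means LT-enriched (liver
#' metastasis), negative means PT-enriched. `|Rsc| > 1` corresponds to more
#' than a 2-fold change; the reported fold change is `2^|Rsc|`.
#'
#' @param n_pt,n_lt pooled per-protein counts (vectors allowed).
#' @param t_pt,t_lt group grand totals.
#' @param f pseudo-count > 0, default 0.5.
#' @return numeric vector of Rsc values, finite for all non-negative counts.
#' @examples
#' compute_rsc(5, 20, 1000, 1000)  # ~ 1.92
#' @export
compute_rsc <- function(n_pt, n_lt, t_pt, t_lt, f = 0.5) {
  check_pos(f, "f")
  if (any(n_pt > t_pt) || any(n_lt > t_lt))
    stop_config("pooled protein count exceeds its group total")
  if (any(n_pt < 0) || any(n_lt < 0))
    stop_config("counts must be non-negative")
  log2((n_lt + f) / (n_pt + f)) + log2((t_pt - n_pt + f) / (t_lt - n_lt + f))
}

#' Normalized spectral abundance factor (NSAF)
#'
#' Within one group, a protein's spectral abundance factor is its pooled
#' count divided by its sequence length, SAF_i = n_i / L_i; NSAF_i rescales
#' the SAFs to sum to one, giving a relative abundance in \[0, 1\].
#' Undetected proteins (n = 0) get NSAF 0.
#'
#' @param n pooled counts for one group (named by accession, or `accession`
#'   supplied separately).
#' @param lengths an [annotation_table()] or a named vector of sequence
#'   lengths; every accession with n > 0 must have a length.
#' @param accession accessions matching `n` (defaults to `names(n)`).
#' @return numeric vector of NSAF values summing to 1 (0 if no detection).
#' @export
compute_nsaf <- function(n, lengths, accession = names(n)) {
  if (inherits(lengths, "annotation_table") || is.data.frame(lengths))
    lengths <- stats::setNames(lengths$length, lengths$accession)
  if (is.null(accession))
    stop_config("accessions are required to look up lengths")
  L <- lengths[accession]
  missing_len <- accession[n > 0 & (is.na(L) | is.null(L))]
  if (length(missing_len) > 0L)
    stop_config("missing length for detected protein(s): %s",
                paste(utils::head(missing_len, 5L), collapse = ", "))
  saf <- ifelse(n > 0, n / L, 0)
  tot <- sum(saf)
  out <- if (tot > 0) saf / tot else rep(0, length(n))
  stats::setNames(as.numeric(out), accession)
}

#' Spectral index (SpI)
#'
#' A bounded differential score in \[-1, +1\] combining relative pooled
#' abundance with the detection frequency across replicate samples:
#'
#' \deqn{SpI = \frac{\sum c_{LT}}{\sum c_{PT}+\sum c_{LT}}\cdot\frac{d_{LT}}{m_{LT}}
#'           - \frac{\sum c_{PT}}{\sum c_{PT}+\sum c_{LT}}\cdot\frac{d_{PT}}{m_{PT}}}
#'
#' where d is the number of samples of the group with a non-zero count and m
#' the group size. SpI = +1 iff the protein is seen in every LT sample and no
#' PT sample; -1 is the mirror case; values near 0 indicate similar
#' abundance. Sign convention matches Rsc (positive = LT-enriched). Proteins
#' with no detection anywhere get `NA` (undefined), never 0.
#'
#' @param x a [count_matrix()].
#' @return named numeric vector of SpI values (NA for all-zero proteins).
#' @export
compute_spi <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  grp <- attr(x, "samples")$group
  pt <- x[, grp == "PT", drop = FALSE]
  lt <- x[, grp == "LT", drop = FALSE]
  c_pt <- rowSums(pt); c_lt <- rowSums(lt)
  d_pt <- rowSums(pt > 0); d_lt <- rowSums(lt > 0)
  tot <- c_pt + c_lt
  spi <- ifelse(tot == 0, NA_real_,
                (c_lt / tot) * (d_lt / ncol(lt)) -
                (c_pt / tot) * (d_pt / ncol(pt)))
  stats::setNames(as.numeric(spi), rownames(x))
}

#' Likelihood-ratio G-test on pooled spectral counts
#'
#' For each protein, tests independence in the 2x2 table
#' \[(n_PT, n_LT), (t_PT - n_PT, t_LT - n_LT)\]:
#' G = 2 * sum O * ln(O/E) with expected counts E from the margins and the
#' convention 0 * ln(0/E) = 0; the p-value is the upper tail of chi-square
#' with 1 degree of freedom. The Williams small-sample correction
#' (G / q with q = 1 + (N/t_PT + N/t_LT - 1)(N/r1 + N/r2 - 1)/(6N)) is
#' available but off by default.
#'
#' @inheritParams compute_rsc
#' @param correction `"none"` (default) or `"williams"`.
#' @return list with numeric vectors `G` and `p`.
#' @export
g_test <- function(n_pt, n_lt, t_pt, t_lt, correction = c("none", "williams")) {
  correction <- match.arg(correction)
  n_pt <- as.numeric(n_pt); n_lt <- as.numeric(n_lt)
  t_pt <- as.numeric(t_pt); t_lt <- as.numeric(t_lt)
  if (any(t_pt - n_pt < 0) || any(t_lt - n_lt < 0))
    stop_config("pooled protein count exceeds its group total")
  if (any(t_pt <= 0) || any(t_lt <= 0))
    stop_config("group totals must be positive")
  xlogx <- function(o, e) ifelse(o == 0, 0, o * log(o / e))
  r1 <- n_pt + n_lt
  r2 <- (t_pt - n_pt) + (t_lt - n_lt)
  N <- t_pt + t_lt
  e11 <- r1 * t_pt / N; e12 <- r1 * t_lt / N
  e21 <- r2 * t_pt / N; e22 <- r2 * t_lt / N
  G <- 2 * (xlogx(n_pt, e11) + xlogx(n_lt, e12) +
            xlogx(t_pt - n_pt, e21) + xlogx(t_lt - n_lt, e22))
  G <- pmax(G, 0)  # guard tiny negative rounding at O == E
  if (correction == "williams") {
    q <- 1 + (N / t_pt + N / t_lt - 1) * (N / pmax(r1, 1) + N / pmax(r2, 1) - 1) / (6 * N)
    G <- G / q
  }
  list(G = G, p = stats::pchisq(G, df = 1, lower.tail = FALSE))
}

#' Apply the candidate-selection gate
#'
#' A protein is selected iff `|Rsc| > rsc_threshold` and `p < alpha`, both
#' strict. Direction is the sign of Rsc (`"LT"` for positive, `"PT"` for
#' negative). Optional secondary filters on the spectral index and the
#' between-group NSAF ratio are available but applied only when set, since
#' they are screening aids without a canonical cutoff. The result is sorted
#' by decreasing `|Rsc|`, ties broken by increasing p then accession.
#'
#' @param records data.frame with at least `accession`, `Rsc`, `p` (and
#'   `SpI`, `NSAF_PT`, `NSAF_LT` if the optional filters are used), e.g. the
#'   table of a [spectral_dea()] fit.
#' @param rsc_threshold strict |Rsc| gate, default 1 (2-fold).
#' @param alpha strict G-test significance gate, default 0.05.
#' @param spi_min if set, additionally require `|SpI| >= spi_min`.
#' @param nsaf_ratio_min if set, additionally require the larger/smaller
#'   NSAF ratio to be at least this (proteins absent in one group pass).
#' @return the selected rows with a `direction` column, sorted.
#' @export
select_candidates <- function(records, rsc_threshold = 1, alpha = 0.05,
                              spi_min = NULL, nsaf_ratio_min = NULL) {
  check_pos(rsc_threshold, "rsc_threshold")
  check_prob(alpha, "alpha")
  keep <- abs(records$Rsc) > rsc_threshold & records$p < alpha
  if (!is.null(spi_min))
    keep <- keep & !is.na(records$SpI) & abs(records$SpI) >= spi_min
  if (!is.null(nsaf_ratio_min)) {
    lo <- pmin(records$NSAF_PT, records$NSAF_LT)
    hi <- pmax(records$NSAF_PT, records$NSAF_LT)
    keep <- keep & (lo == 0 | hi / lo >= nsaf_ratio_min)
  }
  out <- records[keep, , drop = FALSE]
  out$direction <- ifelse(out$Rsc > 0, "LT", "PT")
  out[order(-abs(out$Rsc), out$p, out$accession), , drop = FALSE]
}

#' Identification Venn partition
#'
#' A protein counts as identified in a group iff its pooled group count is
#' positive. `venn_summary()` derives the partition from a count matrix;
#' `venn_from_sizes()` builds it from published set sizes (per-group
#' identification counts and their overlap) when only presence lists are
#' available.
#'
#' @param x a [count_matrix()].
#' @return list of class `"venn_summary"` with counts `PT_only`, `LT_only`,
#'   `shared`, `total` and the matching percentages of the union.
#' @examples
#' venn_from_sizes(2622, 2993, 1893)  # 729 / 1100 / 1893 of 3722
#' @export
venn_summary <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  grp <- attr(x, "samples")$group
  in_pt <- rowSums(x[, grp == "PT", drop = FALSE]) > 0
  in_lt <- rowSums(x[, grp == "LT", drop = FALSE]) > 0
  new_venn(sum(in_pt & !in_lt), sum(!in_pt & in_lt), sum(in_pt & in_lt))
}

#' @rdname venn_summary
#' @param n_pt,n_lt total identifications in each group.
#' @param n_shared identifications common to both groups.
#' @export
venn_from_sizes <- function(n_pt, n_lt, n_shared) {
  if (n_shared > min(n_pt, n_lt))
    stop_config("overlap cannot exceed either set size")
  new_venn(n_pt - n_shared, n_lt - n_shared, n_shared)
}

new_venn <- function(pt_only, lt_only, shared) {
  total <- pt_only + lt_only + shared
  pct <- if (total > 0) 100 * c(pt_only, lt_only, shared) / total else rep(NA_real_, 3)
  structure(list(PT_only = as.integer(pt_only), LT_only = as.integer(lt_only),
                 shared = as.integer(shared), total = as.integer(total),
                 pct_PT_only = pct[1L], pct_LT_only = pct[2L],
                 pct_shared = pct[3L]),
            class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat(sprintf("Identified proteins: %d total\n", x$total))
  cat(sprintf("  PT only: %5d (%.1f%%)\n", x$PT_only, x$pct_PT_only))
  cat(sprintf("  LT only: %5d (%.1f%%)\n", x$LT_only, x$pct_LT_only))
  cat(sprintf("  shared : %5d (%.1f%%)\n", x$shared, x$pct_shared))
  invisible(x)
}
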