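#' Spectral-count matrix with sample metadata
#'
#' The discovery-stage substrate: an integer matrix of spectral counts with
#' proteins (UniProt-style accessions, treated as opaque text) in rows and
#' samples in columns. Every sample carries a tissue group, `"PT"` (primary
#' pancreatic tumor) or `"LT"` (paired liver metastasis), and optionally a
#' case identifier linking the paired samples of one patient.
#'
#' @param counts integer matrix, proteins x samples; non-negative whole
#'   numbers; rownames are unique accessions, colnames unique sample IDs.
#' @param group character vector, one of `"PT"`/`"LT"` per sample.
#' @param case optional character vector of case IDs, one per sample.
#' @return An object of class `"count_matrix"`: the validated matrix with a
#'   `samples` attribute (data.frame of `sample`, `group`, `case`).
#' @examples
#' m <- matrix(c(2L, 0L, 3L, 1L), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("PT_1", "LT_1")))
#' cm <- count_matrix(m, group = c("PT", "LT"), case = c("c1", "c1"))
#' sample_groups(cm)
#' @export
count_matrix <- function(counts, group, case = NULL) {
  if (!is.matrix(counts)) stop_config("'counts' must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_config("'counts' must have accession rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop_config("duplicate accession: %s",
                rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(colnames(counts)))
    stop_config("duplicate sample ID: %s",
                colnames(counts)[duplicated(colnames(counts))][1L])
  bad <- which(!(is_wholenumber(counts) & counts >= 0), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_config(
      "counts must be non-negative integers; offending cell: protein %s, sample %s (value %s)",
      rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]],
      format(counts[bad[1L, , drop = FALSE]]))
  storage.mode(counts) <- "integer"
  group <- as.character(group)
  if (length(group) != ncol(counts))
    stop_config("'group' must have one entry per sample")
  if (!all(group %in% c("PT", "LT")))
    stop_config("sample groups must be 'PT' or 'LT'; got: %s",
                paste(setdiff(unique(group), c("PT", "LT")), collapse = ", "))
  if (!is.null(case)) {
    case <- as.character(case)
    if (length(case) != ncol(counts))
      stop_config("'case' must have one entry per sample")
  } else {
    case <- rep(NA_character_, ncol(counts))
  }
  structure(counts,
            samples = data.frame(sample = colnames(counts), group = group,
                                 case = case, stringsAsFactors = FALSE),
            class = c("count_matrix", "matrix", "array"))
}

#' @rdname count_matrix
#' @param x a `count_matrix`.
#' @export
sample_groups <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  stats::setNames(attr(x, "samples")$group, attr(x, "samples")$sample)
}

#' @rdname count_matrix
#' @export
sample_cases <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  stats::setNames(attr(x, "samples")$case, attr(x, "samples")$sample)
}

#' @export
print.count_matrix <- function(x, ...) {
  s <- attr(x, "samples")
  cat(sprintf("Spectral-count matrix: %d proteins x %d samples (%d PT, %d LT)\n",
              nrow(x), ncol(x), sum(s$group == "PT"), sum(s$group == "LT")))
  cat(sprintf("Total counts: PT %d, LT %d\n",
              sum(x[, s$group == "PT", drop = FALSE]),
              sum(x[, s$group == "LT", drop = FALSE])))
  invisible(x)
}
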