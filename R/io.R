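#' Read a spectral-count matrix from TSV
#'
#' The count table is a tab-separated file with an `accession` column followed
#' by one integer column per sample. The sample map is a separate TSV with
#' columns `sample`, `group` (PT/LT) and optionally `case`; every count column
#' must appear in the map. Missing cells are rejected: a protein that was not
#' identified in a sample must be written as an explicit 0 by the producer,
#' because presence/absence drives the identification Venn partition.
#'
#' @param path path to the count TSV.
#' @param sample_map_path path to the sample-map TSV.
#' @return a [count_matrix()].
#' @export
read_count_table <- function(path, sample_map_path) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character", na.strings = NULL)
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop_config("count table '%s' is empty or has no sample columns", path)
  if (names(raw)[1L] != "accession")
    stop_config("first column of '%s' must be 'accession'", path)
  map <- utils::read.delim(sample_map_path, check.names = FALSE,
                           colClasses = "character")
  if (!all(c("sample", "group") %in% names(map)))
    stop_config("sample map must have columns 'sample' and 'group'")
  acc <- raw$accession
  if (anyDuplicated(acc))
    stop_config("duplicate accession in '%s': %s", path,
                acc[duplicated(acc)][1L])
  samples <- names(raw)[-1L]
  missing_map <- setdiff(samples, map$sample)
  if (length(missing_map) > 0L)
    stop_config("sample(s) missing from the group map: %s",
                paste(missing_map, collapse = ", "))
  counts <- matrix(NA_integer_, nrow(raw), length(samples),
                   dimnames = list(acc, samples))
  for (j in samples) {
    v <- raw[[j]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) | num < 0 | !is_wholenumber(num))
    if (length(bad) > 0L)
      stop_config("invalid count '%s' at protein %s, sample %s",
                  v[bad[1L]], acc[bad[1L]], j)
    counts[, j] <- as.integer(num)
  }
  idx <- match(samples, map$sample)
  count_matrix(counts, group = map$group[idx],
               case = if ("case" %in% names(map)) map$case[idx])
}

#' Write a spectral-count matrix (and its sample map) as TSV
#'
#' Inverse of [read_count_table()]: `read_count_table(write_count_table(x))`
#' reproduces `x` bit-exactly, preserving row and column order.
#'
#' @param x a [count_matrix()].
#' @param path output TSV path for the counts.
#' @param sample_map_path output TSV path for the sample map.
#' @export
write_count_table <- function(x, path, sample_map_path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(accession = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(attr(x, "samples"), sample_map_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Protein annotation table (lengths, symbols)
#'
#' Carries the per-protein sequence length L (amino acids) used by the NSAF
#' length correction, plus an optional display symbol and description.
#'
#' @param accession unique protein accessions.
#' @param length positive integer sequence lengths (residues).
#' @param symbol optional display symbols.
#' @param description optional free text.
#' @return data.frame of class `"annotation_table"`.
#' @export
annotation_table <- function(accession, length, symbol = NA_character_,
                             description = NA_character_) {
  accession <- as.character(accession)
  if (anyDuplicated(accession))
    stop_config("duplicate accession: %s",
                accession[duplicated(accession)][1L])
  if (any(!is_wholenumber(length) | length < 1))
    stop_config("protein length must be a positive integer; offending accession: %s",
                accession[which(!is_wholenumber(length) | length < 1)[1L]])
  structure(data.frame(accession = accession, length = as.integer(length),
                       symbol = as.character(symbol),
                       description = as.character(description),
                       stringsAsFactors = FALSE),
            class = c("annotation_table", "data.frame"))
}

#' Derive protein lengths from a protein FASTA file
#'
#' The accession is the first whitespace-delimited token of each header; the
#' length is the number of residues with gap (`-`, `.`) and stop (`*`)
#' characters excluded, so line wrapping and alignment artifacts do not
#' change L.
#'
#' @param path protein FASTA file.
#' @return an [annotation_table()].
#' @export
lengths_from_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop_config("no FASTA records in '%s'", path)
  headers <- names(seqs)
  acc <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(acc))
    stop_config("duplicate accession in FASTA: %s", acc[duplicated(acc)][1L])
  chars <- as.character(seqs)
  lens <- nchar(gsub("[-.*]", "", chars))
  if (any(lens == 0L))
    stop_config("empty sequence for accession: %s", acc[lens == 0L][1L])
  desc <- sub("^\\S+\\s*", "", headers)
  annotation_table(acc, lens, description = ifelse(desc == "", NA, desc))
}

#' Read an annotation table from TSV
#'
#' Expects columns `accession` and `length`; `symbol` and `description` are
#' optional.
#' @param path TSV path.
#' @return an [annotation_table()].
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("accession", "length") %in% names(df)))
    stop_config("annotation TSV must have columns 'accession' and 'length'")
  annotation_table(df$accession, df$length,
                   symbol = if ("symbol" %in% names(df)) df$symbol else NA,
                   description = if ("description" %in% names(df)) df$description else NA)
}

cohort_required_cols <- c(
  "patient_id", "group", "gender", "age", "function_type", "who_grade",
  "ki67", "mitotic_count", "tumor_size", "lymph_node_metastasis",
  "vascular_invasion", "lymphatic_invasion", "enets_stage",
  "liver_rfs_months", "liver_recurrence", "os_months", "death")

#' Read and validate a patient cohort table
#'
#' CSV, one row per patient. Required columns:
#' `patient_id`; `group` (`synchronous` / `metachronous` / `none` liver
#' metastasis); `gender`; `age` (years); `function_type`; `who_grade`
#' (G1/G2/G3); `ki67` (% in \[0,100\]); `mitotic_count` (integer >= 0);
#' `tumor_size` (mm, > 0); `lymph_node_metastasis`, `vascular_invasion`,
#' `lymphatic_invasion` (0/1); `enets_stage` (I-IV); `liver_rfs_months`
#' (empty for synchronous patients, who have liver metastasis at diagnosis);
#' `liver_recurrence` (0/1); `os_months`; `death` (0/1). Any column named
#' `marker_<SYMBOL>` is a binary immunohistochemistry positivity call
#' (positive = at least 10% of tumor cells stained; the thresholding happens
#' upstream of this table).
#'
#' A synchronous patient with a liver-RFS time present triggers a warning and
#' the time is dropped (synchronous patients are excluded from liver-RFS
#' analyses).
#'
#' @param path CSV path.
#' @return data.frame of class `"cohort_table"`; marker column names are in
#'   `attr(x, "markers")`.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop_config("cohort file '%s' has no rows", path)
  as_cohort_table(df)
}

#' @rdname read_cohort
#' @param df a data.frame with the cohort columns.
#' @export
as_cohort_table <- function(df) {
  miss <- setdiff(cohort_required_cols, names(df))
  if (length(miss) > 0L)
    stop_config("cohort is missing column(s): %s", paste(miss, collapse = ", "))
  row_id <- function(i) sprintf("row %d (patient %s)", i, df$patient_id[i])
  if (anyDuplicated(df$patient_id))
    stop_config("duplicate patient_id: %s",
                df$patient_id[duplicated(df$patient_id)][1L])
  bad <- which(!df$group %in% c("synchronous", "metachronous", "none"))
  if (length(bad)) stop_config("unknown metastasis group '%s' at %s",
                               df$group[bad[1L]], row_id(bad[1L]))
  bad <- which(!df$who_grade %in% c("G1", "G2", "G3"))
  if (length(bad)) stop_config("unknown WHO grade '%s' at %s",
                               df$who_grade[bad[1L]], row_id(bad[1L]))
  bad <- which(!df$enets_stage %in% c("I", "II", "III", "IV"))
  if (length(bad)) stop_config("unknown ENETS stage '%s' at %s",
                               df$enets_stage[bad[1L]], row_id(bad[1L]))
  bad <- which(is.na(df$ki67) | df$ki67 < 0 | df$ki67 > 100)
  if (length(bad)) stop_config("Ki-67 outside [0, 100] at %s", row_id(bad[1L]))
  bad <- which(is.na(df$tumor_size) | df$tumor_size <= 0)
  if (length(bad)) stop_config("non-positive tumor size at %s", row_id(bad[1L]))
  bad <- which(!is_wholenumber(df$mitotic_count) | df$mitotic_count < 0)
  if (length(bad)) stop_config("invalid mitotic count at %s", row_id(bad[1L]))
  for (col in c("lymph_node_metastasis", "vascular_invasion",
                "lymphatic_invasion", "liver_recurrence", "death")) {
    v <- df[[col]]
    bad <- which(!(is.na(v) | v %in% c(0, 1)))
    if (length(bad)) stop_config("column '%s' must be 0/1 at %s",
                                 col, row_id(bad[1L]))
  }
  for (col in c("liver_rfs_months", "os_months")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad)) stop_config("negative time in '%s' at %s",
                                 col, row_id(bad[1L]))
  }
  sync_with_rfs <- which(df$group == "synchronous" & !is.na(df$liver_rfs_months))
  if (length(sync_with_rfs) > 0L) {
    warning(sprintf(
      "synchronous patient(s) with a liver-RFS time; field ignored: %s",
      paste(df$patient_id[sync_with_rfs], collapse = ", ")), call. = FALSE)
    df$liver_rfs_months[sync_with_rfs] <- NA_real_
    df$liver_recurrence[sync_with_rfs] <- NA_integer_
  }
  markers <- grep("^marker_", names(df), value = TRUE)
  for (col in markers) {
    bad <- which(!df[[col]] %in% c(0, 1))
    if (length(bad)) stop_config("marker column '%s' must be 0/1 at %s",
                                 col, row_id(bad[1L]))
  }
  structure(df, markers = sub("^marker_", "", markers),
            class = c("cohort_table", "data.frame"))
}

#' @rdname read_cohort
#' @param x a `cohort_table`.
#' @export
write_cohort <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Write an analysis report as TSV tables plus a JSON summary
#'
#' Each data.frame element of `results` is written as `<name>.tsv`; the whole
#' structure (data.frames included) is serialized to `summary.json`. A
#' `report_hash` (MD5 of the JSON) is written alongside so reruns can be
#' checked for bit-identity.
#'
#' @param results named list of data.frames and scalar summaries.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(results)) {
    el <- results[[nm]]
    if (is.data.frame(el))
      utils::write.table(el, file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  json_path <- file.path(dir, "summary.json")
  jsonlite::write_json(results, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  writeLines(unname(tools::md5sum(json_path)), file.path(dir, "report_hash"))
  invisible(dir)
}
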