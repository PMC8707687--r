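# Readers/writers for the package's TSV dialects: wide reporter matrices
# (first column `accession`, remaining columns `<plex>_<channel>`, missing
# cells empty), sample maps, and simulation truth tables.

#' Write a reporter matrix as wide TSV
#'
#' @param matrix proteins x columns numeric matrix with accession rownames
#'   and `<plex>_<channel>` column names; `NA` cells are written empty.
#' @param path output TSV path.
#' @export
write_reporter_matrix <- function(matrix, path) {
  df <- data.frame(accession = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a reporter matrix from wide TSV
#'
#' @param path TSV written by [write_reporter_matrix()] (or matching its
#'   dialect: first column the protein accession, empty cells missing).
#' @return numeric matrix with accession rownames.
#' @export
read_reporter_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("reporter matrix TSV needs accession + data columns")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Write a sample map as TSV
#'
#' @param sample_map data.frame with columns `column_id`, `plex`,
#'   `channel`, `subject_id`, `replicate`.
#' @param path output TSV path.
#' @export
write_sample_map <- function(sample_map, path) {
  utils::write.table(sample_map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a sample map from TSV
#'
#' @param path TSV written by [write_sample_map()].
#' @return validated sample map data.frame.
#' @export
read_sample_map <- function(path) {
  sm <- utils::read.delim(path, check.names = FALSE,
                          na.strings = c("", "NA"),
                          colClasses = c(channel = "character"),
                          stringsAsFactors = FALSE)
  sm$channel <- as.character(sm$channel)
  validate_sample_map(sm)
  sm$plex <- as.integer(sm$plex)
  sm$replicate <- suppressWarnings(as.integer(sm$replicate))
  sm
}

#' Write a simulation truth table as TSV
#'
#' @param truth per-protein ground truth from [simulate_dataset()].
#' @param path output TSV path.
#' @export
write_simulation_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a simulation truth table from TSV
#'
#' @param path TSV written by [write_simulation_truth()].
#' @return data.frame of per-protein ground truth.
#' @export
read_simulation_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a variation table from TSV
#'
#' Accepts the numeric TSV written by the `cv` CLI subcommand or any table
#' with `accession` and `cv_total` columns.
#'
#' @param path TSV path.
#' @return data.frame variation table.
#' @export
read_variation_table <- function(path) {
  vt <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("accession", "cv_total") %in% names(vt))) {
    stop("variation table needs at least accession and cv_total columns")
  }
  vt
}

# Unformatted numeric variation table (full precision), used by the CLI so
# that downstream power analysis does not lose digits.
#' @keywords internal
write_variation_table_raw <- function(variation, path) {
  utils::write.table(variation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
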