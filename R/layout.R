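#' TMT 10-plex reporter channel labels
#'
#' The ten reporter channel labels of a TMT 10-plex kit, in ascending
#' reporter-mass order. Channels `126` and `131` are conventionally used for
#' pooled internal controls in the duplicate design supported by this
#' package; the eight interior channels carry individual samples.
#'
#' @format Character vector of length 10.
#' @export
TMT10_CHANNELS <- c("126", "127N", "127C", "128N", "128C",
                    "129N", "129C", "130N", "130C", "131")

#' Column key for a plex/channel measurement
#'
#' Reporter matrices name their columns `<plex>_<channel>`, e.g. `P01_126`.
#'
#' @param plex integer plex (run) index, 1-based.
#' @param channel channel label, e.g. `"127N"`.
#' @return character vector of column keys.
#' @export
column_key <- function(plex, channel) {
  sprintf("P%02d_%s", as.integer(plex), as.character(channel))
}

#' Validate a sample map, optionally against a reporter matrix
#'
#' A sample map annotates every column of a reporter matrix with its plex,
#' channel label, subject (or the pool marker `"POOL"` for internal-control
#' channels) and replicate index. Checks: required columns; within each plex
#' every channel label occurs at most once; every non-pool (subject,
#' replicate) pair maps to exactly one column; and, if a matrix is supplied,
#' every matrix column resolves in the map.
#'
#' @param sample_map data.frame with columns `column_id`, `plex`, `channel`,
#'   `subject_id`, `replicate`.
#' @param matrix optional reporter matrix whose columns must all be mapped.
#' @return the sample map, invisibly, with `plex` and `replicate` coerced to
#'   integer.
#' @export
validate_sample_map <- function(sample_map, matrix = NULL) {
  required <- c("column_id", "plex", "channel", "subject_id", "replicate")
  missing_cols <- setdiff(required, names(sample_map))
  if (length(missing_cols) > 0L) {
    stop("sample map lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  sample_map$plex <- as.integer(sample_map$plex)
  sample_map$replicate <- suppressWarnings(as.integer(sample_map$replicate))
  if (anyDuplicated(sample_map$column_id)) {
    stop("sample map has duplicated column_id entries")
  }
  dup_chan <- duplicated(sample_map[, c("plex", "channel")])
  if (any(dup_chan)) {
    stop("plex ", sample_map$plex[dup_chan][1L],
         " has more than one column for channel ",
         sample_map$channel[dup_chan][1L])
  }
  smp <- sample_map[sample_map$subject_id != "POOL", , drop = FALSE]
  key <- paste(smp$subject_id, smp$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- smp[duplicated(key), , drop = FALSE][1L, ]
    stop("subject ", bad$subject_id, " replicate ", bad$replicate,
         " maps to more than one column")
  }
  if (!is.null(matrix)) {
    unmapped <- setdiff(colnames(matrix), sample_map$column_id)
    if (length(unmapped) > 0L) {
      stop("matrix column(s) not present in sample map: ",
           paste(utils::head(unmapped, 5L), collapse = ", "))
    }
  }
  invisible(sample_map)
}

#' @keywords internal
sample_rows <- function(sample_map) {
  sample_map[sample_map$subject_id != "POOL", , drop = FALSE]
}

#' @keywords internal
control_rows <- function(sample_map, channel = NULL) {
  out <- sample_map[sample_map$subject_id == "POOL", , drop = FALSE]
  if (!is.null(channel)) out <- out[out$channel == channel, , drop = FALSE]
  out
}

# Designed number of sample measurements (the denominator of the
# completeness filter): distinct (subject, replicate) pairs in the map,
# whether or not their column survived upstream processing.
#' @keywords internal
designed_count <- function(sample_map) {
  smp <- sample_rows(sample_map)
  nrow(unique(smp[, c("subject_id", "replicate")]))
}
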