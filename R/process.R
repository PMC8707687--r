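#' Global equal-sum normalization
#'
#' Scales every column so that all column sums (over present values) are
#' equal: each column is multiplied by `target / colsum`, where the target
#' is the mean of all column sums across all channels and plexes. The mean
#' preserves the global intensity scale. Missing cells are excluded from
#' the sums, not imputed.
#'
#' @param matrix reporter matrix (proteins x columns, `NA` = missing).
#' @return normalized matrix; after the call all column sums agree to
#'   within 1e-9 relative.
#' @export
normalize_global_equal_sum <- function(matrix) {
  sums <- colSums(matrix, na.rm = TRUE)
  empty <- colSums(!is.na(matrix)) == 0L
  if (any(empty)) {
    stop("column(s) with no present values cannot be normalized: ",
         paste(colnames(matrix)[empty], collapse = ", "))
  }
  if (any(sums <= 0)) {
    stop("column(s) with non-positive sum cannot be normalized: ",
         paste(colnames(matrix)[sums <= 0], collapse = ", "))
  }
  target <- mean(sums)
  sweep(matrix, 2, target / sums, `*`)
}

#' Scale plexes to the averaged internal control
#'
#' Aligns plexes on the pooled internal-control channel. In the default
#' protein-wise mode, for each protein the values in every plex are scaled
#' so that the plex's control value equals the across-plex average control
#' value for that protein. A protein whose control value is missing in a
#' plex keeps that plex's values unscaled; the number of such protein-plex
#' cells is reported in the `n_unscaled` attribute. The alternative
#' `"global"` mode applies one channel-wise factor per plex (the grand mean
#' of per-plex control means over the plex's control mean).
#'
#' @param matrix reporter matrix.
#' @param sample_map sample map for the matrix.
#' @param control_channel label of the control channel used as the anchor.
#' @param method `"protein"` (per-protein across-plex alignment, default)
#'   or `"global"` (a single factor per plex).
#' @return scaled matrix with attribute `n_unscaled`.
#' @export
scale_to_control <- function(matrix, sample_map, control_channel = "126",
                             method = c("protein", "global")) {
  method <- match.arg(method)
  sample_map <- validate_sample_map(sample_map, matrix)
  plexes <- sort(unique(sample_map$plex))
  ctrl <- control_rows(sample_map, control_channel)
  ctrl_of_plex <- ctrl$column_id[match(plexes, ctrl$plex)]
  if (anyNA(ctrl_of_plex) || !all(ctrl_of_plex %in% colnames(matrix))) {
    bad <- plexes[is.na(ctrl_of_plex) |
                    !(ctrl_of_plex %in% colnames(matrix))]
    stop("control channel ", control_channel,
         " is absent from plex(es): ", paste(bad, collapse = ", "))
  }
  ctrl_mat <- matrix[, ctrl_of_plex, drop = FALSE]  # proteins x plexes
  out <- matrix
  n_unscaled <- 0L
  if (method == "protein") {
    avg <- rowMeans(ctrl_mat, na.rm = TRUE)
    factors <- avg / ctrl_mat                        # proteins x plexes
    bad <- !is.finite(factors)
    n_unscaled <- sum(bad)
    factors[bad] <- 1
    for (k in seq_along(plexes)) {
      cols <- sample_map$column_id[sample_map$plex == plexes[k]]
      cols <- intersect(cols, colnames(out))
      out[, cols] <- out[, cols, drop = FALSE] * factors[, k]
    }
  } else {
    plex_mean <- colMeans(ctrl_mat, na.rm = TRUE)
    target <- mean(plex_mean)
    for (k in seq_along(plexes)) {
      cols <- sample_map$column_id[sample_map$plex == plexes[k]]
      cols <- intersect(cols, colnames(out))
      out[, cols] <- out[, cols, drop = FALSE] * (target / plex_mean[k])
    }
  }
  attr(out, "n_unscaled") <- n_unscaled
  out
}

#' Relative abundance versus the internal control
#'
#' Divides every sample measurement by its plex's control value for the
#' same protein. Cells whose control value is missing or zero become
#' missing. Control columns (all pooled channels) are dropped from the
#' result by default; keep them to inspect the control-vs-control QC ratio
#' (the anchor channel's self-ratio is identically 1).
#'
#' @inheritParams scale_to_control
#' @param drop_controls drop pooled-control columns from the result.
#' @return matrix of relative abundances.
#' @export
relative_abundance <- function(matrix, sample_map, control_channel = "126",
                               drop_controls = TRUE) {
  sample_map <- validate_sample_map(sample_map, matrix)
  plexes <- sort(unique(sample_map$plex))
  ctrl <- control_rows(sample_map, control_channel)
  ctrl_of_plex <- ctrl$column_id[match(plexes, ctrl$plex)]
  if (anyNA(ctrl_of_plex) || !all(ctrl_of_plex %in% colnames(matrix))) {
    bad <- plexes[is.na(ctrl_of_plex) |
                    !(ctrl_of_plex %in% colnames(matrix))]
    stop("control channel ", control_channel,
         " is absent from plex(es): ", paste(bad, collapse = ", "))
  }
  denom <- matrix[, ctrl_of_plex, drop = FALSE]
  denom[!is.na(denom) & denom == 0] <- NA_real_
  out <- matrix
  plex_of_col <- sample_map$plex[match(colnames(matrix),
                                       sample_map$column_id)]
  for (k in seq_along(plexes)) {
    cols <- which(plex_of_col == plexes[k])
    out[, cols] <- matrix[, cols, drop = FALSE] / denom[, k]
  }
  if (drop_controls) {
    keep <- sample_map$subject_id[match(colnames(out),
                                        sample_map$column_id)] != "POOL"
    out <- out[, keep, drop = FALSE]
  }
  out
}

#' Full reporter-matrix processing chain
#'
#' Composes the processing stages in their canonical order:
#' impurity correction (if a spec is given) -> global equal-sum
#' normalization -> control scaling -> relative abundance versus the
#' internal control. Downstream of the correction the chain is invariant
#' to rescaling any input column by a constant (normalization removes
#' per-column factors exactly).
#'
#' @inheritParams scale_to_control
#' @param impurity_spec optional [impurity_spec()]; `NULL` skips
#'   correction.
#' @param scale_method passed to [scale_to_control()].
#' @param drop_controls passed to [relative_abundance()].
#' @return matrix of relative abundances.
#' @export
process_reporter_matrix <- function(matrix, sample_map,
                                    impurity_spec = NULL,
                                    control_channel = "126",
                                    scale_method = "protein",
                                    drop_controls = TRUE) {
  if (!is.null(impurity_spec)) {
    matrix <- correct_impurities(matrix, impurity_spec, sample_map)
  }
  matrix <- normalize_global_equal_sum(matrix)
  matrix <- scale_to_control(matrix, sample_map,
                             control_channel = control_channel,
                             method = scale_method)
  relative_abundance(matrix, sample_map,
                     control_channel = control_channel,
                     drop_controls = drop_controls)
}
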