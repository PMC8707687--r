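#' Filter proteins by quantification completeness
#'
#' Retains proteins quantified in at least `threshold` of the designed
#' sample measurements. The denominator is the designed measurement count
#' (subjects x replicates as annotated in the sample map, e.g. 84 for the
#' duplicate design), not the per-protein observed maximum, and the
#' boundary is inclusive: a protein present in exactly half the designed
#' measurements survives the default 50% filter. Pooled-control columns
#' never count.
#'
#' @param matrix reporter matrix (typically of relative abundances).
#' @param sample_map sample map for the matrix.
#' @param threshold required fraction of designed measurements, in (0, 1].
#' @return the filtered matrix (row order preserved); a message reports
#'   how many proteins were removed.
#' @export
filter_by_completeness <- function(matrix, sample_map, threshold = 0.5) {
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]")
  }
  sample_map <- validate_sample_map(sample_map)
  n_designed <- designed_count(sample_map)
  cols <- intersect(sample_rows(sample_map)$column_id, colnames(matrix))
  n_present <- rowSums(!is.na(matrix[, cols, drop = FALSE]))
  keep <- n_present / n_designed >= threshold
  if (any(!keep)) {
    message("filter_by_completeness: removed ", sum(!keep), " of ",
            length(keep), " proteins below ",
            round(100 * threshold), "% completeness")
  }
  matrix[keep, , drop = FALSE]
}

#' Analytical coefficient of variation from replicate preparations
#'
#' For each protein, every subject with at least two present replicate
#' measurements contributes an individual analytical CV
#' `CV_pt = sd(replicates) / mean(replicates) * 100` (sample SD,
#' denominator n-1). The protein's analytical CV is the unweighted mean of
#' these per-subject CVs; subjects with fewer than two present replicates
#' are excluded. Note that for duplicates the pair SD underestimates the
#' true analytical SD by the half-normal factor `sqrt(2/pi) ~ 0.798` in
#' expectation; this estimator applies no correction (standard duplicate
#' practice in clinical chemistry), so the bias must be kept in mind when
#' comparing against known truth.
#'
#' @param matrix reporter matrix of relative abundances.
#' @param sample_map sample map for the matrix.
#' @return data.frame with `accession`, `cv_analytical` (percent, `NA` when
#'   no subject has a complete pair) and `n_pairs_used`.
#' @export
cv_analytical <- function(matrix, sample_map) {
  sample_map <- validate_sample_map(sample_map)
  smp <- sample_rows(sample_map)
  smp <- smp[smp$column_id %in% colnames(matrix), , drop = FALSE]
  subjects <- unique(smp$subject_id)
  np <- nrow(matrix)
  cvpt <- matrix(NA_real_, np, length(subjects))
  for (k in seq_along(subjects)) {
    cols <- smp$column_id[smp$subject_id == subjects[k]]
    if (length(cols) < 2L) next
    sub <- matrix[, cols, drop = FALSE]
    cnt <- rowSums(!is.na(sub))
    m <- rowMeans(sub, na.rm = TRUE)
    ss <- rowSums((sub - m)^2, na.rm = TRUE)
    sdv <- sqrt(ss / pmax(cnt - 1L, 1L))
    ok <- cnt >= 2L & is.finite(m) & m > 0
    cvpt[ok, k] <- sdv[ok] / m[ok] * 100
  }
  n_pairs <- as.integer(rowSums(!is.na(cvpt)))
  cva <- rep(NA_real_, np)
  has <- n_pairs >= 1L
  cva[has] <- rowMeans(cvpt[has, , drop = FALSE], na.rm = TRUE)
  data.frame(accession = rownames(matrix),
             cv_analytical = cva,
             n_pairs_used = n_pairs,
             stringsAsFactors = FALSE)
}

#' Total coefficient of variation across all measurements
#'
#' Mean, sample SD (denominator n-1) and CV of each protein's relative
#' abundances over all present sample measurements — both replicates of
#' every subject (the default), or over per-subject replicate means when
#' `over = "subject_means"`. Proteins with fewer than two present values
#' get `NA` statistics.
#'
#' @inheritParams cv_analytical
#' @param over `"measurements"` (all present measurements, default) or
#'   `"subject_means"` (replicates averaged per subject first).
#' @return data.frame with `accession`, `n_present`, `mean_total`,
#'   `sd_total`, `cv_total` (percent).
#' @export
cv_total <- function(matrix, sample_map,
                     over = c("measurements", "subject_means")) {
  over <- match.arg(over)
  sample_map <- validate_sample_map(sample_map)
  smp <- sample_rows(sample_map)
  smp <- smp[smp$column_id %in% colnames(matrix), , drop = FALSE]
  sub <- matrix[, smp$column_id, drop = FALSE]
  n_present <- as.integer(rowSums(!is.na(sub)))
  if (over == "subject_means") {
    subjects <- unique(smp$subject_id)
    agg <- vapply(subjects, function(s) {
      cols <- smp$column_id[smp$subject_id == s]
      rowMeans(matrix[, cols, drop = FALSE], na.rm = TRUE)
    }, numeric(nrow(matrix)))
    if (is.null(dim(agg))) agg <- matrix(agg, nrow = nrow(matrix))
    agg[!is.finite(agg)] <- NA_real_
    sub <- agg
  }
  cnt <- rowSums(!is.na(sub))
  m <- rowMeans(sub, na.rm = TRUE)
  ss <- rowSums((sub - m)^2, na.rm = TRUE)
  sdv <- sqrt(ss / pmax(cnt - 1L, 1L))
  ok <- cnt >= 2L & is.finite(m)
  m[!ok] <- NA_real_
  sdv[!ok] <- NA_real_
  cv <- ifelse(ok & m > 0, sdv / m * 100, NA_real_)
  data.frame(accession = rownames(matrix),
             n_present = n_present,
             mean_total = m,
             sd_total = sdv,
             cv_total = cv,
             stringsAsFactors = FALSE)
}

#' Inter-individual biological CV by variance decomposition
#'
#' `CV_biological = sqrt(CV_total^2 - CV_analytical^2)`, the square-root
#' difference of squares: total variance is the sum of independent
#' biological and analytical variance components on the CV scale
#' (pre-analytical variation is taken as zero). When sampling noise makes
#' `CV_analytical` exceed `CV_total` the decomposition would be negative;
#' such proteins return 0 and are flagged in the `clamped` attribute.
#'
#' @param cv_total total CV in percent (vectorized; `NA` propagates).
#' @param cv_analytical analytical CV in percent.
#' @return numeric vector of biological CVs in percent, with a logical
#'   attribute `clamped` marking proteins clamped to zero.
#' @examples
#' cv_biological(92.3, 7.6)   # 91.99... -> 92.0 at 1 decimal
#' cv_biological(38.3, 2.7)   # 38.2 at 1 decimal
#' @export
cv_biological <- function(cv_total, cv_analytical) {
  if (any(cv_total < 0, na.rm = TRUE) ||
      any(cv_analytical < 0, na.rm = TRUE)) {
    stop("CVs must be non-negative")
  }
  n <- max(length(cv_total), length(cv_analytical))
  cv_total <- rep_len(cv_total, n)
  cv_analytical <- rep_len(cv_analytical, n)
  d <- cv_total^2 - cv_analytical^2
  clamped <- !is.na(d) & d < 0
  out <- sqrt(pmax(d, 0))
  attr(out, "clamped") <- clamped
  out
}

#' Per-protein variation table
#'
#' Runs the completeness filter (optional) and assembles the full
#' variation record per protein: presence count, total mean/SD/CV over all
#' present measurements, analytical CV from replicate pairs, and the
#' decomposed biological CV.
#'
#' @inheritParams cv_analytical
#' @param threshold completeness threshold passed to
#'   [filter_by_completeness()]; `NULL` skips the filter.
#' @param total_over passed to [cv_total()] as `over`.
#' @return data.frame with columns `accession`, `n_present`, `mean_total`,
#'   `sd_total`, `cv_total`, `cv_analytical`, `n_pairs_used`,
#'   `cv_biological`, `cv_bio_clamped`.
#' @export
compute_variation <- function(matrix, sample_map, threshold = 0.5,
                              total_over = "measurements") {
  if (!is.null(threshold)) {
    matrix <- filter_by_completeness(matrix, sample_map, threshold)
  }
  tot <- cv_total(matrix, sample_map, over = total_over)
  ana <- cv_analytical(matrix, sample_map)
  bio <- cv_biological(tot$cv_total, ana$cv_analytical)
  out <- data.frame(tot,
                    cv_analytical = ana$cv_analytical,
                    n_pairs_used = ana$n_pairs_used,
                    cv_biological = as.numeric(bio),
                    cv_bio_clamped = attr(bio, "clamped"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cohort summary of a variation table
#'
#' Medians, box-plot style quantiles (1/25/50/75/99 percentiles) and
#' histogram bin counts with cumulative protein counts for the three CV
#' measures, over proteins with defined values.
#'
#' @param variation a variation table from [compute_variation()].
#' @param bin_width histogram bin width in percentage points.
#' @return list with `medians` (named vector), `quantiles` (data.frame,
#'   one row per measure) and `histogram` (long data.frame: `measure`,
#'   `bin_low`, `bin_high`, `count`, `cumulative`).
#' @export
summarize_variation <- function(variation, bin_width = 5) {
  if (nrow(variation) == 0L) stop("variation table is empty")
  measures <- c("cv_total", "cv_analytical", "cv_biological")
  medians <- vapply(measures, function(m)
    stats::median(variation[[m]], na.rm = TRUE), numeric(1))
  probs <- c(0.01, 0.25, 0.5, 0.75, 0.99)
  qs <- t(vapply(measures, function(m)
    stats::quantile(variation[[m]], probs, na.rm = TRUE, names = FALSE),
    numeric(length(probs))))
  quantiles <- data.frame(measure = measures, qs, stringsAsFactors = FALSE)
  names(quantiles)[-1] <- paste0("p", probs * 100)
  hist_list <- lapply(measures, function(m) {
    x <- variation[[m]]
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(NULL)
    top <- max(bin_width, ceiling(max(x) / bin_width) * bin_width)
    breaks <- seq(0, top, by = bin_width)
    cnt <- as.integer(table(cut(x, breaks, right = FALSE,
                                include.lowest = TRUE)))
    data.frame(measure = m,
               bin_low = utils::head(breaks, -1),
               bin_high = breaks[-1],
               count = cnt,
               cumulative = cumsum(cnt),
               stringsAsFactors = FALSE)
  })
  list(medians = medians,
       quantiles = quantiles,
       histogram = do.call(rbind, hist_list))
}
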