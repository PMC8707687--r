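# Deterministic TSV report writers. CVs render at 1 decimal, other
# statistics at 4 significant digits; identical inputs produce
# byte-identical files.

#' @keywords internal
fmt_cv <- function(x) ifelse(is.na(x), "", formatC(x, format = "f",
                                                   digits = 1))

#' @keywords internal
fmt_num <- function(x) ifelse(is.na(x), "", formatC(x, format = "g",
                                                    digits = 6))

#' @keywords internal
write_tsv_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a variation table as a formatted TSV report
#'
#' CV columns are rendered at 1 decimal; means and SDs at 6 significant
#' digits. Column order and formatting are deterministic.
#'
#' @param variation variation table (needs `accession`; recognises the
#'   columns produced by [compute_variation()]).
#' @param path output TSV path.
#' @export
write_variation_table <- function(variation, path) {
  out <- data.frame(accession = variation$accession,
                    stringsAsFactors = FALSE)
  if (!is.null(variation$description)) out$description <- variation$description
  if (!is.null(variation$n_present)) out$n_present <- variation$n_present
  if (!is.null(variation$mean_total)) {
    out$mean_total <- fmt_num(variation$mean_total)
  }
  if (!is.null(variation$sd_total)) out$sd_total <- fmt_num(variation$sd_total)
  for (cv in c("cv_total", "cv_analytical", "cv_biological")) {
    if (!is.null(variation[[cv]])) out[[cv]] <- fmt_cv(variation[[cv]])
  }
  if (!is.null(variation$n_pairs_used)) {
    out$n_pairs_used <- variation$n_pairs_used
  }
  write_tsv_report(out, path)
}

#' Write a sample-size grid as a TSV report
#'
#' Rows are effect sizes, columns variance percentiles; cells read
#' `n (lo-hi)` when bootstrap intervals are present, plain `n` otherwise.
#' An empty grid writes headers only.
#'
#' @param grid a [sample_size_grid()] result.
#' @param path output TSV path.
#' @export
write_sample_size_grid <- function(grid, path) {
  cells <- format_grid_cells(grid)
  rn <- rownames(cells)
  if (is.null(rn)) rn <- character(nrow(cells))
  df <- cbind(data.frame(effect_size = rn,
                         stringsAsFactors = FALSE),
              as.data.frame(cells, stringsAsFactors = FALSE))
  write_tsv_report(df, path)
}

#' Write a reference-comparison table as a TSV report
#'
#' @param comparison result of [compare_to_reference()].
#' @param path output TSV path.
#' @export
write_comparison <- function(comparison, path) {
  out <- comparison
  for (cv in c("cv_total", "cv_analytical", "cv_biological",
               "eflm_cv_biological", "abs_diff")) {
    if (!is.null(out[[cv]])) out[[cv]] <- fmt_cv(out[[cv]])
  }
  if (!is.null(out$rel_diff)) out$rel_diff <- fmt_num(out$rel_diff)
  write_tsv_report(out, path)
}

#' Write all standard reports for an analysis
#'
#' Emits the per-protein variation table, the sample-size grid, the
#' reference comparison, box-plot style CV quantiles and CV histogram
#' counts into a directory. Any input left `NULL` is skipped.
#'
#' @param variation variation table, or `NULL`.
#' @param grid sample-size grid, or `NULL`.
#' @param comparison reference comparison, or `NULL`.
#' @param dir output directory (created if needed).
#' @param bin_width histogram bin width (percentage points).
#' @return character vector of files written.
#' @export
render_tables <- function(variation = NULL, grid = NULL,
                          comparison = NULL, dir = ".", bin_width = 5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  if (!is.null(variation)) {
    p <- file.path(dir, "variation_table.tsv")
    write_variation_table(variation, p)
    written <- c(written, p)
    s <- summarize_variation(variation, bin_width = bin_width)
    q <- s$quantiles
    q[-1] <- lapply(q[-1], fmt_cv)
    p <- file.path(dir, "cv_quantiles.tsv")
    write_tsv_report(q, p)
    written <- c(written, p)
    p <- file.path(dir, "cv_histogram.tsv")
    write_tsv_report(s$histogram, p)
    written <- c(written, p)
  }
  if (!is.null(grid)) {
    p <- file.path(dir, "sample_size_grid.tsv")
    write_sample_size_grid(grid, p)
    written <- c(written, p)
  }
  if (!is.null(comparison)) {
    p <- file.path(dir, "reference_comparison.tsv")
    write_comparison(comparison, p)
    written <- c(written, p)
  }
  invisible(written)
}
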