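# Shared builders for small in-code fixtures.

# A minimal two-plex map: per plex, control channels 126/131 (POOL) and two
# sample channels carrying one subject's duplicate preparation.
two_plex_map <- function() {
  data.frame(
    column_id = c("P01_126", "P01_127N", "P01_127C", "P01_131",
                  "P02_126", "P02_127N", "P02_127C", "P02_131"),
    plex = rep(1:2, each = 4),
    channel = rep(c("126", "127N", "127C", "131"), 2),
    subject_id = rep(c("POOL", "S01", "S01", "POOL",
                       "POOL", "S02", "S02", "POOL")),
    replicate = c(NA, 1, 2, NA, NA, 1, 2, NA),
    stringsAsFactors = FALSE
  )
}

# Matrix of the full duplicate design (84 sample + 22 control columns) in
# which protein k is present in exactly `counts[k]` of the 84 designed
# sample measurements; control cells are always present.
presence_matrix <- function(counts, seed = 42) {
  sim <- simulate_dataset(simulation_config(n_proteins = length(counts),
                                            seed = seed))
  smap <- sim$sample_map
  mat <- sim$matrix
  sample_cols <- smap$column_id[smap$subject_id != "POOL"]
  for (k in seq_along(counts)) {
    absent <- sample_cols[seq_len(length(sample_cols) - counts[k]) +
                            counts[k]]
    if (counts[k] < length(sample_cols)) mat[k, absent] <- NA_real_
  }
  list(matrix = mat, sample_map = smap)
}

# Variation-table stub from explicit CVs (cv scale percentiles only).
vt_from_cvs <- function(cvs) {
  data.frame(accession = sprintf("X%03d", seq_along(cvs)),
             n_present = 84,
             mean_total = 1,
             sd_total = cvs / 100,
             cv_total = cvs,
             cv_analytical = 0,
             n_pairs_used = 42,
             cv_biological = cvs,
             cv_bio_clamped = FALSE,
             stringsAsFactors = FALSE)
}
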