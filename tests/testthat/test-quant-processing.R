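test_that("impurity correction inverts the toy forward example", {
  map <- two_plex_map()[1:4, ]
  m <- matrix(c(0.95, 0.05, 0.05, 0.95), 2,
              dimnames = list(c("127N", "127C"), c("127N", "127C")))
  spec2 <- impurity_spec(m)
  observed <- matrix(c(95, 5), nrow = 1,
                     dimnames = list("P1", c("P01_127N", "P01_127C")))
  toy_map <- map[map$channel %in% c("127N", "127C"), ]
  corrected <- correct_impurities(observed, spec2, toy_map)
  expect_equal(unname(corrected[1, ]), c(100, 0), tolerance = 1e-12)
  # identity spec is a no-op
  full <- matrix(c(10, 100, 0, 20), nrow = 1,
                 dimnames = list("P1", map$column_id))
  expect_equal(correct_impurities(full, impurity_identity(), map), full,
               ignore_attr = "n_clipped")
})

test_that("simulate -> mix -> correct round-trips to < 1e-8 relative error", {
  spec <- read_impurity_table(system.file("extdata",
                                          "tmt10_impurity_synthetic.tsv",
                                          package = "tmtvar"))
  # round trip is exact only on complete data: a missing cell's received
  # leakage is unobservable, so correction around it is approximate
  sim <- simulate_dataset(simulation_config(n_proteins = 60, seed = 4))
  mixed <- apply_impurity_mixing(sim$matrix, spec, sim$sample_map)
  recovered <- correct_impurities(mixed, spec, sim$sample_map)
  expect_identical(is.na(recovered), is.na(sim$matrix))
  rel_err <- abs(recovered - sim$matrix) / sim$matrix
  expect_lt(max(rel_err, na.rm = TRUE), 1e-8)
  # with missing cells the correction stays within the leak magnitude
  simna <- simulate_dataset(simulation_config(n_proteins = 60, seed = 4,
                                              missing_rate = 0.05))
  mixedna <- apply_impurity_mixing(simna$matrix, spec, simna$sample_map)
  recna <- correct_impurities(mixedna, spec, simna$sample_map)
  expect_lt(max(abs(recna - simna$matrix) / simna$matrix, na.rm = TRUE),
            0.15)
})

test_that("singular mixing matrices are rejected naming the plex", {
  map <- two_plex_map()[1:4, ]
  singular <- matrix(c(0.5, 0.5, 0.5, 0.5), 2,
                     dimnames = list(c("127N", "127C"), c("127N", "127C")))
  spec <- impurity_spec(singular)
  toy <- matrix(c(50, 50), nrow = 1,
                dimnames = list("P1", c("P01_127N", "P01_127C")))
  toy_map <- map[map$channel %in% c("127N", "127C"), ]
  expect_error(correct_impurities(toy, spec, toy_map), "plex 1")
})

test_that("equal-sum normalization equalizes column sums", {
  mat <- matrix(c(1, 4, 5, 3, 9, 18), nrow = 3,
                dimnames = list(paste0("P", 1:3), c("P01_126", "P01_127N")))
  norm <- normalize_global_equal_sum(mat)
  expect_equal(unname(colSums(norm)), c(20, 20))
  # already-equal sums: identity
  expect_equal(normalize_global_equal_sum(norm), norm)
  # random simulated matrix with missingness: relative spread < 1e-9
  sim <- simulate_dataset(simulation_config(n_proteins = 80, seed = 21,
                                            missing_rate = 0.1))
  sums <- colSums(normalize_global_equal_sum(sim$matrix), na.rm = TRUE)
  expect_lt(diff(range(sums)) / mean(sums), 1e-9)
  # all-missing column is an error naming the column
  bad <- mat
  bad[, 2] <- NA_real_
  expect_error(normalize_global_equal_sum(bad), "P01_127N")
})

test_that("control scaling aligns plexes on the averaged control", {
  map <- two_plex_map()
  mat <- matrix(c(8, 16, 24, 8,
                  12, 24, 36, 12), nrow = 1,
                dimnames = list("P1", map$column_id))
  scaled <- scale_to_control(mat, map, "126")
  # controls 8 and 12 average to 10: plex 1 x 10/8, plex 2 x 10/12
  expect_equal(unname(scaled[1, ]), c(10, 20, 30, 10, 10, 20, 30, 10),
               ignore_attr = TRUE)
  # single plex: control already equals its own average
  one <- mat[, 1:4, drop = FALSE]
  expect_equal(scale_to_control(one, map[1:4, ], "126"), one,
               ignore_attr = "n_unscaled")
  # absent control channel errors naming the plex
  expect_error(scale_to_control(mat[, -5, drop = FALSE], map[-5, ], "126"),
               "plex")
})

test_that("control scaling removes generator-injected plex batch factors", {
  cfg <- simulation_config(n_proteins = 40, seed = 13, cv_biological = 25,
                           cv_analytical = 0, plex_factor_cv = 20)
  sim <- simulate_dataset(cfg)
  scaled <- scale_to_control(sim$matrix, sim$sample_map, "126")
  # residual per-plex factor: plex mean of value / latent true value; with
  # zero analytical noise the only across-plex structure left is batch
  smap <- sim$sample_map
  pool_cols <- smap$column_id[smap$subject_id == "POOL" &
                                smap$channel == "126"]
  pool_vals <- scaled[, pool_cols]
  resid <- colMeans(pool_vals / rowMeans(pool_vals))
  expect_lt(stats::sd(resid) / mean(resid) * 100, 1)
})

test_that("relative abundance divides by the plex control and drops pools", {
  map <- two_plex_map()
  mat <- matrix(c(25, 50, 75, 25,
                  10, 30, 5, 10), nrow = 1,
                dimnames = list("P1", map$column_id))
  rel <- relative_abundance(mat, map, "126")
  expect_identical(colnames(rel), c("P01_127N", "P01_127C",
                                    "P02_127N", "P02_127C"))
  expect_equal(unname(rel[1, ]), c(2, 3, 3, 0.5))
  # keeping controls: the anchor's self-ratio is identically 1
  rel_all <- relative_abundance(mat, map, "126", drop_controls = FALSE)
  expect_equal(unname(rel_all[1, c("P01_126", "P02_126")]), c(1, 1))
  # missing control knocks out that plex's ratios for the protein
  mat[1, "P02_126"] <- NA_real_
  rel_na <- relative_abundance(mat, map, "126")
  expect_true(all(is.na(rel_na[1, c("P02_127N", "P02_127C")])))
  expect_false(anyNA(rel_na[1, c("P01_127N", "P01_127C")]))
})

test_that("zero-noise ratios equal the closed form mu L / mean(A)", {
  sim <- simulate_dataset(simulation_config(n_proteins = 10, seed = 8,
                                            cv_biological = 30,
                                            cv_analytical = 0))
  rel <- relative_abundance(sim$matrix, sim$sample_map, "126")
  smap <- sim$sample_map
  smp <- smap[smap$subject_id != "POOL", ]
  # reconstruct latent A from the zero-noise matrix itself
  A <- sim$matrix[, smp$column_id[smp$replicate == 1]]
  pool <- rowMeans(A)
  for (cc in colnames(rel)) {
    subj <- smp$subject_id[smp$column_id == cc]
    idx <- match(subj, smp$subject_id[smp$replicate == 1])
    expect_equal(unname(rel[, cc]), unname(A[, idx] / pool),
                 tolerance = 1e-9)
  }
})

test_that("the composed pipeline is invariant to per-column input rescaling", {
  sim <- simulate_dataset(simulation_config(n_proteins = 50, seed = 17,
                                            missing_rate = 0.05,
                                            plex_factor_cv = 10))
  base <- process_reporter_matrix(sim$matrix, sim$sample_map)
  set.seed(99)
  consts <- stats::runif(ncol(sim$matrix), 0.2, 5)
  rescaled <- sweep(sim$matrix, 2, consts, `*`)
  again <- process_reporter_matrix(rescaled, sim$sample_map)
  expect_equal(again, base, tolerance = 1e-9)
})
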