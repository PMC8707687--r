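test_that("completeness filter is inclusive at the boundary over 84 designed", {
  px <- presence_matrix(c(41, 42, 43))
  kept <- suppressMessages(
    filter_by_completeness(px$matrix, px$sample_map, 0.5))
  expect_identical(rownames(kept), c("SIMP0002", "SIMP0003"))
  expect_message(filter_by_completeness(px$matrix, px$sample_map, 0.5),
                 "removed 1 of 3")
  expect_error(filter_by_completeness(px$matrix, px$sample_map, 0),
               "threshold")
})

test_that("hand-computable presence counts give the expected retained set", {
  counts <- c(0L, seq(10L, 80L, by = 10L), 84L)
  px <- presence_matrix(counts)
  kept <- suppressMessages(
    filter_by_completeness(px$matrix, px$sample_map, 0.5))
  expect_identical(rownames(kept),
                   rownames(px$matrix)[counts >= 42L])
})

test_that("analytical CV matches two-point hand computations", {
  map <- two_plex_map()
  mk <- function(v1, v2) {
    matrix(c(1, v1, v2, 1, 1, NA, NA, 1), nrow = 1,
           dimnames = list("P1", map$column_id))
  }
  same <- cv_analytical(mk(1.0, 1.0), map)
  expect_equal(same$cv_analytical, 0)
  expect_identical(same$n_pairs_used, 1L)
  pair <- cv_analytical(mk(0.9, 1.1), map)
  expect_equal(pair$cv_analytical, stats::sd(c(0.9, 1.1)) / 1 * 100,
               tolerance = 1e-12)
  expect_equal(pair$cv_analytical, 14.14214, tolerance = 1e-6)
  # a subject with a single present replicate is excluded entirely
  lone <- mk(0.9, NA)
  expect_true(is.na(cv_analytical(lone, map)$cv_analytical))
  expect_identical(cv_analytical(lone, map)$n_pairs_used, 0L)
})

test_that("duplicate-pair SD estimator shows the sqrt(2/pi) bias", {
  sim <- simulate_dataset(simulation_config(n_proteins = 10000, seed = 303,
                                            cv_biological = 0,
                                            cv_analytical = 5))
  ana <- cv_analytical(sim$matrix, sim$sample_map)
  expect_identical(unique(ana$n_pairs_used), 42L)
  expect_lt(abs(mean(ana$cv_analytical) - sqrt(2 / pi) * 5), 0.1)
})

test_that("total CV matches hand computations and flags short rows", {
  map <- two_plex_map()
  mat <- matrix(c(1, 1, 1, 1, 1, 1, 1, 1,
                  1, 0.8, 1.2, 1, 1, NA, NA, 1,
                  1, 2, NA, 1, 1, NA, NA, 1), nrow = 3, byrow = TRUE,
                dimnames = list(c("A", "B", "C"), map$column_id))
  tot <- cv_total(mat, map)
  expect_equal(tot$cv_total[1], 0)
  expect_equal(tot$mean_total[2], 1.0)
  expect_equal(tot$sd_total[2], 0.2828427, tolerance = 1e-6)
  expect_equal(tot$cv_total[2], 28.28427, tolerance = 1e-5)
  expect_true(is.na(tot$cv_total[3]))  # a single present value
  expect_identical(tot$n_present, c(4L, 2L, 1L))
})

test_that("zero-analytical-noise recovery approaches the true biological CV", {
  sim <- simulate_dataset(simulation_config(n_proteins = 600, seed = 41,
                                            cv_biological = 20,
                                            cv_analytical = 0))
  tot <- cv_total(sim$matrix, sim$sample_map)
  expect_lt(abs(stats::median(tot$cv_total) - 20), 1.5)
})

test_that("biological CV is the square-root difference of squares", {
  # published rows recompute to the printed value at 1 decimal
  expect_equal(as.numeric(round(cv_biological(92.3, 7.6), 1)), 92.0)
  expect_equal(as.numeric(round(cv_biological(38.3, 2.7), 1)), 38.2)
  # identity when the analytical component vanishes
  expect_equal(as.numeric(cv_biological(17.3, 0)), 17.3)
  # clamped to zero, flagged, when analytical exceeds total
  out <- cv_biological(c(10, 5), c(5, 10))
  expect_equal(as.numeric(out), c(sqrt(75), 0))
  expect_identical(attr(out, "clamped"), c(FALSE, TRUE))
  expect_error(cv_biological(-1, 5), "non-negative")
})

test_that("Pythagorean closure holds for every unclamped protein", {
  sim <- simulate_dataset(simulation_config(n_proteins = 200, seed = 53,
                                            missing_rate = 0.1))
  vt <- suppressMessages(compute_variation(sim$matrix, sim$sample_map))
  ok <- !is.na(vt$cv_biological) & !vt$cv_bio_clamped &
    !is.na(vt$cv_analytical)
  recomposed <- sqrt(vt$cv_biological[ok]^2 + vt$cv_analytical[ok]^2)
  expect_equal(recomposed, vt$cv_total[ok], tolerance = 1e-9)
})

test_that("per-protein CVs are invariant to rescaling a protein's row", {
  sim <- simulate_dataset(simulation_config(n_proteins = 20, seed = 61))
  vt1 <- compute_variation(sim$matrix, sim$sample_map, threshold = NULL)
  scaled <- sim$matrix * 1000
  vt2 <- compute_variation(scaled, sim$sample_map, threshold = NULL)
  expect_equal(vt2$cv_total, vt1$cv_total, tolerance = 1e-9)
  expect_equal(vt2$cv_analytical, vt1$cv_analytical, tolerance = 1e-9)
  expect_equal(vt2$cv_biological, vt1$cv_biological, tolerance = 1e-9)
})

test_that("cohort medians are ordered analytical < biological <= total", {
  sim <- simulate_dataset(simulation_config(n_proteins = 500, seed = 71,
                                            cv_biological = 19.2,
                                            cv_analytical = 5.3))
  vt <- compute_variation(sim$matrix, sim$sample_map)
  s <- summarize_variation(vt)
  expect_lt(s$medians["cv_analytical"], s$medians["cv_biological"])
  expect_lte(s$medians["cv_biological"], s$medians["cv_total"])
  # variance addition: median total CV near sqrt(5.3^2 + 19.2^2) ~ 19.9
  expect_lt(abs(s$medians["cv_total"] - sqrt(5.3^2 + 19.2^2)), 1.5)
})

test_that("summaries expose medians and conserving histograms", {
  one <- vt_from_cvs(12)
  s1 <- summarize_variation(one)
  expect_equal(unname(s1$medians["cv_total"]), 12)
  three <- vt_from_cvs(c(10, 20, 30))
  expect_equal(unname(summarize_variation(three)$medians["cv_total"]), 20)
  h <- summarize_variation(three)$histogram
  for (m in unique(h$measure)) {
    expect_identical(sum(h$count[h$measure == m]), 3L)
    expect_identical(max(h$cumulative[h$measure == m]), 3L)
  }
})

test_that("subject-means mode reduces the replicate-noise share of total CV", {
  sim <- simulate_dataset(simulation_config(n_proteins = 200, seed = 83,
                                            cv_biological = 10,
                                            cv_analytical = 15))
  meas <- cv_total(sim$matrix, sim$sample_map, over = "measurements")
  subj <- cv_total(sim$matrix, sim$sample_map, over = "subject_means")
  expect_lt(stats::median(subj$cv_total), stats::median(meas$cv_total))
})
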