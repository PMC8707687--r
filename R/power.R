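#' Parameters for sample-size and power calculations
#'
#' Collects the constants of the two-group normal-quantile sample-size
#' formula and the grid layout. At the defaults (two-sided alpha 0.05,
#' power 0.80) the normal quantiles are `z_alpha = 1.96` and
#' `z_beta = 0.8416`, giving the multiplier
#' `2 * (z_alpha + z_beta)^2 ~ 15.698`.
#'
#' @param alpha two-sided significance level.
#' @param power target power (1 - beta).
#' @param effect_sizes fold changes (> 1) to tabulate.
#' @param percentiles variance percentiles (in (0, 100]) to tabulate; the
#'   sample maximum is appended as its own column when `include_max`.
#' @param include_max include a "maximum variance" column.
#' @param bootstrap_reps bootstrap resamples for confidence intervals.
#' @param ci_level confidence level of the bootstrap intervals.
#' @param seed integer seed for the bootstrap.
#' @return object of class `power_params` with derived `z_alpha`,
#'   `z_beta`.
#' @export
power_params <- function(alpha = 0.05, power = 0.80,
                         effect_sizes = c(1.1, 1.2, 1.5, 2.0),
                         percentiles = c(70, 75, 80, 85),
                         include_max = TRUE,
                         bootstrap_reps = 1000,
                         ci_level = 0.95,
                         seed = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (power <= 0 || power >= 1) stop("power must lie in (0, 1)")
  if (any(effect_sizes <= 1)) stop("effect sizes (fold changes) must be > 1")
  if (any(percentiles <= 0 | percentiles > 100)) {
    stop("percentiles must lie in (0, 100]")
  }
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must lie in (0, 1)")
  structure(list(alpha = alpha, power = power,
                 z_alpha = stats::qnorm(1 - alpha / 2),
                 z_beta = stats::qnorm(power),
                 effect_sizes = effect_sizes,
                 percentiles = percentiles,
                 include_max = include_max,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 ci_level = ci_level,
                 seed = seed),
            class = "power_params")
}

#' Required per-group sample size (exact, pre-ceiling)
#'
#' `n = 2 (z_alpha + z_beta)^2 sigma^2 / delta^2` for a two-group
#' comparison of means with common SD `sigma` and absolute difference
#' `delta`. The two normal quantiles are summed: the usual convention
#' writes the formula with `z_{1-beta}` entering positively, and only the
#' sum reproduces the quadratic scaling of published sample-size grids
#' (`n` at fold 1.1 = 4 x `n` at fold 1.2).
#'
#' @param sigma standard deviation of the measurement (same scale as
#'   `delta`).
#' @param delta absolute between-group difference to detect.
#' @param params a [power_params()].
#' @return the un-ceiled sample size (numeric, vectorized).
#' @export
sample_size_exact <- function(sigma, delta, params = power_params()) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (any(delta <= 0)) stop("delta must be positive")
  2 * (params$z_alpha + params$z_beta)^2 * sigma^2 / delta^2
}

#' Required per-group sample size (integer)
#'
#' Ceiling of [sample_size_exact()]; always at least 1.
#'
#' @inheritParams sample_size_exact
#' @return integer sample size per group.
#' @examples
#' sample_size(1, 1)            # 16 at the defaults
#' sample_size(0.2, 0.5)        # 3
#' @export
sample_size <- function(sigma, delta, params = power_params()) {
  as.integer(ceiling(sample_size_exact(sigma, delta, params)))
}

#' Convert a fold change to an absolute effect
#'
#' On the relative-abundance scale (measurements are ratios to a pooled
#' control, centred near 1) a fold change `f` between groups corresponds
#' to the absolute difference `delta = (f - 1) * mean_ref`. With the CV
#' formulation (`mean_ref = 1`, sigma = CV/100) the required n depends on
#' the protein only through its CV.
#'
#' @param fold fold change (> 1).
#' @param mean_ref reference-group mean relative abundance.
#' @return absolute effect size `delta`.
#' @export
effect_to_delta <- function(fold, mean_ref = 1) {
  if (any(fold <= 1)) stop("fold change must be > 1")
  (fold - 1) * mean_ref
}

#' @keywords internal
grid_sigmas <- function(variation, params, scale) {
  if (scale == "cv") {
    x <- variation$cv_total[!is.na(variation$cv_total)] / 100
  } else {
    x <- variation$sd_total[!is.na(variation$sd_total)]
  }
  if (length(x) < 2L) stop("need at least 2 proteins with defined variation")
  sig <- stats::quantile(x, params$percentiles / 100, type = 7,
                         names = FALSE)
  labels <- paste0("p", params$percentiles)
  if (params$include_max) {
    sig <- c(sig, max(x))
    labels <- c(labels, "max")
  }
  names(sig) <- labels
  sig
}

#' @keywords internal
grid_matrices <- function(variation, params, scale) {
  sig <- grid_sigmas(variation, params, scale)
  mean_ref <- if (scale == "cv") 1 else {
    stats::median(variation$mean_total, na.rm = TRUE)
  }
  delta <- effect_to_delta(params$effect_sizes, mean_ref)
  exact <- outer(delta, sig, function(d, s)
    sample_size_exact(s, d, params))
  dimnames(exact) <- list(format(params$effect_sizes), names(sig))
  list(sigma = sig, exact = exact, n = ceiling(exact))
}

#' Sample-size grid over effect sizes and variance percentiles
#'
#' For each variance percentile `q`, `sigma_q` is the q-th empirical
#' percentile (linear interpolation) of per-protein variation — `CV_total
#' / 100` in the default CV formulation (with `mean_ref = 1`), or
#' `SD_total` in the SD formulation. "Maximum" is the sample maximum, not
#' a percentile. Each cell holds the per-group n required to detect the
#' row's fold change at the column's variance level.
#'
#' @param variation variation table from [compute_variation()] (needs
#'   `cv_total`; `sd_total` and `mean_total` for `scale = "sd"`).
#' @param params a [power_params()].
#' @param scale `"cv"` (default) or `"sd"`.
#' @return object of class `sample_size_grid`: list with `n` (integer
#'   matrix, effect sizes x percentiles), `exact` (pre-ceiling), `sigma`,
#'   `ci_low`/`ci_high` (`NULL` until [sample_size_ci()]), `params`,
#'   `scale`.
#' @export
sample_size_grid <- function(variation, params = power_params(),
                             scale = c("cv", "sd")) {
  scale <- match.arg(scale)
  if (nrow(variation) == 0L) stop("variation table is empty")
  g <- grid_matrices(variation, params, scale)
  structure(list(n = g$n, exact = g$exact, sigma = g$sigma,
                 ci_low = NULL, ci_high = NULL,
                 params = params, scale = scale),
            class = "sample_size_grid")
}

#' Bootstrap confidence intervals for the sample-size grid
#'
#' Nonparametric percentile bootstrap over proteins: rows of the variation
#' table are resampled with replacement, the percentile sigmas and every
#' grid cell are recomputed, and the `(1-ci)/2` and `1-(1-ci)/2` empirical
#' quantiles of the ceiled cell values give the interval. Seeded via
#' `params$seed`.
#'
#' @inheritParams sample_size_grid
#' @return a `sample_size_grid` with `ci_low` and `ci_high` filled in
#'   (integer matrices).
#' @export
sample_size_ci <- function(variation, params = power_params(),
                           scale = c("cv", "sd")) {
  scale <- match.arg(scale)
  if (params$bootstrap_reps < 100L) {
    stop("bootstrap_reps must be at least 100")
  }
  if (nrow(variation) < 2L) stop("need at least 2 proteins")
  grid <- sample_size_grid(variation, params, scale)
  if (!is.null(params$seed)) set.seed(params$seed)
  reps <- params$bootstrap_reps
  cells <- array(NA_real_, dim = c(dim(grid$n), reps))
  for (b in seq_len(reps)) {
    idx <- sample.int(nrow(variation), replace = TRUE)
    cells[, , b] <- grid_matrices(variation[idx, , drop = FALSE],
                                  params, scale)$n
  }
  probs <- c((1 - params$ci_level) / 2, 1 - (1 - params$ci_level) / 2)
  qs <- apply(cells, c(1, 2), stats::quantile, probs = probs,
              names = FALSE)
  ci_low <- ceiling(qs[1, , ])
  ci_high <- ceiling(qs[2, , ])
  dimnames(ci_low) <- dimnames(ci_high) <- dimnames(grid$n)
  grid$ci_low <- ci_low
  grid$ci_high <- ci_high
  grid
}

#' @export
print.sample_size_grid <- function(x, ...) {
  cat("sample_size_grid (", x$scale, " formulation; alpha = ",
      x$params$alpha, ", power = ", x$params$power, ")\n", sep = "")
  print(format_grid_cells(x))
  invisible(x)
}

# "n (lo-hi)" display cells; plain n when no intervals are present
#' @keywords internal
format_grid_cells <- function(grid) {
  n <- grid$n
  out <- matrix(format(n, trim = TRUE), nrow = nrow(n), ncol = ncol(n),
                dimnames = dimnames(n))
  if (!is.null(grid$ci_low)) {
    out[] <- sprintf("%d (%d-%d)", as.integer(n),
                     as.integer(grid$ci_low), as.integer(grid$ci_high))
  }
  out
}

#' Empirical power of the two-group comparison at a given n
#'
#' Monte-Carlo check of the sample-size formula: simulates two groups of
#' `n` normal observations with SD `sigma` whose means differ by `delta`
#' and reports the rejection rate. The default `"z"` test (known sigma)
#' matches the normal-quantile formula; the `"t"` option uses Welch's
#' t-test and reveals the formula's small-sample optimism.
#'
#' @param n per-group sample size.
#' @param sigma common SD.
#' @param delta true mean difference.
#' @param params a [power_params()] (supplies alpha).
#' @param reps Monte-Carlo replicates.
#' @param test `"z"` or `"t"`.
#' @param seed optional seed.
#' @return empirical power (fraction of rejections).
#' @export
empirical_power <- function(n, sigma, delta, params = power_params(),
                            reps = 10000, test = c("z", "t"),
                            seed = NULL) {
  test <- match.arg(test)
  if (!is.null(seed)) set.seed(seed)
  crit <- stats::qnorm(1 - params$alpha / 2)
  if (test == "z") {
    se <- sigma * sqrt(2 / n)
    diffs <- stats::rnorm(reps, mean = delta, sd = se)
    return(mean(abs(diffs / se) > crit))
  }
  rej <- logical(reps)
  for (b in seq_len(reps)) {
    x <- stats::rnorm(n, 0, sigma)
    y <- stats::rnorm(n, delta, sigma)
    rej[b] <- stats::t.test(x, y)$p.value < params$alpha
  }
  mean(rej)
}
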