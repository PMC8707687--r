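#' Configuration for the duplicate-design TMT simulator
#'
#' Describes a multiplexed plasma-proteome experiment in which `n_subjects`
#' individuals are each prepared `n_replicates` times and distributed over
#' 10-plex sets whose channels 126 and 131 carry a pooled internal control.
#' The defaults emulate the duplicate design this package targets:
#' 42 subjects x 2 replicate preparations = 84 sample measurements filling
#' eleven 10-plexes (8 sample channels each), with per-protein biological
#' CV 19.2% and analytical CV 5.3% (cohort medians typical of abundant
#' plasma proteins measured by TMT LC-MS/MS).
#'
#' Both noise components are multiplicative log-normal, parameterized so
#' the *stated* CV is the distribution's true coefficient of variation
#' (`sdlog = sqrt(log(1 + (cv/100)^2))`, unit mean). Plasma protein
#' concentrations are positive and biological CVs can approach 100%, where
#' additive Gaussian noise would produce negative abundances.
#'
#' @param n_proteins number of simulated proteins.
#' @param n_subjects number of individuals.
#' @param n_replicates replicate preparations per individual (2 for the
#'   duplicate design).
#' @param channels_per_plex channels per plex; the supported layout is 10.
#' @param control_channels labels of pooled-control channels.
#' @param cv_biological per-protein inter-individual biological CV in
#'   percent: a scalar (recycled), a vector of length `n_proteins`, or a
#'   function of `n` returning such a vector.
#' @param cv_analytical per-protein analytical CV in percent; same forms.
#' @param missing_rate probability in `[0, 1)` that any cell is missing
#'   (missing completely at random); scalar or per-protein vector.
#' @param mean_log10_range range of `log10` true mean abundances; means are
#'   drawn log-uniformly (reporter intensities of abundant plasma proteins
#'   span several orders of magnitude).
#' @param plex_factor_cv CV (percent) of optional log-normal plex-level
#'   batch multipliers; 0 disables batch effects.
#' @param duplicate_layout how replicate pairs are assigned to plexes:
#'   `"random"` (seeded permutation; duplicates may or may not share a
#'   plex), `"same_plex"` (duplicates co-plexed), or `"cross_plex"`
#'   (duplicates forced into different plexes).
#' @param impurity_spec optional [impurity_spec()] applied as a forward
#'   mixing model to the generated signals.
#' @param seed integer seed; the simulation is reproducible given the seed.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_proteins = 265,
                              n_subjects = 42,
                              n_replicates = 2,
                              channels_per_plex = 10,
                              control_channels = c("126", "131"),
                              cv_biological = 19.2,
                              cv_analytical = 5.3,
                              missing_rate = 0,
                              mean_log10_range = c(5, 9),
                              plex_factor_cv = 0,
                              duplicate_layout = c("random", "same_plex",
                                                   "cross_plex"),
                              impurity_spec = NULL,
                              seed = NULL) {
  duplicate_layout <- match.arg(duplicate_layout)
  if (n_proteins < 1) stop("need at least 1 protein to simulate")
  if (n_subjects < 1) stop("need at least 1 subject")
  if (n_replicates < 1) stop("need at least 1 replicate")
  if (channels_per_plex != 10) {
    stop("the supported layout is the 10-plex kit; got channels_per_plex = ",
         channels_per_plex)
  }
  if (!all(control_channels %in% TMT10_CHANNELS)) {
    stop("control channels must be TMT10 labels")
  }
  if (any(missing_rate < 0) || any(missing_rate >= 1)) {
    stop("missing_rate must lie in [0, 1)")
  }
  if (plex_factor_cv < 0) stop("plex_factor_cv must be >= 0")
  if (!is.null(impurity_spec) && !inherits(impurity_spec, "impurity_spec")) {
    stop("impurity_spec must be built with impurity_spec()")
  }
  cfg <- structure(list(
    n_proteins = as.integer(n_proteins),
    n_subjects = as.integer(n_subjects),
    n_replicates = as.integer(n_replicates),
    channels_per_plex = as.integer(channels_per_plex),
    control_channels = as.character(control_channels),
    cv_biological = cv_biological,
    cv_analytical = cv_analytical,
    missing_rate = missing_rate,
    mean_log10_range = mean_log10_range,
    plex_factor_cv = plex_factor_cv,
    duplicate_layout = duplicate_layout,
    impurity_spec = impurity_spec,
    seed = seed
  ), class = "simulation_config")
  cfg
}

#' @export
format.simulation_config <- function(x, ...) {
  fmt_num <- function(v) paste(format(v, trim = TRUE), collapse = ",")
  keys <- c(
    n_proteins = x$n_proteins,
    n_subjects = x$n_subjects,
    n_replicates = x$n_replicates,
    channels_per_plex = x$channels_per_plex,
    control_channels = paste(x$control_channels, collapse = ","),
    cv_biological = if (is.function(x$cv_biological)) "<function>"
                    else fmt_num(x$cv_biological),
    cv_analytical = if (is.function(x$cv_analytical)) "<function>"
                    else fmt_num(x$cv_analytical),
    missing_rate = fmt_num(x$missing_rate),
    mean_log10_range = fmt_num(x$mean_log10_range),
    plex_factor_cv = fmt_num(x$plex_factor_cv),
    duplicate_layout = x$duplicate_layout,
    impurity = if (is.null(x$impurity_spec)) "none" else "custom",
    seed = if (is.null(x$seed)) "none" else x$seed
  )
  paste0(names(keys), " = ", unname(keys))
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config\n")
  cat(paste0("  ", format(x)), sep = "\n")
  invisible(x)
}

#' Write a simulation config as a key = value text file
#'
#' @param config a [simulation_config()].
#' @param path output file.
#' @export
write_simulation_config <- function(config, path) {
  writeLines(format(config), path)
  invisible(path)
}

# Resolve a CV / rate parameter to a per-protein vector.
#' @keywords internal
resolve_per_protein <- function(x, n, what, positive = TRUE) {
  v <- if (is.function(x)) x(n) else x
  if (length(v) == 1L) v <- rep(v, n)
  if (length(v) != n) {
    stop(what, " must be a scalar, a length-", n,
         " vector, or a function of n")
  }
  v <- as.numeric(v)
  if (positive && any(v < 0)) stop(what, " must be non-negative")
  v
}

# log-normal with unit mean and the given percent CV
#' @keywords internal
rlnorm_unit <- function(n, cv_percent) {
  sdlog <- sqrt(log1p((cv_percent / 100)^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Assign the n_subjects x n_replicates measurements to plex slots.
# Returns a data.frame (subject, replicate, plex, slot_in_plex).
#' @keywords internal
assign_layout <- function(n_subjects, n_replicates, slots_per_plex,
                          duplicate_layout) {
  n_meas <- n_subjects * n_replicates
  n_plex <- ceiling(n_meas / slots_per_plex)
  meas <- expand.grid(replicate = seq_len(n_replicates),
                      subject = seq_len(n_subjects))[, c("subject",
                                                         "replicate")]
  order_random <- function() sample.int(n_meas)
  ord <- switch(duplicate_layout,
    same_plex = {
      # subject-blocked order keeps pairs adjacent; slots_per_plex is even
      # in the 10-plex layout so adjacent pairs share a plex
      subj <- sample.int(n_subjects)
      as.vector(vapply(subj, function(s)
        which(meas$subject == s), integer(n_replicates)))
    },
    cross_plex = {
      ok <- FALSE
      for (try in seq_len(2000L)) {
        o <- order_random()
        px <- (match(seq_len(n_meas), o) - 1L) %/% slots_per_plex
        ok <- !any(tapply(px, meas$subject, function(p)
          anyDuplicated(p) > 0L))
        if (ok) break
      }
      if (!ok) stop("could not find a cross-plex assignment; ",
                    "too few plexes for the requested layout")
      o
    },
    random = order_random()
  )
  pos <- match(seq_len(n_meas), ord)
  data.frame(subject = meas$subject,
             replicate = meas$replicate,
             plex = (pos - 1L) %/% slots_per_plex + 1L,
             slot = (pos - 1L) %% slots_per_plex + 1L)
}

#' Simulate a duplicate-design multiplexed reporter dataset
#'
#' Generates a reporter matrix with known ground truth. For protein *p* and
#' subject *i* the true abundance is `A_pi = mu_p * L_pi`, with `L_pi`
#' log-normal, unit mean, CV `cv_biological[p]/100`. Every measurement
#' (each replicate preparation) observes `A_pi * E` with `E` log-normal,
#' unit mean, CV `cv_analytical[p]/100`, drawn independently per cell.
#' Pooled-control channels carry the arithmetic mean of all sample true
#' abundances for the protein, subject to their own analytical noise draw.
#' Optional plex batch multipliers, forward impurity mixing, and MCAR
#' missingness are applied in that order.
#'
#' @param config a [simulation_config()].
#' @return list with elements
#'   \describe{
#'     \item{matrix}{proteins x columns reporter matrix (`NA` = missing),
#'       columns named `<plex>_<channel>`.}
#'     \item{sample_map}{data.frame (`column_id`, `plex`, `channel`,
#'       `subject_id`, `replicate`); pooled controls have
#'       `subject_id = "POOL"` and `replicate = NA`.}
#'     \item{truth}{per-protein ground truth (`accession`, `true_mean`,
#'       `true_cv_bio`, `true_cv_analytical`, `missing_rate`).}
#'     \item{plex_factors}{the batch multipliers actually applied.}
#'     \item{config}{the input configuration.}
#'   }
#' @examples
#' sim <- simulate_dataset(simulation_config(n_proteins = 20, seed = 1))
#' dim(sim$matrix)
#' table(sim$sample_map$subject_id == "POOL")
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  np <- config$n_proteins
  ns <- config$n_subjects
  nr <- config$n_replicates

  cv_bio <- resolve_per_protein(config$cv_biological, np, "cv_biological")
  cv_ana <- resolve_per_protein(config$cv_analytical, np, "cv_analytical")
  miss <- resolve_per_protein(config$missing_rate, np, "missing_rate")
  if (any(miss >= 1)) stop("missing_rate must lie in [0, 1)")

  sample_channels <- setdiff(TMT10_CHANNELS, config$control_channels)
  slots_per_plex <- length(sample_channels)
  layout <- assign_layout(ns, nr, slots_per_plex, config$duplicate_layout)
  n_plex <- max(layout$plex)

  accession <- sprintf("SIMP%04d", seq_len(np))
  subj_id <- sprintf("S%02d", seq_len(ns))
  mu <- 10^stats::runif(np, config$mean_log10_range[1],
                        config$mean_log10_range[2])

  # latent per-subject true abundances
  L <- matrix(rlnorm_unit(np * ns, cv_bio), nrow = np)
  A <- mu * L
  # pooled control: mean of all sample true abundances (equal replicate
  # multiplicity makes this the across-subject mean)
  pool_true <- rowMeans(A)

  # sample map: sample slots in layout order, then the control channels
  smap_samples <- data.frame(
    column_id = column_key(layout$plex, sample_channels[layout$slot]),
    plex = layout$plex,
    channel = sample_channels[layout$slot],
    subject_id = subj_id[layout$subject],
    replicate = layout$replicate,
    stringsAsFactors = FALSE
  )
  smap_ctrl <- expand.grid(channel = config$control_channels,
                           plex = seq_len(n_plex),
                           stringsAsFactors = FALSE)
  smap_ctrl <- data.frame(
    column_id = column_key(smap_ctrl$plex, smap_ctrl$channel),
    plex = smap_ctrl$plex,
    channel = smap_ctrl$channel,
    subject_id = "POOL",
    replicate = NA_integer_,
    stringsAsFactors = FALSE
  )
  smap <- rbind(smap_samples, smap_ctrl)
  ord <- order(smap$plex, match(smap$channel, TMT10_CHANNELS))
  smap <- smap[ord, , drop = FALSE]
  rownames(smap) <- NULL

  mat <- matrix(NA_real_, nrow = np, ncol = nrow(smap),
                dimnames = list(accession, smap$column_id))
  is_pool <- smap$subject_id == "POOL"
  true_col <- matrix(NA_real_, nrow = np, ncol = nrow(smap))
  true_col[, is_pool] <- pool_true
  subj_idx <- match(smap$subject_id, subj_id)
  true_col[, !is_pool] <- A[, subj_idx[!is_pool], drop = FALSE]

  E <- matrix(rlnorm_unit(np * nrow(smap), cv_ana), nrow = np)
  mat[] <- true_col * E

  plex_factors <- rep(1, n_plex)
  if (config$plex_factor_cv > 0) {
    plex_factors <- rlnorm_unit(n_plex, config$plex_factor_cv)
    mat <- sweep(mat, 2, plex_factors[smap$plex], `*`)
  }
  if (!is.null(config$impurity_spec)) {
    mat <- apply_impurity_mixing(mat, config$impurity_spec, smap)
  }
  if (any(miss > 0)) {
    drop <- matrix(stats::runif(np * nrow(smap)) < miss, nrow = np)
    mat[drop] <- NA_real_
  }

  truth <- data.frame(accession = accession,
                      true_mean = mu,
                      true_cv_bio = cv_bio,
                      true_cv_analytical = cv_ana,
                      missing_rate = miss,
                      stringsAsFactors = FALSE)
  list(matrix = mat, sample_map = smap, truth = truth,
       plex_factors = plex_factors, config = config)
}
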