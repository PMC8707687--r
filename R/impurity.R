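#' Construct an isotope-impurity specification
#'
#' Reporter ion signals leak between channels because the isobaric labels
#' are not isotopically pure. The leakage is modelled as a column-stochastic
#' mixing matrix `M`: `M[i, j]` is the fraction of channel `j`'s true signal
#' observed in channel `i`, and `observed = M %*% true` within each plex.
#' Columns may sum to less than 1 when part of a channel's signal leaks
#' outside the measured channel set (that signal is lost).
#'
#' @param mixing square numeric matrix, rows and columns in channel order.
#' @param channels character channel labels; defaults to
#'   `colnames(mixing)`.
#' @return an object of class `impurity_spec`.
#' @seealso [impurity_from_factors()] for kit-style percentage tables,
#'   [impurity_identity()] for the no-leakage spec.
#' @export
impurity_spec <- function(mixing, channels = colnames(mixing)) {
  mixing <- as.matrix(mixing)
  if (nrow(mixing) != ncol(mixing)) {
    stop("mixing matrix must be square")
  }
  if (is.null(channels)) {
    stop("channel labels are required (set colnames or pass `channels`)")
  }
  if (length(channels) != ncol(mixing)) {
    stop("length of `channels` must match the mixing matrix dimension")
  }
  if (any(mixing < 0)) {
    stop("impurity fractions must be non-negative")
  }
  tol <- 1e-8
  # columns are source channels: retained + leaked fractions sum to <= 1
  # (rows may exceed 1 only pathologically -- a channel cannot receive more
  # than the total signal of all sources, which colSums already bounds)
  if (any(colSums(mixing) > 1 + tol)) {
    stop("column sums of the mixing matrix exceed 1: ",
         "each channel's retained + leaked fractions must sum to at most 1")
  }
  dimnames(mixing) <- list(channels, channels)
  structure(list(channels = as.character(channels), mixing = mixing),
            class = "impurity_spec")
}

#' Identity (no leakage) impurity specification
#'
#' @param channels channel labels; defaults to the TMT 10-plex set.
#' @return an `impurity_spec` whose mixing matrix is the identity.
#' @export
impurity_identity <- function(channels = TMT10_CHANNELS) {
  impurity_spec(diag(length(channels)), channels = channels)
}

#' Build an impurity spec from a kit-style correction-factor table
#'
#' Vendor kits report, for each label, the percentage of its signal that
#' appears two channels below (`minus2`), one below (`minus1`), one above
#' (`plus1`) and two above (`plus2`) in the reporter-mass sequence. The
#' retained (diagonal) fraction is one minus the sum of the four leak
#' fractions; leakage off either end of the channel sequence is lost.
#'
#' Positions are taken along the plex's channel sequence
#' (126, 127N, ..., 131), a common simplification of the true N/C
#' isotopologue routing.
#'
#' @param factors data.frame with columns `channel`, `minus2`, `minus1`,
#'   `plus1`, `plus2` (percent).
#' @return an `impurity_spec`.
#' @export
impurity_from_factors <- function(factors) {
  required <- c("channel", "minus2", "minus1", "plus1", "plus2")
  if (!all(required %in% names(factors))) {
    stop("factor table needs columns: ", paste(required, collapse = ", "))
  }
  ch <- as.character(factors$channel)
  k <- length(ch)
  frac <- as.matrix(factors[, c("minus2", "minus1", "plus1", "plus2")]) / 100
  if (any(frac < 0)) stop("impurity fractions must be non-negative")
  if (any(rowSums(frac) > 1)) {
    stop("per-channel impurity fractions sum to more than 100%")
  }
  offsets <- c(-2L, -1L, 1L, 2L)
  m <- matrix(0, k, k, dimnames = list(ch, ch))
  for (j in seq_len(k)) {
    for (o in seq_along(offsets)) {
      i <- j + offsets[o]
      if (i >= 1L && i <= k) m[i, j] <- frac[j, o]
    }
    m[j, j] <- 1 - sum(frac[j, ])
  }
  impurity_spec(m, channels = ch)
}

#' Read a kit-style impurity table from TSV
#'
#' @param path TSV file with columns `channel`, `minus2`, `minus1`,
#'   `plus1`, `plus2` (percent).
#' @return an `impurity_spec`.
#' @export
read_impurity_table <- function(path) {
  impurity_from_factors(utils::read.delim(path, check.names = TRUE,
                                          stringsAsFactors = FALSE))
}

#' @export
print.impurity_spec <- function(x, ...) {
  cat("impurity_spec:", length(x$channels), "channels;",
      "retained fractions", paste(round(diag(x$mixing), 3), collapse = " "),
      "\n")
  invisible(x)
}

# Mixing restricted to the channels present in one plex. Channels with no
# column (unused slots in a partially filled plex) carry no signal and
# receive none that we could store, so both the forward model and the
# inverse operate on M[present, present]; this keeps mix -> correct an
# exact round trip.
#' @keywords internal
plex_mixing <- function(spec, channels) {
  missing_ch <- setdiff(channels, spec$channels)
  if (length(missing_ch) > 0L) {
    stop("impurity spec lacks channel(s): ",
         paste(missing_ch, collapse = ", "))
  }
  spec$mixing[channels, channels, drop = FALSE]
}

#' @keywords internal
apply_per_plex <- function(matrix, sample_map, spec, fun) {
  sample_map <- validate_sample_map(sample_map, matrix)
  out <- matrix
  n_clipped <- 0L
  for (px in sort(unique(sample_map$plex))) {
    rows <- sample_map[sample_map$plex == px, , drop = FALSE]
    rows <- rows[rows$column_id %in% colnames(matrix), , drop = FALSE]
    ord <- match(rows$channel, TMT10_CHANNELS)
    rows <- rows[order(ifelse(is.na(ord), seq_along(ord) + 100L, ord)), ,
                 drop = FALSE]
    m <- plex_mixing(spec, rows$channel)
    y <- t(matrix[, rows$column_id, drop = FALSE])   # channels x proteins
    na_mask <- is.na(y)
    y[na_mask] <- 0
    x <- fun(m, y, px)
    clip <- x < 0
    n_clipped <- n_clipped + sum(clip & !na_mask)
    x[clip] <- 0
    x[na_mask] <- NA_real_
    out[, rows$column_id] <- t(x)
  }
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Forward isotope-impurity mixing (simulation model)
#'
#' Applies the column-stochastic mixing matrix to each plex's channel
#' vector, per protein: `observed = M %*% true`. Missing cells contribute
#' nothing and stay missing. This is the forward model whose inverse is
#' [correct_impurities()]; the pair round-trips exactly.
#'
#' @param matrix reporter matrix (proteins x columns, `NA` = missing).
#' @param spec an [impurity_spec()].
#' @param sample_map sample map resolving each column to (plex, channel).
#' @return mixed reporter matrix of the same shape.
#' @export
apply_impurity_mixing <- function(matrix, spec, sample_map) {
  stopifnot(inherits(spec, "impurity_spec"))
  out <- apply_per_plex(matrix, sample_map, spec,
                        function(m, y, px) m %*% y)
  attr(out, "n_clipped") <- NULL
  out
}

#' Correct reporter signals for isotope impurities
#'
#' Solves the per-plex linear mixing system `M %*% true = observed` for the
#' true channel intensities of every protein. Missing cells are treated as
#' zero during the solve and restored to missing afterwards — the leakage
#' a missing cell received is unobservable, so correction of its
#' neighbours is approximate (error bounded by the leak fractions);
#' on complete data the inverse of [apply_impurity_mixing()] is exact.
#' Negative
#' solutions (possible with noisy data) are clipped to zero and counted in
#' the `n_clipped` attribute (a message reports the count).
#'
#' @inheritParams apply_impurity_mixing
#' @param kappa_max condition-number threshold above which the plex's
#'   mixing matrix is rejected as ill-conditioned.
#' @return corrected reporter matrix; attribute `n_clipped` holds the
#'   number of negative solutions clipped to zero.
#' @export
correct_impurities <- function(matrix, spec, sample_map, kappa_max = 1e8) {
  stopifnot(inherits(spec, "impurity_spec"))
  out <- apply_per_plex(matrix, sample_map, spec, function(m, y, px) {
    kappa <- kappa(m, exact = TRUE)
    if (!is.finite(kappa) || kappa > kappa_max) {
      stop("mixing matrix for plex ", px, " is singular or ill-conditioned",
           " (condition number ", format(kappa, digits = 3), ")")
    }
    solve(m, y)
  })
  if (attr(out, "n_clipped") > 0L) {
    message("correct_impurities: clipped ", attr(out, "n_clipped"),
            " negative solution(s) to zero")
  }
  out
}
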