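#' Global signal regression
#'
#' Removes the global signal — the mean time series over all grayordinate
#' rows — from every row by least squares, then re-centers and renormalizes
#' the rows. Every returned row is exactly orthogonal to the global signal.
#' Note that this operation mathematically induces negative correlations in
#' subsequent seed-based maps even when all underlying couplings are
#' nonnegative; it is provided for comparison, not as a recommendation.
#'
#' @param data Row-normalized space x time matrix.
#' @return Matrix of the same shape, row-normalized and orthogonal to the
#'   global signal. Errors if the global signal is numerically zero, or if a
#'   row is left (numerically) dead by the regression.
#' @export
global_signal_regress <- function(data) {
  check_normalized(data, what = "data", require_centered = TRUE)
  g <- colMeans(data)
  gn2 <- sum(g^2)
  if (gn2 < 1e-20) stop("global signal is numerically zero")
  coef <- drop(data %*% g) / gn2
  resid <- data - outer(coef, g)
  normalize_timeseries(resid)
}

#' Seed-based subcortical correlation map
#'
#' Places a single-vertex seed at a cortical grayordinate and computes, per
#' subject (optionally after \code{\link{global_signal_regress}}), the
#' Pearson correlation between the seed's time series and every subcortical
#' voxel's time series. Subject maps are combined by Fisher z-averaging
#' (correlations are clipped to +/-(1 - 1e-12) before the transform). Note
#' that temporal synchronization does not change these full-window
#' correlations, so the map may be computed on raw or synced data
#' identically.
#'
#' @param dataset A row-normalized \code{\link{grayordinate_dataset}}.
#' @param seed_index Grayordinate index of the seed; must be cortical.
#' @param gsr Apply global signal regression first.
#' @return An object of class \code{seed_correlation_map}: list with
#'   \code{seed_index}, \code{gsr}, \code{per_subject_maps} (subcortical x
#'   subject matrix of r values), \code{group_map} (inverse-Fisher of the
#'   mean z) and \code{n_subjects}.
#' @export
seed_correlation_map <- function(dataset, seed_index, gsr = FALSE) {
  stopifnot(inherits(dataset, "grayordinate_dataset"))
  seed_index <- as.integer(seed_index)
  if (!seed_index %in% dataset$cortical_index) {
    stop("seed must be a cortical grayordinate index")
  }
  si <- dataset$subcortical_index
  s <- n_subjects(dataset)
  per <- matrix(NA_real_, length(si), s)
  for (i in seq_len(s)) {
    x <- dataset$subjects[[i]]
    if (gsr) x <- global_signal_regress(x)
    seed_row <- x[seed_index, ]
    if (stats::sd(seed_row) == 0) {
      stop(sprintf("seed time series is constant in subject %d", i))
    }
    sr <- seed_row - mean(seed_row)
    sr <- sr / sqrt(sum(sr^2))
    xs <- x[si, , drop = FALSE]
    xs <- xs - rowMeans(xs)
    xs <- xs / sqrt(rowSums(xs^2))
    per[, i] <- drop(xs %*% sr)
  }
  clip <- 1 - 1e-12
  z <- fisher_z(pmin(pmax(per, -clip), clip))
  structure(
    list(
      seed_index = seed_index,
      gsr = isTRUE(gsr),
      per_subject_maps = per,
      group_map = inv_fisher_z(rowMeans(z)),
      n_subjects = s
    ),
    class = "seed_correlation_map"
  )
}

#' Compare two subcortical maps
#'
#' Quantifies the agreement between two maps (e.g. a tensor-derived network
#' map and a seed-based correlation map) over their common finite support:
#' Pearson correlation, Spearman rank correlation, and the fraction of
#' voxels on which the signs agree.
#'
#' @param map_a,map_b Numeric vectors of equal length with at least 3 common
#'   finite entries.
#' @return List with \code{pearson}, \code{spearman} and
#'   \code{sign_agreement}.
#' @export
compare_maps <- function(map_a, map_b) {
  stopifnot(length(map_a) == length(map_b))
  ok <- is.finite(map_a) & is.finite(map_b)
  if (sum(ok) < 3L) stop("need at least 3 common finite entries")
  a <- map_a[ok]; b <- map_b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero-variance input: correlations undefined")
  }
  list(
    pearson = stats::cor(a, b),
    spearman = stats::cor(a, b, method = "spearman"),
    sign_agreement = mean(sign(a) == sign(b))
  )
}
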