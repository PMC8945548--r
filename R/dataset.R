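#' Multi-subject grayordinate dataset
#'
#' Container for per-subject space x time BOLD matrices sampled on a shared
#' "grayordinate"-style space: a set of cortical vertices plus a set of
#' subcortical voxels arranged on a 3-D integer grid. The two index sets are
#' disjoint and together cover every row of the subject matrices.
#'
#' @param subjects List of numeric matrices, all of identical dimension
#'   (space x time), one per subject.
#' @param cortical_index Integer indices into the space axis for cortical
#'   vertices.
#' @param subcortical_index Integer indices for subcortical voxels (disjoint
#'   from \code{cortical_index}; the union must cover all rows).
#' @param subcortical_grid_coords Integer matrix (one row per subcortical
#'   voxel, columns x/y/z) giving each subcortical voxel's position on the
#'   3-D grid.
#' @param grid_dims Dimensions of the subcortical grid.
#' @param subject_ids Optional character labels; defaults to
#'   \code{"sub-01"}, ...
#' @param normalize If \code{TRUE}, rows of every subject matrix are centered
#'   and scaled to unit norm with \code{\link{normalize_timeseries}}.
#'
#' @return An object of class \code{grayordinate_dataset}.
#' @export
grayordinate_dataset <- function(subjects, cortical_index, subcortical_index,
                                 subcortical_grid_coords = NULL,
                                 grid_dims = NULL, subject_ids = NULL,
                                 normalize = FALSE) {
  stopifnot(is.list(subjects), length(subjects) >= 1L)
  dims <- vapply(subjects, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all subject matrices must share identical dimensions")
  }
  v <- dims[1, 1]
  cortical_index <- as.integer(cortical_index)
  subcortical_index <- as.integer(subcortical_index)
  if (length(intersect(cortical_index, subcortical_index)) > 0L) {
    stop("cortical and subcortical index sets overlap")
  }
  if (!setequal(c(cortical_index, subcortical_index), seq_len(v))) {
    stop("cortical and subcortical indices must partition the space axis")
  }
  if (!is.null(subcortical_grid_coords)) {
    subcortical_grid_coords <- as.matrix(subcortical_grid_coords)
    stopifnot(nrow(subcortical_grid_coords) == length(subcortical_index),
              ncol(subcortical_grid_coords) == 3L)
  }
  if (normalize) subjects <- lapply(subjects, normalize_timeseries)
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("sub-%02d", seq_along(subjects))
  }
  structure(
    list(
      subjects = subjects,
      cortical_index = cortical_index,
      subcortical_index = subcortical_index,
      subcortical_grid_coords = subcortical_grid_coords,
      grid_dims = grid_dims,
      subject_ids = subject_ids
    ),
    class = "grayordinate_dataset"
  )
}

#' @export
print.grayordinate_dataset <- function(x, ...) {
  cat(sprintf(
    "grayordinate_dataset: %d subjects, V = %d (%d cortical + %d subcortical), T = %d\n",
    length(x$subjects), nrow(x$subjects[[1]]), length(x$cortical_index),
    length(x$subcortical_index), ncol(x$subjects[[1]])
  ))
  invisible(x)
}

n_space <- function(dataset) nrow(dataset$subjects[[1]])
n_time <- function(dataset) ncol(dataset$subjects[[1]])
n_subjects <- function(dataset) length(dataset$subjects)
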