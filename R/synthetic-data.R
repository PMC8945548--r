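#' Configuration for the synthetic grayordinate generator
#'
#' Defines the study conditions emulated by \code{\link{generate_dataset}}:
#' a group of subjects sharing a small number of low-rank spatiotemporal
#' networks (one of them a dominant global "physiological" component), with
#' subject-specific participation levels, per-subject temporal misalignment
#' by random orthogonal transforms, and additive Gaussian noise.
#'
#' @param n_cortical_vertices Number of cortical vertices.
#' @param subcortical_grid 3-D dimensions of the subcortical voxel grid; the
#'   number of subcortical voxels is their product.
#' @param n_timepoints Number of time frames per subject.
#' @param n_subjects Number of subjects (at least 2).
#' @param n_networks Ground-truth rank, including the global component.
#' @param network_magnitudes Positive network magnitudes (lambda), sorted
#'   descending; the first (largest) entry is the global component, the
#'   second the DMN-like target network.
#' @param snr Ratio of signal variance to noise variance per subject;
#'   \code{Inf} disables noise.
#' @param temporal_band Frequency band (cycles/frame) for the band-limited
#'   network dynamics. The default 0.01--0.1 matches the slow fluctuations
#'   typical of resting-state BOLD at a 1 s frame interval.
#' @param misalign If \code{TRUE}, each subject's data is rotated on the
#'   time axis by a random (Haar) orthogonal transform, emulating the
#'   temporal asynchrony of spontaneous activity across subjects.
#' @param seed Integer seed; all generator randomness derives from it.
#' @param keep_noise If \code{TRUE}, the realized noise matrices are stored
#'   in the ground truth (memory permitting) so signal/noise variance ratios
#'   can be recomputed exactly.
#' @return An object of class \code{synth_config}.
#' @export
synth_config <- function(n_cortical_vertices = 1600L,
                         subcortical_grid = c(10L, 10L, 4L),
                         n_timepoints = 300L,
                         n_subjects = 40L,
                         n_networks = 5L,
                         network_magnitudes = c(5, 3, 2, 1.5, 1),
                         snr = 2,
                         temporal_band = c(0.01, 0.1),
                         misalign = TRUE,
                         seed = 1L,
                         keep_noise = FALSE) {
  n_sub_vox <- prod(subcortical_grid)
  v <- n_cortical_vertices + n_sub_vox
  if (length(network_magnitudes) != n_networks) {
    stop("network_magnitudes must have length n_networks")
  }
  if (any(network_magnitudes <= 0)) stop("network_magnitudes must be strictly positive")
  if (is.unsorted(rev(network_magnitudes))) {
    stop("network_magnitudes must be sorted descending")
  }
  if (n_timepoints < n_networks) stop("n_timepoints must be >= n_networks")
  if (n_subjects < 2L) stop("need at least 2 subjects")
  if (!(snr > 0)) stop("snr must be positive")
  if (n_networks >= min(v, n_timepoints)) {
    stop("n_networks >= min(V, T): degenerate rank")
  }
  if (length(temporal_band) != 2L || temporal_band[1] < 0 ||
      temporal_band[2] <= temporal_band[1] || temporal_band[2] > 0.5) {
    stop("temporal_band must be an increasing pair within (0, 0.5]")
  }
  structure(
    list(
      n_cortical_vertices = as.integer(n_cortical_vertices),
      subcortical_grid = as.integer(subcortical_grid),
      n_subcortical_voxels = as.integer(n_sub_vox),
      n_timepoints = as.integer(n_timepoints),
      n_subjects = as.integer(n_subjects),
      n_networks = as.integer(n_networks),
      network_magnitudes = as.numeric(network_magnitudes),
      snr = snr,
      temporal_band = as.numeric(temporal_band),
      misalign = isTRUE(misalign),
      seed = as.integer(seed),
      keep_noise = isTRUE(keep_noise)
    ),
    class = "synth_config"
  )
}

# Default toy ROI layout for the subcortical grid: a "thalamus" sphere
# containing "CL", a "brainstem" sphere containing "VTA", a "caudate", and
# touching "putamen"/"GP" spheres (the anti-correlated pair). Radii are in
# voxel units. Requires a grid of at least 10 x 10 x 4.
#' Default toy subcortical ROI specification
#'
#' @param grid_dims Subcortical grid dimensions (minimum 10 x 10 x 4).
#' @return List of \code{list(name, center, radius)} entries suitable for
#'   \code{\link{generate_toy_atlas}}.
#' @export
default_roi_spec <- function(grid_dims = c(10L, 10L, 4L)) {
  if (any(grid_dims < c(10L, 10L, 4L))) {
    stop("default_roi_spec needs a grid of at least 10 x 10 x 4")
  }
  list(
    list(name = "thalamus", center = c(3, 3, 2), radius = 1.5),
    list(name = "CL", center = c(3, 3, 2), radius = 1),
    list(name = "brainstem", center = c(8, 3, 2), radius = 1.5),
    list(name = "VTA", center = c(8, 3, 2), radius = 1),
    list(name = "caudate", center = c(3, 8, 2), radius = 1.5),
    list(name = "putamen", center = c(6, 8, 2), radius = 1.5),
    list(name = "GP", center = c(9, 8, 2), radius = 1.5)
  )
}

# Smooth 1-D bump on a circular vertex coordinate (used for cortical maps).
circular_bump <- function(n, center_frac, width_frac) {
  pos <- seq_len(n) / n
  d <- abs(pos - center_frac)
  d <- pmin(d, 1 - d)
  exp(-d^2 / (2 * width_frac^2))
}

# Smooth 3-D bump centered on a grid point, evaluated at given coordinates.
grid_bump <- function(coords, center, sigma) {
  d2 <- (coords[, 1] - center[1])^2 + (coords[, 2] - center[2])^2 +
    (coords[, 3] - center[3])^2
  exp(-d2 / (2 * sigma^2))
}

# Simple smoothing of white noise by a circular moving average; used only to
# give the global map mild, positive spatial variation.
smooth_circular <- function(x, k = 9L) {
  n <- length(x)
  idx <- outer(seq_len(n), seq(-(k %/% 2), k %/% 2), function(i, o) ((i + o - 1L) %% n) + 1L)
  rowMeans(matrix(x[idx], n))
}

# Band-limited unit-norm temporal courses: white Gaussian series are
# band-passed in the Fourier domain (DC always removed), then orthogonalized
# across networks by QR so the ground-truth factors are non-collinear.
bandlimited_courses <- function(t_len, r, band) {
  b <- matrix(stats::rnorm(t_len * r), t_len, r)
  freq <- c(0, seq_len(t_len - 1)) / t_len
  freq <- pmin(freq, 1 - freq) # two-sided frequency axis in cycles/frame
  keep <- freq >= band[1] & freq <= band[2]
  for (j in seq_len(r)) {
    f <- stats::fft(b[, j])
    f[!keep] <- 0
    b[, j] <- Re(stats::fft(f, inverse = TRUE)) / t_len
  }
  qd <- qr(b)
  q <- qr.Q(qd)
  d <- sign(diag(qr.R(qd)))
  d[d == 0] <- 1
  q * rep(d, each = t_len)
}

#' Generate a synthetic multi-subject grayordinate dataset with ground truth
#'
#' Each subject's data is built as
#' \deqn{X_s = \left(\sum_r \lambda_r c_{rs}\, a_r b_r^\top\right) Q_s + \epsilon_s,}
#' where \code{a_r} (spatial maps), \code{b_r} (temporal courses) and
#' \code{c_r} (subject loadings) are unit-norm factors, \code{Q_s} is a
#' per-subject random temporal orthogonal transform (identity when
#' \code{misalign} is off) and \code{\epsilon_s} is i.i.d. Gaussian noise
#' scaled so the per-subject signal/noise variance ratio equals
#' \code{config$snr}. Rows are then centered and scaled to unit norm, the
#' form the downstream synchronization and tensor stages require.
#'
#' Network 1 is a near-uniform positive global "physiological" component with
#' the largest magnitude. Network 2 is the DMN-like target: positive cortical
#' hubs, positive subcortical weights in the toy "CL", "VTA" and "caudate"
#' ROIs and negative weights in "putamen" and "GP" (the anti-correlated
#' pair). Remaining networks are smooth blobs at deterministic alternative
#' locations.
#'
#' @param config A \code{\link{synth_config}}.
#' @param roi_spec Toy atlas specification; defaults to
#'   \code{\link{default_roi_spec}} on the configured grid.
#' @return List with elements \code{dataset} (a
#'   \code{\link{grayordinate_dataset}}, row-normalized) and
#'   \code{ground_truth} (class \code{synthetic_ground_truth}: factor
#'   matrices, magnitudes, misalignment transforms, toy atlas, DMN index,
#'   suggested seed vertex, per-subject noise SDs, and the noise matrices
#'   when \code{keep_noise} is set).
#' @export
generate_dataset <- function(config, roi_spec = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(roi_spec)) roi_spec <- default_roi_spec(config$subcortical_grid)

  nc <- config$n_cortical_vertices
  grid <- config$subcortical_grid
  nsub <- config$n_subcortical_voxels
  v <- nc + nsub
  t_len <- config$n_timepoints
  s <- config$n_subjects
  r <- config$n_networks
  lambda <- config$network_magnitudes

  atlas <- generate_toy_atlas(grid, roi_spec)
  coords <- as.matrix(expand.grid(
    x = seq_len(grid[1]), y = seq_len(grid[2]), z = seq_len(grid[3])
  ))
  storage.mode(coords) <- "integer"

  set.seed(config$seed)

  roi_center <- function(name) {
    roi_spec[[which(vapply(roi_spec, `[[`, "", "name") == name)]]$center
  }

  ## ---- spatial maps ----
  a <- matrix(0, v, r)
  # global component: near-uniform positive
  a[, 1] <- 1 + 0.1 * smooth_circular(stats::rnorm(v))
  a[a[, 1] <= 0.05, 1] <- 0.05
  # DMN-like target: three cortical hubs + signed subcortical patches
  cort <- 1.0 * circular_bump(nc, 0.20, 0.04) +
    0.8 * circular_bump(nc, 0.50, 0.04) +
    0.8 * circular_bump(nc, 0.80, 0.04)
  subc <- 0.3 * grid_bump(coords, roi_center("CL"), 1.2) +
    0.3 * grid_bump(coords, roi_center("VTA"), 1.2) +
    0.3 * grid_bump(coords, roi_center("caudate"), 1.2) -
    0.2 * grid_bump(coords, roi_center("putamen"), 1.2) -
    0.2 * grid_bump(coords, roi_center("GP"), 1.2)
  a[, 2] <- c(cort, subc)
  # remaining networks: smooth bumps at deterministic distinct locations
  if (r >= 3L) {
    for (j in seq(3L, r)) {
      frac <- ((j - 2) * 0.17 + 0.05) %% 1
      cort_j <- circular_bump(nc, frac, 0.05) +
        0.7 * circular_bump(nc, (frac + 0.37) %% 1, 0.05)
      ctr_j <- c(
        1 + (7 * j) %% grid[1], 1 + (3 * j) %% grid[2], 1 + j %% grid[3]
      )
      subc_j <- 0.25 * grid_bump(coords, ctr_j, 1.5)
      a[, j] <- c(cort_j, subc_j)
    }
  }
  a <- sweep(a, 2, sqrt(colSums(a^2)), "/")

  ## ---- temporal courses and subject loadings ----
  b <- bandlimited_courses(t_len, r, config$temporal_band)
  cmat <- matrix(exp(stats::rnorm(s * r, 0, 0.5)), s, r)
  cmat <- sweep(cmat, 2, sqrt(colSums(cmat^2)), "/")

  ## ---- misalignment ----
  qs <- vector("list", s)
  for (i in seq_len(s)) {
    qs[[i]] <- if (config$misalign) rorth(t_len) else diag(t_len)
  }

  ## ---- per-subject data ----
  subjects <- vector("list", s)
  noise_sd <- numeric(s)
  noise <- if (config$keep_noise) vector("list", s) else NULL
  for (i in seq_len(s)) {
    m <- a %*% (t(b) * (lambda * cmat[i, ]))
    m <- m %*% qs[[i]]
    if (is.finite(config$snr)) {
      noise_sd[i] <- sqrt(stats::var(as.vector(m)) / config$snr)
      eps <- matrix(stats::rnorm(v * t_len), v, t_len) * noise_sd[i]
    } else {
      noise_sd[i] <- 0
      eps <- matrix(0, v, t_len)
    }
    if (config$keep_noise) noise[[i]] <- eps
    subjects[[i]] <- m + eps
  }
  raw <- subjects
  subjects <- lapply(subjects, normalize_timeseries)

  dataset <- grayordinate_dataset(
    subjects = subjects,
    cortical_index = seq_len(nc),
    subcortical_index = nc + seq_len(nsub),
    subcortical_grid_coords = coords,
    grid_dims = grid
  )

  ground_truth <- structure(
    list(
      spatial_maps = a,
      temporal_courses = b,
      subject_loadings = cmat,
      magnitudes = lambda,
      misalignment_transforms = qs,
      atlas = atlas,
      seed = config$seed,
      global_index = 1L,
      dmn_index = 2L,
      seed_vertex = as.integer(round(0.20 * nc)),
      noise_sd = noise_sd,
      noise = noise,
      unnormalized = if (config$keep_noise) raw else NULL,
      config = config
    ),
    class = "synthetic_ground_truth"
  )

  list(dataset = dataset, ground_truth = ground_truth)
}

#' Rasterize a toy spherical ROI atlas
#'
#' Builds an integer label volume from a list of named spheres. Labels are
#' assigned in specification order and later entries overwrite earlier ones
#' on overlap, so every voxel carries exactly one label (0 = background).
#' Each ROI also gets a probabilistic map with Gaussian fall-off from its
#' center (useful for exercising probability-map thresholding), and a
#' containment hierarchy is derived geometrically: a sphere wholly inside
#' another is recorded as its child, which downstream ROI-vs-region tests
#' use to form "region including ROI" voxel sets.
#'
#' @param grid_dims 3-D grid dimensions.
#' @param roi_spec List of \code{list(name, center, radius)}; names must be
#'   unique, and every integer voxel within \code{radius} of \code{center}
#'   must lie inside the grid.
#' @param voxel_size Physical voxel size in mm (per axis).
#' @return An object of class \code{roi_atlas}: integer \code{labels} array,
#'   \code{names} (label -> name), per-ROI \code{prob_maps},
#'   \code{voxel_size} and \code{hierarchy}.
#' @export
generate_toy_atlas <- function(grid_dims, roi_spec, voxel_size = c(1, 1, 1)) {
  nms <- vapply(roi_spec, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate ROI name in roi_spec")
  coords <- as.matrix(expand.grid(
    x = seq_len(grid_dims[1]), y = seq_len(grid_dims[2]), z = seq_len(grid_dims[3])
  ))
  labels <- array(0L, dim = grid_dims)
  prob_maps <- list()
  for (k in seq_along(roi_spec)) {
    ctr <- roi_spec[[k]]$center
    rad <- roi_spec[[k]]$radius
    d <- sqrt((coords[, 1] - ctr[1])^2 + (coords[, 2] - ctr[2])^2 +
                (coords[, 3] - ctr[3])^2)
    inside <- d <= rad
    if (!any(inside)) stop(sprintf("ROI '%s' is empty after rasterization", nms[k]))
    # "fits in grid": the continuous sphere must not extend past the voxel grid
    if (any(ctr - rad < 0.5) || any(ctr + rad > grid_dims + 0.5)) {
      stop(sprintf("ROI '%s' does not fit in the grid", nms[k]))
    }
    labels[coords[inside, , drop = FALSE]] <- k
    sigma <- (rad + 0.5) / 2
    pm <- array(0, dim = grid_dims)
    pm[coords] <- exp(-d^2 / (2 * sigma^2))
    pm[pm < 1e-6] <- 0
    prob_maps[[nms[k]]] <- pm
  }
  for (k in seq_along(roi_spec)) {
    if (!any(labels == k)) {
      stop(sprintf("ROI '%s' is empty (fully overwritten by later ROIs)", nms[k]))
    }
  }
  # geometric containment -> hierarchy
  hierarchy <- list()
  for (k in seq_along(roi_spec)) {
    for (j in seq_along(roi_spec)) {
      if (j == k) next
      dc <- sqrt(sum((roi_spec[[k]]$center - roi_spec[[j]]$center)^2))
      if (dc + roi_spec[[j]]$radius <= roi_spec[[k]]$radius) {
        hierarchy[[nms[k]]] <- c(hierarchy[[nms[k]]], nms[j])
      }
    }
  }
  roi_atlas(labels, stats::setNames(seq_along(nms), nms), prob_maps,
            voxel_size, hierarchy)
}
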