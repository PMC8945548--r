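#' ROI atlas container
#'
#' An integer label volume (0 = background, every nonzero label named) with
#' optional per-ROI probabilistic maps, physical voxel size, and an optional
#' containment hierarchy mapping a region name to the ROI names geometrically
#' inside it (used to form "region including ROI" voxel sets for the
#' ROI-vs-region tests).
#'
#' @param labels 3-D integer array of labels.
#' @param names Named integer vector mapping ROI name to label value.
#' @param prob_maps Optional named list of 3-D probability arrays in [0, 1].
#' @param voxel_size Physical voxel size in mm per axis.
#' @param hierarchy Optional named list: region name -> character vector of
#'   contained ROI names.
#' @return An object of class \code{roi_atlas}.
#' @export
roi_atlas <- function(labels, names, prob_maps = list(),
                      voxel_size = c(1, 1, 1), hierarchy = list()) {
  stopifnot(length(dim(labels)) == 3L)
  storage.mode(labels) <- "integer"
  present <- setdiff(unique(as.vector(labels)), 0L)
  if (!all(present %in% names)) {
    stop("every nonzero label must be named")
  }
  structure(
    list(
      labels = labels,
      names = names,
      prob_maps = prob_maps,
      voxel_size = as.numeric(voxel_size),
      hierarchy = hierarchy
    ),
    class = "roi_atlas"
  )
}

#' @export
print.roi_atlas <- function(x, ...) {
  cat(sprintf(
    "roi_atlas: %s grid, %d ROIs (%s), voxel size %s mm\n",
    paste(dim(x$labels), collapse = "x"), length(x$names),
    paste(names(x$names), collapse = ", "),
    paste(x$voxel_size, collapse = "x")
  ))
  invisible(x)
}

atlas_label <- function(atlas, name) {
  if (!name %in% names(atlas$names)) {
    stop(sprintf("unknown ROI name '%s'", name), call. = FALSE)
  }
  unname(atlas$names[[name]])
}

#' Linear voxel indices of an ROI
#'
#' @param atlas A \code{\link{roi_atlas}}.
#' @param name ROI name.
#' @param include_children If \code{TRUE} (default), voxels of ROIs recorded
#'   as contained in this region by the atlas hierarchy are included — e.g.
#'   the full thalamus including a nucleus that overwrote part of its label.
#' @return Integer vector of linear indices into the label array.
#' @export
roi_voxel_indices <- function(atlas, name, include_children = TRUE) {
  idx <- which(atlas$labels == atlas_label(atlas, name))
  if (include_children && name %in% names(atlas$hierarchy)) {
    for (child in atlas$hierarchy[[name]]) {
      idx <- c(idx, which(atlas$labels == atlas_label(atlas, child)))
    }
  }
  sort(unique(idx))
}

#' Morphological erosion by a physical-radius sphere
#'
#' Erodes a boolean mask with a spherical structuring element of the given
#' physical radius, rasterized at the mask's voxel size (a voxel survives if
#' every voxel within the radius, including out-of-volume positions treated
#' as background, is in the mask). Radius 0 is the identity. Used to pull
#' adjacent structures (e.g. putamen and globus pallidus) apart before ROI
#' statistics so signal spillover between them is avoided.
#'
#' @param mask 3-D logical array.
#' @param radius_mm Erosion radius in mm (>= 0).
#' @param voxel_size Voxel size in mm per axis.
#' @return Eroded logical array; if nothing survives, an empty mask is
#'   returned with a warning (not an error).
#' @export
erode_mask <- function(mask, radius_mm, voxel_size = c(1, 1, 1)) {
  stopifnot(length(dim(mask)) == 3L, radius_mm >= 0)
  mask <- mask != 0
  if (radius_mm == 0) return(mask)
  dm <- dim(mask)
  rng <- floor(radius_mm / voxel_size)
  offs <- as.matrix(expand.grid(
    dx = seq(-rng[1], rng[1]), dy = seq(-rng[2], rng[2]), dz = seq(-rng[3], rng[3])
  ))
  keep <- sqrt((offs[, 1] * voxel_size[1])^2 + (offs[, 2] * voxel_size[2])^2 +
                 (offs[, 3] * voxel_size[3])^2) <= radius_mm
  offs <- offs[keep, , drop = FALSE]
  out <- array(TRUE, dim = dm)
  for (k in seq_len(nrow(offs))) {
    sh <- array(FALSE, dim = dm)
    src_x <- seq_len(dm[1]) + offs[k, 1]
    src_y <- seq_len(dm[2]) + offs[k, 2]
    src_z <- seq_len(dm[3]) + offs[k, 3]
    ok_x <- src_x >= 1 & src_x <= dm[1]
    ok_y <- src_y >= 1 & src_y <= dm[2]
    ok_z <- src_z >= 1 & src_z <= dm[3]
    sh[ok_x, ok_y, ok_z] <- mask[src_x[ok_x], src_y[ok_y], src_z[ok_z]]
    out <- out & sh
  }
  if (!any(out)) warning("mask is empty after erosion")
  out
}

#' Threshold a probabilistic ROI map
#'
#' Returns the mask \code{prob_map > threshold} together with the percentile
#' the threshold corresponds to within the map's nonzero support, so a
#' stated threshold/percentile pairing (e.g. 0.03 at the 88th percentile for
#' a small thalamic nucleus) can be checked on any map.
#'
#' @param prob_map 3-D array of probabilities in [0, 1].
#' @param threshold Probability threshold.
#' @return List with \code{mask} (logical array) and \code{percentile}
#'   (percentage of nonzero values at or below the threshold).
#' @export
threshold_probability_map <- function(prob_map, threshold) {
  if (any(prob_map < 0 | prob_map > 1, na.rm = TRUE)) {
    stop("probability map values must lie in [0, 1]")
  }
  nz <- prob_map[prob_map > 0]
  if (length(nz) == 0L) stop("probability map has no nonzero support")
  list(
    mask = prob_map > threshold,
    percentile = 100 * mean(nz <= threshold)
  )
}

#' Values of a volumetric map within an ROI
#'
#' @param volume 3-D array (same grid as the atlas); NaN voxels (outside the
#'   map support) are excluded.
#' @param atlas A \code{\link{roi_atlas}}.
#' @param roi ROI name.
#' @param include_children Passed to \code{\link{roi_voxel_indices}}.
#' @return Numeric vector of map values at the ROI's voxels; an error if the
#'   ROI does not intersect the map support.
#' @export
roi_values <- function(volume, atlas, roi, include_children = TRUE) {
  stopifnot(all(dim(volume) == dim(atlas$labels)))
  vals <- volume[roi_voxel_indices(atlas, roi, include_children)]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) {
    stop(sprintf("ROI '%s' does not intersect the map support", roi))
  }
  vals
}

#' Welch t-test of an ROI against its containing region
#'
#' One-sided Welch (unequal-variance) two-sample t-test of whether the map
#' mean within the ROI exceeds the mean within the containing region. The
#' region's voxel set includes the ROI's (mirroring "CL versus the entire
#' thalamus including CL"); \code{exclude_roi = TRUE} removes the ROI voxels
#' from the region for sensitivity analysis. The test is delegated to
#' \code{stats::t.test} with the Welch degrees of freedom.
#'
#' @param volume 3-D map on the atlas grid.
#' @param atlas A \code{\link{roi_atlas}}.
#' @param roi,region ROI and containing-region names; the ROI's voxels must
#'   be a subset of the region's.
#' @param alternative \code{"greater"} (default, "significantly higher") or
#'   \code{"two.sided"}.
#' @param exclude_roi Exclude ROI voxels from the region sample.
#' @return List with \code{t}, \code{p} (one-sided by default), \code{df}
#'   and the two sample sizes.
#' @export
roi_vs_region_ttest <- function(volume, atlas, roi, region,
                                alternative = c("greater", "two.sided"),
                                exclude_roi = FALSE) {
  alternative <- match.arg(alternative)
  idx_roi <- roi_voxel_indices(atlas, roi)
  idx_reg <- roi_voxel_indices(atlas, region)
  if (!all(idx_roi %in% idx_reg)) {
    stop(sprintf("ROI '%s' is not a subset of region '%s'", roi, region))
  }
  if (exclude_roi) idx_reg <- setdiff(idx_reg, idx_roi)
  x <- volume[idx_roi]; x <- x[is.finite(x)]
  y <- volume[idx_reg]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("need at least 2 finite values in both ROI and region")
  }
  tt <- stats::t.test(x, y, alternative = alternative, var.equal = FALSE)
  list(
    t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
    n_roi = length(x), n_region = length(y)
  )
}

# Euler characteristic density of a 3-D t-field at threshold u (unit-variance
# t field, df degrees of freedom), per resel.
ec_density_t3 <- function(u, df) {
  (4 * log(2))^(3 / 2) / (2 * pi)^2 *
    (1 + u^2 / df)^(-(df - 1) / 2) * ((df - 1) / df * u^2 - 1)
}

#' Random-field-theory correction of an ROI p-value
#'
#' Corrects a t-test p-value for the voxelwise multiple comparisons implied
#' by searching a smooth volume, using the expected Euler characteristic of
#' a 3-D t-field: the resel (resolution element) count is
#' \code{roi_volume_mm3 / fwhm_mm^3} and the corrected p-value is
#' \deqn{p_{corr} = \min(1,\; p_{raw} + \max(0,\; resels\, \rho_3(t))),}
#' where \eqn{\rho_3} is the published 3-D Euler-characteristic density of a
#' t-field. Only the 3-D (volume) term plus the 0-D tail term (the raw
#' p-value itself) are used; lower-dimensional boundary terms are omitted,
#' which is exact for boundaryless search regions and slightly liberal
#' otherwise. The 3-D term is clamped at zero so the corrected p-value is
#' never below the raw one and is monotone non-decreasing in the resel
#' count.
#'
#' @param p_raw Uncorrected (one-sided) p-value.
#' @param t Observed t statistic (the threshold of the excursion).
#' @param df Degrees of freedom (> 0).
#' @param roi_volume_mm3 Search volume in mm^3 (> 0).
#' @param fwhm_mm Full width at half maximum of the effective spatial
#'   smoothing in mm (> 0); the default used in this package is 2 mm, the
#'   smoothing applied in standard minimal preprocessing.
#' @return Corrected p-value in [p_raw, 1].
#' @export
rft_correct <- function(p_raw, t, df, roi_volume_mm3, fwhm_mm) {
  if (any(df <= 0)) stop("df must be positive")
  if (any(fwhm_mm <= 0)) stop("fwhm_mm must be positive")
  if (any(roi_volume_mm3 <= 0)) stop("roi_volume_mm3 must be positive")
  resels <- roi_volume_mm3 / fwhm_mm^3
  pmin(1, p_raw + pmax(0, resels * ec_density_t3(t, df)))
}

#' Per-ROI statistics table for a normalized subcortical map
#'
#' For each requested (ROI, containing region) pair: the map values within
#' the ROI, their count and median, the one-sided Welch t statistic against
#' the region, the raw and RFT-corrected p-values, the resel count, and
#' significance flags at the requested alpha levels. Per-pair errors (e.g.
#' an ROI outside the map support) produce an NA row with a warning; unknown
#' ROI or region names are a configuration error and abort.
#'
#' @param volume 3-D map on the atlas grid (NaN outside support).
#' @param atlas A \code{\link{roi_atlas}} on the same grid.
#' @param roi_region_pairs Data frame with columns \code{roi} and
#'   \code{region}.
#' @param fwhm Effective smoothing FWHM in mm for the resel computation.
#' @param alphas Two significance cutoffs (default 0.05 and 0.001).
#' @param alternative Test sidedness, see \code{\link{roi_vs_region_ttest}}.
#' @param out_tsv Optional path; if given, the table is written as TSV.
#' @return Data frame of class \code{roi_stats_table}, one row per pair,
#'   with the per-ROI value vectors attached as the \code{"values"}
#'   attribute (for violin-style plotting).
#' @export
summarize_rois <- function(volume, atlas, roi_region_pairs, fwhm = 2,
                           alphas = c(0.05, 0.001),
                           alternative = "greater", out_tsv = NULL) {
  stopifnot(is.data.frame(roi_region_pairs),
            all(c("roi", "region") %in% names(roi_region_pairs)))
  for (nm in unique(c(roi_region_pairs$roi, roi_region_pairs$region))) {
    atlas_label(atlas, nm) # unknown name -> abort
  }
  n <- nrow(roi_region_pairs)
  res <- data.frame(
    roi = roi_region_pairs$roi, region = roi_region_pairs$region,
    n_voxels = NA_integer_, median = NA_real_, t_statistic = NA_real_,
    df = NA_real_, p_raw = NA_real_, resels = NA_real_,
    p_corrected = NA_real_,
    stringsAsFactors = FALSE
  )
  values <- vector("list", n)
  names(values) <- roi_region_pairs$roi
  vox_mm3 <- prod(atlas$voxel_size)
  for (i in seq_len(n)) {
    row <- tryCatch({
      vals <- roi_values(volume, atlas, res$roi[i])
      tt <- roi_vs_region_ttest(volume, atlas, res$roi[i], res$region[i],
                                alternative = alternative)
      vol_mm3 <- length(vals) * vox_mm3
      pc <- rft_correct(tt$p, tt$t, tt$df, vol_mm3, fwhm)
      list(vals = vals, tt = tt, resels = vol_mm3 / fwhm^3, pc = pc)
    }, error = function(e) {
      warning(sprintf("ROI '%s': %s", res$roi[i], conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(row)) next
    values[[i]] <- row$vals
    res$n_voxels[i] <- length(row$vals)
    res$median[i] <- stats::median(row$vals)
    res$t_statistic[i] <- row$tt$t
    res$df[i] <- row$tt$df
    res$p_raw[i] <- row$tt$p
    res$resels[i] <- row$resels
    res$p_corrected[i] <- row$pc
  }
  for (a in alphas) {
    res[[sprintf("significant_at_%g", a)]] <-
      !is.na(res$p_corrected) & res$p_corrected < a
  }
  if (!is.null(out_tsv)) {
    utils::write.table(res, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  attr(res, "values") <- values
  class(res) <- c("roi_stats_table", class(res))
  res
}

# Nearest-neighbor upsampling of atlas labels (and prob maps) onto the
# voxel-center-aligned fine grid used by upsample_volume, with the voxel
# size reduced accordingly.
#' Upsample an atlas to match an upsampled volume
#'
#' Labels are resampled by nearest neighbor onto the fine grid produced by
#' \code{\link{upsample_volume}} (dimension \code{(n - 1) * factor + 1},
#' samples at \code{1 + (j - 1)/factor}); the voxel size is divided by the
#' factor so physical ROI volumes are preserved up to rasterization.
#'
#' @param atlas A \code{\link{roi_atlas}}.
#' @param factor Integer upsampling factor (>= 1).
#' @return A \code{roi_atlas} on the fine grid.
#' @export
upsample_atlas <- function(atlas, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be a positive integer")
  if (factor == 1L) return(atlas)
  dm <- dim(atlas$labels)
  out_dims <- (dm - 1L) * factor + 1L
  nn <- lapply(seq_len(3), function(ax) {
    pmin(pmax(as.integer(round(1 + (seq_len(out_dims[ax]) - 1) / factor)), 1L), dm[ax])
  })
  labels <- atlas$labels[nn[[1]], nn[[2]], nn[[3]]]
  prob_maps <- lapply(atlas$prob_maps, function(pm) pm[nn[[1]], nn[[2]], nn[[3]]])
  roi_atlas(labels, atlas$names, prob_maps, atlas$voxel_size / factor,
            atlas$hierarchy)
}
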