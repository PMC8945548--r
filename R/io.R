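#' Write / read a grayordinate dataset container
#'
#' The dataset is stored as a single RDS container holding the per-subject
#' space x time matrices, both grayordinate index sets, the subcortical grid
#' coordinates and dimensions, and the subject labels (plus the generating
#' configuration and seed when the dataset came from the synthetic
#' generator).
#'
#' @param dataset A \code{\link{grayordinate_dataset}}.
#' @param path File path (conventionally \code{.rds}).
#' @return \code{write_dataset} returns the path invisibly;
#'   \code{read_dataset} returns the dataset.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "grayordinate_dataset"))
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "grayordinate_dataset")) {
    stop("file does not contain a grayordinate_dataset")
  }
  x
}

#' Write / read ground truth for a synthetic dataset
#'
#' @param ground_truth A \code{synthetic_ground_truth}.
#' @param path File path (conventionally \code{.rds}).
#' @export
write_ground_truth <- function(ground_truth, path) {
  stopifnot(inherits(ground_truth, "synthetic_ground_truth"))
  saveRDS(ground_truth, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "synthetic_ground_truth")) {
    stop("file does not contain a synthetic_ground_truth")
  }
  x
}

#' Write a 3-D volume as NIfTI-1
#'
#' @param volume 3-D numeric array.
#' @param path Output path (\code{.nii} or \code{.nii.gz}).
#' @param voxel_size Voxel size in mm per axis (written into the header and
#'   the diagonal affine).
#' @export
write_volume <- function(volume, path, voxel_size = c(1, 1, 1)) {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.vector(img), dim = dim(img))
}

#' Write / read an ROI atlas as NIfTI + JSON sidecar
#'
#' The label volume is written as \code{<prefix>_labels.nii.gz}, each
#' probabilistic map as \code{<prefix>_prob_<name>.nii.gz}, and a JSON
#' sidecar \code{<prefix>_atlas.json} records the name map, voxel size and
#' containment hierarchy.
#'
#' @param atlas A \code{\link{roi_atlas}}.
#' @param prefix Path prefix for the output files.
#' @export
write_atlas <- function(atlas, prefix) {
  stopifnot(inherits(atlas, "roi_atlas"))
  write_volume(atlas$labels, paste0(prefix, "_labels.nii.gz"),
               atlas$voxel_size)
  for (nm in names(atlas$prob_maps)) {
    write_volume(atlas$prob_maps[[nm]],
                 paste0(prefix, "_prob_", nm, ".nii.gz"), atlas$voxel_size)
  }
  sidecar <- list(
    names = as.list(atlas$names),
    voxel_size = atlas$voxel_size,
    hierarchy = atlas$hierarchy,
    prob_maps = as.list(names(atlas$prob_maps))
  )
  jsonlite::write_json(sidecar, paste0(prefix, "_atlas.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(prefix) {
  sidecar <- jsonlite::read_json(paste0(prefix, "_atlas.json"))
  labels <- read_volume(paste0(prefix, "_labels.nii.gz"))
  storage.mode(labels) <- "integer"
  prob_maps <- list()
  for (nm in unlist(sidecar$prob_maps)) {
    prob_maps[[nm]] <- read_volume(paste0(prefix, "_prob_", nm, ".nii.gz"))
  }
  hierarchy <- lapply(sidecar$hierarchy, function(x) unlist(x))
  roi_atlas(labels,
            stats::setNames(as.integer(unlist(sidecar$names)),
                            names(sidecar$names)),
            prob_maps, as.numeric(unlist(sidecar$voxel_size)), hierarchy)
}

#' Write a pipeline run record as JSON
#'
#' @param record Run-record list from \code{\link{run_pipeline}}.
#' @param path Output path.
#' @export
write_run_record <- function(record, path) {
  jsonlite::write_json(record, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
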