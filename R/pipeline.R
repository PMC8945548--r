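#' Pipeline configuration
#'
#' Gathers all tunable parameters of the end-to-end analysis. Every source
#' of randomness in a run derives from \code{seed}, so a run is a pure
#' function of (inputs, config) and re-running with identical inputs
#' reproduces all numeric outputs bit-identically.
#'
#' @param rank CP rank \code{R} for the decomposition (30 is the
#'   conventional over-estimate at full scale; smaller values suffice for
#'   the dominant networks).
#' @param opts Optimizer settings from \code{\link{nascar_opts}}.
#' @param quantile Cortical quantile used to normalize the subcortical map.
#' @param fwhm Effective smoothing FWHM (mm) for resel computation.
#' @param alphas Significance cutoffs for the ROI table.
#' @param upsample_factor Integer trilinear upsampling factor for the
#'   subcortical volume (and nearest-neighbor factor for the atlas).
#' @param seed Master integer seed.
#' @param seed_vertex Cortical grayordinate for the seed-based comparison
#'   map (\code{NULL} skips the seed stage).
#' @param gsr Also compute the seed map with global signal regression.
#' @param roi_region_pairs Data frame of (roi, region) pairs for the ROI
#'   table; default tests "CL" against "thalamus" and "VTA" against
#'   "brainstem".
#' @param sync_tol,sync_max_iter Group synchronization controls.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(rank = 8L, opts = nascar_opts(), quantile = 0.95,
                            fwhm = 2, alphas = c(0.05, 0.001),
                            upsample_factor = 2L, seed = 1L,
                            seed_vertex = NULL, gsr = TRUE,
                            roi_region_pairs = NULL,
                            sync_tol = 1e-6, sync_max_iter = 20L) {
  if (is.null(roi_region_pairs)) {
    roi_region_pairs <- data.frame(
      roi = c("CL", "VTA"), region = c("thalamus", "brainstem"),
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(
      rank = as.integer(rank), opts = opts, quantile = quantile,
      fwhm = fwhm, alphas = alphas,
      upsample_factor = as.integer(upsample_factor),
      seed = as.integer(seed), seed_vertex = seed_vertex, gsr = isTRUE(gsr),
      roi_region_pairs = roi_region_pairs,
      sync_tol = sync_tol, sync_max_iter = as.integer(sync_max_iter)
    ),
    class = "pipeline_config"
  )
}

run_stage <- function(name, record, output_dir, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) e)
  if (inherits(res, "error")) {
    record$failed_stage <- name
    record$error <- conditionMessage(res)
    if (!is.null(output_dir)) {
      write_run_record(record, file.path(output_dir, "run_record.json"))
    }
    stop(sprintf("pipeline failed at stage '%s': %s", name,
                 conditionMessage(res)), call. = FALSE)
  }
  attr(res, "stage_seconds") <- proc.time()[["elapsed"]] - t0
  res
}

#' Run the full network-identification pipeline
#'
#' Executes, in order: group temporal synchronization, tensor formation,
#' rank-\code{R} CP decomposition, template-based component selection,
#' cortical/subcortical map splitting, cortical-quantile normalization,
#' trilinear volume upsampling, ROI statistics with RFT correction, and
#' (optionally) a seed-based correlation comparison. Any stage error aborts
#' with the stage name after persisting a partial run record.
#'
#' @param dataset A row-normalized \code{\link{grayordinate_dataset}}.
#' @param atlas A \code{\link{roi_atlas}} on the dataset's subcortical grid.
#' @param template Cortical template map used to select the target network.
#' @param config A \code{\link{pipeline_config}}.
#' @param output_dir Optional directory; when given, the normalized
#'   subcortical volume (NIfTI), the ROI table (TSV) and the run record
#'   (JSON) are written there.
#' @return List with all stage results (\code{sync}, \code{decomposition},
#'   \code{selection}, \code{maps}, \code{roi_table}, \code{seed_maps},
#'   \code{comparison}) plus \code{record} (config hash, per-stage timings,
#'   selected component magnitude rank, explained variance, output paths).
#' @export
run_pipeline <- function(dataset, atlas, template, config = pipeline_config(),
                         output_dir = NULL) {
  stopifnot(inherits(dataset, "grayordinate_dataset"),
            inherits(atlas, "roi_atlas"),
            inherits(config, "pipeline_config"))
  if (!is.null(output_dir) && !dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }
  record <- list(
    config_hash = object_hash(config),
    software_version = as.character(utils::packageVersion("braintensor")),
    timings = list(), outputs = list()
  )
  tick <- function(name, res) {
    record$timings[[name]] <<- attr(res, "stage_seconds")
    res
  }

  sync <- tick("sync", run_stage("sync", record, output_dir,
    group_brainsync(dataset, tol = config$sync_tol,
                    max_iter = config$sync_max_iter)))
  tensor <- tick("tensor", run_stage("tensor", record, output_dir,
    build_tensor(sync$synced, synced = TRUE)))
  decomp <- tick("decompose", run_stage("decompose", record, output_dir,
    nascar_decompose(tensor, config$rank, config$opts, seed = config$seed)))
  sel <- tick("select", run_stage("select", record, output_dir,
    select_network(decomp, template, dataset$cortical_index)))
  maps <- tick("maps", run_stage("maps", record, output_dir, {
    parts <- split_spatial_map(sel$component, dataset)
    norm <- normalize_subcortical(parts$subcortical_map, parts$cortical_map,
                                  prob = config$quantile)
    vol <- upsample_volume(norm$normalized_map,
                           dataset$subcortical_grid_coords,
                           dataset$grid_dims, config$upsample_factor)
    c(parts, norm, list(upsampled_volume = vol))
  }))
  fine_atlas <- upsample_atlas(atlas, config$upsample_factor)
  roi_table <- tick("roi_stats", run_stage("roi_stats", record, output_dir,
    summarize_rois(maps$upsampled_volume, fine_atlas,
                   config$roi_region_pairs, fwhm = config$fwhm,
                   alphas = config$alphas,
                   out_tsv = if (is.null(output_dir)) NULL else
                     file.path(output_dir, "roi_stats.tsv"))))

  seed_maps <- NULL
  comparison <- NULL
  if (!is.null(config$seed_vertex)) {
    seed_maps <- tick("seed_map", run_stage("seed_map", record, output_dir, {
      out <- list(raw = seed_correlation_map(dataset, config$seed_vertex,
                                             gsr = FALSE))
      if (config$gsr) {
        out$gsr <- seed_correlation_map(dataset, config$seed_vertex,
                                        gsr = TRUE)
      }
      out
    }))
    comparison <- compare_maps(maps$normalized_map,
                               seed_maps$raw$group_map)
  }

  record$selected_index <- sel$index
  record$lambda_rank <- sel$lambda_rank
  record$template_correlation <- sel$correlation
  record$explained_variance <- explained_variance(decomp, tensor)
  record$sync_converged <- sync$converged

  if (!is.null(output_dir)) {
    vol_path <- file.path(output_dir, "normalized_subcortical_map.nii.gz")
    write_volume(maps$upsampled_volume, vol_path,
                 voxel_size = atlas$voxel_size / config$upsample_factor)
    record$outputs <- list(
      volume = vol_path,
      roi_table = file.path(output_dir, "roi_stats.tsv"),
      run_record = file.path(output_dir, "run_record.json")
    )
    write_run_record(record, record$outputs$run_record)
  }

  list(
    sync = sync, tensor = tensor, decomposition = decomp, selection = sel,
    maps = maps, roi_table = roi_table, seed_maps = seed_maps,
    comparison = comparison, record = record
  )
}

#' Split-half reproducibility experiment
#'
#' Randomly splits the subjects into two equal halves (seeded by the
#' config's master seed) and runs the identification chain — group
#' synchronization, tensor formation, CP decomposition and template-based
#' selection — on each half independently, including an independent virtual
#' reference per half. Reports the Pearson correlation between the two
#' selected components' full grayordinate spatial maps after sign alignment
#' (CP components are sign indeterminate, so the maps are aligned to
#' positive correlation before comparison; the statistic is invariant to
#' which half is labeled A or B).
#'
#' @param dataset A row-normalized \code{\link{grayordinate_dataset}} with
#'   at least 4 subjects.
#' @param template Cortical template map for component selection.
#' @param config A \code{\link{pipeline_config}}.
#' @return List with \code{map_a}, \code{map_b} (full spatial maps),
#'   \code{correlation} (NA with a warning if selection fails in either
#'   half), \code{half_indices} and per-half selection metadata.
#' @export
split_half_experiment <- function(dataset, template,
                                  config = pipeline_config()) {
  stopifnot(inherits(dataset, "grayordinate_dataset"))
  s <- n_subjects(dataset)
  if (s < 4L) stop("split-half experiment needs at least 4 subjects")
  set.seed(config$seed)
  half_size <- floor(s / 2)
  ia <- sort(sample(seq_len(s), half_size))
  ib <- sort(setdiff(seq_len(s), ia))[seq_len(half_size)]

  run_half <- function(idx) {
    half <- dataset
    half$subjects <- dataset$subjects[idx]
    half$subject_ids <- dataset$subject_ids[idx]
    sync <- group_brainsync(half, tol = config$sync_tol,
                            max_iter = config$sync_max_iter)
    tensor <- build_tensor(sync$synced, synced = TRUE)
    decomp <- nascar_decompose(tensor, config$rank, config$opts,
                               seed = config$seed)
    select_network(decomp, template, dataset$cortical_index)
  }

  sel_a <- tryCatch(run_half(ia), error = function(e) e)
  sel_b <- tryCatch(run_half(ib), error = function(e) e)
  if (inherits(sel_a, "error") || inherits(sel_b, "error")) {
    bad <- if (inherits(sel_a, "error")) sel_a else sel_b
    warning("component selection failed in one half: ",
            conditionMessage(bad))
    return(list(map_a = NULL, map_b = NULL, correlation = NA_real_,
                half_indices = list(a = ia, b = ib)))
  }
  map_a <- sel_a$component$spatial
  map_b <- sel_b$component$spatial
  r <- stats::cor(map_a, map_b)
  if (r < 0) {
    map_b <- -map_b
    r <- -r
  }
  list(
    map_a = map_a, map_b = map_b, correlation = r,
    half_indices = list(a = ia, b = ib),
    selection = list(
      a = sel_a[c("index", "lambda_rank", "correlation")],
      b = sel_b[c("index", "lambda_rank", "correlation")]
    )
  )
}
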