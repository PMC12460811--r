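# End-to-end pipeline: synchronize -> preprocess -> segment -> mesh ->
# split -> register -> morph -> strain -> summarize (-> ridges when
# annotated), with structured per-stage logging and provenance.

#' Pipeline configuration
#'
#' @param input_dir directory of exported TIFFs + sidecar (alternative to
#'   `movie`)
#' @param movie an in-memory [volume_movie()] (alternative to `input_dir`)
#' @param out_dir output directory (created); NULL disables file output
#' @param K number of cardiac phases
#' @param target_spacing registration voxel spacing (um per axis)
#' @param rolling_ball_radius background-removal radius (px); 0 disables
#' @param closing_radius_um segmentation closing radius (um)
#' @param registration a [motion_spec()]
#' @param region optional half-space region spec (list point, normal)
#' @param region_band_um endocardial overlap band for region selection
#' @param ridge_annotations optional path to a ridge-annotation JSON or a
#'   list of [ridge_trace()]
#' @param write_vtk write per-phase VTK surfaces
#' @param seed RNG seed recorded and set for the run
#' @return config list
#' @export
pipeline_config <- function(input_dir = NULL, movie = NULL, out_dir = NULL,
                            K = 10, target_spacing = c(0.8, 0.8, 1),
                            rolling_ball_radius = 40,
                            closing_radius_um = 1.0,
                            registration = motion_spec(),
                            region = NULL, region_band_um = 12,
                            ridge_annotations = NULL, write_vtk = FALSE,
                            seed = 1L) {
  cfg <- list(input_dir = input_dir, out_dir = out_dir, K = K,
              target_spacing = target_spacing,
              rolling_ball_radius = rolling_ball_radius,
              closing_radius_um = closing_radius_um,
              registration = registration, region = region,
              region_band_um = region_band_um,
              ridge_annotations = ridge_annotations,
              write_vtk = write_vtk, seed = as.integer(seed))
  cfg$movie <- movie
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file path
#' @return config list (defaults filled in via [pipeline_config()])
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  reg <- do.call(motion_spec, if (is.null(y$registration)) list() else
    y$registration)
  y$registration <- NULL
  y$movie <- NULL
  do.call(pipeline_config, c(y, list(registration = reg)))
}

#' Run the 4-D strain-mapping pipeline
#'
#' Stages: synchronization into K phases, background removal, resampling,
#' reference-phase segmentation, surface meshing, epi/endo split, region
#' selection, cyclic registration, mesh morphing, per-element area strain,
#' and regional summaries; ridge metrics when annotations are supplied.
#' Outputs (when `out_dir` is set): a strain-summary CSV, per-phase VTK
#' surfaces, a ridge-metric CSV, the resolved configuration, and a
#' structured JSON log with per-stage provenance.
#'
#' @param cfg a [pipeline_config()]
#' @return report list with all intermediate objects and the log
#' @export
run_pipeline <- function(cfg) {
  set.seed(cfg$seed)
  log <- list()
  stamp <- function(stage, ...) {
    log[[length(log) + 1]] <<- c(list(stage = stage), list(...))
  }
  fail <- function(stage, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  movie <- cfg$movie
  if (is.null(movie)) {
    if (is.null(cfg$input_dir)) stop("config needs input_dir or movie")
    movie <- tryCatch(read_movies(cfg$input_dir),
                      error = function(e) fail("read", e))
  }
  stamp("read", n_slices = length(movie$slices),
        frame_rate = movie$frame_rate)

  cycle <- tryCatch(reconstruct_4d(movie$slices, K = cfg$K),
                    error = function(e) fail("sync", e))
  stamp("sync", K = cycle$K, median_period_s = median(cycle$periods,
                                                     na.rm = TRUE),
        excluded = length(cycle$excluded))

  prep <- tryCatch({
    vols <- lapply(cycle$volumes, function(v) {
      if (cfg$rolling_ball_radius > 0) {
        rolling_ball(v, cfg$rolling_ball_radius)
      } else v
    })
    res <- lapply(vols, function(v) resample_volume(v, cycle$spacing,
                                                    cfg$target_spacing))
    list(volumes = lapply(res, `[[`, "vol"),
         spacing = res[[1]]$spacing)
  }, error = function(e) fail("preprocess", e))
  cycle_r <- cycle
  cycle_r$volumes <- prep$volumes
  cycle_r$spacing <- prep$spacing
  stamp("preprocess", spacing_um = prep$spacing,
        dims = dim(prep$volumes[[1]]))

  model <- tryCatch(fit_motion(cycle_r, cfg$registration),
                    error = function(e) fail("register", e))
  ref <- model$ref_phase
  stamp("register", ref_phase = ref,
        final_metric = model$report[[length(model$report)]]$phase_metric)

  seg <- tryCatch(
    segment_myocardium(cycle_r$volumes[[ref + 1L]], cycle_r$spacing,
                       closing_radius_um = cfg$closing_radius_um),
    error = function(e) fail("segment", e))
  stamp("segment", foreground_voxels = sum(seg$labels))

  mesh <- tryCatch(split_epi_endo(mesh_surface(seg)),
                   error = function(e) fail("mesh", e))
  if (!is.null(cfg$region)) {
    mesh <- tryCatch(select_region(mesh, cfg$region, cfg$region_band_um),
                     error = function(e) fail("region", e))
  }
  stamp("mesh", triangles = nrow(mesh$triangles),
        epi = sum(mesh$surface == "epi"),
        endo = sum(mesh$surface == "endo"),
        region = sum(mesh$region))

  surfaces <- tryCatch(morph_mesh(mesh, model),
                       error = function(e) fail("morph", e))
  field <- area_strain(surfaces)
  summary <- summarize_strain(field, mesh)
  stamp("strain", kept = length(field$kept),
        excluded = length(field$excluded))

  ridge_metrics <- NULL
  if (!is.null(cfg$ridge_annotations)) {
    traces <- if (is.character(cfg$ridge_annotations)) {
      read_ridge_annotations(cfg$ridge_annotations)
    } else cfg$ridge_annotations
    sys_ph <- pick_systole_phase(model, mesh)
    ridge_metrics <- do.call(rbind, lapply(traces, function(tr) {
      m <- measure_ridge_shortening(tr, model, sys_ph)
      data.frame(id = m$id, class = m$class, length_ref = m$length_ref,
                 length_sys = m$length_sys, shortening = m$shortening,
                 systole_phase = sys_ph)
    }))
    stamp("ridges", n = nrow(ridge_metrics), systole_phase = sys_ph)
  }

  report <- list(cycle = cycle_r, model = model, segmentation = seg,
                 mesh = mesh, surfaces = surfaces, strain = field,
                 summary = summary, ridge_metrics = ridge_metrics,
                 log = log, seed = cfg$seed)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(summary, file.path(cfg$out_dir, "strain_summary.csv"),
              row.names = FALSE)
    if (!is.null(ridge_metrics)) {
      write.csv(ridge_metrics, file.path(cfg$out_dir, "ridge_metrics.csv"),
                row.names = FALSE)
    }
    if (cfg$write_vtk) {
      write_strain_vtk(surfaces, field, cfg$out_dir)
    }
    cfg_out <- cfg
    cfg_out$movie <- NULL
    cfg_path <- file.path(cfg$out_dir, "resolved_config.json")
    jsonlite::write_json(cfg_out, cfg_path, auto_unbox = TRUE, digits = NA,
                         force = TRUE, pretty = TRUE)
    prov <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                 package_version =
                   as.character(utils::packageVersion("strain4d")),
                 seed = cfg$seed, log = log)
    jsonlite::write_json(prov, file.path(cfg$out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
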