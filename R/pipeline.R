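#' Pipeline configuration with reference defaults
#'
#' All stage parameters in one place: intensity window (-900, -115) HU,
#' oral-cavity volume window (3, 9.66) cm^3, vertex-merge tolerance 1e-6 cm,
#' Taubin lambda 0.60 / nu 0.635 / 20 iterations, cap thickness 0.3 mm and
#' radius scale 1.5, turbulence intensity 4 percent, C_mu 0.09, breathing
#' period 2 s with 100 L/min peak flow.
#' @param ... overrides for any default field.
#' @export
pipeline_config <- function(...) {
  cfg <- list(I0 = -900, I1 = -115,
              oral_low = 3, oral_high = 9.66,
              median_kernel = 3L,
              metal_threshold = 2500,
              merge_eps_mm = 1e-5,
              taubin_lambda = 0.60, taubin_nu = 0.635, taubin_n = 20L,
              cap_thickness_mm = 0.3, cap_scale = 1.5,
              turbulence_I = 0.04, C_mu = 0.09,
              Q_max_lpm = 100, period_s = 2,
              pitch_mm = NULL, resample_mm = 0.5,
              seed = 1L,
              smooth = TRUE, reduce_metal = TRUE)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Run the airway-modeling pipeline end to end
#'
#' Stages: HU volume -> air-cavity mask -> raw surface -> watertight repair
#' -> Taubin smoothing -> centerline network -> capped geometry -> CFD case
#' (+ optional dose preparation from deposition records). Entry stage is
#' inferred from the input: a [scalar_volume()] enters at segmentation, a
#' logical mask at surface extraction, a [surface_mesh()] (or STL path) at
#' repair. Every stage appends to the returned manifest.
#'
#' @param input a `scalar_volume`, logical mask array, `surface_mesh`, or
#'   path to `.nii`/`.nii.gz`/`.stl`.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for stage outputs (STL, JSON).
#' @param mask_spacing spacing when `input` is a bare mask array.
#' @param records optional [deposition_records()] for dose preparation.
#' @return list with the stage outputs (`mask`, `surface`, `repaired`,
#'   `network`, `capped`, `case`, `batches`) and `manifest`.
#' @export
run_pipeline <- function(input, config = pipeline_config(), out_dir = NULL,
                         mask_spacing = c(1, 1, 1), records = NULL) {
  manifest <- list()
  t_start <- proc.time()[3]
  log_stage <- function(stage, ...) {
    manifest[[length(manifest) + 1L]] <<-
      c(list(stage = stage, elapsed_s = round(proc.time()[3] - t_start, 3)),
        list(...))
  }
  if (is.character(input)) {
    input <- if (grepl("\\.stl$", input, ignore.case = TRUE)) read_stl(input)
    else read_volume(input)
  }
  mask <- NULL; spacing <- mask_spacing; origin <- c(0, 0, 0)
  surface <- NULL
  if (inherits(input, "scalar_volume")) {
    vol <- input
    spacing <- vol$spacing
    vol_n <- normalize_window(vol, window_params(config$I0, config$I1))
    if (config$reduce_metal && any(vol$values >= config$metal_threshold)) {
      vol <- reduce_metal_artifacts(vol, config$metal_threshold)
      vol_n <- normalize_window(vol, window_params(config$I0, config$I1))
    }
    vol_n <- median_denoise(vol_n, config$median_kernel)
    vol_e <- edge_refine(vol_n)
    vol_e <- laplacian_enhance(vol_e)
    filt <- body_filter_params(config$oral_low, config$oral_high)
    mask <- segment_air_cavities(vol_e, filt)
    log_stage("segment", n_air_voxels = sum(mask),
              bodies = nrow(attr(mask, "report")))
  } else if (is.logical(input) && is.array(input)) {
    mask <- input
  } else if (inherits(input, "surface_mesh")) {
    surface <- input
  } else stop("unsupported input for the pipeline")

  if (is.null(surface)) {
    if (!any(mask)) stop("segmentation produced an empty mask")
    surface <- extract_surface(mask, spacing, origin)
    log_stage("surface", n_faces = nrow(surface$faces))
  }
  rep <- repair_to_watertight(surface, eps = config$merge_eps_mm)
  repaired <- rep$mesh
  log_stage("repair", iterations = rep$report$iterations,
            watertight = rep$report$watertight)
  if (config$smooth) {
    repaired <- taubin_smooth(repaired,
                              taubin_params(config$taubin_lambda,
                                            config$taubin_nu,
                                            config$taubin_n))
    log_stage("smooth", lambda = config$taubin_lambda,
              nu = config$taubin_nu, n = config$taubin_n)
  }
  net <- build_network(repaired, pitch = config$pitch_mm,
                       resample_mm = config$resample_mm)
  log_stage("centerline", endpoints = length(net$endpoints),
            branches = length(unique(net$branch_id)))
  capped <- cap_all(repaired, net, scale = config$cap_scale,
                    t = config$cap_thickness_mm)
  log_stage("cap", patches = nrow(capped$patches))
  case <- emit_case(capped,
                    breathing_pattern(config$Q_max_lpm, config$period_s),
                    I = config$turbulence_I)
  log_stage("cfd_case", u_ref = case$turbulence$u_ref)
  batches <- NULL
  if (!is.null(records)) {
    recs <- assign_activity(records)
    batches <- batch_sources(recs, dual_decay = TRUE)
    log_stage("dose_prep", n_batches = length(batches))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_stl(repaired, file.path(out_dir, "repaired.stl"))
    write_network_json(net, file.path(out_dir, "centerline.json"))
    write_stl(capped$mesh, file.path(out_dir, "capped.stl"))
    write_patches_json(capped, file.path(out_dir, "patches.json"))
    write_case_json(case, file.path(out_dir, "case.json"))
    if (!is.null(batches))
      write_source_batches(batches, file.path(out_dir, "sources.txt"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  list(mask = mask, surface = surface, repaired = repaired, network = net,
       capped = capped, case = case, batches = batches, manifest = manifest)
}
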