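#' Configure the end-to-end phantom pipeline
#'
#' Bundles per-stage settings for [run_pipeline()]. The pipeline simulates a
#' phantom per subject, segments it, meshes it, runs the prone to zero-gravity
#' to supine deformation, warps the labels, measures local density in the
#' ultrasound-equivalent ROI, and reports cohort statistics. The supine
#' breast depth "measured on ultrasound" is emulated as
#' `supine_depth_ratio x` the zero-gravity depth.
#'
#' @param n_subjects Subjects to simulate.
#' @param seed Master seed; subject i uses `seed + i` throughout.
#' @param phantom Baseline [phantom_spec()] (per-subject seed and target
#'   density are overridden).
#' @param cohort [cohort_config()] supplying the density / ROI-depth /
#'   stiffness distributions.
#' @param materials [material_params()].
#' @param solver [solver_options()].
#' @param target_edge_mm Mesh lattice edge (mm).
#' @param supine_depth_ratio Target supine depth as a fraction of the
#'   zero-gravity depth.
#' @param out_dir Optional directory for stage outputs (NIfTI masks, VTK
#'   meshes, report JSON); `NULL` writes nothing.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 2L, seed = 1L,
                            phantom = phantom_spec(),
                            cohort = cohort_config(),
                            materials = material_params(),
                            solver = solver_options(),
                            target_edge_mm = 8,
                            supine_depth_ratio = 0.8,
                            out_dir = NULL) {
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 phantom = phantom, cohort = cohort, materials = materials,
                 solver = solver, target_edge_mm = target_edge_mm,
                 supine_depth_ratio = supine_depth_ratio, out_dir = out_dir),
            class = "pipeline_config")
}

#' Save / load a pipeline configuration as JSON
#' @param config A `pipeline_config`.
#' @param path JSON path.
#' @return `path` invisibly / the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(lapply(unclass(config), unclass), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipeline_config(
    n_subjects = raw$n_subjects, seed = raw$seed,
    phantom = do.call(phantom_spec, raw$phantom),
    cohort = do.call(cohort_config,
                     c(raw$cohort[setdiff(names(raw$cohort), "correlations")],
                       list(correlations = if (is.null(raw$cohort$correlations))
                         NULL else as.matrix(raw$cohort$correlations)))),
    materials = do.call(material_params, raw$materials[c("K", "nu", "rho")]),
    solver = do.call(solver_options,
                     raw$solver[setdiff(names(raw$solver), character(0))]),
    target_edge_mm = raw$target_edge_mm,
    supine_depth_ratio = raw$supine_depth_ratio,
    out_dir = raw$out_dir)
  cfg
}

run_one_subject <- function(config, i, stiffness_row) {
  t0 <- Sys.time()
  cc <- config$cohort
  set.seed(config$seed + i)
  target <- min(40, max(2, rnorm(1, cc$whole_density_mean, cc$whole_density_sd)))
  roi_depth <- clip_low(rnorm(1, cc$roi_depth_mean, cc$roi_depth_sd), 0.1)
  ps <- config$phantom
  ps$target_percent_density <- target
  ps$seed <- config$seed + i
  ph <- generate_phantom(ps)

  seg <- segment_breast(ph$image, chest_mask = ph$chest_mask)
  surf <- extract_surface(seg$breast_mask, spacing = ph$image$spacing,
                          origin = ph$image$origin)
  mesh <- tetrahedralize(surf, config$target_edge_mm)
  mesh <- label_elements(mesh, seg$fgt_mask, seg$breast_mask,
                         ph$image$spacing, ph$image$origin)
  mesh <- mark_fixed_boundary(mesh, ph$chest_plane$point, ph$chest_plane$normal,
                              tol_mm = 0.51 * config$target_edge_mm)
  mesh <- set_nipple_node(mesh, ph$nipple_mm)

  zg <- estimate_zero_gravity(mesh, config$materials, options = config$solver)
  target_depth <- config$supine_depth_ratio * breast_depth(zg$mesh)
  sup <- load_supine_until_depth(zg$mesh, config$materials, target_depth,
                                 options = config$solver)
  labels <- warp_labels(mesh, sup$nodes, seg$fgt_mask, seg$breast_mask,
                        ph$image$spacing, ph$image$origin)
  nip_sup <- sup$nodes[mesh$nipple_node, ]
  roi <- place_roi(labels, ph$image$spacing, ph$image$origin, nip_sup,
                   depth_cm = min(roi_depth, 0.8 * sup$achieved_depth_cm),
                   width_cm = cc$roi_window_cm[1],
                   height_cm = cc$roi_window_cm[2])
  local_density <- local_percent_density(labels, roi)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    tag <- sprintf("subject%03d", i)
    write_nifti(image_volume(labels, ph$image$spacing, ph$image$origin),
                file.path(config$out_dir, paste0(tag, "_supine_labels.nii.gz")))
    write_vtk_mesh(mesh, file.path(config$out_dir, paste0(tag, "_prone.vtk")))
    write_vtk_mesh(mesh, file.path(config$out_dir, paste0(tag, "_supine.vtk")),
                   nodes_mm = sup$nodes,
                   point_vectors = list(displacement = sup$nodes - mesh$nodes))
  }
  data.frame(subject_id = sprintf("P%03d", i),
             age = stiffness_row$age,
             breast_volume = seg$breast_volume,
             fgt_volume = seg$fgt_volume,
             whole_percent_density = seg$percent_density,
             local_percent_density = local_density,
             stiffness = stiffness_row$stiffness,
             roi_depth = roi_depth,
             zero_gravity_depth = breast_depth(zg$mesh),
             supine_depth = sup$achieved_depth_cm,
             load_factor = sup$load_factor,
             seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
             stringsAsFactors = FALSE)
}

#' Run the end-to-end phantom pipeline
#'
#' Executes simulate, segment, mesh, deform, measure, and report for each
#' subject. A failing stage aborts that subject only; the failure is recorded
#' and the pipeline continues. Deterministic given the config seeds.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`: `subjects` (per-subject
#'   measurement rows), `failures` (subject index + condition message),
#'   and `report` (a [cohort_report()] when >= 3 subjects succeeded,
#'   with synthetic stiffness values attached from the cohort model).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cc <- config$cohort
  cc$seed <- config$seed
  stiff <- sample_cohort(cc, n = max(config$n_subjects, 1L))
  rows <- list()
  failures <- list()
  for (i in seq_len(config$n_subjects)) {
    res <- tryCatch(run_one_subject(config, i, stiff[i, ]),
                    error = function(e)
                      structure(conditionMessage(e), class = "subject_failure"))
    if (inherits(res, "subject_failure")) {
      failures[[length(failures) + 1]] <- list(subject = i, message = res)
      message(sprintf("subject %d failed: %s", i, res))
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  subjects <- if (length(rows)) do.call(rbind, rows) else NULL
  report <- NULL
  if (!is.null(subjects) && nrow(subjects) >= 3) {
    tab <- subjects
    tab$stiffness_repeats <- stiff$stiffness_repeats[seq_len(nrow(subjects))]
    report <- cohort_report(tab)
  }
  if (!is.null(config$out_dir) && !is.null(report))
    write_report(report, file.path(config$out_dir, "cohort_report.json"))
  structure(list(subjects = subjects, failures = failures, report = report),
            class = "pipeline_result")
}
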