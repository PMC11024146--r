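#' End-to-end pipeline configuration
#'
#' Collects every knob of [run_pipeline()] with reproducible defaults; the
#' resolved configuration is echoed into the run manifest so a run can be
#' reproduced bit-identically from its output directory.
#'
#' @param n_subjects cohort size.
#' @param cohort_seed integer seed driving all randomness.
#' @param variability meniscal profile perturbation SD (mm).
#' @param noise_sigma observation jitter SD (mm).
#' @param ppsa_degree polynomial degree of the PPSA corrections (at most
#'   number of poses - 1).
#' @param sample_angles flexion angles (degrees) at which exact poses are
#'   extracted from each subject's PPSA model (clamped per subject to the
#'   calibrated interval).
#' @param metric_direction surface-distance direction for validation.
#' @param voxel MRI voxel dimensions (mm) for the accuracy criterion.
#' @param fit [fit_config()] used for all meniscus fits.
#' @param skip_loo omit the leave-one-out validation stage.
#' @param output_dir run directory (created; default: a fresh tempdir).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 11, cohort_seed = 1L,
                            variability = 0.5, noise_sigma = 0.3571,
                            ppsa_degree = 3L,
                            sample_angles = c(0, 30, 60, 90),
                            metric_direction = "symmetric",
                            voxel = c(0.3571, 0.3571, 1.5),
                            fit = fit_config(),
                            skip_loo = FALSE,
                            output_dir = NULL) {
  if (n_subjects < 1) stop("configuration error: n_subjects must be >= 1")
  if (ppsa_degree < 1 || ppsa_degree > 3)
    stop("configuration error: ppsa_degree must be in 1..3 ",
         "(four poses per subject)")
  if (!metric_direction %in% c("symmetric", "one_sided"))
    stop("configuration error: unknown metric direction '",
         metric_direction, "'")
  structure(list(n_subjects = as.integer(n_subjects),
                 cohort_seed = as.integer(cohort_seed),
                 variability = variability, noise_sigma = noise_sigma,
                 ppsa_degree = as.integer(ppsa_degree),
                 sample_angles = as.numeric(sample_angles),
                 metric_direction = metric_direction,
                 voxel = as.numeric(voxel), fit = fit,
                 skip_loo = isTRUE(skip_loo), output_dir = output_dir),
            class = "pipeline_config")
}

pipeline_log <- function(con, ...) {
  msg <- paste0(...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full dynamic meniscal modeling workflow
#'
#' Executes the complete workflow on a synthetic cohort: cohort generation
#' (bones, cartilage, elastically fitted menisci in four loaded poses),
#' rigid Procrustes bone placement from noisy sparse cortical points
#' (checked against the analytic motion), subject-specific PPSA model
#' fitting, extraction of poses at exact flexion angles, cohort-mean
#' meniscal displacement analysis (maximal point-dependent displacement
#' per structure and angle, plus anatomical-region maxima), and
#' leave-one-out validation with median/range error tables.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the cohort, PPSA models, displacement
#'   table, LOO result and the run directory; all artifacts are also
#'   written to `config$output_dir` (mean meshes as PLY with displacement
#'   scalars, tables as CSV, a JSON manifest, a log).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) stop("not a pipeline_config")
  out_dir <- config$output_dir
  if (is.null(out_dir))
    out_dir <- file.path(tempdir(), paste0("meniscusdyn-run-",
                                           config$cohort_seed))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(log_con))
  stage <- "synth"
  result <- tryCatch({
    pipeline_log(log_con, "run_pipeline: seed ", config$cohort_seed,
                 ", n = ", config$n_subjects)

    cohort <- generate_population(config$n_subjects, config$cohort_seed,
                                  variability = config$variability,
                                  noise_sigma = config$noise_sigma,
                                  config = config$fit)
    pipeline_log(log_con, "synth: generated ", length(cohort), " subjects")

    stage <- "bone_placement"
    proc_err <- with_seed(config$cohort_seed + 1L, {
      vapply(cohort, function(s) {
        max(vapply(seq_along(s$poses), function(k) {
          src <- s$sparse_cortical_points$reference
          tgt <- s$sparse_cortical_points$per_pose[[k]] +
            matrix(stats::rnorm(length(src), 0, config$noise_sigma),
                   nrow(src), 3)
          fit <- rigid_procrustes(src, tgt)
          rotation_angle_between(fit$rotation,
                                 s$analytic_motion[[k]]$rotation) * 180 / pi
        }, 0))
      }, 0)
    })
    pipeline_log(log_con, sprintf(
      "bone placement: max Procrustes rotation error %.4f deg",
      max(proc_err)))

    stage <- "ppsa"
    models <- lapply(cohort, function(s) {
      layout <- shape_layout(s$poses[[1]])
      angles <- vapply(s$poses, function(p)
        flexion_angle(p$femur, s$tibial_frame, s$shaft_vertex_indices), 0)
      vecs <- lapply(s$poses, assemble_shape_vector, layout = layout)
      fit_ppsa(vecs, angles, degree = config$ppsa_degree, layout = layout)
    })
    pipeline_log(log_con, "ppsa: fitted ", length(models),
                 " subject-specific models")

    stage <- "exact_angles"
    lo <- max(vapply(models, function(m) m$angle_interval[1], 0))
    hi <- min(vapply(models, function(m) m$angle_interval[2], 0))
    angles <- pmin(pmax(config$sample_angles, lo), hi)
    pipeline_log(log_con, sprintf(
      "exact-angle extraction at %s deg (common calibrated interval [%.2f, %.2f])",
      paste(sprintf("%.2f", angles), collapse = "/"), lo, hi))
    sampled <- lapply(models, function(m)
      lapply(angles, function(a) sample_pose(m, a)))

    stage <- "displacement"
    frames <- lapply(cohort, `[[`, "tibial_frame")
    mean_menisci <- list()
    for (side in c("medial", "lateral")) {
      comp <- paste0("meniscus_", side)
      mean_menisci[[side]] <- lapply(seq_along(angles), function(ai)
        mean_corresponded_mesh(lapply(seq_along(sampled), function(si)
          extract_component(sampled[[si]][[ai]], comp)), frames))
    }
    disp_rows <- list()
    for (side in c("medial", "lateral")) {
      ref <- mean_menisci[[side]][[1]]
      # region masks from the template-built cohort mesh (same topology;
      # sampled poses do not carry the tube-construction attributes)
      masks <- meniscus_region_masks(cohort[[1]]$poses[[1]][[comp]])
      for (ai in seq_along(angles)[-1]) {
        fld <- displacement_field(ref, mean_menisci[[side]][[ai]],
                                  source_label = sprintf("%g", angles[1]),
                                  target_label = sprintf("%g", angles[ai]))
        mx <- max_point_displacement(fld)
        disp_rows[[length(disp_rows) + 1]] <- data.frame(
          structure = side, angle = config$sample_angles[ai],
          max_displacement_mm = mx$mm, vertex = mx$vertex,
          anterior_horn_mm = max_point_displacement(fld,
                                                    masks$anterior_horn)$mm,
          body_mm = max_point_displacement(fld, masks$body)$mm,
          posterior_horn_mm = max_point_displacement(fld,
                                                     masks$posterior_horn)$mm)
        write_mesh(mean_menisci[[side]][[ai]],
                   file.path(out_dir, sprintf("mean_%s_%g.ply", side,
                                              config$sample_angles[ai])),
                   vertex_scalar = fld$magnitudes)
        write_displacement_field(fld, file.path(
          out_dir, sprintf("displacement_%s_%g.csv", side,
                           config$sample_angles[ai])))
      }
      write_mesh(ref, file.path(out_dir, sprintf("mean_%s_%g.ply", side,
                                                 config$sample_angles[1])))
    }
    displacement_table <- do.call(rbind, disp_rows)
    utils::write.csv(displacement_table,
                     file.path(out_dir, "displacement_table.csv"),
                     row.names = FALSE)
    pipeline_log(log_con, sprintf(
      "displacement: max point-dependent displacement %.2f mm (medial), %.2f mm (lateral)",
      max(displacement_table$max_displacement_mm[
        displacement_table$structure == "medial"]),
      max(displacement_table$max_displacement_mm[
        displacement_table$structure == "lateral"])))

    loo <- NULL
    if (!config$skip_loo) {
      stage <- "validation"
      loo <- leave_one_out(cohort, config = config$fit,
                           direction = config$metric_direction)
      write_cohort_summary(loo$summary,
                           file.path(out_dir, "loo_summary.csv"))
      vx <- max(config$voxel)
      med_asd <- loo$summary[loo$summary$metric == "ASD", ]
      pipeline_log(log_con, sprintf(
        "validation: max median ASD %.3f mm (voxel criterion %.2f mm: %s)",
        max(med_asd$median), vx,
        if (max(med_asd$median) <= vx) "pass" else "fail"))
    }

    manifest <- list(config = unclass_recursive(config),
                     achieved_angles = lapply(cohort, `[[`,
                                              "achieved_angles"),
                     subject_seeds = vapply(cohort, function(s)
                       s$params$seed, 0L),
                     sampled_angles = angles,
                     procrustes_max_rotation_error_deg = max(proc_err))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    pipeline_log(log_con, "done: outputs in ", out_dir)
    list(cohort = cohort, models = models,
         displacement_table = displacement_table,
         procrustes_errors = proc_err, loo = loo, output_dir = out_dir)
  }, error = function(e) {
    pipeline_log(log_con, "FAILED at stage '", stage, "': ",
                 conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

unclass_recursive <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_recursive) else x
}
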