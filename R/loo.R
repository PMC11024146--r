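#' Leave-one-out validation of meniscal anatomy prediction
#'
#' For each held-out subject, the cohort-mean meniscal dimension profiles
#' and the cohort-mean cartilage thickness map are rebuilt from the
#' remaining subjects (profiles normalized to a common reference femoral
#' length before averaging), rescaled by the held-out subject's femoral
#' length, instantiated on that subject's own bony anatomy (centerline,
#' horn anchors, bone meshes and poses are observed inputs, as segmented
#' bones are in practice), and the menisci are fitted elastically in all
#' four poses.  Predicted and ground-truth menisci are then compared with
#' [surface_error_report()] per structure and flexion angle.
#'
#' @param cohort list of [generate_subject()] results (>= 3 subjects).
#' @param config [fit_config()] for the prediction fits.
#' @param direction metric direction, see [surface_error_report()].
#' @return object of class `loo_result`: `summary` (a `cohort_summary`
#'   data frame of median/min/max per structure, angle and metric),
#'   `metrics` (long data frame of per-subject RMSE/ASD/HD), `error_maps`
#'   (per structure x angle mean point-dependent error vectors),
#'   `failures` (per-subject fit failures, excluded from the summary).
#' @export
leave_one_out <- function(cohort, config = fit_config(),
                          direction = c("symmetric", "one_sided")) {
  direction <- match.arg(direction)
  n <- length(cohort)
  if (n < 3) stop("leave-one-out needs at least 3 subjects, got ", n)
  lapply(cohort, function(s) {
    if (!inherits(s, "synthetic_subject")) stop("not a synthetic_subject")
  })
  Lref <- .ref_femoral_length
  sides <- c("medial", "lateral")

  rows <- list()
  maps <- list()
  failures <- list()
  for (j in seq_len(n)) {
    subj <- cohort[[j]]
    others <- cohort[-j]
    Lj <- subj$params$femoral_length
    res <- tryCatch({
      pred <- predict_subject_menisci(subj, others, Lj, Lref, config)
      local_rows <- list()
      for (side in sides) {
        comp <- paste0("meniscus_", side)
        for (k in seq_along(subj$poses)) {
          rep_ <- surface_error_report(pred[[side]][[k]],
                                       subj$poses[[k]][[comp]],
                                       direction = direction)
          local_rows[[length(local_rows) + 1]] <- data.frame(
            subject = j, structure = side,
            angle = subj$poses[[k]]$label,
            rmse = rep_$rmse, asd = rep_$asd, hd = rep_$hd)
          key <- paste(side, subj$poses[[k]]$label, sep = "_")
          maps[[key]] <- c(maps[[key]], list(rep_$per_point_errors))
        }
      }
      do.call(rbind, local_rows)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <-
        list(subject = j, message = conditionMessage(res))
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  if (length(rows) == 0) stop("all leave-one-out fits failed")
  metrics <- do.call(rbind, rows)

  cells <- list()
  for (side in sides) {
    for (ang in unique(metrics$angle)) {
      sub <- metrics[metrics$structure == side & metrics$angle == ang, ]
      for (met in c("rmse", "asd", "hd")) {
        mr <- median_range_summary(sub[[met]])
        cells[[length(cells) + 1]] <- data.frame(
          structure = side, angle = ang, metric = toupper(met),
          median = mr$median, min = mr$min, max = mr$max,
          n_subjects = nrow(sub))
      }
    }
  }
  summary <- do.call(rbind, cells)
  class(summary) <- c("cohort_summary", "data.frame")
  structure(list(summary = summary,
                 metrics = metrics,
                 error_maps = lapply(maps, mean_point_error_map),
                 failures = failures,
                 direction = direction),
            class = "loo_result")
}

# prediction of one subject's menisci from the other subjects' statistics
predict_subject_menisci <- function(subj, others, Lj, Lref, config) {
  norm_profile <- function(s, side, what)
    s$templates[[side]][[what]] * Lref / s$params$femoral_length
  # cohort-mean cartilage map, normalized then rescaled
  tbar <- rowMeans(vapply(others, function(s)
    s$cartilage_map$thickness * Lref / s$params$femoral_length,
    numeric(length(subj$cartilage_map$thickness)))) * Lj / Lref
  map_mean <- cartilage_thickness_map(subj$cartilage_map$bone_vertex_indices,
                                      tbar, Lj)
  fem_cart0 <- mesh_subset(
    build_cartilage_surface(subj$femur_reference, map_mean),
    unlist(attr(subj$femur_reference,
                "component_ranges")[c("condyle_medial",
                                      "condyle_lateral")]))

  out <- list()
  for (side in c("medial", "lateral")) {
    hbar <- rowMeans(vapply(others, norm_profile, side = side,
                            what = "height_profile",
                            numeric(subj$templates[[side]]$sections)))
    wbar <- rowMeans(vapply(others, norm_profile, side = side,
                            what = "width_profile",
                            numeric(subj$templates[[side]]$sections)))
    tpl <- meniscus_template(subj$templates[[side]]$centerline,
                             hbar * Lj / Lref, wbar * Lj / Lref,
                             Lj, subj$templates[[side]]$attachment_sections)
    tube0 <- build_template_tube(tpl, Lj, subj$anchors[[side]],
                                 paste0("meniscus_", side))
    cur <- tube0
    fits <- vector("list", length(subj$poses))
    for (k in seq_along(subj$poses)) {
      fem_cart_k <- apply_transform(fem_cart0, subj$analytic_motion[[k]])
      fit <- fit_meniscus(cur, fem_cart_k, subj$tibial_cartilage,
                          config = config, rest_mesh = tube0)
      cur <- fit$mesh
      fits[[k]] <- fit$mesh
    }
    out[[side]] <- fits
  }
  out
}

#' @export
print.loo_result <- function(x, ...) {
  cat("Leave-one-out validation (", x$direction, " distances, n = ",
      x$summary$n_subjects[1], ")\n\n", sep = "")
  print(format_cohort_summary(x$summary))
  if (length(x$failures) > 0)
    cat("\n", length(x$failures), "subject(s) failed and were excluded\n")
  invisible(x)
}

#' Format a cohort summary as a median (min-max) table
#'
#' Renders the per-structure, per-angle error table in the conventional
#' "median (min-max)" layout, metrics as rows.
#'
#' @param summary a `cohort_summary` data frame from [leave_one_out()].
#' @return data frame of formatted strings.
#' @export
format_cohort_summary <- function(summary) {
  cell <- function(st, an, met) {
    r <- summary[summary$structure == st & summary$angle == an &
                   summary$metric == met, ]
    if (nrow(r) == 0) return(NA_character_)
    sprintf("%.2f (%.2f-%.2f)", r$median, r$min, r$max)
  }
  angs <- unique(summary$angle)
  out <- list()
  for (met in c("RMSE", "ASD", "HD")) {
    for (st in unique(summary$structure)) {
      out[[paste(met, st)]] <- vapply(angs, cell, "", st = st, met = met)
    }
  }
  df <- as.data.frame(out, check.names = FALSE, optional = TRUE)
  rownames(df) <- paste0(angs, " deg")
  t(df)
}

#' Write a cohort summary to CSV
#'
#' @param summary a `cohort_summary` data frame.
#' @param path output CSV path.
#' @export
write_cohort_summary <- function(summary, path) {
  utils::write.csv(as.data.frame(summary), path, row.names = FALSE)
  invisible(path)
}
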