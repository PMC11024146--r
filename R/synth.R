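#' Parameters of one synthetic knee subject
#'
#' The synthetic cohort stands in for a restricted in-vivo MRI dataset: a
#' parametric right knee with spherical femoral condyles (so contact
#' geometry has closed forms usable as oracles), a grid-topped tibial
#' plateau, medial-pivot/rollback femorotibial kinematics, template-based
#' menisci fitted elastically per pose, and vertex-level segmentation noise
#' at MRI voxel scale applied to "observed" copies only.
#'
#' Defaults describe a young-adult cohort (about 1.65 m body height, femur
#' around 432 mm): condylar radii just over 2 cm, four loaded poses near
#' 0/30/60/90 degrees approximated with a goniometer, and in-plane-voxel
#' noise of 0.3571 mm.  The lateral condyle translates posteriorly faster
#' than the medial one (medial pivot, femoral rollback).
#'
#' @param femoral_length mm.
#' @param condyle_radius_medial,condyle_radius_lateral condylar sphere
#'   radii (mm) at `femoral_length`; internally specified at the cohort
#'   reference length and scaled.
#' @param condyle_spacing center-to-center mediolateral distance (mm).
#' @param plateau_ap,plateau_ml tibial plateau extents (mm).
#' @param cartilage_femoral_peak,cartilage_tibial peak femoral / uniform
#'   tibial cartilage thickness (mm) at the reference femoral length.
#' @param meniscus_h_peak,meniscus_h_horn,meniscus_w_peak,meniscus_w_horn
#'   meniscal height/width profile parameters (mm) at mid-body (peak) and
#'   at the horns, already at this subject's femoral length.
#' @param pivot_medial,pivot_lateral posterior translation of each condyle
#'   per degree of flexion (mm/deg); lateral must be >= medial.  The
#'   defaults (0.02 and 0.12) encode a strong medial pivot: about 2 mm of
#'   medial and 11 mm of lateral posterior translation over 0-90 degrees,
#'   the scale reported for loaded deep flexion in vivo.
#' @param noise_sigma segmentation jitter SD (mm) for observed meshes.
#' @param nominal_angles goniometer-nominal flexion angles (degrees).
#' @param goniometer_error_range half-width (degrees) of the uniform
#'   goniometer approximation error.
#' @param seed integer RNG seed; recorded in all outputs.
#' @return object of class `subject_params`.
#' @export
subject_params <- function(femoral_length = 432,
                           condyle_radius_medial = 22 * femoral_length / 432,
                           condyle_radius_lateral = 21 * femoral_length / 432,
                           condyle_spacing = 46 * femoral_length / 432,
                           plateau_ap = 55 * femoral_length / 432,
                           plateau_ml = 80 * femoral_length / 432,
                           cartilage_femoral_peak = 2.2 * femoral_length / 432,
                           cartilage_tibial = 2.0 * femoral_length / 432,
                           meniscus_h_peak = 4.5 * femoral_length / 432,
                           meniscus_h_horn = 2.2 * femoral_length / 432,
                           meniscus_w_peak = 9.0 * femoral_length / 432,
                           meniscus_w_horn = 4.5 * femoral_length / 432,
                           pivot_medial = 0.02,
                           pivot_lateral = 0.12,
                           noise_sigma = 0.3571,
                           nominal_angles = c(0, 30, 60, 90),
                           goniometer_error_range = 5,
                           seed = 1L) {
  p <- list(femoral_length = femoral_length,
            condyle_radius_medial = condyle_radius_medial,
            condyle_radius_lateral = condyle_radius_lateral,
            condyle_spacing = condyle_spacing,
            plateau_ap = plateau_ap, plateau_ml = plateau_ml,
            cartilage_femoral_peak = cartilage_femoral_peak,
            cartilage_tibial = cartilage_tibial,
            meniscus_h_peak = meniscus_h_peak,
            meniscus_h_horn = meniscus_h_horn,
            meniscus_w_peak = meniscus_w_peak,
            meniscus_w_horn = meniscus_w_horn,
            pivot_medial = pivot_medial, pivot_lateral = pivot_lateral,
            noise_sigma = noise_sigma,
            nominal_angles = as.numeric(nominal_angles),
            goniometer_error_range = goniometer_error_range,
            seed = as.integer(seed))
  lens <- c(p$femoral_length, p$condyle_radius_medial,
            p$condyle_radius_lateral, p$condyle_spacing, p$plateau_ap,
            p$plateau_ml, p$cartilage_femoral_peak, p$cartilage_tibial,
            p$meniscus_h_peak, p$meniscus_h_horn, p$meniscus_w_peak,
            p$meniscus_w_horn)
  if (any(lens <= 0)) stop("all lengths must be positive")
  if (p$pivot_lateral < p$pivot_medial)
    stop("medial pivot encoding requires pivot_lateral >= pivot_medial")
  if (p$noise_sigma < 0) stop("noise_sigma must be nonnegative")
  structure(p, class = "subject_params")
}

# cohort reference femoral length (mm) all profiles are normalized to
.ref_femoral_length <- 432

# z of the condylar sphere centers: cartilage-covered sphere resting on the
# tibial cartilage plane (tibial plateau bone top at z = 0)
.condyle_center <- function(p, side) {
  r <- if (side == "medial") p$condyle_radius_medial else
    p$condyle_radius_lateral
  y <- if (side == "medial") p$condyle_spacing / 2 else -p$condyle_spacing / 2
  c(0, y, r + p$cartilage_femoral_peak + p$cartilage_tibial)
}

build_synth_tibia <- function(p) {
  ratio <- p$femoral_length / .ref_femoral_length
  plateau <- mesh_slab_grid(c(0, 0, -6 * ratio),
                            c(p$plateau_ap, p$plateau_ml, 12 * ratio),
                            nx = 9, ny = 11)
  shaft <- mesh_cylinder(c(0, 0, -12 * ratio), c(0, 0, -130 * ratio),
                         radius = 13 * ratio, n_seg = 12)
  tuber <- mesh_box(c(16 * ratio, 0, -20 * ratio),
                    c(10, 14, 16) * ratio)
  fibula <- mesh_cylinder(c(0, -(p$plateau_ml / 2 + 7), -20 * ratio),
                          c(0, -(p$plateau_ml / 2 + 7), -120 * ratio),
                          radius = 5 * ratio, n_seg = 8)
  tibia <- mesh_union(list(plateau = plateau, shaft = shaft,
                           tuberosity = tuber, fibula = fibula),
                      label = "tibia_fibula")
  attr(tibia, "plateau_top_indices") <-
    attr(tibia, "component_ranges")$plateau[attr(plateau, "top_indices")]
  tibia
}

build_synth_femur <- function(p) {
  ratio <- p$femoral_length / .ref_femoral_length
  cm <- .condyle_center(p, "medial")
  cl <- .condyle_center(p, "lateral")
  med <- mesh_uv_sphere(cm, p$condyle_radius_medial, n_lat = 9, n_lon = 12)
  lat <- mesh_uv_sphere(cl, p$condyle_radius_lateral, n_lat = 9, n_lon = 12)
  z0 <- max(cm[3] + p$condyle_radius_medial,
            cl[3] + p$condyle_radius_lateral) - 8 * ratio
  shaft <- mesh_cylinder(c(0, 0, z0), c(0, 0, z0 + 140 * ratio),
                         radius = 15 * ratio, n_seg = 12)
  femur <- mesh_union(list(condyle_medial = med, condyle_lateral = lat,
                           shaft = shaft), label = "femur")
  rng <- attr(femur, "component_ranges")
  attr(femur, "shaft_indices") <- rng$shaft
  attr(femur, "condyle_centers") <- rbind(medial = cm, lateral = cl)
  femur
}

# femoral articular cartilage: thickest at the inferior pole of each
# condyle, thinning toward the equator
femoral_thickness_map <- function(femur, p) {
  rng <- attr(femur, "component_ranges")
  centers <- attr(femur, "condyle_centers")
  radii <- c(p$condyle_radius_medial, p$condyle_radius_lateral)
  idx <- integer(0)
  thick <- numeric(0)
  for (k in 1:2) {
    ids <- rng[[c("condyle_medial", "condyle_lateral")[k]]]
    v <- femur$vertices[ids, , drop = FALSE]
    rel_z <- (centers[k, 3] - v[, 3]) / radii[k]   # 1 at inferior pole
    art <- rel_z > 0.05
    idx <- c(idx, ids[art])
    thick <- c(thick, p$cartilage_femoral_peak *
                 (0.55 + 0.45 * pmin(pmax(rel_z[art], 0), 1)))
  }
  cartilage_thickness_map(idx, thick, p$femoral_length)
}

# C-shaped meniscus template around one condyle; anterior horn first
synth_meniscus_template <- function(p, side, sections = 16) {
  r <- if (side == "medial") p$condyle_radius_medial else
    p$condyle_radius_lateral
  center <- .condyle_center(p, side)[1:2]
  R <- if (side == "medial") 0.58 * r else 0.60 * r
  half_gap <- if (side == "medial") 55 else 35   # deg; medial C is shorter
  if (side == "medial") {
    phi <- seq(-90 + half_gap, -90 - half_gap + 360,
               length.out = sections) * pi / 180
    phi <- rev(phi)       # anterior (x > 0) horn first
  } else {
    phi <- seq(90 - half_gap + 360, 90 + half_gap,
               length.out = sections) * pi / 180
  }
  s <- seq(0, 1, length.out = sections)
  h <- p$meniscus_h_horn + (p$meniscus_h_peak - p$meniscus_h_horn) *
    sin(pi * s)
  w <- p$meniscus_w_horn + (p$meniscus_w_peak - p$meniscus_w_horn) *
    sin(pi * s)
  z_ct <- p$cartilage_tibial
  cl <- cbind(center[1] + R * cos(phi), center[2] + R * sin(phi),
              z_ct + 0.1 + h / 3)
  meniscus_template(cl, h, w, p$femoral_length, attachment_sections = 1L)
}

# rigid femoral motion at flexion angle theta (deg): rotation about the
# transcondylar axis, a yaw encoding the extra lateral posterior
# translation (medial pivot), and the shared posterior rollback
femur_pose_transform <- function(p, theta) {
  cm <- .condyle_center(p, "medial")
  cl <- .condyle_center(p, "lateral")
  axis <- cm - cl
  axis <- axis / sqrt(sum(axis^2))
  R1 <- rotation_about_axis(axis, theta)
  T1 <- rigid_transform(R1, cm - as.vector(R1 %*% cm))
  sin_phi <- -(p$pivot_lateral - p$pivot_medial) * theta / p$condyle_spacing
  phi <- asin(pmin(pmax(sin_phi, -1), 1)) * 180 / pi
  R2 <- rotation_about_axis(c(0, 0, 1), phi)
  T2 <- rigid_transform(R2, cm - as.vector(R2 %*% cm))
  T3 <- rigid_transform(diag(3), c(-p$pivot_medial * theta, 0, 0))
  compose_transforms(T3, compose_transforms(T2, T1))
}

#' Generate one synthetic knee subject
#'
#' Builds the parametric bones, the cartilage layers, and four loaded
#' poses: the femur moves by the analytic medial-pivot/rollback transform
#' at each achieved flexion angle (nominal plus goniometer error), the
#' menisci are template tubes fitted elastically against the posed femoral
#' cartilage (the converged fits are the ground truth), observed copies
#' carry vertex jitter of SD `noise_sigma` (ground truth is never
#' perturbed), and 300 paired cortical surface points per pose support the
#' rigid Procrustes bone-placement stage.  Fully reproducible from
#' `params$seed`.
#'
#' @param params a [subject_params()].
#' @param config [fit_config()] used for the meniscus fits.
#' @return object of class `synthetic_subject`: `params`, `poses` (four
#'   ground-truth [knee_pose()]s), `observed_poses`, `achieved_angles`,
#'   `analytic_motion` (per-pose [rigid_transform()]s),
#'   `sparse_cortical_points` (`reference` matrix + per-pose list),
#'   cartilage meshes, templates, anchors, the tibial frame and the
#'   femoral shaft/plateau index masks.
#' @export
generate_subject <- function(params, config = fit_config()) {
  if (!inherits(params, "subject_params")) stop("not a subject_params")
  p <- params
  with_seed(p$seed, {
    tibia <- build_synth_tibia(p)
    femur0 <- build_synth_femur(p)
    fmap <- femoral_thickness_map(femur0, p)
    # articular submeshes carry the cartilage used in the fits: the
    # menisci can only ever touch the condyles and the plateau
    fem_cart0 <- mesh_subset(
      build_cartilage_surface(femur0, fmap),
      unlist(attr(femur0, "component_ranges")[c("condyle_medial",
                                                "condyle_lateral")]))
    tmap <- cartilage_thickness_map(attr(tibia, "plateau_top_indices"),
                                    rep(p$cartilage_tibial,
                                        length(attr(tibia,
                                                    "plateau_top_indices"))),
                                    p$femoral_length)
    tib_cart <- mesh_subset(build_cartilage_surface(tibia, tmap),
                            attr(tibia, "component_ranges")$plateau)
    frame <- tibial_frame(tibia, attr(tibia, "plateau_top_indices"))

    g <- p$goniometer_error_range
    err <- c(stats::runif(1, 0, g),
             stats::runif(length(p$nominal_angles) - 1, -g, g))
    achieved <- p$nominal_angles + err
    if (any(diff(achieved) <= 0))
      stop("achieved flexion angles are not strictly increasing")
    # infeasibility guard: condylar cartilage must stay above the plateau
    if (.condyle_center(p, "medial")[3] <
        p$condyle_radius_medial + p$cartilage_femoral_peak - 1e-9)
      stop("infeasible geometry: condyles intersect the plateau at extension")

    tpl_med <- synth_meniscus_template(p, "medial")
    tpl_lat <- synth_meniscus_template(p, "lateral")
    anch_med <- tpl_med$centerline[c(1, tpl_med$sections), , drop = FALSE]
    anch_lat <- tpl_lat$centerline[c(1, tpl_lat$sections), , drop = FALSE]
    tube_med <- build_template_tube(tpl_med, p$femoral_length, anch_med,
                                    "meniscus_medial")
    tube_lat <- build_template_tube(tpl_lat, p$femoral_length, anch_lat,
                                    "meniscus_lateral")

    motions <- lapply(achieved, function(th) femur_pose_transform(p, th))
    poses <- vector("list", length(achieved))
    fem_carts <- vector("list", length(achieved))
    fit_reports <- vector("list", length(achieved))
    cur_med <- tube_med
    cur_lat <- tube_lat
    for (k in seq_along(achieved)) {
      femur_k <- apply_transform(femur0, motions[[k]])
      fem_cart_k <- apply_transform(fem_cart0, motions[[k]])
      fit_med <- fit_meniscus(cur_med, fem_cart_k, tib_cart, config = config,
                              rest_mesh = tube_med)
      fit_lat <- fit_meniscus(cur_lat, fem_cart_k, tib_cart, config = config,
                              rest_mesh = tube_lat)
      cur_med <- fit_med$mesh
      cur_lat <- fit_lat$mesh
      poses[[k]] <- knee_pose(femur_k, tibia, fit_med$mesh, fit_lat$mesh,
                              flexion_angle = achieved[k],
                              label = sprintf("%g", p$nominal_angles[k]))
      fem_carts[[k]] <- fem_cart_k
      fit_reports[[k]] <- list(medial = fit_med$report,
                               lateral = fit_lat$report)
    }

    femur_surface_pts <- sample_surface_points(femur0, 300)
    sparse <- list(reference = femur_surface_pts,
                   per_pose = lapply(motions, function(tr)
                     apply_transform(femur_surface_pts, tr)))

    observed <- lapply(poses, function(pose) {
      if (p$noise_sigma == 0) return(pose)
      for (nm in ppsa_component_names()) {
        v <- pose[[nm]]$vertices
        pose[[nm]]$vertices <- v +
          matrix(stats::rnorm(length(v), 0, p$noise_sigma), nrow(v), 3)
      }
      pose
    })

    structure(list(params = p,
                   femur_reference = femur0,
                   tibia = tibia,
                   poses = poses,
                   observed_poses = observed,
                   achieved_angles = achieved,
                   analytic_motion = motions,
                   fit_reports = fit_reports,
                   initial_tubes = list(medial = tube_med,
                                        lateral = tube_lat),
                   sparse_cortical_points = sparse,
                   femoral_cartilage = fem_carts,
                   tibial_cartilage = tib_cart,
                   cartilage_map = fmap,
                   templates = list(medial = tpl_med, lateral = tpl_lat),
                   anchors = list(medial = anch_med, lateral = anch_lat),
                   tibial_frame = frame,
                   plateau_vertex_indices =
                     attr(tibia, "plateau_top_indices"),
                   shaft_vertex_indices = attr(femur0, "shaft_indices")),
              class = "synthetic_subject")
  })
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf(paste0("synthetic_subject (seed %d): femoral length %.1f mm,",
                     " achieved angles %s deg\n"),
              x$params$seed, x$params$femoral_length,
              paste(sprintf("%.1f", x$achieved_angles), collapse = "/")))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Femoral lengths are drawn around the cohort mean (432 mm, SD 18 mm,
#' matching a 1.65 m +/- 0.07 m young-adult cohort); meniscal profile
#' parameters are the cohort profile scaled by each subject's femoral
#' length ratio plus Gaussian perturbations of SD `variability`;
#' per-subject seeds are derived deterministically from `cohort_seed`.
#'
#' @param n number of subjects (>= 1).
#' @param cohort_seed integer seed for the cohort-level draws.
#' @param variability SD (mm) of the meniscal profile perturbations.
#' @param noise_sigma observation jitter SD (mm) passed to every subject.
#' @param config [fit_config()] for the meniscus fits.
#' @return list of [generate_subject()] results.
#' @export
generate_population <- function(n, cohort_seed = 1L, variability = 0.5,
                                noise_sigma = 0.3571,
                                config = fit_config()) {
  if (n < 1) stop("cohort size must be at least 1")
  draws <- with_seed(cohort_seed, {
    list(lengths = stats::rnorm(n, .ref_femoral_length, 18),
         seeds = sample.int(2^30, n),
         perturb = matrix(stats::rnorm(4L * n, 0, variability), n, 4))
  })
  lapply(seq_len(n), function(i) {
    L <- draws$lengths[i]
    ratio <- L / .ref_femoral_length
    dp <- draws$perturb[i, ]
    prm <- subject_params(
      femoral_length = L,
      meniscus_h_peak = max(4.5 * ratio + dp[1], 1.5),
      meniscus_h_horn = max(2.2 * ratio + dp[2] * 0.5, 0.8),
      meniscus_w_peak = max(9.0 * ratio + dp[3], 3.0),
      meniscus_w_horn = max(4.5 * ratio + dp[4] * 0.5, 1.5),
      noise_sigma = noise_sigma,
      seed = draws$seeds[i])
    generate_subject(prm, config = config)
  })
}

#' Ground-truth displacement field of a component between two poses
#'
#' Exact field from the stored noise-free geometry: for bone components it
#' equals the analytic rigid femoral motion applied to the reference
#' vertices (the tibia is the fixed frame, so its field is zero).
#'
#' @param subject a [generate_subject()] result.
#' @param from_label,to_label nominal pose labels (e.g. `"0"`, `"90"`).
#' @param component a component name as in [extract_component()].
#' @return a [displacement_field()].
#' @export
ground_truth_displacement <- function(subject, from_label, to_label,
                                      component) {
  if (!inherits(subject, "synthetic_subject")) stop("not a synthetic_subject")
  labs <- vapply(subject$poses, `[[`, "", "label")
  i <- match(as.character(from_label), labs)
  j <- match(as.character(to_label), labs)
  if (is.na(i)) stop("unknown pose label '", from_label, "'")
  if (is.na(j)) stop("unknown pose label '", to_label, "'")
  displacement_field(extract_component(subject$poses[[i]], component),
                     extract_component(subject$poses[[j]], component),
                     source_label = labs[i], target_label = labs[j])
}
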