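#' Cartilage thickness map
#'
#' Per-vertex cartilage thickness keyed to articular-surface vertices of a
#' bone mesh, together with the femoral length of the reference anatomy the
#' map was measured on.  Subject-specific maps are obtained by linear
#' scaling with the subject's femoral length ([scale_thickness_map()]).
#'
#' @param bone_vertex_indices integer indices of articular vertices on the
#'   target bone mesh (unique).
#' @param thickness per-index thickness in mm (all >= 0).
#' @param reference_femoral_length femoral length (mm) of the reference
#'   anatomy.
#' @return object of class `cartilage_thickness_map`.
#' @export
cartilage_thickness_map <- function(bone_vertex_indices, thickness,
                                    reference_femoral_length) {
  bone_vertex_indices <- as.integer(bone_vertex_indices)
  thickness <- as.numeric(thickness)
  if (length(bone_vertex_indices) != length(thickness))
    stop("indices and thickness must have equal length")
  if (anyDuplicated(bone_vertex_indices))
    stop("duplicate vertex indices in thickness map")
  if (any(thickness < 0)) stop("negative cartilage thickness")
  if (reference_femoral_length <= 0)
    stop("reference femoral length must be positive")
  structure(list(bone_vertex_indices = bone_vertex_indices,
                 thickness = thickness,
                 reference_femoral_length = reference_femoral_length),
            class = "cartilage_thickness_map")
}

#' Scale a cartilage thickness map to a subject's femoral length
#'
#' Every thickness is multiplied by `femoral_length / reference_femoral_length`;
#' the vertex indices are unchanged.
#'
#' @param map a [cartilage_thickness_map()].
#' @param femoral_length subject femoral length in mm (> 0).
#' @return the scaled map (its reference length becomes `femoral_length`).
#' @export
scale_thickness_map <- function(map, femoral_length) {
  if (!inherits(map, "cartilage_thickness_map")) stop("not a thickness map")
  if (femoral_length <= 0) stop("femoral length must be positive")
  ratio <- femoral_length / map$reference_femoral_length
  cartilage_thickness_map(map$bone_vertex_indices, map$thickness * ratio,
                          femoral_length)
}

#' Construct a cartilage surface by normal offset of a bone mesh
#'
#' Articular vertices listed in the thickness map are displaced outward
#' along their vertex normals by the mapped thickness; all other vertices
#' are unmoved.  The face array is untouched, so correspondence with the
#' bone mesh is preserved.  If the offset locally inverts a triangle
#' (thickness too large for the local curvature) a warning lists the
#' affected vertices, and the surface is still returned.
#'
#' @param bone a closed [triangle_mesh()].
#' @param map a [cartilage_thickness_map()] with indices valid for `bone`.
#' @return a [triangle_mesh()] labeled `"cartilage"`.
#' @export
build_cartilage_surface <- function(bone, map) {
  stopifnot_mesh(bone)
  if (!inherits(map, "cartilage_thickness_map")) stop("not a thickness map")
  idx <- map$bone_vertex_indices
  if (length(idx) > 0 && (min(idx) < 1L || max(idx) > n_vertices(bone)))
    stop("thickness map indices out of range for this bone mesh")
  nrm <- vertex_normals(bone)
  v <- bone$vertices
  v[idx, ] <- v[idx, ] + nrm[idx, , drop = FALSE] * map$thickness
  out <- triangle_mesh(v, bone$faces, "cartilage")
  # flag faces whose normal flipped: local self-intersection of the offset
  old_cr <- face_cross(bone)
  new_cr <- face_cross(out)
  flipped <- rowSums(old_cr * new_cr) < 0
  if (any(flipped)) {
    bad <- sort(unique(as.vector(bone$faces[flipped, ])))
    warning("cartilage offset self-intersects locally at vertices: ",
            paste(utils::head(bad, 20), collapse = ", "))
  }
  out
}

#' Meniscus dimension template
#'
#' The generative prior for a meniscus: an anterior-to-posterior horn
#' centerline with height and width profiles sampled along it, and the
#' femoral length of the reference anatomy.  Heights and widths scale
#' linearly with a subject's femoral length when the template is
#' instantiated by [build_template_tube()].
#'
#' @param centerline numeric matrix (sections x 3), ordered from the
#'   anterior to the posterior horn (mm).
#' @param height_profile,width_profile per-section height/width in mm
#'   (strictly positive).
#' @param reference_femoral_length mm.
#' @param attachment_sections number of sections at each end of the
#'   centerline whose tube vertices are horn attachments (fixed to the
#'   tibial plateau).
#' @return object of class `meniscus_template`.
#' @export
meniscus_template <- function(centerline, height_profile, width_profile,
                              reference_femoral_length,
                              attachment_sections = 1L) {
  centerline <- as.matrix(centerline)
  if (ncol(centerline) != 3L) stop("centerline must be n x 3")
  ns <- nrow(centerline)
  if (ns < 4L) stop("centerline needs at least 4 sections")
  if (length(height_profile) != ns || length(width_profile) != ns)
    stop("profiles must have one value per centerline section")
  if (any(height_profile <= 0) || any(width_profile <= 0))
    stop("height and width profiles must be strictly positive")
  if (reference_femoral_length <= 0)
    stop("reference femoral length must be positive")
  seg <- sqrt(rowSums(diff(centerline)^2))
  if (any(seg == 0)) stop("centerline has repeated consecutive points")
  structure(list(centerline = centerline,
                 height_profile = as.numeric(height_profile),
                 width_profile = as.numeric(width_profile),
                 reference_femoral_length = reference_femoral_length,
                 attachment_sections = as.integer(attachment_sections),
                 sections = ns),
            class = "meniscus_template")
}

# Wedge cross-section ring in centered profile coordinates (d inward, z up):
# the triangle with a peripheral wall of height h at the outer edge, a flat
# inferior face of width w, and a tapering inner tip.  Points are sampled
# on the triangle perimeter so the polygon area is exactly h*w/2; offsets
# are centered on the triangle centroid so the centerline is mid-tissue.
wedge_ring <- function(h, w) {
  pts <- rbind(
    c(0, 0), c(0, h / 2), c(0, h),                 # outer wall, bottom->top
    c(w / 3, 2 * h / 3), c(2 * w / 3, h / 3),      # inner taper
    c(w, 0),                                       # inner tip
    c(2 * w / 3, 0), c(w / 3, 0))                  # flat inferior face
  sweep(pts, 2, c(w / 3, h / 3))                   # centroid at origin
}

#' Build a meniscus tube from a template
#'
#' Sweeps a wedge cross-section (flat inferior face, peripheral wall of
#' height `h(s)`, inner taper over width `w(s)`) along the template
#' centerline.  Heights and widths are scaled by
#' `femoral_length / reference_femoral_length`; the centerline length is
#' not scaled.  The tube is rigidly positioned (rotation about the vertical
#' axis plus translation) so its horn endpoints land on the two anchor
#' points, with any residual closed by a linear blend along the centerline.
#' Vertex layout is section-major and fully deterministic, so repeated
#' builds are bit-identical and vertex `k` corresponds across poses and
#' subjects by construction.
#'
#' @param template a [meniscus_template()].
#' @param femoral_length subject femoral length (mm).
#' @param attachments 2 x 3 matrix: anterior and posterior horn anchor
#'   points (mm).
#' @param label component tag for the resulting mesh.
#' @return closed [triangle_mesh()] with attributes `attachment_vertices`
#'   (indices fixed to the plateau), `ring_size`, `sections`.
#' @export
build_template_tube <- function(template, femoral_length, attachments,
                                label = "meniscus") {
  if (!inherits(template, "meniscus_template")) stop("not a meniscus_template")
  if (femoral_length <= 0) stop("femoral length must be positive")
  attachments <- matrix(as.numeric(attachments), ncol = 3)
  if (nrow(attachments) != 2L) stop("attachments must be a 2 x 3 matrix")
  if (sqrt(sum((attachments[1, ] - attachments[2, ])^2)) < 1e-9)
    stop("attachment anchors coincide")
  lam <- femoral_length / template$reference_femoral_length
  h <- template$height_profile * lam
  w <- template$width_profile * lam
  cl <- template$centerline
  ns <- template$sections

  # rigid placement: rotate about z to map the horn chord onto the anchor
  # chord, translate chord midpoints together
  e0 <- cl[1, ]; e1 <- cl[ns, ]
  chord_t <- cl[ns, ] - cl[1, ]
  chord_a <- attachments[2, ] - attachments[1, ]
  ang <- atan2(chord_a[2], chord_a[1]) - atan2(chord_t[2], chord_t[1])
  R <- rotation_about_axis(c(0, 0, 1), ang * 180 / pi)
  mid_t <- (e0 + e1) / 2
  mid_a <- (attachments[1, ] + attachments[2, ]) / 2
  cl <- sweep(sweep(cl, 2, mid_t) %*% t(R), 2, mid_a, "+")
  # linear blend closes any residual end mismatch (zero when the anchors
  # are geometrically consistent with the template chord)
  r0 <- attachments[1, ] - cl[1, ]
  r1 <- attachments[2, ] - cl[ns, ]
  s <- arclength_param(cl)
  cl <- cl + outer(1 - s, r0) + outer(s, r1)

  # local frames: tangent by central differences, inward horizontal normal,
  # global vertical up (the tube rests on the plateau plane)
  tang <- rbind(cl[2, ] - cl[1, ],
                cl[3:ns, ] - cl[1:(ns - 2), ],
                cl[ns, ] - cl[ns - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))
  up <- c(0, 0, 1)
  nin <- cbind(up[2] * tang[, 3] - up[3] * tang[, 2],
               up[3] * tang[, 1] - up[1] * tang[, 3],
               up[1] * tang[, 2] - up[2] * tang[, 1])
  nin <- nin / sqrt(rowSums(nin^2))
  centroid <- colMeans(cl)
  flip <- rowSums(nin * sweep(-cl, 2, -centroid)) < 0
  nin[flip, ] <- -nin[flip, ]

  # curvature guard: the inner tip must not cross the centerline's local
  # center of curvature
  if (ns >= 3) {
    kappa <- discrete_curvature(cl)
    reach <- (2 / 3) * w
    bad <- which(kappa * reach >= 1)
    if (length(bad) > 0)
      stop(sprintf(paste0("cross-section self-intersection from centerline ",
                          "curvature near arclength s = %.3f"), s[bad[1]]))
  }

  ring_n <- nrow(wedge_ring(1, 1))
  verts <- matrix(0, ns * ring_n + 2L, 3)
  for (i in seq_len(ns)) {
    ring <- wedge_ring(h[i], w[i])
    verts[(i - 1L) * ring_n + seq_len(ring_n), ] <-
      sweep(outer(ring[, 1], nin[i, ]) + outer(ring[, 2], up), 2, cl[i, ], "+")
  }
  cap0 <- ns * ring_n + 1L
  cap1 <- ns * ring_n + 2L
  verts[cap0, ] <- cl[1, ]
  verts[cap1, ] <- cl[ns, ]

  rid <- function(i, k) (i - 1L) * ring_n + ((k - 1L) %% ring_n) + 1L
  faces <- vector("list", 2L * (ns - 1L) * ring_n + 2L * ring_n)
  fi <- 0L
  for (i in seq_len(ns - 1L)) {
    for (k in seq_len(ring_n)) {
      fi <- fi + 1L; faces[[fi]] <- c(rid(i, k), rid(i, k + 1), rid(i + 1, k + 1))
      fi <- fi + 1L; faces[[fi]] <- c(rid(i, k), rid(i + 1, k + 1), rid(i + 1, k))
    }
  }
  for (k in seq_len(ring_n)) {
    fi <- fi + 1L; faces[[fi]] <- c(cap0, rid(1, k + 1), rid(1, k))
    fi <- fi + 1L; faces[[fi]] <- c(cap1, rid(ns, k), rid(ns, k + 1))
  }
  mesh <- triangle_mesh(verts, do.call(rbind, faces), label)
  if (compute_volume(mesh) < 0)   # enforce outward orientation
    mesh$faces <- mesh$faces[, c(1, 3, 2)]

  na <- template$attachment_sections
  att <- c(as.vector(vapply(seq_len(na),
                            function(i) (i - 1L) * ring_n + seq_len(ring_n),
                            integer(ring_n))),
           as.vector(vapply(ns - seq_len(na) + 1L,
                            function(i) (i - 1L) * ring_n + seq_len(ring_n),
                            integer(ring_n))),
           cap0, cap1)
  attr(mesh, "attachment_vertices") <- sort(unique(att))
  attr(mesh, "ring_size") <- ring_n
  attr(mesh, "sections") <- ns
  mesh
}

arclength_param <- function(cl) {
  seg <- sqrt(rowSums(diff(cl)^2))
  s <- c(0, cumsum(seg))
  s / s[length(s)]
}

discrete_curvature <- function(cl) {
  ns <- nrow(cl)
  kappa <- numeric(ns)
  for (i in 2:(ns - 1)) {
    a <- cl[i, ] - cl[i - 1, ]
    b <- cl[i + 1, ] - cl[i, ]
    cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
    la <- sqrt(sum(a^2)); lb <- sqrt(sum(b^2))
    lc <- sqrt(sum((cl[i + 1, ] - cl[i - 1, ])^2))
    kappa[i] <- 2 * sqrt(sum(cr^2)) / (la * lb * lc)
  }
  kappa[1] <- kappa[2]
  kappa[ns] <- kappa[ns - 1]
  kappa
}

#' Solver configuration for the elastic meniscus fit
#'
#' @param penetration_tolerance maximum tolerated cartilage penetration
#'   depth in mm (constraint on the accepted fit).
#' @param volume_tolerance maximum tolerated relative volume drift.
#' @param contact_weight,penetration_weight,elastic_weight,smoothing_weight
#'   nonnegative energy weights.
#' @param contact_range mm; vertices within this unsigned distance of the
#'   femoral cartilage are attracted to it.
#' @param max_iterations iteration cap.
#' @param step_tolerance convergence threshold on the maximum vertex move
#'   per iteration (mm).
#' @param energy_tolerance relative energy-decrease threshold: the fit
#'   also stops (after a burn-in of 30 iterations) once an accepted step
#'   lowers the energy by less than this fraction.  The default trades a
#'   shape change well below the imaging noise scale for roughly a third
#'   of the iterations.
#' @param step_size gradient step scale (dimensionless).
#' @return object of class `fit_config`.
#' @export
fit_config <- function(penetration_tolerance = 0.05,
                       volume_tolerance = 1e-3,
                       contact_weight = 0.5,
                       penetration_weight = 1,
                       elastic_weight = 0.4,
                       smoothing_weight = 0.15,
                       contact_range = 1.5,
                       max_iterations = 500L,
                       step_tolerance = 1e-3,
                       energy_tolerance = 1e-5,
                       step_size = 0.8) {
  if (penetration_tolerance <= 0 || volume_tolerance <= 0 ||
      step_tolerance <= 0 || energy_tolerance <= 0)
    stop("tolerances must be strictly positive")
  w <- c(contact_weight, penetration_weight, elastic_weight, smoothing_weight)
  if (any(w < 0)) stop("weights must be nonnegative")
  if (contact_weight <= 0 && penetration_weight <= 0)
    stop("at least one of contact/penetration weight must be positive")
  structure(list(penetration_tolerance = penetration_tolerance,
                 volume_tolerance = volume_tolerance,
                 contact_weight = contact_weight,
                 penetration_weight = penetration_weight,
                 elastic_weight = elastic_weight,
                 smoothing_weight = smoothing_weight,
                 contact_range = contact_range,
                 max_iterations = as.integer(max_iterations),
                 step_tolerance = step_tolerance,
                 energy_tolerance = energy_tolerance,
                 step_size = step_size),
            class = "fit_config")
}

# signed distance query without per-call closedness revalidation; callers
# must have verified the mesh is closed (hot path of the fit loop).  The
# 6 mm sign band skips the winding-number test for far points: fit scenes
# never bury vertices deeper than the initial press depth (< 4 mm), and
# the hard projection keeps later penetrations below the tolerance.
.signed_query <- function(points, mesh, hint = NULL) {
  if (is.null(hint)) hint <- integer(0)
  cpp_signed_mesh_query(points, mesh$vertices, mesh$faces - 1L,
                        sign_band = 6, hint = hint)
}

mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# energy of a candidate configuration (see fit_meniscus); the fairness
# term penalizes deviation of the Laplacian (delta) coordinates from the
# rest shape's, so the rest shape itself is energy-free
fit_energy <- function(X, df, dt, edges, L0, nbr, delta0, config) {
  pen_f <- pmax(0, -df)
  pen_t <- pmax(0, -dt)
  contact <- pmax(0, pmin(df, config$contact_range))
  el <- sqrt(rowSums((X[edges[, 1], ] - X[edges[, 2], ])^2)) - L0
  lap <- (X - nbr %*% X) - delta0
  config$penetration_weight * sum(pen_f^2 + pen_t^2) +
    config$contact_weight * sum(contact^2) +
    config$elastic_weight * sum(el^2) +
    config$smoothing_weight * sum(lap^2)
}

#' Elastic, volume-preserving meniscus fit against condylar geometry
#'
#' Deforms an initial meniscus tube so that it conforms to the femoral
#' condyle cartilage without penetrating the femoral or tibial cartilage,
#' while preserving its enclosed volume, keeping the horn attachment
#' vertices exactly fixed, and never changing the mesh topology (so
#' anatomical correspondence is preserved by construction).
#'
#' The solver is a deterministic block-iterative scheme: a damped gradient
#' step on an energy combining contact attraction (vertices near the
#' femoral cartilage are pulled onto it), quadratic penetration penalties
#' against both cartilages, elastic edge-length deviation from the rest
#' shape, and a Laplacian fairness term on the deviation from the rest
#' shape's delta coordinates; followed each iteration by a hard projection
#' of penetrating vertices onto the cartilage surfaces and a
#' volume-restoring uniform offset along vertex normals applied to free,
#' non-contact vertices.  Steps that increase the energy are retried with a
#' smaller step, so the recorded energy is non-increasing across accepted
#' iterations.
#'
#' A constraint-free rest shape is an exact fixed point.  When fitting a
#' sequence of poses, pass the previous pose's fit as `initial` (a warm
#' start that preserves correspondence) and the template tube as
#' `rest_mesh`, so the elastic memory always refers to the undeformed
#' anatomy and deformations do not accumulate across poses.
#'
#' @param initial closed [triangle_mesh()] (typically from
#'   [build_template_tube()]).
#' @param femoral_cartilage,tibial_cartilage closed, outward-oriented
#'   cartilage meshes in the same frame as `initial`.
#' @param attachment_vertex_indices vertices held exactly fixed; defaults
#'   to the `attachment_vertices` attribute of `initial`.
#' @param config a [fit_config()].
#' @param rest_mesh topology-identical mesh defining the elastic rest
#'   state (edge lengths and delta coordinates); defaults to `initial`.
#' @return list of class `meniscus_fit` with elements `mesh` (the fitted
#'   mesh, topology identical to the input) and `report` (iterations,
#'   energy trace, max penetration, volume drift, convergence flag, config
#'   echo).
#' @export
fit_meniscus <- function(initial, femoral_cartilage, tibial_cartilage,
                         attachment_vertex_indices = NULL,
                         config = fit_config(), rest_mesh = NULL) {
  stopifnot_mesh(initial)
  if (is.null(rest_mesh)) rest_mesh <- initial
  if (!identical(rest_mesh$faces, initial$faces) ||
      n_vertices(rest_mesh) != n_vertices(initial))
    stop("rest_mesh must be topology-identical to the initial mesh")
  if (is.null(attachment_vertex_indices))
    attachment_vertex_indices <- attr(initial, "attachment_vertices")
  att <- as.integer(attachment_vertex_indices)
  nv <- n_vertices(initial)
  if (length(att) > 0 && (min(att) < 1L || max(att) > nv))
    stop("attachment vertex indices out of range")
  if (nrow(boundary_edges(initial)) > 0L) stop("initial mesh must be closed")
  if (nrow(boundary_edges(femoral_cartilage)) > 0L)
    stop("femoral cartilage mesh must be closed for signed distances")
  if (nrow(boundary_edges(tibial_cartilage)) > 0L)
    stop("tibial cartilage mesh must be closed for signed distances")

  V0 <- compute_volume(initial)
  X0 <- initial$vertices
  # infeasibility guard: fixed attachments buried inside cartilage
  if (length(att) > 0) {
    da <- pmin(surface_distance(X0[att, , drop = FALSE], femoral_cartilage,
                                signed = TRUE),
               surface_distance(X0[att, , drop = FALSE], tibial_cartilage,
                                signed = TRUE))
    if (min(da) < -config$penetration_tolerance)
      stop("infeasible geometry: attachment vertices lie inside cartilage ",
           "(depth ", format(-min(da), digits = 3), " mm)")
  }

  edges <- mesh_edges(initial)
  XR <- rest_mesh$vertices
  L0 <- sqrt(rowSums((XR[edges[, 1], ] - XR[edges[, 2], ])^2))
  # dense neighbor-average operator (uniform Laplacian)
  nbr_idx <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  nbr <- matrix(0, nv, nv)
  for (i in seq_len(nv)) {
    js <- nbr_idx[[as.character(i)]]
    nbr[i, js] <- 1 / length(js)
  }
  delta0 <- XR - nbr %*% XR     # rest-shape delta coordinates
  free <- setdiff(seq_len(nv), att)

  X <- X0
  qf <- .signed_query(X, femoral_cartilage)
  qt <- .signed_query(X, tibial_cartilage)
  energy <- fit_energy(X, qf$distance, qt$distance, edges, L0, nbr, delta0,
                       config)
  energies <- energy
  gamma <- config$step_size
  converged <- FALSE
  iters <- 0L

  for (iter in seq_len(config$max_iterations)) {
    iters <- iter
    df <- qf$distance; dt <- qt$distance
    # outward unit direction from each cartilage surface
    dir_f <- X - qf$closest
    nf <- sqrt(rowSums(dir_f^2)); nf[nf == 0] <- 1
    dir_f <- dir_f / nf * ifelse(df < 0, -1, 1)
    dir_t <- X - qt$closest
    nt <- sqrt(rowSums(dir_t^2)); nt[nt == 0] <- 1
    dir_t <- dir_t / nt * ifelse(dt < 0, -1, 1)

    disp <- matrix(0, nv, 3)
    # penetration: push out to the surface
    pf <- pmax(0, -df); pt <- pmax(0, -dt)
    disp <- disp + config$penetration_weight * (dir_f * pf + dir_t * pt)
    # contact attraction toward the femoral cartilage
    cf <- ifelse(df > 0 & df <= config$contact_range, df, 0)
    disp <- disp - config$contact_weight * dir_f * cf
    # elastic restoration of edge lengths
    ev <- X[edges[, 2], ] - X[edges[, 1], ]
    el <- sqrt(rowSums(ev^2))
    fmag <- (el - L0) / pmax(el, 1e-12)
    fvec <- ev * fmag
    elas <- matrix(0, nv, 3)
    for (k in 1:3) {
      elas[, k] <- tapply_sum(fvec[, k], edges[, 1], nv) -
        tapply_sum(fvec[, k], edges[, 2], nv)
    }
    disp <- disp + config$elastic_weight * elas
    # Laplacian fairness: pull the delta coordinates toward the rest shape
    disp <- disp + config$smoothing_weight * (nbr %*% X - X + delta0)

    accepted <- FALSE
    g <- gamma
    for (try in 1:5) {
      Xn <- X + g * disp
      Xn[att, ] <- X0[att, ]
      # hard projection of penetrating vertices onto the surfaces
      qfn <- .signed_query(Xn, femoral_cartilage, hint = qf$triangle)
      pen <- qfn$distance < 0
      pen[att] <- FALSE
      if (any(pen))
        Xn[pen, ] <- qfn$closest[pen, , drop = FALSE]
      qtn <- .signed_query(Xn, tibial_cartilage, hint = qt$triangle)
      pen <- qtn$distance < 0
      pen[att] <- FALSE
      if (any(pen))
        Xn[pen, ] <- qtn$closest[pen, , drop = FALSE]
      # volume restoration on free vertices clear of both cartilages
      # (pre-projection distances suffice: projected vertices were
      # penetrating and are excluded either way)
      clear <- setdiff(which(qfn$distance > 0.3 & qtn$distance > 0.3), att)
      Xn <- restore_volume(Xn, initial$faces, clear, V0)
      Xn[att, ] <- X0[att, ]
      qfn <- .signed_query(Xn, femoral_cartilage, hint = qfn$triangle)
      qtn <- .signed_query(Xn, tibial_cartilage, hint = qtn$triangle)
      en <- fit_energy(Xn, qfn$distance, qtn$distance, edges, L0, nbr,
                       delta0, config)
      if (en <= energy + 1e-12) { accepted <- TRUE; break }
      g <- g / 2
    }
    if (!accepted) { converged <- TRUE; break }
    # remember the step scale that worked; cautiously regrow it
    gamma <- min(g * 1.3, config$step_size)
    move <- max(sqrt(rowSums((Xn - X)^2)))
    drop_rel <- (energy - en) / max(en, 1e-12)
    X <- Xn; qf <- qfn; qt <- qtn; energy <- en
    energies <- c(energies, en)
    if (move < config$step_tolerance) { converged <- TRUE; break }
    if (iter >= 30 && drop_rel < config$energy_tolerance) {
      converged <- TRUE
      break
    }
  }

  # constraint polish: alternate hard penetration projection and volume
  # restoration until both constraints hold simultaneously
  for (pol in seq_len(30)) {
    qf <- .signed_query(X, femoral_cartilage, hint = qf$triangle)
    qt <- .signed_query(X, tibial_cartilage, hint = qt$triangle)
    max_pen <- max(0, -min(qf$distance), -min(qt$distance))
    vol_ok <- abs(signed_volume_raw(X, initial$faces) - V0) / V0 <=
      0.5 * config$volume_tolerance
    if (max_pen <= 0.5 * config$penetration_tolerance && vol_ok) break
    pen <- qf$distance < 0
    pen[att] <- FALSE
    if (any(pen)) X[pen, ] <- qf$closest[pen, , drop = FALSE]
    qt <- .signed_query(X, tibial_cartilage, hint = qt$triangle)
    pen <- qt$distance < 0
    pen[att] <- FALSE
    if (any(pen)) X[pen, ] <- qt$closest[pen, , drop = FALSE]
    qf <- .signed_query(X, femoral_cartilage, hint = qf$triangle)
    qt <- .signed_query(X, tibial_cartilage, hint = qt$triangle)
    clear <- setdiff(which(qf$distance > 0.3 & qt$distance > 0.3), att)
    X <- restore_volume(X, initial$faces, clear, V0)
    X[att, ] <- X0[att, ]
  }
  qf <- .signed_query(X, femoral_cartilage, hint = qf$triangle)
  qt <- .signed_query(X, tibial_cartilage, hint = qt$triangle)

  fitted <- triangle_mesh(X, initial$faces, initial$label)
  attributes(fitted)[c("attachment_vertices", "ring_size", "sections")] <-
    attributes(initial)[c("attachment_vertices", "ring_size", "sections")]
  Vf <- compute_volume(fitted)
  max_pen <- max(0, -min(qf$distance), -min(qt$distance))
  report <- list(iterations = iters,
                 energies = energies,
                 final_energy = energy,
                 max_penetration = max_pen,
                 volume_initial = V0,
                 volume_fitted = Vf,
                 volume_drift = abs(Vf - V0) / V0,
                 converged = converged,
                 config = unclass(config))
  if (!converged)
    stop(structure(class = c("meniscusdyn_nonconvergence", "error",
                             "condition"),
                   list(message = sprintf(
                     paste0("meniscus fit did not converge after %d ",
                            "iterations (max penetration %.4f mm, volume ",
                            "drift %.2e)"),
                     iters, max_pen, report$volume_drift),
                     call = sys.call(-1),
                     partial = fitted, report = report)))
  structure(list(mesh = fitted, report = report), class = "meniscus_fit")
}

# divergence-theorem volume without validation overhead (hot path)
signed_volume_raw <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

vertex_normals_raw <- function(v, f) {
  m <- structure(list(vertices = v, faces = f, label = NULL),
                 class = "triangle_mesh")
  cr <- face_cross(m)
  nv <- nrow(v)
  acc <- matrix(0, nv, 3)
  for (k in 1:3) {
    acc[, 1] <- acc[, 1] + tapply_sum(cr[, 1], f[, k], nv)
    acc[, 2] <- acc[, 2] + tapply_sum(cr[, 2], f[, k], nv)
    acc[, 3] <- acc[, 3] + tapply_sum(cr[, 3], f[, k], nv)
  }
  nrm <- sqrt(rowSums(acc^2))
  nrm[nrm == 0] <- 1
  acc / nrm
}

# uniform offset along vertex normals over `idx`, solving the 1-D volume
# equation V(c) = V0 by safeguarded Newton (V(c) is a cubic in c)
restore_volume <- function(X, faces, idx, V0) {
  if (length(idx) == 0) return(X)
  nrm <- vertex_normals_raw(X, faces)
  volc <- function(c_) {
    Xc <- X
    Xc[idx, ] <- Xc[idx, ] + c_ * nrm[idx, , drop = FALSE]
    signed_volume_raw(Xc, faces)
  }
  c_ <- 0
  for (it in 1:6) {
    v <- volc(c_)
    if (abs(v - V0) < 1e-10 * V0) break
    h <- 1e-5
    dv <- (volc(c_ + h) - v) / h
    if (!is.finite(dv) || abs(dv) < 1e-12) break
    step <- (V0 - v) / dv
    step <- max(min(step, 0.5), -0.5)   # mm safeguard
    c_ <- c_ + step
  }
  X[idx, ] <- X[idx, ] + c_ * nrm[idx, , drop = FALSE]
  X
}

#' @export
print.meniscus_fit <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("meniscus_fit: %d iterations, converged=%s\n",
                     "  max penetration %.4g mm, volume drift %.3g\n"),
              r$iterations, r$converged, r$max_penetration, r$volume_drift))
  invisible(x)
}

#' Serialize a fit report to JSON
#'
#' @param fit a `meniscus_fit` (or its `report` element).
#' @param path output file.
#' @export
write_fit_report <- function(fit, path) {
  rep <- if (inherits(fit, "meniscus_fit")) fit$report else fit
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read/write a cartilage thickness map as CSV
#'
#' Columns `vertex_index`, `thickness_mm`; the reference femoral length is
#' carried in a `# reference_femoral_length_mm:` header comment.
#'
#' @param map a [cartilage_thickness_map()].
#' @param path CSV file path.
#' @export
write_thickness_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# reference_femoral_length_mm: %.17g",
                     map$reference_femoral_length), con)
  utils::write.csv(data.frame(vertex_index = map$bone_vertex_indices,
                              thickness_mm = map$thickness),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_thickness_map
#' @export
read_thickness_map <- function(path) {
  first <- readLines(path, n = 1)
  ref <- as.numeric(sub("# reference_femoral_length_mm: *", "", first))
  df <- utils::read.csv(path, comment.char = "#")
  cartilage_thickness_map(df$vertex_index, df$thickness_mm, ref)
}
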