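#' Articulated knee pose
#'
#' One articulated configuration of the knee: femur, tibia-fibula and the
#' two menisci in a shared coordinate frame, with its flexion angle.
#' Meniscus meshes are topology-identical across poses of one subject, so
#' vertex indices correspond anatomically.
#'
#' @param femur,tibia_fibula,meniscus_medial,meniscus_lateral
#'   [triangle_mesh()] components.
#' @param flexion_angle degrees (0 = extended).
#' @param label nominal pose tag, e.g. `"0"`, `"30"`, `"60"`, `"90"`.
#' @return object of class `knee_pose`.
#' @export
knee_pose <- function(femur, tibia_fibula, meniscus_medial, meniscus_lateral,
                      flexion_angle = NA_real_, label = NULL) {
  comps <- list(femur = femur, tibia_fibula = tibia_fibula,
                meniscus_medial = meniscus_medial,
                meniscus_lateral = meniscus_lateral)
  lapply(comps, stopifnot_mesh)
  structure(c(comps, list(flexion_angle = as.numeric(flexion_angle),
                          label = label)),
            class = "knee_pose")
}

#' @export
print.knee_pose <- function(x, ...) {
  cat(sprintf("knee_pose [%s], flexion %.2f deg\n",
              if (is.null(x$label)) "?" else x$label, x$flexion_angle))
  for (nm in ppsa_component_names())
    cat(sprintf("  %s: %d vertices\n", nm, n_vertices(x[[nm]])))
  invisible(x)
}

ppsa_component_names <- function() {
  c("femur", "tibia_fibula", "meniscus_medial", "meniscus_lateral")
}

#' Shape-vector layout of a knee pose
#'
#' Records the component spans (vertex counts) and shared face arrays used
#' to flatten a [knee_pose()] into a shape vector and back.  All poses
#' entering one PPSA model must share one layout.
#'
#' @param pose a reference [knee_pose()].
#' @return object of class `shape_layout`.
#' @export
shape_layout <- function(pose) {
  if (!inherits(pose, "knee_pose")) stop("not a knee_pose")
  comps <- lapply(ppsa_component_names(), function(nm)
    list(n_vertices = n_vertices(pose[[nm]]), faces = pose[[nm]]$faces,
         label = pose[[nm]]$label))
  names(comps) <- ppsa_component_names()
  structure(list(components = comps,
                 total_length = 3L * sum(vapply(comps, `[[`, 0L,
                                                "n_vertices"))),
            class = "shape_layout")
}

#' Flatten a knee pose into a shape vector
#'
#' Deterministic flattening: components in fixed order (femur,
#' tibia-fibula, medial meniscus, lateral meniscus), vertex-major
#' (x1, y1, z1, x2, ...).  Round-trips exactly with
#' [disassemble_shape_vector()].
#'
#' @param pose a [knee_pose()].
#' @param layout the [shape_layout()] shared by all poses of the model.
#' @return numeric vector of length `layout$total_length`.
#' @export
assemble_shape_vector <- function(pose, layout) {
  if (!inherits(pose, "knee_pose")) stop("not a knee_pose")
  if (!inherits(layout, "shape_layout")) stop("not a shape_layout")
  parts <- lapply(ppsa_component_names(), function(nm) {
    comp <- layout$components[[nm]]
    mesh <- pose[[nm]]
    if (n_vertices(mesh) != comp$n_vertices)
      stop("component '", nm, "' has ", n_vertices(mesh),
           " vertices; layout expects ", comp$n_vertices)
    if (!identical(mesh$faces, comp$faces))
      stop("component '", nm, "' face array differs from the layout ",
           "(correspondence violated)")
    as.vector(t(mesh$vertices))
  })
  unlist(parts, use.names = FALSE)
}

#' Unflatten a shape vector into a knee pose
#'
#' @param values numeric shape vector.
#' @param layout the [shape_layout()].
#' @param flexion_angle,label passed to [knee_pose()].
#' @return a [knee_pose()].
#' @export
disassemble_shape_vector <- function(values, layout, flexion_angle = NA_real_,
                                     label = NULL) {
  if (!inherits(layout, "shape_layout")) stop("not a shape_layout")
  if (length(values) != layout$total_length)
    stop("shape vector length ", length(values), " != layout length ",
         layout$total_length)
  meshes <- list()
  off <- 0L
  for (nm in ppsa_component_names()) {
    comp <- layout$components[[nm]]
    n <- comp$n_vertices
    v <- matrix(values[off + seq_len(3L * n)], n, 3, byrow = TRUE)
    meshes[[nm]] <- triangle_mesh(v, comp$faces, comp$label)
    off <- off + 3L * n
  }
  knee_pose(meshes$femur, meshes$tibia_fibula, meshes$meniscus_medial,
            meshes$meniscus_lateral, flexion_angle, label)
}

#' Extract one component mesh from a knee pose
#'
#' Vertex order is preserved, so components extracted from different poses
#' of one subject are corresponded and can feed [displacement_field()].
#'
#' @param pose a [knee_pose()].
#' @param component_label one of `"femur"`, `"tibia_fibula"`,
#'   `"meniscus_medial"`, `"meniscus_lateral"`.
#' @return a [triangle_mesh()].
#' @export
extract_component <- function(pose, component_label) {
  if (!inherits(pose, "knee_pose")) stop("not a knee_pose")
  if (!component_label %in% ppsa_component_names())
    stop("unknown component label '", component_label, "' (expected one of ",
         paste(ppsa_component_names(), collapse = ", "), ")")
  pose[[component_label]]
}

polyval_asc <- function(coef, x) {
  # coefficients in ascending order (intercept first)
  acc <- 0
  for (k in rev(seq_along(coef))) acc <- acc * x + coef[k]
  acc
}

polyfit_asc <- function(x, y, degree) {
  A <- outer(x, 0:degree, "^")
  qr.coef(qr(A), y)
}

#' Fit a Principal Polynomial Shape Analysis model
#'
#' Subject-specific non-linear shape model of the articulated knee over
#' flexion.  The corresponded poses are flattened ([assemble_shape_vector()]),
#' mean-centered and decomposed by SVD.  The first principal direction
#' carries the latent flexion-extension parameter: the latent score of pose
#' i is its projection on that direction.  Every orthogonal-complement
#' coordinate is then fitted as a polynomial in the latent score (the
#' "principal polynomial"), and a monotone calibration polynomial maps the
#' latent score to the flexion angle so that poses can be indexed by exact
#' angle ([sample_pose()]).  With `degree = n - 1` (the default) the model
#' interpolates all n training poses to machine precision.
#'
#' No Procrustes pre-alignment is applied across poses: the relative bone
#' motion is the signal the model must capture, so aligning it away would
#' destroy the flexion variation.
#'
#' @param vectors list of shape vectors (or an n x P matrix, one pose per
#'   row), n >= 3.
#' @param flexion_angles degrees, one per pose, all distinct.
#' @param degree polynomial degree for the correction terms,
#'   `1 <= degree <= n - 1`.
#' @param layout the [shape_layout()] (stored for sampling).
#' @return object of class `ppsa_model`.
#' @export
fit_ppsa <- function(vectors, flexion_angles, degree = NULL, layout = NULL) {
  X <- if (is.list(vectors)) do.call(rbind, vectors) else as.matrix(vectors)
  n <- nrow(X)
  if (n < 3) stop("PPSA needs at least 3 poses, got ", n)
  if (length(flexion_angles) != n)
    stop("need one flexion angle per pose")
  if (anyDuplicated(flexion_angles))
    stop("duplicate flexion angles: poses must be at distinct angles")
  if (is.null(degree)) degree <- n - 1L
  if (degree < 1 || degree > n - 1)
    stop("degree must be between 1 and n - 1 = ", n - 1, ", got ", degree)

  mean_shape <- colMeans(X)
  Xc <- sweep(X, 2, mean_shape)
  sv <- svd(Xc, nu = n, nv = 0)
  # principal directions from the small-side SVD: V = Xc^T U / d
  d <- sv$d
  r <- n - 1L                      # centered data has rank <= n - 1
  V <- crossprod(Xc, sv$u[, seq_len(r), drop = FALSE])
  V <- sweep(V, 2, pmax(d[seq_len(r)], 1e-300), "/")
  # directions with (numerically) zero variance are meaningless: zero them
  # so degenerate motions yield exactly vanishing corrections
  V[, d[seq_len(r)] < 1e-12 * max(d[1], 1)] <- 0
  scores1 <- as.vector(Xc %*% V[, 1])
  if (stats::cor(scores1, flexion_angles) < 0) {
    V[, 1] <- -V[, 1]
    scores1 <- -scores1
  }
  corr_dirs <- V[, -1, drop = FALSE]
  corr_coords <- Xc %*% corr_dirs            # n x (r - 1)
  poly_coef <- vapply(seq_len(ncol(corr_dirs)), function(j)
    polyfit_asc(scores1, corr_coords[, j], degree), numeric(degree + 1))
  poly_coef <- matrix(poly_coef, nrow = degree + 1)

  angle_coef <- polyfit_asc(scores1, flexion_angles, n - 1L)
  t_range <- range(scores1)
  grid <- seq(t_range[1], t_range[2], length.out = 512)
  if (any(diff(polyval_asc(angle_coef, grid)) <= 0))
    stop("angle calibration is not strictly monotone on the training ",
         "score interval: flexion is not the dominant mode; model invalid")

  structure(list(mean_shape = mean_shape,
                 principal_direction = V[, 1],
                 correction_directions = corr_dirs,
                 polynomial_coefficients = poly_coef,
                 degree = as.integer(degree),
                 training_scores = scores1,
                 training_angles = as.numeric(flexion_angles),
                 angle_calibration = angle_coef,
                 score_interval = t_range,
                 angle_interval = range(flexion_angles),
                 layout = layout),
            class = "ppsa_model")
}

#' @export
print.ppsa_model <- function(x, ...) {
  cat(sprintf(paste0("ppsa_model: %d poses, correction degree %d\n",
                     "  calibrated flexion interval [%.2f, %.2f] deg\n"),
              length(x$training_scores), x$degree, x$angle_interval[1],
              x$angle_interval[2]))
  invisible(x)
}

# evaluate the model's shape vector at latent score t
ppsa_shape_at <- function(model, t) {
  x <- model$mean_shape + t * model$principal_direction
  if (ncol(model$correction_directions) > 0) {
    cvals <- vapply(seq_len(ncol(model$correction_directions)), function(j)
      polyval_asc(model$polynomial_coefficients[, j], t), 0)
    x <- x + as.vector(model$correction_directions %*% cvals)
  }
  x
}

#' Sample a knee pose at an exact flexion angle
#'
#' Recovers the latent score for the requested angle by bisection on the
#' monotone angle calibration (score tolerance 1e-10), evaluates the
#' principal polynomial there and unflattens the result into a
#' [knee_pose()].
#'
#' @param model a [ppsa_model()] fitted with a layout.
#' @param flexion_angle requested angle in degrees; must lie inside the
#'   calibrated interval unless `extrapolate = TRUE`.
#' @param layout optional [shape_layout()] override.
#' @param extrapolate allow sampling outside the calibrated angle interval
#'   (with a warning); the polynomial is unreliable out there.
#' @return a [knee_pose()] at the requested angle.
#' @export
sample_pose <- function(model, flexion_angle, layout = NULL,
                        extrapolate = FALSE) {
  if (!inherits(model, "ppsa_model")) stop("not a ppsa_model")
  if (is.null(layout)) layout <- model$layout
  if (is.null(layout)) stop("no shape layout available for sampling")
  lo <- model$angle_interval[1]
  hi <- model$angle_interval[2]
  if (flexion_angle < lo - 1e-9 || flexion_angle > hi + 1e-9) {
    if (!extrapolate)
      stop(sprintf(paste0("flexion angle %.2f deg outside the calibrated ",
                          "interval [%.2f, %.2f]; set extrapolate = TRUE ",
                          "to override"), flexion_angle, lo, hi))
    warning(sprintf("extrapolating outside the calibrated interval [%.2f, %.2f]",
                    lo, hi))
  }
  tlo <- model$score_interval[1]
  thi <- model$score_interval[2]
  if (flexion_angle <= lo) {
    t <- tlo - (lo - flexion_angle) /
      max(ppsa_angle_slope(model, tlo), 1e-9)
  } else if (flexion_angle >= hi) {
    t <- thi + (flexion_angle - hi) /
      max(ppsa_angle_slope(model, thi), 1e-9)
  } else {
    f <- function(t) polyval_asc(model$angle_calibration, t) - flexion_angle
    a <- tlo
    b <- thi
    while (b - a > 1e-10) {
      m <- (a + b) / 2
      if (f(m) > 0) b <- m else a <- m
    }
    t <- (a + b) / 2
  }
  disassemble_shape_vector(ppsa_shape_at(model, t), layout,
                           flexion_angle = flexion_angle,
                           label = sprintf("%g", flexion_angle))
}

ppsa_angle_slope <- function(model, t) {
  co <- model$angle_calibration
  if (length(co) < 2) return(0)
  dcoef <- co[-1] * seq_len(length(co) - 1)
  polyval_asc(dcoef, t)
}

#' Serialize / restore a PPSA model as JSON
#'
#' Stores every numeric field at full precision; the layout's face arrays
#' are included so a restored model can sample poses directly.
#'
#' @param model a `ppsa_model`.
#' @param path JSON file path.
#' @export
write_ppsa_model <- function(model, path) {
  obj <- unclass(model)
  if (!is.null(obj$layout)) obj$layout <- unclass(obj$layout)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_ppsa_model
#' @export
read_ppsa_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$mean_shape <- as.numeric(obj$mean_shape)
  obj$principal_direction <- as.numeric(obj$principal_direction)
  obj$correction_directions <- matrix(obj$correction_directions,
                                      ncol = length(obj$training_scores) - 2L)
  obj$polynomial_coefficients <- matrix(obj$polynomial_coefficients,
                                        nrow = obj$degree + 1L)
  if (!is.null(obj$layout)) {
    comps <- lapply(obj$layout$components, function(cc) {
      cc$faces <- matrix(as.integer(cc$faces), ncol = 3)
      cc$n_vertices <- as.integer(cc$n_vertices)
      cc
    })
    obj$layout <- structure(list(components = comps,
                                 total_length = as.integer(
                                   obj$layout$total_length)),
                            class = "shape_layout")
  }
  structure(obj, class = "ppsa_model")
}
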