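#' Anatomical tibial coordinate frame
#'
#' Builds a right-handed anatomical frame from the tibial plateau:
#' the mediolateral (ML) axis is the leading principal axis of the plateau
#' vertices, the superoinferior (SI) axis is the best-fit-plane normal of
#' the plateau (superior positive, i.e. pointing away from the tibial
#' shaft), and the anteroposterior (AP) axis completes the frame as
#' `ap = ml x si`, so that `ap x ml = si`.  The AP sign is fixed
#' deterministically by requiring the whole-bone centroid offset from the
#' plateau centroid (pulled anteriorly by the tibial tuberosity) to have a
#' positive anterior component.  Anterior and superior are positive; for a
#' right knee the positive ML direction is medial.
#'
#' @param tibia tibia-fibula [triangle_mesh()].
#' @param plateau_vertex_indices indices of plateau vertices on `tibia`
#'   (>= 3, not collinear).
#' @return object of class `tibial_frame` with `origin` (plateau centroid),
#'   `ap_axis`, `ml_axis`, `si_axis`.
#' @export
tibial_frame <- function(tibia, plateau_vertex_indices) {
  stopifnot_mesh(tibia)
  idx <- as.integer(plateau_vertex_indices)
  if (length(idx) < 3) stop("need at least 3 plateau vertices")
  P <- tibia$vertices[idx, , drop = FALSE]
  o <- colMeans(P)
  sv <- svd(sweep(P, 2, o))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate plateau: vertices are collinear (rank < 2)")
  ml <- sv$v[, 1]
  si <- sv$v[, 3]
  below <- colMeans(tibia$vertices) - o     # shaft pulls centroid inferior
  if (sum(si * below) > 0) si <- -si        # superior positive
  ap <- cross3(ml, si)
  # anterior indicator: tuberosity-side centroid offset, SI/ML removed
  ind <- below - sum(below * si) * si - sum(below * ml) * ml
  if (sum(ap * ind) < 0) {
    ml <- -ml
    ap <- -ap
  }
  structure(list(origin = o, ap_axis = ap, ml_axis = ml, si_axis = si),
            class = "tibial_frame")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.tibial_frame <- function(x, ...) {
  cat("tibial_frame\n  origin:", round(x$origin, 3), "\n  ap:",
      round(x$ap_axis, 4), "\n  ml:", round(x$ml_axis, 4), "\n  si:",
      round(x$si_axis, 4), "\n")
  invisible(x)
}

#' Express points or a mesh in a tibial frame
#'
#' Coordinates become (AP, ML, SI) components relative to the frame origin.
#'
#' @param x n x 3 point matrix or [triangle_mesh()].
#' @param frame a [tibial_frame()].
#' @export
frame_coordinates <- function(x, frame) {
  if (!inherits(frame, "tibial_frame")) stop("not a tibial_frame")
  if (inherits(x, "triangle_mesh")) {
    x$vertices <- frame_coordinates(x$vertices, frame)
    return(x)
  }
  R <- cbind(frame$ap_axis, frame$ml_axis, frame$si_axis)
  sweep(as.matrix(x), 2, frame$origin) %*% R
}

#' Knee flexion angle from bone meshes
#'
#' Sagittal-plane angle between the femoral shaft principal axis and the
#' tibial long (SI) axis: the femoral shaft axis is the leading principal
#' axis of the supplied shaft vertices, oriented proximally (away from the
#' femur centroid), projected onto the sagittal plane (normal = ML axis).
#' 0 degrees at full extension; axial (internal/external) rotation is
#' excluded by the sagittal projection.
#'
#' @param femur femoral [triangle_mesh()].
#' @param frame the subject's [tibial_frame()] (its SI axis stands in for
#'   the tibial shaft axis).
#' @param shaft_vertex_indices indices of femoral shaft vertices.
#' @return flexion angle in degrees, in [0, 180).
#' @export
flexion_angle <- function(femur, frame, shaft_vertex_indices) {
  stopifnot_mesh(femur)
  if (!inherits(frame, "tibial_frame")) stop("not a tibial_frame")
  idx <- as.integer(shaft_vertex_indices)
  if (length(idx) == 0) stop("empty femoral shaft vertex mask")
  S <- femur$vertices[idx, , drop = FALSE]
  o <- colMeans(S)
  a <- svd(sweep(S, 2, o))$v[, 1]
  # orient proximally: from the distal (condylar) bulk toward the shaft
  if (sum(a * (o - colMeans(femur$vertices))) < 0) a <- -a
  # sagittal projection
  a <- a - sum(a * frame$ml_axis) * frame$ml_axis
  na <- sqrt(sum(a^2))
  if (na < 1e-9) stop("femoral shaft axis parallel to the ML axis")
  a <- a / na
  acos(pmin(1, pmax(-1, sum(a * frame$si_axis)))) * 180 / pi
}

#' Point-dependent displacement field between corresponded meshes
#'
#' Per-vertex displacement between two topology-identical meshes: vertex
#' index identity carries anatomical correspondence, so `vector[k]` is the
#' 3D motion of anatomical location `k` and `magnitudes[k]` its Euclidean
#' point-dependent distance in mm (as opposed to a single-direction
#' anteroposterior measurement, see [ap_projection()]).
#'
#' @param reference,moved topology-identical [triangle_mesh()] objects.
#' @param source_label,target_label optional pose tags (e.g. "0", "60").
#' @return object of class `displacement_field` with `vectors` (n x 3),
#'   `magnitudes`, `source_label`, `target_label`.
#' @export
displacement_field <- function(reference, moved, source_label = NULL,
                               target_label = NULL) {
  stopifnot_mesh(reference)
  stopifnot_mesh(moved)
  if (n_vertices(reference) != n_vertices(moved) ||
      !identical(reference$faces, moved$faces))
    stop("meshes are not topology-identical: correspondence violated")
  vec <- moved$vertices - reference$vertices
  structure(list(vectors = vec,
                 magnitudes = sqrt(rowSums(vec^2)),
                 source_label = source_label,
                 target_label = target_label),
            class = "displacement_field")
}

#' Anteroposterior projection of a displacement field
#'
#' The classic single-direction measurement: `|vector[k] . ap_axis|` per
#' vertex.  Always bounded above by the 3D point-dependent magnitude at the
#' same vertex.
#'
#' @param field a [displacement_field()].
#' @param frame a [tibial_frame()] in the same coordinate system.
#' @return numeric vector of per-vertex AP magnitudes (mm).
#' @export
ap_projection <- function(field, frame) {
  if (!inherits(field, "displacement_field")) stop("not a displacement_field")
  if (!inherits(frame, "tibial_frame")) stop("not a tibial_frame")
  abs(as.vector(field$vectors %*% frame$ap_axis))
}

#' Maximal point-dependent displacement
#'
#' @param field a [displacement_field()].
#' @param region_mask optional integer vertex indices restricting the
#'   search (e.g. an anterior-horn region).
#' @return list with `mm` (maximum magnitude) and `vertex` (its index; ties
#'   broken by the lowest index).
#' @export
max_point_displacement <- function(field, region_mask = NULL) {
  if (!inherits(field, "displacement_field")) stop("not a displacement_field")
  idx <- if (is.null(region_mask)) seq_along(field$magnitudes)
         else as.integer(region_mask)
  if (length(idx) == 0) stop("empty region mask")
  k <- idx[which.max(field$magnitudes[idx])]
  list(mm = field$magnitudes[k], vertex = k)
}

#' Anatomical thirds of a meniscus tube
#'
#' Splits the vertices of a template-built meniscus ([build_template_tube()])
#' into the conventional anatomical regions by arclength third: anterior
#' horn, body, posterior horn (cap vertices are assigned to their horns).
#'
#' @param mesh a meniscus mesh carrying the `sections`/`ring_size`
#'   attributes set by [build_template_tube()].
#' @return named list of integer vertex index vectors
#'   (`anterior_horn`, `body`, `posterior_horn`).
#' @export
meniscus_region_masks <- function(mesh) {
  stopifnot_mesh(mesh)
  ns <- attr(mesh, "sections")
  ring <- attr(mesh, "ring_size")
  if (is.null(ns) || is.null(ring))
    stop("mesh lacks sections/ring_size attributes ",
         "(not built by build_template_tube)")
  section_of <- rep(seq_len(ns), each = ring)
  s <- (section_of - 1) / (ns - 1)
  ring_ids <- seq_len(ns * ring)
  cap0 <- ns * ring + 1L
  cap1 <- ns * ring + 2L
  list(anterior_horn = c(ring_ids[s < 1 / 3], cap0),
       body = ring_ids[s >= 1 / 3 & s <= 2 / 3],
       posterior_horn = c(ring_ids[s > 2 / 3], cap1))
}

#' Corresponded mesh set
#'
#' A list of meshes sharing one face array, where vertex index `k` denotes
#' the same anatomical location in every member.
#'
#' @param meshes list of topology-identical [triangle_mesh()] objects.
#' @return object of class `corresponded_mesh_set` with `meshes` and
#'   `shared_faces`.
#' @export
corresponded_mesh_set <- function(meshes) {
  if (length(meshes) < 1) stop("empty mesh list")
  lapply(meshes, stopifnot_mesh)
  f <- meshes[[1]]$faces
  nv <- n_vertices(meshes[[1]])
  for (m in meshes[-1]) {
    if (n_vertices(m) != nv || !identical(m$faces, f))
      stop("meshes are not topology-identical: correspondence violated")
  }
  structure(list(meshes = meshes, shared_faces = f),
            class = "corresponded_mesh_set")
}

#' Cohort mean of corresponded meshes
#'
#' Each mesh is rigidly re-expressed in its subject's tibial frame (frame
#' origin to the origin, axes to the canonical AP/ML/SI axes -- no size
#' normalization, so millimeter displacement semantics are preserved), then
#' vertices are averaged arithmetically per index.
#'
#' @param meshes a [corresponded_mesh_set()] (or list of meshes).
#' @param frames list with one [tibial_frame()] per mesh.
#' @return the mean [triangle_mesh()] in canonical frame coordinates.
#' @export
mean_corresponded_mesh <- function(meshes, frames) {
  if (inherits(meshes, "corresponded_mesh_set")) meshes <- meshes$meshes
  set <- corresponded_mesh_set(meshes)
  if (length(frames) != length(set$meshes))
    stop("need one tibial frame per mesh")
  acc <- 0
  for (i in seq_along(set$meshes))
    acc <- acc + frame_coordinates(set$meshes[[i]]$vertices, frames[[i]])
  triangle_mesh(acc / length(set$meshes), set$shared_faces,
                set$meshes[[1]]$label)
}

#' Export a displacement field
#'
#' `write_displacement_field()` writes a CSV with columns `vertex_index`,
#' `dx`, `dy`, `dz`, `magnitude_mm`.  For color-mapped pose plots, attach
#' `field$magnitudes` to a mesh via `write_mesh(..., vertex_scalar = )`.
#'
#' @param field a [displacement_field()].
#' @param path output CSV path.
#' @export
write_displacement_field <- function(field, path) {
  if (!inherits(field, "displacement_field")) stop("not a displacement_field")
  utils::write.csv(data.frame(vertex_index = seq_len(nrow(field$vectors)),
                              dx = field$vectors[, 1],
                              dy = field$vectors[, 2],
                              dz = field$vectors[, 3],
                              magnitude_mm = field$magnitudes),
                   path, row.names = FALSE)
  invisible(path)
}
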