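#' Triangulated surface mesh
#'
#' The basic container of the package: an ordered vertex matrix in
#' millimeters and a face matrix of 1-based vertex indices.  Vertex order is
#' meaningful throughout the package -- anatomical correspondence across
#' poses and subjects is carried by vertex index identity, so no operation
#' in the package ever reorders vertices.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param label optional free-text component tag, e.g. `"femur"`,
#'   `"tibia_fibula"`, `"meniscus_medial"`, `"meniscus_lateral"`,
#'   `"cartilage"`.
#' @return object of class `triangle_mesh` with elements `vertices`,
#'   `faces`, `label`.
#' @export
triangle_mesh <- function(vertices, faces, label = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (nrow(faces) > 0L) {
    if (ncol(faces) != 3L) stop("faces must have 3 columns")
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face index out of range: vertex count is ", nrow(vertices))
    degen <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
      faces[, 2] == faces[, 3]
    if (any(degen))
      stop("degenerate faces (repeated vertex index) at rows: ",
           paste(utils::head(which(degen), 10), collapse = ", "))
  }
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces, label = label),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("triangle_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "faces", if (!is.null(x$label)) paste0("[", x$label, "]"), "\n")
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)
n_faces <- function(mesh) nrow(mesh$faces)

stopifnot_mesh <- function(mesh) {
  if (!inherits(mesh, "triangle_mesh")) stop("not a triangle_mesh")
  invisible(mesh)
}

#' Boundary edges of a mesh
#'
#' An edge is a boundary edge when it belongs to exactly one face.  Closed
#' meshes have none.
#'
#' @param mesh a [triangle_mesh()].
#' @return integer matrix of boundary edges (two columns of vertex indices);
#'   zero rows for a closed mesh.
#' @export
boundary_edges <- function(mesh) {
  stopifnot_mesh(mesh)
  f <- mesh$faces
  e <- rbind(f[, c(1, 2), drop = FALSE], f[, c(2, 3), drop = FALSE],
             f[, c(3, 1), drop = FALSE])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  open_keys <- names(tab)[tab == 1L]
  if (length(open_keys) == 0L)
    return(matrix(integer(0), ncol = 2))
  e[match(open_keys, key), , drop = FALSE]
}

#' @rdname boundary_edges
#' @export
is_closed <- function(mesh) nrow(boundary_edges(mesh)) == 0L

#' Signed volume of a closed mesh
#'
#' Divergence-theorem volume: the sum of signed tetrahedron volumes spanned
#' by each face and the origin.  Positive for consistently outward-oriented
#' meshes, and invariant under rigid transforms.  Meshes made of several
#' disjoint closed components return the sum of component volumes.
#'
#' @param mesh closed, consistently oriented [triangle_mesh()].
#' @return volume in mm^3.
#' @export
compute_volume <- function(mesh) {
  stopifnot_mesh(mesh)
  nb <- nrow(boundary_edges(mesh))
  if (nb > 0L)
    stop("mesh is not closed: ", nb, " boundary edges")
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cross_bc <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
                    b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
                    b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(rowSums(a * cross_bc)) / 6
}

face_cross <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Face areas (mm^2) of a mesh
#' @param mesh a [triangle_mesh()].
#' @export
face_areas <- function(mesh) {
  cr <- face_cross(mesh)
  sqrt(rowSums(cr^2)) / 2
}

#' Per-vertex unit normals
#'
#' Area-weighted average of the incident face normals (the cross-product
#' form carries the area weight automatically), normalized to unit length.
#' Points outward on closed, consistently outward-oriented meshes.
#'
#' @param mesh a [triangle_mesh()] with no degenerate faces.
#' @return numeric matrix, one unit row vector per vertex.
#' @export
vertex_normals <- function(mesh) {
  stopifnot_mesh(mesh)
  cr <- face_cross(mesh)   # face normal * 2*area
  nv <- n_vertices(mesh)
  acc <- matrix(0, nv, 3)
  f <- mesh$faces
  for (k in 1:3) {
    idx <- f[, k]
    acc[, 1] <- acc[, 1] + unname(tapply_sum(cr[, 1], idx, nv))
    acc[, 2] <- acc[, 2] + unname(tapply_sum(cr[, 2], idx, nv))
    acc[, 3] <- acc[, 3] + unname(tapply_sum(cr[, 3], idx, nv))
  }
  nrm <- sqrt(rowSums(acc^2))
  isolated <- !(seq_len(nv) %in% as.vector(f))
  if (any(isolated))
    stop("isolated vertices (no incident face): ",
         paste(utils::head(which(isolated), 10), collapse = ", "))
  if (any(nrm == 0))
    stop("zero normal at vertices: ",
         paste(utils::head(which(nrm == 0), 10), collapse = ", "))
  acc / nrm
}

# fast grouped sum onto 1..n (rowsum keeps numeric exactness)
tapply_sum <- function(x, group, n) {
  out <- numeric(n)
  s <- rowsum(x, group)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Rigid transform (rotation + translation, no scale)
#'
#' @param rotation 3x3 proper orthonormal matrix (det +1).
#' @param translation length-3 numeric vector (mm).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- unname(as.numeric(translation))
  if (!all(dim(rotation) == c(3, 3))) stop("rotation must be 3x3")
  if (length(translation) != 3L) stop("translation must have length 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation has determinant ", det(rotation), " (improper)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation:", round(x$translation, 6), "\n")
  invisible(x)
}

#' Apply a rigid transform to points or a mesh
#'
#' @param x a [triangle_mesh()] or an n x 3 point matrix.
#' @param transform a [rigid_transform()].
#' @return object of the same kind as `x`, transformed.
#' @export
apply_transform <- function(x, transform) {
  if (!inherits(transform, "rigid_transform")) stop("not a rigid_transform")
  if (inherits(x, "triangle_mesh")) {
    x$vertices <- apply_transform(x$vertices, transform)
    return(x)
  }
  pts <- as.matrix(x)
  sweep(pts %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Compose and invert rigid transforms
#'
#' `compose_transforms(a, b)` applies `b` first, then `a`.
#'
#' @param a,b,transform [rigid_transform()] objects.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' @rdname compose_transforms
#' @export
invert_transform <- function(transform) {
  rigid_transform(t(transform$rotation),
                  -as.vector(t(transform$rotation) %*% transform$translation))
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `angle_deg` degrees about unit `axis`.
#' @param axis length-3 vector (normalized internally).
#' @param angle_deg angle in degrees.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Least-squares rigid Procrustes alignment of paired point sets
#'
#' Solves for the rotation + translation (no scaling, no reflection)
#' minimizing the mean squared distance between paired points, via SVD of
#' the cross-covariance matrix (Kabsch).  A reflection-optimal solution is
#' corrected to a proper rotation by flipping the smallest singular vector.
#'
#' @param source,target n x 3 matrices of paired points (row i of `source`
#'   corresponds to row i of `target`); n >= 3, not collinear.
#' @return a [rigid_transform()] mapping source onto target, with an
#'   additional element `rms`: the root-mean-square residual (mm) after
#'   alignment.
#' @export
rigid_procrustes <- function(source, target) {
  source <- as.matrix(source)
  target <- as.matrix(target)
  if (!all(dim(source) == dim(target)))
    stop("source and target must have identical dimensions")
  n <- nrow(source)
  if (n < 3L) stop("at least 3 paired points are required, got ", n)
  mu_s <- colMeans(source)
  mu_t <- colMeans(target)
  S <- sweep(source, 2, mu_s)
  T_ <- sweep(target, 2, mu_t)
  sv_src <- svd(S)$d
  if (sv_src[2] < 1e-9 * max(sv_src[1], 1))
    stop("source points are collinear; rotation is not identifiable")
  H <- crossprod(S, T_)
  sv <- svd(H)
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- mu_t - as.vector(R %*% mu_s)
  out <- rigid_transform(R, t_vec)
  fitted <- apply_transform(source, out)
  out$rms <- sqrt(mean(rowSums((fitted - target)^2)))
  out
}

#' Angle (radians) between two rotation matrices
#'
#' Geodesic distance on SO(3); used to quantify Procrustes recovery error.
#' @param r1,r2 3x3 rotation matrices.
#' @export
rotation_angle_between <- function(r1, r2) {
  A <- crossprod(r1, r2)
  # atan2 form: well-conditioned for both tiny and large angles (acos of
  # the trace loses ~sqrt(eps) precision near zero)
  sin_t <- sqrt((A[3, 2] - A[2, 3])^2 + (A[1, 3] - A[3, 1])^2 +
                  (A[2, 1] - A[1, 2])^2) / 2
  cos_t <- (sum(diag(A)) - 1) / 2
  atan2(sin_t, cos_t)
}

#' Point-to-surface distances
#'
#' Exact nearest point-to-triangle distance of each query point to a mesh.
#' The scan is pruned with conservative per-triangle bounding spheres but is
#' numerically identical to an exhaustive scan over all triangles; ties are
#' broken by the lowest triangle index.  In signed mode (closed oriented
#' meshes only) points inside the surface get negative distances, with
#' inside/outside decided by the generalized winding number -- robust for
#' queries near the surface.
#'
#' @param points n x 3 matrix of query points (mm).
#' @param mesh a [triangle_mesh()].
#' @param signed if `TRUE`, return signed distances (negative inside).
#' @return numeric vector of distances (mm).
#' @seealso [point_mesh_query()] for nearest points and triangle indices.
#' @export
surface_distance <- function(points, mesh, signed = FALSE) {
  q <- point_mesh_query(points, mesh, signed = signed)
  q$distance
}

#' Nearest-point query against a mesh
#'
#' Like [surface_distance()] but also returns the nearest surface point and
#' the (1-based, lowest-index on ties) nearest triangle per query.
#'
#' @inheritParams surface_distance
#' @return list with `distance`, `triangle`, `closest` (n x 3 matrix).
#' @export
point_mesh_query <- function(points, mesh, signed = FALSE) {
  stopifnot_mesh(mesh)
  if (n_faces(mesh) == 0L) stop("mesh has no faces")
  points <- matrix(as.numeric(points), ncol = 3)
  res <- cpp_point_mesh_distance(points, mesh$vertices, mesh$faces - 1L)
  if (signed) {
    nb <- nrow(boundary_edges(mesh))
    if (nb > 0L)
      stop("signed distance requires a closed mesh (", nb,
           " boundary edges)")
    w <- cpp_winding_number(points, mesh$vertices, mesh$faces - 1L)
    res$distance <- ifelse(w > 0.5, -res$distance, res$distance)
    res$winding <- w
  }
  res
}
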