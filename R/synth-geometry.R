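#' Extruded grid slab
#'
#' A closed rectangular slab whose top and bottom faces are regular
#' `nx x ny` vertex grids (so normal-offset cartilage layers stay flat over
#' the interior, unlike a plain 8-vertex box).  Used for the tibial
#' plateau.
#'
#' @param center slab center (mm).
#' @param dims length-3 edge lengths (mm).
#' @param nx,ny grid vertex counts of the top/bottom faces.
#' @param label optional component tag.
#' @return closed [triangle_mesh()] with attribute `top_indices` (the top
#'   grid vertex indices).
#' @export
mesh_slab_grid <- function(center, dims, nx = 9, ny = 11, label = NULL) {
  stopifnot(nx >= 2, ny >= 2)
  xs <- seq(-dims[1] / 2, dims[1] / 2, length.out = nx)
  ys <- seq(-dims[2] / 2, dims[2] / 2, length.out = ny)
  g <- as.matrix(expand.grid(x = xs, y = ys))
  nxy <- nx * ny
  verts <- rbind(cbind(g, dims[3] / 2), cbind(g, -dims[3] / 2))
  verts <- sweep(verts, 2, center, "+")
  idx <- function(i, j) (j - 1L) * nx + i
  faces <- list()
  for (j in seq_len(ny - 1)) {
    for (i in seq_len(nx - 1)) {
      a <- idx(i, j); b <- idx(i + 1, j)
      c_ <- idx(i + 1, j + 1); d <- idx(i, j + 1)
      faces[[length(faces) + 1]] <- c(a, b, c_)       # top, +z
      faces[[length(faces) + 1]] <- c(a, c_, d)
      faces[[length(faces) + 1]] <- c(a + nxy, c_ + nxy, b + nxy)  # bottom
      faces[[length(faces) + 1]] <- c(a + nxy, d + nxy, c_ + nxy)
    }
  }
  # perimeter, counterclockwise viewed from above
  ring <- c(idx(seq_len(nx), 1L),
            idx(nx, seq(2L, ny)),
            idx(seq(nx - 1L, 1L), ny),
            idx(1L, seq(ny - 1L, 2L)))
  nr <- length(ring)
  for (k in seq_len(nr)) {
    a <- ring[k]
    b <- ring[if (k == nr) 1L else k + 1L]
    faces[[length(faces) + 1]] <- c(a, a + nxy, b + nxy)
    faces[[length(faces) + 1]] <- c(a, b + nxy, b)
  }
  out <- triangle_mesh(verts, do.call(rbind, faces), label)
  attr(out, "top_indices") <- seq_len(nxy)
  out
}

#' Concatenate meshes into one multi-component mesh
#'
#' Vertex and face arrays are stacked in order; each input's vertex index
#' range is recorded in the `component_ranges` attribute so anatomical
#' sub-regions (shaft, condyles, plateau, ...) remain addressable.
#'
#' @param meshes named list of [triangle_mesh()] objects.
#' @param label component tag of the combined mesh.
#' @return a [triangle_mesh()] with attribute `component_ranges` (named
#'   list of integer index vectors).
#' @export
mesh_union <- function(meshes, label = NULL) {
  if (is.null(names(meshes)) || any(!nzchar(names(meshes))))
    stop("meshes must be a named list")
  verts <- NULL
  faces <- NULL
  ranges <- list()
  off <- 0L
  for (nm in names(meshes)) {
    m <- meshes[[nm]]
    stopifnot_mesh(m)
    verts <- rbind(verts, m$vertices)
    faces <- rbind(faces, m$faces + off)
    ranges[[nm]] <- off + seq_len(n_vertices(m))
    off <- off + n_vertices(m)
  }
  out <- triangle_mesh(verts, faces, label)
  attr(out, "component_ranges") <- ranges
  out
}

#' Submesh spanned by a vertex subset
#'
#' Keeps the faces whose three corners all belong to `vertex_indices` and
#' remaps indices; vertex order within the subset is preserved.  Selecting
#' whole closed components yields a closed submesh.
#'
#' @param mesh a [triangle_mesh()].
#' @param vertex_indices vertices to keep.
#' @return a [triangle_mesh()].
#' @export
mesh_subset <- function(mesh, vertex_indices) {
  stopifnot_mesh(mesh)
  keep <- sort(unique(as.integer(vertex_indices)))
  remap <- integer(n_vertices(mesh))
  remap[keep] <- seq_along(keep)
  f <- mesh$faces
  inside <- matrix(f %in% keep, nrow(f), 3)
  f <- f[rowSums(inside) == 3L, , drop = FALSE]
  triangle_mesh(mesh$vertices[keep, , drop = FALSE],
                matrix(remap[f], ncol = 3), mesh$label)
}

#' Area-weighted random surface points
#'
#' Uniformly distributed random points on a mesh surface: faces sampled
#' proportionally to area, positions by uniform barycentric coordinates.
#' Reproducible from the R random stream.
#'
#' @param mesh a [triangle_mesh()].
#' @param n number of points.
#' @return n x 3 matrix of surface points (mm).
#' @export
sample_surface_points <- function(mesh, n) {
  stopifnot_mesh(mesh)
  areas <- face_areas(mesh)
  fi <- sample.int(n_faces(mesh), n, replace = TRUE, prob = areas)
  u <- stats::runif(n)
  v <- stats::runif(n)
  flip <- u + v > 1
  u[flip] <- 1 - u[flip]
  v[flip] <- 1 - v[flip]
  f <- mesh$faces[fi, , drop = FALSE]
  a <- mesh$vertices[f[, 1], , drop = FALSE]
  b <- mesh$vertices[f[, 2], , drop = FALSE]
  c_ <- mesh$vertices[f[, 3], , drop = FALSE]
  a + u * (b - a) + v * (c_ - a)
}

# evaluate an expression under a temporary RNG seed, restoring the caller's
# random stream afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}
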