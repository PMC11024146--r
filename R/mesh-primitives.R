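#' Parametric mesh primitives
#'
#' Closed, consistently outward-oriented primitive meshes used by the
#' synthetic knee generator and as analytic oracles in tests: axis-aligned
#' box, UV sphere, subdivided icosphere, capped cylinder, and an open flat
#' rectangular patch.
#'
#' @param center length-3 center (mm).
#' @param dims length-3 box edge lengths (mm).
#' @param label optional component tag.
#' @return a [triangle_mesh()].
#' @name mesh_primitives
NULL

#' @rdname mesh_primitives
#' @export
mesh_box <- function(center = c(0, 0, 0), dims = c(1, 1, 1), label = NULL) {
  h <- dims / 2
  v <- as.matrix(expand.grid(x = c(-h[1], h[1]), y = c(-h[2], h[2]),
                             z = c(-h[3], h[3])))
  v <- sweep(v, 2, center, "+")
  # outward-oriented faces of the unit cube on the expand.grid vertex order
  f <- rbind(
    c(1, 5, 7), c(1, 7, 3),   # x = -h
    c(2, 4, 8), c(2, 8, 6),   # x = +h
    c(1, 2, 6), c(1, 6, 5),   # y = -h
    c(3, 8, 4), c(3, 7, 8),   # y = +h
    c(1, 3, 4), c(1, 4, 2),   # z = -h
    c(5, 6, 8), c(5, 8, 7))   # z = +h
  triangle_mesh(v, f, label)
}

#' @rdname mesh_primitives
#' @param radius sphere/cylinder radius (mm).
#' @param n_lat,n_lon latitude bands and longitude steps of the UV sphere.
#' @export
mesh_uv_sphere <- function(center = c(0, 0, 0), radius = 1, n_lat = 12,
                           n_lon = 18, label = NULL) {
  stopifnot(n_lat >= 2, n_lon >= 3)
  verts <- matrix(0, 2 + (n_lat - 1) * n_lon, 3)
  verts[1, ] <- c(0, 0, radius)
  k <- 1
  for (i in seq_len(n_lat - 1)) {
    th <- pi * i / n_lat
    for (j in seq_len(n_lon) - 1) {
      ph <- 2 * pi * j / n_lon
      k <- k + 1
      verts[k, ] <- radius * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    }
  }
  verts[k + 1, ] <- c(0, 0, -radius)
  bottom <- k + 1
  ring <- function(i, j) 1L + (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  faces <- list()
  for (j in seq_len(n_lon))
    faces[[length(faces) + 1]] <- c(1L, ring(1, j), ring(1, j + 1))
  for (i in seq_len(n_lat - 2)) {
    for (j in seq_len(n_lon)) {
      faces[[length(faces) + 1]] <- c(ring(i, j), ring(i + 1, j),
                                      ring(i + 1, j + 1))
      faces[[length(faces) + 1]] <- c(ring(i, j), ring(i + 1, j + 1),
                                      ring(i, j + 1))
    }
  }
  for (j in seq_len(n_lon))
    faces[[length(faces) + 1]] <- c(bottom, ring(n_lat - 1, j + 1),
                                    ring(n_lat - 1, j))
  verts <- sweep(verts, 2, center, "+")
  triangle_mesh(verts, do.call(rbind, faces), label)
}

#' @rdname mesh_primitives
#' @param subdivisions icosphere subdivision level (0 = icosahedron).
#' @export
mesh_icosphere <- function(radius = 1, subdivisions = 2, center = c(0, 0, 0),
                           label = NULL) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    midpoint_cache <- new.env(hash = TRUE)
    vlist <- lapply(seq_len(nrow(v)), function(i) v[i, ])
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- midpoint_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (vlist[[i]] + vlist[[j]]) / 2
      m <- m / sqrt(sum(m^2))
      vlist[[length(vlist) + 1]] <<- m
      idx <- length(vlist)
      midpoint_cache[[key]] <- idx
      idx
    }
    newf <- matrix(0L, 4 * nrow(f), 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c_ <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf[4 * k - 3, ] <- c(a, ab, ca)
      newf[4 * k - 2, ] <- c(b, bc, ab)
      newf[4 * k - 1, ] <- c(c_, ca, bc)
      newf[4 * k, ] <- c(ab, bc, ca)
    }
    v <- do.call(rbind, vlist)
    f <- newf
  }
  triangle_mesh(sweep(v * radius, 2, center, "+"), f, label)
}

#' @rdname mesh_primitives
#' @param p0,p1 cylinder axis endpoints (mm).
#' @param n_seg segments around the circumference.
#' @param caps close the ends with triangle fans.
#' @export
mesh_cylinder <- function(p0, p1, radius, n_seg = 16, caps = TRUE,
                          label = NULL) {
  axis <- p1 - p0
  h <- sqrt(sum(axis^2))
  if (h <= 0) stop("cylinder endpoints coincide")
  w <- axis / h
  u <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- u - sum(u * w) * w
  u <- u / sqrt(sum(u^2))
  vv <- c(w[2] * u[3] - w[3] * u[2], w[3] * u[1] - w[1] * u[3],
          w[1] * u[2] - w[2] * u[1])
  ang <- 2 * pi * (seq_len(n_seg) - 1) / n_seg
  circ <- outer(cos(ang), u) + outer(sin(ang), vv)
  bot <- sweep(radius * circ, 2, p0, "+")
  top <- sweep(radius * circ, 2, p1, "+")
  verts <- rbind(bot, top)
  nb <- function(j) ((j - 1L) %% n_seg) + 1L
  faces <- list()
  for (j in seq_len(n_seg)) {
    faces[[length(faces) + 1]] <- c(j, nb(j + 1), n_seg + nb(j + 1))
    faces[[length(faces) + 1]] <- c(j, n_seg + nb(j + 1), n_seg + j)
  }
  if (caps) {
    verts <- rbind(verts, p0, p1)
    cb <- 2L * n_seg + 1L
    ct <- 2L * n_seg + 2L
    for (j in seq_len(n_seg)) {
      faces[[length(faces) + 1]] <- c(cb, nb(j + 1), j)
      faces[[length(faces) + 1]] <- c(ct, n_seg + j, n_seg + nb(j + 1))
    }
  }
  triangle_mesh(verts, do.call(rbind, faces), label)
}

#' @rdname mesh_primitives
#' @param nx,ny grid vertex counts of the flat patch.
#' @param dx grid spacing (mm).
#' @export
mesh_flat_patch <- function(nx = 5, ny = 5, dx = 1, label = NULL) {
  g <- as.matrix(expand.grid(x = (seq_len(nx) - 1) * dx,
                             y = (seq_len(ny) - 1) * dx))
  verts <- cbind(g, 0)
  idx <- function(i, j) (j - 1L) * nx + i
  faces <- list()
  for (j in seq_len(ny - 1)) {
    for (i in seq_len(nx - 1)) {
      faces[[length(faces) + 1]] <- c(idx(i, j), idx(i + 1, j),
                                      idx(i + 1, j + 1))
      faces[[length(faces) + 1]] <- c(idx(i, j), idx(i + 1, j + 1),
                                      idx(i, j + 1))
    }
  }
  triangle_mesh(verts, do.call(rbind, faces), label)
}
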