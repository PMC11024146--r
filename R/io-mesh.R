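#' Read a triangulated mesh from PLY, STL or OBJ
#'
#' The format is inferred from the file extension.  Vertex order is
#' preserved exactly as stored in the file: vertex order carries anatomical
#' correspondence in this package, so the readers never reorder, merge or
#' weld vertices (in particular STL triangle soup is kept as a soup).
#' ASCII and binary-little-endian PLY dialects are both accepted, as are
#' ASCII and binary STL.
#'
#' @param path file path ending in `.ply`, `.stl` or `.obj`.
#' @param label optional component tag for the resulting mesh.
#' @return a [triangle_mesh()].  If the PLY file carries a per-vertex
#'   `quality` scalar (used for error/displacement maps), it is attached as
#'   the `"vertex_scalar"` attribute.
#' @export
read_mesh <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path, label),
         stl = read_stl(path, label),
         obj = read_obj(path, label),
         stop("unsupported mesh extension '.", ext,
              "' (supported: ply, stl, obj): ", path))
}

#' Write a triangulated mesh to PLY, STL or OBJ
#'
#' The format is inferred from the file extension.  PLY is written as
#' binary-little-endian by default (`ascii = TRUE` switches to the ASCII
#' dialect) with double-precision coordinates, so `read_mesh(write_mesh(m))`
#' round-trips the vertex array bit-exactly and in order.  STL stores one
#' vertex triplet per facet (no welding), OBJ stores shared vertices.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path ending in `.ply`, `.stl` or `.obj`.
#' @param ascii for PLY/STL: write the ASCII dialect.
#' @param vertex_scalar optional numeric per-vertex scalar written as a PLY
#'   `quality` property (color-mappable error or displacement maps).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, ascii = FALSE, vertex_scalar = NULL) {
  stopifnot_mesh(mesh)
  if (!is.null(vertex_scalar) && length(vertex_scalar) != n_vertices(mesh))
    stop("vertex_scalar must have one value per vertex")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = write_ply(mesh, path, ascii, vertex_scalar),
         stl = write_stl(mesh, path, ascii),
         obj = write_obj(mesh, path),
         stop("unsupported mesh extension '.", ext,
              "' (supported: ply, stl, obj): ", path))
  invisible(path)
}

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(con, type) {
  sz <- ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64"))
    readBin(con, "double", 1, size = sz, endian = "little")
  else
    readBin(con, "integer", 1, size = sz, endian = "little",
            signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
}

read_ply <- function(path, label = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(trimws(magic), "ply"))
    stop("not a PLY file (missing 'ply' magic): ", path)
  fmt <- NULL
  elements <- list()   # list of list(name, count, props = list(name,type,list_count_type))
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("unexpected end of PLY header: ", path)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0 || tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
      if (!fmt %in% c("ascii", "binary_little_endian"))
        stop("unsupported PLY format '", fmt, "': ", path)
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop("PLY property before element in header: ", path)
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[5], type = tok[4], count_type = tok[3])
      } else {
        cur$props[[length(cur$props) + 1]] <- list(name = tok[3], type = tok[2])
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (is.null(fmt)) stop("PLY header lacks a format line: ", path)
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("PLY file lacks vertex/face elements: ", path)

  vertex_el <- elements$vertex
  face_el <- elements$face
  vprops <- vapply(vertex_el$props, `[[`, "", "name")
  if (!all(c("x", "y", "z") %in% vprops))
    stop("PLY vertex element lacks x/y/z properties: ", path)

  if (fmt == "ascii") {
    rest <- readLines(con)
    rest <- rest[nzchar(trimws(rest))]
    nv <- vertex_el$count
    nf <- face_el$count
    if (length(rest) < nv + nf)
      stop("truncated ASCII PLY body (expected ", nv + nf, " rows, found ",
           length(rest), "): ", path)
    vdat <- matrix(NA_real_, nv, length(vprops))
    for (i in seq_len(nv)) {
      vals <- as.numeric(strsplit(trimws(rest[i]), "\\s+")[[1]])
      vdat[i, ] <- vals[seq_along(vprops)]
    }
    faces <- matrix(NA_integer_, nf, 3)
    for (i in seq_len(nf)) {
      vals <- as.numeric(strsplit(trimws(rest[nv + i]), "\\s+")[[1]])
      if (vals[1] != 3)
        stop("non-triangular PLY face (", vals[1], " vertices) at face ", i,
             ": ", path)
      faces[i, ] <- as.integer(vals[2:4]) + 1L
    }
  } else {
    nv <- vertex_el$count
    vdat <- matrix(NA_real_, nv, length(vertex_el$props))
    for (i in seq_len(nv)) {
      for (j in seq_along(vertex_el$props)) {
        val <- ply_read_scalar(con, vertex_el$props[[j]]$type)
        if (length(val) == 0) stop("truncated binary PLY vertex data: ", path)
        vdat[i, j] <- val
      }
    }
    nf <- face_el$count
    faces <- matrix(NA_integer_, nf, 3)
    lp <- face_el$props[[1]]
    for (i in seq_len(nf)) {
      cnt <- ply_read_scalar(con, lp$count_type)
      if (length(cnt) == 0) stop("truncated binary PLY face data: ", path)
      if (cnt != 3)
        stop("non-triangular PLY face (", cnt, " vertices) at face ", i,
             ": ", path)
      idx <- vapply(1:3, function(k) ply_read_scalar(con, lp$type), 0)
      faces[i, ] <- as.integer(idx) + 1L
    }
  }
  verts <- vdat[, match(c("x", "y", "z"), vprops), drop = FALSE]
  mesh <- triangle_mesh(verts, faces, label)
  if ("quality" %in% vprops)
    attr(mesh, "vertex_scalar") <- vdat[, match("quality", vprops)]
  mesh
}

write_ply <- function(mesh, path, ascii = FALSE, vertex_scalar = NULL) {
  nv <- n_vertices(mesh)
  nf <- n_faces(mesh)
  header <- c("ply",
              sprintf("format %s 1.0",
                      if (ascii) "ascii" else "binary_little_endian"),
              "comment written by meniscusdyn",
              sprintf("element vertex %d", nv),
              "property double x", "property double y", "property double z",
              if (!is.null(vertex_scalar)) "property double quality",
              sprintf("element face %d", nf),
              "property list uchar int vertex_indices",
              "end_header")
  vdat <- mesh$vertices
  if (!is.null(vertex_scalar)) vdat <- cbind(vdat, as.numeric(vertex_scalar))
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(apply(vdat, 1, function(r)
      paste(sprintf("%.17g", r), collapse = " ")), con)
    writeLines(apply(mesh$faces - 1L, 1, function(r)
      paste(c(3L, r), collapse = " ")), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    writeBin(as.vector(t(vdat)), con, size = 8, endian = "little")
    fm <- t(mesh$faces - 1L)
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(fm[, i]), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

read_obj <- function(path, label = NULL) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  if (length(vlines) == 0 || length(flines) == 0)
    stop("OBJ file lacks v/f records: ", path)
  verts <- t(vapply(strsplit(trimws(vlines), "\\s+"), function(tok)
    as.numeric(tok[2:4]), numeric(3)))
  faces <- t(vapply(strsplit(trimws(flines), "\\s+"), function(tok) {
    if (length(tok) != 4)
      stop("non-triangular OBJ face: '", paste(tok, collapse = " "),
           "' in ", path)
    as.integer(vapply(strsplit(tok[2:4], "/"), `[[`, "", 1))
  }, integer(3)))
  if (anyNA(verts) || anyNA(faces)) stop("malformed OBJ records in ", path)
  triangle_mesh(verts, faces, label)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# written by meniscusdyn", con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste("v", paste(sprintf("%.17g", r), collapse = " "))), con)
  writeLines(apply(mesh$faces, 1, function(r)
    paste("f", paste(r, collapse = " "))), con)
  invisible(path)
}

read_stl <- function(path, label = NULL) {
  # sniff ASCII vs binary: ASCII STL starts with "solid" AND contains
  # "facet" in the first chunk (binary headers may also start with "solid")
  head_raw <- readBin(path, "raw", n = 512)
  printable <- head_raw >= as.raw(0x20) & head_raw <= as.raw(0x7e) |
    head_raw == as.raw(0x0a) | head_raw == as.raw(0x0d)
  head_txt <- rawToChar(head_raw[printable])
  is_ascii <- grepl("^\\s*solid", head_txt) && grepl("facet", head_txt)
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vlines) == 0 || length(vlines) %% 3 != 0)
      stop("malformed ASCII STL (vertex count ", length(vlines),
           " not a multiple of 3): ", path)
    verts <- t(vapply(strsplit(trimws(vlines), "\\s+"), function(tok)
      as.numeric(tok[2:4]), numeric(3)))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80)
    nf <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(nf) == 0 || nf < 0) stop("truncated binary STL header: ", path)
    verts <- matrix(NA_real_, nf * 3L, 3)
    for (i in seq_len(nf)) {
      rec <- readBin(con, "double", 12, size = 4, endian = "little")
      if (length(rec) < 12) stop("truncated binary STL at facet ", i, ": ",
                                 path)
      verts[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
      readBin(con, "raw", 2)
    }
  }
  nf <- nrow(verts) / 3L
  faces <- matrix(seq_len(3L * nf), nf, 3, byrow = TRUE)
  triangle_mesh(verts, faces, label)
}

write_stl <- function(mesh, path, ascii = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  cr <- face_cross(mesh)
  nrm <- cr / pmax(sqrt(rowSums(cr^2)), 1e-300)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid meniscusdyn", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1],
                           nrm[i, 2], nrm[i, 3]),
                   "    outer loop",
                   sprintf("      vertex %.9g %.9g %.9g",
                           v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid meniscusdyn", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", "meniscusdyn binary STL"))
    writeBin(hdr[1:80], con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(c(nrm[i, ], t(v[f[i, ], ])), con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
  invisible(path)
}
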