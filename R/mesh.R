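#' Triangle surface meshes
#'
#' A `triangle_mesh` stores the vertices (n x 3 matrix, mm) and triangles
#' (m x 3 integer matrix of 1-based vertex indices) of one unilateral
#' cavity surface. Construction validates index bounds and drops
#' degenerate (zero-area) triangles.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param triangles integer m x 3 matrix of 1-based vertex indices.
#' @param clean drop degenerate triangles and deduplicate vertices
#'   (within 1e-9 mm) instead of erroring on them.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, triangles, clean = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L || ncol(triangles) != 3L)
    .mc_stop("vertices and triangles must both have 3 columns",
             class = "mesh_error")
  if (!all(is.finite(vertices)))
    .mc_stop("non-finite vertex coordinates", class = "mesh_error")
  if (nrow(triangles) < 1L)
    .mc_stop("mesh has no triangles", class = "mesh_error")
  if (anyNA(triangles) || min(triangles) < 1L ||
      max(triangles) > nrow(vertices))
    .mc_stop("triangle index out of range", class = "mesh_error")
  if (clean) {
    dd <- .dedup_vertices(vertices, tol = 1e-9)
    vertices <- dd$vertices
    triangles[] <- dd$map[triangles]
  }
  if (clean) {
    keep <- .triangle_areas(vertices, triangles) > 1e-12
    triangles <- triangles[keep, , drop = FALSE]
  }
  if (nrow(triangles) < 1L)
    .mc_stop("mesh has no non-degenerate triangles", class = "mesh_error")
  structure(list(vertices = vertices, triangles = triangles),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh: %d vertices, %d triangles, area %.2f mm^2>\n",
              nrow(x$vertices), nrow(x$triangles), mesh_area(x)))
  invisible(x)
}

# merge vertices closer than tol; returns new vertex matrix and old->new map
.dedup_vertices <- function(vertices, tol = 1e-9) {
  key <- paste(round(vertices[, 1] / tol), round(vertices[, 2] / tol),
               round(vertices[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  list(vertices = vertices[first, , drop = FALSE], map = map)
}

.triangle_areas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  e1 <- vertices[triangles[, 2], , drop = FALSE] - a
  e2 <- vertices[triangles[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a [triangle_mesh()].
#' @export
mesh_area <- function(mesh) {
  sum(.triangle_areas(mesh$vertices, mesh$triangles))
}

#' Read a surface mesh from STL (ASCII or binary) or PLY (ASCII)
#'
#' Vertices are deduplicated within 1e-9 mm (STL repeats each facet's
#' corners) and zero-area triangles are dropped.
#'
#' @param path path to an `.stl` or `.ply` file.
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path) || file.info(path)$size == 0)
    .mc_stop("unreadable or empty mesh file: %s", path, class = "format_error")
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
    stl = .read_stl(path),
    ply = .read_ply_ascii(path),
    .mc_stop("unsupported mesh format '%s': %s", ext, path,
             class = "format_error"))
  mesh
}

.read_stl <- function(path) {
  size <- file.info(path)$size
  # binary STL: 80-byte header + uint32 facet count + 50 bytes per facet
  if (size >= 84) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80)
    n <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (!is.na(n) && n >= 0 && size == 84 + 50 * as.numeric(n)) {
      rec <- readBin(con, "raw", 50 * n)
      idx <- rep(seq(0L, 50L * (n - 1L), by = 50L), each = 36L) +
        rep(13:48, times = n)  # skip the 12-byte facet normal
      coords <- readBin(rec[idx], "numeric", n = 9L * n, size = 4,
                        endian = "little")
      v <- matrix(coords, ncol = 3, byrow = TRUE)
      tri <- matrix(seq_len(3L * n), ncol = 3, byrow = TRUE)
      return(triangle_mesh(v, tri))
    }
    close(con)
    on.exit(NULL)
  }
  .read_stl_ascii(path)
}

.read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    .mc_stop("not a valid ASCII STL (no vertex triplets): %s", path,
             class = "format_error")
  nums <- lapply(strsplit(trimws(vl), "\\s+"),
                 function(x) as.numeric(x[2:4]))
  v <- do.call(rbind, nums)
  if (any(!is.finite(v)))
    .mc_stop("non-numeric vertex in ASCII STL: %s", path,
             class = "format_error")
  tri <- matrix(seq_len(nrow(v)), ncol = 3, byrow = TRUE)
  triangle_mesh(v, tri)
}

.read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || trimws(lines[1]) != "ply")
    .mc_stop("not a PLY file: %s", path, class = "format_error")
  endh <- match("end_header", trimws(lines))
  if (is.na(endh))
    .mc_stop("PLY header not terminated: %s", path, class = "format_error")
  head <- trimws(lines[seq_len(endh)])
  if (!any(grepl("^format\\s+ascii", head)))
    .mc_stop("only ASCII PLY is supported: %s", path, class = "format_error")
  nv <- as.integer(sub("^element\\s+vertex\\s+", "",
                       grep("^element\\s+vertex\\s", head, value = TRUE)[1]))
  nf <- as.integer(sub("^element\\s+face\\s+", "",
                       grep("^element\\s+face\\s", head, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf))
    .mc_stop("PLY header missing vertex/face counts: %s", path,
             class = "format_error")
  body <- trimws(lines[(endh + 1):length(lines)])
  body <- body[nzchar(body)]
  if (length(body) < nv + nf)
    .mc_stop("PLY body truncated: %s", path, class = "format_error")
  v <- do.call(rbind, lapply(strsplit(body[seq_len(nv)], "\\s+"),
                             function(x) as.numeric(x[1:3])))
  f <- do.call(rbind, lapply(strsplit(body[nv + seq_len(nf)], "\\s+"),
                             function(x) as.integer(x)))
  if (any(f[, 1] != 3L))
    .mc_stop("only triangular PLY faces are supported: %s", path,
             class = "format_error")
  triangle_mesh(v, f[, 2:4, drop = FALSE] + 1L)
}

#' Write a mesh as ASCII STL
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @export
write_mesh_stl <- function(mesh, path) {
  v <- mesh$vertices
  tri <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid morphocavity", con)
  for (t in seq_len(nrow(tri))) {
    p <- v[tri[t, ], , drop = FALSE]
    nrm <- .face_normal(p)
    writeLines(c(
      sprintf("  facet normal %.9g %.9g %.9g", nrm[1], nrm[2], nrm[3]),
      "    outer loop",
      sprintf("      vertex %.9g %.9g %.9g", p[, 1], p[, 2], p[, 3]),
      "    endloop",
      "  endfacet"), con)
  }
  writeLines("endsolid morphocavity", con)
  invisible(path)
}

.face_normal <- function(p) {
  n <- .cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])
  len <- sqrt(sum(n^2))
  if (len < 1e-300) c(0, 0, 1) else n / len
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Mirror a mesh or coordinate matrix across the sagittal plane
#'
#' The sagittal plane is x = 0 in the package convention (X medio-lateral,
#' Y antero-posterior, Z infero-superior): mirroring negates X. For meshes
#' the triangle winding is flipped so outward normals stay outward.
#'
#' @param x a [triangle_mesh()] or an n x 3 coordinate matrix.
#' @return the mirrored object, same type as the input.
#' @export
mirror_sagittal <- function(x) {
  if (inherits(x, "triangle_mesh")) {
    v <- x$vertices
    v[, 1] <- -v[, 1]
    structure(list(vertices = v,
                   triangles = x$triangles[, c(1L, 3L, 2L), drop = FALSE]),
              class = "triangle_mesh")
  } else if (inherits(x, "landmark_config")) {
    x$coordinates[, 1] <- -x$coordinates[, 1]
    x
  } else {
    x <- if (is.null(dim(x))) matrix(x, ncol = 3) else as.matrix(x)
    x[, 1] <- -x[, 1]
    x
  }
}

#' Closest point on a mesh surface
#'
#' Exact point-to-triangle projection over all triangles; ties between
#' equidistant triangles resolve to the lowest triangle index.
#'
#' @param p a single 3-vector or an m x 3 matrix of query points.
#' @param mesh a [triangle_mesh()].
#' @return a list with `point` (m x 3 matrix of surface feet), `triangle`
#'   (1-based triangle index) and `distance` (mm).
#' @export
closest_point_on_mesh <- function(p, mesh) {
  q <- if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
  storage.mode(q) <- "double"
  res <- closest_points_cpp(mesh$vertices, mesh$triangles - 1L, q)
  list(point = res$point, triangle = res$triangle + 1L,
       distance = res$distance)
}

# area-weighted vertex/edge-aware surface normal at the surface point
# returned by closest_point_on_mesh; used to build sliding tangent planes
.surface_normal <- function(point, triangle, mesh) {
  v <- mesh$vertices
  tri <- mesh$triangles
  corners <- v[tri[triangle, ], , drop = FALSE]
  # barycentric coordinates of the foot point in its host triangle
  bc <- .barycentric(point, corners)
  onv <- which(bc > 1 - 1e-9)
  one <- which(bc < 1e-9)
  if (length(onv) == 1) {        # vertex case: average incident face normals
    vid <- tri[triangle, onv]
    inc <- which(tri[, 1] == vid | tri[, 2] == vid | tri[, 3] == vid)
  } else if (length(one) == 1) { # edge case: both faces sharing the edge
    e <- tri[triangle, setdiff(1:3, one)]
    inc <- which((tri[, 1] %in% e) + (tri[, 2] %in% e) + (tri[, 3] %in% e) == 2)
    if (length(inc) == 0) inc <- triangle
  } else {
    inc <- triangle
  }
  n <- c(0, 0, 0)
  for (t in inc) {
    p <- v[tri[t, ], , drop = FALSE]
    n <- n + .cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])  # 2*area-weighted
  }
  len <- sqrt(sum(n^2))
  if (len < 1e-300) {
    n <- .face_normal(corners)
  } else {
    n <- n / len
  }
  n
}

.barycentric <- function(p, corners) {
  e1 <- corners[2, ] - corners[1, ]
  e2 <- corners[3, ] - corners[1, ]
  d <- p - corners[1, ]
  m <- rbind(c(sum(e1 * e1), sum(e1 * e2)), c(sum(e1 * e2), sum(e2 * e2)))
  rhs <- c(sum(d * e1), sum(d * e2))
  uv <- tryCatch(solve(m, rhs), error = function(e) c(1 / 3, 1 / 3))
  c(1 - sum(uv), uv)
}
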