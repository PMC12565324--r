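# mesh and landmark IO, mirroring, closest-point projection

test_that("read_mesh parses ASCII STL, binary STL and PLY", {
  # minimal single-triangle ASCII STL
  stl <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid t", "facet normal 0 0 1", "outer loop",
               "vertex 0 0 0", "vertex 1 0 0", "vertex 0 1 0",
               "endloop", "endfacet", "endsolid t"), stl)
  m <- read_mesh(stl)
  expect_equal(nrow(m$vertices), 3)
  expect_equal(nrow(m$triangles), 1)

  # binary STL cube: 12 facets collapse to 8 unique vertices
  cube <- withr::local_tempfile(fileext = ".stl")
  write_cube_stl_binary(cube)
  mc <- read_mesh(cube)
  expect_equal(nrow(mc$vertices), 8)
  expect_equal(nrow(mc$triangles), 12)
  expect_equal(mesh_area(mc), 6, tolerance = 1e-12)

  # ASCII PLY round trip of the same geometry
  ply <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 3",
               "property float x", "property float y", "property float z",
               "element face 1", "property list uchar int vertex_indices",
               "end_header", "0 0 0", "2 0 0", "0 2 0", "3 0 1 2"), ply)
  mp <- read_mesh(ply)
  expect_equal(mesh_area(mp), 2)

  # zero-byte and unknown files are format errors
  empty <- withr::local_tempfile(fileext = ".stl")
  file.create(empty)
  expect_error(read_mesh(empty), class = "format_error")
  expect_error(read_mesh(file.path(tempdir(), "nope.stl")),
               class = "format_error")
})

test_that("STL writer round-trips through the reader", {
  mesh <- plane_mesh(3)
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh_stl(mesh, path)
  back <- read_mesh(path)
  expect_equal(mesh_area(back), mesh_area(mesh), tolerance = 1e-9)
  expect_equal(nrow(back$triangles), nrow(mesh$triangles))
})

test_that("degenerate triangles are dropped at construction", {
  v <- rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(2,0,0))
  f <- rbind(c(1,2,3), c(1,2,4))     # second triangle is collinear
  m <- triangle_mesh(v, f)
  expect_equal(nrow(m$triangles), 1)
  expect_error(triangle_mesh(v, rbind(c(1,2,5))), class = "mesh_error")
})

test_that("landmark files round-trip losslessly in both dialects", {
  set.seed(7)
  cfg <- landmark_config(matrix(rnorm(630), 210),
                         c(rep(0L, 10), rep(1:2, each = 100)), "spec01")
  for (dialect in c("csv", "tps")) {
    f <- withr::local_tempfile(fileext = ".txt")
    write_landmarks(cfg, f, dialect)
    back <- read_landmarks(f, dialect)
    expect_identical(back$coordinates, cfg$coordinates)
    if (dialect == "csv") {
      expect_identical(back$patch_ids, cfg$patch_ids)
    } else {
      expect_identical(back$specimen_id, "spec01")
    }
  }
})

test_that("TPS dialect header and count validation", {
  cfg <- landmark_config(diag(3), rep(0L, 3), "three")
  f <- withr::local_tempfile()
  write_landmarks(cfg, f, "tps")
  expect_identical(readLines(f)[1], "LM3=3")
  # corrupt the count
  lines <- readLines(f)
  lines[1] <- "LM3=5"
  writeLines(lines, f)
  expect_error(read_landmarks(f, "tps"), class = "parse_error")
})

test_that("CSV parsing is header-driven and rejects NaN", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("z,x,id,patch,y", "3,1,0,0,2", "6,4,1,0,5"), f)
  cfg <- read_landmarks(f, "csv")
  expect_equal(cfg$coordinates, rbind(c(1, 2, 3), c(4, 5, 6)))
  bad <- landmark_config(rbind(c(1, 2, 3)), 0L)
  bad$coordinates[1, 1] <- NaN
  expect_error(write_landmarks(bad, f), class = "validation_error")
})

test_that("sagittal mirroring is an involution and an isometry", {
  set.seed(11)
  x <- matrix(rnorm(60), 20)
  expect_identical(mirror_sagittal(mirror_sagittal(x)), x)
  expect_equal(mirror_sagittal(c(1, 2, 3))[1, ], c(-1, 2, 3))
  # all pairwise distances preserved
  d0 <- dist(x); d1 <- dist(mirror_sagittal(x))
  expect_all_close(d0, d1, 1e-12)
  # mesh: area preserved, winding flip keeps triangle set valid
  mesh <- sphere_mesh(2)
  mm <- mirror_sagittal(mesh)
  expect_equal(mesh_area(mm), mesh_area(mesh), tolerance = 1e-12)
  expect_identical(mirror_sagittal(mirror_sagittal(mesh)), mesh)
})

test_that("closest_point_on_mesh handles vertex, face and edge feet", {
  tri <- triangle_mesh(rbind(c(0,0,0), c(1,0,0), c(0,1,0)), rbind(1:3))
  # on a vertex
  r <- closest_point_on_mesh(c(1, 0, 0), tri)
  expect_equal(r$distance, 0)
  expect_equal(r$point[1, ], c(1, 0, 0))
  # perpendicular foot above the face
  r <- closest_point_on_mesh(c(0.25, 0.25, 1), tri)
  expect_equal(r$point[1, ], c(0.25, 0.25, 0))
  expect_equal(r$distance, 1)
  # beyond the hypotenuse edge: foot on the edge
  r <- closest_point_on_mesh(c(1, 1, 0), tri)
  expect_equal(r$point[1, ], c(0.5, 0.5, 0))
})

test_that("closest point beats a dense surface-sampling oracle", {
  mesh <- sphere_mesh(2)
  set.seed(3)
  # oracle: 1e5 random points on the surface via random triangle + barycentric
  areas <- morphocavity:::.triangle_areas(mesh$vertices, mesh$triangles)
  ti <- sample.int(nrow(mesh$triangles), 1e5, replace = TRUE, prob = areas)
  r1 <- sqrt(runif(1e5)); r2 <- runif(1e5)
  a <- mesh$vertices[mesh$triangles[ti, 1], ]
  b <- mesh$vertices[mesh$triangles[ti, 2], ]
  cc <- mesh$vertices[mesh$triangles[ti, 3], ]
  pts <- (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * cc
  for (q in list(c(2, 0.3, 0.1), c(0.2, 0.1, 0.05), c(-1.5, 1.2, 0.4))) {
    found <- closest_point_on_mesh(q, mesh)$distance
    oracle <- sqrt(min(colSums((t(pts) - q)^2)))
    expect_lte(found, oracle + 1e-12)
    expect_lt(oracle - found, 2e-2)   # sampling resolution slack
  }
  # zero distance iff on the surface
  onsurf <- closest_point_on_mesh(pts[1:50, ], mesh)$distance
  expect_lt(max(onsurf), 1e-9)
})

test_that("equidistant ties pick the lowest triangle index", {
  # two parallel triangles equidistant from the midpoint
  v <- rbind(c(0,0,0), c(1,0,0), c(0,1,0),
             c(0,0,2), c(1,0,2), c(0,1,2))
  m <- triangle_mesh(v, rbind(c(1,2,3), c(4,5,6)))
  r <- closest_point_on_mesh(c(0.2, 0.2, 1), m)
  expect_equal(r$triangle, 1L)
})
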