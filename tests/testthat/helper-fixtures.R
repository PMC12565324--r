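# Shared fixtures, built in code at test time.

# memoised expensive fixtures
.fixture_env <- new.env(parent = emptyenv())
memo <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

test_template <- function() memo("template", generate_template())

# flat z = 0 grid mesh on [0, w] x [0, h]
plane_mesh <- function(n = 4, w = 1, h = 1) {
  g <- expand.grid(x = seq(0, w, length.out = n + 1),
                   y = seq(0, h, length.out = n + 1))
  v <- cbind(g$x, g$y, 0)
  idx <- function(i, j) (j - 1) * (n + 1) + i
  tris <- list()
  for (j in 1:n) for (i in 1:n) {
    a <- idx(i, j); b <- idx(i + 1, j); cc <- idx(i + 1, j + 1); d <- idx(i, j + 1)
    tris <- c(tris, list(c(a, b, cc), c(a, cc, d)))
  }
  triangle_mesh(v, do.call(rbind, tris))
}

# unit icosphere-ish mesh: subdivided octahedron projected on the sphere
sphere_mesh <- function(subdiv = 3, radius = 1) {
  v <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  f <- rbind(c(1,3,5), c(3,2,5), c(2,4,5), c(4,1,5),
             c(3,1,6), c(2,3,6), c(4,2,6), c(1,4,6))
  for (s in seq_len(subdiv)) {
    nf <- list()
    for (t in seq_len(nrow(f))) {
      a <- f[t,1]; b <- f[t,2]; cc <- f[t,3]
      mids <- rbind((v[a,]+v[b,])/2, (v[b,]+v[cc,])/2, (v[cc,]+v[a,])/2)
      mids <- mids / sqrt(rowSums(mids^2))
      base <- nrow(v)
      v <- rbind(v, mids)
      ab <- base+1; bc <- base+2; ca <- base+3
      nf <- c(nf, list(c(a,ab,ca), c(ab,b,bc), c(ca,bc,cc), c(ab,bc,ca)))
    }
    f <- do.call(rbind, nf)
  }
  triangle_mesh(v * radius, f)   # constructor dedups the shared midpoints
}

# binary STL of the unit cube (12 triangles), written at test time
write_cube_stl_binary <- function(path) {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # 12 triangles, outward winding
  f <- rbind(c(1,3,2), c(2,3,4),  # z = 0
             c(5,6,7), c(6,8,7),  # z = 1
             c(1,2,5), c(2,6,5),  # y = 0
             c(3,7,4), c(4,7,8),  # y = 1
             c(1,5,3), c(3,5,7),  # x = 0
             c(2,4,6), c(4,8,6))  # x = 1
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  for (t in seq_len(nrow(f))) {
    writeBin(numeric(3), con, size = 4, endian = "little")       # normal
    for (corner in f[t, ])
      writeBin(as.numeric(v[corner, ]), con, size = 4, endian = "little")
    writeBin(raw(2), con)                                        # attr bytes
  }
  invisible(path)
}

random_rotation <- function() {
  qrres <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qrres)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# n random landmark configurations around a base shape
random_configs <- function(n, base, sd = 0.1) {
  lapply(seq_len(n), function(i)
    base + matrix(rnorm(length(base), 0, sd), nrow(base)))
}

expect_all_close <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(a - b)), tol)
}
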