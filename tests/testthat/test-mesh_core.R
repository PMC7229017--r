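test_that("tri_mesh rejects degenerate input", {
  expect_error(tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        rbind(c(1, 2, 3))),
               class = "radcs_validation_error")
  # coplanar square
  expect_error(tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                              c(1, 1, 0)),
                        rbind(c(1, 2, 3), c(2, 4, 3))),
               class = "radcs_validation_error")
  expect_error(tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                              c(0, 0, NA)),
                        rbind(c(1, 2, 3))),
               class = "radcs_validation_error")
  expect_error(tri_mesh(tetra_mesh()$vertices, rbind(c(1, 2, 9))),
               class = "radcs_validation_error")
})

test_that("STL and PLY round-trips preserve geometry", {
  g <- generate_radius(radius_shape_params(vertex_spacing = 4, seed = 3))
  m <- g$mesh
  cases <- list(list(fmt = "stl", binary = FALSE, tol = 1e-6),
                list(fmt = "ply", binary = FALSE, tol = 1e-6),
                list(fmt = "ply", binary = TRUE, tol = 1e-6),
                # binary STL stores float32: ~1e-5 mm at bone scale
                list(fmt = "stl", binary = TRUE, tol = 1e-3))
  for (cs in cases) {
    path <- tempfile(fileext = paste0(".", cs$fmt))
    write_mesh(m, path, binary = cs$binary)
    m2 <- read_mesh(path)
    expect_equal(nrow(m2$faces), nrow(m$faces))
    expect_equal(nrow(m2$vertices), nrow(m$vertices))
    # STL loses indexing: compare sorted vertex sets
    v1 <- m$vertices[order(m$vertices[, 1], m$vertices[, 2],
                           m$vertices[, 3]), ]
    v2 <- m2$vertices[order(m2$vertices[, 1], m2$vertices[, 2],
                            m2$vertices[, 3]), ]
    expect_lt(max(abs(v1 - v2)), cs$tol)
    # surface area is an indexing-independent integrity check
    expect_equal(mesh_area(m2), mesh_area(m), tolerance = 1e-6)
    unlink(path)
  }
})

test_that("minimal ASCII STL of a tetrahedron parses", {
  path <- tempfile(fileext = ".stl")
  write_mesh(tetra_mesh(), path)
  m <- read_mesh(path)
  expect_s3_class(m, "tri_mesh")
  expect_equal(nrow(m$faces), 4L)
  expect_equal(nrow(m$vertices), 4L)
  unlink(path)
})

test_that("truncated and malformed files raise format errors", {
  path <- tempfile(fileext = ".stl")
  write_mesh(tetra_mesh(), path)
  txt <- readLines(path)
  writeLines(txt[1:5], path)                     # cut mid-facet
  expect_error(read_mesh(path), class = "radcs_format_error")

  pathb <- tempfile(fileext = ".ply")
  write_mesh(tetra_mesh(), pathb, binary = TRUE)
  raw <- readBin(pathb, "raw", file.info(pathb)$size)
  writeBin(raw[1:(length(raw) - 10)], pathb)     # truncate body
  expect_error(read_mesh(pathb), class = "radcs_format_error")

  expect_error(read_mesh(tempfile(fileext = ".stl")),
               class = "radcs_format_error")
  nofmt <- tempfile(fileext = ".xyz")
  writeLines("not a mesh", nofmt)
  expect_error(read_mesh(nofmt), class = "radcs_format_error")
  unlink(c(path, pathb, nofmt))
})

test_that("apply_rigid matches closed forms and preserves distances", {
  m <- tetra_mesh()
  expect_equal(apply_rigid(m, rigid_transform())$vertices, m$vertices)
  tr <- rigid_transform(translation = c(1, 2, 3))
  expect_equal(apply_rigid(m, tr)$vertices[1, ], c(1, 2, 3))
  rz90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  out <- apply_rigid(m, rigid_transform(rotation = rz90))
  expect_equal(out$vertices[2, ], c(0, 1, 0), tolerance = 1e-12)

  set.seed(11)
  g <- generate_radius(radius_shape_params(vertex_spacing = 5))
  rot <- random_rotation()
  moved <- apply_rigid(g$mesh, rigid_transform(rot, c(50, -20, 10)))
  i <- sample(nrow(g$mesh$vertices), 40)
  d0 <- as.matrix(dist(g$mesh$vertices[i, ]))
  d1 <- as.matrix(dist(moved$vertices[i, ]))
  expect_lt(max(abs(d0 - d1)), 1e-9)

  expect_error(rigid_transform(rotation = diag(3) * 2),
               class = "radcs_validation_error")
  expect_error(rigid_transform(rotation = diag(c(1, 1, -1))),
               class = "radcs_validation_error")
})

test_that("mirror_mesh reflects x, flips winding and volume, is involutive", {
  m <- tetra_mesh()
  mm <- mirror_mesh(m)
  expect_equal(mm$vertices[, 1], -m$vertices[, 1])
  expect_equal(mm$vertices[, 2:3], m$vertices[, 2:3])
  expect_equal(mm$faces[1, ], c(1L, 3L, 2L))
  expect_identical(mirror_mesh(mm), m)

  # winding reversal restores outward orientation after the reflection,
  # so the signed volume (and its sign) is preserved
  g <- generate_radius(radius_shape_params(vertex_spacing = 5))
  expect_equal(signed_volume(mirror_mesh(g$mesh)), signed_volume(g$mesh))
  # without the winding flip the reflection would invert orientation
  flipped_only <- tri_mesh(g$mesh$vertices,
                           g$mesh$faces[, c(1, 3, 2)])
  expect_equal(signed_volume(flipped_only), -signed_volume(g$mesh))
  i <- seq(1, nrow(g$mesh$vertices), by = 37)
  expect_equal(as.matrix(dist(mirror_mesh(g$mesh)$vertices[i, ])),
               as.matrix(dist(g$mesh$vertices[i, ])), tolerance = 1e-12)
})

test_that("extent_along projects correctly", {
  m <- cylinder_mesh(radius = 5, height = 100, n_seg = 12, n_ring = 5)
  e <- extent_along(m, c(0, 0, 1))
  expect_equal(c(e$min, e$max, e$length), c(0, 100, 100))
  e2 <- extent_along(m, c(0, 0, -1))
  expect_equal(c(e2$min, e2$max, e2$length), c(-100, 0, 100))
  expect_error(extent_along(m, c(0, 0, 0)), class = "radcs_validation_error")
})

test_that("clip_fraction cuts at the plane and preserves the identity case", {
  m <- cylinder_mesh(radius = 5, height = 100)
  c40 <- clip_fraction(m, c(0, 0, 1), 0.4)
  expect_gte(min(c40$vertices[, 3]), 60 - 1e-9)
  expect_equal(extent_along(c40, c(0, 0, 1))$length, 40, tolerance = 1e-9)

  expect_identical(clip_fraction(m, c(0, 0, 1), 1), m)
  expect_error(clip_fraction(m, c(0, 0, 1), 0),
               class = "radcs_validation_error")
  expect_error(clip_fraction(m, c(0, 0, 1), 1.5),
               class = "radcs_validation_error")
})

test_that("clipped cylinder area matches the closed form within 2%", {
  r <- 5; h <- 100
  m <- cylinder_mesh(radius = r, height = h)
  half <- clip_fraction(m, c(0, 0, 1), 0.5)
  # lateral area of the retained half of an open cylinder
  expect_equal(mesh_area(half), pi * r * h,
               tolerance = 0.02)
})

test_that("clip_fraction is monotone in the retained vertex set", {
  g <- generate_radius(radius_shape_params(vertex_spacing = 4, seed = 5))
  axis <- c(0, 0, 1)
  key <- function(m) {
    apply(round(m$vertices, 9), 1, paste, collapse = "|")
  }
  orig <- key(g$mesh)
  k30 <- intersect(key(clip_fraction(g$mesh, axis, 0.3)), orig)
  k60 <- intersect(key(clip_fraction(g$mesh, axis, 0.6)), orig)
  expect_true(all(k30 %in% k60))
  expect_gt(length(k60), length(k30))
})
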