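#' Triangulated surface mesh
#'
#' The geometric substrate of the package: a bone surface as a triangulated
#' mesh with vertex coordinates in millimetres in a right-handed global frame.
#' Degenerate inputs (fewer than four vertices, coplanar vertex sets,
#' out-of-range face indices, non-finite coordinates) are rejected.
#'
#' @param vertices numeric matrix, one row per vertex, three columns (mm).
#' @param faces integer matrix, one row per triangle, three 1-based vertex
#'   indices per row.
#' @return An object of class `tri_mesh` with elements `vertices` and `faces`.
#' @examples
#' v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
#' f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
#' m <- tri_mesh(v, f)
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L) {
    abort_radcs("vertices and faces must have 3 columns",
                "radcs_validation_error")
  }
  if (any(!is.finite(vertices))) {
    abort_radcs("all vertex coordinates must be finite",
                "radcs_validation_error")
  }
  n <- nrow(vertices)
  if (n < 4L) {
    abort_radcs("mesh must have at least 4 vertices", "radcs_validation_error")
  }
  if (nrow(faces) < 1L || any(faces < 1L) || any(faces > n)) {
    abort_radcs("face indices must lie in [1, n_vertices]",
                "radcs_validation_error")
  }
  # non-coplanarity: centered vertex matrix must have rank 3
  ctr <- colMeans(vertices)
  cv <- crossprod(sweep(vertices, 2L, ctr))
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[3L] <= 1e-10 * max(ev[1L], .Machine$double.eps)) {
    abort_radcs("mesh vertices are (near-)coplanar; degenerate mesh rejected",
                "radcs_validation_error")
  }
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

assert_tri_mesh <- function(mesh) {
  if (!inherits(mesh, "tri_mesh")) {
    abort_radcs("expected a `tri_mesh` object", "radcs_validation_error")
  }
  mesh
}

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric 3-vector (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)) || any(!is.finite(rotation))) {
    abort_radcs("rotation must be a finite 3x3 matrix",
                "radcs_validation_error")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    abort_radcs("rotation matrix is not orthonormal within 1e-9",
                "radcs_validation_error")
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    abort_radcs("rotation matrix must have determinant +1 (no reflections)",
                "radcs_validation_error")
  }
  if (!is.numeric(translation) || length(translation) != 3L ||
      any(!is.finite(translation))) {
    abort_radcs("translation must be a finite 3-vector",
                "radcs_validation_error")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to a mesh
#'
#' Each vertex `v` maps to `R v + t`; face connectivity is untouched, so all
#' pairwise distances are preserved.
#'
#' @param mesh a [tri_mesh()].
#' @param transform a [rigid_transform()].
#' @return The transformed `tri_mesh`.
#' @export
apply_rigid <- function(mesh, transform) {
  assert_tri_mesh(mesh)
  if (!inherits(transform, "rigid_transform")) {
    transform <- rigid_transform(transform$rotation, transform$translation)
  }
  v <- mesh$vertices %*% t(transform$rotation)
  v <- sweep(v, 2L, transform$translation, `+`)
  structure(list(vertices = v, faces = mesh$faces), class = "tri_mesh")
}

#' Mirror a mesh across the x = 0 plane
#'
#' Left bones are mirrored so left and right sides share one analysis. The
#' reflection is `x -> -x`; face winding is reversed so outward orientation
#' (sign of the enclosed volume) is preserved.
#'
#' @param mesh a [tri_mesh()].
#' @return The mirrored `tri_mesh`.
#' @export
mirror_mesh <- function(mesh) {
  assert_tri_mesh(mesh)
  v <- mesh$vertices
  v[, 1L] <- -v[, 1L]
  f <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  structure(list(vertices = v, faces = f), class = "tri_mesh")
}

#' Extent of a mesh along a direction
#'
#' Projects all vertices onto a unit axis and returns the extreme projection
#' values and the spanned length, the quantity used to define "percentage of
#' radial length".
#'
#' @param mesh a [tri_mesh()].
#' @param axis numeric 3-vector; normalized internally, must be non-zero.
#' @return A list with `min`, `max` and `length` (mm).
#' @export
extent_along <- function(mesh, axis) {
  assert_tri_mesh(mesh)
  axis <- as_unit3(axis)
  s <- as.numeric(mesh$vertices %*% axis)
  list(min = min(s), max = max(s), length = max(s) - min(s))
}

#' Shorten a mesh by clipping its proximal part
#'
#' Keeps the distal fraction of the mesh along `axis` (which must point
#' distal). The cutting plane sits at `max - keep_fraction * length` of the
#' vertex projections; triangles crossing the plane are cut at the plane so
#' the retained extent is exact, and the cut is left open (no cap), because
#' downstream inertia computations use vertices only and a cap would add
#' artificial vertex density.
#'
#' @param mesh a [tri_mesh()].
#' @param axis distal direction (3-vector, normalized internally).
#' @param keep_fraction fraction of the extent to keep, in (0, 1].
#' @return The clipped `tri_mesh`.
#' @export
clip_fraction <- function(mesh, axis, keep_fraction) {
  assert_tri_mesh(mesh)
  axis <- as_unit3(axis)
  stopifnot_scalar_number(keep_fraction, "keep_fraction")
  if (keep_fraction <= 0 || keep_fraction > 1) {
    abort_radcs("keep_fraction must lie in (0, 1]", "radcs_validation_error")
  }
  if (keep_fraction == 1) {
    return(mesh)
  }
  s <- as.numeric(mesh$vertices %*% axis)
  s0 <- max(s) - keep_fraction * (max(s) - min(s))
  d <- s - s0
  keep <- d >= 0

  f <- mesh$faces
  kf <- matrix(keep[f], ncol = 3L)
  nk <- rowSums(kf)

  verts <- mesh$vertices
  n0 <- nrow(verts)
  new_pts <- list()
  edge_key <- character(0)

  cut_edge <- function(a, b) {
    key <- if (a < b) paste0(a, "_", b) else paste0(b, "_", a)
    hit <- match(key, edge_key)
    if (!is.na(hit)) {
      return(n0 + hit)
    }
    t <- d[a] / (d[a] - d[b])
    p <- verts[a, ] + t * (verts[b, ] - verts[a, ])
    edge_key[[length(edge_key) + 1L]] <<- key
    new_pts[[length(new_pts) + 1L]] <<- p
    n0 + length(new_pts)
  }

  out <- vector("list", sum(nk %in% c(1L, 2L)) * 2L + sum(nk == 3L))
  nf <- 0L
  add_face <- function(tri) {
    nf <<- nf + 1L
    out[[nf]] <<- tri
  }
  full <- which(nk == 3L)
  for (i in full) add_face(f[i, ])
  for (i in which(nk == 1L)) {
    tri <- f[i, ]
    k <- kf[i, ]
    r <- which(k)            # rotate kept vertex to first position
    tri <- tri[((r - 1L + 0:2) %% 3L) + 1L]
    add_face(c(tri[1L], cut_edge(tri[1L], tri[2L]), cut_edge(tri[3L], tri[1L])))
  }
  for (i in which(nk == 2L)) {
    tri <- f[i, ]
    k <- kf[i, ]
    r <- which(!k)           # rotate dropped vertex to first position
    tri <- tri[((r - 1L + 0:2) %% 3L) + 1L]
    pab <- cut_edge(tri[1L], tri[2L])
    pca <- cut_edge(tri[3L], tri[1L])
    add_face(c(pab, tri[2L], tri[3L]))
    add_face(c(pab, tri[3L], pca))
  }
  if (nf == 0L) {
    abort_radcs("clip produced an empty mesh", "radcs_validation_error")
  }
  faces <- do.call(rbind, out[seq_len(nf)])
  allv <- rbind(verts, do.call(rbind, c(new_pts, list(NULL))))
  used <- sort(unique(as.integer(faces)))
  remap <- integer(nrow(allv))
  remap[used] <- seq_along(used)
  faces <- matrix(remap[faces], ncol = 3L)
  tri_mesh(allv[used, , drop = FALSE], faces)
}

#' Signed volume enclosed by a mesh
#'
#' Divergence-theorem sum of signed tetrahedra volumes; positive for
#' consistently outward-wound closed surfaces. Mirroring flips its sign.
#'
#' @param mesh a [tri_mesh()].
#' @return Signed volume in mm^3.
#' @export
signed_volume <- function(mesh) {
  assert_tri_mesh(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  sum(a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) -
      a[, 2L] * (b[, 1L] * c_[, 3L] - b[, 3L] * c_[, 1L]) +
      a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])) / 6
}

#' Test whether a mesh is watertight
#'
#' Every undirected edge must be shared by exactly two faces.
#'
#' @param mesh a [tri_mesh()].
#' @return `TRUE` or `FALSE`.
#' @export
is_watertight <- function(mesh) {
  assert_tri_mesh(mesh)
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  all(table(key) == 2L)
}
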