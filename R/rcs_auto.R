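# Automatic RCS placement: inertia tensor of the mesh vertices, long axis
# from the smallest-eigenvalue eigenvector, distal-window centroid, ray-cast
# origin on the distal articular surface, x-axis toward the styloid.

#' Inertia tensor of a point cloud
#'
#' Second-moment (inertia) tensor of a set of points about their centroid,
#' with unit mass per point:
#' \eqn{T = \sum_i (\|r_i\|^2 I_3 - r_i r_i^T)}, \eqn{r_i = p_i - centroid}.
#' The eigen-decomposition is returned with eigenvalues sorted ascending; the
#' eigenvector of the smallest eigenvalue is the elongation axis of the cloud.
#'
#' @param points numeric matrix, one row per point, 3 columns (mm).
#' @return An object of class `inertia_result` with `tensor`, `eigenvalues`
#'   (ascending), `eigenvectors` (columns matched to eigenvalues) and
#'   `centroid`.
#' @export
inertia_tensor <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 4L || any(!is.finite(points))) {
    abort_radcs("need >= 4 finite 3D points", "radcs_validation_error")
  }
  ctr <- unname(colMeans(points))
  r <- unname(sweep(points, 2L, ctr))
  sq <- sum(r * r)
  tensor <- sq * diag(3) - crossprod(r)
  # geometric degeneracy: centered points of rank < 2 (coincident/collinear)
  sv <- svd(r, nu = 0L, nv = 0L)$d
  if (sv[2L] <= 1e-6 * max(sv[1L], .Machine$double.eps)) {
    abort_radcs("points are coincident or collinear; inertia axes undefined",
                "radcs_degenerate_geometry")
  }
  e <- eigen(tensor, symmetric = TRUE)
  ord <- order(e$values)
  structure(list(tensor = tensor,
                 eigenvalues = e$values[ord],
                 eigenvectors = e$vectors[, ord, drop = FALSE],
                 centroid = ctr),
            class = "inertia_result")
}

#' Bone long axis from an inertia decomposition
#'
#' The eigenvector of the smallest eigenvalue points along the direction of
#' elongation (the bone axis); its sign is unresolved at this stage. Objects
#' without a clear elongation direction (smallest two eigenvalues equal within
#' a relative gap of 1e-6) are rejected.
#'
#' @param inertia an `inertia_result` from [inertia_tensor()].
#' @return Unit 3-vector.
#' @export
long_axis <- function(inertia) {
  if (!inherits(inertia, "inertia_result")) {
    abort_radcs("expected an `inertia_result`", "radcs_validation_error")
  }
  ev <- inertia$eigenvalues
  if ((ev[2L] - ev[1L]) <= 1e-6 * max(ev[3L], .Machine$double.eps)) {
    abort_radcs("object is not elongated: two smallest inertia eigenvalues coincide",
                "radcs_ambiguous_axis")
  }
  as.numeric(inertia$eigenvectors[, 1L])
}

#' Resolve the sign of the long axis against a global hint
#'
#' Eigenvector analysis fixes the orientation of the bone axis but not its
#' +/- direction; the scan convention (global +z points distal) resolves it:
#' the returned axis is the one whose dot product with `global_up` is
#' non-negative.
#'
#' @param axis unit 3-vector.
#' @param global_up unit 3-vector, the scanner direction known to point
#'   distal.
#' @return `axis` or `-axis`.
#' @export
orient_z <- function(axis, global_up) {
  axis <- as_unit3(axis, "axis")
  global_up <- as_unit3(global_up, "global_up")
  d <- sum(axis * global_up)
  if (abs(d) < 1e-12) {
    abort_radcs("axis is perpendicular to global_up; distal direction ambiguous",
                "radcs_orientation_ambiguous")
  }
  if (d >= 0) axis else -axis
}

#' Distal window along the bone axis
#'
#' The projection interval holding the distal `frac` of the available bone
#' length, at least `min_len_mm` long, clamped to the available length
#' (partial bones shorter than the clamp use whatever is available).
#'
#' @param mesh a [tri_mesh()].
#' @param z_axis unit 3-vector oriented distal.
#' @param frac distal fraction (default 0.15).
#' @param min_len_mm minimum window length in mm (default 20).
#' @return List with `lo` and `hi` projection bounds (mm).
#' @export
distal_window <- function(mesh, z_axis, frac = 0.15, min_len_mm = 20) {
  ext <- extent_along(mesh, z_axis)
  w <- max(frac * ext$length, min_len_mm)
  w <- min(w, ext$length)
  list(lo = ext$max - w, hi = ext$max)
}

#' Styloid point of a mesh
#'
#' The radial styloid is identified as the mesh vertex with the largest
#' projection onto the distal axis (the "highest" point of the bone); exact
#' ties resolve to the lowest vertex index for determinism.
#'
#' @param mesh a [tri_mesh()].
#' @param z_axis unit 3-vector oriented distal.
#' @return List with `point` (3-vector) and `index` (vertex row).
#' @export
styloid_point <- function(mesh, z_axis) {
  assert_tri_mesh(mesh)
  z_axis <- as_unit3(z_axis, "z_axis")
  s <- as.numeric(mesh$vertices %*% z_axis)
  i <- which.max(s)                       # which.max takes the first maximum
  list(point = as.numeric(mesh$vertices[i, ]), index = i)
}

# all intersections of the vertical line through (px, py) with the mesh,
# computed in a frame where the bone axis is +z; returns hit z-values
ray_hits_z <- function(v, f, px, py) {
  x1 <- v[f[, 1L], 1L]; y1 <- v[f[, 1L], 2L]; z1 <- v[f[, 1L], 3L]
  x2 <- v[f[, 2L], 1L]; y2 <- v[f[, 2L], 2L]; z2 <- v[f[, 2L], 3L]
  x3 <- v[f[, 3L], 1L]; y3 <- v[f[, 3L], 2L]; z3 <- v[f[, 3L], 3L]
  d <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  ok <- abs(d) > 1e-12
  u <- ((px - x1) * (y3 - y1) - (py - y1) * (x3 - x1)) / d
  w <- ((py - y1) * (x2 - x1) - (px - x1) * (y2 - y1)) / d
  eps <- 1e-9
  inside <- ok & u >= -eps & w >= -eps & (u + w) <= 1 + eps
  z1[inside] + u[inside] * (z2[inside] - z1[inside]) +
    w[inside] * (z3[inside] - z1[inside])
}

#' Automatic placement of the radial coordinate system
#'
#' Implements the automatic placement procedure:
#' \enumerate{
#'   \item inertia tensor of all mesh vertices; the smallest-eigenvalue
#'     eigenvector is the bone axis, its sign resolved against `global_up`;
#'   \item the mesh is aligned so the bone axis is vertical (+z);
#'   \item the distal window (distal `distal_frac` of the length, at least
#'     `distal_min_len` mm, or whatever is available) is selected and its
#'     vertex centroid computed; the z-axis line is translated to pass
#'     through that centroid;
#'   \item the origin is the most distal intersection of that line with the
#'     mesh (ray cast along +z from the centroid; if the line misses all
#'     triangles, the vertex within 2 mm of the line with maximal projection
#'     is used);
#'   \item the x-axis points from the origin toward the styloid (the highest
#'     vertex), orthogonalized against z; y = z x x completes the
#'     right-handed triad;
#'   \item everything is transformed back to the original frame.
#' }
#' The procedure is fully deterministic.
#'
#' @param mesh a [tri_mesh()].
#' @param global_up unit 3-vector known to point distal (default `c(0,0,1)`,
#'   the scanner axis for prone, arm-overhead acquisition).
#' @param distal_frac distal window fraction (default 0.15).
#' @param distal_min_len distal window minimum length in mm (default 20).
#' @return A list with `cs` (the [coordinate_system()]) and `trace`, a record
#'   of intermediates: `temp_axes`, `distal_window`, `distal_centroid`,
#'   `styloid_point`, `styloid_index`, `origin_rule` ("ray" or "fallback"),
#'   and `final`.
#' @export
place_rcs <- function(mesh, global_up = c(0, 0, 1),
                      distal_frac = 0.15, distal_min_len = 20) {
  assert_tri_mesh(mesh)
  global_up <- as_unit3(global_up, "global_up")

  ir <- inertia_tensor(mesh$vertices)
  z <- orient_z(long_axis(ir), global_up)

  # temporary frame: z = bone axis; x/y from the remaining eigenvectors,
  # re-orthogonalized and right-handed (their direction is immaterial: all
  # downstream steps are rotations about z away from them)
  x0 <- as.numeric(ir$eigenvectors[, 2L])
  y0 <- normalize(cross3(z, x0))
  x0 <- cross3(y0, z)
  rot <- cbind(x0, y0, z, deparse.level = 0L)   # columns: local -> global

  va <- sweep(mesh$vertices, 2L, ir$centroid) %*% rot  # aligned frame
  f <- mesh$faces

  zmax <- max(va[, 3L])
  zmin <- min(va[, 3L])
  len <- zmax - zmin
  w <- min(max(distal_frac * len, distal_min_len), len)
  lo <- zmax - w
  sel <- va[, 3L] >= lo
  ctr <- colMeans(va[sel, , drop = FALSE])

  hits <- ray_hits_z(va, f, ctr[1L], ctr[2L])
  hits <- hits[hits >= ctr[3L] - 1e-9]
  if (length(hits) > 0L) {
    origin_a <- c(ctr[1L], ctr[2L], max(hits))
    origin_rule <- "ray"
  } else {
    near <- which(sqrt((va[, 1L] - ctr[1L])^2 + (va[, 2L] - ctr[2L])^2) <= 2)
    if (length(near) == 0L) {
      abort_radcs("placement failed at origin stage: distal ray misses the mesh and no vertex lies within 2 mm of the axis line",
                  "radcs_placement_error")
    }
    iv <- near[which.max(va[near, 3L])]
    origin_a <- c(ctr[1L], ctr[2L], va[iv, 3L])
    origin_rule <- "fallback"
  }

  sty_i <- which.max(va[, 3L])
  sty_a <- as.numeric(va[sty_i, ])
  dxy <- c(sty_a[1L] - origin_a[1L], sty_a[2L] - origin_a[2L])
  if (vnorm(dxy) < 1e-9) {
    abort_radcs("placement failed at styloid stage: styloid lies on the z-axis line",
                "radcs_placement_error")
  }
  x_a <- c(dxy / vnorm(dxy), 0)
  y_a <- c(-x_a[2L], x_a[1L], 0)          # z x x with z = (0,0,1)

  # back to the original frame
  to_world <- function(p) as.numeric(rot %*% p)
  origin_w <- ir$centroid + to_world(origin_a)
  cs <- coordinate_system(origin = origin_w,
                          x_axis = to_world(x_a),
                          y_axis = to_world(y_a),
                          z_axis = z)
  trace <- list(
    temp_axes = coordinate_system(ir$centroid, x0, y0, z),
    distal_window = list(lo = lo, hi = zmax),
    distal_centroid = ir$centroid + to_world(ctr),
    styloid_point = as.numeric(mesh$vertices[sty_i, ]),
    styloid_index = sty_i,
    origin_rule = origin_rule,
    final = cs
  )
  list(cs = cs, trace = trace)
}
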