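#' Anatomical coordinate system
#'
#' An origin plus a right-handed orthonormal axis triad, all in the global
#' frame. For the radius, z points distal along the bone axis
#' (pro-supination), x toward the radial styloid (flexion-extension) and
#' y = z x x (radioulnar deviation).
#'
#' @param origin numeric 3-vector (mm).
#' @param x_axis,y_axis,z_axis unit 3-vectors; must be pairwise orthogonal
#'   within 1e-9 and satisfy x cross y = z (right-hand rule).
#' @return An object of class `coordinate_system`.
#' @export
coordinate_system <- function(origin, x_axis, y_axis, z_axis) {
  for (nm in c("origin", "x_axis", "y_axis", "z_axis")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 3L || any(!is.finite(v))) {
      abort_radcs(sprintf("`%s` must be a finite 3-vector", nm),
                  "radcs_validation_error")
    }
  }
  ax <- list(x_axis, y_axis, z_axis)
  for (a in ax) {
    if (abs(vnorm(a) - 1) > 1e-9) {
      abort_radcs("axes must be unit length within 1e-9",
                  "radcs_validation_error")
    }
  }
  if (abs(sum(x_axis * y_axis)) > 1e-9 ||
      abs(sum(y_axis * z_axis)) > 1e-9 ||
      abs(sum(x_axis * z_axis)) > 1e-9) {
    abort_radcs("axes must be pairwise orthogonal within 1e-9",
                "radcs_validation_error")
  }
  if (max(abs(cross3(x_axis, y_axis) - z_axis)) > 1e-9) {
    abort_radcs("axes must be right-handed: x cross y = z within 1e-9",
                "radcs_validation_error")
  }
  structure(list(origin = as.numeric(origin), x_axis = as.numeric(x_axis),
                 y_axis = as.numeric(y_axis), z_axis = as.numeric(z_axis)),
            class = "coordinate_system")
}

#' @export
print.coordinate_system <- function(x, ...) {
  cat("<coordinate_system>\n")
  cat(sprintf("  origin: %9.3f %9.3f %9.3f\n",
              x$origin[1L], x$origin[2L], x$origin[3L]))
  for (nm in c("x_axis", "y_axis", "z_axis")) {
    cat(sprintf("  %s: %9.6f %9.6f %9.6f\n",
                nm, x[[nm]][1L], x[[nm]][2L], x[[nm]][3L]))
  }
  invisible(x)
}

assert_cs <- function(cs) {
  if (!inherits(cs, "coordinate_system")) {
    abort_radcs("expected a `coordinate_system` object",
                "radcs_validation_error")
  }
  cs
}

# rotation matrix with the axes as columns (local -> global)
cs_rotation <- function(cs) {
  cbind(cs$x_axis, cs$y_axis, cs$z_axis, deparse.level = 0L)
}

# apply a rigid transform to a coordinate system (frame moves with the body)
transform_cs <- function(cs, transform) {
  r <- transform$rotation
  coordinate_system(origin = as.numeric(r %*% cs$origin) +
                      transform$translation,
                    x_axis = as.numeric(r %*% cs$x_axis),
                    y_axis = as.numeric(r %*% cs$y_axis),
                    z_axis = as.numeric(r %*% cs$z_axis))
}
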