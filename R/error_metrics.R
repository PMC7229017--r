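# Pose difference between a reference coordinate system (full-length bone,
# CS100) and a test system (shortened bone or simulated manual placement),
# decomposed in the reference frame with the y-x-z Euler sequence.

#' Rigid transform from a reference to a test coordinate system
#'
#' The transform, expressed in the reference frame, that maps the reference
#' system onto the test system: `rotation = R_ref' R_test` and
#' `translation = R_ref' (o_test - o_ref)`, where `R_*` carries the axes as
#' columns.
#'
#' @param reference,test [coordinate_system()] objects.
#' @return A [rigid_transform()].
#' @export
cs_to_cs <- function(reference, test) {
  assert_cs(reference)
  assert_cs(test)
  # bit-identical frames map by the exact identity; skipping the matrix
  # product avoids ~1e-16 rounding in the self-comparison case
  if (identical(unclass(reference), unclass(test))) {
    return(rigid_transform())
  }
  rr <- cs_rotation(reference)
  rt <- cs_rotation(test)
  rigid_transform(rotation = crossprod(rr, rt),
                  translation = as.numeric(
                    crossprod(rr, test$origin - reference$origin)))
}

rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3L, 3L)
}
rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3L, 3L)
}
rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3L, 3L)
}

#' Compose a rotation from y-x-z Euler angles
#'
#' `R = Ry(phiy) Rx(phix) Rz(phiz)` (intrinsic y-x-z), angles in degrees.
#'
#' @param phiy,phix,phiz angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
compose_yxz <- function(phiy, phix, phiz) {
  d <- pi / 180
  rot_y(phiy * d) %*% rot_x(phix * d) %*% rot_z(phiz * d)
}

#' Decompose a rotation into y-x-z Euler angles
#'
#' Inverse of [compose_yxz()]: returns angles (degrees) such that
#' `Ry(phiy) Rx(phix) Rz(phiz)` reproduces the input. `phix` lies in
#' \[-90, 90\] (the middle angle of the sequence), `phiy` and `phiz` in
#' (-180, 180\]. At gimbal lock (`|cos(phix)| ~ 0`) the convention
#' `phiz = 0` is applied and the remaining rotation absorbed into `phiy`.
#'
#' @param rotation 3x3 orthonormal matrix, determinant +1 within 1e-9.
#' @return Named numeric vector `c(phiy, phix, phiz)` in degrees.
#' @export
euler_yxz <- function(rotation) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9) {
    abort_radcs("input is not a rotation matrix (orthonormal, det +1)",
                "radcs_validation_error")
  }
  # R = Ry Rx Rz:
  #   R[2,3] = -sin(phix); R[2,1] = cos(phix) sin(phiz);
  #   R[2,2] = cos(phix) cos(phiz); R[1,3] = sin(phiy) cos(phix);
  #   R[3,3] = cos(phiy) cos(phix)
  sx <- -rotation[2L, 3L]
  sx <- max(-1, min(1, sx))
  phix <- asin(sx)
  cx <- cos(phix)
  if (abs(cx) < 1e-9) {
    phiz <- 0
    phiy <- atan2(-rotation[3L, 1L], rotation[1L, 1L])
  } else {
    phiy <- atan2(rotation[1L, 3L], rotation[3L, 3L])
    phiz <- atan2(rotation[2L, 1L], rotation[2L, 2L])
  }
  r <- 180 / pi
  c(phiy = phiy * r, phix = phix * r, phiz = phiz * r)
}

#' Pose error between two coordinate systems
#'
#' Translation components are the [cs_to_cs()] translation (mm, reference
#' frame); rotation components are the y-x-z Euler angles of its rotation
#' (degrees). Totals are the quadratic sums
#' \eqn{d_{err} = \sqrt{\Delta x^2 + \Delta y^2 + \Delta z^2}} and
#' \eqn{\varphi_{err} = \sqrt{\Delta\varphi_x^2 + \Delta\varphi_y^2 +
#' \Delta\varphi_z^2}}. Note that \eqn{\varphi_{err}} is a quadratic sum of
#' Euler components, not a geodesic rotation angle, and can exceed 180
#' degrees.
#'
#' @param reference,test [coordinate_system()] objects.
#' @return An object of class `pose_error`: a named list with `dx`, `dy`,
#'   `dz`, `phix`, `phiy`, `phiz`, `d_err`, `phi_err`.
#' @export
pose_error <- function(reference, test) {
  tr <- cs_to_cs(reference, test)
  ang <- euler_yxz(tr$rotation)
  t <- tr$translation
  structure(list(dx = t[1L], dy = t[2L], dz = t[3L],
                 phix = unname(ang["phix"]),
                 phiy = unname(ang["phiy"]),
                 phiz = unname(ang["phiz"]),
                 d_err = sqrt(sum(t^2)),
                 phi_err = sqrt(sum(ang^2))),
            class = "pose_error")
}

#' @export
print.pose_error <- function(x, ...) {
  cat(sprintf("<pose_error> d_err %.3f mm (dx %.3f dy %.3f dz %.3f), phi_err %.3f deg (phix %.3f phiy %.3f phiz %.3f)\n",
              x$d_err, x$dx, x$dy, x$dz, x$phi_err, x$phix, x$phiy, x$phiz))
  invisible(x)
}

#' Summary statistics for error samples
#'
#' Accuracy is the median, precision the interquartile range (with minimum
#' and maximum); quartiles use the linear-interpolation (type 7) rule.
#'
#' @param values non-empty numeric vector.
#' @return List with `median`, `q1`, `q3`, `min`, `max`.
#' @export
summarize_errors <- function(values) {
  if (!is.numeric(values) || length(values) == 0L || any(!is.finite(values))) {
    abort_radcs("`values` must be a non-empty finite numeric vector",
                "radcs_validation_error")
  }
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  list(median = q[2L], q1 = q[1L], q3 = q[3L],
       min = min(values), max = max(values))
}

#' Pose errors as a one-row data frame
#'
#' @param x a `pose_error`.
#' @param ... unused.
#' @return data.frame with columns dx, dy, dz, phiy, phix, phiz, d_err,
#'   phi_err.
#' @export
as.data.frame.pose_error <- function(x, ...) {
  data.frame(dx = x$dx, dy = x$dy, dz = x$dz,
             phiy = x$phiy, phix = x$phix, phiz = x$phiz,
             d_err = x$d_err, phi_err = x$phi_err)
}
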