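#' Rigid 2D transform
#'
#' A rigid (Euclidean) planar transform: rotation by `angle` about `center`,
#' followed by translation. Acting on a point \eqn{p}:
#' \deqn{p' = R(\theta)\,(p - c) + c + t}
#' with \eqn{R(\theta)} the rotation matrix. This is the only alignment model
#' used anywhere in the package: no scaling, no shear, no reflection, so
#' histological structures are moved but never distorted. The class is closed
#' under composition and inversion, and the linear part is orthogonal with
#' determinant +1 by construction (the transform is parameterized by angle and
#' translation, never by a free 2x2 matrix).
#'
#' Coordinates are pixel coordinates: x along columns, y along rows, 1-indexed
#' pixel centers. The rotation center defaults to the image center and is
#' stored explicitly so serialized transforms are unambiguous.
#'
#' @param angle rotation angle in radians (counter-clockwise in x-right,
#'   y-down image coordinates).
#' @param tx,ty translation in pixels.
#' @param center numeric length-2, the rotation center `(cx, cy)` in pixels.
#' @return An object of class `rigid2d`.
#' @examples
#' t1 <- rigid2d(pi / 6, 2, -1, center = c(64.5, 64.5))
#' t2 <- rigid2d_invert(t1)
#' rigid2d_compose(t2, t1)  # identity
#' @export
rigid2d <- function(angle = 0, tx = 0, ty = 0, center = c(0, 0)) {
  stopifnot(is.numeric(angle), length(angle) == 1L, is.finite(angle),
            is.numeric(tx), length(tx) == 1L, is.finite(tx),
            is.numeric(ty), length(ty) == 1L, is.finite(ty),
            is.numeric(center), length(center) == 2L, all(is.finite(center)))
  structure(list(angle = angle, tx = tx, ty = ty,
                 center = as.numeric(center)),
            class = "rigid2d")
}

#' @export
print.rigid2d <- function(x, ...) {
  cat(sprintf("rigid2d: angle %.4f deg, t = (%.3f, %.3f) px, center (%.1f, %.1f)\n",
              x$angle * 180 / pi, x$tx, x$ty, x$center[1], x$center[2]))
  invisible(x)
}

#' Rotation matrix of a rigid transform
#'
#' @param t a `rigid2d`.
#' @return 2x2 rotation matrix.
#' @export
rigid2d_matrix <- function(t) {
  ca <- cos(t$angle); sa <- sin(t$angle)
  matrix(c(ca, sa, -sa, ca), 2, 2)
}

#' Apply a rigid transform to points
#'
#' @param t a `rigid2d`.
#' @param xy n x 2 matrix (or length-2 vector) of `(x, y)` pixel coordinates.
#' @return transformed coordinates, same shape.
#' @export
rigid2d_apply <- function(t, xy) {
  vec <- is.null(dim(xy))
  xy <- rbind(xy)
  R <- rigid2d_matrix(t)
  out <- sweep(xy, 2, t$center) %*% t(R)
  out <- sweep(out, 2, t$center + c(t$tx, t$ty), "+")
  if (vec) out[1, ] else out
}

#' Compose two rigid transforms
#'
#' Returns `b` applied after `a` (i.e. \eqn{b \circ a}). Both must share the
#' same rotation center; the composition is again a `rigid2d` about that
#' center: angle \eqn{\theta_a + \theta_b}, translation
#' \eqn{R_b t_a + t_b}.
#'
#' @param b,a `rigid2d` objects with identical centers.
#' @return a `rigid2d`.
#' @export
rigid2d_compose <- function(b, a) {
  stopifnot(inherits(a, "rigid2d"), inherits(b, "rigid2d"))
  if (max(abs(a$center - b$center)) > 1e-9)
    stop("cannot compose rigid2d transforms with different rotation centers")
  Rb <- rigid2d_matrix(b)
  t_new <- Rb %*% c(a$tx, a$ty) + c(b$tx, b$ty)
  rigid2d(a$angle + b$angle, t_new[1], t_new[2], a$center)
}

#' Invert a rigid transform
#'
#' @param t a `rigid2d`.
#' @return the inverse `rigid2d` (same center).
#' @export
rigid2d_invert <- function(t) {
  Ri <- rigid2d_matrix(rigid2d(-t$angle))
  ti <- -Ri %*% c(t$tx, t$ty)
  rigid2d(-t$angle, ti[1], ti[2], t$center)
}

#' Identity test helper
#' @param t a `rigid2d`
#' @param tol tolerance on angle (rad) and translation (px)
#' @return logical
#' @export
rigid2d_is_identity <- function(t, tol = 1e-9) {
  abs(t$angle) <= tol && abs(t$tx) <= tol && abs(t$ty) <= tol
}

# Angle/translation discrepancy between two transforms about the same center;
# used by tests and recovery summaries. Angle difference wrapped to (-pi, pi].
rigid2d_error <- function(est, ref) {
  d <- rigid2d_compose(rigid2d_invert(ref), est)
  ang <- atan2(sin(d$angle), cos(d$angle))
  c(angle_deg = abs(ang) * 180 / pi, trans_px = sqrt(d$tx^2 + d$ty^2))
}
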