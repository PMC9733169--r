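#' Planar rigid transform
#'
#' A rotation about the vertical (z) axis plus a horizontal translation,
#' acting identically on every z-slice of a volume. The transform maps a
#' point `p = (x, y)` to `R(theta) (p - c) + c + (tx, ty)`, where `c` is the
#' rotation center (voxel units, 0-based) and `R(theta)` rotates
#' counter-clockwise by `theta_deg` degrees.
#'
#' @param theta_deg rotation angle in degrees (counter-clockwise in x-y).
#' @param tx,ty horizontal translation in voxels.
#' @param center length-2 numeric, rotation center `(cx, cy)` in voxels.
#' @return an object of class `rigid2d`.
#' @export
rigid2d <- function(theta_deg = 0, tx = 0, ty = 0, center = c(0, 0)) {
  stopifnot(is_scalar_num(theta_deg), is_scalar_num(tx), is_scalar_num(ty),
            is.numeric(center), length(center) == 2L, all(is.finite(center)))
  structure(list(theta_deg = unname(theta_deg), tx = unname(tx),
                 ty = unname(ty), center = unname(as.numeric(center))),
            class = "rigid2d")
}

#' @export
print.rigid2d <- function(x, ...) {
  cat(sprintf("rigid2d: theta = %.4f deg, t = (%.4f, %.4f), center = (%.2f, %.2f)\n",
              x$theta_deg, x$tx, x$ty, x$center[1], x$center[2]))
  if (!is.null(attr(x, "converged")))
    cat(sprintf("  converged: %s, rms: %.4f\n", attr(x, "converged"), attr(x, "rms")))
  invisible(x)
}

rot2 <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Homogeneous matrix form of a planar rigid transform
#'
#' @param transform a [rigid2d()].
#' @return a 3 x 3 matrix acting on column vectors `(x, y, 1)`.
#' @export
transform_matrix <- function(transform) {
  R <- rot2(transform$theta_deg)
  c0 <- transform$center
  t0 <- c0 - as.vector(R %*% c0) + c(transform$tx, transform$ty)
  rbind(cbind(R, t0), c(0, 0, 1))
}

matrix_to_rigid2d <- function(A, center = c(0, 0)) {
  theta <- atan2(A[2, 1], A[1, 1]) * 180 / pi
  R <- A[1:2, 1:2]
  t0 <- A[1:2, 3]
  tc <- t0 - center + as.vector(R %*% center)
  rigid2d(theta, tc[1], tc[2], center = center)
}

#' Compose two planar rigid transforms
#'
#' Returns the transform equivalent to applying `b` first, then `a`.
#' The result is expressed about `a`'s center.
#'
#' @param a,b [rigid2d()] objects.
#' @export
compose_transforms <- function(a, b) {
  matrix_to_rigid2d(transform_matrix(a) %*% transform_matrix(b), center = a$center)
}

#' Invert a planar rigid transform
#'
#' @param transform a [rigid2d()].
#' @export
invert_transform <- function(transform) {
  matrix_to_rigid2d(solve(transform_matrix(transform)), center = transform$center)
}

#' Apply a planar rigid transform to 2D points
#'
#' @param transform a [rigid2d()].
#' @param points an `n x 2` matrix of `(x, y)` coordinates (voxels).
#' @return the transformed `n x 2` matrix.
#' @export
transform_points <- function(transform, points) {
  points <- rbind(points)
  A <- transform_matrix(transform)
  out <- cbind(points, 1) %*% t(A)
  out <- out[, 1:2, drop = FALSE]
  dimnames(out) <- NULL
  out
}

#' Deviation of a planar rigid transform from the identity
#'
#' Reports the absolute rotation angle and the displacement of the rotation
#' center, the two quantities used to decide whether a composed
#' (recovered after true) transform is close enough to the identity.
#'
#' @param transform a [rigid2d()].
#' @param at optional `(x, y)` point at which to measure displacement;
#'   defaults to the transform's own center.
#' @return named numeric vector `c(angle_deg, displacement)`.
#' @export
transform_deviation <- function(transform, at = NULL) {
  if (is.null(at)) at <- transform$center
  p <- transform_points(transform, rbind(at))
  c(angle_deg = abs(transform$theta_deg),
    displacement = sqrt(sum((p - at)^2)))
}
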