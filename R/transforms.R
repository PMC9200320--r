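# Rigid-body transforms and rotation parameterizations.
#
# A rigid transform is stored as a 3x3 proper rotation matrix `R` plus a
# translation 3-vector `t` (Angstrom); it acts on a point as x -> R x + t.
# Rotations are composed internally via matrices, exchanged with users in
# degrees, and exposed as rotation vectors (axis * angle, radians) where a
# minimal 3-parameter form is needed (residue-pair transforms).

#' Construct a rigid transform
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 numeric translation (Angstrom).
#' @return An object of class `rigid_transform` with fields `R` and `t`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  structure(list(R = rotation, t = as.numeric(translation)),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
rt_identity <- function() rigid_transform()

#' Apply a rigid transform to points
#'
#' @param tf `rigid_transform`.
#' @param x either a length-3 vector or an n x 3 coordinate matrix.
#' @return Transformed coordinates, same shape as `x`.
#' @export
rt_apply <- function(tf, x) {
  if (is.matrix(x)) {
    out <- x %*% t(tf$R)
    out[, 1] <- out[, 1] + tf$t[1]
    out[, 2] <- out[, 2] + tf$t[2]
    out[, 3] <- out[, 3] + tf$t[3]
    out
  } else {
    as.numeric(tf$R %*% x + tf$t)
  }
}

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` is the transform "apply `b`, then `a`".
#' @param a,b `rigid_transform` objects.
#' @export
rt_compose <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param tf `rigid_transform`.
#' @export
rt_invert <- function(tf) {
  Rt <- t(tf$R)
  rigid_transform(Rt, as.numeric(-Rt %*% tf$t))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix from a rotation vector (Rodrigues formula)
#'
#' @param v rotation vector: unit axis times angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotvec_to_matrix <- function(v) {
  theta <- vnorm(v)
  if (theta < 1e-12) return(diag(3))
  k <- v / theta
  K <- matrix(c(0, k[3], -k[2],
                -k[3], 0, k[1],
                k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Rotation vector (log map) of a rotation matrix
#'
#' Returns axis * angle with angle in [0, pi]; the angle-pi branch is resolved
#' from the diagonal of the rotation matrix.
#' @param R 3x3 rotation matrix.
#' @export
matrix_to_rotvec <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  theta <- acos(ct)
  if (theta < 1e-9) return(c(0, 0, 0))
  if (abs(pi - theta) < 1e-6) {
    # near 180 degrees: axis from the symmetric part
    B <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(B), 0))
    # fix signs using off-diagonal elements
    i <- which.max(ax)
    if (i == 1) {
      ax[2] <- B[1, 2] / ax[1]; ax[3] <- B[1, 3] / ax[1]
    } else if (i == 2) {
      ax[1] <- B[1, 2] / ax[2]; ax[3] <- B[2, 3] / ax[2]
    } else {
      ax[1] <- B[1, 3] / ax[3]; ax[2] <- B[2, 3] / ax[3]
    }
    return(unit(ax) * theta)
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(theta))
  ax * theta
}

#' Rotation matrix about an axis
#'
#' @param axis length-3 axis (need not be unit).
#' @param angle_deg rotation angle in degrees.
#' @export
axis_angle_matrix <- function(axis, angle_deg) {
  rotvec_to_matrix(unit(axis) * deg2rad(angle_deg))
}

# Rigid transform rotating by matrix Rm about a fixed point p.
rotation_about_point <- function(Rm, p) {
  rigid_transform(Rm, as.numeric(p - Rm %*% p))
}

# Uniform random unit vector (uses the session RNG).
random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- vnorm(v)
    if (n > 1e-8) return(v / n)
  }
}

# Uniform random rotation matrix via a normalized Gaussian quaternion.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}
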