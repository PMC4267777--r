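## Rotation and Fourier-grid utilities shared by all stages.
##
## Conventions (asserted in the test suite):
##  * Euler angles are intrinsic ZYZ in degrees: R = Rz(phi) Ry(theta) Rz(psi).
##    phi is the in-plane angle of a projection.
##  * A pose rotation R maps reference-frame coordinates to the laboratory
##    frame; the projected image is P(x, y) = sum_z V(R^T (x - sx, y - sy, z)).
##  * Volumes are cubic arrays [x, y, z] with the physical centre at 0-based
##    voxel index N %/% 2 on every axis; boxes are even.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

rot_z <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_y <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `deg` degrees about the (not necessarily unit)
#' vector `axis`.
#'
#' @param axis numeric length-3 axis.
#' @param deg rotation angle in degrees.
#' @return a 3x3 proper rotation matrix.
#' @keywords internal
rot_axis <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- deg2rad(deg)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Convert ZYZ Euler angles (degrees) to a rotation matrix
#' @param phi,theta,psi Euler angles in degrees (intrinsic ZYZ).
#' @return 3x3 rotation matrix `Rz(phi) %*% Ry(theta) %*% Rz(psi)`.
#' @export
euler_to_matrix <- function(phi, theta, psi) {
  rot_z(phi) %*% rot_y(theta) %*% rot_z(psi)
}

#' Convert a rotation matrix to ZYZ Euler angles (degrees)
#'
#' Angles are canonicalized to phi, psi in [0, 360) and theta in [0, 180].
#' @param R a 3x3 rotation matrix.
#' @return named numeric vector `c(phi, theta, psi)`.
#' @export
matrix_to_euler <- function(R) {
  ct <- max(-1, min(1, R[3, 3]))
  theta <- rad2deg(acos(ct))
  if (abs(ct) > 1 - 1e-12) {
    ## degenerate: only phi + psi (or phi - psi) defined; put it all in phi
    phi <- rad2deg(atan2(R[2, 1], R[1, 1]))
    if (ct < 0) phi <- -phi
    psi <- 0
  } else {
    phi <- rad2deg(atan2(R[2, 3], R[1, 3]))
    psi <- rad2deg(atan2(R[3, 2], -R[3, 1]))
  }
  c(phi = phi %% 360, theta = theta, psi = psi %% 360)
}

#' Geodesic distance between two rotations
#'
#' @param R1,R2 3x3 rotation matrices.
#' @return the rotation angle of `t(R1) %*% R2`, in degrees.
#' @export
rotation_distance <- function(R1, R2) {
  tr <- sum(diag(crossprod(R1, R2)))
  rad2deg(acos(max(-1, min(1, (tr - 1) / 2))))
}

#' Random rotation matrices, uniform over SO(3)
#'
#' Draws unit quaternions from a 4-D Gaussian (uses the current RNG state).
#' @param n number of rotations.
#' @return a list of `n` rotation matrices.
#' @export
random_rotations <- function(n) {
  lapply(seq_len(n), function(i) {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
      2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
      2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
    ), 3, 3)
  })
}

## ---- centred FFT helpers (even boxes only) ----

## For even N, fftshift and ifftshift coincide: swap the two halves.
fftshift_idx <- function(n) c((n / 2 + 1):n, 1:(n / 2))

fftshift2 <- function(x) {
  n <- nrow(x)
  x[fftshift_idx(n), fftshift_idx(ncol(x))]
}

fftshift3 <- function(x) {
  d <- dim(x)
  x[fftshift_idx(d[1]), fftshift_idx(d[2]), fftshift_idx(d[3])]
}

## centred 2-D FFT: DC at 0-based index N/2
cfft2 <- function(x) fftshift2(stats::fft(fftshift2(x)))
cifft2 <- function(x) fftshift2(stats::fft(fftshift2(x), inverse = TRUE)) / length(x)
cfft3 <- function(x) fftshift3(stats::fft(fftshift3(x)))
cifft3 <- function(x) fftshift3(stats::fft(fftshift3(x), inverse = TRUE)) / length(x)

## centred frequency index along one axis of an even box
freq_axis <- function(n) seq_len(n) - 1 - n %/% 2

## |k| (voxel-frequency radius) array for an N^3 box
freq_radius3 <- function(n) {
  k <- freq_axis(n)
  kx <- array(k, c(n, n, n))
  ky <- aperm(kx, c(2, 1, 3))
  kz <- aperm(kx, c(3, 2, 1))
  sqrt(kx^2 + ky^2 + kz^2)
}

## centred coordinate arrays (voxels) for an N^3 box
coord_arrays <- function(n) {
  x <- freq_axis(n)
  ax <- array(x, c(n, n, n))
  list(x = ax, y = aperm(ax, c(2, 1, 3)), z = aperm(ax, c(3, 2, 1)))
}
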