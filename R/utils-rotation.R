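# Rotation and quaternion utilities.
#
# Conventions: rotation matrices are 3x3, orthonormal, det +1, and map
# segment/sensor-local coordinates into world coordinates (columns are the
# local axes expressed in world). Quaternions are length-4 numeric vectors
# (w, x, y, z), unit norm, same local-to-world convention.

rot_axis <- function(axis, angle) {
  c <- cos(angle); s <- sin(angle)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3),
    y = matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3),
    z = matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3),
    stop("unknown rotation axis: ", axis)
  )
}

#' Compose a rotation from three intrinsic Euler angles
#'
#' Builds the rotation matrix `R = R1(a1) %*% R2(a2) %*% R3(a3)` for an
#' intrinsic (body-fixed) rotation sequence such as `"yxy"` (the ISB
#' humerothoracic sequence: plane of elevation, elevation, axial rotation)
#' or `"zxy"` (thorax relative to world).
#'
#' @param angles numeric length 3, in degrees.
#' @param sequence one of `"yxy"`, `"zxz"`, `"zxy"`, `"zyx"`, `"xyz"`.
#' @return 3x3 rotation matrix.
#' @seealso [decompose_angles()]
#' @export
compose_angles <- function(angles, sequence = "yxy") {
  sequence <- check_euler_sequence(sequence)
  stopifnot(length(angles) == 3L, all(is.finite(angles)))
  a <- angles * pi / 180
  ax <- strsplit(sequence, "")[[1]]
  rot_axis(ax[1], a[1]) %*% rot_axis(ax[2], a[2]) %*% rot_axis(ax[3], a[3])
}

check_euler_sequence <- function(sequence) {
  supported <- c("yxy", "zxz", "zxy", "zyx", "xyz")
  if (!is.character(sequence) || length(sequence) != 1L ||
      !(sequence %in% supported)) {
    stop("unsupported Euler sequence '", sequence, "'; supported: ",
         paste(supported, collapse = ", "))
  }
  sequence
}

#' Decompose a rotation into three intrinsic Euler angles
#'
#' Inverse of [compose_angles()]: extracts `(a1, a2, a3)` in degrees such
#' that composing them in the given intrinsic sequence reproduces `R`.
#' Symmetric sequences (`"yxy"`, `"zxz"`) return the middle angle in
#' `[0, 180]`; Tait-Bryan sequences return it in `[-90, 90]`. When the
#' rotation is within about 1 degree of the sequence's gimbal-lock
#' configuration the result carries attribute `gimbal = TRUE` (the returned
#' angles still reproduce `R` but the split between first and third angle is
#' ill-determined there).
#'
#' @param R 3x3 rotation matrix.
#' @param sequence as in [compose_angles()].
#' @return numeric length 3 (degrees), attribute `gimbal` logical.
#' @export
decompose_angles <- function(R, sequence = "yxy") {
  sequence <- check_euler_sequence(sequence)
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)))
  clamp1 <- function(x) min(1, max(-1, x))
  gtol <- 1 * pi / 180  # gimbal proximity flag threshold
  ax <- strsplit(sequence, "")[[1]]
  # at the singularity only a +/- c is determined: put c = 0 and read a off
  # the residual single-axis rotation M = R %*% R2(b)^-1
  first_axis_angle <- function(M, axis) {
    switch(axis,
      x = atan2(M[3, 2], M[2, 2]),
      y = atan2(M[1, 3], M[1, 1]),
      z = atan2(M[2, 1], M[1, 1]))
  }
  if (sequence == "yxy") {
    b <- atan2(sqrt(R[1, 2]^2 + R[3, 2]^2), R[2, 2])
    degen <- sin(b) <= 1e-12
    if (!degen) {
      a <- atan2(R[1, 2], R[3, 2])
      c <- atan2(R[2, 1], -R[2, 3])
    }
  } else if (sequence == "zxz") {
    b <- atan2(sqrt(R[1, 3]^2 + R[2, 3]^2), R[3, 3])
    degen <- sin(b) <= 1e-12
    if (!degen) {
      a <- atan2(R[1, 3], -R[2, 3])
      c <- atan2(R[3, 1], R[3, 2])
    }
  } else if (sequence == "zxy") {
    b <- asin(clamp1(R[3, 2]))
    degen <- abs(cos(b)) <= 1e-12
    if (!degen) {
      a <- atan2(-R[1, 2], R[2, 2])
      c <- atan2(-R[3, 1], R[3, 3])
    }
  } else if (sequence == "zyx") {
    b <- asin(clamp1(-R[3, 1]))
    degen <- abs(cos(b)) <= 1e-12
    if (!degen) {
      a <- atan2(R[2, 1], R[1, 1])
      c <- atan2(R[3, 2], R[3, 3])
    }
  } else {  # xyz
    b <- asin(clamp1(R[1, 3]))
    degen <- abs(cos(b)) <= 1e-12
    if (!degen) {
      a <- atan2(-R[2, 3], R[3, 3])
      c <- atan2(-R[1, 2], R[1, 1])
    }
  }
  if (degen) {
    M <- R %*% t(rot_axis(ax[2], b))
    a <- first_axis_angle(M, ax[1])
    c <- 0
  }
  symmetric <- ax[1] == ax[3]
  gimbal <- if (symmetric) (b < gtol) || (b > pi - gtol) else abs(abs(b) - pi / 2) < gtol
  out <- c(a, b, c) * 180 / pi
  attr(out, "gimbal") <- gimbal
  out
}

# quaternion (w,x,y,z) -> rotation matrix (local-to-world)
quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

# rotation matrix -> quaternion, Shepperd's method (stable for all traces)
rot_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

quat_normalize <- function(q) q / sqrt(sum(q^2))

# rotation-matrix logarithm: returns the rotation vector (axis * angle, rad)
rot_log <- function(R) {
  cang <- (R[1, 1] + R[2, 2] + R[3, 3] - 1) / 2
  cang <- min(1, max(-1, cang))
  ang <- acos(cang)
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (ang < 1e-8) return(v / 2)  # small-angle limit
  if (ang > pi - 1e-6) {
    # near pi: axis from the symmetric part
    B <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(B), 0))
    k <- which.max(axis)
    if (axis[k] > 0) {
      axis <- B[, k] / axis[k]
      axis <- axis / sqrt(sum(axis^2))
    }
    return(axis * ang)
  }
  v * ang / (2 * sin(ang))
}

# check orthonormality with det +1
is_rotation <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

# re-orthonormalize a near-rotation matrix via SVD projection
orthonormalize <- function(R) {
  s <- svd(R)
  U <- s$u; V <- s$v
  D <- diag(c(1, 1, det(U %*% t(V))))
  U %*% D %*% t(V)
}

# numerically stable hemisphere alignment for a quaternion series (n x 4)
quat_continuous <- function(Q) {
  if (nrow(Q) < 2L) return(Q)
  for (i in 2:nrow(Q)) {
    if (sum(Q[i, ] * Q[i - 1, ]) < 0) Q[i, ] <- -Q[i, ]
  }
  Q
}
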