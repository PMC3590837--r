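# Time differentiation of uniformly sampled series: 2nd-order central
# differences in the interior with 2nd-order one-sided stencils at the ends
# (the convention throughout the pipeline).

central_diff <- function(x, fs) {
  vec <- is.null(dim(x))
  X <- as.matrix(x)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 frames to differentiate")
  h <- 1 / fs
  D <- matrix(0, n, ncol(X))
  D[2:(n - 1), ] <- (X[3:n, , drop = FALSE] - X[1:(n - 2), , drop = FALSE]) / (2 * h)
  D[1, ] <- (-3 * X[1, ] + 4 * X[2, ] - X[3, ]) / (2 * h)
  D[n, ] <- (3 * X[n, ] - 4 * X[n - 1, ] + X[n - 2, ]) / (2 * h)
  if (vec) drop(D) else D
}

central_diff2 <- function(x, fs) central_diff(central_diff(x, fs), fs)

#' Angular velocity and acceleration of segment frames
#'
#' Extracts each segment's world-frame angular velocity from frame-to-frame
#' rotation increments — the matrix logarithm of `R[t+1] %*% t(R[t-1])`
#' divided by `2/fs` (centred; one-sided at the ends) — and angular
#' acceleration by central differences of the velocity.
#'
#' @param frames a `segment_frames` object, or a single 3 x 3 x n rotation
#'   array.
#' @param fs frame rate, Hz.
#' @return for `segment_frames` input, a named list per segment of lists
#'   with `omega` and `alpha` (n x 3, rad/s and rad/s^2, world frame); for
#'   an array input, one such list.
#' @export
angular_kinematics <- function(frames, fs) {
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  if (inherits(frames, "segment_frames")) {
    segs <- setdiff(names(frames), "n_frames")
    out <- lapply(segs, function(s) rotation_rates(frames[[s]]$R, fs))
    names(out) <- segs
    return(out)
  }
  rotation_rates(frames, fs)
}

rotation_rates <- function(R, fs) {
  stopifnot(length(dim(R)) == 3L, all(dim(R)[1:2] == 3L))
  n <- dim(R)[3]
  if (n < 5L) stop("need at least 5 frames for angular kinematics")
  h <- 1 / fs
  omega <- matrix(0, n, 3)
  for (k in 2:(n - 1)) omega[k, ] <- rot_log(R[, , k + 1] %*% t(R[, , k - 1])) / (2 * h)
  omega[1, ] <- rot_log(R[, , 2] %*% t(R[, , 1])) / h
  omega[n, ] <- rot_log(R[, , n] %*% t(R[, , n - 1])) / h
  alpha <- central_diff(omega, fs)
  list(omega = omega, alpha = alpha)
}
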