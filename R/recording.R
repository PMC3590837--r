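# MotionRecording container: per-sensor 6-DOF time series at a fixed rate.
#
# World frame convention: x toward home plate (throwing direction), z
# vertical up, y by the right-hand rule (to the pitcher's left for a
# right-hander facing home). Orientations are unit quaternions (w, x, y, z)
# mapping sensor-local coordinates to world.

#' Construct a motion recording
#'
#' @param fs frame rate, Hz (electromagnetic capture collected at 144 Hz).
#' @param sensors named list; each element a list with `pos` (n x 3 matrix,
#'   m, world) and `quat` (n x 4 matrix, unit quaternions w,x,y,z).
#' @param handedness `"R"` or `"L"` (throwing hand).
#' @param time optional time vector (s); defaults to `(0:(n-1)) / fs`.
#' @return object of class `motion_recording`.
#' @export
motion_recording <- function(fs, sensors, handedness = "R", time = NULL) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be positive")
  if (!is.list(sensors) || is.null(names(sensors)) || any(!nzchar(names(sensors))))
    stop("sensors must be a named list")
  handedness <- match.arg(handedness, c("R", "L"))
  n <- NULL
  for (lab in names(sensors)) {
    s <- sensors[[lab]]
    if (!is.matrix(s$pos) || ncol(s$pos) != 3L)
      stop("sensor '", lab, "': pos must be an n x 3 matrix")
    if (!is.matrix(s$quat) || ncol(s$quat) != 4L)
      stop("sensor '", lab, "': quat must be an n x 4 matrix")
    if (nrow(s$pos) != nrow(s$quat))
      stop("sensor '", lab, "': pos and quat frame counts differ")
    if (is.null(n)) n <- nrow(s$pos)
    if (nrow(s$pos) != n) stop("sensor '", lab, "': frame count differs from other sensors")
    qn <- sqrt(rowSums(s$quat^2))
    if (any(abs(qn - 1) > 1e-6))
      stop("sensor '", lab, "': quaternions deviate from unit norm by more than 1e-6")
    sensors[[lab]]$quat <- s$quat / qn
  }
  if (is.null(time)) time <- (seq_len(n) - 1L) / fs
  if (length(time) != n) stop("time length must equal frame count")
  dt <- diff(time)
  if (n > 1L && (any(dt <= 0) || max(abs(dt - 1 / fs)) > 1e-6 / fs))
    stop("time base must be uniform at 1/fs")
  structure(
    list(fs = fs, time = time, sensors = sensors, handedness = handedness),
    class = "motion_recording"
  )
}

n_frames <- function(recording) nrow(recording$sensors[[1]]$pos)

#' @export
print.motion_recording <- function(x, ...) {
  cat("Motion recording: ", n_frames(x), " frames at ", x$fs, " Hz (",
      signif(n_frames(x) / x$fs, 4), " s), handedness ", x$handedness, "\n",
      "sensors: ", paste(names(x$sensors), collapse = ", "), "\n", sep = "")
  invisible(x)
}

sensor_rotations <- function(recording, label) {
  s <- recording$sensors[[label]]
  if (is.null(s)) stop("sensor '", label, "' not present in recording")
  n <- nrow(s$pos)
  R <- array(0, c(3, 3, n))
  for (i in seq_len(n)) R[, , i] <- quat_to_rot(s$quat[i, ])
  R
}

#' Mirror a recording across the vertical-throwing plane
#'
#' Reflects a recording in the plane spanned by the throwing direction (x)
#' and the vertical (z) — i.e. negates the world y axis — so that a
#' left-handed pitcher's delivery reads as its right-handed twin. Positions
#' have their y component negated; orientations are conjugated by the same
#' reflection (quaternion `(w, x, y, z) -> (w, -x, y, -z)`), which keeps
#' every rigid-body relationship intact and keeps rotation determinants +1.
#' The handedness flag is flipped. Applying the mirror twice returns the
#' original recording bit-for-bit.
#'
#' Sensor-local landmark offsets digitized on the unmirrored body must be
#' mirrored alongside the recording; see [mirror_landmark_map()].
#'
#' @param recording a [motion_recording()].
#' @return the mirrored `motion_recording`.
#' @export
mirror_world_z <- function(recording) {
  stopifnot(inherits(recording, "motion_recording"))
  out <- recording
  for (lab in names(out$sensors)) {
    out$sensors[[lab]]$pos[, 2] <- -out$sensors[[lab]]$pos[, 2]
    q <- out$sensors[[lab]]$quat
    q[, 2] <- -q[, 2]
    q[, 4] <- -q[, 4]
    out$sensors[[lab]]$quat <- q
  }
  out$handedness <- if (recording$handedness == "L") "R" else "L"
  out
}
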