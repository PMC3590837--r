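#' Detect pitch events: stride-foot contact, maximum external rotation, ball release
#'
#' The three events bounding the phases of interest are located from the
#' kinematics alone:
#' \describe{
#'   \item{SFC}{stride-foot contact — first frame at which the lead-shank
#'     distal point's height falls below a threshold (by default 5% of
#'     subject height above the lowest recorded shank height) and its
#'     downward vertical velocity has returned to zero.}
#'   \item{MER}{maximum shoulder external rotation — frame of the extremum
#'     of the humerothoracic axial-rotation angle (third angle of the ISB
#'     y-x'-y'' decomposition). An extremum on the first/last frame raises
#'     a warning.}
#'   \item{BR}{ball release — frame of peak resultant hand-centre-of-mass
#'     speed after MER.}
#' }
#' The arm-cocking phase is `[SFC, MER]` (anterior force peaks near MER)
#' and the arm-acceleration phase `[MER, BR]` (proximal force peaks near
#' BR).
#'
#' @param frames a `segment_frames` object from [build_segment_frames()].
#' @param fs frame rate, Hz.
#' @param hand_com optional n x 3 world hand-COM trajectory; defaults to
#'   the hand-frame origin (styloid midpoint).
#' @param shank_z numeric vector of the lead-shank distal point's world
#'   height (m) per frame; required for SFC detection.
#' @param height_cm subject height (cm), used for the SFC threshold.
#' @param sfc_height_frac SFC threshold as a fraction of subject height
#'   above the lowest shank height (default 0.05).
#' @return object of class `pitch_events`: list with integer frame indices
#'   `sfc`, `mer`, `br`, plus `axial_deg` (the humerothoracic axial-rotation
#'   series) and any `warnings`.
#' @export
detect_events <- function(frames, fs, hand_com = NULL, shank_z = NULL,
                          height_cm = NULL, sfc_height_frac = 0.05) {
  stopifnot(inherits(frames, "segment_frames"))
  n <- frames$n_frames
  warnings <- character(0)

  # humerothoracic axial rotation (y-x'-y'' third angle)
  axial <- numeric(n)
  for (k in seq_len(n)) {
    Rrel <- crossprod(frames$torso$R[, , k], frames$humerus$R[, , k])
    axial[k] <- decompose_angles(Rrel, "yxy")[3]
  }
  mer <- which.max(abs(axial - axial[1]))
  if (mer == 1L || mer == n) {
    warnings <- c(warnings, "axial-rotation extremum lies on a recording boundary")
    warning("maximum external rotation falls on a recording boundary")
  }

  # stride-foot contact
  if (is.null(shank_z)) {
    sfc <- 1L
    warnings <- c(warnings, "no lead-shank trajectory supplied; SFC set to frame 1")
  } else {
    stopifnot(length(shank_z) == n)
    # contact timing needs only low-frequency content; the extra smoothing
    # (zero-phase, so no lag) stabilises the settle-velocity test under
    # sensor noise
    if (n > 13L) shank_z <- lowpass_filter(shank_z, fs, fc = min(6, fs / 4))
    href <- if (is.null(height_cm)) 100 * diff(range(shank_z)) / 0.13 else height_cm
    thr <- min(shank_z) + sfc_height_frac * href / 100
    vz <- central_diff(shank_z, fs)
    below <- which(shank_z < thr)
    if (!length(below)) {
      sfc <- which.min(shank_z)
      warnings <- c(warnings, "shank never crosses the SFC height threshold; using minimum height")
    } else {
      k0 <- below[1]
      # settled when the descent speed has decayed to a few percent of its peak
      v_eps <- 0.015 * max(-vz, 0)
      settled <- which(vz[k0:n] >= -v_eps)
      sfc <- if (length(settled)) k0 + settled[1] - 1L else which.min(shank_z)
    }
  }

  # ball release: peak hand-COM speed after MER
  if (is.null(hand_com)) hand_com <- frames$hand$origin
  stopifnot(nrow(hand_com) == n)
  speed <- sqrt(rowSums(central_diff(hand_com, fs)^2))
  if (mer >= n - 1L)
    stop("events out of order: no frames after maximum external rotation (recording truncated?)")
  br <- mer + which.max(speed[(mer + 1L):n])
  if (br >= n)
    stop("events out of order: peak hand speed on the final frame - recording appears truncated before ball release")
  if (!(sfc < mer && mer < br))
    stop("events out of order: SFC=", sfc, ", MER=", mer, ", BR=", br,
         " (expected SFC < MER < BR)")

  structure(list(sfc = as.integer(sfc), mer = as.integer(mer), br = as.integer(br),
                 axial_deg = axial, warnings = warnings),
            class = "pitch_events")
}

#' @export
print.pitch_events <- function(x, ...) {
  cat("Pitch events (frames): SFC =", x$sfc, " MER =", x$mer, " BR =", x$br, "\n")
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
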