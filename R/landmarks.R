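# Landmark digitization: each palpated bony landmark is stored as a fixed
# offset in the local frame of the sensor mounted on the same segment. The
# glenohumeral rotation centre is deliberately absent — it cannot be
# palpated and is estimated functionally (see estimate_gh_center).

#' Required bony-landmark names
#'
#' Thorax: C7 and T8 spinous processes, suprasternal notch. Throwing
#' humerus: medial and lateral epicondyles. Throwing forearm: radial and
#' ulnar styloid processes. Non-throwing-side duplicates (prefix `nt_`) may
#' be present but are not required by the kinetic chain.
#' @return character vector of landmark names.
#' @export
required_landmarks <- function() {
  c("c7", "t8", "suprasternal_notch",
    "epicondyle_medial", "epicondyle_lateral",
    "styloid_radial", "styloid_ulnar")
}

#' Construct a landmark map
#'
#' @param df data.frame with columns `landmark`, `sensor`, `ox`, `oy`, `oz`
#'   (offset of the landmark in its host sensor's local frame, m).
#' @return object of class `landmark_map` (validated data.frame).
#' @export
landmark_map <- function(df) {
  need <- c("landmark", "sensor", "ox", "oy", "oz")
  if (!is.data.frame(df) || !all(need %in% names(df)))
    stop("landmark map needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$landmark)) stop("duplicate landmark names in map")
  off <- as.matrix(df[, c("ox", "oy", "oz")])
  if (!all(is.finite(off))) stop("non-finite landmark offsets")
  missing <- setdiff(required_landmarks(), df$landmark)
  if (length(missing))
    stop("landmark map is missing required landmarks: ",
         paste(missing, collapse = ", "))
  structure(as.data.frame(df), class = c("landmark_map", "data.frame"))
}

#' Transform digitized landmarks to world coordinates
#'
#' For each landmark, applies its host sensor's pose frame-by-frame:
#' `global = sensor_position + sensor_rotation %*% offset`.
#'
#' @param recording a [motion_recording()].
#' @param map a [landmark_map()].
#' @return named list of n x 3 matrices (m, world), one per landmark.
#' @export
landmarks_to_global <- function(recording, map) {
  stopifnot(inherits(recording, "motion_recording"))
  if (!inherits(map, "landmark_map")) map <- landmark_map(map)
  unknown <- setdiff(unique(map$sensor), names(recording$sensors))
  if (length(unknown))
    stop("landmark map references sensors absent from recording: ",
         paste(unknown, collapse = ", "))
  n <- n_frames(recording)
  rot_cache <- list()
  out <- vector("list", nrow(map))
  names(out) <- map$landmark
  for (i in seq_len(nrow(map))) {
    lab <- map$sensor[i]
    if (is.null(rot_cache[[lab]])) rot_cache[[lab]] <- sensor_rotations(recording, lab)
    R <- rot_cache[[lab]]
    p <- recording$sensors[[lab]]$pos
    off <- c(map$ox[i], map$oy[i], map$oz[i])
    g <- matrix(0, n, 3)
    for (k in seq_len(n)) g[k, ] <- p[k, ] + R[, , k] %*% off
    out[[i]] <- g
  }
  out
}

#' Mirror a landmark map alongside a mirrored recording
#'
#' When a recording is reflected with [mirror_world_z()], sensor frames are
#' conjugated by the reflection, so sensor-local landmark offsets must have
#' their y component negated to keep landmark world positions consistent
#' with the mirrored body.
#'
#' @param map a [landmark_map()].
#' @return the mirrored `landmark_map`.
#' @export
mirror_landmark_map <- function(map) {
  if (!inherits(map, "landmark_map")) map <- landmark_map(map)
  map$oy <- -map$oy
  map
}
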