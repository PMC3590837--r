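#' Build anatomical segment frames from global landmarks
#'
#' Constructs right-handed orthonormal anatomical frames for the thorax,
#' throwing humerus, forearm and hand following the International Society of
#' Biomechanics shoulder/elbow recommendations, adapted to the landmark set
#' digitized here. In every local frame y points proximally (up the
#' segment), x anteriorly, z laterally (to the right of a right-handed
#' thrower); columns of each rotation are the local axes in world
#' coordinates. Left-handed recordings are mirrored to right-handed form
#' before frame construction (see [mirror_world_z()]), so one convention
#' serves both.
#'
#' Frame definitions:
#' \describe{
#'   \item{torso}{origin at the suprasternal notch; y from T8 toward the
#'     midpoint of C7 and the notch; x anterior, in the plane of the notch
#'     and the spine landmarks.}
#'   \item{humerus}{origin at the GH centre; y from the epicondyle midpoint
#'     (elbow centre) to the GH centre; z lateral via the epicondyle axis.}
#'   \item{forearm}{origin at the elbow centre; y from the styloid midpoint
#'     to the elbow centre; z lateral via the styloid axis.}
#'   \item{hand}{no hand sensor exists, so the hand rides rigidly on the
#'     forearm: origin at the styloid midpoint, orientation equal to the
#'     forearm frame.}
#' }
#'
#' @param landmarks named list of n x 3 world landmark series, as returned
#'   by [landmarks_to_global()].
#' @param gh_world n x 3 world trajectory of the GH centre, from
#'   [estimate_gh_center()] + its torso-frame re-expression.
#' @return object of class `segment_frames`: list of segments, each with
#'   `origin` (n x 3) and `R` (3 x 3 x n rotation, local-to-world), plus
#'   `n_frames`.
#' @export
build_segment_frames <- function(landmarks, gh_world) {
  need <- required_landmarks()
  missing <- setdiff(need, names(landmarks))
  if (length(missing)) stop("missing landmarks: ", paste(missing, collapse = ", "))
  n <- nrow(landmarks[[need[1]]])
  stopifnot(nrow(gh_world) == n)

  ij <- landmarks$suprasternal_notch; c7 <- landmarks$c7; t8 <- landmarks$t8
  em <- landmarks$epicondyle_medial; el <- landmarks$epicondyle_lateral
  rs <- landmarks$styloid_radial; us <- landmarks$styloid_ulnar
  elbow <- (em + el) / 2
  wrist <- (rs + us) / 2

  torso <- list(origin = ij, R = array(0, c(3, 3, n)))
  humerus <- list(origin = gh_world, R = array(0, c(3, 3, n)))
  forearm <- list(origin = elbow, R = array(0, c(3, 3, n)))
  hand <- list(origin = wrist, R = array(0, c(3, 3, n)))

  for (k in seq_len(n)) {
    # thorax
    y <- unit_or_stop((ij[k, ] + c7[k, ]) / 2 - t8[k, ], "torso (spine landmarks coincide)")
    d <- ij[k, ] - c7[k, ]
    x <- d - sum(d * y) * y
    x <- unit_or_stop(x, "torso (suprasternal notch collinear with spine)")
    torso$R[, , k] <- cbind(x, y, cross3(x, y))
    # humerus
    yh <- unit_or_stop(gh_world[k, ] - elbow[k, ], "humerus (GH centre coincides with elbow)")
    zt <- el[k, ] - em[k, ]
    xh <- cross3(yh, zt)
    xh <- unit_or_stop(xh, "humerus (epicondyle axis collinear with long axis)")
    humerus$R[, , k] <- cbind(xh, yh, cross3(xh, yh))
    # forearm
    yf <- unit_or_stop(elbow[k, ] - wrist[k, ], "forearm (elbow coincides with wrist)")
    zf <- rs[k, ] - us[k, ]
    xf <- cross3(yf, zf)
    xf <- unit_or_stop(xf, "forearm (styloid axis collinear with long axis)")
    forearm$R[, , k] <- cbind(xf, yf, cross3(xf, yf))
    hand$R[, , k] <- forearm$R[, , k]
  }
  structure(list(torso = torso, humerus = humerus, forearm = forearm,
                 hand = hand, n_frames = n),
            class = "segment_frames")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit_or_stop <- function(v, what) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-10) stop("degenerate landmark geometry for segment ", what)
  v / nv
}

#' @export
print.segment_frames <- function(x, ...) {
  cat("Anatomical segment frames:", x$n_frames, "frames;",
      "segments:", paste(setdiff(names(x), "n_frames"), collapse = ", "), "\n")
  invisible(x)
}
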