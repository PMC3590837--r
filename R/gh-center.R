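#' Estimate the glenohumeral rotation centre by least-squares pivot fitting
#'
#' The GH centre cannot be palpated, so it is estimated functionally as the
#' point that moves least during short rotational movements of the humerus
#' relative to the torso. Expressing the humerus-sensor pose in the
#' torso-sensor frame as `(R_k, t_k)`, the pivot satisfies
#' `R_k p + t_k = c` for all frames, where `p` is the pivot in the
#' humerus-sensor frame and `c` its (fixed) position in the torso-sensor
#' frame. Stacking all frames gives an overdetermined linear system in
#' `(p, c)` solved in closed form by QR least squares — the classic
#' functional joint-centre (pivot / SCoRE-type) fit.
#'
#' Motion about a single axis (or pure translation) leaves the pivot
#' undetermined along that axis; such inputs are flagged `ill_conditioned`
#' via the condition number of the stacked design matrix, and the (pseudo)
#' solution is still returned with a warning.
#'
#' @param humerus_pos,humerus_quat n x 3 / n x 4 humerus-sensor pose (world).
#' @param torso_pos,torso_quat n x 3 / n x 4 torso-sensor pose (world).
#' @param cond_tol condition-number threshold for the ill-conditioning flag.
#' @return list with `center_torso` (pivot in torso-sensor frame, m),
#'   `center_humerus` (pivot in humerus-sensor frame, m), `rms_m` (residual
#'   root-mean-square distance of the pivot trajectory from its mean, m),
#'   `condition` (design condition number), `ill_conditioned` (logical).
#' @export
estimate_gh_center <- function(humerus_pos, humerus_quat, torso_pos, torso_quat,
                               cond_tol = 1e4) {
  n <- nrow(humerus_pos)
  stopifnot(nrow(humerus_quat) == n, nrow(torso_pos) == n, nrow(torso_quat) == n)
  if (n < 50L) stop("pivot fit needs at least 50 frames of rotational movement")
  # humerus pose expressed in the torso-sensor frame
  A <- matrix(0, 3L * n, 6L)
  rhs <- numeric(3L * n)
  I3 <- diag(3)
  for (k in seq_len(n)) {
    Rt <- quat_to_rot(torso_quat[k, ])
    Rh <- quat_to_rot(humerus_quat[k, ])
    Rk <- crossprod(Rt, Rh)                      # t(Rt) %*% Rh
    tk <- crossprod(Rt, humerus_pos[k, ] - torso_pos[k, ])
    i <- (3L * (k - 1L) + 1L):(3L * k)
    A[i, 1:3] <- Rk
    A[i, 4:6] <- -I3
    rhs[i] <- -tk
  }
  qr_fit <- qr(A)
  sol <- qr.coef(qr_fit, rhs)
  sv <- svd(A, nu = 0, nv = 0)$d
  condition <- sv[1] / max(sv[length(sv)], .Machine$double.eps)
  ill <- !is.finite(condition) || condition > cond_tol
  if (ill) warning("pivot fit is ill-conditioned (condition number ",
                   format(condition, digits = 3),
                   "): motion spans too few rotation axes")
  p <- sol[1:3]
  c0 <- sol[4:6]
  # residual: spread of the humerus-frame pivot trajectory in torso frame
  traj <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    Rt <- quat_to_rot(torso_quat[k, ])
    Rh <- quat_to_rot(humerus_quat[k, ])
    traj[k, ] <- crossprod(Rt, Rh %*% p + humerus_pos[k, ] - torso_pos[k, ])
  }
  rms <- sqrt(mean(rowSums(sweep(traj, 2, colMeans(traj))^2)))
  list(center_torso = unname(c0), center_humerus = unname(p),
       rms_m = rms, condition = condition, ill_conditioned = ill)
}

# re-express a torso-sensor-frame point in world coordinates per frame
gh_center_world <- function(recording, torso_label, center_torso) {
  s <- recording$sensors[[torso_label]]
  if (is.null(s)) stop("sensor '", torso_label, "' not in recording")
  n <- nrow(s$pos)
  out <- matrix(0, n, 3)
  for (k in seq_len(n)) out[k, ] <- s$pos[k, ] + quat_to_rot(s$quat[k, ]) %*% center_torso
  out
}
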