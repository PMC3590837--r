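# Inverse dynamics over the four-link torso-arm chain. The torso serves as
# the (kinematic) base; the humerus, forearm and hand carry inertia, with
# the ball riding in the hand until ball release. All forces are in Newtons
# in the world frame unless resolved into anatomical components.

gravity_vec <- function() c(0, 0, -GRAVITY)

#' Segment centre-of-mass and angular kinematics for the arm chain
#'
#' Computes per-frame COM position, velocity and acceleration for the
#' humerus, forearm, hand and ball from anatomical frames and the scaled
#' segment model, together with segment angular velocity/acceleration.
#' COM positions lie on each segment's long axis at the published fraction
#' of segment length from the proximal end; the hand extends distally from
#' the styloid midpoint along the forearm axis, and the ball sits at the
#' hand's distal end. Differentiation is 2nd-order central with one-sided
#' ends.
#'
#' @param frames a `segment_frames` object.
#' @param model a `segment_model` from [scale_segment_parameters()].
#' @param fs frame rate, Hz.
#' @return list of per-body kinematics (`humerus`, `forearm`, `hand`,
#'   `ball`), each with `pos`, `vel`, `acc` (n x 3) and, for the segments,
#'   `R`, `omega`, `alpha`; plus `fs` and `n_frames`.
#' @export
segment_com_kinematics <- function(frames, model, fs) {
  stopifnot(inherits(frames, "segment_frames"), inherits(model, "segment_model"))
  n <- frames$n_frames
  gh <- frames$humerus$origin
  elbow <- frames$forearm$origin
  wrist <- frames$hand$origin

  hum <- segment_row(model, "humerus")
  fore <- segment_row(model, "forearm")
  hand <- segment_row(model, "hand")

  com_hum <- gh + hum$com_fraction * (elbow - gh)
  com_fore <- elbow + fore$com_fraction * (wrist - elbow)
  u_dist <- wrist - elbow
  u_dist <- u_dist / sqrt(rowSums(u_dist^2))
  hand_tip <- wrist + hand$length_m * u_dist
  com_hand <- wrist + hand$com_fraction * (hand_tip - wrist)
  ball_pos <- hand_tip

  ang <- angular_kinematics(frames, fs)
  body <- function(pos, seg = NULL) {
    out <- list(pos = pos, vel = central_diff(pos, fs), acc = central_diff2(pos, fs))
    if (!is.null(seg)) {
      out$R <- frames[[seg]]$R
      out$omega <- ang[[seg]]$omega
      out$alpha <- ang[[seg]]$alpha
    }
    out
  }
  list(humerus = body(com_hum, "humerus"),
       forearm = body(com_fore, "forearm"),
       hand = body(com_hand, "hand"),
       ball = body(ball_pos),
       joints = list(shoulder = gh, elbow = elbow, wrist = wrist),
       fs = fs, n_frames = n)
}

#' Recursive Newton-Euler inverse dynamics of the arm chain
#'
#' Outward-in recursion from the hand: the net joint-reaction force at each
#' joint is the sum of `m (a_COM - g)` over all bodies distal to it, with
#' the ball's mass included while it is carried (frames up to and including
#' ball release). The force returned at the shoulder is the force applied
#' by the torso to the proximal humerus. Joint moments are computed from
#' the segment Euler equations (inertia diagonal in the segment principal
#' frame from the radii of gyration) and returned alongside, but the force
#' is the quantity of interest here.
#'
#' @param kin segment kinematics from [segment_com_kinematics()] (or the
#'   analytic equivalent supplied by the synthetic-data generator).
#' @param model a `segment_model`.
#' @param events a `pitch_events` object (or a list with `br`); the ball is
#'   carried for frames `<= events$br`.
#' @return object of class `joint_kinetics`: list with `shoulder`, `elbow`,
#'   `wrist` force matrices (n x 3, world, N) and `moment_shoulder`,
#'   `moment_elbow`, `moment_wrist` (n x 3, N m).
#' @export
newton_euler_chain <- function(kin, model, events) {
  stopifnot(inherits(model, "segment_model"))
  need <- c("humerus", "forearm", "hand", "ball")
  missing <- setdiff(need, names(kin))
  if (length(missing)) stop("segment kinematics missing: ", paste(missing, collapse = ", "))
  n <- kin$n_frames
  br <- if (is.null(events$br)) n else events$br
  for (b in need) {
    bad <- which(!is.finite(rowSums(kin[[b]]$acc)))
    if (length(bad)) stop("non-finite kinematics for ", b, " at frame ", bad[1])
  }
  g <- gravity_vec()
  m_h <- segment_mass(model, "hand")
  m_f <- segment_mass(model, "forearm")
  m_u <- segment_mass(model, "humerus")
  m_b <- model$ball_mass_kg
  carried <- as.numeric(seq_len(n) <= br)

  net <- function(body, m) m * sweep(kin[[body]]$acc, 2, g)
  f_ball <- net("ball", m_b) * carried
  F_wrist <- net("hand", m_h) + f_ball
  F_elbow <- F_wrist + net("forearm", m_f)
  F_shoulder <- F_elbow + net("humerus", m_u)

  # moments about each joint centre (Euler equations + transport terms)
  mom <- function(joint, bodies, masses) {
    p <- kin$joints[[joint]]
    M <- matrix(0, n, 3)
    for (i in seq_along(bodies)) {
      b <- bodies[i]; m <- masses[i]
      fi <- net(b, m)
      if (b == "ball") fi <- fi * carried
      r <- kin[[b]]$pos - p
      M <- M + t(vapply(seq_len(n), function(k) cross3(r[k, ], fi[k, ]), numeric(3)))
      if (!is.null(kin[[b]]$R)) {
        seg <- segment_row(model, b)
        Iloc <- m * diag(c(seg$rg_sagittal_m^2, seg$rg_longitudinal_m^2, seg$rg_transverse_m^2))
        for (k in seq_len(n)) {
          Rk <- kin[[b]]$R[, , k]
          Iw <- Rk %*% Iloc %*% t(Rk)
          w <- kin[[b]]$omega[k, ]
          M[k, ] <- M[k, ] + Iw %*% kin[[b]]$alpha[k, ] + cross3(w, Iw %*% w)
        }
      }
    }
    M
  }
  structure(list(
    shoulder = F_shoulder, elbow = F_elbow, wrist = F_wrist,
    moment_wrist = mom("wrist", c("hand", "ball"), c(m_h, m_b)),
    moment_elbow = mom("elbow", c("hand", "ball", "forearm"), c(m_h, m_b, m_f)),
    moment_shoulder = mom("shoulder", c("hand", "ball", "forearm", "humerus"),
                          c(m_h, m_b, m_f, m_u)),
    br = br, n_frames = n
  ), class = "joint_kinetics")
}

#' Shoulder force by direct momentum differentiation (oracle)
#'
#' Independent cross-check of the Newton-Euler recursion: the shoulder
#' joint-reaction force equals the time derivative of the distal chain's
#' total linear momentum minus its weight,
#' `F = d/dt(sum m_i v_i) - sum m_i g`, computed directly from the segment
#' COM trajectories with no recursion. With piecewise-constant masses (the
#' ball leaves at release) this is `sum m_i (a_i - g)` evaluated framewise.
#' If velocities/accelerations are absent they are obtained by central
#' differences of the positions.
#'
#' @param kin list of per-body kinematics as in [newton_euler_chain()]
#'   (needs `humerus`, `forearm`, `hand`, `ball`).
#' @param model a `segment_model`.
#' @param br ball-release frame; the ball's momentum counts for frames
#'   `<= br`.
#' @return n x 3 matrix of shoulder force (N, world).
#' @export
momentum_oracle <- function(kin, model, br = NULL) {
  stopifnot(inherits(model, "segment_model"))
  need <- c("humerus", "forearm", "hand", "ball")
  missing <- setdiff(need, names(kin))
  if (length(missing)) stop("segment kinematics missing: ", paste(missing, collapse = ", "))
  n <- kin$n_frames
  if (is.null(br)) br <- n
  g <- gravity_vec()
  masses <- c(humerus = segment_mass(model, "humerus"),
              forearm = segment_mass(model, "forearm"),
              hand = segment_mass(model, "hand"),
              ball = model$ball_mass_kg)
  F <- matrix(0, n, 3)
  for (b in need) {
    acc <- kin[[b]]$acc
    if (is.null(acc)) acc <- central_diff2(kin[[b]]$pos, kin$fs)
    contrib <- masses[[b]] * sweep(acc, 2, g)
    if (b == "ball") contrib <- contrib * as.numeric(seq_len(n) <= br)
    F <- F + contrib
  }
  F
}

#' Resolve the shoulder force into anatomical components
#'
#' Projects the world-frame shoulder force onto the humerus anatomical
#' axes: anterior along the humeral x axis (positive anteriorly), proximal
#' along the humeral long axis y (positive toward the GH centre, i.e.
#' resisting distraction), and superior along the remaining axis z (which
#' points roughly superiorly with the arm abducted in the delivery). The
#' three components reconstruct the vector exactly, so their squared sum
#' equals the squared force norm.
#'
#' @param force n x 3 world force (N).
#' @param humerus_R 3 x 3 x n humerus rotation array (local-to-world).
#' @return n x 3 matrix with columns `anterior`, `superior`, `proximal` (N).
#' @export
resolve_shoulder_components <- function(force, humerus_R) {
  n <- nrow(force)
  stopifnot(dim(humerus_R)[3] == n)
  out <- matrix(0, n, 3, dimnames = list(NULL, c("anterior", "superior", "proximal")))
  for (k in seq_len(n)) {
    R <- humerus_R[, , k]
    if (!is_rotation(R, tol = 1e-6)) stop("humerus frame at frame ", k, " is not orthonormal")
    local <- crossprod(R, force[k, ])
    out[k, ] <- c(local[1], local[3], local[2])
  }
  out
}

#' Normalize a force to percent bodyweight
#'
#' `%BW = 100 * F / (m * g)` with `g = 9.81` m/s^2 exactly.
#'
#' @param force_n force (N); vector or matrix.
#' @param mass_kg body mass, kg (> 0).
#' @return same shape as `force_n`, in percent bodyweight.
#' @export
normalize_percent_bw <- function(force_n, mass_kg) {
  if (!is.numeric(mass_kg) || length(mass_kg) != 1L || !is.finite(mass_kg) || mass_kg <= 0)
    stop("mass_kg must be a single positive number")
  100 * force_n / (mass_kg * GRAVITY)
}

#' Assemble the per-frame shoulder kinetics series
#'
#' @param force n x 3 world shoulder force (N).
#' @param humerus_R humerus rotations as in [resolve_shoulder_components()].
#' @param mass_kg body mass for percent-bodyweight normalization.
#' @param fs frame rate, Hz.
#' @return object of class `shoulder_kinetics`: data.frame with columns
#'   `frame`, `time_s`, `fx`, `fy`, `fz`, `anterior_n`, `superior_n`,
#'   `proximal_n` and their `_pctbw` counterparts.
#' @export
shoulder_kinetics_series <- function(force, humerus_R, mass_kg, fs) {
  comp <- resolve_shoulder_components(force, humerus_R)
  n <- nrow(force)
  df <- data.frame(
    frame = seq_len(n), time_s = (seq_len(n) - 1) / fs,
    fx = force[, 1], fy = force[, 2], fz = force[, 3],
    anterior_n = comp[, "anterior"], superior_n = comp[, "superior"],
    proximal_n = comp[, "proximal"]
  )
  for (cc in c("anterior", "superior", "proximal"))
    df[[paste0(cc, "_pctbw")]] <- normalize_percent_bw(df[[paste0(cc, "_n")]], mass_kg)
  attr(df, "mass_kg") <- mass_kg
  attr(df, "fs") <- fs
  class(df) <- c("shoulder_kinetics", "data.frame")
  df
}

#' Extract peak anterior and proximal shoulder forces
#'
#' PAF is the maximum anterior component over the arm-cocking phase
#' `[SFC, MER]`; PPF the maximum proximal component over arm acceleration
#' `[MER, BR]`. Ties break to the earliest frame.
#'
#' @param series a `shoulder_kinetics` data.frame.
#' @param events a `pitch_events` object (frame indices `sfc < mer < br`).
#' @return object of class `peak_kinetics`: list with `paf_n`, `paf_pctbw`,
#'   `paf_frame`, `ppf_n`, `ppf_pctbw`, `ppf_frame`, `events`.
#' @export
extract_peak_kinetics <- function(series, events) {
  stopifnot(inherits(series, "shoulder_kinetics"))
  n <- nrow(series)
  sfc <- events$sfc; mer <- events$mer; br <- events$br
  if (!(sfc >= 1 && br <= n)) stop("event frames outside the recording")
  if (!(sfc < mer)) stop("empty arm-cocking window: SFC (", sfc, ") must precede MER (", mer, ")")
  if (!(mer < br)) stop("empty arm-acceleration window: MER (", mer, ") must precede BR (", br, ")")
  cock <- sfc:mer
  acc <- mer:br
  ia <- cock[which.max(series$anterior_n[cock])]
  ip <- acc[which.max(series$proximal_n[acc])]
  structure(list(
    paf_n = series$anterior_n[ia], paf_pctbw = series$anterior_pctbw[ia], paf_frame = ia,
    ppf_n = series$proximal_n[ip], ppf_pctbw = series$proximal_pctbw[ip], ppf_frame = ip,
    events = list(sfc = sfc, mer = mer, br = br)
  ), class = "peak_kinetics")
}

#' @export
print.peak_kinetics <- function(x, ...) {
  cat(sprintf("Peak shoulder kinetics:\n  PAF = %.2f N (%.1f %%BW) at frame %d [cocking %d-%d]\n  PPF = %.2f N (%.1f %%BW) at frame %d [acceleration %d-%d]\n",
              x$paf_n, x$paf_pctbw, x$paf_frame, x$events$sfc, x$events$mer,
              x$ppf_n, x$ppf_pctbw, x$ppf_frame, x$events$mer, x$events$br))
  invisible(x)
}

#' Compare estimated shoulder kinetics against ground truth
#'
#' Summarizes the relative difference between an estimated kinetics series
#' and the generator's ground truth: the relative error of each peak (PAF,
#' PPF, each against the true peak within the true phase windows) and the
#' mean framewise component error over `[SFC, BR]` scaled by the true peak
#' magnitude of each component.
#'
#' @param series estimated `shoulder_kinetics`.
#' @param truth a `ground_truth` object from [generate_pitch_motion()].
#' @return list with `paf_pct`, `ppf_pct`, `peak_mean_pct`, `mean_pct` (all
#'   percentages).
#' @export
validate_kinetics <- function(series, truth) {
  stopifnot(inherits(series, "shoulder_kinetics"))
  n <- nrow(series)
  if (length(truth$anterior_n) != n)
    stop("length mismatch: estimate has ", n, " frames, truth ", length(truth$anterior_n))
  ev <- truth$events
  cock <- ev$sfc:ev$mer
  accw <- ev$mer:ev$br
  paf_t <- max(truth$anterior_n[cock])
  ppf_t <- max(truth$proximal_n[accw])
  paf_e <- max(series$anterior_n[cock])
  ppf_e <- max(series$proximal_n[accw])
  paf_pct <- 100 * abs(paf_e - paf_t) / abs(paf_t)
  ppf_pct <- 100 * abs(ppf_e - ppf_t) / abs(ppf_t)
  span <- ev$sfc:ev$br
  mean_pct <- 100 * mean(c(
    abs(series$anterior_n[span] - truth$anterior_n[span]) / max(abs(truth$anterior_n[span])),
    abs(series$proximal_n[span] - truth$proximal_n[span]) / max(abs(truth$proximal_n[span]))
  ))
  list(paf_pct = paf_pct, ppf_pct = ppf_pct,
       peak_mean_pct = (paf_pct + ppf_pct) / 2, mean_pct = mean_pct)
}

#' Plot a shoulder-kinetics series
#'
#' Base-graphics plot of the anterior, superior and proximal force
#' components against time, with optional event markers.
#'
#' @param x a `shoulder_kinetics` object.
#' @param events optional `pitch_events` to mark SFC/MER/BR.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.shoulder_kinetics <- function(x, events = NULL, ...) {
  graphics::matplot(x$time_s, cbind(x$anterior_n, x$superior_n, x$proximal_n),
                    type = "l", lty = 1, col = c(2, 3, 4),
                    xlab = "time (s)", ylab = "shoulder force (N)", ...)
  graphics::legend("topleft", c("anterior", "superior", "proximal"),
                   col = c(2, 3, 4), lty = 1, bty = "n")
  if (!is.null(events)) {
    graphics::abline(v = x$time_s[c(events$sfc, events$mer, events$br)], lty = 3)
    graphics::mtext(c("SFC", "MER", "BR"), side = 3,
                    at = x$time_s[c(events$sfc, events$mer, events$br)], cex = 0.8)
  }
  invisible(x)
}
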