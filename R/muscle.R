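# Hill-type muscle model: contractile element with force-length and
# force-velocity relationships, parallel damping and passive-elastic
# elements, linear muscle-joint geometry with constant moment arms, and a
# surrogate metabolic-rate model.

#' Force-length relationship of the contractile element
#'
#' \deqn{k(\xi) = 0.32 + 0.71 e^{-1.112(\xi - 1)} \sin(3.722(\xi - 0.656))}
#' with \eqn{\xi = L / \bar L} the normalized muscle length.
#'
#' @param xi Normalized length (> 0).
#' @return Dimensionless force scale.
#' @export
#' @examples
#' force_length(1)      # ~ 1.0001
#' force_length(0.656)  # sine term vanishes: 0.32
force_length <- function(xi) {
  0.32 + 0.71 * exp(-1.112 * (xi - 1.0)) * sin(3.722 * (xi - 0.656))
}

#' Force-velocity relationship of the contractile element
#'
#' \deqn{h(\eta) = 1 + \tanh(3 \eta)} with \eqn{\eta = \dot L / \bar{\dot L}}
#' the normalized contraction velocity, positive while lengthening, so the
#' eccentric branch exceeds 1. Range (0, 2).
#'
#' @param eta Normalized velocity.
#' @return Dimensionless force scale.
#' @export
force_velocity <- function(eta) 1 + tanh(3.0 * eta)

#' Muscle tension
#'
#' \deqn{F = \bar F^{CE} k(\xi) h(\eta) \alpha + c^{PD} \dot L +
#'   k^{PE} (e^{15 (L - \bar L)} - 1)}
#'
#' The raw value is returned; the tendon force applied to the skeleton is
#' clamped at zero separately (muscles cannot push; see
#' [applied_tension()]).
#'
#' @param muscle One row of the muscle table (list or data.frame row) with
#'   `f_max`, `l_opt`, `v_max`, `c_pd`, `k_pe`.
#' @param L,Ldot Muscle length and lengthening velocity (m, m/s).
#' @param alpha Activation in \[0, 1\].
#' @return Tension (N), unclamped.
#' @export
muscle_tension <- function(muscle, L, Ldot, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  xi <- L / muscle$l_opt
  eta <- Ldot / muscle$v_max
  muscle$f_max * force_length(xi) * force_velocity(eta) * alpha +
    muscle$c_pd * Ldot +
    muscle$k_pe * (exp(15 * (L - muscle$l_opt)) - 1.0)
}

#' @rdname muscle_tension
#' @export
applied_tension <- function(muscle, L, Ldot, alpha) {
  max(0, muscle_tension(muscle, L, Ldot, alpha))
}

#' Muscle lengths, velocities and moment arms from body state
#'
#' Linear muscle-joint geometry: each muscle length is its optimal length
#' plus the signed moment arm times the joint excursion from the standing
#' reference, summed over spanned joints. The torque contribution of a
#' tension F about joint j is \eqn{-F r_j} (virtual work with
#' \eqn{dL/d\theta_j = r_j}).
#'
#' @param q,qd Generalized coordinates/velocities (length 9).
#' @param config A `fogsim_config`.
#' @return List with 18-vectors `L`, `Ldot` and an 18 x 6 moment-arm
#'   matrix `R` (columns hip_l, knee_l, ankle_l, hip_r, knee_r, ankle_r);
#'   muscle order is the 9 left-side muscles then the 9 right-side ones.
#' @export
muscle_kinematics <- function(q, qd, config = default_parameters()) {
  if (any(!is.finite(c(q, qd)))) stop("muscle_kinematics: non-finite input")
  mt <- config$muscles; ps <- config$posture
  ja <- joint_angles(q); jv <- joint_velocities(qd)
  ref <- c(ps$hip_ref, ps$knee_ref, ps$ankle_ref)
  R <- matrix(0, 18, 6)
  L <- numeric(18); Ldot <- numeric(18)
  for (side in 0:1) {
    jcols <- 1:3 + 3 * side
    rows <- 1:9 + 9 * side
    arms <- as.matrix(mt[, c("r_hip", "r_knee", "r_ankle")])
    R[rows, jcols] <- arms
    exc <- as.numeric(ja[jcols]) - ref
    L[rows] <- mt$l_opt + as.numeric(arms %*% exc)
    Ldot[rows] <- as.numeric(arms %*% as.numeric(jv[jcols]))
  }
  list(L = L, Ldot = Ldot, R = R,
       names = c(paste0(mt$name, "_l"), paste0(mt$name, "_r")))
}

#' Instantaneous metabolic rate of one muscle
#'
#' Surrogate energetics model: a basal term plus activation-dependent
#' maintenance and shortening terms, scaled by the muscle's force and
#' velocity capacity so the rate doubles when the maximum isometric
#' tension doubles at identical normalized state:
#' \deqn{\dot E = \bar F^{CE} \bar{\dot L} (c_0 + c_1 \alpha +
#'   c_2 \alpha \max(0, -\eta))}
#' Nonnegative and nondecreasing in activation by construction; used only
#' inside the cost of transport.
#'
#' @param muscle One row of the muscle table.
#' @param alpha Activation in \[0, 1\].
#' @param eta Normalized velocity (positive lengthening).
#' @param metabolic Constants list (`default_parameters()$metabolic`).
#' @return Rate (W), >= 0.
#' @export
metabolic_rate <- function(muscle, alpha, eta,
                           metabolic = default_parameters()$metabolic) {
  muscle$f_max * muscle$v_max *
    (metabolic$c0 + metabolic$c1 * alpha +
       metabolic$c2 * alpha * max(0, -eta))
}
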