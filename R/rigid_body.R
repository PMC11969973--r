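# Planar rigid-body dynamics of the 7-link chain (HAT, thighs, shanks, feet).
#
# Generalized coordinates q (9): hip position (x, y), then segment angles
# hat, thigh_L, shank_L, foot_L, thigh_R, shank_R, foot_R. Leg segment
# angles are measured counterclockwise from the vertical (down direction
# for the legs, up for the HAT); foot angles counterclockwise from the
# horizontal heel->toe axis. Joint angles: hip = thigh - hat,
# knee = shank - thigh, ankle = foot - shank.

# direction helpers: e() points proximal->distal for hanging segments,
# u() points hip->head for the HAT
.seg_e  <- function(th) c(sin(th), -cos(th))
.seg_ep <- function(th) c(cos(th), sin(th))
.hat_u  <- function(th) c(-sin(th), cos(th))
.hat_up <- function(th) c(-cos(th), -sin(th))
.rot    <- function(th, v) c(cos(th) * v[1] - sin(th) * v[2],
                             sin(th) * v[1] + cos(th) * v[2])
.rotp   <- function(th, v) c(-sin(th) * v[1] - cos(th) * v[2],
                             cos(th) * v[1] - sin(th) * v[2])

#' Derived joint angles of a coordinate vector
#'
#' @param q Generalized coordinates (length 9).
#' @return Named vector: hip/knee/ankle for each side (rad).
#' @export
joint_angles <- function(q) {
  c(hip_l = q[4] - q[3], knee_l = q[5] - q[4], ankle_l = q[6] - q[5],
    hip_r = q[7] - q[3], knee_r = q[8] - q[7], ankle_r = q[9] - q[8])
}

# Full kinematics: joint/contact/com positions, Jacobians and velocity-
# product (bias) accelerations for each of the 7 bodies and 4 contact points.
body_kinematics <- function(q, qd, body) {
  sg <- body$segments; fg <- body$foot_geom
  hip <- q[1:2]; vhip <- qd[1:2]
  out <- list()
  # bodies: list(name, m, I, idx_angle, pos, J (2x9), bias (2))
  J0 <- matrix(0, 2, 9); J0[1, 1] <- 1; J0[2, 2] <- 1

  mk_hat <- function() {
    J <- J0; th <- q[3]
    pos <- hip + sg$hat$com * .hat_u(th)
    J[, 3] <- sg$hat$com * .hat_up(th)
    bias <- -sg$hat$com * .hat_u(th) * qd[3]^2
    list(name = "hat", m = sg$hat$mass, I = sg$hat$inertia, ia = 3L,
         pos = pos, J = J, bias = bias)
  }
  mk_leg <- function(it, is, if_) {
    tht <- q[it]; ths <- q[is]; thf <- q[if_]
    knee  <- hip + sg$thigh$length * .seg_e(tht)
    ankle <- knee + sg$shank$length * .seg_e(ths)
    thigh_com <- hip + sg$thigh$com * .seg_e(tht)
    shank_com <- knee + sg$shank$com * .seg_e(ths)
    foot_com  <- ankle + .rot(thf, c(fg$com_x, -fg$com_y))
    Jt <- J0; Jt[, it] <- sg$thigh$com * .seg_ep(tht)
    Js <- J0; Js[, it] <- sg$thigh$length * .seg_ep(tht)
    Js[, is] <- sg$shank$com * .seg_ep(ths)
    Jf <- J0; Jf[, it] <- sg$thigh$length * .seg_ep(tht)
    Jf[, is] <- sg$shank$length * .seg_ep(ths)
    Jf[, if_] <- .rotp(thf, c(fg$com_x, -fg$com_y))
    bt <- -sg$thigh$com * .seg_e(tht) * qd[it]^2
    bs <- -sg$thigh$length * .seg_e(tht) * qd[it]^2 -
      sg$shank$com * .seg_e(ths) * qd[is]^2
    bf <- -sg$thigh$length * .seg_e(tht) * qd[it]^2 -
      sg$shank$length * .seg_e(ths) * qd[is]^2 -
      .rot(thf, c(fg$com_x, -fg$com_y)) * qd[if_]^2
    # contact points
    mk_pt <- function(local) {
      Jp <- J0; Jp[, it] <- sg$thigh$length * .seg_ep(tht)
      Jp[, is] <- sg$shank$length * .seg_ep(ths)
      Jp[, if_] <- .rotp(thf, local)
      list(pos = ankle + .rot(thf, local), J = Jp,
           vel = as.numeric(Jp %*% qd))
    }
    heel <- mk_pt(c(-fg$heel_back, -fg$ankle_height))
    toe  <- mk_pt(c(fg$toe_front, -fg$ankle_height))
    list(
      thigh = list(m = sg$thigh$mass, I = sg$thigh$inertia, ia = it,
                   pos = thigh_com, J = Jt, bias = bt),
      shank = list(m = sg$shank$mass, I = sg$shank$inertia, ia = is,
                   pos = shank_com, J = Js, bias = bs),
      foot  = list(m = sg$foot$mass, I = sg$foot$inertia, ia = if_,
                   pos = foot_com, J = Jf, bias = bf),
      knee = knee, ankle = ankle, heel = heel, toe = toe,
      shank_mid = knee + 0.5 * sg$shank$length * .seg_e(ths)
    )
  }
  out$hat <- mk_hat()
  out$left  <- mk_leg(4L, 5L, 6L)
  out$right <- mk_leg(7L, 8L, 9L)
  out
}

#' Joint-limit torque
#'
#' Restoring torque applied when a knee or ankle joint leaves its range of
#' motion: zero inside the range, and a linear elastic + damping torque
#' directed back toward the range outside it. Knee range \eqn{[-2.8, -0.1]}
#' rad with stiffness 2.0e3 N m/rad and damping 3.0e2 N m s/rad; ankle
#' range \eqn{[-1.0, 0.54]} rad with stiffness 2.0e3 and damping 3.0e1.
#'
#' @param angle Joint angle (rad).
#' @param velocity Joint angular velocity (rad/s).
#' @param joint `"knee"` or `"ankle"`.
#' @param body Body parameter list (`default_parameters()$body`).
#' @return Torque (N m).
#' @export
joint_limit_torque <- function(angle, velocity, joint = c("knee", "ankle"),
                               body = default_parameters()$body) {
  joint <- match.arg(joint)
  if (!is.finite(angle) || !is.finite(velocity))
    stop("joint_limit_torque: non-finite input")
  lim <- body$joint_limits[[joint]]
  lo <- lim$range[1]; hi <- lim$range[2]
  if (angle < lo) {
    lim$stiffness * (lo - angle) - lim$damping * velocity
  } else if (angle > hi) {
    -lim$stiffness * (angle - hi) - lim$damping * velocity
  } else 0
}

#' Unilateral spring-damper ground contact force
#'
#' Zero above ground. When the point penetrates, the vertical force is
#' stiffness x penetration + damping x (downward velocity), clamped at
#' zero (the ground cannot pull); the horizontal force is a spring
#' anchored at the touchdown position plus a damper, active only while
#' the vertical force is positive.
#'
#' @param point c(x, y) position of the heel/toe point (m); ground at y = 0.
#' @param velocity c(vx, vy) of the point (m/s).
#' @param anchor_x Horizontal anchor set at touchdown (m); defaults to the
#'   current x (pure damping) when the point was airborne.
#' @param body Body parameter list.
#' @return c(fx, fy) in N.
#' @export
contact_force <- function(point, velocity, anchor_x = point[1],
                          body = default_parameters()$body) {
  if (any(!is.finite(c(point, velocity, anchor_x))))
    stop("contact_force: non-finite input")
  cc <- body$contact
  if (point[2] >= 0) return(c(0, 0))
  fy <- cc$ky * (-point[2]) - cc$cy * velocity[2]
  if (fy <= 0) return(c(0, 0))
  fx <- cc$kx * (anchor_x - point[1]) - cc$cx * velocity[1]
  c(fx, fy)
}

# internal: torques (hip_l, knee_l, ankle_l, hip_r, knee_r, ankle_r) ->
# generalized force on the 9 coordinates
joint_torques_to_generalized <- function(tau) {
  Q <- numeric(9)
  Q[4] <- Q[4] + tau[1]; Q[3] <- Q[3] - tau[1]   # hip L
  Q[5] <- Q[5] + tau[2]; Q[4] <- Q[4] - tau[2]   # knee L
  Q[6] <- Q[6] + tau[3]; Q[5] <- Q[5] - tau[3]   # ankle L
  Q[7] <- Q[7] + tau[4]; Q[3] <- Q[3] - tau[4]   # hip R
  Q[8] <- Q[8] + tau[5]; Q[7] <- Q[7] - tau[5]   # knee R
  Q[9] <- Q[9] + tau[6]; Q[8] <- Q[8] - tau[6]   # ankle R
  Q
}

#' Equations of motion of the 7-link chain
#'
#' Computes generalized accelerations for given coordinates, velocities
#' and per-joint muscle torques, including gravity, joint viscosity,
#' joint-limit torques and ground contact. Lagrangian assembly: mass
#' matrix from the body Jacobians, velocity-product bias from their time
#' derivatives.
#'
#' @param q,qd Generalized coordinates and velocities (length 9).
#' @param muscle_torques Torques (N m) in the order hip_l, knee_l, ankle_l,
#'   hip_r, knee_r, ankle_r. Defaults to all zero.
#' @param body Body parameter list.
#' @param anchors Optional list with `x` (4 anchor positions, heel_l,
#'   toe_l, heel_r, toe_r) and `active` (logical 4) for the horizontal
#'   stick contact; defaults to anchors at the current positions.
#' @param include Named logical list switching force groups on/off
#'   (`gravity`, `viscosity`, `limits`, `contact`); conservation tests
#'   disable subsets.
#' @return List: `qdd` (length 9), `grf` (vertical GRF per limb, N),
#'   `contact_forces` (4 x 2 matrix).
#' @export
equations_of_motion <- function(q, qd, muscle_torques = numeric(6),
                                body = default_parameters()$body,
                                anchors = NULL,
                                include = list(gravity = TRUE,
                                               viscosity = TRUE,
                                               limits = TRUE,
                                               contact = TRUE)) {
  stopifnot(length(q) == 9, length(qd) == 9, length(muscle_torques) == 6)
  if (any(!is.finite(c(q, qd, muscle_torques))))
    stop("equations_of_motion: non-finite input")
  kin <- body_kinematics(q, qd, body)
  bodies <- list(kin$hat, kin$left$thigh, kin$left$shank, kin$left$foot,
                 kin$right$thigh, kin$right$shank, kin$right$foot)
  M <- matrix(0, 9, 9); Cv <- numeric(9); Q <- numeric(9)
  g <- body$gravity
  for (b in bodies) {
    M <- M + b$m * crossprod(b$J)
    M[b$ia, b$ia] <- M[b$ia, b$ia] + b$I
    Cv <- Cv + b$m * as.numeric(t(b$J) %*% b$bias)
    if (isTRUE(include$gravity))
      Q <- Q + as.numeric(t(b$J) %*% c(0, -b$m * g))
  }
  ja <- joint_angles(q); jv <- joint_velocities(qd)
  tau <- muscle_torques
  cf <- matrix(0, 4, 2)
  if (isTRUE(include$viscosity)) {
    bv <- body$joint_viscosity
    tau <- tau - as.numeric(
      bv[c("hip", "knee", "ankle", "hip", "knee", "ankle")] * jv)
  }
  if (isTRUE(include$limits)) {
    tau <- tau + c(0, joint_limit_torque(ja[2], jv[2], "knee", body),
                   joint_limit_torque(ja[3], jv[3], "ankle", body),
                   0, joint_limit_torque(ja[5], jv[5], "knee", body),
                   joint_limit_torque(ja[6], jv[6], "ankle", body))
  }
  if (isTRUE(include$contact)) {
    pts <- list(kin$left$heel, kin$left$toe, kin$right$heel, kin$right$toe)
    for (i in seq_along(pts)) {
      p <- pts[[i]]
      ax <- if (!is.null(anchors) && anchors$active[i]) anchors$x[i] else p$pos[1]
      f <- contact_force(p$pos, p$vel, ax, body)
      cf[i, ] <- f
      if (any(f != 0)) Q <- Q + as.numeric(t(p$J) %*% f)
    }
  }
  Q <- Q + joint_torques_to_generalized(tau)
  qdd <- tryCatch(solve(M, Q - Cv),
                  error = function(e) stop("singular mass matrix"))
  list(qdd = as.numeric(qdd),
       grf = c(left = cf[1, 2] + cf[2, 2], right = cf[3, 2] + cf[4, 2]),
       contact_forces = cf)
}

#' @rdname joint_angles
#' @param qd Generalized velocities (length 9).
#' @export
joint_velocities <- function(qd) {
  c(hip_l = qd[4] - qd[3], knee_l = qd[5] - qd[4], ankle_l = qd[6] - qd[5],
    hip_r = qd[7] - qd[3], knee_r = qd[8] - qd[7], ankle_r = qd[9] - qd[8])
}

#' Total mechanical energy of the chain
#'
#' Kinetic plus gravitational potential energy; used by the conservation
#' tests of the passive dynamics.
#'
#' @inheritParams equations_of_motion
#' @return Energy (J).
#' @export
mechanical_energy <- function(q, qd, body = default_parameters()$body) {
  kin <- body_kinematics(q, qd, body)
  bodies <- list(kin$hat, kin$left$thigh, kin$left$shank, kin$left$foot,
                 kin$right$thigh, kin$right$shank, kin$right$foot)
  E <- 0
  for (b in bodies) {
    v <- as.numeric(b$J %*% qd)
    E <- E + 0.5 * b$m * sum(v^2) + 0.5 * b$I * qd[b$ia]^2 +
      b$m * body$gravity * b$pos[2]
  }
  E
}

#' Standing posture coordinate vector
#'
#' Builds the initial upright double-support posture from the config:
#' symmetric legs, slight forward HAT lean, knees slightly flexed, feet
#' flat, with the hip height set so the soles just touch the ground.
#'
#' @param config A `fogsim_config`.
#' @return List `q`, `qd` (zeros), `standing_hip_height`.
#' @export
standing_posture <- function(config = default_parameters()) {
  ini <- config$sim$initial; sg <- config$body$segments
  th <- ini$thigh; sh <- th + ini$knee
  y <- sg$thigh$length * cos(th) + sg$shank$length * cos(sh) +
    config$body$foot_geom$ankle_height
  # pre-settle the contact springs to static equilibrium so the run does
  # not start with a drop transient
  settle <- config$body$total_mass * config$body$gravity /
    (4 * config$body$contact$ky)
  q <- c(0, y - settle, ini$hat, th, sh, ini$foot, th, sh, ini$foot)
  list(q = q, qd = numeric(9), standing_hip_height = y)
}
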