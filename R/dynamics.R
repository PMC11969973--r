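# Assembly of the complete coupled ODE right-hand side: body + muscles +
# MLR + CPG + motoneurons. This R composition is the reference definition
# of the model; the C++ engine used by run_gait() mirrors it exactly and
# is tested against it.

# state vector layout (length 45):
#   1:9   generalized coordinates q
#   10:18 generalized velocities qd
#   19:20 MLR internal states (u_ppn, u_cnf)
#   21:32 CPG internal states u_i
#   33:44 CPG adaptation states v_i
#   45    accumulated metabolic energy (J), integrated as quadrature
STATE_LENGTH <- 45L

#' Initial full state vector
#'
#' Standing posture, zero velocities, MLR at rest, zero accumulated
#' energy. The CPG internal states carry a small fixed left/right
#' asymmetric seed (`config$sim$initial$cpg_seed`): a perfectly
#' symmetric state is a degenerate equilibrium of the bilaterally
#' symmetric dynamics from which alternating gait can never emerge, so
#' the seed plays the role of the infinitesimal fluctuation that picks
#' which leg swings first.
#'
#' @param config A `fogsim_config`.
#' @return Numeric vector of length 45.
#' @export
initial_state <- function(config = default_parameters()) {
  sp <- standing_posture(config)
  eps <- config$sim$initial$cpg_seed
  u <- numeric(12)
  u[1] <- eps   # left hip flexor half-centre leads
  u[8] <- eps   # right hip extensor half-centre
  c(sp$q, sp$qd, 0, 0, u, rep(0, 12), 0)
}

#' Full coupled right-hand side (reference implementation)
#'
#' Evaluates the time derivative of the complete state for the planar
#' body, Hill muscles, MLR, CPG and motoneurons, with the higher-center
#' command active during the first 3 s.
#'
#' @param t Time (s).
#' @param state Full state vector (length 45).
#' @param theta Free-parameter vector (length 49).
#' @param s_ppn,s_cnf Higher-center command intensities.
#' @param anchors List `x` (4), `active` (logical 4) for the horizontal
#'   contact anchors (heel_l, toe_l, heel_r, toe_r).
#' @param config A `fogsim_config`.
#' @return List: `dstate` (length 45), `grf` (2), `alpha` (18),
#'   `tension` (18, applied), `torques` (6, from muscles).
#' @export
full_derivatives <- function(t, state, theta, s_ppn = 1, s_cnf = 1,
                             anchors = NULL, config = default_parameters()) {
  stopifnot(length(state) == STATE_LENGTH)
  th <- split_free_parameters(theta)
  q <- state[1:9]; qd <- state[10:18]
  mlr_state <- state[19:20]
  u <- state[21:32]; v <- state[33:44]

  # neural input pieces need the GRFs: evaluate contact first
  kin <- body_kinematics(q, qd, config$body)
  pts <- list(kin$left$heel, kin$left$toe, kin$right$heel, kin$right$toe)
  cf <- matrix(0, 4, 2)
  for (i in seq_along(pts)) {
    p <- pts[[i]]
    ax <- if (!is.null(anchors) && anchors$active[i]) anchors$x[i] else p$pos[1]
    cf[i, ] <- contact_force(p$pos, p$vel, ax, config$body)
  }
  grf <- c(cf[1, 2] + cf[2, 2], cf[3, 2] + cf[4, 2])

  # neural
  hc <- higher_center_input(t, s_ppn, s_cnf, config$mlr)
  dmlr <- mlr_derivatives(mlr_state, hc, config$mlr)
  feed <- sensory_feedback(q, grf, th$feed, config)
  W <- cpg_weight_matrix(th$cpg)
  dcpg <- cpg_derivatives(u, v, W, th$u0 * mlr_state[2], feed, config$cpg)
  y <- pmax(0, u)
  P <- posture_control(q, qd, grf, th$pos, config)
  alpha <- motoneuron_output(y, P, mlr_state[1], config)

  # muscles
  mk <- muscle_kinematics(q, qd, config)
  mt <- config$muscles
  tension <- numeric(18); edot <- 0
  for (m in 1:18) {
    row <- mt[(m - 1) %% 9 + 1, ]
    tension[m] <- applied_tension(row, mk$L[m], mk$Ldot[m], alpha[m])
    edot <- edot + metabolic_rate(row, alpha[m], mk$Ldot[m] / row$v_max,
                                  config$metabolic)
  }
  torques <- -as.numeric(t(mk$R) %*% tension)

  eom <- equations_of_motion(q, qd, torques, config$body, anchors)
  dstate <- c(qd, eom$qdd, dmlr, dcpg$du, dcpg$dv, edot)
  list(dstate = dstate, grf = grf, alpha = alpha, tension = tension,
       torques = torques)
}

#' One RK4 step of the full system (reference implementation)
#'
#' Contact anchors are held fixed across the four sub-evaluations and
#' updated after the step from the new contact state (stick model:
#' the horizontal spring anchors at touchdown and releases when the
#' vertical force returns to zero).
#'
#' @inheritParams full_derivatives
#' @param dt Step size (s).
#' @return List: `state`, `anchors`, `grf` (evaluated at the step start).
#' @export
rk4_step <- function(t, state, dt, theta, s_ppn = 1, s_cnf = 1,
                     anchors = NULL, config = default_parameters()) {
  if (is.null(anchors)) anchors <- list(x = numeric(4),
                                        active = rep(FALSE, 4))
  f <- function(tt, ss) full_derivatives(tt, ss, theta, s_ppn, s_cnf,
                                         anchors, config)
  k1 <- f(t, state)
  k2 <- f(t + dt / 2, state + dt / 2 * k1$dstate)
  k3 <- f(t + dt / 2, state + dt / 2 * k2$dstate)
  k4 <- f(t + dt, state + dt * k3$dstate)
  new_state <- state + dt / 6 *
    (k1$dstate + 2 * k2$dstate + 2 * k3$dstate + k4$dstate)
  anchors <- update_anchors(new_state, anchors, config)
  list(state = new_state, anchors = anchors, grf = k1$grf)
}

# refresh the stick-contact anchors from the new state
update_anchors <- function(state, anchors, config) {
  q <- state[1:9]; qd <- state[10:18]
  kin <- body_kinematics(q, qd, config$body)
  pts <- list(kin$left$heel, kin$left$toe, kin$right$heel, kin$right$toe)
  for (i in seq_along(pts)) {
    p <- pts[[i]]
    fy <- if (p$pos[2] < 0)
      max(0, config$body$contact$ky * (-p$pos[2]) -
            config$body$contact$cy * p$vel[2]) else 0
    if (fy > 0 && !anchors$active[i]) {
      anchors$active[i] <- TRUE
      anchors$x[i] <- p$pos[1]
    } else if (fy <= 0) {
      anchors$active[i] <- FALSE
    }
  }
  anchors
}
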