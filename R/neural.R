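# Neural control: brainstem MLR model (PPN + CnF rate neurons), 12-unit
# Matsuoka central pattern generator, sensory feedback, posture control,
# and alpha-motoneuron output.
#
# CPG unit order: hipF, hipE, kneeF, kneeE, ankleF, ankleE for the left
# leg (1..6), then the same for the right leg (7..12). "F"/"E" denote the
# flexor and extensor half-centre of each joint oscillator.

#' Higher-center command to the MLR
#'
#' Piecewise-constant external drive: the commanded intensity during the
#' first 3 s of the simulation (boundary included), unit intensity after.
#'
#' @param t Time (s), >= 0.
#' @param s_ppn,s_cnf Commanded intensities during the initial window.
#' @param mlr MLR parameter list (for the switch time).
#' @return c(hc_ppn, hc_cnf).
#' @export
higher_center_input <- function(t, s_ppn, s_cnf,
                                mlr = default_parameters()$mlr) {
  stopifnot(t >= 0)
  if (t <= mlr$switch_time) c(s_ppn, s_cnf)
  else c(mlr$post_switch, mlr$post_switch)
}

#' Time derivatives of the MLR internal states
#'
#' Mutually-coupled rate neurons for the pedunculopontine (PPN) and
#' cuneiform (CnF) nuclei:
#' \deqn{\tau^{PPN} \dot u^{PPN} = -u^{PPN} +
#'   w^{PPN \leftarrow CnF} \max(0, u^{CnF}) - \beta^{PPN} u^{PPN} +
#'   w^{HC} HC^{PPN}(t)} and symmetrically for CnF. The default
#' coefficients are calibrated so the fixed point under unit input is
#' exactly (1, 1).
#'
#' @param state c(u_ppn, u_cnf).
#' @param hc c(hc_ppn, hc_cnf) higher-center inputs.
#' @param mlr MLR parameter list.
#' @return c(du_ppn, du_cnf) (1/s).
#' @export
mlr_derivatives <- function(state, hc, mlr = default_parameters()$mlr) {
  u_ppn <- state[1]; u_cnf <- state[2]
  c((-u_ppn + mlr$w_ppn_cnf * max(0, u_cnf) - mlr$beta_ppn * u_ppn +
       mlr$w_hc * hc[1]) / mlr$tau_ppn,
    (-u_cnf + mlr$w_cnf_ppn * max(0, u_ppn) - mlr$beta_cnf * u_cnf +
       mlr$w_hc * hc[2]) / mlr$tau_cnf)
}

#' Integrate the MLR subsystem alone
#'
#' Fixed-step RK4 on the two-neuron MLR model with a given
#' higher-center command; used for calibration checks, the pulse-response
#' comparison and the drive traces of the sweep.
#'
#' @param s_ppn,s_cnf Commanded intensities (see [higher_center_input()]).
#' @param duration,dt Integration horizon and step (s).
#' @param state0 Initial c(u_ppn, u_cnf).
#' @param hc_fun Optional override `function(t) c(hc_ppn, hc_cnf)`.
#' @param mlr MLR parameter list.
#' @return Data frame with columns t, u_ppn, u_cnf.
#' @export
integrate_mlr <- function(s_ppn = 1, s_cnf = 1, duration = 10, dt = 1e-3,
                          state0 = c(0, 0), hc_fun = NULL,
                          mlr = default_parameters()$mlr) {
  n <- floor(duration / dt)
  out <- matrix(0, n + 1, 3)
  u <- state0
  out[1, ] <- c(0, u)
  hc_at <- if (is.null(hc_fun))
    function(t) higher_center_input(t, s_ppn, s_cnf, mlr) else hc_fun
  for (i in seq_len(n)) {
    t <- (i - 1) * dt
    k1 <- mlr_derivatives(u, hc_at(t), mlr)
    k2 <- mlr_derivatives(u + dt / 2 * k1, hc_at(t + dt / 2), mlr)
    k3 <- mlr_derivatives(u + dt / 2 * k2, hc_at(t + dt / 2), mlr)
    k4 <- mlr_derivatives(u + dt * k3, hc_at(t + dt), mlr)
    u <- u + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1, ] <- c(i * dt, u)
  }
  stats::setNames(as.data.frame(out), c("t", "u_ppn", "u_cnf"))
}

#' Free CPG connection gains expanded to the 12 x 12 weight matrix
#'
#' Nine nonnegative gains parameterize the matrix through the left/right
#' and flexor/extensor symmetry skeleton (all entries inhibitory):
#' within-pair mutual inhibition at hip/knee/ankle (gains 1-3),
#' ipsilateral hipF->kneeE, hipE->kneeF, hipF->ankleE, hipE->ankleF
#' couplings (4-7), and contralateral same-function mutual inhibition of
#' the hip (8) and knee (9) units. Diagonal is zero.
#'
#' @param gains Numeric vector of length 9 (nonnegative).
#' @return 12 x 12 matrix W, entry `W[i, j]` weighting output j into unit i.
#' @export
cpg_weight_matrix <- function(gains) {
  stopifnot(length(gains) == 9)
  W <- matrix(0, 12, 12)
  for (off in c(0, 6)) {
    hf <- 1 + off; he <- 2 + off; kf <- 3 + off; ke <- 4 + off
    af <- 5 + off; ae <- 6 + off
    W[hf, he] <- W[he, hf] <- -gains[1]
    W[kf, ke] <- W[ke, kf] <- -gains[2]
    W[af, ae] <- W[ae, af] <- -gains[3]
    W[ke, hf] <- -gains[4]
    W[kf, he] <- -gains[5]
    W[ae, hf] <- -gains[6]
    W[af, he] <- -gains[7]
  }
  W[1, 7] <- W[7, 1] <- W[2, 8] <- W[8, 2] <- -gains[8]
  W[3, 9] <- W[9, 3] <- W[4, 10] <- W[10, 4] <- -gains[9]
  W
}

#' Time derivatives of the CPG states
#'
#' Matsuoka-form rate units with self-inhibitory adaptation:
#' \deqn{\tau \dot u_i = -u_i + \sum_j W_{ij} y_j - \beta v_i +
#'   u_0 u^{CnF} + Feed_i, \quad \tau' \dot v_i = -v_i + y_i, \quad
#'   y_i = \max(0, u_i).}
#'
#' @param u,v Internal and adaptation states (length 12).
#' @param W 12 x 12 connection matrix (see [cpg_weight_matrix()]).
#' @param drive Scalar external drive `u0 * u_cnf`.
#' @param feed Feedback vector (length 12), zero when feedback is off.
#' @param cpg CPG constant list.
#' @return List `du`, `dv`.
#' @export
cpg_derivatives <- function(u, v, W, drive, feed = numeric(12),
                            cpg = default_parameters()$cpg) {
  y <- pmax(0, u)
  list(du = (-u + as.numeric(W %*% y) - cpg$beta * v + drive + feed) / cpg$tau,
       dv = (-v + y) / cpg$tau_prime)
}

#' Integrate the CPG subsystem alone
#'
#' Fixed-step RK4 with constant CnF drive and feedback off; used for the
#' autonomous limit-cycle and quiescence checks.
#'
#' @param gains Free connection gains (length 9).
#' @param u0 External-input weight.
#' @param u_cnf Constant CnF activity.
#' @param duration,dt Horizon and step (s).
#' @param state0 Optional list `u`, `v` (defaults: small asymmetric seed).
#' @param cpg CPG constant list.
#' @return List: `t`, matrix `y` (samples x 12).
#' @export
integrate_cpg <- function(gains, u0, u_cnf = 1, duration = 10, dt = 1e-3,
                          state0 = NULL, cpg = default_parameters()$cpg) {
  W <- cpg_weight_matrix(gains)
  if (is.null(state0)) {
    u <- rep(c(0.1, -0.1), 6) * rep(c(1, 1, -1, -1, 1, 1), each = 2)
    v <- numeric(12)
  } else {
    u <- state0$u; v <- state0$v
  }
  drive <- u0 * u_cnf
  n <- floor(duration / dt)
  Y <- matrix(0, n + 1, 12)
  Y[1, ] <- pmax(0, u)
  deriv <- function(u, v) cpg_derivatives(u, v, W, drive, numeric(12), cpg)
  for (i in seq_len(n)) {
    k1 <- deriv(u, v)
    k2 <- deriv(u + dt / 2 * k1$du, v + dt / 2 * k1$dv)
    k3 <- deriv(u + dt / 2 * k2$du, v + dt / 2 * k2$dv)
    k4 <- deriv(u + dt * k3$du, v + dt * k3$dv)
    u <- u + dt / 6 * (k1$du + 2 * k2$du + 2 * k3$du + k4$du)
    v <- v + dt / 6 * (k1$dv + 2 * k2$dv + 2 * k3$dv + k4$dv)
    Y[i + 1, ] <- pmax(0, u)
  }
  list(t = seq(0, n) * dt, y = Y)
}

#' Sensory feedback onto the CPG units
#'
#' Linear, left/right mirror-symmetric combination of the segment angles
#' (relative to vertical; the HAT angle is shared by both sides) and the
#' two vertical ground-reaction forces (normalized by half body weight),
#' parameterized by 16 nonnegative weights. The structural signs implement
#' stretch-type and load-type reflexes onto the flexor/extensor
#' half-centres; the weights scale them.
#'
#' @param q Generalized coordinates (length 9).
#' @param grf c(left, right) vertical GRFs (N).
#' @param weights Feedback weights (length 16).
#' @param config A `fogsim_config`.
#' @return Feedback vector (length 12, CPG unit order).
#' @export
sensory_feedback <- function(q, grf, weights, config = default_parameters()) {
  if (length(weights) != 16) stop("sensory_feedback: expected 16 weights")
  w <- weights
  hat <- q[3]
  gn <- grf / (0.5 * config$body$total_mass * config$body$gravity)
  th <- c(q[4], q[7]); sh <- c(q[5], q[8]); ft <- c(q[6], q[9])
  feed <- numeric(12)
  for (s in 1:2) {
    o <- 3 - s
    off <- 6 * (s - 1)
    feed[off + 1] <- -w[1] * th[s] + w[2] * gn[o] - w[3] * gn[s] - w[4] * hat
    feed[off + 2] <- w[5] * th[s] + w[6] * gn[s] + w[7] * th[o]
    feed[off + 3] <- -w[8] * sh[s] - w[9] * gn[s] + w[10] * gn[o]
    feed[off + 4] <- w[11] * sh[s] + w[12] * gn[s]
    feed[off + 5] <- -w[13] * gn[s] - w[14] * ft[s]
    feed[off + 6] <- w[15] * gn[s] + w[16] * sh[s]
  }
  feed
}

#' Posture control onto the motoneurons
#'
#' Stance-gated upright-posture responses parameterized by 23 nonnegative
#' weights, mirror-symmetric between legs: antigravity support of the
#' extensor muscles proportional to limb load, PD control of HAT pitch at
#' the hip, an ankle strategy, knee-collapse support, swing-phase flexor
#' and dorsiflexor assistance, and single-support load transfer. Entries
#' are signed so that a negative value excites the muscle once passed
#' through the motoneuron sigmoid (whose argument is
#' \eqn{\sum w^\alpha y + P / u^{PPN}}).
#'
#' @param q,qd Generalized coordinates/velocities.
#' @param grf c(left, right) vertical GRFs (N).
#' @param weights Posture weights (length 23).
#' @param config A `fogsim_config`.
#' @return P vector (length 18, muscle order left then right).
#' @export
posture_control <- function(q, qd, grf, weights,
                            config = default_parameters()) {
  if (length(weights) != 23) stop("posture_control: expected 23 weights")
  w <- weights; ps <- config$posture
  gn <- pmin(1, pmax(0, grf / (0.5 * config$body$total_mass *
                                 config$body$gravity)))
  p <- q[3] - ps$hat_ref
  pd <- qd[3]
  ja <- joint_angles(q)
  jv <- joint_velocities(qd)
  P <- numeric(18)
  for (s in 1:2) {
    o <- 3 - s
    off <- 9 * (s - 1)
    g <- gn[s]; go <- gn[o]
    hipdev <- ja[1 + 3 * (s - 1)] - ps$hip_ref
    kneedev <- ja[2 + 3 * (s - 1)] - ps$knee_ref
    # ankle strategy senses body sway: absolute shank angle (and rate)
    # relative to the standing reference, positive when swaying backward
    shank_ref <- ps$hat_ref + ps$hip_ref + ps$knee_ref
    swaydev <- q[5 + 3 * (s - 1)] - shank_ref
    swayvel <- qd[5 + 3 * (s - 1)]
    P[off + 1] <- -w[1] * g + w[6] * g * p + w[8] * g * pd -
      w[17] * g * hipdev - w[22] * (g - go)                       # GM
    P[off + 2] <- -w[7] * g * p - w[9] * g * pd - w[14] * (1 - g) +
      w[18] * g * hipdev                                          # IL
    P[off + 3] <- -w[4] * g                                       # BFL
    P[off + 4] <- 0                                               # RF
    P[off + 5] <- -w[16] * (1 - g)                                # BFS
    P[off + 6] <- -w[2] * g + w[12] * g * kneedev                 # VA
    P[off + 7] <- -w[5] * g + w[13] * g * kneedev                 # GC
    P[off + 8] <- -w[3] * g + w[10] * g * p + w[19] * g * swaydev +
      w[21] * g * swayvel                                         # SO
    P[off + 9] <- -w[11] * g * p - w[15] * (1 - g) -
      w[20] * g * swaydev - w[21] * g * swayvel -
      w[23] * g                                                   # TA
    # w23: tonic stance dorsiflexor tone; shifts the sway equilibrium
    # (and with it the centre of pressure) forward for gait initiation
  }
  P
}

#' Fixed CPG-to-motoneuron routing matrix
#'
#' Maps the 12 CPG outputs onto the 18 muscles: each muscle is driven by
#' the half-centre(s) of the joint(s) it spans, with negative entries
#' (the motoneuron sigmoid is decreasing in its argument, so negative
#' weights excite). Biarticular muscles receive a weaker secondary drive
#' from their second joint.
#'
#' @param motoneuron Motoneuron parameter list.
#' @return 18 x 12 matrix.
#' @export
motoneuron_weight_matrix <- function(motoneuron = default_parameters()$motoneuron) {
  wp <- motoneuron$w_primary; ws <- motoneuron$w_secondary
  wt <- motoneuron$w_tertiary
  W <- matrix(0, 18, 12)
  for (s in 0:1) {
    mo <- 9 * s; co <- 6 * s
    hf <- co + 1; he <- co + 2; kf <- co + 3; ke <- co + 4
    af <- co + 5; ae <- co + 6
    W[mo + 1, he] <- -wp                        # GM <- hip extensor
    W[mo + 2, hf] <- -wp                        # IL <- hip flexor
    W[mo + 3, he] <- -ws; W[mo + 3, kf] <- -wt  # BFL
    W[mo + 4, hf] <- -ws; W[mo + 4, ke] <- -wt  # RF
    W[mo + 5, kf] <- -wp                        # BFS
    W[mo + 6, ke] <- -wp                        # VA
    W[mo + 7, ae] <- -ws; W[mo + 7, kf] <- -wt  # GC
    W[mo + 8, ae] <- -wp                        # SO
    W[mo + 9, af] <- -wp                        # TA
  }
  W
}

#' Alpha-motoneuron output
#'
#' \deqn{\alpha_m = \frac{2}{1 + \exp(0.25 (\sum_i w^\alpha_{mi} y_i +
#'   P_m / u^{PPN}))} - 1,} clamped to \[0, 1\]. Higher PPN activity
#' attenuates the posture-control contribution (the muscle-tone release
#' pathway); `u_ppn` is floored at a small epsilon inside the division
#' only, so the system stays integrable when PPN drive is zero.
#'
#' @param y CPG outputs (length 12, nonnegative).
#' @param P Posture-control vector (length 18).
#' @param u_ppn PPN internal state (scalar).
#' @param config A `fogsim_config`.
#' @return Activation vector (length 18), each in \[0, 1\].
#' @export
motoneuron_output <- function(y, P, u_ppn, config = default_parameters()) {
  mn <- config$motoneuron
  Wa <- motoneuron_weight_matrix(mn)
  arg <- as.numeric(Wa %*% y) + P / max(u_ppn, mn$u_ppn_floor)
  raw <- 2.0 / (1.0 + exp(mn$gain * arg)) - 1.0
  pmin(1, pmax(0, raw))
}
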