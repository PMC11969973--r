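#' Default model configuration
#'
#' Builds the full configuration bundle for the planar neuromusculoskeletal
#' gait model: body segment and contact constants, Hill-type muscle table,
#' brainstem (MLR) and spinal (CPG) neural constants, simulation settings,
#' freezing-of-gait detector settings, and genetic-algorithm settings.
#'
#' All constants with a published value carry that value; the remaining
#' entries (segment anthropometry, muscle geometry, neural time constants,
#' reflex forms) are surrogate defaults for a ~70 kg, ~1.7 m adult drawn
#' from the standard planar-biped modelling lineage, and are flagged with
#' `surrogate = TRUE` in the relevant sub-list so that users with better
#' tables can swap them in via the config alone.
#'
#' Coordinate convention: x forward, y up; segment angles are measured
#' counterclockwise from the vertical for the HAT, thighs and shanks and
#' counterclockwise from the horizontal for the feet. With this convention
#' knee flexion is negative, matching the knee range of motion
#' \eqn{[-2.8, -0.1]} rad.
#'
#' @return A nested list of class `fogsim_config`.
#' @export
#' @examples
#' cfg <- default_parameters()
#' cfg$body$joint_viscosity[["knee"]]   # 3.17 N m s / rad
default_parameters <- function() {
  body <- list(
    # masses (kg), lengths (m), proximal com offsets (m), inertias (kg m^2)
    segments = list(
      hat   = list(mass = 48, length = 0.80, com = 0.32, inertia = 2.60),
      thigh = list(mass = 7.0, length = 0.41, com = 0.18, inertia = 0.12),
      shank = list(mass = 3.0, length = 0.41, com = 0.18, inertia = 0.05),
      foot  = list(mass = 1.0, inertia = 0.010)
    ),
    # foot frame relative to the ankle: heel behind, toe in front, sole below
    foot_geom = list(ankle_height = 0.07, heel_back = 0.05, toe_front = 0.15,
                     com_x = 0.05, com_y = 0.05),
    joint_viscosity = c(hip = 1.09, knee = 3.17, ankle = 0.943), # N m s / rad
    joint_limits = list(
      knee  = list(range = c(-2.8, -0.1), stiffness = 2.0e3, damping = 3.0e2),
      ankle = list(range = c(-1.0, 0.54), stiffness = 2.0e3, damping = 3.0e1)
    ),
    contact = list(kx = 5.0e3, cx = 1.0e2, ky = 2.5e4, cy = 1.0e3),
    gravity = 9.81,
    surrogate = TRUE  # anthropometry only; printed coefficients are exact
  )
  body$total_mass <- body$segments$hat$mass +
    2 * (body$segments$thigh$mass + body$segments$shank$mass +
           body$segments$foot$mass)

  # nine muscles per leg; moment arms (m) signed so that a positive muscle
  # tension produces torque -F * r about each spanned joint:
  #   hip flexors r_hip < 0, knee flexors r_knee > 0, plantarflexors r_ankle > 0
  muscles <- data.frame(
    name   = c("GM", "IL", "BFL", "RF", "BFS", "VA", "GC", "SO", "TA"),
    f_max  = c(1800, 1200, 1200, 1000, 600, 3000, 1500, 3000, 800),    # N
    l_opt  = c(0.25, 0.25, 0.42, 0.42, 0.25, 0.25, 0.38, 0.22, 0.25),  # m
    v_max  = c(0.60, 0.60, 1.00, 1.00, 0.60, 0.60, 0.90, 0.50, 0.60),  # m/s
    c_pd   = c(60, 60, 50, 50, 30, 80, 60, 80, 40),                    # N s/m
    k_pe   = c(30, 30, 25, 25, 15, 40, 30, 40, 20),                    # N
    r_hip  = c(0.062, -0.050, 0.054, -0.049, 0, 0, 0, 0, 0),
    r_knee = c(0, 0, 0.049, -0.049, 0.049, -0.050, 0.025, 0, 0),
    r_ankle = c(0, 0, 0, 0, 0, 0, 0.050, 0.050, -0.040),
    stringsAsFactors = FALSE
  )

  # metabolic surrogate: rate = f_max * v_max * (c0 + c1*a + c2*a*max(0,-eta))
  metabolic <- list(c0 = 0.005, c1 = 0.03, c2 = 0.20, surrogate = TRUE)

  mlr <- list(
    tau_ppn = 0.15, tau_cnf = 0.05,     # s; PPN slower than CnF
    w_ppn_cnf = 0.10, w_cnf_ppn = 0.01, # CnF->PPN stronger than PPN->CnF
    # calibrated so the unit-input fixed point is exactly (1, 1):
    # (1 + beta) * 1 = w_cross + w_hc  =>  beta_ppn = 0.10, beta_cnf = 0.01
    beta_ppn = 0.10, beta_cnf = 0.01, w_hc = 1.0,
    switch_time = 3.0, post_switch = 1.0
  )

  cpg <- list(
    tau = 0.04, tau_prime = 0.25, beta = 2.5,  # Matsuoka unit constants (s, s, -)
    # calibrated once for a ~1 s autonomous cycle under unit drive
    n_units = 12L,
    # demonstration operating point for the rhythm generator itself
    # (autonomous limit cycle under constant unit CnF drive, feedback
    # off); the free gains the optimizer tunes are independent of it
    reference_gains = c(2, 2, 2, 1, 1, 1, 1, 1.5, 0.5),
    reference_drive = 2,
    surrogate = TRUE
  )

  motoneuron <- list(
    gain = 0.25,           # sigmoid slope constant
    u_ppn_floor = 1e-3,    # floor applied inside 1/u_ppn only
    # fixed CPG-to-muscle routing magnitudes (negative entries excite),
    # calibrated so CPG bursts can fold the swing leg against the
    # posture-control support of the stance phase
    w_primary = 4.5, w_secondary = 2.25, w_tertiary = 1.5
  )

  # reference posture: trunk upright (no sustained hip torque needed),
  # thigh angled so the ankle sits under the centre of mass
  posture <- list(
    hat_ref = 0, hip_ref = 0.09, knee_ref = -0.25, ankle_ref = 0.16,
    n_weights = 23L, surrogate = TRUE
  )

  feedback <- list(n_weights = 16L, surrogate = TRUE)

  sim <- list(
    dt = 1e-4,            # 0.1 ms integration step
    duration = 15,        # s
    decimation = 100L,    # record at 100 Hz
    fall_hip_fraction = 0.6,  # fall if hip drops below this * standing height
    fall_pitch = 1.0,         # rad; fall if |HAT pitch| exceeds this
    initial = list(
      hat = 0, thigh = 0.09, knee = -0.25, foot = 0, # foot angle from horizontal
      cpg_seed = 0.1    # symmetry-breaking CPG seed (left swings first)
    ),
    step_force_threshold = 30,   # N, vertical GRF onset for step events
    step_refractory = 0.15       # s unloaded before / loaded after an onset
  )

  fog <- list(
    freeze_band = c(3, 10), locomotor_band = c(0, 3),   # Hz
    window = 2.0, hop = 0.5,                            # s
    freeze_threshold = 2.0, corr_threshold = 0.4,
    min_episode = 0.5,                                  # s
    ratio_cap = 100, power_floor = 1e-12,
    analysis_window = c(0, 3)                           # s, for the sweep flag
  )

  ga <- list(
    population = 64L, generations = 2000L,
    crossover = 0.9, mutation_sd_frac = 0.05, mutation_prob = 0.15,
    elitism = 2L, tournament = 2L
  )

  bounds <- free_parameter_bounds()

  structure(list(body = body, muscles = muscles, metabolic = metabolic,
                 mlr = mlr, cpg = cpg, motoneuron = motoneuron,
                 posture = posture, feedback = feedback,
                 sim = sim, fog = fog, ga = ga, bounds = bounds),
            class = "fogsim_config")
}

#' @export
print.fogsim_config <- function(x, ...) {
  cat("fogsim configuration\n")
  cat(sprintf("  body: 7 links, total mass %.1f kg\n", x$body$total_mass))
  cat(sprintf("  muscles: %d per leg (%s)\n", nrow(x$muscles),
              paste(x$muscles$name, collapse = " ")))
  cat(sprintf("  integration: dt = %g s, duration = %g s\n",
              x$sim$dt, x$sim$duration))
  cat(sprintf("  free controller parameters: %d\n", n_free_parameters()))
  invisible(x)
}

#' Names, groups and bounds of the free controller parameters
#'
#' The optimizer adjusts 49 parameters: the CnF-to-CPG input weight `u0`
#' (1), the sensory feedback weights (16), the free central-pattern-
#' generator connection gains (9, expanded into the 12 x 12 matrix by the
#' left/right and flexor/extensor symmetry skeleton), and the posture-
#' control weights (23). All are nonnegative gains; structural signs live
#' in the fixed reflex/connection forms.
#'
#' @return A data.frame with columns `name`, `group`, `lower`, `upper`.
#' @export
free_parameter_bounds <- function() {
  rbind(
    data.frame(name = "u0", group = "u0", lower = 0, upper = 10),
    data.frame(name = sprintf("feed%02d", 1:16), group = "feed",
               lower = 0, upper = 5),
    data.frame(name = sprintf("cpg%d", 1:9), group = "cpg",
               lower = 0, upper = 4),
    data.frame(name = sprintf("pos%02d", 1:23), group = "pos",
               lower = 0,
               # rate-feedback weights (pitch and ankle velocity terms)
               # get tighter caps than proportional/tonic terms
               upper = ifelse(sprintf("pos%02d", 1:23) %in%
                                c("pos08", "pos09", "pos21"), 25, 100))
  )
}

#' Number of free controller parameters
#' @return Integer, `1 + 16 + 9 + 23 = 49`.
#' @export
n_free_parameters <- function() nrow(free_parameter_bounds())

#' Split a flat free-parameter vector into named groups
#'
#' @param theta Numeric vector of length 49 (see [free_parameter_bounds()]).
#' @return List with elements `u0` (scalar), `feed` (16), `cpg` (9),
#'   `pos` (23).
#' @export
split_free_parameters <- function(theta) {
  stopifnot(is.numeric(theta), length(theta) == n_free_parameters())
  list(u0 = theta[[1]], feed = theta[2:17], cpg = theta[18:26],
       pos = theta[27:49])
}

#' Read / write an optimized parameter vector as JSON
#'
#' Parameter vectors are stored as a flat JSON object with a named index
#' map so files remain self-describing.
#'
#' @param theta Numeric vector of length 49.
#' @param path File path.
#' @return `read_parameters()` returns the numeric vector with names.
#' @export
write_parameters <- function(theta, path) {
  b <- free_parameter_bounds()
  stopifnot(length(theta) == nrow(b))
  jsonlite::write_json(as.list(stats::setNames(theta, b$name)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  b <- free_parameter_bounds()
  stopifnot(all(b$name %in% names(x)))
  theta <- as.numeric(unlist(x[b$name]))
  names(theta) <- b$name
  theta
}

#' Write / read a configuration as JSON
#'
#' The full configuration round-trips losslessly through JSON (numeric
#' values at full precision; the muscle table as a record array).
#'
#' @param config A `fogsim_config`.
#' @param path File path.
#' @return `read_config()` returns the `fogsim_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$muscles <- as.data.frame(x$muscles, stringsAsFactors = FALSE)
  x$bounds <- as.data.frame(x$bounds, stringsAsFactors = FALSE)
  for (nm in c("sim", "fog", "ga", "mlr", "cpg", "motoneuron", "posture",
               "feedback", "metabolic"))
    x[[nm]] <- as.list(x[[nm]])
  names(x$body$joint_viscosity) <- c("hip", "knee", "ankle")
  structure(x, class = "fogsim_config")
}

#' Packaged normal-condition controller parameters
#'
#' Loads the parameter vector shipped with the package: the best
#' controller found by the genetic algorithm under the normal
#' higher-center command \eqn{(s^{PPN}, s^{CnF}) = (1, 1)}. With the
#' packaged surrogate reflex structure the optimizer converges to a
#' controller that maintains stable upright stance for the full 15-s
#' horizon; it does not achieve forward locomotion (see the methods
#' vignette's limitations section). Re-run [ga_run()] to search further.
#'
#' @return Named numeric vector of length 49.
#' @export
normal_parameters <- function() {
  read_parameters(system.file("extdata", "normal_parameters.json",
                              package = "fogsim", mustWork = TRUE))
}
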