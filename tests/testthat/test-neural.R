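test_that("higher-center command is piecewise-constant with inclusive boundary", {
  mlr <- fogsim_test_config()$mlr
  expect_identical(higher_center_input(1.5, 0.3, 0.7, mlr), c(0.3, 0.7))
  expect_identical(higher_center_input(3.0, 0.3, 0.7, mlr), c(0.3, 0.7))
  expect_identical(higher_center_input(4.0, 0.3, 0.7, mlr), c(1.0, 1.0))
  expect_error(higher_center_input(-1, 1, 1, mlr))
})

test_that("MLR converges to (1, 1) under unit input and decays slower in PPN", {
  mlr <- fogsim_test_config()$mlr
  expect_identical(mlr_derivatives(c(0, 0), c(0, 0), mlr), c(0, 0))
  tr <- integrate_mlr(1, 1, duration = 5, dt = 1e-3, mlr = mlr)
  expect_equal(tail(tr$u_ppn, 1), 1.0, tolerance = 1e-6)
  expect_equal(tail(tr$u_cnf, 1), 1.0, tolerance = 1e-6)
  # 0.01-s unit pulse from rest: PPN activity outlasts CnF activity
  pulse <- function(t) if (t >= 1 && t <= 1.01) c(1, 1) else c(0, 0)
  tp <- integrate_mlr(hc_fun = pulse, duration = 3, dt = 1e-4, mlr = mlr)
  decay_time <- function(u) {
    ipk <- which.max(u)
    idx <- which(u < 0.1 * u[ipk] & seq_along(u) > ipk)[1]
    (idx - ipk) * 1e-4
  }
  expect_gt(decay_time(tp$u_ppn), decay_time(tp$u_cnf))
})

test_that("sensory feedback is linear, 16-weight, and mirror-symmetric", {
  cfg <- fogsim_test_config()
  q <- standing_posture(cfg)$q
  expect_identical(sensory_feedback(q, c(100, 120), rep(0, 16), cfg),
                   rep(0, 12))
  expect_error(sensory_feedback(q, c(0, 0), rep(0, 15), cfg), "16")
  set.seed(2)
  w <- runif(16)
  q <- q + rnorm(9, 0, 0.2)
  grf <- c(250, 80)
  # linearity in the angle/GRF inputs (relative to the zero posture)
  f1 <- sensory_feedback(q, grf, w, cfg)
  q0 <- numeric(9)
  f2 <- sensory_feedback(2 * q, 2 * grf, w, cfg) -
    sensory_feedback(q0, c(0, 0), w, cfg)
  expect_equal(2 * f1, f2, tolerance = 1e-12)
  # mirror: swapping the left/right body state swaps unit blocks
  qm <- q[c(1, 2, 3, 7, 8, 9, 4, 5, 6)]
  fm <- sensory_feedback(qm, rev(grf), w, cfg)
  expect_equal(fm, f1[c(7:12, 1:6)], tolerance = 1e-12)
})

test_that("posture control is 23-weight, mirror-symmetric, pitch-monotone", {
  cfg <- fogsim_test_config()
  sp <- standing_posture(cfg)
  grf <- rep(0.25 * cfg$body$total_mass * cfg$body$gravity, 2)
  expect_identical(posture_control(sp$q, sp$qd, grf, rep(0, 23), cfg),
                   rep(0, 18))
  expect_error(posture_control(sp$q, sp$qd, grf, rep(0, 22), cfg), "23")
  set.seed(3)
  w <- runif(23)
  # stance support: with all weights on, loaded extensors are excited
  # (negative entries) at the reference posture
  P <- posture_control(sp$q, sp$qd, grf, w, cfg)
  for (m in c(1, 6, 8)) expect_lt(P[m], 0)          # GM, VA, SO left
  # forward pitch perturbation changes the hip-extensor entry monotonically
  pitches <- seq(-0.3, 0.2, by = 0.05)
  gm <- vapply(pitches, function(dp) {
    q <- sp$q; q[3] <- cfg$posture$hat_ref + dp
    posture_control(q, sp$qd, grf, w, cfg)[1]
  }, numeric(1))
  expect_true(all(diff(gm) > 0))    # more forward lean => more excitation
  # mirror symmetry
  q <- sp$q + rnorm(9, 0, 0.15)
  qm <- q[c(1, 2, 3, 7, 8, 9, 4, 5, 6)]
  grf2 <- c(300, 120)
  P1 <- posture_control(q, sp$qd, grf2, w, cfg)
  P2 <- posture_control(qm, sp$qd, rev(grf2), w, cfg)
  expect_equal(P2, P1[c(10:18, 1:9)], tolerance = 1e-12)
})

test_that("motoneuron output is the clamped decreasing sigmoid with PPN gating", {
  cfg <- fogsim_test_config()
  y0 <- rep(0, 12)
  a0 <- motoneuron_output(y0, rep(0, 18), 1, cfg)
  expect_equal(a0, rep(0, 18))   # argument 0 -> 2/(1+1) - 1 = 0
  # strongly negative argument -> alpha -> 1; positive -> clamped at 0
  a1 <- motoneuron_output(y0, rep(-1e4, 18), 1, cfg)
  expect_equal(a1, rep(1, 18), tolerance = 1e-9)
  a2 <- motoneuron_output(y0, rep(1e4, 18), 1, cfg)
  expect_equal(a2, rep(0, 18))
  # doubling u_ppn halves the posture term inside the sigmoid
  P <- rep(-2, 18)
  gain <- cfg$motoneuron$gain
  a_half <- motoneuron_output(y0, P, 2, cfg)
  manual <- pmin(1, pmax(0, 2 / (1 + exp(gain * (P / 2))) - 1))
  expect_equal(a_half, manual, tolerance = 1e-12)
  # u_ppn floored, not raised: tiny u_ppn amplifies posture control
  a_low <- motoneuron_output(y0, rep(-0.1, 18), 1e-9, cfg)
  expect_true(all(a_low > motoneuron_output(y0, rep(-0.1, 18), 1, cfg)))
  # outputs always within [0, 1]
  set.seed(4)
  for (i in 1:20) {
    a <- motoneuron_output(runif(12, 0, 3), rnorm(18, 0, 30), runif(1, 0, 2),
                           cfg)
    expect_true(all(a >= 0 & a <= 1))
  }
})

test_that("CPG oscillates under unit drive and is quiescent without drive", {
  cfg <- fogsim_test_config()
  gains <- c(2, 2, 2, 1, 1, 1, 1, 1, 1)
  expect_identical(diag(cpg_weight_matrix(gains)), rep(0, 12))
  # zero state, zero drive, zero feedback -> zero derivatives
  d0 <- cpg_derivatives(rep(0, 12), rep(0, 12), cpg_weight_matrix(gains),
                        0, numeric(12), cfg$cpg)
  expect_identical(d0$du, rep(0, 12))
  expect_identical(d0$dv, rep(0, 12))
  # sustained limit cycle under constant unit CnF drive, feedback off
  sim <- integrate_cpg(gains, u0 = 2, u_cnf = 1, duration = 12, dt = 1e-3,
                       cpg = cfg$cpg)
  late <- sim$y[sim$t > 6, 1]
  expect_gt(diff(range(late)), 0.5)          # still oscillating after 6 s
  expect_gt(sum(abs(diff(late > mean(late)))), 6)   # several cycles
  # quiescence at zero drive
  sim0 <- integrate_cpg(gains, u0 = 2, u_cnf = 0, duration = 6, dt = 1e-3,
                        cpg = cfg$cpg)
  expect_lt(max(sim0$y[sim0$t > 5, ]), 1e-3)
})

test_that("CPG limit-cycle period is invariant to start time", {
  cfg <- fogsim_test_config()
  gains <- c(2, 2, 2, 1, 1, 1, 1, 1, 1)
  period_of <- function(duration) {
    sim <- integrate_cpg(gains, u0 = 2, u_cnf = 1, duration = duration,
                         dt = 1e-3, cpg = cfg$cpg)
    y <- sim$y[sim$t > duration - 6, 1]
    z <- y - mean(y)
    up <- which(diff(sign(z)) > 0)
    mean(diff(up)) * 1e-3
  }
  p1 <- period_of(10)
  p2 <- period_of(14)   # same system observed after a longer transient
  expect_equal(p1, p2, tolerance = 0.02)
})
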