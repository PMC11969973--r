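test_that("joint-limit torque is zero inside the range and linear outside", {
  body <- fogsim_test_config()$body
  expect_identical(joint_limit_torque(-1.0, 0, "knee", body), 0)
  expect_identical(joint_limit_torque(-0.1, 0, "knee", body), 0)
  # 0.1 rad beyond the lower knee bound: 2e3 * 0.1 = 200 N m, restoring (+)
  expect_equal(joint_limit_torque(-2.9, 0, "knee", body), 200,
               tolerance = 1e-12)
  # 0.1 rad beyond the upper ankle bound: restoring toward range (-)
  expect_equal(joint_limit_torque(0.64, 0, "ankle", body), -200,
               tolerance = 1e-12)
  # continuous at the boundary
  eps <- 1e-9
  expect_lt(abs(joint_limit_torque(-2.8 - eps, 0, "knee", body)), 1e-4)
  # damping acts only outside the range, opposing velocity
  expect_equal(joint_limit_torque(-2.9, -1, "knee", body),
               200 + 300, tolerance = 1e-12)
  expect_error(joint_limit_torque(NaN, 0, "knee", body), "non-finite")
})

test_that("contact force is unilateral spring-damper with stick friction", {
  body <- fogsim_test_config()$body
  expect_identical(contact_force(c(0, 0.01), c(0, 0), body = body), c(0, 0))
  # penetration 0.01 m at rest: 2.5e4 * 0.01 = 250 N up
  f <- contact_force(c(0, -0.01), c(0, 0), body = body)
  expect_equal(f[2], 250, tolerance = 1e-12)
  expect_equal(f[1], 0, tolerance = 1e-12)
  # fast upward motion: spring + damper < 0 clamps to zero (no adhesion)
  f2 <- contact_force(c(0, -0.001), c(0, 1), body = body)
  expect_identical(f2, c(0, 0))
  # horizontal spring anchored at touchdown point
  f3 <- contact_force(c(0.02, -0.01), c(0, 0), anchor_x = 0, body = body)
  expect_equal(f3[1], 5e3 * (-0.02), tolerance = 1e-12)
  expect_error(contact_force(c(NA, 0), c(0, 0), body = body), "non-finite")
})

test_that("suspended chain under gravity alone accelerates its COM at -g", {
  cfg <- fogsim_test_config()
  set.seed(11)
  q <- c(0, 2.5, rnorm(7, 0, 0.4))   # airborne, no contact
  qd <- rnorm(9, 0, 0.3)
  res <- equations_of_motion(q, qd, numeric(6), cfg$body,
                             include = list(gravity = TRUE,
                                            viscosity = FALSE,
                                            limits = FALSE,
                                            contact = FALSE))
  # COM acceleration from the body Jacobians: sum m (J qdd + bias) / M
  kin <- fogsim:::body_kinematics(q, qd, cfg$body)
  bodies <- list(kin$hat, kin$left$thigh, kin$left$shank, kin$left$foot,
                 kin$right$thigh, kin$right$shank, kin$right$foot)
  acc <- c(0, 0)
  for (b in bodies) acc <- acc + b$m * (as.numeric(b$J %*% res$qdd) + b$bias)
  acc <- acc / cfg$body$total_mass
  expect_equal(acc, c(0, -cfg$body$gravity), tolerance = 1e-9)
  expect_identical(unname(res$grf), c(0, 0))
})

test_that("passive mechanical energy is conserved by RK4 at 0.1 ms", {
  cfg <- fogsim_test_config()
  set.seed(3)
  q <- c(0, 1.5, rnorm(7, 0, 0.3))
  qd <- rnorm(9, 0, 0.4)
  inc <- list(gravity = TRUE, viscosity = FALSE, limits = FALSE,
              contact = FALSE)
  f <- function(s) {
    e <- equations_of_motion(s[1:9], s[10:18], numeric(6), cfg$body,
                             include = inc)
    c(s[10:18], e$qdd)
  }
  st <- c(q, qd); dt <- 1e-4
  E0 <- mechanical_energy(q, qd, cfg$body)
  for (i in 1:10000) {   # 1 simulated second
    k1 <- f(st); k2 <- f(st + dt / 2 * k1); k3 <- f(st + dt / 2 * k2)
    k4 <- f(st + dt * k3)
    st <- st + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  E1 <- mechanical_energy(st[1:9], st[10:18], cfg$body)
  expect_lt(abs(E1 - E0) / abs(E0), 1e-6)
})

test_that("configured coefficients carry their published values", {
  cfg <- fogsim_test_config()
  expect_identical(unname(cfg$body$joint_viscosity),
                   c(1.09, 3.17, 0.943))
  expect_identical(cfg$body$joint_limits$knee$range, c(-2.8, -0.1))
  expect_identical(cfg$body$joint_limits$ankle$range, c(-1.0, 0.54))
  expect_identical(cfg$body$joint_limits$knee$stiffness, 2.0e3)
  expect_identical(cfg$body$joint_limits$knee$damping, 3.0e2)
  expect_identical(cfg$body$joint_limits$ankle$damping, 3.0e1)
  expect_identical(cfg$body$contact$kx, 5.0e3)
  expect_identical(cfg$body$contact$cx, 1.0e2)
  expect_identical(cfg$body$contact$ky, 2.5e4)
  expect_identical(cfg$body$contact$cy, 1.0e3)
  expect_identical(cfg$mlr$w_ppn_cnf, 0.10)
  expect_identical(cfg$mlr$w_cnf_ppn, 0.01)
  expect_gt(cfg$mlr$tau_ppn, cfg$mlr$tau_cnf)
})

test_that("configuration round-trips through JSON", {
  cfg <- fogsim_test_config()
  path <- tempfile(fileext = ".json")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$body$joint_viscosity, cfg$body$joint_viscosity)
  expect_equal(cfg2$body$contact, cfg$body$contact)
  expect_equal(cfg2$muscles, cfg$muscles)
  expect_equal(cfg2$mlr, cfg$mlr)
  expect_equal(cfg2$sim$dt, cfg$sim$dt)
  # and a second dump is byte-identical
  path2 <- tempfile(fileext = ".json")
  write_config(cfg2, path2)
  expect_identical(readLines(path), readLines(path2))
})
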