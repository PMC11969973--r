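test_that("fitness evaluates the printed branch formula", {
  # immediate fall: branch D < 10 with penalty
  expect_equal(gait_fitness(list(D = 0, S = 0, T = 0, C = NA, fell = TRUE)),
               2.5, tolerance = 1e-12)
  expect_equal(gait_fitness(list(D = 9, S = 10, T = 10, C = NA,
                                 fell = FALSE)),
               24.5, tolerance = 1e-12)
  expect_equal(gait_fitness(list(D = 10, S = 10, T = 15, C = 2.5,
                                 fell = FALSE)),
               42, tolerance = 1e-12)
  # missing cost of transport on the walking branch is an error
  expect_error(gait_fitness(list(D = 12, S = 10, T = 15, C = NA,
                                 fell = FALSE)), "cost of transport")
  # branch assignment depends only on D >= 10
  j1 <- gait_fitness(list(D = 9.999, S = 0, T = 15, C = 5, fell = FALSE))
  j2 <- gait_fitness(list(D = 10.001, S = 0, T = 15, C = 5, fell = FALSE))
  expect_equal(j1, 1.5 * 9.999 + 0.1 * 15 + 5, tolerance = 1e-12)
  expect_equal(j2, 10.001 + 5 + 20, tolerance = 1e-12)
})

test_that("free-parameter vector has the printed arithmetic", {
  b <- free_parameter_bounds()
  expect_identical(nrow(b), 49L)
  expect_identical(n_free_parameters(), 49L)
  expect_identical(as.integer(table(b$group)[c("u0", "feed", "cpg", "pos")]),
                   c(1L, 16L, 9L, 23L))
  th <- as.numeric(seq_len(49))
  sp <- split_free_parameters(th)
  expect_identical(sp$u0, 1)
  expect_identical(length(sp$feed), 16L)
  expect_identical(length(sp$cpg), 9L)
  expect_identical(length(sp$pos), 23L)
  # round-trip through JSON storage
  path <- tempfile(fileext = ".json")
  write_parameters(th, path)
  expect_identical(unname(read_parameters(path)), as.numeric(th))
})

test_that("GA solves the sphere benchmark and keeps elitist monotonicity", {
  cfg <- fogsim_test_config()
  # swap-in separable objective on the same bounded 49-space
  target <- 0.5
  obj <- function(theta) list(J = -sum((theta - target)^2), metrics = NULL)
  cfg2 <- cfg
  cfg2$bounds$lower[] <- 0; cfg2$bounds$upper[] <- 1
  res <- ga_run(obj, cfg2, generations = 200, population = 50, seed = 7)
  expect_gt(res$best_J, -1e-2)
  # elitism: best-so-far fitness never decreases
  expect_true(all(diff(res$history$best_J) >= 0))
  # reproducibility: identical seeds, identical histories
  res2 <- ga_run(obj, cfg2, generations = 25, population = 30, seed = 12)
  res3 <- ga_run(obj, cfg2, generations = 25, population = 30, seed = 12)
  expect_identical(res2$history, res3$history)
  expect_identical(res2$best, res3$best)
})

test_that("GA survives objective crashes by scoring them at the minimum", {
  cfg <- fogsim_test_config()
  cfg2 <- cfg
  cfg2$bounds$lower[] <- 0; cfg2$bounds$upper[] <- 1
  obj <- function(theta) {
    if (theta[1] > 0.5) stop("synthetic crash")
    list(J = -sum((theta - 0.2)^2), metrics = NULL)
  }
  res <- ga_run(obj, cfg2, generations = 10, population = 20, seed = 3)
  expect_true(is.finite(res$best_J))
  expect_lte(res$best[1], 0.5)
})

test_that("sweep grid has 40,000 pairs on the half-open command square", {
  g <- sweep_grid()
  expect_identical(nrow(g), 40000L)
  expect_identical(length(unique(g$s_ppn)), 200L)
  expect_identical(length(unique(g$s_cnf)), 200L)
  expect_equal(min(g$s_ppn), 0)
  expect_equal(max(g$s_ppn), 1.99)
  expect_true(all(abs(diff(sort(unique(g$s_cnf))) - 0.01) < 1e-12))
  # the normal command pair is on the grid
  expect_true(any(g$s_ppn == 1 & g$s_cnf == 1))
})

test_that("command pair (1, 1) reproduces the unmodified run bitwise", {
  cfg <- fogsim_test_config()
  theta <- rep(0.4, n_free_parameters())
  a <- run_gait(theta, 1, 1, cfg, duration = 4)
  # s = 1 during the first 3 s is indistinguishable from the post-switch
  # command, so any other path through higher_center_input is identical
  b <- run_gait(theta, cfg$mlr$post_switch, cfg$mlr$post_switch, cfg,
                duration = 4)
  expect_identical(a$state, b$state)
})

test_that("CnF drive during the command window is monotone in s_cnf", {
  # ODE-level check: mean CnF activity over the first 3 s is strictly
  # lower at s_cnf = 0 than at s_cnf = 1
  m0 <- integrate_mlr(1, 0, duration = 3, dt = 1e-3)
  m1 <- integrate_mlr(1, 1, duration = 3, dt = 1e-3)
  expect_lt(mean(m0$u_cnf), mean(m1$u_cnf))
})

test_that("sweep records the per-cell fields and tolerates failures", {
  cfg <- fogsim_test_config()
  theta <- rep(0.4, n_free_parameters())
  cf <- cfg; cf$sim$dt <- 5e-4; cf$sim$decimation <- 20L
  g <- data.frame(s_ppn = c(1, 0.5), s_cnf = c(1, 0))
  sw <- run_sweep(theta, g, cf)
  expect_identical(nrow(sw), 2L)
  expect_identical(names(sw),
                   c("s_ppn", "s_cnf", "walked", "distance_15s",
                     "distance_3s", "freeze_ratio_3s", "fog"))
  expect_true(all(!sw$walked))   # an arbitrary controller falls
})
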