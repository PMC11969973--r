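# shared helpers: a cached default config and a constructor for small
# hand-built trajectories used by the event/metric tests

fogsim_test_config <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- default_parameters()
    cfg
  }
})

# build a minimal fogsim_trajectory from explicit series; state columns
# not supplied stay zero
make_traj <- function(t, x_hip = numeric(length(t)),
                      grf_left = numeric(length(t)),
                      grf_right = numeric(length(t)),
                      energy = numeric(length(t)),
                      fall_time = NA_real_,
                      config = fogsim_test_config()) {
  n <- length(t)
  st <- matrix(0, n, 45)
  st[, 1] <- x_hip
  st[, 2] <- standing_posture(config)$q[2]
  st[, 45] <- energy
  structure(list(t = t, state = st, grf = cbind(grf_left, grf_right),
                 alpha = matrix(0, n, 18), fall_time = fall_time,
                 aborted = FALSE, duration = max(t), config = config,
                 theta = rep(0, n_free_parameters()), s_ppn = 1, s_cnf = 1),
            class = "fogsim_trajectory")
}

# random but physically sane full state for derivative comparisons
random_state <- function(config = fogsim_test_config()) {
  st <- initial_state(config)
  st[1:9] <- st[1:9] + stats::rnorm(9, 0, 0.1)
  st[10:18] <- stats::rnorm(9, 0, 0.3)
  st[19:44] <- stats::rnorm(26, 0.3, 0.3)
  st
}
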