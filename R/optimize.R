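# Genetic-algorithm optimization of the 49 free controller parameters,
# the fitness function, and the (s_ppn, s_cnf) abnormal-command sweep.

#' Gait fitness
#'
#' \deqn{J = 1.5D + 0.5S + 0.1T + P + 5 \quad (D < 10\,m)}
#' \deqn{J = 1.0D + 0.2S + P + 25/C + 20 \quad (D \ge 10\,m)}
#' with penalty \eqn{P = -2.5} applied iff the model fell, and C the
#' gross metabolic cost of transport.
#'
#' @param metrics A `fogsim_metrics` (or compatible list with D, S, T, C,
#'   fell).
#' @return Scalar fitness J (to maximize).
#' @export
gait_fitness <- function(metrics) {
  P <- if (isTRUE(metrics$fell)) -2.5 else 0
  if (metrics$D < 10) {
    1.5 * metrics$D + 0.5 * metrics$S + 0.1 * metrics$T + P + 5.0
  } else {
    if (is.na(metrics$C))
      stop("gait_fitness: cost of transport missing on the D >= 10 m branch")
    1.0 * metrics$D + 0.2 * metrics$S + P + 25 / metrics$C + 20.0
  }
}

# default objective: simulate and score; crashes score at -Inf handled
# by the GA loop
gait_objective <- function(config, s_ppn = 1, s_cnf = 1) {
  function(theta) {
    traj <- run_gait(theta, s_ppn, s_cnf, config)
    m <- gait_metrics(traj)
    list(J = gait_fitness(m), metrics = m)
  }
}

#' Run the genetic algorithm
#'
#' Real-coded generational GA over the 49 free parameters: tournament
#' selection, per-gene arithmetic blend crossover, Gaussian mutation
#' (sd = 5% of each gene's range), elitism. Any objective failure scores
#' that individual at the minimum fitness and the search continues. Fully
#' seeded: identical seeds give identical histories. Evaluation goes
#' through a pluggable parallel map (`lapply`-compatible) so workers can
#' be swapped in without changing results.
#'
#' @param objective Function `theta -> list(J, metrics)`; defaults to
#'   simulating gait under the normal command and scoring with
#'   [gait_fitness()].
#' @param config A `fogsim_config` (GA settings under `config$ga`,
#'   bounds under `config$bounds`).
#' @param generations,population Overrides of the config values.
#' @param seed Integer seed.
#' @param stop_when Optional predicate on the best individual's metrics;
#'   the run stops early when it returns TRUE (e.g. walked >= 10 m
#'   without falling).
#' @param parallel_map An `lapply`-like function used to evaluate the
#'   population.
#' @param init Optional matrix (population x 49) of starting individuals.
#' @param callback Optional function called after each generation with
#'   `(generation, best, best_J, best_metrics)`; useful for checkpointing
#'   long runs.
#' @param verbose Print per-generation progress.
#' @return List of class `fogsim_ga`: `best` (named theta), `best_J`,
#'   `best_metrics`, `history` (data.frame generation/best_J/mean_J),
#'   `population` (final), `seed`.
#' @export
ga_run <- function(objective = NULL, config = default_parameters(),
                   generations = config$ga$generations,
                   population = config$ga$population,
                   seed = 1, stop_when = NULL,
                   parallel_map = lapply, init = NULL, callback = NULL,
                   verbose = FALSE) {
  if (is.null(objective)) objective <- gait_objective(config)
  b <- config$bounds
  np <- nrow(b)
  ga <- config$ga
  set.seed(seed)
  pop <- if (is.null(init)) {
    t(replicate(population, stats::runif(np, b$lower, b$upper)))
  } else {
    stopifnot(ncol(init) == np)
    extra <- max(0, population - nrow(init))
    filler <- if (extra > 0)
      t(replicate(extra, stats::runif(np, b$lower, b$upper)))
    rbind(init[seq_len(min(nrow(init), population)), , drop = FALSE],
          filler)
  }
  range_ <- b$upper - b$lower
  evaluate <- function(P) {
    res <- parallel_map(seq_len(nrow(P)), function(i) {
      tryCatch(objective(P[i, ]), error = function(e) list(J = -Inf,
                                                           metrics = NULL))
    })
    res
  }
  history <- data.frame(generation = integer(0), best_J = numeric(0),
                        mean_J = numeric(0))
  best <- NULL; best_J <- -Inf; best_metrics <- NULL
  for (gen in seq_len(generations)) {
    evals <- evaluate(pop)
    J <- vapply(evals, function(e) as.numeric(e$J), numeric(1))
    J[!is.finite(J)] <- min(J[is.finite(J)], 0) - 1
    ord <- order(J, decreasing = TRUE)
    if (J[ord[1]] > best_J) {
      best_J <- J[ord[1]]
      best <- pop[ord[1], ]
      best_metrics <- evals[[ord[1]]]$metrics
    }
    history <- rbind(history, data.frame(generation = gen,
                                         best_J = best_J,
                                         mean_J = mean(J)))
    if (verbose)
      message(sprintf("gen %d: best %.3f (all-time %.3f), mean %.3f",
                      gen, J[ord[1]], best_J, mean(J)))
    if (!is.null(callback)) callback(gen, best, best_J, best_metrics)
    if (!is.null(stop_when) && !is.null(best_metrics) &&
        isTRUE(stop_when(best_metrics))) break
    if (gen == generations) break
    # next generation: elites + tournament/crossover/mutation
    newpop <- matrix(0, population, np)
    nel <- min(ga$elitism, population)
    newpop[seq_len(nel), ] <- pop[ord[seq_len(nel)], , drop = FALSE]
    tournament <- function() {
      cand <- sample.int(population, ga$tournament)
      cand[which.max(J[cand])]
    }
    # mutation scale anneals geometrically with a floor, for fine
    # convergence while keeping late-stage exploration alive
    sd_scale <- ga$mutation_sd_frac * max(0.15, 0.985^gen)
    for (i in (nel + 1):population) {
      p1 <- pop[tournament(), ]; p2 <- pop[tournament(), ]
      child <- if (stats::runif(1) < ga$crossover) {
        u <- stats::runif(np)
        u * p1 + (1 - u) * p2
      } else p1
      mut <- stats::runif(np) < ga$mutation_prob
      child[mut] <- child[mut] +
        stats::rnorm(sum(mut), 0, sd_scale * range_[mut])
      newpop[i, ] <- pmin(b$upper, pmax(b$lower, child))
    }
    pop <- newpop
  }
  names(best) <- b$name
  structure(list(best = best, best_J = best_J, best_metrics = best_metrics,
                 history = history, population = pop, seed = seed),
            class = "fogsim_ga")
}

#' @export
print.fogsim_ga <- function(x, ...) {
  cat(sprintf("fogsim GA: %d generations run, best J = %.3f\n",
              nrow(x$history), x$best_J))
  if (!is.null(x$best_metrics)) print(x$best_metrics)
  invisible(x)
}

#' The abnormal-command sweep grid
#'
#' Both brainstem command intensities are varied from 0.00 in increments
#' of 0.01 over a half-open range below 2.00: 200 values per axis, 40,000
#' pairs in total.
#'
#' @return Data frame with columns `s_ppn`, `s_cnf` (40,000 rows).
#' @export
sweep_grid <- function() {
  v <- seq(0, 199) / 100
  g <- expand.grid(s_ppn = v, s_cnf = v, KEEP.OUT.ATTRS = FALSE)
  g[order(g$s_ppn, g$s_cnf), , drop = FALSE]
}

#' Run the (s_ppn, s_cnf) sweep
#'
#' One 15-s simulation per grid pair with the higher-center command
#' modified only during the first 3 s, recording walked distance (full
#' and first 3 s), the fall flag, the first-3-s freeze ratio, and the
#' freezing-of-gait flag from the detector. Rows are independent, so the
#' result does not depend on evaluation order or worker count; individual
#' failures are recorded as falls and the sweep continues.
#'
#' @param theta Optimized normal-model parameter vector (length 49).
#' @param grid Data frame with `s_ppn`, `s_cnf`; defaults to the full
#'   40,000-pair grid. Subset it for desk-scale runs.
#' @param config A `fogsim_config`.
#' @param parallel_map An `lapply`-like function.
#' @return Data frame: s_ppn, s_cnf, walked, distance_15s, distance_3s,
#'   freeze_ratio_3s, fog.
#' @export
run_sweep <- function(theta, grid = sweep_grid(),
                      config = default_parameters(),
                      parallel_map = lapply) {
  rows <- parallel_map(seq_len(nrow(grid)), function(i) {
    s_ppn <- grid$s_ppn[i]; s_cnf <- grid$s_cnf[i]
    tryCatch({
      traj <- run_gait(theta, s_ppn, s_cnf, config)
      m <- gait_metrics(traj)
      # too-short (early-fall) series cannot be windowed: not freezing
      fg <- tryCatch(detect_fog(traj, config),
                     error = function(e) list(is_fog = FALSE))
      sig <- leg_signals(traj)
      aw <- config$fog$analysis_window
      sel <- sig$t >= aw[1] & sig$t <= aw[2]
      fr3 <- tryCatch(
        first_window_freeze_ratio(sig[sel, ], config),
        error = function(e) NA_real_)
      data.frame(s_ppn = s_ppn, s_cnf = s_cnf,
                 walked = !m$fell, distance_15s = m$D, distance_3s = m$D3,
                 freeze_ratio_3s = fr3, fog = fg$is_fog)
    }, error = function(e)
      data.frame(s_ppn = s_ppn, s_cnf = s_cnf, walked = FALSE,
                 distance_15s = NA_real_, distance_3s = NA_real_,
                 freeze_ratio_3s = NA_real_, fog = FALSE))
  })
  do.call(rbind, rows)
}
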