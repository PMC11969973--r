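# Deterministic synthetic-input generators: gait-like sensor signals
# with planted freezing intervals for the detector, and planted Gaussian
# blobs in (s_ppn, s_cnf) space for the cluster analysis. Pure functions
# of their spec and seed.

#' Synthetic lower-leg gait signals with planted freezing intervals
#'
#' Emulates the sensor signals the freezing-of-gait detector consumes:
#' anti-phase sinusoidal locomotor acceleration and angular velocity for
#' the two legs at the locomotor frequency, with optional planted
#' trembling intervals (freeze-band frequency, configurable left/right
#' correlation: 1 = identical phase, 0 = independent phases) during
#' which the locomotor component is suppressed, plus seeded Gaussian
#' noise.
#'
#' @param spec List: `rate` (Hz, default 100), `duration` (s, default
#'   15), `locomotor_freq` (Hz, default 1), `amplitude` (default 1),
#'   `intervals` (data.frame start, end, freq, corr; default none),
#'   `tremble_amplitude` (default 1), `noise` (sd, default 0.02),
#'   `seed` (default 1).
#' @return List of class `fogsim_signals`: `signals` (data.frame t,
#'   accel_left, accel_right, omega_left, omega_right), `truth`
#'   (the planted interval table), `spec`.
#' @export
synthetic_gait_signals <- function(spec = list()) {
  d <- utils::modifyList(list(rate = 100, duration = 15, locomotor_freq = 1,
                              amplitude = 1, intervals = NULL,
                              tremble_amplitude = 1, noise = 0.02,
                              seed = 1), spec)
  stopifnot(d$locomotor_freq < d$rate / 2)
  set.seed(d$seed)
  t <- seq(0, d$duration - 1 / d$rate, by = 1 / d$rate)
  w <- 2 * pi * d$locomotor_freq
  acc_l <- d$amplitude * sin(w * t)
  acc_r <- d$amplitude * sin(w * t + pi)
  om_l <- d$amplitude * cos(w * t)
  om_r <- d$amplitude * cos(w * t + pi)
  truth <- d$intervals
  if (!is.null(truth) && nrow(truth)) {
    stopifnot(all(truth$start >= 0), all(truth$end <= d$duration),
              all(truth$freq < d$rate / 2))
    for (i in seq_len(nrow(truth))) {
      sel <- t >= truth$start[i] & t < truth$end[i]
      corr <- truth$corr[i]
      ta <- d$tremble_amplitude
      wf <- 2 * pi * truth$freq[i]
      # the uncorrelated component is a tone detuned by 1 Hz (an integer
      # number of beat cycles per analysis window), so windowed Pearson
      # correlation with the in-band tone is near zero by orthogonality
      wd <- 2 * pi * (truth$freq[i] + 1)
      stopifnot(truth$freq[i] + 1 < d$rate / 2)
      mix <- function(a, b) corr * a + sqrt(1 - corr^2) * b
      ph <- stats::runif(4, 0, 2 * pi)
      acc_l[sel] <- ta * sin(wf * t[sel] + ph[1])
      acc_r[sel] <- ta * mix(sin(wf * t[sel] + ph[1]),
                             sin(wd * t[sel] + ph[2]))
      om_l[sel] <- ta * cos(wf * t[sel] + ph[3])
      om_r[sel] <- ta * mix(cos(wf * t[sel] + ph[3]),
                            cos(wd * t[sel] + ph[4]))
    }
  } else {
    truth <- data.frame(start = numeric(0), end = numeric(0),
                        freq = numeric(0), corr = numeric(0))
  }
  n <- length(t)
  sig <- data.frame(
    t = t,
    accel_left = acc_l + stats::rnorm(n, 0, d$noise),
    accel_right = acc_r + stats::rnorm(n, 0, d$noise),
    omega_left = om_l + stats::rnorm(n, 0, d$noise),
    omega_right = om_r + stats::rnorm(n, 0, d$noise))
  structure(list(signals = sig, truth = truth, spec = d),
            class = "fogsim_signals")
}

#' Planted Gaussian blobs in (s_ppn, s_cnf) space
#'
#' Seeded Gaussian clusters clipped to the command square \eqn{[0, 2]^2},
#' with ground-truth labels, for testing the cluster pipeline.
#'
#' @param spec List: `centers` (matrix k x 2), `counts` (length k),
#'   `spread` (sd, scalar or length k), `seed`.
#' @return List of class `fogsim_blobs`: `points` (data.frame s_ppn,
#'   s_cnf), `labels` (integer), `spec`.
#' @export
synthetic_cluster_points <- function(spec = list()) {
  d <- utils::modifyList(
    list(centers = rbind(c(0.4, 0.4), c(1.6, 0.4), c(0.4, 1.6),
                         c(1.6, 1.6)),
         counts = c(27, 64, 53, 12), spread = 0.08, seed = 1), spec)
  k <- nrow(d$centers)
  stopifnot(length(d$counts) == k, all(d$counts >= 1), all(d$spread > 0))
  spread <- rep(d$spread, length.out = k)
  set.seed(d$seed)
  pts <- do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(stats::rnorm(d$counts[i], d$centers[i, 1], spread[i]),
          stats::rnorm(d$counts[i], d$centers[i, 2], spread[i]))
  }))
  pts[] <- pmin(2, pmax(0, pts))
  structure(list(points = data.frame(s_ppn = pts[, 1], s_cnf = pts[, 2]),
                 labels = rep(seq_len(k), d$counts), spec = d),
            class = "fogsim_blobs")
}
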