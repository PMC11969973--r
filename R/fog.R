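# Freezing-of-gait detection: windowed freeze ratio (spectral power in
# the 3-10 Hz freeze band over the 0-3 Hz locomotor band) from lower-leg
# anteroposterior acceleration, plus bilateral correlation of the
# lower-leg angular velocities; episode declaration.

# one-sided band power of a detrended window via the FFT.
# bands are half-open [lo, hi) so the 3 Hz bin belongs to the freeze band.
band_power <- function(x, fs, band) {
  n <- length(x)
  x <- x - mean(x)
  X <- stats::fft(x)
  freqs <- (seq_len(n) - 1) * fs / n
  half <- seq_len(floor(n / 2) + 1)
  p <- Mod(X[half])^2 / n
  f <- freqs[half]
  sum(p[f >= band[1] & f < band[2]])
}

# freeze ratio of one already-extracted window
window_freeze_ratio <- function(x, fs, fog) {
  pf <- band_power(x, fs, fog$freeze_band)
  pl <- band_power(x, fs, fog$locomotor_band)
  if (pl < fog$power_floor) return(fog$ratio_cap)
  min(fog$ratio_cap, pf / pl)
}

#' Windowed freeze ratio of an acceleration series
#'
#' Per window: the series is mean-detrended, Fourier-transformed, and the
#' one-sided power summed over the freeze band (3-10 Hz) is divided by
#' the power in the locomotor band (0-3 Hz); larger values indicate
#' stronger freezing. Windows whose locomotor power falls below a small
#' floor get the configured cap (never infinity) and are flagged
#' degenerate. Amplitude-invariant by construction (a ratio of powers).
#'
#' @param accel Uniformly sampled acceleration series.
#' @param fs Sampling rate (Hz), > 20.
#' @param config A `fogsim_config` (detector settings under `$fog`).
#' @return Data frame: `t` (window start, s), `ratio`, `degenerate`.
#' @export
freeze_ratio <- function(accel, fs, config = default_parameters()) {
  fog <- config$fog
  stopifnot(fs > 20)
  wn <- round(fog$window * fs); hp <- max(1, round(fog$hop * fs))
  if (length(accel) < wn) stop("freeze_ratio: series shorter than a window")
  starts <- seq(1, length(accel) - wn + 1, by = hp)
  out <- lapply(starts, function(i) {
    x <- accel[i:(i + wn - 1)]
    pl <- band_power(x, fs, fog$locomotor_band)
    deg <- pl < fog$power_floor
    data.frame(t = (i - 1) / fs,
               ratio = if (deg) fog$ratio_cap
                       else min(fog$ratio_cap,
                                band_power(x, fs, fog$freeze_band) / pl),
               degenerate = deg)
  })
  do.call(rbind, out)
}

#' Windowed bilateral correlation of the lower-leg angular velocities
#'
#' Per-window Pearson correlation between the left and right series.
#' Zero-variance windows get correlation 0 and a degenerate flag.
#'
#' @param left,right Equal-length series at the same sampling rate.
#' @param fs Sampling rate (Hz).
#' @param config A `fogsim_config`.
#' @return Data frame: `t` (window start, s), `r`, `degenerate`.
#' @export
bilateral_correlation <- function(left, right, fs,
                                  config = default_parameters()) {
  fog <- config$fog
  stopifnot(length(left) == length(right))
  wn <- round(fog$window * fs); hp <- max(1, round(fog$hop * fs))
  if (length(left) < wn)
    stop("bilateral_correlation: series shorter than a window")
  starts <- seq(1, length(left) - wn + 1, by = hp)
  out <- lapply(starts, function(i) {
    l <- left[i:(i + wn - 1)]; r <- right[i:(i + wn - 1)]
    deg <- stats::sd(l) == 0 || stats::sd(r) == 0
    data.frame(t = (i - 1) / fs,
               r = if (deg) 0 else stats::cor(l, r),
               degenerate = deg)
  })
  do.call(rbind, out)
}

# freeze ratio of a whole short segment treated as a single window,
# taking the larger of the two legs; used for the sweep's first-3-s value
first_window_freeze_ratio <- function(signals, config = default_parameters()) {
  fs <- 1 / stats::median(diff(signals$t))
  max(window_freeze_ratio(signals$accel_left, fs, config$fog),
      window_freeze_ratio(signals$accel_right, fs, config$fog))
}

#' Detect freezing-of-gait episodes
#'
#' A window is freezing-positive when its freeze ratio exceeds the
#' threshold (by default the larger of the two legs' ratios) AND the
#' bilateral coupling of the lower-leg angular velocities is low
#' (|Pearson r| below the correlation threshold; during normal
#' alternating gait the two shanks are strongly anti-phase coupled, so
#' the magnitude carries the coupling). Consecutive positive windows are
#' merged into episodes; episodes shorter than the minimum duration are
#' dropped. `is_fog` reports whether any episode intersects the analysis
#' window (the first 3 s by default, where the abnormal command acts).
#'
#' @param x A `fogsim_trajectory`, or a data frame with columns `t`,
#'   `accel_left`, `accel_right`, `omega_left`, `omega_right`.
#' @param config A `fogsim_config`.
#' @param leg Which leg's acceleration feeds the ratio: "max" (default),
#'   "left" or "right".
#' @return List of class `fogsim_fog`: `episodes` (data.frame start, end,
#'   peak_ratio, mean_correlation), `is_fog`, `windows` (per-window
#'   table).
#' @export
detect_fog <- function(x, config = default_parameters(),
                       leg = c("max", "left", "right")) {
  leg <- match.arg(leg)
  sig <- if (inherits(x, "fogsim_trajectory")) leg_signals(x) else x
  need <- c("t", "accel_left", "accel_right", "omega_left", "omega_right")
  stopifnot(all(need %in% names(sig)))
  fog <- config$fog
  fs <- 1 / stats::median(diff(sig$t))
  frl <- freeze_ratio(sig$accel_left, fs, config)
  frr <- freeze_ratio(sig$accel_right, fs, config)
  ratio <- switch(leg, max = pmax(frl$ratio, frr$ratio),
                  left = frl$ratio, right = frr$ratio)
  degenerate <- switch(leg, max = frl$degenerate | frr$degenerate,
                       left = frl$degenerate, right = frr$degenerate)
  bc <- bilateral_correlation(sig$omega_left, sig$omega_right, fs, config)
  # degenerate windows (no signal power / no variance) carry no evidence
  # of trembling and never fire
  w <- data.frame(t = frl$t, ratio = ratio, r = bc$r,
                  positive = ratio > fog$freeze_threshold &
                    abs(bc$r) < fog$corr_threshold &
                    !degenerate & !bc$degenerate)
  # merge runs of positive windows into episodes
  episodes <- NULL
  run <- rle(w$positive)
  idx_end <- cumsum(run$lengths)
  idx_start <- idx_end - run$lengths + 1
  t0 <- sig$t[1]
  for (j in seq_along(run$values)) {
    if (!run$values[j]) next
    i1 <- idx_start[j]; i2 <- idx_end[j]
    ep <- data.frame(start = t0 + w$t[i1],
                     end = t0 + w$t[i2] + fog$window,
                     peak_ratio = max(w$ratio[i1:i2]),
                     mean_correlation = mean(w$r[i1:i2]))
    episodes <- rbind(episodes, ep)
  }
  if (is.null(episodes))
    episodes <- data.frame(start = numeric(0), end = numeric(0),
                           peak_ratio = numeric(0),
                           mean_correlation = numeric(0))
  # windows span `window` seconds: merge episodes whose spans overlap
  if (nrow(episodes) > 1) {
    episodes <- episodes[order(episodes$start), , drop = FALSE]
    merged <- episodes[1, ]
    for (i in 2:nrow(episodes)) {
      last <- nrow(merged)
      if (episodes$start[i] <= merged$end[last]) {
        merged$end[last] <- max(merged$end[last], episodes$end[i])
        merged$peak_ratio[last] <- max(merged$peak_ratio[last],
                                       episodes$peak_ratio[i])
        merged$mean_correlation[last] <-
          mean(c(merged$mean_correlation[last],
                 episodes$mean_correlation[i]))
      } else merged <- rbind(merged, episodes[i, ])
    }
    episodes <- merged
  }
  episodes <- episodes[episodes$end - episodes$start >= fog$min_episode, ,
                       drop = FALSE]
  aw <- fog$analysis_window
  is_fog <- any(episodes$start <= aw[2] & episodes$end >= aw[1])
  structure(list(episodes = episodes, is_fog = is_fog, windows = w),
            class = "fogsim_fog")
}

#' @export
print.fogsim_fog <- function(x, ...) {
  cat(sprintf("fogsim FOG detection: %d episode(s); is_fog = %s\n",
              nrow(x$episodes), x$is_fog))
  if (nrow(x$episodes)) print(x$episodes, row.names = FALSE)
  invisible(x)
}
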