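#' Simulation configuration for synthetic sensorimotor EEG
#'
#' Bundles every knob of the synthetic-data generator: acquisition
#' parameters, the trial schedule of one motor-imagery (MI) run, the depth of
#' the lateralized event-related desynchronization (ERD) imposed on the mu
#' and beta rhythms, the 1/f background, and artifact rates.
#'
#' The trial structure is a 5-s baseline, a 3-s preparation cue, a 5-s MI
#' interval and an inter-trial interval drawn uniformly from 0--4 s. A run
#' holds 40 trials (20 per hand) in pseudorandomized order, three runs
#' (`T`, `NF1`, `NF2`) form a block, and three blocks form a session-level
#' dataset. During the MI interval the amplitude of the hemisphere
#' contralateral to the imagined hand is scaled by `sqrt(1 - depth)` so that
#' band power drops by exactly `depth`; the ipsilateral hemisphere receives
#' `ipsi_ratio * depth`.
#'
#' @param n_channels number of EEG channels (default 64).
#' @param fs sampling rate in Hz (default 500).
#' @param n_runs_per_block runs per MI block (default 3: `T`, `NF1`, `NF2`).
#' @param n_blocks number of MI blocks (default 3).
#' @param n_trials_per_run trials per run, must be even (default 40).
#' @param baseline_dur,cue_dur,mi_dur trial segment durations in seconds
#'   (defaults 5, 3, 5).
#' @param iti_range two numbers, the support of the uniform inter-trial
#'   interval in seconds (default `c(0, 4)`).
#' @param erd_depth_mu,erd_depth_beta fractional contralateral power decrease
#'   in the mu (8--12 Hz) and beta (13--30 Hz) band during MI, in `[0, 1]`.
#' @param ipsi_ratio fraction of the contralateral depth applied to the
#'   ipsilateral hemisphere (default 0.5).
#' @param noise_exponent slope `a` of the 1/f^a background (default 1).
#' @param snr amplitude ratio of each rhythm source to the in-band background
#'   noise at the source's peak sensor (default 3).
#' @param blink_rate,emg_rate artifact rates in events per minute (default 0).
#' @param seed integer seed fixing all randomness of the generator.
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_channels = 16, n_trials_per_run = 8, seed = 1)
#' sched <- generate_schedule(cfg)
#' @export
sim_config <- function(n_channels = 64, fs = 500,
                       n_runs_per_block = 3, n_blocks = 3,
                       n_trials_per_run = 40,
                       baseline_dur = 5, cue_dur = 3, mi_dur = 5,
                       iti_range = c(0, 4),
                       erd_depth_mu = 0.3, erd_depth_beta = 0.3,
                       ipsi_ratio = 0.5,
                       noise_exponent = 1, snr = 3,
                       blink_rate = 0, emg_rate = 0,
                       seed = 1L) {
  cfg <- list(
    n_channels = as.integer(n_channels), fs = fs,
    n_runs_per_block = as.integer(n_runs_per_block),
    n_blocks = as.integer(n_blocks),
    n_trials_per_run = as.integer(n_trials_per_run),
    baseline_dur = baseline_dur, cue_dur = cue_dur, mi_dur = mi_dur,
    iti_range = iti_range,
    erd_depth_mu = erd_depth_mu, erd_depth_beta = erd_depth_beta,
    ipsi_ratio = ipsi_ratio,
    noise_exponent = noise_exponent, snr = snr,
    blink_rate = blink_rate, emg_rate = emg_rate,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_channels < 4) stop_cfg("need at least 4 channels")
    if (fs <= 0) stop_cfg("fs must be positive")
    if (n_trials_per_run %% 2L != 0L)
      stop_cfg("n_trials_per_run must be even (balanced hands), got %d",
               n_trials_per_run)
    if (any(c(baseline_dur, cue_dur, mi_dur) <= 0))
      stop_cfg("all trial durations must be > 0")
    if (length(iti_range) != 2 || iti_range[1] < 0 ||
        iti_range[2] < iti_range[1])
      stop_cfg("iti_range must be c(lo, hi) with 0 <= lo <= hi")
    for (d in c(erd_depth_mu, erd_depth_beta))
      if (d < 0 || d > 1) stop_cfg("ERD depths must lie in [0, 1]")
    if (ipsi_ratio < 0 || ipsi_ratio > 1)
      stop_cfg("ipsi_ratio must lie in [0, 1]")
    if (snr <= 0) stop_cfg("snr must be positive")
    if (blink_rate < 0 || emg_rate < 0) stop_cfg("artifact rates must be >= 0")
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic MI-EEG configuration\n")
  cat(sprintf("  %d channels @ %g Hz; %d blocks x %d runs x %d trials\n",
              x$n_channels, x$fs, x$n_blocks, x$n_runs_per_block,
              x$n_trials_per_run))
  cat(sprintf("  trial: %g s baseline + %g s cue + %g s MI, ITI U(%g, %g) s\n",
              x$baseline_dur, x$cue_dur, x$mi_dur,
              x$iti_range[1], x$iti_range[2]))
  cat(sprintf("  ERD depth mu %.2f / beta %.2f, ipsi ratio %.2f, snr %g\n",
              x$erd_depth_mu, x$erd_depth_beta, x$ipsi_ratio, x$snr))
  cat(sprintf("  1/f exponent %g; blinks %g/min, EMG bursts %g/min; seed %d\n",
              x$noise_exponent, x$blink_rate, x$emg_rate, x$seed))
  invisible(x)
}

#' Generic equidistant 2-D electrode layout
#'
#' Places `n` electrodes on concentric rings of a unit disc (an idealization
#' of an equidistant cap) and labels three regions used by the generator and
#' by the scored CSP filter selection: the left and right sensorimotor
#' clusters and a frontal cluster.
#'
#' @param n number of electrodes.
#' @return data.frame with columns `label`, `x`, `y` (unit-disc coordinates,
#'   +x = right, +y = anterior) and `region`
#'   (`"left_sm"`, `"right_sm"`, `"frontal"`, `"other"`).
#' @export
equidistant_layout <- function(n = 64) {
  ## ring sizes ~ proportional to circumference
  pos <- matrix(0, 0, 2)
  n_rings <- max(2L, ceiling(sqrt(n / 3)))
  radii <- seq(0, 1, length.out = n_rings + 1L)[-1]
  weights <- radii / sum(radii)
  counts <- pmax(1L, round(weights * (n - 1L)))
  while (sum(counts) + 1L > n) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  while (sum(counts) + 1L < n) counts[which.max(radii)] <- counts[which.max(radii)] + 1L
  pos <- rbind(c(0, 0))
  for (r in seq_along(radii)) {
    k <- counts[r]
    th <- 2 * pi * (seq_len(k) - 1) / k + (r %% 2) * pi / k
    pos <- rbind(pos, cbind(radii[r] * sin(th), radii[r] * cos(th)))
  }
  pos <- pos[seq_len(n), , drop = FALSE]
  d_left  <- sqrt((pos[, 1] + 0.4)^2 + (pos[, 2] - 0.15)^2)
  d_right <- sqrt((pos[, 1] - 0.4)^2 + (pos[, 2] - 0.15)^2)
  region <- rep("other", n)
  region[rank(d_left,  ties.method = "first") <= max(3L, n %/% 10L)] <- "left_sm"
  region[rank(d_right, ties.method = "first") <= max(3L, n %/% 10L)] <- "right_sm"
  region[region == "other" & pos[, 2] > 0.6] <- "frontal"
  data.frame(label = sprintf("E%02d", seq_len(n)),
             x = pos[, 1], y = pos[, 2], region = region,
             stringsAsFactors = FALSE)
}

#' Central channel subset for CSP
#'
#' Returns the `n` channels closest to the vertex of the layout, emulating
#' the restriction of CSP fitting to a central subset of the cap (49 of 64
#' channels at full scale).
#'
#' @param layout a layout data.frame as from [equidistant_layout()].
#' @param n subset size; truncated to the number of available channels.
#' @return integer vector of channel indices, sorted.
#' @export
central_channels <- function(layout, n = 49) {
  n <- min(n, nrow(layout))
  r <- sqrt(layout$x^2 + layout$y^2)
  sort(order(r)[seq_len(n)])
}
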