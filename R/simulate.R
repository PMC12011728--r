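## Synthetic sensorimotor EEG generation: a small forward model with two
## lateralized mu/beta rhythm sources whose amplitude is attenuated during
## motor-imagery intervals, on top of spatially mixed 1/f background noise.

#' Gaussian-power-law ("1/f") noise
#'
#' White Gaussian noise shaped in the frequency domain so its power spectrum
#' falls off as `1/f^exponent`. The DC bin is zeroed.
#' @param n length in samples.
#' @param exponent spectral slope `a` in `1/f^a`.
#' @return numeric vector, unit variance.
#' @keywords internal
colored_noise <- function(n, exponent = 1) {
  if (exponent == 0) return(stats::rnorm(n))
  m <- stats::nextn(n, c(2, 3, 5))    # composite length: fast mixed-radix FFT
  x <- stats::rnorm(m)
  X <- stats::fft(x)
  k <- seq_len(m) - 1L
  f <- pmin(k, m - k)                 # two-sided frequency index
  scale <- c(0, f[-1]^(-exponent / 2))
  y <- Re(stats::fft(X * scale, inverse = TRUE))[seq_len(n)] / m
  y / stats::sd(y)
}

#' Band-limited Gaussian noise (ideal FFT mask)
#' @keywords internal
bandlimited_noise <- function(n, fs, f1, f2) {
  m <- stats::nextn(n, c(2, 3, 5))
  x <- stats::rnorm(m)
  X <- stats::fft(x)
  f <- pmin(seq_len(m) - 1L, m - (seq_len(m) - 1L)) * fs / m
  X[f < f1 | f > f2] <- 0
  y <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)] / m
  y / stats::sd(y)
}

## SD of one channel within a frequency band, via FFT mask.
band_sd <- function(x, fs, f1, f2) {
  n <- length(x)
  m <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(m - n)))
  f <- pmin(seq_len(m) - 1L, m - (seq_len(m) - 1L)) * fs / m
  X[f < f1 | f > f2] <- 0
  stats::sd(Re(stats::fft(X, inverse = TRUE))[seq_len(n)] / m)
}

gauss_topography <- function(layout, center, sigma = 0.3) {
  d2 <- (layout$x - center[1])^2 + (layout$y - center[2])^2
  exp(-d2 / (2 * sigma^2))
}

## Per-sample amplitude envelope for one hemisphere/band source: 1 outside
## MI, sqrt(1 - depth_eff) inside, with 0.25-s linear ramps.
erd_envelope <- function(n, fs, events, hemi, depth, ipsi_ratio, mi_dur) {
  lvl <- rep(1, n)
  if (depth > 0 && nrow(events)) {
    mi_len <- as.integer(round(mi_dur * fs))
    contra_hand <- if (hemi == "left") "right" else "left"
    for (i in seq_len(nrow(events))) {
      d_eff <- if (events$hand[i] == contra_hand) depth else ipsi_ratio * depth
      idx <- events$onset_sample[i] + seq_len(mi_len) - 1L
      idx <- idx[idx >= 1L & idx <= n]
      lvl[idx] <- sqrt(1 - d_eff)
    }
    lvl <- moving_average(lvl, max(1L, as.integer(round(0.25 * fs))))
  }
  lvl
}

#' Simulate a continuous multi-channel EEG recording
#'
#' Renders the events of (typically) one run as continuous EEG: four
#' narrow-band rhythm sources (left/right hemisphere x mu/beta) with
#' Gaussian spatial topographies over the sensorimotor clusters, amplitude-
#' attenuated during each MI interval so that contralateral band power drops
#' by exactly the configured depth (`sqrt(1 - depth)` on the amplitude
#' scale, 0.25-s ramps), on top of spatially mixed `1/f` background noise
#' scaled to a ~10 uV channel standard deviation. Each source's amplitude is
#' set so that its SD at the topography's peak sensor is `snr` times the
#' in-band background SD there.
#'
#' @param config a [sim_config()].
#' @param events an `event_table` with onsets local to this recording
#'   (e.g. one run extracted from [generate_schedule()]); `NULL` simulates
#'   run `T` of block 1 of the config's own schedule.
#' @param seed seed for this recording (default `config$seed`). The full
#'   pipeline derives distinct per-run seeds from the global seed.
#' @return an object of class `continuous_recording`: list with `data`
#'   (channels x samples matrix, uV), `fs`, `channel_labels`, `layout`
#'   and `events`.
#' @export
simulate_recording <- function(config, events = NULL, seed = config$seed) {
  validate_sim_config(config)
  if (is.null(events))
    events <- run_events(generate_schedule(config), "T", 1)
  fs <- config$fs
  n <- attr(events, "n_samples") %||%
    (max(0L, events$onset_sample) +
       as.integer(round((config$mi_dur + 4) * fs)))
  if (nrow(events)) {
    if (min(events$onset_sample) < 1L || max(events$onset_sample) > n)
      stop_cfg("event onsets do not fit in the simulated duration")
  }
  layout <- equidistant_layout(config$n_channels)
  C <- config$n_channels
  set.seed(seed)

  ## spatially mixed 1/f background + small independent sensor noise
  src <- matrix(0, C, n)
  for (i in seq_len(C)) src[i, ] <- colored_noise(n, config$noise_exponent)
  D2 <- outer(layout$x, layout$x, "-")^2 + outer(layout$y, layout$y, "-")^2
  A <- exp(-D2 / (2 * 0.3^2))
  A <- A / sqrt(rowSums(A^2))
  noise <- A %*% src + 0.1 * matrix(stats::rnorm(C * n), C, n)
  noise <- noise * (10 / stats::median(apply(noise, 1, stats::sd)))

  bands <- list(mu = c(8, 12, config$erd_depth_mu),
                beta = c(13, 30, config$erd_depth_beta))
  centers <- list(left = c(-0.4, 0.15), right = c(0.4, 0.15))
  data <- noise
  for (hemi in names(centers)) {
    topo <- gauss_topography(layout, centers[[hemi]])
    peak <- which.max(topo)
    for (bn in names(bands)) {
      b <- bands[[bn]]
      s <- bandlimited_noise(n, fs, b[1], b[2])
      env <- erd_envelope(n, fs, events, hemi, b[3],
                          config$ipsi_ratio, config$mi_dur)
      amp <- config$snr * band_sd(noise[peak, ], fs, b[1], b[2]) / max(topo)
      data <- data + topo %*% t(amp * s * env)
    }
  }
  structure(list(data = data, fs = fs, channel_labels = layout$label,
                 layout = layout, events = events),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("Continuous recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat(sprintf("  %d events; channel SD %.1f uV (median)\n",
              nrow(x$events), stats::median(apply(x$data, 1, stats::sd))))
  invisible(x)
}

#' Inject blink and EMG-burst artifacts
#'
#' Adds transients that exercise the artifact-rejection rules: blinks
#' (0.4-s raised-cosine deflections, frontal topography) at `blink_rate`
#' per minute, and EMG bursts (1--1.5 s of 40--200 Hz noise at high
#' amplitude) on the two outermost channels at `emg_rate` per minute.
#' Ground-truth intervals are attached as attribute `"artifacts"`.
#'
#' @param rec a `continuous_recording`.
#' @param config a [sim_config()] supplying the rates.
#' @param seed seed for artifact placement.
#' @return the recording with artifacts added; with rates of 0 the input is
#'   returned unchanged (empty ground-truth table).
#' @export
inject_artifacts <- function(rec, config, seed = config$seed + 1000L) {
  stopifnot(inherits(rec, "continuous_recording"))
  n <- ncol(rec$data); fs <- rec$fs
  minutes <- n / fs / 60
  gt <- data.frame(kind = character(), onset_sample = integer(),
                   duration = integer(), channel = integer())
  if (config$blink_rate == 0 && config$emg_rate == 0) {
    attr(rec, "artifacts") <- gt
    return(rec)
  }
  set.seed(seed)
  if (config$blink_rate > 0) {
    k <- stats::rpois(1, config$blink_rate * minutes)
    topo <- gauss_topography(rec$layout, c(0, 0.85), sigma = 0.25)
    len <- as.integer(round(0.4 * fs))
    wave <- 100 * 0.5 * (1 - cos(2 * pi * seq_len(len) / (len + 1)))
    for (i in seq_len(k)) {
      o <- sample.int(n - len, 1)
      rec$data[, o + seq_len(len) - 1L] <-
        rec$data[, o + seq_len(len) - 1L] + topo %*% t(wave)
      gt <- rbind(gt, data.frame(kind = "blink", onset_sample = o,
                                 duration = len, channel = NA_integer_))
    }
  }
  if (config$emg_rate > 0) {
    r <- sqrt(rec$layout$x^2 + rec$layout$y^2)
    emg_ch <- order(r, decreasing = TRUE)[1:2]
    k <- stats::rpois(1, config$emg_rate * minutes)
    for (i in seq_len(k)) {
      dur <- as.integer(round(stats::runif(1, 1, 1.5) * fs))
      o <- sample.int(n - dur, 1)
      ch <- emg_ch[1 + (i %% 2)]
      burst <- 50 * bandlimited_noise(dur, fs, 40, min(200, fs / 2 - 1))
      rec$data[ch, o + seq_len(dur) - 1L] <-
        rec$data[ch, o + seq_len(dur) - 1L] + burst
      gt <- rbind(gt, data.frame(kind = "emg", onset_sample = o,
                                 duration = dur, channel = ch))
    }
  }
  attr(rec, "artifacts") <- gt
  rec
}
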