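## Epoching, baseline handling, channel QC and artifact rejection.

#' Segment a continuous recording into epochs
#'
#' Cuts one epoch per event over the closed-open window `[window[1],
#' window[2])` in seconds relative to MI onset (time 0 = MI onset). Events
#' whose window exceeds the recording bounds are dropped; the count is
#' recorded in the attribute `"n_dropped"` and reported via a message.
#'
#' @param rec a `continuous_recording`.
#' @param events an `event_table`; defaults to the recording's own events.
#' @param window two numbers in seconds, e.g. `c(-7, 9)` for the offline
#'   analysis window (8000 samples at 500 Hz).
#' @return an object of class `epoch_set`: `data` (trials x channels x
#'   samples array), `time` (s, relative to MI onset), `fs`, per-trial
#'   `hand`/`run`/`block`/`trial_index`, rejection mask `rejected` with
#'   `reason`, `channel_labels`, `layout`.
#' @export
epoch_data <- function(rec, events = rec$events, window = c(-7, 9)) {
  stopifnot(inherits(rec, "continuous_recording"))
  fs <- rec$fs
  n <- ncol(rec$data)
  i0 <- as.integer(round(window[1] * fs))
  ns <- as.integer(round((window[2] - window[1]) * fs))
  start <- events$onset_sample + i0
  ok <- start >= 1L & (start + ns - 1L) <= n
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(sprintf("epoch_data: dropped %d event(s) outside recording bounds",
                    n_dropped))
  ev <- events[ok, , drop = FALSE]
  dat <- array(0, dim = c(nrow(ev), nrow(rec$data), ns))
  for (i in seq_len(nrow(ev)))
    dat[i, , ] <- rec$data[, start[ok][i] + seq_len(ns) - 1L]
  structure(list(
    data = dat,
    time = window[1] + (seq_len(ns) - 1L) / fs,
    fs = fs,
    hand = ev$hand, run = ev$run, block = ev$block,
    trial_index = ev$trial_index,
    rejected = rep(FALSE, nrow(ev)),
    reason = rep(NA_character_, nrow(ev)),
    channel_labels = rec$channel_labels,
    layout = rec$layout,
    n_dropped = n_dropped),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Epoch set: %d trials x %d channels x %d samples (%.1f to %.1f s)\n",
              d[1], d[2], d[3], x$time[1], x$time[length(x$time)] + 1 / x$fs))
  cat(sprintf("  hands: %d left / %d right; rejected: %d\n",
              sum(x$hand == "left"), sum(x$hand == "right"),
              sum(x$rejected)))
  invisible(x)
}

n_trials <- function(ep) dim(ep$data)[1]

kept_trials <- function(ep) which(!ep$rejected)

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the reference interval
#' (closed-open, seconds relative to MI onset).
#'
#' @param ep an `epoch_set`.
#' @param interval baseline interval, default `c(-6, -4)`.
#' @return the corrected `epoch_set`; the mean over the interval is 0
#'   afterwards.
#' @export
baseline_correct <- function(ep, interval = c(-6, -4)) {
  idx <- interval_index(interval, ep$time[1], ep$fs, length(ep$time))
  m <- apply(ep$data[, , idx, drop = FALSE], c(1, 2), mean)
  ep$data <- ep$data - as.vector(m)     # recycles over the sample dimension
  ep
}

#' Channel quality-control configuration
#'
#' @param sd_bound bad-channel boundary: channels whose overall SD lies
#'   outside `mean(SD) +/- sd_bound * sd(SD)` across channels are flagged
#'   (default 2).
#' @param msd_window moving-SD window in samples for the EMG burst rule
#'   (default 250).
#' @param msd_factor a trial is flagged when its centered moving SD exceeds
#'   `msd_factor` times the trial-channel's overall SD (default 2.5).
#' @param amp_threshold absolute amplitude threshold in uV for epoch
#'   rejection on band-passed EEG (default 100).
#' @return an object of class `qc_config`.
#' @export
qc_config <- function(sd_bound = 2, msd_window = 250, msd_factor = 2.5,
                      amp_threshold = 100) {
  stopifnot(sd_bound > 0, msd_window > 0, msd_factor > 0, amp_threshold > 0)
  structure(list(sd_bound = sd_bound, msd_window = as.integer(msd_window),
                 msd_factor = msd_factor, amp_threshold = amp_threshold),
            class = "qc_config")
}

#' Detect bad channels by standard-deviation outlier bounds
#'
#' Flags channels whose standard deviation lies outside
#' `mean(SD) +/- sd_bound * sd(SD)` computed across all channels.
#'
#' @param rec a `continuous_recording` (or channels x samples matrix).
#' @param qc a [qc_config()].
#' @return integer vector of bad channel indices (possibly empty).
#' @export
detect_bad_channels <- function(rec, qc = qc_config()) {
  x <- if (inherits(rec, "continuous_recording")) rec$data else rec
  if (nrow(x) < 3) stop_cfg("need at least 3 channels for channel QC")
  sds <- apply(x, 1, stats::sd)
  s <- stats::sd(sds)
  if (s == 0) return(integer())
  which(sds > mean(sds) + qc$sd_bound * s | sds < mean(sds) - qc$sd_bound * s)
}

#' Interpolate bad channels and re-reference to common average
#'
#' Bad channels are replaced by the inverse-distance-weighted mean of up to
#' 6 nearest good neighbors on the 2-D layout, then all channels are
#' re-referenced to the common average (per-sample channel mean becomes 0).
#'
#' @param ep an `epoch_set`.
#' @param bad_channels integer indices of bad channels (from
#'   [detect_bad_channels()]).
#' @param max_neighbors neighbors used for interpolation (default 6).
#' @return the re-referenced `epoch_set`.
#' @export
prepare_reference <- function(ep, bad_channels = integer(),
                              max_neighbors = 6) {
  C <- dim(ep$data)[2]
  if (length(bad_channels) > 0.25 * C)
    stop_cfg("more than 25%% of channels flagged bad (%d of %d): aborting",
             length(bad_channels), C)
  if (length(bad_channels)) {
    good <- setdiff(seq_len(C), bad_channels)
    for (ch in bad_channels) {
      d <- sqrt((ep$layout$x[good] - ep$layout$x[ch])^2 +
                  (ep$layout$y[good] - ep$layout$y[ch])^2)
      nb <- good[order(d)[seq_len(min(max_neighbors, length(good)))]]
      w <- 1 / pmax(sort(d)[seq_along(nb)], 1e-12)
      w <- w / sum(w)
      ep$data[, ch, ] <- apply(
        ep$data[, nb, , drop = FALSE] *
          rep(w, each = dim(ep$data)[1]), c(1, 3), sum)
    }
  }
  avg <- apply(ep$data, c(1, 3), mean)
  for (ch in seq_len(C)) ep$data[, ch, ] <- ep$data[, ch, ] - avg
  ep
}

#' Flag artifact-contaminated trials
#'
#' Two rules, joined by OR into the epoch set's rejection mask:
#' `"msd"` -- a trial is flagged when, on any channel, the centered
#' `msd_window`-sample moving standard deviation exceeds `msd_factor` times
#' that trial-channel's overall standard deviation (the EMG movement-
#' artifact rule); `"amplitude"` -- a trial is flagged when any sample
#' exceeds `amp_threshold` uV in magnitude (band-passed EEG rule).
#'
#' @param ep an `epoch_set`.
#' @param qc a [qc_config()].
#' @param method `"msd"` or `"amplitude"`.
#' @return the `epoch_set` with updated `rejected`/`reason`.
#' @export
artifact_mask <- function(ep, qc = qc_config(),
                          method = c("msd", "amplitude")) {
  method <- match.arg(method)
  d <- dim(ep$data)
  if (method == "msd" && qc$msd_window >= d[3])
    stop_cfg("msd_window (%d) must be shorter than the epoch (%d samples)",
             qc$msd_window, d[3])
  for (i in seq_len(d[1])) {
    hit <- FALSE
    for (ch in seq_len(d[2])) {
      x <- ep$data[i, ch, ]
      if (method == "msd") {
        s <- stats::sd(x)
        if (s > 0 && any(moving_sd(x, qc$msd_window) > qc$msd_factor * s)) {
          hit <- TRUE; break
        }
      } else if (any(abs(x) > qc$amp_threshold)) {
        hit <- TRUE; break
      }
    }
    if (hit && !ep$rejected[i]) {
      ep$rejected[i] <- TRUE
      ep$reason[i] <- method
    }
  }
  ep
}

#' Subset or concatenate epoch sets
#'
#' `subset_trials` keeps the given trial indices; `bind_epochs`
#' concatenates epoch sets recorded with identical channel sets and time
#' axes (e.g. the three runs of a block before block-level CSP).
#'
#' @param ep an `epoch_set`.
#' @param idx integer or logical trial indices.
#' @return an `epoch_set`.
#' @export
subset_trials <- function(ep, idx) {
  ep$data <- ep$data[idx, , , drop = FALSE]
  for (f in c("hand", "run", "block", "trial_index", "rejected", "reason"))
    ep[[f]] <- ep[[f]][idx]
  ep
}

#' @rdname subset_trials
#' @param eps list of `epoch_set`s.
#' @export
bind_epochs <- function(eps) {
  stopifnot(length(eps) >= 1)
  for (e in eps[-1]) {
    if (!isTRUE(all.equal(eps[[1]]$time, e$time)))
      stop_cfg("epoch sets have different time axes")
    if (dim(e$data)[2] != dim(eps[[1]]$data)[2])
      stop_cfg("epoch sets have different channel counts")
  }
  out <- eps[[1]]
  out$data <- do.call(abind_trials, lapply(eps, `[[`, "data"))
  for (f in c("hand", "run", "block", "trial_index", "rejected", "reason"))
    out[[f]] <- unlist(lapply(eps, `[[`, f), use.names = FALSE)
  out
}

## rbind for trials x channels x samples arrays
abind_trials <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  nt <- sum(vapply(arrs, function(a) dim(a)[1], 0L))
  out <- array(0, c(nt, d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}
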