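## Shared fixtures. Simulations here are deliberately small (12 channels,
## 12-20 trials) so the suite stays fast; full-scale generation is covered
## by the generator's own contracts.

quick_cfg <- function(..., n_channels = 12, n_trials_per_run = 12,
                      snr = 10, seed = 1) {
  sim_config(n_channels = n_channels, n_trials_per_run = n_trials_per_run,
             snr = snr, seed = seed, ...)
}

## one simulated run (continuous recording)
sim_run <- function(cfg, run = "T", block = 1) {
  simulate_recording(cfg, run_events(generate_schedule(cfg), run, block))
}

## hand-built epoch set from an explicit trials x channels x samples array
toy_epochs <- function(data, fs = 100, t0 = -7, hand = NULL,
                       layout = NULL) {
  d <- dim(data)
  structure(list(
    data = data,
    time = t0 + (seq_len(d[3]) - 1) / fs,
    fs = fs,
    hand = hand %||% rep(c("left", "right"), length.out = d[1]),
    run = rep("T", d[1]), block = rep(1L, d[1]),
    trial_index = seq_len(d[1]),
    rejected = rep(FALSE, d[1]),
    reason = rep(NA_character_, d[1]),
    channel_labels = sprintf("E%02d", seq_len(d[2])),
    layout = layout %||% equidistant_layout(d[2])),
    class = "epoch_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## standard offline band-pass chain used by several tests
band_chain <- function(rec) {
  pf <- preset_filters(rec$fs)
  fir_filter(fir_filter(rec, pf$hp8), pf$lp30)
}

## Welch-style band power oracle: mean periodogram power in [f1, f2] over
## 1-s segments starting at the given sample indices of one channel
welch_band_power <- function(x, starts, len, fs, f1, f2) {
  ps <- sapply(starts, function(s) {
    seg <- x[s + seq_len(len) - 1L]
    sp <- Mod(fft(seg))^2 / len
    f <- (seq_len(len) - 1) * fs / len
    sum(sp[f >= f1 & f <= f2 & f <= fs / 2]) / len
  })
  mean(ps)
}
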