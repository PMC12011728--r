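## Temporal filtering. Designs come from the signal package (window-method
## FIR via fir1 with a Hamming window; Butterworth IIR); application is
## either causal (online path, group delay = order/2 for linear-phase FIR)
## or zero-phase (offline path, forward-backward with odd-reflection edge
## padding of at least 3 x order samples).

#' Filter specification
#'
#' @param kind `"fir-highpass"`, `"fir-lowpass"` or `"butter-bandpass"`.
#' @param cutoff_hz one cutoff (FIR) or two band edges (Butterworth), Hz.
#' @param order filter order (e.g. 826 for the 8-Hz high-pass, 220 for the
#'   30-Hz low-pass, 4 for the 8--30 Hz Butterworth of the online path).
#' @param window FIR design window; only `"hamming"` is supported.
#' @param passband_ripple_db nominal passband ripple (dB) recorded for
#'   provenance with the Butterworth band-pass; it does not alter the
#'   maximally flat Butterworth design.
#' @param mode `"zero-phase"` (forward-backward) or `"causal"`.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("fir-highpass", "fir-lowpass",
                                 "butter-bandpass"),
                        cutoff_hz, order, window = "hamming",
                        passband_ripple_db = NULL,
                        mode = c("zero-phase", "causal")) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  if (!identical(window, "hamming")) stop_cfg("only the hamming window is supported")
  if (order <= 0) stop_cfg("filter order must be > 0")
  n_cut <- if (kind == "butter-bandpass") 2L else 1L
  if (length(cutoff_hz) != n_cut)
    stop_cfg("%s needs %d cutoff frequency(ies)", kind, n_cut)
  if (any(cutoff_hz <= 0)) stop_cfg("cutoffs must be positive")
  structure(list(kind = kind, cutoff_hz = cutoff_hz,
                 order = as.integer(order), window = window,
                 passband_ripple_db = passband_ripple_db, mode = mode),
            class = "filter_spec")
}

#' Standard filter presets of the analysis chain
#'
#' @param fs sampling rate (Hz), used only for validation at apply time.
#' @return named list of [filter_spec()]s: `hp8` (FIR high-pass 8 Hz,
#'   order 826), `lp30` (FIR low-pass 30 Hz, order 220) for the offline
#'   zero-phase chain; `butter_band` (4th-order Butterworth 8--30 Hz,
#'   0.5 dB nominal ripple, causal) for the online feature path; `emg_hp`
#'   (FIR high-pass 25 Hz, order 264) for the EMG artifact path.
#' @export
preset_filters <- function(fs = 500) {
  list(hp8 = filter_spec("fir-highpass", 8, 826),
       lp30 = filter_spec("fir-lowpass", 30, 220),
       butter_band = filter_spec("butter-bandpass", c(8, 30), 4,
                                 passband_ripple_db = 0.5, mode = "causal"),
       emg_hp = filter_spec("fir-highpass", 25, 264))
}

filter_coefficients <- function(spec, fs) {
  nyq <- fs / 2
  if (any(spec$cutoff_hz >= nyq))
    stop_cfg("cutoff frequency >= Nyquist (%g Hz)", nyq)
  w <- spec$cutoff_hz / nyq
  switch(spec$kind,
    "fir-highpass" = {
      o <- spec$order
      if (o %% 2L == 1L) o <- o + 1L   # even order => odd-length type-I HP
      list(b = as.numeric(signal::fir1(o, w, type = "high",
                                       window = signal::hamming(o + 1))),
           a = 1)
    },
    "fir-lowpass" = list(
      b = as.numeric(signal::fir1(spec$order, w, type = "low",
                                  window = signal::hamming(spec$order + 1))),
      a = 1),
    "butter-bandpass" = {
      bt <- signal::butter(spec$order, w, type = "pass")
      list(b = bt$b, a = bt$a)
    })
}

## same-length FIR convolution via FFT at a composite length (equivalent to
## stats/signal filter(b, 1, x), i.e. the causal convolution truncated to n)
fft_conv <- function(b, x) {
  n <- length(x)
  m <- stats::nextn(n + length(b) - 1L, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(m - n)))
  B <- stats::fft(c(b, numeric(m - length(b))))
  Re(stats::fft(X * B, inverse = TRUE))[seq_len(n)] / m
}

filter_one <- function(x, ba, mode, order) {
  run <- function(z) {
    if (length(ba$a) == 1 && ba$a[1] == 1)
      fft_conv(ba$b, z)
    else
      as.numeric(signal::filter(ba$b, ba$a, z))
  }
  if (mode == "causal") return(run(x))
  n <- length(x)
  pad <- min(3L * order, n - 1L)
  left <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  z <- c(left, x, right)
  z <- run(z)
  z <- rev(run(rev(z)))
  z[pad + seq_len(n)]
}

#' Apply a temporal filter
#'
#' Filters every channel of a recording (or every row of a plain matrix).
#' Zero-phase mode applies the filter forward and backward after odd-
#' reflection padding of `3 * order` samples, so narrow-band components
#' suffer no group delay; causal mode applies a single forward pass
#' (linear-phase FIR group delay = `order/2` samples).
#'
#' @param rec a `continuous_recording`, or a channels x samples matrix.
#' @param spec a [filter_spec()].
#' @param fs sampling rate; taken from the recording when available.
#' @return the filtered recording (or matrix).
#' @export
fir_filter <- function(rec, spec, fs = NULL) {
  stopifnot(inherits(spec, "filter_spec"))
  if (inherits(rec, "continuous_recording")) {
    rec$data <- fir_filter(rec$data, spec, fs = rec$fs)
    return(rec)
  }
  if (is.null(fs)) stop_cfg("fs is required when filtering a bare matrix")
  ba <- filter_coefficients(spec, fs)
  t(apply(rec, 1, filter_one, ba = ba, mode = spec$mode, order = spec$order))
}

#' Frequency response of a filter specification
#'
#' Magnitude response evaluated at the requested frequencies. For
#' zero-phase specifications the effective (forward-backward) magnitude
#' `|H|^2` is returned.
#'
#' @param spec a [filter_spec()].
#' @param fs sampling rate (Hz).
#' @param freq frequencies (Hz) at which to evaluate.
#' @return numeric vector of magnitudes.
#' @export
filter_response <- function(spec, fs, freq) {
  ba <- filter_coefficients(spec, fs)
  h <- vapply(freq, function(f) {
    z <- exp(-1i * 2 * pi * f / fs * (seq_along(ba$b) - 1))
    num <- sum(ba$b * z)
    den <- if (length(ba$a) > 1)
      sum(ba$a * exp(-1i * 2 * pi * f / fs * (seq_along(ba$a) - 1)))
    else 1
    Mod(num / den)
  }, 0)
  if (spec$mode == "zero-phase") h^2 else h
}
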