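#' erdnf: motor-imagery neurofeedback simulation and ERD analysis
#'
#' @keywords internal
"_PACKAGE"

## Shared internal helpers. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)

## Closed-open [start, end) sample index range for a time interval expressed
## in seconds on an epoch/recording time axis starting at `t0`.
interval_index <- function(interval, t0, fs, n) {
  i0 <- round((interval[1] - t0) * fs) + 1L
  i1 <- round((interval[2] - t0) * fs)        # end-exclusive
  if (i0 < 1L || i1 > n || i1 < i0)
    stop_cfg("interval [%g, %g) s falls outside the available time axis",
             interval[1], interval[2])
  seq.int(i0, i1)
}

## Centered moving average with edge truncation; width in samples.
## A step function smoothed this way acquires linear ramps of `width` samples.
moving_average <- function(x, width) {
  width <- as.integer(width)
  if (width <= 1L) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- width %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (width - half - 1L), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## Centered moving standard deviation (window truncated at the edges).
moving_sd <- function(x, width) {
  width <- as.integer(width)
  n <- length(x)
  cs1 <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  half <- width %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (width - half - 1L), n)
  w <- hi - lo + 1L
  s1 <- cs1[hi + 1L] - cs1[lo]
  s2 <- cs2[hi + 1L] - cs2[lo]
  v <- (s2 - s1^2 / w) / pmax(w - 1L, 1L)
  sqrt(pmax(v, 0))
}

## Content hash used by the pipeline manifest (md5 of a serialized object).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
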