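#' Generate a pseudorandomized trial schedule
#'
#' Builds the event table for a full synthetic session: `n_blocks` blocks of
#' `n_runs_per_block` runs (`T`, `NF1`, `NF2`, ...) with `n_trials_per_run`
#' trials each, half left-hand and half right-hand, in pseudorandomized
#' order with at most 3 consecutive same-hand trials. Each trial occupies
#' `baseline + cue + MI + ITI` seconds with the inter-trial interval drawn
#' uniformly from `iti_range`. Event onsets mark MI onset, in samples, on a
#' global session timeline in which runs are laid end to end (each run ends
#' with a 4-s tail so that epochs extending 9 s past the last MI onset fit).
#'
#' @param config a [sim_config()].
#' @return a data.frame of class `event_table` with columns `onset_sample`
#'   (integer, MI onset), `hand` (`"left"`/`"right"`), `run` (`"T"`,
#'   `"NF1"`, `"NF2"`, ...), `block` (integer) and `trial_index` (integer,
#'   within run). Attribute `run_bounds` holds each run's first and last
#'   sample on the session timeline.
#' @export
generate_schedule <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  fs <- config$fs
  run_names <- c("T", "NF1", "NF2", paste0("NF", seq_len(97) + 2))
  runs <- run_names[seq_len(config$n_runs_per_block)]
  tail_pad <- 4                        # s, after the last MI interval

  rows <- list()
  bounds <- list()
  offset <- 0L
  for (b in seq_len(config$n_blocks)) {
    for (r in runs) {
      nt <- config$n_trials_per_run
      run_start <- offset + 1L
      if (nt > 0L) {
        hands <- pseudorandom_hands(nt)
        iti <- stats::runif(nt, config$iti_range[1], config$iti_range[2])
        trial_dur <- config$baseline_dur + config$cue_dur + config$mi_dur + iti
        starts <- cumsum(c(0, trial_dur[-nt]))
        mi_onset <- starts + config$baseline_dur + config$cue_dur
        onset_sample <- offset + as.integer(round(mi_onset * fs)) + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          onset_sample = onset_sample, hand = hands, run = r, block = b,
          trial_index = seq_len(nt), stringsAsFactors = FALSE)
        run_len <- as.integer(round((sum(trial_dur) + tail_pad) * fs))
      } else {
        run_len <- as.integer(round(tail_pad * fs))
      }
      bounds[[length(bounds) + 1L]] <- data.frame(
        run = r, block = b, first_sample = run_start,
        last_sample = offset + run_len)
      offset <- offset + run_len
    }
  }
  ev <- if (length(rows)) do.call(rbind, rows) else
    data.frame(onset_sample = integer(), hand = character(),
               run = character(), block = integer(),
               trial_index = integer(), stringsAsFactors = FALSE)
  attr(ev, "run_bounds") <- do.call(rbind, bounds)
  attr(ev, "fs") <- fs
  class(ev) <- c("event_table", "data.frame")
  ev
}

## Balanced left/right sequence, no more than 3 consecutive repeats.
## Sequential construction weighted by the remaining counts; the rare
## dead-ends near the end of the sequence trigger a restart.
pseudorandom_hands <- function(n) {
  if (n == 0L) return(character())
  repeat {
    rem <- c(left = n %/% 2L, right = n %/% 2L)
    out <- character(n)
    last <- ""; streak <- 0L; ok <- TRUE
    for (i in seq_len(n)) {
      cand <- names(rem)[rem > 0L]
      if (streak >= 3L) cand <- setdiff(cand, last)
      if (!length(cand)) { ok <- FALSE; break }
      h <- if (length(cand) == 1L) cand else
        sample(cand, 1L, prob = rem[cand])
      out[i] <- h
      streak <- if (identical(h, last)) streak + 1L else 1L
      last <- h
      rem[h] <- rem[h] - 1L
    }
    if (ok) return(out)
  }
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("Event table: %d trials (%d left / %d right), %d block(s)\n",
              nrow(x), sum(x$hand == "left"), sum(x$hand == "right"),
              length(unique(x$block))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Extract one run's events from a session schedule
#'
#' Returns the schedule subset for one run with onsets rebased to that
#' run's own recording timeline (first sample of the run = sample 1), as
#' expected by [simulate_recording()]. The run's length in samples is
#' attached as attribute `"n_samples"`.
#'
#' @param schedule an `event_table` from [generate_schedule()].
#' @param run run name (`"T"`, `"NF1"`, `"NF2"`).
#' @param block block number.
#' @return an `event_table` for the run.
#' @export
run_events <- function(schedule, run, block) {
  rb <- attr(schedule, "run_bounds")
  sel <- rb$run == run & rb$block == block
  if (!any(sel)) stop_cfg("run %s / block %d not in schedule", run, block)
  first <- rb$first_sample[sel]
  ev <- schedule[schedule$run == run & schedule$block == block, , drop = FALSE]
  ev$onset_sample <- ev$onset_sample - first + 1L
  attr(ev, "n_samples") <- rb$last_sample[sel] - first + 1L
  attr(ev, "fs") <- attr(schedule, "fs")
  class(ev) <- c("event_table", "data.frame")
  ev
}
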