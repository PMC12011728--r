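## Event-related desynchronization. Power is averaged across trials first,
## then expressed as relative change against the mean power of the
## pre-stimulus reference interval: ERD% = (A - R) / R * 100, with A the
## trial-averaged power timecourse and R the mean of A over the reference
## interval. Negative values are desynchronization.

#' Compute an ERD timecourse from CSP-projected epochs
#'
#' Squares the single virtual channel, averages across non-rejected trials,
#' applies an optional moving-average smoothing, and normalizes to percent
#' change relative to the reference interval.
#'
#' @param ep a single-channel `epoch_set` (from [apply_csp()]).
#' @param reference reference interval in seconds, default `c(-6, -4)`.
#' @param smooth moving-average window in seconds (default 0.25; 0
#'   disables smoothing).
#' @param laterality stored metadata tag (`"contra"` or `"ipsi"`).
#' @return an object of class `erd_timecourse`: `time`, `erd` (percent),
#'   `power` (trial-averaged smoothed power, uV^2), `ref_power` (scalar R),
#'   `n_trials`, `laterality`, `run`, `block`, `fs`.
#' @export
compute_erd <- function(ep, reference = c(-6, -4), smooth = 0.25,
                        laterality = "contra") {
  stopifnot(inherits(ep, "epoch_set"))
  if (dim(ep$data)[2] != 1)
    stop_cfg("compute_erd expects a single (CSP-projected) channel")
  keep <- kept_trials(ep)
  if (!length(keep)) stop_cfg("no non-rejected trials")
  P <- ep$data[keep, 1, , drop = FALSE]^2
  A <- apply(P, 3, mean)
  if (smooth > 0)
    A <- moving_average(A, max(1L, as.integer(round(smooth * ep$fs))))
  ridx <- interval_index(reference, ep$time[1], ep$fs, length(ep$time))
  R <- mean(A[ridx])
  if (R <= 0) stop_cfg("reference power is not positive")
  structure(list(time = ep$time, erd = (A - R) / R * 100,
                 power = A, ref_power = R, n_trials = length(keep),
                 laterality = laterality,
                 run = unique(ep$run), block = unique(ep$block),
                 fs = ep$fs, reference = reference),
            class = "erd_timecourse")
}

#' @export
print.erd_timecourse <- function(x, ...) {
  cat(sprintf("ERD timecourse (%s, %d trials): %.1f to %.1f s\n",
              x$laterality, x$n_trials, x$time[1],
              x$time[length(x$time)] + 1 / x$fs))
  mi <- x$time >= 0.5 & x$time < 4.5
  cat(sprintf("  mean ERD over 0.5-4.5 s: %.1f%%\n", mean(x$erd[mi])))
  invisible(x)
}

#' @export
plot.erd_timecourse <- function(x, ...) {
  graphics::plot(x$time, x$erd, type = "l", xlab = "time re MI onset [s]",
                 ylab = "relative power [%]", ...)
  graphics::abline(h = 0, v = c(0, 5), lty = 3)
  invisible(x)
}

#' Average left- and right-hand contralateral ERD timecourses
#'
#' Pointwise unweighted mean of the two relative-power curves; trial counts
#' are summed.
#'
#' @param left_tc,right_tc `erd_timecourse`s on the same time axis and
#'   laterality.
#' @return an `erd_timecourse`.
#' @export
average_contralateral <- function(left_tc, right_tc) {
  if (!isTRUE(all.equal(left_tc$time, right_tc$time)))
    stop_cfg("time axes differ")
  if (!identical(left_tc$laterality, right_tc$laterality))
    stop_cfg("lateralities differ")
  out <- left_tc
  out$erd <- (left_tc$erd + right_tc$erd) / 2
  out$power <- (left_tc$power + right_tc$power) / 2
  out$ref_power <- (left_tc$ref_power + right_tc$ref_power) / 2
  out$n_trials <- left_tc$n_trials + right_tc$n_trials
  out$run <- unique(c(left_tc$run, right_tc$run))
  out
}

#' Pool ERD across runs at the trial level
#'
#' Trial-count-weighted pooling of the trial-averaged power curves (and
#' reference powers) of several runs, after which the relative change is
#' recomputed -- equivalent to concatenating the runs' trials before
#' averaging. Used to form the NF measure from runs NF1 and NF2.
#'
#' @param ... `erd_timecourse`s on the same time axis.
#' @return an `erd_timecourse` with `n_trials` the total.
#' @export
pool_runs <- function(...) {
  tcs <- list(...)
  if (length(tcs) == 1 && is.list(tcs[[1]]) &&
      !inherits(tcs[[1]], "erd_timecourse")) tcs <- tcs[[1]]
  stopifnot(length(tcs) >= 1)
  for (tc in tcs[-1])
    if (!isTRUE(all.equal(tcs[[1]]$time, tc$time)))
      stop_cfg("time axes differ")
  w <- vapply(tcs, `[[`, 0, "n_trials")
  A <- Reduce(`+`, Map(function(tc, wi) wi * tc$power, tcs, w)) / sum(w)
  R <- sum(w * vapply(tcs, `[[`, 0, "ref_power")) / sum(w)
  out <- tcs[[1]]
  out$power <- A
  out$ref_power <- R
  out$erd <- (A - R) / R * 100
  out$n_trials <- sum(w)
  out$run <- unlist(lapply(tcs, `[[`, "run"))
  out
}

#' Scalar block summary: training vs neurofeedback ERD
#'
#' Reduces the ERD timecourses of one block's three runs to the two scalars
#' entering the statistics: `T_MI_ERD` (mean ERD of the training run over
#' the MI window) and `NF_MI_ERD` (mean ERD over the MI window after
#' pooling the trials of NF1 and NF2).
#'
#' @param tcs named list with elements `T`, `NF1`, `NF2`, each an
#'   `erd_timecourse` (contralateral, hand-averaged).
#' @param mi_window scalar-summary window in seconds (default
#'   `c(0.5, 4.5)`; `c(0, 5)` selects the full MI interval).
#' @param participant,block identifiers carried into the output row.
#' @return one-row data.frame: `participant`, `block`, `T_MI_ERD`,
#'   `NF_MI_ERD`, `n_trials_T`, `n_trials_NF`.
#' @export
summarize_block <- function(tcs, mi_window = c(0.5, 4.5),
                            participant = NA, block = NA) {
  missing_runs <- setdiff(c("T", "NF1", "NF2"), names(tcs))
  if (length(missing_runs))
    stop_cfg("missing run(s): %s", paste(missing_runs, collapse = ", "))
  mi_mean <- function(tc) {
    idx <- interval_index(mi_window, tc$time[1], tc$fs, length(tc$time))
    mean(tc$erd[idx])
  }
  nf <- pool_runs(tcs$NF1, tcs$NF2)
  if (is.na(block)) block <- tcs$T$block[1]
  data.frame(participant = participant, block = block,
             T_MI_ERD = mi_mean(tcs$T), NF_MI_ERD = mi_mean(nf),
             n_trials_T = tcs$T$n_trials, n_trials_NF = nf$n_trials)
}

#' Baseline power of an epoch set
#'
#' Mean squared amplitude over the reference interval, averaged over all
#' non-rejected trials (trials of both NF runs are pooled upstream to give
#' one baseline measure per block).
#'
#' @param ep an `epoch_set` (single CSP channel or raw channels; all
#'   channels are averaged).
#' @param interval reference interval in seconds, default `c(-6, -4)`.
#' @return scalar power (uV^2).
#' @export
baseline_power <- function(ep, interval = c(-6, -4)) {
  keep <- kept_trials(ep)
  if (!length(keep)) stop_cfg("no non-rejected trials")
  idx <- interval_index(interval, ep$time[1], ep$fs, length(ep$time))
  mean(ep$data[keep, , idx, drop = FALSE]^2)
}
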