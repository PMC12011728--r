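## End-to-end orchestration: simulate -> preprocess -> CSP -> neurofeedback
## -> ERD -> statistics, with a run manifest proving the no-leakage
## calibration chain (run T calibrates NF1, NF1 calibrates NF2).

#' Pipeline configuration
#'
#' @param sim a [sim_config()] describing one run's acquisition and the
#'   generator's ERD depths (run `T` uses these depths verbatim).
#' @param n_subjects named integer vector of subjects per group, e.g.
#'   `c(quiet_rest = 17, documentaries = 17)`; a single unnamed number
#'   simulates one group.
#' @param qc a [qc_config()].
#' @param nf_depth_gain additional ERD depth (both bands) during NF runs
#'   relative to run `T` -- the built-in neurofeedback effect
#'   (default 0.15).
#' @param group_depth_effect additional depth applied to every run of the
#'   second group (default 0: groups identical, the study's null).
#' @param csp_window,csp_gamma,select_mode CSP settings (see [csp()]).
#' @param n_central size of the central channel subset for CSP
#'   (default 49, truncated to the montage).
#' @param nf_k,nf_gamma classifier settings (see [lda_cv()]).
#' @param erd_reference,erd_smooth,mi_window ERD settings (see
#'   [compute_erd()] and [summarize_block()]).
#' @param holm_variant see [holm_adjust()].
#' @param online run the online calibration chain (CSP + classifier
#'   triplet + borders per run, feedback traces for NF runs).
#' @param seed global seed; all per-run seeds are derived from it.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            n_subjects = c(quiet_rest = 17,
                                           documentaries = 17),
                            qc = qc_config(),
                            nf_depth_gain = 0.15,
                            group_depth_effect = 0,
                            csp_window = c(0.5, 4.5), csp_gamma = 0.05,
                            select_mode = "scored", n_central = 49,
                            nf_k = 7, nf_gamma = 0.05,
                            erd_reference = c(-6, -4), erd_smooth = 0.25,
                            mi_window = c(0.5, 4.5),
                            holm_variant = "standard",
                            online = TRUE,
                            seed = 1L) {
  if (is.null(names(n_subjects)))
    names(n_subjects) <- c("quiet_rest", "documentaries")[seq_along(n_subjects)]
  structure(list(sim = sim, n_subjects = n_subjects, qc = qc,
                 nf_depth_gain = nf_depth_gain,
                 group_depth_effect = group_depth_effect,
                 csp_window = csp_window, csp_gamma = csp_gamma,
                 select_mode = select_mode, n_central = n_central,
                 nf_k = nf_k, nf_gamma = nf_gamma,
                 erd_reference = erd_reference, erd_smooth = erd_smooth,
                 mi_window = mi_window, holm_variant = holm_variant,
                 online = online, seed = as.integer(seed)),
            class = "pipeline_config")
}

derive_seed <- function(seed, ...) {
  idx <- c(...)
  as.integer((seed + sum(idx * c(1000003, 10007, 101, 7)[seq_along(idx)])) %%
               2147483647)
}

#' Run the full analysis pipeline on synthetic data
#'
#' For every group, subject and block: simulates the three runs (`T`,
#' `NF1`, `NF2`; NF runs carry `nf_depth_gain` extra ERD depth), runs the
#' offline path (zero-phase 8/30-Hz FIR chain, epoching from -7 to 9 s,
#' baseline correction, bad-channel interpolation and common-average
#' reference, amplitude-based trial rejection, block-level CSP over the
#' pooled runs, contralateral ERD, block summaries with baseline power)
#' and, when `config$online` is set, the online calibration chain (causal
#' 8--30 Hz Butterworth, run-level CSP, classifier triplet and borders fit
#' on the preceding run, feedback traces for NF1 and NF2). Ends with the
#' statistics stage.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: `summaries` (one row per
#'   participant x block), `stats` (see [stats_stage()]), `feedback`
#'   (per-bin feedback traces of the NF runs, if online), `manifest`
#'   (stage bookkeeping with input/output hashes and trial counts),
#'   `config`.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  pf <- preset_filters(config$sim$fs)
  groups <- names(config$n_subjects)
  summaries <- list(); manifest <- list(); feedback <- list()
  log_stage <- function(...) manifest[[length(manifest) + 1L]] <<-
    data.frame(..., timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
               stringsAsFactors = FALSE)

  for (gi in seq_along(groups)) {
    for (s in seq_len(config$n_subjects[gi])) {
      for (b in seq_len(config$sim$n_blocks)) {
        eps_off <- list(); eps_on <- list()
        for (ri in 1:3) {
          r <- c("T", "NF1", "NF2")[ri]
          gain <- if (r == "T") 0 else config$nf_depth_gain
          geff <- if (gi == 2) config$group_depth_effect else 0
          cfg_r <- config$sim
          cfg_r$n_blocks <- 1L; cfg_r$n_runs_per_block <- 1L
          cfg_r$erd_depth_mu <- min(1, cfg_r$erd_depth_mu + gain + geff)
          cfg_r$erd_depth_beta <- min(1, cfg_r$erd_depth_beta + gain + geff)
          cfg_r$seed <- derive_seed(config$seed, gi, s, b, ri)
          ev <- run_events(generate_schedule(cfg_r), "T", 1)
          ev$run <- r; ev$block <- b
          rec <- simulate_recording(cfg_r, ev)
          if (cfg_r$blink_rate > 0 || cfg_r$emg_rate > 0)
            rec <- inject_artifacts(rec, cfg_r)
          in_hash <- object_hash(rec$data)

          bad <- detect_bad_channels(rec, config$qc)
          recf <- fir_filter(fir_filter(rec, pf$hp8), pf$lp30)
          ep <- epoch_data(recf, ev, window = c(-7, 9))
          ep <- baseline_correct(ep, config$erd_reference)
          ep <- prepare_reference(ep, bad)
          ep <- artifact_mask(ep, config$qc, "amplitude")
          eps_off[[r]] <- ep
          log_stage(stage = "preprocess", group = groups[gi],
                    participant = s, block = b, run = r,
                    train_run = NA, score_run = NA,
                    n_kept = sum(!ep$rejected), n_rejected = sum(ep$rejected),
                    input_hash = in_hash, output_hash = object_hash(ep$data))
          if (config$online) {
            reco <- fir_filter(rec, pf$butter_band)
            eps_on[[r]] <- epoch_data(reco, ev, window = c(-7, 5))
          }
        }

        if (config$online) {
          ## calibration chain: T -> NF1 -> NF2 (never score the training run)
          for (step in list(c("T", "NF1"), c("NF1", "NF2"))) {
            tr <- step[1]; sc <- step[2]
            model <- csp(eps_on[[tr]], config$csp_window, config$csp_gamma,
                         channels = central_channels(eps_on[[tr]]$layout,
                                                     config$n_central),
                         select_mode = config$select_mode)
            trip <- train_nf(eps_on[[tr]], model, k = config$nf_k,
                             gamma = config$nf_gamma)
            proj <- apply_csp(eps_on[[sc]], model, "both")
            mi <- extract_features(proj, "mi")
            tracep <- map_feedback(classify_stream(mi, trip), mi$hand,
                                   trip$borders)
            tracep$trial <- mi$trial; tracep$bin_onset <- mi$bin_onset
            tracep$group <- groups[gi]; tracep$participant <- s
            tracep$block <- b; tracep$run <- sc
            feedback[[length(feedback) + 1L]] <- tracep
            log_stage(stage = "neurofeedback", group = groups[gi],
                      participant = s, block = b, run = sc,
                      train_run = tr, score_run = sc,
                      n_kept = length(unique(mi$trial)), n_rejected = 0L,
                      input_hash = object_hash(trip$borders),
                      output_hash = object_hash(tracep))
          }
        }

        pooled <- bind_epochs(eps_off)
        model_b <- csp(pooled, config$csp_window, config$csp_gamma,
                       channels = central_channels(pooled$layout,
                                                   config$n_central),
                       select_mode = config$select_mode)
        tcs <- lapply(eps_off, function(ep) {
          contra <- apply_csp(ep, model_b, "contra")
          erd_hand <- function(h)
            compute_erd(subset_trials(contra, contra$hand == h &
                                        !contra$rejected),
                        config$erd_reference, config$erd_smooth)
          average_contralateral(erd_hand("left"), erd_hand("right"))
        })
        nf_pool <- bind_epochs(list(apply_csp(eps_off$NF1, model_b, "contra"),
                                    apply_csp(eps_off$NF2, model_b, "contra")))
        row <- summarize_block(tcs, config$mi_window,
                               participant = sprintf("%s_%02d", groups[gi], s),
                               block = b)
        row$group <- groups[gi]
        row$baseline_power <- baseline_power(nf_pool, config$erd_reference)
        summaries[[length(summaries) + 1L]] <- row
        log_stage(stage = "erd", group = groups[gi], participant = s,
                  block = b, run = "block", train_run = NA, score_run = NA,
                  n_kept = row$n_trials_T + row$n_trials_NF, n_rejected = 0L,
                  input_hash = object_hash(model_b$W),
                  output_hash = object_hash(row))
      }
    }
  }
  summaries <- do.call(rbind, summaries)
  stats <- stats_stage(summaries, config$holm_variant)
  structure(list(summaries = summaries, stats = stats,
                 feedback = if (length(feedback))
                   do.call(rbind, feedback) else NULL,
                 manifest = do.call(rbind, manifest), config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d participants x %d blocks (%s)\n",
              length(unique(x$summaries$participant)),
              length(unique(x$summaries$block)),
              paste(names(x$config$n_subjects), collapse = " vs ")))
  cat("Paired T-vs-NF table:\n")
  print(format_stats_table(x$stats$table1), row.names = FALSE)
  invisible(x)
}

format_stats_table <- function(tab) {
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], function(v) round(v, 3))
  tab
}

#' Export pipeline tables as CSV
#'
#' Writes `summaries.csv`, `table1.csv`, `table2.csv`, `baseline.csv`,
#' `anova.csv` and `manifest.csv` (those present) with full numeric
#' precision, so that re-reading a summary CSV and re-running the
#' statistics stage reproduces identical statistics.
#'
#' @param result a `pipeline_result` (or a list with `summaries`,
#'   `stats`, `manifest`).
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
export_tables <- function(result, dir) {
  if (is.null(result$summaries) || !nrow(result$summaries))
    stop_cfg("export_tables: the erd stage produced no block summaries")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wr <- function(df, name) {
    if (is.null(df)) return()
    p <- file.path(dir, paste0(name, ".csv"))
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths[[length(paths) + 1L]] <<- p
  }
  wr(result$summaries, "summaries")
  wr(result$stats$table1, "table1")
  wr(result$stats$table2, "table2")
  wr(result$stats$baseline, "baseline")
  wr(result$stats$anova, "anova")
  wr(result$manifest, "manifest")
  invisible(unlist(paths))
}

#' Read exported block summaries
#' @param path path to a `summaries.csv` written by [export_tables()].
#' @return data.frame of block summaries.
#' @export
read_summaries <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
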