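## Result-table builders mirroring the study's two tables: per-block paired
## tests of training-run vs neurofeedback-run ERD, and per-block
## independent group comparisons, each with Holm-adjusted p-values.

#' Per-block paired comparison of training vs neurofeedback ERD
#'
#' For every block, a one-sided paired t-test of `T_MI_ERD` against
#' `NF_MI_ERD` (training ERD expected less negative than NF ERD), with
#' Cohen's d and its one-sided 95% CI, Holm-adjusted across blocks.
#'
#' @param summaries data.frame with columns `participant`, `block`,
#'   `T_MI_ERD`, `NF_MI_ERD` (one row per participant x block).
#' @param holm_variant passed to [holm_adjust()].
#' @return data.frame with columns `block`, `t`, `df`, `p`, `p_holm`, `d`,
#'   `ci_lo`, `ci_hi`, `N`, `M_T`, `SD_T`, `M_NF`, `SD_NF`.
#' @export
table1_stats <- function(summaries, holm_variant = "standard") {
  blocks <- sort(unique(summaries$block))
  rows <- lapply(blocks, function(b) {
    s <- summaries[summaries$block == b, ]
    s <- s[order(s$participant), ]
    tt <- paired_ttest(s$T_MI_ERD, s$NF_MI_ERD, alternative = "greater")
    data.frame(block = b, t = tt$t, df = tt$df, p = tt$p, p_holm = NA,
               d = tt$d, ci_lo = tt$ci_d[1], ci_hi = tt$ci_d[2],
               N = tt$n, M_T = tt$mean_a, SD_T = tt$sd_a,
               M_NF = tt$mean_b, SD_NF = tt$sd_b)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p, holm_variant)
  out
}

#' Per-block independent group comparison of neurofeedback ERD
#'
#' For every block, a pooled-variance independent t-test of `NF_MI_ERD`
#' between the two groups, oriented as reference group minus the other
#' (documentaries minus quiet rest in the study's layout), with Cohen's d,
#' the 95% CI of the mean difference, Holm adjustment across blocks, and
#' Shapiro-Wilk / Levene assumption checks attached.
#'
#' @param summaries data.frame with columns `participant`, `group`,
#'   `block`, `NF_MI_ERD`.
#' @param reference_group group whose mean enters with positive sign;
#'   defaults to `"documentaries"` when present, else the second group
#'   level.
#' @param value column to compare (default `"NF_MI_ERD"`; use
#'   `"baseline_power"` for the baseline-power comparison).
#' @param holm_variant passed to [holm_adjust()].
#' @return data.frame with columns `block`, `t`, `df`, `p`, `p_holm`, `d`,
#'   `ci_lo`, `ci_hi`, `N`, `M_ref`, `SD_ref`, `M_other`, `SD_other`,
#'   `shapiro_p_ref`, `shapiro_p_other`, `levene_p`.
#' @export
table2_stats <- function(summaries, reference_group = NULL,
                         value = "NF_MI_ERD", holm_variant = "standard") {
  groups <- unique(summaries$group)
  if (length(groups) != 2) stop_cfg("need exactly 2 groups, got %d",
                                    length(groups))
  ref <- reference_group %||%
    (if ("documentaries" %in% groups) "documentaries" else groups[2])
  other <- setdiff(groups, ref)
  blocks <- sort(unique(summaries$block))
  rows <- lapply(blocks, function(b) {
    s <- summaries[summaries$block == b, ]
    xr <- s[[value]][s$group == ref]
    xo <- s[[value]][s$group == other]
    tt <- independent_ttest(xr, xo)
    ac <- if (min(length(xr), length(xo)) >= 3) assumption_checks(xr, xo)
    else list(shapiro_p = c(NA_real_, NA_real_), levene_p = NA_real_)
    data.frame(block = b, t = tt$t, df = tt$df, p = tt$p, p_holm = NA,
               d = tt$d, ci_lo = tt$ci_diff[1], ci_hi = tt$ci_diff[2],
               N = tt$n[1], M_ref = tt$mean_a, SD_ref = tt$sd_a,
               M_other = tt$mean_b, SD_other = tt$sd_b,
               shapiro_p_ref = ac$shapiro_p[1],
               shapiro_p_other = ac$shapiro_p[2],
               levene_p = ac$levene_p)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p, holm_variant)
  attr(out, "reference_group") <- ref
  out
}

#' Run the full statistics stage on block summaries
#'
#' Produces the paired-test table, and -- when two groups are present --
#' the group-comparison table, the baseline-power comparison and the mixed
#' repeated-measures ANOVA of `NF_MI_ERD` (blocks within, group between).
#'
#' @param summaries data.frame with columns `participant`, `group`,
#'   `block`, `T_MI_ERD`, `NF_MI_ERD` and optionally `baseline_power`.
#' @param holm_variant passed to [holm_adjust()].
#' @param table1_group group used for the paired table (default: first).
#' @return list with `table1`, `table2`, `baseline`, `anova` (the latter
#'   three `NULL` for a single group).
#' @export
stats_stage <- function(summaries, holm_variant = "standard",
                        table1_group = NULL) {
  groups <- unique(summaries$group)
  g1 <- table1_group %||% groups[1]
  res <- list(table1 = table1_stats(summaries[summaries$group == g1, ],
                                    holm_variant),
              table2 = NULL, baseline = NULL, anova = NULL)
  if (length(groups) == 2) {
    res$table2 <- table2_stats(summaries, holm_variant = holm_variant)
    if ("baseline_power" %in% names(summaries))
      res$baseline <- table2_stats(summaries, value = "baseline_power",
                                   holm_variant = holm_variant)
  }
  wide <- reshape_blocks(summaries, "NF_MI_ERD")
  ## the repeated-measures ANOVA needs at least two blocks
  if (ncol(wide$y) >= 2)
    res$anova <- rm_anova_mixed(wide$y,
                                if (length(groups) == 2) wide$group)
  res
}

## long summaries -> subjects x blocks matrix (+ group vector)
reshape_blocks <- function(summaries, value) {
  blocks <- sort(unique(summaries$block))
  key <- interaction(summaries$group, summaries$participant, drop = TRUE)
  subj <- levels(key)
  y <- matrix(NA_real_, length(subj), length(blocks),
              dimnames = list(subj, paste0("block", blocks)))
  for (i in seq_len(nrow(summaries)))
    y[as.character(key[i]), match(summaries$block[i], blocks)] <-
      summaries[[value]][i]
  grp <- summaries$group[match(subj, as.character(key))]
  list(y = y, group = if (length(unique(grp)) > 1) factor(grp) else NULL)
}
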