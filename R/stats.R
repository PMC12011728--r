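## The study's statistical battery: paired and pooled independent t-tests
## with Cohen's d and its noncentral-t confidence interval, Bonferroni-Holm
## adjustment (standard step-down and the raw-multiplier variant that
## matches the printed tables), mixed repeated-measures ANOVA with
## Mauchly's sphericity test and Greenhouse-Geisser correction, and
## Shapiro-Wilk / Levene assumption checks.

#' Paired t-test with Cohen's d
#'
#' One-sided (`"greater"`: mean(a) > mean(b)) or two-sided paired t-test.
#' `d = mean(a - b) / sd(a - b) = t / sqrt(n)`; its confidence interval is
#' derived from the noncentral t distribution (one-sided tests give a
#' one-sided 95% interval `(lower, Inf)`).
#'
#' @param a,b paired samples of equal length.
#' @param alternative `"greater"` or `"two.sided"`.
#' @param conf_level confidence level (default 0.95).
#' @return an object of class `ttest_result`: `t`, `df`, `p`, `d`, `ci_d`,
#'   `ci_diff`, `n`, `mean_a`, `sd_a`, `mean_b`, `sd_b`, `type`.
#' @export
paired_ttest <- function(a, b, alternative = c("greater", "two.sided"),
                         conf_level = 0.95) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b)) stop_cfg("paired samples must have equal length")
  n <- length(a)
  if (n < 2) stop_cfg("need at least 2 pairs")
  dif <- a - b
  if (stats::sd(dif) == 0) stop_cfg("zero variance of paired differences")
  tt <- stats::t.test(a, b, paired = TRUE, alternative = alternative,
                      conf.level = conf_level)
  t <- unname(tt$statistic)
  d <- t / sqrt(n)
  structure(list(t = t, df = n - 1L, p = tt$p.value, p_holm = NA_real_,
                 d = d, ci_d = d_ci_noncentral(t, n - 1L, sqrt(n),
                                               alternative, conf_level),
                 ci_diff = unname(tt$conf.int),
                 n = n, mean_a = mean(a), sd_a = stats::sd(a),
                 mean_b = mean(b), sd_b = stats::sd(b),
                 alternative = alternative, type = "paired"),
            class = "ttest_result")
}

## CI for Cohen's d by inverting the noncentral t distribution:
## d = ncp / scale, where t ~ noncentral t(df, ncp) and scale = sqrt(n)
## (paired) or sqrt(n1 n2 / (n1 + n2)) (independent).
d_ci_noncentral <- function(t, df, scale, alternative, conf_level) {
  pr <- if (alternative == "two.sided") (1 - conf_level) / 2
        else 1 - conf_level
  bound <- function(prob) {
    f <- function(ncp) suppressWarnings(stats::pt(t, df, ncp)) - prob
    hi <- max(abs(t), 1) + 10
    if (f(-hi) * f(hi) > 0) return(sign(prob - 0.5) * Inf)
    stats::uniroot(f, c(-hi, hi), tol = 1e-9)$root / scale
  }
  if (alternative == "greater") c(bound(1 - pr), Inf)
  else c(bound(1 - pr), bound(pr))
}

#' Cohen's d from a paired t statistic
#'
#' `d = t / sqrt(n)` -- the only effect size recomputable from a printed
#' paired-test row when the per-subject differences are unavailable.
#' @param t paired t statistic.
#' @param n number of pairs.
#' @return Cohen's d.
#' @examples
#' d_from_t_paired(5.185, 17)   # 1.258
#' @export
d_from_t_paired <- function(t, n) {
  if (n < 2) stop_cfg("n must be >= 2")
  t / sqrt(n)
}

#' Pooled-variance independent-samples t-test
#'
#' Accepts raw samples or printed summaries `(mean, sd, n)` per group.
#' Group 1 is the reference: `t` and `d` carry the sign of
#' `mean1 - mean2` (for the group tables here, documentaries minus quiet
#' rest). `d = (m1 - m2) / s_pooled` with the pooled SD; `df = n1 + n2 - 2`.
#' The reported confidence interval is the two-sided interval for the mean
#' difference.
#'
#' @param x,y raw samples, or `NULL` when summaries are given.
#' @param mean1,sd1,n1,mean2,sd2,n2 printed group summaries (used when
#'   `x`/`y` are `NULL`).
#' @param conf_level confidence level (default 0.95).
#' @return a `ttest_result` (two-sided p).
#' @export
independent_ttest <- function(x = NULL, y = NULL,
                              mean1 = NULL, sd1 = NULL, n1 = NULL,
                              mean2 = NULL, sd2 = NULL, n2 = NULL,
                              conf_level = 0.95) {
  if (!is.null(x)) {
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
  }
  if (!is.null(y)) {
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  if (any(vapply(list(mean1, sd1, n1, mean2, sd2, n2), is.null, TRUE)))
    stop_cfg("provide raw samples or complete (mean, sd, n) summaries")
  if (n1 < 2 || n2 < 2) stop_cfg("need n >= 2 per group")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) stop_cfg("zero pooled variance")
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (mean1 - mean2) / se
  p <- 2 * stats::pt(-abs(t), df)
  d <- (mean1 - mean2) / sqrt(sp2)
  ci_diff <- (mean1 - mean2) +
    c(-1, 1) * stats::qt(1 - (1 - conf_level) / 2, df) * se
  structure(list(t = t, df = df, p = p, p_holm = NA_real_, d = d,
                 ci_d = d_ci_noncentral(t, df, sqrt(n1 * n2 / (n1 + n2)),
                                        "two.sided", conf_level),
                 ci_diff = ci_diff, n = c(n1, n2),
                 mean_a = mean1, sd_a = sd1, mean_b = mean2, sd_b = sd2,
                 alternative = "two.sided", type = "independent"),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, digits = 3, ...) {
  cat(sprintf("%s t-test: t(%d) = %.*f, p = %.4g, d = %.*f\n",
              if (x$type == "paired") "Paired" else "Independent",
              x$df, digits, x$t, x$p, digits, x$d))
  cat(sprintf("  95%% CI for d: (%.3f, %.3f); for the difference: (%.3f, %.3f)\n",
              x$ci_d[1], x$ci_d[2], x$ci_diff[1], x$ci_diff[2]))
  invisible(x)
}

#' Bonferroni-Holm adjustment
#'
#' `variant = "standard"` is the step-down procedure with cumulative-max
#' monotonicity enforcement (identical to `p.adjust(method = "holm")`).
#' `variant = "raw-multiplier"` multiplies each p by `m - rank + 1` without
#' the monotonicity step -- the convention that reproduces the printed
#' group-comparison table, whose adjusted values are non-monotone. Both are
#' capped at 1; a non-monotone raw-multiplier outcome triggers a message.
#'
#' @param pvals raw p-values in `[0, 1]`.
#' @param variant `"standard"` or `"raw-multiplier"`.
#' @return adjusted p-values in input order.
#' @export
holm_adjust <- function(pvals, variant = c("standard", "raw-multiplier")) {
  variant <- match.arg(variant)
  if (any(pvals < 0 | pvals > 1)) stop_cfg("p-values must lie in [0, 1]")
  if (variant == "standard") return(stats::p.adjust(pvals, method = "holm"))
  m <- length(pvals)
  rk <- rank(pvals, ties.method = "first")
  adj <- pmin(pvals * (m - rk + 1), 1)
  if (is.unsorted(adj[order(pvals)]))
    message("holm_adjust: raw-multiplier adjustment is non-monotone here")
  adj
}

#' Mixed repeated-measures ANOVA
#'
#' Classical sums-of-squares decomposition for a balanced design with one
#' within-subject factor (columns of `y`, e.g. blocks) and an optional
#' between-subjects factor. Reports per term: F, degrees of freedom, p,
#' eta squared (`SS_term / SS_total`, total including between-subject
#' variance; `partial = TRUE` switches to partial eta squared), and for
#' within terms Mauchly's sphericity test and the Greenhouse-Geisser
#' epsilon with the epsilon-corrected p (reported whenever the factor has
#' more than 2 levels; `gg_epsilon = 1` exactly at k = 2).
#'
#' @param y numeric matrix, subjects x within levels (no missing cells).
#' @param group optional factor of length `nrow(y)`.
#' @param partial report partial eta squared instead of classical.
#' @return data.frame of class `anova_result`, one row per term
#'   (`group`, `within`, `within:group` as applicable) with columns `term`,
#'   `F`, `df_num`, `df_den`, `p`, `eta_sq`, `mauchly_W`, `mauchly_p`,
#'   `gg_epsilon`, `p_gg`.
#' @export
rm_anova_mixed <- function(y, group = NULL, partial = FALSE) {
  y <- as.matrix(y)
  if (anyNA(y)) stop_cfg("missing cells are not supported (no imputation)")
  n <- nrow(y); k <- ncol(y)
  if (k < 2 || n < 2) stop_cfg("need >= 2 subjects and >= 2 within levels")
  if (!is.null(group)) {
    group <- as.factor(group)
    if (length(group) != n) stop_cfg("group length must match nrow(y)")
    if (length(unique(table(group))) != 1)
      stop_cfg("unbalanced groups are not supported")
  }
  g <- if (is.null(group)) 1L else nlevels(group)
  grand <- mean(y)
  subj_m <- rowMeans(y)
  col_m <- colMeans(y)
  ss_total <- sum((y - grand)^2)
  ss_between_subj <- k * sum((subj_m - grand)^2)
  ss_within_block <- n * sum((col_m - grand)^2)

  if (g > 1) {
    grp_m <- tapply(subj_m, group, mean)
    n_per <- table(group)[1]
    ss_group <- k * sum(n_per * (grp_m - grand)^2)
    cell_m <- apply(y, 2, function(col) tapply(col, group, mean))  # g x k
    ss_inter <- n_per * sum((t(cell_m) - outer(col_m, rep(1, g)) -
                               outer(rep(1, k), grp_m) + grand)^2)
  } else {
    ss_group <- 0; ss_inter <- 0
  }
  ss_err_between <- ss_between_subj - ss_group
  ss_err_within <- ss_total - ss_between_subj - ss_within_block - ss_inter

  df_group <- g - 1L
  df_err_between <- n - g
  df_within <- k - 1L
  df_inter <- (k - 1L) * (g - 1L)
  df_err_within <- (n - g) * (k - 1L)

  ## sphericity on the pooled within-group covariance of the k columns
  centered <- if (g > 1) {
    res <- y
    for (lev in levels(group))
      res[group == lev, ] <- scale(y[group == lev, , drop = FALSE],
                                   scale = FALSE)
    res
  } else scale(y, scale = FALSE)
  S <- crossprod(centered) / (n - g)
  M <- contr_orthonormal(k)
  A <- t(M) %*% S %*% M
  lam <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  gg_eps <- sum(lam)^2 / ((k - 1) * sum(lam^2))
  if (k == 2) {
    W <- 1; mauchly_p <- NA_real_; gg_eps <- 1
  } else {
    ## Box's chi-square approximation with the second-order term
    pp <- k - 1L
    nn <- n - g
    W <- det(A) / (sum(diag(A)) / pp)^pp
    rho <- 1 - (2 * pp^2 + pp + 2) / (6 * pp * nn)
    w2 <- (pp + 2) * (pp - 1) * (pp - 2) * (2 * pp^3 + 6 * pp^2 + 3 * pp + 2) /
      (288 * (nn * pp * rho)^2)
    z <- -nn * rho * log(max(W, .Machine$double.xmin))
    dfm <- pp * (pp + 1) / 2 - 1
    pr1 <- stats::pchisq(z, dfm, lower.tail = FALSE)
    pr2 <- stats::pchisq(z, dfm + 4, lower.tail = FALSE)
    mauchly_p <- pr1 + w2 * (pr2 - pr1)
  }

  row <- function(term, ss, df1, ss_err, df2, within) {
    F <- (ss / df1) / (ss_err / df2)
    p <- stats::pf(F, df1, df2, lower.tail = FALSE)
    eta <- if (partial) ss / (ss + ss_err) else ss / ss_total
    if (within && k > 2) {
      p_gg <- stats::pf(F, gg_eps * df1, gg_eps * df2, lower.tail = FALSE)
      data.frame(term = term, F = F, df_num = df1, df_den = df2, p = p,
                 eta_sq = eta, mauchly_W = W, mauchly_p = mauchly_p,
                 gg_epsilon = gg_eps, p_gg = p_gg)
    } else data.frame(term = term, F = F, df_num = df1, df_den = df2, p = p,
                      eta_sq = eta, mauchly_W = if (within) W else NA_real_,
                      mauchly_p = if (within) mauchly_p else NA_real_,
                      gg_epsilon = if (within) gg_eps else NA_real_,
                      p_gg = if (within) p else NA_real_)
  }
  out <- list()
  if (g > 1)
    out$group <- row("group", ss_group, df_group, ss_err_between,
                     df_err_between, within = FALSE)
  out$within <- row("within", ss_within_block, df_within, ss_err_within,
                    df_err_within, within = TRUE)
  if (g > 1)
    out$inter <- row("within:group", ss_inter, df_inter, ss_err_within,
                     df_err_within, within = TRUE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("anova_result", "data.frame")
  res
}

## k x (k-1) orthonormal contrasts (Helmert, normalized)
contr_orthonormal <- function(k) {
  M <- stats::contr.helmert(k)
  sweep(M, 2, sqrt(colSums(M^2)), "/")
}

#' Normality and variance-homogeneity checks for two groups
#'
#' Shapiro-Wilk per group and Levene's test (mean centering) across
#' groups, as attached to the group-comparison t-tests.
#'
#' @param x,y the two samples (each `n >= 3`).
#' @return list with `shapiro_p` (length 2), `shapiro_W` (length 2),
#'   `levene_p`, `levene_F`.
#' @export
assumption_checks <- function(x, y) {
  if (length(x) < 3 || length(y) < 3) stop_cfg("need n >= 3 per group")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_cfg("Shapiro-Wilk is undefined for a constant sample")
  sx <- stats::shapiro.test(x)
  sy <- stats::shapiro.test(y)
  lev <- car::leveneTest(c(x, y),
                         factor(rep(c("a", "b"), c(length(x), length(y)))),
                         center = mean)
  list(shapiro_W = c(unname(sx$statistic), unname(sy$statistic)),
       shapiro_p = c(sx$p.value, sy$p.value),
       levene_F = lev$`F value`[1], levene_p = lev$`Pr(>F)`[1])
}
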