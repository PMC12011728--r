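test_that("paired t-test matches hand arithmetic and symmetric nulls", {
  a <- c(3, 5, 7); b <- c(1, 2, 3)
  d <- a - b                              # 2, 3, 4
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  res <- paired_ttest(a, b, "two.sided")
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$d, t_hand / sqrt(3), tolerance = 1e-12)
  ## +1/-1 differences: t = 0, two-sided p = 1
  res0 <- paired_ttest(c(2, 1), c(1, 2), "two.sided")
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  expect_error(paired_ttest(c(1, 2), c(0, 1)), "zero variance")
})

test_that("paired effect sizes and their CIs reproduce the printed table", {
  ## d = t / sqrt(n) for the three blocks
  expect_equal(round(d_from_t_paired(5.185, 17), 3), 1.258)
  expect_equal(round(d_from_t_paired(4.041, 17), 3), 0.980)
  expect_equal(round(d_from_t_paired(3.932, 17), 3), 0.954)
  expect_equal(d_from_t_paired(0, 17), 0)
  ## one-sided p at the printed t is < 0.001, df = 16
  expect_lt(pt(5.185, 16, lower.tail = FALSE), 0.001)
  expect_lt(pt(3.932, 16, lower.tail = FALSE), 0.001)
  ## noncentral-t lower CI bound for d at t = 5.185 prints as 0.704
  ci <- erdnf:::d_ci_noncentral(5.185, 16, sqrt(17), "greater", 0.95)
  expect_equal(round(ci[1], 3), 0.704)
  expect_equal(ci[2], Inf)
})

test_that("pooled independent tests reproduce the printed group comparisons", {
  ## documentaries minus quiet rest, n = 17 per group, df = 32
  rows <- list(
    list(m1 = -25.289, s1 = 14.490, m2 = -29.285, s2 = 9.589,
         t = 0.948, d = 0.325, ci = c(-4.588, 12.580)),
    list(m1 = -32.005, s1 = 20.773, m2 = -25.939, s2 = 11.003,
         t = -1.064, d = -0.365, ci = c(-17.679, 5.548)),
    list(m1 = -25.966, s1 = 19.851, m2 = -24.731, s2 = 10.582,
         t = -0.226, d = -0.078, ci = c(-12.349, 9.878)))
  for (r in rows) {
    res <- independent_ttest(mean1 = r$m1, sd1 = r$s1, n1 = 17,
                             mean2 = r$m2, sd2 = r$s2, n2 = 17)
    expect_equal(res$df, 32)
    expect_equal(round(res$t, 3), r$t)
    expect_equal(round(res$d, 3), r$d)
    ## the printed CI was computed from unrounded group summaries; with the
    ## rounded inputs the last digit can differ by one
    expect_lt(max(abs(res$ci_diff - r$ci)), 0.002)
  }
  ## equal means give t = 0; degenerate input errors
  expect_equal(independent_ttest(mean1 = 1, sd1 = 2, n1 = 5,
                                 mean2 = 1, sd2 = 3, n2 = 5)$t, 0)
  expect_error(independent_ttest(mean1 = 1, sd1 = 0, n1 = 5,
                                 mean2 = 1, sd2 = 0, n2 = 5), "variance")
})

test_that("raw samples and their summaries give identical independent tests", {
  set.seed(1)
  x <- rnorm(17, -25, 14); y <- rnorm(17, -29, 10)
  a <- independent_ttest(x, y)
  b <- independent_ttest(mean1 = mean(x), sd1 = sd(x), n1 = 17,
                         mean2 = mean(y), sd2 = sd(y), n2 = 17)
  expect_equal(a$t, b$t, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("both Holm variants are hand-verified on the printed p-values", {
  p <- c(0.350, 0.295, 0.822)
  std <- holm_adjust(p, "standard")
  expect_equal(std, c(0.885, 0.885, 0.885))
  expect_equal(std, p.adjust(p, "holm"))   # step-down with monotonicity
  raw <- suppressMessages(holm_adjust(p, "raw-multiplier"))
  expect_equal(raw, c(0.700, 0.885, 0.822))  # as printed, non-monotone
  expect_message(holm_adjust(p, "raw-multiplier"), "non-monotone")
  ## smallest raw p maps to 0.885 under both conventions
  expect_equal(std[2], 0.885)
  expect_equal(raw[2], 0.885)
  expect_equal(holm_adjust(0.03, "standard"), 0.03)   # m = 1 unchanged
  expect_equal(holm_adjust(c(0.9, 0.8), "raw-multiplier")[2], 1)  # capped
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("a two-level within design reduces to the squared paired t", {
  set.seed(2)
  y <- cbind(rnorm(12, -20, 8), rnorm(12, -26, 9))
  res <- rm_anova_mixed(y)
  tt <- paired_ttest(y[, 1], y[, 2], "two.sided")
  expect_equal(res$F[res$term == "within"], tt$t^2, tolerance = 1e-9)
  expect_equal(res$p[res$term == "within"], tt$p, tolerance = 1e-9)
  expect_equal(res$gg_epsilon[res$term == "within"], 1)
})

test_that("the mixed-model sum-of-squares tableau matches a hand computation", {
  ## 3 subjects x 3 levels, worked by hand
  y <- rbind(c(1, 2, 3),
             c(2, 4, 6),
             c(3, 6, 9))
  ## grand = 4; SS_total = 1+4+9+... = sum((y-4)^2) = 48
  ## subject means 2,4,6 -> SS_between = 3*((2-4)^2+(0)^2+(2)^2) = 24
  ## level means 2,4,6 -> SS_within_levels = 3*8 = 24
  ## interaction/error = 48 - 24 - 24 = 0 -> F -> Inf; perturb instead
  y[1, 1] <- 2
  grand <- mean(y)
  ss_tot <- sum((y - grand)^2)
  sm <- rowMeans(y); cm <- colMeans(y)
  ss_b <- 3 * sum((sm - grand)^2)
  ss_w <- 3 * sum((cm - grand)^2)
  ss_e <- ss_tot - ss_b - ss_w
  res <- rm_anova_mixed(y)
  expect_equal(res$F[res$term == "within"],
               (ss_w / 2) / (ss_e / 4), tolerance = 1e-9)
  expect_equal(res$eta_sq[res$term == "within"], ss_w / ss_tot,
               tolerance = 1e-9)
})

test_that("the mixed ANOVA agrees with aov() on F, df and p for all terms", {
  set.seed(3)
  n <- 10; k <- 3
  y <- matrix(rnorm(2 * n * k, -25, 8), 2 * n, k)
  y[seq_len(n), 2] <- y[seq_len(n), 2] - 4      # some structure
  grp <- factor(rep(c("a", "b"), each = n))
  res <- rm_anova_mixed(y, grp)
  long <- data.frame(v = as.vector(y),
                     block = factor(rep(seq_len(k), each = 2 * n)),
                     subj = factor(rep(seq_len(2 * n), k)),
                     grp = rep(grp, k))
  fit <- summary(aov(v ~ grp * block + Error(subj / block), long))
  btw <- fit[["Error: subj"]][[1]]
  wth <- fit[["Error: subj:block"]][[1]]
  pick <- function(tab, row, col) tab[trimws(rownames(tab)) == row, col]
  expect_equal(res$F[res$term == "group"], pick(btw, "grp", "F value"),
               tolerance = 1e-9)
  expect_equal(res$F[res$term == "within"], pick(wth, "block", "F value"),
               tolerance = 1e-9)
  expect_equal(res$F[res$term == "within:group"],
               pick(wth, "grp:block", "F value"), tolerance = 1e-9)
  expect_equal(res$p[res$term == "within:group"],
               pick(wth, "grp:block", "Pr(>F)"), tolerance = 1e-9)
  expect_equal(res$df_num, c(1, 2, 2))
  expect_equal(res$df_den, c(2 * n - 2, (2 * n - 2) * 2, (2 * n - 2) * 2))
})

test_that("Mauchly's W and the Greenhouse-Geisser epsilon match the mlm oracle", {
  set.seed(4)
  n <- 14; k <- 4
  y <- matrix(rnorm(n * k), n, k) %*% matrix(runif(k * k, -1, 1), k)
  res <- rm_anova_mixed(y)
  fit <- lm(y ~ 1)
  mt <- mauchly.test(fit, X = ~1)
  expect_equal(res$mauchly_W[res$term == "within"], unname(mt$statistic),
               tolerance = 1e-8)
  expect_equal(res$mauchly_p[res$term == "within"], mt$p.value,
               tolerance = 1e-3)
  av <- anova(fit, X = ~1, test = "Spherical")
  gg_line <- grep("Greenhouse-Geisser", attr(av, "heading"), value = TRUE)
  eps_oracle <- as.numeric(sub(".*epsilon[: ]+([0-9.]+).*", "\\1", gg_line))
  expect_equal(res$gg_epsilon[res$term == "within"], eps_oracle,
               tolerance = 1e-3)
  ## epsilon bounds
  expect_gte(res$gg_epsilon[res$term == "within"], 1 / (k - 1))
  expect_lte(res$gg_epsilon[res$term == "within"], 1)
})

test_that("unbalanced or incomplete tables are refused", {
  y <- matrix(rnorm(12), 4, 3)
  y[2, 3] <- NA
  expect_error(rm_anova_mixed(y), "missing")
  expect_error(rm_anova_mixed(matrix(rnorm(12), 4, 3),
                              factor(c("a", "a", "a", "b"))),
               "unbalanced")
})

test_that("one-sided paired tests hold their nominal type-I error", {
  set.seed(5)
  n <- 17; reps <- 4000
  x <- matrix(rnorm(n * reps), n)
  m <- colMeans(x)
  s <- sqrt((colSums(x^2) - n * m^2) / (n - 1))
  t <- m / (s / sqrt(n))
  rate <- mean(t > qt(0.95, n - 1))
  expect_equal(rate, 0.05, tolerance = 0.2)
  ## and the package's test agrees with the vectorized computation
  res <- paired_ttest(x[, 1], rep(0, n), "greater")
  expect_equal(res$t, t[1], tolerance = 1e-9)
})

test_that("assumption checks flag unequal spread and pass Gaussian samples", {
  set.seed(6)
  x <- rnorm(40); y <- rnorm(40)
  ac <- assumption_checks(x, y)
  expect_gt(ac$levene_p, 0.01)
  expect_length(ac$shapiro_p, 2)
  ## doubling one spread is detected most of the time
  hits <- mean(replicate(60, {
    a <- rnorm(100); b <- rnorm(100, 0, 2)
    assumption_checks(a, b)$levene_p < 0.05
  }))
  expect_gte(hits, 0.8)
  ## Shapiro-Wilk holds its size approximately
  set.seed(7)
  rej <- mean(replicate(400, shapiro.test(rnorm(50))$p.value < 0.05))
  expect_equal(rej, 0.05, tolerance = 0.02 / 0.05)
  expect_error(assumption_checks(rep(1, 5), rnorm(5)), "constant")
})

test_that("rmANOVA p-values are uniform under the null", {
  set.seed(8)
  ps <- replicate(800, {
    y <- matrix(rnorm(8 * 3), 8, 3)
    res <- rm_anova_mixed(y)
    res$p[res$term == "within"]
  })
  ks <- ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("block tables assemble with the printed column layout", {
  set.seed(9)
  sm <- expand.grid(participant = sprintf("p%02d", 1:17), block = 1:3)
  sm$T_MI_ERD <- rnorm(nrow(sm), -10, 15)
  sm$NF_MI_ERD <- sm$T_MI_ERD - 15 + rnorm(nrow(sm), 0, 6)
  t1 <- table1_stats(sm)
  expect_equal(names(t1), c("block", "t", "df", "p", "p_holm", "d",
                            "ci_lo", "ci_hi", "N", "M_T", "SD_T",
                            "M_NF", "SD_NF"))
  expect_equal(t1$df, rep(16, 3))
  expect_true(all(t1$t > 0))              # built-in NF effect: T > NF
  sm$group <- rep(c("quiet_rest", "documentaries"),
                  length.out = nrow(sm))
  sm2 <- do.call(rbind, lapply(c("quiet_rest", "documentaries"), function(g) {
    s <- sm; s$group <- g
    s$participant <- paste0(g, s$participant); s
  }))
  t2 <- table2_stats(sm2)
  expect_equal(attr(t2, "reference_group"), "documentaries")
  expect_equal(t2$df, rep(32, 3))
  st <- stats_stage(sm2)
  expect_equal(st$anova$term, c("group", "within", "within:group"))
  expect_equal(st$anova$df_den[2], 64)    # (34 - 2) * 2
})
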