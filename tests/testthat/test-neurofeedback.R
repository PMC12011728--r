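## feature_set constructor for classifier-level tests
fake_features <- function(x, trial = seq_len(nrow(as.matrix(x)))) {
  x <- as.matrix(x)
  structure(list(x = x, trial = trial,
                 hand = rep("right", nrow(x)),
                 bin_onset = rep(0, nrow(x)), segment = "mi"),
            class = "feature_set")
}

test_that("a 4-s segment yields 49 bins with alternating 31/32-sample hops", {
  cfg <- quick_cfg(n_trials_per_run = 2, seed = 1)
  rec <- sim_run(cfg)
  ep <- epoch_data(rec, window = c(-7, 5))
  ep1 <- ep; ep1$data <- ep$data[, 1, , drop = FALSE]
  ep1$channel_labels <- ep1$channel_labels[1]
  ft <- extract_features(ep1, "mi")
  expect_equal(nrow(ft$x), 2 * 49)       # floor((4-1)/0.0625)+1 per trial
  on <- sort(unique(round((ft$bin_onset - 0.5) * 500)))
  expect_equal(on, round((0:48) * 31.25))
  hops <- diff(on)
  expect_true(all(hops %in% c(31, 32)))
  expect_equal(mean(hops), 31.25)
})

test_that("features are stationary for a constant sinusoid and obey log scaling", {
  fs <- 500
  t <- (seq_len(13 * fs) - 1) / fs
  dat <- array(sin(2 * pi * 10 * t), c(1, 1, length(t)))
  ep <- toy_epochs(dat, fs = fs, t0 = -7)
  ft <- extract_features(ep, "mi")
  expect_lt(diff(range(ft$x)), 1e-6)
  ep2 <- ep; ep2$data <- ep2$data * 2
  ft2 <- extract_features(ep2, "mi")
  expect_equal(ft2$x - ft$x, matrix(log(4), nrow(ft$x), 1),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("grouped LDA CV is perfect on separated classes and at chance on shuffled labels", {
  set.seed(2)
  a <- fake_features(rnorm(200, 5, 0.1), trial = rep(1:20, each = 10))
  b <- fake_features(rnorm(200, -5, 0.1), trial = rep(21:40, each = 10))
  fit <- lda_cv(a, b, k = 5)
  expect_equal(fit$cv_accuracy, 1)
  ## shuffled labels: pool and relabel at random, n = 500 per class
  set.seed(3)
  x <- rnorm(1000, 0, 1)
  lab <- sample(rep(c(TRUE, FALSE), 500))
  fs_a <- fake_features(x[lab], trial = seq_len(500))
  fs_b <- fake_features(x[!lab], trial = 500 + seq_len(500))
  fit0 <- lda_cv(fs_a, fs_b, k = 7)
  expect_equal(fit0$cv_accuracy, 0.5, tolerance = 0.1)
})

test_that("CV accuracy approaches the Gaussian Bayes rate", {
  set.seed(4)
  delta <- 1.2
  n <- 2000
  a <- fake_features(rnorm(n, delta / 2), trial = seq_len(n))
  b <- fake_features(rnorm(n, -delta / 2), trial = n + seq_len(n))
  fit <- lda_cv(a, b, k = 7, gamma = 0)
  expect_equal(fit$cv_accuracy, pnorm(delta / 2), tolerance = 0.02 / pnorm(delta / 2))
})

test_that("the border is the linear-interpolation upper quartile of held-out target scores", {
  expect_equal(compute_border(1:8), 6.25)
  expect_equal(compute_border(rep(3.7, 10)), 3.7)
  expect_equal(compute_border(1:8 + 2.5), 6.25 + 2.5)
  clf <- list(cv_scores = data.frame(score = c(1:8, -(1:8)),
                                     is_target = rep(c(TRUE, FALSE), each = 8)))
  expect_equal(compute_border(clf), 6.25)
  expect_equal(compute_border(clf, pooled = TRUE),
               unname(quantile(c(1:8, -(1:8)), 0.75)))
  expect_error(compute_border(numeric()), "scores")
})

test_that("stream scores are affine in the features with the documented signs", {
  set.seed(5)
  w <- c(0.8, -0.3)
  clf <- function(w, b) structure(list(w = w, b = b), class = "lda_cv")
  trip <- structure(list(LR = clf(w, 0.1), BaseL = clf(c(0, 1), 0),
                         BaseR = clf(c(1, 0), 0),
                         borders = c(LR = 1, BaseL = 1, BaseR = 1)),
                    class = "nf_triplet")
  x <- matrix(rnorm(40), 20, 2)
  ft <- fake_features(x)
  sc <- classify_stream(ft, trip)
  expect_equal(sc[, "LR"], drop(x %*% w) + 0.1, ignore_attr = TRUE)
  ## a feature on the hyperplane scores 0
  x0 <- matrix(c(1, (0.1 + 0.8) / 0.3), 1)      # w.x + b = 0
  expect_equal(classify_stream(fake_features(x0), trip)[1, "LR"], 0,
               tolerance = 1e-12, ignore_attr = TRUE)
  ## negating weights and bias negates every score
  trip2 <- trip; trip2$LR <- clf(-w, -0.1)
  expect_equal(classify_stream(ft, trip2)[, "LR"], -sc[, "LR"],
               ignore_attr = TRUE)
  ## monotone in the projection
  ord <- order(x %*% w)
  expect_equal(order(sc[, "LR"]), ord)
})

test_that("feedback mapping clips, scales and routes by hand", {
  borders <- c(LR = 2, BaseL = 4, BaseR = 8)
  sc <- rbind(c(0, 0, 0), c(2, 4, 8), c(1, 2, 4), c(-5, -20, 12))
  colnames(sc) <- c("LR", "BaseL", "BaseR")
  tr <- map_feedback(sc, c("left", "right", "left", "right"), borders)
  expect_equal(tr$x, c(0, 1, 0.5, -1))
  expect_equal(tr$y, c(0, 1, 0.5, 1))   # row 4: right hand -> BaseR = 12/8 clipped
  expect_true(all(abs(tr$x) <= 1 & abs(tr$y) <= 1))
  expect_error(map_feedback(sc, "left", c(LR = 0, BaseL = 1, BaseR = 1)),
               "positive")
})

test_that("feedback coordinates are invariant to feature rescaling with recomputed borders", {
  set.seed(6)
  cfg <- quick_cfg(n_trials_per_run = 14, snr = 10, seed = 6,
                   erd_depth_mu = 0.4, erd_depth_beta = 0.4)
  rec <- sim_run(cfg)
  pf <- preset_filters()
  ep <- epoch_data(fir_filter(rec, pf$butter_band), window = c(-7, 5))
  mod <- csp(ep)
  proj <- apply_csp(ep, mod, "both")
  mi <- extract_features(proj, "mi")
  ## rescaling all amplitudes shifts log powers by a constant; classifiers
  ## retrained on shifted features with recomputed borders give identical
  ## feedback up to numerical noise
  run_nf <- function(epz) {
    set.seed(99)
    trip <- train_nf(epz, mod, k = 3)
    projz <- apply_csp(epz, mod, "both")
    miz <- extract_features(projz, "mi")
    map_feedback(classify_stream(miz, trip), miz$hand, trip$borders)
  }
  t1 <- run_nf(ep)
  eps <- ep; eps$data <- eps$data * 3
  t2 <- run_nf(eps)
  expect_equal(t1$x, t2$x, tolerance = 1e-6)
  expect_equal(t1$y, t2$y, tolerance = 1e-6)
})

test_that("fold bookkeeping rejects impossible splits", {
  a <- fake_features(rnorm(12), trial = rep(1:4, each = 3))
  b <- fake_features(rnorm(12), trial = 10 + rep(1:4, each = 3))
  expect_error(lda_cv(a, b, k = 7), "exceeds")
})
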