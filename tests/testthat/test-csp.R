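test_that("closed-form 2x2 covariances give eigenvalues {0.8, 0.2} and axis filters", {
  fit <- csp_from_covariances(diag(c(4, 1)), diag(c(1, 4)))
  expect_equal(fit$eigenvalues, c(0.8, 0.2), tolerance = 1e-9)
  ## axis-aligned filters: each row has one dominant coefficient
  W <- abs(fit$W / sqrt(rowSums(fit$W^2)))
  expect_equal(max(W[1, ]), 1, tolerance = 1e-9)
  expect_equal(max(W[2, ]), 1, tolerance = 1e-9)
})

test_that("identical class covariances give all eigenvalues 1/2", {
  set.seed(1)
  A <- crossprod(matrix(rnorm(36), 6))
  fit <- csp_from_covariances(A, A)
  expect_equal(fit$eigenvalues, rep(0.5, 6), tolerance = 1e-6)
})

test_that("filters diagonalize the pooled covariance and match a dense oracle", {
  set.seed(2)
  p <- 8
  CL <- crossprod(matrix(rnorm(p * p * 4), ncol = p)) / (4 * p)
  CR <- crossprod(matrix(rnorm(p * p * 4), ncol = p)) / (4 * p)
  fit <- csp_from_covariances(CL, CR)
  D <- fit$W %*% (CL + CR) %*% t(fit$W)
  expect_lt(max(abs(D - diag(p))), 1e-8)
  ## independent oracle: non-symmetric generalized eigenproblem solved via
  ## solve(Cp) %*% CL
  o <- eigen(solve(CL + CR) %*% CL)
  expect_equal(sort(Re(o$values)), sort(fit$eigenvalues), tolerance = 1e-6)
  for (j in seq_len(p)) {
    v <- Re(o$vectors[, order(-Re(o$values))[j]])
    w <- fit$W[j, ]
    align <- abs(sum(v * w)) / sqrt(sum(v^2) * sum(w^2))
    expect_equal(align, 1, tolerance = 1e-6)
  }
  ## patterns are the inverse of the filter matrix
  expect_equal(fit$patterns %*% fit$W, diag(p), tolerance = 1e-8)
})

test_that("class swap maps eigenvalues to their complements", {
  set.seed(3)
  CL <- crossprod(matrix(rnorm(50 * 5), ncol = 5)) / 250
  CR <- crossprod(matrix(rnorm(50 * 5), ncol = 5)) / 250
  a <- csp_from_covariances(CL, CR)
  b <- csp_from_covariances(CR, CL)
  expect_equal(sort(a$eigenvalues), sort(1 - b$eigenvalues),
               tolerance = 1e-8)
})

test_that("eigenvalues and downstream ERD are invariant to global scaling", {
  cfg <- quick_cfg(n_trials_per_run = 8, seed = 4)
  rec <- sim_run(cfg)
  ep <- epoch_data(band_chain(rec), window = c(-7, 9))
  ep2 <- ep; ep2$data <- ep2$data * 7.3
  m1 <- csp(ep); m2 <- csp(ep2)
  expect_equal(m1$eigenvalues, m2$eigenvalues, tolerance = 1e-9)
  e1 <- compute_erd(subset_trials(apply_csp(ep, m1, "contra"),
                                  ep$hand == "left"))
  e2 <- compute_erd(subset_trials(apply_csp(ep2, m2, "contra"),
                                  ep$hand == "left"))
  expect_equal(e1$erd, e2$erd, tolerance = 1e-6)
})

test_that("selected filters behave contralaterally on lateralized data", {
  cfg <- quick_cfg(n_trials_per_run = 20, snr = 10, seed = 5,
                   erd_depth_mu = 0.4, erd_depth_beta = 0.4)
  rec <- sim_run(cfg)
  ep <- epoch_data(band_chain(rec), window = c(-7, 9))
  mod <- csp(ep, select_mode = "eigenvalue")
  expect_equal(mod$selected$right, 1L)
  expect_equal(mod$selected$left, nrow(mod$W))
  ## left-class filter: MI-window variance smaller on left-hand trials
  idx <- which(ep$time >= 0.5 & ep$time < 4.5)
  vl <- vr <- numeric()
  for (i in seq_along(ep$hand)) {
    y <- mod$W[mod$selected$left, ] %*% ep$data[i, , idx]
    if (ep$hand[i] == "left") vl <- c(vl, var(drop(y)))
    else vr <- c(vr, var(drop(y)))
  }
  expect_lt(mean(vl), mean(vr))
})

test_that("projection through a one-hot filter returns the raw channel", {
  cfg <- quick_cfg(n_trials_per_run = 4, seed = 6)
  rec <- sim_run(cfg)
  ep <- epoch_data(rec, window = c(-1, 5))
  mod <- csp(ep, select_mode = "none")
  mod$W[1, ] <- 0; mod$W[1, 3] <- 1      # identity filter for channel 3
  mod$selected <- list(right = 1L, left = 1L)
  out <- apply_csp(ep, mod, "contra")
  expect_equal(out$data[2, 1, ], ep$data[2, 3, ], tolerance = 1e-12)
  ## contra mode routes left-hand trials through the left-class filter
  mod$W[2, ] <- 0; mod$W[2, 5] <- 1
  mod$selected <- list(right = 1L, left = 2L)
  out2 <- apply_csp(ep, mod, "contra")
  lt <- which(ep$hand == "left")[1]
  expect_equal(out2$data[lt, 1, ], ep$data[lt, 5, ], tolerance = 1e-12)
  ## ipsi mode swaps the routing
  out3 <- apply_csp(ep, mod, "ipsi")
  expect_equal(out3$data[lt, 1, ], ep$data[lt, 3, ], tolerance = 1e-12)
})

test_that("scored selection rejects a noise-dominated extreme filter", {
  cfg <- quick_cfg(n_channels = 16, n_trials_per_run = 20, snr = 8,
                   seed = 7, erd_depth_mu = 0.35, erd_depth_beta = 0.35)
  rec <- sim_run(cfg)
  ## corrupt one far-frontal channel with class-correlated noise so that an
  ## eigenvalue-extreme filter latches onto it
  frontal <- which.max(rec$layout$y)
  ev <- rec$events
  g <- rep(1, ncol(rec$data))
  for (i in seq_len(nrow(ev))) if (ev$hand[i] == "left") {
    idx <- ev$onset_sample[i] + seq_len(as.integer(5 * rec$fs)) - 1L
    g[idx] <- 4
  }
  rec$data[frontal, ] <- rec$data[frontal, ] * g
  ep <- epoch_data(band_chain(rec), window = c(-7, 9))
  m_eig <- csp(ep, select_mode = "eigenvalue")
  m_sc <- csp(ep, select_mode = "scored")
  score <- function(m, j) plausibility_score(m, j)
  ## the scored pick is at least as plausible as the plain extreme
  expect_gte(score(m_sc, m_sc$selected$right), score(m_eig, m_eig$selected$right))
  expect_gte(score(m_sc, m_sc$selected$left), score(m_eig, m_eig$selected$left))
  ## and the corrupted channel does not dominate the scored picks
  dom <- function(m, j) {
    p <- abs(m$patterns[, j]); which.max(p)
  }
  expect_false(dom(m_sc, m_sc$selected$left) == frontal &&
                 dom(m_sc, m_sc$selected$right) == frontal)
})

test_that("model serialization round-trips filters and selection", {
  cfg <- quick_cfg(n_trials_per_run = 6, seed = 8)
  rec <- sim_run(cfg)
  ep <- epoch_data(band_chain(rec), window = c(-7, 9))
  mod <- csp(ep)
  path <- tempfile(fileext = ".csp")
  write_csp(mod, path)
  back <- read_csp(path)
  expect_equal(back$W, mod$W, tolerance = 1e-12)
  expect_equal(back$eigenvalues, mod$eigenvalues, tolerance = 1e-12)
  expect_equal(back$selected$right, mod$selected$right)
  expect_equal(back$channel_subset, mod$channel_subset)
})

test_that("degenerate inputs raise errors", {
  cfg <- quick_cfg(n_trials_per_run = 4, seed = 9)
  rec <- sim_run(cfg)
  ep <- epoch_data(rec, window = c(-1, 5))
  ep$rejected[ep$hand == "left"] <- TRUE
  expect_error(csp(ep), "2 non-rejected trials")
  expect_error(select_filters(csp(epoch_data(rec, window = c(-1, 5)),
                                  select_mode = "none"), 20),
               "filters")
})
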