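## Common Spatial Patterns. Filters solve the generalized eigenproblem
## C_L w = lambda (C_L + C_R) w via whitening of the pooled covariance;
## eigenvalues lie in (0, 1) and express each filter's share of left-class
## variance. Class covariances are averages of per-trial trace-normalized
## covariances over the MI window, with optional shrinkage regularization.

#' Fit Common Spatial Patterns for left- vs right-hand motor imagery
#'
#' @param ep an `epoch_set`, band-filtered 8--30 Hz; rejected trials are
#'   excluded automatically.
#' @param window covariance window in seconds relative to MI onset
#'   (default `c(0.5, 4.5)`).
#' @param gamma shrinkage weight: each class covariance becomes
#'   `(1 - gamma) C + gamma tr(C)/p I` (default 0.05).
#' @param channels integer channel subset to fit on (e.g.
#'   [central_channels()]); default all channels.
#' @param n_per_class,select_mode passed on to [select_filters()];
#'   `select_mode = "none"` skips selection.
#' @return an object of class `csp`: `W` (filters x channels, rows sorted
#'   by descending eigenvalue), `eigenvalues`, `patterns` (channels x
#'   filters, the columns of `solve(W)`), `selected` (list with `left`,
#'   `right` filter indices), `channel_subset`, `layout`.
#' @examples
#' cfg <- sim_config(n_channels = 16, n_trials_per_run = 12, seed = 3)
#' rec <- simulate_recording(cfg)
#' ep <- epoch_data(fir_filter(rec, preset_filters()$hp8), window = c(-1, 5))
#' mod <- csp(ep)
#' @export
csp <- function(ep, window = c(0.5, 4.5), gamma = 0.05, channels = NULL,
                n_per_class = 1, select_mode = c("scored", "eigenvalue",
                                                 "none")) {
  select_mode <- match.arg(select_mode)
  stopifnot(inherits(ep, "epoch_set"))
  channels <- channels %||% seq_len(dim(ep$data)[2])
  keep <- kept_trials(ep)
  hands <- ep$hand[keep]
  if (sum(hands == "left") < 2 || sum(hands == "right") < 2)
    stop_cfg("need at least 2 non-rejected trials per class")
  idx <- interval_index(window, ep$time[1], ep$fs, length(ep$time))

  cov_class <- function(which_hand) {
    tr <- keep[hands == which_hand]
    p <- length(channels)
    acc <- matrix(0, p, p)
    for (i in tr) {
      X <- ep$data[i, channels, idx]
      Ci <- X %*% t(X)
      acc <- acc + Ci / sum(diag(Ci))
    }
    C <- acc / length(tr)
    (1 - gamma) * C + gamma * sum(diag(C)) / p * diag(p)
  }
  fit <- csp_from_covariances(cov_class("left"), cov_class("right"))
  model <- structure(c(fit, list(
    selected = NULL, channel_subset = channels,
    channel_labels = ep$channel_labels[channels],
    layout = ep$layout[channels, , drop = FALSE],
    window = window, gamma = gamma)), class = "csp")
  if (select_mode != "none")
    model <- select_filters(model, n_per_class, mode = select_mode)
  model
}

#' CSP from class covariance matrices
#'
#' Solves `C_L w = lambda (C_L + C_R) w` directly from the two class
#' covariances (the numerical core of [csp()], exposed for closed-form
#' checks).
#' @param C_L,C_R symmetric positive-definite class covariances.
#' @return list with `W`, `eigenvalues`, `patterns`.
#' @export
csp_from_covariances <- function(C_L, C_R) {
  Cp <- C_L + C_R
  e <- eigen(Cp, symmetric = TRUE)
  tol <- max(e$values) * 1e-10
  if (any(e$values < tol))
    stop_cfg("pooled covariance is singular; increase shrinkage gamma")
  Wh <- diag(1 / sqrt(e$values)) %*% t(e$vectors)
  S <- Wh %*% C_L %*% t(Wh)
  S <- (S + t(S)) / 2
  u <- eigen(S, symmetric = TRUE)        # descending eigenvalues
  W <- t(u$vectors) %*% Wh
  ## sign convention: largest-magnitude coefficient of each filter positive
  for (j in seq_len(nrow(W))) {
    k <- which.max(abs(W[j, ]))
    if (W[j, k] < 0) W[j, ] <- -W[j, ]
  }
  list(W = W, eigenvalues = pmin(pmax(u$values, 0), 1),
       patterns = solve(W))
}

#' @export
print.csp <- function(x, ...) {
  cat(sprintf("CSP model: %d filters on %d channels\n",
              nrow(x$W), ncol(x$W)))
  ev <- x$eigenvalues
  cat(sprintf("  eigenvalue range: %.3f .. %.3f\n", min(ev), max(ev)))
  if (!is.null(x$selected))
    cat(sprintf("  selected: right = filter %d (lambda %.3f), left = filter %d (lambda %.3f)\n",
                x$selected$right, ev[x$selected$right],
                x$selected$left, ev[x$selected$left]))
  invisible(x)
}

#' @export
coef.csp <- function(object, ...) object$W

#' Select one spatial filter per class
#'
#' `"eigenvalue"` mode takes the `n_per_class` filters at each eigenvalue
#' extreme. `"scored"` mode emulates manual plausibility screening: among
#' the 3 most extreme filters per side it picks the one whose pattern
#' concentrates over the sensorimotor clusters and is spatially smooth
#' (score = cluster weight x smoothness). The right-class filter sits at
#' the high-eigenvalue extreme (left-class variance maximal, i.e. right-
#' hand MI suppresses it contralaterally), the left-class filter at the
#' low extreme.
#'
#' @param model a `csp` model.
#' @param n_per_class filters kept per class (default 1, as online).
#' @param mode `"eigenvalue"` or `"scored"`.
#' @return the model with `selected = list(right = , left = )` filled in
#'   (indices of the first filter per class).
#' @export
select_filters <- function(model, n_per_class = 1,
                           mode = c("eigenvalue", "scored")) {
  mode <- match.arg(mode)
  nf <- nrow(model$W)
  if (n_per_class < 1) stop_cfg("n_per_class must be >= 1")
  if (2 * n_per_class > nf)
    stop_cfg("requested %d filters per class but only %d filters exist",
             n_per_class, nf)
  if (mode == "eigenvalue") {
    right <- seq_len(n_per_class)
    left <- nf + 1L - seq_len(n_per_class)
  } else {
    cand_r <- seq_len(min(3L, nf))
    cand_l <- nf + 1L - seq_len(min(3L, nf))
    right <- cand_r[order(plausibility_score(model, cand_r),
                          decreasing = TRUE)][seq_len(n_per_class)]
    left <- cand_l[order(plausibility_score(model, cand_l),
                         decreasing = TRUE)][seq_len(n_per_class)]
  }
  model$selected <- list(right = right[1], left = left[1],
                         right_all = right, left_all = left, mode = mode)
  model
}

#' Plausibility score of CSP patterns
#'
#' Sensorimotor-cluster weight (share of squared pattern mass over the
#' `left_sm`/`right_sm` layout regions) times spatial smoothness
#' (`1/(1 + roughness)`, roughness = normalized mean squared deviation of
#' each channel's pattern value from the mean of its 4 nearest neighbors).
#'
#' @param model a `csp` model with a layout.
#' @param filters filter indices to score.
#' @return numeric scores in `[0, 1]`.
#' @export
plausibility_score <- function(model, filters) {
  lay <- model$layout
  sm <- lay$region %in% c("left_sm", "right_sm")
  D <- sqrt(outer(lay$x, lay$x, "-")^2 + outer(lay$y, lay$y, "-")^2)
  diag(D) <- Inf
  nb <- apply(D, 1, function(d) order(d)[1:4])
  vapply(filters, function(j) {
    p <- model$patterns[, j]
    w_sm <- sum(p[sm]^2) / sum(p^2)
    nb_mean <- apply(nb, 2, function(k) mean(p[k]))
    rough <- mean((p - nb_mean)^2) / stats::var(p)
    w_sm / (1 + rough)
  }, 0)
}

#' Project epochs through selected CSP filters
#'
#' `laterality = "contra"` applies each hand's own filter (right filter to
#' right-hand trials, left filter to left-hand trials), yielding the
#' contralateral component; `"ipsi"` swaps them; `"both"` applies both
#' selected filters to every trial (the two-channel feature path for
#' neurofeedback).
#'
#' @param ep an `epoch_set` on the same channel set the model was fit on
#'   (the model's `channel_subset` is applied).
#' @param model a `csp` model with `selected` populated.
#' @param laterality `"contra"`, `"ipsi"` or `"both"`.
#' @return an `epoch_set` with 1 (`contra`/`ipsi`) or 2 (`both`) virtual
#'   channels.
#' @export
apply_csp <- function(ep, model, laterality = c("contra", "ipsi", "both")) {
  laterality <- match.arg(laterality)
  if (is.null(model$selected))
    stop_cfg("model has no selected filters; run select_filters() first")
  if (max(model$channel_subset) > dim(ep$data)[2])
    stop_cfg("epoch set has fewer channels than the model's channel subset")
  d <- dim(ep$data)
  W <- model$W
  sel <- model$selected
  if (laterality == "both") {
    out <- array(0, c(d[1], 2L, d[3]))
    for (i in seq_len(d[1])) {
      X <- ep$data[i, model$channel_subset, ]
      out[i, 1, ] <- W[sel$right, ] %*% X
      out[i, 2, ] <- W[sel$left, ] %*% X
    }
    labels <- c("csp_right", "csp_left")
  } else {
    out <- array(0, c(d[1], 1L, d[3]))
    for (i in seq_len(d[1])) {
      own <- if (ep$hand[i] == "right") sel$right else sel$left
      other <- if (ep$hand[i] == "right") sel$left else sel$right
      f <- if (laterality == "contra") own else other
      out[i, 1, ] <- W[f, ] %*% ep$data[i, model$channel_subset, ]
    }
    labels <- paste0("csp_", laterality)
  }
  ep$data <- out
  ep$channel_labels <- labels
  ep$layout <- NULL
  ep
}

#' Serialize / restore a CSP model as structured text
#'
#' Writes filters, eigenvalues, channel subset and selection provenance to
#' a plain-text file (DCF-like sections with CSV payloads) and reads them
#' back.
#' @param model a `csp` model.
#' @param path file path.
#' @return `write_csp` returns the path invisibly; `read_csp` the model.
#' @export
write_csp <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# csp model",
               sprintf("channels: %s",
                       paste(model$channel_subset, collapse = ",")),
               sprintf("eigenvalues: %s",
                       paste(format(model$eigenvalues, digits = 17),
                             collapse = ",")),
               sprintf("selected_right: %d", model$selected$right %||% NA),
               sprintf("selected_left: %d", model$selected$left %||% NA),
               sprintf("selection_mode: %s",
                       model$selected$mode %||% "none"),
               "W:"), con)
  utils::write.table(format(model$W, digits = 17), con, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_csp
#' @export
read_csp <- function(path) {
  lines <- readLines(path)
  field <- function(key)
    sub(paste0(key, ": "), "", grep(paste0("^", key, ":"), lines,
                                    value = TRUE)[1])
  w_at <- which(lines == "W:")
  W <- as.matrix(utils::read.table(text = lines[(w_at + 1):length(lines)],
                                   sep = ","))
  dimnames(W) <- NULL
  ev <- as.numeric(strsplit(field("eigenvalues"), ",")[[1]])
  structure(list(
    W = W, eigenvalues = ev, patterns = solve(W),
    selected = list(right = as.integer(field("selected_right")),
                    left = as.integer(field("selected_left")),
                    mode = field("selection_mode")),
    channel_subset = as.integer(strsplit(field("channels"), ",")[[1]])),
    class = "csp")
}
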