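## Online neurofeedback quantities: log band-power features in overlapping
## 1-s bins, three cross-validated linear discriminants (LR, BaseL, BaseR),
## quartile border calibration, and the feedback ball mapping.

#' Extract log band-power features from CSP-projected epochs
#'
#' Slides 1-s bins with a 0.9375-s overlap over the chosen segment of every
#' non-rejected trial. The nominal hop of 0.0625 s is 31.25 samples at
#' 500 Hz; bin onsets are placed at `round(k * hop * fs)`, i.e. alternating
#' 31/32-sample hops, so the cumulative overlap matches 0.9375 s exactly on
#' average. The feature of a bin is `log(mean(x^2))` per virtual channel.
#'
#' @param ep an `epoch_set` (typically CSP-projected, 1--2 channels).
#' @param segment `"mi"` (0.5--4.5 s after MI onset) or `"baseline"`
#'   (-7 to -3 s), or a numeric interval in seconds.
#' @param bin_dur bin length in seconds (default 1).
#' @param hop nominal hop in seconds (default 0.0625, i.e. 0.9375 s overlap).
#' @param eps floor for the mean square before the log (default 1e-12);
#'   an all-zero bin is floored with a warning.
#' @return an object of class `feature_set`: `x` (observations x channels
#'   matrix of log powers), `trial` (epoch index per observation),
#'   `hand`, `bin_onset` (s), `segment`.
#' @export
extract_features <- function(ep, segment = c("mi", "baseline"),
                             bin_dur = 1, hop = 0.0625, eps = 1e-12) {
  if (is.character(segment)) {
    segment <- match.arg(segment)
    interval <- if (segment == "mi") c(0.5, 4.5) else c(-7, -3)
    seg_name <- segment
  } else {
    interval <- segment
    seg_name <- sprintf("[%g,%g)", interval[1], interval[2])
  }
  idx <- interval_index(interval, ep$time[1], ep$fs, length(ep$time))
  bin_len <- as.integer(round(bin_dur * ep$fs))
  n_bins <- floor((length(idx) - bin_len) / (hop * ep$fs)) + 1L
  if (n_bins < 1) stop_cfg("segment shorter than one bin")
  onsets <- as.integer(round((seq_len(n_bins) - 1L) * hop * ep$fs))
  keep <- kept_trials(ep)
  C <- dim(ep$data)[2]
  x <- matrix(0, length(keep) * n_bins, C,
              dimnames = list(NULL, ep$channel_labels))
  floored <- FALSE
  for (k in seq_along(keep)) {
    X <- ep$data[keep[k], , idx, drop = FALSE]
    for (b in seq_len(n_bins)) {
      seg <- X[1, , onsets[b] + seq_len(bin_len), drop = FALSE]
      p <- apply(seg^2, 2, mean)
      if (any(p < eps)) { p <- pmax(p, eps); floored <- TRUE }
      x[(k - 1L) * n_bins + b, ] <- log(p)
    }
  }
  if (floored) warning("zero-power bin(s) floored at eps before log")
  structure(list(x = x,
                 trial = rep(keep, each = n_bins),
                 hand = rep(ep$hand[keep], each = n_bins),
                 bin_onset = interval[1] + rep(onsets, length(keep)) / ep$fs,
                 segment = seg_name),
            class = "feature_set")
}

#' Linear discriminant with grouped, stratified k-fold cross-validation
#'
#' Fits an LDA (pooled within-class covariance with shrinkage) separating
#' class A (target, positive score) from class B. Cross-validation is
#' stratified by class and grouped by trial: all bins of one trial land in
#' the same fold, so overlapping bins never straddle the train/test split.
#' Held-out decision scores are collected for border calibration; the
#' returned classifier is refit on all data.
#'
#' @param features_a,features_b `feature_set`s for the target and the
#'   other class (e.g. right-MI vs left-MI for LR; MI vs baseline for the
#'   Base classifiers).
#' @param k number of folds (default 7).
#' @param gamma covariance shrinkage weight (default 0.05).
#' @return an object of class `lda_cv`: `w`, `b` (score = `w . x + b`,
#'   positive = class A evidence), `fold_accuracy`, `cv_scores`
#'   (data.frame `score`, `is_target`, `trial` of held-out bins), `k`.
#' @export
lda_cv <- function(features_a, features_b, k = 7, gamma = 0.05) {
  xa <- features_a$x; xb <- features_b$x
  if (ncol(xa) != ncol(xb)) stop_cfg("feature dimensions differ")
  ta <- features_a$trial; tb <- features_b$trial
  ua <- unique(ta); ub <- unique(tb)
  if (length(ua) < k || length(ub) < k)
    stop_cfg("k = %d exceeds the smaller class size (%d / %d trials)",
             k, length(ua), length(ub))
  fold_a <- fold_assignment(length(ua), k)
  fold_b <- fold_assignment(length(ub), k)
  obs_fold_a <- fold_a[match(ta, ua)]
  obs_fold_b <- fold_b[match(tb, ub)]

  acc <- numeric(k)
  sc <- vector("list", k)
  for (f in seq_len(k)) {
    fit <- lda_fit(xa[obs_fold_a != f, , drop = FALSE],
                   xb[obs_fold_b != f, , drop = FALSE], gamma)
    sa <- drop(xa[obs_fold_a == f, , drop = FALSE] %*% fit$w + fit$b)
    sb <- drop(xb[obs_fold_b == f, , drop = FALSE] %*% fit$w + fit$b)
    acc[f] <- mean(c(sa > 0, sb <= 0))
    sc[[f]] <- data.frame(score = c(sa, sb),
                          is_target = rep(c(TRUE, FALSE),
                                          c(length(sa), length(sb))),
                          trial = c(ta[obs_fold_a == f],
                                    tb[obs_fold_b == f]))
  }
  fit <- lda_fit(xa, xb, gamma)
  structure(list(w = fit$w, b = fit$b, fold_accuracy = acc,
                 cv_accuracy = mean(acc),
                 cv_scores = do.call(rbind, sc), k = k, gamma = gamma),
            class = "lda_cv")
}

## round-robin fold labels over shuffled group order (uses the RNG;
## callers wanting reproducibility set the seed)
fold_assignment <- function(n_groups, k) {
  sample(rep_len(seq_len(k), n_groups))
}

lda_fit <- function(xa, xb, gamma) {
  ma <- colMeans(xa); mb <- colMeans(xb)
  p <- ncol(xa)
  Sa <- stats::cov(xa); Sb <- stats::cov(xb)
  S <- ((nrow(xa) - 1) * Sa + (nrow(xb) - 1) * Sb) /
    (nrow(xa) + nrow(xb) - 2)
  S <- (1 - gamma) * S + gamma * sum(diag(S)) / p * diag(p)
  w <- drop(solve(S, ma - mb))
  list(w = w, b = -sum(w * (ma + mb) / 2))
}

#' @export
print.lda_cv <- function(x, ...) {
  cat(sprintf("LDA (%d-fold grouped CV): accuracy %.3f (folds %.2f .. %.2f)\n",
              x$k, x$cv_accuracy, min(x$fold_accuracy),
              max(x$fold_accuracy)))
  invisible(x)
}

#' Border value of a classifier
#'
#' The border defines the on-screen dynamic range of the feedback object:
#' the 75th percentile (linear-interpolation convention, `quantile`
#' type 7) of the held-out decision scores of the classifier's target
#' class.
#'
#' @param clf an `lda_cv` (its held-out `cv_scores` are used), or a bare
#'   numeric vector of scores.
#' @param pooled if `TRUE`, use held-out scores of both classes rather
#'   than the target class only (default `FALSE`).
#' @return the border (scalar).
#' @export
compute_border <- function(clf, pooled = FALSE) {
  s <- if (is.numeric(clf)) clf else {
    cs <- clf$cv_scores
    if (pooled) cs$score else cs$score[cs$is_target]
  }
  if (!length(s)) stop_cfg("no scores available for border computation")
  unname(stats::quantile(s, 0.75, type = 7))
}

#' Train the three neurofeedback classifiers of one run
#'
#' From a band-filtered epoch set and a fitted CSP model, extracts MI and
#' baseline features on the two selected CSP channels and trains the
#' classifier triplet that controls the feedback ball: `LR` (right-MI vs
#' left-MI, horizontal lateralization; positive = right evidence), `BaseL`
#' (left-MI vs baseline on the left-class filter) and `BaseR` (right-MI vs
#' baseline on the right-class filter), each with its border.
#'
#' @param ep band-filtered `epoch_set` of the training run.
#' @param model a `csp` model with selected filters.
#' @param k CV folds (default 7).
#' @param gamma LDA shrinkage (default 0.05).
#' @param pooled_border use pooled-class borders (default `FALSE`:
#'   target-class upper quartile).
#' @return an object of class `nf_triplet`: classifiers `LR`, `BaseL`,
#'   `BaseR` and `borders` (named numeric vector).
#' @export
train_nf <- function(ep, model, k = 7, gamma = 0.05,
                     pooled_border = FALSE) {
  proj <- apply_csp(ep, model, "both")   # ch 1 = right filter, 2 = left
  mi <- extract_features(proj, "mi")
  base <- extract_features(proj, "baseline")
  pick <- function(fs, hand_sel, col) {
    sel <- fs$hand %in% hand_sel
    structure(list(x = fs$x[sel, col, drop = FALSE],
                   trial = fs$trial[sel], hand = fs$hand[sel],
                   bin_onset = fs$bin_onset[sel], segment = fs$segment),
              class = "feature_set")
  }
  ## All three classifiers see the same 2-D feature vector (log power of
  ## the right- and left-class CSP channels). Class A = the state whose
  ## evidence drives the ball: right MI for LR, MI-vs-baseline for Base*.
  lr <- lda_cv(pick(mi, "right", 1:2), pick(mi, "left", 1:2), k, gamma)
  base_l <- lda_cv(pick(mi, "left", 1:2), pick(base, "left", 1:2), k, gamma)
  base_r <- lda_cv(pick(mi, "right", 1:2), pick(base, "right", 1:2), k, gamma)
  structure(list(LR = lr, BaseL = base_l, BaseR = base_r,
                 borders = c(LR = compute_border(lr, pooled_border),
                             BaseL = compute_border(base_l, pooled_border),
                             BaseR = compute_border(base_r, pooled_border))),
            class = "nf_triplet")
}

#' @export
print.nf_triplet <- function(x, ...) {
  cat("Neurofeedback classifier triplet\n")
  for (nm in c("LR", "BaseL", "BaseR"))
    cat(sprintf("  %-5s CV accuracy %.3f, border %.3f\n", nm,
                x[[nm]]$cv_accuracy, x$borders[nm]))
  invisible(x)
}

#' Score a feature stream with the classifier triplet
#'
#' @param features a `feature_set` on the two CSP channels (column 1 =
#'   right filter, column 2 = left filter), e.g. MI-segment bins of a
#'   later run.
#' @param triplet an `nf_triplet`.
#' @return matrix (observations x 3) of raw decision scores `LR`, `BaseL`,
#'   `BaseR`; `LR > 0` means right-hand evidence.
#' @export
classify_stream <- function(features, triplet) {
  x <- features$x
  if (ncol(x) != 2) stop_cfg("expected 2 CSP feature channels, got %d",
                             ncol(x))
  score <- function(clf) drop(x %*% clf$w + clf$b)
  cbind(LR = score(triplet$LR),
        BaseL = score(triplet$BaseL),
        BaseR = score(triplet$BaseR))
}

#' Map classifier scores to feedback ball coordinates
#'
#' `x = clip(LR / border_LR, -1, 1)` (lateralization; left-hand success
#' drives the ball left, x -> -1) and `y = clip(Base_hand / border_hand,
#' -1, 1)` (contralateral ERD strength; success drives it up, y -> +1).
#'
#' @param scores matrix from [classify_stream()] (columns `LR`, `BaseL`,
#'   `BaseR`).
#' @param hand `"left"` or `"right"`, one value or one per row.
#' @param borders named vector with `LR`, `BaseL`, `BaseR`, all > 0.
#' @return an object of class `feedback_trace`: data.frame with `x`, `y`
#'   in `[-1, 1]` and `hand`.
#' @export
map_feedback <- function(scores, hand, borders) {
  if (any(borders <= 0)) stop_cfg("all borders must be positive")
  hand <- rep_len(hand, nrow(scores))
  clip <- function(v) pmin(pmax(v, -1), 1)
  base <- ifelse(hand == "left", scores[, "BaseL"] / borders["BaseL"],
                 scores[, "BaseR"] / borders["BaseR"])
  out <- data.frame(x = clip(scores[, "LR"] / borders["LR"]),
                    y = clip(base), hand = hand)
  class(out) <- c("feedback_trace", "data.frame")
  out
}
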