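# Shared fixtures and independent oracles, built in code at test time.

# Symmetric calibration: all four maximal excursions equal `d` mm, so every
# target distance is 0.75 * d.
sym_calib <- function(d = 40) {
  compute_calibration(list(forward = d, backward = d, left = d, right = d))
}

# Asymmetric calibration from explicit maxima.
asym_calib <- function(forward, backward, left, right) {
  compute_calibration(list(forward = forward, backward = backward,
                           left = left, right = right))
}

origin_center <- function() tibble::tibble(x = 0, y = 0)

# RFA set with a fixed centre at the origin (no median recentering).
fixed_rfas <- function(calib = sym_calib()) {
  build_rfas(calib, center = origin_center())
}

random_trajectory <- function(n = 200, sd = 15, fs = 100) {
  cop_trajectory((0:(n - 1)) / fs, rnorm(n, 0, sd), rnorm(n, 0, sd), fs = fs)
}

# Per-sample region membership by direct four-inequality checks (loop oracle,
# independent of the vectorised implementation).
oracle_classify <- function(points, rfas) {
  ctr <- attr(rfas, "center")
  b <- function(col) setNames(rfas[[col]], rfas$direction)
  b33 <- b("b33"); b67 <- b("b67"); b100 <- b("b100")
  out <- character(nrow(points))
  for (i in seq_len(nrow(points))) {
    dx <- points$x[i] - ctr[["x"]]
    dy <- points$y[i] - ctr[["y"]]
    inside <- function(bb)
      dx <= bb[["right"]] && -dx <= bb[["left"]] &&
      dy <= bb[["forward"]] && -dy <= bb[["backward"]]
    out[i] <- if (inside(b33)) "1" else if (inside(b67)) "2"
      else if (inside(b100)) "3" else "outside"
  }
  factor(out, levels = c("1", "2", "3", "outside"))
}

# Brute-force AUC: proportion of correctly ordered (positive, negative) score
# pairs, ties counted half, for higher-is-positive orientation.
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

# Exhaustive Youden search over every observed threshold, counting the
# confusion matrix directly; same tie-break contract as the implementation
# (max J, then max sensitivity, then the more extreme cutoff).
oracle_youden <- function(scores, pos, orientation) {
  thr <- sort(unique(scores))
  best <- NULL
  for (th in thr) {
    pred <- if (orientation == "higher_is_positive") scores >= th else scores <= th
    sens <- sum(pred & pos) / sum(pos)
    spec <- sum(!pred & !pos) / sum(!pos)
    j <- sens + spec - 1
    better <- is.null(best) || j > best$j ||
      (j == best$j && sens > best$sens) ||
      (j == best$j && sens == best$sens &&
         (if (orientation == "lower_is_positive") th < best$cutoff else th > best$cutoff))
    if (better) best <- list(cutoff = th, sens = sens, spec = spec, j = j)
  }
  best
}

# Explicit two-way ANOVA variance components by scalar loops (sums of
# squares computed term by term), then the ICC(2,k) formula.
oracle_icc2k <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  ss_rows <- 0
  for (i in seq_len(n)) ss_rows <- ss_rows + k * (sum(m[i, ]) / k - grand)^2
  ss_cols <- 0
  for (j in seq_len(k)) ss_cols <- ss_cols + n * (sum(m[, j]) / n - grand)^2
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) ss_tot <- ss_tot + (m[i, j] - grand)^2
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (msc - mse) / n)
}

# Log-likelihood of the single-predictor logistic model.
logistic_ll <- function(beta0, beta1, x, y) {
  eta <- beta0 + beta1 * x
  sum(y * eta - log1p(exp(eta)))
}

# Two-stage dense grid search for the logistic MLE (coarse sweep over a wide
# box, then a fine grid around the coarse optimum).
oracle_logistic_grid <- function(x, y) {
  best <- c(0, 0); best_ll <- -Inf
  for (b0 in seq(-10, 10, by = 0.25)) for (b1 in seq(-10, 10, by = 0.25)) {
    ll <- logistic_ll(b0, b1, x, y)
    if (ll > best_ll) { best_ll <- ll; best <- c(b0, b1) }
  }
  for (b0 in seq(best[1] - 0.3, best[1] + 0.3, by = 0.005))
    for (b1 in seq(best[2] - 0.3, best[2] + 0.3, by = 0.005)) {
      ll <- logistic_ll(b0, b1, x, y)
      if (ll > best_ll) { best_ll <- ll; best <- c(b0, b1) }
    }
  list(beta = best, ll = best_ll)
}
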