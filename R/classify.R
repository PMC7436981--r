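#' Fear-of-falling group from the FES-I total score
#'
#' Delbaere-style cutoffs: 16-22 is low concern, 23-64 high concern.
#'
#' @param fes_i Integer vector of FES-I totals in 16..64.
#' @return Character vector, `"low"` or `"high"`.
#' @examples
#' fesi_group(c(16, 22, 23, 64))
#' @export
fesi_group <- function(fes_i) {
  fes_i <- as.integer(fes_i)
  if (any(is.na(fes_i)) || any(fes_i < 16L | fes_i > 64L))
    abort("FES-I scores must be integers in 16..64", class = "ftrcop_data_error")
  ifelse(fes_i <= 22L, "low", "high")
}

# Coerce labels to logical "is positive", with positive_class naming the
# positive level (default "high", the high-FoF group).
.as_positive <- function(labels, positive_class = "high") {
  if (is.logical(labels)) return(labels)
  as.character(labels) == positive_class
}

#' Single-predictor binary logistic regression
#'
#' Maximum-likelihood fit of `P(y = 1) = plogis(beta0 + beta1 * x)` via
#' [stats::glm()], reported on the odds-ratio scale with a Wald 95% CI.
#' Complete or quasi-complete separation is detected (fitted probabilities
#' pinned at 0/1, or an exploding slope) and flagged: the fit is returned
#' with `converged = FALSE` and an infinite CI rather than an error.
#'
#' @param data A data frame, or `NULL` to pass vectors directly.
#' @param x Predictor column (tidy-eval) or numeric vector.
#' @param y Label column or vector; coerced with `positive_class`.
#' @param positive_class Level treated as the event (default `"high"`).
#' @return An object of class `fof_logistic`: a list with `beta0`, `beta1`,
#'   `odds_ratio`, `or_ci95`, `p_value`, `log_lik`, `n`, `converged`,
#'   `separation` and the underlying `glm` fit.
#' @export
fit_logistic <- function(data = NULL, x, y, positive_class = "high") {
  if (is.data.frame(data)) {
    xv <- as.numeric(dplyr::pull(data, {{ x }}))
    yv <- dplyr::pull(data, {{ y }})
  } else {
    xv <- as.numeric(x); yv <- y
  }
  yv <- .as_positive(yv, positive_class)
  keep <- is.finite(xv) & !is.na(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(unique(yv)) < 2L)
    abort("both classes must be present to fit a logistic model",
          class = "ftrcop_data_error")
  separation_warned <- FALSE
  fit <- withCallingHandlers(
    glm(yv ~ xv, family = binomial(),
        control = list(epsilon = 1e-10, maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation_warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  separation <- separation_warned && (abs(beta[2L]) > 10 / max(sd(xv), 1e-12) || se[2L] > 1e3)
  z <- beta[2L] / se[2L]
  structure(list(
    beta0 = unname(beta[1L]), beta1 = unname(beta[2L]),
    odds_ratio = exp(unname(beta[2L])),
    or_ci95 = if (separation) c(0, Inf) else
      exp(unname(beta[2L]) + c(-1, 1) * qnorm(0.975) * se[2L]),
    p_value = 2 * pnorm(-abs(z)),
    log_lik = as.numeric(logLik(fit)),
    n = length(xv),
    converged = fit$converged && !separation,
    separation = separation,
    fit = fit), class = "fof_logistic")
}

#' @export
print.fof_logistic <- function(x, ...) {
  cat(sprintf("<fof_logistic: OR = %.3g [%.3g, %.3g], p = %.3g, logLik = %.3f, n = %d%s>\n",
              x$odds_ratio, x$or_ci95[1], x$or_ci95[2], x$p_value, x$log_lik, x$n,
              if (x$separation) ", SEPARATED" else ""))
  invisible(x)
}

# Sensitivity/specificity at every candidate threshold.
# For orientation "higher_is_positive" predict positive when score >= thr;
# for "lower_is_positive" when score <= thr. Thresholds are the observed
# score values plus -Inf/+Inf so the curve reaches (0,1) and (1,0).
.roc_points <- function(scores, pos, orientation) {
  thr <- c(-Inf, sort(unique(scores)), Inf)
  np <- sum(pos); nn <- sum(!pos)
  sens <- spec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- if (orientation == "higher_is_positive") scores >= thr[i] else scores <= thr[i]
    sens[i] <- sum(pred & pos) / np
    spec[i] <- sum(!pred & !pos) / nn
  }
  tibble::tibble(threshold = thr, sensitivity = sens, specificity = spec)
}

# Rank (Mann-Whitney) AUC with tie correction, for higher-is-positive scores.
.auc_rank <- function(scores, pos) {
  r <- rank(scores)
  np <- sum(pos); nn <- sum(!pos)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC analysis with Youden-optimal cutoff
#'
#' Computes the ROC curve over all observed score thresholds, the AUC by the
#' rank (Mann-Whitney) formulation with tie correction, a seeded stratified
#' bootstrap 95% CI for the AUC, and the Youden-optimal cutoff
#' (maximising J = sensitivity + specificity - 1; ties broken by higher
#' sensitivity, then the more extreme cutoff). The orientation is chosen
#' automatically so that AUC >= 0.5 and is reported: `lower_is_positive`
#' means low scores indicate the positive class (as for the FTR1/2 index,
#' where low values indicate high fear of falling).
#'
#' @param data A data frame, or `NULL` to pass vectors.
#' @param scores Score column (tidy-eval) or numeric vector.
#' @param labels Label column or vector.
#' @param positive_class Level treated as positive (default `"high"`).
#' @param orientation `"auto"` (default), `"higher_is_positive"` or
#'   `"lower_is_positive"`.
#' @param boot_n Bootstrap resamples for the AUC CI (default 2000; 0 skips).
#' @param seed Seed for the bootstrap (default 1).
#' @return An object of class `cop_roc`: list with `curve` (tibble), `auc`,
#'   `auc_ci95`, `orientation`, `youden_cutoff`, `youden_sens`,
#'   `youden_spec`, `n_pos`, `n_neg`, `degenerate`.
#' @export
roc_analysis <- function(data = NULL, scores, labels, positive_class = "high",
                         orientation = c("auto", "higher_is_positive", "lower_is_positive"),
                         boot_n = 2000L, seed = 1L) {
  orientation <- match.arg(orientation)
  if (is.data.frame(data)) {
    sv <- as.numeric(dplyr::pull(data, {{ scores }}))
    lv <- dplyr::pull(data, {{ labels }})
  } else {
    sv <- as.numeric(scores); lv <- labels
  }
  pos <- .as_positive(lv, positive_class)
  if (sum(pos) == 0L || sum(!pos) == 0L)
    abort("both classes must be present for ROC analysis", class = "ftrcop_data_error")

  degenerate <- length(unique(sv)) == 1L
  auc_hi <- if (degenerate) 0.5 else .auc_rank(sv, pos)
  if (orientation == "auto")
    orientation <- if (auc_hi >= 0.5) "higher_is_positive" else "lower_is_positive"
  auc <- if (orientation == "higher_is_positive") auc_hi else 1 - auc_hi

  curve <- .roc_points(sv, pos, orientation)
  yj <- youden_from_curve(curve, orientation)

  ci <- c(NA_real_, NA_real_)
  if (boot_n > 0L && !degenerate) {
    ip <- which(pos); im <- which(!pos)
    boot <- local_seed(seed, {
      vapply(seq_len(boot_n), function(b) {
        bi <- c(sample(ip, length(ip), replace = TRUE),
                sample(im, length(im), replace = TRUE))
        a <- .auc_rank(sv[bi], pos[bi])
        if (orientation == "higher_is_positive") a else 1 - a
      }, 1.0)
    })
    ci <- unname(quantile(boot, c(0.025, 0.975), type = 7))
  }

  structure(list(curve = curve, auc = auc, auc_ci95 = ci,
                 orientation = orientation,
                 youden_cutoff = yj$cutoff, youden_sens = yj$sens,
                 youden_spec = yj$spec,
                 n_pos = sum(pos), n_neg = sum(!pos),
                 degenerate = degenerate),
            class = "cop_roc")
}

#' @export
print.cop_roc <- function(x, ...) {
  cat(sprintf("<cop_roc: AUC = %.3f [%.3f, %.3f], %s, Youden cutoff %s %.4g (sens %.3f, spec %.3f)>\n",
              x$auc, x$auc_ci95[1], x$auc_ci95[2], x$orientation,
              if (x$orientation == "lower_is_positive") "<=" else ">=",
              x$youden_cutoff, x$youden_sens, x$youden_spec))
  invisible(x)
}

# Youden maximiser over the finite thresholds of a .roc_points() curve.
youden_from_curve <- function(curve, orientation) {
  finite <- is.finite(curve$threshold)
  thr <- curve$threshold[finite]
  sens <- curve$sensitivity[finite]
  spec <- curve$specificity[finite]
  j <- sens + spec - 1
  best <- which(j == max(j))
  if (length(best) > 1L) best <- best[sens[best] == max(sens[best])]
  if (length(best) > 1L) {
    # more extreme = further in the predicted-positive direction
    best <- if (orientation == "lower_is_positive") best[which.min(thr[best])]
            else best[which.max(thr[best])]
  }
  list(cutoff = thr[best], sens = sens[best], spec = spec[best], j = j[best])
}

#' Youden-optimal cutoff of an existing ROC
#'
#' @param roc A [roc_analysis()] result.
#' @return A one-row tibble: `cutoff`, `sensitivity`, `specificity`, `j`.
#' @export
youden_cutoff <- function(roc) {
  yj <- youden_from_curve(roc$curve, roc$orientation)
  tibble::tibble(cutoff = yj$cutoff, sensitivity = yj$sens,
                 specificity = yj$spec, j = yj$j)
}

#' Corrected Akaike information criterion
#'
#' `"aicc"` (default) is the small-sample correction
#' \eqn{-2 \ln L + 2k + 2k(k+1)/(n-k-1)}; `"consistent"` is Bozdogan's
#' \eqn{-2 \ln L + k(\ln n + 1)}. Model ranking (lower is better) is what
#' the pipeline uses, not the absolute value.
#'
#' @param log_likelihood Maximised log-likelihood (nats).
#' @param k_params Number of free parameters.
#' @param n Sample size.
#' @param variant `"aicc"` or `"consistent"`.
#' @return The criterion value.
#' @examples
#' caic(-10, 2, 38)                       # 24 + 12/35
#' caic(-10, 2, 38, variant = "consistent")
#' @export
caic <- function(log_likelihood, k_params, n, variant = c("aicc", "consistent")) {
  variant <- match.arg(variant)
  if (variant == "aicc") {
    if (n <= k_params + 1)
      abort("AICc requires n > k + 1", class = "ftrcop_parameter_error")
    -2 * log_likelihood + 2 * k_params + 2 * k_params * (k_params + 1) / (n - k_params - 1)
  } else {
    -2 * log_likelihood + k_params * (log(n) + 1)
  }
}

#' Stratified fivefold cross-validation of a single-predictor classifier
#'
#' Folds are stratified by class from a seeded shuffle. In each fold a
#' logistic model is fitted on the training portion, the Youden-optimal
#' operating point is derived from the training ROC (on the predicted
#' probabilities), and the held-out fold is classified against a decision
#' boundary placed midway between that optimal threshold and the adjacent
#' observed value on the other side — the midpoint generalises to unseen
#' scores that fall inside the training gap, unlike the inclusive
#' observed-value cutoff used for reporting. The pooled confusion matrix
#' gives the error, sensitivity and specificity percentages.
#' Bit-reproducible under a fixed seed.
#'
#' @param data A data frame, or `NULL` to pass vectors.
#' @param scores Score column (tidy-eval) or numeric vector.
#' @param labels Label column or vector.
#' @param folds Number of folds (default 5).
#' @param seed Seed for the stratified shuffle.
#' @param positive_class Level treated as positive (default `"high"`).
#' @param reuse_global_cutoff Use one Youden cutoff from the full sample
#'   instead of re-deriving per fold (default `FALSE`).
#' @return A one-row tibble of class `cv_result`: `folds`, `error_pct`,
#'   `sensitivity_pct`, `specificity_pct`, `tp`, `fp`, `tn`, `fn`, `seed`.
#' @export
crossvalidate <- function(data = NULL, scores, labels, folds = 5L, seed = 1L,
                          positive_class = "high", reuse_global_cutoff = FALSE) {
  if (is.data.frame(data)) {
    sv <- as.numeric(dplyr::pull(data, {{ scores }}))
    lv <- dplyr::pull(data, {{ labels }})
  } else {
    sv <- as.numeric(scores); lv <- labels
  }
  pos <- .as_positive(lv, positive_class)
  if (min(sum(pos), sum(!pos)) < folds)
    abort(sprintf("each class needs at least %d members for %d-fold CV", folds, folds),
          class = "ftrcop_data_error")
  fold_of <- integer(length(sv))
  local_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- sample(which(pos == cls))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  # Youden-optimal probability threshold, moved to the midpoint between it
  # and the next observed probability below, so held-out scores landing in
  # the training gap are classified sensibly.
  boundary <- function(p_train, pos_train) {
    roc <- roc_analysis(scores = p_train, labels = pos_train, positive_class = TRUE,
                        orientation = "higher_is_positive", boot_n = 0L)
    cut <- youden_cutoff(roc)$cutoff
    lower <- p_train[p_train < cut]
    if (length(lower) == 0L) cut / 2 else (cut + max(lower)) / 2
  }
  global_cut <- if (reuse_global_cutoff) {
    fit <- fit_logistic(x = sv, y = pos, positive_class = TRUE)
    p <- predict(fit$fit, newdata = data.frame(xv = sv), type = "response")
    boundary(p, pos)
  }
  tp <- fp <- tn <- fn <- 0L
  for (f in seq_len(folds)) {
    tr <- fold_of != f; te <- !tr
    fit <- fit_logistic(x = sv[tr], y = pos[tr], positive_class = TRUE)
    p_tr <- predict(fit$fit, newdata = data.frame(xv = sv[tr]), type = "response")
    cut <- if (reuse_global_cutoff) global_cut else boundary(p_tr, pos[tr])
    p_te <- predict(fit$fit, newdata = data.frame(xv = sv[te]), type = "response")
    pred <- p_te >= cut
    tp <- tp + sum(pred & pos[te]); fn <- fn + sum(!pred & pos[te])
    tn <- tn + sum(!pred & !pos[te]); fp <- fp + sum(pred & !pos[te])
  }
  out <- tibble::tibble(
    folds = folds,
    error_pct = 100 * (fp + fn) / (tp + fp + tn + fn),
    sensitivity_pct = 100 * tp / (tp + fn),
    specificity_pct = 100 * tn / (tn + fp),
    tp = tp, fp = fp, tn = tn, fn = fn, seed = seed)
  class(out) <- c("cv_result", class(out))
  out
}

#' Apply a fixed decision threshold to the FTR1/2 index
#'
#' The clinical decision rule: an FTR1/2 at or below the cutoff indicates
#' the high fear-of-falling group (low values mean relatively little time in
#' the inner region). The default cutoff 2.83 is the ground-level rule; 2.71
#' is the 40-cm-height variant. Both are inclusive. An infinite FTR1/2
#' (degenerate, no time in region 2) maps to `"low"` under the default
#' orientation.
#'
#' @param ftr12 Numeric vector of FTR1/2 values.
#' @param cutoff Decision threshold (default 2.83).
#' @param orientation `"lower_is_positive"` (default) or
#'   `"higher_is_positive"`.
#' @return Character vector, `"high"` or `"low"`.
#' @examples
#' apply_threshold(c(2.83, 2.84))          # "high" "low"
#' apply_threshold(2.71, cutoff = 2.71)    # "high"
#' @export
apply_threshold <- function(ftr12, cutoff = 2.83,
                            orientation = c("lower_is_positive", "higher_is_positive")) {
  orientation <- match.arg(orientation)
  hit <- if (orientation == "lower_is_positive") ftr12 <= cutoff else ftr12 >= cutoff
  ifelse(hit, "high", "low")
}
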