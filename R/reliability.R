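icc_bands <- function(icc) {
  if (!is.finite(icc)) return(NA_character_)
  if (icc < 0.40) "poor" else if (icc < 0.75) "acceptable" else "high"
}

sem_bands <- function(sem_pct) {
  if (!is.finite(sem_pct)) return(NA_character_)
  if (sem_pct > 20) "poor" else if (sem_pct > 10) "acceptable" else "high"
}

#' Intra-class correlation ICC(2,k) with SEM
#'
#' Two-way random-effects, absolute-agreement, average-of-k-measures
#' intraclass correlation from the two-way ANOVA mean squares:
#' \deqn{ICC(2,k) = (MS_R - MS_E) / (MS_R + (MS_C - MS_E)/n)}
#' with subjects as rows and trials as columns. The 95% CI is the
#' F-distribution interval for the single-measure agreement form
#' (Satterthwaite degrees of freedom), stepped up to k measures via
#' Spearman-Brown. The standard error of measurement is
#' `SD_pooled * sqrt(1 - ICC)` (the pooled SD of all observations;
#' `sem_formula = "ms_error"` uses `sqrt(MS_E)` instead) and
#' `%SEM = SEM / grand mean x 100`.
#'
#' Interpretation bands: ICC < 0.40 poor, 0.40-0.75 acceptable, >= 0.75 high
#' relative reliability; %SEM > 20 poor, 10-20 acceptable, <= 10 high
#' absolute reliability.
#'
#' @param table An `n x k` numeric matrix or data frame (subjects x trials),
#'   no missing cells, `n >= 2`, `k >= 2`.
#' @param form `"agreement"` (default, the (2,k) absolute-agreement form) or
#'   `"consistency"` (`(MS_R - MS_E)/MS_R`, ICC(3,k)-style).
#' @param sem_formula `"pooled_sd"` (default) or `"ms_error"`.
#' @param conf_level Confidence level for the ICC interval (default 0.95).
#' @return A one-row tibble of class `reliability_report`: `icc`, `icc_lo`,
#'   `icc_hi`, `sem`, `sem_pct`, `relative_label`, `absolute_label`,
#'   `n_subjects`, `k_trials`, `degenerate`.
#' @export
icc_2k <- function(table, form = c("agreement", "consistency"),
                   sem_formula = c("pooled_sd", "ms_error"), conf_level = 0.95) {
  form <- match.arg(form)
  sem_formula <- match.arg(sem_formula)
  m <- as.matrix(table)
  if (anyNA(m))
    abort("missing cells in the subjects x trials table", class = "ftrcop_data_error")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L)
    abort("need at least 2 subjects and 2 trials", class = "ftrcop_data_error")

  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_total <- sum((m - grand)^2)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))

  degenerate <- ss_total < .Machine$double.eps * max(1, abs(grand))^2 * n * k
  if (degenerate) {
    icc <- NA_real_; lo <- NA_real_; hi <- NA_real_
  } else if (form == "agreement") {
    icc <- (msr - mse) / (msr + (msc - mse) / n)
    # single-measure (A,1) F interval with Satterthwaite df, then Spearman-Brown
    icc1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    alpha <- 1 - conf_level
    a <- (k * icc1) / (n * (1 - icc1))
    b <- 1 + (k * icc1 * (n - 1)) / (n * (1 - icc1))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f2 <- qf(1 - alpha / 2, n - 1, v)
    f3 <- qf(1 - alpha / 2, v, n - 1)
    lo1 <- n * (msr - f2 * mse) / (f2 * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi1 <- n * (f3 * msr - mse) / (k * msc + (k * n - k - n) * mse + n * f3 * msr)
    sb <- function(r) r * k / (1 + r * (k - 1))
    lo <- sb(lo1); hi <- sb(hi1)
  } else {
    icc <- (msr - mse) / msr
    alpha <- 1 - conf_level
    f_obs <- msr / mse
    lo <- 1 - qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1)) / f_obs
    hi <- 1 - 1 / (qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1) * f_obs)
  }

  sd_pooled <- sd(as.vector(m))
  sem <- if (degenerate) 0 else switch(sem_formula,
    pooled_sd = sd_pooled * sqrt(max(0, 1 - icc)),
    ms_error = sqrt(mse))
  sem_pct <- if (abs(grand) < .Machine$double.eps) NA_real_ else sem / grand * 100

  out <- tibble::tibble(
    icc = icc, icc_lo = lo, icc_hi = hi,
    sem = sem, sem_pct = sem_pct,
    relative_label = icc_bands(icc), absolute_label = sem_bands(sem_pct),
    n_subjects = n, k_trials = k, degenerate = degenerate)
  class(out) <- c("reliability_report", class(out))
  out
}

correlation_bands <- function(r) {
  a <- abs(r)
  if (!is.finite(a)) NA_character_
  else if (a > 0.50) "strong" else if (a >= 0.35) "moderate"
  else if (a >= 0.20) "weak" else "negligible"
}

#' Correlation with clinical interpretation bands
#'
#' Pearson or Spearman correlation with the conventional strength bands on
#' |r|: 0.00-0.19 negligible, 0.20-0.34 weak, 0.35-0.50 moderate, > 0.50
#' strong. `method = "auto"` uses Spearman when a Shapiro-Wilk test rejects
#' normality (p <= 0.05) for either variable, Pearson otherwise.
#'
#' @param data A data frame containing the two variables (tibble-first), or
#'   `NULL` if `x` and `y` are vectors.
#' @param x,y Column names (tidy-eval) when `data` is supplied, else numeric
#'   vectors.
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @return A one-row tibble of class `correlation_report`: `method`, `r`,
#'   `r_squared`, `p_value`, `strength_label`, `n`, `degenerate`.
#' @export
correlate <- function(data = NULL, x, y, method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  if (is.data.frame(data)) {
    xv <- as.numeric(dplyr::pull(data, {{ x }}))
    yv <- as.numeric(dplyr::pull(data, {{ y }}))
  } else {
    xv <- as.numeric(x); yv <- as.numeric(y)
  }
  if (length(xv) != length(yv) || length(xv) < 3L)
    abort("x and y must have equal length >= 3", class = "ftrcop_data_error")
  if (sd(xv) == 0 || sd(yv) == 0) {
    out <- tibble::tibble(method = NA_character_, r = NA_real_, r_squared = NA_real_,
                          p_value = NA_real_, strength_label = NA_character_,
                          n = length(xv), degenerate = TRUE)
    class(out) <- c("correlation_report", class(out))
    return(out)
  }
  if (method == "auto") {
    method <- if (shapiro.test(xv)$p.value <= 0.05 || shapiro.test(yv)$p.value <= 0.05)
      "spearman" else "pearson"
  }
  ct <- suppressWarnings(cor.test(xv, yv, method = method, exact = FALSE))
  r <- unname(ct$estimate)
  out <- tibble::tibble(method = method, r = r,
                        r_squared = if (method == "pearson") r^2 else NA_real_,
                        p_value = ct$p.value, strength_label = correlation_bands(r),
                        n = length(xv), degenerate = FALSE)
  class(out) <- c("correlation_report", class(out))
  out
}

#' Screen a feature table for multicollinearity
#'
#' Flags every pair of features whose absolute Pearson correlation exceeds
#' 0.80 (strictly), the conventional pre-screen before entering predictors
#' into a logistic model.
#'
#' @param features A data frame of numeric feature columns (>= 2).
#' @param threshold Flagging threshold on |r| (default 0.80, strict).
#' @return A tibble with columns `feature_a`, `feature_b`, `r`; zero rows if
#'   no pair is collinear.
#' @export
collinearity_screen <- function(features, threshold = 0.80) {
  m <- as.matrix(dplyr::select(tibble::as_tibble(features), dplyr::where(is.numeric)))
  if (ncol(m) < 2L)
    abort("need at least 2 numeric features", class = "ftrcop_data_error")
  cm <- cor(m)
  pairs <- which(upper.tri(cm) & abs(cm) > threshold, arr.ind = TRUE)
  tibble::tibble(feature_a = colnames(cm)[pairs[, 1L]],
                 feature_b = colnames(cm)[pairs[, 2L]],
                 r = cm[pairs])
}
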