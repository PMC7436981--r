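#' Analyse one session: preprocess, build RFAs, compute FTRs
#'
#' Runs the full single-subject pipeline: each trial is preprocessed
#' (home estimation, quiet-stance trim, zero-phase low-pass), the RFAs are
#' built per repetition around that repetition's CoP median, and the FTRs
#' are computed; the three repetitions of each height level are then
#' averaged with [aggregate_trials()].
#'
#' @param session A [los_session()] with calibration and trials.
#' @param reference RFA reference distance, `"target"` (default) or `"max"`.
#' @param ratio Aggregation rule for `ftr12`, see [aggregate_trials()].
#' @param pooled_median Use one median centre pooled across the repetitions
#'   of a height level instead of per-repetition centres (default `FALSE`).
#' @param ... Passed to [preprocess_trial()].
#' @return A list of class `session_analysis`: `trials` (one row per
#'   repetition: `subject_id`, `height_level`, `repetition_index`, FTR
#'   columns) and `conditions` (one aggregated row per height level).
#' @export
analyze_session <- function(session, reference = c("target", "max"),
                            ratio = c("ratio_of_means", "mean_of_ratios"),
                            pooled_median = FALSE, ...) {
  reference <- match.arg(reference)
  ratio <- match.arg(ratio)
  if (is.null(session$calibration))
    abort("session has no calibration; FTRs cannot be computed",
          class = "ftrcop_data_error")
  sid <- session$subject$subject_id %||% NA_character_

  pp <- purrr::map(session$trials, function(tr) {
    tryCatch(preprocess_trial(tr$traj, ...),
             error = function(e) abort(
               sprintf("trial %s rep %s: %s", tr$height_level, tr$repetition_index,
                       conditionMessage(e)),
               class = "ftrcop_data_error"))
  })

  centers <- NULL
  if (pooled_median) {
    levels_seen <- vapply(session$trials, `[[`, "", "height_level")
    centers <- purrr::map(split(pp, levels_seen), function(pps) {
      xs <- unlist(purrr::map(pps, ~ .x$traj$x))
      ys <- unlist(purrr::map(pps, ~ .x$traj$y))
      tibble::tibble(x = median(xs), y = median(ys))
    })
  }

  trials <- purrr::map2(session$trials, pp, function(tr, p) {
    ctr <- if (pooled_median) centers[[tr$height_level]] else NULL
    rfas <- build_rfas(session$calibration, p$traj, reference = reference,
                       center = ctr)
    dplyr::bind_cols(
      tibble::tibble(subject_id = sid, height_level = tr$height_level,
                     repetition_index = tr$repetition_index),
      compute_ftrs(p$traj, rfas))
  })
  trials <- dplyr::bind_rows(trials)

  conditions <- trials |>
    dplyr::group_by(.data$subject_id, .data$height_level) |>
    dplyr::group_modify(~ aggregate_trials(.x, ratio = ratio)) |>
    dplyr::ungroup()

  structure(list(trials = trials, conditions = conditions),
            class = "session_analysis")
}

#' Per-subject feature table for a cohort
#'
#' Runs [analyze_session()] over every session and assembles the classifier
#' features: per-condition aggregated `ftr1`, `ftr2`, `ftr3` and `ftr12` at
#' ground level plus `ftr12` at 40 cm, joined with the FES-I score and the
#' fear-of-falling group.
#'
#' @param cohort A list of [los_session()] objects (e.g. [make_cohort()]).
#' @param ... Passed to [analyze_session()].
#' @return A list of class `cohort_analysis`: `features` (one row per
#'   subject), `trials` (all per-repetition rows, for reliability analysis).
#' @export
analyze_cohort <- function(cohort, ...) {
  analyses <- purrr::map(cohort, analyze_session, ...)
  trials <- dplyr::bind_rows(purrr::map(analyses, "trials"))
  conditions <- dplyr::bind_rows(purrr::map(analyses, "conditions"))

  subjects <- dplyr::bind_rows(purrr::map(cohort, "subject"))
  wide <- conditions |>
    dplyr::select("subject_id", "height_level", "ftr1", "ftr2", "ftr3", "ftr12") |>
    tidyr::pivot_wider(names_from = "height_level",
                       values_from = c("ftr1", "ftr2", "ftr3", "ftr12"))
  features <- dplyr::left_join(wide, subjects, by = "subject_id")
  structure(list(features = features, trials = trials, conditions = conditions),
            class = "cohort_analysis")
}

#' Test-retest reliability table over the cohort's repetitions
#'
#' For each height level and each FTR measure, arranges the subjects x
#' repetitions matrix and computes ICC(2,k) with SEM via [icc_2k()] — the
#' intra-session reliability layout of the measure's validation.
#'
#' @param trials A per-repetition tibble as returned in
#'   `analyze_cohort()$trials` (columns `subject_id`, `height_level`,
#'   `repetition_index` and the measures).
#' @param measures Character vector of measure columns (default
#'   `c("ftr1", "ftr2", "ftr3")`).
#' @param ... Passed to [icc_2k()].
#' @return A tibble with one row per height level x measure, containing the
#'   `reliability_report` columns.
#' @export
reliability_table <- function(trials, measures = c("ftr1", "ftr2", "ftr3"), ...) {
  combos <- tidyr::expand_grid(height_level = unique(trials$height_level),
                               measure = measures)
  purrr::pmap_dfr(combos, function(height_level, measure) {
    wide <- trials |>
      dplyr::filter(.data$height_level == !!height_level) |>
      dplyr::select("subject_id", "repetition_index", dplyr::all_of(measure)) |>
      tidyr::pivot_wider(names_from = "repetition_index",
                         values_from = dplyr::all_of(measure)) |>
      dplyr::select(-"subject_id")
    dplyr::bind_cols(tibble::tibble(height_level = height_level, measure = measure),
                     icc_2k(as.matrix(wide), ...))
  })
}

#' Fit and compare the fear-of-falling classifier models
#'
#' For each candidate predictor (by default `ftr1`, `ftr2` and `ftr3` at
#' ground level, `ftr12` at ground and at 40 cm) fits the single-predictor
#' logistic model of group membership, runs the ROC analysis with
#' Youden-optimal cutoff, computes the corrected AIC, and evaluates the
#' model with stratified fivefold cross-validation. The best model is the
#' one with the lowest CAIC.
#'
#' @param features A feature table with a `fof_group` column (e.g.
#'   `analyze_cohort()$features`).
#' @param models Named character vector: names are model labels, values are
#'   feature columns. Missing columns are skipped.
#' @param seed Seed for the bootstrap CI and the CV folds.
#' @param caic_variant Passed to [caic()].
#' @param boot_n Bootstrap resamples for the AUC CI.
#' @param ... Passed to [crossvalidate()].
#' @return A tibble of class `fof_model_comparison`, one row per model:
#'   odds ratio + CI + p, AUC + CI, Youden cutoff/sens/spec, overall
#'   accuracy at the cutoff, CAIC, CV error/sensitivity/specificity, and
#'   `best` flagging the lowest-CAIC model.
#' @export
classify_cohort <- function(features,
                            models = c(ftr1 = "ftr1_ground", ftr2 = "ftr2_ground",
                                       ftr12_ground = "ftr12_ground",
                                       ftr12_40cm = "ftr12_h40cm"),
                            seed = 1L, caic_variant = "aicc", boot_n = 2000L, ...) {
  if (!"fof_group" %in% names(features))
    abort("features must contain a 'fof_group' column", class = "ftrcop_data_error")
  models <- models[unname(models) %in% names(features)]
  if (length(models) == 0L)
    abort("none of the requested model columns are present",
          class = "ftrcop_data_error")
  rows <- purrr::imap(models, function(col, label) {
    x <- features[[col]]
    y <- features$fof_group
    fit <- fit_logistic(x = x, y = y)
    roc <- roc_analysis(scores = x, labels = y, boot_n = boot_n, seed = seed)
    pred <- apply_threshold(x, cutoff = roc$youden_cutoff,
                            orientation = roc$orientation)
    acc <- 100 * mean(pred == y)
    cv <- crossvalidate(scores = x, labels = y, seed = seed, ...)
    tibble::tibble(
      model = label, predictor = col, n = fit$n,
      odds_ratio = fit$odds_ratio,
      or_lo = fit$or_ci95[1L], or_hi = fit$or_ci95[2L], p_value = fit$p_value,
      separation = fit$separation,
      auc = roc$auc, auc_lo = roc$auc_ci95[1L], auc_hi = roc$auc_ci95[2L],
      orientation = roc$orientation,
      cutoff = roc$youden_cutoff,
      sensitivity_pct = 100 * roc$youden_sens,
      specificity_pct = 100 * roc$youden_spec,
      accuracy_pct = acc,
      caic = caic(fit$log_lik, 2L, fit$n, variant = caic_variant),
      cv_error_pct = cv$error_pct,
      cv_sensitivity_pct = cv$sensitivity_pct,
      cv_specificity_pct = cv$specificity_pct)
  })
  out <- dplyr::bind_rows(rows)
  out$best <- out$caic == min(out$caic)
  class(out) <- c("fof_model_comparison", class(out))
  out
}
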