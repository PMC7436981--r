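test_that("FES-I grouping uses the 22/23 cutoff inclusively", {
  expect_equal(fesi_group(22), "low")
  expect_equal(fesi_group(23), "high")
  expect_equal(fesi_group(16), "low")
  expect_equal(fesi_group(64), "high")
  expect_error(fesi_group(15), class = "ftrcop_data_error")
  expect_error(fesi_group(65), class = "ftrcop_data_error")
})

test_that("logistic fit attains the grid-search maximum likelihood", {
  withr::local_seed(50)
  done <- 0
  for (i in 1:20) {
    if (done >= 5) break
    n <- 12
    x <- rnorm(n)
    y <- runif(n) < stats::plogis(0.5 + x)
    if (length(unique(y)) < 2) next
    fit <- fit_logistic(x = x, y = y, positive_class = TRUE)
    # the grid box covers |beta| <= 10; skip quasi-separated draws outside it
    if (fit$separation || max(abs(c(fit$beta0, fit$beta1))) > 8) next
    g <- oracle_logistic_grid(x, as.numeric(y))
    expect_gte(fit$log_lik, g$ll - 1e-6)       # MLE dominates any grid point
    expect_lt(abs(fit$log_lik - g$ll), 1e-4)   # and the dense grid gets this close
    done <- done + 1
  }
  expect_gte(done, 5)
})

test_that("logistic slope is null for permuted labels and flags separation", {
  withr::local_seed(51)
  x <- rnorm(300)
  y <- sample(rep(c("low", "high"), 150))
  fit <- fit_logistic(x = x, y = y)
  expect_true(fit$or_ci95[1] <= 1 && 1 <= fit$or_ci95[2])

  xs <- c(1:6, 10:15)
  ys <- rep(c("low", "high"), each = 6)
  sep <- fit_logistic(x = xs, y = ys)
  expect_true(sep$separation)
  expect_false(sep$converged)
  expect_equal(sep$or_ci95, c(0, Inf))

  expect_error(fit_logistic(x = 1:10, y = rep("high", 10)),
               class = "ftrcop_data_error")
})

test_that("AUC equals brute-force pair counting, including ties", {
  r <- roc_analysis(scores = c(1, 2, 3, 4), labels = c("low", "low", "high", "high"),
                    orientation = "higher_is_positive", boot_n = 0)
  expect_equal(r$auc, 1)

  r_tie <- roc_analysis(scores = c(1, 2, 2, 4), labels = c("low", "low", "high", "high"),
                        orientation = "higher_is_positive", boot_n = 0)
  expect_equal(r_tie$auc,
               oracle_auc(c(1, 2, 2, 4), c(FALSE, FALSE, TRUE, TRUE)))

  # label-independent scores: AUC near chance
  withr::local_seed(52)
  s <- rnorm(2000); l <- sample(rep(c("low", "high"), 1000))
  expect_equal(roc_analysis(scores = s, labels = l, boot_n = 0,
                            orientation = "higher_is_positive")$auc, 0.5,
               tolerance = 0.04)

  # degenerate: constant scores
  dg <- roc_analysis(scores = rep(1, 10), labels = rep(c("low", "high"), 5), boot_n = 0)
  expect_equal(dg$auc, 0.5)
  expect_true(dg$degenerate)
})

test_that("ROC curve reaches both corners and the CI brackets the AUC", {
  withr::local_seed(53)
  s <- c(rnorm(20, 0), rnorm(20, 1.5))
  l <- rep(c("low", "high"), each = 20)
  r <- roc_analysis(scores = s, labels = l, boot_n = 200, seed = 5)
  expect_true(any(r$curve$sensitivity == 1 & r$curve$specificity == 0))
  expect_true(any(r$curve$sensitivity == 0 & r$curve$specificity == 1))
  expect_true(r$auc_ci95[1] <= r$auc && r$auc <= r$auc_ci95[2])
})

test_that("Youden cutoff equals exhaustive enumeration on random small datasets", {
  withr::local_seed(54)
  for (i in 1:60) {
    n <- sample(6:50, 1)
    scores <- round(rnorm(n), sample(0:2, 1))   # induce ties
    pos <- runif(n) < 0.5
    if (sum(pos) == 0 || sum(!pos) == 0) next
    r <- roc_analysis(scores = scores, labels = pos, positive_class = TRUE, boot_n = 0)
    yc <- youden_cutoff(r)
    or <- oracle_youden(scores, pos, r$orientation)
    expect_equal(r$auc, max(oracle_auc(scores, pos), 1 - oracle_auc(scores, pos)),
                 tolerance = 1e-12)
    expect_equal(yc$cutoff, or$cutoff)
    expect_equal(yc$sensitivity, or$sens, tolerance = 1e-12)
    expect_equal(yc$specificity, or$spec, tolerance = 1e-12)
  }
})

test_that("the Youden point reclassifies training data at its reported sens/spec", {
  withr::local_seed(55)
  s <- c(rnorm(25, 0, 1.2), rnorm(25, 2, 1.2))
  l <- rep(c("low", "high"), each = 25)
  r <- roc_analysis(scores = s, labels = l, boot_n = 0)
  pred <- apply_threshold(s, cutoff = r$youden_cutoff, orientation = r$orientation)
  pos <- l == "high"
  expect_equal(mean(pred[pos] == "high"), r$youden_sens)
  expect_equal(mean(pred[!pos] == "low"), r$youden_spec)
})

test_that("corrected AIC variants follow their formulas and preserve ranking", {
  expect_equal(caic(-10, 2, 38), 24 + 12 / 35)
  expect_equal(caic(-10, 2, 38, variant = "consistent"), 20 + 2 * (log(38) + 1))
  # equal k and n: the better likelihood wins under both variants
  expect_lt(caic(-8, 2, 38), caic(-10, 2, 38))
  expect_lt(caic(-8, 2, 38, variant = "consistent"),
            caic(-10, 2, 38, variant = "consistent"))
  expect_error(caic(-10, 2, 3), class = "ftrcop_parameter_error")
})

test_that("cross-validation separates separable data and is seed-reproducible", {
  s <- c(seq(1, 2, length.out = 15), seq(5, 6, length.out = 15))
  l <- rep(c("high", "low"), each = 15)
  cv <- crossvalidate(scores = s, labels = l, seed = 3)
  expect_equal(cv$error_pct, 0)
  expect_equal(cv$sensitivity_pct, 100)
  expect_equal(cv$specificity_pct, 100)

  expect_identical(crossvalidate(scores = s, labels = l, seed = 3), cv)

  withr::local_seed(56)
  s2 <- rnorm(200); l2 <- sample(rep(c("low", "high"), 100))
  cv2 <- crossvalidate(scores = s2, labels = l2, seed = 4)
  expect_lt(abs(cv2$error_pct - 50), 10)

  expect_error(crossvalidate(scores = 1:8, labels = rep(c("low", "high"), 4), folds = 5),
               class = "ftrcop_data_error")
})

test_that("the fixed decision rule is inclusive at the printed cutoffs", {
  expect_equal(apply_threshold(2.83), "high")
  expect_equal(apply_threshold(2.84), "low")
  expect_equal(apply_threshold(2.71, cutoff = 2.71), "high")
  expect_equal(apply_threshold(2.72, cutoff = 2.71), "low")
  expect_equal(apply_threshold(Inf), "low")
})

test_that("tidiers expose model and ROC summaries as tibbles", {
  withr::local_seed(57)
  x <- rnorm(40); y <- runif(40) < stats::plogis(x)
  fit <- fit_logistic(x = x, y = y, positive_class = TRUE)
  td <- tidy(fit)
  expect_equal(td$term, c("intercept", "slope"))
  expect_equal(td$odds_ratio[2], fit$odds_ratio)
  gl <- glance(fit)
  expect_equal(gl$log_lik, fit$log_lik)

  r <- roc_analysis(scores = x, labels = y, positive_class = TRUE, boot_n = 0)
  expect_true(all(c("threshold", "sensitivity", "specificity", "j") %in% names(tidy(r))))
  expect_equal(glance(r)$auc, r$auc)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(58)
  s <- round(c(rnorm(30, 0), rnorm(30, 1)), 1)   # with ties
  l <- rep(c(0, 1), each = 30)
  ours <- roc_analysis(scores = s, labels = l, positive_class = 1,
                       orientation = "higher_is_positive", boot_n = 0)
  ref <- suppressMessages(pROC::auc(pROC::roc(l, s, direction = "<", quiet = TRUE)))
  expect_equal(ours$auc, as.numeric(ref), tolerance = 1e-12)
})
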