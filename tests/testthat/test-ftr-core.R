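test_that("RFA boundaries are 33/67/100% of the reference distance", {
  calib <- sym_calib(40)   # target distance 30 everywhere
  rfas <- fixed_rfas(calib)
  expect_equal(rfas$b33, rep(9.9, 4))
  expect_equal(rfas$b67, rep(20.1, 4))
  expect_equal(rfas$b100, rep(30, 4))
  # nesting invariant
  expect_true(all(rfas$b33 < rfas$b67 & rfas$b67 < rfas$b100))
  # alternative reference: raw maximal excursion
  rmax <- build_rfas(calib, center = origin_center(), reference = "max")
  expect_equal(rmax$b100, rep(40, 4))
})

test_that("RFA centre is the per-axis median and shifts with the data", {
  withr::local_seed(14)
  n <- 101   # odd so the median is an order statistic
  tr <- random_trajectory(n)
  rfas <- build_rfas(sym_calib(), tr)
  sx <- sort(tr$x); sy <- sort(tr$y)   # sort-and-pick oracle
  expect_equal(attr(rfas, "center")[["x"]], sx[(n + 1) / 2])
  expect_equal(attr(rfas, "center")[["y"]], sy[(n + 1) / 2])

  shifted <- cop_trajectory(tr$t, tr$x + 4, tr$y - 6)
  rfas2 <- build_rfas(sym_calib(), shifted)
  expect_equal(attr(rfas2, "center")[["x"]], attr(rfas, "center")[["x"]] + 4)
  expect_equal(attr(rfas2, "center")[["y"]], attr(rfas, "center")[["y"]] - 6)
  expect_equal(rfas2$b33, rfas$b33)   # boundaries unchanged by translation
})

test_that("sample classification matches the four-inequality oracle and closes inner boundaries", {
  rfas <- fixed_rfas(sym_calib(40))
  expect_equal(as.character(classify_samples(tibble::tibble(x = 0, y = 0), rfas)), "1")
  # exactly on the 33% boundary -> region 1 (closed toward the smaller region)
  expect_equal(as.character(classify_samples(tibble::tibble(x = 9.9, y = 0), rfas)), "1")
  expect_equal(as.character(classify_samples(tibble::tibble(x = 20.1, y = 0), rfas)), "2")
  expect_equal(as.character(classify_samples(tibble::tibble(x = 30, y = 0), rfas)), "3")
  expect_equal(as.character(classify_samples(tibble::tibble(x = 30.0001, y = 0), rfas)), "outside")

  withr::local_seed(15)
  pts <- tibble::tibble(x = runif(10000, -45, 45), y = runif(10000, -45, 45))
  expect_identical(classify_samples(pts, rfas), oracle_classify(pts, rfas))

  # asymmetric extents are applied per side
  rfas_a <- build_rfas(asym_calib(40, 20, 20, 40), center = origin_center())
  p <- tibble::tibble(x = c(0, 0), y = c(25, -25))
  expect_equal(as.character(classify_samples(p, rfas_a)), c("3", "outside"))
})

test_that("FTRs count sample dwell fractions and conserve total time", {
  calib <- sym_calib(40)
  rfas <- fixed_rfas(calib)
  fs <- 100

  at_center <- cop_trajectory((0:9) / fs, rep(0, 10), rep(0, 10), fs = fs)
  res <- compute_ftrs(at_center, rfas)
  expect_equal(c(res$ftr1, res$ftr2, res$ftr3, res$ftr_out), c(100, 0, 0, 0))
  expect_true(is.infinite(res$ftr12) && res$ftr12_degenerate)

  # 12 samples placed 6/3/3 in regions 1/2/3
  x <- c(rep(0, 6), rep(15, 3), rep(25, 3))
  tr12 <- cop_trajectory((0:11) / fs, x, rep(0, 12), fs = fs)
  res12 <- compute_ftrs(tr12, rfas)
  expect_equal(c(res12$ftr1, res12$ftr2, res12$ftr3), c(50, 25, 25))
  expect_equal(res12$ftr12, 2)

  far <- cop_trajectory((0:9) / fs, rep(100, 10), rep(100, 10), fs = fs)
  res_far <- compute_ftrs(far, rfas)
  expect_equal(res_far$ftr_out, 100)
  expect_equal(res_far$ftr1 + res_far$ftr2 + res_far$ftr3, 0)
})

test_that("conservation, nesting and scale coherence hold on random trajectories", {
  withr::local_seed(16)
  for (i in 1:25) {
    calib <- asym_calib(runif(1, 20, 60), runif(1, 20, 60),
                        runif(1, 20, 60), runif(1, 20, 60))
    tr <- random_trajectory(n = 150, sd = runif(1, 5, 40))
    rfas <- build_rfas(calib, tr)
    res <- compute_ftrs(tr, rfas)
    expect_lt(abs(res$ftr1 + res$ftr2 + res$ftr3 + res$ftr_out - 100), 1e-9)

    # nesting: cumulative time inside 33% <= 67% <= 100%
    expect_true(res$ftr1 <= res$ftr1 + res$ftr2)
    expect_true(res$ftr1 + res$ftr2 <= res$ftr1 + res$ftr2 + res$ftr3)

    # scaling trajectory and calibration together leaves FTRs unchanged
    k <- runif(1, 0.5, 3)
    calib_k <- compute_calibration(list(
      forward = k * calib$max_excursion_mm[calib$direction == "forward"],
      backward = k * calib$max_excursion_mm[calib$direction == "backward"],
      left = k * calib$max_excursion_mm[calib$direction == "left"],
      right = k * calib$max_excursion_mm[calib$direction == "right"]))
    tr_k <- cop_trajectory(tr$t, k * tr$x, k * tr$y)
    res_k <- compute_ftrs(tr_k, build_rfas(calib_k, tr_k))
    expect_equal(c(res_k$ftr1, res_k$ftr2, res_k$ftr3, res_k$ftr_out),
                 c(res$ftr1, res$ftr2, res$ftr3, res$ftr_out), tolerance = 1e-9)
  }
})

test_that("trial aggregation averages components with ratio-of-means default", {
  one <- compute_ftrs(cop_trajectory((0:11) / 100, c(rep(0, 6), rep(15, 3), rep(25, 3)),
                                     rep(0, 12)), fixed_rfas())
  agg_same <- aggregate_trials(list(one, one, one))
  expect_equal(agg_same$ftr1, one$ftr1)
  expect_equal(agg_same$ftr12, one$ftr12)

  mk <- function(f1, f2) {
    r <- one
    r$ftr1 <- f1; r$ftr2 <- f2; r$ftr3 <- 100 - f1 - f2; r$ftr_out <- 0
    r$ftr12 <- f1 / f2
    r
  }
  trio <- list(mk(60, 20), mk(50, 25), mk(40, 30))
  agg <- aggregate_trials(trio)
  expect_equal(agg$ftr1, 50)
  expect_equal(agg$ftr2, 25)
  expect_equal(agg$ftr12, 2)
  agg_mr <- aggregate_trials(trio, ratio = "mean_of_ratios")
  expect_equal(agg_mr$ftr12, (3 + 2 + 4 / 3) / 3, tolerance = 1e-12)

  expect_error(aggregate_trials(list()), class = "ftrcop_data_error")
})
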