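test_that("calibration takes the per-direction maximum and 75% target distance", {
  calib <- compute_calibration(list(forward = c(38, 40, 35), backward = c(30, 31, 29),
                                    left = c(25, 27, 26), right = c(28, 26, 27)))
  expect_equal(calib$max_excursion_mm[calib$direction == "forward"], 40)
  expect_equal(calib$target_distance_mm[calib$direction == "forward"], 30)
  expect_equal(calib$target_distance_mm / calib$max_excursion_mm, rep(0.75, 4))

  single <- compute_calibration(list(forward = 33, backward = 22, left = 11, right = 44))
  expect_equal(single$max_excursion_mm, c(33, 22, 11, 44))

  withr::local_seed(8)
  attempts <- purrr::map(setNames(1:4, c("forward", "backward", "left", "right")),
                         ~ runif(5, 10, 50))
  calib2 <- compute_calibration(attempts)
  for (d in names(attempts)) {
    best <- -Inf
    for (v in attempts[[d]]) if (v > best) best <- v   # loop-and-compare oracle
    expect_equal(calib2$max_excursion_mm[calib2$direction == d], best)
  }

  expect_error(compute_calibration(list(forward = -1, backward = 1, left = 1, right = 1)),
               class = "ftrcop_data_error")
  expect_error(compute_calibration(list(forward = 1, backward = 1, left = 1)),
               "right", class = "ftrcop_format_error")
})

test_that("targets sit on the movement rectangle, cardinals on their axes", {
  home <- tibble::tibble(x = 0, y = 0)
  sym <- place_targets(sym_calib(40), home)   # all target distances 30
  fr <- sym[sym$direction == "forward_right", ]
  expect_equal(c(fr$x, fr$y), c(30, 30), tolerance = 1e-12)
  expect_equal(unlist(sym[sym$direction == "forward", c("x", "y")]),
               c(x = 0, y = 30), tolerance = 1e-12)

  # forward 30, right 15: the 45-degree ray exits on the right edge first
  mix <- place_targets(asym_calib(40, 40, 40, 20), home)
  fr2 <- mix[mix$direction == "forward_right", ]
  expect_equal(c(fr2$x, fr2$y), c(15, 15), tolerance = 1e-12)

  # random asymmetric calibrations: every target on the rectangle boundary
  withr::local_seed(12)
  for (rep in 1:10) {
    calib <- asym_calib(runif(1, 20, 60), runif(1, 20, 60),
                        runif(1, 20, 60), runif(1, 20, 60))
    d <- setNames(calib$target_distance_mm, calib$direction)
    lay <- place_targets(calib, home)
    for (i in seq_len(nrow(lay))) {
      px <- lay$x[i]; py <- lay$y[i]
      on_x_edge <- abs(px - d[["right"]]) < 1e-9 || abs(px + d[["left"]]) < 1e-9
      on_y_edge <- abs(py - d[["forward"]]) < 1e-9 || abs(py + d[["backward"]]) < 1e-9
      inside <- px <= d[["right"]] + 1e-9 && -px <= d[["left"]] + 1e-9 &&
        py <= d[["forward"]] + 1e-9 && -py <= d[["backward"]] + 1e-9
      expect_true(inside && (on_x_edge || on_y_edge))
    }
  }

  # translation equivariance of the whole layout
  lay0 <- place_targets(sym_calib(40), home)
  lay1 <- place_targets(sym_calib(40), tibble::tibble(x = 7, y = -2))
  expect_equal(lay1$x, lay0$x + 7, tolerance = 1e-12)
  expect_equal(lay1$y, lay0$y - 2, tolerance = 1e-12)

  expect_error(place_targets(sym_calib(), home, target_radius = 0),
               class = "ftrcop_parameter_error")
})

test_that("a trajectory that never leaves home scores zero", {
  withr::local_seed(3)
  layout <- place_targets(sym_calib(40), origin_center(), target_radius = 3)
  fs <- 100
  n <- 30 * fs
  tr <- cop_trajectory((0:(n - 1)) / fs, rnorm(n, 0, 0.3), rnorm(n, 0, 0.3), fs = fs)
  sc <- detect_hits(tr, layout)
  expect_equal(attr(sc, "total_score"), 0L)
})

test_that("the 10-s timeout boundary is inclusive", {
  layout <- place_targets(sym_calib(40), origin_center(), target_radius = 3)
  fs <- 100
  mk <- function(touch_t) {
    n <- round((touch_t + 0.5) * fs)
    x <- rep(0, n); y <- rep(0, n)
    i <- round(touch_t * fs) + 1
    y[i:n] <- 30   # jump onto the forward target and stay
    cop_trajectory((0:(n - 1)) / fs, x, y, fs = fs)
  }
  order <- c("forward", "backward", "left", "right",
             "forward_right", "back_right", "back_left", "forward_left")
  hit <- detect_hits(mk(9.99), layout, order = order)
  expect_true(hit$hit[1])
  expect_equal(hit$time_to_hit[1], 9.99)
  miss <- detect_hits(mk(10.01), layout, order = order)
  expect_false(miss$hit[1])
})

test_that("simulated perfect subject scores 8 and replay matches ground truth", {
  prof <- sim_profile("low_fof_like", hit_probability = 1,
                      reach_accuracy = 0, tremor_amplitude = 0)
  calib <- sym_calib(40)
  layout <- place_targets(calib, origin_center())
  sim <- simulate_los_trial(prof, layout, seed = 9)
  expect_equal(sim$true_score, 8L)
  sc <- detect_hits(preprocess_trial(sim$traj), layout, order = sim$order)
  expect_equal(attr(sc, "total_score"), 8L)
  expect_false(attr(sc, "truncated"))

  none <- simulate_los_trial(sim_profile("low_fof_like", hit_probability = 0),
                             layout, seed = 9)
  expect_equal(none$true_score, 0L)
})

test_that("replayed score reproduces the simulator's ground truth across profiles", {
  home <- origin_center()
  for (s in 1:8) {
    prof <- sim_profile(if (s %% 2) "low_fof_like" else "high_fof_like")
    calib <- compute_calibration(simulate_calibration(prof, seed = 200 + s))
    layout <- place_targets(calib, home)
    sim <- simulate_los_trial(prof, layout, seed = s)
    sc <- detect_hits(preprocess_trial(sim$traj), layout, order = sim$order)
    expect_equal(attr(sc, "total_score"), sim$true_score)
    expect_false(attr(sc, "truncated"))
  }
})

test_that("total score is monotone non-decreasing in the target radius", {
  home <- origin_center()
  prof <- sim_profile("high_fof_like")
  calib <- compute_calibration(simulate_calibration(prof, seed = 77))
  for (s in c(5, 6)) {
    lay0 <- place_targets(calib, home)
    sim <- simulate_los_trial(prof, lay0, seed = s)
    pp <- preprocess_trial(sim$traj)
    r0 <- attr(lay0, "target_radius")
    scores <- purrr::map_int(c(1, 1.5, 2.5), function(f) {
      lay <- place_targets(calib, home, target_radius = r0 * f)
      attr(detect_hits(pp, lay, order = sim$order), "total_score")
    })
    expect_true(all(diff(scores) >= 0))
  }
})
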