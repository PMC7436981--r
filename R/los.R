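new_calibration <- function(direction, max_excursion_mm, n_attempts = NA_integer_) {
  out <- tibble::tibble(direction = direction,
                        max_excursion_mm = as.numeric(max_excursion_mm),
                        target_distance_mm = 0.75 * as.numeric(max_excursion_mm))
  out <- out[match(.cardinals, out$direction), ]
  attr(out, "n_attempts") <- n_attempts
  class(out) <- c("cop_calibration", class(out))
  out
}

#' Compute a calibration profile from maximal-excursion attempts
#'
#' During calibration the subject leans as far as possible forward, backward,
#' left and right; the maximal CoP excursion per direction (relative to home)
#' over the recorded attempts defines the movement range, and 75% of it is
#' the secure target distance used to place the LoS targets.
#'
#' @param attempts Either a named list with elements `forward`, `backward`,
#'   `left`, `right`, each a numeric vector of excursion magnitudes in mm, or
#'   a data frame with columns `direction` and `excursion_mm`.
#' @return A tibble of class `cop_calibration` with columns `direction`,
#'   `max_excursion_mm` and `target_distance_mm` (= 0.75 x max), and an
#'   `n_attempts` attribute.
#' @examples
#' compute_calibration(list(forward = c(38, 40, 35), backward = c(30, 31, 29),
#'                          left = c(25, 27, 26), right = c(28, 26, 27)))
#' @export
compute_calibration <- function(attempts) {
  if (is.data.frame(attempts)) {
    if (!all(c("direction", "excursion_mm") %in% names(attempts)))
      abort("attempts data frame needs columns 'direction' and 'excursion_mm'",
            class = "ftrcop_format_error")
    attempts <- split(attempts$excursion_mm, attempts$direction)
  }
  missing_dir <- setdiff(.cardinals, names(attempts))
  if (length(missing_dir) > 0L)
    abort(paste0("missing calibration direction(s): ", paste(missing_dir, collapse = ", ")),
          class = "ftrcop_format_error")
  maxima <- purrr::map_dbl(attempts[.cardinals], function(v) {
    v <- as.numeric(v)
    if (length(v) < 1L || any(!is.finite(v)) || any(v <= 0))
      abort("calibration excursions must be positive and finite",
            class = "ftrcop_data_error")
    max(v)
  })
  new_calibration(.cardinals, maxima,
                  n_attempts = max(lengths(attempts[.cardinals])))
}

# Per-direction target distance lookup -> named numeric (forward/backward/left/right)
calib_distances <- function(calib, reference = c("target", "max")) {
  reference <- match.arg(reference)
  d <- if (reference == "target") calib$target_distance_mm else calib$max_excursion_mm
  setNames(d, calib$direction)
}

#' Place the eight LoS targets around the home position
#'
#' Cardinal targets sit at the calibrated target distance along their axis.
#' Diagonal targets sit where the 45-degree ray meets the boundary of the
#' movement rectangle whose half-extents are the per-direction target
#' distances (the movement area is treated as a rectangle); alternatively an
#' elliptical interpolation between adjacent cardinal distances can be used.
#'
#' @param calib A [compute_calibration()] profile.
#' @param home A one-row data frame with columns `x`, `y` (mm), e.g. from
#'   [estimate_home()].
#' @param target_radius Hit tolerance in mm. Defaults to 10% of the mean
#'   cardinal target distance (the on-screen target size is a protocol choice,
#'   not a measured quantity).
#' @param diagonal `"rectangle"` (default, ray-rectangle intersection) or
#'   `"ellipse"`.
#' @return A tibble of class `los_layout` with columns `direction`, `x`, `y`
#'   (absolute target positions, mm) and attributes `home`, `target_radius`
#'   and `distances` (the per-cardinal target distances).
#' @export
place_targets <- function(calib, home, target_radius = NULL,
                          diagonal = c("rectangle", "ellipse")) {
  diagonal <- match.arg(diagonal)
  d <- calib_distances(calib)
  target_radius <- target_radius %||% (0.1 * mean(d))
  if (!is.finite(target_radius) || target_radius <= 0)
    abort("target_radius must be a positive number", class = "ftrcop_parameter_error")
  offsets <- purrr::map(.directions8, function(dir) {
    u <- .dir_unit(dir)
    dx_lim <- if (u[1] >= 0) d[["right"]] else d[["left"]]
    dy_lim <- if (u[2] >= 0) d[["forward"]] else d[["backward"]]
    if (dir %in% .cardinals) {
      u * if (u[1] != 0) dx_lim else dy_lim
    } else if (diagonal == "rectangle") {
      s <- min(dx_lim / abs(u[1]), dy_lim / abs(u[2]))
      u * s
    } else {
      r <- 1 / sqrt((u[1] / dx_lim)^2 + (u[2] / dy_lim)^2)
      u * r
    }
  })
  out <- tibble::tibble(
    direction = .directions8,
    x = home$x[1L] + purrr::map_dbl(offsets, 1L),
    y = home$y[1L] + purrr::map_dbl(offsets, 2L)
  )
  attr(out, "home") <- c(x = home$x[1L], y = home$y[1L])
  attr(out, "target_radius") <- target_radius
  attr(out, "distances") <- d
  class(out) <- c("los_layout", class(out))
  out
}

# First index >= from at which `ok` holds continuously for span seconds
# (sample spacing 1/fs); returns the index where the span completes, or NA.
.first_hold_end <- function(ok, from, span, fs) {
  need <- round(span * fs)
  n <- length(ok)
  i <- from
  while (i <= n) {
    if (!ok[i]) { i <- i + 1L; next }
    run_end <- i
    while (run_end < n && ok[run_end + 1L]) run_end <- run_end + 1L
    if (run_end - i >= need) return(i + need)
    i <- run_end + 1L
  }
  NA_integer_
}

#' Score a limit-of-stability trial by replaying its phase timeline
#'
#' Replays the task against the preprocessed trajectory: each target phase
#' ends at the first sample within `target_radius` of the blinking target
#' (a hit; at most `timeout` seconds from phase onset, inclusive), or at the
#' timeout (a miss). Either way the subject must then return and remain
#' within `home_radius` of home continuously for `hold` seconds before the
#' next target starts. The total score is the number of targets hit (0-8).
#'
#' @param trial A `preprocessed_trial` (from [preprocess_trial()]) or a
#'   [cop_trajectory] whose time starts at the first task sample.
#' @param layout A [place_targets()] layout.
#' @param order Character vector of the 8 directions in presentation order.
#' @param timeout Per-target time limit in seconds (default 10).
#' @param hold Required continuous home dwell in seconds (default 5).
#' @param home_radius Home tolerance in mm; defaults to the layout's
#'   `target_radius`.
#' @return A tibble of class `los_score` with columns `direction`, `hit`,
#'   `time_to_hit` (s, `NA` on miss) and `onset_s`, plus attributes
#'   `total_score` and `truncated`.
#' @export
detect_hits <- function(trial, layout, order = .directions8,
                        timeout = 10, hold = 5, home_radius = NULL) {
  traj <- if (inherits(trial, "preprocessed_trial")) trial$traj else as_cop_trajectory(trial)
  if (!setequal(order, .directions8) || length(order) != 8L)
    abort("order must be a permutation of the 8 target directions",
          class = "ftrcop_parameter_error")
  fs <- cop_fs(traj)
  home <- attr(layout, "home")
  radius <- attr(layout, "target_radius")
  home_radius <- home_radius %||% radius
  n <- nrow(traj)
  d_home <- sqrt((traj$x - home[["x"]])^2 + (traj$y - home[["y"]])^2)
  home_ok <- d_home <= home_radius

  res <- tibble::tibble(direction = order, hit = FALSE,
                        time_to_hit = NA_real_, onset_s = NA_real_)
  truncated <- FALSE
  i <- 1L
  for (k in seq_len(8L)) {
    if (i > n) { truncated <- TRUE; break }
    onset <- traj$t[i]
    res$onset_s[k] <- onset
    tgt <- layout[layout$direction == order[k], ]
    # scan only the timeout window
    last <- min(n, i + ceiling(timeout * fs) + 1L)
    idx <- i:last
    in_window <- traj$t[idx] - onset <= timeout + 1e-9
    d_tgt <- sqrt((traj$x[idx] - tgt$x)^2 + (traj$y[idx] - tgt$y)^2)
    hit_at <- idx[which(d_tgt <= radius & in_window)[1L]]
    if (!is.na(hit_at)) {
      res$hit[k] <- TRUE
      res$time_to_hit[k] <- traj$t[hit_at] - onset
      i <- hit_at
    } else {
      if (traj$t[n] - onset < timeout - 1e-9) { truncated <- TRUE; break }
      i <- which(traj$t - onset > timeout - 1e-9)[1L]
    }
    # home phase
    end_i <- .first_hold_end(home_ok, i, hold, fs)
    if (is.na(end_i)) {
      if (k < 8L) truncated <- TRUE
      break
    }
    i <- end_i
  }
  attr(res, "total_score") <- sum(res$hit)
  attr(res, "truncated") <- truncated
  class(res) <- c("los_score", class(res))
  res
}
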