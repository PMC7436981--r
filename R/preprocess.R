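# Single IIR pass with steady-state initial conditions (the filter state that
# reproduces a constant input exactly), so DC passes without a start-up
# transient.
.iir_pass <- function(b, a, x) {
  ord <- max(length(a), length(b)) - 1L
  x0 <- x[1L]
  dc <- sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x0, ord), init.y = rep(x0 * dc, ord)))
}

# Zero-phase (forward-backward) filtering with odd reflective padding at both
# ends; the effective magnitude response is the square of the single-pass one.
.filtfilt_reflect <- function(b, a, x, padlen) {
  n <- length(x)
  pre <- 2 * x[1L] - x[(padlen + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  ext <- c(pre, x, post)
  y <- .iir_pass(b, a, ext)
  y <- rev(.iir_pass(b, a, rev(y)))
  y[(padlen + 1L):(padlen + n)]
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass forward and backward (zero phase, so dwell
#' times are not shifted in time), with odd reflective padding and
#' steady-state initialisation at each end. Because of the two passes the
#' effective magnitude response is the squared single-pass response: the gain
#' at the cutoff frequency is 1/2, not 1/sqrt(2). `order` is the order of the
#' designed prototype per pass (the posturography convention), i.e. an
#' 8th-order effective magnitude for the default `order = 4`.
#'
#' @param traj A [cop_trajectory].
#' @param order Filter order per pass (default 4).
#' @param cutoff Cutoff frequency in Hz (default 10); must be below Nyquist.
#' @return A filtered [cop_trajectory] with identical timestamps.
#' @examples
#' tr <- cop_trajectory(seq(0, 2, by = 0.01), sin(2 * pi * 2 * seq(0, 2, by = 0.01)), 0 * 0:200)
#' filt <- lowpass_filter(tr)
#' @export
lowpass_filter <- function(traj, order = 4L, cutoff = 10) {
  traj <- as_cop_trajectory(traj)
  fs <- cop_fs(traj)
  if (cutoff >= fs / 2)
    abort(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                  cutoff, fs / 2), class = "ftrcop_parameter_error")
  padlen <- 3L * (order + 1L)
  if (nrow(traj) <= padlen)
    abort(sprintf("signal too short to filter: %d samples, need > %d",
                  nrow(traj), padlen), class = "ftrcop_data_error")
  bw <- signal::butter(order, cutoff / (fs / 2), type = "low")
  cop_trajectory(traj$t,
                 .filtfilt_reflect(bw$b, bw$a, traj$x, padlen),
                 .filtfilt_reflect(bw$b, bw$a, traj$y, padlen),
                 fs = fs)
}

#' Estimate the home position from initial quiet stance
#'
#' The home position is the arithmetic mean CoP over the first `window`
#' seconds of the recording (the quiet-stance phase that precedes the task).
#'
#' @param traj A [cop_trajectory].
#' @param window Averaging window in seconds from the start (default 5).
#' @return A one-row tibble with columns `x` and `y` (mm).
#' @export
estimate_home <- function(traj, window = 5) {
  traj <- as_cop_trajectory(traj)
  dur <- traj$t[nrow(traj)] - traj$t[1L] + 1 / cop_fs(traj)
  if (dur < window)
    abort(sprintf("trajectory too short for home estimation: %.3f s available, %.3f s required",
                  dur, window), class = "ftrcop_data_error")
  keep <- traj$t - traj$t[1L] < window
  tibble::tibble(x = mean(traj$x[keep]), y = mean(traj$y[keep]))
}

#' Preprocess a limit-of-stability trial
#'
#' Estimates the home position from the raw initial quiet stance, removes
#' that quiet-stance prefix, re-zeroes time, and low-pass filters the
#' remainder. The default order (trim, then filter) treats the task phase as
#' the analysis signal; set `filter_before_trim = TRUE` to filter the whole
#' recording first (this changes a few samples near the trim boundary).
#'
#' @param traj A raw [cop_trajectory] covering quiet stance plus the task.
#' @param quiet_stance_s Duration of the quiet-stance prefix (default 5 s).
#' @param order,cutoff Passed to [lowpass_filter()].
#' @param filter_before_trim Filter across the trim boundary instead of after
#'   trimming (default `FALSE`).
#' @param home_from Estimate home from the `"raw"` (default) or `"filtered"`
#'   quiet-stance samples.
#' @return A list of class `preprocessed_trial` with elements `traj` (the
#'   filtered, trimmed trajectory, time starting at 0), `home` (tibble) and
#'   `removed_duration` (seconds).
#' @export
preprocess_trial <- function(traj, quiet_stance_s = 5, order = 4L, cutoff = 10,
                             filter_before_trim = FALSE, home_from = c("raw", "filtered")) {
  home_from <- match.arg(home_from)
  traj <- as_cop_trajectory(traj)
  fs <- cop_fs(traj)
  dur <- traj$t[nrow(traj)] - traj$t[1L]
  if (dur <= quiet_stance_s)
    abort(sprintf("trial duration %.3f s does not exceed the %.3f s quiet-stance prefix",
                  dur, quiet_stance_s), class = "ftrcop_data_error")
  home_src <- if (home_from == "raw") traj else lowpass_filter(traj, order, cutoff)
  home <- estimate_home(home_src, window = quiet_stance_s)

  trim <- function(tr) {
    keep <- tr$t - tr$t[1L] >= quiet_stance_s - 1e-9
    cop_trajectory(tr$t[keep] - tr$t[keep][1L], tr$x[keep], tr$y[keep], fs = fs)
  }
  out <- if (filter_before_trim) {
    trim(lowpass_filter(traj, order, cutoff))
  } else {
    lowpass_filter(trim(traj), order, cutoff)
  }
  structure(list(traj = out, home = home, removed_duration = quiet_stance_s),
            class = "preprocessed_trial")
}
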