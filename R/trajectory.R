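#' Construct a centre-of-pressure trajectory
#'
#' A CoP trajectory is a tibble with columns `t` (seconds, strictly increasing
#' and uniformly sampled), `x` (millimetres, mediolateral, positive toward the
#' subject's right) and `y` (millimetres, anteroposterior, positive anterior),
#' carrying the sampling rate as the `fs` attribute.
#'
#' @param t Numeric vector of sample times in seconds.
#' @param x,y Numeric vectors of CoP position in millimetres, same length as `t`.
#' @param fs Sampling rate in Hz. If `NULL`, inferred as `1 / median(diff(t))`.
#' @return A tibble of class `cop_trajectory` with columns `t`, `x`, `y` and an
#'   `fs` attribute.
#' @examples
#' tr <- cop_trajectory(t = seq(0, 1, by = 0.01), x = rnorm(101), y = rnorm(101))
#' cop_fs(tr)
#' @export
cop_trajectory <- function(t, x, y, fs = NULL) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  if (length(t) < 2L)
    abort("a CoP trajectory needs at least 2 samples", class = "ftrcop_data_error")
  if (length(x) != length(t) || length(y) != length(t))
    abort("t, x and y must have the same length", class = "ftrcop_data_error")
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad) > 0L)
    abort(paste0("non-finite CoP samples: ", length(bad), " value(s) at indices ",
                 paste(head(bad, 5L), collapse = ", "),
                 if (length(bad) > 5L) ", ..." else ""),
          class = "ftrcop_data_error")
  dt <- diff(t)
  nonmono <- which(dt <= 0)
  if (length(nonmono) > 0L)
    abort(paste0("time not strictly increasing at index ", nonmono[1L] + 1L),
          class = "ftrcop_data_error")
  if (is.null(fs)) fs <- 1 / median(dt)
  if (!is.finite(fs) || fs <= 0)
    abort("sampling rate must be a positive number", class = "ftrcop_data_error")
  if (max(abs(dt - 1 / fs)) >= 1e-6)
    abort(paste0("sampling not uniform at ", signif(fs, 6), " Hz: max |dt - 1/fs| = ",
                 signif(max(abs(dt - 1 / fs)), 3), " s"),
          class = "ftrcop_data_error")
  out <- tibble::new_tibble(list(t = t, x = x, y = y),
                            nrow = length(t),
                            class = "cop_trajectory", fs = fs)
  out
}

#' Sampling rate of a trajectory
#' @param traj A `cop_trajectory` (or any data frame with a `t` column).
#' @return Sampling rate in Hz.
#' @export
cop_fs <- function(traj) {
  fs <- attr(traj, "fs")
  if (is.null(fs)) fs <- 1 / median(diff(traj$t))
  fs
}

# Rebuild the class/attributes after dplyr/tidyr operations strip them.
as_cop_trajectory <- function(df, fs = NULL) {
  cop_trajectory(df$t, df$x, df$y, fs = fs %||% attr(df, "fs"))
}

#' @export
print.cop_trajectory <- function(x, ...) {
  cat(sprintf("<cop_trajectory: %d samples @ %.6g Hz, %.2f s>\n",
              nrow(x), cop_fs(x), x$t[nrow(x)] - x$t[1L]))
  NextMethod()
}
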