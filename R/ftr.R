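#' Build the three nested rectangular functional areas (RFAs)
#'
#' The RFAs are three co-centric rectangles centred on the per-axis median of
#' the analysed CoP samples. The per-direction boundary distances are 33%,
#' 67% and 100% of that direction's reference distance. By default the
#' reference is the calibrated target distance (75% of the maximal
#' excursion), because target placement defines the movement rectangle;
#' `reference = "max"` uses the raw maximal excursion instead.
#'
#' The three regions used downstream are disjoint bands: region 1 is the
#' inner rectangle, region 2 the 33-67% band, region 3 the 67-100% band;
#' samples beyond the outermost rectangle fall outside (tracked separately).
#'
#' @param calib A [compute_calibration()] profile.
#' @param traj A preprocessed [cop_trajectory] (quiet stance removed); its
#'   per-axis median becomes the RFA centre.
#' @param reference `"target"` (default) or `"max"`.
#' @param center Optional fixed centre, a one-row data frame with `x`, `y`;
#'   overrides the median (used by the dwell-mode simulator harness).
#' @param levels Fractions of the reference distance (default `c(0.33, 0.67, 1)`).
#' @return A tibble of class `rfa_set` with columns `direction`, `b33`,
#'   `b67`, `b100` (mm from the centre) and attributes `center` and `levels`.
#' @export
build_rfas <- function(calib, traj = NULL, reference = c("target", "max"),
                       center = NULL, levels = c(0.33, 0.67, 1)) {
  reference <- match.arg(reference)
  if (is.null(center)) {
    if (is.null(traj) || nrow(traj) == 0L)
      abort("a trajectory (or an explicit center) is required to centre the RFAs",
            class = "ftrcop_data_error")
    center <- c(x = median(traj$x), y = median(traj$y))
  } else {
    center <- c(x = center$x[1L], y = center$y[1L])
  }
  if (length(levels) != 3L || any(diff(levels) <= 0) || any(levels <= 0))
    abort("levels must be three increasing positive fractions",
          class = "ftrcop_parameter_error")
  d <- calib_distances(calib, reference)
  out <- tibble::tibble(direction = .cardinals,
                        b33 = unname(levels[1L] * d[.cardinals]),
                        b67 = unname(levels[2L] * d[.cardinals]),
                        b100 = unname(levels[3L] * d[.cardinals]))
  attr(out, "center") <- center
  attr(out, "levels") <- levels
  class(out) <- c("rfa_set", class(out))
  out
}

# Named per-direction distances at one level of an rfa_set.
rfa_level <- function(rfas, col) setNames(rfas[[col]], rfas$direction)

#' Classify CoP samples into RFA regions
#'
#' Assigns each point to region 1 (inner rectangle), 2 (33-67% band), 3
#' (67-100% band) or `outside`. Boundaries are closed toward the smaller
#' region (a point exactly on the 33% boundary is region 1), which is
#' measure-zero on continuous data but deterministic on grid data. Per-side
#' asymmetric extents are respected: the `forward` distance applies on the +y
#' side of the centre, `right` on the +x side, and so on.
#'
#' @param points A data frame with columns `x`, `y` (mm), e.g. a
#'   [cop_trajectory].
#' @param rfas An [build_rfas()] RFA set.
#' @return A factor of length `nrow(points)` with levels
#'   `"1", "2", "3", "outside"`.
#' @export
classify_samples <- function(points, rfas) {
  ctr <- attr(rfas, "center")
  dx <- points$x - ctr[["x"]]
  dy <- points$y - ctr[["y"]]
  inside <- function(col) {
    b <- rfa_level(rfas, col)
    dx <= b[["right"]] & -dx <= b[["left"]] & dy <= b[["forward"]] & -dy <= b[["backward"]]
  }
  in1 <- inside("b33"); in2 <- inside("b67"); in3 <- inside("b100")
  region <- rep("outside", length(dx))
  region[in3] <- "3"
  region[in2] <- "2"
  region[in1] <- "1"
  factor(region, levels = c("1", "2", "3", "outside"))
}

#' Compute functional time ratios (FTRs) for a trial
#'
#' The functional time ratio of region i is the percentage of analysed trial
#' time the CoP spends in that region: time present in region i divided by
#' total time, times 100. With uniform sampling this is the sample fraction;
#' no boundary-crossing interpolation is performed. The `ftr12` index is
#' `ftr1 / ftr2`; when no time is spent in region 2 it is `Inf` and flagged.
#'
#' @param traj A preprocessed [cop_trajectory].
#' @param rfas An [build_rfas()] RFA set (its centre is used as given).
#' @return A one-row tibble of class `ftr_result` with columns `ftr1`,
#'   `ftr2`, `ftr3`, `ftr_out` (percent, summing to 100), `ftr12`,
#'   `ftr12_degenerate` (logical) and `n_samples`.
#' @examples
#' calib <- compute_calibration(list(forward = 40, backward = 40, left = 40, right = 40))
#' tr <- cop_trajectory(seq(0, 0.11, by = 0.01), rnorm(12, sd = 8), rnorm(12, sd = 8))
#' compute_ftrs(tr, build_rfas(calib, tr))
#' @export
compute_ftrs <- function(traj, rfas) {
  if (is.null(traj) || nrow(traj) == 0L)
    abort("empty trajectory", class = "ftrcop_data_error")
  region <- classify_samples(traj, rfas)
  n <- length(region)
  pct <- 100 * as.numeric(table(region)) / n
  ftr1 <- pct[1L]; ftr2 <- pct[2L]; ftr3 <- pct[3L]; ftr_out <- pct[4L]
  degenerate <- ftr2 == 0
  out <- tibble::tibble(ftr1 = ftr1, ftr2 = ftr2, ftr3 = ftr3, ftr_out = ftr_out,
                        ftr12 = if (degenerate) Inf else ftr1 / ftr2,
                        ftr12_degenerate = degenerate,
                        n_samples = n)
  class(out) <- c("ftr_result", class(out))
  out
}

#' Aggregate FTR results over repeated trials
#'
#' Averages the region percentages component-wise over the (typically three)
#' repetitions of a condition. The aggregate `ftr12` is the ratio of the
#' mean `ftr1` to the mean `ftr2` by default; `ratio = "mean_of_ratios"`
#' averages the per-trial ratios instead.
#'
#' @param results A list of [compute_ftrs()] results, or a tibble of stacked
#'   rows.
#' @param ratio `"ratio_of_means"` (default) or `"mean_of_ratios"`.
#' @return A one-row `ftr_result` tibble; `n_samples` is the total.
#' @export
aggregate_trials <- function(results, ratio = c("ratio_of_means", "mean_of_ratios")) {
  ratio <- match.arg(ratio)
  df <- if (is.data.frame(results)) results else dplyr::bind_rows(results)
  if (nrow(df) == 0L)
    abort("no FTR results to aggregate", class = "ftrcop_data_error")
  m <- dplyr::summarise(df, dplyr::across(c("ftr1", "ftr2", "ftr3", "ftr_out"), mean))
  degenerate <- m$ftr2 == 0
  ftr12 <- if (ratio == "ratio_of_means") {
    if (degenerate) Inf else m$ftr1 / m$ftr2
  } else {
    if (any(df$ftr12_degenerate)) { degenerate <- TRUE; Inf } else mean(df$ftr12)
  }
  out <- tibble::tibble(m, ftr12 = ftr12, ftr12_degenerate = degenerate,
                        n_samples = sum(df$n_samples))
  class(out) <- c("ftr_result", class(out))
  out
}
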