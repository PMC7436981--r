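#' Plot a CoP trajectory over its rectangular functional areas
#'
#' Shows the stabilogram path with the three nested RFA rectangles (inner
#' region, 33-67% band, 67-100% band) centred on the CoP median — the
#' standard picture for reading where a trial's time went.
#'
#' @param traj A preprocessed [cop_trajectory].
#' @param rfas An [build_rfas()] RFA set.
#' @return A ggplot object.
#' @export
plot_rfa <- function(traj, rfas) {
  ctr <- attr(rfas, "center")
  rects <- purrr::map_dfr(c("b33", "b67", "b100"), function(col) {
    b <- rfa_level(rfas, col)
    tibble::tibble(level = col,
                   xmin = ctr[["x"]] - b[["left"]], xmax = ctr[["x"]] + b[["right"]],
                   ymin = ctr[["y"]] - b[["backward"]], ymax = ctr[["y"]] + b[["forward"]])
  })
  ggplot2::ggplot() +
    ggplot2::geom_rect(data = rects,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    colour = .data$level),
                       fill = NA, linewidth = 0.4) +
    ggplot2::geom_path(data = tibble::as_tibble(traj),
                       ggplot2::aes(x = .data$x, y = .data$y),
                       alpha = 0.5, linewidth = 0.2) +
    ggplot2::annotate("point", x = ctr[["x"]], y = ctr[["y"]], shape = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "mediolateral x (mm)", y = "anteroposterior y (mm)",
                  colour = "RFA level") +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#'
#' Draws the curve in (1 - specificity, sensitivity) space with the
#' Youden-optimal point marked in red.
#'
#' @param object A `cop_roc` object from [roc_analysis()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot cop_roc
#' @export
autoplot.cop_roc <- function(object, ...) {
  curve <- dplyr::arrange(object$curve, 1 - .data$specificity, .data$sensitivity)
  yp <- youden_cutoff(object)
  ggplot2::ggplot(curve, ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::annotate("point", x = 1 - yp$specificity, y = yp$sensitivity,
                      colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("AUC = %.3f", object$auc),
                  x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_minimal()
}

#' Plot FTR composition per condition
#'
#' Stacked-bar view of where trial time went (region 1, 2, 3, outside) for
#' each height level, per subject or aggregated.
#'
#' @param ftr_table A tibble with `height_level` and the FTR columns, e.g.
#'   `analyze_session()$conditions`.
#' @return A ggplot object.
#' @export
plot_ftr_composition <- function(ftr_table) {
  long <- ftr_table |>
    dplyr::select(dplyr::any_of(c("subject_id", "height_level")),
                  "ftr1", "ftr2", "ftr3", "ftr_out") |>
    tidyr::pivot_longer(c("ftr1", "ftr2", "ftr3", "ftr_out"),
                        names_to = "region", values_to = "percent")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$height_level, y = .data$percent,
                                     fill = .data$region)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "% of analysed trial time", fill = "RFA region") +
    ggplot2::theme_minimal()
}
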