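#' Plot a calibration model's threshold surface
#'
#' Predicted optimal threshold against TBR, one curve per post-filter FWHM
#' (and, for models with an area term, faceted by cross-section area).
#'
#' @param object A `ts_calibration`.
#' @param tbr_range TBR range to draw.
#' @param fwhm Post-filter FWHM values (ignored for models without the
#'   term).
#' @param area Cross-section areas (mm^2) for models with an area term.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ts_calibration <- function(object, tbr_range = c(2.5, 70),
                                    fwhm = c(4, 6, 8, 11),
                                    area = c(380, 1075, 2588), ...) {
  has_fwhm <- "x3_fwhm" %in% names(object$coefficients)
  has_area <- "x1_area" %in% names(object$coefficients)
  grid <- tidyr::expand_grid(
    tbr = seq(tbr_range[1], tbr_range[2], length.out = 200),
    fwhm = if (has_fwhm) fwhm else NA_real_,
    area = if (has_area) area else NA_real_
  )
  grid$ts <- predict_ts(object, tbr = grid$tbr,
                        fwhm = if (has_fwhm) grid$fwhm,
                        area = if (has_area) grid$area)$ts
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$tbr, y = .data$ts))
  p <- if (has_fwhm) {
    p + ggplot2::geom_line(ggplot2::aes(colour = factor(.data$fwhm))) +
      ggplot2::labs(colour = "FWHM (mm)")
  } else {
    p + ggplot2::geom_line()
  }
  if (has_area) p <- p + ggplot2::facet_wrap(~area, labeller = ggplot2::label_both)
  p + ggplot2::labs(x = "Target-to-background ratio",
                    y = "Optimal threshold (% of max)",
                    title = object$scanner_model) +
    ggplot2::theme_minimal()
}

#' Box-and-whisker plot of holdout residuals
#'
#' @param object A `residual_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.residual_summary <- function(object, ...) {
  res <- attr(object, "residuals")
  ggplot2::ggplot(tibble(residual = res), ggplot2::aes(x = "", y = .data$residual)) +
    ggplot2::geom_boxplot(width = 0.3) +
    ggplot2::labs(x = NULL, y = "TS observed - TS predicted (percentage points)") +
    ggplot2::theme_minimal()
}

#' Overlay of a segmentation mask on its hottest slice
#'
#' @param object A `btv_segmentation`.
#' @param img The [image_volume()] the segmentation was computed on.
#' @param slice Slice index; default the slice with the largest contoured
#'   area.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.btv_segmentation <- function(object, img, slice = NULL, ...) {
  if (is.null(slice)) {
    slice <- object$per_slice$slice[which.max(object$per_slice$area_mm2)]
  }
  sl <- img$data[, , slice]
  msk <- object$mask[, , slice]
  d <- tidyr::expand_grid(i = seq_len(nrow(sl)), j = seq_len(ncol(sl)))
  d$intensity <- sl[cbind(d$i, d$j)]
  d$inside <- msk[cbind(d$i, d$j)]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$i, y = .data$j)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::geom_point(data = d[d$inside, ], colour = "cyan", size = 0.3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("TS %.1f%% segmentation, slice %d",
                                  object$ts_applied, slice),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
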