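# 3D box window in mm: list/vector c(xmin, xmax, ymin, ymax, zmin, zmax)
window_indices <- function(vol, window) {
  w <- as.numeric(window)
  if (length(w) != 6L) abort("`window` must be c(xmin, xmax, ymin, ymax, zmin, zmax) in mm.")
  ax <- lapply(1:3, function(a) {
    co <- axis_coords(vol, a)
    idx <- which(co >= w[2 * a - 1] & co <= w[2 * a])
    if (!length(idx)) abort("lesion window is empty along an axis.")
    idx
  })
  ax
}

new_btv_segmentation <- function(ts_applied, measured_tbr, mask, vol,
                                 model_id, bg, iterations = 1L,
                                 converged = TRUE) {
  px_area <- prod(vol$voxel[1:2])
  per_slice <- tibble(
    slice = seq_len(dim(mask)[3]),
    z_mm = axis_coords(vol, 3),
    area_mm2 = apply(mask, 3, sum) * px_area
  )
  per_slice <- per_slice[per_slice$area_mm2 > 0, ]
  structure(list(
    ts_applied = ts_applied,
    measured_tbr = measured_tbr,
    mask = mask,
    per_slice = per_slice,
    max_area_mm2 = if (nrow(per_slice)) max(per_slice$area_mm2) else 0,
    volume_ml = sum(mask) * prod(vol$voxel) / 1000,
    model_id = model_id,
    bg = bg,
    voxel = vol$voxel,
    iterations = iterations,
    converged = converged
  ), class = "btv_segmentation")
}

#' @export
print.btv_segmentation <- function(x, ...) {
  cat("<btv_segmentation> model: ", x$model_id, "\n", sep = "")
  cat(sprintf("  measured TBR %.2f, applied TS %.1f%%\n",
              x$measured_tbr, x$ts_applied))
  cat(sprintf("  BTV %.2f mL over %d slices; max cross section %.1f mm^2\n",
              x$volume_ml, nrow(x$per_slice), x$max_area_mm2))
  if (x$iterations > 1L || !x$converged) {
    cat(sprintf("  area iteration: %d step(s), converged: %s\n",
                x$iterations, x$converged))
  }
  invisible(x)
}

# shared contouring core: threshold at ts% of window max, keep the
# 26-connected component containing the max, embedded in the full grid
contour_btv <- function(vol, ax, ts_percent) {
  sub <- vol$data[ax[[1]], ax[[2]], ax[[3]], drop = FALSE]
  mx <- max(sub)
  m <- sub >= ts_percent / 100 * mx
  comp <- flood_fill3d(m, which.max(sub))
  mask <- array(FALSE, dim(vol$data))
  mask[ax[[1]], ax[[2]], ax[[3]]] <- comp
  mask
}

segment_measurements <- function(vol, ax, bg_rois, roi_diameter) {
  sub <- vol$data[ax[[1]], ax[[2]], ax[[3]], drop = FALSE]
  peak <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  peak_slice <- ax[[3]][peak[3]]
  bg <- background_mean(vol, peak_slice, roi_centers = bg_rois,
                        roi_diameter = roi_diameter)
  tbr <- max(sub) / bg$bg_mean
  list(bg = bg, tbr = tbr, peak_slice = peak_slice)
}

#' Delineate a biological target volume with a calibrated threshold model
#'
#' Measures the background and the target-to-background ratio on the image,
#' predicts the optimal threshold from the calibration model, thresholds
#' the lesion window at that percentage of the window maximum, and keeps
#' the 26-connected component containing the maximum. Reports per-slice
#' cross-section areas and the total volume.
#'
#' Models containing an area term cannot be applied in one pass (the area
#' is unknown before segmenting); use [area_model_iteration()] for those.
#'
#' @param img An [image_volume()].
#' @param window Lesion bounding box in mm:
#'   `c(xmin, xmax, ymin, ymax, zmin, zmax)`.
#' @param model A `ts_calibration` without an `x1_area` term.
#' @param fwhm_used Transaxial post-filter FWHM (mm) actually applied in the
#'   reconstruction — a known input, never estimated from the image.
#' @param bg_rois Background ROI centres (n x 2 matrix, mm); default
#'   [default_background_rois()].
#' @param roi_diameter Background ROI diameter, mm.
#' @param tbr Optional: use this TBR instead of the image-measured one
#'   (e.g. a nominal ratio).
#' @return A `btv_segmentation`.
#' @export
delineate_btv <- function(img, window, model, fwhm_used,
                          bg_rois = default_background_rois(),
                          roi_diameter = 17, tbr = NULL) {
  stopifnot(inherits(img, "image_volume"), inherits(model, "ts_calibration"))
  if ("x1_area" %in% names(model$coefficients)) {
    abort("model has an area term; use area_model_iteration().")
  }
  ax <- window_indices(img, window)
  meas <- segment_measurements(img, ax, bg_rois, roi_diameter)
  tbr_use <- tbr %||% meas$tbr
  if (tbr_use < 1.2) abort("insufficient contrast: measured TBR below 1.2.")
  if (tbr_use > 70) warn("TBR above the calibrated range (2.5-70).")
  ts <- predict_ts(model, tbr = tbr_use, fwhm = fwhm_used)$ts
  mask <- contour_btv(img, ax, ts)
  new_btv_segmentation(ts, tbr_use, mask, img, model$scanner_model, meas$bg)
}

#' Apply an area-dependent calibration model by fixed-point iteration
#'
#' Calibration models with an area coefficient need the lesion cross-section
#' area, which is unknown before segmenting. Starting from the area obtained
#' at a 50% threshold, this alternates threshold prediction and contouring
#' until the maximal cross-section area changes by less than `tol` mm^2, or
#' `max_iter` iterations are reached (in which case the best iterate is
#' returned flagged as non-converged).
#'
#' @inheritParams delineate_btv
#' @param model A `ts_calibration`; an area-free model converges in a
#'   single iteration and gives the same result as [delineate_btv()].
#' @param max_iter Maximum number of iterations.
#' @param tol Convergence tolerance on the maximal cross-section area, mm^2.
#' @return A `btv_segmentation` with `iterations` and `converged` filled in.
#' @export
area_model_iteration <- function(img, window, model, fwhm_used,
                                 bg_rois = default_background_rois(),
                                 roi_diameter = 17, tbr = NULL,
                                 max_iter = 20, tol = 1) {
  stopifnot(inherits(img, "image_volume"), inherits(model, "ts_calibration"))
  ax <- window_indices(img, window)
  meas <- segment_measurements(img, ax, bg_rois, roi_diameter)
  tbr_use <- tbr %||% meas$tbr
  if (tbr_use < 1.2) abort("insufficient contrast: measured TBR below 1.2.")
  if (tbr_use > 70) warn("TBR above the calibrated range (2.5-70).")
  has_area <- "x1_area" %in% names(model$coefficients)
  px_area <- prod(img$voxel[1:2])
  max_area <- function(mask) max(apply(mask, 3, sum)) * px_area

  area <- max_area(contour_btv(img, ax, 50))  # 50%-threshold initializer
  iterations <- 0L
  converged <- !has_area
  repeat {
    iterations <- iterations + 1L
    ts <- predict_ts(model, tbr = tbr_use, fwhm = fwhm_used,
                     area = if (has_area) area)$ts
    mask <- contour_btv(img, ax, ts)
    new_area <- max_area(mask)
    if (!has_area || abs(new_area - area) < tol) {
      converged <- TRUE
      area <- new_area
      break
    }
    area <- new_area
    if (iterations >= max_iter) {
      converged <- FALSE
      break
    }
  }
  if (has_area && area < 133) {
    warn("contoured cross section below the calibrated range (> 133 mm^2).")
  }
  new_btv_segmentation(ts, tbr_use, mask, img, model$scanner_model, meas$bg,
                       iterations = iterations, converged = converged)
}

#' Write a segmentation mask as a 0/1 NIfTI volume
#'
#' @param seg A `btv_segmentation`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(seg, path) {
  stopifnot(inherits(seg, "btv_segmentation"))
  vol <- image_volume(array(as.numeric(seg$mask), dim(seg$mask)),
                      voxel = seg$voxel)
  write_volume(vol, path)
}
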