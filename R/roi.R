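#' Default background ROI positions
#'
#' Six regions of interest placed in the warm background inside the sphere
#' ring (radius 30 mm from the phantom axis, midway between the ring-sphere
#' angles), clear of every sphere in the default layout.
#'
#' @param radius Placement radius in mm.
#' @param n Number of ROIs.
#' @param angle_offset Angular offset in degrees from the ring-sphere angles.
#' @return An `n x 2` matrix of (x, y) centres in mm.
#' @export
default_background_rois <- function(radius = 30, n = 6, angle_offset = 30) {
  ang <- (angle_offset + (seq_len(n) - 1) * 360 / n) * pi / 180
  cbind(x = radius * cos(ang), y = radius * sin(ang))
}

# extract a transaxial slice as a matrix carrying its geometry
extract_slice <- function(vol, slice_index) {
  stopifnot(inherits(vol, "image_volume"))
  k <- as.integer(slice_index)
  if (k < 1L || k > dim(vol$data)[3]) abort("`slice_index` out of range.")
  structure(vol$data[, , k],
            pixel = vol$voxel[1:2], origin2d = vol$origin[1:2],
            z = axis_coords(vol, 3)[k])
}

slice_coords <- function(slice) {
  px <- attr(slice, "pixel"); o <- attr(slice, "origin2d")
  list(x = o[1] + (seq_len(nrow(slice)) - 1) * px[1],
       y = o[2] + (seq_len(ncol(slice)) - 1) * px[2],
       pixel = px)
}

#' Background statistics from circular ROIs
#'
#' Computes the background value (BG) as the mean intensity over the union
#' of circular ROIs (default six, 17 mm diameter) placed in the background
#' of a transaxial slice, together with its standard deviation.
#'
#' @param img An [image_volume()].
#' @param slice_index Transaxial slice on which the ROIs are placed.
#' @param roi_centers Matrix (n x 2) of ROI centres in mm; default
#'   [default_background_rois()].
#' @param roi_diameter ROI diameter in mm (default 17).
#' @param truth Optional [phantom_spec()]; when supplied, an ROI
#'   geometrically intersecting any sphere is an error.
#' @return A one-row tibble: `bg_mean`, `bg_sd`, `roi_count`, `n_pixels`.
#' @export
background_mean <- function(img, slice_index, roi_centers = default_background_rois(),
                            roi_diameter = 17, truth = NULL) {
  sl <- extract_slice(img, slice_index)
  co <- slice_coords(sl)
  r_roi <- roi_diameter / 2
  roi_centers <- as.matrix(roi_centers)
  xr <- range(co$x); yr <- range(co$y)
  sel <- matrix(FALSE, nrow(sl), ncol(sl))
  for (i in seq_len(nrow(roi_centers))) {
    cx <- roi_centers[i, 1]; cy <- roi_centers[i, 2]
    if (cx - r_roi < xr[1] - co$pixel[1] / 2 || cx + r_roi > xr[2] + co$pixel[1] / 2 ||
        cy - r_roi < yr[1] - co$pixel[2] / 2 || cy + r_roi > yr[2] + co$pixel[2] / 2) {
      abort(sprintf("background ROI %d extends outside the image.", i))
    }
    if (!is.null(truth)) {
      sp <- truth$spheres
      dz <- abs(attr(sl, "z") - sp$cz)
      r_sp <- sp$internal_diameter / 2
      inplane <- ifelse(dz < r_sp, sqrt(pmax(r_sp^2 - dz^2, 0)), 0)
      d <- sqrt((sp$cx - cx)^2 + (sp$cy - cy)^2)
      hit <- which(inplane > 0 & d < r_roi + inplane)
      if (length(hit)) {
        abort(sprintf("background ROI %d intersects sphere '%s'.",
                      i, sp$sphere_id[hit[1]]))
      }
    }
    d2 <- outer((co$x - cx)^2, (co$y - cy)^2, `+`)
    sel <- sel | (d2 <= r_roi^2)
  }
  px <- sl[sel]
  tibble(bg_mean = mean(px), bg_sd = stats::sd(px),
         roi_count = nrow(roi_centers), n_pixels = length(px))
}

# max pixel in the circular ROI encircling a sphere's central cross section
encircling_max <- function(img, sphere, margin_vox = 2) {
  k <- nearest_slice(img, sphere$cz)
  sl <- extract_slice(img, k)
  co <- slice_coords(sl)
  r <- sphere$internal_diameter / 2 + margin_vox * max(co$pixel)
  d2 <- outer((co$x - sphere$cx)^2, (co$y - sphere$cy)^2, `+`)
  max(sl[d2 <= r^2])
}

#' Measured target-to-background ratio
#'
#' The maximum pixel intensity in an ROI encircling the sphere's central
#' cross section (circle of radius ID/2 plus a two-voxel margin), divided by
#' the background mean. Partial-volume blurring makes the measured TBR fall
#' below the nominal ratio for small spheres.
#'
#' @param img An [image_volume()].
#' @param sphere One row of a sphere tibble (see [sphere_spec()]).
#' @param bg Background statistics from [background_mean()].
#' @param margin_vox Margin of the encircling ROI, in voxels.
#' @return The measured TBR (scalar).
#' @export
measured_tbr <- function(img, sphere, bg, margin_vox = 2) {
  if (bg$bg_mean <= 0) abort("background mean must be positive.")
  encircling_max(img, sphere, margin_vox) / bg$bg_mean
}

#' Objective detectability rule
#'
#' A sphere counts as detectable when the maximum intensity in its
#' encircling ROI exceeds `bg_mean + k * bg_sd`. This is a numeric proxy for
#' the visual detectability assessment used in phantom reading sessions; the
#' multiplier `k` is a configuration knob (default 3).
#'
#' @inheritParams measured_tbr
#' @param k Detectability multiplier.
#' @return Logical flag.
#' @export
detectable <- function(img, sphere, bg, k = 3, margin_vox = 2) {
  encircling_max(img, sphere, margin_vox) > bg$bg_mean + k * bg$bg_sd
}

#' Autocontour a cross section at a percentage threshold
#'
#' Thresholds a transaxial slice at `ts_percent` of the maximum intensity
#' found in a square window centred on the target, and keeps the
#' 8-connected component containing that maximum. The contoured area is the
#' pixel count times the pixel area.
#'
#' @param slice A slice from an [image_volume()] (internally extracted), or
#'   an [image_volume()] together with `slice_index`.
#' @param ts_percent Threshold, percent of the window maximum (1--100).
#' @param center Length-2 (x, y) target centre in mm.
#' @param window_mm Side length of the search window in mm.
#' @param slice_index Slice to use when `slice` is a volume.
#' @return A list: `mask` (logical matrix over the full slice), `area_mm2`,
#'   `max_intensity`, `threshold` (absolute intensity), `n_pixels`.
#' @export
autocontour_area <- function(slice, ts_percent, center, window_mm,
                             slice_index = NULL) {
  if (inherits(slice, "image_volume")) {
    if (is.null(slice_index)) abort("`slice_index` required with a volume.")
    slice <- extract_slice(slice, slice_index)
  }
  if (ts_percent < 1 || ts_percent > 100) {
    abort("`ts_percent` must lie in [1, 100].")
  }
  co <- slice_coords(slice)
  ix <- which(abs(co$x - center[1]) <= window_mm / 2)
  iy <- which(abs(co$y - center[2]) <= window_mm / 2)
  if (!length(ix) || !length(iy)) abort("autocontour window is empty.")
  win <- slice[ix, iy, drop = FALSE]
  mx <- max(win)
  thr <- ts_percent / 100 * mx
  mask_w <- flood_fill2d(win >= thr, which.max(win))
  mask <- matrix(FALSE, nrow(slice), ncol(slice))
  mask[ix, iy] <- mask_w
  px_area <- prod(co$pixel)
  list(mask = mask, area_mm2 = sum(mask_w) * px_area,
       max_intensity = mx, threshold = thr, n_pixels = sum(mask_w))
}

#' Optimal threshold search for one sphere
#'
#' Scans thresholds from `step` to 100% of the window maximum in steps of
#' `step` percent, autocontours the sphere's central cross section at each
#' threshold, and returns the threshold whose contoured area best matches
#' the known physical cross-section area (ties broken toward the larger
#' threshold). The search converges when the best area mismatch is below
#' `tolerance` (default 10 mm^2).
#'
#' @param img An [image_volume()] (the sphere's central slice is used), or a
#'   slice extracted from one.
#' @param sphere One row of a sphere tibble (needs `cx`, `cy`, `cz`,
#'   `internal_diameter`, `true_area`).
#' @param tolerance Convergence tolerance on the area mismatch, mm^2.
#' @param step Threshold step, percent.
#' @param margin_mm Window margin scale: the search window side is
#'   `internal_diameter + 4 * margin_mm` (default margin 3 mm, of the order
#'   of the PSF sigma).
#' @return A one-row tibble: `ts_percent`, `measured_area`, `area_error`
#'   (measured minus true, mm^2), `converged`, `max_intensity`.
#' @export
find_optimal_ts <- function(img, sphere, tolerance = 10, step = 1,
                            margin_mm = 3) {
  slice <- if (inherits(img, "image_volume")) {
    extract_slice(img, nearest_slice(img, sphere$cz))
  } else img
  co <- slice_coords(slice)
  side <- sphere$internal_diameter + 4 * margin_mm
  ix <- which(abs(co$x - sphere$cx) <= side / 2)
  iy <- which(abs(co$y - sphere$cy) <= side / 2)
  if (!length(ix) || !length(iy)) abort("threshold-search window is empty.")
  win <- slice[ix, iy, drop = FALSE]
  mx <- max(win)
  start <- which.max(win)
  px_area <- prod(co$pixel)
  ts_grid <- seq(step, 100, by = step)
  areas <- vapply(ts_grid, function(ts) {
    m <- win >= ts / 100 * mx
    if (!m[start]) return(0)
    sum(flood_fill2d(m, start)) * px_area
  }, numeric(1))
  if (all(areas == 0)) abort("no threshold yields a nonempty contour.")
  err <- abs(areas - sphere$true_area)
  best <- max(which(err == min(err)))  # ties toward the larger threshold
  tibble(ts_percent = ts_grid[best],
         measured_area = areas[best],
         area_error = areas[best] - sphere$true_area,
         converged = err[best] < tolerance,
         max_intensity = mx)
}

#' Build the measurement table from a simulated experiment grid
#'
#' Runs the image analysis for every acquisition in the grid: background
#' statistics on the central plane, the detectability rule per sphere,
#' measured TBR, and the optimal-threshold search. Undetectable spheres are
#' skipped and counted (this is what separates the theoretical and the
#' realised number of data points).
#'
#' @param grid Output of [generate_experiment_grid()].
#' @param roi_centers,roi_diameter Background ROI layout
#'   (see [background_mean()]).
#' @param tolerance,step,margin_mm Threshold-search settings
#'   (see [find_optimal_ts()]).
#' @param detect_k Detectability multiplier (see [detectable()]).
#' @return A tibble with one row per detectable sphere per acquisition:
#'   `scanner_id`, `sphere_id`, `x1_area` (true cross-section area, mm^2),
#'   `tbr_nominal`, `tbr_measured`, `x2` (`1 - 1/tbr_measured`), `x3_fwhm`,
#'   `esd`, `em_iterations`, `bg_mean`, `bg_sd`, `ts`, `measured_area`,
#'   `converged`, `seed`, plus any scalar reconstruction extras. The number
#'   of skipped (undetectable) sphere-acquisitions is attached as attribute
#'   `"skipped"`.
#' @export
build_records <- function(grid, roi_centers = default_background_rois(),
                          roi_diameter = 17, tolerance = 10, step = 1,
                          margin_mm = 3, detect_k = 3) {
  skipped <- 0L
  rows <- purrr::map(grid, function(entry) {
    img <- entry$volume
    meta <- entry$meta
    spheres <- meta$spheres
    k0 <- nearest_slice(img, stats::median(spheres$cz))
    bg <- background_mean(img, k0, roi_centers = roi_centers,
                          roi_diameter = roi_diameter)
    purrr::map_dfr(seq_len(nrow(spheres)), function(s) {
      sp <- spheres[s, ]
      if (!detectable(img, sp, bg, k = detect_k)) {
        skipped <<- skipped + 1L
        return(NULL)
      }
      tbr_m <- measured_tbr(img, sp, bg)
      opt <- find_optimal_ts(img, sp, tolerance = tolerance, step = step,
                             margin_mm = margin_mm)
      extras <- meta$extras[vapply(meta$extras, function(e)
        is.atomic(e) && length(e) == 1L, logical(1))]
      row <- tibble(scanner_id = meta$scanner_id,
               sphere_id = sp$sphere_id,
               x1_area = sp$true_area,
               tbr_nominal = meta$tbr_nominal,
               tbr_measured = tbr_m,
               x2 = 1 - 1 / tbr_m,
               x3_fwhm = meta$transaxial_fwhm,
               esd = meta$esd,
               em_iterations = meta$em_iterations,
               bg_mean = bg$bg_mean, bg_sd = bg$bg_sd,
               ts = opt$ts_percent,
               measured_area = opt$measured_area,
               converged = opt$converged,
               seed = meta$seed)
      if (length(extras)) row <- dplyr::bind_cols(row, as_tibble(extras))
      row
    })
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  out
}

#' Read and write measurement tables
#'
#' Measurement records are stored as tab-separated text.
#'
#' @param records Tibble of measurement records (see [build_records()]).
#' @param path File path.
#' @return `write_records()` returns `path` invisibly; `read_records()` the
#'   tibble.
#' @export
write_records <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
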