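#' Sphere specification
#'
#' Describes one fillable sphere of the digital phantom: its centre (mm),
#' internal diameter (mm), and the derived ground-truth maximal cross-section
#' area (mm^2) and volume (mL).
#'
#' @param sphere_id Character label.
#' @param center Length-3 numeric, sphere centre in mm.
#' @param internal_diameter Internal diameter in mm (> 0).
#' @return A one-row tibble with columns `sphere_id`, `cx`, `cy`, `cz`,
#'   `internal_diameter`, `true_area` (mm^2) and `true_volume` (mL).
#' @examples
#' sphere_spec("s22", c(0, 57.2, 0), 22)
#' @export
sphere_spec <- function(sphere_id, center, internal_diameter) {
  if (internal_diameter <= 0) abort("`internal_diameter` must be > 0.")
  r <- internal_diameter / 2
  tibble(
    sphere_id = as.character(sphere_id),
    cx = center[1], cy = center[2], cz = center[3],
    internal_diameter = internal_diameter,
    true_area = pi * r^2,
    true_volume = 4 / 3 * pi * r^3 * 1e-3
  )
}

# standard internal diameters (mm) of the IEC body phantom sphere set:
# 6 coplanar spheres plus two micro spheres and one large sphere at the bottom
iec_sphere_ids <- function() c(6.5, 8.1, 10, 13, 17, 22, 28, 37, 57.4)

#' Default IEC-style sphere layout
#'
#' Six spheres (ID 10--37 mm) on a coplanar ring of radius 57.2 mm, with the
#' two micro spheres (6.5, 8.1 mm) and the 57.4 mm sphere placed below the
#' ring in the same transaxial plane. Exact offsets are configurable by
#' building the tibble yourself with [sphere_spec()].
#'
#' @param ring_radius Ring radius in mm for the six coplanar spheres.
#' @param bottom_y y coordinate (mm) of the bottom row of spheres.
#' @return Tibble of sphere specifications (one row per sphere).
#' @export
iec_spheres <- function(ring_radius = 57.2, bottom_y = -95) {
  ring_ids <- c(10, 13, 17, 22, 28, 37)
  ang <- (seq_along(ring_ids) - 1) * 60 * pi / 180
  ring <- purrr::map2_dfr(ring_ids, ang, function(id, a) {
    sphere_spec(paste0("s", id),
                c(ring_radius * cos(a), ring_radius * sin(a), 0), id)
  })
  bottom <- dplyr::bind_rows(
    sphere_spec("s6.5", c(-45, bottom_y, 0), 6.5),
    sphere_spec("s8.1", c(45, bottom_y, 0), 8.1),
    sphere_spec("s57.4", c(0, bottom_y, 0), 57.4)
  )
  dplyr::bind_rows(ring, bottom)
}

#' Phantom specification
#'
#' Geometry and activity of the digital IEC-style phantom: a set of
#' non-overlapping hot spheres in a uniform warm background.
#'
#' @param spheres Tibble of sphere specifications ([sphere_spec()] rows);
#'   default [iec_spheres()].
#' @param background_activity Background activity concentration, kBq/mL
#'   (default 3).
#' @param tbr_nominal Nominal target-to-background ratio (>= 1): sphere
#'   activity is `tbr_nominal * background_activity`.
#' @return An object of class `phantom_spec`.
#' @examples
#' ph <- iec_phantom(tbr_nominal = 8)
#' ph$spheres$internal_diameter
#' @export
phantom_spec <- function(spheres = iec_spheres(), background_activity = 3,
                         tbr_nominal = 8) {
  spheres <- as_tibble(spheres)
  if (nrow(spheres) == 0) abort("`spheres` must contain at least one sphere.")
  if (tbr_nominal < 1) abort("`tbr_nominal` must be >= 1.")
  if (background_activity <= 0) abort("`background_activity` must be > 0.")
  # pairwise non-overlap
  if (nrow(spheres) > 1) {
    ctr <- as.matrix(spheres[, c("cx", "cy", "cz")])
    rad <- spheres$internal_diameter / 2
    d <- as.matrix(stats::dist(ctr))
    lim <- outer(rad, rad, `+`)
    diag(d) <- Inf
    if (any(d < lim)) {
      bad <- which(d < lim, arr.ind = TRUE)[1, ]
      abort(sprintf("spheres '%s' and '%s' overlap.",
                    spheres$sphere_id[bad[1]], spheres$sphere_id[bad[2]]))
    }
  }
  structure(list(spheres = spheres,
                 background_activity = background_activity,
                 tbr_nominal = tbr_nominal),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @param ... Passed on to [phantom_spec()].
#' @export
iec_phantom <- function(tbr_nominal = 8, ...) {
  phantom_spec(tbr_nominal = tbr_nominal, ...)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> ", nrow(x$spheres), " spheres, background ",
      x$background_activity, " kBq/mL, nominal TBR ", x$tbr_nominal,
      "\n", sep = "")
  invisible(x)
}

#' Rasterise the noiseless ground-truth activity map
#'
#' Voxels whose centre lies inside a sphere take the hot activity
#' `tbr_nominal * background_activity`; all other voxels take the background
#' activity. No blurring or noise is applied; this is the digital truth that
#' [simulate_scan()] degrades.
#'
#' @param phantom A [phantom_spec()].
#' @param dim Length-3 integer grid size (transaxial x, y, axial z).
#' @param voxel Length-3 voxel spacing in mm.
#' @param origin Optional grid origin (mm); default centres the grid.
#' @return An [image_volume()] in kBq/mL.
#' @examples
#' truth <- build_activity_map(iec_phantom(8), dim = c(64, 64, 16))
#' range(truth$data)
#' @export
build_activity_map <- function(phantom, dim = c(128, 128, 47),
                               voxel = c(2.7, 2.7, 3.3), origin = NULL) {
  stopifnot(inherits(phantom, "phantom_spec"))
  vol <- image_volume(array(phantom$background_activity, dim),
                      voxel = voxel, origin = origin)
  xs <- axis_coords(vol, 1); ys <- axis_coords(vol, 2); zs <- axis_coords(vol, 3)
  lo <- c(min(xs), min(ys), min(zs)) - vol$voxel / 2
  hi <- c(max(xs), max(ys), max(zs)) + vol$voxel / 2
  hot <- phantom$tbr_nominal * phantom$background_activity
  for (s in seq_len(nrow(phantom$spheres))) {
    sp <- phantom$spheres[s, ]
    r <- sp$internal_diameter / 2
    ctr <- c(sp$cx, sp$cy, sp$cz)
    if (any(ctr - r < lo) || any(ctr + r > hi)) {
      abort(sprintf("sphere '%s' does not fit inside the voxel grid.",
                    sp$sphere_id))
    }
    ix <- which(abs(xs - ctr[1]) <= r)
    iy <- which(abs(ys - ctr[2]) <= r)
    iz <- which(abs(zs - ctr[3]) <= r)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (xs[ix] - ctr[1])^2
    dy2 <- (ys[iy] - ctr[2])^2
    dz2 <- (zs[iz] - ctr[3])^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    inside <- d2 <= r^2
    if (any(inside)) {
      sub <- vol$data[ix, iy, iz, drop = FALSE]
      sub[inside] <- hot
      vol$data[ix, iy, iz] <- sub
    }
  }
  vol
}
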