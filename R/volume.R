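#' 3D image volume with voxel spacing
#'
#' A light container for a 3D intensity grid on a regular voxel lattice.
#' Intensities are activity-concentration-like (kBq/mL-equivalent), voxel
#' spacing is in mm. The coordinate of voxel `(i, j, k)` is
#' `origin + (c(i, j, k) - 1) * voxel`, i.e. `origin` is the centre of the
#' first voxel. The first two array dimensions span the transaxial plane;
#' the third is axial.
#'
#' @param data Numeric 3D array of intensities (finite).
#' @param voxel Length-3 positive numeric, voxel edge lengths in mm.
#' @param origin Length-3 numeric, mm coordinate of the first voxel centre.
#'   Defaults to centring the grid on the coordinate origin.
#' @return An object of class `image_volume`.
#' @examples
#' vol <- image_volume(array(3, c(8, 8, 4)), voxel = c(2.7, 2.7, 3.3))
#' dim(vol$data)
#' @export
image_volume <- function(data, voxel = c(2.7, 2.7, 3.3), origin = NULL) {
  data <- unclass(data)
  if (length(dim(data)) != 3L) abort("`data` must be a 3D array.")
  if (any(dim(data) < 1L)) abort("all volume dimensions must be >= 1.")
  if (!all(is.finite(data))) abort("volume intensities must be finite.")
  voxel <- as.numeric(voxel)
  if (length(voxel) != 3L || any(voxel <= 0)) {
    abort("`voxel` must be three strictly positive lengths (mm).")
  }
  if (is.null(origin)) origin <- -(dim(data) - 1) / 2 * voxel
  origin <- as.numeric(origin)
  if (length(origin) != 3L) abort("`origin` must have length 3.")
  structure(list(data = data, voxel = voxel, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", paste(signif(x$voxel, 4), collapse = " x "),
      " mm spacing\n", sep = "")
  cat("  intensity range: ",
      paste(signif(range(x$data), 4), collapse = " .. "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

# voxel-centre coordinates along one axis (mm)
axis_coords <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$data)[axis]) - 1) * vol$voxel[axis]
}

# index of the transaxial slice whose plane is closest to z (mm)
nearest_slice <- function(vol, z) {
  which.min(abs(axis_coords(vol, 3) - z))
}

#' Read and write image volumes as NIfTI-1
#'
#' Volumes are stored with mm voxel spacing in the NIfTI header. Reading
#' recovers the spacing; the origin is taken from the stored offset when
#' present, otherwise the grid is centred.
#'
#' @param vol An [image_volume()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `write_volume()` returns `path` invisibly; `read_volume()` returns
#'   an [image_volume()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$voxel
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1:3]
  image_volume(as.array(img), voxel = vox)
}

#' Write or read the ground-truth sidecar for a simulated volume
#'
#' The sidecar is a structured-text (YAML) file recording the phantom
#' geometry (sphere centres, internal diameters), nominal TBR, background
#' activity, acquisition (ESD, PSF width, noise coefficient, seed) and
#' reconstruction parameters of a simulated acquisition.
#'
#' @param meta Named list of ground-truth metadata (as attached by
#'   [generate_experiment_grid()]).
#' @param path File path for the YAML sidecar.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` the list.
#' @export
write_truth <- function(meta, path) {
  ser <- meta
  if (!is.null(ser$spheres)) ser$spheres <- as.data.frame(ser$spheres)
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  meta <- yaml::read_yaml(path)
  if (!is.null(meta$spheres)) {
    meta$spheres <- as_tibble(lapply(meta$spheres, unlist))
  }
  meta
}
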