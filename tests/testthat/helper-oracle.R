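# Independent oracle for the optimal threshold on a Gaussian-blurred disk.
#
# The 2D convolution of a unit disk of radius R with an isotropic Gaussian
# of width sigma, evaluated at distance d from the centre, is
#   f(d) = int_0^R (r / sigma^2) exp(-(r^2 + d^2) / (2 sigma^2))
#                  I0(r d / sigma^2) dr,
# computed here by direct quadrature with the exponentially scaled Bessel
# function for stability. The threshold that recovers the true area is the
# blurred intensity at the true boundary relative to the blurred maximum
# (the profile is radially nonincreasing), which is independent of the
# package's grid-based search.

oracle_disk_value <- function(d, R, sigma) {
  integrand <- function(r) {
    (r / sigma^2) * exp(-(r - d)^2 / (2 * sigma^2)) *
      besselI(r * d / sigma^2, 0, expon.scaled = TRUE)
  }
  stats::integrate(integrand, 0, R, rel.tol = 1e-10)$value
}

oracle_ts_percent <- function(ID, fwhm, bg = 1, hot = 5) {
  R <- ID / 2
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  f_edge <- oracle_disk_value(R, R, sigma)
  f_ctr <- oracle_disk_value(0, R, sigma)
  100 * (bg + (hot - bg) * f_edge) / (bg + (hot - bg) * f_ctr)
}

# single-slice volume holding a rasterised disk (voxel-centre membership)
make_disk_volume <- function(ID, fwhm = 0, bg = 1, hot = 5, pixel = 1) {
  half <- ID / 2 + 2 * fwhm + 10
  n <- 2 * ceiling(half / pixel) + 1
  vol <- image_volume(array(bg, c(n, n, 1)), voxel = c(pixel, pixel, 1))
  x <- vol$origin[1] + (seq_len(n) - 1) * pixel
  d2 <- outer(x^2, x^2, `+`)
  sl <- vol$data[, , 1]
  sl[d2 <= (ID / 2)^2] <- hot
  vol$data[, , 1] <- sl
  if (fwhm > 0) vol <- apply_transaxial_filter(vol, fwhm)
  vol
}

disk_sphere_row <- function(ID) {
  sphere_spec(paste0("disk", ID), c(0, 0, 0), ID)
}
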