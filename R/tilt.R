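# Tilt geometry and the missing wedge.

#' Describe a single-axis tilt scheme
#'
#' The tilt range determines the double-wedge region of Fourier space a
#' tomogram actually samples: with a maximum tilt of `max_deg`, directions
#' within `90 - max_deg` degrees of the beam (z) axis are never measured.
#'
#' @param min_deg,max_deg tilt range in degrees (`min_deg < max_deg`).
#' @param step_deg tilt increment in degrees (> 0); retained for
#'   provenance, the wedge support depends only on the range.
#' @param tilt_axis which in-plane axis the stage tilts about, "x" or "y".
#' @return an object of class `tilt_scheme`.
#' @export
tilt_scheme <- function(min_deg = -51, max_deg = 51, step_deg = 3,
                        tilt_axis = c("y", "x")) {
  tilt_axis <- match.arg(tilt_axis)
  if (!is.finite(min_deg) || !is.finite(max_deg) || min_deg >= max_deg)
    stop("need min_deg < max_deg")
  if (!is.finite(step_deg) || step_deg <= 0) stop("step_deg must be > 0")
  structure(list(min_deg = min_deg, max_deg = max_deg, step_deg = step_deg,
                 tilt_axis = tilt_axis),
            class = "tilt_scheme")
}

#' Fourier support mask of a tilt scheme
#'
#' Returns the binary mask over the FFT grid of a volume of dimensions
#' `dims`: TRUE where the single-axis tilt series samples Fourier space,
#' FALSE inside the missing double wedge. A spatial frequency
#' `(kx, ky, kz)` is sampled when some tilt angle in the range places it in
#' a measured central section. `azimuth_deg` rotates the support about z,
#' which is the wedge carried by a particle that has itself been rotated
#' in-plane by that azimuth.
#'
#' @param dims integer vector of 3 grid dimensions.
#' @param tilt a [tilt_scheme()].
#' @param azimuth_deg in-plane rotation (degrees, counterclockwise) that
#'   has been applied to the volume carrying this wedge.
#' @return logical 3D array (TRUE = sampled).
#' @export
wedge_mask <- function(dims, tilt, azimuth_deg = 0) {
  stopifnot(inherits(tilt, "tilt_scheme"))
  fx <- fft_freqs(dims[1])
  fy <- fft_freqs(dims[2])
  fz <- fft_freqs(dims[3])
  # in-plane frequency component along the tilt-normal direction:
  # tilting about y leaves ky untouched; the wedge lives in the (kx, kz)
  # plane. Rotating the volume by `a` about z rotates its wedge likewise,
  # so evaluate the support on back-rotated in-plane frequencies.
  a <- azimuth_deg * pi / 180
  if (tilt$tilt_axis == "y") {
    u2d <- outer(fx * cos(a), fy * sin(a), "+")   # kx' = kx cos a + ky sin a
  } else {
    u2d <- outer(-fx * sin(a), fy * cos(a), "+")  # ky' = -kx sin a + ky cos a
  }
  u <- array(u2d, c(dims[1], dims[2], dims[3]))
  w <- aperm(array(rep(fz, each = dims[1] * dims[2]), dims), c(1, 2, 3))
  # a frequency is sampled iff the tilt angle th with tan(th) = -kz/k_inplane
  # lies in the collected range (Friedel symmetry folds the sign).
  th <- atan2(-w, u) * 180 / pi
  th[th > 90] <- th[th > 90] - 180
  th[th <= -90] <- th[th <= -90] + 180
  m <- th >= tilt$min_deg & th <= tilt$max_deg
  m[1, 1, 1] <- TRUE  # DC always measured
  m
}

#' Impose the missing wedge on a volume
#'
#' Zeroes all Fourier coefficients outside the double-wedge support implied
#' by the tilt range, i.e. simulates what a limited single-axis tilt series
#' can actually reconstruct. The operation is an orthogonal projection, so
#' applying it twice equals applying it once.
#'
#' @param vol a [density_volume()].
#' @param tilt a [tilt_scheme()]; recorded as the wedge of the output.
#' @return real-valued [density_volume()] carrying `tilt` as its wedge.
#' @export
apply_missing_wedge <- function(vol, tilt) {
  stopifnot(is_density_volume(vol), inherits(tilt, "tilt_scheme"))
  d <- dim(vol$grid)
  m <- wedge_mask(d, tilt, azimuth_deg = vol$meta$wedge_azimuth_deg %||% 0)
  g <- Re(fft(fft(vol$grid) * m, inverse = TRUE)) / prod(d)
  density_volume(g, vol$voxel_size_nm, vol$origin_nm, wedge = tilt,
                 meta = vol$meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
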