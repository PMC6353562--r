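# In-plane rotation and subvoxel translation of volumes.

# Precompute the bicubic (Catmull-Rom) gather map for rotating an
# nx x ny plane by `angle_deg` (counterclockwise) about the box centre.
# Out-of-bounds samples read as 0. Cubic interpolation keeps the
# rotation accurate to well under 2% RMS for maps at the working
# resolution, where bilinear interpolation loses >10%.
rot_xy_map <- function(nx, ny, angle_deg) {
  cx <- (nx + 1) / 2
  cy <- (ny + 1) / 2
  th <- angle_deg * pi / 180
  dx <- rep(seq_len(nx) - cx, times = ny)
  dy <- rep(seq_len(ny) - cy, each = nx)
  # inverse map: source coords for each destination pixel
  xs <- cos(th) * dx + sin(th) * dy + cx
  ys <- -sin(th) * dx + cos(th) * dy + cy
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  cr <- function(t) cbind(
    -0.5 * t + t^2 - 0.5 * t^3,
    1 - 2.5 * t^2 + 1.5 * t^3,
    0.5 * t + 2 * t^2 - 1.5 * t^3,
    -0.5 * t^2 + 0.5 * t^3)
  wx <- cr(fx)
  wy <- cr(fy)
  npix <- length(xs)
  idx <- matrix(1L, npix, 16L)
  w <- matrix(0, npix, 16L)
  k <- 0L
  for (jy in -1:2) for (jx in -1:2) {
    k <- k + 1L
    xi <- x0 + jx
    yi <- y0 + jy
    ok <- xi >= 1 & xi <= nx & yi >= 1 & yi <= ny
    idx[ok, k] <- xi[ok] + (yi[ok] - 1L) * nx
    w[, k] <- wx[, jx + 2] * wy[, jy + 2] * ok
  }
  list(idx = idx, w = w)
}

# Apply a precomputed rotation map to every z-slice of a 3D array.
apply_rot_map <- function(arr, map) {
  d <- dim(arr)
  a <- matrix(arr, d[1] * d[2], d[3])
  out <- map$w[, 1] * a[map$idx[, 1], , drop = FALSE]
  for (k in 2:16)
    out <- out + map$w[, k] * a[map$idx[, k], , drop = FALSE]
  array(out, d)
}

# Shift every line of `g` running along the first array dimension by a
# per-column amount `s` (in voxels, indexed by the second dimension),
# identically across the third dimension, via FFT phase ramps.
shear_x <- function(g, s) {
  d <- dim(g)
  M <- matrix(g, d[1], d[2] * d[3])
  ph <- exp(-2i * pi * outer(fft_freqs(d[1]), rep(s, d[3])))
  Re(stats::mvfft(stats::mvfft(M) * ph, inverse = TRUE)) / d[1]
}

# Exact in-plane rotation of a 3D array about the box centre by the
# classical three-shear (x, y, x) decomposition with Fourier-interpolated
# shears: band-limited content rotates without interpolation loss.
# Angles beyond +/-45 degrees are composed from exact quarter-turns.
rotate_grid_z <- function(g, angle_deg) {
  a <- ((angle_deg + 180) %% 360) - 180  # to (-180, 180]
  # peel off exact 90-degree turns: counterclockwise quarter turn maps
  # (x, y) -> (-y, x), i.e. transpose then reverse the new x axis
  quarter <- function(g) {
    d <- dim(g)
    aperm(g, c(2, 1, 3))[d[2]:1, , , drop = FALSE]
  }
  while (a > 45) {
    g <- quarter(g)
    a <- a - 90
  }
  while (a < -45) {
    g <- quarter(quarter(quarter(g)))
    a <- a + 90
  }
  if (abs(a) < 1e-12) return(g)
  th <- a * pi / 180
  d <- dim(g)
  cx <- (d[1] + 1) / 2
  cy <- (d[2] + 1) / 2
  alpha <- -tan(th / 2)
  beta <- sin(th)
  # content rotation out(p) = in(R(-th) p): apply the inverse shears in
  # reverse order, each as a resampling shear
  g <- array(shear_x(g, alpha * (seq_len(d[2]) - cy)), d)
  g <- aperm(g, c(2, 1, 3))
  g <- array(shear_x(g, beta * (seq_len(d[1]) - cx)), dim(g))
  g <- aperm(g, c(2, 1, 3))
  array(shear_x(g, alpha * (seq_len(d[2]) - cy)), d)
}

#' Rotate a volume about the docking (z) axis
#'
#' Counterclockwise in-plane rotation by `angle_deg` about the vertical
#' axis through the box centre (each z slice rotates identically), using
#' the exact Fourier three-shear decomposition, which loses no signal for
#' band-limited content. If the input carries a missing-wedge descriptor
#' the accumulated in-plane wedge azimuth is tracked in
#' `meta$wedge_azimuth_deg`.
#'
#' @param vol a [density_volume()] (or bare 3D array, returned as array).
#' @param angle_deg rotation angle in degrees.
#' @return rotated volume of the same class as the input.
#' @export
rotate_volume_z <- function(vol, angle_deg) {
  if (!is_density_volume(vol))
    return(rotate_grid_z(vol, angle_deg))
  g <- rotate_grid_z(vol$grid, angle_deg)
  out <- density_volume(g, vol$voxel_size_nm, vol$origin_nm, vol$wedge,
                        vol$meta)
  if (!is.null(vol$wedge))
    out$meta$wedge_azimuth_deg <-
      ((vol$meta$wedge_azimuth_deg %||% 0) + angle_deg) %% 360
  out
}

#' Translate a volume by a subvoxel shift
#'
#' Shifts the content by `shift_vox` voxels (positive = towards higher
#' indices) via a Fourier phase ramp, so subvoxel shifts are exact for
#' band-limited data. Content wraps cyclically.
#'
#' @param vol a [density_volume()] or 3D array.
#' @param shift_vox numeric length-3 shift in voxels.
#' @return shifted volume of the same class as the input.
#' @export
shift_volume <- function(vol, shift_vox) {
  g <- as_grid(vol)
  d <- dim(g)
  if (all(shift_vox == 0)) return(vol)
  ph <- function(n, s) exp(-2i * pi * fft_freqs(n) * s)
  ramp <- outer(outer(ph(d[1], shift_vox[1]), ph(d[2], shift_vox[2])),
                ph(d[3], shift_vox[3]))
  out <- Re(fft(fft(g) * ramp, inverse = TRUE)) / prod(d)
  if (!is_density_volume(vol)) return(out)
  density_volume(out, vol$voxel_size_nm, vol$origin_nm, vol$wedge, vol$meta)
}
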