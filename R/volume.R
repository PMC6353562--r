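# Density volumes: the common currency of the pipeline.

#' Construct a density volume
#'
#' A `density_volume` wraps a 3D numeric array together with its isotropic
#' voxel size and, optionally, the tilt scheme describing which part of
#' Fourier space the data actually samples (the missing-wedge descriptor).
#'
#' The world coordinate frame is right-handed with z the docking axis
#' (membrane below, vesicle above) and the box centre at the origin; the
#' voxel at index `(i, j, k)` has world coordinate
#' `(i - (n + 1) / 2) * voxel_size_nm` along each axis. Arbitrary metadata
#' (e.g. the membrane plane position `pm_z_nm`) travels in `meta`.
#'
#' @param grid 3D numeric array of density values (arbitrary units,
#'   density-above-background convention: protein and membrane positive).
#' @param voxel_size_nm isotropic voxel edge length in nm (> 0).
#' @param origin_nm world coordinate of the centre of voxel (1,1,1);
#'   defaults to the symmetric frame described above.
#' @param wedge optional [tilt_scheme()] describing the Fourier support.
#' @param meta named list of free-form metadata.
#' @return an object of class `density_volume`.
#' @export
density_volume <- function(grid, voxel_size_nm, origin_nm = NULL,
                           wedge = NULL, meta = list()) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("`grid` must be a 3D array")
  if (!is.numeric(voxel_size_nm) || length(voxel_size_nm) != 1L ||
      !is.finite(voxel_size_nm) || voxel_size_nm <= 0)
    stop("`voxel_size_nm` must be a single positive number")
  if (is.null(origin_nm))
    origin_nm <- -(dim(grid) + 1) / 2 * voxel_size_nm + voxel_size_nm
  if (!is.null(wedge) && !inherits(wedge, "tilt_scheme"))
    stop("`wedge` must be NULL or a tilt_scheme")
  structure(list(grid = grid, voxel_size_nm = voxel_size_nm,
                 origin_nm = origin_nm, wedge = wedge, meta = meta),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("density_volume %d x %d x %d, voxel %.3f nm%s\n",
              d[1], d[2], d[3], x$voxel_size_nm,
              if (is.null(x$wedge)) "" else
                sprintf(", wedge %+.0f..%+.0f deg about %s",
                        x$wedge$min_deg, x$wedge$max_deg, x$wedge$tilt_axis)))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(x$grid), max(x$grid), mean(x$grid)))
  invisible(x)
}

is_density_volume <- function(x) inherits(x, "density_volume")

as_grid <- function(x) if (is_density_volume(x)) x$grid else x

# World coordinates (nm) of voxel centres along each axis.
vox_axes <- function(vol) {
  d <- dim(vol$grid)
  v <- vol$voxel_size_nm
  lapply(seq_len(3), function(a) vol$origin_nm[a] + (seq_len(d[a]) - 1) * v)
}

# Fractional Fourier frequencies (cycles / voxel) for one axis length.
fft_freqs <- function(n) {
  c(seq(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L)) / n
}

#' Block-average binning of a volume
#'
#' Downsamples by the block mean over `factor`^3 voxel blocks; the voxel
#' size is multiplied by `factor`. Mirrors the 4x4x4 binning conventionally
#' applied to subtomograms to boost contrast before alignment.
#'
#' @param vol a [density_volume()].
#' @param factor positive integer bin factor; the grid dimensions must be
#'   divisible by it.
#' @return the binned [density_volume()].
#' @export
bin_volume <- function(vol, factor) {
  stopifnot(is_density_volume(vol))
  factor <- as.integer(factor)
  if (length(factor) != 1L || is.na(factor) || factor < 1L)
    stop("`factor` must be a positive integer")
  d <- dim(vol$grid)
  if (any(d %% factor != 0L))
    stop(sprintf("grid dimensions (%s) not divisible by bin factor %d",
                 paste(d, collapse = "x"), factor))
  if (factor == 1L) return(vol)
  nd <- d %/% factor
  a <- array(vol$grid, c(factor, nd[1], factor, nd[2], factor, nd[3]))
  g <- apply(a, c(2, 4, 6), mean)
  density_volume(g, vol$voxel_size_nm * factor, wedge = vol$wedge,
                 meta = vol$meta)
}

#' Low-pass filter a volume in Fourier space
#'
#' Applies a raised-cosine (soft-edged) low-pass filter centred on the
#' spatial frequency `1 / cutoff_nm`. The transition band spans
#' `(1 -/+ rolloff) / cutoff_nm`, so the response is 1 well below the cutoff
#' and 0 well above it.
#'
#' @param vol a [density_volume()].
#' @param cutoff_nm resolution cutoff in nm; must exceed twice the voxel
#'   size (the Nyquist-equivalent spacing).
#' @param rolloff fractional half-width of the raised-cosine transition
#'   band (default 0.2).
#' @return the filtered [density_volume()] (real-valued).
#' @export
lowpass_filter <- function(vol, cutoff_nm, rolloff = 0.2) {
  stopifnot(is_density_volume(vol))
  if (!is.finite(cutoff_nm) || cutoff_nm <= 2 * vol$voxel_size_nm)
    stop("`cutoff_nm` must exceed twice the voxel size")
  d <- dim(vol$grid)
  # frequency magnitude in cycles / nm
  fx <- fft_freqs(d[1]) / vol$voxel_size_nm
  fy <- fft_freqs(d[2]) / vol$voxel_size_nm
  fz <- fft_freqs(d[3]) / vol$voxel_size_nm
  f2 <- outer(outer(fx^2, fy^2, "+"), fz^2, "+")
  f <- sqrt(f2)
  fc <- 1 / cutoff_nm
  flo <- fc * (1 - rolloff)
  fhi <- fc * (1 + rolloff)
  h <- array(0, d)
  h[f <= flo] <- 1
  tb <- f > flo & f < fhi
  h[tb] <- 0.5 * (1 + cos(pi * (f[tb] - flo) / (fhi - flo)))
  g <- Re(fft(fft(vol$grid) * h, inverse = TRUE)) / prod(d)
  density_volume(g, vol$voxel_size_nm, vol$origin_nm, vol$wedge, vol$meta)
}

# Soft-edged spherical mask (1 inside, cosine edge of `edge_nm`).
spherical_mask <- function(vol, radius_nm, center_nm = c(0, 0, 0),
                           edge_nm = 2 * vol$voxel_size_nm) {
  ax <- vox_axes(vol)
  r2 <- outer(outer((ax[[1]] - center_nm[1])^2, (ax[[2]] - center_nm[2])^2,
                    "+"), (ax[[3]] - center_nm[3])^2, "+")
  r <- sqrt(r2)
  m <- array(0, dim(vol$grid))
  m[r <= radius_nm] <- 1
  tb <- r > radius_nm & r < radius_nm + edge_nm
  m[tb] <- 0.5 * (1 + cos(pi * (r[tb] - radius_nm) / edge_nm))
  m
}

# Interface mask: slab of z-range `slab_nm` above the membrane plane,
# annulus `annulus_nm = c(rmin, rmax)` about the docking (z) axis.
interface_mask <- function(vol, pm_z_nm = vol$meta$pm_z_nm,
                           slab_nm = c(2, 8), annulus_nm = c(8, 28)) {
  if (is.null(pm_z_nm)) stop("membrane plane z (`pm_z_nm`) is not known")
  ax <- vox_axes(vol)
  rxy <- sqrt(outer(ax[[1]]^2, ax[[2]]^2, "+"))
  inz <- ax[[3]] >= pm_z_nm + slab_nm[1] & ax[[3]] <= pm_z_nm + slab_nm[2]
  inr <- rxy >= annulus_nm[1] & rxy <= annulus_nm[2]
  m <- array(0, dim(vol$grid))
  m[, , inz] <- inr
  m
}

# z-slice index range of the interface slab (used for cropped alignment).
slab_z_indices <- function(vol, pm_z_nm = vol$meta$pm_z_nm,
                           slab_nm = c(2, 8)) {
  if (is.null(pm_z_nm)) stop("membrane plane z (`pm_z_nm`) is not known")
  z <- vox_axes(vol)[[3]]
  which(z >= pm_z_nm + slab_nm[1] & z <= pm_z_nm + slab_nm[2])
}
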