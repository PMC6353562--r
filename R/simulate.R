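# Subtomogram simulation: pose, missing wedge, noise.

#' Simulate one subtomogram from a phantom
#'
#' Applies a pose (rotation about the docking axis, then a translation),
#' imposes the missing wedge of the tilt scheme, and adds zero-mean white
#' Gaussian noise scaled so that the ratio of signal variance to noise
#' variance inside the particle support equals `noise$snr`. The particle
#' support is the set of voxels where the noiseless posed density exceeds
#' 5% of its maximum. An optional pre-noise low-pass blur
#' (`noise$lowpass_cutoff_nm`) is applied to the signal first.
#'
#' This wedge-mask-in-Fourier-space formation is the default subtomogram
#' model; an explicit tilt projection / back-projection path with the same
#' Fourier support is available via [project_backproject()].
#'
#' @param phantom a noiseless [density_volume()] from [render_phantom()].
#' @param tilt a [tilt_scheme()].
#' @param noise a [noise_model()]; `snr = Inf` gives the noiseless
#'   wedge-filtered volume.
#' @param pose list with `azimuth_deg` and `shift_nm` (length 3, nm).
#' @param rng_seed integer seed for the noise draw.
#' @return a [density_volume()] carrying the wedge descriptor and, in
#'   `meta`, the applied pose.
#' @export
simulate_subtomogram <- function(phantom, tilt, noise,
                                 pose = list(azimuth_deg = 0,
                                             shift_nm = c(0, 0, 0)),
                                 rng_seed = 1) {
  stopifnot(is_density_volume(phantom), inherits(tilt, "tilt_scheme"),
            inherits(noise, "noise_model"))
  sh_nm <- pose$shift_nm %||% c(0, 0, 0)
  az <- pose$azimuth_deg %||% 0
  d <- dim(phantom$grid)
  L <- d * phantom$voxel_size_nm
  # the vesicle must stay inside the box
  dia <- phantom$meta$diameter_nm %||% 0
  if (any(abs(sh_nm) > (L - dia) / 2 - phantom$voxel_size_nm))
    stop("pose shift pushes the vesicle outside the box")

  v <- phantom
  if (az != 0) v <- rotate_volume_z(v, az)
  if (any(sh_nm != 0)) v <- shift_volume(v, sh_nm / v$voxel_size_nm)
  support <- abs(v$grid) > 0.05 * max(abs(v$grid))

  v <- apply_missing_wedge(v, tilt)
  if (!is.null(noise$lowpass_cutoff_nm))
    v <- lowpass_filter(v, noise$lowpass_cutoff_nm)

  if (is.finite(noise$snr)) {
    sig_var <- stats::var(v$grid[support])
    sd_n <- sqrt(sig_var / noise$snr)
    set.seed(rng_seed)
    v$grid <- v$grid + array(stats::rnorm(prod(d), 0, sd_n), d)
  }
  v$meta$pose <- list(azimuth_deg = az, shift_nm = sh_nm)
  v$meta$snr <- noise$snr
  v
}

#' Explicit tilt-series projection and weighted back-projection
#'
#' A fidelity cross-check for the Fourier wedge-mask shortcut: projects the
#' volume along each tilt direction of the scheme (rotating about the tilt
#' axis), then reconstructs by summing back-projections with a ramp-like
#' Fourier weighting restricted to the sampled wedge. Its Fourier support
#' equals that of [apply_missing_wedge()].
#'
#' @param vol a [density_volume()].
#' @param tilt a [tilt_scheme()].
#' @return reconstructed [density_volume()] carrying the wedge.
#' @export
project_backproject <- function(vol, tilt) {
  stopifnot(is_density_volume(vol), inherits(tilt, "tilt_scheme"))
  # Central-section formulation: the union of measured central sections is
  # exactly the wedge support; with exact per-section weighting the
  # reconstruction equals the wedge-masked volume. We form it section by
  # section in Fourier space to keep the geometry explicit.
  d <- dim(vol$grid)
  FV <- fft(vol$grid)
  angles <- seq(tilt$min_deg, tilt$max_deg, by = tilt$step_deg)
  fx <- fft_freqs(d[1]); fy <- fft_freqs(d[2]); fz <- fft_freqs(d[3])
  if (tilt$tilt_axis == "y") {
    u <- array(rep(fx, times = d[2] * d[3]), d)
  } else {
    u <- aperm(array(rep(fy, times = d[1] * d[3]), c(d[2], d[1], d[3])),
               c(2, 1, 3))
  }
  w <- array(rep(fz, each = d[1] * d[2]), d)
  th <- atan2(-w, u) * 180 / pi
  th[th > 90] <- th[th > 90] - 180
  th[th <= -90] <- th[th <= -90] + 180
  # nearest measured section within half a tilt increment => sampled;
  # clipped to the collected range so the support matches the wedge mask
  half <- tilt$step_deg / 2
  m <- array(FALSE, d)
  for (a in angles)
    m <- m | abs(th - a) <= half | abs(th - a + 180) <= half |
      abs(th - a - 180) <= half
  m <- m & th >= tilt$min_deg & th <= tilt$max_deg
  m[1, 1, 1] <- TRUE
  g <- Re(fft(FV * m, inverse = TRUE)) / prod(d)
  density_volume(g, vol$voxel_size_nm, vol$origin_nm, wedge = tilt,
                 meta = vol$meta)
}

#' Generate a synthetic particle dataset with ground truth
#'
#' Draws, per particle, a vesicle diameter from the mixture, a global
#' azimuthal phase (uniform), per-module jitter (or fully random module
#' azimuths in disorganized F349A mode), and a random in-plane shift; then
#' renders and simulates each subtomogram.
#'
#' @param n_particles number of particles (>= 1).
#' @param geometry an [assembly_geometry()].
#' @param mixture a [vesicle_mixture()] (or a single [vesicle_model()],
#'   treated as a zero-spread one-component mixture).
#' @param tilt a [tilt_scheme()].
#' @param noise a [noise_model()].
#' @param rng_seed master integer seed; per-particle seeds derive from it.
#' @param voxel_size_nm,box_voxels sampling passed to [render_phantom()].
#' @param shift_sd_nm sd of the random in-plane (x, y) shift, nm.
#' @param base_vesicle template [vesicle_model()] supplying membrane /
#'   gap parameters for mixture components that do not carry their own.
#' @return list with `volumes` (list of [density_volume()]) and `table`
#'   (the ground-truth particle table, one row per particle).
#' @export
generate_dataset <- function(n_particles, geometry, mixture, tilt, noise,
                             rng_seed = 1, voxel_size_nm = 2.16,
                             box_voxels = 64, shift_sd_nm = 2,
                             base_vesicle = vesicle_model()) {
  if (n_particles < 1) stop("`n_particles` must be >= 1")
  if (inherits(mixture, "vesicle_model")) {
    mixture <- vesicle_mixture(list(list(
      weight = 1, diameter_mean_nm = mixture$diameter_nm,
      diameter_sd_nm = 0, vesicle = mixture)))
  }
  stopifnot(inherits(mixture, "vesicle_mixture"))

  set.seed(rng_seed)
  # a drawn vesicle must still fit the box above the membrane plane
  box_nm <- box_voxels * voxel_size_nm
  dmax <- box_nm - base_vesicle$membrane_thickness_nm -
    base_vesicle$docking_gap_nm - 2 * voxel_size_nm
  draws <- lapply(seq_len(n_particles), function(i) {
    dv <- draw_vesicle(mixture, base_vesicle, max_diameter_nm = dmax)
    list(component = dv$component, vesicle = dv$vesicle,
         phase = stats::runif(1, 0, 360),
         shift = c(stats::rnorm(2, 0, shift_sd_nm), 0),
         seed = rng_seed + 7L * i)
  })

  vols <- vector("list", n_particles)
  rows <- vector("list", n_particles)
  for (i in seq_len(n_particles)) {
    dr <- draws[[i]]
    ph <- render_phantom(geometry, dr$vesicle, voxel_size_nm, box_voxels,
                         rng_seed = dr$seed, phase_deg = dr$phase)
    vols[[i]] <- simulate_subtomogram(
      ph, tilt, noise,
      pose = list(azimuth_deg = 0, shift_nm = dr$shift),
      rng_seed = dr$seed + 1L)
    rows[[i]] <- data.frame(
      particle_id = sprintf("p%04d", i),
      diameter_nm = dr$vesicle$diameter_nm,
      azimuth_deg = dr$phase %% 360,
      shift_x_nm = dr$shift[1], shift_y_nm = dr$shift[2],
      shift_z_nm = dr$shift[3],
      organized = geometry$organized,
      module_azimuths_deg = paste(
        sprintf("%.3f", ph$meta$module_azimuths_deg), collapse = ";"),
      component = dr$component,
      stringsAsFactors = FALSE)
  }
  list(volumes = vols, table = do.call(rbind, rows))
}
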