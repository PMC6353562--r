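# Ground-truth phantom rendering.

# Soft (anti-aliased) indicator: 1 where u >= w/2 inside, 0 outside,
# linear ramp of width w across the boundary. u is the signed distance
# into the shape (positive inside).
ramp_in <- function(u, w) pmin(pmax(u / w + 0.5, 0), 1)

#' Render a noiseless docked-vesicle phantom
#'
#' Builds the full-Fourier-support ground-truth density of one docked
#' vesicle: a spherical membrane shell resting `docking_gap_nm` above a
#' planar membrane slab, with the interface assembly (radial rods on a
#' ring, optional weak central mass, optional thin torus) in the gap.
#' Shapes are rendered with a one-voxel soft edge to limit aliasing.
#'
#' The membrane top surface sits at world z = `pm_z_nm` (stored in the
#' output metadata); by default the membrane + gap + vesicle stack is
#' centred vertically in the box, and the docking axis is the z axis
#' through the box centre.
#'
#' @param geometry an [assembly_geometry()].
#' @param vesicle a [vesicle_model()].
#' @param voxel_size_nm sampling, nm / voxel (default 2.16, i.e. 4x-binned
#'   5.4 A pixels).
#' @param box_voxels cubic box edge in voxels (default 64).
#' @param rng_seed integer seed governing the global azimuthal phase,
#'   per-module jitter, and disorganized-mode azimuths.
#' @param phase_deg optional fixed global azimuthal phase; `NULL` draws it
#'   uniformly from the seed.
#' @param center_xy_nm lateral (x, y) placement of the vesicle axis.
#' @param include_membrane,include_vesicle render the planar membrane /
#'   the vesicle shell (disable to compose multi-vesicle scenes).
#' @return a [density_volume()] with `meta` fields `pm_z_nm`,
#'   `phase_deg`, `module_azimuths_deg`, `diameter_nm`, `organized`.
#' @export
render_phantom <- function(geometry, vesicle, voxel_size_nm = 2.16,
                           box_voxels = 64, rng_seed = 1, phase_deg = NULL,
                           center_xy_nm = c(0, 0),
                           include_membrane = TRUE, include_vesicle = TRUE) {
  stopifnot(inherits(geometry, "assembly_geometry"),
            inherits(vesicle, "vesicle_model"))
  n <- as.integer(box_voxels)
  L <- n * voxel_size_nm
  tm <- vesicle$membrane_thickness_nm
  D <- vesicle$diameter_nm
  gap <- vesicle$docking_gap_nm
  if (tm + gap + D > L)
    stop(sprintf("box (%.1f nm) too small for membrane + gap + vesicle (%.1f nm)",
                 L, tm + gap + D))
  if (max(D, geometry$ring_diameter_nm + geometry$module_dims_nm[1]) > L)
    stop("box too small laterally for the vesicle or the interface ring")

  z_pm <- vesicle$pm_offset_nm %||% (-(gap + D - tm) / 2)
  ax <- (seq_len(n) - (n + 1) / 2) * voxel_size_nm
  x <- ax - center_xy_nm[1]
  y <- ax - center_xy_nm[2]
  z <- ax
  w <- voxel_size_nm

  g <- array(0, c(n, n, n))
  rxy2 <- outer(x^2, y^2, "+")

  if (include_membrane) {
    mz <- ramp_in(pmin(z - (z_pm - tm), z_pm - z), w)
    iz <- which(mz > 0)
    for (k in iz) g[, , k] <- g[, , k] + vesicle$membrane_density * mz[k]
  }

  if (include_vesicle) {
    zc <- z_pm + gap + D / 2
    iz <- which(abs(z - zc) <= D / 2 + w)
    for (k in iz) {
      r <- sqrt(rxy2 + (z[k] - zc)^2)
      sh <- ramp_in(r - (D / 2 - tm), w) * ramp_in(D / 2 - r, w)
      g[, , k] <- g[, , k] + vesicle$membrane_density * sh
    }
  }

  # interface assembly
  set.seed(rng_seed)
  nm <- geometry$n_modules
  if (is.null(phase_deg)) phase_deg <- stats::runif(1, 0, 360)
  if (nm > 0) {
    if (geometry$organized) {
      azi <- phase_deg + (seq_len(nm) - 1) * 360 / nm +
        stats::rnorm(nm, 0, geometry$angular_jitter_deg)
    } else {
      azi <- stats::runif(nm, 0, 360)
    }
    azi <- azi %% 360
  } else azi <- numeric(0)

  z_mod <- z_pm + gap / 2
  dims <- geometry$module_dims_nm
  rring <- geometry$ring_diameter_nm / 2
  if (nm > 0) {
    iz <- which(abs(z - z_mod) <= dims[3] / 2 + w)
    wz <- ramp_in(dims[3] / 2 - abs(z[iz] - z_mod), w)
    for (m in seq_len(nm)) {
      th <- azi[m] * pi / 180
      # rod frame: u radial (about the ring-centre radius), v tangential
      u <- outer(cos(th) * x, sin(th) * y, "+") - rring
      v <- outer(-sin(th) * x, cos(th) * y, "+")
      xy <- geometry$module_density *
        ramp_in(dims[1] / 2 - abs(u), w) * ramp_in(dims[2] / 2 - abs(v), w)
      for (j in seq_along(iz))
        g[, , iz[j]] <- g[, , iz[j]] + xy * wz[j]
    }
  }

  if (geometry$central_mass_density > 0 && nm > 0) {
    rc <- geometry$central_mass_radius_nm
    dc <- geometry$central_mass_density * geometry$module_density
    iz <- which(abs(z - z_mod) <= rc + w)
    for (k in iz) {
      r <- sqrt(rxy2 + (z[k] - z_mod)^2)
      g[, , k] <- g[, , k] + dc * ramp_in(rc - r, w)
    }
  }

  if (geometry$syt_ring_thickness_nm > 0) {
    rt <- geometry$syt_ring_thickness_nm / 2
    iz <- which(abs(z - z_mod) <= rt + w)
    rxy <- sqrt(rxy2)
    for (k in iz) {
      rr <- sqrt((rxy - rring)^2 + (z[k] - z_mod)^2)
      g[, , k] <- g[, , k] + geometry$module_density * ramp_in(rt - rr, w)
    }
  }

  density_volume(g, voxel_size_nm,
                 meta = list(pm_z_nm = z_pm, phase_deg = phase_deg %% 360,
                             module_azimuths_deg = azi,
                             diameter_nm = D, gap_nm = gap,
                             membrane_thickness_nm = tm,
                             organized = geometry$organized))
}
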