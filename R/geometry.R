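# Ground-truth geometry of the vesicle-membrane interface assembly.

#' Describe the interface protein assembly
#'
#' Parameterizes the arrangement of protein masses at the vesicle-plasma
#' membrane interface: `n_modules` rod-shaped ~250 kDa-scale densities
#' whose centres sit on a circle of `ring_diameter_nm` in the docking gap,
#' an optional weak central mass, and an optional thin torus standing in
#' for a Synaptotagmin ring-like oligomer. With `organized = TRUE` the
#' module azimuths form a regular lattice (spacing `360 / n_modules`
#' degrees) plus one global phase and optional per-module jitter; with
#' `organized = FALSE` ("F349A mode", emulating the oligomerization-dead
#' Syt1 mutant) every module azimuth is drawn independently and uniformly
#' per particle.
#'
#' @param n_modules number of interface protein masses (>= 0).
#' @param ring_diameter_nm diameter of the circle of module centres (> 0).
#' @param angular_jitter_deg sd of per-module azimuthal jitter, degrees.
#' @param module_dims_nm full rod extents (length, width, height) in nm;
#'   the long axis points radially.
#' @param module_density positive density contrast of a module.
#' @param central_mass_density central mass contrast as a fraction of
#'   `module_density` (must be < 1: the central mass is weak).
#' @param central_mass_radius_nm radius of the central mass sphere.
#' @param syt_ring_thickness_nm minor diameter of the optional thin torus
#'   at the ring radius; 0 disables it.
#' @param organized logical; FALSE selects the disorganized F349A mode.
#' @return an object of class `assembly_geometry`.
#' @export
assembly_geometry <- function(n_modules = 6, ring_diameter_nm = 35,
                              angular_jitter_deg = 0,
                              module_dims_nm = c(10, 4, 4),
                              module_density = 1,
                              central_mass_density = 0.3,
                              central_mass_radius_nm = 6,
                              syt_ring_thickness_nm = 0,
                              organized = TRUE) {
  if (n_modules < 0 || n_modules != round(n_modules))
    stop("`n_modules` must be a non-negative integer")
  if (ring_diameter_nm <= 0) stop("`ring_diameter_nm` must be > 0")
  if (angular_jitter_deg < 0) stop("`angular_jitter_deg` must be >= 0")
  if (length(module_dims_nm) != 3 || any(module_dims_nm <= 0))
    stop("`module_dims_nm` must be 3 positive extents")
  if (module_density <= 0) stop("`module_density` must be > 0")
  if (central_mass_density < 0 || central_mass_density >= 1)
    stop("`central_mass_density` must be in [0, 1): the central mass is weak")
  if (syt_ring_thickness_nm < 0) stop("`syt_ring_thickness_nm` must be >= 0")
  structure(list(n_modules = as.integer(n_modules),
                 ring_diameter_nm = ring_diameter_nm,
                 angular_jitter_deg = angular_jitter_deg,
                 module_dims_nm = module_dims_nm,
                 module_density = module_density,
                 central_mass_density = central_mass_density,
                 central_mass_radius_nm = central_mass_radius_nm,
                 syt_ring_thickness_nm = syt_ring_thickness_nm,
                 organized = isTRUE(organized)),
            class = "assembly_geometry")
}

#' Describe a docked vesicle
#'
#' @param diameter_nm outer vesicle diameter (> 2 x membrane thickness).
#' @param membrane_thickness_nm bilayer shell thickness.
#' @param docking_gap_nm clearance between the vesicle periphery and the
#'   membrane plane, occupied by the interface assembly.
#' @param pm_offset_nm world z of the membrane top surface; `NULL` centres
#'   the full membrane + gap + vesicle stack vertically in the box.
#' @param membrane_density density contrast of membrane voxels.
#' @return an object of class `vesicle_model`.
#' @export
vesicle_model <- function(diameter_nm = 45, membrane_thickness_nm = 5,
                          docking_gap_nm = 10, pm_offset_nm = NULL,
                          membrane_density = 1) {
  if (diameter_nm <= 2 * membrane_thickness_nm)
    stop("`diameter_nm` must exceed twice the membrane thickness")
  if (docking_gap_nm < 0) stop("`docking_gap_nm` must be >= 0")
  if (membrane_density <= 0) stop("`membrane_density` must be > 0")
  structure(list(diameter_nm = diameter_nm,
                 membrane_thickness_nm = membrane_thickness_nm,
                 docking_gap_nm = docking_gap_nm,
                 pm_offset_nm = pm_offset_nm,
                 membrane_density = membrane_density),
            class = "vesicle_model")
}

#' Describe the additive noise model
#'
#' `snr` is the ratio of signal variance to noise variance measured inside
#' the particle support (voxels occupied by membrane or protein).
#'
#' @param snr positive signal-to-noise variance ratio; `Inf` for noiseless.
#' @param lowpass_cutoff_nm optional blurring scale applied to the signal
#'   before noise is added; `NULL` disables.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(snr = 0.1, lowpass_cutoff_nm = NULL) {
  if (!(snr > 0)) stop("`snr` must be > 0")
  structure(list(snr = snr, lowpass_cutoff_nm = lowpass_cutoff_nm),
            class = "noise_model")
}

#' Describe a mixture of vesicle populations
#'
#' Each component is a [vesicle_model()] template plus a truncated-normal
#' diameter distribution and a mixture weight. Used to emulate, e.g., a
#' dominant ~45 nm synaptic-like population alongside larger dense-core
#' vesicles.
#'
#' @param components list of lists with fields `weight`,
#'   `diameter_mean_nm`, `diameter_sd_nm`, and optionally `vesicle`
#'   (a [vesicle_model()] template whose diameter is overridden per draw).
#' @return an object of class `vesicle_mixture`.
#' @export
vesicle_mixture <- function(components) {
  if (!is.list(components) || length(components) == 0)
    stop("mixture must have at least one component")
  for (cmp in components) {
    if (is.null(cmp$weight) || cmp$weight <= 0)
      stop("each component needs a positive `weight`")
    if (is.null(cmp$diameter_mean_nm) || cmp$diameter_mean_nm <= 0)
      stop("each component needs a positive `diameter_mean_nm`")
  }
  structure(list(components = components), class = "vesicle_mixture")
}

# Draw one (component index, diameter) pair from a mixture. Diameters are
# truncated below so the vesicle stays a valid shell and, optionally,
# above so it still fits the subtomogram box.
draw_vesicle <- function(mixture, base_vesicle, max_diameter_nm = Inf) {
  w <- vapply(mixture$components, function(c) c$weight, numeric(1))
  k <- sample.int(length(w), 1, prob = w)
  cmp <- mixture$components[[k]]
  tmpl <- cmp$vesicle %||% base_vesicle
  dmin <- 2 * tmpl$membrane_thickness_nm + 2
  for (try in 1:1000) {
    d <- stats::rnorm(1, cmp$diameter_mean_nm, cmp$diameter_sd_nm %||% 0)
    if (d > dmin && d <= max_diameter_nm) break
    if (try == 1000)
      stop(sprintf(
        "could not draw a vesicle diameter in (%.1f, %.1f] nm from component %d",
        dmin, max_diameter_nm, k))
  }
  v <- tmpl
  v$diameter_nm <- d
  list(component = k, vesicle = v)
}
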