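# Shared fixtures: small phantoms and simulated particle sets, plus a
# memoised cache so expensive end-to-end runs are computed once per
# test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

default_phantom <- function(phase_deg = 0, seed = 1, ...) {
  render_phantom(assembly_geometry(...), vesicle_model(),
                 rng_seed = seed, phase_deg = phase_deg)
}

# small organized particle set (noiseless unless snr given)
make_particles <- function(n = 6, snr = Inf, seed = 1, organized = TRUE,
                           box = 48, voxel = 2.16, shift_sd = 0) {
  generate_dataset(
    n,
    assembly_geometry(organized = organized),
    vesicle_mixture(list(list(weight = 1, diameter_mean_nm = 45,
                              diameter_sd_nm = 0))),
    tilt_scheme(-51, 51, 3),
    noise_model(snr = snr),
    rng_seed = seed, voxel_size_nm = voxel, box_voxels = box,
    shift_sd_nm = shift_sd)
}

# the full-size recovery run shared between pipeline and acceptance tests
ring_recovery_report <- function() {
  cached("ring_recovery", {
    run_experiment(canned_experiment("ring_recovery", rng_seed = 7))
  })
}

mixture_census_report <- function() {
  cached("mixture_census", {
    run_experiment(canned_experiment("mixture_census", rng_seed = 7))
  })
}

# two-population mixture used by the MSA / HAC unit tests
msa_mix_dataset <- function() {
  cached("msa_mix", generate_dataset(
    24, assembly_geometry(n_modules = 0, central_mass_density = 0),
    vesicle_mixture(list(
      list(weight = 0.5, diameter_mean_nm = 45, diameter_sd_nm = 1),
      list(weight = 0.5, diameter_mean_nm = 120, diameter_sd_nm = 3))),
    tilt_scheme(-51, 51, 3), noise_model(snr = 0.5), rng_seed = 8,
    voxel_size_nm = 3.4, box_voxels = 56, shift_sd_nm = 0))
}

# one scaled-down disorganized (or organized) interface run: returns the
# detection p-value and, optionally, the interface average
small_interface_run <- function(seed, organized, average = FALSE,
                                n = 30) {
  ds <- generate_dataset(
    n, assembly_geometry(organized = organized),
    vesicle_mixture(list(list(weight = 1, diameter_mean_nm = 45,
                              diameter_sd_nm = 2))),
    tilt_scheme(-51, 51, 3), noise_model(snr = 0.1),
    rng_seed = seed, voxel_size_nm = 2.16, box_voxels = 48,
    shift_sd_nm = 0)
  pm <- ds$volumes[[1]]$meta$pm_z_nm
  fa <- align_focused(ds$volumes, alignment_params(), pm_z_nm = pm,
                      average = average)
  sig <- symmetry_significance(fa$profiles, smooth_deg = 6.8,
                               rng_seed = seed + 500)
  avg <- if (average) {
    a <- lowpass_filter(fa$average, 5)
    a$meta$pm_z_nm <- pm
    a
  } else NULL
  list(p_value = sig$p_value, detected_order = sig$detected_order,
       average = avg)
}

# 20 seeded disorganized-mode detection p-values (the type-I control)
f349a_null_pvalues <- function() {
  cached("f349a_nulls", vapply(1:20, function(i)
    small_interface_run(3000 + 17 * i, organized = FALSE)$p_value,
    numeric(1)))
}

# relative RMS difference between two volumes over the interface slab,
# restricted to within `r_max_nm` of the docking axis
region_rel_rms <- function(a, b, r_max_nm = 30,
                           pm_z_nm = a$meta$pm_z_nm) {
  iz <- slab_z_indices(a, pm_z_nm)
  ax <- vox_axes_nm(a)
  inr <- sqrt(outer(ax[[1]]^2, ax[[2]]^2, "+")) <= r_max_nm
  num <- den <- 0
  for (k in iz) {
    dd <- (b$grid[, , k] - a$grid[, , k])[inr]
    num <- num + sum(dd^2)
    den <- den + sum(a$grid[, , k][inr]^2)
  }
  sqrt(num / den)
}

# voxel-centre world coordinates (test-side copy of the package logic)
vox_axes_nm <- function(vol) {
  d <- dim(vol$grid)
  lapply(1:3, function(a)
    vol$origin_nm[a] + (seq_len(d[a]) - 1) * vol$voxel_size_nm)
}
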