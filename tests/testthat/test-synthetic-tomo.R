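tilt51 <- tilt_scheme(-51, 51, 3)

test_that("organized phantom has n disjoint modules on the lattice", {
  ph <- default_phantom(phase_deg = 10)
  # suprathreshold structure inside the interface slab: exactly 6 rods
  ss <- sigma_structure(ph, levels = 2)
  comps <- ss$components$sigma_2
  expect_identical(sum(!comps$central), 6L)
  az <- sort((atan2(comps$y_nm[!comps$central], comps$x_nm[!comps$central]) *
                180 / pi) %% 360)
  expect_equal(az, 10 + (0:5) * 60, tolerance = 3)
})

test_that("an empty assembly leaves the interface annulus at background", {
  g0 <- assembly_geometry(n_modules = 0, central_mass_density = 0)
  ph <- render_phantom(g0, vesicle_model(), rng_seed = 1)
  prof <- azimuthal_profile(ph)
  expect_equal(max(abs(prof)), 0, tolerance = 1e-9)
})

test_that("disorganized (F349A) interfaces differ across seeds, vesicle identical", {
  gF <- assembly_geometry(organized = FALSE)
  a <- render_phantom(gF, vesicle_model(), rng_seed = 11)
  b <- render_phantom(gF, vesicle_model(), rng_seed = 12)
  iz <- slab_z_indices(a)
  expect_gt(max(abs(a$grid[, , iz] - b$grid[, , iz])), 0)
  # voxels above the interface (vesicle body) are identical
  top <- (max(iz) + 3):dim(a$grid)[3]
  expect_equal(a$grid[, , top], b$grid[, , top])
})

test_that("phantom geometry is invariant under the lattice rotation", {
  # rendering at phase and phase + 60 produces the same module set,
  # voxel for voxel: the lattice invariance is exact by construction
  a <- default_phantom(phase_deg = 17)
  b <- default_phantom(phase_deg = 77)
  expect_equal(a$grid, b$grid, tolerance = 1e-12)
  # the C6-symmetrized working-resolution map is rotation-invariant
  # (rasterizing rods on a square grid leaves small orientation-dependent
  # aliasing in the raw render, which symmetrization averages away)
  al <- symmetrize_cn(lowpass_filter(a, 5), 6)
  rot <- rotate_volume_z(al, 60)
  expect_lt(region_rel_rms(al, rot, r_max_nm = 30), 0.02)
})

test_that("box sizing and density validation are enforced", {
  expect_error(render_phantom(assembly_geometry(),
                              vesicle_model(diameter_nm = 120),
                              box_voxels = 48), "too small")
  expect_error(assembly_geometry(module_density = -1), "module_density")
  expect_error(assembly_geometry(central_mass_density = 1.2), "weak")
  expect_error(vesicle_model(diameter_nm = 8), "exceed")
})

test_that("missing wedge is an idempotent projection that loses power", {
  ph <- default_phantom()
  w1 <- apply_missing_wedge(ph, tilt51)
  w2 <- apply_missing_wedge(w1, tilt51)
  expect_equal(w2$grid, w1$grid, tolerance = 1e-6)
  expect_lt(sum(w1$grid^2), sum(ph$grid^2))
  # full tilt range: no wedge at all
  id <- apply_missing_wedge(ph, tilt_scheme(-90, 90, 3))
  expect_equal(id$grid, ph$grid, tolerance = 1e-9)
})

test_that("the wedge elongates an isotropic blob along z", {
  n <- 48
  ax <- (seq_len(n) - (n + 1) / 2) * 2.16
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  blob <- density_volume(array(exp(-r2 / (2 * 6^2)), c(n, n, n)), 2.16)
  wb <- apply_missing_wedge(blob, tilt51)
  # full width at half maximum of the central line profile per axis
  fwhm <- function(p) {
    half <- max(p) / 2
    2.16 * sum(p >= half)
  }
  c0 <- n / 2
  fz <- fwhm(wb$grid[c0, c0, ])
  fx <- fwhm(wb$grid[, c0, c0])
  expect_gt(fz, 1.1 * fx)
})

test_that("explicit project/backproject matches the Fourier wedge shortcut", {
  ph <- bin_volume(default_phantom(), 2)  # 32^3 keeps this quick
  a <- apply_missing_wedge(ph, tilt51)
  b <- project_backproject(ph, tilt51)
  expect_gt(constrained_ccc(a, b), 0.999)
})

test_that("subtomogram simulation is deterministic and respects snr", {
  ph <- default_phantom()
  nz <- noise_model(snr = 0.5)
  s1 <- simulate_subtomogram(ph, tilt51, nz, rng_seed = 3)
  s2 <- simulate_subtomogram(ph, tilt51, nz, rng_seed = 3)
  expect_identical(s1$grid, s2$grid)
  # noiseless identity pose equals the wedge-filtered phantom
  s0 <- simulate_subtomogram(ph, tilt51, noise_model(snr = Inf))
  expect_equal(s0$grid, apply_missing_wedge(ph, tilt51)$grid,
               tolerance = 1e-9)
  expect_error(simulate_subtomogram(
    ph, tilt51, nz, pose = list(azimuth_deg = 0, shift_nm = c(60, 0, 0))),
    "outside the box")
})

test_that("correlation with the clean signal rises monotonically with snr", {
  ph <- bin_volume(default_phantom(), 2)
  clean <- apply_missing_wedge(ph, tilt51)
  support <- abs(ph$grid) > 0.05 * max(abs(ph$grid))
  snrs <- c(0.05, 0.1, 0.5, 2)
  cors <- vapply(snrs, function(s) {
    mean(vapply(1:20, function(i) {
      sim <- simulate_subtomogram(ph, tilt51, noise_model(snr = s),
                                  rng_seed = 100 * i)
      cor(sim$grid[support], clean$grid[support])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(cors > 0 & cors < 1))
  expect_true(all(diff(cors) > 0))
})

test_that("ensemble of disorganized phantoms has a flat azimuthal profile", {
  # 200 disorganized phantoms contribute 1200 uniformly placed modules;
  # the ensemble azimuthal profile must be flat up to the binomial
  # placement noise (~45 overlapping modules per azimuth -> ~15%
  # relative sd) with no preferred rotational order. This is the
  # mechanism behind the weak, smeared density of disorganized averages.
  gF <- assembly_geometry(organized = FALSE, central_mass_density = 0)
  acc <- NULL
  for (i in 1:200) {
    ph <- render_phantom(gF, vesicle_model(), voxel_size_nm = 2.16,
                         box_voxels = 48, rng_seed = 1000 + i)
    p <- azimuthal_profile(ph)
    acc <- if (is.null(acc)) p else acc + p
  }
  acc <- acc / 200
  expect_lt(stats::sd(acc) / mean(acc), 3 * sqrt(1 / 45))
  # and specifically no sixfold preference survives the ensemble
  expect_lt(unname(svtomo:::profile_power(acc, 6)), 0.2)
})

test_that("dataset generation reproduces the requested populations", {
  ds1 <- generate_dataset(
    50, assembly_geometry(),
    vesicle_mixture(list(list(weight = 1, diameter_mean_nm = 45,
                              diameter_sd_nm = 2))),
    tilt51, noise_model(snr = 1), rng_seed = 5,
    voxel_size_nm = 2.16, box_voxels = 48, shift_sd_nm = 0)
  expect_length(ds1$volumes, 50)
  # sample mean within 3 sd of the mean
  expect_lt(abs(mean(ds1$table$diameter_nm) - 45), 3 * 2 / sqrt(50))

  ds2 <- generate_dataset(
    200, assembly_geometry(),
    vesicle_mixture(list(
      list(weight = 0.7, diameter_mean_nm = 45, diameter_sd_nm = 5),
      list(weight = 0.3, diameter_mean_nm = 120, diameter_sd_nm = 15))),
    tilt51, noise_model(snr = 1), rng_seed = 6,
    voxel_size_nm = 3.4, box_voxels = 56, shift_sd_nm = 0)
  frac_small <- mean(ds2$table$component == 1)
  expect_lt(abs(frac_small - 0.7), 0.10)

  ds3 <- generate_dataset(1, assembly_geometry(),
                          vesicle_model(), tilt51, noise_model(snr = 1),
                          rng_seed = 1, box_voxels = 48)
  expect_length(ds3$volumes, 1)
  expect_identical(nrow(ds3$table), 1L)
  expect_error(generate_dataset(0, assembly_geometry(), vesicle_model(),
                                tilt51, noise_model(snr = 1)), ">= 1")
})
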