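# Build a slab-only volume whose interface density is an analytic
# function of azimuth, for spectrum ground truth.
analytic_ring_volume <- function(fun, n = 48, voxel = 2.16) {
  ax <- (seq_len(n) - (n + 1) / 2) * voxel
  rxy <- sqrt(outer(ax^2, ax^2, "+"))
  th <- atan2(rep(ax, each = n), rep(ax, times = n))
  # soft radial edges: hard edges alias on the square grid and leave a
  # fixed fourfold ripple in the profile
  env <- pmin(pmax((rxy - 10) / (2 * voxel) + 0.5, 0), 1) *
    pmin(pmax((26 - rxy) / (2 * voxel) + 0.5, 0), 1)
  ring <- env * matrix(fun(th), n, n)
  g <- array(0, c(n, n, n))
  pm <- -10
  iz <- which(ax >= pm + 2 & ax <= pm + 8)
  for (k in iz) g[, , k] <- ring
  density_volume(g, voxel, meta = list(pm_z_nm = pm))
}

test_that("a pure cos(6 theta) density is detected as order 6", {
  vol <- analytic_ring_volume(function(th) 1 + cos(6 * th))
  sp <- rotational_spectrum(vol, orders = 2:12, n_perm = 199)
  expect_identical(sp$detected_order, 6L)
  expect_gte(unname(sp$power["6"]), 0.99)
  expect_lt(sp$p_value, 0.05)
})

test_that("a rotationally uniform density shows no significant order", {
  vol <- analytic_ring_volume(function(th) rep(1, length(th)))
  # drown the fixed square-grid voxelization ripple in random noise so
  # the profile fluctuations are exchangeable, as the permutation null
  # assumes
  set.seed(8)
  vol$grid <- vol$grid + array(rnorm(length(vol$grid), 0, 0.05),
                               dim(vol$grid))
  sp <- rotational_spectrum(vol, orders = 2:12, n_perm = 199)
  expect_gt(sp$p_value, 0.05)
  expect_lt(max(sp$power), 0.2)
})

test_that("Cn symmetrization makes the map invariant under 360/n rotation", {
  ph <- default_phantom(phase_deg = 13)
  noisy <- ph
  set.seed(3)
  noisy$grid <- noisy$grid + array(rnorm(length(ph$grid), 0, 0.3),
                                   dim(ph$grid))
  sym <- symmetrize_cn(lowpass_filter(noisy, 5), 6)
  rot <- rotate_volume_z(sym, 60)
  # compare within the analysis region (the cyclic shears of the exact
  # rotation wrap content only at the box corners)
  err <- region_rel_rms(sym, rot, r_max_nm = 30)
  expect_lt(err, 0.02)
  expect_identical(sym$meta$symmetry_imposed, 6L)
  expect_identical(symmetrize_cn(ph, 1)$grid, ph$grid)
})

test_that("symmetrized power concentrates at multiples of n", {
  ph <- lowpass_filter(default_phantom(phase_deg = 40), 5)
  sym <- symmetrize_cn(ph, 6)
  prof <- azimuthal_profile(sym)
  co <- Mod(stats::fft(prof) / length(prof))^2
  nonDC <- co[2:60]
  at6 <- sum(nonDC[seq(6, 59, by = 6)])
  expect_gte(at6 / sum(nonDC), 0.9)
})

test_that("imposed symmetry is flagged as imposed, not detected", {
  gF <- assembly_geometry(organized = FALSE)
  avg <- NULL
  pm <- NULL
  for (i in 1:10) {
    ph <- render_phantom(gF, vesicle_model(), voxel_size_nm = 2.16,
                         box_voxels = 48, rng_seed = 600 + i)
    pm <- ph$meta$pm_z_nm
    avg <- if (is.null(avg)) ph$grid else avg + ph$grid
  }
  vol <- density_volume(avg / 10, 2.16, meta = list(pm_z_nm = pm))
  sym <- symmetrize_cn(vol, 6)
  rm <- ring_peaks(sym)
  expect_identical(rm$symmetry_imposed, 6L)
  expect_match(paste(capture.output(print(rm)), collapse = " "),
               "imposed, not detected")
})

test_that("ring measurement recovers counts, spacings and diameter", {
  r6 <- ring_peaks(default_phantom(phase_deg = 0))
  expect_identical(r6$n_peaks, 6L)
  expect_true(all(abs(r6$spacings_deg - 60) < 2))
  expect_equal(sum(r6$spacings_deg), 360, tolerance = 1e-9)
  expect_lt(abs(r6$ring_diameter_nm - 35), 1)

  g5 <- assembly_geometry(n_modules = 5)
  r5 <- ring_peaks(render_phantom(g5, vesicle_model(), rng_seed = 1,
                                  phase_deg = 7))
  expect_identical(r5$n_peaks, 5L)
  expect_true(all(abs(r5$spacings_deg - 72) < 2))

  # uniform annulus: no peaks, not an error
  g0 <- assembly_geometry(n_modules = 0, central_mass_density = 0,
                          syt_ring_thickness_nm = 4)
  r0 <- ring_peaks(render_phantom(g0, vesicle_model(), rng_seed = 1))
  expect_identical(r0$n_peaks, 0L)
})

test_that("a thin torus at the ring radius is invisible at 5 nm resolution", {
  ves <- vesicle_model()
  with_t <- assembly_geometry(syt_ring_thickness_nm = 4)
  without <- assembly_geometry()
  a <- lowpass_filter(render_phantom(without, ves, rng_seed = 1,
                                     phase_deg = 20), 5)
  b <- lowpass_filter(render_phantom(with_t, ves, rng_seed = 1,
                                     phase_deg = 20), 5)
  sa <- rotational_spectrum(a, n_perm = 99)
  sb <- rotational_spectrum(b, n_perm = 99)
  expect_identical(sa$detected_order, sb$detected_order)
  ra <- ring_peaks(a)
  rb <- ring_peaks(b)
  expect_identical(ra$n_peaks, rb$n_peaks)
  expect_lt(abs(ra$ring_diameter_nm - rb$ring_diameter_nm), 1)
})

test_that("sigma structure separates strong modules from the weak centre", {
  ph <- default_phantom(phase_deg = 25)  # central mass 0.3 x module
  ss <- sigma_structure(ph, levels = c(1, 2))
  s2 <- ss$components$sigma_2
  s1 <- ss$components$sigma_1
  expect_identical(sum(!s2$central), 6L)
  expect_identical(sum(s2$central), 0L)
  expect_gte(nrow(s1), 7)
  expect_identical(sum(s1$central), 1L)
  # level-set nesting: suprathreshold volume shrinks with sigma
  expect_lt(sum(s2$voxels), sum(s1$voxels))
  expect_error(sigma_structure(density_volume(array(1, c(16, 16, 16)), 1)),
               "constant")
})

test_that("sigma thresholds follow the map statistics", {
  ph <- default_phantom()
  ss <- sigma_structure(ph, levels = c(1, 2))
  expect_equal(ss$thresholds, ss$mean + c(1, 2) * ss$sd)
  expect_gt(ss$sd, 0)
})
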