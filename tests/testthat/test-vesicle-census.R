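test_that("diameter_from_area is exact on analytic circles", {
  expect_equal(diameter_from_area(pi * 22.5^2), 45)
  expect_equal(diameter_from_area(pi), 2)
  expect_equal(diameter_from_area(pi * 60^2), 120)
  expect_equal(diameter_from_area(1590.43), 45, tolerance = 1e-4)
  expect_error(diameter_from_area(0), "positive")
  expect_error(diameter_from_area(-3), "positive")
})

test_that("a noiseless 45 nm phantom yields one accurate detection", {
  ph <- default_phantom()
  det <- detect_vesicles(ph, c(35, 60))
  expect_identical(nrow(det), 1L)
  true_z <- ph$meta$pm_z_nm + 10 + 22.5
  expect_lt(max(abs(c(det$center_x_nm, det$center_y_nm,
                      det$center_z_nm - true_z))), 2.16)
  expect_lt(abs(det$diameter_nm - 45), 2.16)
})

test_that("an empty volume yields no detections", {
  ev <- density_volume(array(0, c(48, 48, 48)), 2.16)
  expect_identical(nrow(detect_vesicles(ev, c(35, 60))), 0L)
})

test_that("two well-separated vesicles are both recovered at snr 0.5", {
  g0 <- assembly_geometry(n_modules = 0, central_mass_density = 0)
  memb <- render_phantom(g0, vesicle_model(), voxel_size_nm = 3.4,
                         box_voxels = 80, rng_seed = 1,
                         center_xy_nm = c(-60, 0), include_vesicle = FALSE)
  pm <- memb$meta$pm_z_nm
  v1 <- render_phantom(g0, vesicle_model(pm_offset_nm = pm),
                       voxel_size_nm = 3.4, box_voxels = 80, rng_seed = 1,
                       center_xy_nm = c(-60, 0), include_membrane = FALSE)
  v2 <- render_phantom(g0, vesicle_model(diameter_nm = 120,
                                         pm_offset_nm = pm),
                       voxel_size_nm = 3.4, box_voxels = 80, rng_seed = 1,
                       center_xy_nm = c(55, 20), include_membrane = FALSE)
  scene <- memb
  scene$grid <- memb$grid + v1$grid + v2$grid
  support <- scene$grid > 0.05
  sd_n <- sqrt(stats::var(scene$grid[support]) / 0.5)
  set.seed(9)
  scene$grid <- scene$grid + array(rnorm(length(scene$grid), 0, sd_n),
                                   dim(scene$grid))
  det <- detect_vesicles(scene, c(35, 135))
  expect_identical(nrow(det), 2L)
  det <- det[order(det$diameter_nm), ]
  expect_lt(sqrt(sum((c(det$center_x_nm[1], det$center_y_nm[1]) -
                        c(-60, 0))^2)), 2 * 3.4)
  expect_lt(sqrt(sum((c(det$center_x_nm[2], det$center_y_nm[2]) -
                        c(55, 20))^2)), 2 * 3.4)
  expect_lt(abs(det$diameter_nm[1] - 45), 4)
  expect_lt(abs(det$diameter_nm[2] - 120), 5)
})

test_that("diameter estimates on noiseless phantoms are within one voxel", {
  g0 <- assembly_geometry(n_modules = 0, central_mass_density = 0)
  for (D in c(40, 60, 90, 130)) {
    ph <- render_phantom(g0, vesicle_model(diameter_nm = D),
                         voxel_size_nm = 3.4, box_voxels = 56, rng_seed = 1)
    zc <- ph$meta$pm_z_nm + 10 + D / 2
    est <- fit_vesicle_diameter(ph, c(0, 0, zc), c(35, 135))
    expect_lt(abs(est - D), 3.4)
  }
})

test_that("docked classification applies the clearance criterion", {
  rec <- data.frame(center_x_nm = 0, center_y_nm = 0, center_z_nm = 27.5,
                    diameter_nm = 45, score = 1,
                    distance_to_pm_nm = NA_real_)
  # membrane plane at 0 -> periphery gap 5 nm
  lab <- density_volume(array(0L, c(48, 48, 48)), 2.16)
  out <- classify_docked(rec, pm_z_nm = 0, label_volume = lab,
                         proximity_nm = 20)
  expect_true(out$docked)
  expect_equal(out$distance_to_pm_nm, 5)

  # labelled organelle voxel inside the corridor breaks docking
  lab2 <- lab
  zax <- (seq_len(48) - 24.5) * 2.16
  kz <- which.min(abs(zax - 2.5))  # inside the corridor, above the plane
  lab2$grid[24:26, 24:26, kz] <- 1L
  out2 <- classify_docked(rec, pm_z_nm = 0, label_volume = lab2,
                          proximity_nm = 20)
  expect_false(out2$docked)
  expect_false(out2$clearance_ok)

  # too far from the membrane
  far <- rec
  far$center_z_nm <- 52.5  # gap 30 nm
  out3 <- classify_docked(far, pm_z_nm = 0, label_volume = lab,
                          proximity_nm = 20)
  expect_false(out3$docked)

  # monotone in the proximity threshold
  gaps <- seq(0, 40, by = 5)
  docked_at <- function(thr) {
    r <- do.call(rbind, lapply(seq_along(gaps), function(i) {
      ri <- rec
      ri$center_z_nm <- gaps[i] + 22.5
      ri
    }))
    classify_docked(r, pm_z_nm = 0, proximity_nm = thr)$docked
  }
  lo <- docked_at(10)
  hi <- docked_at(25)
  expect_true(all(hi[lo]))  # raising the threshold never un-docks
})

test_that("proximal fractions and the two-proportion comparison behave", {
  x <- rep(c(TRUE, FALSE), c(49, 51))
  pf <- proximal_fraction(x)
  expect_equal(pf$fraction, 0.49)
  expect_true(pf$ci[1] < 0.49 && 0.49 < pf$ci[2])

  a <- rep(c(TRUE, FALSE), c(491, 509))
  b <- rep(c(TRUE, FALSE), c(253, 747))
  cmp <- proximal_fraction(a, other = b)
  expect_lt(cmp$p_value, 0.05)

  same <- proximal_fraction(a, other = a)
  expect_equal(same$p_value, 1)
  expect_error(proximal_fraction(logical(0)), "empty")
})

test_that("diameter histogram is a relative-frequency table", {
  h1 <- diameter_histogram(45, bin_width_nm = 10)
  expect_equal(sum(h1$rel_frequency), 1)
  expect_identical(nrow(h1[h1$count > 0, ]), 1L)

  set.seed(2)
  d <- c(rnorm(350, 45, 5), rnorm(150, 120, 15))
  h <- diameter_histogram(d, bin_width_nm = 10)
  expect_equal(sum(h$rel_frequency), 1, tolerance = 1e-9)
  small <- sum(h$rel_frequency[h$bin_hi_nm <= 100])
  expect_lt(abs(small - 0.7), 0.06)
})
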