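tilt51 <- tilt_scheme(-51, 51, 3)

test_that("binning halves and quarters grids with mean preservation", {
  g <- array(rnorm(32^3), c(32, 32, 32))
  vol <- density_volume(g, 0.54)
  b4 <- bin_volume(vol, 4)
  expect_identical(dim(b4$grid), rep(8L, 3))
  expect_equal(b4$voxel_size_nm, 2.16)
  expect_equal(mean(b4$grid), mean(g), tolerance = 1e-12)
  expect_identical(bin_volume(vol, 1), vol)
  cv <- density_volume(array(3.5, c(8, 8, 8)), 1)
  expect_equal(bin_volume(cv, 2)$grid, array(3.5, c(4, 4, 4)))
  expect_error(bin_volume(density_volume(array(0, c(9, 9, 9)), 1), 4),
               "not divisible")
})

test_that("low-pass filter behaves in its limits and in the stop band", {
  ph <- default_phantom()
  # the passband limit: a cutoff just above the Nyquist-equivalent
  # spacing touches only the corner frequencies, and tightening the
  # cutoff towards that limit monotonically approaches the identity
  err_at <- function(co) {
    f <- lowpass_filter(ph, co)
    sqrt(mean((f$grid - ph$grid)^2)) / sqrt(mean(ph$grid^2))
  }
  errs <- vapply(c(4.4, 6, 9), err_at, numeric(1))
  expect_lt(errs[1], 0.06)
  expect_true(all(diff(errs) > 0))
  # the mean (DC) is always preserved
  expect_equal(mean(lowpass_filter(ph, 6)$grid), mean(ph$grid),
               tolerance = 1e-12)
  # near-idempotence at a working cutoff
  f1 <- lowpass_filter(ph, 5)
  f2 <- lowpass_filter(f1, 5)
  expect_lt(sqrt(mean((f2$grid - f1$grid)^2)) / sqrt(mean(f1$grid^2)), 0.02)
  # white noise: power above the cutoff drops by >= 100x
  set.seed(4)
  wn <- density_volume(array(rnorm(48^3), c(48, 48, 48)), 2.16)
  fw <- lowpass_filter(wn, 5)
  d <- dim(wn$grid)
  fr <- sqrt(outer(outer(svtomo:::fft_freqs(d[1])^2,
                         svtomo:::fft_freqs(d[2])^2, "+"),
                   svtomo:::fft_freqs(d[3])^2, "+")) / 2.16
  hi <- fr > 1 / 4.5  # clearly above the 1/5 nm^-1 cutoff
  p_in <- sum(Mod(fft(wn$grid))[hi]^2)
  p_out <- sum(Mod(fft(fw$grid))[hi]^2)
  expect_lt(p_out / p_in, 0.01)
  expect_error(lowpass_filter(ph, 2 * 2.16), "exceed")
})

test_that("constrained correlation has the right fixed points", {
  ph <- bin_volume(default_phantom(), 2)
  x <- apply_missing_wedge(ph, tilt51)
  expect_equal(constrained_ccc(x, x), 1, tolerance = 1e-6)
  neg <- x
  neg$grid <- -neg$grid
  expect_equal(constrained_ccc(x, neg), -1, tolerance = 1e-6)
})

test_that("constrained correlation matches a brute-force oracle on 16^3", {
  # oracle: project both volumes onto the common Fourier support by
  # explicit DFT-coefficient masking, then correlate in real space
  set.seed(11)
  n <- 16
  va <- density_volume(array(rnorm(n^3), c(n, n, n)), 2.16, wedge = tilt51)
  rot <- tilt_scheme(-51, 51, 3, tilt_axis = "x")  # a 90-degree-rotated wedge
  vb <- density_volume(array(rnorm(n^3), c(n, n, n)), 2.16, wedge = rot)
  d <- rep(n, 3)
  S <- wedge_mask(d, tilt51) & wedge_mask(d, rot)
  S[1, 1, 1] <- FALSE
  proj <- function(g) Re(fft(fft(g) * S, inverse = TRUE)) / prod(d)
  pa <- proj(va$grid)
  pb <- proj(vb$grid)
  oracle <- sum(pa * pb) / sqrt(sum(pa^2) * sum(pb^2))
  expect_equal(constrained_ccc(va, vb), oracle, tolerance = 1e-4)

  none <- tilt_scheme(-90, -89.9, 0.05)
  va2 <- va
  va2$wedge <- none
  expect_error(constrained_ccc(va2, vb), "empty Fourier support")
})

test_that("global alignment recovers known shifts", {
  ph <- default_phantom(seed = 2)
  true_vox <- rbind(c(3, -2, 0), c(-3, 1, 0), c(2, 3, 0),
                    c(0, 0, 0), c(-1, -3, 0))
  vols <- lapply(1:5, function(i)
    simulate_subtomogram(ph, tilt51, noise_model(snr = Inf),
                         pose = list(azimuth_deg = 0,
                                     shift_nm = true_vox[i, ] * 2.16),
                         rng_seed = i))
  ga <- align_global(vols, alignment_params())
  rec <- ga$shifts_nm / 2.16
  ctr <- sweep(true_vox, 2, colMeans(true_vox))
  expect_lt(max(abs(rec - ctr)), 0.5)
  expect_false(any(ga$flagged))
  # monotone convergence of the mean score
  expect_true(all(diff(ga$scores) > -1e-3))
})

test_that("a single particle aligns to itself with zero shift", {
  vols <- list(simulate_subtomogram(default_phantom(), tilt51,
                                    noise_model(snr = Inf)))
  ga <- align_global(vols, alignment_params())
  expect_equal(ga$shifts_nm, matrix(0, 1, 3))
  expect_equal(ga$average$grid, vols[[1]]$grid)
})

test_that("noisy shift recovery stays below one voxel on average", {
  ph <- default_phantom(seed = 3)
  set.seed(21)
  n <- 24
  true_sh <- cbind(rnorm(n, 0, 2), rnorm(n, 0, 2), 0) * 2.16
  true_sh <- pmin(pmax(true_sh, -6), 6)
  vols <- lapply(1:n, function(i)
    simulate_subtomogram(ph, tilt51, noise_model(snr = 0.1),
                         pose = list(azimuth_deg = 0,
                                     shift_nm = true_sh[i, ]),
                         rng_seed = 400 + i))
  ga <- align_global(vols, alignment_params())
  ctr <- sweep(true_sh, 2, colMeans(true_sh))
  resid <- sqrt(rowSums((ga$shifts_nm - ctr)^2)) / 2.16
  expect_lt(mean(resid), 1)
})

test_that("focused alignment recovers azimuths modulo the lattice", {
  phases <- c(0, 12, 25, 37, 48, 55, 3, 31)
  vols <- lapply(seq_along(phases), function(i) {
    ph <- default_phantom(phase_deg = phases[i])
    simulate_subtomogram(ph, tilt51, noise_model(snr = Inf), rng_seed = i)
  })
  fa <- align_focused(vols, alignment_params())
  err <- (fa$azimuths_deg - phases) %% 60
  err <- pmin(err, 60 - err)
  # up to one search step after removing the common lattice offset
  err <- err - stats::median(err)
  expect_lt(max(abs(err)), 5)
})

test_that("aligning randomly rotated copies raises C6 self-correlation", {
  phases <- seq(5, 355, by = 44)
  vols <- lapply(seq_along(phases), function(i) {
    ph <- default_phantom(phase_deg = phases[i])
    simulate_subtomogram(ph, tilt51, noise_model(snr = 1), rng_seed = 30 + i)
  })
  # C6 self-correlation of the azimuthal structure: circular correlation
  # of the centred interface profile with its 60-degree shift (a plain
  # voxel correlation is dominated by the rotationally symmetric
  # background and saturates near 1 for any blurry average)
  c6_selfcorr <- function(vol) {
    p <- azimuthal_profile(vol) - mean(azimuthal_profile(vol))
    sh <- 60 / (360 / length(p))
    cor(p, c(p[-(1:sh)], p[1:sh]))
  }
  before <- average_class(vols, rep(1, length(vols)), 1,
                          wedge_compensation = FALSE)
  before$meta$pm_z_nm <- vols[[1]]$meta$pm_z_nm
  fa <- align_focused(vols, alignment_params())
  after <- fa$average
  expect_gt(c6_selfcorr(after), c6_selfcorr(before))
})

test_that("MSA separates sizes and has non-increasing component variance", {
  ds <- msa_mix_dataset()
  f <- msa_features(ds$volumes, n_components = 5)
  sdev <- attr(f, "sdev")
  expect_true(all(diff(sdev) <= 1e-9))
  # the first component separates the two populations with no overlap
  small <- ds$table$component == 1
  rng_small <- range(f[small, 1])
  rng_big <- range(f[!small, 1])
  expect_true(rng_small[2] < rng_big[1] || rng_big[2] < rng_small[1])
  expect_error(msa_features(ds$volumes, n_components = 30),
               "cannot exceed")
})

test_that("identical particles give zero MSA scores", {
  v <- simulate_subtomogram(default_phantom(), tilt51,
                            noise_model(snr = Inf))
  f <- msa_features(list(v, v, v), n_components = 2)
  expect_lt(max(abs(f)), 1e-8)
})

test_that("HAC classification separates the size mixture exactly", {
  ds <- msa_mix_dataset()
  f <- msa_features(ds$volumes, n_components = 5)
  labs <- hac_classify(f, 2)
  expect_identical(length(unique(labs)), 2L)
  tab <- table(labs, ds$table$component)
  expect_identical(min(apply(tab, 1, max)) + min(apply(tab, 1, min)),
                   min(apply(tab, 1, max)))  # zero off-diagonal
  # singleton classes when n_classes = n
  labs1 <- hac_classify(f, nrow(f))
  expect_identical(sort(unique(labs1)), seq_len(nrow(f)))
  # clustering agreement is invariant under input shuffling
  set.seed(5)
  perm <- sample(nrow(f))
  labs_p <- hac_classify(f[perm, ], 2)
  expect_identical(labs_p, labs[perm])
})

test_that("size-class selection applies the diameter window", {
  d <- c(rnorm(30, 44, 0.5), rnorm(30, 58, 0.5), rnorm(30, 120, 2))
  labs <- rep(1:3, each = 30)
  sel <- select_size_class(d, labs, class_params())
  expect_identical(sel$classes_kept, 1L)
  expect_true(all(sel$selected[1:30]) && !any(sel$selected[-(1:30)]))
  expect_warning(select_size_class(rep(100, 10), rep(1:2, 5)),
                 "empty selection")
})

test_that("iterative refinement reaches the target homogeneity", {
  set.seed(9)
  d <- rnorm(150, 45, 5)
  rf <- refine_size_selection(d, class_params())
  expect_lte(rf$sd_nm, 2)
  expect_true(all(diff(rf$history) < 0))
  expect_lt(abs(rf$mean_nm - 45), 1.5)
})

test_that("class averaging preserves identical members and floors occupancy", {
  v <- simulate_subtomogram(default_phantom(), tilt51,
                            noise_model(snr = Inf))
  avg <- average_class(list(v, v, v), rep(1, 3), 1)
  expect_equal(avg$grid, v$grid, tolerance = 1e-6)
  expect_gte(avg$meta$occupancy_min, 0)
  expect_error(average_class(list(v), 2, 1), "no members")
})
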