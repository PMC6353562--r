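# Rotational symmetry detection, Cn averaging, and ring geometry.

# Azimuthal profile of a slab array: the slab is resampled onto a regular
# polar grid (bilinear interpolation, radial step of half a voxel), then
# averaged over z and over radius with area (r) weighting. Interpolated
# polar sampling avoids the angular aliasing that per-voxel azimuth
# binning shows when bins are narrower than a voxel. Bin centres at
# (k - 0.5) * 360 / n_bins.
azimuthal_profile_core <- function(g, x, y, annulus_nm, n_bins = 120L) {
  d <- dim(g)
  w <- x[2] - x[1]
  dr <- w / 2
  radii <- seq(annulus_nm[1] + dr / 2, annulus_nm[2] - dr / 2, by = dr)
  th <- (seq_len(n_bins) - 0.5) * 2 * pi / n_bins
  X <- outer(radii, cos(th))
  Y <- outer(radii, sin(th))
  ix <- (X - x[1]) / w + 1
  iy <- (Y - y[1]) / w + 1
  i0 <- pmin(pmax(floor(ix), 1), d[1] - 1)
  j0 <- pmin(pmax(floor(iy), 1), d[2] - 1)
  fx <- pmin(pmax(ix - i0, 0), 1)
  fy <- pmin(pmax(iy - j0, 0), 1)
  i00 <- i0 + (j0 - 1) * d[1]
  acc <- 0
  for (k in seq_len(d[3])) {
    sl <- g[, , k]
    acc <- acc + (1 - fx) * (1 - fy) * sl[i00] +
      fx * (1 - fy) * sl[i00 + 1] +
      (1 - fx) * fy * sl[i00 + d[1]] +
      fx * fy * sl[i00 + d[1] + 1]
  }
  pol <- acc / d[3]                      # radii x azimuth
  as.numeric(crossprod(pol, radii) / sum(radii))
}

#' Azimuthal density profile of the interface region
#'
#' @param vol a [density_volume()].
#' @param pm_z_nm membrane plane z (defaults to metadata).
#' @param slab_nm z-range above the plane.
#' @param annulus_nm radial window about the docking axis.
#' @param n_bins number of azimuth bins.
#' @return numeric vector of length `n_bins` (mean density per azimuth).
#' @export
azimuthal_profile <- function(vol, pm_z_nm = vol$meta$pm_z_nm,
                              slab_nm = c(2, 8), annulus_nm = c(8, 28),
                              n_bins = 120L) {
  iz <- slab_z_indices(vol, pm_z_nm, slab_nm)
  if (!length(iz)) stop("empty interface slab")
  ax <- vox_axes(vol)
  azimuthal_profile_core(vol$grid[, , iz, drop = FALSE], ax[[1]], ax[[2]],
                         annulus_nm, n_bins)
}

#' Radial density profile of the interface slab
#'
#' @inheritParams azimuthal_profile
#' @param r_max_nm outer radius of the profile.
#' @return data.frame with `r_nm` (bin centres) and `density`.
#' @export
radial_profile <- function(vol, pm_z_nm = vol$meta$pm_z_nm,
                           slab_nm = c(2, 8), r_max_nm = NULL) {
  iz <- slab_z_indices(vol, pm_z_nm, slab_nm)
  if (!length(iz)) stop("empty interface slab")
  ax <- vox_axes(vol)
  w <- vol$voxel_size_nm
  if (is.null(r_max_nm)) r_max_nm <- min(dim(vol$grid)[1:2]) / 2 * w
  rxy <- sqrt(outer(ax[[1]]^2, ax[[2]]^2, "+"))
  nb <- floor(r_max_nm / w)
  bins <- floor(rxy / w) + 1L
  sel <- bins <= nb
  b <- bins[sel]
  prof <- rep(0, nb)
  cnt <- rep(0, nb)
  for (k in iz) {
    s <- vol$grid[, , k][sel]
    prof <- prof + tabulate_sum(b, s, nb)
    cnt <- cnt + tabulate(b, nb)
  }
  data.frame(r_nm = (seq_len(nb) - 0.5) * w, density = prof / pmax(cnt, 1))
}

# normalized azimuthal harmonic power of a profile at the given orders:
# |c_n|^2 / sum over non-DC orders up to the profile Nyquist.
profile_power <- function(prof, orders) {
  co <- stats::fft(prof) / length(prof)
  nmax <- floor(length(prof) / 2)
  tot <- sum(Mod(co[2:(nmax + 1)])^2)
  if (tot == 0) return(stats::setNames(rep(0, length(orders)), orders))
  stats::setNames(Mod(co[orders + 1])^2 / tot, orders)
}

# circular Gaussian smoothing of a periodic profile (sd in bins)
circ_smooth <- function(p, sd_bins) {
  n <- length(p)
  k <- stats::dnorm(pmin(0:(n - 1), n - (0:(n - 1))), sd = sd_bins)
  k <- k / sum(k)
  Re(stats::fft(stats::fft(p) * stats::fft(k), inverse = TRUE)) / n
}

#' Rotational symmetry spectrum of the interface density
#'
#' Resamples the interface slab to an azimuthal profile, Fourier-transforms
#' it, and reports the normalized harmonic power at each tested order,
#' together with a detected order and its significance:
#'
#' * with per-particle `profiles` (rows = aligned particle azimuthal
#'   profiles, e.g. from [align_focused()]) the test is delegated to
#'   [symmetry_significance()]: by default the spectral-contrast t-test
#'   on per-particle power, whose statistic is invariant to how the
#'   particles were rotationally aligned, so alignment of pure noise
#'   cannot bias it (`method = "per_particle_power"`); random
#'   per-particle rotation scrambles of the mean profile are also
#'   available (`method = "mean_profile_scramble"`), though they
#'   overstate significance for individually structured but mutually
#'   disorganized particles;
#' * for a single map, contiguous blocks of the profile are permuted and
#'   each order's power is studentized against its own permutation null
#'   (`method = "block_scramble"`).
#'
#' @param vol a [density_volume()] (the map whose spectrum is reported).
#' @param pm_z_nm,slab_nm,annulus_nm,n_bins as [azimuthal_profile()].
#' @param orders integer orders to test (default 2:12).
#' @param profiles optional matrix of per-particle aligned profiles.
#' @param method significance scheme (see above); defaults to
#'   `"per_particle_power"` when `profiles` is given, else
#'   `"block_scramble"`.
#' @param n_perm number of permutations (default 499).
#' @param block_deg block width for block permutation schemes, degrees.
#' @param smooth_deg optional circular Gaussian smoothing (sd, degrees)
#'   applied to profiles before measuring power, matching the angular
#'   footprint of the map's working resolution at the annulus radius;
#'   permutation nulls are smoothed after scrambling so observed and null
#'   statistics are comparable.
#' @param rng_seed seed for the permutations.
#' @return object of class `symmetry_spectrum`: list with `orders`,
#'   `power` (normalized), `detected_order`, `p_value`, `method`.
#' @export
rotational_spectrum <- function(vol, pm_z_nm = vol$meta$pm_z_nm,
                                slab_nm = c(2, 8), annulus_nm = c(8, 28),
                                n_bins = 120L, orders = 2:12,
                                profiles = NULL, method = NULL,
                                n_perm = 499L, block_deg = 30,
                                smooth_deg = NULL, rng_seed = 1) {
  raw_prof <- azimuthal_profile(vol, pm_z_nm, slab_nm, annulus_nm, n_bins)
  sm <- if (is.null(smooth_deg) || smooth_deg <= 0) identity else
    function(p) circ_smooth(p, smooth_deg / (360 / length(p)))
  prof <- sm(raw_prof)
  pw <- profile_power(prof, orders)
  detected <- orders[which.max(pw)]
  if (is.null(method))
    method <- if (is.null(profiles)) "block_scramble" else
      "per_particle_power"
  method <- match.arg(method, c("per_particle_power",
                                "mean_profile_scramble", "block_scramble"))
  set.seed(rng_seed)
  nb <- n_bins
  bl <- max(1L, round(block_deg / (360 / nb)))
  nblk <- nb %/% bl

  block_permute <- function(p) {
    usable <- nblk * bl
    blocks <- matrix(p[seq_len(usable)], bl, nblk)
    out <- p
    out[seq_len(usable)] <- as.numeric(blocks[, sample.int(nblk)])
    out
  }

  if (method == "block_scramble") {
    st <- studentized_power_test(
      obs_all = pw,
      null_draw = function() profile_power(sm(block_permute(raw_prof)),
                                           orders),
      orders = orders, n_perm = n_perm)
  } else {
    st <- symmetry_significance(profiles, orders = orders, method = method,
                                n_perm = n_perm, block_deg = block_deg,
                                smooth_deg = smooth_deg,
                                wedge_orders = if (is.null(vol$wedge) &&
                                                   is.null(vol$meta$n_members))
                                  integer(0) else 2L,
                                rng_seed = rng_seed)
  }
  structure(list(orders = orders, power = pw,
                 detected_order = st$detected_order, z = st$z,
                 p_value = st$p_value, method = method, profile = prof),
            class = "symmetry_spectrum")
}

# Studentized max-over-orders permutation test: polar resampling and
# smoothing leave the noise spectrum coloured (low orders ride a higher
# baseline), so each order's power is standardized against its own
# permutation null before taking the maximum over orders; the same max-z
# statistic is evaluated on the null draws themselves for the p-value.
studentized_power_test <- function(obs_all, null_draw, orders, n_perm) {
  null_mat <- t(replicate(n_perm, null_draw()))
  mu <- colMeans(null_mat)
  sdv <- pmax(apply(null_mat, 2, stats::sd), 1e-12)
  z_obs <- (obs_all - mu) / sdv
  null_z <- sweep(sweep(null_mat, 2, mu), 2, sdv, "/")
  list(detected_order = orders[which.max(z_obs)],
       z = stats::setNames(z_obs, orders),
       p_value = (1 + sum(apply(null_z, 1, max) >= max(z_obs))) /
         (n_perm + 1))
}

#' Significance of rotational symmetry from particle profiles
#'
#' The profile-level half of [rotational_spectrum()], usable without a
#' map: given per-particle azimuthal interface profiles, tests whether
#' some rotational order carries more power than expected under
#' independently placed modules.
#'
#' `"per_particle_power"` (default) is a spectral-contrast t-test on the
#' per-particle normalized harmonic power: the power at each order is
#' compared with the mean of its two neighbours (the smooth module
#' form-factor envelope cancels; a shared lattice does not), and the
#' paired differences are t-tested across particles with a Bonferroni
#' correction over orders. The statistic is rotation-invariant per
#' particle, so alignment of pure noise cannot bias it.
#' `"mean_profile_scramble"` instead scores the mean aligned profile
#' against random per-particle rotations; note that rotational alignment
#' to a common reference also coheres unrelated per-particle structure,
#' so this scheme overstates significance for particles that are
#' individually structured but mutually disorganized.
#'
#' @param profiles matrix of aligned per-particle azimuthal profiles
#'   (rows = particles).
#' @param wedge_orders orders excluded from testing and from baselines
#'   under `"per_particle_power"` because the single-axis missing wedge
#'   imprints them on every particle (default: order 2); set to
#'   `integer(0)` for full-support data.
#' @inheritParams rotational_spectrum
#' @return list with `detected_order`, `z` (per-order standardized
#'   excess power), `p_value`, `power` (the observed per-order statistic).
#' @export
symmetry_significance <- function(profiles, orders = 2:12,
                                  method = c("per_particle_power",
                                             "mean_profile_scramble"),
                                  n_perm = 499L, block_deg = 30,
                                  smooth_deg = NULL, wedge_orders = 2L,
                                  rng_seed = 1) {
  if (is.null(profiles) || !is.matrix(profiles))
    stop("`profiles` must be a matrix of per-particle profiles")
  method <- match.arg(method)
  nb <- ncol(profiles)
  sm <- if (is.null(smooth_deg) || smooth_deg <= 0) identity else
    function(p) circ_smooth(p, smooth_deg / (360 / nb))
  set.seed(rng_seed)
  bl <- max(1L, round(block_deg / (360 / nb)))
  nblk <- nb %/% bl
  block_permute <- function(p) {
    usable <- nblk * bl
    blocks <- matrix(p[seq_len(usable)], bl, nblk)
    out <- p
    out[seq_len(usable)] <- as.numeric(blocks[, sample.int(nblk)])
    out
  }
  if (method == "per_particle_power") {
    # spectral-contrast t-test: under disorganized (independently placed)
    # modules the expected per-particle power is a smooth function of the
    # order (module form factor x flat placement spectrum), while a
    # shared lattice concentrates power at its order. The statistic is,
    # per particle, the power at order n minus the mean of the
    # neighbouring orders; a paired one-sided t-test across particles is
    # self-calibrating (cross-particle variability sets the scale) and
    # independent of how the particles were rotationally aligned.
    # Orders in `wedge_orders` are excluded as candidates and baselines:
    # a single-axis missing wedge attenuates the interface azimuthally
    # with 180-degree periodicity, imprinting fixed order-2 power on
    # every particle regardless of module organization.
    tested <- setdiff(orders, wedge_orders)
    ext <- sort(unique(c(tested, tested - 1, tested + 1)))
    ext <- ext[ext >= 1 & ext <= floor(nb / 2) - 1]
    PP <- t(apply(profiles, 1, function(p) profile_power(sm(p), ext)))
    n <- nrow(PP)
    good_nb <- function(o) {
      cand <- setdiff(c(o - 1, o + 1), wedge_orders)
      cand <- cand[cand %in% ext]
      if (!length(cand)) cand <- intersect(c(o - 2, o + 2), ext)
      cand
    }
    tt <- vapply(tested, function(o) {
      i <- match(o, ext)
      nbs <- match(good_nb(o), ext)
      if (!length(nbs)) return(c(0, 1))
      nb_mean <- rowMeans(PP[, nbs, drop = FALSE])
      D <- PP[, i] - nb_mean
      if (n < 3 || stats::sd(D) == 0) return(c(0, 1))
      tv <- mean(D) / (stats::sd(D) / sqrt(n))
      c(tv, stats::pt(tv, n - 1, lower.tail = FALSE))
    }, numeric(2))
    # prefer the fundamental: a Cn lattice also powers its harmonics, so
    # among clearly significant orders discard integer multiples of other
    # significant orders and keep the strongest of the rest
    alpha_adj <- 0.05 / length(tested)
    so <- tested[tt[2, ] < alpha_adj]
    detected <- if (length(so)) {
      fund <- so[!vapply(so, function(o)
        any(so != o & o %% so == 0), logical(1))]
      fund[which.max(tt[1, match(fund, tested)])]
    } else tested[which.max(tt[1, ])]
    obs_all <- colMeans(PP)[match(tested, ext)]
    st <- list(detected_order = detected,
               z = stats::setNames(tt[1, ], tested),
               p_value = min(1, length(tested) * min(tt[2, ])))
  } else {
    obs_all <- profile_power(sm(colMeans(profiles)), orders)
    n <- nrow(profiles)
    st <- studentized_power_test(
      obs_all, function() {
        rot <- sample.int(nb, n, replace = TRUE) - 1L
        m <- colMeans(t(vapply(seq_len(n), function(i) {
          p <- profiles[i, ]
          k <- rot[i]
          if (k == 0L) p else c(p[(k + 1):nb], p[seq_len(k)])
        }, numeric(nb))))
        profile_power(sm(m), orders)
      }, orders, n_perm)
  }
  st$power <- obs_all
  st
}

#' @export
print.symmetry_spectrum <- function(x, ...) {
  cat(sprintf("symmetry spectrum: detected order %d (power %.3f), p = %.4g [%s]\n",
              x$detected_order, max(x$power), x$p_value, x$method))
  invisible(x)
}

#' Impose n-fold rotational symmetry
#'
#' Averages a map with its `n - 1` copies rotated by multiples of
#' `360 / n` degrees about the docking axis. The output records
#' `meta$symmetry_imposed = n`: an imposed symmetry is a processing choice,
#' not a detection, and downstream reports flag it as such (symmetrizing a
#' disorganized average can manufacture apparent ring structure).
#'
#' @param vol a [density_volume()].
#' @param n symmetry order (>= 1).
#' @return the symmetrized [density_volume()].
#' @export
symmetrize_cn <- function(vol, n) {
  stopifnot(is_density_volume(vol), n >= 1)
  if (n == 1) return(vol)
  d <- dim(vol$grid)
  acc <- vol$grid
  for (k in seq_len(n - 1))
    acc <- acc + rotate_grid_z(vol$grid, 360 * k / n)
  out <- vol
  out$grid <- acc / n
  out$meta$symmetry_imposed <- as.integer(n)
  out
}

#' Interface ring measurement
#'
#' Finds azimuthal peaks of the interface profile (with circular
#' wrap-around and a prominence threshold), their circular spacings
#' (which sum to 360 degrees), and the ring diameter as twice the radial
#' position of the on-peak excess density. The measurement is two-pass:
#' peaks found over the full annulus give a first ring-radius estimate,
#' and the final peak set is read from an annulus focused on the ring
#' (+/- `ring_halfwidth_nm`), which suppresses off-ring clutter.
#'
#' @inheritParams azimuthal_profile
#' @param min_prominence peak prominence threshold as a fraction of the
#'   most prominent peak (default 0.5): secondary bumps well below the
#'   dominant density peaks are not counted.
#' @param smooth_bins light circular smoothing of the profile before
#'   peak finding (bins; breaks the flat tops of noiseless rod
#'   profiles).
#' @param ring_halfwidth_nm radial half-width of the focused second-pass
#'   annulus about the measured ring radius.
#' @param expected_n optional peak count, typically the rotational order
#'   detected by the calibrated significance test: the `expected_n` most
#'   prominent maxima are reported and their positions and spacings
#'   measured, instead of thresholding prominences. On noisy class
#'   averages the weakest genuine density peak and the strongest clutter
#'   bump can have comparable prominence, so a fixed threshold
#'   over- or under-counts, while the prominence ranking stays correct;
#'   the count itself is then established by the order test, not by the
#'   map's maxima.
#' @return object of class `ring_measurement`: `n_peaks`,
#'   `peak_azimuths_deg`, `spacings_deg`, `ring_diameter_nm`,
#'   `peak_prominences`, and the profiles used.
#' @export
ring_peaks <- function(vol, pm_z_nm = vol$meta$pm_z_nm, slab_nm = c(2, 8),
                       annulus_nm = c(8, 28), n_bins = 180L,
                       min_prominence = 0.5, smooth_bins = 1,
                       ring_halfwidth_nm = 6, expected_n = NULL) {
  step <- 360 / n_bins

  # circular peak finding with true prominences: a peak's prominence is
  # its height above the higher of the lowest points on the way to the
  # nearest higher profile value on each side (the global maximum keys
  # off the global minimum); peaks well below the dominant one are not
  # counted, and an essentially uniform profile has no peaks
  find_peaks <- function(prof) {
    rng <- diff(range(prof))
    if (rng <= 0 || rng < 0.1 * max(abs(mean(prof)), 1e-12)) return(NULL)
    cand <- which(prof > c(prof[n_bins], prof[-n_bins]) &
                    prof >= c(prof[-1], prof[1]))
    if (!length(cand)) return(NULL)
    prom <- vapply(cand, function(i) {
      v <- prof[i]
      walk <- function(dir) {
        lo <- v
        j <- i
        for (s in seq_len(n_bins - 1)) {
          j <- ((j - 1 + dir) %% n_bins) + 1
          if (prof[j] > v) return(lo)
          lo <- min(lo, prof[j])
        }
        lo
      }
      v - max(walk(1L), walk(-1L))
    }, numeric(1))
    keep <- if (is.null(expected_n)) {
      prom >= min_prominence * max(prom)
    } else {
      # rank by prominence, keep the expected number (micro-ripples floor)
      ok <- prom >= 0.05 * max(prom)
      rank(-prom, ties.method = "first") <= expected_n & ok
    }
    if (!any(keep)) return(NULL)
    idx <- cand[keep]
    off <- vapply(idx, function(i) {
      y <- prof[((i + (-2:0)) %% n_bins) + 1]
      parabolic_offset(y, 2)
    }, numeric(1))
    list(az = ((idx - 0.5 + off) * step) %% 360, prom = prom[keep])
  }

  smooth_prof <- function(p) if (smooth_bins > 0) circ_smooth(p, smooth_bins)
    else p

  # pass 1: peaks over the full annulus -> first ring-radius estimate
  prof <- smooth_prof(azimuthal_profile(vol, pm_z_nm, slab_nm, annulus_nm,
                                        n_bins))
  pk <- find_peaks(prof)

  # Ring radius: radial centroid of the on-peak excess density. Narrow
  # sectors centred on the detected peak azimuths sample the module
  # interior at every radius (no 1/r geometry), and subtracting the
  # radial profile of equally narrow trough sectors (midway between
  # peaks) cancels everything azimuth-uniform: membrane and vesicle-cap
  # smear from the missing wedge, and the central mass.
  rp <- radial_profile(vol, pm_z_nm, slab_nm,
                       r_max_nm = annulus_nm[2] + 4)
  inwin <- which(rp$r_nm >= annulus_nm[1] & rp$r_nm <= annulus_nm[2])
  ring_radius <- function(pk) {
    dens <- rp$density[inwin]
    if (!is.null(pk) && length(pk$az) > 1) {
      az <- sort(pk$az)
      trough <- (az + c(diff(az), 360 - (az[length(az)] - az[1])) / 2) %% 360
      hw <- min(5, 90 / length(az))
      sect_in <- radial_profile_sectors(vol, pm_z_nm, slab_nm,
                                        r_max_nm = annulus_nm[2] + 4,
                                        az_deg = az, half_width_deg = hw)
      sect_out <- radial_profile_sectors(vol, pm_z_nm, slab_nm,
                                         r_max_nm = annulus_nm[2] + 4,
                                         az_deg = trough, half_width_deg = hw)
      dens <- (sect_in - sect_out)[inwin]
    }
    wgt <- pmax(dens - min(dens), 0)
    if (sum(wgt) > 0) sum(rp$r_nm[inwin] * wgt) / sum(wgt) else
      rp$r_nm[inwin[which.max(rp$density[inwin])]]
  }
  r_peak <- ring_radius(pk)

  # pass 2: re-read the peaks from an annulus focused on the ring, which
  # suppresses off-ring clutter, then refine the radius with the final
  # peak set
  ann2 <- c(max(annulus_nm[1], r_peak - ring_halfwidth_nm),
            min(annulus_nm[2], r_peak + ring_halfwidth_nm))
  if (diff(ann2) > 2 * vol$voxel_size_nm) {
    prof2 <- smooth_prof(azimuthal_profile(vol, pm_z_nm, slab_nm, ann2,
                                           n_bins))
    pk2 <- find_peaks(prof2)
    if (!is.null(pk2)) {
      pk <- pk2
      prof <- prof2
      r_peak <- ring_radius(pk)
    }
  }
  if (is.null(pk)) {
    res <- list(n_peaks = 0L, peak_azimuths_deg = numeric(0),
                spacings_deg = numeric(0),
                ring_diameter_nm = 2 * r_peak,
                peak_prominences = numeric(0))
  } else {
    o <- order(pk$az)
    az <- pk$az[o]
    sp <- if (length(az) > 1) c(diff(az), 360 - (az[length(az)] - az[1]))
      else 360
    res <- list(n_peaks = length(az), peak_azimuths_deg = az,
                spacings_deg = sp, ring_diameter_nm = 2 * r_peak,
                peak_prominences = pk$prom[o])
  }
  res$azimuthal_profile <- prof
  res$radial_profile <- rp
  res$symmetry_imposed <- vol$meta$symmetry_imposed
  structure(res, class = "ring_measurement")
}

#' @export
print.ring_measurement <- function(x, ...) {
  cat(sprintf("ring: %d peaks, diameter %.1f nm%s\n", x$n_peaks,
              x$ring_diameter_nm,
              if (!is.null(x$symmetry_imposed))
                sprintf(" [C%d symmetry imposed, not detected]",
                        x$symmetry_imposed) else ""))
  if (x$n_peaks > 1)
    cat(sprintf("  spacings: %s deg\n",
                paste(sprintf("%.1f", x$spacings_deg), collapse = ", ")))
  invisible(x)
}

# Mean radial profile restricted to narrow azimuthal sectors centred on
# the given azimuths (degrees).
radial_profile_sectors <- function(vol, pm_z_nm, slab_nm, r_max_nm,
                                   az_deg, half_width_deg) {
  iz <- slab_z_indices(vol, pm_z_nm, slab_nm)
  ax <- vox_axes(vol)
  w <- vol$voxel_size_nm
  rxy <- sqrt(outer(ax[[1]]^2, ax[[2]]^2, "+"))
  th <- (atan2(rep(ax[[2]], each = length(ax[[1]])),
               rep(ax[[1]], times = length(ax[[2]]))) / pi * 180) %% 360
  dmin <- apply(vapply(az_deg, function(a) {
    d <- abs(th - a) %% 360
    pmin(d, 360 - d)
  }, numeric(length(th))), 1, min)
  insec <- matrix(dmin <= half_width_deg, nrow(rxy), ncol(rxy))
  nb <- floor(r_max_nm / w)
  bins <- floor(rxy / w) + 1L
  s2 <- (bins <= nb) & insec
  b <- bins[s2]
  prof <- rep(0, nb)
  cnt <- rep(0, nb)
  for (k in iz) {
    prof <- prof + tabulate_sum(b, vol$grid[, , k][s2], nb)
    cnt <- cnt + tabulate(b, nb)
  }
  prof / pmax(cnt, 1)
}

#' Connected suprathreshold structure at sigma levels
#'
#' For each level `mean + k * sd` (map statistics computed with a border
#' margin excluded), labels the 6-connected components of the
#' suprathreshold voxels inside the interface region and reports, per
#' component, its voxel volume and centroid, and whether it is central
#' (centroid within `central_radius_nm` of the docking axis).
#'
#' @param vol a [density_volume()].
#' @param levels numeric vector of sigma multipliers (default `c(1, 2)`).
#' @param pm_z_nm,slab_nm membrane plane and slab as elsewhere.
#' @param r_max_nm lateral extent of the interface region considered.
#' @param central_radius_nm components with centroid radius below this are
#'   classed as central.
#' @param border_vox border margin excluded from the map statistics.
#' @param min_voxels ignore components smaller than this.
#' @return object of class `sigma_structure`: per-level data.frames with
#'   one row per component (`voxels`, `volume_nm3`, `x_nm`, `y_nm`,
#'   `z_nm`, `r_nm`, `central`), plus `mean`, `sd`, `thresholds`.
#' @export
sigma_structure <- function(vol, levels = c(1, 2),
                            pm_z_nm = vol$meta$pm_z_nm, slab_nm = c(2, 8),
                            r_max_nm = NULL, central_radius_nm = 6,
                            border_vox = 2, min_voxels = 2) {
  stopifnot(is_density_volume(vol))
  d <- dim(vol$grid)
  inner <- vol$grid[(border_vox + 1):(d[1] - border_vox),
                    (border_vox + 1):(d[2] - border_vox),
                    (border_vox + 1):(d[3] - border_vox)]
  mu <- mean(inner)
  sdev <- stats::sd(inner)
  if (!is.finite(sdev) || sdev == 0)
    stop("constant map: sigma levels are undefined")
  iz <- slab_z_indices(vol, pm_z_nm, slab_nm)
  if (!length(iz)) stop("empty interface slab")
  ax <- vox_axes(vol)
  if (is.null(r_max_nm)) r_max_nm <- min(d[1:2]) / 2 * vol$voxel_size_nm - 2
  rxy <- sqrt(outer(ax[[1]]^2, ax[[2]]^2, "+"))
  region2d <- rxy <= r_max_nm

  out <- list()
  thr <- mu + levels * sdev
  for (li in seq_along(levels)) {
    sub <- vol$grid[, , iz, drop = FALSE]
    m <- array(FALSE, dim(sub))
    for (k in seq_along(iz)) m[, , k] <- sub[, , k] > thr[li] & region2d
    lab <- label_components_3d(m)
    comps <- data.frame(voxels = integer(0), volume_nm3 = numeric(0),
                        x_nm = numeric(0), y_nm = numeric(0),
                        z_nm = numeric(0), r_nm = numeric(0),
                        central = logical(0))
    if (max(lab) > 0) {
      idx <- which(lab > 0)
      ai <- arrayInd(idx, dim(lab))
      lv <- lab[idx]
      xs <- ax[[1]][ai[, 1]]
      ys <- ax[[2]][ai[, 2]]
      zs <- ax[[3]][iz][ai[, 3]]
      cx <- tapply(xs, lv, mean)
      cy <- tapply(ys, lv, mean)
      cz <- tapply(zs, lv, mean)
      nvx <- tabulate(lv)
      keep <- nvx >= min_voxels
      rr <- sqrt(cx^2 + cy^2)
      comps <- data.frame(voxels = nvx[keep],
                          volume_nm3 = nvx[keep] * vol$voxel_size_nm^3,
                          x_nm = as.numeric(cx[keep]),
                          y_nm = as.numeric(cy[keep]),
                          z_nm = as.numeric(cz[keep]),
                          r_nm = as.numeric(rr[keep]),
                          central = as.numeric(rr[keep]) < central_radius_nm)
    }
    out[[sprintf("sigma_%g", levels[li])]] <- comps
  }
  structure(list(levels = levels, thresholds = thr, mean = mu, sd = sdev,
                 components = out), class = "sigma_structure")
}

# 6-connected component labelling of a logical 3D array (iterative BFS).
label_components_3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  nxt <- 0L
  nxy <- d[1] * d[2]
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      ai <- arrayInd(cur, d)
      for (off in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                       c(0, 0, -1), c(0, 0, 1))) {
        ni <- sweep(ai, 2, off, "+")
        ok <- ni[, 1] >= 1 & ni[, 1] <= d[1] & ni[, 2] >= 1 &
          ni[, 2] <= d[2] & ni[, 3] >= 1 & ni[, 3] <= d[3]
        if (!any(ok)) next
        lin <- ni[ok, 1] + (ni[ok, 2] - 1) * d[1] + (ni[ok, 3] - 1) * nxy
        new <- lin[mask[lin] & lab[lin] == 0L]
        if (length(new)) {
          lab[new] <- nxt
          queue <- c(queue, new)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}
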