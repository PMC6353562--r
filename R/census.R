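# Vesicle detection, diameter estimation, and the docked-vesicle criterion.

#' Vesicle diameter from a cross-section area
#'
#' Converts the area of an (equatorial) vesicle cross-section to a
#' diameter under the sphere assumption: `d = 2 * sqrt(area / pi)`.
#'
#' @param area_nm2 cross-section area(s) in nm^2 (> 0).
#' @return diameter(s) in nm.
#' @export
diameter_from_area <- function(area_nm2) {
  if (any(!is.finite(area_nm2)) || any(area_nm2 <= 0))
    stop("`area_nm2` must be positive")
  2 * sqrt(area_nm2 / pi)
}

# Wrap-centred spherical-shell template for matched filtering: the shell
# minus its mean over a ball support just enclosing it, zero outside.
# Confining the zero-mean background to the ball keeps nearby structure
# (the planar membrane one docking gap below, the interface assembly)
# out of the comparison.
shell_template <- function(dims, voxel_nm, outer_radius_nm, thickness_nm) {
  w <- voxel_nm
  ax <- lapply(dims, function(n) {
    i <- seq_len(n) - 1
    pmin(i, n - i) * w  # wrapped distance from voxel (1,1,1)
  })
  r <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+"))
  t <- ramp_in(r - (outer_radius_nm - thickness_nm), w) *
    ramp_in(outer_radius_nm - r, w)
  ball <- ramp_in(outer_radius_nm + 2 - r, w)
  (t - sum(t * ball) / sum(ball)) * ball
}

#' Detect vesicles by spherical-shell template matching
#'
#' Scans a discrete set of outer diameters with zero-mean spherical-shell
#' matched filters (membrane-thickness shells), keeps the best-matching
#' diameter per position, and extracts peaks by greedy non-maximum
#' suppression so accepted centres are at least one vesicle radius apart.
#'
#' @param vol a [density_volume()].
#' @param diameter_range_nm length-2 vector of outer diameters to search.
#' @param step_nm diameter step of the search grid (default: 2 voxels).
#' @param membrane_thickness_nm shell thickness of the template.
#' @param min_z_score noise-floor threshold on the matched-filter
#'   response, in robust standard deviations above the response median.
#' @param min_rel_amplitude additionally require the fitted shell
#'   amplitude to reach this fraction of the strongest response in the
#'   volume (suppresses partial matches, e.g. the template grazing the
#'   planar membrane).
#' @param refine_diameter refine each accepted diameter below the grid
#'   step by parabolic interpolation of the matched-filter response
#'   across the radius grid.
#' @param pm_z_nm membrane plane z (nm); when known, the gap between the
#'   vesicle periphery and the plane is reported.
#' @return data.frame with one row per detection: `center_x_nm`,
#'   `center_y_nm`, `center_z_nm`, `diameter_nm`, `score`,
#'   `distance_to_pm_nm` (NA when no plane given).
#' @export
detect_vesicles <- function(vol, diameter_range_nm,
                            step_nm = 2 * vol$voxel_size_nm,
                            membrane_thickness_nm = 5,
                            min_z_score = 7, min_rel_amplitude = 0.5,
                            refine_diameter = TRUE,
                            pm_z_nm = vol$meta$pm_z_nm) {
  stopifnot(is_density_volume(vol), length(diameter_range_nm) == 2)
  d <- dim(vol$grid)
  L <- d * vol$voxel_size_nm
  if (any(diameter_range_nm <= 0) || max(diameter_range_nm) > min(L))
    stop("diameter range must be positive and fit inside the box")
  dias <- seq(diameter_range_nm[1], diameter_range_nm[2], by = step_nm)

  FV <- fft(vol$grid)
  # templates carry the same missing wedge as the data, so the response
  # peak over the radius grid is a model-matched diameter estimate
  WM <- if (is.null(vol$wedge)) NULL else
    wedge_mask(d, vol$wedge, vol$meta$wedge_azimuth_deg %||% 0)
  best <- array(-Inf, d)
  best_dia <- array(dias[1], d)
  resp_all <- vector("list", length(dias))
  for (ri in seq_along(dias)) {
    tmpl <- shell_template(d, vol$voxel_size_nm, dias[ri] / 2,
                           membrane_thickness_nm)
    FT <- fft(tmpl)
    if (!is.null(WM)) FT[!WM] <- 0
    # amplitude (projection-coefficient) normalization: the response
    # estimates the shell density, comparable across radii
    resp <- Re(fft(FV * Conj(FT), inverse = TRUE)) / prod(d) /
      max(sum(Mod(FT)^2) / prod(d), 1e-12)
    resp_all[[ri]] <- resp
    upd <- resp > best
    best[upd] <- resp[upd]
    best_dia[upd] <- dias[ri]
  }

  sdr <- stats::mad(best)
  if (!is.finite(sdr) || sdr == 0) sdr <- stats::sd(best)
  if (!is.finite(sdr) || sdr == 0) return(empty_vesicle_table())
  thr <- max(stats::median(best) + min_z_score * sdr,
             min_rel_amplitude * max(best))
  # candidates must also be local maxima of the response field
  locmax <- array(TRUE, d)
  for (a in 1:3) for (s in c(-1, 1)) {
    shifted <- shift_int(best, a, s)
    locmax <- locmax & best >= shifted
  }
  cand <- which(best > thr & locmax, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty_vesicle_table())
  sc <- best[cand]
  o <- order(sc, decreasing = TRUE)
  cand <- cand[o, , drop = FALSE]
  sc <- sc[o]

  ax <- vox_axes(vol)
  acc <- list()
  for (i in seq_len(nrow(cand))) {
    # sub-voxel centre from a parabolic fit of the response field
    ijk <- cand[i, ]
    off <- vapply(1:3, function(a) {
      lo <- ijk
      hi <- ijk
      lo[a] <- max(1, ijk[a] - 1)
      hi[a] <- min(d[a], ijk[a] + 1)
      y <- c(best[lo[1], lo[2], lo[3]], best[ijk[1], ijk[2], ijk[3]],
             best[hi[1], hi[2], hi[3]])
      parabolic_offset(y, 2)
    }, numeric(1))
    p_nm <- c(ax[[1]][ijk[1]], ax[[2]][ijk[2]], ax[[3]][ijk[3]]) +
      off * vol$voxel_size_nm
    dia <- best_dia[ijk[1], ijk[2], ijk[3]]
    keep <- TRUE
    for (a in acc) {
      if (sqrt(sum((p_nm - a$p)^2)) < max(a$dia, dia) / 2) {
        keep <- FALSE
        break
      }
    }
    if (keep) acc[[length(acc) + 1]] <- list(p = p_nm, dia = dia,
                                             score = sc[i], ijk = ijk)
  }

  rows <- lapply(acc, function(a) {
    dia <- a$dia
    if (refine_diameter) {
      # parabolic interpolation of the matched-filter response across
      # the radius grid at the detected centre
      ri <- which.min(abs(dias - dia))
      if (ri > 1 && ri < length(dias)) {
        y <- vapply(ri + (-1:1), function(j)
          resp_all[[j]][a$ijk[1], a$ijk[2], a$ijk[3]], numeric(1))
        dia <- dias[ri] + parabolic_offset(y, 2) * step_nm
      }
    }
    data.frame(center_x_nm = a$p[1], center_y_nm = a$p[2],
               center_z_nm = a$p[3], diameter_nm = dia, score = a$score,
               distance_to_pm_nm = if (is.null(pm_z_nm)) NA_real_ else
                 (a$p[3] - dia / 2) - pm_z_nm)
  })
  do.call(rbind, rows)
}

# integer circular shift of a 3D array along one axis
shift_int <- function(a, axis, s) {
  n <- dim(a)[axis]
  idx <- ((seq_len(n) - 1 - s) %% n) + 1
  switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

empty_vesicle_table <- function() {
  data.frame(center_x_nm = numeric(0), center_y_nm = numeric(0),
             center_z_nm = numeric(0), diameter_nm = numeric(0),
             score = numeric(0), distance_to_pm_nm = numeric(0))
}

#' Refine a vesicle diameter by an equatorial-band sphere fit
#'
#' For each xy slice in a band about the vesicle centre, the
#' membrane-shell circle radius is measured as the baseline-subtracted
#' centroid of the slice's radial density profile (half-voxel bins,
#' lightly smoothed) near its peak. Under the sphere assumption those
#' per-slice radii obey `r(z)^2 = R^2 - (z - z0)^2`, so `r^2 + z^2` is
#' linear in `z`; an ordinary least-squares line gives the mid-shell
#' sphere radius `R` and the true equator `z0` simultaneously, making the
#' estimate insensitive to errors in the detected centre along z (the
#' axis blurred by the missing wedge). The outer diameter is
#' `2 R + thickness`.
#'
#' @param vol a [density_volume()].
#' @param center_nm vesicle centre, world nm (z may be approximate).
#' @param diameter_range_nm outer-diameter search window.
#' @param membrane_thickness_nm assumed shell thickness.
#' @param diameter_hint_nm approximate diameter (e.g. the best-matching
#'   template of [detect_vesicles()]), used to choose the slice band;
#'   `NULL` falls back to the window midpoint.
#' @return estimated outer diameter (nm), or NA if no shell is found.
#' @export
fit_vesicle_diameter <- function(vol, center_nm, diameter_range_nm,
                                 membrane_thickness_nm = 5,
                                 diameter_hint_nm = NULL) {
  ax <- vox_axes(vol)
  w <- vol$voxel_size_nm
  t <- membrane_thickness_nm
  hint <- diameter_hint_nm %||% mean(diameter_range_nm)
  band <- max(2 * w, 0.3 * hint / 2)
  iz <- which(abs(ax[[3]] - center_nm[3]) <= band)
  if (!length(iz)) return(NA_real_)
  rxy <- sqrt(outer((ax[[1]] - center_nm[1])^2,
                    (ax[[2]] - center_nm[2])^2, "+"))
  bw <- w / 2
  nb <- floor((diameter_range_nm[2] / 2 + t) / bw)
  if (nb < 4) return(NA_real_)
  bins <- floor(rxy / bw) + 1L
  sel <- bins <= nb
  bsel <- bins[sel]
  cnt <- tabulate(bsel, nb)
  r_mid <- (seq_len(nb) - 0.5) * bw
  lo <- diameter_range_nm[1] / 2 - t / 2
  hi <- diameter_range_nm[2] / 2 - t / 2
  inwin <- which(r_mid >= lo & r_mid <= hi)
  if (!length(inwin)) return(NA_real_)

  slice_prof <- function(k) {
    prof <- tabulate_sum(bsel, vol$grid[, , k][sel], nb) / pmax(cnt, 1)
    prof <- as.numeric(stats::filter(prof, rep(1 / 3, 3)))
    prof[is.na(prof)] <- 0
    prof
  }
  profs <- vapply(iz, slice_prof, numeric(nb))
  # locate the shell window once, on the band-summed profile: per-slice
  # peak picking is noise-biased towards the sparsely sampled inner bins
  prof_all <- rowSums(profs)
  i_all <- inwin[which.max(prof_all[inwin])]
  wd <- which(abs(r_mid - r_mid[i_all]) <= t)
  fits <- apply(profs, 2, function(prof) {
    pw <- pmax(prof[wd] - min(prof[wd]), 0)
    if (sum(pw) == 0) return(c(NA_real_, 0))
    c(sum(r_mid[wd] * pw) / sum(pw), max(prof[wd]))
  })
  ok <- is.finite(fits[1, ]) & fits[2, ] >= 0.5 * max(fits[2, ])
  if (sum(ok) < 3) {
    # too few usable slices: fall back to the single best slice
    if (!any(ok)) return(NA_real_)
    k <- which.max(fits[2, ])
    return(2 * fits[1, k] + t)
  }
  z <- ax[[3]][iz][ok]
  y <- fits[1, ok]^2 + z^2          # = (R^2 - z0^2) + 2 z0 z
  co <- stats::coef(stats::lm(y ~ z))
  z0 <- co[2] / 2
  R2 <- co[1] + z0^2
  if (!is.finite(R2) || R2 <= 0) return(NA_real_)
  unname(2 * sqrt(R2) + t)
}

# sum of `x` per integer bin (like tabulate, but summing weights)
tabulate_sum <- function(bin, x, nbins) {
  out <- numeric(nbins)
  s <- rowsum(x, bin)  # rownames: sorted unique bins
  out[as.integer(rownames(s))] <- s
  out
}

# 3-point parabolic sub-bin peak offset in [-0.5, 0.5]
parabolic_offset <- function(y, i) {
  if (i <= 1 || i >= length(y)) return(0)
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom >= 0) return(0)
  off <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  max(-0.5, min(0.5, off))
}

#' Apply the docked-vesicle criterion
#'
#' A vesicle is docked when (a) the gap between its periphery and the
#' membrane plane does not exceed `proximity_nm`, and (b) the cylindrical
#' corridor of one vesicle radius between its periphery and the plane
#' contains no labelled organelle voxel (the automated surrogate for
#' requiring the absence of any organelle between the vesicle and the cell
#' boundary).
#'
#' @param records data.frame of detections ([detect_vesicles()] columns).
#' @param pm_z_nm membrane plane z, world nm.
#' @param label_volume optional [density_volume()] whose grid holds
#'   positive integer organelle labels on the same frame as the source.
#' @param proximity_nm proximity threshold on the periphery-plane gap.
#' @return `records` with columns `distance_to_pm_nm`, `clearance_ok`,
#'   `docked` filled in.
#' @export
classify_docked <- function(records, pm_z_nm, label_volume = NULL,
                            proximity_nm = 20) {
  if (!nrow(records)) {
    records$clearance_ok <- logical(0)
    records$docked <- logical(0)
    return(records)
  }
  gap <- (records$center_z_nm - records$diameter_nm / 2) - pm_z_nm
  records$distance_to_pm_nm <- gap
  clearance <- rep(TRUE, nrow(records))
  if (!is.null(label_volume)) {
    stopifnot(is_density_volume(label_volume))
    ax <- vox_axes(label_volume)
    w <- label_volume$voxel_size_nm
    for (i in seq_len(nrow(records))) {
      # half-voxel margins so neither membrane nor vesicle voxels are
      # counted while a one-voxel-thin corridor is still inspected
      zlo <- pm_z_nm + w / 2
      zhi <- records$center_z_nm[i] - records$diameter_nm[i] / 2 - w / 2
      if (zhi <= zlo) next
      iz <- which(ax[[3]] > zlo & ax[[3]] < zhi)
      if (!length(iz)) next
      r2 <- outer((ax[[1]] - records$center_x_nm[i])^2,
                  (ax[[2]] - records$center_y_nm[i])^2, "+")
      inr <- r2 <= (records$diameter_nm[i] / 2)^2
      for (k in iz) {
        if (any(label_volume$grid[, , k][inr] > 0)) {
          clearance[i] <- FALSE
          break
        }
      }
    }
  }
  records$clearance_ok <- clearance
  records$docked <- gap <= proximity_nm & clearance
  records
}

#' Proportion of proximal / docked vesicles, with CI and cohort comparison
#'
#' @param docked logical vector (or data.frame with a `docked` column).
#' @param other optional second cohort for a two-proportion comparison.
#' @param conf_level confidence level of the Wilson interval.
#' @return list with `fraction`, `n`, `ci` (Wilson), and, when `other` is
#'   given, `p_value` from a continuity-corrected two-proportion z-test.
#' @export
proximal_fraction <- function(docked, other = NULL, conf_level = 0.95) {
  as_flags <- function(x) {
    if (is.data.frame(x)) x <- x$docked
    x <- as.logical(x)
    if (!length(x)) stop("empty cohort")
    x[!is.na(x)]
  }
  x <- as_flags(docked)
  k <- sum(x)
  n <- length(x)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  ci <- (p + z^2 / (2 * n) + c(-1, 1) * z *
           sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) / (1 + z^2 / n)
  out <- list(fraction = p, n = n, ci = ci)
  if (!is.null(other)) {
    y <- as_flags(other)
    ht <- stats::prop.test(c(k, sum(y)), c(n, length(y)), correct = TRUE)
    out$p_value <- ht$p.value
    out$other_fraction <- mean(y)
  }
  out
}

#' Relative-frequency histogram of vesicle diameters
#'
#' @param diameters numeric vector of diameters (nm), or a data.frame with
#'   a `diameter_nm` column.
#' @param bin_width_nm histogram bin width.
#' @return data.frame with `bin_lo_nm`, `bin_hi_nm`, `count`,
#'   `rel_frequency` (summing to 1).
#' @export
diameter_histogram <- function(diameters, bin_width_nm = 10) {
  if (is.data.frame(diameters)) diameters <- diameters$diameter_nm
  diameters <- diameters[is.finite(diameters)]
  if (!length(diameters)) stop("no diameters to bin")
  lo <- floor(min(diameters) / bin_width_nm) * bin_width_nm
  breaks <- seq(lo, max(diameters) + bin_width_nm, by = bin_width_nm)
  h <- graphics::hist(diameters, breaks = breaks, plot = FALSE, right = FALSE)
  data.frame(bin_lo_nm = h$breaks[-length(h$breaks)],
             bin_hi_nm = h$breaks[-1], count = h$counts,
             rel_frequency = h$counts / length(diameters))
}
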