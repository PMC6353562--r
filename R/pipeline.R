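# The subtomogram workflow: wedge-constrained correlation, global and
# focused alignment, MSA + hierarchical ascendant classification,
# size-class selection, and wedge-compensated class averaging.

#' Alignment parameters
#'
#' @param bin_factor integer binning applied before alignment.
#' @param lowpass_cutoff_nm low-pass cutoff used when scoring (nm).
#' @param n_cycles maximum alignment cycles (default 5).
#' @param azimuth_step_deg azimuthal search step; must divide 360.
#' @param shift_search_nm translational search radius (nm).
#' @param slab_nm interface slab z-range above the membrane plane (nm).
#' @param annulus_nm interface annulus radii about the docking axis (nm).
#' @param mask_radius_nm radius of the spherical mask for global
#'   (vesicle-centred) alignment.
#' @param converge_vox stop when the mean shift update falls below this
#'   many voxels.
#' @return an object of class `alignment_params`.
#' @export
alignment_params <- function(bin_factor = 4, lowpass_cutoff_nm = 5,
                             n_cycles = 5, azimuth_step_deg = 5,
                             shift_search_nm = 8, slab_nm = c(2, 8),
                             annulus_nm = c(8, 28), mask_radius_nm = 30,
                             converge_vox = 0.5) {
  if (bin_factor < 1 || bin_factor != round(bin_factor))
    stop("`bin_factor` must be a positive integer")
  if (n_cycles < 1) stop("`n_cycles` must be >= 1")
  if (360 %% azimuth_step_deg != 0)
    stop("`azimuth_step_deg` must divide 360")
  structure(list(bin_factor = as.integer(bin_factor),
                 lowpass_cutoff_nm = lowpass_cutoff_nm,
                 n_cycles = as.integer(n_cycles),
                 azimuth_step_deg = azimuth_step_deg,
                 shift_search_nm = shift_search_nm, slab_nm = slab_nm,
                 annulus_nm = annulus_nm, mask_radius_nm = mask_radius_nm,
                 converge_vox = converge_vox),
            class = "alignment_params")
}

#' Classification parameters
#'
#' @param n_classes_stage1 classes for the size/shape sorting stage.
#' @param n_classes_stage2 classes for the focused interface stage.
#' @param n_components number of MSA (principal) components retained.
#' @param select_diameter_nm centre of the selected size class (nm).
#' @param select_tolerance_nm half-width of the selection window (nm).
#' @param refine_sd_nm target diameter spread of the iteratively refined
#'   subset; refinement stops once the spread stops improving or reaches
#'   this homogeneity.
#' @param linkage agglomeration rule passed to [stats::hclust()].
#' @return an object of class `class_params`.
#' @export
class_params <- function(n_classes_stage1 = 20, n_classes_stage2 = 10,
                         n_components = 10, select_diameter_nm = 45,
                         select_tolerance_nm = 5, refine_sd_nm = 2,
                         linkage = "ward.D2") {
  if (n_classes_stage1 < 2 || n_classes_stage2 < 2)
    stop("class counts must be >= 2")
  if (select_tolerance_nm <= 0) stop("`select_tolerance_nm` must be > 0")
  structure(list(n_classes_stage1 = as.integer(n_classes_stage1),
                 n_classes_stage2 = as.integer(n_classes_stage2),
                 n_components = as.integer(n_components),
                 select_diameter_nm = select_diameter_nm,
                 select_tolerance_nm = select_tolerance_nm,
                 refine_sd_nm = refine_sd_nm, linkage = linkage),
            class = "class_params")
}

#' Missing-wedge-constrained cross-correlation
#'
#' Normalized cross-correlation of two volumes evaluated only over the
#' intersection of their Fourier wedge supports (and, optionally, after a
#' real-space mask). The DC term is excluded, making the score invariant
#' to additive offsets; identical volumes score 1, sign-flipped copies -1.
#'
#' @param a,b [density_volume()]s on the same grid, each optionally
#'   carrying a wedge descriptor (`NULL` = full support).
#' @param mask optional real-space weighting array (same dimensions).
#' @return correlation in [-1, 1].
#' @export
constrained_ccc <- function(a, b, mask = NULL) {
  stopifnot(is_density_volume(a), is_density_volume(b))
  if (!identical(dim(a$grid), dim(b$grid)))
    stop("volumes must share a grid")
  d <- dim(a$grid)
  S <- array(TRUE, d)
  if (!is.null(a$wedge))
    S <- S & wedge_mask(d, a$wedge, a$meta$wedge_azimuth_deg %||% 0)
  if (!is.null(b$wedge))
    S <- S & wedge_mask(d, b$wedge, b$meta$wedge_azimuth_deg %||% 0)
  S[1, 1, 1] <- FALSE  # drop DC
  if (!any(S)) stop("empty Fourier support intersection")
  ga <- a$grid
  gb <- b$grid
  if (!is.null(mask)) {
    wsum <- sum(mask)
    ga <- (ga - sum(ga * mask) / wsum) * mask
    gb <- (gb - sum(gb * mask) / wsum) * mask
  }
  FA <- fft(ga)[S]
  FB <- fft(gb)[S]
  num <- sum(Re(FA * Conj(FB)))
  den <- sqrt(sum(Mod(FA)^2) * sum(Mod(FB)^2))
  if (den == 0) stop("zero variance on the constrained support")
  num / den
}

#' Global (vesicle-centred) translational alignment
#'
#' Iteratively translates each particle to maximize its wedge-constrained
#' correlation with the running average under a soft spherical mask,
#' using FFT cross-correlation with parabolic sub-voxel refinement.
#' Stops after `n_cycles` or when the mean shift update drops below
#' `converge_vox` voxels. Particles whose shift exceeds the search range
#' are flagged and excluded from the average.
#'
#' @param volumes list of [density_volume()]s on a common grid.
#' @param params an [alignment_params()].
#' @param mask_center_nm centre of the spherical alignment mask.
#' @return list with `shifts_nm` (n x 3 matrix: accumulated particle
#'   shifts relative to the average), `aligned` (list of shifted volumes),
#'   `average` ([density_volume()]), `scores` (per-cycle mean constrained
#'   correlation), `flagged` (logical).
#' @export
align_global <- function(volumes, params = alignment_params(),
                         mask_center_nm = c(0, 0, 0)) {
  n <- length(volumes)
  if (n < 1) stop("need at least one particle")
  v1 <- volumes[[1]]
  d <- dim(v1$grid)
  vx <- v1$voxel_size_nm
  if (n == 1) {
    return(list(shifts_nm = matrix(0, 1, 3), aligned = volumes,
                average = v1, scores = numeric(0), flagged = FALSE))
  }
  mask <- spherical_mask(v1, params$mask_radius_nm, mask_center_nm)
  S <- if (is.null(v1$wedge)) NULL else wedge_mask(d, v1$wedge)
  smax <- max(1L, round(params$shift_search_nm / vx))
  lp <- lowpass_response(d, vx, params$lowpass_cutoff_nm)

  FP <- lapply(volumes, function(v) fft(v$grid))
  # particle norms on the scoring support (fixed across cycles)
  pnorm <- vapply(FP, function(f) {
    fl <- f * lp
    if (!is.null(S)) fl[!S] <- 0
    sqrt(sum(Mod(fl)^2))
  }, numeric(1))
  shifts <- matrix(0, n, 3)
  flagged <- rep(FALSE, n)
  scores <- numeric(0)
  avgF <- Reduce(`+`, FP) / n

  sub_idx <- function(nk) c(1:(smax + 1), (nk - smax + 1):nk)
  decode_lag <- function(m) if (m <= smax + 1) m - 1 else m - 2 * smax - 2
  for (cyc in seq_len(params$n_cycles)) {
    refg <- Re(fft(avgF * lp, inverse = TRUE)) / prod(d) * mask
    FR <- fft(refg)
    if (!is.null(S)) FR[!S] <- 0
    rnorm_ <- sqrt(sum(Mod(FR)^2))
    upd <- 0
    cyc_scores <- numeric(n)
    newF <- vector("list", n)
    for (i in seq_len(n)) {
      # cc(s) = <ref, particle shifted to lag s>, restricted to the wedge
      cc <- Re(fft(Conj(FR) * FP[[i]] * lp, inverse = TRUE)) / prod(d)
      sub <- cc[sub_idx(d[1]), sub_idx(d[2]), sub_idx(d[3])]
      ijk <- arrayInd(which.max(sub), dim(sub))
      s_vox <- vapply(1:3, function(a) decode_lag(ijk[a]), numeric(1))
      peak <- max(sub)
      # parabolic sub-voxel refinement along each axis
      for (a in 1:3) {
        at <- function(s) {
          pos <- s_vox
          pos[a] <- s
          cc[(round(pos[1]) %% d[1]) + 1, (round(pos[2]) %% d[2]) + 1,
             (round(pos[3]) %% d[3]) + 1]
        }
        y <- c(at(s_vox[a] - 1), at(s_vox[a]), at(s_vox[a] + 1))
        s_vox[a] <- s_vox[a] + parabolic_offset(y, 2)
      }
      if (sqrt(sum(s_vox^2)) > smax + 1) {
        flagged[i] <- TRUE
        s_vox <- shifts[i, ] / vx
      }
      upd <- upd + sqrt(sum((s_vox * vx - shifts[i, ])^2)) / vx
      shifts[i, ] <- s_vox * vx
      cyc_scores[i] <- if (pnorm[i] > 0 && rnorm_ > 0)
        prod(d) * peak / (pnorm[i] * rnorm_) else 0
    }
    keep <- !flagged
    # remove the common drift: alignment is only defined up to a global
    # translation, and downstream masks (membrane plane, interface slab)
    # are anchored to the original frame
    shifts[keep, ] <- sweep(shifts[keep, , drop = FALSE], 2,
                            colMeans(shifts[keep, , drop = FALSE]))
    for (i in seq_len(n))
      newF[[i]] <- FP[[i]] * phase_ramp(d, -shifts[i, ] / vx)
    avgF <- Reduce(`+`, newF[keep]) / sum(keep)
    scores <- c(scores, mean(cyc_scores[keep]))
    if (upd / n < params$converge_vox) break
  }
  aligned <- lapply(seq_len(n), function(i)
    shift_volume(volumes[[i]], -shifts[i, ] / vx))
  avg <- density_volume(Re(fft(avgF, inverse = TRUE)) / prod(d), vx,
                        v1$origin_nm, v1$wedge, v1$meta)
  list(shifts_nm = shifts, aligned = aligned, average = avg,
       scores = scores, flagged = flagged)
}

phase_ramp <- function(d, shift_vox) {
  ph <- function(n, s) exp(-2i * pi * fft_freqs(n) * s)
  outer(outer(ph(d[1], shift_vox[1]), ph(d[2], shift_vox[2])),
        ph(d[3], shift_vox[3]))
}

lowpass_response <- function(d, voxel_nm, cutoff_nm, rolloff = 0.2) {
  if (is.null(cutoff_nm)) return(array(1, d))
  fx <- fft_freqs(d[1]) / voxel_nm
  fy <- fft_freqs(d[2]) / voxel_nm
  fz <- fft_freqs(d[3]) / voxel_nm
  f <- sqrt(outer(outer(fx^2, fy^2, "+"), fz^2, "+"))
  fc <- 1 / cutoff_nm
  flo <- fc * (1 - rolloff)
  fhi <- fc * (1 + rolloff)
  h <- array(0, d)
  h[f <= flo] <- 1
  tb <- f > flo & f < fhi
  h[tb] <- 0.5 * (1 + cos(pi * (f[tb] - flo) / (fhi - flo)))
  h
}

#' Focused azimuthal alignment at the vesicle-membrane interface
#'
#' Aligns globally centred particles rotationally about the docking axis
#' by exhaustive azimuthal search (step `azimuth_step_deg`), scoring the
#' wedge-constrained correlation inside the interface slab / annulus mask,
#' with an optional +/-1 voxel in-plane translational refinement. The
#' reference is bootstrapped from the first particle and replaced by the
#' aligned running average each cycle.
#'
#' @param volumes list of globally aligned [density_volume()]s.
#' @param params an [alignment_params()].
#' @param pm_z_nm membrane plane z (defaults to the first particle's
#'   metadata).
#' @param local_shift_vox in-plane translational refinement radius
#'   (voxels; 0 disables).
#' @param average build the wedge-compensated interface average (skip to
#'   save the per-particle rotations when only azimuths are needed).
#' @return list with `azimuths_deg` (recovered particle azimuths: rotating
#'   particle i by `-azimuths_deg[i]` brings it into register with the
#'   reference frame), `scores` (per-cycle mean best correlation),
#'   `shifts_nm` (n x 2 in-plane refinements), `profiles` (matrix of
#'   per-particle aligned azimuthal interface profiles), and `average`
#'   (the wedge-compensated interface average, a [density_volume()]).
#' @export
align_focused <- function(volumes, params = alignment_params(),
                          pm_z_nm = NULL, local_shift_vox = 1,
                          average = TRUE) {
  n <- length(volumes)
  if (n < 1) stop("need at least one particle")
  v1 <- volumes[[1]]
  vx <- v1$voxel_size_nm
  if (is.null(pm_z_nm)) pm_z_nm <- v1$meta$pm_z_nm
  iz <- slab_z_indices(v1, pm_z_nm, params$slab_nm)
  if (!length(iz)) stop("interface slab is empty for this grid")
  d2 <- c(dim(v1$grid)[1:2], length(iz))

  # annulus mask on the slab (rotationally symmetric => commutes with the
  # azimuthal search)
  ax <- vox_axes(v1)
  rxy <- sqrt(outer(ax[[1]]^2, ax[[2]]^2, "+"))
  m2 <- rxy >= params$annulus_nm[1] & rxy <= params$annulus_nm[2]
  if (!any(m2)) stop("interface annulus mask is empty")
  mask3 <- array(rep(m2, length(iz)), d2)

  lp <- lowpass_response(d2, vx, params$lowpass_cutoff_nm)
  S <- if (is.null(v1$wedge)) array(TRUE, d2) else wedge_mask(d2, v1$wedge)
  S[1, 1, 1] <- FALSE
  Sidx <- which(S)
  lpS <- lp[Sidx]

  crops <- lapply(volumes, function(v) v$grid[, , iz, drop = FALSE])
  FP <- lapply(crops, function(g) fft(g * mask3)[Sidx] * lpS)
  pnorm <- vapply(FP, function(f) sqrt(sum(Mod(f)^2)), numeric(1))

  angles <- seq(0, 360 - params$azimuth_step_deg,
                by = params$azimuth_step_deg)
  maps <- lapply(angles, function(a) rot_xy_map(d2[1], d2[2], a))

  # in-plane shift ramps for the local translational refinement
  sh_offsets <- if (local_shift_vox > 0) {
    as.matrix(expand.grid(sx = -local_shift_vox:local_shift_vox,
                          sy = -local_shift_vox:local_shift_vox))
  } else matrix(0, 1, 2, dimnames = list(NULL, c("sx", "sy")))
  fx <- fft_freqs(d2[1])
  fy <- fft_freqs(d2[2])
  ramps <- apply(sh_offsets, 1, function(s) {
    r2 <- outer(exp(-2i * pi * fx * s[1]), exp(-2i * pi * fy * s[2]))
    array(rep(r2, d2[3]), d2)[Sidx]
  })

  ref <- crops[[1]]
  azims <- rep(0, n)
  shifts <- matrix(0, n, 2)
  scores <- numeric(0)
  for (cyc in seq_len(params$n_cycles)) {
    U <- vapply(maps, function(mp) {
      fr <- fft(apply_rot_map(ref, mp) * mask3)[Sidx] * lpS
      fr / sqrt(sum(Mod(fr)^2))
    }, complex(length(Sidx)))
    best <- numeric(n)
    for (i in seq_len(n)) {
      sc <- Re(crossprod(Conj(U), FP[[i]])) / pnorm[i]
      k <- which.max(sc)
      azims[i] <- angles[k]
      if (nrow(sh_offsets) > 1) {
        u <- U[, k]
        ssc <- vapply(seq_len(ncol(ramps)), function(j)
          Re(sum(Conj(u) * (FP[[i]] * ramps[, j]))) / pnorm[i], numeric(1))
        jb <- which.max(ssc)
        shifts[i, ] <- sh_offsets[jb, ] * vx
        best[i] <- ssc[jb]
      } else best[i] <- sc[k]
    }
    scores <- c(scores, mean(best))
    # rebuild reference from aligned crops
    acc <- array(0, d2)
    for (i in seq_len(n)) {
      g <- crops[[i]]
      if (any(shifts[i, ] != 0))
        g <- shift_volume(g, c(-shifts[i, ] / vx, 0))
      acc <- acc + apply_rot_map(g, rot_xy_map(d2[1], d2[2], -azims[i]))
    }
    ref <- acc / n
  }

  n_bins <- 120L
  profiles <- t(vapply(seq_len(n), function(i) {
    g <- apply_rot_map(crops[[i]], rot_xy_map(d2[1], d2[2], -azims[i]))
    azimuthal_profile_core(g, ax[[1]], ax[[2]], params$annulus_nm, n_bins)
  }, numeric(n_bins)))

  avg <- if (average)
    average_class(volumes, rep(1L, n), 1L, azimuths_deg = azims,
                  shifts_nm = cbind(shifts, 0)) else NULL
  list(azimuths_deg = azims, scores = scores, shifts_nm = shifts,
       profiles = profiles, average = avg)
}

#' MSA feature extraction (principal-component scores)
#'
#' The classical electron-microscopy meaning of multivariate statistical
#' analysis: particles are vectorized over the masked voxels, centred, and
#' projected onto the leading principal components.
#'
#' @param volumes list of aligned [density_volume()]s.
#' @param mask real-space mask array (non-zero voxels are used); `NULL`
#'   uses all voxels.
#' @param n_components number of components (<= number of particles).
#' @return matrix of scores (particles x components) with attribute
#'   `"sdev"` holding the component standard deviations.
#' @export
msa_features <- function(volumes, mask = NULL, n_components = 10) {
  n <- length(volumes)
  if (n_components > n) stop("`n_components` cannot exceed the particle count")
  sel <- if (is.null(mask)) TRUE else which(mask != 0)
  X <- t(vapply(volumes, function(v) as.numeric(v$grid[sel]),
                numeric(if (is.null(mask)) length(volumes[[1]]$grid)
                        else length(sel))))
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = n_components)
  out <- p$x
  attr(out, "sdev") <- p$sdev
  out
}

#' Hierarchical ascendant classification
#'
#' Agglomerative clustering of MSA feature vectors (Euclidean distance,
#' Ward linkage by default). Class labels are renumbered by decreasing
#' class size, ties broken by lowest member index, so the labelling is
#' deterministic given the input order.
#'
#' @param features numeric matrix (particles x features) or vector.
#' @param n_classes number of classes (<= number of particles).
#' @param linkage agglomeration method for [stats::hclust()].
#' @return integer vector of class labels in 1..n_classes.
#' @export
hac_classify <- function(features, n_classes, linkage = "ward.D2") {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n_classes > n) stop("`n_classes` cannot exceed the particle count")
  hc <- stats::hclust(stats::dist(features), method = linkage)
  raw <- stats::cutree(hc, k = n_classes)
  # renumber: largest class first; ties by first occurrence
  sizes <- tabulate(raw, n_classes)
  first <- vapply(seq_len(n_classes), function(k) match(k, raw), numeric(1))
  ord <- order(-sizes, first)
  match(raw, ord)
}

#' Select the homogeneous size class
#'
#' Keeps the classes whose mean diameter lies within
#' `select_diameter_nm +/- select_tolerance_nm`.
#'
#' @param diameters_nm per-particle diameter estimates.
#' @param labels class labels from [hac_classify()].
#' @param params a [class_params()].
#' @return list with `selected` (logical per particle), `classes_kept`,
#'   `mean_nm`, `sd_nm` of the selected subset (NA when empty).
#' @export
select_size_class <- function(diameters_nm, labels, params = class_params()) {
  means <- tapply(diameters_nm, labels, mean)
  keep_classes <- as.integer(names(means)[
    abs(means - params$select_diameter_nm) <= params$select_tolerance_nm])
  sel <- labels %in% keep_classes
  if (!any(sel)) {
    warning("no class falls inside the selection window; empty selection")
    return(list(selected = sel, classes_kept = integer(0),
                mean_nm = NA_real_, sd_nm = NA_real_))
  }
  list(selected = sel, classes_kept = keep_classes,
       mean_nm = mean(diameters_nm[sel]), sd_nm = stats::sd(diameters_nm[sel]))
}

#' Iterative re-classification towards a homogeneous size subset
#'
#' Repeatedly re-classifies the current subset and discards the class
#' whose mean diameter lies farthest from the target, until the subset's
#' diameter spread stops improving or reaches the target homogeneity
#' (`refine_sd_nm`). This mirrors refining a selected size class over
#' several classification cycles until no further improvement in size
#' homogeneity.
#'
#' @param diameters_nm per-particle diameter estimates of the already
#'   selected subset.
#' @param params a [class_params()].
#' @param features optional feature matrix for classification; by default
#'   classes are formed on the diameters themselves.
#' @param max_iter safety cap on refinement iterations.
#' @return list with `selected` (logical per input particle), `mean_nm`,
#'   `sd_nm`, and `history` (sd after each iteration).
#' @export
refine_size_selection <- function(diameters_nm, params = class_params(),
                                  features = NULL, max_iter = 50) {
  keep <- rep(TRUE, length(diameters_nm))
  history <- stats::sd(diameters_nm)
  for (it in seq_len(max_iter)) {
    idx <- which(keep)
    cur_sd <- stats::sd(diameters_nm[idx])
    if (!is.finite(cur_sd) || cur_sd <= params$refine_sd_nm) break
    k <- min(params$n_classes_stage1, max(2L, floor(length(idx) / 2)))
    f <- if (is.null(features)) matrix(diameters_nm[idx], ncol = 1)
      else features[idx, , drop = FALSE]
    labs <- hac_classify(f, k, params$linkage)
    means <- tapply(diameters_nm[idx], labs, mean)
    worst <- as.integer(names(means)[
      which.max(abs(means - params$select_diameter_nm))])
    drop_idx <- idx[labs == worst]
    if (length(drop_idx) >= length(idx)) break
    new_keep <- keep
    new_keep[drop_idx] <- FALSE
    new_sd <- stats::sd(diameters_nm[new_keep])
    if (!is.finite(new_sd) || new_sd >= cur_sd) break
    keep <- new_keep
    history <- c(history, new_sd)
  }
  list(selected = keep, mean_nm = mean(diameters_nm[keep]),
       sd_nm = stats::sd(diameters_nm[keep]), history = history)
}

#' Wedge-compensated class average
#'
#' Averages the members of one class in Fourier space with per-frequency
#' wedge-occupancy normalization: each particle contributes its (optionally
#' rotated and shifted) transform and its wedge support; the accumulated
#' transform is divided by the per-frequency occupancy, floored at a small
#' constant so sparsely seen regions are not blown up.
#'
#' @param volumes list of [density_volume()]s.
#' @param labels integer class labels (one per volume).
#' @param class_id the class to average.
#' @param azimuths_deg optional per-particle azimuths; particle i is
#'   rotated by `-azimuths_deg[i]` before averaging.
#' @param shifts_nm optional n x 3 per-particle shifts, removed before
#'   averaging.
#' @param wedge_compensation divide by the wedge occupancy (otherwise a
#'   plain voxelwise mean is returned).
#' @param occupancy_floor_frac floor on the occupancy, as a fraction of
#'   the class size (at least one particle's worth). The default of 0.5
#'   limits compensation to 2x: frequencies sampled by fewer than half
#'   the class carry mostly noise at low snr, and boosting them further
#'   trades a little attenuation for a large noise amplification.
#' @return the class-average [density_volume()]; `meta$occupancy_min`
#'   records the minimum occupancy before flooring.
#' @export
average_class <- function(volumes, labels, class_id, azimuths_deg = NULL,
                          shifts_nm = NULL, wedge_compensation = TRUE,
                          occupancy_floor_frac = 0.5) {
  members <- which(labels == class_id)
  if (!length(members)) stop("class has no members")
  v1 <- volumes[[members[1]]]
  d <- dim(v1$grid)
  vx <- v1$voxel_size_nm
  accF <- array(0i, d)
  occ <- array(0, d)
  for (i in members) {
    v <- volumes[[i]]
    g <- v$grid
    if (!is.null(shifts_nm) && any(shifts_nm[i, ] != 0))
      g <- shift_volume(g, -shifts_nm[i, ] / vx)
    a <- if (is.null(azimuths_deg)) 0 else azimuths_deg[i]
    if (a != 0) g <- rotate_grid_z(g, -a)
    accF <- accF + fft(g)
    occ <- occ + if (is.null(v$wedge)) 1 else
      wedge_mask(d, v$wedge, ((v$meta$wedge_azimuth_deg %||% 0) - a) %% 360)
  }
  n <- length(members)
  if (wedge_compensation) {
    floor_c <- max(1, occupancy_floor_frac * n)
    g <- Re(fft(accF / pmax(occ, floor_c), inverse = TRUE)) / prod(d)
  } else {
    g <- Re(fft(accF / n, inverse = TRUE)) / prod(d)
  }
  meta <- v1$meta
  meta$occupancy_min <- min(occ)
  meta$n_members <- n
  density_volume(g, vx, v1$origin_nm,
                 wedge = if (n == 1) v1$wedge else NULL, meta = meta)
}
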