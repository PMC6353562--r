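# Scripted end-to-end experiments: the reproducible benchmark surface.

#' Define an end-to-end experiment
#'
#' Bundles every input of a synthetic study — dataset parameters, pipeline
#' parameters, and stage switches — into one fully seeded, serializable
#' specification.
#'
#' @param name experiment name.
#' @param n_particles number of simulated particles.
#' @param geometry an [assembly_geometry()].
#' @param mixture a [vesicle_mixture()] or single [vesicle_model()].
#' @param tilt a [tilt_scheme()].
#' @param noise a [noise_model()].
#' @param rng_seed master seed.
#' @param voxel_size_nm,box_voxels sampling of the simulated subtomograms.
#' @param shift_sd_nm sd of the random in-plane particle shifts.
#' @param align an [alignment_params()].
#' @param classes a [class_params()].
#' @param do_global_align run translational (vesicle-centred) alignment.
#' @param do_interface run the focused interface stage (alignment,
#'   stage-2 classification, pooled average, symmetry and ring analysis).
#' @param do_refine run iterative size-selection refinement.
#' @param detect_range_nm outer-diameter search window of the census.
#' @return an object of class `experiment_spec`.
#' @export
experiment_spec <- function(name, n_particles, geometry, mixture, tilt,
                            noise, rng_seed = 1, voxel_size_nm = 2.16,
                            box_voxels = 64, shift_sd_nm = 2,
                            align = alignment_params(),
                            classes = class_params(),
                            do_global_align = TRUE, do_interface = TRUE,
                            do_refine = FALSE,
                            detect_range_nm = c(35, 60)) {
  if (n_particles < 1) stop("`n_particles` must be >= 1")
  structure(list(name = name, n_particles = as.integer(n_particles),
                 geometry = geometry, mixture = mixture, tilt = tilt,
                 noise = noise, rng_seed = as.integer(rng_seed),
                 voxel_size_nm = voxel_size_nm,
                 box_voxels = as.integer(box_voxels),
                 shift_sd_nm = shift_sd_nm, align = align,
                 classes = classes, do_global_align = do_global_align,
                 do_interface = do_interface, do_refine = do_refine,
                 detect_range_nm = detect_range_nm),
            class = "experiment_spec")
}

#' Canned experiment specifications
#'
#' Two reference studies ship with the package:
#'
#' * `"ring_recovery"`: 100 organized particles (6 modules on a 35 nm
#'   ring under 45 nm vesicles, +/-51 degree wedge, snr 0.1) pushed
#'   through the full pipeline; the expected recovery is symmetry order 6,
#'   ~60 degree spacings, ~35 nm ring diameter.
#' * `"f349a_null"`: identical but with disorganized (per-particle random)
#'   module azimuths, the in-silico analogue of the oligomerization-dead
#'   Syt1 F349A mutant; symmetry detection should stay at chance.
#' * `"mixture_census"`: 200 particles from a 70/30 mixture of ~45 nm
#'   synaptic-like and ~120 nm dense-core-like vesicles (snr 0.5), for
#'   the size classification / selection stage.
#'
#' @param name one of `"ring_recovery"`, `"f349a_null"`,
#'   `"mixture_census"`.
#' @param rng_seed master seed.
#' @return an [experiment_spec()].
#' @export
canned_experiment <- function(name = c("ring_recovery", "f349a_null",
                                       "mixture_census"), rng_seed = 1) {
  name <- match.arg(name)
  if (name %in% c("ring_recovery", "f349a_null")) {
    experiment_spec(
      name = name, n_particles = 100,
      geometry = assembly_geometry(n_modules = 6, ring_diameter_nm = 35,
                                   organized = name == "ring_recovery"),
      mixture = vesicle_mixture(list(list(
        weight = 1, diameter_mean_nm = 45, diameter_sd_nm = 2))),
      tilt = tilt_scheme(-51, 51, 3),
      noise = noise_model(snr = 0.1),
      rng_seed = rng_seed, voxel_size_nm = 2.16, box_voxels = 64,
      shift_sd_nm = 2, do_interface = TRUE, do_refine = FALSE,
      detect_range_nm = c(35, 60))
  } else {
    experiment_spec(
      name = name, n_particles = 200,
      geometry = assembly_geometry(n_modules = 6, ring_diameter_nm = 35),
      mixture = vesicle_mixture(list(
        list(weight = 0.7, diameter_mean_nm = 45, diameter_sd_nm = 5),
        list(weight = 0.3, diameter_mean_nm = 120, diameter_sd_nm = 15))),
      tilt = tilt_scheme(-51, 51, 3),
      noise = noise_model(snr = 0.5),
      rng_seed = rng_seed, voxel_size_nm = 3.4, box_voxels = 56,
      shift_sd_nm = 2, do_global_align = FALSE, do_interface = FALSE,
      do_refine = TRUE, detect_range_nm = c(35, 135))
  }
}

#' Run an end-to-end experiment
#'
#' Executes generate -> census -> (alignment) -> MSA/HAC ->
#' size selection -> (focused interface stage -> symmetry / ring
#' analysis) -> (refinement), collecting per-stage diagnostics. A stage
#' failure yields a partial report naming the failing stage.
#'
#' @param spec an [experiment_spec()].
#' @param verbose print stage progress.
#' @return object of class `experiment_report`: list with `name`, `seed`,
#'   `stages` (diagnostics), `recovered` (headline numbers), and `failed`
#'   (NULL, or the name of the failed stage with the error message).
#' @export
run_experiment <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  t0 <- Sys.time()
  report <- list(name = spec$name, seed = spec$rng_seed,
                 n_particles = spec$n_particles, stages = list(),
                 recovered = list(), failed = NULL)
  say <- function(...) if (verbose) message(sprintf(...))
  fail <- function(stage, e) {
    report$failed <<- list(stage = stage, message = conditionMessage(e))
    report
  }

  # -- generate ------------------------------------------------------------
  ds <- tryCatch({
    say("[%s] generating %d particles", spec$name, spec$n_particles)
    generate_dataset(spec$n_particles, spec$geometry, spec$mixture,
                     spec$tilt, spec$noise, rng_seed = spec$rng_seed,
                     voxel_size_nm = spec$voxel_size_nm,
                     box_voxels = spec$box_voxels,
                     shift_sd_nm = spec$shift_sd_nm)
  }, error = function(e) e)
  if (inherits(ds, "error")) return(fail("generate", ds))
  report$stages$generate <- list(n = length(ds$volumes),
                                 true_mean_diameter_nm =
                                   mean(ds$table$diameter_nm))
  pm_z <- ds$volumes[[1]]$meta$pm_z_nm

  # -- census --------------------------------------------------------------
  census <- tryCatch({
    say("[%s] census", spec$name)
    # particles are extracted centred on their vesicle, so the detection
    # must lie close to the box axis; stray peaks are ignored
    r_ok <- spec$align$shift_search_nm + 2 * spec$voxel_size_nm
    rows <- lapply(ds$volumes, function(v) {
      det <- detect_vesicles(v, spec$detect_range_nm,
                             step_nm = spec$voxel_size_nm,
                             membrane_thickness_nm = 5, pm_z_nm = pm_z)
      det <- det[sqrt(det$center_x_nm^2 + det$center_y_nm^2) <= r_ok, ,
                 drop = FALSE]
      if (nrow(det) == 0)
        data.frame(diameter_nm = NA_real_, center_x_nm = NA_real_,
                   center_y_nm = NA_real_, center_z_nm = NA_real_)
      else det[which.max(det$score),
               c("diameter_nm", "center_x_nm", "center_y_nm", "center_z_nm")]
    })
    do.call(rbind, rows)
  }, error = function(e) e)
  if (inherits(census, "error")) return(fail("census", census))
  centers <- as.matrix(census[, c("center_x_nm", "center_y_nm",
                                  "center_z_nm")])
  census <- census$diameter_nm
  ok <- is.finite(census)
  report$stages$census <- list(
    n_detected = sum(ok),
    mean_abs_error_nm = mean(abs(census[ok] - ds$table$diameter_nm[ok])))

  # -- global alignment ----------------------------------------------------
  vols <- ds$volumes
  if (spec$do_global_align) {
    ga <- tryCatch({
      say("[%s] global alignment", spec$name)
      align_global(vols, spec$align)
    }, error = function(e) e)
    if (inherits(ga, "error")) return(fail("align_global", ga))
    vols <- ga$aligned
    report$stages$align_global <- list(scores = ga$scores,
                                       n_flagged = sum(ga$flagged))
  }

  # -- stage-1 classification and size selection ---------------------------
  # classification + selection, iterated while the subset's diameter
  # spread still improves materially ("until no further improvement in
  # the homogeneity"). Without global alignment, particles are centred on
  # their detected vesicle for feature extraction, so classes see
  # concentric shells and sort cleanly by size.
  sel <- tryCatch({
    say("[%s] MSA/HAC into %d classes", spec$name,
        spec$classes$n_classes_stage1)
    msa_vols <- vols
    if (!spec$do_global_align) {
      vx <- spec$voxel_size_nm
      msa_vols <- lapply(seq_along(vols), function(i) {
        if (!ok[i]) return(vols[[i]])
        shift_volume(vols[[i]], -centers[i, ] / vx)
      })
    }
    selected <- ok
    passes <- 0L
    kept <- integer(0)
    repeat {
      passes <- passes + 1L
      idx <- which(selected)
      nc <- min(spec$classes$n_components, length(idx) - 1L)
      k1 <- min(spec$classes$n_classes_stage1, max(2L, length(idx) %/% 2))
      feats <- msa_features(msa_vols[idx], mask = NULL, n_components = nc)
      labs <- hac_classify(feats, k1, spec$classes$linkage)
      s <- select_size_class(census[idx], labs, spec$classes)
      if (passes == 1L) kept <- s$classes_kept
      new_sel <- selected
      new_sel[idx[!s$selected]] <- FALSE
      if (identical(new_sel, selected) || passes >= 4L || !any(new_sel))
        break
      # apply only while the spread improves by more than 10%
      if (passes > 1L &&
          stats::sd(census[new_sel]) >= 0.9 * stats::sd(census[selected]))
        break
      selected <- new_sel
    }
    list(selected = selected, passes = passes, kept = kept)
  }, error = function(e) e)
  if (inherits(sel, "error")) return(fail("classify_stage1", sel))
  selected <- sel$selected
  report$stages$classify_stage1 <- list(
    n_classes = spec$classes$n_classes_stage1, passes = sel$passes,
    classes_kept = sel$kept, n_selected = sum(selected))
  report$recovered$subset_mean_nm <- mean(census[selected])
  report$recovered$subset_sd_nm <- stats::sd(census[selected])

  # -- iterative refinement of the size selection --------------------------
  if (spec$do_refine && sum(selected) > 4) {
    rf <- tryCatch({
      say("[%s] refining size selection", spec$name)
      refine_size_selection(census[selected], spec$classes)
    }, error = function(e) e)
    if (inherits(rf, "error")) return(fail("refine_selection", rf))
    report$stages$refine <- list(history = rf$history,
                                 n_final = sum(rf$selected))
    report$recovered$refined_mean_nm <- rf$mean_nm
    report$recovered$refined_sd_nm <- rf$sd_nm
  }

  # -- focused interface stage ---------------------------------------------
  if (spec$do_interface) {
    if (sum(selected) < 2) return(fail("align_focused", simpleError(
      "fewer than two particles selected for the interface stage")))
    fvols <- vols[selected]
    fa <- tryCatch({
      say("[%s] focused interface alignment", spec$name)
      align_focused(fvols, spec$align, pm_z_nm = pm_z)
    }, error = function(e) e)
    if (inherits(fa, "error")) return(fail("align_focused", fa))
    report$stages$align_focused <- list(scores = fa$scores)

    sym <- tryCatch({
      say("[%s] stage-2 classes, pooled average, symmetry", spec$name)
      n2 <- min(spec$classes$n_classes_stage2, length(fvols))
      labs2 <- hac_classify(fa$profiles, n2, spec$classes$linkage)
      # analyse the average at the working resolution; the matching
      # angular smoothing is applied to the per-particle profiles
      avg <- lowpass_filter(fa$average, spec$align$lowpass_cutoff_nm)
      smooth_deg <- spec$align$lowpass_cutoff_nm /
        mean(spec$align$annulus_nm) * 180 / pi / 2.355
      spect <- rotational_spectrum(avg, pm_z_nm = pm_z,
                                   slab_nm = spec$align$slab_nm,
                                   annulus_nm = spec$align$annulus_nm,
                                   profiles = fa$profiles,
                                   smooth_deg = smooth_deg,
                                   rng_seed = spec$rng_seed + 101L)
      ring <- ring_peaks(avg, pm_z_nm = pm_z,
                         slab_nm = spec$align$slab_nm,
                         annulus_nm = spec$align$annulus_nm,
                         expected_n = spect$detected_order)
      list(labs2 = labs2, avg = avg, spect = spect, ring = ring)
    }, error = function(e) e)
    if (inherits(sym, "error")) return(fail("symmetry", sym))
    report$stages$classify_stage2 <- list(
      n_classes = length(unique(sym$labs2)))
    report$recovered$detected_order <- sym$spect$detected_order
    report$recovered$symmetry_p_value <- sym$spect$p_value
    report$recovered$symmetry_power <- unname(max(sym$spect$power))
    report$recovered$n_peaks <- sym$ring$n_peaks
    report$recovered$mean_spacing_deg <-
      if (sym$ring$n_peaks > 1) mean(sym$ring$spacings_deg) else NA_real_
    report$recovered$ring_diameter_nm <- sym$ring$ring_diameter_nm
    report$average <- sym$avg
    report$spectrum <- sym$spect
    report$ring <- sym$ring
    report$profiles <- fa$profiles
  }

  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  class(report) <- "experiment_report"
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("experiment '%s' (seed %d, n = %d)%s\n", x$name, x$seed,
              x$n_particles,
              if (is.null(x$failed)) "" else
                sprintf(" FAILED at stage '%s': %s", x$failed$stage,
                        x$failed$message)))
  r <- x$recovered
  if (!is.null(r$subset_mean_nm))
    cat(sprintf("  selected subset: mean %.2f nm, sd %.2f nm\n",
                r$subset_mean_nm, r$subset_sd_nm))
  if (!is.null(r$refined_sd_nm))
    cat(sprintf("  refined subset:  mean %.2f nm, sd %.2f nm\n",
                r$refined_mean_nm, r$refined_sd_nm))
  if (!is.null(r$detected_order))
    cat(sprintf("  symmetry: order %d (p = %.4g), %d peaks, mean spacing %.1f deg, ring %.1f nm\n",
                r$detected_order, r$symmetry_p_value, r$n_peaks,
                r$mean_spacing_deg %||% NA, r$ring_diameter_nm))
  if (!is.null(x$elapsed_s)) cat(sprintf("  elapsed: %.1f s\n", x$elapsed_s))
  invisible(x)
}

#' Write an experiment report as JSON
#'
#' Serializes the scalar diagnostics of a report (volumes and profile
#' matrices are omitted) to a JSON file.
#'
#' @param report an `experiment_report`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path) {
  keep <- report[c("name", "seed", "n_particles", "stages", "recovered",
                   "failed", "elapsed_s")]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
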