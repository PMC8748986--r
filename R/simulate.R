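#' Parameters of the synthetic 3D-tissue generator
#'
#' The generator emulates the statistical structure of epidermal nucleus
#' segmentations: a hard-core point pattern in a slab (nuclei cannot
#' overlap), lognormal nucleus volumes, a tunable mean sphericity, and an
#' "atypical" mixture component of enlarged, irregular nuclei whose
#' prevalence grows with lesion severity. Defaults are desk-scale study
#' conditions: a 0.3 x 0.2 mm en-face field (about 600 nuclei at healthy
#' density, spaced ~21 um in 3D, well under the 50 um neighbor cutoff),
#' a 100 um slab (epidermis-scale), volumes with median 150 um^3 and
#' geometric SD 1.3, and mean compactness 0.75.
#'
#' @param fov_x_mm,fov_y_mm En-face field of view, mm.
#' @param slab_z_um Slab depth, um.
#' @param target_density Target en-face density, nuclei per mm^2.
#' @param hardcore_min_dist Minimum center-to-center distance, um.
#' @param volume_median Median nucleus volume, um^3.
#' @param volume_gsd Geometric standard deviation of volumes (> 1).
#' @param compactness_mean,compactness_sd Target mean and spread of
#'   per-nucleus compactness, in (0, 1].
#' @param atypical_fraction Probability a nucleus is drawn from the
#'   atypical component.
#' @param atypical_volume_factor Volume multiplier of atypical nuclei.
#' @param atypical_roughness_factor Surface-perturbation amplitude
#'   multiplier of atypical nuclei (lowers their compactness).
#' @param image_volume_jitter_gsd Between-image biological variability:
#'   lognormal multiplier (geometric SD) applied to the volume median of
#'   each image. Set to 1 for none.
#' @param image_compactness_jitter_sd Between-image normal offset on the
#'   compactness target mean.
#' @param image_density_jitter_gsd Lognormal subject multiplier on the
#'   per-image target density (geometric SD; 1 for none).
#' @param image_atypia_jitter_gsd Lognormal severity multiplier on the
#'   per-image atypical fraction (capped at 0.9; 1 for none), emulating
#'   lesion-to-lesion heterogeneity.
#' @param seed Default seed for [simulate_image()].
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(fov_x_mm = 0.3, fov_y_mm = 0.2, slab_z_um = 100,
                          target_density = 10000, hardcore_min_dist = 7,
                          volume_median = 150, volume_gsd = 1.3,
                          compactness_mean = 0.75, compactness_sd = 0.08,
                          atypical_fraction = 0,
                          atypical_volume_factor = 2.5,
                          atypical_roughness_factor = 2,
                          image_volume_jitter_gsd = 1.12,
                          image_compactness_jitter_sd = 0.03,
                          image_density_jitter_gsd = 1.10,
                          image_atypia_jitter_gsd = 2.0,
                          seed = 1L) {
  stopifnot(fov_x_mm > 0, fov_y_mm > 0, slab_z_um > 0, target_density > 0,
            hardcore_min_dist >= 0, volume_median > 0, volume_gsd >= 1,
            compactness_mean > 0, compactness_mean <= 1, compactness_sd >= 0,
            atypical_fraction >= 0, atypical_fraction <= 1,
            atypical_volume_factor > 0, atypical_roughness_factor > 0,
            image_volume_jitter_gsd >= 1, image_compactness_jitter_sd >= 0,
            image_density_jitter_gsd >= 1, image_atypia_jitter_gsd >= 1)
  structure(as.list(environment()), class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat("<tissue_params> fov ", x$fov_x_mm, "x", x$fov_y_mm, " mm, slab ",
      x$slab_z_um, " um, density ", x$target_density, "/mm^2, atypical ",
      100 * x$atypical_fraction, "%\n", sep = "")
  invisible(x)
}

# smooth low-order angular perturbation field evaluated on the direction
# set: a random combination of degree-2 Legendre lobes, normalized to
# zero mean and unit SD across directions
random_surface_field <- function(dirs) {
  v <- matrix(rnorm(12), 4, 3)
  v <- v / sqrt(rowSums(v^2))
  coefs <- rnorm(4)
  ct <- dirs$directions %*% t(v)
  f <- as.vector(((3 * ct^2 - 1) / 2) %*% coefs)
  s <- sd(f)
  if (s < 1e-12) f else (f - mean(f)) / s
}

# amplitude -> mean realized compactness curve for a direction set;
# probe shapes share the construction of simulate_image
.sim_cache <- new.env(parent = emptyenv())

roughness_curve <- function(dirs, n_probe = 24) {
  key <- paste0("curve_", dirs$n_rays)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  amps <- c(0, 0.02, 0.05, 0.09, 0.14, 0.2, 0.28, 0.4, 0.55, 0.75, 1, 1.3)
  curve <- with_seed(769345L, {
    fields <- replicate(n_probe, random_surface_field(dirs))
    vapply(amps, function(a) {
      rays <- t(pmax(1 + a * fields, 0.15))
      mean(shape_metrics(shape_table(matrix(0, n_probe, 3), rays), dirs)$compactness)
    }, numeric(1))
  })
  out <- list(amps = amps, compactness = curve)
  .sim_cache[[key]] <- out
  out
}

amp_for_compactness <- function(target, dirs) {
  cv <- roughness_curve(dirs)
  # curve is monotone decreasing in amplitude
  approx(x = rev(cv$compactness), y = rev(cv$amps),
         xout = pmin(pmax(target, min(cv$compactness)), max(cv$compactness)),
         rule = 2)$y
}

#' Simulate one 3D image of segmented nuclei
#'
#' The nucleus count is Poisson with mean `target_density` times the
#' en-face area (a hard-core-thinned Poisson process), and each image
#' draws its own biological offsets (volume-median multiplier and
#' compactness-target shift), so images of one class differ the way
#' subjects do. Centers are placed by hard-core rejection sampling
#' (uniform proposals, rejected within `hardcore_min_dist` of an accepted
#' center). Each nucleus draws a target volume from the lognormal law
#' (multiplied by
#' `atypical_volume_factor` with probability `atypical_fraction`), a
#' target compactness from the truncated normal law, and a smooth
#' low-order angular perturbation whose amplitude is calibrated so the
#' realized compactness matches the target on average (atypical nuclei
#' get `atypical_roughness_factor` times the amplitude). Rays are rescaled
#' so each realized polyhedron volume equals its target exactly. Fully
#' deterministic given the seed.
#'
#' @param params A [tissue_params()] object.
#' @param diagnosis Diagnosis label stored with the image.
#' @param dirs A [direction_set()]; default 96 rays.
#' @param image_id,patient_id Identifiers.
#' @param seed Seed (defaults to `params$seed`).
#' @return List with `shapes` (shape table) and `info` (one manifest row:
#'   identifiers, diagnosis, seed, field-of-view extents).
#' @export
simulate_image <- function(params, diagnosis = "healthy", dirs = NULL,
                           image_id = "img1", patient_id = "pat1",
                           seed = NULL) {
  stopifnot(inherits(params, "tissue_params"))
  is_pathological(diagnosis) # validates the label
  dirs <- dirs %||% direction_set(96)
  seed <- seed %||% params$seed
  fx <- params$fov_x_mm * 1000; fy <- params$fov_y_mm * 1000
  n_expected <- params$target_density * params$fov_x_mm * params$fov_y_mm
  if (round(n_expected) < 1) stop("empty image: target density gives 0 nuclei")

  with_seed(seed, {
    dens_mult <- exp(rnorm(1, 0, log(params$image_density_jitter_gsd)))
    n_target <- stats::rpois(1, n_expected * dens_mult)
    if (n_target < 1) stop("empty image: Poisson draw gave 0 nuclei")
    vol_median <- params$volume_median *
      exp(rnorm(1, 0, log(params$image_volume_jitter_gsd)))
    comp_mean <- params$compactness_mean +
      rnorm(1, 0, params$image_compactness_jitter_sd)
    frac <- min(0.9, params$atypical_fraction *
                  exp(rnorm(1, 0, log(params$image_atypia_jitter_gsd))))
    # hard-core rejection sampling of centers
    ctr <- matrix(NA_real_, n_target, 3)
    n_acc <- 0L
    attempts <- 0L
    max_attempts <- 60L * n_target
    h2 <- params$hardcore_min_dist^2
    while (n_acc < n_target && attempts < max_attempts) {
      attempts <- attempts + 1L
      p <- c(runif(1, 0, fx), runif(1, 0, fy), runif(1, 0, params$slab_z_um))
      if (n_acc > 0) {
        d2 <- (ctr[seq_len(n_acc), 1] - p[1])^2 +
              (ctr[seq_len(n_acc), 2] - p[2])^2 +
              (ctr[seq_len(n_acc), 3] - p[3])^2
        if (min(d2) < h2) next
      }
      n_acc <- n_acc + 1L
      ctr[n_acc, ] <- p
    }
    if (n_acc < n_target) {
      warning("hard-core packing shortfall for ", image_id, ": placed ",
              n_acc, " of ", n_target, " nuclei")
      ctr <- ctr[seq_len(n_acc), , drop = FALSE]
    }
    n <- n_acc

    atypical <- runif(n) < frac
    vol <- rlnorm(n, meanlog = log(vol_median),
                  sdlog = log(params$volume_gsd))
    vol[atypical] <- vol[atypical] * params$atypical_volume_factor
    target_c <- pmin(0.99, pmax(0.35, rnorm(n, comp_mean,
                                            params$compactness_sd)))
    amp <- amp_for_compactness(target_c, dirs)
    amp[atypical] <- amp[atypical] * params$atypical_roughness_factor

    radius <- (3 * vol / (4 * pi))^(1 / 3)
    rays <- matrix(NA_real_, n, dirs$n_rays)
    for (i in seq_len(n)) {
      f <- random_surface_field(dirs)
      rays[i, ] <- radius[i] * pmax(1 + amp[i] * f, 0.15)
    }
    # rescale so each realized polyhedron volume equals its target
    fct <- dirs$faces
    raw_vol <- as.vector((rays[, fct[, 1], drop = FALSE] *
                          rays[, fct[, 2], drop = FALSE] *
                          rays[, fct[, 3], drop = FALSE]) %*% (dirs$face_det / 6))
    rays <- rays * (vol / raw_vol)^(1 / 3)

    shapes <- shape_table(ctr, rays, image_id = image_id,
                          nucleus_id = seq_len(n))
    info <- tibble::tibble(
      image_id = image_id, patient_id = patient_id, diagnosis = diagnosis,
      seed = seed, fov_x_mm = params$fov_x_mm, fov_y_mm = params$fov_y_mm,
      slab_z_um = params$slab_z_um, n_nuclei = n
    )
    list(shapes = shapes, info = info)
  })
}

#' Per-class generator presets of graded severity
#'
#' Healthy baseline (with a 4% background of irregular nuclei — normal
#' skin is not atypia-free), then subclinical AK (mild), AK (moderate)
#' and Bowen (strong) presets differing in en-face density (lower in
#' lesional skin) and in the prevalence of the enlarged/irregular
#' atypical component (15%, 35%, 60% before the per-image severity
#' multiplier), reproducing the directions observed in lesional skin:
#' lower density, larger and more heterogeneous volumes, lower
#' compactness, larger inter-nucleus distances, with severity ordered
#' subclinical AK < AK < Bowen.
#'
#' @param base A [tissue_params()] object used as the healthy baseline.
#' @return Named list of `tissue_params`, one per diagnosis class.
#' @export
tissue_presets <- function(base = tissue_params()) {
  modify <- function(p, ...) {
    do.call(tissue_params, utils::modifyList(unclass(p), list(...)))
  }
  list(
    healthy = modify(base, atypical_fraction = 0.04),
    subclinical_ak = modify(base, target_density = 9000,
                            atypical_fraction = 0.15),
    ak = modify(base, target_density = 8000, atypical_fraction = 0.35),
    bowen = modify(base, target_density = 7000, atypical_fraction = 0.60)
  )
}

#' Simulate a seeded cohort of 3D images
#'
#' Class counts default to the clinical cohort layout this pipeline is
#' designed around: 114 healthy, 34 subclinical AK, 30 AK and 7 Bowen
#' images (185 in total). Per-image seeds are derived from the master
#' seed, so cohorts are bit-reproducible.
#'
#' @param n_per_class Named integer vector of image counts per diagnosis.
#' @param presets Named list of [tissue_params()] per class
#'   ([tissue_presets()] by default).
#' @param seed Master seed.
#' @param dirs A [direction_set()].
#' @param n_patients_per_class Images are attributed to this many
#'   patients per class, round-robin.
#' @return List with `shapes` (all images stacked) and `manifest`
#'   (image_id, patient_id, diagnosis, seed, field of view).
#' @export
simulate_cohort <- function(n_per_class = c(healthy = 114,
                                            subclinical_ak = 34,
                                            ak = 30, bowen = 7),
                            presets = tissue_presets(), seed = 1L,
                            dirs = NULL,
                            n_patients_per_class = c(healthy = 38,
                                                     subclinical_ak = 18,
                                                     ak = 22, bowen = 7)) {
  dirs <- dirs %||% direction_set(96)
  classes <- names(n_per_class)
  bad <- setdiff(classes, names(presets))
  if (length(bad) > 0) stop("no preset for class(es): ", paste(bad, collapse = ", "))
  is_pathological(classes)
  n_total <- sum(n_per_class)
  img_seeds <- with_seed(seed, sample.int(2147483646L, n_total))
  shapes <- vector("list", n_total)
  infos <- vector("list", n_total)
  idx <- 0L
  for (cls in classes) {
    npat <- max(1L, n_patients_per_class[[cls]] %||% n_per_class[[cls]])
    for (i in seq_len(n_per_class[[cls]])) {
      idx <- idx + 1L
      sim <- simulate_image(
        presets[[cls]], diagnosis = cls, dirs = dirs,
        image_id = sprintf("%s_%03d", cls, i),
        patient_id = sprintf("%s_pat%02d", cls, (i - 1L) %% npat + 1L),
        seed = img_seeds[idx]
      )
      shapes[[idx]] <- sim$shapes
      infos[[idx]] <- sim$info
    }
  }
  list(shapes = dplyr::bind_rows(shapes), manifest = dplyr::bind_rows(infos))
}
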