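## Synthetic age-encoded brain phantoms.
##
## Each phantom is a cubic volume holding four tissue classes: background,
## white matter (WM), non-white-matter brain tissue (NWM, a cortical shell),
## and a mirrored pair of lateral-ventricle (LV) ellipsoids whose size grows
## linearly with the subject's chronological age. The LV size is the only age
## signal, which makes the phantoms a controlled stand-in for skull-stripped,
## registered T1-weighted volumes with anatomical segmentations.

#' Phantom generator parameters
#'
#' @param grid_size voxels per axis of the cubic volume (>= 16).
#' @param voxel_mm isotropic voxel edge length in mm.
#' @param brain_radius_frac fraction of the half-grid occupied by the largest
#'   brain semi-axis.
#' @param base_ventricle_radius_vox mean LV radius (voxels) at `age_min`.
#' @param ventricle_growth_vox_per_year mean LV radius increment per year of
#'   age.
#' @param ventricle_radius_sd between-subject standard deviation of the LV
#'   radius (voxels) around its age-expected value, truncated at two standard
#'   deviations. Real cohorts show large ventricular variability at any given
#'   age, so the age trend is statistical, not deterministic; set to 0 for a
#'   deterministic radius.
#' @param tissue_means named numeric vector of intensity means for
#'   `wm`, `nwm`, `lv`; defaults are T1-like (WM bright, CSF dark).
#' @param tissue_sds named numeric vector of intensity standard deviations.
#' @param age_min youngest age the geometry is anchored to: at `age_min` the
#'   LV radius equals `base_ventricle_radius_vox`.
#' @param age_max oldest age the geometry must accommodate; used to verify the
#'   largest ventricle stays strictly inside the white matter.
#' @param seed RNG seed for intensity sampling.
#' @return a list of class `phantom_params`.
#' @export
phantom_params <- function(grid_size = 32L,
                           voxel_mm = 2,
                           brain_radius_frac = 0.9,
                           base_ventricle_radius_vox = 2,
                           ventricle_growth_vox_per_year = 0.02,
                           ventricle_radius_sd = 1,
                           tissue_means = c(wm = 110, nwm = 80, lv = 30),
                           tissue_sds = c(wm = 8, nwm = 10, lv = 6),
                           age_min = 40,
                           age_max = 90,
                           seed = 1L) {
  p <- list(grid_size = as.integer(grid_size), voxel_mm = voxel_mm,
            brain_radius_frac = brain_radius_frac,
            base_ventricle_radius_vox = base_ventricle_radius_vox,
            ventricle_growth_vox_per_year = ventricle_growth_vox_per_year,
            ventricle_radius_sd = ventricle_radius_sd,
            tissue_means = tissue_means, tissue_sds = tissue_sds,
            age_min = age_min, age_max = age_max, seed = as.integer(seed))
  class(p) <- "phantom_params"
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  if (p$grid_size < 16L) stop_arg("grid_size must be >= 16")
  if (p$base_ventricle_radius_vox < 1) stop_arg("base_ventricle_radius_vox must be >= 1")
  if (p$ventricle_radius_sd < 0) stop_arg("ventricle_radius_sd must be >= 0")
  if (any(p$tissue_sds < 0)) stop_arg("tissue_sds must all be >= 0")
  need <- c("wm", "nwm", "lv")
  if (!all(need %in% names(p$tissue_means)) || !all(need %in% names(p$tissue_sds)))
    stop_arg("tissue_means and tissue_sds must name wm, nwm, lv")
  if (anyDuplicated(p$tissue_means[need]))
    stop_arg("tissue intensity means must be pairwise distinct")
  if (p$age_min >= p$age_max) stop_arg("age_min must be < age_max")
  ## the largest ventricle (age_max plus the truncated jitter) must fit
  ## strictly inside the white matter
  geo <- phantom_geometry(p)
  r_max <- ventricle_radius(p$age_max, p) + 2 * p$ventricle_radius_sd
  lv_outer <- geo$lv_offset_x + r_max * geo$lv_shape[1L]
  if (lv_outer >= geo$wm_semi[1L] ||
      r_max * geo$lv_shape[2L] >= geo$wm_semi[2L] ||
      r_max * geo$lv_shape[3L] >= geo$wm_semi[3L])
    stop_arg("ventricle at age_max does not fit inside the white matter ellipsoid; ",
             "reduce ventricle_growth_vox_per_year or enlarge the grid")
  invisible(p)
}

## fixed shape ratios: a mildly anisotropic brain, a WM core, and two
## antero-posteriorly elongated LV ellipsoids mirrored about the midline
phantom_geometry <- function(p) {
  half <- p$grid_size / 2
  brain_semi <- p$brain_radius_frac * half * c(1, 0.92, 0.85)
  wm_semi <- 0.72 * brain_semi
  list(centre = (p$grid_size + 1) / 2,
       brain_semi = brain_semi,
       wm_semi = wm_semi,
       lv_offset_x = 0.42 * wm_semi[1L],
       lv_shape = c(0.55, 1.30, 0.80))
}

#' Age-expected LV radius
#'
#' The deterministic component of the ventricle encoding:
#' `base + growth * (ca - age_min)`. A generated subject's radius adds a
#' seeded, truncated Gaussian jitter of standard deviation
#' `ventricle_radius_sd` around this value.
#'
#' @param ca chronological age in years.
#' @param params a [phantom_params()] object.
#' @return radius in voxels.
#' @export
ventricle_radius <- function(ca, params) {
  params$base_ventricle_radius_vox +
    params$ventricle_growth_vox_per_year * (ca - params$age_min)
}

#' Subject record
#'
#' @param subject_id opaque identifier.
#' @param ca chronological age in years (finite, positive).
#' @return a list of class `subject_record`.
#' @export
subject_record <- function(subject_id, ca) {
  assert_scalar_num(ca, "ca")
  if (ca <= 0) stop_arg("ca must be > 0")
  structure(list(subject_id = as.character(subject_id), ca = ca),
            class = "subject_record")
}

#' Generate one labeled phantom volume
#'
#' Builds the label geometry from the subject's age-expected ventricle radius
#' plus a seeded between-subject jitter, then draws voxel intensities per
#' tissue class from Gaussian distributions (clipped at zero). Background
#' voxels are exactly zero. Deterministic given `(record, params, seed)`.
#'
#' @param record a [subject_record()].
#' @param params a [phantom_params()].
#' @param seed RNG seed for the intensity draw; defaults to `params$seed`.
#' @return list with `intensity` ([intensity_volume()]) and `labels`
#'   ([label_volume()]).
#' @export
generate_phantom <- function(record, params, seed = params$seed) {
  geo <- phantom_geometry(params)
  g <- params$grid_size
  r <- ventricle_radius(record$ca, params)
  if (params$ventricle_radius_sd > 0) {
    jit <- withr::with_seed(derive_seed(seed, "lv-jitter"),
                            stats::rnorm(1, 0, params$ventricle_radius_sd))
    jit <- max(min(jit, 2 * params$ventricle_radius_sd),
               -2 * params$ventricle_radius_sd)
    r <- max(r + jit, 1)
  }
  lv_semi <- r * geo$lv_shape
  if (geo$lv_offset_x + lv_semi[1L] >= geo$wm_semi[1L] ||
      any(lv_semi[2:3] >= geo$wm_semi[2:3]))
    stop_arg("ventricle implied by ca = ", record$ca,
             " exceeds the white matter ellipsoid")

  ax <- seq_len(g) - geo$centre
  ## squared normalized ellipsoid coordinates, built axis-wise
  sq <- function(semi, offset_x = 0) {
    ex <- (ax - offset_x)^2 / semi[1L]^2
    ey <- ax^2 / semi[2L]^2
    ez <- ax^2 / semi[3L]^2
    outer(outer(ex, ey, `+`), ez, `+`)
  }
  inside_brain <- sq(geo$brain_semi) <= 1
  inside_wm <- sq(geo$wm_semi) <= 1
  inside_lv <- (sq(lv_semi, geo$lv_offset_x) <= 1) | (sq(lv_semi, -geo$lv_offset_x) <= 1)
  if (any(inside_lv & !inside_wm))
    stop_arg("ventricle voxels fall outside the white matter core")

  lm <- default_label_map()
  lab <- array(lm[["background"]], c(g, g, g))
  lab[inside_brain] <- lm[["nwm"]]
  lab[inside_wm] <- lm[["wm"]]
  lab[inside_lv] <- lm[["lv"]]

  img <- withr::with_seed(seed, {
    v <- array(0, c(g, g, g))
    for (tl in c("wm", "nwm", "lv")) {
      sel <- lab == lm[[tl]]
      v[sel] <- pmax(stats::rnorm(sum(sel), params$tissue_means[[tl]],
                                  params$tissue_sds[[tl]]), 0)
    }
    v
  })
  list(intensity = intensity_volume(img, params$voxel_mm),
       labels = label_volume(lab))
}

#' Generate a phantom cohort with uniformly distributed ages
#'
#' Ages are drawn uniformly over `[age_low, age_high]`; each subject gets an
#' independent intensity-noise seed derived from `seed`, so the cohort is
#' reproducible and order-independent.
#'
#' @param n number of subjects (>= 0).
#' @param age_low,age_high age range in years, `age_low < age_high`.
#' @param params a [phantom_params()]; its `age_min`/`age_max` must cover the
#'   requested range.
#' @param seed master seed.
#' @return list of subjects, each a list with `record`, `intensity`, `labels`.
#' @export
generate_cohort <- function(n, age_low, age_high, params = phantom_params(),
                            seed = params$seed) {
  if (length(n) != 1L || n < 0) stop_arg("n must be a non-negative count")
  if (age_low >= age_high) stop_arg("age_low must be < age_high")
  n <- as.integer(n)
  if (n == 0L) return(list())
  ages <- withr::with_seed(derive_seed(seed, "cohort-ages"),
                           stats::runif(n, age_low, age_high))
  lapply(seq_len(n), function(i) {
    rec <- subject_record(sprintf("S%04d", i), ages[i])
    ph <- generate_phantom(rec, params, seed = derive_seed(seed, "phantom", i))
    list(record = rec, intensity = ph$intensity, labels = ph$labels)
  })
}

#' Chronological ages of a cohort
#' @param cohort result of [generate_cohort()].
#' @return numeric vector of ages.
#' @export
cohort_ages <- function(cohort) {
  vapply(cohort, function(s) s$record$ca, numeric(1))
}

#' Write a cohort to disk as NIfTI volumes plus a CSV manifest
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return path to the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(s) {
    ipath <- file.path(dir, paste0(s$record$subject_id, "_t1.nii.gz"))
    lpath <- file.path(dir, paste0(s$record$subject_id, "_labels.nii.gz"))
    write_volume_nifti(s$intensity, ipath)
    write_volume_nifti(s$labels, lpath, voxel_mm = voxel_mm(s$intensity))
    data.frame(subject_id = s$record$subject_id, ca = s$record$ca,
               intensity_path = ipath, labels_path = lpath,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}
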