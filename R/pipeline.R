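## Experiment orchestration: simulate -> perturb -> train -> attribute ->
## evaluate, each stage reading and writing plain files (NIfTI volumes, CSV
## manifests, JSON sidecars) under one output directory, with every random
## choice derived from a single master seed.

#' Full experiment configuration
#'
#' @param phantom a [phantom_params()].
#' @param n_subjects cohort size.
#' @param age_low,age_high cohort age range in years.
#' @param split named fractions for train/val/test; must sum to 1.
#' @param cnn a [cnn_config()]; its `input_size` must equal the phantom grid.
#' @param attribution an [attribution_options()].
#' @param methods attribution methods to run (default all seven).
#' @param nmi_bins histogram bins for the NMI metric.
#' @param seed master seed; all stage seeds are derived from it.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(phantom = phantom_params(),
                              n_subjects = 200L,
                              age_low = 40, age_high = 90,
                              split = c(train = 0.8, val = 0.1, test = 0.1),
                              cnn = cnn_config(input_size = phantom$grid_size,
                                               n_blocks = 2L,
                                               filters = c(4L, 8L),
                                               conv_kernel = 3L,
                                               dropout_blocks = 2L,
                                               dense_sizes = 32L,
                                               learning_rate = 1e-3,
                                               patience = 8L,
                                               max_epochs = 30L,
                                               batch_size = 8L),
                              attribution = attribution_options(),
                              methods = ATTRIBUTION_METHODS,
                              nmi_bins = 64L,
                              seed = 1L) {
  if (abs(sum(split) - 1) > 1e-9) stop_arg("split fractions must sum to 1")
  if (!all(c("train", "val", "test") %in% names(split)))
    stop_arg("split must name train, val, test")
  if (cnn$input_size != phantom$grid_size)
    stop_arg("cnn input_size must equal the phantom grid_size")
  if (age_low < phantom$age_min || age_high > phantom$age_max)
    stop_arg("cohort age range must lie within the phantom's age_min..age_max")
  structure(list(phantom = phantom, n_subjects = as.integer(n_subjects),
                 age_low = age_low, age_high = age_high, split = split,
                 cnn = cnn, attribution = attribution, methods = methods,
                 nmi_bins = as.integer(nmi_bins), seed = as.integer(seed)),
            class = "experiment_config")
}

#' Assign cohort subjects to train/validation/test splits
#'
#' Uses floor counts for train and validation and the remainder for test
#' (e.g. 30 subjects at 80/10/10 gives 24/3/3), over a seeded permutation,
#' so the splits are disjoint and their union is the cohort.
#'
#' @param n cohort size.
#' @param split named fractions summing to 1.
#' @param seed RNG seed.
#' @return character vector of length `n` with values
#'   `"train"`/`"val"`/`"test"`.
#' @export
assign_splits <- function(n, split, seed = 1L) {
  n_train <- floor(n * split[["train"]])
  n_val <- floor(n * split[["val"]])
  perm <- withr::with_seed(seed, sample.int(n))
  out <- character(n)
  out[perm[seq_len(n_train)]] <- "train"
  out[perm[n_train + seq_len(n_val)]] <- "val"
  out[out == ""] <- "test"
  out
}

check_out_dir <- function(out_dir, force) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !force)
    stop_arg("output directory ", out_dir,
             " is not empty; pass force = TRUE to overwrite")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  invisible(out_dir)
}

#' Simulate a phantom cohort and write it to disk
#'
#' Writes per-subject intensity and label NIfTI volumes, plus `manifest.csv`
#' with subject id, chronological age, file paths, and split assignment.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory.
#' @param force overwrite a non-empty directory.
#' @return the manifest data.frame, invisibly.
#' @export
cmd_simulate <- function(config, out_dir, force = FALSE) {
  check_out_dir(out_dir, force)
  cohort <- generate_cohort(config$n_subjects, config$age_low, config$age_high,
                            config$phantom,
                            seed = derive_seed(config$seed, "simulate"))
  write_cohort(cohort, out_dir)
  manifest <- utils::read.csv(file.path(out_dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  manifest$split <- assign_splits(nrow(manifest), config$split,
                                  seed = derive_seed(config$seed, "split"))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

read_manifest <- function(out_dir) {
  path <- file.path(out_dir, "manifest.csv")
  if (!file.exists(path)) stop_arg("no cohort manifest in ", out_dir,
                                   "; run cmd_simulate first")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

load_labels <- function(path) {
  v <- read_volume_nifti(path)
  label_volume(array(as.integer(round(v)), dim(v)))
}

#' Perturb a simulated cohort and build the surrogate ground truth
#'
#' Computes each subject's dilation coefficient from the cohort age
#' distribution, dilates the ventricles, and writes perturbed volumes, a
#' JSON ledger per subject (coefficient, replaced-voxel count, seed), the
#' cohort ground-truth map, and the fixation map.
#'
#' @param config an [experiment_config()].
#' @param out_dir directory holding a simulated cohort.
#' @return data.frame ledger, invisibly.
#' @export
cmd_perturb <- function(config, out_dir) {
  manifest <- read_manifest(out_dir)
  cas <- manifest$ca
  pairs <- vector("list", nrow(manifest))
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    vol <- read_volume_nifti(manifest$intensity_path[i])
    lab <- load_labels(manifest$labels_path[i])
    coeff <- dilation_coefficient(cas[i], cas)
    seed_i <- derive_seed(config$seed, "perturb", i)
    res <- dilate_ventricles(vol, lab, coeff, seed = seed_i)
    ppath <- file.path(out_dir, paste0(manifest$subject_id[i],
                                       "_perturbed.nii.gz"))
    write_volume_nifti(res$perturbed, ppath)
    ledger <- list(subject_id = manifest$subject_id[i], ca = cas[i],
                   coefficient = coeff,
                   n_replaced = length(res$replaced_voxels),
                   n_peripheric = length(res$peripheric_voxels),
                   seed = seed_i)
    write_json_sidecar(ledger, file.path(out_dir,
                                         paste0(manifest$subject_id[i],
                                                "_perturb.json")))
    pairs[[i]] <- list(original = vol, perturbed = res$perturbed)
    rows[[i]] <- as.data.frame(c(ledger, perturbed_path = ppath),
                               stringsAsFactors = FALSE)
  }
  gt <- build_ground_truth(pairs)
  write_volume_nifti(gt, file.path(out_dir, "ground_truth.nii.gz"),
                     voxel_mm = config$phantom$voxel_mm)
  write_volume_nifti(binarize_fixation(gt),
                     file.path(out_dir, "fixation.nii.gz"),
                     voxel_mm = config$phantom$voxel_mm)
  ledger <- do.call(rbind, rows)
  utils::write.csv(ledger, file.path(out_dir, "perturb_manifest.csv"),
                   row.names = FALSE)
  invisible(ledger)
}

load_split_volumes <- function(manifest, split, dilated, out_dir) {
  rows <- manifest[manifest$split == split, , drop = FALSE]
  if (nrow(rows) == 0L) stop_arg("split ", split, " is empty")
  paths <- if (dilated)
    file.path(out_dir, paste0(rows$subject_id, "_perturbed.nii.gz"))
  else rows$intensity_path
  if (!all(file.exists(paths)))
    stop_arg("missing volumes for split ", split,
             if (dilated) "; run cmd_perturb first")
  list(volumes = lapply(paths, read_volume_nifti), ages = rows$ca,
       subject_ids = rows$subject_id)
}

#' Train the brain-age CNN on a simulated cohort
#'
#' Trains on unperturbed volumes by default (the non-dilated model) or on
#' perturbed volumes with `dilated = TRUE` (the dilated model). Saves a JSON
#' checkpoint and a CSV training history.
#'
#' @param config an [experiment_config()].
#' @param out_dir directory holding the cohort (and, if `dilated`, the
#'   perturbed volumes).
#' @param dilated train on perturbed volumes.
#' @return the [train_model()] result, invisibly.
#' @export
cmd_train <- function(config, out_dir, dilated = FALSE) {
  manifest <- read_manifest(out_dir)
  tr <- load_split_volumes(manifest, "train", dilated, out_dir)
  va <- load_split_volumes(manifest, "val", dilated, out_dir)
  cfg <- config$cnn
  cfg$seed <- derive_seed(config$seed, if (dilated) "train-d" else "train-nd")
  cfg$geometry <- NULL
  cfg <- do.call(cnn_config, cfg[setdiff(names(cfg), "geometry")])
  model <- build_model(cfg)
  fit <- train_model(model, volume_dataset(tr$volumes, tr$ages),
                     volume_dataset(va$volumes, va$ages))
  tag <- if (dilated) "dilated" else "nondilated"
  save_model_checkpoint(fit$model,
                        file.path(out_dir, paste0("model_", tag, ".json")))
  utils::write.csv(fit$history,
                   file.path(out_dir, paste0("history_", tag, ".csv")),
                   row.names = FALSE)
  invisible(fit)
}

#' Compute saliency maps for the test split
#'
#' For each test subject and requested method, computes the raw attribution,
#' normalizes it to a saliency probability density, and writes the
#' cohort-mean map per method as NIfTI with a JSON sidecar (method, options,
#' seed).
#'
#' @param config an [experiment_config()].
#' @param out_dir experiment directory.
#' @param checkpoint path to a model checkpoint (from [cmd_train()]).
#' @param methods subset of the seven method tags.
#' @param dilated attribute on perturbed test volumes.
#' @param tag filename tag for the written maps (defaults to the checkpoint
#'   tag).
#' @return named list of cohort-mean saliency maps, invisibly.
#' @export
cmd_attribute <- function(config, out_dir, checkpoint,
                          methods = config$methods, dilated = FALSE,
                          tag = NULL) {
  bad <- setdiff(methods, ATTRIBUTION_METHODS)
  if (length(bad) > 0L) stop_arg("unknown method name(s): ",
                                 paste(bad, collapse = ", "))
  manifest <- read_manifest(out_dir)
  te <- load_split_volumes(manifest, "test", dilated, out_dir)
  model <- load_model_checkpoint(checkpoint)
  tag <- tag %||% sub("^model_(.*)\\.json$", "\\1", basename(checkpoint))
  opts <- config$attribution
  ## the baseline pool for gradient SHAP is the test cohort itself
  if (is.null(opts$gshap_baselines))
    opts$gshap_baselines <- lapply(te$volumes, as_plain_array)
  mean_maps <- list()
  for (m in methods) {
    maps <- lapply(seq_along(te$volumes), function(i) {
      o <- opts
      o$seed <- derive_seed(config$seed, paste0("attr-", m), i)
      normalize_saliency(compute_attribution(model, te$volumes[[i]], m, o))
    })
    mm <- cohort_mean_map(maps)
    mean_maps[[m]] <- mm
    write_volume_nifti(mm, file.path(out_dir,
                                     sprintf("saliency_%s_%s.nii.gz", tag, m)),
                       voxel_mm = config$phantom$voxel_mm)
    write_json_sidecar(list(method = m, tag = tag,
                            n_subjects = length(maps),
                            ig_points = opts$ig_points,
                            gshap_samples = opts$gshap_samples,
                            gshap_sigma = opts$gshap_sigma,
                            master_seed = config$seed),
                       file.path(out_dir,
                                 sprintf("saliency_%s_%s.json", tag, m)))
  }
  invisible(mean_maps)
}

#' Score written saliency maps against the ground truth
#'
#' Computes the five similarity metrics per method plus percent differences
#' against the masked-gradient baseline, and writes the report as CSV and
#' JSON.
#'
#' @param config an [experiment_config()].
#' @param out_dir experiment directory holding saliency and ground-truth
#'   maps.
#' @param tag which model's maps to evaluate (`"nondilated"` or
#'   `"dilated"`).
#' @param methods method tags expected on disk.
#' @return a `similarity_report`, invisibly.
#' @export
cmd_evaluate <- function(config, out_dir, tag = "dilated",
                         methods = config$methods) {
  gt_path <- file.path(out_dir, "ground_truth.nii.gz")
  if (!file.exists(gt_path)) stop_arg("no ground truth in ", out_dir)
  gt <- as_plain_array(read_volume_nifti(gt_path))
  gt <- gt / sum(gt)
  fixation <- binarize_fixation(gt)
  maps <- lapply(methods, function(m) {
    p <- file.path(out_dir, sprintf("saliency_%s_%s.nii.gz", tag, m))
    if (!file.exists(p)) stop_arg("missing saliency map: ", p)
    v <- as_plain_array(read_volume_nifti(p))
    if (!same_shape(v, gt)) stop_arg("map ", m, " does not match ground truth")
    v / sum(v)
  })
  names(maps) <- methods
  report <- percent_diff_vs_baseline(
    score_saliency_maps(maps, gt, fixation, config$nmi_bins),
    baseline_method = if ("MG" %in% methods) "MG" else methods[1L])
  write_similarity_report(report,
                          file.path(out_dir, paste0("report_", tag, ".csv")),
                          file.path(out_dir, paste0("report_", tag, ".json")))
  invisible(report)
}

#' Run the full experiment end to end
#'
#' simulate -> perturb -> train (non-dilated and dilated) -> attribute ->
#' evaluate, all under one master seed; two runs with the same configuration
#' produce identical reports.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory.
#' @param force overwrite a non-empty directory.
#' @return list with both similarity reports, invisibly.
#' @export
run_experiment <- function(config, out_dir, force = FALSE) {
  cmd_simulate(config, out_dir, force)
  cmd_perturb(config, out_dir)
  cmd_train(config, out_dir, dilated = FALSE)
  cmd_train(config, out_dir, dilated = TRUE)
  cmd_attribute(config, out_dir, file.path(out_dir, "model_nondilated.json"))
  cmd_attribute(config, out_dir, file.path(out_dir, "model_dilated.json"))
  reports <- list(
    nondilated = cmd_evaluate(config, out_dir, "nondilated"),
    dilated = cmd_evaluate(config, out_dir, "dilated"))
  invisible(reports)
}

#' Spatially shuffled permutation null for a saliency map's scores
#'
#' Permutes the voxels of a saliency map `n_shuffles` times (seeded) and
#' recomputes each metric, yielding a chance-level distribution against which
#' the observed scores can be tested one-sided.
#'
#' @param s normalized saliency map.
#' @param ground_truth normalized ground-truth map.
#' @param fixation binary fixation map.
#' @param n_shuffles number of permutations (default 100).
#' @param seed RNG seed.
#' @param nmi_bins histogram bins for NMI.
#' @return list with `observed` (named scores) and `null` (matrix
#'   `n_shuffles` x 5) and `p` (one-sided permutation p-values).
#' @export
shuffled_null_scores <- function(s, ground_truth, fixation, n_shuffles = 100L,
                                 seed = 1L, nmi_bins = 64L) {
  score_one <- function(m) {
    c(DC = dice(binarize_saliency_for_dice(m, fixation), fixation),
      NMI = nmi(m, ground_truth, nmi_bins),
      NSS = nss(m, fixation),
      CC = cc(m, ground_truth),
      SIM = sim(m, as_plain_array(ground_truth)))
  }
  obs <- score_one(s)
  dims <- dim(s)
  sv <- as.vector(as_plain_array(s))
  null <- withr::with_seed(seed, {
    t(vapply(seq_len(n_shuffles), function(i) {
      score_one(array(sample(sv), dims))
    }, numeric(5L)))
  })
  p <- vapply(names(obs), function(k) {
    (1 + sum(null[, k] >= obs[[k]])) / (n_shuffles + 1)
  }, numeric(1L))
  list(observed = obs, null = null, p = p)
}
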