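## Age-proportional ventricular dilation and surrogate ground truth.
##
## The perturbation enlarges the lateral ventricles into adjacent white matter
## by replacing a CA-determined fraction of adjacent-white-matter (AWM) voxel
## intensities with ventricle intensities, then re-assigns the new boundary of
## the enlarged ventricle from the adjacent non-white-matter (ANWM) intensity
## distribution. Averaging |perturbed - original| across a cohort yields a
## surrogate ground-truth map of where the synthetic age signal was injected.

## face-neighbor (6-connectivity) shift: result[i] = m[i + dir * e_axis],
## with FALSE beyond the volume border
shift_mask <- function(m, axis, dir) {
  d <- dim(m)
  out <- array(FALSE, d)
  idx_src <- vector("list", 3L)
  idx_dst <- vector("list", 3L)
  for (a in 1:3) idx_src[[a]] <- idx_dst[[a]] <- seq_len(d[a])
  if (dir > 0) {
    idx_dst[[axis]] <- seq_len(d[axis] - 1L)
    idx_src[[axis]] <- 2:d[axis]
  } else {
    idx_dst[[axis]] <- 2:d[axis]
    idx_src[[axis]] <- seq_len(d[axis] - 1L)
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

## voxels of a binary mask with at least one face neighbor outside the mask
## (the volume border counts as outside)
mask_edge_voxels <- function(mask) {
  all_inside <- array(TRUE, dim(mask))
  for (axis in 1:3) for (dir in c(-1L, 1L))
    all_inside <- all_inside & shift_mask(mask, axis, dir)
  which(mask & !all_inside)
}

## union of face neighbors of a voxel index set, as a logical mask
neighbor_mask <- function(idx, dims) {
  m <- array(FALSE, dims)
  m[idx] <- TRUE
  nb <- array(FALSE, dims)
  for (axis in 1:3) for (dir in c(-1L, 1L))
    nb <- nb | shift_mask(m, axis, dir)
  nb
}

#' Map chronological age to a dilation coefficient
#'
#' Ages at or below the cohort's 5th percentile receive coefficient 0 (no
#' dilation); ages at or above the 95th percentile receive 1 (maximum
#' dilation); ages in between are mapped linearly in age between the two
#' percentile anchors.
#'
#' @param ca chronological age in years.
#' @param cohort_cas numeric vector of cohort ages (nonempty).
#' @return a coefficient in `[0, 1]`.
#' @export
dilation_coefficient <- function(ca, cohort_cas) {
  if (length(cohort_cas) == 0L) stop_arg("cohort_cas must be nonempty")
  assert_scalar_num(ca, "ca")
  q <- stats::quantile(cohort_cas, c(0.05, 0.95), names = FALSE)
  if (q[1L] >= q[2L])
    stop_arg("degenerate cohort age distribution: 5th and 95th percentiles coincide")
  if (ca <= q[1L]) return(0)
  if (ca >= q[2L]) return(1)
  (ca - q[1L]) / (q[2L] - q[1L])
}

#' Find the edge voxels of a labeled structure
#'
#' Returns the voxels carrying `structure` that have at least one
#' face-adjacent (6-connectivity) neighbor with a different label; the volume
#' border counts as a different label.
#'
#' @param labels a [label_volume()].
#' @param structure label name (default `"lv"`).
#' @return sorted integer vector of linear voxel indices (possibly empty).
#' @export
find_edge_voxels <- function(labels, structure = "lv") {
  lm <- attr(labels, "label_map")
  if (!structure %in% names(lm)) stop_arg("unknown structure label: ", structure)
  mask_edge_voxels(as_plain_array(labels) == lm[[structure]])
}

#' Split the neighbors of ventricle edge voxels into AWM and ANWM
#'
#' Face neighbors of the edge set that are not themselves ventricle voxels are
#' split by label: white matter neighbors form the AWM set, any other
#' non-background label forms the ANWM set.
#'
#' @param labels a [label_volume()].
#' @param edges linear indices of LV edge voxels (from [find_edge_voxels()]).
#' @return list with sorted integer index vectors `awm` and `anwm`.
#' @export
split_adjacent <- function(labels, edges) {
  lm <- attr(labels, "label_map")
  lab <- as_plain_array(labels)
  nb <- neighbor_mask(edges, dim(lab))
  nb[edges] <- FALSE            # exclude the edge voxels themselves
  nb[lab == lm[["lv"]]] <- FALSE  # adjacency is to non-LV tissue only
  cand <- which(nb)
  list(awm = cand[lab[cand] == lm[["wm"]]],
       anwm = cand[lab[cand] != lm[["wm"]] & lab[cand] != lm[["background"]]])
}

#' Dilate the lateral ventricles into adjacent white matter
#'
#' Selects `round(coeff * |AWM|)` AWM voxels uniformly without replacement
#' (round half to even) and sets each selected voxel's intensity to that of
#' its nearest LV edge voxel (Euclidean distance in voxel units, ties broken
#' by lexicographic coordinate order). The edge voxels of the enlarged LV
#' region are then re-assigned the mean ANWM intensity, reflecting that
#' structure boundaries carry their own intensity distribution; this boundary
#' step is skipped when no voxel was replaced or the ANWM set is empty.
#'
#' @param volume an [intensity_volume()].
#' @param labels the paired [label_volume()].
#' @param coeff dilation coefficient in `[0, 1]`.
#' @param seed RNG seed for the AWM selection.
#' @return an object of class `perturbation_result`: list with `perturbed`
#'   (intensity volume), `replaced_voxels` and `peripheric_voxels` (sorted
#'   linear indices), and `coefficient`.
#' @export
dilate_ventricles <- function(volume, labels, coeff, seed = 1L) {
  if (!same_shape(volume, labels)) stop_arg("volume and labels differ in shape")
  assert_scalar_num(coeff, "coeff")
  if (coeff < 0 || coeff > 1) stop_arg("coeff must lie in [0, 1]")
  lm <- attr(labels, "label_map")
  lab <- as_plain_array(labels)
  dims <- dim(lab)
  lv_idx <- which(lab == lm[["lv"]])
  if (length(lv_idx) == 0L) stop_arg("label volume contains no lateral-ventricle voxels")

  edges <- find_edge_voxels(labels, "lv")
  adj <- split_adjacent(labels, edges)
  n_rep <- round(coeff * length(adj$awm))

  img <- as_plain_array(volume)
  replaced <- integer(0)
  peripheric <- integer(0)
  if (n_rep > 0L) {
    replaced <- sort(withr::with_seed(seed, sample(adj$awm, n_rep)))
    ## nearest LV edge voxel supplies the replacement intensity
    edges_lex <- order_lexicographic(edges, dims)
    ec <- index_to_coord(edges_lex, dims)
    rc <- index_to_coord(replaced, dims)
    d2 <- outer(rowSums(rc^2), rep(1, nrow(ec))) +
      outer(rep(1, nrow(rc)), rowSums(ec^2)) - 2 * rc %*% t(ec)
    nearest <- edges_lex[max.col(-d2, ties.method = "first")]
    img[replaced] <- img[nearest]
    ## re-assign the new boundary of the enlarged ventricle from ANWM
    if (length(adj$anwm) > 0L) {
      enlarged <- array(FALSE, dims)
      enlarged[lv_idx] <- TRUE
      enlarged[replaced] <- TRUE
      peripheric <- sort(mask_edge_voxels(enlarged))
      img[peripheric] <- mean(as_plain_array(volume)[adj$anwm])
    }
  }
  structure(list(perturbed = intensity_volume(img, voxel_mm(volume)),
                 replaced_voxels = replaced,
                 peripheric_voxels = peripheric,
                 coefficient = coeff),
            class = "perturbation_result")
}

#' Build the surrogate ground-truth map from perturbed/original pairs
#'
#' Voxelwise mean of `|perturbed - original|` across all pairs, normalized to
#' total mass 1. The support of this map marks where the synthetic age signal
#' was injected.
#'
#' @param pairs nonempty list; each element a list with elements `original`
#'   and `perturbed`, all volumes of one shape.
#' @return a nonnegative 3D array of total mass 1, class `sv_ground_truth`.
#' @export
build_ground_truth <- function(pairs) {
  if (length(pairs) == 0L) stop_arg("pairs must be nonempty")
  d <- dim(pairs[[1L]]$original)
  acc <- array(0, d)
  for (p in pairs) {
    if (!identical(dim(p$original), d) || !identical(dim(p$perturbed), d))
      stop_arg("all pairs must share one shape")
    acc <- acc + abs(as_plain_array(p$perturbed) - as_plain_array(p$original))
  }
  acc <- acc / length(pairs)
  total <- sum(acc)
  if (total == 0)
    stop_arg("degenerate ground truth: no pair differs anywhere")
  structure(acc / total, class = "sv_ground_truth")
}

#' Binarize a ground-truth map into a fixation map
#'
#' The fixation map is the indicator of the ground truth's nonzero support.
#'
#' @param gt a ground-truth map from [build_ground_truth()].
#' @return binary 3D array (0/1), class `sv_fixation`.
#' @export
binarize_fixation <- function(gt) {
  g <- as_plain_array(gt)
  if (!any(g > 0)) stop_arg("ground truth has empty support")
  structure(array(as.numeric(g > 0), dim(g)), class = "sv_fixation")
}
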