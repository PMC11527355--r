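## Saliency normalization and similarity scoring.
##
## Raw attributions are converted to unitless saliency probability densities
## (absolute value, total mass 1) and scored against the surrogate ground
## truth with five measures: Sorensen-Dice (DC) and normalized mutual
## information (NMI) as image-similarity measures, and normalized scan-path
## saliency (NSS), Pearson correlation (CC), and histogram intersection
## similarity (SIM) as saliency-benchmark measures. DC and NSS consume the
## binary fixation map; NMI, CC, and SIM the continuous ground truth.

#' Normalize a raw attribution into a saliency probability density
#'
#' Takes absolute values and divides by the total, so the map is nonnegative
#' with total mass 1 and comparable across methods of arbitrary scale.
#'
#' @param raw a `raw_attribution` (or bare 3D array).
#' @return 3D array of total mass 1, class `sv_saliency`, with attribute
#'   `method`.
#' @export
normalize_saliency <- function(raw) {
  dat <- if (inherits(raw, "raw_attribution")) raw$data else as_plain_array(raw)
  method <- if (inherits(raw, "raw_attribution")) raw$method else NA_character_
  a <- abs(dat)
  total <- sum(a)
  if (total == 0)
    stop_arg("degenerate attribution: all-zero field cannot be normalized")
  structure(a / total, class = "sv_saliency", method = method)
}

#' Cohort-mean saliency map
#'
#' Voxelwise mean of per-subject normalized maps, renormalized to mass 1 so
#' the density invariant is preserved.
#'
#' @param maps nonempty list of normalized saliency maps (one shape).
#' @return 3D array of total mass 1, class `sv_saliency`.
#' @export
cohort_mean_map <- function(maps) {
  if (length(maps) == 0L) stop_arg("maps must be nonempty")
  d <- dim(maps[[1L]])
  acc <- array(0, d)
  for (m in maps) {
    if (!identical(dim(m), d)) stop_arg("all maps must share one shape")
    acc <- acc + as_plain_array(m)
  }
  acc <- acc / length(maps)
  structure(acc / sum(acc), class = "sv_saliency",
            method = attr(maps[[1L]], "method"))
}

#' Sorensen-Dice coefficient of two binary maps
#'
#' `2 |A intersect B| / (|A| + |B|)`: 0 for disjoint supports, 1 for perfect
#' overlap.
#'
#' @param a,b binary arrays of one shape, not both empty.
#' @return score in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!same_shape(a, b)) stop_arg("maps differ in shape")
  av <- as_plain_array(a) != 0
  bv <- as_plain_array(b) != 0
  na <- sum(av); nb <- sum(bv)
  if (na + nb == 0L) stop_arg("Dice undefined: both maps are empty")
  2 * sum(av & bv) / (na + nb)
}

#' Binarize a continuous saliency map for the Dice comparison
#'
#' Selects the N most salient voxels, where N is the size of the fixation
#' support, so the comparison is threshold-free and scale-invariant. Ties at
#' the threshold are broken by lexicographic (x, y, z) coordinate order.
#'
#' @param s normalized saliency map.
#' @param fixation binary fixation map of the same shape.
#' @return binary array with exactly N ones.
#' @export
binarize_saliency_for_dice <- function(s, fixation) {
  if (!same_shape(s, fixation)) stop_arg("maps differ in shape")
  n <- sum(as_plain_array(fixation) != 0)
  if (n == 0L) stop_arg("fixation map is empty")
  if (n > length(s)) stop_arg("fixation support exceeds the voxel count")
  dims <- dim(s)
  sv <- as.vector(as_plain_array(s))
  co <- index_to_coord(seq_along(sv), dims)
  ord <- order(-sv, co[, 1L], co[, 2L], co[, 3L])
  out <- array(0, dims)
  out[ord[seq_len(n)]] <- 1
  out
}

#' Normalized mutual information of two scalar maps
#'
#' `(H(A) + H(B)) / H(A, B)` from a joint histogram over equal-width bins
#' spanning each map's own range: 1 for independent maps, 2 for perfectly
#' predictable ones.
#'
#' @param a,b scalar arrays of one shape, neither constant.
#' @param bins number of histogram bins per axis (default 64).
#' @return score in `[1, 2]`.
#' @export
nmi <- function(a, b, bins = 64L) {
  if (!same_shape(a, b)) stop_arg("maps differ in shape")
  av <- as.vector(as_plain_array(a))
  bv <- as.vector(as_plain_array(b))
  if (max(av) == min(av) || max(bv) == min(bv))
    stop_arg("NMI undefined for a constant map (zero entropy)")
  ia <- bin_index(av, bins)
  ib <- bin_index(bv, bins)
  joint <- table(ia, ib) / length(av)
  pa <- rowSums(joint)
  pb <- colSums(joint)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  (ent(pa) + ent(pb)) / ent(joint)
}

bin_index <- function(v, bins) {
  r <- range(v)
  i <- floor((v - r[1L]) / (r[2L] - r[1L]) * bins) + 1L
  pmin(i, bins)
}

#' Normalized scan-path saliency
#'
#' The saliency map is z-scored over all voxels (population standard
#' deviation), and the mean z-value over the fixation support is returned: the
#' average standardized saliency the method assigns to ground-truth voxels.
#'
#' @param s saliency map (non-constant).
#' @param fixation binary fixation map of the same shape (nonempty).
#' @return finite score (unbounded).
#' @export
nss <- function(s, fixation) {
  if (!same_shape(s, fixation)) stop_arg("maps differ in shape")
  sv <- as.vector(as_plain_array(s))
  sdp <- sqrt(mean((sv - mean(sv))^2))
  if (sdp == 0) stop_arg("NSS undefined for a constant saliency map")
  fix <- as.vector(as_plain_array(fixation)) != 0
  if (!any(fix)) stop_arg("fixation map is empty")
  z <- (sv - mean(sv)) / sdp
  mean(z[fix])
}

#' Pearson correlation of two maps
#'
#' Covariance divided by the product of standard deviations, over all voxels.
#'
#' @param a,b arrays of one shape, neither constant.
#' @return score in `[-1, 1]`.
#' @export
cc <- function(a, b) {
  if (!same_shape(a, b)) stop_arg("maps differ in shape")
  av <- as.vector(as_plain_array(a))
  bv <- as.vector(as_plain_array(b))
  if (stats::sd(av) == 0 || stats::sd(bv) == 0)
    stop_arg("CC undefined for a constant map")
  stats::cor(av, bv)
}

#' Histogram-intersection similarity of two probability maps
#'
#' Both maps must be normalized to total mass 1; the score is the sum of
#' voxelwise minima: 0 for disjoint supports, 1 iff the maps are identical.
#'
#' @param a,b nonnegative arrays of one shape, each summing to 1 (within
#'   1e-6).
#' @return score in `[0, 1]`.
#' @export
sim <- function(a, b) {
  if (!same_shape(a, b)) stop_arg("maps differ in shape")
  av <- as_plain_array(a); bv <- as_plain_array(b)
  if (abs(sum(av) - 1) > 1e-6 || abs(sum(bv) - 1) > 1e-6)
    stop_arg("SIM requires maps normalized to total mass 1")
  sum(pmin(av, bv))
}

#' Score saliency maps against the ground truth with all five metrics
#'
#' DC and NSS are computed against the binary fixation map (DC after top-N
#' binarization of the saliency map); NMI, CC, and SIM against the continuous
#' normalized ground truth.
#'
#' @param maps named list of normalized saliency maps (names = method tags).
#' @param ground_truth normalized ground-truth map from
#'   [build_ground_truth()].
#' @param fixation binary fixation map from [binarize_fixation()]; derived
#'   from `ground_truth` when `NULL`.
#' @param nmi_bins histogram bins for NMI.
#' @return data.frame with one row per method and columns
#'   `method, DC, NMI, NSS, CC, SIM`.
#' @export
score_saliency_maps <- function(maps, ground_truth, fixation = NULL,
                                nmi_bins = 64L) {
  if (is.null(fixation)) fixation <- binarize_fixation(ground_truth)
  rows <- lapply(names(maps), function(m) {
    s <- maps[[m]]
    if (!same_shape(s, ground_truth)) stop_arg("map ", m, " differs in shape")
    data.frame(method = m,
               DC = dice(binarize_saliency_for_dice(s, fixation), fixation),
               NMI = nmi(s, ground_truth, nmi_bins),
               NSS = nss(s, fixation),
               CC = cc(s, ground_truth),
               SIM = sim(s, as_plain_array(ground_truth)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Percent difference of every method's scores against a baseline method
#'
#' `100 * (score_method - score_baseline) / |score_baseline|` per metric;
#' cells with a zero baseline score are flagged `NA` (undefined percentage).
#'
#' @param scores data.frame from [score_saliency_maps()].
#' @param baseline_method method tag of the reference row (default `"MG"`).
#' @return a `similarity_report`: the input with `pd_<metric>` columns added
#'   and the baseline recorded as an attribute.
#' @export
percent_diff_vs_baseline <- function(scores, baseline_method = "MG") {
  if (!baseline_method %in% scores$method)
    stop_arg("baseline method ", baseline_method, " absent from the report")
  metrics <- c("DC", "NMI", "NSS", "CC", "SIM")
  base <- scores[scores$method == baseline_method, metrics]
  for (m in metrics) {
    b <- base[[m]]
    scores[[paste0("pd_", m)]] <-
      if (is.na(b) || b == 0) NA_real_ else 100 * (scores[[m]] - b) / abs(b)
  }
  structure(scores, baseline = baseline_method,
            class = c("similarity_report", class(scores)))
}

#' Write a similarity report as CSV and JSON
#' @param report a `similarity_report`.
#' @param path_csv,path_json output paths (either may be `NULL`).
#' @return invisibly, the report.
#' @export
write_similarity_report <- function(report, path_csv = NULL, path_json = NULL) {
  if (!is.null(path_csv)) utils::write.csv(report, path_csv, row.names = FALSE)
  if (!is.null(path_json)) write_json_sidecar(report, path_json)
  invisible(report)
}
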