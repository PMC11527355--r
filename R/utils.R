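#' @keywords internal
"_PACKAGE"

## Seed fan-out -----------------------------------------------------------

#' Derive a child seed from a master seed
#'
#' Deterministically maps a master seed plus a stage label (and optional item
#' index) to a 32-bit seed, so that every stage and every subject gets its own
#' independent, reproducible random stream regardless of evaluation order.
#'
#' @param master integer master seed.
#' @param stage character stage label (e.g. `"phantom"`, `"train"`).
#' @param index optional non-negative integer (e.g. subject index).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  ## simple 64-bit-safe LCG-style mix, kept below 2^31 for set.seed()
  v <- (abs(master) %% 1e9) * 2654435.0 + h * 97003.0 + index * 7919.0
  as.integer(v %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

assert_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_arg(name, " must be a finite numeric scalar")
  invisible(x)
}

## Volume containers ------------------------------------------------------

#' Construct an intensity volume
#'
#' An intensity volume is a cubic 3D numeric array with a `voxel_mm` attribute
#' giving the isotropic voxel edge length in millimetres. Background voxels are
#' zero by the skull-stripped convention.
#'
#' @param data cubic 3D numeric array of finite values.
#' @param voxel_mm isotropic voxel edge length (mm).
#' @return the array with class `sv_volume` and attribute `voxel_mm`.
#' @export
intensity_volume <- function(data, voxel_mm = 1) {
  d <- dim(data)
  if (is.null(d) || length(d) != 3L || length(unique(d)) != 1L)
    stop_arg("intensity volume must be a cubic 3D array")
  if (!all(is.finite(data))) stop_arg("intensity volume must be finite everywhere")
  assert_scalar_num(voxel_mm, "voxel_mm")
  structure(data, voxel_mm = voxel_mm, class = c("sv_volume", class(data)))
}

#' Construct a label volume
#'
#' @param data cubic 3D integer array of label codes.
#' @param label_map named integer vector mapping label names to codes; must
#'   contain at least `background`, `wm`, `nwm`, `lv`.
#' @return the array with class `sv_labels` and attribute `label_map`.
#' @export
label_volume <- function(data, label_map = default_label_map()) {
  d <- dim(data)
  if (is.null(d) || length(d) != 3L) stop_arg("label volume must be a 3D array")
  need <- c("background", "wm", "nwm", "lv")
  if (!all(need %in% names(label_map)))
    stop_arg("label_map must name: ", paste(need, collapse = ", "))
  if (!all(data %in% label_map))
    stop_arg("label volume contains codes absent from label_map")
  structure(data, label_map = label_map, class = c("sv_labels", class(data)))
}

#' Default label coding for phantom tissue classes
#' @return named integer vector.
#' @export
default_label_map <- function() {
  c(background = 0L, wm = 1L, nwm = 2L, lv = 3L)
}

voxel_mm <- function(volume) attr(volume, "voxel_mm") %||% 1

same_shape <- function(a, b) identical(dim(a), dim(b))

#' Strip a volume down to a bare 3D array
#' @param x a volume-like array (intensity, label, saliency, ...).
#' @return the same data as a plain array with only its `dim` attribute.
#' @export
as_plain_array <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

## Coordinate helpers -----------------------------------------------------

#' Convert linear voxel indices to (x, y, z) coordinates and back
#'
#' Voxel sets (replaced voxels, edge voxels, fixation supports) are handled
#' as 1-based linear indices in column-major (x-fastest) order; these helpers
#' convert between that representation and integer coordinates.
#'
#' @param idx integer vector of linear indices.
#' @param coord integer matrix with one (x, y, z) row per voxel.
#' @param dims length-3 integer volume dimensions.
#' @return `index_to_coord`: an `n x 3` coordinate matrix;
#'   `coord_to_index`: an integer vector.
#' @export
index_to_coord <- function(idx, dims) {
  idx0 <- idx - 1L
  cbind(idx0 %% dims[1L],
        (idx0 %/% dims[1L]) %% dims[2L],
        idx0 %/% (dims[1L] * dims[2L])) + 1L
}

#' @rdname index_to_coord
#' @export
coord_to_index <- function(coord, dims) {
  (coord[, 3L] - 1L) * dims[1L] * dims[2L] + (coord[, 2L] - 1L) * dims[1L] + coord[, 1L]
}

## order linear indices by (x, y, z) lexicographic coordinate order
order_lexicographic <- function(idx, dims) {
  co <- index_to_coord(idx, dims)
  idx[order(co[, 1L], co[, 2L], co[, 3L])]
}

## Interpolation ----------------------------------------------------------

#' Trilinear upsampling of a 3D field
#'
#' Resamples a 3D array to a target cubic size using trilinear interpolation
#' with half-voxel (align-corners = FALSE) coordinate mapping, i.e. voxel
#' centres of the output grid are mapped into the input grid. Used to bring a
#' coarse Grad-CAM map back to input resolution.
#'
#' @param x 3D numeric array.
#' @param out_dim integer vector of length 3 (or scalar) target size.
#' @param method `"trilinear"` (default) or `"nearest"`.
#' @return 3D numeric array of size `out_dim`.
#' @export
upsample_volume <- function(x, out_dim, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  din <- dim(x)
  if (length(out_dim) == 1L) out_dim <- rep(as.integer(out_dim), 3L)
  ## map output voxel centres to continuous input coordinates
  axes <- lapply(1:3, function(a) {
    scale <- din[a] / out_dim[a]
    (seq_len(out_dim[a]) - 0.5) * scale + 0.5
  })
  if (method == "nearest") {
    ia <- lapply(1:3, function(a) pmin(pmax(round(axes[[a]]), 1L), din[a]))
    return(array(x[as.matrix(expand.grid(ia[[1]], ia[[2]], ia[[3]]))], out_dim))
  }
  lo <- lapply(1:3, function(a) pmin(pmax(floor(axes[[a]]), 1L), din[a]))
  hi <- lapply(1:3, function(a) pmin(lo[[a]] + 1L, din[a]))
  fr <- lapply(1:3, function(a) pmin(pmax(axes[[a]] - lo[[a]], 0), 1))
  g <- function(ix, iy, iz) array(x[cbind(ix, iy, iz)], out_dim)
  ex <- expand.grid(x = seq_len(out_dim[1]), y = seq_len(out_dim[2]), z = seq_len(out_dim[3]))
  lx <- lo[[1]][ex$x]; hx <- hi[[1]][ex$x]; fx <- fr[[1]][ex$x]
  ly <- lo[[2]][ex$y]; hy <- hi[[2]][ex$y]; fy <- fr[[2]][ex$y]
  lz <- lo[[3]][ex$z]; hz <- hi[[3]][ex$z]; fz <- fr[[3]][ex$z]
  out <-
    g(lx, ly, lz) * (1 - fx) * (1 - fy) * (1 - fz) +
    g(hx, ly, lz) * fx       * (1 - fy) * (1 - fz) +
    g(lx, hy, lz) * (1 - fx) * fy       * (1 - fz) +
    g(hx, hy, lz) * fx       * fy       * (1 - fz) +
    g(lx, ly, hz) * (1 - fx) * (1 - fy) * fz +
    g(hx, ly, hz) * fx       * (1 - fy) * fz +
    g(lx, hy, hz) * (1 - fx) * fy       * fz +
    g(hx, hy, hz) * fx       * fy       * fz
  array(out, out_dim)
}

## NIfTI / sidecar I/O ----------------------------------------------------

#' Write a volume as NIfTI-1
#'
#' @param volume 3D array (intensity, label, or saliency field).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param voxel_mm isotropic voxel size recorded in the header; defaults to
#'   the volume's own `voxel_mm` attribute (1 mm if absent).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(volume, path, voxel_mm = NULL) {
  if (is.null(voxel_mm)) voxel_mm <- attr(volume, "voxel_mm") %||% 1
  img <- RNifti::asNifti(as_plain_array(volume))
  RNifti::pixdim(img) <- rep(voxel_mm, 3L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume written by [write_volume_nifti()]
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @return 3D array with a `voxel_mm` attribute.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1L]
  intensity_volume(array(as.numeric(img), dim(img)), voxel_mm = vox)
}

write_json_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
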