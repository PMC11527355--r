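## Seven attribution-based saliency methods with one uniform contract:
## model + input volume (+ options) -> raw signed voxelwise attribution field.
## Absolute values and normalization to a probability density happen later,
## in normalize_saliency(), so all methods share a single raw-gradient scale.

ATTRIBUTION_METHODS <- c("G", "IXG", "MG", "GB", "GGC", "IG", "GSHAP")

#' Options shared by the attribution methods
#'
#' @param ig_points number of Gauss-Legendre quadrature nodes for integrated
#'   gradients (default 50).
#' @param gshap_samples number of noise draws for gradient SHAP (default 5).
#' @param gshap_sigma standard deviation of the Gaussian input noise for
#'   gradient SHAP (default 0: no noise, matching the common reference
#'   default).
#' @param ig_baseline reference volume for IG; `NULL` means all-zero.
#' @param gshap_baselines list of reference volumes for gradient SHAP;
#'   `NULL` means a single all-zero baseline.
#' @param mask binary brain mask for the masked-gradient method; `NULL` means
#'   the nonzero-intensity support of the input (skull-stripped convention).
#' @param target_block convolutional block index for guided Grad-CAM; `NULL`
#'   means the final block.
#' @param upsample `"trilinear"` (default) or `"nearest"` for Grad-CAM.
#' @param seed RNG seed for the stochastic method (gradient SHAP).
#' @return list of class `attribution_options`.
#' @export
attribution_options <- function(ig_points = 50L, gshap_samples = 5L,
                                gshap_sigma = 0, ig_baseline = NULL,
                                gshap_baselines = NULL, mask = NULL,
                                target_block = NULL,
                                upsample = "trilinear", seed = 1L) {
  if (ig_points < 1L) stop_arg("ig_points must be >= 1")
  if (gshap_samples < 1L) stop_arg("gshap_samples must be >= 1")
  if (gshap_sigma < 0) stop_arg("gshap_sigma must be >= 0")
  structure(list(ig_points = as.integer(ig_points),
                 gshap_samples = as.integer(gshap_samples),
                 gshap_sigma = gshap_sigma, ig_baseline = ig_baseline,
                 gshap_baselines = gshap_baselines, mask = mask,
                 target_block = target_block, upsample = upsample,
                 seed = as.integer(seed)),
            class = "attribution_options")
}

raw_attribution <- function(data, method, options = list()) {
  if (!all(is.finite(data))) stop_arg(method, " attribution contains non-finite values")
  structure(list(data = as_plain_array(data), method = method, options = options),
            class = "raw_attribution")
}

#' Gradient saliency (G)
#'
#' The gradient of the model's scalar output with respect to every input
#' voxel: the first-order sensitivity of the estimated brain age to intensity
#' changes. Returned signed; magnitudes are taken at normalization.
#'
#' @param model a volumetric model ([build_model()] or
#'   [linear_volume_model()]).
#' @param x input volume matching the model geometry.
#' @return a `raw_attribution`.
#' @export
grad_saliency <- function(model, x) {
  raw_attribution(model_input_gradient(model, x), "G")
}

#' Input x gradient (IXG)
#'
#' Voxelwise product of the input volume with the gradient saliency field,
#' which steers attribution toward high-intensity voxels inside the brain.
#'
#' @inheritParams grad_saliency
#' @return a `raw_attribution`.
#' @export
input_x_gradient <- function(model, x) {
  g <- model_input_gradient(model, x)
  raw_attribution(as_plain_array(x) * g, "IXG")
}

#' Masked gradient (MG)
#'
#' Gradient saliency with voxels outside a binary brain mask set to zero.
#' With skull-stripped inputs the default mask is the nonzero-intensity
#' support of the volume.
#'
#' @inheritParams grad_saliency
#' @param mask binary array of the input's shape; `NULL` for the default.
#' @return a `raw_attribution`.
#' @export
masked_gradient <- function(model, x, mask = NULL) {
  if (is.null(mask)) mask <- as_plain_array(x) != 0
  if (!same_shape(mask, x)) stop_arg("mask shape must match the input")
  mv <- as.numeric(mask)
  if (!all(mv %in% c(0, 1))) stop_arg("mask must be binary")
  g <- model_input_gradient(model, x)
  raw_attribution(g * array(mv, dim(x)), "MG", list(mask_voxels = sum(mv)))
}

#' Guided backpropagation (GB)
#'
#' Gradient computed with the guided ReLU convention: during the backward
#' pass each ReLU zeroes gradients where its forward activation was
#' non-positive (as usual) and additionally where the incoming gradient is
#' negative, so only evidence that increases the output flows back. For a
#' model without ReLUs this reduces to the plain gradient.
#'
#' @inheritParams grad_saliency
#' @return a `raw_attribution`.
#' @export
guided_backprop <- function(model, x) {
  raw_attribution(model_input_gradient(model, x, guided = TRUE), "GB")
}

#' Guided Grad-CAM (GGC)
#'
#' A coarse class-activation map is built at a convolutional block: each
#' channel's post-ReLU feature map is weighted by the spatial mean of the
#' output's gradient with respect to that channel, the weighted sum is
#' rectified, and the result is upsampled to input resolution (trilinear by
#' default). The upsampled map is multiplied voxelwise with guided
#' backpropagation to restore fine spatial detail.
#'
#' @inheritParams grad_saliency
#' @param target_block convolutional block index; `NULL` selects the final
#'   block.
#' @param upsample `"trilinear"` or `"nearest"`.
#' @return a `raw_attribution`.
#' @export
guided_gradcam <- function(model, x, target_block = NULL,
                           upsample = "trilinear") {
  if (!inherits(model, "ba_cnn"))
    stop_arg("guided Grad-CAM requires a convolutional model")
  block <- target_block %||% model$config$n_blocks
  cap <- cnn_capture_block(model, x, block)
  s_conv <- cap$d_conv^3
  n_chan <- dim(cap$act)[2L]
  act <- matrix(cap$act, s_conv, n_chan)
  alpha <- colMeans(matrix(cap$grad, s_conv, n_chan))
  cam <- pmax(act %*% alpha, 0)
  cam3 <- array(cam, rep(cap$d_conv, 3L))
  cam_up <- upsample_volume(cam3, dim(x)[1L], method = upsample)
  gb <- model_input_gradient(model, x, guided = TRUE)
  raw_attribution(cam_up * gb, "GGC", list(target_block = block))
}

#' Integrated gradients (IG)
#'
#' Path integral of the gradient along the straight line from a baseline
#' volume to the input, approximated with Gauss-Legendre quadrature:
#' `attr_i = (x_i - b_i) * sum_k w_k * d f / d x_i` evaluated at
#' `b + t_k (x - b)`, with nodes and weights mapped to `[0, 1]`. Satisfies
#' the completeness property `sum(attr) ~ f(x) - f(b)`.
#'
#' @inheritParams grad_saliency
#' @param baseline reference volume; `NULL` means all-zero.
#' @param n_points number of quadrature nodes (>= 1), default 50.
#' @return a `raw_attribution`.
#' @export
integrated_gradients <- function(model, x, baseline = NULL, n_points = 50L) {
  if (is.null(baseline)) baseline <- array(0, dim(x))
  if (!same_shape(baseline, x)) stop_arg("baseline shape must match the input")
  n_points <- as.integer(n_points)
  if (n_points < 1L) stop_arg("n_points must be >= 1")
  q <- gauss_legendre_01(n_points)
  diff <- as_plain_array(x) - as_plain_array(baseline)
  acc <- array(0, dim(x))
  for (k in seq_len(n_points)) {
    pt <- as_plain_array(baseline) + q$nodes[k] * diff
    acc <- acc + q$weights[k] * model_input_gradient(model, pt)
  }
  raw_attribution(diff * acc, "IG", list(n_points = n_points))
}

## Gauss-Legendre nodes/weights mapped affinely from [-1, 1] to [0, 1]
gauss_legendre_01 <- function(n) {
  if (n == 1L) return(list(nodes = 0.5, weights = 1))
  gl <- pracma::gaussLegendre(n, 0, 1)
  list(nodes = gl$x, weights = gl$w)
}

#' Gradient SHAP (GSHAP)
#'
#' Stochastic approximation of integrated gradients over a distribution of
#' baselines: for each of `n_samples` draws the input is jittered with
#' Gaussian noise, a baseline is chosen uniformly from the pool, and the
#' gradient is evaluated at a uniformly random point on the segment from the
#' baseline to the jittered input; the contribution is the gradient times
#' (jittered input - baseline), averaged over draws.
#'
#' @inheritParams grad_saliency
#' @param baselines nonempty list of reference volumes; `NULL` means a single
#'   all-zero baseline.
#' @param n_samples number of draws (>= 1), default 5.
#' @param sigma Gaussian input-noise standard deviation (>= 0).
#' @param seed RNG seed making the estimate reproducible.
#' @return a `raw_attribution`.
#' @export
gradient_shap <- function(model, x, baselines = NULL, n_samples = 5L,
                          sigma = 0, seed = 1L) {
  if (is.null(baselines)) baselines <- list(array(0, dim(x)))
  if (length(baselines) == 0L) stop_arg("baselines must be nonempty")
  if (n_samples < 1L) stop_arg("n_samples must be >= 1")
  if (sigma < 0) stop_arg("sigma must be >= 0")
  for (b in baselines)
    if (!same_shape(b, x)) stop_arg("every baseline must match the input shape")
  xv <- as_plain_array(x)
  acc <- array(0, dim(x))
  withr::with_seed(seed, {
    for (s in seq_len(n_samples)) {
      xt <- xv + if (sigma > 0) array(stats::rnorm(length(xv), 0, sigma), dim(xv))
                 else 0
      b <- as_plain_array(baselines[[sample.int(length(baselines), 1L)]])
      t_s <- stats::runif(1L)
      g <- model_input_gradient(model, b + t_s * (xt - b))
      acc <- acc + (xt - b) * g
    }
  })
  raw_attribution(acc / n_samples, "GSHAP",
                  list(n_samples = n_samples, sigma = sigma, seed = seed))
}

#' Compute one attribution map by method name
#'
#' Uniform dispatcher over the seven methods: `"G"`, `"IXG"`, `"MG"`, `"GB"`,
#' `"GGC"`, `"IG"`, `"GSHAP"`.
#'
#' @inheritParams grad_saliency
#' @param method method tag.
#' @param options an [attribution_options()] object.
#' @return a `raw_attribution`.
#' @export
compute_attribution <- function(model, x, method,
                                options = attribution_options()) {
  method <- match.arg(method, ATTRIBUTION_METHODS)
  switch(method,
    G = grad_saliency(model, x),
    IXG = input_x_gradient(model, x),
    MG = masked_gradient(model, x, options$mask),
    GB = guided_backprop(model, x),
    GGC = guided_gradcam(model, x, options$target_block, options$upsample),
    IG = integrated_gradients(model, x, options$ig_baseline, options$ig_points),
    GSHAP = gradient_shap(model, x, options$gshap_baselines,
                          options$gshap_samples, options$gshap_sigma,
                          options$seed))
}
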