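lin_fixture <- function(seed = 1) {
  withr::with_seed(seed, list(
    w = array(stats::rnorm(27), c(3, 3, 3)),
    x = array(stats::rnorm(27), c(3, 3, 3))))
}

test_that("gradient-family methods are exact on an analytic linear model", {
  f <- lin_fixture()
  m <- linear_volume_model(f$w, b = 2)
  expect_equal(grad_saliency(m, f$x)$data, f$w)
  expect_equal(input_x_gradient(m, f$x)$data, f$x * f$w)
  ## no ReLUs: guided backprop degenerates to the plain gradient
  expect_equal(guided_backprop(m, f$x)$data, f$w)
  ## constant model: zero field everywhere
  z <- linear_volume_model(array(0, c(3, 3, 3)), b = 5)
  expect_true(all(grad_saliency(z, f$x)$data == 0))
  ## zero input: IXG vanishes
  expect_true(all(input_x_gradient(m, array(0, c(3, 3, 3)))$data == 0))
})

test_that("integrated gradients is exact for linear models at any node count", {
  f <- lin_fixture(2)
  m <- linear_volume_model(f$w)
  for (np in c(1L, 2L, 5L, 50L))
    expect_equal(integrated_gradients(m, f$x, n_points = np)$data, f$x * f$w,
                 tolerance = 1e-10)
  ## nonzero baseline: (x - b) * w
  b <- withr::with_seed(3, array(stats::rnorm(27), c(3, 3, 3)))
  expect_equal(integrated_gradients(m, f$x, baseline = b)$data,
               (f$x - b) * f$w, tolerance = 1e-10)
  ## x = baseline: zero field
  expect_true(all(integrated_gradients(m, f$x, baseline = f$x)$data == 0))
  expect_error(integrated_gradients(m, f$x, baseline = array(0, c(2, 2, 2))),
               "shape")
})

test_that("gradient SHAP reduces to (x - b) * w without noise and converges to IG", {
  f <- lin_fixture(4)
  m <- linear_volume_model(f$w)
  ## sigma = 0, baselines = {x}: zero field for any sample count
  expect_true(all(gradient_shap(m, f$x, baselines = list(f$x),
                                n_samples = 4, sigma = 0)$data == 0))
  ## sigma = 0, single zero baseline: exact x * w
  expect_equal(gradient_shap(m, f$x, n_samples = 3, sigma = 0, seed = 5)$data,
               f$x * f$w, tolerance = 1e-12)
  ## with noise and a baseline pool, the average converges to IG at the
  ## mean baseline (constant gradient makes this exact in expectation)
  pool <- withr::with_seed(6, lapply(1:3, function(i)
    array(stats::rnorm(27, 0, 0.5), c(3, 3, 3))))
  gs <- gradient_shap(m, f$x, baselines = pool, n_samples = 400,
                      sigma = 0.05, seed = 7)$data
  bbar <- Reduce(`+`, pool) / 3
  ig <- integrated_gradients(m, f$x, baseline = bbar)$data
  expect_lt(max(abs(gs - ig)), 0.1)
  ## determinism under one seed
  g1 <- gradient_shap(m, f$x, n_samples = 5, sigma = 0.1, seed = 8)$data
  g2 <- gradient_shap(m, f$x, n_samples = 5, sigma = 0.1, seed = 8)$data
  expect_identical(g1, g2)
  expect_error(gradient_shap(m, f$x, baselines = list()), "nonempty")
})

test_that("IXG and MG relate to the raw gradient exactly on a CNN", {
  m <- tiny_cnn()
  x <- withr::with_seed(9, array(stats::rnorm(1000, 50, 15), c(10, 10, 10)))
  x[1:150] <- 0                       # synthetic background
  g <- grad_saliency(m, x)$data
  expect_equal(input_x_gradient(m, x)$data, as_plain_array(x) * g)
  ## all-ones mask leaves G untouched; default mask zeroes the background
  expect_equal(masked_gradient(m, x, mask = array(1, dim(x)))$data, g)
  mg <- masked_gradient(m, x)$data
  expect_true(all(mg[1:150] == 0))
  expect_equal(mg[x != 0], g[x != 0])
  ## all-zero mask produces the degenerate field normalization must reject
  mg0 <- masked_gradient(m, x, mask = array(0, dim(x)))
  expect_true(all(mg0$data == 0))
  expect_error(normalize_saliency(mg0), "degenerate")
})

test_that("guided backpropagation gates exactly as a hand-computed toy", {
  ## one conv block (2^3 kernel -> single unit), no hidden dense layer:
  ## out = d * ReLU(gamma * (w.x - rm) / sqrt(rv + eps) + beta) + bias
  cfg <- cnn_config(input_size = 2L, n_blocks = 1L, filters = 1L,
                    conv_kernel = 2L, pool_kernel = 1L,
                    dense_sizes = integer(0), dropout_rate = 0)
  m <- build_model(cfg)
  w <- c(0.5, -0.25, 1, 0.75, -0.5, 0.25, -1, 0.5)
  m$blocks[[1]]$W <- matrix(w, 8, 1)
  m$blocks[[1]]$b <- 0.1
  m$blocks[[1]]$gamma <- 2; m$blocks[[1]]$beta <- 0.3
  m$blocks[[1]]$rm <- 0.2; m$blocks[[1]]$rv <- 0.64
  x <- array(c(1, 2, 0.5, 1, 1.5, 0.5, 0.25, 1), c(2, 2, 2))
  inv <- 1 / sqrt(0.64 + 1e-5)
  pre <- 2 * (sum(w * x) + 0.1 - 0.2) * inv + 0.3
  expect_gt(pre, 0)                    # ReLU active in this configuration
  ## positive head weight: guided equals plain, both analytic
  m$dense[[1]]$W <- matrix(3, 1, 1); m$dense[[1]]$b <- 0
  expected <- 3 * 2 * inv * array(w, c(2, 2, 2))
  expect_equal(model_forward(m, x), 3 * pre)
  expect_equal(grad_saliency(m, x)$data, expected, tolerance = 1e-12)
  expect_equal(guided_backprop(m, x)$data, expected, tolerance = 1e-12)
  ## negative head weight: plain gradient flips sign, guided gate closes
  m$dense[[1]]$W <- matrix(-3, 1, 1)
  expect_equal(grad_saliency(m, x)$data, -expected, tolerance = 1e-12)
  expect_true(all(guided_backprop(m, x)$data == 0))
})

test_that("guided Grad-CAM weights activations by mean gradient and refines with GB", {
  ## single-channel 1^3-kernel block: activations and gradients computable by hand
  cfg <- cnn_config(input_size = 2L, n_blocks = 1L, filters = 1L,
                    conv_kernel = 1L, pool_kernel = 2L,
                    dense_sizes = integer(0), dropout_rate = 0)
  m <- build_model(cfg)
  m$blocks[[1]]$W <- matrix(1.5, 1, 1)
  m$blocks[[1]]$b <- 0
  m$blocks[[1]]$gamma <- 1; m$blocks[[1]]$beta <- 0
  m$blocks[[1]]$rm <- 0; m$blocks[[1]]$rv <- 1 - 1e-5
  m$dense[[1]]$W <- matrix(2, 1, 1); m$dense[[1]]$b <- 0
  x <- array(c(0.2, 0.8, 0.4, 0.1, 0.3, 0.5, 0.6, 0.7), c(2, 2, 2))
  ## act = ReLU(1.5 x) = 1.5 x; max-pool picks voxel 2 (x = 0.8);
  ## output grad at act: 2 on the argmax voxel, 0 elsewhere -> alpha = 2/8
  act <- 1.5 * x
  alpha <- 2 / 8
  cam <- pmax(alpha * act, 0)          # upsampling 2^3 -> 2^3 is the identity
  gb <- array(0, c(2, 2, 2)); gb[2] <- 2 * 1.5
  expect_equal(guided_gradcam(m, x)$data, cam * gb, tolerance = 1e-6)

  ## on a larger model: shape preserved, zero wherever GB is zero
  m2 <- tiny_cnn()
  x2 <- withr::with_seed(10, array(stats::rnorm(1000, 40, 12), c(10, 10, 10)))
  ggc <- guided_gradcam(m2, x2)
  expect_equal(dim(ggc$data), dim(x2))
  gb2 <- guided_backprop(m2, x2)$data
  expect_true(all(ggc$data[gb2 == 0] == 0))
  expect_error(guided_gradcam(m2, x2, target_block = 5L), "block")
  expect_error(guided_gradcam(linear_volume_model(array(1, c(2, 2, 2))),
                              array(1, c(2, 2, 2))), "convolutional")
})

test_that("every method returns a finite field of the input's shape, statelessly", {
  m <- tiny_cnn()
  x <- withr::with_seed(11, array(abs(stats::rnorm(1000, 30, 10)), c(10, 10, 10)))
  before <- model_forward(m, x)
  opts <- attribution_options(ig_points = 8L, gshap_samples = 3L,
                              gshap_sigma = 0.5, seed = 3L)
  for (method in c("G", "IXG", "MG", "GB", "GGC", "IG", "GSHAP")) {
    r1 <- compute_attribution(m, x, method, opts)
    r2 <- compute_attribution(m, x, method, opts)
    expect_equal(dim(r1$data), dim(x))
    expect_true(all(is.finite(r1$data)))
    expect_identical(r1$data, r2$data)  # repeatable under one seed
  }
  expect_identical(model_forward(m, x), before)   # model state untouched
  expect_error(compute_attribution(m, x, "XYZ"), "arg")
})
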