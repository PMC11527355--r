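## 3D-CNN brain-age regressor.
##
## The network maps a cubic intensity volume to a scalar estimated brain age.
## Architecture: a stack of convolutional blocks, each convolution (valid
## padding) -> batch normalization -> ReLU -> max pooling, with dropout on
## configurable blocks; then flatten and dense layers (ReLU on hidden layers,
## linear scalar output). Trained with MAE loss and Adam, with patience-based
## early stopping and best-epoch weight restoration.
##
## Implementation: im2col convolution driven by BLAS matmul, with index
## matrices cached per geometry and chunked when they would be large. Batches
## are held as (spatial, channel, sample) arrays with x-fastest flattening.
## The same backward machinery serves training and input-gradient attribution
## (including the guided-ReLU variant and Grad-CAM feature capture).

#' CNN architecture and training configuration
#'
#' Defaults reproduce the full-scale architecture: 128^3 input, four blocks of
#' 16/32/64/128 filters with 6^3 convolution kernels, 2^3 max pooling, dropout
#' 0.2 on blocks 2-4, a 128-unit dense layer, MAE loss with Adam at learning
#' rate 1e-4, and early-stopping patience of 20 epochs. Reduced desk-scale
#' configurations shrink `input_size`, `filters`, and `conv_kernel` through
#' the same code path.
#'
#' @param input_size voxels per axis of the input cube.
#' @param n_blocks number of convolutional blocks.
#' @param filters integer vector of per-block filter counts (length `n_blocks`).
#' @param conv_kernel cubic convolution kernel edge (voxels).
#' @param pool_kernel cubic max-pooling kernel edge (stride = kernel).
#' @param dropout_rate dropout fraction in `[0, 1)`.
#' @param dropout_blocks indices of blocks carrying dropout (after pooling).
#' @param dense_sizes widths of hidden dense layers (may be empty).
#' @param learning_rate Adam step size.
#' @param patience epochs without validation improvement before stopping.
#' @param max_epochs hard epoch cap.
#' @param batch_size minibatch size.
#' @param seed RNG seed for initialization, shuffling, and dropout.
#' @return a list of class `cnn_config`.
#' @export
cnn_config <- function(input_size = 128L, n_blocks = 4L,
                       filters = c(16L, 32L, 64L, 128L),
                       conv_kernel = 6L, pool_kernel = 2L,
                       dropout_rate = 0.2, dropout_blocks = 2:4,
                       dense_sizes = 128L,
                       learning_rate = 1e-4, patience = 20L,
                       max_epochs = 100L, batch_size = 4L, seed = 1L) {
  cfg <- list(input_size = as.integer(input_size), n_blocks = as.integer(n_blocks),
              filters = as.integer(filters), conv_kernel = as.integer(conv_kernel),
              pool_kernel = as.integer(pool_kernel), dropout_rate = dropout_rate,
              dropout_blocks = as.integer(dropout_blocks),
              dense_sizes = as.integer(dense_sizes),
              learning_rate = learning_rate, patience = as.integer(patience),
              max_epochs = as.integer(max_epochs), batch_size = as.integer(batch_size),
              seed = as.integer(seed))
  class(cfg) <- "cnn_config"
  if (cfg$n_blocks < 1L) stop_arg("n_blocks must be >= 1")
  if (length(cfg$filters) != cfg$n_blocks)
    stop_arg("filters must have one entry per block")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop_arg("dropout_rate must lie in [0, 1)")
  if (cfg$patience < 1L) stop_arg("patience must be >= 1")
  cfg$geometry <- cnn_geometry(cfg)   # validates kernel/pool feasibility
  cfg
}

## per-block spatial sizes; errors if the kernel outgrows its feature map
cnn_geometry <- function(cfg) {
  d <- cfg$input_size
  blocks <- vector("list", cfg$n_blocks)
  c_in <- 1L
  for (b in seq_len(cfg$n_blocks)) {
    d_conv <- d - cfg$conv_kernel + 1L
    if (d_conv < 1L)
      stop_arg("block ", b, ": convolution kernel (", cfg$conv_kernel,
               ") larger than its ", d, "^3 feature map")
    d_pool <- d_conv %/% cfg$pool_kernel
    if (d_pool < 1L)
      stop_arg("block ", b, ": pooling would empty the ", d_conv, "^3 feature map")
    blocks[[b]] <- list(d_in = d, d_conv = d_conv, d_pool = d_pool,
                        c_in = c_in, c_out = cfg$filters[b])
    d <- d_pool
    c_in <- cfg$filters[b]
  }
  list(blocks = blocks, flat_size = d^3 * c_in)
}

## index-matrix caches -----------------------------------------------------

.sv_idx_cache <- new.env(parent = emptyenv())

## linear positions (1-based) of conv output origins within a d_in^3 grid
conv_out_positions <- function(d_in, d_out) {
  px <- 0:(d_out - 1L)
  as.vector(outer(outer(px, px * d_in, `+`), px * d_in * d_in, `+`)) + 1L
}

## per-channel kernel offsets (0-based) incl. channel stride
conv_kernel_offsets <- function(d_in, k, c_in) {
  kx <- 0:(k - 1L)
  spatial <- as.vector(outer(outer(kx, kx * d_in, `+`), kx * d_in * d_in, `+`))
  as.vector(outer(spatial, (0:(c_in - 1L)) * d_in^3, `+`))
}

## full im2col index matrix, cached when small enough to keep
conv_idx_matrix <- function(d_in, k, c_in, d_out) {
  key <- paste("conv", d_in, k, c_in, sep = "_")
  if (!is.null(.sv_idx_cache[[key]])) return(.sv_idx_cache[[key]])
  pos <- conv_out_positions(d_in, d_out)
  off <- conv_kernel_offsets(d_in, k, c_in)
  idx <- outer(pos, off, `+`)
  if (length(idx) <= 3e7) .sv_idx_cache[[key]] <- idx
  idx
}

pool_idx_matrix <- function(d_conv, p, d_pool) {
  key <- paste("pool", d_conv, p, sep = "_")
  if (!is.null(.sv_idx_cache[[key]])) return(.sv_idx_cache[[key]])
  px <- (0:(d_pool - 1L)) * p
  pos <- as.vector(outer(outer(px, px * d_conv, `+`), px * d_conv * d_conv, `+`)) + 1L
  kx <- 0:(p - 1L)
  off <- as.vector(outer(outer(kx, kx * d_conv, `+`), kx * d_conv * d_conv, `+`))
  idx <- outer(pos, off, `+`)
  .sv_idx_cache[[key]] <- idx
  idx
}

## row chunks keeping chunk_rows * ncol(idx) below ~3e7 elements
row_chunks <- function(n_rows, n_cols, limit = 3e7) {
  per <- max(1L, as.integer(limit %/% n_cols))
  starts <- seq.int(1L, n_rows, by = per)
  lapply(starts, function(s) s:min(s + per - 1L, n_rows))
}

cube_root <- function(n) as.integer(round(n^(1 / 3)))

## convolution forward for one flattened sample (length d_in^3 * c_in);
## optionally returns the im2col matrix for reuse by the weight gradient
conv_fwd_one <- function(x_flat, W, bvec, bg, keep_col = FALSE) {
  s_out <- bg$d_conv^3
  k3c <- nrow(W)
  k <- cube_root(k3c %/% bg$c_in)
  col <- NULL
  if (s_out * k3c <= 3e7) {
    idx <- conv_idx_matrix(bg$d_in, k, bg$c_in, bg$d_conv)
    col <- x_flat[idx]
    dim(col) <- dim(idx)
    out <- col %*% W
    if (!keep_col) col <- NULL
  } else {
    pos <- conv_out_positions(bg$d_in, bg$d_conv)
    off <- conv_kernel_offsets(bg$d_in, k, bg$c_in)
    out <- matrix(0, s_out, ncol(W))
    for (rows in row_chunks(s_out, k3c)) {
      idx <- outer(pos[rows], off, `+`)
      cc <- x_flat[idx]
      dim(cc) <- dim(idx)
      out[rows, ] <- cc %*% W
    }
  }
  list(z = out + rep(bvec, each = s_out), col = col)
}

## weight gradient dW = col' dZ, regathering the im2col matrix if not cached
conv_weight_grad <- function(x_flat, col, dZ_n, bg, k3c) {
  if (!is.null(col)) return(crossprod(col, dZ_n))
  s_out <- bg$d_conv^3
  k <- cube_root(k3c %/% bg$c_in)
  if (s_out * k3c <= 3e7) {
    idx <- conv_idx_matrix(bg$d_in, k, bg$c_in, bg$d_conv)
    col <- x_flat[idx]
    dim(col) <- dim(idx)
    return(crossprod(col, dZ_n))
  }
  pos <- conv_out_positions(bg$d_in, bg$d_conv)
  off <- conv_kernel_offsets(bg$d_in, k, bg$c_in)
  dW <- matrix(0, k3c, ncol(dZ_n))
  for (rows in row_chunks(s_out, k3c)) {
    idx <- outer(pos[rows], off, `+`)
    cc <- x_flat[idx]
    dim(cc) <- dim(idx)
    dW <- dW + crossprod(cc, dZ_n[rows, , drop = FALSE])
  }
  dW
}

## kernel-flipped weights for the transposed convolution: (k3*c_out, c_in)
flip_weights <- function(W, k3, c_in, c_out) {
  Wa <- array(W, c(k3, c_in, c_out))
  Wa <- Wa[k3:1, , , drop = FALSE]
  matrix(aperm(Wa, c(1L, 3L, 2L)), k3 * c_out, c_in)
}

## linear positions of the d_conv^3 block inside the (d_conv + 2(k-1))^3
## zero-padded grid used by the transposed convolution
pad_positions <- function(d_conv, k) {
  d_pad <- d_conv + 2L * (k - 1L)
  key <- paste("pad", d_conv, k, sep = "_")
  if (!is.null(.sv_idx_cache[[key]])) return(.sv_idx_cache[[key]])
  shift <- (k - 1L) * (1L + d_pad + d_pad * d_pad)
  pos <- conv_out_positions(d_pad, d_conv) + shift
  .sv_idx_cache[[key]] <- pos
  pos
}

## input gradient of the convolution as a transposed convolution:
## dZ_n (s_out, c_out) -> dx (d_in^3 * c_in), pure gather + matmul
conv_input_grad_one <- function(dZ_n, bg, k, Wr) {
  c_out <- ncol(dZ_n)
  d_pad <- bg$d_conv + 2L * (k - 1L)
  pz <- numeric(d_pad^3 * c_out)
  tgt <- outer(pad_positions(bg$d_conv, k), (0:(c_out - 1L)) * d_pad^3, `+`)
  pz[tgt] <- dZ_n
  s_in <- bg$d_in^3
  k3co <- nrow(Wr)
  if (s_in * k3co <= 3e7) {
    idx <- conv_idx_matrix(d_pad, k, c_out, bg$d_in)
    colb <- pz[idx]
    dim(colb) <- dim(idx)
    dx <- colb %*% Wr
  } else {
    pos <- conv_out_positions(d_pad, bg$d_in)
    off <- conv_kernel_offsets(d_pad, k, c_out)
    dx <- matrix(0, s_in, ncol(Wr))
    for (rows in row_chunks(s_in, k3co)) {
      idx <- outer(pos[rows], off, `+`)
      colb <- pz[idx]
      dim(colb) <- dim(idx)
      dx[rows, ] <- colb %*% Wr
    }
  }
  dim(dx) <- NULL
  dx
}

## model construction ------------------------------------------------------

#' Build a 3D-CNN brain-age model
#'
#' Weights use seeded He-normal initialization; batch-norm scale/shift start
#' at 1/0 with unit running variance, so an untrained model with zero input
#' produces output zero.
#'
#' @param config a [cnn_config()].
#' @return an object of class `ba_cnn`.
#' @export
build_model <- function(config) {
  geom <- config$geometry %||% cnn_geometry(config)
  withr::with_seed(derive_seed(config$seed, "init"), {
    k3 <- config$conv_kernel^3
    blocks <- lapply(geom$blocks, function(bg) {
      fan_in <- k3 * bg$c_in
      list(W = matrix(stats::rnorm(fan_in * bg$c_out, 0, sqrt(2 / fan_in)),
                      fan_in, bg$c_out),
           b = numeric(bg$c_out),
           gamma = rep(1, bg$c_out), beta = numeric(bg$c_out),
           rm = numeric(bg$c_out), rv = rep(1, bg$c_out))
    })
    sizes <- c(geom$flat_size, config$dense_sizes, 1L)
    dense <- lapply(seq_len(length(sizes) - 1L), function(i) {
      list(W = matrix(stats::rnorm(sizes[i] * sizes[i + 1L], 0, sqrt(2 / sizes[i])),
                      sizes[i], sizes[i + 1L]),
           b = numeric(sizes[i + 1L]))
    })
    structure(list(config = config, geom = geom, blocks = blocks, dense = dense,
                   out_center = 0, out_scale = 1),
              class = "ba_cnn")
  })
}

#' Total number of trainable parameters
#'
#' Counts convolution weights and biases, batch-norm scale and shift, and
#' dense weights and biases (running statistics are not trainable).
#'
#' @param model a `ba_cnn` model.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  n <- 0L
  for (bl in model$blocks)
    n <- n + length(bl$W) + length(bl$b) + length(bl$gamma) + length(bl$beta)
  for (dl in model$dense) n <- n + length(dl$W) + length(dl$b)
  n
}

## forward / backward ------------------------------------------------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

## X: (S_in * C_in, N) matrix (a (S, 1, N) array is accepted and reshaped).
## Activations flow between blocks as (spatial * channels, N) matrices whose
## column-major order makes the (spatial, channels * N) view a free reshape.
cnn_forward <- function(model, X, training = FALSE, keep_cache = training,
                        capture_block = NULL, update_bn = training) {
  cfg <- model$config
  if (length(dim(X)) == 3L) dim(X) <- c(dim(X)[1L] * dim(X)[2L], dim(X)[3L])
  N <- ncol(X)
  cur <- X
  caches <- vector("list", cfg$n_blocks)
  capture <- NULL
  for (b in seq_len(cfg$n_blocks)) {
    bg <- model$geom$blocks[[b]]
    bl <- model$blocks[[b]]
    S <- bg$d_conv^3
    C <- bg$c_out
    CN <- C * N
    exp_ch <- function(v) rep(rep(v, each = S), times = N)
    chmean <- function(M) rowSums(matrix(.colSums(M, S, CN), C, N)) / (S * N)
    keep_col <- keep_cache && (S * nrow(bl$W) * N <= 6e7)
    Z <- matrix(0, S, CN)
    cols <- if (keep_col) vector("list", N)
    for (n in seq_len(N)) {
      r <- conv_fwd_one(cur[, n], bl$W, bl$b, bg, keep_col)
      Z[, (n - 1L) * C + seq_len(C)] <- r$z
      if (keep_col) cols[[n]] <- r$col
    }
    ## batch normalization (batch statistics when training, running when not)
    if (training) {
      mu <- chmean(Z)
      ctr <- Z - exp_ch(mu)
      va <- chmean(ctr * ctr)
      invstd <- 1 / sqrt(va + BN_EPS)
      xhat <- ctr * exp_ch(invstd)
      if (update_bn) {
        model$blocks[[b]]$rm <- (1 - BN_MOMENTUM) * bl$rm + BN_MOMENTUM * mu
        model$blocks[[b]]$rv <- (1 - BN_MOMENTUM) * bl$rv + BN_MOMENTUM * va
      }
    } else {
      invstd <- 1 / sqrt(bl$rv + BN_EPS)
      xhat <- (Z - exp_ch(bl$rm)) * exp_ch(invstd)
    }
    A <- pmax(xhat * exp_ch(bl$gamma) + exp_ch(bl$beta), 0)   # BN affine + ReLU
    if (!is.null(capture_block) && capture_block == b)
      capture <- list(act = A, d_conv = bg$d_conv, c_out = C, block = b)
    ## max pooling (vectorized across channels and samples)
    pidx <- pool_idx_matrix(bg$d_conv, cfg$pool_kernel, bg$d_pool)
    Sp <- bg$d_pool^3
    p3 <- ncol(pidx)
    P <- A[pidx[, 1L], , drop = FALSE]
    best_o <- matrix(1L, Sp, CN)
    if (p3 > 1L) for (o in 2:p3) {
      cand <- A[pidx[, o], , drop = FALSE]
      bet <- cand > P
      P[bet] <- cand[bet]
      best_o[bet] <- o
    }
    amax <- matrix(pidx[cbind(rep.int(seq_len(Sp), CN), as.vector(best_o))],
                   Sp, CN)
    ## dropout (inverted) on configured blocks during training
    dmask <- NULL
    if (training && cfg$dropout_rate > 0 && b %in% cfg$dropout_blocks) {
      dmask <- matrix(stats::runif(length(P)) >= cfg$dropout_rate, Sp, CN)
      P <- P * dmask / (1 - cfg$dropout_rate)
    }
    if (keep_cache)
      caches[[b]] <- list(x_in = cur, cols = cols,
                          xhat = if (training) xhat, invstd = invstd,
                          act = A, amax = amax, dmask = dmask)
    dim(P) <- c(Sp * C, N)
    cur <- P
  }
  ## dense head
  Fmat <- cur
  dense_cache <- vector("list", length(model$dense))
  nd <- length(model$dense)
  for (i in seq_len(nd)) {
    dl <- model$dense[[i]]
    H <- crossprod(dl$W, Fmat) + dl$b    # (out, N)
    if (i < nd) {
      Hr <- pmax(H, 0)
      if (keep_cache) dense_cache[[i]] <- list(x_in = Fmat, act = Hr)
      Fmat <- Hr
    } else {
      if (keep_cache) dense_cache[[i]] <- list(x_in = Fmat)
      Fmat <- H
    }
  }
  raw <- as.vector(Fmat)
  list(pred = raw * model$out_scale + model$out_center,
       caches = caches, dense_cache = dense_cache,
       capture = capture, model = model)
}

## Backward pass. dpred: (N). Returns parameter grads and/or input grads.
## guided: apply the guided-backprop ReLU gate (zero where incoming gradient
## is negative, in addition to the usual zero where the activation was <= 0).
cnn_backward <- function(model, fwd, dpred, need_param_grads = TRUE,
                         need_input_grad = FALSE, guided = FALSE,
                         training = TRUE, capture_block = NULL) {
  cfg <- model$config
  N <- length(dpred)
  gmul <- function(g, act) {
    g <- g * (act > 0)
    if (guided) g <- g * (g > 0)
    g
  }
  dG <- if (need_param_grads)
    list(blocks = vector("list", cfg$n_blocks),
         dense = vector("list", length(model$dense)))
  ## dense head backward
  dF <- matrix(dpred * model$out_scale, 1L, N)
  nd <- length(model$dense)
  for (i in rev(seq_len(nd))) {
    dl <- model$dense[[i]]
    dc <- fwd$dense_cache[[i]]
    if (i < nd) dF <- gmul(dF, dc$act)
    if (need_param_grads)
      dG$dense[[i]] <- list(W = dc$x_in %*% t(dF), b = rowSums(dF))
    dF <- dl$W %*% dF                    # (in, N)
  }
  dP <- dF                               # (flat, N) = (Sp * C, N) of last block
  captured_grad <- NULL
  for (b in rev(seq_len(cfg$n_blocks))) {
    bg <- model$geom$blocks[[b]]
    bl <- model$blocks[[b]]
    ca <- fwd$caches[[b]]
    S <- bg$d_conv^3
    C <- bg$c_out
    CN <- C * N
    Sp <- bg$d_pool^3
    exp_ch <- function(v) rep(rep(v, each = S), times = N)
    chsum <- function(M) rowSums(matrix(.colSums(M, S, CN), C, N))
    dim(dP) <- c(Sp, CN)
    if (!is.null(ca$dmask))
      dP <- dP * ca$dmask / (1 - cfg$dropout_rate)
    ## unpool: route gradient to the argmax voxel (pool windows are disjoint)
    dA <- matrix(0, S, CN)
    lin <- as.vector(ca$amax) + rep.int((0:(CN - 1L)) * S, rep.int(Sp, CN))
    dA[lin] <- dP
    dA <- gmul(dA, ca$act)               # ReLU (optionally guided)
    if (!is.null(capture_block) && capture_block == b)
      captured_grad <- dA
    ## batch-norm backward
    if (training) {
      Mtot <- S * N
      sum_dy <- chsum(dA)
      sum_dy_xhat <- chsum(dA * ca$xhat)
      dZ <- exp_ch(bl$gamma * ca$invstd / Mtot) *
        (Mtot * dA - exp_ch(sum_dy) - ca$xhat * exp_ch(sum_dy_xhat))
      if (need_param_grads)
        bn_grads <- list(gamma = sum_dy_xhat, beta = sum_dy)
    } else {
      dZ <- dA * exp_ch(bl$gamma * ca$invstd)
      if (need_param_grads)
        bn_grads <- list(gamma = chsum(dA * ca$xhat), beta = chsum(dA))
    }
    ## convolution backward (transposed convolution for the input gradient)
    need_dx <- need_input_grad || b > 1L
    db <- chsum(dZ)
    dW <- if (need_param_grads) matrix(0, nrow(bl$W), ncol(bl$W))
    Wr <- if (need_dx) flip_weights(bl$W, cfg$conv_kernel^3, bg$c_in, C)
    dX <- if (need_dx) matrix(0, bg$d_in^3 * bg$c_in, N)
    for (n in seq_len(N)) {
      dzn <- dZ[, (n - 1L) * C + seq_len(C), drop = FALSE]
      if (need_param_grads)
        dW <- dW + conv_weight_grad(ca$x_in[, n],
                                    if (!is.null(ca$cols)) ca$cols[[n]],
                                    dzn, bg, nrow(bl$W))
      if (need_dx) dX[, n] <- conv_input_grad_one(dzn, bg, cfg$conv_kernel, Wr)
    }
    if (need_param_grads)
      dG$blocks[[b]] <- list(W = dW, b = db,
                             gamma = bn_grads$gamma, beta = bn_grads$beta)
    dP <- dX
  }
  list(grads = dG, input_grad = dP, captured_grad = captured_grad)
}

## model interface used by the attribution layer ---------------------------

#' Forward pass of a volumetric model
#' @param model a model object (`ba_cnn` or [linear_volume_model()]).
#' @param x cubic 3D array matching the model's input geometry.
#' @return scalar prediction.
#' @export
model_forward <- function(model, x) UseMethod("model_forward")

#' Gradient of a volumetric model's scalar output with respect to its input
#' @param model a model object.
#' @param x cubic 3D array.
#' @param guided apply the guided-backprop ReLU convention.
#' @return 3D array of the input's shape.
#' @export
model_input_gradient <- function(model, x, guided = FALSE) {
  UseMethod("model_input_gradient")
}

check_cnn_input <- function(model, x) {
  d <- dim(x)
  s <- model$config$input_size
  if (is.null(d) || length(d) != 3L || !all(d == s))
    stop_arg("input volume must be ", s, "^3 to match the model")
  invisible(x)
}

#' @export
model_forward.ba_cnn <- function(model, x) {
  check_cnn_input(model, x)
  X <- array(as.numeric(x), c(model$config$input_size^3, 1L, 1L))
  cnn_forward(model, X, training = FALSE, keep_cache = FALSE)$pred
}

#' @export
model_input_gradient.ba_cnn <- function(model, x, guided = FALSE) {
  check_cnn_input(model, x)
  s <- model$config$input_size
  X <- array(as.numeric(x), c(s^3, 1L, 1L))
  fwd <- cnn_forward(model, X, training = FALSE, keep_cache = TRUE)
  bwd <- cnn_backward(model, fwd, dpred = 1, need_param_grads = FALSE,
                      need_input_grad = TRUE, guided = guided, training = FALSE)
  array(bwd$input_grad, c(s, s, s))
}

## Grad-CAM support: activations of (and output gradient at) a conv block's
## post-ReLU feature map, evaluation mode, plain (non-guided) gradients.
cnn_capture_block <- function(model, x, block) {
  check_cnn_input(model, x)
  if (block < 1L || block > model$config$n_blocks)
    stop_arg("target block must be in 1..", model$config$n_blocks)
  s <- model$config$input_size
  X <- array(as.numeric(x), c(s^3, 1L, 1L))
  fwd <- cnn_forward(model, X, training = FALSE, keep_cache = TRUE,
                     capture_block = block)
  bwd <- cnn_backward(model, fwd, dpred = 1, need_param_grads = FALSE,
                      need_input_grad = FALSE, guided = FALSE,
                      training = FALSE, capture_block = block)
  list(act = matrix(fwd$capture$act, fwd$capture$d_conv^3, fwd$capture$c_out),
       grad = matrix(bwd$captured_grad, fwd$capture$d_conv^3, fwd$capture$c_out),
       d_conv = fwd$capture$d_conv)
}

#' Analytic linear volumetric model
#'
#' `f(x) = sum(w * x) + b`. A reference model with a closed-form gradient,
#' used to validate attribution methods against their analytic values.
#'
#' @param w 3D array of weights.
#' @param b scalar intercept.
#' @return an object of class `linear_vol_model`.
#' @export
linear_volume_model <- function(w, b = 0) {
  stopifnot(length(dim(w)) == 3L)
  structure(list(w = w, b = b), class = "linear_vol_model")
}

#' @export
model_forward.linear_vol_model <- function(model, x) {
  if (!same_shape(x, model$w)) stop_arg("input shape does not match the model")
  sum(model$w * as_plain_array(x)) + model$b
}

#' @export
model_input_gradient.linear_vol_model <- function(model, x, guided = FALSE) {
  if (!same_shape(x, model$w)) stop_arg("input shape does not match the model")
  as_plain_array(model$w)
}

## training ----------------------------------------------------------------

#' Bundle volumes and ages into a training dataset
#' @param volumes list of cubic 3D arrays (one shape).
#' @param ages numeric vector of chronological ages, one per volume.
#' @return a list of class `volume_dataset`.
#' @export
volume_dataset <- function(volumes, ages) {
  if (length(volumes) != length(ages)) stop_arg("one age per volume required")
  if (length(volumes) == 0L) stop_arg("dataset must be nonempty")
  structure(list(volumes = volumes, ages = as.numeric(ages)),
            class = "volume_dataset")
}

## stack a list of volumes into an (S, 1, N) array
stack_volumes <- function(volumes, s) {
  N <- length(volumes)
  X <- array(0, c(s^3, 1L, N))
  for (n in seq_len(N)) X[, 1L, n] <- as.numeric(volumes[[n]])
  X
}

adam_init <- function(params) lapply(params, function(p) list(m = p * 0, v = p * 0))

adam_step <- function(p, g, st, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mhat <- st$m / (1 - b1^t)
  vhat <- st$v / (1 - b2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), st = st)
}

model_mae <- function(model, dataset, batch_size = 8L) {
  preds <- predict_batch(model, dataset$volumes, batch_size)
  mean(abs(preds - dataset$ages))
}

#' Estimate brain age for a batch of volumes
#' @param model a `ba_cnn`.
#' @param volumes list of cubic 3D arrays matching the model geometry.
#' @param batch_size forward-pass minibatch size.
#' @return numeric vector of estimated brain ages, one per volume.
#' @export
predict_batch <- function(model, volumes, batch_size = 8L) {
  s <- model$config$input_size
  n <- length(volumes)
  out <- numeric(n)
  for (start in seq.int(1L, n, by = batch_size)) {
    ii <- start:min(start + batch_size - 1L, n)
    X <- stack_volumes(volumes[ii], s)
    out[ii] <- cnn_forward(model, X, training = FALSE, keep_cache = FALSE)$pred
  }
  out
}

#' Train a brain-age CNN with MAE loss, Adam, and early stopping
#'
#' Optimizes mean absolute error with Adam at the configured learning rate.
#' After each epoch the validation MAE is computed; when it has not improved
#' for `patience` consecutive epochs (or `max_epochs` is reached) training
#' stops and the weights of the best-validation epoch are restored. Targets
#' are standardized internally (the model carries the affine output mapping),
#' which keeps the optimization well-scaled without changing the function the
#' model represents.
#'
#' @param model a freshly built (or partially trained) `ba_cnn`.
#' @param train_set,val_set [volume_dataset()] objects; must be nonempty and
#'   disjoint.
#' @param val_metric optional function `(model, epoch) -> numeric` replacing
#'   the default validation-MAE computation (e.g. a custom criterion).
#' @param verbose print per-epoch losses.
#' @return list with `model` (best weights), `history` (data.frame of epoch,
#'   train_mae, val_mae), `best_epoch`, `stopped_epoch`.
#' @export
train_model <- function(model, train_set, val_set, val_metric = NULL,
                        verbose = FALSE) {
  if (!inherits(train_set, "volume_dataset") ||
      (!inherits(val_set, "volume_dataset") && is.null(val_metric)))
    stop_arg("train_set and val_set must be volume_dataset objects")
  cfg <- model$config
  ## output standardization anchored to the training targets
  y_mu <- mean(train_set$ages)
  y_sd <- stats::sd(train_set$ages)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  model$out_center <- y_mu
  model$out_scale <- y_sd

  n_train <- length(train_set$volumes)
  s <- cfg$input_size
  opt <- list(blocks = lapply(model$blocks, function(bl)
                adam_init(bl[c("W", "b", "gamma", "beta")])),
              dense = lapply(model$dense, function(dl) adam_init(dl[c("W", "b")])))
  t_step <- 0L
  history <- data.frame(epoch = integer(), train_mae = numeric(),
                        val_mae = numeric())
  best_val <- Inf
  best_epoch <- 0L
  best_weights <- NULL
  wait <- 0L
  stopped_epoch <- cfg$max_epochs

  withr::with_seed(derive_seed(cfg$seed, "train"), {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n_train)
      epoch_abs <- 0
      for (start in seq.int(1L, n_train, by = cfg$batch_size)) {
        ii <- ord[start:min(start + cfg$batch_size - 1L, n_train)]
        X <- stack_volumes(train_set$volumes[ii], s)
        y <- train_set$ages[ii]
        fwd <- cnn_forward(model, X, training = TRUE)
        model <- fwd$model              # running BN stats updated
        resid <- fwd$pred - y
        if (!all(is.finite(resid)))
          stop_arg("non-finite loss at epoch ", epoch,
                   "; try a lower learning rate")
        epoch_abs <- epoch_abs + sum(abs(resid))
        dpred <- sign(resid) / length(ii)
        bwd <- cnn_backward(model, fwd, dpred, need_param_grads = TRUE,
                            need_input_grad = FALSE, training = TRUE)
        t_step <- t_step + 1L
        for (b in seq_along(model$blocks)) {
          for (nm in c("W", "b", "gamma", "beta")) {
            up <- adam_step(model$blocks[[b]][[nm]], bwd$grads$blocks[[b]][[nm]],
                            opt$blocks[[b]][[nm]], cfg$learning_rate, t_step)
            model$blocks[[b]][[nm]] <- up$p
            opt$blocks[[b]][[nm]] <- up$st
          }
        }
        for (i in seq_along(model$dense)) {
          for (nm in c("W", "b")) {
            up <- adam_step(model$dense[[i]][[nm]], bwd$grads$dense[[i]][[nm]],
                            opt$dense[[i]][[nm]], cfg$learning_rate, t_step)
            model$dense[[i]][[nm]] <- up$p
            opt$dense[[i]][[nm]] <- up$st
          }
        }
      }
      train_mae <- epoch_abs / n_train
      val_mae <- if (is.null(val_metric)) model_mae(model, val_set)
                 else val_metric(model, epoch)
      history <- rbind(history, data.frame(epoch = epoch, train_mae = train_mae,
                                           val_mae = val_mae))
      if (verbose)
        message(sprintf("epoch %3d  train MAE %.3f  val MAE %.3f",
                        epoch, train_mae, val_mae))
      if (val_mae < best_val) {
        best_val <- val_mae
        best_epoch <- epoch
        best_weights <- list(blocks = model$blocks, dense = model$dense)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) {
          stopped_epoch <- epoch
          break
        }
      }
      stopped_epoch <- epoch
    }
  })
  if (!is.null(best_weights)) {
    model$blocks <- best_weights$blocks
    model$dense <- best_weights$dense
  }
  list(model = model,
       history = structure(history, best_epoch = best_epoch,
                           stopped_epoch = stopped_epoch),
       best_epoch = best_epoch, stopped_epoch = stopped_epoch)
}

#' Estimate brain age for a single volume
#' @param model a trained `ba_cnn` (or any model with a [model_forward()]
#'   method).
#' @param volume cubic 3D array matching the model input geometry.
#' @return estimated brain age in years (finite scalar).
#' @export
estimate_ba <- function(model, volume) {
  p <- model_forward(model, volume)
  if (!is.finite(p)) stop_arg("model produced a non-finite estimate")
  p
}

#' Integer-factor block-mean down-sampling
#'
#' Averages non-overlapping `factor^3` blocks, e.g. a 256^3 volume at 1 mm
#' becomes a 128^3 volume at 2 mm.
#'
#' @param volume cubic 3D array.
#' @param factor positive integer dividing the grid size.
#' @return down-sampled [intensity_volume()] with `voxel_mm` scaled by
#'   `factor`.
#' @export
downsample <- function(volume, factor) {
  factor <- as.integer(factor)
  d <- dim(volume)[1L]
  if (factor < 1L) stop_arg("factor must be >= 1")
  if (d %% factor != 0L) stop_arg("grid size ", d, " not divisible by ", factor)
  vm <- voxel_mm(volume) * factor
  if (factor == 1L)
    return(intensity_volume(as_plain_array(volume), vm))
  x <- as_plain_array(volume)
  for (axis in 1:3) {
    dd <- dim(x)
    ## average groups of `factor` along the first axis, then rotate axes
    dim(x) <- c(factor, dd[1L] %/% factor * dd[2L] * dd[3L])
    x <- colMeans(x)
    dim(x) <- c(dd[1L] %/% factor, dd[2L], dd[3L])
    x <- aperm(x, c(2L, 3L, 1L))
  }
  intensity_volume(x, vm)
}

#' Save / load a model checkpoint as JSON
#'
#' Weights and configuration are serialized to a single JSON file (portable,
#' text-only). Index caches are rebuilt on load.
#'
#' @param model a `ba_cnn`.
#' @param path output path (`.json`).
#' @return `path` invisibly, or the restored model for
#'   [load_model_checkpoint()].
#' @export
save_model_checkpoint <- function(model, path) {
  payload <- list(
    config = unclass(model$config[setdiff(names(model$config), "geometry")]),
    blocks = lapply(model$blocks, function(bl)
      list(W = as.vector(bl$W), b = bl$b, gamma = bl$gamma, beta = bl$beta,
           rm = bl$rm, rv = bl$rv, dim_W = dim(bl$W))),
    dense = lapply(model$dense, function(dl)
      list(W = as.vector(dl$W), b = dl$b, dim_W = dim(dl$W))),
    out_center = model$out_center, out_scale = model$out_scale)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model_checkpoint
#' @export
load_model_checkpoint <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  cfg <- do.call(cnn_config, p$config[setdiff(names(p$config),
                                              c("geometry"))])
  model <- build_model(cfg)
  model$blocks <- lapply(seq_along(model$blocks), function(b) {
    bl <- p$blocks[[b]]
    list(W = matrix(bl$W, bl$dim_W[1L], bl$dim_W[2L]), b = bl$b,
         gamma = bl$gamma, beta = bl$beta, rm = bl$rm, rv = bl$rv)
  })
  model$dense <- lapply(seq_along(model$dense), function(i) {
    dl <- p$dense[[i]]
    list(W = matrix(dl$W, dl$dim_W[1L], dl$dim_W[2L]), b = dl$b)
  })
  model$out_center <- p$out_center
  model$out_scale <- p$out_scale
  model
}
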