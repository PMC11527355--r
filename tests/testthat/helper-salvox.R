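## Shared fixtures, all built in code at test time.

## reduced CNN used across attribution / training tests
tiny_cnn_config <- function(...) {
  defaults <- list(input_size = 10L, n_blocks = 2L, filters = c(3L, 4L),
                   conv_kernel = 3L, dense_sizes = 8L, dropout_rate = 0,
                   learning_rate = 1e-2, batch_size = 2L, max_epochs = 10L,
                   patience = 10L, seed = 42L)
  do.call(cnn_config, utils::modifyList(defaults, list(...)))
}

## built model with randomized (non-identity) batch-norm running statistics,
## so evaluation-mode normalization is exercised non-trivially
tiny_cnn <- function(cfg = tiny_cnn_config(), stats_seed = 7L) {
  m <- build_model(cfg)
  withr::with_seed(stats_seed, {
    for (b in seq_along(m$blocks)) {
      nc <- length(m$blocks[[b]]$rm)
      m$blocks[[b]]$rm <- stats::rnorm(nc, 0, 0.2)
      m$blocks[[b]]$rv <- stats::runif(nc, 0.5, 1.5)
    }
  })
  m
}

## small phantom parameters that keep 16^3 grids geometrically valid
small_phantom_params <- function(...) {
  defaults <- list(grid_size = 16L, ventricle_radius_sd = 0.3, age_max = 60)
  do.call(phantom_params, utils::modifyList(defaults, list(...)))
}

## labeled cube whose LV box (1 x 2 x 16) has a 6-connected WM shell of
## exactly 2*(1*2 + 2*16 + 16*1) = 100 adjacent white-matter voxels
toy_awm100 <- function() {
  g <- 20L
  lm <- default_label_map()
  lab <- array(lm[["wm"]], c(g, g, g))
  lab[10L, 10:11, 3:18] <- lm[["lv"]]
  labels <- label_volume(lab)
  img <- array(100, c(g, g, g))
  img[lab == lm[["lv"]]] <- 30
  list(intensity = intensity_volume(img, 1), labels = labels)
}

## 3^3 LV cube centred in a 9^3 volume of `surround` tissue
lv_cube_labels <- function(surround = "wm") {
  lm <- default_label_map()
  lab <- array(lm[[surround]], c(9L, 9L, 9L))
  lab[4:6, 4:6, 4:6] <- lm[["lv"]]
  label_volume(lab)
}

## brute-force 6-connectivity edge scan, independent of the implementation
brute_force_edges <- function(lab, code) {
  d <- dim(lab)
  out <- integer(0)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (lab[x, y, z] != code) next
    nb <- rbind(c(x - 1, y, z), c(x + 1, y, z), c(x, y - 1, z),
                c(x, y + 1, z), c(x, y, z - 1), c(x, y, z + 1))
    edge <- FALSE
    for (r in seq_len(6)) {
      p <- nb[r, ]
      if (any(p < 1) || any(p > d)) { edge <- TRUE; break }
      if (lab[p[1], p[2], p[3]] != code) { edge <- TRUE; break }
    }
    if (edge) out <- c(out, (z - 1) * d[1] * d[2] + (y - 1) * d[1] + x)
  }
  sort(out)
}
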