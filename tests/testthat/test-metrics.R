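unit_map <- function(vals, d = c(2, 2, 2)) array(vals / sum(vals), d)

test_that("saliency normalization produces unit-mass densities from |raw|", {
  raw <- withr::with_seed(1, array(stats::rnorm(64), c(4, 4, 4)))
  s <- normalize_saliency(raw)
  expect_equal(sum(s), 1)
  expect_true(all(s >= 0))
  ## sign symmetry: raw and -raw normalize identically
  expect_equal(as_plain_array(normalize_saliency(-raw)), as_plain_array(s))
  ## all-equal positive raw -> uniform density
  u <- normalize_saliency(array(3, c(4, 4, 4)))
  expect_true(all(abs(u - 1 / 64) < 1e-15))
  expect_error(normalize_saliency(array(0, c(4, 4, 4))), "degenerate")
})

test_that("cohort averaging preserves the density invariant", {
  m1 <- unit_map(c(1, 0, 0, 0, 0, 0, 0, 0))
  m2 <- unit_map(c(0, 0, 0, 1, 0, 0, 0, 0))
  expect_equal(as_plain_array(cohort_mean_map(list(m1))), m1)
  expect_equal(as_plain_array(cohort_mean_map(list(m1, m1))), m1)
  mm <- cohort_mean_map(list(m1, m2))
  expect_equal(mm[1, 1, 1], 0.5)
  expect_equal(mm[2, 2, 1], 0.5)
  expect_equal(sum(mm), 1)
  expect_error(cohort_mean_map(list()), "nonempty")
})

test_that("Dice hits its printed endpoints and the worked midpoint", {
  a <- array(0, c(3, 3, 3)); a[1:4] <- 1
  expect_equal(dice(a, a), 1)
  b <- array(0, c(3, 3, 3)); b[5:8] <- 1
  expect_equal(dice(a, b), 0)
  cc_ <- array(0, c(3, 3, 3)); cc_[3:6] <- 1       # overlap of 2 with a
  expect_equal(dice(a, cc_), 0.5)
  expect_error(dice(array(0, c(2, 2, 2)), array(0, c(2, 2, 2))), "empty")
})

test_that("top-N binarization matches the fixation support size with lexicographic ties", {
  fix <- array(0, c(3, 3, 3)); fix[c(2, 7, 14)] <- 1
  ## saliency equal to the normalized fixation map recovers it exactly
  s <- array(fix / sum(fix), dim(fix))
  bin <- binarize_saliency_for_dice(s, fix)
  expect_equal(dice(bin, fix), 1)
  ## uniform saliency: deterministic tie-break selects the first N voxels in
  ## (x, y, z) tuple order: (1,1,1), (1,1,2), (1,1,3)
  u <- array(1 / 27, c(3, 3, 3))
  bu <- binarize_saliency_for_dice(u, fix)
  expect_equal(which(bu == 1),
               coord_to_index(rbind(c(1, 1, 1), c(1, 1, 2), c(1, 1, 3)),
                              c(3, 3, 3)))
  expect_equal(sum(bu), 3)
})

test_that("NMI spans its printed range and matches a hand-built histogram", {
  a <- withr::with_seed(2, array(stats::runif(40^3), c(40, 40, 40)))
  expect_equal(nmi(a, a), 2)
  b <- withr::with_seed(3, array(stats::runif(40^3), c(40, 40, 40)))
  expect_lt(abs(nmi(a, b) - 1), 0.05)   # independent noise -> ~1
  ## pencil-and-paper joint histogram on 4 voxels, 2 bins:
  ## p(a) = (1/2, 1/2); p(b) = (3/4, 1/4); joint = (1/2, 1/4, 1/4)
  a4 <- array(c(0, 0, 1, 1), c(4, 1, 1))
  b4 <- array(c(0, 0, 0, 1), c(4, 1, 1))
  h_a <- log(2)
  h_b <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  h_ab <- -(0.5 * log(0.5) + 2 * 0.25 * log(0.25))
  expect_equal(nmi(a4, b4, bins = 2), (h_a + h_b) / h_ab)
  expect_error(nmi(a4, array(0, c(2, 2, 2))), "shape")
  expect_error(nmi(array(1, c(4, 1, 1)), b4), "constant")
})

test_that("NSS is the mean z-scored saliency over fixation voxels", {
  s <- unit_map(1:8)
  ## fixation covering the whole grid averages a zero-mean field to 0
  expect_equal(nss(s, array(1, c(2, 2, 2))), 0)
  ## saliency concentrated on the fixated voxels scores positive
  fix <- array(0, c(2, 2, 2)); fix[c(7, 8)] <- 1
  expect_gt(nss(s, fix), 0)
  ## hand computation: values 1..8 (any scale), z over population sd
  v <- 1:8
  z <- (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  expect_equal(nss(s, fix), mean(z[7:8]))
  expect_error(nss(array(1 / 8, c(2, 2, 2)), fix), "constant")
  expect_error(nss(s, array(0, c(2, 2, 2))), "empty")
})

test_that("CC is the Pearson correlation over all voxels", {
  a <- unit_map(c(4, 1, 3, 2, 5, 8, 6, 7))
  expect_equal(cc(a, a), 1)
  expect_equal(cc(a, array(0.9 - 2 * a, dim(a))), -1)
  ## 4-voxel hand computation cross-checked against the closed form
  x <- c(1, 2, 3, 5); y <- c(2, 1, 4, 6)
  expect_equal(cc(array(x, c(4, 1, 1)), array(y, c(4, 1, 1))),
               sum((x - mean(x)) * (y - mean(y))) /
                 sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))
  expect_error(cc(a, array(1, dim(a))), "constant")
})

test_that("SIM sums voxelwise minima of two unit-mass maps", {
  a <- unit_map(c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_equal(sim(a, a), 1)
  b <- unit_map(c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_equal(sim(a, b), 0)
  ## a uniform over 4 voxels, b uniform over 2 of them -> 2 * 0.25 = 0.5
  b2 <- unit_map(c(1, 1, 0, 0, 0, 0, 0, 0))
  expect_equal(sim(a, b2), 0.5)
  expect_error(sim(a, array(2 * b2, dim(b2))), "normalized")
})

test_that("similarity metrics are symmetric and range-conformant on random maps", {
  for (i in 1:5) {
    s <- withr::with_seed(100 + i, {
      a <- normalize_saliency(array(stats::rnorm(6^3), c(6, 6, 6)))
      b <- normalize_saliency(array(stats::rnorm(6^3), c(6, 6, 6)))
      ba <- array(as.numeric(a > stats::median(a)), dim(a))
      bb <- array(as.numeric(b > stats::median(b)), dim(b))
      list(a = a, b = b, ba = ba, bb = bb)
    })
    expect_equal(sim(s$a, s$b), sim(s$b, s$a))
    expect_equal(cc(s$a, s$b), cc(s$b, s$a))
    expect_equal(dice(s$ba, s$bb), dice(s$bb, s$ba))
    expect_true(dice(s$ba, s$bb) >= 0 && dice(s$ba, s$bb) <= 1)
    expect_true(sim(s$a, s$b) >= 0 && sim(s$a, s$b) <= 1)
    v <- nmi(s$a, s$b)
    expect_true(v >= 1 - 1e-9 && v <= 2 + 1e-9)
    expect_true(abs(cc(s$a, s$b)) <= 1)
    expect_true(is.finite(nss(s$a, s$bb)))
    ## SIM reaches 1 only for identical maps
    expect_lt(sim(s$a, s$b), 1)
  }
  ## CC agrees with the standard correlation implementation
  a <- withr::with_seed(42, array(stats::rnorm(125), c(5, 5, 5)))
  b <- withr::with_seed(43, array(stats::rnorm(125), c(5, 5, 5)))
  expect_equal(cc(a, b), stats::cor(as.vector(a), as.vector(b)))
})

test_that("the evaluated ground truth scores perfectly against itself", {
  gt <- withr::with_seed(44, {
    g <- array(0, c(5, 5, 5))
    g[sample(125, 12)] <- stats::runif(12)
    structure(g / sum(g), class = "sv_ground_truth")
  })
  fix <- binarize_fixation(gt)
  rep <- score_saliency_maps(list(GT = as_plain_array(gt)), gt, fix)
  expect_equal(rep$DC, 1)
  expect_equal(rep$CC, 1)
  expect_equal(rep$SIM, 1)
  expect_equal(rep$NMI, 2)
})

test_that("percent differences are anchored to the baseline method", {
  scores <- data.frame(method = c("MG", "IG", "G"),
                       DC = c(0.2, 0.4, 0.1), NMI = c(1.1, 1.1, 1.1),
                       NSS = c(-2, -1, -4), CC = c(0.5, 0.25, 0.5),
                       SIM = c(0.1, 0.1, 0), stringsAsFactors = FALSE)
  rep <- percent_diff_vs_baseline(scores, "MG")
  mg <- rep[rep$method == "MG", ]
  expect_true(all(unlist(mg[paste0("pd_", c("DC", "NMI", "NSS", "CC", "SIM"))]) == 0))
  expect_equal(rep$pd_DC[rep$method == "IG"], 100)     # double the baseline
  expect_equal(rep$pd_DC[rep$method == "G"], -50)      # half the baseline
  ## negative baseline: percent difference uses |baseline| in the denominator
  expect_equal(rep$pd_NSS[rep$method == "IG"], 50)
  ## zero baseline flags the cell as undefined
  scores0 <- scores; scores0$SIM[1] <- 0
  expect_true(is.na(percent_diff_vs_baseline(scores0, "MG")$pd_SIM[2]))
  expect_error(percent_diff_vs_baseline(scores, "GB"), "absent")
})
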