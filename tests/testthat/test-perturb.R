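test_that("dilation coefficient maps age percentiles to [0, 1] as specified", {
  cas <- withr::with_seed(1, stats::runif(200, 40, 90))
  expect_equal(dilation_coefficient(min(cas), cas), 0)
  expect_equal(dilation_coefficient(max(cas), cas), 1)
  q <- stats::quantile(cas, c(0.05, 0.95), names = FALSE)
  expect_equal(dilation_coefficient(q[1], cas), 0)
  expect_equal(dilation_coefficient(q[2], cas), 1)
  expect_equal(dilation_coefficient(mean(q), cas), 0.5)
  ## linear in age between the anchors, bounded outside them
  mid <- q[1] + 0.25 * diff(q)
  expect_equal(dilation_coefficient(mid, cas), 0.25)
  for (ca in seq(20, 110, by = 5)) {
    v <- dilation_coefficient(ca, cas)
    expect_true(v >= 0 && v <= 1)
  }
  expect_error(dilation_coefficient(50, numeric(0)), "nonempty")
  expect_error(dilation_coefficient(50, rep(60, 10)), "degenerate")
})

test_that("edge detection matches a brute-force neighbor scan", {
  lm <- default_label_map()
  ## single isolated LV voxel is its own edge
  lab <- array(lm[["wm"]], c(7, 7, 7))
  lab[4, 4, 4] <- lm[["lv"]]
  lv <- label_volume(lab)
  expect_equal(find_edge_voxels(lv, "lv"), which(lab == lm[["lv"]]))
  ## solid 3^3 cube: the 26 surface voxels are edges, the centre is not
  cube <- lv_cube_labels("wm")
  edges <- find_edge_voxels(cube, "lv")
  expect_length(edges, 26)
  expect_false(coord_to_index(rbind(c(5, 5, 5)), dim(cube)) %in% edges)
  expect_equal(edges, brute_force_edges(as_plain_array(cube), lm[["lv"]]))
  ## absent structure -> empty set
  expect_length(find_edge_voxels(label_volume(array(lm[["wm"]], c(5, 5, 5))), "lv"), 0)
})

test_that("adjacent voxels split into AWM and ANWM by label", {
  lm <- default_label_map()
  ## fully WM-embedded cube: ANWM empty, AWM is the 6-connected shell (54)
  cube <- lv_cube_labels("wm")
  adj <- split_adjacent(cube, find_edge_voxels(cube, "lv"))
  expect_length(adj$anwm, 0)
  expect_length(adj$awm, 54)
  lab <- as_plain_array(cube)
  expect_true(all(lab[adj$awm] == lm[["wm"]]))
  ## fully NWM-embedded cube: AWM empty (symmetric case)
  cube2 <- lv_cube_labels("nwm")
  adj2 <- split_adjacent(cube2, find_edge_voxels(cube2, "lv"))
  expect_length(adj2$awm, 0)
  expect_length(adj2$anwm, 54)
  ## mixed neighborhood partitions all non-LV, non-background neighbors
  lab3 <- as_plain_array(cube)
  lab3[, , 6:9] <- ifelse(lab3[, , 6:9] == lm[["lv"]], lm[["lv"]], lm[["nwm"]])
  mixed <- label_volume(lab3)
  adj3 <- split_adjacent(mixed, find_edge_voxels(mixed, "lv"))
  expect_length(intersect(adj3$awm, adj3$anwm), 0)
  expect_equal(length(adj3$awm) + length(adj3$anwm), 54)
})

test_that("ventricular dilation replaces the prescribed AWM fraction", {
  toy <- toy_awm100()
  adj <- split_adjacent(toy$labels, find_edge_voxels(toy$labels, "lv"))
  expect_length(adj$awm, 100)

  res <- dilate_ventricles(toy$intensity, toy$labels, 0.8, seed = 3)
  expect_length(res$replaced_voxels, 80)
  expect_true(all(res$replaced_voxels %in% adj$awm))
  ## replacement intensities come from LV edge voxels (here uniformly 30)
  expect_true(all(res$perturbed[res$replaced_voxels] == 30))

  ## coefficient 0: no change at all
  res0 <- dilate_ventricles(toy$intensity, toy$labels, 0, seed = 3)
  expect_length(res0$replaced_voxels, 0)
  expect_identical(as_plain_array(res0$perturbed), as_plain_array(toy$intensity))

  ## coefficient 1: the whole AWM set
  res1 <- dilate_ventricles(toy$intensity, toy$labels, 1, seed = 3)
  expect_equal(sort(res1$replaced_voxels), sort(adj$awm))

  ## round-half-to-even at the selection count
  expect_length(dilate_ventricles(toy$intensity, toy$labels, 0.125,
                                  seed = 1)$replaced_voxels, 12)
  expect_length(dilate_ventricles(toy$intensity, toy$labels, 0.135,
                                  seed = 1)$replaced_voxels, 14)
})

test_that("dilation is local, monotone in the coefficient, and deterministic", {
  p <- small_phantom_params()
  ph <- generate_phantom(subject_record("s", 55), p, seed = 4)
  prev <- -1
  for (coeff in c(0, 0.25, 0.5, 0.75, 1)) {
    res <- dilate_ventricles(ph$intensity, ph$labels, coeff, seed = 11)
    expect_gte(length(res$replaced_voxels), prev)
    prev <- length(res$replaced_voxels)
    changed <- which(as_plain_array(res$perturbed) != as_plain_array(ph$intensity))
    expect_true(all(changed %in% union(res$replaced_voxels, res$peripheric_voxels)))
  }
  r1 <- dilate_ventricles(ph$intensity, ph$labels, 0.6, seed = 11)
  r2 <- dilate_ventricles(ph$intensity, ph$labels, 0.6, seed = 11)
  expect_identical(as_plain_array(r1$perturbed), as_plain_array(r2$perturbed))

  no_lv <- label_volume(array(default_label_map()[["wm"]], dim(ph$labels)))
  expect_error(dilate_ventricles(ph$intensity, no_lv, 0.5), "ventricle")
})

test_that("the enlarged ventricle boundary is re-assigned from ANWM", {
  lm <- default_label_map()
  ## LV cube bordered by WM on one side and NWM elsewhere
  lab <- array(lm[["nwm"]], c(9, 9, 9))
  lab[4:6, 4:6, 4:6] <- lm[["lv"]]
  lab[7, 4:6, 4:6] <- lm[["wm"]]          # 9 AWM voxels on the +x face
  labels <- label_volume(lab)
  img <- array(80, c(9, 9, 9))
  img[lab == lm[["lv"]]] <- 30
  img[lab == lm[["wm"]]] <- 110
  vol <- intensity_volume(img, 1)
  adj <- split_adjacent(labels, find_edge_voxels(labels, "lv"))
  expect_length(adj$awm, 9)
  anwm_mean <- mean(img[adj$anwm])
  res <- dilate_ventricles(vol, labels, 1, seed = 2)
  expect_length(res$replaced_voxels, 9)
  expect_gt(length(res$peripheric_voxels), 0)
  expect_true(all(res$perturbed[res$peripheric_voxels] == anwm_mean))
  ## peripheric voxels are the edge of the enlarged (LV + replaced) region
  enlarged <- array(FALSE, dim(lab))
  enlarged[which(lab == lm[["lv"]])] <- TRUE
  enlarged[res$replaced_voxels] <- TRUE
  inner <- which(enlarged)
  expect_true(all(res$peripheric_voxels %in% inner))
})

test_that("ground-truth synthesis averages absolute differences and normalizes", {
  d <- c(4, 4, 4)
  base <- array(1, d)
  ## identical pairs are degenerate
  expect_error(build_ground_truth(list(list(original = base, perturbed = base))),
               "degenerate")
  ## single one-voxel difference -> unit mass there
  v1 <- base; v1[2, 2, 2] <- 5
  gt1 <- build_ground_truth(list(list(original = base, perturbed = v1)))
  expect_equal(sum(gt1), 1)
  expect_equal(gt1[2, 2, 2], 1)
  ## two pairs with differences {4 at v1} and {2 at v1, 2 at v2}:
  ## means 3 and 1 -> mass 3/4 and 1/4
  a1 <- base; a1[2, 2, 2] <- base[2, 2, 2] + 4
  a2 <- base; a2[2, 2, 2] <- base[2, 2, 2] - 2; a2[3, 3, 3] <- base[3, 3, 3] + 2
  gt2 <- build_ground_truth(list(list(original = base, perturbed = a1),
                                 list(original = base, perturbed = a2)))
  expect_equal(gt2[2, 2, 2], 0.75)
  expect_equal(gt2[3, 3, 3], 0.25)
  expect_equal(sum(gt2), 1)
  ## fixation map marks exactly the support
  fix <- binarize_fixation(gt2)
  expect_equal(sum(fix), 2)
  expect_equal(which(fix == 1), sort(c(which(gt2 == 0.75), which(gt2 == 0.25))))
  expect_error(binarize_fixation(array(0, d)), "support")
})
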