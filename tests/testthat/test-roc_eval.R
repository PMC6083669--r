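# Small geometric fixtures; the full-scene ROC properties are exercised in
# the acceptance tests.
unit_bounds <- rbind(min = c(0, 0, 0), max = c(1, 1, 1))

test_that("voxelize matches a direct floor-division scan", {
  empty <- point_cloud(matrix(numeric(0), 0, 3))
  expect_identical(voxelize(empty, 0.1, unit_bounds)$indices, integer(0))

  one <- point_cloud(matrix(c(0.05, 0.05, 0.05), 1, 3))
  vg <- voxelize(one, 0.25, unit_bounds)
  expect_identical(vg$indices, 1L)

  pc <- random_cloud(500, seed = 9)
  vg <- voxelize(pc, 0.2, unit_bounds)
  ijk <- floor(pc$points / 0.2)
  ijk[ijk >= 5] <- 4
  oracle <- sort(unique(as.integer(1 + ijk[, 1] + 5 * (ijk[, 2] + 5 * ijk[, 3]))))
  expect_identical(vg$indices, oracle)

  outside <- point_cloud(matrix(c(2, 2, 2), 1, 3))
  expect_warning(voxelize(outside, 0.2, unit_bounds), "clipped")
})

test_that("confusion anchors hold at r = 0 and beyond the scene diagonal", {
  ref <- random_cloud(300, seed = 10)
  model <- random_cloud(250, seed = 11)
  at0 <- confusion_at(model, ref, 0, voxel_size = 0.1, bounds = unit_bounds)
  expect_identical(c(at0$TP, at0$FP), c(0L, 0L))

  big <- confusion_at(model, ref, sqrt(3) * 2, voxel_size = 0.1,
                      bounds = unit_bounds)
  expect_identical(c(big$FN, big$TN), c(0L, 0L))
  expect_identical(c(big$TPR, big$FPR), c(1, 1))
})

test_that("confusion counts equal the exhaustive per-voxel scan", {
  set.seed(12)
  for (case in 1:3) {
    n <- sample(100:400, 1)
    ref <- matrix(runif(3 * n), n, 3)
    model <- matrix(runif(3 * sample(100:400, 1)), ncol = 3)
    vox <- 1 / 32           # 32^3 grid
    for (r in c(0, 0.05, 0.2, 0.6)) {
      got <- confusion_at(point_cloud(model), point_cloud(ref), r,
                          voxel_size = vox, bounds = unit_bounds)
      want <- bf_confusion(model, ref, r, vox, unit_bounds)
      expect_identical(c(got$TP, got$FP, got$FN, got$TN),
                       as.integer(unname(want)))
    }
  }
})

test_that("grossly unaligned inputs warn rather than fail", {
  ref <- random_cloud(300, seed = 40)
  off <- apply_transform(ref, similarity_transform(translation = c(50, 0, 0)))
  expect_warning(
    confusion_at(off, ref, 0.1, voxel_size = 0.1, bounds = unit_bounds),
    "unaligned")
})

test_that("roc_curve sweeps monotonically and conserves the class totals", {
  ref <- random_cloud(400, seed = 13)
  dg_model <- pc_subset(ref, 1:200)    # heavy omission
  rc <- roc_curve(dg_model, ref, voxel_size = 0.05, bounds = unit_bounds)
  cv <- rc$curve
  expect_identical(c(cv$TPR[1], cv$FPR[1]), c(0, 0))
  expect_identical(c(cv$TPR[nrow(cv)], cv$FPR[nrow(cv)]), c(1, 1))
  expect_true(all(diff(cv$TPR) >= 0))
  expect_true(all(diff(cv$FPR) >= 0))
  expect_true(all(cv$TP + cv$FN == rc$positives))
  expect_true(all(cv$FP + cv$TN == rc$negatives))
})

test_that("an empty model yields a curve with no predictions at finite r", {
  ref <- random_cloud(300, seed = 14)
  empty <- point_cloud(matrix(numeric(0), 0, 3))
  rc <- roc_curve(empty, ref, voxel_size = 0.1, bounds = unit_bounds)
  body <- rc$curve[2:(nrow(rc$curve) - 1), ]
  expect_true(all(body$TP == 0))
  expect_true(all(body$FP == 0))
  expect_identical(rc$curve$TPR[nrow(rc$curve)], 1)
})

test_that("AUC handles canonical curves and matches the independent trapezoid", {
  expect_identical(auc(data.frame(FPR = c(0, 1), TPR = c(0, 1))), 0.5)
  expect_identical(auc(data.frame(FPR = c(0, 0, 1), TPR = c(0, 1, 1))), 1)
  pts <- data.frame(FPR = c(0, 0.2, 0.5, 1), TPR = c(0, 0.6, 0.9, 1))
  expect_equal(auc(pts), bf_trapezoid(pts$FPR, pts$TPR))
  # hand trapezoid: 0.2*0.3 + 0.3*0.75 + 0.5*0.95 = 0.76
  expect_equal(auc(pts), 0.76)
})

test_that("AUC is invariant under shared rigid motion and point order", {
  ref <- random_cloud(400, seed = 15)
  model <- pc_subset(ref, 1:300)
  base <- roc_curve(model, ref, voxel_size = 0.025, bounds = unit_bounds)$auc

  # translations move the grid with the clouds: exactly invariant
  shift <- c(3.2, -1.7, 0.4)
  bounds_t <- unit_bounds + rbind(shift, shift)
  tf_t <- similarity_transform(translation = shift)
  shifted <- roc_curve(apply_transform(model, tf_t), apply_transform(ref, tf_t),
                       voxel_size = 0.025, bounds = bounds_t)$auc
  expect_equal(shifted, base, tolerance = 1e-6)

  # arbitrary rotations re-discretize space on an axis-aligned grid, so
  # invariance holds only up to the grid resolution
  set.seed(16)
  tf <- similarity_transform(1, random_rotation(), rnorm(3))
  ref_m <- apply_transform(ref, tf)
  mod_m <- apply_transform(model, tf)
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  moved_corners <- apply_transform(corners, tf)
  bounds_m <- rbind(min = apply(moved_corners, 2, min),
                    max = apply(moved_corners, 2, max))
  moved <- roc_curve(mod_m, ref_m, voxel_size = 0.025, bounds = bounds_m)$auc
  expect_lt(abs(base - moved), 0.05)

  perm <- sample(300)
  shuffled <- roc_curve(pc_subset(model, perm), ref, voxel_size = 0.025,
                        bounds = unit_bounds)$auc
  expect_identical(shuffled, base)
})

test_that("evaluate produces a complete, deterministic report", {
  sc <- mini_scene(seed = 8)
  dg <- degrade(sc, degrade_spec(omission_fraction = 0.2, jitter_sd = 0.01,
                                 seed = 17))
  cfg <- list(voxel_size = sc$scene_width / 32, octree_level = 6L)
  rep1 <- evaluate(dg, sc, cfg)
  expect_s3_class(rep1, "evaluation_report")
  expect_true(rep1$auc >= 0 && rep1$auc <= 1)
  expect_true(all(c("alignment", "distance", "census", "point_rates",
                    "roc", "auc", "config") %in% names(rep1)))
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_report(rep1, f1)
  rep2 <- evaluate(degrade(sc, degrade_spec(omission_fraction = 0.2,
                                            jitter_sd = 0.01, seed = 17)),
                   sc, cfg)
  write_report(rep2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
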