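test_that("estimate_similarity is exact on noiseless configurations", {
  set.seed(1)
  src <- matrix(rnorm(24), 8, 3)
  id <- estimate_similarity(src, src)
  expect_lt(abs(id$scale - 1), 1e-9)
  expect_lt(max(abs(id$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(id$translation)), 1e-9)

  for (i in 1:5) {
    tf <- similarity_transform(runif(1, 0.5, 2), random_rotation(), rnorm(3, 0, 5))
    K <- sample(3:10, 1)
    src <- matrix(rnorm(3 * K), K, 3)
    est <- estimate_similarity(src, apply_transform(src, tf))
    expect_lt(abs(est$scale - tf$scale), 1e-9)
    expect_lt(max(abs(est$rotation - tf$rotation)), 1e-9)
    expect_lt(max(abs(est$translation - tf$translation)), 1e-9)
    expect_lt(attr(est, "rms"), 1e-9)
  }
})

test_that("degenerate correspondence configurations raise a rank error", {
  line <- cbind(1:5, 2 * (1:5), -1:3 * 0)   # collinear
  expect_error(estimate_similarity(line, line + 1), "degenerate")
  expect_error(estimate_similarity(matrix(0, 2, 3), matrix(0, 2, 3)), "K >= 3")
})

test_that("apply_transform obeys the group laws numerically", {
  set.seed(2)
  pts <- matrix(rnorm(300), 100, 3)
  for (i in 1:10) {
    a <- similarity_transform(runif(1, 0.5, 2), random_rotation(), rnorm(3))
    b <- similarity_transform(runif(1, 0.5, 2), random_rotation(), rnorm(3))
    # identity and inverse
    expect_lt(max(abs(apply_transform(apply_transform(pts, a),
                                      invert_transform(a)) - pts)), 1e-9)
    # composition associativity with application order
    ab <- compose_transform(a, b)
    expect_lt(max(abs(apply_transform(pts, ab) -
                        apply_transform(apply_transform(pts, b), a))), 1e-9)
  }
  pc <- point_cloud(pts, labels = rep(1L, 100))
  same <- apply_transform(pc, similarity_transform())
  expect_equal(same$points, pts)
  expect_identical(same$labels, pc$labels)
})

test_that("noisy target centroids recover the transform precisely", {
  sc <- mini_scene(seed = 3)
  sw <- sc$scene_width
  set.seed(11)
  errs <- t(replicate(30, {
    tf <- similarity_transform(runif(1, 0.5, 2), random_rotation(), rnorm(3, 0, 10))
    noisy <- apply_transform(sc$target_centroids, tf) +
      matrix(rnorm(24, 0, 1e-3 * sw), 8, 3)
    est <- estimate_similarity(sc$target_centroids, noisy)
    rel_rot <- est$rotation %*% t(tf$rotation)
    c(scale = abs(est$scale - tf$scale) / tf$scale,
      rot = cloudtruth:::rotation_angle_deg(rel_rot),
      trans = sqrt(sum((est$translation - tf$translation)^2)) / sw)
  }))
  expect_lt(median(errs[, "scale"]), 0.01)
  expect_lt(median(errs[, "rot"]), 0.5)
  expect_lt(median(errs[, "trans"]), 0.005)
})

test_that("icp_refine returns the identity for already aligned clouds", {
  sc <- mini_scene(seed = 4)
  tf <- icp_refine(sc$reference, sc$reference)
  expect_lt(abs(tf$scale - 1), 1e-9)
  expect_lt(max(abs(tf$rotation - diag(3))), 1e-9)
  expect_lt(attr(tf, "rms"), 1e-9)
  expect_identical(attr(tf, "iterations"), 1L)
})

test_that("icp_refine reduces the RMS of a small misalignment", {
  sc <- mini_scene(seed = 5)
  set.seed(21)
  keep <- sample(n_points(sc$reference), 1e4)
  model <- pc_subset(sc$reference, keep)
  ax <- c(0, 0, 1)
  ang <- 2 * pi / 180
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  perturb <- similarity_transform(1.01, R, c(0.05, -0.05, 0.02))
  moved <- apply_transform(model, perturb)

  init_rms <- {
    nn <- cloudtruth:::cpp_nn(moved$points, sc$reference$points)
    sqrt(mean(nn$dist^2))
  }
  tf <- icp_refine(moved, sc$reference)
  expect_lt(attr(tf, "rms"), init_rms)
})

test_that("icp_refine recovers a known perturbation on distinctive geometry", {
  # the repetitive ground grid can trap ICP in a lattice-shifted minimum, so
  # the recovery harness runs on the tree, whose geometry is unambiguous
  tree <- generate_tree(scene_params(points_per_unit_area = 30,
                                     foliage_points_per_tip = 400L, seed = 5))
  set.seed(21)
  model <- pc_subset(tree, sample(n_points(tree), 1e4))
  ang <- 2 * pi / 180
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  for (s in 1:5) {
    set.seed(s)
    perturb <- similarity_transform(1.01, R, runif(3, -0.05, 0.05))
    tf <- icp_refine(apply_transform(model, perturb), tree, max_iter = 100)
    inv <- invert_transform(perturb)
    expect_lt(abs(tf$scale - inv$scale) / inv$scale, 0.01)
    expect_lt(cloudtruth:::rotation_angle_deg(tf$rotation %*% t(inv$rotation)), 0.5)
    expect_lt(sqrt(sum((tf$translation - inv$translation)^2)), 0.05)
  }
})

test_that("align_to_targets recovers a perturbed pose via labelled cubes", {
  sc <- mini_scene(seed = 6)
  pose <- similarity_transform(1.4, random_rotation(), c(3, -2, 1))
  dg <- degrade(sc, degrade_spec(pose_perturbation = pose, seed = 7))
  tf <- align_to_targets(dg$cloud, sc)
  inv <- invert_transform(pose)
  expect_lt(abs(tf$scale - inv$scale) / inv$scale, 1e-6)
  expect_lt(max(abs(apply_transform(dg$cloud, tf)$points -
                      sc$reference$points)), 1e-6)
})
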