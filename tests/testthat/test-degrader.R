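# Operators are exercised on a small scene; ground-truth recovery at the
# full segmentation scale lives in the acceptance tests.
local_scene <- mini_scene(seed = 2)

test_that("the all-zero spec is the byte-exact identity", {
  dg <- degrade(local_scene, degrade_spec())
  expect_identical(dg$cloud, local_scene$reference)
  expect_identical(dg$manifest$artefact_count, 0L)
  expect_identical(apply_omission(local_scene$reference, degrade_spec()),
                   local_scene$reference)
  expect_identical(add_floating_clusters(local_scene$reference, degrade_spec()),
                   local_scene$reference)
  expect_identical(add_jitter(local_scene$reference, degrade_spec()),
                   local_scene$reference)
  expect_identical(thin_cloud(local_scene$reference, degrade_spec()),
                   local_scene$reference)
  expect_identical(perturb_pose(local_scene$reference, degrade_spec()),
                   local_scene$reference)
})

test_that("omission holes empty their spheres and the fraction rule holds", {
  spec <- degrade_spec(omission_hole_count = 3L, omission_hole_radius = 1.2,
                       omission_fraction = 0.25, seed = 3)
  out <- apply_omission(local_scene$reference, spec)
  ref <- local_scene$reference

  # recount tree-point removal exhaustively
  tree0 <- sum(ref$labels %in% 1:3)
  tree1 <- sum(out$labels %in% 1:3)
  expect_gte((tree0 - tree1) / tree0, spec$omission_fraction)

  # no surviving point inside any hole: every removed region must be empty.
  # Recover hole centres by running the same seeded choice.
  centres <- with_seed(spec$seed + 11L, {
    idx <- which(ref$labels %in% 1:3)
    ref$points[sample(idx, spec$omission_hole_count), , drop = FALSE]
  })
  d <- bf_nn_dist(centres, out$points)
  expect_true(all(d > 0))   # centres themselves were removed
  for (i in seq_len(nrow(centres))) {
    d_all <- sqrt(rowSums(sweep(out$points, 2, centres[i, ])^2))
    expect_true(all(d_all > spec$omission_hole_radius))
  }

  # non-tree points are untouched by the fraction rule (only holes touch them)
  spec2 <- degrade_spec(omission_fraction = 0.5, seed = 3)
  out2 <- apply_omission(local_scene$reference, spec2)
  expect_identical(sum(out2$labels == 0L), sum(ref$labels == 0L))
})

test_that("omission_fraction = 1 removes all tree points and keeps the rest", {
  out <- apply_omission(local_scene$reference, degrade_spec(omission_fraction = 1))
  expect_identical(sum(out$labels %in% 1:3), 0L)
  expect_identical(sum(out$labels == 0L), sum(local_scene$reference$labels == 0L))
})

test_that("floating clusters carry fresh labels and respect separation", {
  spec <- degrade_spec(floating_cluster_count = 12L, seed = 5)
  out <- add_floating_clusters(local_scene$reference, spec)
  new_labels <- setdiff(unique(out$labels), unique(local_scene$reference$labels))
  expect_identical(length(new_labels), 12L)
  expect_true(all(new_labels >= 100L))

  centres <- t(vapply(new_labels, function(lb) {
    colMeans(out$points[out$labels == lb, , drop = FALSE])
  }, numeric(3)))
  # all-pairs scan of the separation rule (centres two cluster diameters apart)
  d <- as.matrix(stats::dist(centres))
  diameter <- 5 * spec$floating_cluster_sd
  expect_gt(min(d[d > 0]), 2 * diameter)
  # and clear of the scene
  gap <- min(bf_nn_dist(centres, local_scene$reference$points))
  expect_gt(gap, 2 * diameter)
})

test_that("an undersized floating region is a placement error", {
  region <- rbind(min = c(0, 0, 40), max = c(0.3, 0.3, 40.2))
  spec <- degrade_spec(floating_cluster_count = 50L, floating_region = region)
  expect_error(add_floating_clusters(local_scene$reference, spec), "placement")
})

test_that("ring points sit at the prescribed radius and height band", {
  spec <- degrade_spec(attached_ring = TRUE, ring_radius = 3, seed = 6)
  out <- add_attached_ring(local_scene$reference, spec)
  ring_lab <- setdiff(unique(out$labels), unique(local_scene$reference$labels))
  expect_identical(length(ring_lab), 1L)
  ring <- out$points[out$labels == ring_lab, ]
  fol <- local_scene$reference$points[local_scene$reference$labels == 3L, ]
  ctr <- c(mean(fol[, 1]), mean(fol[, 2]))
  radial <- sqrt((ring[, 1] - ctr[1])^2 + (ring[, 2] - ctr[2])^2)
  expect_true(all(radial >= 3 - spec$ring_thickness - 1e-12))
  expect_true(all(radial <= 3 + spec$ring_thickness + 1e-12))

  bare <- pc_subset(local_scene$reference, local_scene$reference$labels != 3L)
  expect_error(add_attached_ring(bare, spec), "foliage")
  expect_identical(add_attached_ring(local_scene$reference, degrade_spec()),
                   local_scene$reference)
})

test_that("ghosts copy the named component exactly", {
  spec <- degrade_spec(ghost_component = 1L, ghost_offset = c(5, 0, 0))
  out <- add_ghost(local_scene$reference, spec)
  ref <- local_scene$reference
  glab <- setdiff(unique(out$labels), unique(ref$labels))
  ghost <- out$points[out$labels == glab, ]
  trunk <- ref$points[ref$labels == 1L, ]
  expect_identical(nrow(ghost), nrow(trunk))
  # NN distance from each ghost point to the shifted trunk is exactly 0
  shifted <- sweep(trunk, 2, c(5, 0, 0), `+`)
  expect_true(all(bf_nn_dist(ghost, shifted) == 0))

  # degenerate zero offset is allowed
  out0 <- add_ghost(ref, degrade_spec(ghost_component = 1L,
                                      ghost_offset = c(0, 0, 0)))
  expect_identical(n_points(out0), n_points(ref) + nrow(trunk))
  expect_error(add_ghost(ref, degrade_spec(ghost_component = 77L)), "not present")
})

test_that("thinning keeps a binomial fraction and jitter perturbs in place", {
  big <- point_cloud(matrix(runif(3e5), 1e5, 3))
  spec <- degrade_spec(thinning_keep = 0.5, seed = 8)
  kept <- n_points(thin_cloud(big, spec)) / 1e5
  se <- sqrt(0.25 / 1e5)
  expect_lt(abs(kept - 0.5), 3 * se)

  jit <- add_jitter(big, degrade_spec(jitter_sd = 0.01, seed = 8))
  expect_identical(n_points(jit), n_points(big))
  moved <- sqrt(rowSums((jit$points - big$points)^2))
  expect_gt(min(moved), 0)
  expect_lt(mean(moved), 0.01 * 3)
})

test_that("degrade applies operators in order and books every artefact", {
  spec <- degrade_spec(omission_fraction = 0.1, floating_cluster_count = 4L,
                       attached_ring = TRUE, ghost_component = 1L,
                       thinning_keep = 0.9, jitter_sd = 0.005,
                       pose_perturbation = similarity_transform(
                         scale = 1.2, translation = c(1, 2, 3)),
                       seed = 10)
  dg <- degrade(local_scene, spec)
  expect_identical(dg$manifest$artefact_count, 4L + 1L + 1L)
  expect_identical(sort(unique(dg$manifest$artefacts$type)),
                   c("attached_ring", "floating_cluster", "ghost"))
  expect_true(all(dg$manifest$artefacts$label >= 100L))
  # every manifest label present in the cloud with matching point count
  for (i in seq_len(nrow(dg$manifest$artefacts))) {
    lb <- dg$manifest$artefacts$label[i]
    expect_identical(sum(dg$cloud$labels == lb), dg$manifest$artefacts$n_points[i])
  }
  expect_gte(dg$manifest$omission$achieved_fraction + 1e-12, 0.1)
})

test_that("degradation is deterministic under the seed", {
  spec <- degrade_spec(omission_fraction = 0.2, floating_cluster_count = 3L,
                       jitter_sd = 0.01, thinning_keep = 0.8, seed = 12)
  a <- degrade(local_scene, spec)
  b <- degrade(local_scene, spec)
  expect_identical(a$cloud, b$cloud)
  expect_identical(a$manifest, b$manifest)
})
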