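test_that("a single blob is a single cluster", {
  # the octree grid derives from the cloud's own bbox, so the level must be
  # coarse enough that the voxel edge exceeds the blob's point spacing
  bl <- make_blobs(1, seed = 1, n_each = 600L)
  cc <- connected_components(bl$cloud, octree_level = 3L, min_cluster_points = 5L)
  expect_identical(nrow(cc$clusters), 1L)
})

test_that("two well-separated blobs are two clusters", {
  bl <- make_blobs(2, seed = 2)
  cc <- connected_components(bl$cloud, octree_level = 7L, min_cluster_points = 5L)
  # separation guarantee: gap 10 >> 2 * voxel_edge * sqrt(3)
  expect_gt(10, 2 * cc$voxel_edge * sqrt(3))
  expect_identical(nrow(cc$clusters), 2L)
})

test_that("octree components equal the union-find oracle on k-blob fixtures", {
  for (k in c(2L, 3L, 5L, 8L, 10L)) {
    bl <- make_blobs(k, seed = 10 + k, n_each = 150L)
    cc <- connected_components(bl$cloud, octree_level = 6L,
                               min_cluster_points = 1L)
    oracle <- bf_union_find(bl$cloud$points, threshold = cc$voxel_edge * sqrt(3))
    expect_identical(nrow(cc$clusters), k)
    expect_true(same_partition(cc$membership, oracle))
    expect_true(same_partition(cc$membership, bl$truth))
  }
})

test_that("segmentation is invariant to point order", {
  bl <- make_blobs(4, seed = 3)
  cc1 <- connected_components(bl$cloud, 7L, 1L)
  set.seed(4)
  perm <- sample(n_points(bl$cloud))
  cc2 <- connected_components(pc_subset(bl$cloud, perm), 7L, 1L)
  expect_true(same_partition(cc1$membership[perm], cc2$membership))
})

test_that("component count is non-increasing as the grid coarsens", {
  bl <- make_blobs(6, seed = 5, sd = 0.25)
  counts <- vapply(10:6, function(lv) {
    nrow(connected_components(bl$cloud, lv, 1L)$clusters)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))   # levels 10 -> 6: voxels grow
})

test_that("small clusters land in the residue bucket", {
  bl <- make_blobs(3, seed = 6, n_each = 50L)
  lone <- point_cloud(matrix(c(25, 25, 25, 25.01, 25, 25), 2, 3, byrow = TRUE))
  cc <- connected_components(pc_bind(bl$cloud, lone), 7L, min_cluster_points = 10L)
  expect_identical(nrow(cc$clusters), 3L)
  expect_identical(cc$residue_points, 2L)
  expect_identical(cc$residue_clusters, 1L)
})

test_that("clusters are classified main / attached / floating by gap", {
  # main blob + one near satellite (inside the gap) + one distant satellite
  set.seed(7)
  main <- matrix(runif(3 * 600, 0, 2), 600, 3)
  attached <- sweep(matrix(runif(3 * 60, 0, 0.4), 60, 3), 2, c(2.8, 1, 1), `+`)
  floating <- sweep(matrix(runif(3 * 60, 0, 0.4), 60, 3), 2, c(8, 8, 8), `+`)
  cloud <- point_cloud(rbind(main, attached, floating))
  cc <- connected_components(cloud, 5L, 5L)
  rep <- classify_clusters(cc, cloud, gap_threshold = 1.0)
  expect_identical(unname(rep$counts), c(1L, 1L, 1L))
  expect_identical(rep$clusters$class[1], "main")
  cl_att <- rep$clusters[rep$clusters$class == "attached", ]
  expect_lte(cl_att$min_gap_to_main, 1.0)
  cl_flo <- rep$clusters[rep$clusters$class == "floating", ]
  expect_gt(cl_flo$min_gap_to_main, 1.0)
})

test_that("a tie for largest cluster warns and keeps the lowest id", {
  a <- matrix(runif(300, 0, 1), 100, 3)
  b <- sweep(matrix(runif(300, 0, 1), 100, 3), 2, c(20, 0, 0), `+`)
  cloud <- point_cloud(rbind(a, b))
  cc <- connected_components(cloud, 6L, 5L)
  expect_identical(cc$clusters$point_count, c(100L, 100L))
  expect_warning(classify_clusters(cc, cloud), "tie")
})

test_that("the undegraded reference is one main component, no artefacts", {
  sc <- default_scene()
  cc <- connected_components(sc$reference)
  rep <- classify_clusters(cc, sc$reference)
  expect_identical(unname(rep$counts), c(1L, 0L, 0L))
})

test_that("an attached ring merges with the main component", {
  sc <- default_scene()
  dg <- degrade(sc, degrade_spec(attached_ring = TRUE, seed = 9))
  cen <- census(dg$cloud, sc$reference)
  expect_identical(unname(cen$counts["floating"]), 0L)
  # the ring is inside the main cluster: verify its labelled points merged
  ring_lab <- dg$manifest$artefacts$label[dg$manifest$artefacts$type == "attached_ring"]
  cc <- connected_components(dg$cloud)
  ring_membership <- cc$membership[dg$cloud$labels == ring_lab]
  # merged: effectively all ring points in the main component (a handful may
  # land in sub-threshold residue fragments)
  expect_gt(mean(ring_membership == 1L, na.rm = TRUE), 0.99)
  expect_lt(sum(is.na(ring_membership)), 10L)
})

test_that("census reports identity reconstructions as flawless", {
  sc <- default_scene()
  cen <- census(sc$reference, sc$reference)
  expect_identical(cen$omission_fraction, 0)
  expect_identical(unname(cen$counts["floating"]), 0L)
})
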