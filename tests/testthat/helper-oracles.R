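# Independent brute-force oracles and shared fixtures. Every oracle here is
# deliberately implemented without touching the package's spatial index or
# graph machinery, so tests compare two independent routes to the same
# quantity.

# --- fixtures ---------------------------------------------------------------

.scene_cache <- new.env(parent = emptyenv())

# Full-density reference scene (the package defaults), memoized per seed.
default_scene <- function(seed = 1L) {
  key <- paste0("s", seed)
  if (is.null(.scene_cache[[key]])) {
    .scene_cache[[key]] <- assemble_scene(scene_params(seed = seed))
  }
  .scene_cache[[key]]
}

# Small, fast scene for tests where level-8 voxel connectivity is irrelevant.
mini_scene <- function(seed = 1L) {
  assemble_scene(scene_params(points_per_unit_area = 8,
                              foliage_points_per_tip = 150L,
                              seed = seed))
}

random_cloud <- function(n, seed, scale = 1) {
  set.seed(seed)
  point_cloud(matrix(runif(3 * n), n, 3) * scale)
}

random_rotation <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, pi)
  S <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  K <- ax %*% t(ax)
  cos(ang) * diag(3) + sin(ang) * S + (1 - cos(ang)) * K
}

# Blob fixtures with a guaranteed separation: intra-blob spacing well below
# the voxel edge, inter-blob gaps well above the voxel diagonal, so the
# octree components and the point-pair union-find oracle agree exactly.
make_blobs <- function(k, seed, n_each = 250L, sd = 0.06, span = 10) {
  set.seed(seed)
  centres <- span * as.matrix(expand.grid(0:2, 0:2, 0:2))[seq_len(k), , drop = FALSE]
  pts <- do.call(rbind, lapply(seq_len(k), function(i) {
    b <- matrix(rnorm(3 * n_each, 0, sd), n_each, 3)
    r <- sqrt(rowSums(b^2)); cap <- 2.5 * sd
    b[r > cap, ] <- b[r > cap, , drop = FALSE] * (cap / r[r > cap])
    sweep(b, 2, centres[i, ], `+`)
  }))
  list(cloud = point_cloud(pts), truth = rep(seq_len(k), each = n_each))
}

# --- brute-force nearest neighbours -----------------------------------------

bf_nn_dist <- function(query, target) {
  vapply(seq_len(nrow(query)), function(i) {
    sqrt(min(rowSums(sweep(target, 2, query[i, ])^2)))
  }, numeric(1))
}

# --- brute-force union-find over point pairs --------------------------------

bf_union_find <- function(points, threshold) {
  n <- nrow(points)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  d <- as.matrix(stats::dist(points))
  for (i in seq_len(n - 1)) {
    for (j in which(d[i, (i + 1):n] < threshold) + i) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Two cluster labelings describe the same partition iff their contingency
# table has exactly one non-zero cell per row and per column.
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# --- exhaustive per-voxel confusion scan ------------------------------------

# Direct scan over every voxel centre of the grid: min distance to reference
# and model point sets by vectorized subtraction (no spatial index).
bf_confusion <- function(model_pts, reference_pts, r, voxel_size, bounds) {
  dims <- pmax(1L, as.integer(ceiling((bounds[2, ] - bounds[1, ]) / voxel_size)))
  cx <- bounds[1, 1] + (seq_len(dims[1]) - 0.5) * voxel_size
  cy <- bounds[1, 2] + (seq_len(dims[2]) - 0.5) * voxel_size
  cz <- bounds[1, 3] + (seq_len(dims[3]) - 0.5) * voxel_size
  centres <- as.matrix(expand.grid(x = cx, y = cy, z = cz))
  min_d2 <- function(pts) {
    best <- rep(Inf, nrow(centres))
    for (j in seq_len(nrow(pts))) {
      best <- pmin(best, (centres[, 1] - pts[j, 1])^2 +
                     (centres[, 2] - pts[j, 2])^2 +
                     (centres[, 3] - pts[j, 3])^2)
    }
    best
  }
  r_pos <- voxel_size * sqrt(3) / 2
  pos <- sqrt(min_d2(reference_pts)) <= r_pos
  pred <- if (r > 0) sqrt(min_d2(model_pts)) <= r else rep(FALSE, nrow(centres))
  c(TP = sum(pos & pred), FP = sum(!pos & pred),
    FN = sum(pos & !pred), TN = sum(!pos & !pred))
}

# --- independent trapezoid --------------------------------------------------

bf_trapezoid <- function(fpr, tpr) {
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  total <- 0
  for (i in seq_len(length(fpr) - 1)) {
    total <- total + (fpr[i + 1] - fpr[i]) * (tpr[i] + tpr[i + 1]) / 2
  }
  total
}

# --- recursion-tree segment count -------------------------------------------

bf_segment_count <- function(branches_per_node, depth) {
  if (depth == 0L) return(1L)
  1L + branches_per_node * bf_segment_count(branches_per_node, depth - 1L)
}
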