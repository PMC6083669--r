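#' Parameters for the synthetic tree scene
#'
#' Describes a virtual field plot at the point-cloud level: a single-trunk
#' deciduous tree with recursive branching and foliage, a grass-textured
#' ground plane, and eight brightly coloured cube targets for alignment. The
#' defaults emulate the study conditions the framework is designed for: a
#' 16-unit-tall tree imaged from a 20-unit-radius circular flight, hence a
#' 40-unit ground extent.
#'
#' @param tree_height total tree height in scene units (default 16).
#' @param trunk_radius trunk cylinder radius at the base (default 0.3).
#' @param branching_depth recursion depth of the branching skeleton; 0 gives
#'   a bare trunk (default 4).
#' @param branch_angle_deg tilt of each child branch from its parent axis in
#'   degrees (default 35).
#' @param branches_per_node children spawned at each branch tip (default 3).
#' @param branch_length_ratio child/parent segment length ratio, < 1
#'   (default 0.62).
#' @param foliage_points_per_tip points sampled in the ellipsoidal foliage
#'   blob at each terminal tip (default 1200).
#' @param ground_extent side length of the square ground plane (default 40).
#' @param grass_noise_sd standard deviation of the vertical grass roughness
#'   (default 0.05).
#' @param target_edge edge length of the eight target cubes (default 1).
#' @param points_per_unit_area sampling density on surfaces (ground, bark,
#'   cube faces), points per squared scene unit (default 60).
#' @param seed integer seed fixing the whole scene deterministically.
#' @param point_budget_cap hard cap on generated points; exceeding it is an
#'   error rather than a silent truncation (default 2e6).
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(tree_height = 16,
                         trunk_radius = 0.3,
                         branching_depth = 4L,
                         branch_angle_deg = 35,
                         branches_per_node = 3L,
                         branch_length_ratio = 0.62,
                         foliage_points_per_tip = 1200L,
                         ground_extent = 40,
                         grass_noise_sd = 0.05,
                         target_edge = 1,
                         points_per_unit_area = 60,
                         seed = 1L,
                         point_budget_cap = 2e6) {
  p <- list(tree_height = tree_height, trunk_radius = trunk_radius,
            branching_depth = as.integer(branching_depth),
            branch_angle_deg = branch_angle_deg,
            branches_per_node = as.integer(branches_per_node),
            branch_length_ratio = branch_length_ratio,
            foliage_points_per_tip = as.integer(foliage_points_per_tip),
            ground_extent = ground_extent, grass_noise_sd = grass_noise_sd,
            target_edge = target_edge,
            points_per_unit_area = points_per_unit_area,
            seed = as.integer(seed), point_budget_cap = point_budget_cap)
  stopifnot(p$tree_height > 0, p$trunk_radius > 0, p$branching_depth >= 0L,
            p$branches_per_node >= 1L,
            p$branch_length_ratio > 0, p$branch_length_ratio < 1,
            p$foliage_points_per_tip >= 0L, p$ground_extent > 0,
            p$grass_noise_sd >= 0, p$target_edge > 0,
            p$points_per_unit_area > 0, p$point_budget_cap > 0)
  structure(p, class = "scene_params")
}

# Orthonormal basis perpendicular to a unit vector d.
perp_basis <- function(d) {
  a <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(d[2] * a[3] - d[3] * a[2], d[3] * a[1] - d[1] * a[3],
         d[1] * a[2] - d[2] * a[1])
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2], d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  list(u = u, v = v)
}

# Recursive branching skeleton in unit-trunk coordinates. Each node spawns
# `branches_per_node` children tilted by branch_angle from the parent axis,
# azimuths evenly spread with seeded jitter, lengths shrunk by the ratio.
# Returns a data.frame of segments (one row per cylinder).
tree_skeleton <- function(params) {
  ang <- params$branch_angle_deg * pi / 180
  m <- params$branches_per_node
  ratio <- params$branch_length_ratio
  segs <- vector("list", 0)
  recurse <- function(start, dir, len, depth) {
    end <- start + dir * len
    segs[[length(segs) + 1L]] <<- c(start, end, depth)
    if (depth >= params$branching_depth) return(invisible())
    base <- perp_basis(dir)
    jit <- runif(1, 0, 2 * pi)
    for (k in seq_len(m)) {
      az <- jit + 2 * pi * (k - 1) / m + runif(1, -0.3, 0.3)
      child <- cos(ang) * dir +
        sin(ang) * (cos(az) * base$u + sin(az) * base$v)
      child <- child / sqrt(sum(child^2))
      recurse(end, child, len * ratio, depth + 1L)
    }
  }
  recurse(c(0, 0, 0), c(0, 0, 1), 1, 0L)
  out <- do.call(rbind, segs)
  data.frame(x0 = out[, 1], y0 = out[, 2], z0 = out[, 3],
             x1 = out[, 4], y1 = out[, 5], z1 = out[, 6],
             depth = as.integer(out[, 7]))
}

# Surface-sample one cylinder segment. Guarantees a minimum linear density so
# thin terminal branches stay voxel-connected at the segmentation scales the
# package operates at.
sample_cylinder <- function(p0, p1, radius, density) {
  axis <- p1 - p0
  len <- sqrt(sum(axis^2))
  dir <- axis / len
  n <- max(ceiling(2 * pi * radius * len * density), ceiling(len * 30))
  tpar <- runif(n)
  phi <- runif(n, 0, 2 * pi)
  base <- perp_basis(dir)
  pts <- matrix(rep(p0, each = n), n, 3) + outer(tpar * len, dir) +
    radius * (outer(cos(phi), base$u) + outer(sin(phi), base$v))
  pts
}

#' Generate the synthetic tree cloud
#'
#' Builds a recursive branching skeleton (seeded azimuth jitter, fixed length
#' ratio), scales it so the skeleton top sits at `tree_height`, samples points
#' on trunk and branch cylinder surfaces (labels 1 and 2) and fills an
#' ellipsoidal foliage blob at every terminal tip (label 3).
#'
#' @param params a [scene_params()].
#' @return A labelled [point_cloud()].
#' @export
generate_tree <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(params$seed, {
    skel <- tree_skeleton(params)
    # normalize so skeleton top plus the foliage blob's vertical semi-axis
    # reaches tree_height: crown top == tree_height up to sampling noise
    has_foliage <- params$foliage_points_per_tip > 0L && params$branching_depth > 0L
    foliage_cax_unit <- if (has_foliage) {
      1.56 * params$branch_length_ratio^params$branching_depth
    } else 0
    scale <- params$tree_height / (max(skel$z1) + foliage_cax_unit)
    skel[, 1:6] <- skel[, 1:6] * scale
    radii <- params$trunk_radius *
      params$branch_length_ratio^skel$depth
    lens <- sqrt((skel$x1 - skel$x0)^2 + (skel$y1 - skel$y0)^2 +
                   (skel$z1 - skel$z0)^2)
    planned <- sum(pmax(ceiling(2 * pi * radii * lens * params$points_per_unit_area),
                        ceiling(lens * 30)))
    # a depth-0 tree is a bare trunk: no branches, hence no foliage
    tips <- if (has_foliage) skel$depth == params$branching_depth else
      rep(FALSE, nrow(skel))
    planned <- planned + sum(tips) * params$foliage_points_per_tip
    if (planned > params$point_budget_cap) {
      stop(sprintf("point budget exceeded: %d planned tree points > cap %g",
                   planned, params$point_budget_cap), call. = FALSE)
    }
    parts <- vector("list", nrow(skel) + sum(tips))
    labs <- vector("list", length(parts))
    j <- 0L
    for (i in seq_len(nrow(skel))) {
      pts <- sample_cylinder(c(skel$x0[i], skel$y0[i], skel$z0[i]),
                             c(skel$x1[i], skel$y1[i], skel$z1[i]),
                             radii[i], params$points_per_unit_area)
      j <- j + 1L
      parts[[j]] <- pts
      labs[[j]] <- rep(if (skel$depth[i] == 0L) 1L else 2L, nrow(pts))
    }
    # foliage: points uniform in an ellipsoid around each terminal tip
    tip_len <- scale * params$branch_length_ratio^params$branching_depth
    a <- 1.3 * tip_len          # horizontal semi-axis
    cax <- 1.2 * a              # vertical semi-axis
    for (i in which(tips)) {
      nf <- params$foliage_points_per_tip
      if (nf == 0L) next
      u <- matrix(rnorm(3 * nf), nf, 3)
      u <- u / sqrt(rowSums(u^2))
      r <- runif(nf)^(1 / 3)
      blob <- u * r
      blob <- sweep(blob, 2, c(a, a, cax), `*`)
      blob <- sweep(blob, 2, c(skel$x1[i], skel$y1[i], skel$z1[i]), `+`)
      j <- j + 1L
      parts[[j]] <- blob
      labs[[j]] <- rep(3L, nf)
    }
    point_cloud(do.call(rbind, parts),
                labels = unlist(labs, use.names = FALSE))
  })
}

#' Generate the grass-textured ground plane
#'
#' A planar grid covering `[-ground_extent/2, +ground_extent/2]^2` (plus a
#' seeded uniform remainder so the point count matches the density exactly),
#' with per-point vertical perturbation `Normal(0, grass_noise_sd)` imitating
#' grass roughness. Label 0.
#'
#' @param params a [scene_params()].
#' @return A labelled [point_cloud()].
#' @export
generate_ground <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(params$seed + 1L, {
    half <- params$ground_extent / 2
    area <- params$ground_extent^2
    n <- round(params$points_per_unit_area * area)
    k <- floor(sqrt(n))
    step <- params$ground_extent / k
    gx <- -half + (seq_len(k) - 0.5) * step
    grid <- as.matrix(expand.grid(x = gx, y = gx))
    extra <- n - k^2
    if (extra > 0L) {
      grid <- rbind(grid, cbind(runif(extra, -half, half),
                                runif(extra, -half, half)))
    }
    z <- if (params$grass_noise_sd > 0) {
      rnorm(n, 0, params$grass_noise_sd)
    } else rep(0, n)
    point_cloud(cbind(grid, z), labels = rep(0L, n))
  })
}

# Fixed, saturated, pairwise-distinct colours for the eight targets.
target_palette <- function() {
  matrix(as.integer(c(
    255, 0, 0,
    0, 255, 0,
    0, 0, 255,
    255, 255, 0,
    255, 0, 255,
    0, 255, 255,
    255, 128, 0,
    128, 0, 255)), ncol = 3, byrow = TRUE)
}

#' Place the eight reference target cubes
#'
#' Eight surface-sampled cubes (edge `target_edge`) at fixed, well-separated,
#' non-collinear positions ringing the tree, each with a distinct label
#' (10--17) and a distinct saturated colour. Sampling is antipodally
#' symmetric (every sampled face point is paired with its reflection through
#' the cube centre), so each cube's point centroid equals its placement
#' position exactly.
#'
#' @param params a [scene_params()].
#' @return A list with `cloud` (coloured, labelled [point_cloud()]) and
#'   `centroids` (8 x 3 matrix, rownames = labels).
#' @export
place_targets <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(params$seed + 2L, {
    e <- params$target_edge
    ring_r <- 0.35 * params$ground_extent
    angles <- 2 * pi * (0:7) / 8 + pi / 16
    centres <- cbind(ring_r * cos(angles), ring_r * sin(angles), e / 2)
    pal <- target_palette()
    m_face <- max(ceiling(params$points_per_unit_area * e^2), 16L)
    parts <- vector("list", 8L)
    for (k in 1:8) {
      # sample the three positive faces, then add antipodes
      half_pts <- do.call(rbind, lapply(1:3, function(ax) {
        q <- matrix(runif(2 * m_face, -e / 2, e / 2), m_face, 2)
        p <- matrix(0, m_face, 3)
        p[, ax] <- e / 2
        p[, -ax] <- q
        p
      }))
      pts <- rbind(half_pts, -half_pts)
      pts <- sweep(pts, 2, centres[k, ], `+`)
      parts[[k]] <- point_cloud(
        pts,
        colors = matrix(rep(pal[k, ], each = nrow(pts)), nrow(pts), 3),
        labels = rep(9L + k, nrow(pts)))
    }
    cloud <- do.call(pc_bind, parts)
    dimnames(centres) <- list(10:17, c("x", "y", "z"))
    list(cloud = cloud, centroids = centres)
  })
}

#' Assemble the full reference scene
#'
#' Concatenates tree, ground and targets into one labelled reference cloud
#' and records the eight target centroids and the scene-width normalizer
#' (the larger of the x and y bounding-box extents).
#'
#' @param params a [scene_params()].
#' @return An object of class `scene_model`: list with `reference`
#'   ([point_cloud()]), `target_centroids` (8 x 3), `scene_width`, `params`.
#' @examples
#' sc <- assemble_scene(scene_params(points_per_unit_area = 5,
#'                                   foliage_points_per_tip = 50))
#' sc$scene_width
#' @export
assemble_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  tree <- generate_tree(params)
  ground <- generate_ground(params)
  targets <- place_targets(params)
  reference <- pc_bind(tree, ground, targets$cloud)
  structure(list(reference = reference,
                 target_centroids = targets$centroids,
                 scene_width = scene_width_of(reference$points),
                 params = params),
            class = "scene_model")
}

#' @export
print.scene_model <- function(x, ...) {
  cat(sprintf("<scene_model> %d reference points, scene width %.4g, 8 targets\n",
              n_points(x$reference), x$scene_width))
  invisible(x)
}
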