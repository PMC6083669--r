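#' Specification of a simulated reconstruction degradation
#'
#' Parameterizes the artefact classes observed in photogrammetric
#' reconstructions of vegetation: errors of omission (holes and missing tree
#' fraction), floating sky clusters, attached rings enveloping the upper
#' crown, ghosts (duplicated components), coordinate jitter, density
#' thinning, and a pose/scale perturbation standing in for the unaligned
#' reconstruction frame. Applied to a reference scene it yields a simulated
#' "reconstruction" with full ground truth for every injected artefact.
#'
#' @param omission_fraction fraction of tree points (labels 1--3) to remove,
#'   in `[0, 1]`.
#' @param omission_hole_count number of spherical holes carved around random
#'   tree points.
#' @param omission_hole_radius radius of each hole (scene units).
#' @param floating_cluster_count number of disconnected sky clusters to add.
#' @param floating_cluster_points points per floating cluster.
#' @param floating_cluster_sd spatial sd of each Gaussian cluster; the point
#'   distribution is truncated at 2.5 sd, so the cluster diameter is
#'   `5 * sd`.
#' @param floating_region optional 2 x 3 matrix (rows min, max) bounding the
#'   cluster centres; default: a slab above the scene, clear of it by
#'   `floating_clearance`.
#' @param floating_clearance minimum gap between cluster centres and the
#'   scene bounding box (default `2 * 5 * floating_cluster_sd`, i.e. twice
#'   the cluster diameter).
#' @param attached_ring if `TRUE`, add a horizontal torus of points touching
#'   the upper half of the crown.
#' @param ring_radius torus major radius; `NULL` = auto (98th percentile of
#'   foliage radial extent at ring height).
#' @param ring_thickness torus tube radius (default 0.4).
#' @param ring_points points in the ring (default 4000).
#' @param ghost_component label of a component to duplicate (e.g. 1 = trunk),
#'   or `NULL` for none.
#' @param ghost_offset rigid offset applied to the ghost copy.
#' @param jitter_sd sd of iid Gaussian coordinate noise (default 0).
#' @param thinning_keep probability of keeping each point, in `(0, 1]`.
#' @param pose_perturbation optional [similarity_transform()] applied last.
#' @param seed integer seed fixing the whole degradation.
#' @return An object of class `degrade_spec`.
#' @export
degrade_spec <- function(omission_fraction = 0,
                         omission_hole_count = 0L,
                         omission_hole_radius = 1.5,
                         floating_cluster_count = 0L,
                         floating_cluster_points = 200L,
                         floating_cluster_sd = 0.1,
                         floating_region = NULL,
                         floating_clearance = NULL,
                         attached_ring = FALSE,
                         ring_radius = NULL,
                         ring_thickness = 0.4,
                         ring_points = 4000L,
                         ghost_component = NULL,
                         ghost_offset = c(5, 0, 0),
                         jitter_sd = 0,
                         thinning_keep = 1,
                         pose_perturbation = NULL,
                         seed = 1L) {
  s <- list(omission_fraction = omission_fraction,
            omission_hole_count = as.integer(omission_hole_count),
            omission_hole_radius = omission_hole_radius,
            floating_cluster_count = as.integer(floating_cluster_count),
            floating_cluster_points = as.integer(floating_cluster_points),
            floating_cluster_sd = floating_cluster_sd,
            floating_region = if (!is.null(floating_region)) as.matrix(floating_region),
            floating_clearance = floating_clearance %||% (10 * floating_cluster_sd),
            attached_ring = isTRUE(attached_ring),
            ring_radius = ring_radius, ring_thickness = ring_thickness,
            ring_points = as.integer(ring_points),
            ghost_component = ghost_component, ghost_offset = as.numeric(ghost_offset),
            jitter_sd = jitter_sd, thinning_keep = thinning_keep,
            pose_perturbation = pose_perturbation, seed = as.integer(seed))
  stopifnot(s$omission_fraction >= 0, s$omission_fraction <= 1,
            s$omission_hole_count >= 0L, s$omission_hole_radius > 0,
            s$floating_cluster_count >= 0L, s$floating_cluster_points >= 1L,
            s$floating_cluster_sd > 0, s$ring_thickness > 0,
            s$jitter_sd >= 0, s$thinning_keep > 0, s$thinning_keep <= 1,
            length(s$ghost_offset) == 3L)
  if (!is.null(s$pose_perturbation)) {
    stopifnot(inherits(s$pose_perturbation, "similarity_transform"))
  }
  structure(s, class = "degrade_spec")
}

TREE_LABELS <- 1:3
ARTEFACT_LABEL_BASE <- 100L

next_artefact_label <- function(cloud) {
  if (is.null(cloud$labels)) return(ARTEFACT_LABEL_BASE)
  art <- cloud$labels[cloud$labels >= ARTEFACT_LABEL_BASE]
  if (length(art) == 0L) ARTEFACT_LABEL_BASE else max(art) + 1L
}

tree_point_index <- function(cloud) {
  if (is.null(cloud$labels)) seq_len(n_points(cloud))
  else which(cloud$labels %in% TREE_LABELS)
}

#' Remove tree structure: holes and random omission
#'
#' Carves `omission_hole_count` spherical holes of radius
#' `omission_hole_radius` centred on randomly chosen tree points (all points
#' inside a hole are removed), then removes further random tree points until
#' at least `omission_fraction` of the original tree points are gone.
#' Non-tree labels are untouched by the fraction rule.
#'
#' @param cloud a labelled [point_cloud()].
#' @param spec a [degrade_spec()].
#' @return The degraded [point_cloud()]; identity when the spec requests no
#'   omission.
#' @export
apply_omission <- function(cloud, spec) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(spec, "degrade_spec"))
  if (spec$omission_fraction == 0 && spec$omission_hole_count == 0L) return(cloud)
  with_seed(spec$seed + 11L, {
    tree0 <- tree_point_index(cloud)
    n_tree0 <- length(tree0)
    drop <- logical(n_points(cloud))
    if (spec$omission_hole_count > 0L && n_tree0 > 0L) {
      centres <- cloud$points[sample(tree0, min(spec$omission_hole_count, n_tree0)), ,
                              drop = FALSE]
      d <- cpp_nn(cloud$points, centres)$dist
      drop[d <= spec$omission_hole_radius] <- TRUE
    }
    if (spec$omission_fraction > 0 && n_tree0 > 0L) {
      need <- ceiling(spec$omission_fraction * n_tree0)
      gone <- sum(drop[tree0])
      if (gone < need) {
        survivors <- tree0[!drop[tree0]]
        drop[sample(survivors, min(need - gone, length(survivors)))] <- TRUE
      }
    }
    pc_subset(cloud, !drop)
  })
}

# Default floating region: a slab above the scene crown, horizontally within
# the central 60% of the bounding box, vertically clear of the inflated bbox.
default_floating_region <- function(cloud, spec) {
  bb <- bbox_of(cloud$points)
  ext <- bbox_extent(bb)
  cx <- (bb[1, ] + bb[2, ]) / 2
  z0 <- bb["max", 3] + spec$floating_clearance + 0.05
  rbind(min = c(cx[1] - 0.3 * ext[1], cx[2] - 0.3 * ext[2], z0),
        max = c(cx[1] + 0.3 * ext[1], cx[2] + 0.3 * ext[2], z0 + 0.5))
}

#' Add disconnected floating clusters
#'
#' Appends `floating_cluster_count` truncated-Gaussian blobs in the sky
#' region, each under a fresh artefact label (>= 100). Cluster centres are
#' placed on a seeded jitter-free grid whose spacing guarantees pairwise
#' centre separation of at least twice the cluster diameter, and the region
#' must not intersect the scene bounding box inflated by
#' `floating_clearance`.
#'
#' @inheritParams apply_omission
#' @return The augmented [point_cloud()]; identity when the count is 0.
#' @export
add_floating_clusters <- function(cloud, spec) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(spec, "degrade_spec"))
  if (spec$floating_cluster_count == 0L) return(cloud)
  with_seed(spec$seed + 16L, {
    region <- spec$floating_region %||% default_floating_region(cloud, spec)
    bb <- bbox_of(cloud$points)
    infl <- rbind(min = bb["min", ] - spec$floating_clearance,
                  max = bb["max", ] + spec$floating_clearance)
    disjoint <- any(region["min", ] > infl["max", ] | region["max", ] < infl["min", ])
    if (!disjoint) {
      stop("floating_region intersects the scene bounding box inflated by the clearance",
           call. = FALSE)
    }
    diameter <- 5 * spec$floating_cluster_sd            # 2 x 2.5-sd truncation
    spacing <- 2 * diameter * 1.05
    ext <- region["max", ] - region["min", ]
    nxyz <- pmax(1L, floor(ext / spacing))
    centres_axis <- lapply(1:3, function(a) {
      region["min", a] + (seq_len(nxyz[a]) - 0.5) * ext[a] / nxyz[a]
    })
    grid <- as.matrix(expand.grid(centres_axis))
    if (nrow(grid) < spec$floating_cluster_count) {
      stop(sprintf("placement error: region holds %d cluster sites, %d requested",
                   nrow(grid), spec$floating_cluster_count), call. = FALSE)
    }
    centres <- grid[sample(nrow(grid), spec$floating_cluster_count), , drop = FALSE]
    lab0 <- next_artefact_label(cloud)
    parts <- vector("list", nrow(centres))
    for (k in seq_len(nrow(centres))) {
      np <- spec$floating_cluster_points
      pts <- matrix(rnorm(3 * np, 0, spec$floating_cluster_sd), np, 3)
      rr <- sqrt(rowSums(pts^2))
      cap <- 2.5 * spec$floating_cluster_sd
      over <- rr > cap
      if (any(over)) pts[over, ] <- pts[over, , drop = FALSE] * (cap / rr[over])
      pts <- sweep(pts, 2, centres[k, ], `+`)
      parts[[k]] <- point_cloud(pts, labels = rep(lab0 + k - 1L, np))
    }
    do.call(pc_bind, c(list(cloud), parts))
  })
}

#' Add an attached ring artefact around the upper crown
#'
#' Appends a horizontal torus of points centred on the crown axis at the
#' upper-crown height (75th percentile of foliage height). By default the
#' major radius is chosen so the ring touches the crown surface (98th
#' percentile of the foliage radial extent), which makes it merge with the
#' main component under default segmentation settings -- the signature of an
#' attached, rather than floating, artefact.
#'
#' @inheritParams apply_omission
#' @return The augmented [point_cloud()]; identity when the ring is disabled.
#' @export
add_attached_ring <- function(cloud, spec) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(spec, "degrade_spec"))
  if (!spec$attached_ring) return(cloud)
  if (is.null(cloud$labels) || !any(cloud$labels == 3L)) {
    stop("attached ring requires foliage points (label 3) in the cloud", call. = FALSE)
  }
  with_seed(spec$seed + 15L, {
    fol <- cloud$points[cloud$labels == 3L, , drop = FALSE]
    centre <- c(mean(fol[, 1]), mean(fol[, 2]))
    z_ring <- quantile(fol[, 3], 0.75, names = FALSE)
    # auto radius from the crown's radial extent AT ring height, so the
    # torus intersects the crown surface there (attached, not floating)
    band <- abs(fol[, 3] - z_ring) <= 0.1 * diff(range(fol[, 3]))
    if (sum(band) < 50L) band <- rep(TRUE, nrow(fol))
    radial <- sqrt((fol[band, 1] - centre[1])^2 + (fol[band, 2] - centre[2])^2)
    major <- spec$ring_radius %||% quantile(radial, 0.95, names = FALSE)
    np <- spec$ring_points
    theta <- runif(np, 0, 2 * pi)
    phi <- runif(np, 0, 2 * pi)
    rho <- spec$ring_thickness * sqrt(runif(np))
    rr <- major + rho * cos(phi)
    pts <- cbind(centre[1] + rr * cos(theta),
                 centre[2] + rr * sin(theta),
                 z_ring + rho * sin(phi))
    ring <- point_cloud(pts, labels = rep(next_artefact_label(cloud), np))
    pc_bind(cloud, ring)
  })
}

#' Duplicate a component as a ghost
#'
#' Copies every point of the named component, applies the rigid offset, and
#' relabels the copy with a fresh artefact id -- emulating object parts that
#' appear more than once in a reconstruction because of camera-pose errors.
#'
#' @inheritParams apply_omission
#' @return The augmented [point_cloud()]; identity when no ghost is requested.
#' @export
add_ghost <- function(cloud, spec) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(spec, "degrade_spec"))
  if (is.null(spec$ghost_component)) return(cloud)
  if (is.null(cloud$labels) || !any(cloud$labels == spec$ghost_component)) {
    stop(sprintf("ghost component label %s not present in cloud",
                 spec$ghost_component), call. = FALSE)
  }
  sel <- cloud$labels == spec$ghost_component
  ghost <- point_cloud(
    sweep(cloud$points[sel, , drop = FALSE], 2, spec$ghost_offset, `+`),
    colors = if (!is.null(cloud$colors)) cloud$colors[sel, , drop = FALSE],
    labels = rep(next_artefact_label(cloud), sum(sel)))
  pc_bind(cloud, ghost)
}

#' Coordinate jitter, density thinning and pose perturbation
#'
#' `add_jitter` adds iid `Normal(0, jitter_sd)` noise to every coordinate;
#' `thin_cloud` keeps a seeded Bernoulli(`thinning_keep`) subset;
#' `perturb_pose` applies the spec's similarity transform to the whole cloud
#' (modelling the arbitrary frame of an unaligned reconstruction). Each is
#' the identity when its parameter is at the neutral value.
#'
#' @inheritParams apply_omission
#' @return A [point_cloud()].
#' @export
add_jitter <- function(cloud, spec) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(spec, "degrade_spec"))
  if (spec$jitter_sd == 0) return(cloud)
  with_seed(spec$seed + 13L, {
    out <- cloud
    n <- n_points(cloud)
    out$points <- cloud$points + matrix(rnorm(3 * n, 0, spec$jitter_sd), n, 3)
    out
  })
}

#' @rdname add_jitter
#' @export
thin_cloud <- function(cloud, spec) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(spec, "degrade_spec"))
  if (spec$thinning_keep == 1) return(cloud)
  with_seed(spec$seed + 12L, {
    keep <- runif(n_points(cloud)) < spec$thinning_keep
    pc_subset(cloud, keep)
  })
}

#' @rdname add_jitter
#' @export
perturb_pose <- function(cloud, spec) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(spec, "degrade_spec"))
  if (is.null(spec$pose_perturbation)) return(cloud)
  apply_transform(cloud, spec$pose_perturbation)
}

#' Degrade a reference scene into a simulated reconstruction
#'
#' Applies the degradation operators in the fixed order omission, thinning,
#' jitter, ghost, attached ring, floating clusters, pose perturbation (so
#' noise never blurs artefact labels and misalignment affects the whole
#' output), and emits a manifest recording the ground-truth parameters of
#' every injected artefact.
#'
#' @param scene a [scene_model()] (or a labelled reference [point_cloud()]).
#' @param spec a [degrade_spec()].
#' @return An object of class `degraded_model`: list with `cloud` (the
#'   simulated reconstruction) and `manifest` (ground truth: achieved
#'   omission/thinning, per-artefact table, pose, seed).
#' @examples
#' sc <- assemble_scene(scene_params(points_per_unit_area = 5,
#'                                   foliage_points_per_tip = 50))
#' dg <- degrade(sc, degrade_spec(omission_fraction = 0.2,
#'                                floating_cluster_count = 5))
#' dg$manifest$artefacts
#' @export
degrade <- function(scene, spec = degrade_spec()) {
  reference <- if (inherits(scene, "scene_model")) scene$reference else scene
  stopifnot(inherits(reference, "point_cloud"), inherits(spec, "degrade_spec"))
  n_tree0 <- length(tree_point_index(reference))

  artefact_rows <- list()
  note_artefacts <- function(before, after, type) {
    new_labels <- setdiff(unique(after$labels %||% integer(0)),
                          unique(before$labels %||% integer(0)))
    new_labels <- new_labels[new_labels >= ARTEFACT_LABEL_BASE]
    for (lb in sort(new_labels)) {
      idx <- which(after$labels == lb)
      ctr <- colMeans(after$points[idx, , drop = FALSE])
      artefact_rows[[length(artefact_rows) + 1L]] <<- data.frame(
        label = lb, type = type, n_points = length(idx),
        x = ctr[1], y = ctr[2], z = ctr[3], row.names = NULL)
    }
  }

  cloud <- apply_omission(reference, spec)
  n_tree_after <- length(tree_point_index(cloud))
  achieved_omission <- if (n_tree0 > 0L) 1 - n_tree_after / n_tree0 else 0
  # same quantity over all reference points: directly comparable with the
  # census omission fraction, which is measured over the whole reference
  achieved_omission_all <- 1 - n_points(cloud) / n_points(reference)

  n_before_thin <- n_points(cloud)
  cloud <- thin_cloud(cloud, spec)
  achieved_keep <- if (n_before_thin > 0L) n_points(cloud) / n_before_thin else 1

  cloud <- add_jitter(cloud, spec)

  prev <- cloud; cloud <- add_ghost(cloud, spec)
  note_artefacts(prev, cloud, "ghost")
  prev <- cloud; cloud <- add_attached_ring(cloud, spec)
  note_artefacts(prev, cloud, "attached_ring")
  prev <- cloud; cloud <- add_floating_clusters(cloud, spec)
  note_artefacts(prev, cloud, "floating_cluster")
  cloud <- perturb_pose(cloud, spec)

  artefacts <- if (length(artefact_rows)) {
    do.call(rbind, artefact_rows)
  } else {
    data.frame(label = integer(0), type = character(0), n_points = integer(0),
               x = numeric(0), y = numeric(0), z = numeric(0))
  }
  manifest <- list(
    seed = spec$seed,
    omission = list(requested_fraction = spec$omission_fraction,
                    achieved_fraction = achieved_omission,
                    achieved_fraction_all_points = achieved_omission_all,
                    hole_count = spec$omission_hole_count,
                    hole_radius = spec$omission_hole_radius),
    thinning = list(keep = spec$thinning_keep, achieved_keep = achieved_keep),
    jitter_sd = spec$jitter_sd,
    pose_perturbed = !is.null(spec$pose_perturbation),
    artefacts = artefacts,
    artefact_count = nrow(artefacts))
  structure(list(cloud = cloud, manifest = manifest), class = "degraded_model")
}

#' Write a degradation manifest as JSON
#' @param manifest the `manifest` element of a [degrade()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
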