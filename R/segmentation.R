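#' Octree-grid connected components
#'
#' Reproduces the connected-components census used to count floating and
#' attached artefacts: the cloud's own bounding box is divided into an
#' octree grid at the given level (voxel edge = largest bounding-box extent
#' divided by `2^level`; level 8 gives 256 cells per axis), points are mapped
#' to voxels, and components are maximal sets of occupied voxels connected
#' under 26-neighbourhood. Clusters below `min_cluster_points` are merged
#' into a residue bucket and reported separately.
#'
#' @param cloud a non-empty [point_cloud()].
#' @param octree_level grid level, 1--12 (default 8).
#' @param min_cluster_points smallest reportable cluster (default 10).
#' @return An object of class `cloud_components`: list with `membership`
#'   (per-point cluster id, `NA` for residue points; ids ordered by
#'   decreasing point count, ties broken by first occurrence), `clusters`
#'   (data.frame: id, point_count, bbox columns), `residue_points`,
#'   `residue_clusters`, `voxel_edge`, `octree_level`, `min_cluster_points`.
#' @export
connected_components <- function(cloud, octree_level = 8L, min_cluster_points = 10L) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) == 0L) stop("cloud must be non-empty", call. = FALSE)
  octree_level <- as.integer(octree_level)
  if (octree_level < 1L || octree_level > 12L) {
    stop("octree_level must be between 1 and 12", call. = FALSE)
  }
  bb <- bbox_of(cloud$points)
  B <- 2L^octree_level
  edge <- max(bbox_extent(bb)) / B
  if (!is.finite(edge) || edge <= 0) {
    # all points coincide: one voxel, one cluster
    edge <- .Machine$double.eps
  }
  ijk <- floor(sweep(cloud$points, 2, bb["min", ]) / edge)
  ijk[ijk >= B] <- B - 1        # points on the upper boundary
  ijk[ijk < 0] <- 0
  key <- ijk[, 1] + B * (ijk[, 2] + B * ijk[, 3])   # exact in doubles (B <= 2^12)
  occ <- sort(unique(key))
  vox_of_point <- match(key, occ)

  # 26-connectivity: half the neighbourhood suffices for undirected edges
  occ_ijk <- cbind(occ %% B, (occ %/% B) %% B, occ %/% (B * B))
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[offsets[, 3] > 0 |
                       (offsets[, 3] == 0 & (offsets[, 2] > 0 |
                          (offsets[, 2] == 0 & offsets[, 1] > 0))), , drop = FALSE]
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offsets))) {
    nb <- sweep(occ_ijk, 2, offsets[r, ], `+`)
    ok <- nb[, 1] >= 0 & nb[, 1] < B & nb[, 2] >= 0 & nb[, 2] < B &
      nb[, 3] >= 0 & nb[, 3] < B
    if (!any(ok)) next
    nkey <- nb[ok, 1] + B * (nb[ok, 2] + B * nb[ok, 3])
    j <- match(nkey, occ)
    hit <- !is.na(j)
    if (any(hit)) {
      from <- c(from, which(ok)[hit])
      to <- c(to, j[hit])
    }
  }
  g <- igraph::make_empty_graph(n = length(occ), directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  comp <- igraph::components(g)$membership

  point_comp <- comp[vox_of_point]
  sizes <- tabulate(point_comp, nbins = max(comp))
  keep_ids <- which(sizes >= min_cluster_points)
  # renumber by decreasing point count; ties by lowest original component id
  ord <- keep_ids[order(-sizes[keep_ids], keep_ids)]
  new_id <- rep(NA_integer_, max(comp))
  new_id[ord] <- seq_along(ord)
  membership <- new_id[point_comp]

  clusters <- do.call(rbind, lapply(seq_along(ord), function(i) {
    idx <- which(membership == i)
    bbi <- bbox_of(cloud$points[idx, , drop = FALSE])
    data.frame(id = i, point_count = length(idx),
               xmin = bbi[1, 1], xmax = bbi[2, 1], ymin = bbi[1, 2],
               ymax = bbi[2, 2], zmin = bbi[1, 3], zmax = bbi[2, 3])
  }))
  if (is.null(clusters)) {
    clusters <- data.frame(id = integer(0), point_count = integer(0),
                           xmin = numeric(0), xmax = numeric(0),
                           ymin = numeric(0), ymax = numeric(0),
                           zmin = numeric(0), zmax = numeric(0))
  }
  structure(list(membership = membership, clusters = clusters,
                 residue_points = sum(is.na(membership)),
                 residue_clusters = sum(sizes > 0 & sizes < min_cluster_points),
                 voxel_edge = edge, octree_level = octree_level,
                 min_cluster_points = as.integer(min_cluster_points)),
            class = "cloud_components")
}

#' @export
print.cloud_components <- function(x, ...) {
  cat(sprintf("<cloud_components> level %d (voxel edge %.4g): %d cluster(s), %d residue point(s)\n",
              x$octree_level, x$voxel_edge, nrow(x$clusters), x$residue_points))
  invisible(x)
}

#' Classify clusters as main, attached or floating
#'
#' The largest cluster by point count is the main reconstruction (ties
#' resolved toward the lowest cluster id, with a warning). Every other
#' cluster is `attached` if its minimum point-to-main distance is at most
#' `gap_threshold` (default twice the voxel edge at the operating level:
#' "touching at grid resolution"), else `floating`.
#'
#' @param components a [connected_components()] result.
#' @param cloud the [point_cloud()] the components were computed on.
#' @param gap_threshold attachment distance threshold (scene units);
#'   default `2 * voxel_edge`.
#' @return An object of class `artefact_report`: the cluster table augmented
#'   with `class` and `min_gap_to_main`, plus the parameters used.
#' @export
classify_clusters <- function(components, cloud, gap_threshold = NULL) {
  stopifnot(inherits(components, "cloud_components"), inherits(cloud, "point_cloud"))
  gap_threshold <- gap_threshold %||% (2 * components$voxel_edge)
  cl <- components$clusters
  if (nrow(cl) == 0L) {
    stop("no clusters to classify (cloud empty or below min_cluster_points)",
         call. = FALSE)
  }
  if (nrow(cl) > 1L && cl$point_count[1] == cl$point_count[2]) {
    warning("tie for largest cluster; main resolved to the lowest cluster id")
  }
  main_pts <- cloud$points[which(components$membership == 1L), , drop = FALSE]
  cl$class <- "main"
  cl$min_gap_to_main <- 0
  if (nrow(cl) > 1L) {
    for (i in 2:nrow(cl)) {
      pts <- cloud$points[which(components$membership == i), , drop = FALSE]
      gap <- min(cpp_nn(pts, main_pts)$dist)
      cl$min_gap_to_main[i] <- gap
      cl$class[i] <- if (gap <= gap_threshold) "attached" else "floating"
    }
  }
  structure(list(clusters = cl,
                 counts = c(main = 1L,
                            attached = sum(cl$class == "attached"),
                            floating = sum(cl$class == "floating")),
                 gap_threshold = gap_threshold,
                 octree_level = components$octree_level,
                 voxel_edge = components$voxel_edge,
                 min_cluster_points = components$min_cluster_points,
                 connectivity = "26-neighbourhood",
                 residue_points = components$residue_points),
            class = "artefact_report")
}

#' @export
print.artefact_report <- function(x, ...) {
  cat(sprintf("<artefact_report> level %d, gap %.4g: %d main, %d attached, %d floating\n",
              x$octree_level, x$gap_threshold, x$counts["main"],
              x$counts["attached"], x$counts["floating"]))
  invisible(x)
}

#' Artefact and omission census of a reconstruction
#'
#' Combines the segmentation census of the model cloud (floating/attached
#' cluster counts) with a reference-to-model distance field measuring errors
#' of omission: the omission fraction is the share of reference points
#' farther than `omission_threshold` from any model point. The threshold
#' should match the scale at which "present" is judged: the default (equal to
#' `gap_threshold`) measures contiguous voids; a threshold below the
#' reference point spacing counts individually missing points.
#'
#' @param model the reconstruction [point_cloud()] (aligned).
#' @param reference the reference [point_cloud()].
#' @param octree_level,min_cluster_points passed to [connected_components()].
#' @param gap_threshold attachment threshold, see [classify_clusters()].
#' @param omission_threshold distance beyond which a reference point counts
#'   as omitted; default `gap_threshold`.
#' @return An object of class `census_report`: list with `artefacts` (an
#'   `artefact_report`), `omission_fraction`, `counts`, and the parameters.
#' @export
census <- function(model, reference, octree_level = 8L, min_cluster_points = 10L,
                   gap_threshold = NULL, omission_threshold = NULL) {
  stopifnot(inherits(model, "point_cloud"), inherits(reference, "point_cloud"))
  comps <- connected_components(model, octree_level, min_cluster_points)
  report <- classify_clusters(comps, model, gap_threshold)
  omission_threshold <- omission_threshold %||% report$gap_threshold
  field <- nn_distances(reference, model, "reference_to_model",
                        scene_width = scene_width_of(reference$points))
  omission_fraction <- mean(field$distances > omission_threshold)
  structure(list(artefacts = report,
                 omission_fraction = omission_fraction,
                 omission_threshold = omission_threshold,
                 counts = report$counts,
                 octree_level = report$octree_level,
                 voxel_edge = report$voxel_edge),
            class = "census_report")
}

#' @export
print.census_report <- function(x, ...) {
  cat(sprintf("<census_report> %d attached, %d floating; omission fraction %.3f (threshold %.4g)\n",
              x$counts["attached"], x$counts["floating"], x$omission_fraction,
              x$omission_threshold))
  invisible(x)
}
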