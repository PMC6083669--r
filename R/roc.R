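#' Voxel occupancy of a point cloud
#'
#' Discretizes space over `bounds` into cubic voxels of edge `voxel_size` and
#' returns the set of voxels containing at least one point. Points outside
#' the bounds are clipped with a warning. The voxel grid is the device that
#' gives the confusion matrix a well-defined negative class (empty space).
#'
#' @param cloud a [point_cloud()].
#' @param voxel_size voxel edge length (> 0, scene units).
#' @param bounds 2 x 3 matrix (rows min, max) of the grid extent.
#' @return An object of class `voxel_grid`: list with `indices` (sorted
#'   1-based linear indices of occupied voxels, x fastest), `dims`, `origin`,
#'   `voxel_size`, `n_clipped`.
#' @export
voxelize <- function(cloud, voxel_size, bounds) {
  stopifnot(inherits(cloud, "point_cloud"), voxel_size > 0)
  bounds <- as.matrix(bounds)
  stopifnot(all(dim(bounds) == c(2L, 3L)), all(bounds[2, ] > bounds[1, ]))
  dims <- pmax(1L, as.integer(ceiling((bounds[2, ] - bounds[1, ]) / voxel_size)))
  p <- cloud$points
  inside <- rep(TRUE, nrow(p))
  if (nrow(p) > 0L) {
    inside <- p[, 1] >= bounds[1, 1] & p[, 1] <= bounds[2, 1] &
      p[, 2] >= bounds[1, 2] & p[, 2] <= bounds[2, 2] &
      p[, 3] >= bounds[1, 3] & p[, 3] <= bounds[2, 3]
  }
  n_clipped <- sum(!inside)
  if (n_clipped > 0L) {
    warning(sprintf("%d point(s) outside the voxel bounds were clipped", n_clipped))
  }
  p <- p[inside, , drop = FALSE]
  indices <- integer(0)
  if (nrow(p) > 0L) {
    ijk <- floor(sweep(p, 2, bounds[1, ]) / voxel_size)
    for (a in 1:3) ijk[ijk[, a] >= dims[a], a] <- dims[a] - 1
    lin <- 1 + ijk[, 1] + dims[1] * (ijk[, 2] + dims[2] * ijk[, 3])
    indices <- sort(unique(as.integer(lin)))
  }
  structure(list(indices = indices, dims = dims, origin = bounds[1, ],
                 voxel_size = voxel_size, n_clipped = n_clipped),
            class = "voxel_grid")
}

# Default evaluation geometry: voxel edge = scene_width / 256 (the level-8
# octree scale), bounds = reference bbox padded 10% per side so sky artefacts
# fall inside the negative class.
roc_defaults <- function(reference) {
  stopifnot(inherits(reference, "point_cloud"), n_points(reference) > 0L)
  bb <- bbox_of(reference$points)
  pad <- 0.10 * bbox_extent(bb)
  bounds <- rbind(min = bb["min", ] - pad, max = bb["max", ] + pad)
  voxel_size <- scene_width_of(reference$points) / 256
  diag <- scene_diagonal_of(bounds)
  list(voxel_size = voxel_size, bounds = bounds,
       radii = exp(seq(log(voxel_size / 4), log(diag), length.out = 64)),
       diagonal = diag)
}

# Cheap sanity check that the model has been brought into the reference
# frame: median NN distance of a deterministic model subsample against the
# reference, compared with the scene scale. Misalignment degrades the
# confusion counts silently, hence a warning rather than an error.
warn_if_unaligned <- function(model, reference) {
  n <- n_points(model)
  if (n == 0L || n_points(reference) == 0L) return(invisible())
  idx <- seq.int(1L, n, by = max(1L, n %/% 1000L))
  d <- cpp_nn(model$points[idx, , drop = FALSE], reference$points)$dist
  scale <- scene_diagonal_of(bbox_of(reference$points))
  if (median(d) > 0.25 * scale) {
    warning("model appears unaligned to the reference (median NN distance > 25% of the scene diagonal); confusion counts may be meaningless",
            call. = FALSE)
  }
  invisible()
}

# Per-voxel-centre fields over the full grid (the workhorse behind confusion
# counts): the positive-class indicator (a reference point within half a
# voxel diagonal of the centre, computed with a radius-bounded search) and
# the exact NN distance to the model cloud (needed for the radius sweep).
voxel_distance_fields <- function(model, reference, voxel_size, bounds) {
  bounds <- as.matrix(bounds)
  dims <- pmax(1L, as.integer(ceiling((bounds[2, ] - bounds[1, ]) / voxel_size)))
  r_pos <- voxel_size * sqrt(3) / 2
  list(
    pos = cpp_voxel_within(reference$points, bounds[1, ], voxel_size, dims, r_pos),
    d_model = cpp_voxel_nn(model$points, bounds[1, ], voxel_size, dims),
    dims = dims, origin = bounds[1, ], voxel_size = voxel_size,
    r_pos = r_pos)
}

confusion_from_fields <- function(fields, r) {
  pos <- fields$pos
  pos_total <- sum(pos)
  neg_total <- length(pos) - pos_total
  pred <- if (r > 0) fields$d_model <= r else rep(FALSE, length(pos))
  TP <- sum(pred & pos)
  FP <- sum(pred & !pos)
  list(r = r, TP = TP, FP = FP, FN = pos_total - TP, TN = neg_total - FP)
}

#' Confusion counts at one separation-distance threshold
#'
#' Space is discretized into voxels over `bounds`. The positive class is the
#' reference-occupied neighbourhood: voxel centres within half a voxel
#' diagonal of a reference point; all other voxels are negative. The model
#' "predicts" positive wherever a model point lies within the separation
#' distance `r` of the voxel centre (at `r = 0` the predicted set is empty).
#' TP/FP/FN/TN follow as the usual 2 x 2 table; `TP + FN` and `FP + TN` are
#' invariant in `r`.
#'
#' @param model the (aligned) reconstruction [point_cloud()].
#' @param reference the reference [point_cloud()].
#' @param r separation-distance threshold (>= 0, scene units).
#' @param voxel_size,bounds grid geometry; defaults from the reference
#'   ([voxelize()] semantics, scene width / 256 and a 10%-padded bbox).
#' @return A one-row data.frame: `r, TP, FP, FN, TN, TPR, FPR`.
#' @export
confusion_at <- function(model, reference, r, voxel_size = NULL, bounds = NULL) {
  stopifnot(inherits(model, "point_cloud"), inherits(reference, "point_cloud"),
            r >= 0)
  defs <- roc_defaults(reference)
  voxel_size <- voxel_size %||% defs$voxel_size
  bounds <- bounds %||% defs$bounds
  warn_if_unaligned(model, reference)
  fields <- voxel_distance_fields(model, reference, voxel_size, bounds)
  cc <- confusion_from_fields(fields, r)
  data.frame(r = cc$r, TP = cc$TP, FP = cc$FP, FN = cc$FN, TN = cc$TN,
             TPR = if (cc$TP + cc$FN > 0) cc$TP / (cc$TP + cc$FN) else 0,
             FPR = if (cc$FP + cc$TN > 0) cc$FP / (cc$FP + cc$TN) else 0)
}

#' ROC curve over a continuum of separation-distance thresholds
#'
#' Sweeps the separation distance `r` over `radii` and records the true- and
#' false-positive rates of the voxel confusion table at each. By
#' construction the curve starts at (0, 0) (no predictions at `r = 0`) and
#' is completed by the (1, 1) anchor reached when `r` exceeds the scene
#' diagonal; both rates are non-decreasing in `r` (dilation by a growing
#' radius).
#'
#' @inheritParams confusion_at
#' @param radii strictly increasing positive thresholds; default 64 values
#'   geometric from `voxel_size / 4` to the diagonal of the padded bounds.
#' @return An object of class `roc_curve`: list with `curve` (data.frame
#'   `r, TP, FP, FN, TN, TPR, FPR` including the two anchors), `auc`,
#'   `positives`, `negatives`, `voxel_size`, `r_pos`, `bounds`.
#' @export
roc_curve <- function(model, reference, radii = NULL, voxel_size = NULL,
                      bounds = NULL) {
  stopifnot(inherits(model, "point_cloud"), inherits(reference, "point_cloud"))
  defs <- roc_defaults(reference)
  voxel_size <- voxel_size %||% defs$voxel_size
  bounds <- as.matrix(bounds %||% defs$bounds)
  if (is.null(radii)) {
    diag <- scene_diagonal_of(bounds)
    radii <- exp(seq(log(voxel_size / 4), log(diag), length.out = 64))
  }
  radii <- as.numeric(radii)
  stopifnot(all(radii > 0), all(diff(radii) > 0))
  warn_if_unaligned(model, reference)
  fields <- voxel_distance_fields(model, reference, voxel_size, bounds)
  pos <- fields$pos
  pos_total <- sum(pos)
  neg_total <- length(pos) - pos_total
  if (pos_total == 0L) stop("no positive voxels: empty reference?", call. = FALSE)
  sp <- sort(fields$d_model[pos])
  sn <- sort(fields$d_model[!pos])
  TP <- findInterval(radii, sp)
  FP <- findInterval(radii, sn)
  diag <- scene_diagonal_of(bounds)
  curve <- data.frame(
    r = c(0, radii, max(radii[length(radii)], diag)),
    TP = c(0L, TP, pos_total),
    FP = c(0L, FP, neg_total))
  curve$FN <- pos_total - curve$TP
  curve$TN <- neg_total - curve$FP
  curve$TPR <- curve$TP / pos_total
  curve$FPR <- if (neg_total > 0) curve$FP / neg_total else 0
  out <- structure(list(curve = curve, positives = pos_total,
                        negatives = neg_total, voxel_size = voxel_size,
                        r_pos = fields$r_pos, bounds = bounds),
                   class = "roc_curve")
  out$auc <- auc(out)
  out
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d thresholds, %d positive / %d negative voxels, AUC %.4f\n",
              nrow(x$curve) - 2L, x$positives, x$negatives, x$auc))
  invisible(x)
}

#' Area under an ROC curve
#'
#' Trapezoidal integral of the (FPR, TPR) polyline, sorted by FPR with ties
#' resolved by keeping the maximum TPR, clamped to `[0, 1]`.
#'
#' @param x a [roc_curve()], or a data.frame/matrix with `FPR` and `TPR`
#'   columns (or two unnamed columns in that order).
#' @param ... unused.
#' @return The AUC, a number in `[0, 1]`.
#' @examples
#' auc(data.frame(FPR = c(0, 1), TPR = c(0, 1)))   # diagonal: 0.5
#' auc(data.frame(FPR = c(0, 0, 1), TPR = c(0, 1, 1)))  # perfect step: 1
#' @export
auc <- function(x, ...) UseMethod("auc")

#' @rdname auc
#' @export
auc.roc_curve <- function(x, ...) auc(x$curve, ...)

#' @rdname auc
#' @export
auc.default <- function(x, ...) {
  m <- as.data.frame(x)
  if (all(c("FPR", "TPR") %in% names(m))) {
    fpr <- m$FPR; tpr <- m$TPR
  } else if (ncol(m) >= 2L) {
    fpr <- m[[1]]; tpr <- m[[2]]
  } else {
    stop("need FPR and TPR columns", call. = FALSE)
  }
  stopifnot(length(fpr) >= 2L, all(is.finite(fpr)), all(is.finite(tpr)))
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  # one point per FPR value: the maximum TPR attained there
  keep <- rev(!duplicated(rev(fpr)))
  fpr <- fpr[keep]; tpr <- tpr[keep]
  a <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  min(1, max(0, a))
}

#' Write an ROC curve as CSV
#' @param curve a [roc_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roc_csv <- function(curve, path) {
  stopifnot(inherits(curve, "roc_curve"))
  utils::write.csv(curve$curve, path, row.names = FALSE)
  invisible(path)
}

#' Full evaluation of a reconstruction against a reference scene
#'
#' Runs the whole chain: optional target-based alignment (with optional ICP
#' refinement), nearest-neighbour distance fields in both directions with
#' distance-class counts, the segmentation/omission census, and the ROC/AUC
#' statistic. Alongside the voxel-based ROC the report carries the simpler
#' point-based one-sided rates (completeness and correctness at the census
#' threshold) as diagnostics.
#'
#' @param model a [point_cloud()] or a [degrade()] result.
#' @param scene a [scene_model()].
#' @param config named list overriding defaults: `align` ("none", "targets"
#'   or "icp"), `octree_level`, `min_cluster_points`, `gap_threshold`,
#'   `omission_threshold`, `voxel_size`, `radii`, `bounds`, `scheme`
#'   (a [distance_class_scheme()]).
#' @return An object of class `evaluation_report`: nested list with
#'   `alignment`, `distance`, `census`, `roc` (curve data.frame), `auc`,
#'   `config`. Serializable with [write_report()].
#' @export
evaluate <- function(model, scene, config = list()) {
  if (inherits(model, "degraded_model")) model <- model$cloud
  stopifnot(inherits(model, "point_cloud"), inherits(scene, "scene_model"))
  cfg <- utils::modifyList(
    list(align = "none", octree_level = 8L, min_cluster_points = 10L,
         gap_threshold = NULL, omission_threshold = NULL, voxel_size = NULL,
         radii = NULL, bounds = NULL, scheme = distance_class_scheme()),
    config)
  reference <- scene$reference

  alignment <- NULL
  if (cfg$align != "none") {
    tf <- align_to_targets(model, scene, icp = identical(cfg$align, "icp"))
    model <- apply_transform(model, tf)
    alignment <- list(scale = tf$scale,
                      rotation = as.vector(t(tf$rotation)),  # row-major
                      translation = tf$translation,
                      rms = attr(tf, "rms"))
  }

  f_m2r <- nn_distances(model, reference, "model_to_reference",
                        scene_width = scene$scene_width)
  f_r2m <- nn_distances(reference, model, "reference_to_model",
                        scene_width = scene$scene_width)
  cls_m2r <- classify_distances(f_m2r, cfg$scheme)
  cls_r2m <- classify_distances(f_r2m, cfg$scheme)

  cen <- census(model, reference, octree_level = cfg$octree_level,
                min_cluster_points = cfg$min_cluster_points,
                gap_threshold = cfg$gap_threshold,
                omission_threshold = cfg$omission_threshold)
  roc <- roc_curve(model, reference, radii = cfg$radii,
                   voxel_size = cfg$voxel_size, bounds = cfg$bounds)

  thr <- cen$omission_threshold
  report <- list(
    package = "cloudtruth",
    version = as.character(utils::packageVersion("cloudtruth")),
    n_model_points = n_points(model),
    n_reference_points = n_points(reference),
    scene_width = scene$scene_width,
    alignment = alignment,
    distance = list(
      model_to_reference = summary_stats(f_m2r),
      reference_to_model = summary_stats(f_r2m),
      class_counts_model_to_reference = as.list(attr(cls_m2r, "counts")),
      class_counts_reference_to_model = as.list(attr(cls_r2m, "counts"))),
    census = list(floating = unname(cen$counts["floating"]),
                  attached = unname(cen$counts["attached"]),
                  omission_fraction = cen$omission_fraction,
                  omission_threshold = thr,
                  octree_level = cen$octree_level,
                  voxel_edge = cen$voxel_edge),
    point_rates = list(   # one-sided diagnostics, not an ROC
      completeness = mean(f_r2m$distances <= thr),
      correctness = mean(f_m2r$distances <= thr),
      threshold = thr),
    roc = roc$curve,
    auc = roc$auc,
    config = list(align = cfg$align, octree_level = cfg$octree_level,
                  min_cluster_points = cfg$min_cluster_points,
                  voxel_size = roc$voxel_size,
                  scene_width_definition = "largest horizontal bbox extent"))
  class(report) <- c("evaluation_report", "list")
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> AUC %.4f; omission %.3f; %d floating, %d attached\n",
              x$auc, x$census$omission_fraction, x$census$floating,
              x$census$attached))
  invisible(x)
}

#' Write an evaluation report as JSON
#' @param report an [evaluate()] result (or any list).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
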