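#' Point-cloud container
#'
#' The universal currency of the package: `N` 3-D points with optional
#' per-point RGB colour and an optional integer component label. Labels use a
#' closed vocabulary: `0` ground, `1` trunk, `2` branch, `3` foliage,
#' `10..17` the eight reference target cubes, and `>= 100` injected artefact
#' ids. Coordinates are in scene units (whatever the reference uses); all
#' relative thresholds downstream are normalized by scene width.
#'
#' @param points numeric `N x 3` matrix of coordinates (finite).
#' @param colors optional `N x 3` integer matrix of RGB values in 0--255.
#' @param labels optional length-`N` integer vector of component labels.
#' @param strict if `TRUE`, labels outside the closed vocabulary are rejected.
#' @return An object of class `point_cloud`: a list with elements `points`,
#'   `colors` (or `NULL`) and `labels` (or `NULL`).
#' @examples
#' pc <- point_cloud(matrix(rnorm(30), 10, 3), labels = rep(1L, 10))
#' n_points(pc)
#' @export
point_cloud <- function(points, colors = NULL, labels = NULL, strict = FALSE) {
  points <- as_num_matrix3(points)
  if (is.null(points)) points <- matrix(numeric(0), 0L, 3L)
  if (nrow(points) > 0L && !all(is.finite(points))) {
    stop("point coordinates must all be finite", call. = FALSE)
  }
  n <- nrow(points)
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    if (ncol(colors) != 3L || nrow(colors) != n) {
      stop("'colors' must be an N x 3 matrix matching the point count", call. = FALSE)
    }
    storage.mode(colors) <- "integer"
    dimnames(colors) <- NULL
    if (n > 0L && (anyNA(colors) || min(colors) < 0L || max(colors) > 255L)) {
      stop("'colors' must be integers in 0..255", call. = FALSE)
    }
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n) {
      stop("'labels' must have length equal to the point count", call. = FALSE)
    }
    if (anyNA(labels)) stop("'labels' must not contain NA", call. = FALSE)
    if (strict) {
      bad <- !label_is_known(labels)
      if (any(bad)) {
        stop(sprintf("unknown label id(s): %s",
                     paste(sort(unique(labels[bad])), collapse = ", ")),
             call. = FALSE)
      }
    }
  }
  structure(list(points = points, colors = colors, labels = labels),
            class = "point_cloud")
}

# Closed label vocabulary: scene components, target cubes, artefact ids.
label_is_known <- function(labels) {
  labels %in% c(0:3, 10:17) | labels >= 100L
}

#' Number of points in a cloud
#' @param cloud a [point_cloud()].
#' @return Integer point count.
#' @export
n_points <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  nrow(cloud$points)
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points", n_points(x)))
  if (!is.null(x$colors)) cat(", RGB")
  if (!is.null(x$labels)) {
    cat(sprintf(", labels {%s}", paste(sort(unique(x$labels)), collapse = ",")))
  }
  cat("\n")
  if (n_points(x) > 0L) {
    bb <- bbox_of(x$points)
    cat(sprintf("  bbox x[%.3g, %.3g] y[%.3g, %.3g] z[%.3g, %.3g]\n",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  }
  invisible(x)
}

#' Concatenate point clouds
#'
#' Row-binds points in argument order. Labels are kept if every part has
#' them; colours are kept if any part has them, with colourless parts filled
#' with neutral grey (128,128,128).
#'
#' @param ... [point_cloud()] objects.
#' @return A single [point_cloud()].
#' @export
pc_bind <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) > 0L, all(vapply(parts, inherits, TRUE, "point_cloud")))
  points <- do.call(rbind, lapply(parts, `[[`, "points"))
  have_lab <- vapply(parts, function(p) !is.null(p$labels), TRUE)
  labels <- if (all(have_lab)) {
    unlist(lapply(parts, `[[`, "labels"), use.names = FALSE)
  } else NULL
  have_col <- vapply(parts, function(p) !is.null(p$colors), TRUE)
  colors <- if (any(have_col)) {
    do.call(rbind, lapply(parts, function(p) {
      p$colors %||% matrix(128L, n_points(p), 3L)
    }))
  } else NULL
  point_cloud(points, colors = colors, labels = labels)
}

#' Subset a point cloud by row index
#' @param cloud a [point_cloud()].
#' @param idx integer or logical index over points.
#' @return A [point_cloud()] with the selected points and their attributes.
#' @export
pc_subset <- function(cloud, idx) {
  stopifnot(inherits(cloud, "point_cloud"))
  point_cloud(cloud$points[idx, , drop = FALSE],
              colors = if (!is.null(cloud$colors)) cloud$colors[idx, , drop = FALSE],
              labels = if (!is.null(cloud$labels)) cloud$labels[idx])
}
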