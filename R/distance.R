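#' One-sided nearest-neighbour distance field
#'
#' For every point of the query cloud, the exact Euclidean distance to its
#' nearest neighbour in the target cloud, computed with a kd-tree (never
#' approximate, so results are reproducible bit for bit). This is a
#' one-sided evaluator: model-to-reference distances measure commission
#' (spurious structure), reference-to-model distances measure omission
#' (missing structure); the two directions differ whenever the clouds do.
#'
#' @param query the [point_cloud()] at whose points distances are evaluated.
#' @param target the non-empty [point_cloud()] searched for neighbours.
#' @param direction `"model_to_reference"` or `"reference_to_model"`;
#'   bookkeeping for reports.
#' @param scene_width optional normalizer for relative distance classes;
#'   default: the scene width (largest horizontal extent) of the target.
#' @return An object of class `distance_field`: list with `distances`
#'   (length = query size), `nn_index`, `direction`, `scene_width`.
#' @export
nn_distances <- function(query, target,
                         direction = c("model_to_reference", "reference_to_model"),
                         scene_width = NULL) {
  stopifnot(inherits(query, "point_cloud"), inherits(target, "point_cloud"))
  direction <- match.arg(direction)
  if (n_points(target) == 0L) stop("target cloud must be non-empty", call. = FALSE)
  nn <- cpp_nn(query$points, target$points)
  structure(list(distances = nn$dist, nn_index = nn$idx, direction = direction,
                 scene_width = scene_width %||% scene_width_of(target$points)),
            class = "distance_field")
}

#' @export
print.distance_field <- function(x, ...) {
  cat(sprintf("<distance_field> %d points, %s, mean %.4g, max %.4g (scene width %.4g)\n",
              length(x$distances), x$direction, mean(x$distances),
              if (length(x$distances)) max(x$distances) else NA, x$scene_width))
  invisible(x)
}

#' Distance-class scheme
#'
#' The standard colouring of cloud-to-cloud discrepancy maps: distances are
#' normalized by scene width and binned into five classes rendered blue,
#' green, yellow, red and purple. The default class edges are 0.0075, 0.015
#' and 0.0225 of unit scene width; class 3 (red) extends to
#' `outlier_factor` times the last edge and class 4 (purple) collects the
#' outliers beyond. Intervals are half-open: `[lower, upper)`.
#'
#' @param thresholds strictly increasing positive class edges, relative to
#'   unit scene width.
#' @param outlier_factor multiple of the last threshold where the purple
#'   outlier class begins (default 2).
#' @return An object of class `distance_class_scheme` with the four break
#'   points and the colour palette.
#' @export
distance_class_scheme <- function(thresholds = c(0.0075, 0.015, 0.0225),
                                  outlier_factor = 2) {
  thresholds <- as.numeric(thresholds)
  stopifnot(length(thresholds) == 3L, all(thresholds > 0),
            all(diff(thresholds) > 0), outlier_factor > 1)
  structure(list(thresholds = thresholds,
                 breaks = c(thresholds, outlier_factor * thresholds[3]),
                 palette = distance_palette()),
            class = "distance_class_scheme")
}

#' Distance-class colour palette
#'
#' Class 0 blue, 1 green, 2 yellow, 3 red, 4 purple (outliers).
#' @return A 5 x 3 integer RGB matrix, rownames `0..4`.
#' @export
distance_palette <- function() {
  matrix(as.integer(c(
    0, 0, 255,      # 0 blue
    0, 255, 0,      # 1 green
    255, 255, 0,    # 2 yellow
    255, 0, 0,      # 3 red
    160, 32, 240)), # 4 purple
    ncol = 3, byrow = TRUE, dimnames = list(0:4, c("r", "g", "b")))
}

#' Classify a distance field into discrepancy classes
#'
#' Distances are divided by the field's scene width and assigned to the
#' half-open class intervals of the scheme.
#'
#' @param field a [nn_distances()] result.
#' @param scheme a [distance_class_scheme()].
#' @return Integer class ids (0--4) per point, with attribute `counts`
#'   (named class counts summing to the field length).
#' @export
classify_distances <- function(field, scheme = distance_class_scheme()) {
  stopifnot(inherits(field, "distance_field"),
            inherits(scheme, "distance_class_scheme"),
            field$scene_width > 0)
  rel <- field$distances / field$scene_width
  cls <- findInterval(rel, scheme$breaks)   # half-open [lower, upper)
  counts <- tabulate(cls + 1L, nbins = 5L)
  names(counts) <- 0:4
  structure(as.integer(cls), counts = counts)
}

#' Summary statistics of a distance field
#'
#' @param field a non-empty [nn_distances()] result.
#' @param beyond threshold for `fraction_beyond` (scene units); default the
#'   first class edge of the default scheme times scene width.
#' @return A list with `mean`, `rms`, `median`, `p95`, `max`,
#'   `fraction_beyond` (and its threshold), plus `normalized` variants
#'   (divided by scene width).
#' @export
summary_stats <- function(field, beyond = NULL) {
  stopifnot(inherits(field, "distance_field"), length(field$distances) > 0L)
  d <- field$distances
  beyond <- beyond %||% (0.0075 * field$scene_width)
  out <- list(mean = mean(d), rms = sqrt(mean(d^2)), median = median(d),
              p95 = quantile(d, 0.95, names = FALSE), max = max(d),
              beyond_threshold = beyond, fraction_beyond = mean(d > beyond))
  sw <- field$scene_width
  out$normalized <- list(mean = out$mean / sw, rms = out$rms / sw,
                         median = out$median / sw, p95 = out$p95 / sw,
                         max = out$max / sw)
  out
}

#' Write a cloud coloured by distance class
#'
#' Per-point RGB is the fixed class palette (blue, green, yellow, red,
#' purple); output is an ASCII PLY next to any viewer.
#'
#' @param query the [point_cloud()] the classes were computed on.
#' @param classes integer class ids from [classify_distances()].
#' @param path output PLY path.
#' @param precision significant digits for coordinates.
#' @return `path`, invisibly.
#' @export
write_colored_cloud <- function(query, classes, path, precision = 6) {
  stopifnot(inherits(query, "point_cloud"),
            length(classes) == n_points(query),
            all(classes %in% 0:4))
  pal <- distance_palette()
  colored <- point_cloud(query$points, colors = pal[classes + 1L, , drop = FALSE],
                         labels = query$labels)
  write_ply(colored, path, precision = precision)
}
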