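# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All generator/degrader determinism flows through this.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Axis-aligned bounding box of an N x 3 matrix: 2 x 3 matrix (rows min, max).
bbox_of <- function(points) {
  stopifnot(is.matrix(points), ncol(points) == 3L)
  if (nrow(points) == 0L) {
    return(matrix(NA_real_, 2, 3, dimnames = list(c("min", "max"), c("x", "y", "z"))))
  }
  rbind(min = apply(points, 2, min), max = apply(points, 2, max))
}

bbox_extent <- function(bb) bb["max", ] - bb["min", ]

# Largest horizontal (x or y) extent: the scene-width normalizer used for
# relative distance thresholds.
scene_width_of <- function(points) {
  bb <- bbox_of(points)
  max(bbox_extent(bb)[1:2])
}

scene_diagonal_of <- function(bb) sqrt(sum(bbox_extent(bb)^2))

`%||%` <- function(a, b) if (is.null(a)) b else a

as_num_matrix3 <- function(x, what = "points") {
  if (is.null(x)) return(NULL)
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop(sprintf("'%s' must have 3 columns", what), call. = FALSE)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}
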