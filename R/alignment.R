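#' Similarity transform (scale, rotation, translation)
#'
#' The ambiguity class of photogrammetric reconstructions: each reconstruction
#' lives in its own arbitrarily scaled and oriented frame, so mapping into the
#' reference frame requires estimating a 7-parameter similarity
#' `y = s * R * x + t`.
#'
#' @param scale positive scale factor.
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 translation vector.
#' @return An object of class `similarity_transform`.
#' @export
similarity_transform <- function(scale = 1, rotation = diag(3),
                                 translation = c(0, 0, 0)) {
  scale <- as.numeric(scale)
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(length(scale) == 1L, is.finite(scale), scale > 0,
            all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation must be orthonormal (||R'R - I|| < 1e-9)", call. = FALSE)
  }
  if (det(rotation) <= 0) stop("rotation must be proper (det > 0)", call. = FALSE)
  structure(list(scale = scale, rotation = rotation, translation = translation),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity_transform> scale %.6g, rotation angle %.4g deg, t = (%.4g, %.4g, %.4g)\n",
              x$scale, rotation_angle_deg(x$rotation),
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

# Angle of a rotation matrix in degrees (for reporting and recovery tests).
rotation_angle_deg <- function(R) {
  c_ang <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, c_ang))) * 180 / pi
}

#' Apply a similarity transform to points or a cloud
#'
#' @param cloud a [point_cloud()] or an `N x 3` matrix.
#' @param transform a [similarity_transform()].
#' @return The transformed object, attributes carried unchanged.
#' @export
apply_transform <- function(cloud, transform) {
  stopifnot(inherits(transform, "similarity_transform"))
  tf <- function(p) {
    sweep(transform$scale * (p %*% t(transform$rotation)), 2,
          transform$translation, `+`)
  }
  if (inherits(cloud, "point_cloud")) {
    out <- cloud
    out$points <- tf(cloud$points)
    out
  } else {
    tf(as_num_matrix3(cloud))
  }
}

#' Compose and invert similarity transforms
#'
#' `compose_transform(a, b)` is the transform applying `b` first, then `a`.
#'
#' @param a,b,transform [similarity_transform()] objects.
#' @return A [similarity_transform()].
#' @export
compose_transform <- function(a, b) {
  similarity_transform(
    scale = a$scale * b$scale,
    rotation = a$rotation %*% b$rotation,
    translation = a$scale * as.vector(a$rotation %*% b$translation) + a$translation
  )
}

#' @rdname compose_transform
#' @export
invert_transform <- function(transform) {
  Rinv <- t(transform$rotation)
  similarity_transform(
    scale = 1 / transform$scale,
    rotation = Rinv,
    translation = -as.vector(Rinv %*% transform$translation) / transform$scale
  )
}

#' Least-squares similarity transform between point correspondences
#'
#' Closed-form (SVD-based) minimizer of `sum ||s R x_i + t - y_i||^2` over
#' scale, rotation and translation, with the determinant correction that
#' guarantees a proper rotation. Scale is always estimated, since
#' photogrammetric clouds carry arbitrary scale. In the synthetic pipeline
#' the correspondences are the eight target-cube centroids matched by label;
#' for external clouds they come from a correspondence file.
#'
#' @param source_pts `K x 3` matrix of source points (`K >= 3`, not collinear).
#' @param target_pts `K x 3` matrix of corresponding target points.
#' @return A [similarity_transform()] with attribute `rms` (residual
#'   root-mean-square error after alignment).
#' @export
estimate_similarity <- function(source_pts, target_pts) {
  X <- as_num_matrix3(source_pts, "source_pts")
  Y <- as_num_matrix3(target_pts, "target_pts")
  K <- nrow(X)
  if (K < 3L || nrow(Y) != K) {
    stop("need K >= 3 corresponding point pairs", call. = FALSE)
  }
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  S <- crossprod(Yc, Xc) / K          # 3x3 cross-covariance
  sv <- svd(S)
  # degenerate (collinear/coincident) configurations have rank < 2
  if (sv$d[2] <= max(sv$d[1], .Machine$double.eps) * 1e-9) {
    stop("degenerate correspondence configuration (collinear or coincident points)",
         call. = FALSE)
  }
  d <- c(1, 1, sign(det(sv$u) * det(sv$v)))
  R <- sv$u %*% diag(d) %*% t(sv$v)
  var_x <- sum(Xc^2) / K
  s <- sum(sv$d * d) / var_x
  t_vec <- my - s * as.vector(R %*% mx)
  tf <- similarity_transform(scale = s, rotation = R, translation = t_vec)
  resid <- apply_transform(X, tf) - Y
  attr(tf, "rms") <- sqrt(mean(rowSums(resid^2)))
  tf
}

#' Refine an alignment by iterative closest point
#'
#' Alternates nearest-neighbour correspondence with the closed-form similarity
#' fit ([estimate_similarity()]), starting from `init`. Correspondences
#' farther than `cutoff` are discarded for robustness against artefact
#' points. The RMS is non-increasing across returned iterations: if a step
#' would increase it, the previous transform is returned. The initial guess
#' must be within the convergence basin (contract: initial RMS below ~5% of
#' scene width).
#'
#' @param model a [point_cloud()] to be mapped onto `reference`.
#' @param reference the reference [point_cloud()].
#' @param init initial [similarity_transform()].
#' @param max_iter maximum iterations (default 50).
#' @param tol stop when the RMS improvement falls below `tol` (default 1e-8
#'   scene units).
#' @param cutoff correspondence rejection distance; default 5% of the
#'   reference scene width.
#' @return A [similarity_transform()] with attributes `rms` (final
#'   correspondence RMS) and `iterations`.
#' @export
icp_refine <- function(model, reference, init = similarity_transform(),
                       max_iter = 50L, tol = 1e-8, cutoff = NULL) {
  stopifnot(inherits(model, "point_cloud"), inherits(reference, "point_cloud"),
            inherits(init, "similarity_transform"))
  if (n_points(reference) == 0L || n_points(model) == 0L) {
    stop("both clouds must be non-empty", call. = FALSE)
  }
  cutoff <- cutoff %||% (0.05 * scene_width_of(reference$points))
  X <- model$points
  current <- init
  rms_of <- function(tf) {
    moved <- apply_transform(X, tf)
    nn <- cpp_nn(moved, reference$points)
    keep <- nn$dist <= cutoff
    if (!any(keep)) stop("ICP divergence: no correspondences within cutoff", call. = FALSE)
    list(rms = sqrt(mean(nn$dist[keep]^2)), keep = keep, idx = nn$idx)
  }
  cur <- rms_of(current)
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    fit <- estimate_similarity(X[cur$keep, , drop = FALSE],
                               reference$points[cur$idx[cur$keep], , drop = FALSE])
    new <- rms_of(fit)
    iterations <- it
    if (new$rms > cur$rms) break            # never return an increased RMS
    improved <- cur$rms - new$rms
    current <- fit
    cur <- new
    if (improved < tol) break
  }
  attr(current, "rms") <- cur$rms
  attr(current, "iterations") <- iterations
  current
}

#' Align a reconstruction to a reference via labelled targets
#'
#' Convenience wrapper for the synthetic pipeline: computes per-label centroids
#' of the target cubes (labels 10--17) in both clouds, estimates the
#' similarity transform from those correspondences, and optionally refines by
#' ICP.
#'
#' @param model a labelled [point_cloud()] containing target-cube points.
#' @param scene a [scene_model()] (or labelled reference cloud).
#' @param icp if `TRUE`, refine with [icp_refine()].
#' @param ... passed to [icp_refine()].
#' @return The estimated [similarity_transform()].
#' @export
align_to_targets <- function(model, scene, icp = FALSE, ...) {
  ref_cent <- if (inherits(scene, "scene_model")) {
    scene$target_centroids
  } else {
    label_centroids(scene, 10:17)
  }
  mod_cent <- label_centroids(model, as.integer(rownames(ref_cent)))
  tf <- estimate_similarity(mod_cent, ref_cent)
  if (icp) {
    reference <- if (inherits(scene, "scene_model")) scene$reference else scene
    tf <- icp_refine(model, reference, init = tf, ...)
  }
  tf
}

# Per-label centroids for a set of labels; errors if any label is absent.
label_centroids <- function(cloud, labels) {
  stopifnot(inherits(cloud, "point_cloud"), !is.null(cloud$labels))
  out <- matrix(NA_real_, length(labels), 3L,
                dimnames = list(labels, c("x", "y", "z")))
  for (i in seq_along(labels)) {
    sel <- cloud$labels == labels[i]
    if (!any(sel)) {
      stop(sprintf("label %d has no points in the cloud", labels[i]), call. = FALSE)
    }
    out[i, ] <- colMeans(cloud$points[sel, , drop = FALSE])
  }
  out
}
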