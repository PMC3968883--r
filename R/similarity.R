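#' Similarity transforms of the plane
#'
#' A similarity transform maps a point p to `s * R(theta) p + t` with
#' scale `s > 0`, rotation `theta` (radians, counter-clockwise) and
#' translation `t = (tx, ty)` in mm.
#'
#' @param scale positive scale factor.
#' @param rotation rotation angle in radians.
#' @param translation numeric length-2 translation (mm).
#' @return object of class `similarity_transform`.
#' @export
similarity_transform <- function(scale = 1, rotation = 0, translation = c(0, 0)) {
  if (!is.finite(scale) || scale <= 0) stop("similarity_transform: scale must be > 0")
  structure(list(scale = as.numeric(scale), rotation = as.numeric(rotation),
                 translation = as.numeric(translation)),
            class = "similarity_transform")
}

rot_mat <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' @rdname similarity_transform
#' @param transform a `similarity_transform`.
#' @param points an n x 2 point matrix (or contour).
#' @export
apply_similarity <- function(transform, points) {
  pts <- contour_points(points)
  out <- transform$scale * pts %*% t(rot_mat(transform$rotation))
  out[, 1] <- out[, 1] + transform$translation[1]
  out[, 2] <- out[, 2] + transform$translation[2]
  out
}

#' @rdname similarity_transform
#' @export
invert_similarity <- function(transform) {
  s <- 1 / transform$scale
  th <- -transform$rotation
  t0 <- -s * as.numeric(rot_mat(th) %*% transform$translation)
  similarity_transform(s, th, t0)
}

#' @rdname similarity_transform
#' @param a,b `similarity_transform`s; the composition applies `b` first,
#'   then `a`.
#' @export
compose_similarity <- function(a, b) {
  similarity_transform(a$scale * b$scale, a$rotation + b$rotation,
                       a$scale * as.numeric(rot_mat(a$rotation) %*% b$translation) +
                         a$translation)
}

#' Least-squares similarity alignment of two point sets
#'
#' Returns the similarity transform `T` minimising the sum of squared
#' distances between `T(source)` and `target` over corresponding rows
#' (closed form via centroids and the cross-covariance; no reflection is
#' allowed).
#'
#' @param source,target n x 2 point matrices (or contours) with
#'   corresponding rows, n >= 2.
#' @return a [similarity_transform()].
#' @export
align_similarity <- function(source, target) {
  s <- contour_points(source)
  t <- contour_points(target)
  if (nrow(s) != nrow(t)) stop("align_similarity: point counts differ")
  if (nrow(s) < 2) stop("align_similarity: need at least 2 points")
  ms <- colMeans(s); mt <- colMeans(t)
  sc <- sweep(s, 2, ms); tc <- sweep(t, 2, mt)
  d <- sum(sc * sc)
  if (d < .Machine$double.eps * max(1, sum(t * t))) {
    stop("align_similarity: degenerate (zero-spread) source")
  }
  a <- sum(sc * tc)
  b <- sum(sc[, 1] * tc[, 2] - sc[, 2] * tc[, 1])
  scale <- sqrt(a^2 + b^2) / d
  if (scale <= 0) stop("align_similarity: degenerate configuration (zero optimal scale)")
  theta <- atan2(b, a)
  trans <- mt - scale * as.numeric(rot_mat(theta) %*% ms)
  similarity_transform(scale, theta, trans)
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity> scale %.6g, rotation %.6g rad (%.3f deg), translation (%.4g, %.4g)\n",
              x$scale, x$rotation, x$rotation * 180 / pi,
              x$translation[1], x$translation[2]))
  invisible(x)
}

centroid_size <- function(pts) {
  pts <- contour_points(pts)
  c0 <- colMeans(pts)
  sqrt(sum(sweep(pts, 2, c0)^2))
}

# Intrinsic frame orientation: rotate so the major axis of the point
# scatter is vertical and the y-skewness of the points is non-negative.
# Makes the GPA frame independent of which input happened to seed it.
canonical_rotation <- function(pts) {
  pts <- sweep(pts, 2, colMeans(pts))
  C <- crossprod(pts) / nrow(pts)
  e <- eigen(C, symmetric = TRUE)
  v <- e$vectors[, 1]
  ang <- pi / 2 - atan2(v[2], v[1])
  rot <- pts %*% t(rot_mat(ang))
  if (sum(rot[, 2]^3) < 0) ang <- ang + pi
  ang
}

#' Generalized Procrustes alignment of a set of shapes
#'
#' Iteratively aligns every shape to the evolving mean by full similarity
#' transforms and recomputes the mean, until the mean stabilises. The
#' common frame keeps millimetre scale: the mean is re-normalised each
#' iteration to centroid at the origin and centroid size equal to the mean
#' centroid size of the inputs. The frame orientation is canonicalised
#' (major axis of the mean vertical, positive y-skewness) so the result
#' does not depend on the pose of any individual input.
#'
#' @param shapes list of n x 2 point matrices (or contours), equal sizes.
#' @param tol convergence tolerance on the RMS change of the mean (mm).
#' @param max_iter iteration cap; non-convergence gives a warning.
#' @return list with `mean_shape` (n x 2), `aligned` (list of n x 2),
#'   `transforms` (list of [similarity_transform()]s mapping each input
#'   into the common frame), `iterations`, `converged`, `target_size`.
#' @export
generalized_procrustes <- function(shapes, tol = 1e-10, max_iter = 200) {
  shapes <- lapply(shapes, contour_points)
  if (length(shapes) < 2) stop("generalized_procrustes: need at least 2 shapes")
  np <- vapply(shapes, nrow, integer(1))
  if (length(unique(np)) != 1) stop("generalized_procrustes: unequal point counts")
  s0 <- mean(vapply(shapes, centroid_size, numeric(1)))
  normalise <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m * (s0 / centroid_size(m))
  }
  mean_shape <- normalise(shapes[[1]])
  iterations <- 0L
  converged <- FALSE
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    aligned <- lapply(shapes, function(sh) {
      apply_similarity(align_similarity(sh, mean_shape), sh)
    })
    new_mean <- normalise(Reduce(`+`, aligned) / length(aligned))
    delta <- sqrt(mean((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("generalized_procrustes: not converged after ", max_iter, " iterations")
  }
  ang <- canonical_rotation(mean_shape)
  mean_shape <- mean_shape %*% t(rot_mat(ang))
  transforms <- lapply(shapes, align_similarity, target = mean_shape)
  aligned <- Map(apply_similarity, transforms, shapes)
  list(mean_shape = mean_shape, aligned = aligned, transforms = transforms,
       iterations = iterations, converged = converged, target_size = s0)
}
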