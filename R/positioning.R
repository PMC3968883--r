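#' Mean point-to-curve distance
#'
#' Distance from each evaluated point to the nearest location on the open
#' polyline through the ordered curve points, averaged over all evaluated
#' points. For combined left-right configurations the curve must be
#' evaluated per anatomical segment (left contour polyline, right contour
#' polyline) rather than across the gap between femurs: pass `segments`
#' as a list of index vectors, each applying to both the evaluated points
#' and the curve points.
#'
#' @param points evaluated points (n x 2 matrix or contour).
#' @param curve ordered reference points defining the polyline(s).
#' @param segments optional list of index vectors splitting both inputs
#'   into independent open polylines (default: one segment).
#' @param symmetric if `TRUE`, return the mean of both directions
#'   (points to curve and curve to points); default one-directional.
#' @return mean distance in mm.
#' @export
point_to_curve_distance <- function(points, curve, segments = NULL, symmetric = FALSE) {
  P <- contour_points(points)
  C <- contour_points(curve)
  if (nrow(P) == 0 || nrow(C) < 2) stop("point_to_curve_distance: empty input")
  one_way <- function(P, C) {
    if (is.null(segments)) return(mean(point_to_polyline(P, C)))
    d <- unlist(lapply(segments, function(idx) {
      point_to_polyline(P[idx, , drop = FALSE], C[idx, , drop = FALSE])
    }))
    mean(d)
  }
  if (symmetric) (one_way(P, C) + one_way(C, P)) / 2 else one_way(P, C)
}

# Distances from each row of P to the open polyline through rows of C.
point_to_polyline <- function(P, C) {
  n <- nrow(C)
  if (n < 2) stop("point_to_polyline: curve needs at least 2 points")
  A <- C[-n, , drop = FALSE]
  B <- C[-1, , drop = FALSE]
  D <- B - A
  L2 <- pmax(rowSums(D^2), .Machine$double.xmin)
  m <- nrow(P)
  dx0 <- outer(P[, 1], A[, 1], "-")
  dy0 <- outer(P[, 2], A[, 2], "-")
  tt <- sweep(dx0, 2, D[, 1], "*") + sweep(dy0, 2, D[, 2], "*")
  tt <- pmin(pmax(sweep(tt, 2, L2, "/"), 0), 1)
  ex <- dx0 - sweep(tt, 2, D[, 1], "*")
  ey <- dy0 - sweep(tt, 2, D[, 2], "*")
  d2 <- ex^2 + ey^2
  sqrt(apply(d2, 1, min))
}

# Split a 2n-length combined shape vector into per-side displacement
# vectors; mirror the right side into the left frame (negate x).
combined_halves <- function(v, n_points) {
  h <- n_points %/% 2L
  xi <- seq_len(n_points)
  yi <- n_points + xi
  list(dL = c(v[xi[seq_len(h)]], v[yi[seq_len(h)]]),
       dR_mirrored = c(-v[xi[h + seq_len(h)]], v[yi[h + seq_len(h)]]))
}

#' Oppositional-asymmetry score of a combined-model mode
#'
#' Splits the mode's displacement field into left and right halves,
#' mirrors the right half into the left anatomical frame (x components
#' negated; indices already correspond), and returns the cosine
#' similarity between the two 130-dimensional displacement vectors.
#' A score near +1 means the two sides vary as mirror images
#' (symmetric variation); a score near -1 means they vary in opposite
#' directions (an oppositional pattern, the signature of positioning
#' artefacts such as pelvic rotation or unequal shaft sliding). The score
#' is invariant to the arbitrary sign of the mode.
#'
#' @param model a combined `shape_model` (even point count, e.g. 130).
#' @param mode_index 1-based retained-mode index.
#' @param sym_threshold,opp_threshold classification cut-offs: scores
#'   `>= sym_threshold` are `symmetric`, `<= opp_threshold` are
#'   `oppositional`, anything else `indeterminate`.
#' @return list of class `mode_symmetry_score` with `mode_index`, `score`,
#'   `classification`.
#' @export
oppositional_score <- function(model, mode_index, sym_threshold = 0.7,
                               opp_threshold = -0.7) {
  if (model$n_points %% 2L != 0L) {
    stop("oppositional_score: model must be a combined (even point count) model")
  }
  k <- length(model$variances)
  if (mode_index < 1 || mode_index > k) stop("oppositional_score: mode_index out of range")
  h <- combined_halves(model$modes[, mode_index], model$n_points)
  denom <- sqrt(sum(h$dL^2)) * sqrt(sum(h$dR_mirrored^2))
  score <- if (denom == 0) 0 else sum(h$dL * h$dR_mirrored) / denom
  classification <- if (score <= opp_threshold) "oppositional"
    else if (score >= sym_threshold) "symmetric" else "indeterminate"
  structure(list(mode_index = as.integer(mode_index), score = score,
                 classification = classification),
            class = "mode_symmetry_score")
}

#' Classify every retained mode of a combined model
#'
#' @inheritParams oppositional_score
#' @return data.frame with columns `mode_index`, `score`,
#'   `classification`, `variance`, `variance_fraction`.
#' @export
classify_modes <- function(model, sym_threshold = 0.7, opp_threshold = -0.7) {
  if (!(-1 <= opp_threshold && opp_threshold < sym_threshold && sym_threshold <= 1)) {
    stop("classify_modes: need -1 <= opp_threshold < sym_threshold <= 1")
  }
  k <- length(model$variances)
  rows <- lapply(seq_len(k), function(j) {
    s <- oppositional_score(model, j, sym_threshold, opp_threshold)
    data.frame(mode_index = j, score = s$score, classification = s$classification,
               variance = model$variances[j],
               variance_fraction = model$variances[j] / model$total_variance,
               stringsAsFactors = FALSE)
  })
  if (k == 0) {
    return(data.frame(mode_index = integer(0), score = numeric(0),
                      classification = character(0), variance = numeric(0),
                      variance_fraction = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Zero selected modes and re-evaluate point positions
#'
#' Sets the excluded entries of the fitted coefficient vector `b` to zero
#' and reconstructs the posed points, keeping the original pose and
#' residual so only the targeted modes' contributions are removed.
#'
#' @param model a `shape_model`.
#' @param fit the subject's `shape_fit` under that model.
#' @param exclude integer indices (within the retained modes) to zero;
#'   empty set reproduces the original reconstruction.
#' @return n x 2 matrix of re-evaluated points.
#' @export
exclude_modes_and_reevaluate <- function(model, fit, exclude = integer(0)) {
  k <- length(model$variances)
  exclude <- as.integer(exclude)
  if (length(exclude) > 0 && (any(exclude < 1) || any(exclude > k))) {
    stop("exclude_modes_and_reevaluate: mode indices must lie in 1..", k)
  }
  b <- fit$b
  b[exclude] <- 0
  reconstruct_shape(model, list(b = b, pose = fit$pose, residual = fit$residual),
                    include_residual = TRUE)
}

#' Shape change introduced by the positioning adjustment
#'
#' Similarity-aligns the adjusted points onto the original configuration
#' and returns the mean point-to-curve distance over all points, evaluated
#' per femur segment.
#'
#' @param original the subject's original [combined_contour()] (or matrix).
#' @param adjusted the re-evaluated 130 x 2 point matrix.
#' @param symmetric passed to [point_to_curve_distance()].
#' @return mean distance in mm.
#' @export
adjustment_effect <- function(original, adjusted, symmetric = FALSE) {
  orig <- contour_points(original)
  adj <- contour_points(adjusted)
  if (nrow(orig) != nrow(adj)) stop("adjustment_effect: point counts differ")
  h <- nrow(orig) %/% 2L
  aligned <- apply_similarity(align_similarity(adj, orig), adj)
  point_to_curve_distance(aligned, orig,
                          segments = list(seq_len(h), h + seq_len(h)),
                          symmetric = symmetric)
}

#' Build the combined left-right shape model for a dataset
#'
#' Procrustes-aligns the 130-point configurations, orients the common
#' frame so the configuration's mirror axis is vertical (required for the
#' x-negation mirroring used by [oppositional_score()]), builds the PCA
#' model, and computes each subject's `shape_fit` (pose = inverse of its
#' Procrustes transform, coefficients by orthogonal projection).
#'
#' When `symmetry_adapt = TRUE` (default), pairs of retained modes whose
#' variances differ by less than their joint sampling uncertainty are
#' re-rotated within their (statistically unidentifiable) two-dimensional
#' eigenspace so that the basis respects the left-right mirror-swap
#' operator; see [symmetry_refine_modes()]. This removes the arbitrary
#' mixing of mirror-symmetric and oppositional components that plain PCA
#' produces inside near-degenerate eigenvalue pairs, without changing the
#' model subspace.
#'
#' @param contours list of [combined_contour()]s.
#' @param variance_threshold retained-variance fraction (default 0.95).
#' @param symmetry_adapt refine near-degenerate mode pairs (default TRUE).
#' @param gpa_tol,gpa_max_iter passed to [generalized_procrustes()].
#' @return list with `model`, `fits` (named by subject), `subject_ids`,
#'   `gpa` (iterations/convergence info).
#' @export
build_combined_model <- function(contours, variance_threshold = 0.95,
                                 symmetry_adapt = TRUE,
                                 gpa_tol = 1e-10, gpa_max_iter = 200) {
  shapes <- lapply(contours, contour_points)
  gpa <- generalized_procrustes(shapes, tol = gpa_tol, max_iter = gpa_max_iter)
  # Rotate the frame so the left-right mirror axis is vertical: align the
  # side-swapped reflection of the mean onto the mean and split the
  # rotation difference.
  phi <- align_similarity(mirror_swap(gpa$mean_shape), gpa$mean_shape)$rotation
  R <- rot_mat(-phi / 2)
  mean_shape <- gpa$mean_shape %*% t(R)
  transforms <- lapply(shapes, align_similarity, target = mean_shape)
  aligned <- Map(apply_similarity, transforms, shapes)
  model <- build_shape_model(aligned, variance_threshold = variance_threshold)
  if (symmetry_adapt) model <- symmetry_refine_modes(model, model$n_shapes)
  P <- model$modes
  fits <- Map(function(al, tr) {
    v <- shape_to_vec(al) - model$mean_shape
    b <- if (ncol(P) > 0) as.numeric(crossprod(P, v)) else numeric(0)
    resid <- v - if (ncol(P) > 0) as.numeric(P %*% b) else 0
    structure(list(b = b, pose = invert_similarity(tr), residual = resid),
              class = "shape_fit")
  }, aligned, transforms)
  ids <- vapply(contours, function(cc) {
    if (inherits(cc, "combined_contour")) cc$subject_id else "unknown"
  }, character(1))
  names(fits) <- ids
  list(model = model, fits = fits, subject_ids = ids,
       gpa = list(iterations = gpa$iterations, converged = gpa$converged,
                  target_size = gpa$target_size))
}

#' Symmetry-adapted refinement of mixed mode pairs
#'
#' PCA eigenvectors are only identifiable up to rotation inside (near-)
#' degenerate eigenspaces, and sample eigenvalue repulsion hides the
#' degeneracy: two population modes with equal variance typically appear
#' with a visibly non-zero sample gap while their sample eigenvectors are
#' an arbitrary rotation of the population pair. Under the bilateral
#' generative structure -- shared anatomy varies mirror-symmetrically,
#' positioning artefacts oppositionally -- the population covariance
#' commutes with the left-right mirror-swap operator `M`, so its
#' eigenvectors can be chosen as eigenvectors of `M` (oppositional score
#' exactly +1 or -1). For every adjacent retained pair this function
#' diagonalises the restriction of `M` to the pair's two-dimensional
#' subspace and, **only** if that restriction has eigenvalues close to +1
#' and -1 (within `m_tol`, i.e. the subspace genuinely contains one
#' mirror-symmetric and one oppositional direction), replaces the pair by
#' the rotated basis, with variances recomputed along the new directions.
#' A pair that is already pure is left unchanged (the rotation is the
#' identity), and pairs spanning noise directions fail the +1/-1
#' condition -- the mirror restriction of a generic low-dimensional noise
#' subspace has interior eigenvalues -- so no spurious oppositional
#' structure is created. The sweep repeats until stable to resolve mixing
#' across more than two modes.
#'
#' @param model a combined `shape_model`.
#' @param n_shapes sample size used to build the model (kept for
#'   reporting; the gate is the mirror-restriction condition itself).
#' @param m_tol tolerance on the mirror-operator eigenvalues (default 0.2).
#' @return the model with refined `modes` and `variances`.
#' @export
symmetry_refine_modes <- function(model, n_shapes = model$n_shapes, m_tol = 0.2) {
  k <- length(model$variances)
  if (k < 2) return(model)
  np <- model$n_points
  touched <- logical(k)
  for (sweep in seq_len(5)) {
    changed <- FALSE
    j <- 1L
    while (j < k) {
      D <- model$modes[, c(j, j + 1), drop = FALSE]
      MD <- apply(D, 2, mirror_vec, n_points = np)
      A <- (crossprod(D, MD) + t(crossprod(D, MD))) / 2
      e <- eigen(A, symmetric = TRUE)
      if (abs(e$values[1] - 1) < m_tol && abs(e$values[2] + 1) < m_tol &&
          abs(e$vectors[1, 2]) > 1e-8) {
        W <- e$vectors
        v1 <- model$variances[j]; v2 <- model$variances[j + 1]
        new_var <- c(v1 * W[1, 1]^2 + v2 * W[2, 1]^2,
                     v1 * W[1, 2]^2 + v2 * W[2, 2]^2)
        ord <- order(new_var, decreasing = TRUE)
        newD <- (D %*% W)[, ord, drop = FALSE]
        if (max(abs(newD - D)) > 1e-10) changed <- TRUE
        model$modes[, c(j, j + 1)] <- newD
        model$variances[c(j, j + 1)] <- new_var[ord]
        touched[c(j, j + 1)] <- TRUE
        j <- j + 2L
        next
      }
      j <- j + 1L
    }
    if (!changed) break
  }
  for (j in which(touched)) {
    col <- model$modes[, j]
    if (col[which.max(abs(col))] < 0) model$modes[, j] <- -col
  }
  model
}

# Mirror-swap operator on a 2n-length displacement vector: negate the x
# components and swap the left/right blocks (indices correspond).
mirror_vec <- function(v, n_points) {
  h <- n_points %/% 2L
  x <- v[seq_len(n_points)]
  y <- v[n_points + seq_len(n_points)]
  c(-x[h + seq_len(h)], -x[seq_len(h)], y[h + seq_len(h)], y[seq_len(h)])
}

# Reflect a combined configuration about the vertical axis through its
# centroid and swap the side blocks, preserving anatomical correspondence.
mirror_swap <- function(pts) {
  pts <- contour_points(pts)
  h <- nrow(pts) %/% 2L
  cx <- mean(pts[, 1])
  pts[, 1] <- 2 * cx - pts[, 1]
  rbind(pts[h + seq_len(h), , drop = FALSE], pts[seq_len(h), , drop = FALSE])
}

#' Apply the positioning adjustment to a whole dataset
#'
#' Excludes the given (or automatically classified) oppositional modes
#' from every subject's fit and re-evaluates the 130 point positions.
#'
#' @param cm result of [build_combined_model()].
#' @param exclude integer mode indices to exclude, or `NULL` to select all
#'   modes classified oppositional at `opp_threshold`.
#' @param sym_threshold,opp_threshold classification cut-offs (used when
#'   `exclude` is `NULL`).
#' @return list with `adjusted` (named list of 130 x 2 matrices),
#'   `excluded` (mode indices), `mode_scores` (classification table),
#'   `effect` (data.frame of per-subject adjustment distances, mm).
#' @export
adjust_dataset <- function(cm, exclude = NULL, sym_threshold = 0.7,
                           opp_threshold = -0.7) {
  scores <- classify_modes(cm$model, sym_threshold, opp_threshold)
  if (is.null(exclude)) {
    exclude <- scores$mode_index[scores$classification == "oppositional"]
  }
  exclude <- as.integer(exclude)
  adjusted <- lapply(cm$fits, function(f) {
    exclude_modes_and_reevaluate(cm$model, f, exclude)
  })
  eff <- vapply(seq_along(adjusted), function(i) {
    orig <- reconstruct_shape(cm$model, cm$fits[[i]], include_residual = TRUE)
    adjustment_effect(orig, adjusted[[i]])
  }, numeric(1))
  list(adjusted = adjusted, excluded = exclude, mode_scores = scores,
       effect = data.frame(subject_id = cm$subject_ids, effect_mm = eff,
                           stringsAsFactors = FALSE))
}
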