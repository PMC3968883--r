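#' Build a single-femur shape model with all femurs as left femurs
#'
#' Collects the left femur of every subject and the mirror image of the
#' right femur (reflected about a vertical axis; the axis position is
#' irrelevant up to the subsequent Procrustes alignment), aligns all 2n
#' shapes by generalized Procrustes analysis, and builds the 65-point
#' model. Per-femur coefficients are computed by orthogonal projection in
#' the common frame.
#'
#' @param contours list of [combined_contour()]s (or lists with `left`
#'   and `right` [femur_contour()]s).
#' @param variance_threshold retained-variance fraction (default 0.95).
#' @param mirror_axis x-position of the reflection axis for right femurs;
#'   default: each right femur's own centroid x.
#' @param gpa_tol,gpa_max_iter passed to [generalized_procrustes()].
#' @return list with `model` (65-point `shape_model`), `b_left` and
#'   `b_right` (subjects x k coefficient matrices, rows paired by
#'   subject), `fits` (all `shape_fit`s, lefts then rights),
#'   `subject_ids`, `gpa`.
#' @export
build_single_model <- function(contours, variance_threshold = 0.95,
                               mirror_axis = NULL, gpa_tol = 1e-10,
                               gpa_max_iter = 200) {
  pairs <- lapply(contours, function(cc) {
    if (inherits(cc, "combined_contour")) split_combined(cc) else cc
  })
  ids <- vapply(pairs, function(p) p$left$subject_id, character(1))
  lefts <- lapply(pairs, function(p) contour_points(p$left))
  rights <- lapply(pairs, function(p) {
    rp <- contour_points(p$right)
    ax <- if (is.null(mirror_axis)) mean(rp[, 1]) else mirror_axis
    reflect_contour(rp, axis_x = ax)
  })
  shapes <- c(lefts, rights)
  gpa <- generalized_procrustes(shapes, tol = gpa_tol, max_iter = gpa_max_iter)
  model <- build_shape_model(gpa$aligned, variance_threshold = variance_threshold)
  P <- model$modes
  k <- ncol(P)
  fits <- Map(function(al, tr) {
    v <- shape_to_vec(al) - model$mean_shape
    b <- if (k > 0) as.numeric(crossprod(P, v)) else numeric(0)
    structure(list(b = b, pose = invert_similarity(tr),
                   residual = v - if (k > 0) as.numeric(P %*% b) else 0),
              class = "shape_fit")
  }, gpa$aligned, gpa$transforms)
  n <- length(pairs)
  B <- if (k > 0) do.call(rbind, lapply(fits, `[[`, "b")) else matrix(0, 2 * n, 0)
  list(model = model,
       b_left = B[seq_len(n), , drop = FALSE],
       b_right = B[n + seq_len(n), , drop = FALSE],
       fits = fits, subject_ids = ids,
       gpa = list(iterations = gpa$iterations, converged = gpa$converged,
                  target_size = gpa$target_size))
}

#' Left-right shape difference of one subject
#'
#' Reflects the right femur about a vertical axis, similarity-aligns the
#' reflected right onto the left (so the left femur's millimetre scale is
#' preserved), and returns the mean point-to-curve distance of the 65
#' left landmarks against the aligned right contour polyline.
#'
#' @param left,right [femur_contour()]s (or point matrices) of one subject.
#' @param symmetric passed to [point_to_curve_distance()].
#' @return mean distance in mm.
#' @export
left_right_distance <- function(left, right, symmetric = FALSE) {
  lp <- contour_points(left)
  rp <- contour_points(right)
  rr <- reflect_contour(rp, axis_x = mean(rp[, 1]))
  aligned_r <- apply_similarity(align_similarity(rr, lp), rr)
  point_to_curve_distance(lp, aligned_r, symmetric = symmetric)
}

#' Per-subject left-right distances for a dataset
#'
#' @param contours list of [combined_contour()]s or 130 x 2 matrices.
#' @return data.frame with `subject_id` and `lr_distance_mm`.
#' @export
dataset_lr_distances <- function(contours) {
  rows <- lapply(contours, function(cc) {
    pts <- contour_points(cc)
    h <- nrow(pts) %/% 2L
    id <- if (inherits(cc, "combined_contour")) cc$subject_id else "unknown"
    data.frame(subject_id = id,
               lr_distance_mm = left_right_distance(pts[seq_len(h), , drop = FALSE],
                                                    pts[h + seq_len(h), , drop = FALSE]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-mode Welch tests of left vs right coefficients
#'
#' For each retained mode: two-sided Welch's t-test (unequal variances,
#' Welch-Satterthwaite degrees of freedom) comparing the left and right
#' coefficient samples, a Kolmogorov-Smirnov normality check per group
#' against a normal with the sample mean and SD (note: with estimated
#' parameters this is the Lilliefors setting, so the reported KS p-values
#' are approximate/conservative), and significance flags at the family
#' alpha and at the Bonferroni-adjusted per-mode alpha `family_alpha / k`.
#'
#' @param b_left,b_right subjects x k coefficient matrices.
#' @param family_alpha family-wise significance level (default 0.05).
#' @return data.frame with one row per mode (`mode_index`, `mean_b_left`,
#'   `mean_b_right`, `sd_overall`, `sd_lr_difference`, `welch_t`,
#'   `welch_df`, `p_value`, `ks_p_left`, `ks_p_right`, `significant_raw`,
#'   `significant_bonferroni`) and attribute `bonferroni_alpha`.
#' @export
per_mode_tests <- function(b_left, b_right, family_alpha = 0.05) {
  b_left <- as.matrix(b_left); b_right <- as.matrix(b_right)
  k <- ncol(b_left)
  if (ncol(b_right) != k) stop("per_mode_tests: coefficient dimensions differ")
  if (nrow(b_left) < 2 || nrow(b_right) < 2) {
    stop("per_mode_tests: need at least 2 observations per group")
  }
  bonf <- if (k > 0) family_alpha / k else NA_real_
  sdc <- mode_sd_comparison(b_left, b_right)
  rows <- lapply(seq_len(k), function(j) {
    x <- b_left[, j]; y <- b_right[, j]
    degenerate <- stats::sd(x) == 0 && stats::sd(y) == 0
    if (degenerate) {
      tt <- list(statistic = NA_real_, parameter = NA_real_, p.value = NA_real_)
    } else {
      tt <- stats::t.test(x, y, var.equal = FALSE)
    }
    ksp <- function(v) {
      if (stats::sd(v) == 0) return(NA_real_)
      suppressWarnings(stats::ks.test(v, "pnorm", mean(v), stats::sd(v))$p.value)
    }
    data.frame(mode_index = j,
               mean_b_left = mean(x), mean_b_right = mean(y),
               sd_overall = sdc$sd_overall[j],
               sd_lr_difference = sdc$sd_lr_difference[j],
               welch_t = unname(tt$statistic), welch_df = unname(tt$parameter),
               p_value = tt$p.value,
               ks_p_left = ksp(x), ks_p_right = ksp(y),
               significant_raw = !is.na(tt$p.value) && tt$p.value < family_alpha,
               significant_bonferroni = !is.na(tt$p.value) && tt$p.value < bonf,
               degenerate = degenerate)
  })
  out <- if (k > 0) do.call(rbind, rows) else
    data.frame(mode_index = integer(0))
  attr(out, "bonferroni_alpha") <- bonf
  attr(out, "family_alpha") <- family_alpha
  out
}

#' Per-mode SD of the population vs the within-subject left-right difference
#'
#' `sd_overall` is the SD of the mode coefficient over all femurs (left
#' and right pooled); `sd_lr_difference` is the SD over subjects of the
#' paired difference `b_left - b_right`. When anatomy drives a mode, the
#' within-subject difference is far smaller than the population spread.
#'
#' @inheritParams per_mode_tests
#' @return data.frame with `mode_index`, `sd_overall`, `sd_lr_difference`.
#' @export
mode_sd_comparison <- function(b_left, b_right) {
  b_left <- as.matrix(b_left); b_right <- as.matrix(b_right)
  k <- ncol(b_left)
  paired <- nrow(b_left) == nrow(b_right)
  data.frame(mode_index = seq_len(k),
             sd_overall = if (k > 0) apply(rbind(b_left, b_right), 2, stats::sd) else numeric(0),
             sd_lr_difference = if (k > 0 && paired)
               apply(b_left - b_right, 2, stats::sd) else rep(NA_real_, k))
}

#' Full symmetry report for a dataset (optionally before/after adjustment)
#'
#' Builds the single 65-point model (all femurs as lefts), computes the
#' per-subject left-right point-to-curve distances and the per-mode
#' statistics.
#'
#' @param contours list of [combined_contour()]s (original landmarks).
#' @param adjusted optional named list of adjusted 130 x 2 matrices (as
#'   produced by [adjust_dataset()]); when supplied the report is computed
#'   from the adjusted points.
#' @param variance_threshold retained-variance fraction.
#' @param family_alpha family-wise alpha for the per-mode tests.
#' @return object of class `symmetry_report`: list with `n_subjects`,
#'   `mean_lr_distance`, `lr_distances` (per subject), `modes` (the
#'   [per_mode_tests()] table), `bonferroni_alpha`, `k`, `model`.
#' @export
symmetry_report <- function(contours, adjusted = NULL, variance_threshold = 0.95,
                            family_alpha = 0.05) {
  if (!is.null(adjusted)) {
    contours <- Map(function(cc, pts) {
      sides <- split_combined(pts)
      sides$left$subject_id <- cc$subject_id
      sides$right$subject_id <- cc$subject_id
      combined_contour(sides$left, sides$right, subject_id = cc$subject_id)
    }, contours, adjusted)
  }
  sm <- build_single_model(contours, variance_threshold = variance_threshold)
  lr <- dataset_lr_distances(contours)
  modes <- per_mode_tests(sm$b_left, sm$b_right, family_alpha = family_alpha)
  structure(list(n_subjects = length(contours),
                 mean_lr_distance = mean(lr$lr_distance_mm),
                 lr_distances = lr,
                 modes = modes,
                 bonferroni_alpha = attr(modes, "bonferroni_alpha"),
                 family_alpha = family_alpha,
                 k = length(sm$model$variances),
                 model = sm$model,
                 b_left = sm$b_left, b_right = sm$b_right),
            class = "symmetry_report")
}

#' @export
print.symmetry_report <- function(x, ...) {
  cat(sprintf("<symmetry_report> %d subjects, %d retained mode(s)\n",
              x$n_subjects, x$k))
  cat(sprintf("  mean left-right point-to-curve distance: %.1f mm\n",
              round(x$mean_lr_distance, 1)))
  if (x$k > 0) {
    cat(sprintf("  Bonferroni per-mode alpha: %.3f (family alpha %.2f)\n",
                round(x$bonferroni_alpha, 3), x$family_alpha))
    sig <- x$modes$mode_index[x$modes$significant_bonferroni]
    cat("  Bonferroni-significant modes: ",
        if (length(sig)) paste(sig, collapse = ", ") else "none", "\n", sep = "")
  }
  invisible(x)
}
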