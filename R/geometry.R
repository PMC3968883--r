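#' Algebraic least-squares circle fit (Kasa)
#'
#' Solves the linear system `x^2 + y^2 = 2 a x + 2 b y + c` in the least
#' squares sense; the centre is `(a, b)` and the radius
#' `sqrt(c + a^2 + b^2)`. Exact for points lying on a circle.
#'
#' @param points n x 2 matrix, n >= 3, not collinear.
#' @return list with `center` (length 2) and `radius`.
#' @export
fit_circle <- function(points) {
  pts <- contour_points(points)
  if (nrow(pts) < 3) stop("fit_circle: need at least 3 points")
  A <- cbind(2 * pts[, 1], 2 * pts[, 2], 1)
  z <- pts[, 1]^2 + pts[, 2]^2
  qr_A <- qr(A)
  if (qr_A$rank < 3) stop("fit_circle: points are collinear or degenerate")
  sol <- qr.coef(qr_A, z)
  center <- sol[1:2]
  r2 <- sol[3] + sum(center^2)
  if (r2 <= 0) stop("fit_circle: degenerate fit (non-positive radius)")
  list(center = unname(center), radius = sqrt(r2))
}

perp2 <- function(v) c(-v[2], v[1])

# Total-least-squares line through points: returns unit direction and a
# point on the line (the centroid).
tls_line <- function(pts) {
  c0 <- colMeans(pts)
  d <- sweep(pts, 2, c0)
  e <- eigen(crossprod(d), symmetric = TRUE)
  list(point = c0, direction = e$vectors[, 1])
}

# Project polyline points into an axis frame (origin, unit direction d):
# returns u (along d) and v (along perp(d)).
axis_frame <- function(pts, origin, d) {
  rel <- sweep(pts, 2, origin)
  cbind(u = rel %*% d, v = rel %*% perp2(d))
}

#' Conventional hip geometric measurements from a 65-point contour
#'
#' Computes the four standard AP-radiograph measurements:
#' * **head diameter** - twice the radius of the least-squares circle
#'   through the femoral-head landmarks;
#' * **neck width** - the minimum distance between the superior and
#'   inferior neck border polylines measured perpendicular to the neck
#'   axis, where the neck axis runs from the head centre through the
#'   midpoint of the narrowest crossing (found iteratively);
#' * **shaft width** - the mean perpendicular distance between the medial
#'   and lateral shaft border polylines across the paired measurement
#'   levels, relative to the total-least-squares shaft axis through the
#'   border midpoints;
#' * **neck-shaft angle** - the angle between the neck axis (pointing at
#'   the head) and the distally directed shaft axis, reported in the
#'   anatomical (obtuse) convention in degrees.
#'
#' All four are invariant under rigid motion; the three widths scale with
#' the contour and the angle is scale-invariant.
#'
#' @param contour a [femur_contour()] (or 65 x 2 matrix).
#' @param map an [index_map()] describing the landmark scheme.
#' @return data.frame row of class `hip_measurements` with columns
#'   `subject_id`, `side`, `head_diameter`, `neck_width`, `shaft_width`,
#'   `neck_shaft_angle`.
#' @export
measure_hip <- function(contour, map) {
  pts <- contour_points(contour)
  if (nrow(pts) != map$n_points) stop("measure_hip: contour/index_map size mismatch")
  head_fit <- fit_circle(pts[map$head, , drop = FALSE])
  up <- pts[map$neck_upper, , drop = FALSE]
  lo <- pts[map$neck_lower, , drop = FALSE]
  if (nrow(up) < 2 || nrow(lo) < 2) stop("measure_hip: need >= 2 points per neck border")

  # Neck axis: head centre -> narrowest-crossing midpoint, iterated.
  nmid <- (pts[map$neck_axis_anchor[1], ] + pts[map$neck_axis_anchor[2], ]) / 2
  neck_width <- NA_real_
  for (iter in seq_len(12)) {
    d <- head_fit$center - nmid
    nd <- sqrt(sum(d^2))
    if (nd == 0) stop("measure_hip: degenerate neck axis")
    d <- d / nd
    fu <- axis_frame(up, nmid, d)
    fl <- axis_frame(lo, nmid, d)
    ur <- c(max(min(fu[, 1]), min(fl[, 1])), min(max(fu[, 1]), max(fl[, 1])))
    if (ur[1] >= ur[2]) stop("measure_hip: neck borders do not overlap along the axis")
    grid <- seq(ur[1], ur[2], length.out = 400)
    ou <- order(fu[, 1]); ol <- order(fl[, 1])
    vu <- stats::approx(fu[ou, 1], fu[ou, 2], xout = grid, ties = "ordered")$y
    vl <- stats::approx(fl[ol, 1], fl[ol, 2], xout = grid, ties = "ordered")$y
    w <- abs(vu - vl)
    i0 <- which.min(w)
    neck_width <- w[i0]
    nmid_new <- nmid + grid[i0] * d + ((vu[i0] + vl[i0]) / 2) * perp2(d)
    if (sqrt(sum((nmid_new - nmid)^2)) < 1e-10) { nmid <- nmid_new; break }
    nmid <- nmid_new
  }
  neck_dir <- head_fit$center - nmid
  neck_dir <- neck_dir / sqrt(sum(neck_dir^2))

  med <- pts[map$shaft_medial, , drop = FALSE]
  lat <- pts[map$shaft_lateral, , drop = FALSE]
  anchor <- map$shaft_axis_anchor
  med_a <- med[anchor, , drop = FALSE]
  lat_a <- lat[anchor, , drop = FALSE]
  if (nrow(med_a) < 2) stop("measure_hip: need >= 2 shaft anchor pairs")
  mid <- (med_a + lat_a) / 2
  ln <- tls_line(mid)
  ds <- ln$direction
  # Orient distally: index 1 of the shaft pairing is the distal end.
  if (sum((mid[1, ] - mid[nrow(mid), ]) * ds) < 0) ds <- -ds
  nrm <- perp2(ds)
  shaft_width <- mean(abs((med_a - lat_a) %*% nrm))

  ang <- acos(pmin(pmax(sum(neck_dir * ds), -1), 1)) * 180 / pi
  if (ang < 90) ang <- 180 - ang

  id <- if (inherits(contour, "femur_contour")) contour$subject_id else "unknown"
  side <- if (inherits(contour, "femur_contour")) contour$side else NA_character_
  out <- data.frame(subject_id = id, side = side,
                    head_diameter = 2 * head_fit$radius,
                    neck_width = neck_width,
                    shaft_width = shaft_width,
                    neck_shaft_angle = ang,
                    stringsAsFactors = FALSE)
  class(out) <- c("hip_measurements", class(out))
  out
}

#' Measure both hips of every subject in a dataset
#'
#' @param contours list of [combined_contour()]s (or adjusted point
#'   matrices via `points_override`).
#' @param map an [index_map()].
#' @param points_override optional named list of 130 x 2 matrices
#'   replacing each subject's landmark coordinates (e.g. adjusted points).
#' @return data.frame with one row per femur.
#' @export
measure_dataset <- function(contours, map, points_override = NULL) {
  rows <- lapply(contours, function(cc) {
    pts <- if (!is.null(points_override)) points_override[[cc$subject_id]] else cc$points
    sides <- split_combined(pts)
    sides$left$subject_id <- cc$subject_id
    sides$right$subject_id <- cc$subject_id
    rbind(measure_hip(sides$left, map), measure_hip(sides$right, map))
  })
  do.call(rbind, rows)
}

#' Paired left-right asymmetry statistics
#'
#' For a single measurement on the two sides of one subject:
#' `mu = (m_l + m_r) / 2`, the absolute difference `AD = |m_l - m_r|`,
#' and the absolute percent asymmetry `AA% = |m_l - m_r| / mu * 100`.
#'
#' @param m_l,m_r positive measurement values for the left and right side.
#' @param measurement optional measurement name.
#' @return data.frame row with `measurement`, `m_l`, `m_r`, `mu`,
#'   `abs_difference`, `aa_percent`.
#' @export
asymmetry_stats <- function(m_l, m_r, measurement = NA_character_) {
  if (!is.finite(m_l) || !is.finite(m_r) || m_l <= 0 || m_r <= 0) {
    stop("asymmetry_stats: measurement values must be positive")
  }
  mu <- (m_l + m_r) / 2
  ad <- abs(m_l - m_r)
  data.frame(measurement = measurement, m_l = m_l, m_r = m_r, mu = mu,
             abs_difference = ad, aa_percent = ad / mu * 100,
             stringsAsFactors = FALSE)
}

hip_measure_names <- c("head_diameter", "neck_width", "shaft_width", "neck_shaft_angle")

#' Per-subject asymmetry table for a measured dataset
#'
#' @param measurements data.frame from [measure_dataset()].
#' @return data.frame with one row per subject x measurement.
#' @export
dataset_asymmetry <- function(measurements) {
  ids <- unique(measurements$subject_id)
  rows <- lapply(ids, function(id) {
    ml <- measurements[measurements$subject_id == id & measurements$side == "left", ]
    mr <- measurements[measurements$subject_id == id & measurements$side == "right", ]
    if (nrow(ml) != 1 || nrow(mr) != 1) return(NULL)  # missing a side
    do.call(rbind, lapply(hip_measure_names, function(m) {
      cbind(subject_id = id, asymmetry_stats(ml[[m]], mr[[m]], measurement = m))
    }))
  })
  do.call(rbind, rows)
}

#' Cohort summary of measurement values, AD and AA%
#'
#' Per measurement: mean and SD of the per-femur values, of the per-subject
#' absolute differences and of the absolute percent asymmetries, each with
#' a normal-approximation 95% confidence interval of the mean
#' (`mean +/- 1.96 * SD / sqrt(n)`).
#'
#' @param measurements data.frame from [measure_dataset()] (>= 2 subjects).
#' @return data.frame with one row per measurement.
#' @export
summarize_cohort <- function(measurements) {
  asym <- dataset_asymmetry(measurements)
  if (is.null(asym) || length(unique(asym$subject_id)) < 2) {
    stop("summarize_cohort: need at least 2 complete subjects")
  }
  ci <- function(v) {
    n <- length(v)
    half <- 1.96 * stats::sd(v) / sqrt(n)
    c(mean(v) - half, mean(v) + half)
  }
  rows <- lapply(hip_measure_names, function(m) {
    vals <- measurements[[m]]
    a <- asym[asym$measurement == m, ]
    vci <- ci(vals); adci <- ci(a$abs_difference); aaci <- ci(a$aa_percent)
    data.frame(measurement = m,
               n_femurs = length(vals), n_subjects = nrow(a),
               value_mean = mean(vals), value_sd = stats::sd(vals),
               value_ci_lo = vci[1], value_ci_hi = vci[2],
               ad_mean = mean(a$abs_difference), ad_sd = stats::sd(a$abs_difference),
               ad_ci_lo = adci[1], ad_ci_hi = adci[2],
               aa_mean = mean(a$aa_percent), aa_sd = stats::sd(a$aa_percent),
               aa_ci_lo = aaci[1], aa_ci_hi = aaci[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Paired before/after comparison of absolute differences
#'
#' Two-sided paired t-test of the per-subject absolute left-right
#' differences before vs after the positioning adjustment, per
#' measurement.
#'
#' @param measurements_before,measurements_after data.frames from
#'   [measure_dataset()] on the original and adjusted landmarks.
#' @return data.frame with per-measurement mean AD before/after, the
#'   paired t statistic and p-value.
#' @export
compare_adjustment <- function(measurements_before, measurements_after) {
  ab <- dataset_asymmetry(measurements_before)
  aa <- dataset_asymmetry(measurements_after)
  rows <- lapply(hip_measure_names, function(m) {
    b <- ab[ab$measurement == m, ]
    a <- aa[aa$measurement == m, ]
    merged <- merge(b[, c("subject_id", "abs_difference")],
                    a[, c("subject_id", "abs_difference")],
                    by = "subject_id", suffixes = c("_before", "_after"))
    d <- merged$abs_difference_before - merged$abs_difference_after
    tt <- if (stats::sd(d) == 0) list(statistic = NA_real_, p.value = NA_real_) else
      stats::t.test(merged$abs_difference_before, merged$abs_difference_after,
                    paired = TRUE)
    data.frame(measurement = m,
               ad_mean_before = mean(merged$abs_difference_before),
               ad_mean_after = mean(merged$abs_difference_after),
               paired_t = unname(tt$statistic), p_value = tt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
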