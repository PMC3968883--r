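#' Configuration for the synthetic landmark generator
#'
#' Defines the statistical structure the analysis assumes: shared
#' bilateral anatomy with small independent per-point left-right noise,
#' oppositional positioning artefacts (in-plane pelvic rotation and
#' along-border shaft sliding), and a global similarity pose per image.
#' Defaults emulate an adult-female hip cohort: template dimensions are
#' head diameter 51.6 mm, neck width 35.3 mm, shaft width 37.0 mm,
#' neck-shaft angle 126.7 deg, with anatomical SDs of 1.7 mm (head
#' radius), 2.9 mm, 3.2 mm and 5.8 deg respectively.
#'
#' @param n_subjects number of subjects.
#' @param seed integer seed; (config, seed) fully determines the dataset.
#' @param anatomy_sds list: `head_radius_sd`, `neck_width_sd`,
#'   `shaft_width_sd` (mm), `neck_shaft_angle_sd` (deg), `global_size_sd`
#'   (fraction, log-normal size factor shared by both sides).
#' @param lr_noise_sd independent per-point, per-coordinate left-right
#'   anatomical noise SD (mm).
#' @param positioning list: `pelvic_rotation_sd` (deg; in-plane rotation
#'   of both femurs about their own centroids by the same image-frame
#'   angle, which is oppositional relative to the mirror symmetry),
#'   `projection_coupling` (apparent neck-shaft-angle change, in degrees
#'   per degree of pelvic rotation, applied with opposite sign on the two
#'   sides; this is the first-order projective consequence of the 3D
#'   rotation -- a pure in-plane rotation is removed again by any
#'   per-femur similarity alignment and would leave left-right shape
#'   metrics untouched), `shaft_slide_sd` (mm; arc-length
#'   re-parameterisation of the shaft landmarks along the shaft borders),
#'   `slide_prevalence` (fraction of subjects with any slide),
#'   `slide_bilateral_prob` (probability a slide affects both sides, with
#'   independent offsets).
#' @param pose list: `global_rotation_sd` (deg), `translation_sd` (mm),
#'   `scale_sd` (fraction, log-normal) for the per-image similarity pose.
#' @param template named list of [make_template()] arguments overriding
#'   the template defaults.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 100L, seed = 1L,
                             anatomy_sds = list(),
                             lr_noise_sd = 0.3,
                             positioning = list(),
                             pose = list(),
                             template = list()) {
  an <- utils::modifyList(list(head_radius_sd = 1.7, neck_width_sd = 2.9,
                               shaft_width_sd = 3.2, neck_shaft_angle_sd = 5.8,
                               global_size_sd = 0.03), anatomy_sds)
  po <- utils::modifyList(list(pelvic_rotation_sd = 3, projection_coupling = 1,
                               shaft_slide_sd = 2,
                               slide_prevalence = 0.2, slide_bilateral_prob = 0.3),
                          positioning)
  ps <- utils::modifyList(list(global_rotation_sd = 2, translation_sd = 5,
                               scale_sd = 0.02), pose)
  cfg <- structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                        anatomy_sds = an, lr_noise_sd = lr_noise_sd,
                        positioning = po, pose = ps, template = template),
                   class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  sds <- c(unlist(cfg$anatomy_sds), cfg$lr_noise_sd,
           cfg$positioning$pelvic_rotation_sd, cfg$positioning$shaft_slide_sd,
           cfg$positioning$projection_coupling, unlist(cfg$pose))
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("synthetic_config: all SDs must be finite and >= 0")
  }
  pr <- c(cfg$positioning$slide_prevalence, cfg$positioning$slide_bilateral_prob)
  if (any(pr < 0 | pr > 1)) {
    stop("synthetic_config: prevalence/probabilities must lie in [0, 1]")
  }
  if (cfg$n_subjects < 1) stop("synthetic_config: n_subjects must be >= 1")
  invisible(cfg)
}

#' Generate a synthetic paired-femur landmark dataset
#'
#' Per subject: samples one shared anatomy (template dimensions plus a
#' global size factor), instantiates the left femur, mirrors it to create
#' the right femur (indices stay in anatomical correspondence), adds
#' independent per-point noise to each side, applies the positioning
#' artefacts (same image-frame in-plane rotation of both femurs about
#' their own centroids -- oppositional under the mirror relation; and,
#' with the configured prevalence, a shaft slide that translates the
#' shaft landmarks along the straight shaft borders of one or both
#' sides), assembles the 130-point combined configuration and applies a
#' global similarity pose.
#'
#' Randomness is drawn from one stream per subject derived from
#' `(seed, subject index)`, so subject `i` is identical regardless of
#' `n_subjects`.
#'
#' @param config a [synthetic_config()].
#' @return list with `contours` (list of [combined_contour()]s),
#'   `ground_truth` (data.frame of per-subject anatomy, rotation `rho_deg`,
#'   per-side slide offsets and pose parameters), `map` (the template
#'   [index_map()]), `config`.
#' @export
generate_dataset <- function(config) {
  validate_synthetic_config(config)
  tpl_args <- config$template
  an <- config$anatomy_sds
  po <- config$positioning
  ps <- config$pose
  base <- utils::modifyList(list(head_diameter = 51.6, neck_width = 35.3,
                                 shaft_width = 37.0, neck_shaft_angle = 126.7),
                            tpl_args)
  map <- NULL
  contours <- vector("list", config$n_subjects)
  gt <- vector("list", config$n_subjects)
  offset <- 65  # half-distance between femur centroids in the combined frame
  for (i in seq_len(config$n_subjects)) {
    set.seed((config$seed %% 1000003L) * 2011L + i)
    z <- stats::rnorm(5)
    rho <- po$pelvic_rotation_sd * stats::rnorm(1)
    hd <- base$head_diameter + 2 * an$head_radius_sd * z[1]
    nw <- max(base$neck_width + an$neck_width_sd * z[2], 5)
    sw <- max(base$shaft_width + an$shaft_width_sd * z[3], 5)
    nsa <- min(max(base$neck_shaft_angle + an$neck_shaft_angle_sd * z[4], 105), 150)
    hd <- max(hd, nw + 5)  # head must remain wider than the neck
    size_f <- exp(an$global_size_sd * z[5])  # z drawn unscaled so zero-SD configs share the stream
    tpl <- do.call(make_template,
                   utils::modifyList(tpl_args,
                                     list(head_diameter = hd, neck_width = nw,
                                          shaft_width = sw,
                                          neck_shaft_angle = nsa)))
    if (is.null(map)) map <- tpl$map
    raw <- contour_points(tpl$contour)  # isthmus at the origin
    # Apparent neck-shaft-angle change: projective consequence of the
    # pelvic rotation, opposite sign on the two sides. Implemented as a
    # smooth bend of the head/neck block about the isthmus, tapered to
    # zero at the neck/shaft junction so the silhouette stays continuous.
    dang <- po$projection_coupling * rho * pi / 180
    raw_l <- bend_neck(raw, tpl$map, +dang)
    raw_r <- bend_neck(raw, tpl$map, -dang)
    anat_l <- sweep(raw_l * size_f, 2, colMeans(raw_l * size_f))
    anat_r <- sweep(raw_r * size_f, 2, colMeans(raw_r * size_f))
    left <- sweep(anat_l, 2, c(-offset, 0), "+")
    right <- sweep(anat_r, 2, c(-offset, 0), "+")
    right[, 1] <- -right[, 1]  # mirror about x = 0; correspondence kept
    nsa_l <- nsa + po$projection_coupling * rho
    nsa_r <- nsa - po$projection_coupling * rho
    left  <- left  + config$lr_noise_sd * matrix(stats::rnorm(130), 65, 2)
    right <- right + config$lr_noise_sd * matrix(stats::rnorm(130), 65, 2)

    # Shaft slide: translate shaft landmarks along the (vertical) shaft
    # borders; silhouette unchanged, correspondence re-parameterised.
    u_slide <- stats::runif(1); u_bilat <- stats::runif(1); u_side <- stats::runif(1)
    deltas <- po$shaft_slide_sd * stats::rnorm(2)
    slide_l <- 0; slide_r <- 0
    if (u_slide < po$slide_prevalence && po$shaft_slide_sd > 0) {
      if (u_bilat < po$slide_bilateral_prob) {
        slide_l <- deltas[1]; slide_r <- deltas[2]
      } else if (u_side < 0.5) slide_l <- deltas[1] else slide_r <- deltas[2]
    }
    # Re-parameterise along each (vertical) border, clamped to the border
    # extent: the silhouette is unchanged, only the correspondence moves.
    slide_border <- function(pts, idx, delta) {
      y <- pts[idx, 2]
      pts[idx, 2] <- pmin(pmax(y + delta, min(y)), max(y))
      pts
    }
    if (slide_l != 0) {
      left <- slide_border(left, map$shaft_medial, slide_l)
      left <- slide_border(left, map$shaft_lateral, slide_l)
    }
    if (slide_r != 0) {
      right <- slide_border(right, map$shaft_medial, slide_r)
      right <- slide_border(right, map$shaft_lateral, slide_r)
    }

    # Pelvic rotation: same image-frame angle on both femurs, about each
    # femur's own centroid (oppositional under the mirror relation).
    left <- rotate_about(left, rho * pi / 180, colMeans(left))
    right <- rotate_about(right, rho * pi / 180, colMeans(right))

    comb <- rbind(left, right)
    # Global pose anchored at the (fixed) midline origin so it is an
    # imaging transform of the scene, independent of the landmark samples.
    theta <- ps$global_rotation_sd * stats::rnorm(1) * pi / 180
    sc <- exp(ps$scale_sd * stats::rnorm(1))
    tr <- ps$translation_sd * stats::rnorm(2)
    comb <- sweep(sc * rotate_about(comb, theta, c(0, 0)), 2, tr, "+")

    id <- sprintf("S%04d", i)
    sides <- split_combined(comb)
    sides$left$subject_id <- id; sides$right$subject_id <- id
    contours[[i]] <- combined_contour(sides$left, sides$right, subject_id = id)
    gt[[i]] <- data.frame(subject_id = id,
                          head_diameter = hd * size_f, neck_width = nw * size_f,
                          shaft_width = sw * size_f, neck_shaft_angle = nsa,
                          nsa_apparent_left = nsa_l, nsa_apparent_right = nsa_r,
                          size_factor = size_f,
                          rho_deg = rho, slide_left_mm = slide_l,
                          slide_right_mm = slide_r,
                          pose_rotation_deg = theta * 180 / pi,
                          pose_scale = sc, pose_tx = tr[1], pose_ty = tr[2],
                          stringsAsFactors = FALSE)
  }
  list(contours = contours, ground_truth = do.call(rbind, gt), map = map,
       config = config)
}

rotate_about <- function(pts, theta, center) {
  sweep(sweep(pts, 2, center) %*% t(rot_mat(theta)), 2, center, "+")
}

# Rotate the head/neck block about the isthmus (template origin) by
# `angle`, tapering linearly to zero along the neck borders towards the
# shaft junction: head landmarks turn fully, neck landmarks partially,
# shaft landmarks not at all.
bend_neck <- function(pts, map, angle) {
  if (angle == 0) return(pts)
  idx <- c(map$head, map$neck_lower, map$neck_upper)
  nl <- length(map$neck_lower); nu <- length(map$neck_upper)
  wts <- c(rep(1, length(map$head)),
           seq(0, 1, length.out = nl),        # neck_lower runs shaft -> head
           seq(1, 0, length.out = nu))        # neck_upper runs head -> shaft
  for (j in seq_along(idx)) {
    a <- angle * wts[j]
    if (a != 0) pts[idx[j], ] <- pts[idx[j], , drop = FALSE] %*% t(rot_mat(a))
  }
  pts
}
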