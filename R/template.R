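#' Parametric 65-point proximal femur template
#'
#' Deterministically constructs a left proximal femur contour from
#' geometric primitives: a circular femoral-head arc, concave neck borders
#' (parabolic flare about the isthmus), and parallel shaft borders, with
#' no trochanters. The contour is a single open polyline ordered distal
#' medial shaft -> inferior neck border -> head arc -> superior neck
#' border -> distal lateral shaft; the shaft cut is open. Default
#' dimensions are cohort-scale values for adult female hips; the
#' construction guarantees that [measure_hip()] with the returned
#' [index_map()] recovers `head_diameter` and `neck_shaft_angle` (the
#' head landmarks lie exactly on the construction circle, the neck
#' isthmus is sampled exactly, and the shaft borders are exactly
#' parallel).
#'
#' The frame is y-up with the shaft axis vertical (distal pointing down)
#' and the head medial-superior; the template is a left femur.
#'
#' @param head_diameter femoral head diameter, mm.
#' @param neck_width minimal neck width, mm.
#' @param shaft_width shaft width, mm.
#' @param neck_shaft_angle anatomical neck-shaft angle, degrees (90-180).
#' @param neck_length distance from the neck isthmus to the head centre
#'   along the neck axis, mm; default 1.15 x head radius.
#' @param neck_shaft_offset distance from the isthmus to the neck/shaft
#'   axis intersection along the neck axis, mm; default
#'   `1.4 * shaft_width / (2 * cos(neck_shaft_angle - 90 deg))`, which
#'   guarantees the neck borders reach the shaft borders distally for any
#'   admissible angle.
#' @param shaft_length length of the sampled shaft segment, mm.
#' @param neck_flare parabolic widening coefficient of the neck borders
#'   (1/mm); larger values flare faster. Default
#'   `0.2 * (head_radius - neck_width/2) / neck_length^2`, which keeps
#'   the border inside the head circle at the head end so the head/neck
#'   junction always exists.
#' @return list with `contour` (a [femur_contour()], 65 points) and `map`
#'   (the matching [index_map()]).
#' @export
make_template <- function(head_diameter = 51.6, neck_width = 35.3,
                          shaft_width = 37.0, neck_shaft_angle = 126.7,
                          neck_length = NULL, neck_shaft_offset = NULL,
                          shaft_length = 56, neck_flare = NULL) {
  if (neck_shaft_angle <= 90 || neck_shaft_angle >= 180) {
    stop("make_template: neck_shaft_angle must lie in (90, 180) degrees")
  }
  r <- head_diameter / 2
  nw2 <- neck_width / 2
  sw2 <- shaft_width / 2
  phi <- (neck_shaft_angle - 90) * pi / 180
  if (is.null(neck_length)) neck_length <- 1.15 * r
  if (is.null(neck_shaft_offset)) neck_shaft_offset <- 1.4 * sw2 / cos(phi)
  if (is.null(neck_flare)) neck_flare <- 0.2 * (r - nw2) / neck_length^2
  if (min(head_diameter, neck_width, shaft_width, neck_length, shaft_length) <= 0) {
    stop("make_template: lengths must be positive")
  }
  if (nw2 >= r) stop("make_template: neck half-width must be smaller than head radius")
  if (neck_flare <= 0) stop("make_template: neck_flare must be positive")
  dn <- c(cos(phi), sin(phi))       # neck axis, isthmus -> head
  vv <- c(-sin(phi), cos(phi))      # superior-lateral normal
  H <- neck_length * dn             # head centre; isthmus at origin
  Q <- -neck_shaft_offset * dn      # neck/shaft axis intersection
  x_med <- Q[1] + sw2
  x_lat <- Q[1] - sw2
  w <- function(u) nw2 + neck_flare * u^2

  # Neck/shaft junctions: where each neck border reaches its shaft border
  # line (quadratic in the neck-axis coordinate u; take the negative root
  # closest to the isthmus).
  quad_root <- function(a, b, c) {
    disc <- b^2 - 4 * a * c
    if (disc < 0) stop("make_template: neck borders never reach the shaft (adjust parameters)")
    # numerically stable quadratic roots (a can be very small)
    q <- -(b + sign(b) * sqrt(disc)) / 2
    roots <- c(q / a, if (q != 0) c / q else -b / a)
    roots <- roots[is.finite(roots) & roots < 0]
    if (length(roots) == 0) stop("make_template: no distal neck/shaft junction")
    max(roots)
  }
  sphi <- sin(phi); cphi <- cos(phi)
  u_med <- quad_root(neck_flare * sphi, cphi, nw2 * sphi - x_med)
  u_lat <- quad_root(neck_flare * sphi, -cphi, nw2 * sphi + x_lat)

  # Head/neck junction: first intersection of the border offset curve with
  # the head circle, scanning from the isthmus towards the head centre.
  gfun <- function(u) (u - neck_length)^2 + w(u)^2 - r^2
  us <- seq(0, neck_length, length.out = 400)
  gs <- gfun(us)
  cross <- which(gs[-1] <= 0 & gs[-length(gs)] > 0)
  if (length(cross) == 0) stop("make_template: neck borders do not meet the head circle")
  u_head <- stats::uniroot(gfun, c(us[cross[1]], us[cross[1] + 1]), tol = 1e-12)$root

  lower_border <- function(u) t(vapply(u, function(ui) ui * dn - w(ui) * vv, numeric(2)))
  upper_border <- function(u) t(vapply(u, function(ui) ui * dn + w(ui) * vv, numeric(2)))

  p_lo_head <- drop(lower_border(u_head))
  p_up_head <- drop(upper_border(u_head))
  th_lo <- atan2(p_lo_head[2] - H[2], p_lo_head[1] - H[1])
  th_up <- atan2(p_up_head[2] - H[2], p_up_head[1] - H[1])
  while (th_up <= th_lo) th_up <- th_up + 2 * pi
  arc <- seq(th_lo, th_up, length.out = 25)[2:24]
  head_pts <- cbind(H[1] + r * cos(arc), H[2] + r * sin(arc))

  # Border u-grids include u = 0 exactly so the isthmus is a landmark and
  # the measured minimum neck width equals the construction parameter.
  u_lower <- c(seq(u_med, 0, length.out = 4), seq(0, u_head, length.out = 5)[-1])
  u_upper <- c(seq(u_head, 0, length.out = 4), seq(0, u_lat, length.out = 5)[-1])
  neck_lower_pts <- lower_border(u_lower)
  neck_upper_pts <- upper_border(u_upper)

  y_junction <- min(neck_lower_pts[1, 2], neck_upper_pts[8, 2])
  y_top <- y_junction - 2
  y_bot <- y_top - shaft_length
  ylev <- seq(y_bot, y_top, length.out = 13)
  shaft_medial_pts <- cbind(x_med, ylev)          # distal -> proximal
  shaft_lateral_pts <- cbind(x_lat, rev(ylev))    # proximal -> distal

  pts <- rbind(shaft_medial_pts, neck_lower_pts, head_pts, neck_upper_pts,
               shaft_lateral_pts)
  stopifnot(nrow(pts) == 65)
  map <- index_map(head = 22:44,
                   neck_upper = 45:52,
                   neck_lower = 14:21,
                   shaft_medial = 1:13,
                   shaft_lateral = 65:53,
                   neck_axis_anchor = c(17L, 48L),
                   n_points = 65L)
  list(contour = femur_contour(pts, subject_id = "template", side = "left"),
       map = map)
}
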