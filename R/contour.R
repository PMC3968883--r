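#' Landmark contour containers
#'
#' A `femur_contour` holds the ordered 65-point outline of one proximal
#' femur; a `combined_contour` holds the 130-point concatenation of the
#' left (rows 1-65) and right (rows 66-130) femurs of one subject, with
#' row `i` and row `i + 65` anatomically corresponding. Point order is
#' anatomical correspondence: index `i` refers to the same anatomical
#' location on every contour.
#'
#' @param points numeric matrix with 2 columns (x, y) in millimetres.
#' @param subject_id character scalar.
#' @param side `"left"` or `"right"`.
#' @param n_points expected number of points (65 for a single femur).
#' @return An object of class `femur_contour` or `combined_contour`.
#' @export
femur_contour <- function(points, subject_id = "unknown", side = c("left", "right"),
                          n_points = 65L) {
  side <- match.arg(side)
  points <- as_points(points)
  if (nrow(points) != n_points) {
    stop("femur_contour: expected ", n_points, " points, got ", nrow(points))
  }
  structure(list(subject_id = as.character(subject_id), side = side,
                 points = points),
            class = "femur_contour")
}

#' @rdname femur_contour
#' @param left,right `femur_contour` objects for the two sides of one subject.
#' @export
combined_contour <- function(left, right, subject_id = left$subject_id) {
  stopifnot(inherits(left, "femur_contour"), inherits(right, "femur_contour"))
  if (nrow(left$points) != nrow(right$points)) {
    stop("combined_contour: sides have different point counts")
  }
  structure(list(subject_id = as.character(subject_id),
                 points = rbind(left$points, right$points)),
            class = "combined_contour")
}

as_points <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("points must be an n x 2 matrix")
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) stop("points contain non-finite coordinates")
  dimnames(points) <- NULL
  points
}

#' Split a combined configuration into its two femur contours
#'
#' @param combined a `combined_contour` or a 130-row point matrix.
#' @return list with elements `left` and `right` (`femur_contour`s).
#' @export
split_combined <- function(combined) {
  pts <- contour_points(combined)
  n <- nrow(pts)
  if (n %% 2 != 0) stop("combined configuration must have an even point count")
  h <- n %/% 2
  id <- if (inherits(combined, "combined_contour")) combined$subject_id else "unknown"
  list(left  = femur_contour(pts[seq_len(h), , drop = FALSE], id, "left",  n_points = h),
       right = femur_contour(pts[h + seq_len(h), , drop = FALSE], id, "right", n_points = h))
}

#' Extract the coordinate matrix from a contour-like object
#'
#' @param x a `femur_contour`, `combined_contour`, or a plain matrix.
#' @return numeric n x 2 matrix.
#' @export
contour_points <- function(x) {
  if (inherits(x, c("femur_contour", "combined_contour"))) return(x$points)
  as_points(x)
}

#' Reflect a contour about a vertical axis
#'
#' Maps `x` to `2 * axis_x - x` and leaves `y` untouched. Point order is
#' unchanged: landmark indices are anatomical, not geometric, so the
#' mirrored contour stays in correspondence with the original. The side
#' label is toggled because a mirrored left femur has the geometry of a
#' right femur.
#'
#' @param contour a `femur_contour` (or point matrix).
#' @param axis_x x-position (mm) of the vertical mirror axis. Default 0.
#' @return reflected contour of the same class.
#' @export
reflect_contour <- function(contour, axis_x = 0) {
  pts <- contour_points(contour)
  pts[, 1] <- 2 * axis_x - pts[, 1]
  if (inherits(contour, "femur_contour")) {
    femur_contour(pts, contour$subject_id,
                  side = if (contour$side == "left") "right" else "left",
                  n_points = nrow(pts))
  } else {
    pts
  }
}

#' @export
print.femur_contour <- function(x, ...) {
  cat(sprintf("<femur_contour> subject %s, %s side, %d points\n",
              x$subject_id, x$side, nrow(x$points)))
  invisible(x)
}

#' @export
print.combined_contour <- function(x, ...) {
  cat(sprintf("<combined_contour> subject %s, %d points (left rows 1-%d, right rows %d-%d)\n",
              x$subject_id, nrow(x$points), nrow(x$points) %/% 2,
              nrow(x$points) %/% 2 + 1, nrow(x$points)))
  invisible(x)
}

#' Landmark-scheme index map
#'
#' Names the anatomical regions of a 65-point femur contour by landmark
#' index. The scheme is configuration-driven because different landmarking
#' protocols place the region borders differently; defaults follow the
#' synthetic template produced by [make_template()].
#'
#' `shaft_medial` and `shaft_lateral` are ordered distal-to-proximal and
#' are paired positionally (element `j` of each lies at the same level of
#' the shaft). `neck_upper` and `neck_lower` run along the superior and
#' inferior neck borders. `neck_axis_anchor` gives one point on each neck
#' border at the approximate isthmus (used to seed the neck-axis search);
#' `shaft_axis_anchor` lists the paired shaft indices used for the shaft
#' axis fit.
#'
#' @param head integer indices of the femoral-head arc.
#' @param neck_upper,neck_lower integer index sequences of the neck borders.
#' @param shaft_medial,shaft_lateral paired distal-to-proximal shaft border
#'   indices (equal length).
#' @param neck_axis_anchor length-2 integer vector (lower, upper isthmus point).
#' @param shaft_axis_anchor positions (into the shaft pairing) used for the
#'   shaft axis; defaults to all pairs.
#' @param n_points number of landmarks in the scheme (default 65).
#' @return object of class `index_map`.
#' @export
index_map <- function(head, neck_upper, neck_lower, shaft_medial, shaft_lateral,
                      neck_axis_anchor = c(neck_lower[1], neck_upper[length(neck_upper)]),
                      shaft_axis_anchor = seq_along(shaft_medial),
                      n_points = 65L) {
  im <- list(head = as.integer(head),
             neck_upper = as.integer(neck_upper),
             neck_lower = as.integer(neck_lower),
             shaft_medial = as.integer(shaft_medial),
             shaft_lateral = as.integer(shaft_lateral),
             neck_axis_anchor = as.integer(neck_axis_anchor),
             shaft_axis_anchor = as.integer(shaft_axis_anchor),
             n_points = as.integer(n_points))
  validate_index_map(im)
  structure(im, class = "index_map")
}

validate_index_map <- function(im) {
  idx <- c(im$head, im$neck_upper, im$neck_lower, im$shaft_medial, im$shaft_lateral)
  if (any(idx < 1L | idx > im$n_points)) {
    stop("index_map: indices must lie in [1, ", im$n_points, "]")
  }
  if (length(im$shaft_medial) != length(im$shaft_lateral)) {
    stop("index_map: shaft_medial and shaft_lateral must be paired (equal length)")
  }
  regions <- list(im$head, im$neck_upper, im$neck_lower, im$shaft_medial, im$shaft_lateral)
  if (anyDuplicated(unlist(regions))) {
    stop("index_map: regions must be disjoint")
  }
  invisible(im)
}

#' Read / write an index map file
#'
#' Plain-text `name: indices` format, one region per line; indices are
#' comma-separated integers where `a-b` denotes an inclusive run
#' (`head: 22-44`). Lines beginning with `#` are ignored.
#'
#' @param path file path.
#' @export
read_index_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([a-z_]+)\\s*:\\s*(.+)$", ln))[[1]]
    if (length(m) != 3) stop("read_index_map: cannot parse line: ", ln)
    toks <- strsplit(m[3], ",")[[1]]
    idx <- unlist(lapply(trimws(toks), function(t) {
      if (grepl("-", t, fixed = TRUE)) {
        ab <- as.integer(strsplit(t, "-", fixed = TRUE)[[1]])
        seq(ab[1], ab[2])
      } else as.integer(t)
    }))
    fields[[m[2]]] <- idx
  }
  np <- if (!is.null(fields$n_points)) fields$n_points else 65L
  index_map(head = fields$head, neck_upper = fields$neck_upper,
            neck_lower = fields$neck_lower, shaft_medial = fields$shaft_medial,
            shaft_lateral = fields$shaft_lateral,
            neck_axis_anchor = if (is.null(fields$neck_axis_anchor))
              c(fields$neck_lower[1], fields$neck_upper[length(fields$neck_upper)])
              else fields$neck_axis_anchor,
            n_points = np)
}

#' @rdname read_index_map
#' @param im an `index_map`.
#' @export
write_index_map <- function(im, path) {
  fmt <- function(v) paste(v, collapse = ",")
  lines <- c(paste0("n_points: ", im$n_points),
             paste0("head: ", fmt(im$head)),
             paste0("neck_upper: ", fmt(im$neck_upper)),
             paste0("neck_lower: ", fmt(im$neck_lower)),
             paste0("shaft_medial: ", fmt(im$shaft_medial)),
             paste0("shaft_lateral: ", fmt(im$shaft_lateral)),
             paste0("neck_axis_anchor: ", fmt(im$neck_axis_anchor)))
  writeLines(lines, path)
  invisible(path)
}
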