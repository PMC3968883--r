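#' Read a .pts landmark file
#'
#' The dialect is: line 1 `version: 1`, line 2 `n_points: <N>`, line 3 `{`,
#' then N lines of `<x> <y>` (ASCII decimals, space separated), then `}`.
#' Coordinates are taken to be millimetres. Image-processing tools often
#' emit y-down coordinates; pass `y_down = TRUE` to negate y at import so
#' all internal math runs in a y-up frame.
#'
#' @param path file path.
#' @param subject_id,side metadata attached to the returned contour; if
#'   `side = NA` a bare point matrix is returned.
#' @param y_down logical; negate y coordinates at import.
#' @return a [femur_contour()] (or a point matrix when `side` is `NA`).
#' @export
read_pts <- function(path, subject_id = basename(path), side = "left", y_down = FALSE) {
  if (!file.exists(path)) stop("read_pts: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  perr <- function(lineno, msg) {
    stop(sprintf("read_pts: %s at %s line %d", msg, path, lineno))
  }
  if (length(lines) < 4) perr(length(lines), "truncated file")
  if (!grepl("^version:\\s*1\\s*$", lines[1])) perr(1, "malformed header (expected 'version: 1')")
  m <- regmatches(lines[2], regexec("^n_points:\\s*([0-9]+)\\s*$", lines[2]))[[1]]
  if (length(m) != 2) perr(2, "malformed header (expected 'n_points: <N>')")
  n <- as.integer(m[2])
  if (trimws(lines[3]) != "{") perr(3, "expected '{'")
  if (length(lines) < 4 + n) perr(length(lines), sprintf("expected %d coordinate lines", n))
  coords <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    toks <- strsplit(trimws(lines[3 + i]), "\\s+")[[1]]
    if (length(toks) != 2) perr(3 + i, "expected two coordinates")
    xy <- suppressWarnings(as.numeric(toks))
    if (any(is.na(xy))) perr(3 + i, "non-numeric token")
    coords[i, ] <- xy
  }
  if (trimws(lines[4 + n]) != "}") perr(4 + n, "expected '}'")
  if (y_down) coords[, 2] <- -coords[, 2]
  if (is.na(side)) return(coords)
  femur_contour(coords, subject_id = subject_id, side = side, n_points = n)
}

#' Write a .pts landmark file
#'
#' Coordinates are printed with six decimal places; the read/write
#' round-trip is lossless at that precision.
#'
#' @param contour a contour or point matrix.
#' @param path destination file path.
#' @export
write_pts <- function(contour, path) {
  pts <- contour_points(contour)
  lines <- c("version: 1",
             paste0("n_points: ", nrow(pts)),
             "{",
             sprintf("%.6f %.6f", pts[, 1], pts[, 2]),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' Load a paired landmark dataset from a manifest
#'
#' The manifest is a CSV with header `subject_id,left_pts,right_pts`;
#' paths are resolved relative to the manifest's directory unless
#' absolute. Subjects whose files cannot be read are skipped with a
#' warning; the loaded count is reported via `message()`.
#'
#' @param manifest path to the manifest CSV.
#' @param y_down negate y coordinates at import (see [read_pts()]).
#' @return list of [combined_contour()] objects (130 points each).
#' @export
load_dataset <- function(manifest, y_down = FALSE) {
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("subject_id", "left_pts", "right_pts")
  if (!all(need %in% names(tab))) {
    stop("load_dataset: manifest must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(tab) == 0) stop("load_dataset: empty manifest")
  if (anyDuplicated(tab$subject_id)) stop("load_dataset: duplicate subject_id in manifest")
  base <- dirname(manifest)
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  out <- list()
  skipped <- 0L
  for (i in seq_len(nrow(tab))) {
    id <- tab$subject_id[i]
    res <- tryCatch({
      l <- read_pts(resolve(tab$left_pts[i]),  subject_id = id, side = "left",  y_down = y_down)
      r <- read_pts(resolve(tab$right_pts[i]), subject_id = id, side = "right", y_down = y_down)
      combined_contour(l, r, subject_id = id)
    }, error = function(e) {
      warning("load_dataset: skipping subject ", id, ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) skipped <- skipped + 1L else out[[length(out) + 1L]] <- res
  }
  message(sprintf("load_dataset: loaded %d subject(s), skipped %d", length(out), skipped))
  out
}

#' Write a dataset of combined contours as .pts files plus manifest
#'
#' @param contours list of [combined_contour()]s.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(contours, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(contours, function(cc) {
    sides <- split_combined(cc)
    lf <- paste0(cc$subject_id, "_left.pts")
    rf <- paste0(cc$subject_id, "_right.pts")
    write_pts(sides$left,  file.path(dir, lf))
    write_pts(sides$right, file.path(dir, rf))
    data.frame(subject_id = cc$subject_id, left_pts = lf, right_pts = rf,
               stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
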