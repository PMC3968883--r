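#' Run the full left-right symmetry analysis
#'
#' End-to-end replica of the study workflow: load (or simulate) paired
#' landmark data, build the combined 130-point model, score and exclude
#' oppositional-asymmetric modes, re-evaluate all point positions, build
#' single 65-point models before and after adjustment, and produce the
#' symmetry and hip-geometry reports. Every stage is persisted under
#' `out_dir` so each analysis can be re-run in isolation, and the whole
#' run is deterministic given the synthetic config seed.
#'
#' @param out_dir output directory (created; existing files overwritten).
#' @param manifest path to a dataset manifest CSV (exclusive with
#'   `synthetic`).
#' @param synthetic a [synthetic_config()] (exclusive with `manifest`).
#' @param map an [index_map()] for the geometry stage; defaults to the
#'   template map for synthetic data. When `NULL` and data come from a
#'   manifest, the geometry stage is skipped with a message.
#' @param variance_threshold retained-variance fraction for all models.
#' @param exclude integer mode indices to exclude manually; `NULL` (the
#'   default) selects all modes classified oppositional.
#' @param sym_threshold,opp_threshold oppositional classification cut-offs.
#' @param family_alpha family-wise alpha for the per-mode tests.
#' @param y_down negate y at import (manifest input only).
#' @return (invisibly) list with all intermediate objects: `contours`,
#'   `combined` (model + fits), `adjustment`, `report_before`,
#'   `report_after`, `geometry` (or `NULL`), `log`.
#' @export
run_full_analysis <- function(out_dir, manifest = NULL, synthetic = NULL,
                              map = NULL, variance_threshold = 0.95,
                              exclude = NULL, sym_threshold = 0.7,
                              opp_threshold = -0.7, family_alpha = 0.05,
                              y_down = FALSE) {
  if (is.null(manifest) == is.null(synthetic)) {
    stop("run_full_analysis: supply exactly one of manifest or synthetic")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "input"
  log <- list(stages = character(0))
  note <- function(...) message(sprintf(...))
  result <- tryCatch({
    if (!is.null(synthetic)) {
      gen <- generate_dataset(synthetic)
      contours <- gen$contours
      if (is.null(map)) map <- gen$map
      utils::write.csv(gen$ground_truth, file.path(out_dir, "ground_truth.csv"),
                       row.names = FALSE)
      write_dataset(contours, file.path(out_dir, "input"))
      log$seed <- synthetic$seed
    } else {
      contours <- load_dataset(manifest, y_down = y_down)
      if (length(contours) < 3) stop("need at least 3 loadable subjects")
    }
    log$n_subjects <- length(contours)
    note("[input] %d subjects", length(contours))

    stage <- "combined_model"
    cm <- build_combined_model(contours, variance_threshold = variance_threshold)
    write_ssm(cm$model, file.path(out_dir, "combined_model.ssm"))
    k <- length(cm$model$variances)
    vt <- data.frame(mode_index = seq_len(k), variance = cm$model$variances,
                     cumulative_fraction = cumsum(cm$model$variances) /
                       cm$model$total_variance)
    utils::write.csv(vt, file.path(out_dir, "variance_table.csv"), row.names = FALSE)
    log$k_combined <- k
    note("[combined_model] %d modes reach %.0f%% of variance", k,
         100 * variance_threshold)

    stage <- "mode_classification"
    adj <- adjust_dataset(cm, exclude = exclude, sym_threshold = sym_threshold,
                          opp_threshold = opp_threshold)
    utils::write.csv(adj$mode_scores, file.path(out_dir, "mode_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(adj$effect, file.path(out_dir, "adjustment_effect.csv"),
                     row.names = FALSE)
    adj_dir <- file.path(out_dir, "adjusted")
    adj_contours <- Map(function(cc, pts) {
      sides <- split_combined(pts)
      sides$left$subject_id <- cc$subject_id
      sides$right$subject_id <- cc$subject_id
      combined_contour(sides$left, sides$right, subject_id = cc$subject_id)
    }, contours, adj$adjusted)
    write_dataset(adj_contours, adj_dir)
    log$excluded_modes <- adj$excluded
    log$mean_adjustment_effect_mm <- mean(adj$effect$effect_mm)
    note("[adjust] excluded mode(s): %s; mean effect %.2f mm",
         if (length(adj$excluded)) paste(adj$excluded, collapse = ",") else "none",
         mean(adj$effect$effect_mm))

    stage <- "symmetry_before"
    rep_before <- symmetry_report(contours, variance_threshold = variance_threshold,
                                  family_alpha = family_alpha)
    stage <- "symmetry_after"
    rep_after <- symmetry_report(contours, adjusted = adj$adjusted,
                                 variance_threshold = variance_threshold,
                                 family_alpha = family_alpha)
    utils::write.csv(rep_before$modes, file.path(out_dir, "symmetry_before.csv"),
                     row.names = FALSE)
    utils::write.csv(rep_after$modes, file.path(out_dir, "symmetry_after.csv"),
                     row.names = FALSE)
    utils::write.csv(merge(rep_before$lr_distances, rep_after$lr_distances,
                           by = "subject_id", suffixes = c("_before", "_after")),
                     file.path(out_dir, "lr_distances.csv"), row.names = FALSE)
    log$mean_lr_before_mm <- rep_before$mean_lr_distance
    log$mean_lr_after_mm <- rep_after$mean_lr_distance
    note("[symmetry] mean left-right distance %.2f mm before, %.2f mm after",
         rep_before$mean_lr_distance, rep_after$mean_lr_distance)

    stage <- "geometry"
    geometry <- NULL
    if (!is.null(map)) {
      mb <- measure_dataset(contours, map)
      ma <- measure_dataset(contours, map, points_override = adj$adjusted)
      geometry <- list(before = summarize_cohort(mb), after = summarize_cohort(ma),
                       comparison = compare_adjustment(mb, ma),
                       measurements_before = mb, measurements_after = ma)
      utils::write.csv(geometry$before, file.path(out_dir, "geometry_before.csv"),
                       row.names = FALSE)
      utils::write.csv(geometry$after, file.path(out_dir, "geometry_after.csv"),
                       row.names = FALSE)
      utils::write.csv(geometry$comparison,
                       file.path(out_dir, "geometry_comparison.csv"),
                       row.names = FALSE)
    } else {
      note("[geometry] skipped: no index map supplied")
    }

    stage <- "log"
    write_run_log(log, file.path(out_dir, "run_log.json"))
    invisible(list(contours = contours, combined = cm, adjustment = adj,
                   report_before = rep_before, report_after = rep_after,
                   geometry = geometry, log = log))
  }, error = function(e) {
    stop(sprintf("run_full_analysis failed at stage '%s': %s (partial outputs in %s)",
                 stage, conditionMessage(e), out_dir), call. = FALSE)
  })
  result
}

# Minimal flat JSON writer so the run log needs no extra dependencies.
write_run_log <- function(log, path) {
  fmt <- function(v) {
    if (length(v) == 0) return("null")
    if (length(v) > 1) return(paste0("[", paste(vapply(v, fmt, character(1)),
                                                collapse = ", "), "]"))
    if (is.character(v)) sprintf("\"%s\"", v) else format(v, digits = 15)
  }
  keys <- names(log)
  body <- paste(sprintf("  \"%s\": %s", keys,
                        vapply(log[keys], fmt, character(1))), collapse = ",\n")
  writeLines(c("{", body, "}"), path)
  invisible(path)
}
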