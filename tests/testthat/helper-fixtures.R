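# Shared fixtures and independent oracles, all built in code.

# Random open-curve shape: a perturbed arc so polylines are non-degenerate.
random_shape <- function(n = 10, scale = 10) {
  t <- sort(stats::runif(n, 0, 2))
  cbind(scale * cos(t) + stats::rnorm(n, sd = 0.3 * scale),
        scale * sin(t) + stats::rnorm(n, sd = 0.3 * scale))
}

random_similarity <- function(scale = NULL) {
  similarity_transform(scale = if (is.null(scale)) exp(stats::rnorm(1, sd = 0.3)) else scale,
                       rotation = stats::runif(1, -pi, pi),
                       translation = stats::rnorm(2, sd = 20))
}

# Dense-sampling oracle for the point-to-polyline distance: samples each
# segment at `per_segment` points and takes the minimum point-to-sample
# distance. Independent of the closed-form projection used by the package.
dense_curve_oracle <- function(points, curve, per_segment = 1e4) {
  n <- nrow(curve)
  samples <- do.call(rbind, lapply(seq_len(n - 1), function(i) {
    tt <- seq(0, 1, length.out = per_segment)
    cbind(curve[i, 1] + tt * (curve[i + 1, 1] - curve[i, 1]),
          curve[i, 2] + tt * (curve[i + 1, 2] - curve[i, 2]))
  }))
  vapply(seq_len(nrow(points)), function(j) {
    sqrt(min((samples[, 1] - points[j, 1])^2 + (samples[, 2] - points[j, 2])^2))
  }, numeric(1))
}

# Small synthetic dataset for fixture use.
tiny_dataset <- function(n = 6, seed = 11, ...) {
  generate_dataset(synthetic_config(n_subjects = n, seed = seed, ...))
}

# Null generator config: independent sides (no shared anatomy variation,
# no positioning artefacts), only per-point noise.
null_sides_config <- function(n, seed, lr_noise_sd = 0.3) {
  synthetic_config(n_subjects = n, seed = seed,
                   anatomy_sds = list(head_radius_sd = 0, neck_width_sd = 0,
                                      shaft_width_sd = 0, neck_shaft_angle_sd = 0,
                                      global_size_sd = 0),
                   lr_noise_sd = lr_noise_sd,
                   positioning = list(pelvic_rotation_sd = 0, shaft_slide_sd = 0,
                                      slide_prevalence = 0))
}

# Artefact-free config but with anatomy variation kept.
no_artefact_config <- function(n, seed) {
  synthetic_config(n_subjects = n, seed = seed,
                   positioning = list(pelvic_rotation_sd = 0, shaft_slide_sd = 0,
                                      slide_prevalence = 0))
}

# Hand-built combined shape_model with prescribed modes, for score tests.
toy_combined_model <- function(modes, variances = rev(seq_len(ncol(modes)))) {
  modes <- apply(modes, 2, function(v) v / sqrt(sum(v^2)))
  structure(list(n_points = nrow(modes) / 2L,
                 mean_shape = numeric(nrow(modes)),
                 modes = modes,
                 variances = as.numeric(variances),
                 total_variance = sum(variances),
                 variance_threshold = 0.95,
                 n_shapes = 100L),
            class = "shape_model")
}
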