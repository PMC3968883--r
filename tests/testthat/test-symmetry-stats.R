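test_that("Welch test matches the hand-computed closed form", {
  # groups {0,2} vs {1,3}: means 1 and 2, each variance 2, so
  # t = (1-2)/sqrt(2/2 + 2/2) = -1/sqrt(2), Welch-Satterthwaite df = 2
  out <- per_mode_tests(matrix(c(0, 2), 2, 1), matrix(c(1, 3), 2, 1))
  expect_equal(out$welch_t, -1 / sqrt(2), tolerance = 1e-9)
  expect_equal(out$welch_df, 2, tolerance = 1e-9)
  expect_equal(out$p_value, 2 * pt(-1 / sqrt(2), df = 2), tolerance = 1e-9)
})

test_that("identical groups give t = 0 and p = 1", {
  x <- matrix(c(0.3, 1.2, -0.5, 2.0), 4, 1)
  out <- per_mode_tests(x, x)
  expect_equal(out$welch_t, 0)
  expect_equal(out$p_value, 1)
  expect_false(out$significant_raw)
})

test_that("degenerate zero-variance modes are flagged, not tested", {
  z <- matrix(1, 4, 1)
  out <- per_mode_tests(z, z)
  expect_true(out$degenerate)
  expect_true(is.na(out$p_value))
})

test_that("Welch df never drops below min(n1, n2) - 1", {
  set.seed(30)
  for (i in 1:20) {
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    out <- per_mode_tests(matrix(rnorm(n1, sd = runif(1, 0.1, 3))),
                          matrix(rnorm(n2, sd = runif(1, 0.1, 3))))
    expect_gte(out$welch_df, min(n1, n2) - 1 - 1e-9)
  }
})

test_that("Bonferroni significance implies raw significance", {
  set.seed(31)
  b_left <- matrix(rnorm(200), 20, 10)
  b_right <- matrix(rnorm(200, mean = rep(c(0, 2), each = 100)), 20, 10)
  out <- per_mode_tests(b_left, b_right)
  expect_equal(attr(out, "bonferroni_alpha"), 0.005)
  expect_true(all(!out$significant_bonferroni | out$significant_raw))
  expect_true(any(out$significant_bonferroni))
})

test_that("per-mode SDs separate population spread from left-right difference", {
  set.seed(32)
  n <- 2000
  shared <- matrix(rnorm(n * 2), n, 2)
  # paired identical sides: zero left-right difference
  out0 <- mode_sd_comparison(shared, shared)
  expect_equal(out0$sd_lr_difference, c(0, 0))
  # independent unit-variance sides: sd of difference ~ sqrt(2) * overall
  bl <- matrix(rnorm(n * 2), n, 2); br <- matrix(rnorm(n * 2), n, 2)
  out1 <- mode_sd_comparison(bl, br)
  expect_equal(out1$sd_lr_difference / out1$sd_overall, c(sqrt(2), sqrt(2)),
               tolerance = 0.1)
})

test_that("left-right distance vanishes for an exact mirror pair", {
  tpl <- make_template()
  left <- tpl$contour$points
  right <- reflect_contour(left, axis_x = 40)
  expect_equal(left_right_distance(left, right), 0, tolerance = 1e-9)
})

test_that("left-right distance is invariant to rigid motion of either side
           and to rescaling of the right side", {
  set.seed(33)
  gen <- tiny_dataset(2, seed = 33)
  pts <- gen$contours[[1]]$points
  left <- pts[1:65, ]; right <- pts[66:130, ]
  d0 <- left_right_distance(left, right)
  rigid <- similarity_transform(1, 0.7, c(12, -4))
  expect_equal(left_right_distance(apply_similarity(rigid, left), right), d0,
               tolerance = 1e-6)
  any_sim <- similarity_transform(1.7, -1.1, c(-20, 8))
  expect_equal(left_right_distance(left, apply_similarity(any_sim, right)), d0,
               tolerance = 1e-6)
})

test_that("a constant outward-normal offset is recovered as the mean distance", {
  tpl <- make_template()
  left <- tpl$contour$points
  n <- nrow(left)
  # outward normals from neighbouring points along the open contour
  tangents <- rbind(left[2, ] - left[1, ],
                    left[3:n, ] - left[1:(n - 2), ],
                    left[n, ] - left[n - 1, ])
  normals <- cbind(tangents[, 2], -tangents[, 1])
  normals <- normals / sqrt(rowSums(normals^2))
  right_geom <- left + 0.5 * normals
  # the raw point-to-curve distance recovers the constructed offset
  expect_equal(point_to_curve_distance(right_geom, left), 0.5, tolerance = 0.05)
  # the paired metric similarity-aligns first, so a near-uniform inflation
  # is partially absorbed: it can only come out smaller
  right <- reflect_contour(right_geom, axis_x = 0)
  expect_lte(left_right_distance(left, right), 0.5 + 1e-9)
})

test_that("single model on noise-free artefact-free data pairs sides exactly", {
  cfg <- synthetic_config(5, 77, lr_noise_sd = 0,
                          positioning = list(pelvic_rotation_sd = 0,
                                             shaft_slide_sd = 0,
                                             slide_prevalence = 0))
  gen <- generate_dataset(cfg)
  sm <- build_single_model(gen$contours)
  expect_equal(sm$b_left, sm$b_right, tolerance = 1e-6)
  d <- dataset_lr_distances(gen$contours)
  expect_equal(d$lr_distance_mm, rep(0, 5), tolerance = 1e-8)
})

test_that("retained mode count is reproducible across identical runs", {
  gen1 <- tiny_dataset(8, seed = 5)
  gen2 <- tiny_dataset(8, seed = 5)
  sm1 <- build_single_model(gen1$contours)
  sm2 <- build_single_model(gen2$contours)
  expect_identical(length(sm1$model$variances), length(sm2$model$variances))
  expect_equal(sm1$model$modes, sm2$model$modes, tolerance = 1e-12)
})

test_that("symmetry report wires distances, tests and Bonferroni together", {
  gen <- tiny_dataset(8, seed = 9)
  rep <- symmetry_report(gen$contours)
  expect_s3_class(rep, "symmetry_report")
  expect_equal(rep$n_subjects, 8)
  expect_equal(nrow(rep$modes), rep$k)
  expect_equal(rep$bonferroni_alpha, 0.05 / rep$k)
  expect_equal(rep$mean_lr_distance, mean(rep$lr_distances$lr_distance_mm))
  expect_true(all(!rep$modes$significant_bonferroni | rep$modes$significant_raw))
})
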