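test_that("point-to-curve distance handles exact and perpendicular cases", {
  sh <- random_shape(12)
  expect_equal(point_to_curve_distance(sh, sh), 0)
  seg <- rbind(c(-1, 0), c(1, 0))
  expect_equal(point_to_curve_distance(matrix(c(0, 1), 1, 2), seg), 1)
  # beyond the open end the nearest location is the end vertex
  expect_equal(point_to_curve_distance(matrix(c(2, 0), 1, 2), seg), 1)
  expect_error(point_to_curve_distance(sh[0, , drop = FALSE], seg), "empty")
})

test_that("point-to-curve distance matches a dense-sampling oracle", {
  set.seed(20)
  for (i in 1:10) {
    pts <- random_shape(8)
    curve <- random_shape(15)
    mine <- femsym:::point_to_polyline(pts, curve)
    oracle <- dense_curve_oracle(pts, curve, per_segment = 5e3)
    expect_equal(mine, oracle, tolerance = 1e-3)
  }
})

test_that("curve distance never exceeds corresponding-landmark distance", {
  set.seed(21)
  for (i in 1:20) {
    a <- random_shape(10)
    b <- a + matrix(rnorm(20, sd = 0.5), 10, 2)
    d_curve <- point_to_curve_distance(a, b)
    d_pt <- mean(sqrt(rowSums((a - b)^2)))
    expect_lte(d_curve, d_pt + 1e-12)
  }
})

test_that("combined distances are evaluated per femur segment", {
  gen <- tiny_dataset(2)
  pts <- gen$contours[[1]]$points
  # shift the right femur far away: per-segment evaluation keeps the left
  # distance zero, whole-curve evaluation would bridge the gap
  moved <- pts
  moved[66:130, 1] <- moved[66:130, 1] + 500
  d <- point_to_curve_distance(moved, moved, segments = list(1:65, 66:130))
  expect_equal(d, 0)
})

test_that("oppositional score is +1 for mirror modes, -1 for opposed modes", {
  set.seed(22)
  h <- 65
  dL <- matrix(rnorm(2 * h), h, 2)
  mirror_of <- function(d) cbind(-d[, 1], d[, 2])
  as_mode <- function(dL, dR) c(dL[, 1], dR[, 1], dL[, 2], dR[, 2])
  sym_mode <- as_mode(dL, mirror_of(dL))
  opp_mode <- as_mode(dL, -mirror_of(dL))
  model <- toy_combined_model(cbind(sym_mode, opp_mode))
  s1 <- oppositional_score(model, 1)
  s2 <- oppositional_score(model, 2)
  expect_equal(s1$score, 1, tolerance = 1e-12)
  expect_equal(s1$classification, "symmetric")
  expect_equal(s2$score, -1, tolerance = 1e-12)
  expect_equal(s2$classification, "oppositional")
})

test_that("oppositional score is invariant to the sign of the mode", {
  set.seed(23)
  v <- rnorm(260)
  m1 <- toy_combined_model(cbind(v))
  m2 <- toy_combined_model(cbind(-v))
  expect_equal(oppositional_score(m1, 1)$score, oppositional_score(m2, 1)$score,
               tolerance = 1e-12)
})

test_that("classification thresholds behave at their boundaries", {
  set.seed(24)
  v <- rnorm(260)
  model <- toy_combined_model(cbind(v))
  out <- classify_modes(model, sym_threshold = 1, opp_threshold = -1)
  expect_equal(out$classification, "indeterminate")
  expect_error(classify_modes(model, sym_threshold = -0.5, opp_threshold = 0.5),
               "opp_threshold")
  expect_error(oppositional_score(build_shape_model(replicate(4, random_shape(9),
                                                              simplify = FALSE)), 1),
               "combined")
})

test_that("excluding no modes reproduces the original points", {
  gen <- tiny_dataset(5)
  cm <- build_combined_model(gen$contours)
  for (i in seq_along(gen$contours)) {
    out <- exclude_modes_and_reevaluate(cm$model, cm$fits[[i]], integer(0))
    expect_equal(out, gen$contours[[i]]$points, tolerance = 1e-6)
  }
})

test_that("excluding all modes with zero residual leaves the posed mean", {
  gen <- tiny_dataset(4)
  cm <- build_combined_model(gen$contours)
  k <- length(cm$model$variances)
  fit <- cm$fits[[1]]
  fit$residual <- numeric(length(cm$model$mean_shape))
  out <- exclude_modes_and_reevaluate(cm$model, fit, seq_len(k))
  expect_equal(out, apply_similarity(fit$pose, vec_to_shape(cm$model$mean_shape)),
               tolerance = 1e-9)
  expect_error(exclude_modes_and_reevaluate(cm$model, fit, k + 1), "1\\.\\.")
})

test_that("excluding one mode displaces the unposed shape by exactly |b_j|", {
  gen <- tiny_dataset(6)
  cm <- build_combined_model(gen$contours)
  fit <- cm$fits[[3]]
  j <- 1
  full <- exclude_modes_and_reevaluate(cm$model, fit, integer(0))
  drop1 <- exclude_modes_and_reevaluate(cm$model, fit, j)
  unposed_diff <- apply_similarity(invert_similarity(fit$pose), full) -
    apply_similarity(invert_similarity(fit$pose), drop1)
  expect_equal(sqrt(sum(unposed_diff^2)), abs(fit$b[j]), tolerance = 1e-8)
})

test_that("adjustment effect is zero for identical or similarity-posed points", {
  gen <- tiny_dataset(3)
  pts <- gen$contours[[1]]$points
  expect_equal(adjustment_effect(pts, pts), 0, tolerance = 1e-12)
  moved <- apply_similarity(similarity_transform(1.2, 0.4, c(30, -10)), pts)
  expect_equal(adjustment_effect(pts, moved), 0, tolerance = 1e-9)
})

test_that("symmetry refinement unmixes a hand-mixed symmetric/opposed pair", {
  set.seed(25)
  h <- 65
  dL <- matrix(rnorm(2 * h), h, 2)
  as_mode <- function(dL, dR) c(dL[, 1], dR[, 1], dL[, 2], dR[, 2])
  sym_mode <- as_mode(dL, cbind(-dL[, 1], dL[, 2]))
  dL2 <- matrix(rnorm(2 * h), h, 2)
  opp_mode <- as_mode(dL2, -cbind(-dL2[, 1], dL2[, 2]))
  sym_mode <- sym_mode / sqrt(sum(sym_mode^2))
  opp_mode <- opp_mode / sqrt(sum(opp_mode^2))
  opp_mode <- opp_mode - sum(opp_mode * sym_mode) * sym_mode  # orthogonalise
  opp_mode <- opp_mode / sqrt(sum(opp_mode^2))
  ang <- 0.6  # mix heavily
  mixed <- cbind(cos(ang) * sym_mode + sin(ang) * opp_mode,
                 -sin(ang) * sym_mode + cos(ang) * opp_mode)
  model <- toy_combined_model(mixed, variances = c(10, 9.5))
  before <- classify_modes(model)
  expect_true(all(before$classification == "indeterminate"))
  refined <- symmetry_refine_modes(model, n_shapes = 100)
  after <- classify_modes(refined)
  expect_setequal(after$classification, c("symmetric", "oppositional"))
  # subspace unchanged
  expect_equal(abs(det(crossprod(mixed, refined$modes))), 1, tolerance = 1e-8)
})

test_that("symmetry refinement leaves noise-spanned mode pairs untouched", {
  set.seed(26)
  v1 <- rnorm(260); v2 <- rnorm(260)
  v2 <- v2 - sum(v1 * v2) / sum(v1^2) * v1
  model <- toy_combined_model(cbind(v1, v2), variances = c(5, 4.9))
  refined <- symmetry_refine_modes(model, n_shapes = 100)
  expect_equal(refined$modes, model$modes, tolerance = 1e-12)
})
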