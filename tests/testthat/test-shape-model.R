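test_that("similarity transforms compose, invert and round-trip", {
  set.seed(2)
  for (i in 1:10) {
    a <- random_similarity(); b <- random_similarity()
    pts <- random_shape(8)
    expect_equal(apply_similarity(compose_similarity(a, b), pts),
                 apply_similarity(a, apply_similarity(b, pts)), tolerance = 1e-10)
    expect_equal(apply_similarity(invert_similarity(a), apply_similarity(a, pts)),
                 pts, tolerance = 1e-9)
  }
})

test_that("least-squares similarity alignment recovers known transforms", {
  set.seed(3)
  src <- random_shape(12)
  expect_equal(align_similarity(src, src)$scale, 1, tolerance = 1e-12)
  expect_equal(align_similarity(src, src)$rotation, 0, tolerance = 1e-12)
  expect_equal(align_similarity(src, src)$translation, c(0, 0), tolerance = 1e-10)

  tr <- similarity_transform(2, 30 * pi / 180, c(4, -7))
  tgt <- apply_similarity(tr, src)
  est <- align_similarity(src, tgt)
  expect_equal(est$scale, 2, tolerance = 1e-8)
  expect_equal(est$rotation, 30 * pi / 180, tolerance = 1e-8)
  expect_equal(est$translation, c(4, -7), tolerance = 1e-7)

  expect_error(align_similarity(matrix(1, 5, 2), tgt[1:5, ]), "degenerate")
})

test_that("fitted similarity beats thousands of randomly perturbed transforms", {
  set.seed(4)
  src <- random_shape(10); tgt <- random_shape(10)
  best <- align_similarity(src, tgt)
  ssd <- function(tr) sum((apply_similarity(tr, src) - tgt)^2)
  base <- ssd(best)
  perturbed <- replicate(10000, {
    tr <- similarity_transform(best$scale * exp(rnorm(1, sd = 0.05)),
                               best$rotation + rnorm(1, sd = 0.05),
                               best$translation + rnorm(2, sd = 0.5))
    ssd(tr)
  })
  expect_true(all(perturbed >= base - 1e-9))
})

test_that("GPA fixes identical shapes and is order-insensitive", {
  set.seed(5)
  sh <- random_shape(9)
  copies <- replicate(5, sh, simplify = FALSE)
  g <- generalized_procrustes(copies)
  centred <- sweep(sh, 2, colMeans(sh))
  # mean equals the (centred, canonically rotated) common shape
  expect_equal(sort(as.numeric(dist(g$mean_shape))),
               sort(as.numeric(dist(centred))), tolerance = 1e-8)
  for (a in g$aligned) expect_equal(a, g$aligned[[1]], tolerance = 1e-8)

  two <- list(random_shape(9), random_shape(9))
  g12 <- generalized_procrustes(two)
  g21 <- generalized_procrustes(rev(two))
  expect_equal(g12$mean_shape, g21$mean_shape, tolerance = 1e-9)
})

test_that("GPA output is invariant to per-shape similarity perturbation", {
  set.seed(6)
  shapes <- replicate(8, random_shape(10), simplify = FALSE)
  g0 <- generalized_procrustes(shapes)
  # random rotations/translations; scales drawn freely, then renormalised
  # so the set's mean centroid size (the declared mm anchor of the common
  # frame) is preserved
  scales <- exp(rnorm(8, sd = 0.3))
  sizes <- vapply(shapes, femsym:::centroid_size, numeric(1))
  scales <- scales * mean(sizes) / mean(scales * sizes)
  pert <- Map(function(sh, sc) {
    apply_similarity(similarity_transform(sc, runif(1, -pi, pi), rnorm(2, sd = 30)), sh)
  }, shapes, scales)
  g1 <- generalized_procrustes(pert)
  expect_equal(g1$mean_shape, g0$mean_shape, tolerance = 1e-6)
  for (i in seq_along(shapes)) {
    expect_equal(g1$aligned[[i]], g0$aligned[[i]], tolerance = 1e-6)
  }
})

test_that("PCA model matches an independent decomposition of the covariance", {
  set.seed(7)
  shapes <- replicate(20, random_shape(10), simplify = FALSE)
  model <- build_shape_model(shapes, variance_threshold = 1.0)
  X <- do.call(rbind, lapply(shapes, shape_to_vec))
  Xc <- sweep(X, 2, colMeans(X))
  # oracle route: singular values of the centred data matrix
  sv <- svd(Xc)$d^2 / (nrow(X) - 1)
  k <- length(model$variances)
  expect_equal(model$variances, sv[seq_len(k)], tolerance = 1e-8)
  expect_equal(sum(sv), model$total_variance, tolerance = 1e-8)
  # orthonormal modes
  expect_equal(crossprod(model$modes), diag(k), tolerance = 1e-8)
  # full-rank model reconstructs every training shape exactly in the
  # model frame (coefficients by orthogonal projection, no residual)
  for (sh in shapes[1:5]) {
    v <- shape_to_vec(sh) - model$mean_shape
    b <- as.numeric(crossprod(model$modes, v))
    expect_equal(as.numeric(model$modes %*% b), v, tolerance = 1e-8)
  }
})

test_that("primal and dual PCA routes agree", {
  set.seed(8)
  # 2n = 20 < n_shapes = 30 uses the primal route; 2n = 40 > 15 the dual
  for (cfg in list(c(30, 10), c(15, 20))) {
    shapes <- replicate(cfg[1], random_shape(cfg[2]), simplify = FALSE)
    model <- build_shape_model(shapes, variance_threshold = 1.0)
    X <- do.call(rbind, lapply(shapes, shape_to_vec))
    Xc <- sweep(X, 2, colMeans(X))
    sv <- svd(Xc)$d^2 / (nrow(X) - 1)
    expect_equal(model$variances, sv[seq_along(model$variances)], tolerance = 1e-8)
    proj <- Xc %*% model$modes
    expect_equal(tcrossprod(proj, model$modes), Xc, tolerance = 1e-7)
  }
})

test_that("identical training shapes give a zero-variance, zero-mode model", {
  sh <- random_shape(8)
  model <- build_shape_model(replicate(4, sh, simplify = FALSE))
  expect_equal(model$total_variance, 0, tolerance = 1e-18)
  expect_length(model$variances, 0)
})

test_that("retention picks the minimal mode count reaching the threshold", {
  set.seed(9)
  shapes <- replicate(25, random_shape(12), simplify = FALSE)
  model <- build_shape_model(shapes, variance_threshold = 0.9)
  k <- length(model$variances)
  cum <- cumsum(model$variances) / model$total_variance
  expect_gte(cum[k], 0.9)
  if (k > 1) expect_lt(cum[k - 1], 0.9)
})

test_that("fit_shape recovers known coefficients and round-trips", {
  set.seed(10)
  shapes <- replicate(15, random_shape(10), simplify = FALSE)
  # align first: modes of an unaligned model span similarity directions,
  # making the (pose, b) decomposition non-identifiable
  shapes <- generalized_procrustes(shapes)$aligned
  model <- build_shape_model(shapes, variance_threshold = 0.95)
  k <- length(model$variances)
  # zero case: a posed mean
  pose <- random_similarity()
  posed_mean <- apply_similarity(pose, vec_to_shape(model$mean_shape))
  f0 <- fit_shape(model, posed_mean)
  expect_lt(max(abs(f0$b)), 1e-6)
  # inverse-crime recovery of b0 within +/- 3 SD
  b0 <- 2 * sqrt(model$variances) * seq(-1, 1, length.out = k)
  synth <- apply_similarity(pose, vec_to_shape(model$mean_shape +
                                                 as.numeric(model$modes %*% b0)))
  f1 <- fit_shape(model, synth)
  expect_equal(f1$b, b0, tolerance = 1e-6)
  # any shape round-trips through fit + reconstruct with residual
  novel <- random_shape(10)
  f2 <- fit_shape(model, novel)
  expect_equal(reconstruct_shape(model, f2), novel, tolerance = 1e-6)
})

test_that("mode_shape obeys the linear-model algebra", {
  set.seed(11)
  shapes <- replicate(12, random_shape(9), simplify = FALSE)
  model <- build_shape_model(shapes)
  expect_equal(mode_shape(model, 1, 0), vec_to_shape(model$mean_shape))
  plus <- mode_shape(model, 1, 2.5); minus <- mode_shape(model, 1, -2.5)
  expect_equal(plus + minus, 2 * vec_to_shape(model$mean_shape), tolerance = 1e-10)
  disp <- shape_to_vec(plus) - model$mean_shape
  expect_equal(sqrt(sum(disp^2)), 2.5 * sqrt(model$variances[1]), tolerance = 1e-10)
  expect_error(mode_shape(model, length(model$variances) + 1, 1), "out of range")
})

test_that("shape models serialise and deserialise exactly (ssm-v1)", {
  set.seed(12)
  shapes <- replicate(10, random_shape(8), simplify = FALSE)
  model <- build_shape_model(shapes)
  f <- withr::local_tempfile(fileext = ".ssm")
  write_ssm(model, f)
  expect_equal(readLines(f)[1], "ssm-v1")
  back <- read_ssm(f)
  expect_equal(back$mean_shape, model$mean_shape, tolerance = 1e-15)
  expect_equal(back$modes, model$modes, tolerance = 1e-15)
  expect_equal(back$variances, model$variances, tolerance = 1e-15)
  expect_equal(back$n_points, model$n_points)
})
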