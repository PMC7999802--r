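test_that("PCA retains the smallest component count reaching the variance target", {
  set.seed(21)
  X <- matrix(rnorm(6000), 2000, 3)           # isotropic: needs all 3
  expect_equal(fit_pca(X, 0.975)$k, 3L)
  Y <- cbind(rnorm(2000, sd = 40), rnorm(2000, sd = 1), rnorm(2000, sd = 1))
  expect_equal(fit_pca(Y, 0.975)$k, 1L)       # one dominant direction
  p <- fit_pca(X, 0.975)
  expect_equal(crossprod(p$rotation), diag(p$k), tolerance = 1e-10)
  # projection applied identically to train and test
  Z <- pca_apply(p, X[1:5, , drop = FALSE])
  expect_equal(dim(Z), c(5L, p$k))
})

test_that("background GMM training is deterministic and monotone in likelihood", {
  set.seed(22)
  X <- rbind(matrix(rnorm(600, -2), ncol = 2), matrix(rnorm(600, 2), ncol = 2))
  mp <- model_params(K = 5, L = 4)
  g1 <- fit_background_gmm(X, mp, seed = 99)
  g2 <- fit_background_gmm(X, mp, seed = 99)
  expect_identical(g1, g2)
  g3 <- fit_background_gmm(X, mp, seed = 100)
  expect_false(identical(g1$means, g3$means))
  expect_true(all(diff(g1$loglik) >= -1e-8))
  expect_equal(sum(g1$weights), 1, tolerance = 1e-12)
  expect_true(all(g1$vars >= mp$sigma2_sq))
  expect_error(fit_background_gmm(X[1:3, ], mp, 1), "exceeds")
})

test_that("GMM recovers a single tight Gaussian", {
  set.seed(23)
  mu_true <- c(1.5, -0.5)
  X <- cbind(rnorm(5000, mu_true[1]), rnorm(5000, mu_true[2]))
  g <- fit_background_gmm(X, model_params(K = 5, L = 4), seed = 3)
  centroid <- colSums(g$weights * g$means)
  expect_lt(sqrt(sum((centroid - mu_true)^2)), 0.2)
  # every component sits near the mean relative to the data SD
  expect_true(all(sqrt(rowSums(sweep(g$means, 2, mu_true)^2)) < 0.2))
})

test_that("GMM density integrates to one", {
  set.seed(24)
  X <- matrix(rnorm(800), ncol = 2)
  g <- fit_background_gmm(X, model_params(K = 3, L = 4), seed = 5)
  gr <- seq(-25, 25, length.out = 251)
  h <- gr[2] - gr[1]
  dens <- exp(gmm_logdensity(g, as.matrix(expand.grid(gr, gr))))
  expect_equal(sum(dens) * h^2, 1, tolerance = 0.02)
})

test_that("MAP adaptation interpolates means by the relevance rule", {
  set.seed(25)
  mp <- model_params(K = 1, L = 1, r = 16)
  X <- matrix(rnorm(200, 0, 1), ncol = 1)
  bg <- fit_background_gmm(X, mp, seed = 1)
  # n_k = r data points: adapted mean lands exactly midway
  cls <- matrix(rnorm(16, 5), ncol = 1)
  ad <- map_adapt(bg, cls, r = 16)
  expect_equal(ad$means[1, 1], (bg$means[1, 1] + mean(cls)) / 2,
               tolerance = 1e-10)
  # r -> Inf: background unchanged; r = 0: class sample mean
  expect_equal(map_adapt(bg, cls, r = 1e12)$means, bg$means, tolerance = 1e-9)
  expect_equal(map_adapt(bg, cls, r = 0)$means[1, 1], mean(cls),
               tolerance = 1e-10)
  expect_identical(ad$weights, bg$weights)
  expect_identical(ad$vars, bg$vars)
  expect_error(map_adapt(bg, X[0, , drop = FALSE], 16), "empty")
})

test_that("components attracting no data stay at the background", {
  set.seed(26)
  X <- rbind(matrix(rnorm(300, -10), ncol = 1), matrix(rnorm(300, 10), ncol = 1))
  bg <- fit_background_gmm(X, model_params(K = 2, L = 4), seed = 7)
  lo <- which.min(bg$means[, 1]); hi <- which.max(bg$means[, 1])
  cls <- matrix(rnorm(50, 10), ncol = 1)       # only feeds the upper component
  ad <- map_adapt(bg, cls, r = 16)
  expect_equal(ad$means[lo, ], bg$means[lo, ], tolerance = 1e-9)
  expect_false(isTRUE(all.equal(ad$means[hi, ], bg$means[hi, ])))
})

test_that("multiframe scoring matches the brute-force density computation", {
  set.seed(27)
  ctrl <- matrix(rnorm(400, 0), ncol = 4)
  pd <- matrix(rnorm(400, 1), ncol = 4)
  pair <- train_class_models(ctrl, pd, model_params(K = 3, L = 4), seed = 2)
  for (i in 1:5) {
    X <- matrix(rnorm(8 * 4, runif(1, -1, 2)), ncol = 4)
    expect_equal(score_multiframe(pair, X), score_brute(pair, X),
                 tolerance = 1e-10)
  }
})

test_that("score orientation and degenerate cases behave as specified", {
  set.seed(28)
  ctrl <- matrix(rnorm(300, 0), ncol = 3)
  pd <- matrix(rnorm(300, 2), ncol = 3)
  pair <- train_class_models(ctrl, pd, model_params(K = 2, L = 4), seed = 4)
  # identical class models give score zero
  same <- pair; same$pd <- same$control
  expect_equal(score_multiframe(same, matrix(rnorm(9), ncol = 3)), 0)
  # a frame at the PD bulk scores positive
  expect_gt(score_multiframe(pair, matrix(2, 1, 3)), 0)
  expect_error(score_multiframe(pair, matrix(0, 0, 3)), "no frames")
})

test_that("incidence scoring runs the same machinery on scalars", {
  set.seed(29)
  ctrl <- matrix(rnorm(60, 20, 5), ncol = 1)
  pd <- matrix(rnorm(60, 10, 5), ncol = 1)
  pair <- train_class_models(ctrl, pd, model_params(), seed = 6,
                             use_pca = FALSE)
  expect_gt(score_incidence(pair, 8), score_incidence(pair, 22))
  expect_identical(score_incidence(pair, 15), score_incidence(pair, 15))
})

test_that("fusion identities hold exactly", {
  s <- list(S_G1 = 1, S_G2 = 2, S_LM1 = -0.5, S_LM2 = 4)
  expect_equal(fuse_scores(s, alpha = 0.15, 3L), 1.3)
  expect_equal(fuse_scores(s, alpha = 0, 3L), s$S_G1)
  expect_equal(fuse_scores(s, 0.15, 8L) - fuse_scores(s, 0.15, 7L),
               0.15 * s$S_LM2)
  expect_equal(fuse_scores(s, 0.15, 8L),
               s$S_G1 + 0.15 * s$S_G2 + s$S_LM1 + 0.15 * s$S_LM2)
  s$S_LM1 <- NA_real_
  expect_true(is.na(fuse_scores(s, 0.15, 8L)))
  expect_false(is.na(fuse_scores(s, 0.15, 3L)))
  expect_error(fuse_scores(s, 0.15, 9L), "1..8")
})
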