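test_that("dispersion of an alternating-sign frame is exactly 1", {
  for (a in c(0.3, 1, 7)) {
    f <- matrix(rep(c(a, -a), 500), 3, 1000, byrow = TRUE)
    d <- dispersion(f)
    expect_equal(d$D, rep(1, 3), tolerance = 1e-12)
    expect_equal(d$n_valid, 1000L)
  }
})

test_that("dispersion of iid normal data matches E|X-Y| closed forms", {
  set.seed(42)
  # with the outlier gate inactive, D estimates E|X-Y| = 2/sqrt(pi)
  d <- colMeans(t(vapply(1:8, function(i)
    dispersion(matrix(rnorm(3000), 3), gamma5 = 10)$D, numeric(3L))))
  expect_equal(unname(d), rep(2 / sqrt(pi), 3), tolerance = 0.03)
  # the default gate excludes ~2 sd tails jointly over the three axes,
  # shrinking the expectation (Monte-Carlo reference value)
  d2 <- mean(vapply(1:8, function(i)
    dispersion(matrix(rnorm(3000), 3), gamma5 = 2)$D[1], 0))
  expect_equal(d2, 1.006, tolerance = 0.03)
})

test_that("dispersion equals the O(n^2) brute-force oracle", {
  set.seed(5)
  for (i in 1:20) {
    f <- matrix(rnorm(3 * 250, sd = runif(1, 0.5, 2)), 3)
    expect_equal(dispersion(f)$D, disp_brute(f), tolerance = 1e-10)
  }
})

test_that("dispersion is invariant to per-axis affine rescaling", {
  set.seed(6)
  f <- matrix(rnorm(3 * 400), 3)
  g <- f * c(3, 0.1, 40) + c(-2, 5, 100)
  expect_equal(dispersion(f)$D, dispersion(g)$D, tolerance = 1e-12)
})

test_that("dispersion rejects degenerate frames", {
  f <- matrix(rnorm(3 * 100), 3); f[2, ] <- 7
  expect_error(dispersion(f), "zero-variance")
})

test_that("channel-delay correlation matrix has the exact structural properties", {
  set.seed(8)
  f <- matrix(rnorm(3 * 1000), 3)
  R <- channel_delay_corr(f, d = 3, N = 15)
  expect_equal(dim(R), c(45L, 45L))
  expect_equal(R, t(R), tolerance = 1e-12)
  expect_equal(diag(R), rep(1, 45), tolerance = 1e-12)
  # perfectly correlated: shared ramp on all axes
  ramp <- matrix(rep(seq_len(1000), 3), 3, byrow = TRUE)
  expect_equal(channel_delay_corr(ramp, 1, 15), matrix(1, 45, 45),
               tolerance = 1e-9)
})

test_that("independent white-noise axes decorrelate at unit delay scale", {
  set.seed(10)
  f <- matrix(rnorm(3 * 1000), 3)
  R <- channel_delay_corr(f, 1, 15)
  off <- abs(R[upper.tri(R)])
  # r(k) of white noise at n~1000 is ~N(0, 1/n); |r| < 0.1 is ~3 sigma
  expect_gt(mean(off < 0.1), 0.95)
})

test_that("eigenspectrum conserves the per-scale trace and orders eigenvalues", {
  set.seed(12)
  p <- feature_params()
  f <- matrix(rnorm(3 * 1000, sd = 0.01), 3)
  ev <- eigenspectrum(f, p)
  expect_length(ev, 180L)
  for (j in 0:3) {
    s <- ev[j * 45 + 1:45]
    expect_equal(sum(s), 45, tolerance = 1e-6)
    expect_true(all(diff(s) <= 1e-10))
    expect_true(all(s >= 0))
  }
})

test_that("compiled eigenspectrum agrees with the R-level correlation route", {
  set.seed(13)
  f <- matrix(rnorm(3 * 1000), 3)
  for (d in c(1L, 7L)) {
    ev_cpp <- wristpd:::frame_eigenspectrum_cpp(f, d, 15L)
    ev_r <- sort(eigen(channel_delay_corr(f, d, 15), symmetric = TRUE,
                       only.values = TRUE)$values, decreasing = TRUE)
    expect_equal(as.numeric(ev_cpp), pmax(ev_r, 0), tolerance = 1e-8)
  }
})

test_that("a rank-1 frame concentrates the whole spectrum in one eigenvalue", {
  ramp <- matrix(rep(seq_len(1000), 3), 3, byrow = TRUE)
  ev <- eigenspectrum(ramp)
  for (j in 0:3) {
    s <- ev[j * 45 + 1:45]
    expect_equal(s[1], 45, tolerance = 1e-6)
    expect_true(all(s[-1] <= 1e-6))
  }
})

test_that("eigenspectrum is invariant to axis rescaling and permutation", {
  set.seed(14)
  f <- matrix(rnorm(3 * 1000), 3)
  ev <- eigenspectrum(f)
  expect_equal(eigenspectrum(f * c(10, 0.2, 3) + c(1, -4, 0)), ev,
               tolerance = 1e-8)
  expect_equal(eigenspectrum(f[c(3, 1, 2), ]), ev, tolerance = 1e-8)
})

test_that("incidence divides valid frame counts by days observed", {
  fr <- data.frame(kind = c("gait", "gait", "gait", "LM", "LM"),
                   valid = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  inc <- incidence(fr, 0.5)
  expect_equal(inc$gait_frames_per_day, 4)
  expect_equal(inc$lm_frames_per_day, 4)
  empty <- incidence(fr[0, ], 7)
  expect_equal(empty$gait_frames_per_day, 0)
  expect_equal(empty$lm_frames_per_day, 0)
  expect_equal(incidence(data.frame(kind = rep("gait", 140),
                                    valid = TRUE), 7)$gait_frames_per_day, 20)
  expect_error(incidence(fr, 0), "positive")
})

test_that("Cohen's d follows the PD-minus-control pooled-SD convention", {
  expect_equal(cohens_d(c(1, 2, 3), c(2, 3, 4)), -1)
  expect_equal(cohens_d(c(5, 6, 7, 8), c(5, 6, 7, 8)), 0)
  expect_equal(cohens_d(c(2, 3), c(1, 2)), sqrt(2))
  expect_equal(cohens_d(c(1, 2, 3), c(2, 3, 4)),
               -cohens_d(c(2, 3, 4), c(1, 2, 3)))
  expect_error(cohens_d(1, c(1, 2)), ">= 2")
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled")
})

test_that("hourly incidence bins by local hour of day", {
  t0 <- "2000-01-01T00:00:00Z"
  h <- hourly_incidence(c(10.2, 10.5, 10.9) * 3600, t0, 1)
  expect_equal(h[11], 3)
  expect_equal(sum(h), 3)
  # uniform frames over 24 h, 2 days -> flat
  h2 <- hourly_incidence(seq(0, 2 * 86400 - 1, by = 3600) + 1800, t0, 2)
  expect_equal(h2, rep(1, 24))
  # a non-midnight recording start shifts the bins
  h3 <- hourly_incidence(1800, "2000-01-01T09:00:00Z", 1)
  expect_equal(which(h3 > 0), 10L)
})
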