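# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately use naive O(n^2) / exhaustive formulations
# so they share no code path with the implementation.

# O(n^2) dispersion of one axis: mean |z(t1) - z(t2)| over ordered pairs of
# the valid set (self-pairs included), z-scored with the population SD.
disp_brute <- function(frame, gamma5 = 2) {
  z <- t(apply(frame, 1L, function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))))
  valid <- colSums(abs(z) < gamma5) == 3L
  vapply(1:3, function(a) {
    v <- z[a, valid]
    mean(abs(outer(v, v, "-")))
  }, 0)
}

# Direct evaluation of the windowed population SD / mean at one centre time.
energy_brute <- function(m, fs, t_center, tau1) {
  tt <- (seq_along(m) - 1) / fs
  w <- m[abs(tt - t_center) <= tau1]
  mu <- mean(w)
  list(sigma = sqrt(mean((w - mu)^2)), mu = mu, n = length(w))
}

# Pair-counting AUC with explicit loops; ties count 1/2.
auc_brute <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg)
    s <- s + if (p > n) 1 else if (p == n) 0.5 else 0
  s / (length(pos) * length(neg))
}

# Exhaustive threshold sweep for sensitivity at a given FPR bound.
sens_brute <- function(pos, neg, fpr) {
  best <- 0
  for (th in c(-Inf, pos, neg, Inf)) {
    if (mean(neg > th) <= fpr) best <- max(best, mean(pos > th))
  }
  best
}

# A 3-axis sinusoidal gait-like frame with given period (s).
sine_frame <- function(n = 1000L, fs = 100, period = 1.0, amp = 0.5,
                       phases = c(0, 1, 2)) {
  tt <- (seq_len(n) - 1) / fs
  do.call(rbind, lapply(phases, function(ph) amp * sin(2 * pi * tt / period + ph)))
}

# An energy series built directly from a sigma_m vector at 1 s hop.
energy_series <- function(sigma, hop = 1) {
  structure(list(times = (seq_along(sigma) - 1) * hop, sigma_m = sigma,
                 mu_m = rep(1, length(sigma)),
                 n_w = rep(2001L, length(sigma)), hop = hop),
            class = "wpd_energy")
}

# Brute-force multiframe log-likelihood-ratio via direct density sums.
score_brute <- function(pair, X) {
  Z <- zscore_apply(pair$zstats, as.matrix(X))
  if (!is.null(pair$pca)) Z <- pca_apply(pair$pca, Z)
  lik <- function(gmm) {
    vapply(seq_len(nrow(Z)), function(i) {
      sum(vapply(seq_along(gmm$weights), function(k) {
        gmm$weights[k] * prod(stats::dnorm(Z[i, ], gmm$means[k, ],
                                           sqrt(gmm$vars[k, ])))
      }, 0))
    }, 0)
  }
  log(mean(lik(pair$pd))) - log(mean(lik(pair$control)))
}

# Small two-class feature cohort built directly (no simulation): subjects
# carry gait dispersion frames, LM eigenspectrum-sized frames and
# incidences drawn from class-shifted Gaussians.
toy_cohort <- function(n_per_class = 8L, n_frames = 6L, dim_lm = 12L,
                       shift = 1, days = 1, seed = 1) {
  set.seed(seed)
  mk <- function(id, label) {
    s <- if (label == "PD") shift else 0
    ng <- n_frames + sample.int(3L, 1L)
    nl <- n_frames + sample.int(3L, 1L)
    structure(list(
      subject_id = id, label = label, sex = sample(c("M", "F"), 1L),
      t0 = "2000-01-01T00:00:00Z", days_observed = days,
      gait = list(times = sort(runif(ng, 0, days * 86400)),
                  disp = matrix(rnorm(ng * 3, 1 - 0.3 * s, 0.2), ng, 3L),
                  step_time_s = rep(0.5, ng)),
      lm = list(times = sort(runif(nl, 0, days * 86400)),
                eig = matrix(rnorm(nl * dim_lm, 2 + 0.3 * s, 0.3), nl, dim_lm)),
      incidence = list(gait_frames_per_day = ng / days - 2 * s,
                       lm_frames_per_day = nl / days + 2 * s,
                       days_observed = days),
      n_gait_frames = ng, n_lm_frames = nl, n_segments = 2L),
      class = "wpd_subject_features")
  }
  subs <- c(lapply(seq_len(n_per_class), function(i)
    mk(sprintf("C%02d", i), "control")),
    lapply(seq_len(n_per_class), function(i) mk(sprintf("P%02d", i), "PD")))
  cohort_features(subs)
}
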