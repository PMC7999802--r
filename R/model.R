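.logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

#' Fit a z-score transform
#' @param X Feature matrix (rows = observations).
#' @return A list with `mean` and `sd` per dimension (SDs below 1e-12 are
#'   replaced by 1 so constant dimensions pass through unscaled).
#' @export
zscore_fit <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2L, sd)
  s[!is.finite(s) | s < 1e-12] <- 1
  list(mean = mu, sd = s)
}

#' Apply a z-score transform fitted on training data
#' @param z A [zscore_fit()] result.
#' @param X Feature matrix.
#' @return The standardised matrix.
#' @export
zscore_apply <- function(z, X) {
  sweep(sweep(X, 2L, z$mean, "-"), 2L, z$sd, "/")
}

#' Fit a PCA projection retaining a fixed variance fraction
#'
#' Eigen-decomposition of the training covariance; retains the smallest
#' number of components whose cumulative explained variance reaches
#' `var_frac`. The projection is applied identically to training and test
#' data via [pca_apply()].
#'
#' @param X Training feature matrix (already z-scored by training stats).
#' @param var_frac Variance fraction to retain.
#' @return A `wpd_pca` list: `mean`, `rotation` (d x k, orthonormal
#'   columns), `k`, `explained` (cumulative variance fractions).
#' @export
fit_pca <- function(X, var_frac = 0.975) {
  if (nrow(X) < 2L) stop("PCA requires at least 2 training rows")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, "-")
  C <- crossprod(Xc) / nrow(Xc)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  cum <- cumsum(ev) / sum(ev)
  k <- which(cum >= var_frac - 1e-12)[1L]
  structure(list(mean = mu, rotation = e$vectors[, seq_len(k), drop = FALSE],
                 k = k, explained = cum),
            class = "wpd_pca")
}

#' Project data through a fitted PCA
#' @param p A [fit_pca()] object.
#' @param X Feature matrix (same standardisation as the training data).
#' @return The n x k score matrix.
#' @export
pca_apply <- function(p, X) {
  sweep(X, 2L, p$mean, "-") %*% p$rotation
}

# log w_k + log N(x; mu_k, diag Sigma_k) for all rows of X: n x K matrix.
.gmm_logdens <- function(gmm, X) {
  n <- nrow(X); K <- length(gmm$weights)
  out <- matrix(0, n, K)
  for (k in seq_len(K)) {
    sig <- gmm$vars[k, ]
    d <- sweep(X, 2L, gmm$means[k, ], "-")
    q <- rowSums(sweep(d^2, 2L, sig, "/"))
    out[, k] <- log(gmm$weights[k]) - 0.5 * (q + sum(log(2 * pi * sig)))
  }
  out
}

#' Log-density of a diagonal-covariance GMM
#' @param gmm A GMM from [fit_background_gmm()] or [map_adapt()].
#' @param X Feature matrix (rows = observations).
#' @return Vector of per-row log mixture densities.
#' @export
gmm_logdensity <- function(gmm, X) {
  ld <- .gmm_logdens(gmm, as.matrix(X))
  apply(ld, 1L, .logsumexp)
}

#' Fit the background GMM with batch EM
#'
#' Means are initialised at `K` distinct randomly selected training points
#' (seeded); diagonal covariances start at `sigma1_sq` (a deliberately
#' large spherical start on z-scored data, avoiding premature commitment);
#' weights start at `1/K`. Exactly `L` batch EM iterations are run, with
#' the covariance floor `sigma2_sq` enforced at every M-step.
#'
#' @param X Training matrix (rows = frames), z-scored.
#' @param params [model_params()].
#' @param seed Seed for the initial mean selection.
#' @return A `wpd_gmm` list: `weights`, `means` (K x d), `vars` (K x d),
#'   `loglik` (mean training log-likelihood at initialisation and after
#'   each EM iteration, length `L + 1`).
#' @export
fit_background_gmm <- function(X, params = model_params(), seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X); K <- params$K
  if (K > n) stop("K = ", K, " exceeds the number of training frames (", n, ")")
  init <- .with_seed(seed, sample.int(n, K))
  gmm <- structure(list(weights = rep(1 / K, K),
                        means = X[init, , drop = FALSE],
                        vars = matrix(params$sigma1_sq, K, d)),
                   class = "wpd_gmm")
  ll <- numeric(params$L + 1L)
  for (it in seq_len(params$L)) {
    ld <- .gmm_logdens(gmm, X)
    rowmax <- apply(ld, 1L, max)
    ll[it] <- mean(rowmax + log(rowSums(exp(ld - rowmax))))
    resp <- exp(ld - rowmax)
    resp <- resp / rowSums(resp)
    nk <- colSums(resp)
    for (k in seq_len(K)) {
      if (nk[k] < 1e-10) next  # empty component: leave untouched
      mu <- colSums(resp[, k] * X) / nk[k]
      v <- colSums(resp[, k] * X^2) / nk[k] - mu^2
      gmm$means[k, ] <- mu
      gmm$vars[k, ] <- pmax(v, params$sigma2_sq)
    }
    gmm$weights <- nk / n
  }
  ld <- .gmm_logdens(gmm, X)
  rowmax <- apply(ld, 1L, max)
  ll[params$L + 1L] <- mean(rowmax + log(rowSums(exp(ld - rowmax))))
  gmm$loglik <- ll
  gmm
}

#' MAP-adapt a background GMM to class data
#'
#' Single-pass mean-only adaptation: responsibilities under the background
#' give per-component counts `n_k` and data means `E_k[x]`; the adapted
#' mean is `a_k E_k[x] + (1 - a_k) m_k` with `a_k = n_k / (n_k + r)`.
#' Weights and covariances are kept from the background. Components that
#' attract no data are unchanged.
#'
#' @param background A fitted [fit_background_gmm()].
#' @param X Class training matrix (nonempty), same space as the background.
#' @param r Relevance parameter; a value of 0 reproduces the class sample
#'   means where `n_k > 0`, large values stay close to the background.
#' @return The adapted `wpd_gmm`.
#' @export
map_adapt <- function(background, X, r = 16) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("empty class data for MAP adaptation")
  ld <- .gmm_logdens(background, X)
  rowmax <- apply(ld, 1L, max)
  resp <- exp(ld - rowmax)
  resp <- resp / rowSums(resp)
  nk <- colSums(resp)
  adapted <- background
  for (k in seq_along(nk)) {
    if (nk[k] <= 0) next
    Ek <- colSums(resp[, k] * X) / nk[k]
    a <- nk[k] / (nk[k] + r)
    adapted$means[k, ] <- a * Ek + (1 - a) * background$means[k, ]
  }
  adapted$loglik <- NULL
  adapted
}

#' Train a class-model pair for one feature set
#'
#' Fits the training z-score transform, optionally a PCA projection
#' retaining `pca_var_frac` of the variance, a background GMM on all
#' training frames (both classes pooled), and MAP-adapts it into control
#' and PD models.
#'
#' @param control_X,pd_X Training frame matrices per class (rows = frames).
#' @param params [model_params()].
#' @param seed Seed for GMM initialisation.
#' @param use_pca Apply PCA (bypassed for 1-dimensional incidence
#'   features).
#' @return A `wpd_class_gmm_pair` list: `zstats`, `pca` (or NULL),
#'   `background`, `control`, `pd`.
#' @export
train_class_models <- function(control_X, pd_X, params = model_params(),
                               seed = 1L, use_pca = TRUE) {
  control_X <- as.matrix(control_X); pd_X <- as.matrix(pd_X)
  if (nrow(control_X) == 0L || nrow(pd_X) == 0L)
    stop("both classes need training frames")
  all_X <- rbind(control_X, pd_X)
  z <- zscore_fit(all_X)
  Z <- zscore_apply(z, all_X)
  pca <- NULL
  if (use_pca && ncol(Z) > 1L) {
    pca <- fit_pca(Z, params$pca_var_frac)
    Z <- pca_apply(pca, Z)
  }
  bg <- fit_background_gmm(Z, params, seed)
  nc <- nrow(control_X)
  ctrl <- map_adapt(bg, Z[seq_len(nc), , drop = FALSE], params$r)
  pd <- map_adapt(bg, Z[(nc + 1L):nrow(Z), , drop = FALSE], params$r)
  structure(list(zstats = z, pca = pca, background = bg,
                 control = ctrl, pd = pd),
            class = "wpd_class_gmm_pair")
}

.pair_project <- function(pair, X) {
  Z <- zscore_apply(pair$zstats, as.matrix(X))
  if (!is.null(pair$pca)) Z <- pca_apply(pair$pca, Z)
  Z
}

#' Multiframe log-likelihood-ratio score
#'
#' Per frame, each class likelihood is the mixture density under that
#' class's GMM; the net class likelihood is the arithmetic mean of the
#' frame likelihoods (computed with a stabilised log-sum-exp), and the
#' detection score is `log(mean PD likelihood) - log(mean control
#' likelihood)`. Larger scores are more PD-like.
#'
#' @param pair A [train_class_models()] pair.
#' @param X Subject frame matrix in the original feature space (>= 1 row).
#' @return The scalar score.
#' @export
score_multiframe <- function(pair, X) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("no frames to score")
  Z <- .pair_project(pair, X)
  lme <- function(gmm) .logsumexp(gmm_logdensity(gmm, Z)) - log(nrow(Z))
  lme(pair$pd) - lme(pair$control)
}

#' Incidence log-likelihood-ratio score
#'
#' The same GMM machinery applied to the one-dimensional frame-incidence
#' feature, with one observation per subject.
#'
#' @param pair A [train_class_models()] pair fitted on incidence values.
#' @param value The subject's incidence (frames/day; 0 is a valid value).
#' @return The scalar score.
#' @export
score_incidence <- function(pair, value) {
  score_multiframe(pair, matrix(value, 1L, 1L))
}

#' Feature combinations of the detection score grid
#'
#' @return Character vector naming combinations 1--8.
#' @export
score_combinations <- function() {
  c("S_G1", "S_G2", "S_G1+a*S_G2", "S_LM1", "S_LM2", "S_LM1+a*S_LM2",
    "S_G1+a*S_G2+S_LM1", "S_G1+a*S_G2+S_LM1+a*S_LM2")
}

#' Fuse component detection scores
#'
#' Component scores are summed, with weight `alpha` on the incidence
#' scores: e.g. combination 8 is `S_G1 + alpha*S_G2 + S_LM1 +
#' alpha*S_LM2`. Returns `NA` when a required component is unavailable for
#' the subject (such subjects are excluded from that combination's
#' evaluation).
#'
#' @param scores Named list or vector with elements `S_G1`, `S_G2`,
#'   `S_LM1`, `S_LM2` (NA where unavailable).
#' @param alpha Incidence fusion weight.
#' @param combination Integer 1--8 (rows of the score grid).
#' @return The fused scalar score, or `NA`.
#' @export
fuse_scores <- function(scores, alpha = 0.15, combination = 8L) {
  s <- scores
  g1 <- s[["S_G1"]]; g2 <- s[["S_G2"]]
  l1 <- s[["S_LM1"]]; l2 <- s[["S_LM2"]]
  switch(combination,
         g1,
         g2,
         g1 + alpha * g2,
         l1,
         l2,
         l1 + alpha * l2,
         g1 + alpha * g2 + l1,
         g1 + alpha * g2 + l1 + alpha * l2,
         stop("combination must be in 1..8"))
}
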