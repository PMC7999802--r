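#' Segmentation parameters
#'
#' Parameters governing the selection of gait and low-movement (LM) segments
#' and frames from the sliding-window standard deviation of the acceleration
#' magnitude. Durations are in seconds, acceleration thresholds in g, and
#' the autocorrelation peak threshold is a unitless correlation.
#'
#' @param tau1 Window size for local statistics, s. A sample at time `t'`
#'   belongs to the window centred at `t` when `|t - t'| <= tau1`.
#' @param tau2 Minimum gait segment duration, s.
#' @param tau3 Maximum tolerated subthreshold gap within a gait segment, s.
#' @param tau4 Minimum LM segment duration, s.
#' @param tau5 Frame duration, s.
#' @param tau6 Minimum autocorrelation peak delay, s.
#' @param tau7 Maximum autocorrelation peak delay, s.
#' @param gamma1 Minimum windowed magnitude SD for gait, g.
#' @param gamma2 Minimum windowed magnitude SD for LM, g.
#' @param gamma3 Maximum windowed magnitude SD for LM, g.
#' @param gamma4 Minimum gait autocorrelation peak height (normalised
#'   correlation, unitless).
#' @return A validated `wpd_seg_params` list.
#' @export
seg_params <- function(tau1 = 10, tau2 = 30, tau3 = 15, tau4 = 240,
                       tau5 = 10, tau6 = 0.21, tau7 = 1.75,
                       gamma1 = 0.05, gamma2 = 0.001, gamma3 = 0.03,
                       gamma4 = 0.1) {
  p <- list(tau1 = tau1, tau2 = tau2, tau3 = tau3, tau4 = tau4, tau5 = tau5,
            tau6 = tau6, tau7 = tau7, gamma1 = gamma1, gamma2 = gamma2,
            gamma3 = gamma3, gamma4 = gamma4)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("invalid segmentation parameter '", nm, "': must be a positive number")
  }
  if (!(p$gamma2 < p$gamma3))
    stop("invalid parameter 'gamma2'/'gamma3': requires gamma2 < gamma3")
  if (!(p$gamma3 < p$gamma1))
    stop("invalid parameter 'gamma3'/'gamma1': requires gamma3 < gamma1")
  if (!(p$tau6 < p$tau7))
    stop("invalid parameter 'tau6'/'tau7': requires tau6 < tau7")
  if (!(p$tau5 <= p$tau2))
    stop("invalid parameter 'tau5'/'tau2': requires tau5 <= tau2")
  structure(p, class = "wpd_seg_params")
}

#' Feature-extraction parameters
#'
#' @param gamma5 Dispersion outlier threshold in standard units; time points
#'   with any axis at or beyond `gamma5` standard deviations are excluded
#'   from the dispersion average.
#' @param M Number of acceleration channels.
#' @param N Number of delays per channel per delay scale.
#' @param delay_scales Delay spacing per scale, in samples; strictly
#'   increasing positive integers. One channel-delay correlation matrix is
#'   built per scale and the eigenspectra are concatenated.
#' @return A validated `wpd_feature_params` list.
#' @export
feature_params <- function(gamma5 = 2, M = 3, N = 15,
                           delay_scales = c(1L, 3L, 7L, 15L)) {
  if (!is.numeric(gamma5) || length(gamma5) != 1L || gamma5 <= 0)
    stop("invalid parameter 'gamma5': must be a positive number")
  if (!is.numeric(M) || length(M) != 1L || M < 1 || M != round(M))
    stop("invalid parameter 'M': must be an integer >= 1")
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != round(N))
    stop("invalid parameter 'N': must be an integer >= 2")
  ds <- as.integer(delay_scales)
  if (length(ds) < 1L || any(ds <= 0L) || any(diff(ds) <= 0L) ||
      any(ds != delay_scales))
    stop("invalid parameter 'delay_scales': must be strictly increasing positive integers")
  structure(list(gamma5 = gamma5, M = as.integer(M), N = as.integer(N),
                 delay_scales = ds),
            class = "wpd_feature_params")
}

#' Classifier and fusion parameters
#'
#' @param K Number of Gaussian mixture components.
#' @param L Number of batch EM iterations.
#' @param sigma1_sq Initial (large, spherical) GMM variance, applied to
#'   z-scored features.
#' @param sigma2_sq Variance floor applied elementwise to the diagonal
#'   covariances at every M-step.
#' @param r MAP relevance parameter for class adaptation.
#' @param alpha Weight applied to frame-incidence scores during fusion.
#' @param pca_var_frac Fraction of training variance the retained principal
#'   components must explain.
#' @param n_folds Number of cross-validation folds.
#' @param seed Master seed for fold assignment and GMM initialisation.
#' @return A validated `wpd_model_params` list.
#' @export
model_params <- function(K = 5, L = 4, sigma1_sq = 100, sigma2_sq = 0.01,
                         r = 16, alpha = 0.15, pca_var_frac = 0.975,
                         n_folds = 5, seed = 1L) {
  if (!is.numeric(K) || K < 1 || K != round(K))
    stop("invalid parameter 'K': must be an integer >= 1")
  if (!is.numeric(L) || L < 1 || L != round(L))
    stop("invalid parameter 'L': must be an integer >= 1")
  if (!is.numeric(sigma1_sq) || sigma1_sq <= 0)
    stop("invalid parameter 'sigma1_sq': must be positive")
  if (!is.numeric(sigma2_sq) || sigma2_sq <= 0 || sigma2_sq >= sigma1_sq)
    stop("invalid parameter 'sigma2_sq': requires 0 < sigma2_sq < sigma1_sq")
  if (!is.numeric(r) || r < 0)
    stop("invalid parameter 'r': must be nonnegative")
  if (!is.numeric(alpha) || alpha < 0)
    stop("invalid parameter 'alpha': must be nonnegative")
  if (!is.numeric(pca_var_frac) || pca_var_frac <= 0 || pca_var_frac > 1)
    stop("invalid parameter 'pca_var_frac': requires 0 < pca_var_frac <= 1")
  if (!is.numeric(n_folds) || n_folds < 2 || n_folds != round(n_folds))
    stop("invalid parameter 'n_folds': must be an integer >= 2")
  if (!is.numeric(seed) || seed != round(seed))
    stop("invalid parameter 'seed': must be an integer")
  structure(list(K = as.integer(K), L = as.integer(L),
                 sigma1_sq = sigma1_sq, sigma2_sq = sigma2_sq, r = r,
                 alpha = alpha, pca_var_frac = pca_var_frac,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "wpd_model_params")
}

#' Full pipeline configuration
#'
#' Bundles segmentation, feature and model parameters into one validated,
#' serialisable object used by every pipeline stage.
#'
#' @param seg Segmentation parameters from [seg_params()].
#' @param feat Feature parameters from [feature_params()].
#' @param model Model parameters from [model_params()].
#' @return A `wpd_config` list with elements `seg`, `feat`, `model`.
#' @export
wpd_config <- function(seg = seg_params(), feat = feature_params(),
                       model = model_params()) {
  stopifnot(inherits(seg, "wpd_seg_params"),
            inherits(feat, "wpd_feature_params"),
            inherits(model, "wpd_model_params"))
  structure(list(seg = seg, feat = feat, model = model),
            class = "wpd_config")
}

.config_fields <- function() {
  list(seg = names(formals(seg_params)),
       feat = names(formals(feature_params)),
       model = names(formals(model_params)))
}

#' Load a configuration file
#'
#' Reads a flat key-value YAML file in which every key is optional; keys not
#' present take their default values. Keys must belong to the parameter
#' vocabulary of [seg_params()], [feature_params()] or [model_params()].
#'
#' @param path Path to a YAML configuration file. An empty file (or one with
#'   no keys) yields the all-default configuration.
#' @return A validated [wpd_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("malformed config file: expected key: value pairs")
  fields <- .config_fields()
  known <- unlist(fields, use.names = FALSE)
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  build <- function(ctor, nms) do.call(ctor, raw[intersect(names(raw), nms)])
  wpd_config(seg = build(seg_params, fields$seg),
             feat = build(feature_params, fields$feat),
             model = build(model_params, fields$model))
}

#' Write a configuration to a YAML file
#'
#' The written file parses back (via [load_config()]) to an equal
#' configuration.
#'
#' @param config A [wpd_config()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "wpd_config"))
  flat <- c(unclass(config$seg), unclass(config$feat), unclass(config$model))
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @export
print.wpd_config <- function(x, ...) {
  cat("<wpd_config>\n")
  for (part in names(x)) {
    vals <- vapply(x[[part]], function(v) paste(format(v), collapse = ","), "")
    cat("  ", part, ": ", paste(names(vals), vals, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
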