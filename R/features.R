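#' Movement dispersion of a gait frame
#'
#' Each axis is z-scored over the frame (population SD). Time points where
#' any axis lies at or beyond `gamma5` standard units are excluded as
#' outliers; over the remaining valid set V the dispersion in axis i is the
#' mean absolute (L1) difference between all ordered pairs of z-scored
#' values, self-pairs included (normalisation `|V|^2`). Low dispersion
#' indicates a regular, rigid movement profile.
#'
#' @param frame A `3 x n` gait frame matrix.
#' @param gamma5 Outlier threshold in standard units.
#' @return A list: `D` (3 dispersion values, unitless), `n_valid`.
#' @export
dispersion <- function(frame, gamma5 = 2) {
  if (!is.matrix(frame) || nrow(frame) != 3L)
    stop("dispersion requires a 3 x n frame")
  n <- ncol(frame)
  z <- matrix(0, 3L, n)
  for (a in 1:3) {
    v <- frame[a, ]
    mu <- mean(v)
    s <- sqrt(mean((v - mu)^2))
    if (s <= 0) stop("zero-variance axis in gait frame")
    z[a, ] <- (v - mu) / s
  }
  valid <- colSums(abs(z) < gamma5) == 3L
  nv <- sum(valid)
  if (nv < 2L) stop("fewer than 2 non-outlier time points in frame")
  D <- numeric(3L)
  for (a in 1:3) {
    s <- sort(z[a, valid])
    # sum over ordered pairs of |s_i - s_j| = 2 * sum_i (2i - nv - 1) s_(i)
    D[a] <- 2 * sum((2 * seq_len(nv) - nv - 1) * s) / nv^2
  }
  list(D = D, n_valid = nv)
}

#' Channel-delay correlation matrix of an LM frame
#'
#' Builds `M * N` time-delay-embedded copies of the frame -- channel `c`
#' delayed by `k * d` samples, `k = 0..N-1` -- truncated to their common
#' overlap, and returns their Pearson correlation matrix (channel-major
#' block ordering).
#'
#' @param frame An `M x n` frame matrix.
#' @param d Delay spacing for this scale, samples.
#' @param N Delays per channel.
#' @return An `(M*N) x (M*N)` correlation matrix.
#' @export
channel_delay_corr <- function(frame, d, N = 15L) {
  M <- nrow(frame); n <- ncol(frame)
  L <- n - (N - 1L) * d
  if (L < 2L) stop("overlap shorter than 2 samples at delay scale ", d)
  E <- matrix(0, L, M * N)
  for (c in seq_len(M)) for (k in seq_len(N) - 1L) {
    v <- frame[c, (1L + k * d):(L + k * d)]
    if (sd(v) == 0) stop("zero-variance delayed copy in frame")
    E[, c * N - N + k + 1L] <- v
  }
  stats::cor(E)
}

#' Correlation-structure eigenspectrum of an LM frame
#'
#' Eigenvalues of the channel-delay correlation matrix at each delay scale,
#' rank-ordered largest to smallest within scale and concatenated across
#' scales (small scales probe fast dynamics, large scales slow dynamics).
#' Concentration of variance in few eigenvalues indicates low movement
#' dimensionality.
#'
#' @param frame A `3 x n` frame matrix.
#' @param params [feature_params()].
#' @return Numeric vector of `M * N * length(delay_scales)` eigenvalues.
#' @export
eigenspectrum <- function(frame, params = feature_params()) {
  if (nrow(frame) != params$M)
    stop("frame has ", nrow(frame), " channels; expected ", params$M)
  unlist(lapply(params$delay_scales, function(d)
    as.numeric(frame_eigenspectrum_cpp(frame, d, params$N))))
}

#' Frame incidence features
#'
#' @param frames Frame data.frame from [segment_recording()] (columns
#'   `kind`, `valid`).
#' @param days_observed Recorded span, days.
#' @return A list: `gait_frames_per_day`, `lm_frames_per_day`,
#'   `days_observed`.
#' @export
incidence <- function(frames, days_observed) {
  if (days_observed <= 0) stop("days_observed must be positive")
  n_gait <- if (nrow(frames)) sum(frames$kind == "gait" & frames$valid) else 0L
  n_lm <- if (nrow(frames)) sum(frames$kind == "LM") else 0L
  list(gait_frames_per_day = n_gait / days_observed,
       lm_frames_per_day = n_lm / days_observed,
       days_observed = days_observed)
}

#' Cohen's d effect size (PD minus control)
#'
#' Standardised mean difference with the pooled (n-1) standard deviation.
#' The sign convention is PD minus control: a negative d for gait-frame
#' incidence means PD subjects walk less.
#'
#' @param pd Per-subject values in the PD group.
#' @param control Per-subject values in the control group.
#' @return Cohen's d.
#' @export
cohens_d <- function(pd, control) {
  n1 <- length(pd); n2 <- length(control)
  if (n1 < 2L || n2 < 2L) stop("both groups need >= 2 subjects")
  sp2 <- ((n1 - 1) * var(pd) + (n2 - 1) * var(control)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled standard deviation")
  (mean(pd) - mean(control)) / sqrt(sp2)
}

#' Hourly frame incidence
#'
#' Bins frame start times by local hour of day (relative to the recording
#' start timestamp) and normalises by the number of days observed, giving
#' frames per hour-of-day per day.
#'
#' @param start_s Frame start times, s from `t0`.
#' @param t0 Recording start timestamp (ISO-8601).
#' @param days_observed Recorded span, days.
#' @return A 24-vector (hours 0--23).
#' @export
hourly_incidence <- function(start_s, t0, days_observed) {
  origin <- as.POSIXct(t0, tz = "UTC",
                       tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                      "%Y-%m-%dT%H:%M:%OS",
                                      "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"))
  h0 <- as.numeric(format(origin, "%H")) + as.numeric(format(origin, "%M")) / 60
  hr <- floor((h0 + start_s / 3600) %% 24)
  counts <- tabulate(hr + 1L, nbins = 24L)
  counts / days_observed
}

#' Extract all per-subject features from a recording
#'
#' Runs segmentation and framing, then computes dispersion vectors for the
#' valid gait frames, correlation-structure eigenspectra for the LM frames,
#' and the frame incidences.
#'
#' @param rec An [accel_recording()].
#' @param config A [wpd_config()].
#' @return A `wpd_subject_features` list: `subject_id`, `label`, `sex`,
#'   `days_observed`, `t0`, `gait` (list with `times`, `disp` n x 3
#'   matrix, `step_time_s`), `lm` (list with `times`, `eig` n x 180
#'   matrix), `incidence`, and frame counts.
#' @export
extract_features <- function(rec, config = wpd_config()) {
  seg <- segment_recording(rec, config$seg)
  fr <- seg$frames
  days <- recording_days(rec)
  gait_idx <- which(fr$kind == "gait" & fr$valid)
  lm_idx <- which(fr$kind == "LM")
  disp <- matrix(NA_real_, length(gait_idx), 3L)
  for (j in seq_along(gait_idx)) {
    f <- frame_samples(rec, fr$start_s[gait_idx[j]], config$seg$tau5)
    disp[j, ] <- dispersion(f, config$feat$gamma5)$D
  }
  p <- config$feat
  nev <- p$M * p$N * length(p$delay_scales)
  eig <- matrix(NA_real_, length(lm_idx), nev)
  for (j in seq_along(lm_idx)) {
    f <- frame_samples(rec, fr$start_s[lm_idx[j]], config$seg$tau5)
    eig[j, ] <- eigenspectrum(f, p)
  }
  structure(list(subject_id = rec$subject_id, label = rec$label,
                 sex = rec$sex, t0 = rec$t0, days_observed = days,
                 gait = list(times = fr$start_s[gait_idx], disp = disp,
                             step_time_s = fr$step_time_s[gait_idx]),
                 lm = list(times = fr$start_s[lm_idx], eig = eig),
                 incidence = incidence(fr, days),
                 n_gait_frames = length(gait_idx),
                 n_lm_frames = length(lm_idx),
                 n_segments = nrow(seg$segments)),
            class = "wpd_subject_features")
}
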