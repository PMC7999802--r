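#' Acceleration magnitude signal
#'
#' Euclidean norm of the three acceleration axes, sample by sample.
#'
#' @param rec An [accel_recording()] (or a bare `3 x T` matrix).
#' @return Numeric vector of magnitudes, g, same length as the recording.
#' @export
magnitude <- function(rec) {
  x <- if (inherits(rec, "accel_recording")) rec$x else rec
  if (!is.matrix(x) || nrow(x) != 3L)
    stop("magnitude requires a 3-channel recording")
  magnitude_cpp(x)
}

#' Sliding local energy of the magnitude signal
#'
#' Windowed mean and population (1/N) standard deviation of the magnitude,
#' evaluated at window centres spaced `hop` seconds apart. A sample at time
#' `t'` belongs to the window at `t` when `|t - t'| <= tau1`; windows are
#' truncated at the recording edges with the sample count adjusted.
#'
#' @param m Magnitude vector from [magnitude()].
#' @param fs Sampling frequency, Hz.
#' @param tau1 Window half-duration parameter, s.
#' @param hop Spacing of window centres, s. The default of 1 s is two
#'   orders of magnitude finer than the shortest segment duration gate.
#' @return A `wpd_energy` list: `times` (window centres, s), `sigma_m`,
#'   `mu_m` (g), `n_w` (samples per window), `hop`.
#' @export
local_energy <- function(m, fs, tau1 = 10, hop = 1) {
  T <- length(m)
  centers_t <- seq(0, (T - 1) / fs, by = hop)
  if (T < 1 || length(centers_t) < 1L)
    return(structure(list(times = numeric(0), sigma_m = numeric(0),
                          mu_m = numeric(0), n_w = integer(0), hop = hop),
                     class = "wpd_energy"))
  centers_i <- as.integer(round(centers_t * fs)) + 1L
  halfw <- as.integer(floor(tau1 * fs + 1e-9))
  res <- window_moments_cpp(m, centers_i, halfw)
  structure(list(times = centers_t, sigma_m = res$sigma, mu_m = res$mu,
                 n_w = res$n, hop = hop),
            class = "wpd_energy")
}

# Maximal runs of TRUE in a logical vector: matrix with first/last indices.
.runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(first = starts[r$values], last = ends[r$values])
}

.make_segments <- function(kind, times, first, last, hop) {
  data.frame(kind = rep(kind, length(first)),
             start_s = times[first],
             end_s = times[last] + hop)
}

#' Detect gait segments
#'
#' Maximal runs with `sigma_m > gamma1` are merged across subthreshold gaps
#' of duration `<= tau3` (transitively); merged runs whose total span,
#' including tolerated gaps, is at least `tau2` become gait segments.
#' Segment bounds snap to window-centre times; intervals are half-open
#' `[start_s, end_s)`.
#'
#' @param e A [local_energy()] series.
#' @param params [seg_params()].
#' @return A data.frame of segments (`kind`, `start_s`, `end_s`).
#' @export
detect_gait_segments <- function(e, params = seg_params()) {
  mask <- e$sigma_m > params$gamma1
  if (!any(mask)) return(.make_segments("gait", numeric(0), integer(0),
                                        integer(0), e$hop))
  rn <- .runs(mask)
  # transitive gap merge: gap between consecutive runs, in seconds
  if (nrow(rn) > 1L) {
    gap_s <- e$times[rn[-1L, "first"]] - e$times[rn[-nrow(rn), "last"]] - e$hop
    grp <- cumsum(c(0, gap_s > params$tau3))
  } else grp <- 0
  first <- tapply(rn[, "first"], grp, min)
  last <- tapply(rn[, "last"], grp, max)
  seg <- .make_segments("gait", e$times, as.integer(first), as.integer(last),
                        e$hop)
  seg[seg$end_s - seg$start_s >= params$tau2, , drop = FALSE]
}

#' Detect low-movement segments
#'
#' Maximal runs with `gamma2 < sigma_m < gamma3` (strict, no gap tolerance)
#' of span at least `tau4` become LM segments.
#'
#' @inheritParams detect_gait_segments
#' @return A data.frame of segments (`kind`, `start_s`, `end_s`).
#' @export
detect_lm_segments <- function(e, params = seg_params()) {
  mask <- e$sigma_m > params$gamma2 & e$sigma_m < params$gamma3
  if (!any(mask)) return(.make_segments("LM", numeric(0), integer(0),
                                        integer(0), e$hop))
  rn <- .runs(mask)
  seg <- .make_segments("LM", e$times, rn[, "first"], rn[, "last"], e$hop)
  seg[seg$end_s - seg$start_s >= params$tau4, , drop = FALSE]
}

#' Divide segments into contiguous frames
#'
#' Each segment yields `floor(span / tau5)` contiguous frames starting at
#' the segment start; any residual tail is discarded.
#'
#' @param segments Data.frame from the `detect_*` functions (sorted).
#' @param tau5 Frame duration, s.
#' @return A data.frame (`kind`, `start_s`, `segment`) with one row per
#'   frame; `segment` indexes the parent segment row.
#' @export
frame_segments <- function(segments, tau5 = 10) {
  if (nrow(segments) == 0L)
    return(data.frame(kind = character(0), start_s = numeric(0),
                      segment = integer(0)))
  out <- lapply(seq_len(nrow(segments)), function(i) {
    span <- segments$end_s[i] - segments$start_s[i]
    k <- floor(span / tau5)
    if (k < 1) return(NULL)
    data.frame(kind = segments$kind[i],
               start_s = segments$start_s[i] + (seq_len(k) - 1) * tau5,
               segment = i)
  })
  out <- do.call(rbind, out)
  row.names(out) <- NULL
  out
}

#' Extract the sample slice of one frame
#'
#' @param rec An [accel_recording()].
#' @param start_s Frame start on the recording clock, s.
#' @param tau5 Frame duration, s.
#' @return A `3 x (fs * tau5)` matrix.
#' @export
frame_samples <- function(rec, start_s, tau5 = 10) {
  i0 <- as.integer(round(start_s * rec$fs)) + 1L
  i1 <- i0 + as.integer(round(tau5 * rec$fs)) - 1L
  if (i1 > ncol(rec$x)) stop("frame extends past the end of the recording")
  rec$x[, i0:i1, drop = FALSE]
}

#' Validate a gait frame by its autocorrelation structure
#'
#' Per axis, the mean-removed autocorrelation (biased estimator, normalised
#' by lag zero) is evaluated on the sample grid. Delays are restricted to
#' `[tau6, tau7]`; the first local maximum occurring strictly after the
#' first negative autocorrelation value in that range is the candidate step
#' peak. The frame is valid iff all three axes have such a peak with height
#' `> gamma4`. A zero-variance axis makes the frame invalid.
#'
#' @param frame A `3 x n` frame matrix (see [frame_samples()]).
#' @param fs Sampling frequency, Hz.
#' @param params [seg_params()].
#' @return A list: `valid` (logical), `step_time_s` (per-axis peak delay,
#'   NA where no qualifying peak), `step_time_frame` (median across axes),
#'   `height` (per-axis peak height).
#' @export
validate_gait_frame <- function(frame, fs, params = seg_params()) {
  res <- gait_acf_peaks_cpp(frame, fs, params$tau6, params$tau7,
                            params$gamma4)
  res$step_time_frame <- if (res$valid) median(res$step_time_s) else NA_real_
  res
}

#' Segment a recording into gait and LM frames
#'
#' Convenience wrapper running [magnitude()], [local_energy()], both
#' segment detectors, framing and per-frame gait validation.
#'
#' @param rec An [accel_recording()].
#' @param params [seg_params()].
#' @param hop Energy-series hop, s.
#' @return A list with `energy`, `segments` (gait and LM, sorted), and
#'   `frames` (data.frame: `kind`, `start_s`, `segment`, `valid`,
#'   `step_time_s`; LM frames are always `valid`).
#' @export
segment_recording <- function(rec, params = seg_params(), hop = 1) {
  # fused magnitude + windowed moments (identical to
  # local_energy(magnitude(rec), ...), without materialising m in R)
  T <- ncol(rec$x)
  centers_t <- seq(0, (T - 1) / rec$fs, by = hop)
  centers_i <- as.integer(round(centers_t * rec$fs)) + 1L
  halfw <- as.integer(floor(params$tau1 * rec$fs + 1e-9))
  res <- recording_energy_cpp(rec$x, centers_i, halfw)
  e <- structure(list(times = centers_t, sigma_m = res$sigma,
                      mu_m = res$mu, n_w = res$n, hop = hop),
                 class = "wpd_energy")
  gait <- detect_gait_segments(e, params)
  lm <- detect_lm_segments(e, params)
  segments <- rbind(gait, lm)
  segments <- segments[order(segments$start_s), , drop = FALSE]
  row.names(segments) <- NULL
  frames <- frame_segments(segments, params$tau5)
  if (nrow(frames)) {
    frames$valid <- TRUE
    frames$step_time_s <- NA_real_
    gi <- which(frames$kind == "gait")
    for (i in gi) {
      v <- validate_gait_frame(frame_samples(rec, frames$start_s[i],
                                             params$tau5),
                               rec$fs, params)
      frames$valid[i] <- v$valid
      frames$step_time_s[i] <- v$step_time_frame
    }
  } else {
    frames$valid <- logical(0)
    frames$step_time_s <- numeric(0)
  }
  list(energy = e, segments = segments, frames = frames)
}
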