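#' Behavioural profile of a simulated subject
#'
#' Describes the free-living movement behaviour the generator emulates:
#' interleaved bouts of walking (quasiperiodic arm swing) and sustained
#' low-amplitude movement (LM), placed over the day according to a diurnal
#' propensity curve, on top of a gravity offset with slowly drifting
#' orientation and a sensor noise floor.
#'
#' Defaults describe a healthy control subject; class differences are
#' applied through the effect knobs of [cohort_spec()].
#'
#' @param label Class label of the subject.
#' @param gait_bouts_per_day Mean number of walking bouts per day.
#' @param gait_bout_duration Mean walking bout duration, s.
#' @param step_period Mean step period, s (first autocorrelation peak of the
#'   arm-swing signal; plausible range roughly 0.4--1.2 s).
#' @param swing_amplitude Target windowed magnitude SD inside gait bouts, g.
#' @param swing_jitter Fractional cycle-to-cycle variability of the swing.
#'   Larger values give a more variable, smoother swing waveform (higher
#'   movement dispersion); smaller values give a rigid, saturated,
#'   stereotyped swing (lower dispersion).
#' @param lm_bouts_per_day Mean number of LM bouts per day.
#' @param lm_bout_duration Mean LM bout duration, s.
#' @param lm_amplitude Target windowed magnitude SD inside LM bouts, g; must
#'   sit inside the LM detection band.
#' @param lm_n_latent Number of independent band-limited latent sources
#'   mixed into the three axes during LM bouts; controls movement
#'   dimensionality (fewer sources concentrate the eigenspectrum).
#' @param noise_sd Sensor noise floor per axis, g.
#' @param diurnal_weights Nonnegative 24-vector of bout-start propensities
#'   by hour of day (normalised internally).
#' @return A `wpd_profile` list.
#' @export
subject_profile <- function(label = "control",
                            gait_bouts_per_day = 5,
                            gait_bout_duration = 70,
                            step_period = 0.55,
                            swing_amplitude = 0.15,
                            swing_jitter = 0.15,
                            lm_bouts_per_day = 3,
                            lm_bout_duration = 360,
                            lm_amplitude = 0.012,
                            lm_n_latent = 3,
                            noise_sd = 4e-4,
                            diurnal_weights = default_diurnal_weights()) {
  p <- list(label = label, gait_bouts_per_day = gait_bouts_per_day,
            gait_bout_duration = gait_bout_duration,
            step_period = step_period, swing_amplitude = swing_amplitude,
            swing_jitter = swing_jitter, lm_bouts_per_day = lm_bouts_per_day,
            lm_bout_duration = lm_bout_duration, lm_amplitude = lm_amplitude,
            lm_n_latent = lm_n_latent, noise_sd = noise_sd,
            diurnal_weights = diurnal_weights)
  num <- c("gait_bout_duration", "step_period", "swing_amplitude",
           "swing_jitter", "lm_bout_duration", "lm_amplitude", "noise_sd")
  for (nm in num) if (!is.numeric(p[[nm]]) || p[[nm]] <= 0)
    stop("invalid profile field '", nm, "': must be positive")
  for (nm in c("gait_bouts_per_day", "lm_bouts_per_day"))
    if (!is.numeric(p[[nm]]) || p[[nm]] < 0)
      stop("invalid profile field '", nm, "': must be nonnegative")
  if (p$lm_n_latent < 1) stop("invalid profile field 'lm_n_latent': must be >= 1")
  if (length(p$diurnal_weights) != 24L || any(p$diurnal_weights < 0) ||
      sum(p$diurnal_weights) <= 0)
    stop("invalid profile field 'diurnal_weights': need 24 nonnegative values")
  p$diurnal_weights <- p$diurnal_weights / sum(p$diurnal_weights)
  structure(p, class = "wpd_profile")
}

#' Default diurnal bout-start propensities
#'
#' Hourly weights peaked over the late morning to mid afternoon
#' (10:00--16:00), with low but nonzero propensity in the evening and
#' near-zero propensity overnight.
#'
#' @return A normalised 24-vector.
#' @export
default_diurnal_weights <- function() {
  h <- 0:23
  w <- exp(-((h - 13) / 3.2)^2) + 0.15 * (h >= 7 & h <= 22)
  w / sum(w)
}

#' Specification of a synthetic two-class cohort
#'
#' Per-subject profiles are drawn around the control profile with
#' between-subject log-normal spread; PD subjects additionally receive the
#' multiplicative `effect_knobs`. With all knobs at 1 the two classes are
#' exchangeable (a null cohort).
#'
#' @param n_control,n_pd Subjects per class.
#' @param days Recording duration per subject, days.
#' @param seed Master seed; every recording is reproducible from it.
#' @param base Control-class profile (a [subject_profile()]).
#' @param between_sd Named list of between-subject log-normal SDs (on the
#'   log scale) for profile fields.
#' @param effect_knobs Named list of multiplicative PD offsets:
#'   `gait_incidence`, `lm_incidence`, `swing_jitter`, `lm_n_latent`.
#' @param fs Sampling frequency, Hz.
#' @return A `wpd_cohort_spec` list.
#' @export
cohort_spec <- function(n_control, n_pd, days = 1, seed = 1L,
                        base = subject_profile(),
                        between_sd = list(gait_bouts_per_day = 0.45,
                                          gait_bout_duration = 0.25,
                                          swing_amplitude = 0.25,
                                          swing_jitter = 0.25,
                                          lm_bouts_per_day = 0.45,
                                          lm_bout_duration = 0.25,
                                          lm_amplitude = 0.25),
                        effect_knobs = list(gait_incidence = 1,
                                            lm_incidence = 1,
                                            swing_jitter = 1,
                                            lm_n_latent = 1),
                        fs = 100) {
  if (n_control < 1 || n_pd < 1) stop("invalid cohort spec: counts must be >= 1")
  if (days <= 0) stop("invalid cohort spec: days must be positive")
  need <- c("gait_incidence", "lm_incidence", "swing_jitter", "lm_n_latent")
  missing_knobs <- setdiff(need, names(effect_knobs))
  effect_knobs[missing_knobs] <- 1
  structure(list(n_control = as.integer(n_control), n_pd = as.integer(n_pd),
                 days = days, seed = as.integer(seed), base = base,
                 between_sd = between_sd, effect_knobs = effect_knobs,
                 fs = fs),
            class = "wpd_cohort_spec")
}

#' Paper-like effect knobs
#'
#' The multiplicative class offsets used for signal cohorts: PD subjects
#' walk less (gait incidence x0.6), spend more time in sustained
#' low-movement activity (LM incidence x1.5), swing more rigidly (cycle
#' jitter x0.7, lowering gait dispersion) and move with lower
#' dimensionality (latent LM sources x2/3).
#'
#' @return A named list of knobs for [cohort_spec()].
#' @export
pd_effect_knobs <- function() {
  list(gait_incidence = 0.6, lm_incidence = 1.5,
       swing_jitter = 0.7, lm_n_latent = 2 / 3)
}

# Draw one subject's profile from the cohort spec.
.draw_profile <- function(spec, class, seed) {
  .with_seed(seed, {
    b <- spec$base
    ln <- function(mean, nm) {
      s <- spec$between_sd[[nm]]
      if (is.null(s) || s <= 0) return(mean)
      mean * exp(rnorm(1L, -s^2 / 2, s))
    }
    k <- if (class == "PD") spec$effect_knobs else
      list(gait_incidence = 1, lm_incidence = 1, swing_jitter = 1,
           lm_n_latent = 1)
    latent_mean <- b$lm_n_latent * k$lm_n_latent
    q <- max(1L, as.integer(round(latent_mean)) +
               sample(c(-1L, 0L, 1L), 1L, prob = c(0.1, 0.8, 0.1)))
    subject_profile(
      label = class,
      gait_bouts_per_day = ln(b$gait_bouts_per_day * k$gait_incidence,
                              "gait_bouts_per_day"),
      gait_bout_duration = ln(b$gait_bout_duration, "gait_bout_duration"),
      step_period = min(1.2, max(0.4, b$step_period + rnorm(1L, 0, 0.06))),
      swing_amplitude = ln(b$swing_amplitude, "swing_amplitude"),
      swing_jitter = max(0.02, ln(b$swing_jitter * k$swing_jitter,
                                  "swing_jitter")),
      lm_bouts_per_day = ln(b$lm_bouts_per_day * k$lm_incidence,
                            "lm_bouts_per_day"),
      lm_bout_duration = ln(b$lm_bout_duration, "lm_bout_duration"),
      lm_amplitude = min(0.024, max(0.003, ln(b$lm_amplitude, "lm_amplitude"))),
      lm_n_latent = q,
      noise_sd = b$noise_sd,
      diurnal_weights = b$diurnal_weights)
  })
}

# Draw bout start times (s) from the diurnal inhomogeneous Poisson
# process: per (possibly partial) hour of the recorded span, counts are
# Poisson with intensity rate_per_day * weight(hour of day), and starts
# are uniform within the hour.
.draw_bout_starts <- function(rate_per_day, days, weights) {
  if (rate_per_day <= 0) return(numeric(0))
  total_h <- days * 24
  hours <- seq_len(ceiling(total_h - 1e-9)) - 1L
  frac <- pmin(1, total_h - hours)
  lam <- rate_per_day * weights[(hours %% 24L) + 1L] * frac
  counts <- rpois(length(hours), lam)
  if (sum(counts) == 0L) return(numeric(0))
  st <- rep(hours, counts) * 3600 +
    runif(sum(counts)) * rep(3600 * frac, counts)
  sort(st)
}

# Saturated-sine arm swing for one bout: cycle-wise period jitter, slight
# slow amplitude modulation, and a waveform whose saturation grows as the
# jitter shrinks (rigid stereotyped swing => bimodal acceleration marginal
# => low dispersion). The jitter is modulated per bout (walking context
# varies), so a subject's mean dispersion stabilises with the number of
# bouts observed, not the number of frames.
.gait_bout_signal <- function(n, fs, profile) {
  P <- profile$step_period
  jit <- profile$swing_jitter * exp(rnorm(1L, -0.3^2 / 2, 0.3))
  jit <- max(0.02, jit)
  dur <- n / fs
  ncyc <- ceiling(dur / P) + 3L
  per <- pmax(0.25, P * (1 + jit * rnorm(ncyc)))
  bnd <- cumsum(c(0, per))
  tt <- (seq_len(n) - 1) / fs
  ph <- approx(bnd, 0:ncyc, tt, rule = 2)$y        # phase in cycles
  # per-axis saturation and envelope depth, so the three axes carry
  # partially independent regularity information; the steep jitter ->
  # saturation mapping spreads subjects across the waveform family from
  # near-sinusoidal (high dispersion) to near-square (low dispersion)
  kappa <- pmin(30, pmax(1.2, 3 * (0.15 / jit)^2.5 * exp(rnorm(3L, 0, 0.2))))
  axis_amp <- c(1, 0.75, 0.45)
  phi <- runif(3L, 0, 2 * pi)
  depth <- runif(3L, 0.05, 0.15)
  sig <- matrix(0, 3L, n)
  for (a in 1:3) {
    env <- 1 + depth[a] * sin(2 * pi * tt / 7 + runif(1L, 0, 2 * pi))
    sig[a, ] <- axis_amp[a] * env *
      tanh(kappa[a] * sin(2 * pi * ph + phi[a])) / tanh(kappa[a])
  }
  sig * rep(.bout_ramp(n, fs), each = 3L)
}

# Gradual onset/offset envelope: real activity starts and stops smoothly,
# so frames straddling a bout edge still contain scaled-down movement
# rather than an abrupt jump to the noise floor.
.bout_ramp <- function(n, fs, ramp_s = 10) {
  r <- min(as.integer(ramp_s * fs), n %/% 4L)
  if (r < 2L) return(rep(1, n))
  env <- rep(1, n)
  up <- seq(0, 1, length.out = r)
  env[seq_len(r)] <- up
  env[(n - r + 1L):n] <- rev(up)
  env
}

# Latent sources mixed into the three axes via a random mixing matrix
# drawn per bout (sustained low-movement activities differ in kind, but
# the subject's movement dimensionality is stable). Each source is
# band-limited (0.5--5 Hz) with a small broadband component, so the
# source-count signature is visible at short embedding delays as well.
.lm_bout_signal <- function(n, fs, q) {
  bf <- signal::butter(2, c(0.5, 5) / (fs / 2), type = "pass")
  burn <- 400L
  S <- matrix(0, q, n)
  for (i in seq_len(q)) {
    s <- signal::filter(bf, rnorm(n + burn))[(burn + 1L):(burn + n)]
    s <- s / max(sd(s), 1e-12) + 0.3 * rnorm(n)
    S[i, ] <- s
  }
  A <- matrix(rnorm(3L * q), 3L, q)
  (A %*% S) * rep(.bout_ramp(n, fs), each = 3L)
}

# Scale a bout's motion so that the SD of the acceleration magnitude over
# the bout hits `target` (in g). The magnitude is |gvec + motion|, which is
# nonlinear in the scale, so a couple of fixed-point passes are used.
.scale_to_sigma <- function(motion, gvec, target, iters = 2L) {
  sc <- 1
  for (i in seq_len(iters)) {
    m <- sqrt(colSums((gvec + sc * motion)^2))
    s <- sqrt(mean((m - mean(m))^2))
    if (s <= 0) break
    sc <- sc * target / s
  }
  sc * motion
}

#' Simulate one subject's recording
#'
#' Generates `days` of triaxial accelerometry at `fs` Hz: gait bouts as
#' quasiperiodic arm-swing signals, LM bouts as mixtures of band-limited
#' latent sources, elsewhere a sensor noise floor, all riding on a 1 g
#' gravity offset with slowly drifting orientation. The planted bout
#' schedule is attached as attribute `"bout_log"` (data.frame with columns
#' `type`, `start_s`, `end_s`) for use as ground truth.
#'
#' @param profile A [subject_profile()].
#' @param days Recording duration, days (may be fractional).
#' @param fs Sampling frequency, Hz.
#' @param seed Seed; identical seeds give identical recordings.
#' @param subject_id Subject identifier.
#' @param t0 Recording start timestamp (ISO-8601); bout placement uses the
#'   hour of day relative to this origin.
#' @param sex Optional sex marker carried into the recording.
#' @return An [accel_recording()] with attribute `"bout_log"`.
#' @export
simulate_subject <- function(profile, days = 1, fs = 100, seed = 1L,
                             subject_id = "S1",
                             t0 = "2000-01-01T00:00:00Z",
                             sex = NA_character_) {
  stopifnot(inherits(profile, "wpd_profile"))
  T <- as.integer(round(days * 86400 * fs))
  .with_seed(seed, {
    # bout schedule -------------------------------------------------------
    gs <- .draw_bout_starts(profile$gait_bouts_per_day, days,
                            profile$diurnal_weights)
    ls <- .draw_bout_starts(profile$lm_bouts_per_day, days,
                            profile$diurnal_weights)
    gd <- pmax(20, profile$gait_bout_duration *
                 exp(rnorm(length(gs), -0.3^2 / 2, 0.3)))
    ld <- pmax(120, profile$lm_bout_duration *
                 exp(rnorm(length(ls), -0.3^2 / 2, 0.3)))
    bouts <- data.frame(
      type = c(rep("gait", length(gs)), rep("LM", length(ls))),
      start_s = c(gs, ls), end_s = c(gs + gd, ls + ld))
    bouts <- bouts[order(bouts$start_s), , drop = FALSE]
    if (sum(bouts$end_s - bouts$start_s) > 0.6 * days * 86400)
      stop("generation error: bout load exceeds 60% of the recording; ",
           "bouts cannot be placed without overlap")
    keep <- logical(nrow(bouts)); last_end <- -Inf
    for (i in seq_len(nrow(bouts))) {
      if (bouts$start_s[i] >= last_end + 1 &&
          bouts$end_s[i] <= days * 86400) {
        keep[i] <- TRUE
        last_end <- bouts$end_s[i]
      }
    }
    bouts <- bouts[keep, , drop = FALSE]
    row.names(bouts) <- NULL

    # background: piecewise-constant sensor noise (innovations at fs/5)
    # plus gravity on a slowly drifting orientation (random walk on the
    # unit sphere, one node per 120 s, linearly interpolated)
    blk <- 5L
    nb <- as.integer(ceiling(T / blk))
    noise <- matrix(rnorm(3L * nb, 0, profile$noise_sd), 3L, nb)
    node_s <- 120L
    block <- as.integer(node_s * fs)
    nn <- as.integer(ceiling(T / block)) + 1L
    g <- matrix(0, 3L, nn)
    v <- rnorm(3L); v <- v / sqrt(sum(v^2))
    for (i in seq_len(nn)) {
      g[, i] <- v
      v <- v + rnorm(3L, 0, 0.08)
      v <- v / sqrt(sum(v^2))
    }
    x <- assemble_background_cpp(noise, blk, g, block, T)

    # gravity vector at arbitrary sample indices (for bout scaling)
    grav_at <- function(idx) {
      seg <- (idx - 1L) %/% block
      frac <- ((idx - 1L) %% block) / block
      g[, seg + 1L, drop = FALSE] * rep(1 - frac, each = 3L) +
        g[, seg + 2L, drop = FALSE] * rep(frac, each = 3L)
    }

    # bouts ---------------------------------------------------------------
    for (i in seq_len(nrow(bouts))) {
      i0 <- as.integer(floor(bouts$start_s[i] * fs)) + 1L
      i1 <- min(T, as.integer(floor(bouts$end_s[i] * fs)))
      n <- i1 - i0 + 1L
      if (n < fs) next
      if (bouts$type[i] == "gait") {
        mot <- .gait_bout_signal(n, fs, profile)
        target <- profile$swing_amplitude * exp(rnorm(1L, -0.2^2 / 2, 0.2))
        target <- max(target, 0.08)
      } else {
        mot <- .lm_bout_signal(n, fs, profile$lm_n_latent)
        target <- profile$lm_amplitude * exp(rnorm(1L, -0.25^2 / 2, 0.25))
        target <- min(0.025, max(0.003, target))
      }
      mot <- .scale_to_sigma(mot, grav_at(i0:i1), target)
      x[, i0:i1] <- x[, i0:i1] + mot
    }

    rec <- accel_recording(x, fs = fs, subject_id = subject_id,
                           label = profile$label, t0 = t0, sex = sex,
                           validate = FALSE)
    attr(rec, "bout_log") <- bouts
    rec
  })
}

#' Simulate a cohort to disk
#'
#' Draws per-subject profiles from the cohort spec (PD subjects receive the
#' effect knobs), simulates each recording and writes it under `dir`,
#' together with `manifest.csv` (`subject_id,path,label,sex`) and
#' `bout_log.csv` (`subject_id,type,start_s,end_s`). Fully reproducible
#' from `spec$seed`; per-subject seed streams mean that enlarging the
#' cohort leaves earlier subjects' recordings unchanged.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if needed).
#' @return The manifest (invisibly), as read back by [read_manifest()].
#' @export
simulate_cohort <- function(spec, dir) {
  stopifnot(inherits(spec, "wpd_cohort_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- spec$n_control + spec$n_pd
  rows <- vector("list", n)
  logs <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- .simulate_cohort_subject(spec, i)
    p <- file.path(dir, paste0(rec$subject_id, ".parquet"))
    write_recording(rec, p)
    rows[[i]] <- data.frame(subject_id = rec$subject_id,
                            path = basename(p), label = rec$label,
                            sex = rec$sex)
    bl <- attr(rec, "bout_log")
    if (nrow(bl))
      logs[[i]] <- cbind(subject_id = rec$subject_id, bl)
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  bout_log <- do.call(rbind, logs)
  if (is.null(bout_log))
    bout_log <- data.frame(subject_id = character(), type = character(),
                           start_s = numeric(), end_s = numeric())
  write.csv(bout_log, file.path(dir, "bout_log.csv"), row.names = FALSE)
  invisible(read_manifest(file.path(dir, "manifest.csv")))
}

# Simulate the i-th subject of a cohort (1-based over control then PD).
.simulate_cohort_subject <- function(spec, i) {
  n <- spec$n_control + spec$n_pd
  class <- if (i <= spec$n_control) "control" else "PD"
  prof_seeds <- derive_seeds(spec$seed, "profiles", n)
  rec_seeds <- derive_seeds(spec$seed, "recordings", n)
  sex_seeds <- derive_seeds(spec$seed, "sex", n)
  profile <- .draw_profile(spec, class, prof_seeds[i])
  p_male <- if (class == "PD") 0.65 else 0.47
  sex <- .with_seed(sex_seeds[i],
                    if (runif(1L) < p_male) "M" else "F")
  id <- sprintf("%s%03d", if (class == "PD") "PD" else "C",
                if (class == "PD") i - spec$n_control else i)
  simulate_subject(profile, days = spec$days, fs = spec$fs,
                   seed = rec_seeds[i], subject_id = id, sex = sex)
}
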