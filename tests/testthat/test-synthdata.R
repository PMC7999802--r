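# Generator tests run on fractional-day recordings to stay fast; the
# full-day study conditions are exercised in the acceptance suite.

fast_profile <- function(...) {
  # rates scaled up and diurnal weights flattened so that a few hours of
  # recording (starting at midnight) contain several bouts
  args <- modifyList(list(gait_bouts_per_day = 40, gait_bout_duration = 70,
                          lm_bouts_per_day = 20, lm_bout_duration = 330,
                          diurnal_weights = rep(1 / 24, 24)),
                     list(...))
  do.call(subject_profile, args)
}

test_that("identical seeds reproduce recordings bit for bit; distinct seeds differ", {
  p <- fast_profile()
  r1 <- simulate_subject(p, days = 0.05, seed = 5)
  r2 <- simulate_subject(p, days = 0.05, seed = 5)
  expect_identical(r1$x, r2$x)
  expect_identical(attr(r1, "bout_log"), attr(r2, "bout_log"))
  r3 <- simulate_subject(p, days = 0.05, seed = 6)
  expect_false(identical(r1$x, r3$x))
})

test_that("a profile with no bouts yields no detected segments", {
  p <- subject_profile(gait_bouts_per_day = 0, lm_bouts_per_day = 0)
  rec <- simulate_subject(p, days = 0.05, seed = 1)
  seg <- segment_recording(rec)
  expect_equal(nrow(seg$segments), 0L)
  expect_equal(nrow(attr(rec, "bout_log")), 0L)
})

test_that("planted bouts of qualifying duration are recovered by the detectors", {
  p <- fast_profile()
  found_g <- tot_g <- found_l <- tot_l <- 0
  for (s in 1:3) {
    rec <- simulate_subject(p, days = 0.25, seed = s)
    bl <- attr(rec, "bout_log")
    seg <- segment_recording(rec)$segments
    overlaps <- function(b, kind) {
      ss <- seg[seg$kind == kind, ]
      any(ss$start_s < b["end_s"] & ss$end_s > b["start_s"])
    }
    gb <- bl[bl$type == "gait" & bl$end_s - bl$start_s >= 30, ]
    lb <- bl[bl$type == "LM" & bl$end_s - bl$start_s >= 260, ]
    tot_g <- tot_g + nrow(gb); tot_l <- tot_l + nrow(lb)
    for (i in seq_len(nrow(gb)))
      found_g <- found_g + overlaps(unlist(gb[i, c("start_s", "end_s")]), "gait")
    for (i in seq_len(nrow(lb)))
      found_l <- found_l + overlaps(unlist(lb[i, c("start_s", "end_s")]), "LM")
  }
  expect_gt(tot_g, 10); expect_gt(tot_l, 5)
  expect_gte(found_g / tot_g, 0.9)
  expect_gte(found_l / tot_l, 0.9)
})

test_that("windowed sigma_m inside LM bouts stays within the detection band", {
  p <- fast_profile()
  rec <- simulate_subject(p, days = 0.2, seed = 11)
  bl <- attr(rec, "bout_log")
  e <- local_energy(magnitude(rec), rec$fs)
  inside <- rep(FALSE, length(e$times))
  for (i in which(bl$type == "LM")) {
    inside <- inside | (e$times >= bl$start_s[i] + 11 &
                          e$times <= bl$end_s[i] - 11)
  }
  expect_gt(sum(inside), 100)
  frac <- mean(e$sigma_m[inside] > 0.001 & e$sigma_m[inside] < 0.03)
  expect_gt(frac, 0.95)
})

test_that("low-jitter gait bouts pass the periodicity check at high rate", {
  p <- fast_profile(swing_jitter = 0.04)
  rec <- simulate_subject(p, days = 0.2, seed = 21)
  bl <- attr(rec, "bout_log")
  seg <- segment_recording(rec)
  fr <- seg$frames[seg$frames$kind == "gait", ]
  inside <- rep(FALSE, nrow(fr))
  for (i in which(bl$type == "gait"))
    inside <- inside | (fr$start_s >= bl$start_s[i] &
                          fr$start_s + 10 <= bl$end_s[i])
  expect_gt(sum(inside), 20)
  expect_gt(mean(fr$valid[inside]), 0.9)
})

test_that("fewer latent LM sources concentrate the eigenspectrum", {
  p1 <- fast_profile(gait_bouts_per_day = 0, lm_n_latent = 1)
  p3 <- fast_profile(gait_bouts_per_day = 0, lm_n_latent = 3)
  f1 <- extract_features(simulate_subject(p1, days = 0.15, seed = 31))
  f3 <- extract_features(simulate_subject(p3, days = 0.15, seed = 31))
  expect_gt(f1$n_lm_frames, 10); expect_gt(f3$n_lm_frames, 10)
  for (j in 0:3) {
    top1 <- mean(f1$lm$eig[, j * 45 + 1])
    top3 <- mean(f3$lm$eig[, j * 45 + 1])
    expect_gt(top1, top3)
  }
})

test_that("lower swing jitter produces lower gait dispersion", {
  lo <- fast_profile(swing_jitter = 0.08)
  hi <- fast_profile(swing_jitter = 0.25)
  d_lo <- d_hi <- c()
  for (s in 1:2) {
    d_lo <- c(d_lo, colMeans(extract_features(
      simulate_subject(lo, days = 0.15, seed = 40 + s))$gait$disp))
    d_hi <- c(d_hi, colMeans(extract_features(
      simulate_subject(hi, days = 0.15, seed = 40 + s))$gait$disp))
  }
  expect_gt(mean(d_hi), mean(d_lo))
})

test_that("an overloaded bout schedule raises a generation error", {
  p <- fast_profile(gait_bouts_per_day = 2000, gait_bout_duration = 200)
  expect_error(simulate_subject(p, days = 0.1, seed = 1), "generation error")
})

test_that("cohort simulation writes a coherent, reproducible bundle", {
  spec <- cohort_spec(2, 2, days = 0.05, seed = 8,
                      base = fast_profile())
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  m1 <- simulate_cohort(spec, d1)
  m2 <- simulate_cohort(spec, d2)
  expect_equal(m1$subject_id, c("C001", "C002", "PD001", "PD002"))
  expect_equal(m1$label, c("control", "control", "PD", "PD"))
  for (i in seq_len(nrow(m1))) {
    r1 <- read_recording(m1$path[i]); r2 <- read_recording(m2$path[i])
    expect_identical(r1$x, r2$x)
  }
  bl <- read.csv(file.path(d1, "bout_log.csv"))
  expect_true(all(c("subject_id", "type", "start_s", "end_s") %in% names(bl)))
  # growing the cohort must not perturb earlier subjects
  spec_big <- cohort_spec(3, 2, days = 0.05, seed = 8, base = fast_profile())
  d3 <- file.path(tempfile(), "c")
  m3 <- simulate_cohort(spec_big, d3)
  expect_identical(read_recording(m3$path[1])$x, read_recording(m1$path[1])$x)
})

test_that("neutral effect knobs leave the two classes exchangeable in profile", {
  spec <- cohort_spec(1, 1, days = 1, seed = 5)
  pc <- wristpd:::.draw_profile(spec, "control", 123)
  pp <- wristpd:::.draw_profile(spec, "PD", 123)
  for (nm in c("gait_bouts_per_day", "lm_bouts_per_day", "swing_jitter",
               "lm_n_latent"))
    expect_equal(pc[[nm]], pp[[nm]])
  spec2 <- cohort_spec(1, 1, days = 1, seed = 5,
                       effect_knobs = pd_effect_knobs())
  pp2 <- wristpd:::.draw_profile(spec2, "PD", 123)
  expect_lt(pp2$gait_bouts_per_day, pc$gait_bouts_per_day)
  expect_gt(pp2$lm_bouts_per_day, pc$lm_bouts_per_day)
  expect_lt(pp2$swing_jitter, pc$swing_jitter)
})
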