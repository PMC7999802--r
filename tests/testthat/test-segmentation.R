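test_that("magnitude is the per-sample Euclidean norm", {
  rec <- accel_recording(matrix(c(0, 0, 1), 3, 50), 100, "g")
  expect_equal(magnitude(rec), rep(1, 50))
  rec345 <- accel_recording(matrix(c(3, 4, 0), 3, 10), 100, "g")
  expect_equal(magnitude(rec345), rep(5, 10))
  set.seed(4)
  x <- matrix(rnorm(3 * 777), 3)
  expect_equal(magnitude(x), sqrt(colSums(x^2)), tolerance = 1e-12)
  expect_error(magnitude(matrix(0, 2, 10)), "3-channel")
})

test_that("local energy matches the direct windowed-SD evaluation", {
  set.seed(11)
  fs <- 100
  m <- 1 + 0.05 * rnorm(60 * fs) + 0.3 * sin((1:(60 * fs)) / 500)
  e <- local_energy(m, fs, tau1 = 10, hop = 1)
  idx <- sort(sample(seq_along(e$times), 100, replace = TRUE))
  for (i in idx) {
    b <- energy_brute(m, fs, e$times[i], 10)
    expect_equal(e$sigma_m[i], b$sigma, tolerance = 1e-10)
    expect_equal(e$mu_m[i], b$mu, tolerance = 1e-10)
    expect_equal(e$n_w[i], b$n)
  }
})

test_that("local energy closed forms: constant and sinusoidal magnitude", {
  fs <- 100
  e <- local_energy(rep(2, 40 * fs), fs, 10, 1)
  expect_true(all(e$sigma_m == 0))
  expect_equal(e$mu_m, rep(2, length(e$mu_m)))
  tt <- (0:(60 * fs - 1)) / fs
  m <- 1 + 0.1 * sin(2 * pi * tt)
  e <- local_energy(m, fs, 10, 1)
  interior <- e$times >= 11 & e$times <= 49
  expect_equal(e$sigma_m[interior],
               rep(0.1 / sqrt(2), sum(interior)), tolerance = 2e-3)
})

test_that("gait segment detection applies threshold, gap merge and duration gates", {
  p <- seg_params()
  base <- rep(0, 400)
  # isolated 60 s suprathreshold run
  s <- base; s[101:160] <- 0.08
  seg <- detect_gait_segments(energy_series(s), p)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$end_s - seg$start_s, 60)
  # 25 s run: below the 30 s duration gate
  s <- base; s[101:125] <- 0.08
  expect_equal(nrow(detect_gait_segments(energy_series(s), p)), 0L)
  # two 20 s runs with a 10 s tolerated gap merge to one 50 s segment
  s <- base; s[101:120] <- 0.08; s[131:150] <- 0.08
  seg <- detect_gait_segments(energy_series(s), p)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$end_s - seg$start_s, 50)
  # a 16 s gap is not tolerated and both fragments fail the gate
  s <- base; s[101:120] <- 0.08; s[137:156] <- 0.08
  expect_equal(nrow(detect_gait_segments(energy_series(s), p)), 0L)
  # transitive merge across several short gaps
  s <- base; s[101:115] <- 0.08; s[121:135] <- 0.08; s[141:155] <- 0.08
  seg <- detect_gait_segments(energy_series(s), p)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$end_s - seg$start_s, 55)
  expect_equal(nrow(detect_gait_segments(energy_series(rep(0, 100)), p)), 0L)
})

test_that("LM segment detection uses the strict band with no gap tolerance", {
  p <- seg_params()
  base <- rep(0, 500)
  s <- base; s[101:400] <- 0.01
  seg <- detect_lm_segments(energy_series(s), p)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$end_s - seg$start_s, 300)
  s <- base; s[101:400] <- 0.05          # above gamma3
  expect_equal(nrow(detect_lm_segments(energy_series(s), p)), 0L)
  expect_equal(nrow(detect_lm_segments(energy_series(base), p)), 0L)  # 0 not > gamma2
  s <- base; s[101:300] <- 0.01          # 200 s < tau4
  expect_equal(nrow(detect_lm_segments(energy_series(s), p)), 0L)
  # one subthreshold sample splits the run
  s <- base; s[101:400] <- 0.01; s[250] <- 0
  expect_equal(nrow(detect_lm_segments(energy_series(s), p)), 0L)
})

test_that("segments never overlap across kinds on threshold-band signals", {
  p <- seg_params()
  set.seed(2)
  s <- c(rep(0.01, 300), rep(0.08, 60), rep(0.01, 300), rep(0, 50))
  e <- energy_series(s)
  gait <- detect_gait_segments(e, p)
  lm <- detect_lm_segments(e, p)
  for (i in seq_len(nrow(gait))) for (j in seq_len(nrow(lm)))
    expect_true(gait$start_s[i] >= lm$end_s[j] || gait$end_s[i] <= lm$start_s[j])
})

test_that("shifting the energy series shifts segment boundaries equally", {
  p <- seg_params()
  s <- c(rep(0, 50), rep(0.08, 45), rep(0, 105))
  e1 <- energy_series(s)
  e2 <- energy_series(c(rep(0, 7), s))
  s1 <- detect_gait_segments(e1, p)
  s2 <- detect_gait_segments(e2, p)
  expect_equal(s2$start_s, s1$start_s + 7)
  expect_equal(s2$end_s, s1$end_s + 7)
})

test_that("framing yields floor(span/tau5) contiguous frames per segment", {
  seg <- data.frame(kind = c("gait", "LM", "gait"),
                    start_s = c(0, 100, 400),
                    end_s = c(35, 340, 409))
  fr <- frame_segments(seg, 10)
  expect_equal(sum(fr$segment == 1), 3L)   # floor(35/10)
  expect_equal(sum(fr$segment == 2), 24L)  # floor(240/10)
  expect_equal(sum(fr$segment == 3), 0L)   # 9 s: guard
  expect_equal(fr$start_s[fr$segment == 1], c(0, 10, 20))
  expect_equal(diff(fr$start_s[fr$segment == 2]), rep(10, 23))
})

test_that("gait frame validation accepts periodic frames with the right step time", {
  p <- seg_params()
  for (period in c(0.5, 1.0, 1.5)) {
    f <- sine_frame(period = period)
    v <- validate_gait_frame(f, 100, p)
    expect_true(v$valid)
    expect_equal(v$step_time_frame, period, tolerance = 0.02)
  }
  # period outside [tau6, tau7]: no qualifying peak
  expect_false(validate_gait_frame(sine_frame(period = 2.5), 100, p)$valid)
  # constant frame: zero variance
  expect_false(validate_gait_frame(matrix(1, 3, 1000), 100, p)$valid)
})

test_that("white-noise frames rarely pass the periodicity check", {
  set.seed(7)
  p <- seg_params()
  n_valid <- 0L
  for (i in 1:200)
    n_valid <- n_valid +
      validate_gait_frame(matrix(rnorm(3000), 3), 100, p)$valid
  expect_lt(n_valid / 200, 0.05)
})

test_that("segment_recording ties the stages together on a constructed recording", {
  fs <- 100
  set.seed(9)
  # 600 s: noise floor, one 60 s gait-like bout, one 300 s LM-like bout
  tt <- (0:(600 * fs - 1)) / fs
  x <- matrix(rnorm(3 * 600 * fs, 0, 3e-4), 3)
  x[3, ] <- x[3, ] + 1                       # gravity
  g <- tt >= 100 & tt < 160
  for (a in 1:3) x[a, g] <- x[a, g] + 0.2 * sin(2 * pi * tt[g] / 0.5 + a)
  l <- tt >= 250 & tt < 550
  x[3, l] <- x[3, l] + 0.01 * sin(2 * pi * tt[l] / 1.7)
  rec <- accel_recording(x, fs, "c1")
  seg <- segment_recording(rec)
  kinds <- seg$segments$kind
  expect_true(any(kinds == "gait"))
  expect_true(any(kinds == "LM"))
  gaits <- seg$segments[kinds == "gait", ]
  expect_true(any(gaits$start_s < 160 & gaits$end_s > 100))
  expect_true(all(seg$frames$valid[seg$frames$kind == "LM"]))
  gv <- seg$frames$kind == "gait" & seg$frames$start_s >= 100 &
    seg$frames$start_s < 150
  expect_true(all(seg$frames$valid[gv]))
  expect_equal(median(seg$frames$step_time_s[gv]), 0.5, tolerance = 0.02)
})
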