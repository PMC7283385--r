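test_that("waveform construction enforces the envelope invariants", {
  t <- seq(0, 0.5, length.out = 11)
  expect_error(velocity_waveform("aorta", t, rep(1, 11)), "unknown site")
  expect_error(velocity_waveform("lcca", rev(t), rep(1, 11)),
               "strictly increasing")
  expect_error(velocity_waveform("lcca", t, c(rep(1, 10), -0.1)), ">= 0")
  expect_error(velocity_waveform("lcca", t[1:2], c(1, 1)), "3 samples")
  w <- velocity_waveform("lcca", t, rep(1, 11), heart_rate_bpm = 120)
  expect_s3_class(w, "velocity_waveform")
  expect_equal(waveform_period(w), 0.5)
})

test_that("smoothing is the identity for window 1 and reproduces parabolas", {
  w <- mk_wave(abs(rnorm(31, 1, 0.2)), site = "innominate")
  expect_equal(smooth_waveform(w, 1), w)
  # samples exactly on a parabola are invariant under a quadratic fit
  t <- seq(0, 0.5, length.out = 41)
  v <- 2 + 3 * t - 4 * t^2
  wp <- mk_wave(v)
  expect_equal(smooth_waveform(wp, 5)$velocity, v, tolerance = 1e-12)
  expect_error(smooth_waveform(w, 4), "odd")
  expect_error(smooth_waveform(w, 33), "odd integer in")
})

test_that("smoothing reduces the residual of a noisy pulse against the clean one", {
  clean <- gen_waveform(waveform_params(1.5, noise_sd = 0, seed = 1))
  noisy <- gen_waveform(waveform_params(1.5, noise_sd = 0.05, seed = 1))
  sm <- smooth_waveform(noisy, 7)
  raw_sd <- sd(noisy$velocity - clean$velocity)
  sm_sd <- sd(sm$velocity - clean$velocity)
  expect_lt(sm_sd, raw_sd)
})

test_that("interior smoothed values agree with Savitzky-Golay filtering", {
  # same centered quadratic fit on interior points; endpoints differ by design
  set.seed(7)
  v <- pmax(1 + cumsum(rnorm(61, 0, 0.05)), 0)
  w <- mk_wave(v)
  sm <- smooth_waveform(w, 7)
  ref <- signal::sgolayfilt(v, p = 2, n = 7)
  expect_equal(sm$velocity[4:58], pmax(ref, 0)[4:58], tolerance = 1e-9)
})

test_that("period normalization rescales time only and is idempotent", {
  t <- seq(0, 0.75, length.out = 31)           # 80 BPM
  w <- velocity_waveform("lsca", t, pmax(sin(pi * t / 0.75), 0))
  nw <- normalize_period(w, 0.5)
  expect_equal(waveform_period(nw), 0.5)
  expect_equal(nw$time, t * (2 / 3))
  expect_equal(nw$velocity, w$velocity)
  expect_equal(max(nw$velocity), max(w$velocity))
  expect_equal(nw$heart_rate_bpm, 120)
  # already at the target: unchanged; and normalizing twice == once
  w05 <- half_sine(1.2)
  expect_equal(normalize_period(w05, 0.5)$time, w05$time)
  expect_equal(normalize_period(nw, 0.5), nw)
  # synthetic pulse at 95 BPM ends up at exactly 0.5 s / 120 BPM
  w95 <- gen_waveform(waveform_params(1.0, heart_rate_bpm = 95))
  n95 <- normalize_period(w95)
  expect_equal(waveform_period(n95), 0.5, tolerance = 1e-15)
  expect_equal(60 / waveform_period(n95), 120)
})

test_that("peak extraction takes the first occurrence of the maximum", {
  w <- mk_wave(rep(1.0, 11), site = "coarctation")
  expect_equal(peak_of(w), list(t_peak = 0, v_max = 1.0))
  # two equal peaks: earliest wins
  t <- seq(0, 0.5, by = 0.05)
  v <- numeric(length(t)); v[t == 0.1] <- 2; v[t == 0.3] <- 2
  w2 <- velocity_waveform("coarctation", t, v)
  expect_equal(peak_of(w2)$t_peak, 0.1)
  # half-sine coarctation jet
  expect_equal(peak_of(half_sine(3.49, site = "coarctation"))$v_max, 3.49)
  # peak value is invariant under period normalization (exactly)
  w3 <- gen_waveform(waveform_params(2.2, heart_rate_bpm = 77, noise_sd = 0.03))
  expect_identical(peak_of(normalize_period(w3))$v_max, peak_of(w3)$v_max)
})

test_that("uniform resampling is exact on its own grid and for linear data", {
  w <- half_sine(1.5, n = 41)
  r <- resample_uniform(w, 41)
  expect_equal(r$velocity, w$velocity)
  ramp <- mk_wave(seq(0, 2, length.out = 21))
  r2 <- resample_uniform(ramp, 101)
  expect_equal(r2$velocity, seq(0, 2, length.out = 101))
  # endpoints always preserved
  expect_equal(r2$velocity[c(1, 101)], ramp$velocity[c(1, 21)])
  # dense resampling keeps the peak within one grid-spacing slope bound
  p <- gen_waveform(waveform_params(2.0, n_samples = 301))
  rs <- resample_uniform(p, 1000)
  dt <- diff(p$time[1:2])
  slope_bound <- max(abs(diff(p$velocity))) / dt * (waveform_period(p) / 999)
  expect_lte(abs(peak_of(rs)$v_max - peak_of(p)$v_max), slope_bound)
  expect_error(resample_uniform(p, 2), ">= 3")
})

test_that("smoothing does not raise the sampled maximum of unimodal envelopes", {
  for (s in 1:5) {
    w <- gen_waveform(waveform_params(1 + s / 2, noise_sd = 0.04, seed = s,
                                      diastolic_tail_fraction = 0.2))
    expect_lte(max(smooth_waveform(w, 7)$velocity), max(w$velocity) + 1e-12)
  }
})

test_that("waveform text files round-trip through the reader and writer", {
  w <- gen_waveform(waveform_params(1.11, heart_rate_bpm = 108,
                                    noise_sd = 0.02, seed = 3),
                    site = "innominate", phase = "post_repair")
  f <- tempfile(fileext = ".csv")
  write_velocity_waveform(w, f)
  r <- read_velocity_waveform(f)
  expect_equal(r$site, "innominate")
  expect_equal(r$phase, "post_repair")
  expect_equal(r$heart_rate_bpm, 108)
  expect_equal(r$velocity, w$velocity, tolerance = 1e-5)
  expect_equal(r$time, w$time, tolerance = 1e-5)
  # metadata overrides and error paths
  expect_equal(read_velocity_waveform(f, site = "lcca")$site, "lcca")
  expect_error(read_velocity_waveform(tempfile()), "not found")
  bad <- tempfile()
  writeLines(c("0 1", "0.1"), bad)
  expect_error(read_velocity_waveform(bad, site = "lcca"), "two columns")
})
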