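test_that("band-pass gain matches the designed passband", {
  fs <- 500
  t <- seq(0, 20, by = 1 / fs)
  core <- seq(2 * fs, length(t) - 2 * fs)  # trim filter edge transients
  # DC blocked (the 0.3 Hz high-pass edge transient decays over ~ 1/0.3 s,
  # so the DC check trims a wider margin)
  dc <- bandpass(ppg_trace(rep(5, length(t)), fs = fs))
  core_dc <- seq(6 * fs, length(t) - 6 * fs)
  expect_lt(max(abs(dc$value[core_dc])), 0.05)
  # 5 Hz passed at unit gain
  s5 <- bandpass(ppg_trace(sin(2 * pi * 5 * t), fs = fs))
  amp5 <- (max(s5$value[core]) - min(s5$value[core])) / 2
  expect_gt(amp5, 0.95); expect_lt(amp5, 1.05)
  # 50 Hz attenuated
  s50 <- bandpass(ppg_trace(sin(2 * pi * 50 * t), fs = fs))
  amp50 <- (max(s50$value[core]) - min(s50$value[core])) / 2
  expect_lt(amp50, 0.1)
  # invalid band rejected
  expect_error(bandpass(ppg_trace(t, fs = fs), high = 300), "fs/2")
})

test_that("invalid-segment rejection isolates flat and clipped stretches", {
  fs <- 100
  t <- seq(0, 30, by = 1 / fs)
  clean <- sin(2 * pi * 1.2 * t)
  tr <- ppg_trace(clean, fs = fs)
  segs <- reject_invalid(tr)
  expect_length(segs, 1)
  expect_equal(nrow(segs[[1]]), length(clean))
  # a 5 s zeroed gap splits the trace in two
  gap <- clean
  gap[(10 * fs):(15 * fs)] <- 0
  segs2 <- reject_invalid(ppg_trace(gap, fs = fs))
  expect_length(segs2, 2)
  expect_true(all(vapply(segs2, function(s) stats::sd(s$value) > 1e-4, logical(1))))
  # all-flat trace yields nothing
  expect_length(reject_invalid(ppg_trace(rep(1, 3000), fs = fs)), 0)
})

test_that("cycle segmentation recovers the generator's beat count", {
  sh <- pulse_shape()
  # noiseless: troughs at every interior beat boundary
  tr <- bandpass(generate_pulse_train(sh, rep(75, 10), fs = 500))
  cyc <- segment_cycles(tr)
  expect_equal(nrow(cyc), 8)  # 10 beats -> 8 interior trough-to-trough cycles
  # interior cycles hit the true 0.8 s period; the trace-edge cycle may be
  # clipped by the filter transient
  expect_gte(sum(abs(cyc$duration_s - 0.8) < 0.01), 7)
  # noiseless bleed session: n_beats - 2 cycles, exactly
  ses <- quiet_session(duration = 120)
  cyc2 <- segment_cycles(bandpass(ses$ppg))
  expect_equal(nrow(cyc2), nrow(ses$beats) - 2)
  # 5% amplitude noise: within +/- 1 cycle
  sesn <- quiet_session(duration = 120, noise_sd = 0.05, seed = 4)
  cyc3 <- segment_cycles(bandpass(sesn$ppg))
  expect_lte(abs(nrow(cyc3) - (nrow(ses$beats) - 2)), 1)
  # constant trace: empty with a warning
  expect_warning(out <- segment_cycles(ppg_trace(rep(1, 5000), fs = 500)))
  expect_equal(nrow(out), 0)
})

test_that("duration gate discards out-of-band beats", {
  sh <- pulse_shape()
  tr <- bandpass(generate_pulse_train(sh, rep(75, 10), fs = 500))
  # 0.8 s beats exceed 60/80 s: the true cycles are discarded and anything
  # retained must lie inside the admissible duration band
  cyc <- segment_cycles(tr, min_hr = 80)
  expect_lt(nrow(cyc), 8)
  if (nrow(cyc) > 0) {
    expect_true(all(cyc$duration_s >= 60 / 300 & cyc$duration_s <= 60 / 80))
  }
  expect_warning(cyc2 <- segment_cycles(tr, min_hr = 100),
                 "heart-rate band")  # band now excludes 0.64 s too
  expect_equal(nrow(cyc2), 0)
})

test_that("cycle normalization hits 200 points and [0, 1] exactly", {
  # min-max identity on an already-200-point ramp
  ramp <- seq(3, 7, length.out = 200)
  w <- normalize_cycle(ramp)
  expect_equal(w, seq(0, 1, length.out = 200))
  # downsampling a 400-point half-sine
  half <- sin(pi * seq(0, 1, length.out = 400))
  w2 <- normalize_cycle(half)
  expect_length(w2, 200)
  expect_equal(max(abs(w2 - sin(pi * seq(0, 1, length.out = 200)))), 0, tolerance = 1e-3)
  # upsampling a 100-point half-sine via cubic spline
  w3 <- normalize_cycle(sin(pi * seq(0, 1, length.out = 100)))
  expect_equal(max(abs(w3 - sin(pi * seq(0, 1, length.out = 200)))), 0, tolerance = 1e-3)
  # decimate mode also returns 200 in [0, 1]
  w4 <- normalize_cycle(half, resample_mode = "decimate")
  expect_length(w4, 200)
  expect_equal(range(w4), c(0, 1))
  # degenerate inputs
  expect_error(normalize_cycle(rep(2, 50)), "flat")
  expect_error(normalize_cycle(c(1, 2)), "short")
})

test_that("template is the pointwise mean of the first n cycles", {
  a <- seq(0, 1, length.out = 200)
  b <- rev(a)
  cst <- normalize_cycle(sin(pi * seq(0, 1, length.out = 200)))
  expect_equal(make_template(list(a, a, a), 3), a)
  expect_equal(make_template(list(a, b), 2), (a + b) / 2)
  # brute-force elementwise mean on three distinct cycles
  manual <- vapply(1:200, function(k) (a[k] + b[k] + cst[k]) / 3, numeric(1))
  expect_equal(make_template(list(a, b, cst), 3), manual)
  expect_error(make_template(list(a, b), 5), "at least")
})

test_that("sliding sample windows follow the i >= 3 start convention", {
  cyc <- replicate(10, random_waveform(), simplify = FALSE)
  sw <- sliding_samples(cyc, n = 5)
  expect_equal(sw$start_cycle, 3:6)  # 4 windows from 10 cycles
  # n = 1: each sample equals its cycle
  sw1 <- sliding_samples(cyc, n = 1)
  expect_equal(sw1$samples, cyc[3:10])
  # identical cycles collapse onto the template
  same <- replicate(8, cyc[[1]], simplify = FALSE)
  sws <- sliding_samples(same, n = 4)
  expect_true(all(vapply(sws$samples, function(s)
    isTRUE(all.equal(s, make_template(same, 4))), logical(1))))
  # too few cycles: empty
  expect_equal(nrow(sliding_samples(cyc[1:3], n = 5)), 0)
})

test_that("template and sample operators are linear", {
  set.seed(42)
  a <- replicate(6, random_waveform(), simplify = FALSE)
  b <- replicate(6, random_waveform(), simplify = FALSE)
  mix <- Map(function(x, y) 0.3 * x + 0.7 * y, a, b)
  expect_equal(make_template(mix, 4),
               0.3 * make_template(a, 4) + 0.7 * make_template(b, 4))
  sm <- sliding_samples(mix, n = 3)$samples
  sa <- sliding_samples(a, n = 3)$samples
  sb <- sliding_samples(b, n = 3)$samples
  for (i in seq_along(sm)) {
    expect_equal(sm[[i]], 0.3 * sa[[i]] + 0.7 * sb[[i]])
  }
})

test_that("preprocessing output always satisfies the waveform contract", {
  ses <- quiet_session(duration = 60, noise_sd = 0.05, drift_amp = 0.2, seed = 9)
  cyc <- preprocess_ppg(ses$ppg)
  expect_true(all(vapply(cyc$norm, length, integer(1)) == 200))
  rng <- vapply(cyc$norm, range, numeric(2))
  expect_true(all(abs(rng[1, ]) < 1e-9))
  expect_true(all(abs(rng[2, ] - 1) < 1e-9))
})

test_that("trace and waveform round-trip through the CSV formats", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  tr <- generate_pulse_train(pulse_shape(), rep(90, 3), fs = 500)
  write_trace(tr, tmp, meta = list(seed = 1))
  back <- read_trace(tmp)
  expect_equal(back$value, tr$value)
  expect_equal(trace_fs(back), 500)
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  wfs <- replicate(3, random_waveform(), simplify = FALSE)
  write_waveforms(wfs, tmp2, meta = list(n = 3))
  expect_equal(read_waveforms(tmp2), wfs)
})
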