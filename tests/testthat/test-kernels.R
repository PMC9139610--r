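test_that("noise-free synthesis -> extraction recovers implanted kernels", {
  set.seed(11)
  templ <- phnr_template(waveform_model(), default_time)
  K <- as_kernel_set(outer(templ, runif(12, 0.5, 3)))
  rec <- synthesize_raw_recording(K, small_sched, small_areas)
  got <- extract_first_order_kernels(rec, small_sched, small_areas)
  expect_lt(max(abs(got - K)) / max(abs(K)), 0.01)
  expect_equal(attr(got, "time_ms"), default_time)
  # two m-sequence cycles average to the same kernels
  rec2 <- synthesize_raw_recording(K, small_sched, small_areas, n_cycles = 2)
  got2 <- extract_first_order_kernels(rec2, small_sched, small_areas)
  expect_lt(max(abs(got2 - K)) / max(abs(K)), 0.01)
})

test_that("an all-zero recording yields all-zero kernels", {
  n <- round(255 * 1000 / 7)
  rec <- raw_recording(rep(0, n), 1000)
  got <- extract_first_order_kernels(rec, small_sched, small_areas)
  expect_equal(max(abs(got)), 0)
})

test_that("shift-orthogonality confines a single implanted template", {
  m <- generate_msequence(12)
  sched <- derive_segment_sequences(m, 60, 68)
  templ <- phnr_template(waveform_model(), default_time)
  K <- matrix(0, length(default_time), 60)
  K[, 1] <- 2 * templ
  K <- as_kernel_set(K)
  rec <- synthesize_raw_recording(K, sched, default_segments$area)
  got <- extract_first_order_kernels(rec, sched, default_segments$area)
  peak0 <- max(abs(got[, 1]))
  rms_others <- sqrt(colMeans(unclass(got)[, -1]^2))
  expect_lt(max(rms_others), 0.02 * peak0)
  expect_lt(max(abs(got[, 1] - K[, 1])) / peak0, 0.01)
})

test_that("kernel extraction is linear and offset-invariant", {
  set.seed(12)
  templ <- phnr_template(waveform_model(), default_time)
  K1 <- as_kernel_set(outer(templ, runif(12, 0.5, 2)))
  K2 <- as_kernel_set(outer(templ, runif(12, 0.5, 2)))
  r1 <- synthesize_raw_recording(K1, small_sched, small_areas)
  r2 <- synthesize_raw_recording(K2, small_sched, small_areas)
  sum_rec <- raw_recording(r1$samples + r2$samples, 1000)
  k_sum <- extract_first_order_kernels(sum_rec, small_sched, small_areas)
  k_sep <- extract_first_order_kernels(r1, small_sched, small_areas) +
    extract_first_order_kernels(r2, small_sched, small_areas)
  expect_equal(as.numeric(k_sum), as.numeric(k_sep), tolerance = 1e-12)
  # a constant offset on the raw signal is annihilated by the band-pass
  # stage, so the filtered-then-extracted kernels do not move
  f_ref <- bandpass_filter(r1)
  f_off <- bandpass_filter(raw_recording(r1$samples + 1000, 1000))
  k_ref <- extract_first_order_kernels(f_ref, small_sched, small_areas)
  k_off <- extract_first_order_kernels(f_off, small_sched, small_areas)
  expect_lt(max(abs(k_off - k_ref)), 1e-6 * max(abs(k_ref)))
})

test_that("kernel noise shrinks as 1 / sqrt(frame count)", {
  # white recording noise of SD sigma enters each (bias-corrected) kernel
  # with SD sigma * sqrt(2 / M) per unit area: the cross-correlation and
  # the mean-response correction each contribute sigma^2 / M
  sigma <- 50
  sds <- vapply(c(1, 4), function(cyc) {
    per_seed <- vapply(1:8, function(s) {
      set.seed(100 * cyc + s)
      K0 <- as_kernel_set(matrix(0, length(default_time), 12))
      rec <- synthesize_raw_recording(K0, small_sched, small_areas,
                                      n_cycles = cyc, noise_sd = sigma)
      got <- extract_first_order_kernels(rec, small_sched, small_areas)
      stats::sd(as.numeric(sweep(unclass(got), 2, small_areas, "*")))
    }, numeric(1))
    mean(per_seed)
  }, numeric(1))
  predicted <- sigma * sqrt(2 / (255 * c(1, 4)))
  expect_equal(sds, predicted, tolerance = 0.2)
  # four times the frames halve the noise SD
  expect_equal(sds[1] / sds[2], 2, tolerance = 0.2)
})

test_that("synthesis and extraction validate their inputs", {
  templ <- phnr_template(waveform_model(), default_time)
  K <- as_kernel_set(outer(templ, rep(1, 12)))
  expect_error(synthesize_raw_recording(K, small_sched, small_areas[1:5]),
               "one area per segment")
  expect_error(
    synthesize_raw_recording(K, small_sched[, 1:5], small_areas[1:5]),
    "segments"
  )
  short <- raw_recording(rep(0, 1000), 1000)
  expect_error(extract_first_order_kernels(short, small_sched, small_areas),
               "shorter than one")
  # single segment, single nonzero frame: the recording is the scaled
  # template at that onset
  sched1 <- matrix(c(1L, rep(-1L, 254)), ncol = 1)
  K1 <- as_kernel_set(matrix(templ, ncol = 1))
  rec1 <- synthesize_raw_recording(K1, sched1, 5)
  onset_vals <- rec1$samples[1:121]  # lags 0..120 ms of frame 0
  contrib <- 5 * templ[default_time >= 0]
  # frame 0 carries +1, later frames all -1; frame 0's positive lags
  expect_equal(onset_vals, contrib - 0 * onset_vals, tolerance = 1e-12)
})
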