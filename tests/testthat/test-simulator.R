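test_that("stimulus design follows the block protocol", {
  d <- generate_design()
  expect_length(d$trial_onsets_s, 100)
  expect_equal(max(d$trial_onsets_s), 19.8)
  expect_equal(d$trial_onsets_s[1:3], c(0, 0.2, 0.4))
  # two stimuli per trial -> 200 events in total
  n_events <- length(d$trial_onsets_s) * length(d$spot_offsets_s)
  expect_equal(n_events, 200)

  d0 <- generate_design(n_trials = 0)
  expect_length(d0$trial_onsets_s, 0)

  expect_error(generate_design(n_trials = 200), "overflow")
  expect_error(generate_design(trial_spacing_s = -1), "positive")
})

test_that("response kernels are unit-peak with the stated latencies", {
  k <- default_kernels()
  expect_equal(max(k$neural$y), 1)
  expect_equal(max(k$hrf$y), 1)
  expect_equal(k$neural$peak_latency_s, 0.05, tolerance = 1e-3)
  expect_equal(k$hrf$peak_latency_s, 6, tolerance = 0.2)
  expect_equal(k$hb_ratio, 3)
})

test_that("source activity is co-localized and correctly scaled", {
  hm <- small_head()
  src <- hm$sources
  d <- generate_design(n_trials = 5, block_duration_s = 12)
  spA <- activation_spot(src, src$positions[10, ], "A")
  spB <- activation_spot(src, src$positions[300, ], "B")

  act <- simulate_sources(d, list(spA, spB), src,
                          background = c(electrical = 0, hbo = 0, hb = 0))
  spot_vox <- sort(c(spA$voxel_ids, spB$voxel_ids))
  non_spot <- setdiff(seq_len(600), spot_vox)
  expect_true(all(act$electrical[non_spot, ] == 0))
  expect_true(all(act$hbo[non_spot, ] == 0))

  # co-localization: electrical and hemodynamic activity share voxels
  e_vox <- which(rowSums(abs(act$electrical)) > 0)
  h_vox <- which(rowSums(abs(act$hbo)) > 0)
  expect_setequal(e_vox, h_vox)

  # HbO:Hb amplitude ratio is exactly 3, opposite sign
  expect_equal(max(abs(act$hbo)) / max(abs(act$hb)), 3)
  expect_equal(act$hb, -act$hbo / 3)

  expect_error(simulate_sources(d, list(spA, spA), src), "overlap")
})

test_that("a single event reproduces the kernels at the right latencies", {
  hm <- small_head()
  src <- hm$sources
  d <- generate_design(n_trials = 1, block_duration_s = 12,
                       spot_offsets_s = c(A = 1))
  sp <- activation_spot(src, src$positions[42, ], "A")
  act <- simulate_sources(d, list(sp), src,
                          background = c(electrical = 0, hbo = 0, hb = 0))
  v <- sp$voxel_ids[1]
  t_peak_e <- act$time_electrical[which.max(act$electrical[v, ])]
  expect_equal(t_peak_e, 1 + 0.05, tolerance = 2e-3)
  t_peak_h <- act$time_hemodynamic[which.max(act$hbo[v, ])]
  k <- default_kernels()
  expect_equal(t_peak_h, 1 + k$hrf$peak_latency_s, tolerance = 0.15)
  # convolution with a unit impulse returns the kernel itself
  expect_equal(max(act$electrical[v, ]), 1)
})

test_that("recordings respect the configured SNR and are reproducible", {
  hm <- small_head()
  src <- hm$sources
  d <- generate_design()
  sp <- activation_spot(src, src$positions[42, ], "A")
  act <- simulate_sources(d, list(sp), src, seed = 3)
  L <- small_leadfield()
  J <- small_jacobian()

  rec <- generate_recordings(act, L, J, seed = 4)
  noise <- rec$eeg - rec$eeg_clean
  snr_emp <- max(abs(rec$eeg_clean))^2 / stats::var(as.numeric(noise))
  expect_equal(snr_emp, 10, tolerance = 0.1)

  # per-wavelength DOT SNR
  for (w in 1:2) {
    rows <- (w - 1) * 24 + 1:24
    nz <- rec$dod[rows, ] - rec$dod_clean[rows, ]
    snr_w <- max(abs(rec$dod_clean[rows, ]))^2 / stats::var(as.numeric(nz))
    expect_equal(snr_w, c(10, 20)[w], tolerance = 0.25)
  }

  rec2 <- generate_recordings(act, L, J, seed = 4)
  expect_identical(rec$eeg, rec2$eeg)
  expect_identical(rec$dod, rec2$dod)

  rec_inf <- generate_recordings(act, L, J,
                                 snr = c(eeg = Inf, `750` = Inf, `850` = Inf))
  expect_equal(rec_inf$eeg, rec_inf$eeg_clean)
  expect_equal(rec_inf$dod, rec_inf$dod_clean)
})

test_that("clean recordings are linear and scale with the event amplitude", {
  hm <- small_head()
  src <- hm$sources
  d <- generate_design(n_trials = 3, block_duration_s = 10)
  spA <- activation_spot(src, src$positions[10, ], "A")
  spB <- activation_spot(src, src$positions[300, ], "B")
  L <- small_leadfield()
  J <- small_jacobian()
  zero_bg <- c(electrical = 0, hbo = 0, hb = 0)
  no_noise <- c(eeg = Inf, `750` = Inf, `850` = Inf)

  actA <- simulate_sources(d, list(spA), src, background = zero_bg)
  actB <- simulate_sources(d, list(spB), src, background = zero_bg)
  actAB <- simulate_sources(d, list(spA, spB), src, background = zero_bg)

  rA <- generate_recordings(actA, L, J, snr = no_noise)
  rB <- generate_recordings(actB, L, J, snr = no_noise)
  rAB <- generate_recordings(actAB, L, J, snr = no_noise)
  expect_equal(rAB$eeg, rA$eeg + rB$eeg, tolerance = 1e-12)
  expect_equal(rAB$dod, rA$dod + rB$dod, tolerance = 1e-12)

  act2 <- actA
  act2$electrical <- 2 * act2$electrical
  act2$hbo <- 2 * act2$hbo
  act2$hb <- 2 * act2$hb
  r2 <- generate_recordings(act2, L, J, snr = no_noise)
  expect_equal(r2$eeg, 2 * rA$eeg, tolerance = 1e-12)
  expect_equal(r2$dod, 2 * rA$dod, tolerance = 1e-12)
})

test_that("fast sensor-space generator agrees with the faithful path", {
  hm <- small_head()
  src <- hm$sources
  d <- generate_design(n_trials = 10, block_duration_s = 15)
  sp <- activation_spot(src, src$positions[42, ], "A")
  L <- small_leadfield()
  J <- small_jacobian()
  zero_bg <- c(electrical = 0, hbo = 0, hb = 0)
  no_noise <- c(eeg = Inf, `750` = Inf, `850` = Inf)

  # with noise and background off the two paths are algebraically identical
  act <- simulate_sources(d, list(sp), src, background = zero_bg)
  slow <- generate_recordings(act, L, J, snr = no_noise)
  fast <- eegdot:::simulate_recordings_fast(d, list(sp), src, L, J,
                                            background = zero_bg,
                                            snr = no_noise, seed = 1)
  expect_equal(fast$eeg, slow$eeg, tolerance = 1e-10)
  expect_equal(fast$dod, slow$dod, tolerance = 1e-10)

  # the sensor-space background has covariance sd^2 L L^T by construction;
  # compare empirical channel variances of the two paths (statistical check)
  bg <- c(electrical = 1 / 20, hbo = 0, hb = 0)
  act_b <- simulate_sources(d, list(sp), src, background = bg, seed = 7)
  slow_b <- generate_recordings(act_b, L, J, snr = no_noise)
  fast_b <- eegdot:::simulate_recordings_fast(d, list(sp), src, L, J,
                                              background = bg,
                                              snr = no_noise, seed = 8)
  v_slow <- apply(slow_b$eeg - slow$eeg, 1, stats::var)
  v_fast <- apply(fast_b$eeg - fast$eeg, 1, stats::var)
  expect_equal(v_fast, v_slow, tolerance = 0.15)
})
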