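test_that("trial averaging reduces noise like 1/sqrt(N) and is exact on clean data", {
  d <- generate_design()  # 100 trials, 200 ms spacing
  set.seed(6)
  x <- matrix(rnorm(8 * 30000), 8, 30000)
  avg <- preprocess_eeg(x, d, fs = 1000)
  expect_equal(dim(avg$data), c(8, 200))
  expect_equal(avg$n_trials, 100)
  expect_equal(stats::sd(avg$data) / stats::sd(x[, 1:20000]), 1 / sqrt(100),
               tolerance = 0.15)

  # a clean trial-periodic signal averages to any single clean trial
  trial <- matrix(sin(seq_len(200) / 10), 8, 200, byrow = TRUE)
  xp <- trial[, rep(1:200, 150)]
  avg_p <- preprocess_eeg(xp, d, fs = 1000)
  expect_equal(avg_p$data, trial, tolerance = 1e-12, ignore_attr = TRUE)

  d1 <- generate_design(n_trials = 1, block_duration_s = 0.2)
  one <- matrix(rnorm(8 * 200), 8, 200)
  expect_equal(preprocess_eeg(one, d1, fs = 1000)$data, one)

  expect_error(preprocess_eeg(matrix(0, 8, 10), d, fs = 1000), "complete")
})

test_that("DOT preprocessing matches the Butterworth magnitude response", {
  d <- generate_design()
  # DC gain is exactly 1
  const <- matrix(3.7, 2, 300)
  expect_equal(preprocess_dot(const, d, window_s = c(2, 25), fs = 10),
               c(3.7, 3.7), tolerance = 1e-5)

  # analytic two-pass magnitude response of an order-2 low-pass at cutoff 1 Hz:
  # |H(f)|^2 = 1 / (1 + (f/1)^4) applied twice (zero-phase)
  fs <- 100
  tt <- seq(0, 60 - 1 / fs, by = 1 / fs)
  gain <- function(f) {
    x <- matrix(sin(2 * pi * f * tt), 1)
    bf <- signal::butter(2, 1 / (fs / 2), "low")
    y <- signal::filtfilt(bf, x[1, ])
    mid <- seq(round(0.3 * length(tt)), round(0.7 * length(tt)))
    max(abs(y[mid]))
  }
  expect_equal(gain(5), 1 / (1 + 5^4), tolerance = 0.05)
  expect_gt(gain(0.05), 0.99)

  expect_error(preprocess_dot(const, d, fs = 1.5), "sampling rate")
})

test_that("prior weighting follows the exponential saturation form", {
  pr <- build_dot_prior(c(0, 1), k = 0.1, a = 0.1, b = 1)
  expect_equal(pr$q_diag[1], 1 - exp(-0.1), tolerance = 1e-12)  # 0.09516
  expect_equal(pr$q_diag[2], 1 - exp(-1.1), tolerance = 1e-12)  # 0.66713
  expect_equal(round(pr$q_diag, 5), c(0.09516, 0.66713))

  # below-threshold amplitudes fall back to the baseline weight
  pr2 <- build_dot_prior(c(0.05, 1), k = 0.1, a = 0.1, b = 1)
  expect_equal(pr2$q_diag[1], 1 - exp(-0.1))
  expect_true(all(pr2$q_diag > 0 & pr2$q_diag <= 1))

  # weights increase with prior activity
  pr3 <- build_dot_prior(seq(0, 1, 0.1), k = 0, a = 0.1, b = 1)
  expect_true(all(diff(pr3$q_diag) > 0))

  expect_error(build_dot_prior(c(0, 1), b = 0), "`b`")
  expect_error(build_dot_prior(c(0, 1), a = -1), "`a`")
  expect_error(build_dot_prior(c(0, 1), k = 1), "`k`")
})

test_that("EEG reconstruction localizes and respects the prior", {
  L <- small_leadfield()
  src <- small_head()$sources
  v_true <- 42
  y <- L$matrix[, v_true, drop = FALSE]  # noiseless single-voxel source

  m <- reconstruct_eeg(y, L)
  am <- which.max(abs(m$values[, 1]))
  err <- sqrt(sum((src$positions[am, ] - src$positions[v_true, ])^2))
  expect_lt(err, 25)

  # a prior concentrated on the true voxel pins the maximum there
  q <- rep(0.05, 600)
  q[v_true] <- 1
  pr <- structure(list(q_diag = q, params = list()), class = "eegdot_prior")
  m2 <- reconstruct_eeg(y, L, prior = pr)
  expect_equal(which.max(abs(m2$values[, 1])), v_true)

  # all-zero data gives an all-zero map (zero columns are short-circuited)
  m0 <- reconstruct_eeg(matrix(0, 32, 1), L)
  expect_true(all(m0$values == 0))

  # the uniform prior and an explicit all-ones prior are the same code path
  pr1 <- structure(list(q_diag = rep(1, 600), params = list()),
                   class = "eegdot_prior")
  mu <- reconstruct_eeg(y, L)
  m1 <- reconstruct_eeg(y, L, prior = pr1)
  expect_lt(max(abs(mu$values - m1$values)), 1e-10 * max(abs(mu$values)))
})

test_that("DOT reconstruction localizes a single spot", {
  J <- small_jacobian()
  src <- small_head()$sources
  spot <- activation_spot(src, J$channel_midpoints_cortex[7, ], "A")
  beta <- numeric(1200)
  beta[spot$voxel_ids] <- 1                    # HbO increase
  beta[600 + spot$voxel_ids] <- -1 / 3         # Hb decrease
  y <- J$matrix %*% beta

  maps <- reconstruct_dot(as.numeric(y), J)
  am <- which.max(abs(maps$hbo$values[, 1]))
  err <- sqrt(sum((src$positions[am, ] - spot$center)^2))
  expect_lt(err, 10)
  expect_true(maps$hbo$normalized)
  expect_equal(max(abs(maps$hbo$values)), 1)

  expect_warning(z <- reconstruct_dot(numeric(48), J), "zero")
  expect_true(all(z$hbo$values == 0) && all(z$hb$values == 0))

  expect_error(reconstruct_dot(numeric(10), J), "row count")
})

test_that("smoothness kernel tends to the identity as sigma -> 0", {
  src <- small_head()$sources
  G <- smoothness_kernel(src$positions, 1e-4)
  expect_equal(G, diag(600), tolerance = 1e-12, ignore_attr = TRUE)

  J <- small_jacobian()
  spot <- activation_spot(src, J$channel_midpoints_cortex[7, ], "A")
  beta <- numeric(1200)
  beta[spot$voxel_ids] <- 1
  y <- as.numeric(J$matrix %*% beta)
  plain <- reconstruct_dot(y, J)
  smooth0 <- reconstruct_dot(y, J, positions = src$positions,
                             smoothing_sigma_mm = 1e-4)
  # both maps are max-normalized, so compare on the absolute scale
  expect_lt(max(abs(smooth0$hbo$values - plain$hbo$values)), 1e-6)

  expect_error(smoothness_kernel(src$positions, 0), "positive")
})

test_that("MBLL inverts the extinction system exactly", {
  ext <- hemoglobin_extinction()
  dpf <- c(`750` = 6, `850` = 5)
  d_mm <- c(20, 25, 22)
  truth <- cbind(hbo = c(1, -0.5, 2), hb = c(-0.3, 0.2, -0.7))
  dod <- numeric(6)
  for (w in 1:2) {
    E <- log(10) * ext[w, ] * dpf[w]
    for (ch in 1:3) {
      dod[(w - 1) * 3 + ch] <- sum(E * truth[ch, ]) * d_mm[ch]
    }
  }
  got <- mbll(dod, d_mm)
  expect_equal(got, truth, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("projection prior peaks at the active channel and is symmetric", {
  hm <- small_head()
  opt <- small_optodes()
  src <- hm$sources
  J <- small_jacobian()
  ext <- hemoglobin_extinction()
  dpf <- c(`750` = 6, `850` = 5)

  # one active channel: synthesize MBLL-consistent dOD for channel 5 only
  dod <- numeric(48)
  for (w in 1:2) {
    dod[(w - 1) * 24 + 5] <- log(10) * ext[w, "hbo"] * dpf[w] *
      opt$distances_mm[5] * 1.0
  }
  pr <- projection_prior(dod, opt, src)
  am <- which.max(pr$map$values[, 1])
  mid5 <- J$channel_midpoints_cortex[5, ]
  expect_lt(sqrt(sum((src$positions[am, ] - mid5)^2)), src$spacing_mm * 1.2)

  # two equal channels: prior symmetric about their mid-plane
  dod2 <- numeric(48)
  for (w in 1:2) {
    amp <- log(10) * ext[w, "hbo"] * dpf[w]
    dod2[(w - 1) * 24 + 5] <- amp * opt$distances_mm[5]
    dod2[(w - 1) * 24 + 20] <- amp * opt$distances_mm[20]
  }
  pr2 <- projection_prior(dod2, opt, src)
  m1 <- J$channel_midpoints_cortex[5, ]
  m2 <- J$channel_midpoints_cortex[20, ]
  v1 <- pr2$map$values[which.min(colSums((t(src$positions) - m1)^2)), 1]
  v2 <- pr2$map$values[which.min(colSums((t(src$positions) - m2)^2)), 1]
  expect_equal(v1, v2, tolerance = 0.2)
})
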