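test_that("spherical head geometry is constructed as specified", {
  hm <- build_spherical_head(n_sources = 1000)
  r <- sqrt(rowSums(hm$sources$positions^2))
  expect_true(all(abs(r - 80) < 1e-6))
  expect_equal(nrow(hm$sources$positions), 1000)
  nn <- sqrt(rowSums(hm$sources$normals^2))
  expect_true(all(abs(nn - 1) < 1e-12))
  d <- as.matrix(dist(hm$sources$positions[1:100, ]))
  diag(d) <- Inf
  expect_true(min(d) > 0)

  hm2 <- build_spherical_head(n_sources = 1000)
  expect_identical(hm$sources$positions, hm2$sources$positions)

  expect_error(build_spherical_head(shell_radii = c(80, 79, 87, 92)), "increasing")
  expect_error(build_spherical_head(n_sources = 100), "at least 500")
})

test_that("sensor layouts satisfy their geometric contracts", {
  el <- small_electrodes()
  expect_equal(nrow(el$positions), 32)
  expect_true(all(abs(sqrt(rowSums(el$positions^2)) - 92) < 1e-9))
  expect_equal(anyDuplicated(el$labels), 0L)

  el64 <- place_sensors(small_head(), "eeg64")
  expect_equal(nrow(el64$positions), 64)
  expect_equal(anyDuplicated(el64$labels), 0L)

  opt <- small_optodes()
  expect_equal(nrow(opt$channels), 24)
  expect_true(all(opt$distances_mm >= 17 & opt$distances_mm <= 27))

  optx <- place_sensors(small_head(), "dot_regular_plus_detector")
  expect_equal(nrow(optx$channels), 26)
  expect_true(all(optx$distances_mm >= 17 & optx$distances_mm <= 27))

  opth <- place_sensors(small_head(), "dot_high_density")
  expect_true(all(opth$distances_mm >= 7.5 & opth$distances_mm <= 29))
  expect_identical(opth$density, "high")

  expect_error(place_sensors(small_head(), "nope"))
})

test_that("multi-shell leadfield matches the homogeneous-sphere closed form", {
  # with equal conductivities the 4-shell series must reduce to the classical
  # single-sphere radial-dipole potential; truncation high enough that the
  # undamped tail (2n+1) f^(n-1) is < 1e-10
  hm <- build_spherical_head(conductivities = rep(1, 4), n_sources = 600)
  el <- place_sensors(hm, "eeg32")
  L <- compute_eeg_leadfield(hm, el, n_terms = 400)

  R <- 92
  f <- (80 - 2) / R
  ct <- tcrossprod(el$positions / R, hm$sources$normals)
  ct <- pmin(pmax(ct, -1), 1)
  g <- sqrt(1 - 2 * f * ct + f^2)
  V <- (2 * (ct - f) / g^3 + (1 / f) * (1 / g - 1)) / (4 * pi * R^2)
  V <- sweep(V, 2, colMeans(V))

  expect_lt(max(abs(L$matrix - V)) / max(abs(V)), 1e-6)
})

test_that("leadfield columns are average-referenced and peak under the source", {
  L <- small_leadfield()
  expect_lt(max(abs(colSums(L$matrix))), 1e-10)

  # a radial dipole directly beneath an electrode is strongest at it
  hm <- small_head()
  el <- small_electrodes()
  for (e in c(3, 14, 25)) {
    dirs <- hm$sources$normals
    v <- which.max(dirs %*% (el$positions[e, ] / 92))
    expect_equal(unname(which.max(abs(L$matrix[, v]))), e)
  }
})

test_that("leadfield is linear and decays with source depth", {
  L <- small_leadfield()$matrix
  combo <- L[, 1] + 2 * L[, 5] - 0.5 * L[, 9]
  expect_equal(unname(combo),
               as.numeric(L %*% replace(numeric(600), c(1, 5, 9),
                                        c(1, 2, -0.5))))

  hm <- small_head()
  el <- small_electrodes()
  norms <- sapply(c(78, 72, 66, 60), function(r) {
    src <- shell_sources(r, 200)
    Lr <- compute_eeg_leadfield(hm$head, el, src, dipole_depth_mm = 0)
    sqrt(sum(Lr$matrix[, 17]^2))
  })
  expect_true(all(diff(norms) < 0))

  bad <- shell_sources(95, 50)
  expect_error(compute_eeg_leadfield(hm$head, el, bad, dipole_depth_mm = 0),
               "inside")
})

test_that("DOT jacobian is reciprocal, banana-shaped and depth-decaying", {
  hm <- small_head()
  opt <- small_optodes()
  J <- small_jacobian()
  expect_true(all(is.finite(J$matrix)))
  expect_equal(dim(J$matrix), c(48, 1200))

  # zero concentration change maps to zero optical density change
  expect_equal(J$matrix %*% numeric(1200), matrix(0, 48, 1),
               ignore_attr = TRUE)

  # source-detector reciprocity: swapping the roles leaves the row unchanged
  swapped <- opt
  swapped$source_positions <- opt$detector_positions
  swapped$detector_positions <- opt$source_positions
  swapped$channels <- opt$channels[, c(2, 1), drop = FALSE]
  colnames(swapped$channels) <- c("source", "detector")
  Js <- compute_dot_jacobian(hm, swapped)
  expect_lt(max(abs(J$matrix - Js$matrix)), 1e-10 * max(abs(J$matrix)))

  # sensitivity at the SD midpoint beats any voxel >= 20 mm lateral offset
  src <- hm$sources
  for (chn in c(1, 12, 24)) {
    mid <- J$channel_midpoints_cortex[chn, ]
    dmid <- sqrt(colSums((t(src$positions) - mid)^2))
    vm <- which.min(dmid)
    lat <- which(dmid >= 20 & dmid <= 40)
    s <- abs(J$matrix[chn, seq_len(600)])
    expect_gt(s[vm], max(s[lat]))
  }

  # monotone decay along a radial line below the cortex
  el_dirs <- (opt$source_positions[1, ] + opt$detector_positions[1, ]) / 2
  depth_sens <- sapply(c(80, 74, 68, 62), function(r) {
    src_r <- shell_sources(r, 400)
    Jr <- compute_dot_jacobian(hm$head, opt, src_r)
    mdir <- el_dirs / sqrt(sum(el_dirs^2))
    v <- which.max(src_r$positions %*% mdir)
    abs(Jr$matrix[1, v])
  })
  expect_true(all(diff(depth_sens) < 0))
})

test_that("wavelength blocks differ only through optical properties", {
  hm <- build_spherical_head(
    optical_props = list(`750` = list(mua = 0.018, musp = 1.2),
                         `850` = list(mua = 0.018, musp = 1.2)),
    n_sources = 600
  )
  opt <- place_sensors(hm, "dot_regular")
  ext <- rbind(`750` = c(hbo = 1, hb = 1), `850` = c(hbo = 1, hb = 1))
  J <- compute_dot_jacobian(hm, opt, extinction = ext)
  b1 <- J$matrix[1:24, ]
  b2 <- J$matrix[25:48, ]
  expect_equal(b1, b2, ignore_attr = TRUE)
})

test_that("zero scattering is rejected", {
  expect_error(
    build_spherical_head(optical_props = list(
      `750` = list(mua = 0.018, musp = 0), `850` = list(mua = 0.019, musp = 1.1)
    )),
    "scattering"
  )
})
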